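test_that("identical genome specs generate identical output", {
  plants <- tibble::tibble(pathway_id = "histidine_degradation",
                           sub_id = "hut", mode = "intact")
  g1 <- generate_genome(genome_spec("sX", plants, seed = 123))
  g2 <- generate_genome(genome_spec("sX", plants, seed = 123))
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$hits, g2$hits)
  expect_identical(g1$truth, g2$truth)

  # written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_genome(g1, d1); p2 <- write_genome(g2, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), label = f)
  }
})

test_that("planting modes are validated against pathway categories", {
  ok <- function(pathway, sub, mode) {
    genome_spec("s", tibble::tibble(pathway_id = pathway, sub_id = sub,
                                    mode = mode))
  }
  # scrambled needs a multi-component category I/II sub-pathway
  expect_error(ok("indole_production", "tna", "scrambled"), "scrambled")
  # distal-split is category II only
  expect_error(ok("histidine_degradation", "hut", "distal-split"),
               "category II")
  # fused needs two distinct proximal slots
  expect_error(ok("indole_production", "tna", "fused"), "fused")
  expect_s3_class(ok("putrescine_production", "odc", "fused"),
                  "genome_plant_spec")
  # evidence mode only for evidence-only pathways, and vice versa
  expect_error(ok("indole_production", "tna", "evidence"), "evidence-only")
  expect_error(ok("cresol_production", "hpd", "intact"), "evidence-only")
  expect_s3_class(ok("cresol_production", "hpd", "evidence"),
                  "genome_plant_spec")
  expect_error(ok("histidine_degradation", "hut", "sideways"), "unknown")
})

test_that("mode semantics drive the truth table", {
  truth_of <- function(mode, pathway = "spermidine_production", sub = "spe") {
    g <- generate_genome(genome_spec(
      "s", tibble::tibble(pathway_id = pathway, sub_id = sub, mode = mode),
      seed = 5))
    g$truth$present[g$truth$pathway_id == pathway]
  }
  expect_true(truth_of("intact"))
  expect_true(truth_of("distal-split"))
  expect_false(truth_of("partial"))
  expect_false(truth_of("scrambled"))
  expect_true(truth_of("fused", "putrescine_production", "odc"))
  expect_false(truth_of("partial", "indole_production", "tna"))

  ev <- generate_genome(genome_spec(
    "s", tibble::tibble(pathway_id = "cresol_production", sub_id = "hpd",
                        mode = "evidence"), seed = 5))
  expect_true(ev$truth$present[ev$truth$pathway_id == "cresol_production"])
  expect_equal(nrow(ev$evidence), 1)
})

test_that("infeasible layouts error instead of silently truncating", {
  plants <- tibble::tibble(
    pathway_id = c("histidine_degradation", "thf_production"),
    sub_id = c("hut", "hut_thf"),
    mode = "intact")
  tiny <- genome_spec("s", plants, n_replicons = 1L, genes_per_replicon = 6L,
                      seed = 1)
  expect_error(generate_genome(tiny), "infeasible layout")
})

test_that("true hits pass the E-value gate and decoys stay off-catalog", {
  panel <- generate_panel(10, seed = 17)
  doms <- unique(domain_index(default_catalog())$domain_id)
  for (g in panel$genomes) {
    true_hits <- dplyr::filter(g$hits, domain_id %in% doms)
    if (nrow(true_hits) > 0) {
      expect_true(all(true_hits$evalue <= 1e-08))
    }
    decoys <- dplyr::filter(g$hits, !domain_id %in% doms)
    expect_true(all(startsWith(decoys$domain_id, "DECOY_")))
  }
})

test_that("cohort generation plants multiplicative effects deterministically", {
  spec <- cohort_spec(n_genera = 10, samples_per_cohort = 5, seed = 9)
  sim1 <- generate_cohort(spec)
  sim2 <- generate_cohort(spec)
  expect_identical(sim1$abundance, sim2$abundance)
  expect_equal(nrow(sim1$truth), 0)  # no planted effects
  expect_equal(nrow(sim1$design), 10)

  eff <- cohort_spec(n_genera = 10, samples_per_cohort = 50,
                     effects = tibble::tibble(genus = "Genus001",
                                              cohort = "carcinoma",
                                              effect = 10),
                     seed = 9)
  sim <- generate_cohort(eff)
  expect_equal(sim$truth$genus, "Genus001")
  means <- sim$abundance |>
    dplyr::filter(genus == "Genus001") |>
    dplyr::inner_join(sim$design, by = "sample_id") |>
    dplyr::group_by(cohort) |>
    dplyr::summarise(m = mean(count))
  expect_gt(means$m[means$cohort == "carcinoma"],
            3 * means$m[means$cohort == "healthy"])

  # a multiplicative effect of 1 is the null
  null_eff <- cohort_spec(n_genera = 5, samples_per_cohort = 5,
                          effects = tibble::tibble(genus = "Genus001",
                                                   cohort = "carcinoma",
                                                   effect = 1),
                          seed = 3)
  expect_equal(nrow(generate_cohort(null_eff)$truth), 0)

  expect_error(cohort_spec(effects = tibble::tibble(
    genus = "Genus001", cohort = "carcinoma", effect = -2)), "positive")
  expect_error(cohort_spec(effects = tibble::tibble(
    genus = "NoSuch", cohort = "carcinoma", effect = 2)), "undeclared genera")
  expect_error(cohort_spec(samples_per_cohort = 1), ">= 2 samples")
})

test_that("dropout zeroes observations at the requested rate", {
  spec <- cohort_spec(n_genera = 50, samples_per_cohort = 20, dropout = 0.3,
                      seed = 77)
  sim <- generate_cohort(spec)
  rate <- mean(sim$abundance$count == 0)
  expect_gt(rate, 0.25)
  expect_lt(rate, 0.35)
})
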