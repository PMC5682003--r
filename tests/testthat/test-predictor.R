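catalog <- default_catalog()

# plant domain hits for the named components at the given gene indices
plant_hits <- function(genes, pathway, sub, components, gene_idx) {
  comp <- dplyr::filter(catalog$components,
                        pathway_id == pathway, sub_id == sub,
                        component_id %in% components)
  doms <- vapply(components,
                 function(cid) comp$domain_ids[comp$component_id == cid],
                 character(1))
  make_hits(genes$protein_id[gene_idx], unname(doms))
}

strain_profile <- function(genes, hits, evidence = NULL, sid = "s1", ...) {
  prof <- predict_all(list(list(strain_id = sid, genes = genes, hits = hits)),
                      catalog = catalog, evidence = evidence, ...)
  stats::setNames(prof$present, prof$pathway_id)
}

test_that("category I requires the full sub-pathway in one cluster", {
  genes <- make_genes(30)
  intact <- plant_hits(genes, "histidine_degradation", "hut",
                       c("hutH", "hutU", "hutI", "hutG"), 5:8)
  p <- strain_profile(genes, intact)
  expect_true(p[["histidine_degradation"]])

  # the alternative enzyme for the last step also satisfies the slot
  alt <- plant_hits(genes, "histidine_degradation", "hut",
                    c("hutH", "hutU", "hutI", "ftcD"), 5:8)
  expect_true(strain_profile(genes, alt)[["histidine_degradation"]])

  # same components scattered beyond the gap: absent
  scattered <- plant_hits(genes, "histidine_degradation", "hut",
                          c("hutH", "hutU", "hutI", "hutG"),
                          c(1, 10, 20, 29))
  expect_false(strain_profile(genes, scattered)[["histidine_degradation"]])
})

test_that("category II needs the proximal core clustered plus distal homologs", {
  genes <- make_genes(40)
  # SpeD + SpeE operonic but no MetK anywhere: absent
  core_only <- plant_hits(genes, "spermidine_production", "spe",
                          c("speD", "speE"), 10:11)
  expect_false(strain_profile(genes, core_only)[["spermidine_production"]])

  # MetK far away on the same replicon: present
  with_metk <- dplyr::bind_rows(
    core_only,
    plant_hits(genes, "spermidine_production", "spe", "metK", 35))
  expect_true(strain_profile(genes, with_metk)[["spermidine_production"]])

  # core not clustered, MetK present: absent
  split_core <- dplyr::bind_rows(
    plant_hits(genes, "spermidine_production", "spe", "speD", 1),
    plant_hits(genes, "spermidine_production", "spe", "speE", 20),
    plant_hits(genes, "spermidine_production", "spe", "metK", 35))
  expect_false(strain_profile(genes, split_core)[["spermidine_production"]])
})

test_that("category III and evidence-only pathways need no clustering", {
  genes <- make_genes(10)
  # any one of the five H2S enzymes suffices
  h2s <- plant_hits(genes, "h2s_production", "cys",
                    "cystathionine_gamma_lyase", 4)
  expect_true(strain_profile(genes, h2s)[["h2s_production"]])

  # cresol from an evidence record despite zero domain hits
  ev <- tibble::tibble(strain_id = "s1", pathway_id = "cresol_production",
                       component_id = NA_character_, source = "curated")
  p <- strain_profile(genes, make_hits(character(0), character(0)),
                      evidence = ev)
  expect_true(p[["cresol_production"]])
  expect_false(any(p[setdiff(names(p), "cresol_production")]))
})

test_that("a fused arginase/decarboxylase gene satisfies the ODC route", {
  genes <- make_genes(10)
  fused <- make_hits(rep(genes$protein_id[5], 2), c("Arginase", "OKR_DC_1"))
  expect_true(strain_profile(genes, fused)[["putrescine_production"]])
})

test_that("an empty genome is all-absent and duplicate strains error", {
  empty <- list(strain_id = "s0", genes = make_genes(0),
                hits = make_hits(character(0), character(0)))
  prof <- predict_all(list(empty), catalog = catalog)
  expect_false(any(prof$present))
  expect_equal(nrow(prof), 10)

  expect_error(predict_all(list(empty, empty), catalog = catalog),
               "duplicate strain_id")
})

test_that("planted pathways are recovered exactly on a mixed-mode panel", {
  panel <- generate_panel(20, seed = 99)
  strains <- lapply(panel$genomes, function(g) {
    list(strain_id = g$strain_id, genes = g$genes, hits = g$hits)
  })
  prof <- suppressMessages(
    predict_all(strains, catalog = catalog, evidence = panel$evidence))
  cmp <- dplyr::inner_join(tidy(prof), panel$truth,
                           by = c("strain_id", "pathway_id"),
                           suffix = c("_pred", "_truth"))
  expect_equal(cmp$present_pred, cmp$present_truth)
})

test_that("decoy hits on non-catalog domains never change a profile", {
  panel <- generate_panel(5, seed = 7)
  g <- panel$genomes[[1]]
  base <- strain_profile(g$genes, g$hits, sid = g$strain_id)
  withr::with_seed(8, {
    extra <- make_hits(sample(g$genes$protein_id, 30, replace = TRUE),
                       sprintf("DECOY_EXTRA_%02d", 1:30),
                       evalue = 10^runif(30, -30, -2))
  })
  spiked <- strain_profile(g$genes, dplyr::bind_rows(g$hits, extra),
                           sid = g$strain_id)
  expect_identical(spiked, base)
})

test_that("adding a true-domain hit never flips a pathway to absent", {
  panel <- generate_panel(5, seed = 13)
  doms <- unique(domain_index(catalog)$domain_id)
  withr::with_seed(14, {
    for (g in panel$genomes[1:3]) {
      base <- strain_profile(g$genes, g$hits, sid = g$strain_id)
      extra <- make_hits(sample(g$genes$protein_id, 5),
                         sample(doms, 5, replace = TRUE))
      more <- strain_profile(g$genes, dplyr::bind_rows(g$hits, extra),
                             sid = g$strain_id)
      expect_true(all(more[base]), label = g$strain_id)
    }
  })
})
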