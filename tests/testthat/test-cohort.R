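long_table <- function(mat, samples, genera) {
  tibble::tibble(
    sample_id = rep(samples, times = length(genera)),
    genus = rep(genera, each = length(samples)),
    count = as.vector(mat))
}

test_that("relative-abundance normalization sums to one and is idempotent", {
  tab <- tibble::tibble(sample_id = c("a", "a", "b"),
                        genus = c("g1", "g2", "g1"),
                        count = c(2, 2, 7))
  rel <- normalize_relative(tab)
  expect_equal(rel$count, c(0.5, 0.5, 1))
  sums <- rel |> dplyr::group_by(sample_id) |> dplyr::summarise(s = sum(count))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_equal(normalize_relative(rel)$count, rel$count)

  zero <- tibble::tibble(sample_id = "z", genus = "g1", count = 0)
  expect_error(normalize_relative(zero), "z")
})

test_that("identical cohorts yield no differential genera under either test", {
  samples2 <- c(paste0("h", 1:4), paste0("c", 1:4))
  design2 <- tibble::tibble(sample_id = samples2,
                            cohort = rep(c("healthy", "carcinoma"), each = 4))
  vals <- c(1, 2, 3, 4, 1, 2, 3, 4)  # same values in both cohorts
  tab <- tibble::tibble(sample_id = samples2, genus = "g1", count = vals)
  diff <- differential_genera(tab, design2, p_threshold = 0.05)
  expect_equal(nrow(diff), 0)
  expect_equal(tidy(diff)$p_value, 1)
  expect_equal(glance(diff)$test, "welch")

  samples3 <- paste0("s", 1:9)
  design3 <- tibble::tibble(sample_id = samples3,
                            cohort = rep(c("healthy", "adenoma", "carcinoma"),
                                         each = 3))
  tab3 <- tibble::tibble(sample_id = samples3, genus = "g1",
                         count = rep(c(1, 2, 3), 3))
  diff3 <- differential_genera(tab3, design3)
  expect_equal(nrow(diff3), 0)
  expect_equal(glance(diff3)$test, "kruskal-wallis")
})

test_that("design validation rejects tiny or degenerate cohorts", {
  tab <- tibble::tibble(sample_id = c("a", "b", "c"), genus = "g",
                        count = c(1, 2, 3))
  expect_error(
    differential_genera(tab, tibble::tibble(sample_id = c("a", "b", "c"),
                                            cohort = c("h", "h", "c"))),
    "fewer than 2")
  expect_error(
    differential_genera(tab, tibble::tibble(sample_id = c("a", "b", "c"),
                                            cohort = "h")),
    "at least 2 cohorts")
})

test_that("a five-pooled-SD planted shift is detected in the shifted cohort", {
  withr::with_seed(51, {
    n <- 20
    design <- tibble::tibble(
      sample_id = c(sprintf("h%02d", 1:n), sprintf("c%02d", 1:n)),
      cohort = rep(c("healthy", "carcinoma"), each = n))
    base <- matrix(rnorm(2 * n * 10, mean = 10, sd = 1), nrow = 2 * n)
    base[design$cohort == "carcinoma", 1] <- rnorm(n, mean = 15, sd = 1)
    base <- abs(base)
    tab <- long_table(base, design$sample_id, sprintf("g%02d", 1:10))
    diff <- differential_genera(normalize_relative(tab), design)
    expect_true("g01" %in% diff$genus)
    expect_equal(diff$enriched_cohort[diff$genus == "g01"], "carcinoma")
  })
})

test_that("Welch p-values match the Welch-Satterthwaite formula", {
  withr::with_seed(61, {
    for (i in 1:50) {
      nx <- sample(3:12, 1); ny <- sample(3:12, 1)
      x <- rlnorm(nx, 0, 1); y <- rlnorm(ny, 0, sample(c(0.5, 1, 2), 1))
      samples <- c(sprintf("x%02d", 1:nx), sprintf("y%02d", 1:ny))
      design <- tibble::tibble(sample_id = samples,
                               cohort = rep(c("a", "b"), c(nx, ny)))
      tab <- tibble::tibble(sample_id = samples, genus = "g",
                            count = c(x, y))
      got <- tidy(differential_genera(tab, design, p_threshold = 1))$p_value
      expect_equal(got, oracle_welch_p(x, y), tolerance = 1e-9)
    }
  })
})

occurrence_fixture <- function() {
  # 19 carcinoma differential genera, 11 of which carry the putrescine
  # pathway; 15 healthy differential genera, none carrying it
  genera_c <- sprintf("C%02d", 1:19)
  genera_h <- sprintf("H%02d", 1:15)
  diff <- tibble::tibble(
    genus = c(genera_c, genera_h),
    p_value = 0.01, test = "welch",
    enriched_cohort = rep(c("carcinoma", "healthy"), c(19, 15)))
  scores <- tidyr::crossing(
    taxon = c(genera_c, genera_h),
    pathway_id = c("putrescine_production", "indole_production")) |>
    dplyr::mutate(
      S = 0, alpha = 1L,
      pfacs = ifelse(taxon %in% genera_c[1:11] &
                       pathway_id == "putrescine_production", 2.5, 0))
  list(diff = diff, scores = scores)
}

test_that("pathway occurrence reports 11 of 19 as 58% and keeps exact fractions", {
  fx <- occurrence_fixture()
  s <- pathway_occurrence_summary(fx$diff, fx$scores)
  row <- dplyr::filter(s$occurrence, cohort == "carcinoma",
                       pathway_id == "putrescine_production")
  expect_equal(row$n_genera, 19)
  expect_equal(row$n_with_pathway, 11)
  expect_equal(row$pct, 58L)
  expect_equal(row$pct_exact, 100 * 11 / 19)

  # all and none
  all19 <- dplyr::mutate(fx$scores,
                         pfacs = ifelse(pathway_id == "putrescine_production" &
                                          taxon %in% sprintf("C%02d", 1:19),
                                        1, pfacs))
  s2 <- pathway_occurrence_summary(fx$diff, all19)
  expect_equal(dplyr::filter(s2$occurrence, cohort == "carcinoma",
                             pathway_id == "putrescine_production")$pct, 100L)
  expect_equal(dplyr::filter(s$occurrence, cohort == "healthy",
                             pathway_id == "putrescine_production")$pct, 0L)
})

test_that("occurrence depends only on genus sets and Pfacs flags", {
  fx <- occurrence_fixture()
  base <- pathway_occurrence_summary(fx$diff, fx$scores)$occurrence
  # duplicating the differential list (as if samples were doubled) changes
  # nothing
  dup <- pathway_occurrence_summary(dplyr::bind_rows(fx$diff, fx$diff),
                                    fx$scores)$occurrence
  expect_equal(dup, base)
})

test_that("oxygen breakdown computes per-category putrefier fractions", {
  diff <- tibble::tibble(
    genus = sprintf("G%d", 1:6), p_value = 0.01, test = "welch",
    enriched_cohort = "carcinoma")
  oxy <- tibble::tibble(
    genus = sprintf("G%d", 1:5),
    oxygen_class = c(rep("obligate anaerobe", 4), "aerobe"))
  flags <- tibble::tibble(genus = sprintf("G%d", 1:6),
                          putrefier = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  br <- oxygen_breakdown(diff, oxy, flags)
  ob <- dplyr::filter(br, oxygen_class == "obligate anaerobe")
  expect_equal(ob$n_genera, 4)
  expect_equal(ob$fraction_putrefiers, 0.5)
  expect_equal(dplyr::filter(br, oxygen_class == "aerobe")$fraction_putrefiers, 1)
  # the genus without oxygen data lands in 'unknown'
  expect_equal(dplyr::filter(br, oxygen_class == "unknown")$n_genera, 1)
  # no empty-category rows
  expect_false("microaerophile" %in% br$oxygen_class)
})

test_that("round_half_away rounds .5 away from zero", {
  expect_equal(round_half_away(c(57.5, 58.4, 26.5, -0.5, 0.4)),
               c(58, 58, 27, -1, 0))
})
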