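#' Normalize genus counts to per-sample relative abundances
#'
#' Divides each sample's genus counts by the sample total so every sample
#' sums to one. Idempotent: normalizing an already-normalized table changes
#' nothing.
#'
#' @param table Long abundance tibble with columns `sample_id`, `genus`,
#'   `count` (non-negative).
#' @return The table with `count` replaced by relative abundances.
#' @export
normalize_relative <- function(table) {
  if (any(table$count < 0)) abort("abundance counts must be non-negative")
  totals <- table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0)
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(zero, collapse = ", ")))
  table |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(count = .data$count / .data$total) |>
    dplyr::select(-"total")
}

#' Read a samples-by-genera abundance TSV into long form
#'
#' @param path TSV with a `sample_id` column and one column per genus.
#' @return Long tibble `sample_id`, `genus`, `count`.
#' @export
read_abundance <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(wide))
    abort("abundance table must have a 'sample_id' column")
  tidyr::pivot_longer(wide, -"sample_id", names_to = "genus",
                      values_to = "count")
}

#' Differentially abundant genera between cohorts
#'
#' Tests each genus's relative abundance between cohorts: Welch's unequal-
#' variance t-test (two-sided) for two cohorts, the Kruskal–Wallis rank test
#' for three. P-values are unadjusted, mirroring the raw `p <= 0.05`
#' selection the score is built around; set `adjust = "BH"` for an optional
#' Benjamini–Hochberg correction. A genus with zero variance and equal
#' means everywhere is untestable and excluded (p treated as 1). The
#' enriched cohort is the one with the highest mean relative abundance.
#'
#' @param table Normalized long abundance tibble ([normalize_relative()]).
#' @param design Tibble mapping `sample_id` to `cohort` (2 or 3 distinct
#'   cohorts; at least 2 samples each).
#' @param p_threshold Significance cutoff (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `putref_diff` tibble of significant genera: `genus`,
#'   `p_value`, `test`, `enriched_cohort`. The full per-genus test table is
#'   attached as attribute `all_tests` and returned by [tidy()].
#' @export
differential_genera <- function(table, design, p_threshold = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cohorts <- sort(unique(design$cohort))
  if (length(cohorts) < 2)
    abort("design must contain at least 2 cohorts")
  if (length(cohorts) > 3)
    abort("design must contain 2 or 3 cohorts")
  sizes <- design |> dplyr::count(.data$cohort)
  small <- sizes |> dplyr::filter(.data$n < 2)
  if (nrow(small) > 0)
    abort(paste0("cohort(s) with fewer than 2 samples: ",
                 paste(small$cohort, collapse = ", ")))
  test_name <- if (length(cohorts) == 2) "welch" else "kruskal-wallis"

  dat <- table |> dplyr::inner_join(design, by = "sample_id")
  tests <- dat |>
    dplyr::group_by(.data$genus) |>
    dplyr::group_map(function(g, key) {
      groups <- split(g$count, g$cohort)
      p <- genus_p_value(groups, test_name)
      means <- vapply(groups, mean, numeric(1))
      tibble::tibble(genus = key$genus, p_value = p, test = test_name,
                     enriched_cohort = names(means)[which.max(means)])
    }) |>
    dplyr::bind_rows()
  if (adjust == "BH") tests$p_value <- stats::p.adjust(tests$p_value, "BH")

  sig <- tests |>
    dplyr::filter(.data$p_value <= p_threshold) |>
    dplyr::arrange(.data$p_value, .data$genus)
  structure(sig, class = c("putref_diff", class(sig)),
            all_tests = tests, p_threshold = p_threshold)
}

genus_p_value <- function(groups, test_name) {
  # untestable: no variation anywhere and equal means -> p = 1
  if (all(vapply(groups, function(x) stats::var(x) == 0, logical(1))) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1) {
    return(1)
  }
  if (test_name == "welch") {
    # constant-within-group but unequal means: t.test errors; treat as
    # maximally significant separation is not defensible -> p from test
    tryCatch(t.test(groups[[1]], groups[[2]])$p.value,
             error = function(e) 1)
  } else {
    kruskal.test(groups)$p.value
  }
}

#' @exportS3Method generics::tidy
tidy.putref_diff <- function(x, ...) {
  tibble::as_tibble(attr(x, "all_tests"))
}

#' @exportS3Method generics::glance
glance.putref_diff <- function(x, ...) {
  all <- attr(x, "all_tests")
  tibble::tibble(
    n_genera = nrow(all),
    n_significant = nrow(x),
    test = if (nrow(all) > 0) all$test[1] else NA_character_,
    p_threshold = attr(x, "p_threshold")
  )
}

#' Pathway occurrence among differential genera
#'
#' For every cohort and pathway, the percentage of that cohort's
#' differentially abundant genera whose Pfacs for the pathway is positive.
#' A genus is a *putrefier* when it has `pfacs > 0` for at least one
#' pathway; genera absent from the score matrix count as non-putrefiers
#' (reported via a message). Percentages are reported both exactly and as
#' round-half-away-from-zero integers. Cohorts with zero differential
#' genera yield no rows rather than zero percentages.
#'
#' @param diff A `putref_diff` tibble ([differential_genera()]).
#' @param scores A `pfacs_scores` tibble at genus level ([score_matrix()]).
#' @return A list of class `putref_cohort_summary` with elements
#'   `occurrence` (cohort, pathway_id, n_genera, n_with_pathway, pct_exact,
#'   pct) and `putrefiers` (genus, enriched_cohort, putrefier, n_pathways).
#' @export
pathway_occurrence_summary <- function(diff, scores) {
  if (nrow(diff) == 0)
    abort("no differential genera to summarise")
  missing <- setdiff(diff$genus, unique(scores$taxon))
  if (length(missing) > 0)
    inform(paste0(length(missing),
                  " differential genus/genera absent from the Pfacs matrix ",
                  "counted as non-putrefiers: ",
                  paste(missing, collapse = ", ")))

  flags <- diff |>
    dplyr::left_join(scores |>
                       dplyr::group_by(.data$taxon) |>
                       dplyr::summarise(n_pathways = sum(.data$pfacs > 0)),
                     by = c(genus = "taxon")) |>
    dplyr::mutate(n_pathways = dplyr::coalesce(.data$n_pathways, 0L),
                  putrefier = .data$n_pathways > 0) |>
    dplyr::select("genus", "enriched_cohort", "putrefier", "n_pathways")

  pathway_ids <- unique(scores$pathway_id)
  carrier <- scores |>
    dplyr::filter(.data$pfacs > 0) |>
    dplyr::distinct(.data$taxon, .data$pathway_id)

  occurrence <- diff |>
    dplyr::select("genus", cohort = "enriched_cohort") |>
    tidyr::crossing(pathway_id = pathway_ids) |>
    dplyr::left_join(carrier |> dplyr::mutate(has = TRUE),
                     by = c(genus = "taxon", "pathway_id")) |>
    dplyr::group_by(.data$cohort, .data$pathway_id) |>
    dplyr::summarise(
      n_genera = dplyr::n_distinct(.data$genus),
      n_with_pathway = sum(!is.na(.data$has)),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_exact = 100 * .data$n_with_pathway / .data$n_genera,
                  pct = as.integer(round_half_away(.data$pct_exact)))

  structure(list(occurrence = occurrence, putrefiers = flags),
            class = "putref_cohort_summary")
}

#' @export
print.putref_cohort_summary <- function(x, ...) {
  cat("<putref_cohort_summary>\n")
  cat("Putrefiers among differential genera:",
      sum(x$putrefiers$putrefier), "of", nrow(x$putrefiers), "\n")
  print(x$occurrence, n = 30)
  invisible(x)
}

#' Oxygen-requirement breakdown of differential genera
#'
#' For each cohort and oxygen category, the fraction of that cohort's
#' differentially abundant genera that are putrefiers. Genera without
#' oxygen data are grouped under `unknown`. Categories with no genera in a
#' cohort produce no row.
#'
#' @param diff A `putref_diff` tibble.
#' @param genus_oxygen Tibble `genus`, `oxygen_class` ([genus_oxygen()]).
#' @param putrefiers Tibble `genus`, `putrefier` (e.g. the `putrefiers`
#'   element of [pathway_occurrence_summary()]).
#' @return Tibble `cohort`, `oxygen_class`, `n_genera`, `n_putrefiers`,
#'   `fraction_putrefiers`.
#' @export
oxygen_breakdown <- function(diff, genus_oxygen, putrefiers) {
  diff |>
    dplyr::select("genus", cohort = "enriched_cohort") |>
    dplyr::left_join(genus_oxygen, by = "genus") |>
    dplyr::mutate(oxygen_class = dplyr::coalesce(.data$oxygen_class,
                                                 "unknown")) |>
    dplyr::left_join(putrefiers |> dplyr::select("genus", "putrefier"),
                     by = "genus") |>
    dplyr::mutate(putrefier = dplyr::coalesce(.data$putrefier, FALSE)) |>
    dplyr::group_by(.data$cohort, .data$oxygen_class) |>
    dplyr::summarise(
      n_genera = dplyr::n(),
      n_putrefiers = sum(.data$putrefier),
      fraction_putrefiers = mean(.data$putrefier),
      .groups = "drop"
    )
}
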