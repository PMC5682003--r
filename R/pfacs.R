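#' Confidence ranks from sequenced-strain counts
#'
#' Assigns each taxon a percentile for its sequenced-strain count —
#' `100 * (#taxa with strictly smaller count) / (#taxa)` — and maps
#' percentiles to integer confidence ranks alpha in 1..5 by quintile:
#' `alpha = min(5, floor(percentile / 20) + 1)`. Taxa tied on strain count
#' receive identical percentiles and alphas. The rank gives higher weight
#' to groups with more sequenced representatives.
#'
#' @param groups Tibble with columns `taxon` and `strain_count`
#'   (positive integers).
#' @return `groups` with `percentile` and `alpha` columns added.
#' @examples
#' confidence_ranks(tibble::tibble(taxon = letters[1:5],
#'                                 strain_count = c(1, 2, 3, 4, 100)))
#' @export
confidence_ranks <- function(groups) {
  if (nrow(groups) == 0) abort("`groups` must contain at least one taxon")
  if (any(groups$strain_count < 1)) abort("strain_count must be >= 1")
  n <- nrow(groups)
  cnt <- groups$strain_count
  pct <- vapply(cnt, function(x) 100 * sum(cnt < x) / n, numeric(1))
  groups |>
    dplyr::mutate(percentile = pct,
                  alpha = pmin(5L, as.integer(floor(pct / 20)) + 1L))
}

#' The putrefaction score Pfacs
#'
#' `Pfacs = S * alpha`, where `S` is the proportion of a taxon's strains
#' predicted to carry a pathway and `alpha` is the taxon's 1-5 confidence
#' rank ([confidence_ranks()]). Scores range from 0 to 5; a taxon with half
#' its strains carrying a pathway at the top confidence rank scores 2.5.
#'
#' @param S Numeric vector of proportions in `[0, 1]`.
#' @param alpha Integer vector of confidence ranks in `1..5`.
#' @return Numeric vector `S * alpha`.
#' @examples
#' compute_pfacs(0.5, 5)  # 2.5
#' @export
compute_pfacs <- function(S, alpha) {
  if (any(is.na(S)) || any(S < 0 | S > 1))
    abort("`S` must be a proportion in [0, 1]")
  if (any(is.na(alpha)) || any(alpha != as.integer(alpha)) ||
      any(alpha < 1 | alpha > 5))
    abort("`alpha` must be an integer confidence rank in 1..5")
  S * alpha
}

#' Taxon-level Pfacs score matrix
#'
#' Aggregates per-strain pathway profiles to a chosen taxonomic level:
#' for every (taxon, pathway), `S` is the proportion of the taxon's strains
#' with the pathway, `alpha` the taxon's confidence rank over the full
#' strain panel, and `pfacs = S * alpha`. Strains missing a taxon at the
#' requested level are excluded with a message.
#'
#' @param profiles A `putref_profiles` tibble from [predict_all()].
#' @param taxonomy Strain metadata tibble with `strain_id` and the level
#'   column (`genus` or `phylum`); see [read_strain_tables()].
#' @param level `"genus"` (default) or `"phylum"`.
#' @return A `pfacs_scores` tibble: `taxon`, `pathway_id`, `n_strains`,
#'   `S`, `alpha`, `pfacs`, ordered by (taxon, pathway).
#' @export
score_matrix <- function(profiles, taxonomy, level = c("genus", "phylum")) {
  level <- match.arg(level)
  if (!level %in% names(taxonomy))
    abort(paste0("taxonomy table has no '", level, "' column"))

  tax <- taxonomy |>
    dplyr::transmute(.data$strain_id, taxon = .data[[level]])
  prof <- tibble::as_tibble(profiles)[, c("strain_id", "pathway_id", "present")]
  joined <- prof |> dplyr::left_join(tax, by = "strain_id")
  dropped <- joined |>
    dplyr::filter(is.na(.data$taxon)) |>
    dplyr::distinct(.data$strain_id)
  if (nrow(dropped) > 0)
    inform(paste0("excluded ", nrow(dropped), " strain(s) lacking a ", level,
                  " assignment"))
  joined <- joined |> dplyr::filter(!is.na(.data$taxon))
  if (nrow(joined) == 0) abort("no strains with taxonomy at the requested level")

  panel <- joined |>
    dplyr::distinct(.data$strain_id, .data$taxon) |>
    dplyr::count(.data$taxon, name = "strain_count")
  ranks <- confidence_ranks(panel)

  scores <- joined |>
    dplyr::group_by(.data$taxon, .data$pathway_id) |>
    dplyr::summarise(n_strains = dplyr::n_distinct(.data$strain_id),
                     S = mean(.data$present), .groups = "drop") |>
    dplyr::left_join(ranks |> dplyr::select("taxon", "alpha"), by = "taxon") |>
    dplyr::mutate(pfacs = compute_pfacs(.data$S, .data$alpha)) |>
    dplyr::arrange(.data$taxon, .data$pathway_id)
  structure(scores, class = c("pfacs_scores", class(scores)))
}

#' Widen Pfacs scores to a taxa-by-pathway matrix
#'
#' @param scores A `pfacs_scores` tibble from [score_matrix()].
#' @return A tibble with one row per taxon and one numeric column per
#'   pathway, suitable for heatmap rendering or TSV export.
#' @export
pfacs_matrix <- function(scores) {
  scores |>
    dplyr::select("taxon", "pathway_id", "pfacs") |>
    tidyr::pivot_wider(names_from = "pathway_id", values_from = "pfacs") |>
    dplyr::arrange(.data$taxon)
}

#' @exportS3Method generics::tidy
tidy.pfacs_scores <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.pfacs_scores <- function(x, ...) {
  tibble::tibble(
    n_taxa = dplyr::n_distinct(x$taxon),
    n_pathways = dplyr::n_distinct(x$pathway_id),
    max_pfacs = max(x$pfacs),
    n_putrefier_taxa = x |>
      dplyr::group_by(.data$taxon) |>
      dplyr::summarise(p = any(.data$pfacs > 0)) |>
      dplyr::pull(.data$p) |>
      sum()
  )
}
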