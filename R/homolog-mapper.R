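#' Filter domain hits at an E-value threshold
#'
#' Retains hits with `evalue <= threshold` (inclusive boundary, the common
#' convention of homology-search tools), preserving input order. The
#' default threshold of 1e-06 is the one used throughout the pipeline.
#'
#' @param hits Tibble of domain hits ([read_domain_hits()]).
#' @param threshold Positive E-value cutoff; default `1e-06`.
#' @return The retained rows of `hits` (a subset, same columns).
#' @examples
#' hits <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
#'                        domain_id = "D", evalue = c(1e-07, 1e-05, 1e-06),
#'                        bitscore = 50)
#' filter_hits(hits)  # keeps p1 and p3
#' @export
filter_hits <- function(hits, threshold = 1e-06) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    abort("`threshold` must be a single positive number")
  dplyr::filter(hits, .data$evalue <= threshold)
}

#' Map filtered domain hits to catalog components
#'
#' Joins hits to the catalog's domain index and to the gene table, yielding
#' one component candidate per (gene, pathway, sub-pathway, component) with
#' the minimal E-value among that protein's hits for the component's
#' domains. A protein matching the domains of two or more distinct
#' components of one sub-pathway — e.g. a single gene carrying both the
#' `Arginase` and `OKR_DC_1` domains of the ornithine decarboxylase route —
#' produces one candidate per component, each flagged `fused = TRUE`.
#'
#' Hits on proteins absent from the gene table are dropped with a message;
#' hits on domains outside the catalog map to nothing.
#'
#' @param catalog A `putref_catalog`.
#' @param hits Filtered domain-hit tibble (see [filter_hits()]).
#' @param genes Gene tibble ([read_gene_coordinates()]).
#' @param strain_id Strain identifier stamped onto the candidates.
#' @return A tibble of component candidates: `strain_id`, `pathway_id`,
#'   `sub_id`, `component_id`, `gene_id`, `protein_id`, `replicon_id`,
#'   `rank`, `start`, `end`, `strand`, `best_evalue`, `fused`.
#' @export
map_components <- function(catalog, hits, genes, strain_id = "strain") {
  idx <- domain_index(catalog)
  mapped <- dplyr::inner_join(hits, idx, by = "domain_id",
                              relationship = "many-to-many")
  if (nrow(mapped) == 0) {
    return(tibble::tibble(
      strain_id = character(0), pathway_id = character(0),
      sub_id = character(0), component_id = character(0),
      gene_id = character(0), protein_id = character(0),
      replicon_id = character(0), rank = integer(0), start = integer(0),
      end = integer(0), strand = character(0), best_evalue = double(0),
      fused = logical(0)))
  }

  unresolved <- setdiff(unique(mapped$protein_id), genes$protein_id)
  if (length(unresolved) > 0)
    inform(paste0("dropped hits on ", length(unresolved),
                  " protein(s) absent from the gene table for strain ",
                  strain_id))

  cand <- mapped |>
    dplyr::inner_join(genes, by = "protein_id") |>
    dplyr::group_by(.data$pathway_id, .data$sub_id, .data$component_id,
                    .data$protein_id) |>
    dplyr::summarise(
      gene_id = .data$gene_id[1], replicon_id = .data$replicon_id[1],
      rank = .data$rank[1], start = .data$start[1], end = .data$end[1],
      strand = .data$strand[1],
      best_evalue = min(.data$evalue),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$pathway_id, .data$sub_id, .data$protein_id) |>
    dplyr::mutate(fused = dplyr::n_distinct(.data$component_id) >= 2) |>
    dplyr::ungroup() |>
    dplyr::mutate(strain_id = strain_id) |>
    dplyr::select("strain_id", "pathway_id", "sub_id", "component_id",
                  "gene_id", "protein_id", "replicon_id", "rank", "start",
                  "end", "strand", "best_evalue", "fused") |>
    dplyr::arrange(.data$pathway_id, .data$sub_id, .data$replicon_id,
                   .data$rank, .data$component_id)
  cand
}
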