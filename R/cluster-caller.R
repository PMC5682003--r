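#' Group component candidates into gene clusters by genomic proximity
#'
#' Single-linkage grouping on gene rank, per replicon (and per strain,
#' pathway, sub-pathway when several are present): two candidates join one
#' cluster iff they lie on the same replicon and their ranks are connected
#' by a chain of steps of at most `max_gap + 1` ranks, i.e. at most
#' `max_gap` intervening genes between consecutive members. Clusters are
#' maximal and returned in deterministic order (replicon, then minimum
#' rank).
#'
#' Proximity is measured in gene ranks rather than base pairs because rank
#' gaps are robust to annotation density; a base-pair mode (largest allowed
#' inter-gene distance in bp) is available via `bp_mode`.
#'
#' @param candidates Candidate tibble from [map_components()].
#' @param max_gap Non-negative integer: maximum number of intervening genes
#'   between consecutive cluster members (default 2).
#' @param bp_mode If `TRUE`, chain on inter-gene base-pair distance instead
#'   of ranks, using `max_bp`.
#' @param max_bp Largest allowed gap in bp between consecutive members when
#'   `bp_mode = TRUE` (default 5000).
#' @param same_strand If `TRUE`, candidates on different strands are never
#'   chained (off by default; operonic layout is not assumed).
#' @return A tibble with one row per cluster: `cluster_id`, `strain_id`,
#'   `pathway_id`, `sub_id`, `replicon_id`, `min_rank`, `max_rank`,
#'   `n_members`, and a `members` list-column holding the member candidate
#'   rows.
#' @export
call_clusters <- function(candidates, max_gap = 2L, bp_mode = FALSE,
                          max_bp = 5000L, same_strand = FALSE) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || max_gap < 0)
    abort("`max_gap` must be a single non-negative integer")
  empty <- tibble::tibble(
    cluster_id = character(0), strain_id = character(0),
    pathway_id = character(0), sub_id = character(0),
    replicon_id = character(0), min_rank = integer(0), max_rank = integer(0),
    n_members = integer(0), members = list()
  )
  if (nrow(candidates) == 0) return(empty)

  grouped <- candidates |>
    dplyr::group_by(.data$strain_id, .data$pathway_id, .data$sub_id,
                    .data$replicon_id)
  keys <- dplyr::group_keys(grouped)
  parts <- dplyr::group_split(grouped)

  out <- purrr::map2_dfr(parts, seq_along(parts), function(part, gi) {
    key <- if (same_strand) {
      part |> dplyr::arrange(.data$strand, .data$rank, .data$component_id)
    } else {
      part |> dplyr::arrange(.data$rank, .data$component_id)
    }
    # chain split: new cluster when the step to the previous member exceeds
    # the allowed gap
    if (same_strand) {
      new_strand <- c(TRUE, key$strand[-1] != key$strand[-nrow(key)])
    } else {
      new_strand <- rep(FALSE, nrow(key))
      new_strand[1] <- TRUE
    }
    if (bp_mode) {
      gap <- c(0L, pmax(0L, key$start[-1] - key$end[-nrow(key)] - 1L))
      brk <- new_strand | gap > max_bp
    } else {
      step <- c(0L, diff(key$rank))
      brk <- new_strand | step > max_gap + 1
    }
    cid <- cumsum(brk)
    key |>
      dplyr::mutate(.cid = cid) |>
      dplyr::group_by(.data$.cid) |>
      dplyr::group_map(function(m, k) {
        tibble::tibble(
          strain_id = m$strain_id[1], pathway_id = m$pathway_id[1],
          sub_id = m$sub_id[1], replicon_id = m$replicon_id[1],
          min_rank = min(m$rank), max_rank = max(m$rank),
          n_members = nrow(m),
          members = list(dplyr::select(m, -dplyr::any_of(".cid")))
        )
      }) |>
      dplyr::bind_rows()
  })

  out |>
    dplyr::arrange(.data$strain_id, .data$pathway_id, .data$sub_id,
                   .data$replicon_id, .data$min_rank) |>
    dplyr::mutate(cluster_id = sprintf("clu%04d", dplyr::row_number()),
                  .before = 1)
}

#' Does a cluster satisfy a proximity requirement?
#'
#' A cluster satisfies a proximity set when every required component slot
#' has at least one member candidate in the cluster. Slots may be given as
#' a character vector of component ids (each its own slot) or a list of
#' character vectors (components within one element are interchangeable
#' alternatives). Fused candidates count for every component they
#' represent. An empty proximity set is vacuously satisfied.
#'
#' @param cluster One row of the [call_clusters()] output (or its `members`
#'   tibble directly).
#' @param proximity_set Character vector or list of character vectors of
#'   component ids.
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_proximity <- function(cluster, proximity_set) {
  members <- if (is.data.frame(cluster)) {
    if ("members" %in% names(cluster)) {
      dplyr::bind_rows(cluster$members)
    } else {
      cluster
    }
  } else {
    abort("`cluster` must be a cluster row or members tibble")
  }
  slots <- if (is.list(proximity_set)) proximity_set else as.list(proximity_set)
  if (length(slots) == 0) return(TRUE)
  have <- unique(members$component_id)
  all(vapply(slots, function(s) any(s %in% have), logical(1)))
}
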