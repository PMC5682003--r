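#' Predict one pathway's presence in one strain
#'
#' Applies the category rules to a strain's component candidates and
#' clusters:
#' * **category I** sub-pathway: present iff some cluster covers every
#'   component slot of the sub-pathway;
#' * **category II**: present iff some cluster covers the proximal core
#'   slots and every distal slot has at least one candidate anywhere in the
#'   genome (any replicon, including the cluster's own);
#' * **category III**: present iff at least one standalone slot (any member
#'   of an alternative enzyme group) has a candidate anywhere;
#' * **evidence-only** pathways: present iff a matching evidence record
#'   exists for the strain.
#'
#' A pathway is present when any of its sub-pathways is satisfied.
#'
#' @param catalog A `putref_catalog`.
#' @param pathway_id Pathway id from the catalog.
#' @param candidates Candidate tibble for one strain ([map_components()]).
#' @param clusters Cluster tibble for the same strain ([call_clusters()]).
#' @param evidence Optional tibble of evidence records with columns
#'   `strain_id`, `pathway_id` (and optionally `component_id`, `source`).
#' @param strain_id Strain the prediction is for (used to match evidence).
#' @return A list with `present` (logical) and `evidence` (tibble of
#'   satisfied sub-pathways with the supporting cluster/gene/evidence ids;
#'   zero rows when absent).
#' @export
predict_pathway <- function(catalog, pathway_id, candidates, clusters,
                            evidence = NULL, strain_id = "strain") {
  pw <- catalog$pathways[catalog$pathways$pathway_id == pathway_id, ]
  if (nrow(pw) == 0) abort(paste0("unknown pathway_id: ", pathway_id))

  no_evidence <- tibble::tibble(sub_id = character(0), via = character(0),
                                detail = character(0))

  if (pw$evidence_only) {
    hit <- !is.null(evidence) && nrow(evidence) > 0 &&
      any(evidence$strain_id == strain_id & evidence$pathway_id == pathway_id)
    ev <- if (hit) {
      tibble::tibble(sub_id = NA_character_, via = "evidence_list",
                     detail = paste0("evidence record for ", strain_id))
    } else {
      no_evidence
    }
    return(list(present = hit, evidence = ev))
  }

  subs <- catalog$components |>
    dplyr::filter(.data$pathway_id == .env$pathway_id) |>
    dplyr::distinct(.data$sub_id, .data$category)

  cand <- candidates |>
    dplyr::filter(.data$pathway_id == .env$pathway_id)
  clus <- clusters |>
    dplyr::filter(.data$pathway_id == .env$pathway_id)

  ev_rows <- list()
  for (i in seq_len(nrow(subs))) {
    sid <- subs$sub_id[i]
    category <- subs$category[i]
    slots <- sub_slots(catalog, pathway_id, sid) |>
      dplyr::filter(!.data$evidence_only)
    sub_cand <- cand |> dplyr::filter(.data$sub_id == sid)
    if (nrow(slots) == 0) next

    if (category == "III") {
      # any standalone slot anywhere in the genome
      got <- sub_cand |>
        dplyr::semi_join(slots, by = "component_id")
      if (nrow(got) > 0) {
        ev_rows[[length(ev_rows) + 1]] <- tibble::tibble(
          sub_id = sid, via = "standalone",
          detail = paste(unique(got$gene_id), collapse = ";"))
      }
      next
    }

    prox_slots <- slots |> dplyr::filter(.data$in_proximity)
    distal_slots <- slots |> dplyr::filter(!.data$in_proximity)
    prox_sets <- split(prox_slots$component_id, prox_slots$slot_id)
    # category I: all slots are proximal by catalog invariant
    sub_clus <- clus |> dplyr::filter(.data$sub_id == sid)
    ok_cluster <- NULL
    for (j in seq_len(nrow(sub_clus))) {
      if (satisfies_proximity(sub_clus[j, ], prox_sets)) {
        ok_cluster <- sub_clus[j, ]
        break
      }
    }
    if (is.null(ok_cluster)) next
    if (category == "II" && nrow(distal_slots) > 0) {
      distal_sets <- split(distal_slots$component_id, distal_slots$slot_id)
      covered <- vapply(distal_sets,
                        function(s) any(s %in% sub_cand$component_id),
                        logical(1))
      if (!all(covered)) next
    }
    ev_rows[[length(ev_rows) + 1]] <- tibble::tibble(
      sub_id = sid,
      via = if (category == "I") "cluster" else "cluster+distal",
      detail = ok_cluster$cluster_id)
  }

  ev <- if (length(ev_rows) > 0) dplyr::bind_rows(ev_rows) else no_evidence
  list(present = nrow(ev) > 0, evidence = ev)
}

#' Predict all catalog pathways for a panel of strains
#'
#' Runs E-value filtering, component mapping, cluster calling, and the
#' category rules for every strain, returning one profile row per
#' (strain, pathway). A strain with no genes (or no retained hits) gets an
#' all-absent profile apart from evidence-list overrides.
#'
#' @param strains A list of per-strain inputs, each a list with elements
#'   `strain_id`, `genes` (gene tibble) and `hits` (raw domain-hit tibble);
#'   see [read_gene_coordinates()] and [read_domain_hits()].
#' @param catalog A `putref_catalog` (default [default_catalog()]).
#' @param evidence Optional evidence-record tibble (`strain_id`,
#'   `pathway_id`, ...).
#' @param evalue_threshold E-value cutoff for [filter_hits()].
#' @param max_gap Proximity gap for [call_clusters()].
#' @return A `putref_profiles` tibble: `strain_id`, `pathway_id`, `present`,
#'   plus an `evidence` list-column of supporting detail tibbles.
#' @export
predict_all <- function(strains, catalog = default_catalog(), evidence = NULL,
                        evalue_threshold = 1e-06, max_gap = 2L) {
  ids <- vapply(strains, function(s) s$strain_id, character(1))
  if (anyDuplicated(ids))
    abort(paste0("duplicate strain_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))

  rows <- purrr::map_dfr(strains, function(s) {
    profile_strain(catalog, s$strain_id, s$genes, s$hits, evidence,
                   evalue_threshold = evalue_threshold, max_gap = max_gap)
  })
  structure(rows, class = c("putref_profiles", class(rows)))
}

profile_strain <- function(catalog, strain_id, genes, hits, evidence = NULL,
                           evalue_threshold = 1e-06, max_gap = 2L) {
  kept <- filter_hits(hits, threshold = evalue_threshold)
  cand <- map_components(catalog, kept, genes, strain_id = strain_id)
  clus <- call_clusters(cand, max_gap = max_gap)
  purrr::map_dfr(catalog$pathways$pathway_id, function(pid) {
    res <- predict_pathway(catalog, pid, cand, clus, evidence = evidence,
                           strain_id = strain_id)
    tibble::tibble(strain_id = strain_id, pathway_id = pid,
                   present = res$present, evidence = list(res$evidence))
  })
}

#' Widen pathway profiles to a strain-by-pathway 0/1 matrix
#'
#' @param profiles A `putref_profiles` tibble from [predict_all()].
#' @return A tibble with one row per strain and one 0/1 column per pathway.
#' @export
presence_matrix <- function(profiles) {
  profiles |>
    dplyr::mutate(present = as.integer(.data$present)) |>
    dplyr::select("strain_id", "pathway_id", "present") |>
    tidyr::pivot_wider(names_from = "pathway_id", values_from = "present") |>
    dplyr::arrange(.data$strain_id)
}

#' @exportS3Method generics::tidy
tidy.putref_profiles <- function(x, ...) {
  x |>
    dplyr::select("strain_id", "pathway_id", "present") |>
    tibble::as_tibble()
}

#' @exportS3Method generics::glance
glance.putref_profiles <- function(x, ...) {
  tibble::tibble(
    n_strains = dplyr::n_distinct(x$strain_id),
    n_pathways = dplyr::n_distinct(x$pathway_id),
    n_putrefiers = x |>
      dplyr::group_by(.data$strain_id) |>
      dplyr::summarise(p = any(.data$present)) |>
      dplyr::pull(.data$p) |>
      sum()
  )
}
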