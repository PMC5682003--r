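#' Specify a synthetic annotated genome with planted pathway clusters
#'
#' Describes one synthetic strain: its replicon layout, which pathway
#' sub-pathways to plant and how, and the decoy-hit rate. Planting modes:
#' * `intact` — all sub-pathway components at consecutive ranks on one
#'   replicon (pathway recoverable);
#' * `partial` — one required component slot omitted (for category III,
#'   nothing is planted); pathway not recoverable from this plant;
#' * `scrambled` — components separated so that no two fall within the
#'   proximity window (category I/II only); not recoverable;
#' * `fused` — like intact, but the first two proximal components' domains
#'   merge onto a single protein (sub-pathways with at least two distinct
#'   proximal slots, e.g. the ornithine decarboxylase route); recoverable;
#' * `distal-split` — proximal core clustered, distal components placed
#'   elsewhere (category II only); recoverable;
#' * `evidence` — no genes; an external evidence record is emitted
#'   (evidence-only pathways, i.e. cresol); recoverable.
#'
#' @param strain_id Strain identifier.
#' @param plants Tibble with columns `pathway_id`, `sub_id`, `mode`.
#' @param lineage Named character vector with `phylum` and `genus`.
#' @param n_replicons,genes_per_replicon Replicon layout (defaults 2 x 60).
#' @param decoy_rate Per-gene probability of a decoy domain hit on a
#'   non-catalog domain (default 0.15).
#' @param true_evalue_range,decoy_evalue_range Log-uniform E-value ranges
#'   for true and decoy hits.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @param catalog A `putref_catalog` the plants are validated against.
#' @return A `genome_plant_spec` list, validated against the catalog.
#' @export
genome_spec <- function(strain_id, plants,
                        lineage = c(phylum = "Simulobacteria",
                                    genus = "Simulomonas"),
                        n_replicons = 2L, genes_per_replicon = 60L,
                        decoy_rate = 0.15,
                        true_evalue_range = c(1e-30, 1e-08),
                        decoy_evalue_range = c(1e-30, 1e-02),
                        seed = 1L, catalog = default_catalog()) {
  plants <- tibble::as_tibble(plants)
  for (f in c("pathway_id", "sub_id", "mode")) {
    if (!f %in% names(plants))
      abort(paste0("`plants` missing column '", f, "'"))
  }
  if (anyDuplicated(plants[, c("pathway_id", "sub_id")]))
    abort("duplicate (pathway_id, sub_id) in `plants`")
  for (i in seq_len(nrow(plants))) {
    validate_plant(catalog, plants$pathway_id[i], plants$sub_id[i],
                   plants$mode[i])
  }
  if (!all(c("phylum", "genus") %in% names(lineage)))
    abort("`lineage` must name phylum and genus")
  structure(
    list(strain_id = strain_id, plants = plants, lineage = lineage,
         n_replicons = as.integer(n_replicons),
         genes_per_replicon = as.integer(genes_per_replicon),
         decoy_rate = decoy_rate,
         true_evalue_range = true_evalue_range,
         decoy_evalue_range = decoy_evalue_range,
         seed = as.integer(seed)),
    class = "genome_plant_spec"
  )
}

plant_modes <- c("intact", "partial", "scrambled", "fused", "distal-split",
                 "evidence")

validate_plant <- function(catalog, pathway, sub, mode) {
  if (!mode %in% plant_modes)
    abort(paste0("unknown planting mode '", mode, "'"))
  pw <- catalog$pathways[catalog$pathways$pathway_id == pathway, ]
  if (nrow(pw) == 0) abort(paste0("unknown pathway_id: ", pathway))
  if (pw$evidence_only) {
    if (mode != "evidence")
      abort(paste0("pathway '", pathway,
                   "' is evidence-only; only mode 'evidence' is valid"))
    return(invisible(TRUE))
  }
  if (mode == "evidence")
    abort(paste0("mode 'evidence' is only valid for evidence-only pathways"))
  slots <- sub_slots(catalog, pathway, sub)
  if (nrow(slots) == 0)
    abort(paste0("unknown sub-pathway: ", pathway, "/", sub))
  category <- catalog$components$category[
    catalog$components$pathway_id == pathway &
      catalog$components$sub_id == sub][1]
  n_slots <- dplyr::n_distinct(slots$slot_id)
  if (mode == "scrambled" && (category == "III" || n_slots < 2))
    abort(paste0("mode 'scrambled' needs a multi-component category I/II ",
                 "sub-pathway: ", pathway, "/", sub))
  if (mode == "fused" &&
      dplyr::n_distinct(slots$slot_id[slots$in_proximity]) < 2)
    abort(paste0("mode 'fused' needs >= 2 distinct proximal slots: ",
                 pathway, "/", sub))
  if (mode == "distal-split" && category != "II")
    abort(paste0("mode 'distal-split' is only valid for category II: ",
                 pathway, "/", sub))
  invisible(TRUE)
}

# rank separation the generator enforces between genes that must NOT
# co-cluster; breaks single-linkage chains for any max_gap < SCRAMBLE_SEP - 1
SCRAMBLE_SEP <- 12L

#' Generate a synthetic annotated genome
#'
#' Realizes a [genome_spec()]: fills the replicons with genes, plants the
#' requested pathway components with true domain hits (E-values log-uniform
#' within the spec's true range, below the 1e-06 pipeline threshold),
#' sprinkles decoy hits on non-catalog domains, and derives a truth table
#' of expected pathway presence by brute-force evaluation of the category
#' rules over the planted layout. Identical specs produce identical output.
#'
#' The truth table accounts for cross-pathway domain sharing: e.g. planting
#' the full THF-production operon also satisfies histidine degradation,
#' whose final step accepts glutamate formyltransferase as an alternative
#' enzyme.
#'
#' @param spec A `genome_plant_spec`.
#' @param catalog A `putref_catalog` (default [default_catalog()]).
#' @param max_gap Proximity gap assumed when deriving the truth table
#'   (default 2, the pipeline default).
#' @return A list of class `putref_sim_genome`: `strain_id`, `lineage`,
#'   `genes` (gene tibble), `hits` (domain-hit tibble), `evidence`
#'   (evidence records), `truth` (pathway_id, present, modes).
#' @export
generate_genome <- function(spec, catalog = default_catalog(), max_gap = 2L) {
  withr::with_seed(spec$seed, generate_genome_impl(spec, catalog, max_gap))
}

generate_genome_impl <- function(spec, catalog, max_gap) {
  n_rep <- spec$n_replicons
  g_per <- spec$genes_per_replicon
  replicons <- sprintf("%s_rep%d", spec$strain_id, seq_len(n_rep))
  # per-replicon allocation pointer (next free 1-based position)
  ptr <- stats::setNames(rep(1L, n_rep), replicons)

  alloc_block <- function(size) {
    feasible <- names(ptr)[ptr + size - 1L <= g_per]
    if (length(feasible) == 0)
      abort("infeasible layout: more planted genes than replicon slots")
    rep_id <- if (length(feasible) == 1) feasible else sample(feasible, 1)
    pos <- ptr[[rep_id]]
    ptr[[rep_id]] <<- pos + size + SCRAMBLE_SEP
    list(replicon = rep_id, positions = pos:(pos + size - 1L))
  }

  planted <- list()   # tibble rows: replicon, position, domains (list), plant ix
  evidence_rows <- list()

  # choose one concrete member for each slot of a sub-pathway
  choose_members <- function(pathway, sub) {
    slots <- sub_slots(catalog, pathway, sub) |>
      dplyr::filter(!.data$evidence_only)
    slots |>
      dplyr::group_by(.data$slot_id) |>
      dplyr::group_map(function(g, k) {
        pick <- if (nrow(g) == 1) 1L else sample(nrow(g), 1)
        g[pick, ]
      }) |>
      dplyr::bind_rows()
  }

  component_domains <- function(pathway, sub, component) {
    row <- catalog$components[
      catalog$components$pathway_id == pathway &
        catalog$components$sub_id == sub &
        catalog$components$component_id == component, ]
    split_field(row$domain_ids[1])
  }

  add_gene <- function(rep_id, position, domains) {
    planted[[length(planted) + 1]] <<- tibble::tibble(
      replicon_id = rep_id, position = position,
      domains = list(domains))
  }

  for (i in seq_len(nrow(spec$plants))) {
    pathway <- spec$plants$pathway_id[i]
    sub <- spec$plants$sub_id[i]
    mode <- spec$plants$mode[i]

    if (mode == "evidence") {
      evidence_rows[[length(evidence_rows) + 1]] <- tibble::tibble(
        strain_id = spec$strain_id, pathway_id = pathway,
        component_id = NA_character_, source = "synthetic")
      next
    }

    members <- choose_members(pathway, sub)
    category <- catalog$components$category[
      catalog$components$pathway_id == pathway &
        catalog$components$sub_id == sub][1]

    if (mode == "partial") {
      if (category == "III") next  # omit the single enzyme entirely
      drop <- sample(nrow(members), 1)
      members <- members[-drop, ]
      if (nrow(members) == 0) next
      blk <- alloc_block(nrow(members))
      for (j in seq_len(nrow(members))) {
        add_gene(blk$replicon, blk$positions[j],
                 component_domains(pathway, sub, members$component_id[j]))
      }
    } else if (mode == "scrambled") {
      for (j in seq_len(nrow(members))) {
        blk <- alloc_block(1L)
        add_gene(blk$replicon, blk$positions[1],
                 component_domains(pathway, sub, members$component_id[j]))
      }
    } else if (mode == "fused") {
      prox <- members |> dplyr::filter(.data$in_proximity)
      rest <- members |> dplyr::anti_join(prox[1:2, ], by = "component_id")
      fused_domains <- unique(c(
        component_domains(pathway, sub, prox$component_id[1]),
        component_domains(pathway, sub, prox$component_id[2])))
      blk <- alloc_block(1L + nrow(rest))
      add_gene(blk$replicon, blk$positions[1], fused_domains)
      for (j in seq_len(nrow(rest))) {
        add_gene(blk$replicon, blk$positions[1 + j],
                 component_domains(pathway, sub, rest$component_id[j]))
      }
    } else if (mode == "distal-split") {
      prox <- members |> dplyr::filter(.data$in_proximity)
      dist <- members |> dplyr::filter(!.data$in_proximity)
      blk <- alloc_block(nrow(prox))
      for (j in seq_len(nrow(prox))) {
        add_gene(blk$replicon, blk$positions[j],
                 component_domains(pathway, sub, prox$component_id[j]))
      }
      for (j in seq_len(nrow(dist))) {
        blk <- alloc_block(1L)
        add_gene(blk$replicon, blk$positions[1],
                 component_domains(pathway, sub, dist$component_id[j]))
      }
    } else {  # intact
      blk <- alloc_block(nrow(members))
      for (j in seq_len(nrow(members))) {
        add_gene(blk$replicon, blk$positions[j],
                 component_domains(pathway, sub, members$component_id[j]))
      }
    }
  }

  planted_tbl <- if (length(planted) > 0) {
    dplyr::bind_rows(planted)
  } else {
    tibble::tibble(replicon_id = character(0), position = integer(0),
                   domains = list())
  }

  # full gene complement: planted genes plus filler at every other position
  layout <- tidyr::crossing(replicon_id = replicons,
                            position = seq_len(g_per)) |>
    dplyr::left_join(planted_tbl, by = c("replicon_id", "position")) |>
    dplyr::arrange(.data$replicon_id, .data$position) |>
    dplyr::mutate(
      gene_id = sprintf("%s_g%04d", spec$strain_id, dplyr::row_number()),
      protein_id = sprintf("%s_p%04d", spec$strain_id, dplyr::row_number()),
      start = (.data$position - 1L) * 1200L + 1L,
      end = (.data$position - 1L) * 1200L + 900L,
      strand = "+"
    )

  genes <- layout |>
    dplyr::select("gene_id", "protein_id", "replicon_id", "start", "end",
                  "strand") |>
    assign_ranks()

  # true hits for planted domains
  dom_rows <- layout |>
    dplyr::filter(lengths(.data$domains) > 0) |>
    dplyr::select("protein_id", "domains") |>
    tidyr::unnest_longer("domains", values_to = "domain_id")
  true_hits <- if (nrow(dom_rows) > 0) {
    dom_rows |>
      dplyr::mutate(
        evalue = runif_log(dplyr::n(), spec$true_evalue_range[1],
                           spec$true_evalue_range[2]),
        bitscore = round(runif(dplyr::n(), 80, 400), 1))
  } else {
    tibble::tibble(protein_id = character(0), domain_id = character(0),
                   evalue = double(0), bitscore = double(0))
  }

  # decoy hits on non-catalog domains
  is_decoy <- rbinom(nrow(layout), 1, spec$decoy_rate) == 1
  decoy_hits <- if (any(is_decoy)) {
    tibble::tibble(
      protein_id = layout$protein_id[is_decoy],
      domain_id = sprintf("DECOY_%03d", sample(50L, sum(is_decoy),
                                               replace = TRUE)),
      evalue = runif_log(sum(is_decoy), spec$decoy_evalue_range[1],
                         spec$decoy_evalue_range[2]),
      bitscore = round(runif(sum(is_decoy), 10, 60), 1))
  } else {
    true_hits[0, ]
  }
  hits <- dplyr::bind_rows(true_hits, decoy_hits) |>
    dplyr::arrange(.data$protein_id, .data$domain_id)

  evidence <- if (length(evidence_rows) > 0) {
    dplyr::bind_rows(evidence_rows)
  } else {
    tibble::tibble(strain_id = character(0), pathway_id = character(0),
                   component_id = character(0), source = character(0))
  }

  truth <- truth_from_layout(layout, catalog, evidence, spec$strain_id,
                             max_gap = max_gap)
  modes <- spec$plants |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(modes = paste(.data$mode, collapse = ";"))
  truth <- truth |>
    dplyr::left_join(modes, by = "pathway_id") |>
    dplyr::mutate(modes = dplyr::coalesce(.data$modes, ""))

  structure(
    list(strain_id = spec$strain_id, lineage = spec$lineage, genes = genes,
         hits = hits, evidence = evidence, truth = truth),
    class = "putref_sim_genome"
  )
}

# Brute-force evaluation of the category rules over a planted layout.
# Independent of the pipeline path: works on planted positions directly and
# uses pairwise-connected-component clustering rather than sorted chaining.
truth_from_layout <- function(layout, catalog, evidence, strain_id,
                              max_gap = 2L) {
  has_domain <- layout |>
    dplyr::filter(lengths(.data$domains) > 0) |>
    dplyr::select("replicon_id", "position", "domains") |>
    tidyr::unnest_longer("domains", values_to = "domain_id") |>
    dplyr::mutate(domain_id = as.character(.data$domain_id))
  idx <- domain_index(catalog)

  purrr::map_dfr(catalog$pathways$pathway_id, function(pid) {
    pw <- catalog$pathways[catalog$pathways$pathway_id == pid, ]
    if (pw$evidence_only) {
      present <- any(evidence$strain_id == strain_id &
                       evidence$pathway_id == pid)
      return(tibble::tibble(pathway_id = pid, present = present))
    }
    subs <- unique(catalog$components$sub_id[
      catalog$components$pathway_id == pid])
    present <- FALSE
    for (sub in subs) {
      comp <- has_domain |>
        dplyr::inner_join(idx |>
                            dplyr::filter(.data$pathway_id == pid,
                                          .data$sub_id == sub),
                          by = "domain_id")
      if (nrow(comp) == 0) next
      slots <- sub_slots(catalog, pid, sub) |>
        dplyr::filter(!.data$evidence_only)
      category <- catalog$components$category[
        catalog$components$pathway_id == pid &
          catalog$components$sub_id == sub][1]
      slot_sets <- split(slots$component_id, slots$slot_id)

      if (category == "III") {
        if (any(unlist(slot_sets) %in% comp$component_id)) present <- TRUE
        if (present) break
        next
      }

      prox_sets <- slot_sets[unique(
        slots$slot_id[slots$in_proximity])]
      distal_sets <- slot_sets[setdiff(names(slot_sets), names(prox_sets))]

      # brute-force connected components on |position difference| <= max_gap+1
      pos <- comp |> dplyr::distinct(.data$replicon_id, .data$position)
      n <- nrow(pos)
      comp_id <- seq_len(n)
      repeat {
        changed <- FALSE
        for (a in seq_len(n)) for (b in seq_len(n)) {
          if (pos$replicon_id[a] == pos$replicon_id[b] &&
              abs(pos$position[a] - pos$position[b]) <= max_gap + 1 &&
              comp_id[a] != comp_id[b]) {
            comp_id[comp_id == comp_id[b]] <- comp_id[a]
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      for (cc in unique(comp_id)) {
        in_cc <- pos[comp_id == cc, ]
        cc_components <- comp |>
          dplyr::semi_join(in_cc, by = c("replicon_id", "position")) |>
          dplyr::pull(.data$component_id)
        prox_ok <- all(vapply(prox_sets,
                              function(s) any(s %in% cc_components),
                              logical(1)))
        if (!prox_ok) next
        distal_ok <- all(vapply(distal_sets,
                                function(s) any(s %in% comp$component_id),
                                logical(1)))
        if (distal_ok) { present <- TRUE; break }
      }
      if (present) break
    }
    tibble::tibble(pathway_id = pid, present = present)
  })
}

#' Write a synthetic genome's files
#'
#' Writes the GFF3 annotation, the HMMER-style domain-hit table, the truth
#' table, and (if any) evidence records for one simulated strain, in the
#' formats the pipeline reads back.
#'
#' @param genome A `putref_sim_genome` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gff = file.path(dir, paste0(genome$strain_id, ".gff3")),
    hits = file.path(dir, paste0(genome$strain_id, ".domtblout")),
    truth = file.path(dir, paste0(genome$strain_id, "_truth.tsv"))
  )
  write_gene_coordinates(genome$genes, paths[["gff"]])
  write_domain_hits(genome$hits, paths[["hits"]])
  readr::write_tsv(genome$truth, paths[["truth"]])
  if (nrow(genome$evidence) > 0) {
    paths[["evidence"]] <- file.path(dir,
                                     paste0(genome$strain_id, "_evidence.tsv"))
    readr::write_tsv(genome$evidence, paths[["evidence"]])
  }
  invisible(paths)
}

#' Generate a seeded multi-strain synthetic panel
#'
#' Convenience wrapper building one [genome_spec()] per strain with plants
#' drawn across pathways and all planting modes valid for each sub-pathway,
#' then generating every genome. Strains are spread over a configurable
#' number of genera for taxon-level scoring.
#'
#' @param n_strains Number of strains.
#' @param seed Integer master seed.
#' @param n_genera Number of genera to spread strains over (default 5).
#' @param plants_per_strain Range of plants per strain (default 1:3).
#' @param catalog A `putref_catalog`.
#' @return A list with `genomes` (list of `putref_sim_genome`), `taxonomy`
#'   (strain metadata tibble), `truth` (combined truth table), `evidence`
#'   (combined evidence records).
#' @export
generate_panel <- function(n_strains, seed = 1L, n_genera = 5L,
                           plants_per_strain = 1:3,
                           catalog = default_catalog()) {
  # enumerate (pathway, sub, mode) combinations valid under the catalog
  combos <- catalog$components |>
    dplyr::distinct(.data$pathway_id, .data$sub_id) |>
    tidyr::crossing(mode = plant_modes) |>
    dplyr::rowwise() |>
    dplyr::filter(tryCatch({
      validate_plant(catalog, .data$pathway_id, .data$sub_id, .data$mode)
      TRUE
    }, error = function(e) FALSE)) |>
    dplyr::ungroup()

  specs <- withr::with_seed(seed, {
    lapply(seq_len(n_strains), function(i) {
      n_plants <- sample(plants_per_strain, 1)
      take <- combos[sample(nrow(combos), n_plants), c("pathway_id", "sub_id",
                                                       "mode")]
      # a (pathway, sub) may appear once per strain
      take <- take[!duplicated(take[, c("pathway_id", "sub_id")]), ]
      genome_spec(
        strain_id = sprintf("strain%03d", i),
        plants = take,
        lineage = c(phylum = sprintf("Phylum%02d", (i %% 2L) + 1L),
                    genus = sprintf("Genus%02d", (i %% n_genera) + 1L)),
        seed = sample.int(.Machine$integer.max, 1),
        catalog = catalog
      )
    })
  })
  genomes <- lapply(specs, generate_genome, catalog = catalog)
  taxonomy <- purrr::map_dfr(genomes, function(g) {
    tibble::tibble(strain_id = g$strain_id,
                   phylum = unname(g$lineage[["phylum"]]),
                   genus = unname(g$lineage[["genus"]]))
  })
  truth <- purrr::map_dfr(genomes, function(g) {
    dplyr::mutate(g$truth, strain_id = g$strain_id, .before = 1)
  })
  evidence <- purrr::map_dfr(genomes, "evidence")
  list(genomes = genomes, taxonomy = taxonomy, truth = truth,
       evidence = evidence)
}

#' Specify a synthetic cohort abundance simulation
#'
#' Baseline genus abundances are drawn log-normally per (sample, genus);
#' planted effects multiply the expected abundance of a genus in one
#' cohort. A dropout probability can zero out individual observations to
#' emulate undetected taxa.
#'
#' @param n_genera Number of genera.
#' @param samples_per_cohort Samples per cohort (>= 2).
#' @param cohorts Cohort labels (2 or 3 of healthy/adenoma/carcinoma).
#' @param meanlog,sdlog Log-normal baseline parameters.
#' @param dropout Per-observation probability of a zero (default 0).
#' @param effects Tibble `genus`, `cohort`, `effect` (multiplicative,
#'   > 0; 1 = null).
#' @param seed Integer seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_spec <- function(n_genera = 100L, samples_per_cohort = 20L,
                        cohorts = c("healthy", "carcinoma"),
                        meanlog = log(1000), sdlog = 1, dropout = 0,
                        effects = NULL, seed = 1L) {
  if (samples_per_cohort < 2) abort("need >= 2 samples per cohort")
  if (length(cohorts) < 2 || length(cohorts) > 3)
    abort("`cohorts` must contain 2 or 3 labels")
  genera <- sprintf("Genus%03d", seq_len(n_genera))
  if (is.null(effects)) {
    effects <- tibble::tibble(genus = character(0), cohort = character(0),
                              effect = double(0))
  }
  effects <- tibble::as_tibble(effects)
  if (nrow(effects) > 0) {
    if (any(effects$effect <= 0))
      abort("planted effect sizes must be positive")
    bad <- setdiff(effects$genus, genera)
    if (length(bad) > 0)
      abort(paste0("effects reference undeclared genera: ",
                   paste(bad, collapse = ", ")))
    bad <- setdiff(effects$cohort, cohorts)
    if (length(bad) > 0)
      abort(paste0("effects reference undeclared cohorts: ",
                   paste(bad, collapse = ", ")))
  }
  structure(
    list(n_genera = as.integer(n_genera), genera = genera,
         samples_per_cohort = as.integer(samples_per_cohort),
         cohorts = cohorts, meanlog = meanlog, sdlog = sdlog,
         dropout = dropout, effects = effects, seed = as.integer(seed)),
    class = "cohort_sim_spec"
  )
}

#' Generate a synthetic cohort abundance table
#'
#' @param spec A `cohort_sim_spec` from [cohort_spec()].
#' @return A list of class `putref_sim_cohort`: `abundance` (long tibble
#'   `sample_id`, `genus`, `count`), `design` (`sample_id`, `cohort`),
#'   `truth` (genera with planted non-null effects).
#' @export
generate_cohort <- function(spec) {
  withr::with_seed(spec$seed, {
    design <- tidyr::crossing(cohort = spec$cohorts,
                              rep = seq_len(spec$samples_per_cohort)) |>
      dplyr::mutate(sample_id = sprintf("%s_s%02d", .data$cohort, .data$rep)) |>
      dplyr::select("sample_id", "cohort")

    abundance <- tidyr::crossing(design, genus = spec$genera) |>
      dplyr::left_join(spec$effects, by = c("cohort", "genus")) |>
      dplyr::mutate(
        effect = dplyr::coalesce(.data$effect, 1),
        count = rlnorm(dplyr::n(), spec$meanlog, spec$sdlog) * .data$effect
      )
    if (spec$dropout > 0) {
      drop <- rbinom(nrow(abundance), 1, spec$dropout) == 1
      abundance$count[drop] <- 0
    }
    abundance <- abundance |>
      dplyr::select("sample_id", "genus", "count")

    truth <- spec$effects |> dplyr::filter(.data$effect != 1)
    structure(list(abundance = abundance, design = design, truth = truth),
              class = "putref_sim_cohort")
  })
}
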