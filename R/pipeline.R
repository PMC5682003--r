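#' Simulate a full synthetic study into a directory
#'
#' Writes a seeded synthetic strain panel (GFF3 + domain hits + truth +
#' taxonomy) and a cohort abundance study (abundance, design, truth) in the
#' formats the scan/score/cohort stages read.
#'
#' @param outdir Output directory.
#' @param n_strains Panel size (default 50).
#' @param seed Master seed.
#' @param cohort A `cohort_sim_spec`; default is a two-cohort null study.
#' @param catalog A `putref_catalog`.
#' @return Invisibly, a list with the panel and cohort objects.
#' @export
run_simulate <- function(outdir, n_strains = 50L, seed = 1L,
                         cohort = cohort_spec(seed = seed),
                         catalog = default_catalog()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome_dir <- file.path(outdir, "genomes")
  panel <- generate_panel(n_strains, seed = seed, catalog = catalog)
  for (g in panel$genomes) write_genome(g, genome_dir)
  readr::write_tsv(panel$taxonomy, file.path(outdir, "taxonomy.tsv"))
  readr::write_tsv(panel$truth, file.path(outdir, "panel_truth.tsv"))

  sim <- generate_cohort(cohort)
  wide <- sim$abundance |>
    tidyr::pivot_wider(names_from = "genus", values_from = "count")
  readr::write_tsv(wide, file.path(outdir, "abundance.tsv"))
  readr::write_tsv(sim$design, file.path(outdir, "design.tsv"))
  readr::write_tsv(sim$truth, file.path(outdir, "cohort_truth.tsv"))
  inform(paste0("simulated ", n_strains, " strains and ",
                nrow(sim$design), " cohort samples into ", outdir))
  invisible(list(panel = panel, cohort = sim))
}

#' Scan a directory of annotated genomes for putrefaction pathways
#'
#' For every `<strain>.gff3` with a matching `<strain>.domtblout` (and
#' optional `<strain>_evidence.tsv`), runs E-value filtering, component
#' mapping, cluster calling and the category rules, then writes the
#' presence/absence matrix and an evidence detail table.
#'
#' @param indir Directory of genome files.
#' @param outdir Output directory.
#' @param catalog A `putref_catalog` or a path to a catalog YAML.
#' @param evalue_threshold E-value cutoff (default 1e-06).
#' @param max_gap Proximity gap (default 2).
#' @return The `putref_profiles` tibble, invisibly.
#' @export
run_scan <- function(indir, outdir, catalog = default_catalog(),
                     evalue_threshold = 1e-06, max_gap = 2L) {
  if (is.character(catalog)) catalog <- load_catalog(catalog)
  gffs <- sort(list.files(indir, pattern = "\\.gff3$", full.names = TRUE))
  if (length(gffs) == 0) abort(paste0("no genomes found in ", indir))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  strains <- lapply(gffs, function(gff) {
    sid <- sub("\\.gff3$", "", basename(gff))
    hit_path <- file.path(indir, paste0(sid, ".domtblout"))
    if (!file.exists(hit_path))
      abort(paste0("missing domain-hit table for strain ", sid))
    list(strain_id = sid, genes = read_gene_coordinates(gff),
         hits = read_domain_hits(hit_path))
  })
  ev_files <- list.files(indir, pattern = "_evidence\\.tsv$",
                         full.names = TRUE)
  evidence <- if (length(ev_files) > 0) {
    purrr::map_dfr(ev_files, readr::read_tsv, show_col_types = FALSE,
                   progress = FALSE)
  } else {
    NULL
  }

  profiles <- predict_all(strains, catalog = catalog, evidence = evidence,
                          evalue_threshold = evalue_threshold,
                          max_gap = max_gap)
  readr::write_tsv(presence_matrix(profiles),
                   file.path(outdir, "presence_matrix.tsv"))
  detail <- profiles |>
    dplyr::filter(.data$present) |>
    dplyr::mutate(detail = purrr::map_chr(.data$evidence, function(e) {
      paste(paste0(dplyr::coalesce(e$sub_id, "-"), ":", e$via, ":", e$detail),
            collapse = "|")
    })) |>
    dplyr::select("strain_id", "pathway_id", "detail")
  readr::write_tsv(detail, file.path(outdir, "evidence_detail.tsv"))
  n_putref <- glance(profiles)$n_putrefiers
  inform(paste0("scanned ", length(strains), " strain(s); ", n_putref,
                " putrefier(s) found"))
  invisible(profiles)
}

#' Score taxa from a presence matrix and taxonomy
#'
#' @param presence Path to a presence matrix TSV (from [run_scan()]) or a
#'   `putref_profiles` tibble.
#' @param taxonomy Path to a taxonomy TSV or tibble (`strain_id`, `phylum`,
#'   `genus`).
#' @param outdir Output directory.
#' @param level `"genus"` or `"phylum"`.
#' @return The `pfacs_scores` tibble, invisibly.
#' @export
run_score <- function(presence, taxonomy, outdir, level = "genus") {
  prof <- if (is.character(presence)) {
    readr::read_tsv(presence, show_col_types = FALSE, progress = FALSE) |>
      tidyr::pivot_longer(-"strain_id", names_to = "pathway_id",
                          values_to = "present") |>
      dplyr::mutate(present = .data$present > 0)
  } else {
    presence
  }
  if (is.character(taxonomy))
    taxonomy <- readr::read_tsv(taxonomy, show_col_types = FALSE,
                                progress = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scores <- score_matrix(prof, taxonomy, level = level)
  readr::write_tsv(tidy(scores), file.path(outdir,
                                           paste0("pfacs_", level, ".tsv")))
  readr::write_tsv(pfacs_matrix(scores),
                   file.path(outdir, paste0("pfacs_matrix_", level, ".tsv")))
  invisible(scores)
}

#' Run the cohort-comparison stage
#'
#' Normalizes the abundance table, identifies differentially abundant
#' genera (Welch for 2 cohorts, Kruskal–Wallis for 3), and summarizes
#' pathway occurrence and the oxygen breakdown of putrefiers among them.
#'
#' @param abundance Path to a samples-by-genera TSV or a long abundance
#'   tibble.
#' @param design Path/tibble mapping `sample_id` to `cohort`.
#' @param scores A `pfacs_scores` tibble or path to the long Pfacs TSV.
#' @param outdir Output directory.
#' @param oxygen Optional tibble/path with `genus`, `oxygen_class`.
#' @param p_threshold Significance cutoff (default 0.05).
#' @return Invisibly, a list with `diff`, `summary`, `oxygen`.
#' @export
run_cohort <- function(abundance, design, scores, outdir, oxygen = NULL,
                       p_threshold = 0.05) {
  if (is.character(abundance)) abundance <- read_abundance(abundance)
  if (is.character(design))
    design <- readr::read_tsv(design, show_col_types = FALSE, progress = FALSE)
  if (is.character(scores)) {
    scores <- readr::read_tsv(scores, show_col_types = FALSE, progress = FALSE)
    class(scores) <- c("pfacs_scores", class(scores))
  }
  if (is.character(oxygen))
    oxygen <- readr::read_tsv(oxygen, show_col_types = FALSE, progress = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  rel <- normalize_relative(abundance)
  diff <- differential_genera(rel, design, p_threshold = p_threshold)
  inform(paste0("used ", if (length(unique(design$cohort)) == 2) "Welch t-test"
                else "Kruskal-Wallis test", "; ", nrow(diff),
                " differential genus/genera at p <= ", p_threshold))
  readr::write_tsv(tidy(diff), file.path(outdir, "differential_genera.tsv"))

  summary <- NULL
  oxy <- NULL
  if (nrow(diff) > 0) {
    summary <- pathway_occurrence_summary(diff, scores)
    readr::write_tsv(summary$occurrence,
                     file.path(outdir, "pathway_occurrence.tsv"))
    readr::write_tsv(summary$putrefiers,
                     file.path(outdir, "putrefier_flags.tsv"))
    sub <- scores |>
      dplyr::filter(.data$taxon %in% diff$genus)
    readr::write_tsv(tibble::as_tibble(sub),
                     file.path(outdir, "pfacs_differential_genera.tsv"))
    if (!is.null(oxygen)) {
      oxy <- oxygen_breakdown(diff, oxygen, summary$putrefiers)
      readr::write_tsv(oxy, file.path(outdir, "oxygen_breakdown.tsv"))
    }
  }
  invisible(list(diff = diff, summary = summary, oxygen = oxy))
}

#' Run simulate, scan, score and cohort end to end
#'
#' @param outdir Root output directory (stage outputs go to
#'   subdirectories).
#' @param n_strains Panel size.
#' @param seed Master seed.
#' @param level Taxon level for scoring.
#' @param p_threshold Cohort significance cutoff.
#' @return Invisibly, a list with each stage's results.
#' @export
run_all <- function(outdir, n_strains = 50L, seed = 1L, level = "genus",
                    p_threshold = 0.05) {
  sim <- run_simulate(file.path(outdir, "sim"), n_strains = n_strains,
                      seed = seed)
  profiles <- run_scan(file.path(outdir, "sim", "genomes"),
                       file.path(outdir, "scan"))
  scores <- run_score(profiles, file.path(outdir, "sim", "taxonomy.tsv"),
                      file.path(outdir, "score"), level = level)
  cohort <- run_cohort(file.path(outdir, "sim", "abundance.tsv"),
                       file.path(outdir, "sim", "design.tsv"),
                       scores, file.path(outdir, "cohort"),
                       p_threshold = p_threshold)
  invisible(list(sim = sim, profiles = profiles, scores = scores,
                 cohort = cohort))
}
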