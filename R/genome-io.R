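#' Read gene coordinates from a GFF3 file
#'
#' Imports CDS (or, if none, gene) features and returns a gene table with
#' 1-based inclusive coordinates and a per-replicon `rank`: the position
#' index (0-based) of the gene among genes on its replicon ordered by
#' ascending start, ties broken by ascending end then lexicographic gene id.
#' Cluster calling works on these ranks, i.e. on counts of intervening
#' genes, not base pairs.
#'
#' Features lacking both an `ID` and a `protein_id` attribute are skipped
#' with a warning reporting the skipped count.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `protein_id`, `replicon_id`,
#'   `start`, `end`, `strand`, `rank`.
#' @export
read_gene_coordinates <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    abort(paste0("malformed GFF3 line ", bad, " in ", path,
                 ": expected 9 tab-separated fields, found ", nf[nf != 9][1]))
  }

  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))
  if (nrow(df) > 0 && "type" %in% names(df)) {
    keep <- if (any(df$type == "CDS")) "CDS" else "gene"
    df <- df |> dplyr::filter(.data$type == keep)
  }
  if (!"ID" %in% names(df)) df$ID <- NA_character_
  if (!"protein_id" %in% names(df)) df$protein_id <- NA_character_

  no_id <- is.na(df$ID) & is.na(df$protein_id)
  if (any(no_id)) {
    warn(paste0("skipped ", sum(no_id),
                " feature(s) without an ID or protein_id attribute in ", path))
    df <- df[!no_id, , drop = FALSE]
  }

  df |>
    dplyr::transmute(
      gene_id = dplyr::coalesce(.data$ID, .data$protein_id),
      protein_id = dplyr::coalesce(.data$protein_id, .data$ID),
      replicon_id = as.character(.data$seqnames),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      strand = as.character(.data$strand)
    ) |>
    assign_ranks()
}

# Per-replicon 0-based rank by (start, end, gene_id).
assign_ranks <- function(genes) {
  genes |>
    dplyr::arrange(.data$replicon_id, .data$start, .data$end, .data$gene_id) |>
    dplyr::group_by(.data$replicon_id) |>
    dplyr::mutate(rank = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
}

#' Write a gene table as GFF3
#'
#' Inverse of [read_gene_coordinates()]: reading the written file back
#' reproduces the gene table (idempotent round trip).
#'
#' @param genes Gene tibble as returned by [read_gene_coordinates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_coordinates <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$source <- "putrescan"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$protein_id <- genes$protein_id
  rtracklayer::export(sort(gr), path, format = "gff3")
  invisible(path)
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Parses the whitespace-delimited per-domain table written by
#' `hmmscan --domtblout` (comment lines start with `#`): the target name is
#' the profile/domain, the query name the protein, and the full-sequence
#' E-value and bit score are taken for each hit.
#'
#' @param path Path to a domtblout file.
#' @return A tibble with columns `protein_id`, `domain_id`, `evalue`,
#'   `bitscore`, one row per data row of the file.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) abort(paste0("domain-hit file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble::tibble(protein_id = character(0), domain_id = character(0),
                          evalue = double(0), bitscore = double(0)))
  }
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  short <- lengths(fields) < 8
  if (any(short))
    abort(paste0("malformed domain-hit row at line ", keep[which(short)[1]],
                 " in ", path, ": fewer than 8 fields"))
  ev_chr <- vapply(fields, `[[`, character(1), 7L)
  ev <- suppressWarnings(as.numeric(ev_chr))
  if (anyNA(ev))
    abort(paste0("non-numeric e-value '", ev_chr[which(is.na(ev))[1]],
                 "' at line ", keep[which(is.na(ev))[1]], " in ", path))
  bs <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 8L)))
  tibble::tibble(
    protein_id = vapply(fields, `[[`, character(1), 4L),
    domain_id = vapply(fields, `[[`, character(1), 1L),
    evalue = ev,
    bitscore = bs
  )
}

#' Write domain hits in the HMMER3 per-domain tabular dialect
#'
#' @param hits Tibble with `protein_id`, `domain_id`, `evalue`, `bitscore`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ -----"
  ), con)
  if (nrow(hits) > 0) {
    writeLines(sprintf("%-20s %-10s %5d %-20s %-10s %5d %12.6g %6.1f %5.1f",
                       hits$domain_id, "-", 200L, hits$protein_id, "-", 300L,
                       hits$evalue, hits$bitscore, 0), con)
  }
  invisible(path)
}

oxygen_levels <- c("aerobe", "anaerobe", "microaerophile",
                   "facultative anaerobe", "obligate anaerobe")
anaerobe_subtypes <- c("anaerobe", "facultative anaerobe", "obligate anaerobe")

#' Read and join strain metadata tables
#'
#' Joins a strain taxonomy table with pathogen/commensal labels and
#' strain-level oxygen requirements. Strains absent from the labels table
#' default to `unlabeled`; oxygen classes come from the closed five-label
#' vocabulary (aerobe, anaerobe, microaerophile, facultative anaerobe,
#' obligate anaerobe).
#'
#' @param taxonomy Path to a TSV with columns `strain_id`, `phylum`, `genus`
#'   (tab-delimited, header row), or a tibble with those columns.
#' @param labels Optional path/tibble with columns `strain_id`, `label`
#'   (`pathogen`/`commensal`/`unlabeled`).
#' @param oxygen Optional path/tibble with columns `strain_id`, `oxygen`.
#' @return A tibble `strain_id`, `phylum`, `genus`, `label`, `oxygen`.
#' @seealso [genus_oxygen()] for the genus-level collapse rule.
#' @export
read_strain_tables <- function(taxonomy, labels = NULL, oxygen = NULL) {
  read_tsv_arg <- function(x) {
    if (is.character(x) && length(x) == 1) {
      readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
    } else {
      tibble::as_tibble(x)
    }
  }
  tax <- read_tsv_arg(taxonomy)
  for (f in c("strain_id", "phylum", "genus")) {
    if (!f %in% names(tax)) abort(paste0("taxonomy table missing column '", f, "'"))
  }
  meta <- tax |> dplyr::select("strain_id", "phylum", "genus")

  if (!is.null(labels)) {
    lab <- read_tsv_arg(labels)
    bad <- setdiff(unique(lab$label), c("pathogen", "commensal", "unlabeled"))
    if (length(bad) > 0)
      abort(paste0("unknown strain label(s): ", paste(bad, collapse = ", ")))
    meta <- dplyr::left_join(meta, lab |> dplyr::select("strain_id", "label"),
                             by = "strain_id")
  } else {
    meta$label <- NA_character_
  }
  meta$label <- dplyr::coalesce(meta$label, "unlabeled")

  if (!is.null(oxygen)) {
    oxy <- read_tsv_arg(oxygen)
    bad <- which(!oxy$oxygen %in% oxygen_levels)
    if (length(bad) > 0)
      abort(paste0("unknown oxygen category '", oxy$oxygen[bad[1]],
                   "' for strain '", oxy$strain_id[bad[1]], "'"))
    meta <- dplyr::left_join(meta, oxy |> dplyr::select("strain_id", "oxygen"),
                             by = "strain_id")
  } else {
    meta$oxygen <- NA_character_
  }
  meta
}

#' Genus-level oxygen classification
#'
#' Collapses strain-level oxygen requirements to one class per genus. When
#' the strains of a genus disagree but all fall among anaerobic subtypes
#' (anaerobe, facultative anaerobe, obligate anaerobe), the genus gets the
#' generic class `anaerobe`; other conflicts are flagged `ambiguous`.
#'
#' @param strain_meta Tibble from [read_strain_tables()] (needs `genus`,
#'   `oxygen`).
#' @return A tibble `genus`, `oxygen_class`.
#' @export
genus_oxygen <- function(strain_meta) {
  strain_meta |>
    dplyr::filter(!is.na(.data$oxygen)) |>
    dplyr::distinct(.data$genus, .data$oxygen) |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(
      oxygen_class = if (dplyr::n() == 1) {
        .data$oxygen[1]
      } else if (all(.data$oxygen %in% anaerobe_subtypes)) {
        "anaerobe"
      } else {
        "ambiguous"
      },
      .groups = "drop"
    )
}
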