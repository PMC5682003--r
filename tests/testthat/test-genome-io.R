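gff_lines <- function(rows) {
  c("##gff-version 3", rows)
}

write_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GFF3 coordinates pass through and ranks follow start order", {
  path <- write_tmp(gff_lines(c(
    "repA\tsrc\tCDS\t900\t1500\t.\t-\t0\tID=g2;protein_id=p2",
    "repA\tsrc\tCDS\t100\t400\t.\t+\t0\tID=g1;protein_id=p1",
    "repB\tsrc\tCDS\t100\t400\t.\t+\t0\tID=g3;protein_id=p3"
  )), ".gff3")
  genes <- read_gene_coordinates(path)
  g1 <- genes[genes$gene_id == "g1", ]
  expect_equal(g1$start, 100L)
  expect_equal(g1$end, 400L)
  expect_equal(g1$strand, "+")
  # ranks per replicon by ascending start; independent across replicons
  expect_equal(genes$rank[match(c("g1", "g2", "g3"), genes$gene_id)],
               c(0L, 1L, 0L))
})

test_that("GFF3 errors and skips are reported usefully", {
  bad <- write_tmp(gff_lines(c(
    "repA\tsrc\tCDS\t100\t400\t.\t+\t0\tID=g1",
    "repA\tsrc\tCDS\t500\t900"
  )), ".gff3")
  expect_error(read_gene_coordinates(bad), "line 3")

  noid <- write_tmp(gff_lines(c(
    "repA\tsrc\tCDS\t100\t400\t.\t+\t0\tID=g1;protein_id=p1",
    "repA\tsrc\tCDS\t500\t900\t.\t+\t0\tNote=anonymous"
  )), ".gff3")
  expect_warning(genes <- read_gene_coordinates(noid), "skipped 1")
  expect_equal(nrow(genes), 1)
})

test_that("gene table write/read round trip is idempotent", {
  panel <- generate_panel(2, seed = 42)
  g <- panel$genomes[[1]]
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_coordinates(g$genes, path)
  back <- read_gene_coordinates(path)
  ord <- function(x) dplyr::arrange(x, gene_id)
  expect_identical(ord(back), ord(g$genes))
  # ranks are a permutation 0..n-1 on each replicon
  perms <- back |>
    dplyr::group_by(replicon_id) |>
    dplyr::summarise(ok = identical(sort(rank), seq_len(dplyr::n()) - 1L))
  expect_true(all(perms$ok))
})

test_that("domtblout parsing handles scientific notation, comments, errors", {
  path <- write_tmp(c(
    "# comment header",
    "DomX  -  200  protA  -  300  1e-07  55.2  0.1",
    "DomY  -  200  protA  -  300  2.5e-12  80.0  0.0",
    "DomX  -  200  protB  -  300  0.001  12.0  0.2"
  ), ".domtblout")
  hits <- read_domain_hits(path)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$evalue[1], 1e-07)
  expect_equal(hits$evalue[2], 2.5e-12)
  expect_equal(hits$protein_id, c("protA", "protA", "protB"))

  empty <- write_tmp(c("# only", "# comments"), ".domtblout")
  expect_equal(nrow(read_domain_hits(empty)), 0)

  bad <- write_tmp(c("DomX - 200 protA - 300 not_a_number 55.2 0.1"),
                   ".domtblout")
  expect_error(read_domain_hits(bad), "non-numeric e-value.*line 1")
})

test_that("domain-hit write/read round trip preserves hits", {
  hits <- tibble::tibble(
    protein_id = c("p1", "p2"), domain_id = c("Arginase", "OKR_DC_1"),
    evalue = c(1.5e-20, 3e-07), bitscore = c(120.5, 60.1))
  path <- withr::local_tempfile(fileext = ".domtblout")
  write_domain_hits(hits, path)
  back <- read_domain_hits(path)
  expect_equal(back$protein_id, hits$protein_id)
  expect_equal(back$domain_id, hits$domain_id)
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-6)
})

test_that("strain tables join with label defaults and a closed oxygen vocabulary", {
  tax <- tibble::tibble(strain_id = c("s1", "s2", "s3"),
                        phylum = "Firmicutes",
                        genus = c("Streptococcus", "Streptococcus", "Bacillus"))
  labels <- tibble::tibble(strain_id = "s1", label = "pathogen")
  oxy <- tibble::tibble(strain_id = c("s1", "s2", "s3"),
                        oxygen = c("obligate anaerobe", "facultative anaerobe",
                                   "aerobe"))
  meta <- read_strain_tables(tax, labels, oxy)
  expect_equal(meta$label, c("pathogen", "unlabeled", "unlabeled"))

  # conflicting anaerobic subtypes collapse to generic anaerobe
  go <- genus_oxygen(meta)
  expect_equal(go$oxygen_class[go$genus == "Streptococcus"], "anaerobe")
  expect_equal(go$oxygen_class[go$genus == "Bacillus"], "aerobe")

  # aerobe/anaerobe conflict is ambiguous, not collapsed
  oxy2 <- tibble::tibble(strain_id = c("s1", "s2"),
                         oxygen = c("aerobe", "obligate anaerobe"))
  meta2 <- read_strain_tables(tax[1:2, ], NULL, oxy2)
  expect_equal(genus_oxygen(meta2)$oxygen_class, "ambiguous")

  # closed vocabulary
  bad <- tibble::tibble(strain_id = "s1", oxygen = "aerotolerant")
  expect_error(read_strain_tables(tax, NULL, bad), "aerotolerant")
})
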