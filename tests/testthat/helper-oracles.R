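# Independent oracles used across the suite. These deliberately avoid the
# package's implementation paths (sorted-chain clustering, stats::t.test):
# the cluster oracle walks the full pairwise proximity graph, the Welch
# oracle is the Welch-Satterthwaite formula written out.

# Connected components of the pairwise proximity graph over gene ranks on
# one replicon: ranks i, j adjacent iff |ranks[i] - ranks[j]| <= max_gap + 1.
# Returns a canonical list of sorted rank vectors, sorted by first element.
oracle_components <- function(ranks, max_gap) {
  n <- length(ranks)
  if (n == 0) return(list())
  adj <- abs(outer(ranks, ranks, "-")) <= max_gap + 1
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  out <- unname(lapply(split(ranks, comp), function(r) sort(unname(r))))
  out[order(vapply(out, `[`, numeric(1), 1))]
}

# Two-sided Welch t-test p-value straight from the Welch-Satterthwaite
# formula.
oracle_welch_p <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(tstat), df)
}

# Percentile by definition: share of groups with strictly smaller count.
oracle_percentile <- function(counts) {
  vapply(counts, function(x) 100 * sum(counts < x) / length(counts),
         numeric(1))
}

# Minimal candidate tibble for cluster-caller tests: one strain, one
# (pathway, sub), given ranks (optionally component ids / replicons).
make_candidates <- function(ranks,
                            components = paste0("c", seq_along(ranks)),
                            replicons = rep("rep1", length(ranks)),
                            strain = "s1", pathway = "pw", sub = "sub") {
  tibble::tibble(
    strain_id = strain, pathway_id = pathway, sub_id = sub,
    component_id = components,
    gene_id = paste0("g", seq_along(ranks)),
    protein_id = paste0("p", seq_along(ranks)),
    replicon_id = replicons,
    rank = as.integer(ranks),
    start = as.integer(ranks) * 1000L + 1L,
    end = as.integer(ranks) * 1000L + 900L,
    strand = "+",
    best_evalue = 1e-10, fused = FALSE
  )
}

# Gene table on one replicon with n genes at consecutive ranks.
make_genes <- function(n, replicon = "rep1", strain = "s1") {
  tibble::tibble(
    gene_id = sprintf("%s_g%03d", strain, seq_len(n)),
    protein_id = sprintf("%s_p%03d", strain, seq_len(n)),
    replicon_id = replicon,
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = "+",
    rank = seq_len(n) - 1L
  )
}

# Domain hits placing the given domains on the given proteins, all passing
# the default E-value gate.
make_hits <- function(protein_ids, domain_ids, evalue = 1e-10) {
  tibble::tibble(protein_id = protein_ids, domain_id = domain_ids,
                 evalue = evalue, bitscore = 100)
}
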