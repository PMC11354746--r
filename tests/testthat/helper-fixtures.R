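# shared fixtures and independent oracles, built in code

make_aln <- function(seqs, groups = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  g <- if (is.null(groups)) NULL else stats::setNames(groups, names(seqs))
  cr_alignment(seqs, groups = g)
}

write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# brute-force p-distance with pairwise deletion, independent of pair_counts
oracle_p <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[ok] != b[ok]) / sum(ok)
}

# Kimura 2-parameter closed form (independent route for the theta = 0.5 limit)
oracle_k2p <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

# all spanning trees of a small weighted complete graph, by brute force
oracle_mst_edges <- function(D) {
  n <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  m <- nrow(pairs)
  best_w <- Inf; best <- list()
  for (comb in utils::combn(m, n - 1, simplify = FALSE)) {
    uf <- seq_len(n)
    find <- function(i) { while (uf[i] != i) i <- uf[i]; i }
    ok <- TRUE
    for (e in comb) {
      ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
      if (ri == rj) { ok <- FALSE; break }
      uf[ri] <- rj
    }
    if (!ok) next
    w <- sum(D[pairs[comb, , drop = FALSE]])
    if (w < best_w - 1e-9) { best_w <- w; best <- list(comb) }
    else if (abs(w - best_w) < 1e-9) best <- c(best, list(comb))
  }
  # union of edges over all MSTs, as "i-j" keys
  unique(unlist(lapply(best, function(comb) {
    apply(pairs[comb, , drop = FALSE], 1, function(p)
      paste(min(p), max(p), sep = "-"))
  })))
}

random_seqs <- function(n, L, seed) {
  set.seed(seed)
  replicate(n, paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""))
}
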