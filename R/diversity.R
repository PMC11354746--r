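#' Nucleotide diversity of a sample
#'
#' pi is the mean uncorrected pairwise difference (p-distance, pairwise
#' deletion of missing sites) over all n(n-1)/2 unordered pairs of
#' individuals. All samples are used, including identical haplotypes —
#' duplicated haplotypes carry real frequency information here, unlike in
#' lineage-level distance comparisons.
#'
#' @param aln a [cr_alignment()].
#' @param samples optional subset of sample ids.
#' @return pi as a per-site fraction.
#' @export
nuc_diversity <- function(aln, samples = NULL) {
  if (!is.null(samples)) aln <- aln_subset(aln, samples)
  n <- length(aln$ids)
  if (n < 2L) stop("degenerate input: pi needs >= 2 samples", call. = FALSE)
  D <- cr_dist(aln, metric = "p")
  mean(D[upper.tri(D)])
}

# mean p-distance over all cross pairs of two id sets
mean_between <- function(D, ids1, ids2) mean(D[ids1, ids2, drop = FALSE])

#' Decompose nucleotide diversity within and among groups
#'
#' Splits total diversity into its within- and among-population parts
#' using equal group weights w_i = 1/s:
#' pi_S = (1/s) * sum_i pi_i (mean within-group diversity);
#' pi_T = sum_i sum_j w_i w_j pi_ij (total diversity, with pi_ii = pi_i and
#' pi_ij the mean between-group pairwise difference);
#' delta_ST = pi_T - pi_S (mean interpopulation diversity); and
#' N_ST = delta_ST / pi_T, the coefficient of differentiation — the
#' proportion of the total diversity attributable to differences among
#' groups. All reported diversities are multiplied by 100; N_ST is a
#' percentage. Standard errors come from column bootstrap.
#'
#' @param aln a [cr_alignment()] (all samples, duplicates included).
#' @param partition named character vector id -> group; defaults to the
#'   alignment's stored groups. Needs >= 2 groups, each with >= 2 members.
#' @param bootstrap bootstrap replicates for SEs (default 100; 0 = none).
#' @param seed RNG seed, required when `bootstrap > 0`.
#' @return class `diversity_decomposition`: `pi_per_group`, `pi_S`, `pi_T`,
#'   `delta_ST` (all x100), `N_ST` (percent), matching `se_*` fields,
#'   `groups`, `replicates`.
#' @export
decompose_diversity <- function(aln, partition = NULL, bootstrap = 100L,
                                seed = NULL) {
  if (is.null(partition)) partition <- aln$groups
  if (is.null(partition)) stop("no group assignment available", call. = FALSE)
  partition <- partition[names(partition) %in% aln$ids]
  gl <- unique(partition)
  s <- length(gl)
  if (s < 2L) stop("degenerate partition: need >= 2 groups", call. = FALSE)
  sizes <- table(partition)
  if (any(sizes < 2L)) {
    stop("degenerate partition: every group needs >= 2 members (offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")", call. = FALSE)
  }
  core <- function(a) {
    D <- cr_dist(a, metric = "p")
    ids <- split(names(partition), partition)[gl]
    pi_i <- vapply(ids, function(m) {
      sub <- D[m, m, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    w <- 1 / s
    pi_T <- 0
    for (i in seq_len(s)) {
      for (j in seq_len(s)) {
        pij <- if (i == j) pi_i[[i]] else mean_between(D, ids[[i]], ids[[j]])
        pi_T <- pi_T + w * w * pij
      }
    }
    pi_S <- mean(pi_i)
    c(pi_i, pi_S = pi_S, pi_T = pi_T, delta_ST = pi_T - pi_S,
      N_ST = if (pi_T > 0) (pi_T - pi_S) / pi_T else 0)
  }
  est <- core(aln)
  k <- length(est)
  ses <- rep(NA_real_, k)
  if (bootstrap > 0L) {
    if (is.null(seed)) stop("bootstrap requires an explicit seed", call. = FALSE)
    L <- aln$length
    reps <- withr_seed(seed, {
      vapply(seq_len(bootstrap), function(r) {
        cols <- sample.int(L, L, replace = TRUE)
        core(cr_alignment(aln$mat[, cols, drop = FALSE], ids = aln$ids,
                          groups = aln$groups))
      }, numeric(k))
    })
    ses <- apply(reps, 1L, stats::sd)
  }
  names(ses) <- names(est)
  structure(
    list(groups = gl,
         pi_per_group = est[seq_len(s)] * 100,
         pi_S = unname(est["pi_S"]) * 100,
         pi_T = unname(est["pi_T"]) * 100,
         delta_ST = unname(est["delta_ST"]) * 100,
         N_ST = unname(est["N_ST"]) * 100,
         se_pi_per_group = ses[seq_len(s)] * 100,
         se_pi_S = unname(ses["pi_S"]) * 100,
         se_pi_T = unname(ses["pi_T"]) * 100,
         se_delta_ST = unname(ses["delta_ST"]) * 100,
         se_N_ST = unname(ses["N_ST"]) * 100,
         replicates = if (bootstrap > 0L) as.integer(bootstrap) else 0L),
    class = "diversity_decomposition"
  )
}

#' @export
print.diversity_decomposition <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.na(se)) sprintf("%.3g", v) else sprintf("%.3g ± %.2g", v, se)
  }
  cat("Nucleotide diversity decomposition (values x100):\n")
  for (i in seq_along(x$groups)) {
    cat("  pi(", x$groups[i], ") = ",
        fmt(x$pi_per_group[i], x$se_pi_per_group[i]), "\n", sep = "")
  }
  cat("  pi_S =", fmt(x$pi_S, x$se_pi_S), "\n")
  cat("  pi_T =", fmt(x$pi_T, x$se_pi_T), "\n")
  cat("  delta_ST =", fmt(x$delta_ST, x$se_delta_ST), "\n")
  cat("  N_ST (%) =", fmt(x$N_ST, x$se_N_ST), "\n")
  invisible(x)
}

#' Pairwise-group diversity/differentiation matrix
#'
#' For every unordered pair of groups, runs a two-group
#' [decompose_diversity()] and assembles the conventional square layout:
#' within-group pi on the diagonal, the pair's total diversity pi_T above
#' the diagonal, and the coefficient of differentiation N_ST (%) below it.
#'
#' @inheritParams decompose_diversity
#' @return a list with numeric matrices `estimate` and `se`, plus
#'   `groups`; class `nst_matrix`.
#' @export
nst_matrix <- function(aln, partition = NULL, bootstrap = 100L, seed = NULL) {
  if (is.null(partition)) partition <- aln$groups
  if (is.null(partition)) stop("no group assignment available", call. = FALSE)
  partition <- partition[names(partition) %in% aln$ids]
  gl <- unique(partition)
  s <- length(gl)
  if (s < 2L) stop("need >= 2 groups", call. = FALSE)
  est <- matrix(NA_real_, s, s, dimnames = list(gl, gl))
  se <- est
  for (i in seq_len(s - 1L)) {
    for (j in (i + 1L):s) {
      pair_ids <- names(partition)[partition %in% gl[c(i, j)]]
      sub <- aln_subset(aln, pair_ids)
      dec <- decompose_diversity(sub, partition[pair_ids],
                                 bootstrap = bootstrap,
                                 seed = if (is.null(seed)) NULL else
                                   seed + i * s + j)
      est[gl[i], gl[i]] <- dec$pi_per_group[gl[i]]
      est[gl[j], gl[j]] <- dec$pi_per_group[gl[j]]
      se[gl[i], gl[i]] <- dec$se_pi_per_group[gl[i]]
      se[gl[j], gl[j]] <- dec$se_pi_per_group[gl[j]]
      est[gl[i], gl[j]] <- dec$pi_T        # above diagonal
      se[gl[i], gl[j]] <- dec$se_pi_T
      est[gl[j], gl[i]] <- dec$N_ST        # below diagonal
      se[gl[j], gl[i]] <- dec$se_N_ST
    }
  }
  structure(list(estimate = est, se = se, groups = gl), class = "nst_matrix")
}

#' @export
print.nst_matrix <- function(x, ...) {
  cat("Diversity matrix (diagonal: pi x100; above: pi_T x100; below: N_ST %):\n")
  print(round(x$estimate, 3))
  invisible(x)
}

#' Write an [nst_matrix()] as TSV
#' @param x an `nst_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nst_matrix <- function(x, path) {
  fmt <- ifelse(is.na(x$se), sprintf("%.3g", x$estimate),
                sprintf("%.3g ± %.2g", x$estimate, x$se))
  out <- matrix(fmt, nrow(x$estimate), dimnames = dimnames(x$estimate))
  utils::write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
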