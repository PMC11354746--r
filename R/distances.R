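# transition lookup: A<->G, C<->T
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Per-pair site counts feeding the distance formulas
#'
#' For two aligned sequences, counts compared sites n (sites where both
#' carry an unambiguous base), transition differences, transversion
#' differences, and estimates the G+C fraction theta over the compared
#' sites of both sequences; h = 2*theta*(1-theta) is the G+C heterozygosity
#' term of the Tamura 3-parameter correction.
#'
#' @param seq1,seq2 aligned sequences of equal length (strings or character
#'   vectors of bases).
#' @return class `pair_counts`: `n`, `n_ts`, `n_tv`, `P` (= n_ts/n),
#'   `Q` (= n_tv/n), `theta`, `h`.
#' @export
pair_counts <- function(seq1, seq2) {
  a <- if (length(seq1) == 1L) strsplit(toupper(seq1), "")[[1L]] else toupper(seq1)
  b <- if (length(seq2) == 1L) strsplit(toupper(seq2), "")[[1L]] else toupper(seq2)
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  ok <- a %in% BASES & b %in% BASES
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the pair", call. = FALSE)
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  n_ts <- sum(diff & is_transition(a, b))
  n_tv <- sum(diff) - n_ts
  gc <- sum(a %in% c("G", "C")) + sum(b %in% c("G", "C"))
  theta <- gc / (2 * n)
  structure(list(n = n, n_ts = n_ts, n_tv = n_tv,
                 P = n_ts / n, Q = n_tv / n,
                 theta = theta, h = 2 * theta * (1 - theta)),
            class = "pair_counts")
}

#' Uncorrected p-distance from pair counts
#' @param counts a [pair_counts()] object.
#' @return proportion of differing sites (fraction, not percent).
#' @export
p_distance <- function(counts) counts$P + counts$Q

#' Tamura 3-parameter distance from pair counts
#'
#' Corrects the observed proportions of transitions (P) and transversions
#' (Q) for multiple hits while accounting for G+C-content bias:
#' d = -h*ln(1 - P/h - Q) - (1/2)(1-h)*ln(1 - 2Q), with h = 2*theta*(1-theta)
#' estimated from the compared sites of the pair. At theta = 0.5 (h = 0.5)
#' the formula reduces to the Kimura 2-parameter distance. The model
#' assumes equal substitution rates among sites.
#'
#' @param counts a [pair_counts()] object.
#' @return distance in substitutions per site.
#' @export
t3p_distance <- function(counts) {
  h <- counts$h
  arg1 <- 1 - counts$P / h - counts$Q
  arg2 <- 1 - 2 * counts$Q
  if (!is.finite(arg1) || arg1 <= 0 || arg2 <= 0) {
    stop("saturation error: T3P distance undefined for this pair (P=",
         signif(counts$P, 3), ", Q=", signif(counts$Q, 3), ", h=",
         signif(h, 3), ")", call. = FALSE)
  }
  -h * log(arg1) - 0.5 * (1 - h) * log(arg2)
}

#' Pairwise distance matrix
#'
#' @param aln a [cr_alignment()] (or `haplotype_set`, used via its unique
#'   haplotypes).
#' @param metric `"p"` (uncorrected) or `"t3p"` (Tamura 3-parameter).
#' @param deletion `"pairwise"` (default; sites with missing data dropped
#'   per pair) or `"complete"` (columns with any gap/'N'/ambiguity dropped
#'   once for all pairs).
#' @return symmetric numeric matrix of distances (fractions); saturated
#'   pairs (T3P log-domain failures) are `NA` with a warning.
#' @export
cr_dist <- function(aln, metric = c("p", "t3p"),
                    deletion = c("pairwise", "complete")) {
  metric <- match.arg(metric)
  deletion <- match.arg(deletion)
  if (inherits(aln, "haplotype_set")) aln <- haplotype_alignment(aln)
  mat <- aln$mat
  if (deletion == "complete") {
    keep <- apply(mat, 2L, function(col) all(col %in% BASES))
    if (!any(keep)) stop("complete deletion removed every column", call. = FALSE)
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  n_sat <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pc <- pair_counts(mat[i, ], mat[j, ])
      d <- if (metric == "p") p_distance(pc) else
        tryCatch(t3p_distance(pc), error = function(e) NA_real_)
      if (is.na(d)) n_sat <- n_sat + 1L
      D[i, j] <- D[j, i] <- d
    }
  }
  if (n_sat > 0L) {
    warning(n_sat, " saturated pair(s) excluded (T3P undefined)", call. = FALSE)
  }
  attr(D, "n_saturated") <- n_sat
  D
}

#' Mean within- or between-group distance with bootstrap SE
#'
#' Within-group: mean over all unordered pairs inside one group.
#' Between-group: mean over all cross pairs of two groups. When a
#' `haplotype_set` is supplied the mean is taken over unique haplotypes
#' (the convention for lineage-level divergence, where repeated identical
#' sequences would deflate the mean); pass the full alignment to average
#' over all samples. Standard errors come from resampling alignment
#' columns with replacement (see [bootstrap_se()]).
#'
#' @param x a [cr_alignment()] or `haplotype_set`.
#' @param partition named character vector id -> group; defaults to the
#'   groups stored in `x`.
#' @param metric `"p"` or `"t3p"`.
#' @param scope `"within"` or `"between"`.
#' @param groups for `"within"`, one group label; for `"between"`, two.
#' @param deletion passed to [cr_dist()].
#' @param bootstrap number of bootstrap replicates for the SE (0 = no SE;
#'   100 is the conventional default for distance tables).
#' @param seed RNG seed, required when `bootstrap > 0`.
#' @return class `distance_summary`: `metric`, `scope`, `groups`, `mean`
#'   and `se` in percent, `n_pairs`, `n_saturated`, `replicates`.
#' @export
group_mean_distance <- function(x, partition = NULL,
                                metric = c("p", "t3p"),
                                scope = c("within", "between"),
                                groups = NULL,
                                deletion = c("pairwise", "complete"),
                                bootstrap = 0L, seed = NULL) {
  metric <- match.arg(metric)
  scope <- match.arg(scope)
  deletion <- match.arg(deletion)
  aln <- if (inherits(x, "haplotype_set")) haplotype_alignment(x) else x
  if (is.null(partition)) partition <- aln$groups
  if (is.null(partition)) stop("no group assignment available", call. = FALSE)
  if (is.null(groups)) {
    groups <- if (scope == "within") unique(partition)[1L] else
      utils::head(unique(partition), 2L)
  }
  if (scope == "within" && length(groups) != 1L) {
    stop("within-group scope takes exactly one group", call. = FALSE)
  }
  if (scope == "between" && length(groups) != 2L) {
    stop("between-group scope takes exactly two groups", call. = FALSE)
  }
  ids_of <- function(g) names(partition)[partition == g & names(partition) %in% aln$ids]
  stat <- function(a) {
    D <- suppressWarnings(cr_dist(a, metric = metric, deletion = deletion))
    if (scope == "within") {
      m <- ids_of(groups)
      if (length(m) < 2L) stop("within-group scope needs >= 2 members", call. = FALSE)
      sub <- D[m, m, drop = FALSE]
      vals <- sub[upper.tri(sub)]
    } else {
      a1 <- ids_of(groups[1L]); a2 <- ids_of(groups[2L])
      if (length(a1) == 0L || length(a2) == 0L) {
        stop("degenerate partition: empty group in between-group scope",
             call. = FALSE)
      }
      vals <- as.vector(D[a1, a2, drop = FALSE])
    }
    list(mean = mean(vals, na.rm = TRUE), n_pairs = length(vals),
         n_sat = sum(is.na(vals)))
  }
  base <- stat(aln)
  se <- NA_real_
  if (bootstrap > 0L) {
    se <- bootstrap_se(function(a) stat(a)$mean, aln,
                       replicates = bootstrap, seed = seed) * 100
  }
  structure(
    list(metric = metric, scope = scope, groups = groups,
         mean = base$mean * 100, se = se,
         n_pairs = base$n_pairs, n_saturated = base$n_sat,
         replicates = if (bootstrap > 0L) as.integer(bootstrap) else 0L),
    class = "distance_summary"
  )
}

#' @export
print.distance_summary <- function(x, ...) {
  lab <- paste(x$groups, collapse = " / ")
  se_txt <- if (is.na(x$se)) "" else paste0(" ± ", signif(x$se, 3))
  cat(sprintf("%s %s-group distance (%s): %.3f%s %% over %d pairs\n",
              toupper(x$metric), x$scope, lab, x$mean, se_txt, x$n_pairs))
  if (x$n_saturated > 0L) cat("  (", x$n_saturated, "saturated pairs excluded )\n")
  invisible(x)
}

#' Bootstrap standard error by resampling alignment columns
#'
#' Resamples alignment columns with replacement (keeping the original
#' length), recomputes the statistic on each replicate alignment, and
#' returns the standard deviation across replicates.
#'
#' @param statistic function taking a [cr_alignment()] and returning a
#'   single number.
#' @param aln a [cr_alignment()].
#' @param replicates number of bootstrap replicates (>= 2; default 100).
#' @param seed RNG seed (required, for reproducibility).
#' @return the bootstrap SE (same units as `statistic`).
#' @export
bootstrap_se <- function(statistic, aln, replicates = 100L, seed = NULL) {
  if (replicates < 2L) stop("bootstrap needs >= 2 replicates", call. = FALSE)
  if (is.null(seed)) stop("bootstrap requires an explicit seed", call. = FALSE)
  L <- aln$length
  vals <- withr_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- cr_alignment(aln$mat[, cols, drop = FALSE],
                              ids = aln$ids, groups = aln$groups)
      tryCatch(statistic(rep_aln), error = function(e) NA_real_)
    }, numeric(1))
  })
  if (mean(is.na(vals)) > 0.5) {
    stop("unstable estimate: statistic undefined in >50% of bootstrap replicates",
         call. = FALSE)
  }
  stats::sd(vals, na.rm = TRUE)
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Substitution rate ratio between two linked markers
#'
#' For the same taxon split, the ratio k of the mean corrected distance of
#' one marker (e.g. the control region) to another (e.g. COI) measures
#' their relative apparent substitution rates; under clock-like behaviour
#' of both markers k should stay constant across splits, and a rising k
#' with divergence depth signals saturation of the slower marker.
#'
#' @param d_num,d_den `distance_summary` objects (or plain numbers, in
#'   percent) for the numerator and denominator marker at the same split.
#' @return k (dimensionless).
#' @export
rate_ratio <- function(d_num, d_den) {
  num <- if (inherits(d_num, "distance_summary")) d_num$mean else as.numeric(d_num)
  den <- if (inherits(d_den, "distance_summary")) d_den$mean else as.numeric(d_den)
  if (den == 0) stop("division error: denominator distance is zero", call. = FALSE)
  num / den
}
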