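# Sequence simulator used to validate every analysis stage against known
# truth. The mutation process is the reversible 4-state chain that the
# Tamura 3-parameter distance is designed to invert: stationary
# frequencies gc/2 for G and C and (1-gc)/2 for A and T, with transitions
# (A<->G, C<->T) accelerated by a factor kappa relative to transversions.

# rate matrix scaled to one expected substitution per site per unit time
t92_rate_matrix <- function(theta_gc, kappa) {
  pi <- c(A = (1 - theta_gc) / 2, C = theta_gc / 2,
          G = theta_gc / 2, T = (1 - theta_gc) / 2)
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in BASES) {
    for (j in BASES) {
      if (i == j) next
      Q[i, j] <- pi[j] * if (is_transition(i, j)) kappa else 1
    }
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# transition probability matrix P(t) = expm(Q t) via eigendecomposition
t92_pmatrix <- function(Q, t) {
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

# evolve a base vector for branch length t (expected substitutions/site);
# positions where mutable is FALSE are copied unchanged
evolve_seq <- function(seq, Q, t, mutable = NULL) {
  if (t <= 0) return(seq)
  P <- t92_pmatrix(Q, t)
  out <- seq
  idx <- if (is.null(mutable)) seq_along(seq) else which(mutable)
  for (b in BASES) {
    at <- idx[seq[idx] == b]
    if (length(at) > 0L) {
      out[at] <- sample(BASES, length(at), replace = TRUE, prob = P[b, ])
    }
  }
  out
}

draw_root <- function(L, theta_gc) {
  sample(BASES, L, replace = TRUE,
         prob = c((1 - theta_gc) / 2, theta_gc / 2,
                  theta_gc / 2, (1 - theta_gc) / 2))
}

#' Simulate a grouped alignment with known divergence structure
#'
#' Emulates the population structure the control-region analyses assume:
#' haplogroups descended from a common ancestor, with a target between-group
#' tip-to-tip divergence, star-like within-group genealogies, G+C-content
#' bias and transition/transversion bias, and optional mitochondrial
#' introgression (a fraction of one group's samples carrying haplotypes
#' generated from another group's ancestor). Branch lengths are chosen so
#' that the expected within-group pairwise divergence is `within_div` and
#' the expected between-group pairwise divergence is `between_div`
#' (root-to-ancestor branches of (between_div - within_div)/2, ancestor-
#' to-tip branches of within_div/2).
#'
#' @param n_groups number of haplogroups (default 2).
#' @param samples_per_group samples per group (default 10; recycled).
#' @param seq_length alignment length in bp (default 691, a control-region
#'   plus flanking-tRNA sized fragment).
#' @param theta_gc stationary G+C fraction (default 0.154, i.e. 84.6% A+T
#'   as in gomphocerine control regions).
#' @param kappa transition/transversion rate ratio (default 4).
#' @param within_div expected within-group pairwise divergence,
#'   substitutions/site (default 0.004).
#' @param between_div expected between-group pairwise divergence (default
#'   0.05; must be >= `within_div`).
#' @param introgression optional list(donor=, recipient=, fraction=):
#'   that fraction of the recipient group's samples receive haplotypes
#'   simulated from the donor group's ancestor.
#' @param star_like if TRUE (default) tips radiate independently from the
#'   group ancestor (star genealogy).
#' @param conserved_mask optional logical vector of length `seq_length`;
#'   FALSE positions are mutation-suppressed (used for control-region
#'   structural simulations).
#' @param root optional ancestral sequence (character vector) to use
#'   instead of a random stationary draw.
#' @param seed RNG seed (required).
#' @return list with `alignment` (a [cr_alignment()] with groups
#'   `g1..gK`) and `truth` (config, expected within/between divergence,
#'   introgressed sample ids, root sequence).
#' @export
simulate_alignment <- function(n_groups = 2L, samples_per_group = 10L,
                               seq_length = 691L, theta_gc = 0.154,
                               kappa = 4, within_div = 0.004,
                               between_div = 0.05, introgression = NULL,
                               star_like = TRUE, conserved_mask = NULL,
                               root = NULL, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (within_div < 0 || between_div < 0 || between_div >= 0.75) {
    stop("parameter error: divergences must lie in [0, 0.75)", call. = FALSE)
  }
  if (between_div < within_div) {
    stop("parameter error: between_div must be >= within_div", call. = FALSE)
  }
  nper <- rep_len(as.integer(samples_per_group), n_groups)
  Q <- t92_rate_matrix(theta_gc, kappa)
  mutable <- if (is.null(conserved_mask)) NULL else conserved_mask
  withr_seed(seed, {
    anc <- if (is.null(root)) draw_root(seq_length, theta_gc) else {
      r <- if (length(root) == 1L) strsplit(toupper(root), "")[[1L]] else root
      stopifnot(length(r) == seq_length)
      r
    }
    t_anc <- (between_div - within_div) / 2
    t_tip <- within_div / 2
    group_anc <- lapply(seq_len(n_groups), function(g) {
      evolve_seq(anc, Q, t_anc, mutable)
    })
    as_group_idx <- function(x) {
      if (is.character(x)) as.integer(sub("^g", "", x)) else as.integer(x)
    }
    seqs <- character(0); ids <- character(0); grps <- character(0)
    introgressed <- character(0)
    for (g in seq_len(n_groups)) {
      glab <- paste0("g", g)
      donor_idx <- rep(g, nper[g])
      if (!is.null(introgression) &&
          as_group_idx(introgression$recipient) == g) {
        k <- round(introgression$fraction * nper[g])
        if (k > 0L) donor_idx[seq_len(k)] <- as_group_idx(introgression$donor)
      }
      prev_tips <- list()
      for (s in seq_len(nper[g])) {
        src <- group_anc[[donor_idx[s]]]
        # non-star genealogies chain each tip off a random earlier tip of
        # the same source lineage, giving correlated within-group structure
        if (!star_like && length(prev_tips) > 0L && donor_idx[s] == g) {
          src <- prev_tips[[sample.int(length(prev_tips), 1L)]]
        }
        tip <- evolve_seq(src, Q, t_tip, mutable)
        if (donor_idx[s] == g) prev_tips[[length(prev_tips) + 1L]] <- tip
        id <- paste0(glab, "_s", s)
        if (donor_idx[s] != g) introgressed <- c(introgressed, id)
        seqs <- c(seqs, paste(tip, collapse = ""))
        ids <- c(ids, id); grps <- c(grps, glab)
      }
    }
    aln <- cr_alignment(seqs, ids = ids,
                        groups = stats::setNames(grps, ids))
    list(alignment = aln,
         truth = list(n_groups = n_groups, samples_per_group = nper,
                      seq_length = seq_length, theta_gc = theta_gc,
                      kappa = kappa, within_div = within_div,
                      between_div = between_div,
                      introgressed = introgressed,
                      root = paste(anc, collapse = ""), seed = seed))
  })
}

#' Simulate a control-region-like sequence with annotated features
#'
#' Builds a single A+T-rich sequence carrying the structural features the
#' detectors target: evenly spaced conserved blocks (to be mutation-
#' suppressed in downstream population simulation) and a poly-T
#' homopolymer of configurable length near the 3' end, mirroring the
#' T-stretch at the control region / trnI border.
#'
#' @param length sequence length in bp (default 728, a full control-region
#'   length).
#' @param at_content background A+T fraction (default 0.846).
#' @param t_stretch_len poly-T length, 7..11 (default 9).
#' @param n_blocks number of conserved blocks (default 6).
#' @param block_len conserved-block length in bp (default 30).
#' @param seed RNG seed (required).
#' @return list: `seq` (character string), `features` (data frame:
#'   feature, start, end), `mutable` (logical vector; FALSE inside
#'   conserved blocks and the T-stretch).
#' @export
simulate_cr_structure <- function(length = 728L, at_content = 0.846,
                                  t_stretch_len = 9L, n_blocks = 6L,
                                  block_len = 30L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (t_stretch_len < 7L || t_stretch_len > 11L) {
    stop("parameter error: t_stretch_len must be in 7..11", call. = FALSE)
  }
  need <- n_blocks * block_len + t_stretch_len + 2L
  if (length < need + n_blocks) {
    stop("parameter error: features do not fit in ", length, " bp", call. = FALSE)
  }
  withr_seed(seed, {
    gc <- 1 - at_content
    s <- sample(BASES, length, replace = TRUE,
                prob = c(at_content / 2, gc / 2, gc / 2, at_content / 2))
    mutable <- rep(TRUE, length)
    feats <- data.frame(feature = character(0), start = integer(0),
                        end = integer(0))
    # conserved blocks spread over the first ~85% of the sequence
    usable <- floor(length * 0.85)
    gap <- floor((usable - n_blocks * block_len) / (n_blocks + 1L))
    pos <- gap
    for (b in seq_len(n_blocks)) {
      st <- pos + 1L; en <- st + block_len - 1L
      mutable[st:en] <- FALSE
      feats <- rbind(feats, data.frame(
        feature = paste0("CSB", b), start = st, end = en))
      pos <- en + gap
    }
    # T-stretch flanked by purines near the 3' end
    t_end <- length - 1L
    t_start <- t_end - t_stretch_len + 1L
    s[(t_start - 1L)] <- "A"                 # flanking purine
    s[t_start:t_end] <- "T"
    s[length] <- "G"                         # flanking purine
    # no stray T runs >= 7 elsewhere: break any background run
    outside <- setdiff(seq_len(length), t_start:t_end)
    r <- rle(s == "T" & seq_along(s) %in% outside)
    # (background draws at p(T)~0.42 rarely reach 7; break them anyway)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 7L)) {
      s[seq.int(starts[k] + 3L, ends[k], by = 4L)] <- "A"
    }
    mutable[t_start:t_end] <- FALSE
    feats <- rbind(feats, data.frame(feature = "T-stretch",
                                     start = t_start, end = t_end))
    list(seq = paste(s, collapse = ""), features = feats, mutable = mutable)
  })
}

#' Simulate a population sample over a structured control region
#'
#' Evolves `n` sequences from the structural template of
#' [simulate_cr_structure()], suppressing mutation inside conserved blocks
#' and the T-stretch, so that sliding-window and block detectors can be
#' validated by round trip.
#'
#' @param structure output of [simulate_cr_structure()].
#' @param n number of samples (default 20).
#' @param divergence expected pairwise divergence among samples (default
#'   0.05), substitutions/site over mutable positions.
#' @param theta_gc,kappa mutation-process parameters (see
#'   [simulate_alignment()]).
#' @param seed RNG seed (required).
#' @return a [cr_alignment()].
#' @export
simulate_cr_population <- function(structure, n = 20L, divergence = 0.05,
                                   theta_gc = 0.154, kappa = 4, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  L <- nchar(structure$seq)
  sim <- simulate_alignment(
    n_groups = 1L, samples_per_group = n, seq_length = L,
    theta_gc = theta_gc, kappa = kappa,
    within_div = divergence, between_div = divergence,
    conserved_mask = structure$mutable, root = structure$seq, seed = seed)
  sim$alignment
}
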