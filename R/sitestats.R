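# per-column counts of unambiguous bases; gaps/N/ambiguity never count
column_base_counts <- function(mat) {
  vapply(BASES, function(b) colSums(mat == b), numeric(ncol(mat)))
}

#' Classify alignment columns as segregating / parsimony-informative
#'
#' A site is segregating (S) when at least two distinct unambiguous bases
#' occur among its non-missing characters, and parsimony-informative (PIS)
#' when at least two distinct bases each occur in at least two sequences.
#' Gaps, 'N' and ambiguity codes never make a site segregating on their own.
#'
#' @param aln a [cr_alignment()].
#' @param missing_rule `"pairwise"` (default; every column is classified on
#'   its non-missing characters) or `"exclude-gap-columns"` (columns
#'   containing any gap/'N'/ambiguity are excluded from S and PIS entirely).
#' @return class `site_classification`: `S`, `PIS`, `positions_S`,
#'   `positions_PIS`, `singletons` (segregating but not informative),
#'   `excluded` (columns dropped by the missing rule), `length`.
#' @examples
#' aln <- cr_alignment(c("ACGT", "ACGA", "ACGA", "TCGA"))
#' classify_sites(aln)$S   # 2
#' @export
classify_sites <- function(aln,
                           missing_rule = c("pairwise", "exclude-gap-columns")) {
  missing_rule <- match.arg(missing_rule)
  if (length(aln$ids) < 2L) {
    stop("degenerate input: site classification needs >= 2 sequences",
         call. = FALSE)
  }
  mat <- aln$mat
  cc <- column_base_counts(mat)        # L x 4
  if (is.null(dim(cc))) cc <- matrix(cc, nrow = 1L)
  excluded <- integer(0)
  if (missing_rule == "exclude-gap-columns") {
    excluded <- which(rowSums(cc) < nrow(mat))
  }
  n_distinct <- rowSums(cc > 0L)
  n_ge2 <- rowSums(cc >= 2L)
  seg <- n_distinct >= 2L
  pis <- seg & n_ge2 >= 2L
  if (length(excluded) > 0L) {
    seg[excluded] <- FALSE
    pis[excluded] <- FALSE
  }
  structure(
    list(S = sum(seg), PIS = sum(pis),
         positions_S = which(seg), positions_PIS = which(pis),
         singletons = which(seg & !pis),
         excluded = excluded, length = aln$length),
    class = "site_classification"
  )
}

#' @export
print.site_classification <- function(x, ...) {
  cat("Sites:", x$length, "bp; S =", x$S, "; PIS =", x$PIS, "\n")
  invisible(x)
}

#' Sliding-window profile of segregating sites
#'
#' Counts segregating sites (Ss) in windows of `window` bp moved in steps
#' of `step` bp across the alignment — the standard way to visualise where
#' variable regions alternate with conserved sequence blocks along the
#' mitochondrial control region.
#'
#' @param aln a [cr_alignment()].
#' @param window window width in bp (default 40).
#' @param step step in bp (default 1).
#' @return class `window_profile`: `starts` (1-based window starts),
#'   `values` (Ss per window), `window`, `step`.
#' @export
sliding_window_Ss <- function(aln, window = 40L, step = 1L) {
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("window and step must be >= 1", call. = FALSE)
  if (window > aln$length) {
    stop("parameter error: window (", window, ") exceeds alignment length (",
         aln$length, ")", call. = FALSE)
  }
  seg <- integer(aln$length)
  seg[classify_sites(aln)$positions_S] <- 1L
  cs <- c(0L, cumsum(seg))
  starts <- seq.int(1L, aln$length - window + 1L, by = step)
  values <- cs[starts + window] - cs[starts]
  structure(list(starts = starts, values = values,
                 window = window, step = step),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat("Window profile:", length(x$starts), "windows (width", x$window,
      "bp, step", x$step, "bp); Ss range",
      min(x$values), "-", max(x$values), "\n")
  invisible(x)
}

#' Write a window profile as TSV (start, end, Ss)
#' @param profile a `window_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_profile <- function(profile, path) {
  utils::write.table(
    data.frame(start = profile$starts,
               end = profile$starts + profile$window - 1L,
               Ss = profile$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Find homopolymer runs (e.g. the control-region T-stretch)
#'
#' Reports maximal runs of a single base of at least `min_len` bp. Gaps are
#' stripped before scanning, so positions refer to the ungapped sequence.
#'
#' @param seq a single sequence string (or character vector of bases).
#' @param base the base to scan for (default `"T"`).
#' @param min_len minimum run length (default 7, the lower bound of the
#'   polymorphic poly-T stretch length in gomphocerine control regions).
#' @return data frame with columns `base`, `start` (1-based), `length`.
#' @examples
#' detect_homopolymers("AATTTTTTTTGA")   # one 8-bp T run at position 3
#' @export
detect_homopolymers <- function(seq, base = "T", min_len = 7L) {
  v <- if (length(seq) == 1L) strsplit(toupper(seq), "")[[1L]] else toupper(seq)
  v <- v[v != "-"]
  if (length(v) == 0L) {
    return(data.frame(base = character(0), start = integer(0),
                      length = integer(0)))
  }
  r <- rle(v == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= min_len
  data.frame(base = rep(base, sum(hit)), start = starts[hit],
             length = r$lengths[hit])
}

#' Detect conserved blocks from a window profile
#'
#' Conserved sequence blocks (CSBs) appear as maximal runs of consecutive
#' windows whose segregating-site count stays at or below a threshold.
#' Runs are reported as bp spans (first window start to last window end)
#' and kept only when the span is at least `min_block` bp. The default
#' threshold, the 25th percentile of the profile, is a heuristic: published
#' CSB annotations are drawn by eye, so both knobs are exposed.
#'
#' @param profile a `window_profile`.
#' @param threshold maximum Ss for a window to count as conserved; default
#'   the 25th percentile of `profile$values`.
#' @param min_block minimum span in bp (default 20).
#' @return data frame with columns `start`, `end`, `mean_Ss`.
#' @export
detect_conserved_blocks <- function(profile, threshold = NULL,
                                    min_block = 20L) {
  if (length(profile$values) == 0L) stop("empty profile", call. = FALSE)
  if (is.null(threshold)) {
    threshold <- stats::quantile(profile$values, 0.25, names = FALSE)
  }
  low <- profile$values <= threshold
  r <- rle(low)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  out <- data.frame(start = integer(0), end = integer(0), mean_Ss = numeric(0))
  for (k in which(r$values)) {
    i0 <- starts_i[k]; i1 <- ends_i[k]
    span_start <- profile$starts[i0]
    span_end <- profile$starts[i1] + profile$window - 1L
    if (span_end - span_start + 1L >= min_block) {
      out <- rbind(out, data.frame(
        start = span_start, end = span_end,
        mean_Ss = mean(profile$values[i0:i1])))
    }
  }
  out
}

#' Base composition over unambiguous bases
#'
#' Fractions of A, C, G, T with gaps, 'N' and ambiguity codes excluded;
#' the four fractions sum to 1.
#'
#' @param x a [cr_alignment()], a sequence string, or a character vector of
#'   bases.
#' @return named numeric vector `c(A=, C=, G=, T=)`.
#' @export
base_composition <- function(x) {
  v <- if (inherits(x, "cr_alignment")) as.vector(x$mat)
       else if (length(x) == 1L) strsplit(toupper(x), "")[[1L]]
       else toupper(x)
  v <- v[v %in% BASES]
  if (length(v) == 0L) {
    stop("degenerate input: no unambiguous bases", call. = FALSE)
  }
  counts <- table(factor(v, levels = BASES))
  stats::setNames(as.numeric(counts) / length(v), BASES)
}
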