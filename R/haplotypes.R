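#' Collapse an alignment to unique haplotypes
#'
#' Distance comparisons between lineages are made on unique haplotypes so
#' that repeated sampling of a common haplotype does not shrink the mean
#' pairwise distance; diversity statistics, in contrast, use all samples.
#' Two identity rules are offered. `strict` is byte identity on the aligned
#' string (gaps count as characters). `ignore-missing` merges sequences that
#' agree at every site where neither carries a gap, 'N' or ambiguity code;
#' the first-seen sequence becomes the representative.
#'
#' @param aln a [cr_alignment()].
#' @param identity `"strict"` (default) or `"ignore-missing"`.
#' @return an object of class `haplotype_set`: `haplotypes` (named vector of
#'   representative sequence strings), `multiplicity`, `members` (list of
#'   sample ids per haplotype), `H` (number of haplotypes), `length`, and
#'   `groups` carried over from the alignment.
#' @examples
#' aln <- cr_alignment(c(a = "ACGT", b = "ACGT", c = "ACGA"))
#' collapse_haplotypes(aln)$H
#' @export
collapse_haplotypes <- function(aln, identity = c("strict", "ignore-missing")) {
  identity <- match.arg(identity)
  s <- aln_strings(aln)
  if (identity == "strict") {
    keys <- s
    reps <- !duplicated(keys)
    hap_seq <- s[reps]
    assign <- match(keys, hap_seq)
  } else {
    hap_seq <- character(0)
    hap_ids <- character(0)
    assign <- integer(length(s))
    informative <- function(v) !(v %in% c("-", "N", names(IUPAC_AMBIG)))
    for (i in seq_along(s)) {
      v <- aln$mat[i, ]
      ok_i <- informative(v)
      hit <- 0L
      for (h in seq_along(hap_seq)) {
        w <- strsplit(hap_seq[h], "")[[1L]]
        comp <- ok_i & informative(w)
        if (all(v[comp] == w[comp])) { hit <- h; break }
      }
      if (hit == 0L) {
        hap_seq <- c(hap_seq, s[i])
        hap_ids <- c(hap_ids, aln$ids[i])
        hit <- length(hap_seq)
      }
      assign[i] <- hit
    }
    names(hap_seq) <- hap_ids
  }
  members <- split(aln$ids, assign)
  members <- members[order(as.integer(names(members)))]
  names(members) <- names(hap_seq)
  structure(
    list(haplotypes = hap_seq,
         multiplicity = lengths(members),
         members = members,
         H = length(hap_seq),
         length = aln$length,
         groups = aln$groups),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("HaplotypeSet: H =", x$H, "haplotypes from",
      sum(x$multiplicity), "samples,", x$length, "bp\n")
  invisible(x)
}

#' Expand a haplotype set back to one sequence per sample
#'
#' Inverse of [collapse_haplotypes()] under strict identity: each member id
#' receives its haplotype's representative sequence.
#'
#' @param hset a `haplotype_set`.
#' @return a [cr_alignment()].
#' @export
expand_haplotypes <- function(hset) {
  ids <- unlist(hset$members, use.names = FALSE)
  seqs <- rep(unname(hset$haplotypes), hset$multiplicity)
  names(seqs) <- ids
  cr_alignment(seqs, groups = hset$groups)
}

#' Convert a haplotype set to an alignment of its unique sequences
#'
#' Each haplotype contributes one row; the group label of a haplotype is the
#' majority group among its members (ties broken by first occurrence).
#'
#' @param hset a `haplotype_set`.
#' @return a [cr_alignment()] with one row per haplotype.
#' @export
haplotype_alignment <- function(hset) {
  ids <- names(hset$haplotypes)
  g <- NULL
  if (!is.null(hset$groups)) {
    g <- vapply(hset$members, function(m) {
      gm <- hset$groups[m]
      gm <- gm[!is.na(gm)]
      if (length(gm) == 0L) return(NA_character_)
      names(sort(table(gm), decreasing = TRUE))[1L]
    }, "")
    names(g) <- ids
    g <- g[!is.na(g)]
  }
  cr_alignment(unname(hset$haplotypes), ids = ids, groups = g)
}

#' Resolve IUPAC ambiguity codes against the column consensus
#'
#' Direct sequencing of samples carrying nuclear mitochondrial insertions
#' (NUMTs) can yield double peaks recorded as ambiguity codes. Before
#' distance or network analysis these are replaced by the majority
#' unambiguous base of their alignment column (the consensus), either at
#' every site or only at a supplied set of parsimony-informative sites.
#' Ties among majority bases are broken toward the lexicographically
#' smallest base and noted in the resolution log.
#'
#' @param aln a [cr_alignment()].
#' @param mode `"keep"` (no-op), `"consensus"` (replace in-scope ambiguities
#'   by the column consensus), or `"drop"` (remove any sequence that carries
#'   an in-scope ambiguity).
#' @param scope `"all"` sites or `"pis"` (restrict to the sites in `pis`).
#' @param pis 1-based site indices; required when `scope = "pis"`.
#' @return a [cr_alignment()]; attribute `"resolution_log"` is a data frame
#'   of the edits (id, site, from, to, tie).
#' @export
resolve_ambiguities <- function(aln, mode = c("keep", "consensus", "drop"),
                                scope = c("all", "pis"), pis = NULL) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (mode == "keep") return(aln)
  if (scope == "pis") {
    if (is.null(pis)) stop("scope 'pis' requires the pis site list", call. = FALSE)
    if (any(pis < 1L | pis > aln$length)) {
      stop("pis indices out of range 1..", aln$length, call. = FALSE)
    }
    sites <- sort(unique(as.integer(pis)))
  } else {
    sites <- seq_len(aln$length)
  }
  mat <- aln$mat
  ambig <- matrix(FALSE, nrow(mat), ncol(mat))
  ambig[, sites] <- mat[, sites, drop = FALSE] %in% names(IUPAC_AMBIG)
  log <- data.frame(id = character(0), site = integer(0), from = character(0),
                    to = character(0), tie = logical(0))
  if (mode == "drop") {
    drop <- rowSums(ambig) > 0L
    if (all(drop)) stop("drop policy removed every sequence", call. = FALSE)
    kept <- aln$ids[!drop]
    out <- aln_subset(aln, kept)
    attr(out, "resolution_log") <- data.frame(
      id = aln$ids[drop], site = NA_integer_, from = NA_character_,
      to = "dropped", tie = FALSE)
    return(out)
  }
  for (j in sites) {
    rows <- which(ambig[, j])
    if (length(rows) == 0L) next
    col <- mat[, j]
    counts <- table(factor(col[col %in% BASES], levels = BASES))
    if (sum(counts) == 0L) {
      stop("unresolved-site error: column ", j,
           " has no unambiguous base to form a consensus", call. = FALSE)
    }
    top <- names(counts)[counts == max(counts)]
    cons <- sort(top)[1L]   # lexicographic tie-break
    for (i in rows) {
      log <- rbind(log, data.frame(id = aln$ids[i], site = j,
                                   from = mat[i, j], to = cons,
                                   tie = length(top) > 1L))
      mat[i, j] <- cons
    }
  }
  out <- cr_alignment(mat, ids = aln$ids, groups = aln$groups)
  attr(out, "resolution_log") <- log
  out
}

#' Resolve NUMT-driven double-peak records
#'
#' Applies a three-branch rule to records whose chromatograms showed double
#' peaks (coded here as IUPAC ambiguities at annotated sites):
#' (1) keep the alternative states as-is when the record id is listed in
#' `keep_override` (the judgement that the alternatives cause no
#' phylogenetic contradiction is external to this function);
#' (2) if resolving every annotated site toward one reference haplotype is
#' consistent with that haplotype over the whole sequence, remove the
#' alternative nucleotide accordingly;
#' (3) otherwise — no haplotype match, or more than `max_ambiguous` annotated
#' sites — remove the record from the alignment.
#'
#' @param aln a [cr_alignment()].
#' @param double_peaks named list, record id -> integer vector of 1-based
#'   double-peak sites.
#' @param reference_haplotypes a `haplotype_set` of previously identified
#'   haplotypes (see [collapse_haplotypes()]).
#' @param max_ambiguous maximum annotated sites before branch (3) fires
#'   regardless of matching (default 3).
#' @param keep_override record ids forced down branch (1).
#' @return a [cr_alignment()]; attribute `"numt_report"` is a data frame
#'   (id, branch, detail).
#' @export
apply_numt_policy <- function(aln, double_peaks, reference_haplotypes,
                              max_ambiguous = 3L, keep_override = character(0)) {
  unknown <- setdiff(names(double_peaks), aln$ids)
  if (length(unknown) > 0L) {
    stop("double-peak annotation refers to unknown ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mat <- aln$mat
  report <- data.frame(id = character(0), branch = integer(0),
                       detail = character(0))
  drop_ids <- character(0)
  ref_seqs <- reference_haplotypes$haplotypes
  ref_mats <- lapply(ref_seqs, function(s) strsplit(s, "")[[1L]])
  informative <- function(v) v %in% BASES
  for (id in names(double_peaks)) {
    sites <- as.integer(double_peaks[[id]])
    if (any(sites < 1L | sites > aln$length)) {
      stop("double-peak site out of range for record ", id, call. = FALSE)
    }
    if (id %in% keep_override) {
      report <- rbind(report, data.frame(
        id = id, branch = 1L, detail = "alternative states kept (override)"))
      next
    }
    v <- mat[id, ]
    matched <- NA_character_
    # branch (2): try each reference haplotype, lexicographic order of
    # sequence for determinism
    ord <- order(unname(ref_seqs))
    for (h in ord) {
      w <- ref_mats[[h]]
      comp <- informative(v) & informative(w)
      comp[sites] <- FALSE
      if (!all(v[comp] == w[comp])) next
      ok <- TRUE
      for (s in sites) {
        states <- if (v[s] %in% BASES) v[s] else IUPAC_AMBIG[[v[s]]]
        if (is.null(states) || !(w[s] %in% states)) { ok <- FALSE; break }
      }
      if (ok) { matched <- names(ref_seqs)[h]; break }
    }
    if (!is.na(matched) && length(sites) <= max_ambiguous) {
      w <- ref_mats[[which(names(ref_seqs) == matched)]]
      mat[id, sites] <- w[sites]
      report <- rbind(report, data.frame(
        id = id, branch = 2L,
        detail = paste0("resolved toward haplotype ", matched)))
    } else {
      drop_ids <- c(drop_ids, id)
      why <- if (length(sites) > max_ambiguous) {
        paste0(length(sites), " ambiguous sites > ", max_ambiguous)
      } else "no matching reference haplotype"
      report <- rbind(report, data.frame(id = id, branch = 3L, detail = why))
    }
  }
  keep <- setdiff(aln$ids, drop_ids)
  if (length(keep) == 0L) stop("NUMT policy removed every sequence", call. = FALSE)
  g <- if (is.null(aln$groups)) NULL else aln$groups[names(aln$groups) %in% keep]
  out <- cr_alignment(mat[keep, , drop = FALSE], ids = keep, groups = g)
  attr(out, "numt_report") <- report
  out
}
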