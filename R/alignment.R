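# IUPAC alphabet used throughout. Ambiguity codes stand for >1 base;
# '-' is an alignment gap, 'N' fully unknown.
IUPAC_AMBIG <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
BASES <- c("A", "C", "G", "T")
VALID_CHARS <- c(BASES, names(IUPAC_AMBIG), "-")

#' Construct an aligned sequence set
#'
#' An alignment is a set of equal-length sequences over the IUPAC DNA
#' alphabet (A, C, G, T, ambiguity codes, 'N', gap '-'), with unique sample
#' identifiers and an optional sample-to-group assignment. All downstream
#' statistics (site classification, distances, diversity, networks) operate
#' on this container.
#'
#' @param seqs character vector of sequence strings, or a character matrix
#'   with one row per sample and one column per site.
#' @param ids sample identifiers; defaults to the names of `seqs` (or its
#'   rownames).
#' @param groups optional named character vector mapping sample id to group
#'   label; every name must be one of `ids`.
#' @return an object of class `cr_alignment` with components `ids`, `mat`
#'   (character matrix, samples x sites), `groups`, and `length` (site
#'   count in bp).
#' @examples
#' aln <- cr_alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' aln$length
#' @export
cr_alignment <- function(seqs, ids = NULL, groups = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(ids)) ids <- rownames(mat)
  } else {
    if (is.null(ids)) ids <- names(seqs)
    if (length(seqs) == 0L) stop("empty alignment: no sequences", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  if (nrow(mat) == 0L) stop("empty alignment: no sequences", call. = FALSE)
  mat[mat == "U"] <- "T"
  mat <- toupper(mat)
  bad <- matrix(!(mat %in% VALID_CHARS), nrow = nrow(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("format error: non-IUPAC character '", mat[bad][1L],
         "' in record '", ids[idx[1L]], "' at site ", idx[2L], call. = FALSE)
  }
  rownames(mat) <- ids
  if (!is.null(groups)) {
    groups <- vapply(groups, as.character, "")
    if (!all(names(groups) %in% ids)) {
      stop("group table refers to unknown ids: ",
           paste(setdiff(names(groups), ids), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(ids = ids, mat = mat, groups = groups, length = ncol(mat)),
    class = "cr_alignment"
  )
}

#' @export
print.cr_alignment <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", x$length, "bp\n")
  if (!is.null(x$groups)) {
    cat("Groups:", paste(names(table(x$groups)), table(x$groups),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.cr_alignment <- function(x, ...) x$mat

# sequences as strings, named by id
aln_strings <- function(aln) {
  stats::setNames(apply(aln$mat, 1L, paste, collapse = ""), aln$ids)
}

# subset an alignment by sample ids (keeps groups in step)
aln_subset <- function(aln, ids) {
  stopifnot(all(ids %in% aln$ids))
  g <- if (is.null(aln$groups)) NULL else aln$groups[names(aln$groups) %in% ids]
  cr_alignment(aln$mat[ids, , drop = FALSE], ids = ids, groups = g)
}

#' Read an aligned FASTA file
#'
#' Sequences are uppercased and 'U' is mapped to 'T'. All records must have
#' equal length (the file is expected to hold a multiple-sequence
#' alignment, not raw reads).
#'
#' @param path path to a FASTA file.
#' @param groups optional named character vector (id -> group), e.g. from
#'   [read_group_table()].
#' @return a [cr_alignment()].
#' @export
read_fasta <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("format error: empty or malformed FASTA file: ",
                             conditionMessage(e), call. = FALSE))
  if (length(recs) == 0L) stop("format error: empty FASTA file", call. = FALSE)
  seqs <- vapply(recs, function(r) as.character(r)[1L], "")
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), "")
  cr_alignment(seqs, groups = groups)
}

#' Write an alignment to FASTA
#'
#' @param aln a [cr_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  s <- aln_strings(aln)
  seqinr::write.fasta(as.list(s), names = names(s), file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Read a two-column sample-to-group table
#'
#' @param path TSV file with columns `id` and `group` (no header required;
#'   a header line `id<TAB>group` is tolerated).
#' @return named character vector, id -> group.
#' @export
read_group_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "group"))
  if (nrow(tab) > 0L && identical(tolower(tab$id[1L]), "id")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  stats::setNames(as.character(tab$group), tab$id)
}
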