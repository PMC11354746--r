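# Median-joining network construction (Bandelt-style), built from scratch:
# epsilon-relaxed minimum spanning networks over Hamming distances, plus
# iterated quasi-median (Steiner-point) insertion and final pruning of
# median vectors not on any minimal path between observed haplotypes.

hamming_matrix <- function(seqmat) {
  n <- nrow(seqmat)
  D <- matrix(0L, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- sum(seqmat[i, ] != seqmat[j, ])
    }
  }
  D
}

# union-find on 1..n
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }
uf_union <- function(uf, i, j) { uf[uf_find(uf, i)] <- uf_find(uf, j); uf }

# epsilon-relaxed minimum spanning network: edge (i,j) of weight w is kept
# iff i and j are not connected using kept edges of weight < w - epsilon.
# At epsilon = 0 this is the classic MSN, the union of all MSTs.
msn_edges <- function(D, epsilon = 0L) {
  n <- nrow(D)
  if (n < 2L) return(data.frame(from = integer(0), to = integer(0),
                                weight = integer(0)))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[pairs]
  ord <- order(w, pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  kept <- logical(length(w))
  for (lvl in unique(w)) {
    # connectivity from kept edges with weight < lvl - epsilon
    uf <- uf_new(n)
    prior <- which(kept & w < lvl - epsilon)
    for (e in prior) uf <- uf_union(uf, pairs[e, 1L], pairs[e, 2L])
    at <- which(w == lvl)
    kept[at] <- vapply(at, function(e) {
      uf_find(uf, pairs[e, 1L]) != uf_find(uf, pairs[e, 2L])
    }, logical(1))
  }
  data.frame(from = pairs[kept, 1L], to = pairs[kept, 2L], weight = w[kept])
}

# quasi-medians of a sequence triplet: majority state per site; at sites
# where all three states differ, branch over all three.
quasi_medians <- function(u, v, w, max_candidates = 10000L) {
  L <- length(u)
  fixed <- character(L)
  branch <- vector("list", 0L)
  branch_sites <- integer(0)
  for (s in seq_len(L)) {
    st <- c(u[s], v[s], w[s])
    tab <- table(st)
    if (max(tab) >= 2L) {
      fixed[s] <- names(tab)[which.max(tab)]
    } else {
      branch_sites <- c(branch_sites, s)
      branch[[length(branch) + 1L]] <- unique(st)
    }
  }
  if (length(branch_sites) == 0L) return(matrix(fixed, nrow = 1L))
  n_comb <- prod(lengths(branch))
  if (n_comb > max_candidates) {
    stop("median explosion: ", n_comb, " quasi-median candidates exceed cap ",
         max_candidates, call. = FALSE)
  }
  grid <- expand.grid(branch, stringsAsFactors = FALSE)
  out <- matrix(rep(fixed, each = nrow(grid)), nrow = nrow(grid))
  for (k in seq_along(branch_sites)) out[, branch_sites[k]] <- grid[[k]]
  out
}

#' Build a median-joining haplotype network
#'
#' Constructs the haplotype network by (1) computing Hamming distances
#' between unique haplotypes, (2) forming the epsilon-relaxed minimum
#' spanning network, (3) proposing quasi-median vectors (majority state per
#' site; all combinations at sites where the triplet disagrees three ways)
#' for every triplet sharing a common network neighbour, adding the new
#' vectors whose connection cost is within epsilon of the minimum,
#' (4) iterating to a fixed point, and (5) pruning median vectors and links
#' that lie on no minimal path between observed haplotypes. Tie-breaking is
#' lexicographic on node sequences throughout, so the result does not
#' depend on input order.
#'
#' @param haps a `haplotype_set` (see [collapse_haplotypes()]) or a named
#'   character vector of unique equal-length sequences. Ambiguity codes
#'   should be resolved first (see [resolve_ambiguities()]).
#' @param epsilon non-negative integer relaxation; 0 (default) gives the
#'   sparsest network.
#' @param max_candidates cap on quasi-median candidates per triplet
#'   (default 10000); exceeding it is an error.
#' @param max_iter safety cap on median-insertion sweeps.
#' @return class `haplotype_network`: `nodes` (data frame: id, sequence,
#'   multiplicity, group, is_median), `edges` (data frame: from, to,
#'   weight, by node id), `epsilon`.
#' @examples
#' net <- build_mjn(c(h1 = "AACC", h2 = "TTCC", h3 = "ATTC"))
#' net$nodes
#' @export
build_mjn <- function(haps, epsilon = 0L, max_candidates = 10000L,
                      max_iter = 25L) {
  if (inherits(haps, "haplotype_set")) {
    seqs <- haps$haplotypes
    mult <- haps$multiplicity
    grp <- if (is.null(haps$groups)) rep(NA_character_, haps$H) else
      haplotype_alignment(haps)$groups[names(seqs)]
    if (is.null(grp)) grp <- rep(NA_character_, length(seqs))
    grp <- unname(grp[names(seqs)])
  } else {
    seqs <- haps
    if (is.null(names(seqs))) names(seqs) <- paste0("h", seq_along(seqs))
    mult <- rep(1L, length(seqs))
    grp <- rep(NA_character_, length(seqs))
  }
  if (length(seqs) < 2L) stop("need >= 2 haplotypes", call. = FALSE)
  if (anyDuplicated(unname(seqs))) {
    stop("duplicate haplotypes in input; collapse first", call. = FALSE)
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("haplotype sequences must have equal length", call. = FALSE)
  }
  epsilon <- as.integer(epsilon)
  if (epsilon < 0L) stop("epsilon must be >= 0", call. = FALSE)

  full <- do.call(rbind, strsplit(unname(seqs), ""))
  # restrict to variable sites; constant sites contribute no distance
  varsites <- which(apply(full, 2L, function(col) length(unique(col)) > 1L))
  smat <- full[, varsites, drop = FALSE]
  n_obs <- nrow(smat)
  # order observed nodes lexicographically for deterministic construction
  obs_ord <- order(unname(seqs))
  smat <- smat[obs_ord, , drop = FALSE]
  node_seq_var <- apply(smat, 1L, paste, collapse = "")
  obs_names <- names(seqs)[obs_ord]
  mult <- mult[obs_ord]; grp <- grp[obs_ord]

  nodes <- smat                    # rows grow as medians are added
  is_median <- rep(FALSE, n_obs)
  seen <- stats::setNames(seq_len(n_obs), node_seq_var)

  for (iter in seq_len(max_iter)) {
    D <- hamming_matrix(nodes)
    ed <- msn_edges(D, epsilon)
    # adjacency list
    adj <- vector("list", nrow(nodes))
    for (e in seq_len(nrow(ed))) {
      adj[[ed$from[e]]] <- c(adj[[ed$from[e]]], ed$to[e])
      adj[[ed$to[e]]] <- c(adj[[ed$to[e]]], ed$from[e])
    }
    # candidate medians from triplets sharing a common neighbour
    cand <- list(); cost <- numeric(0)
    for (v in seq_len(nrow(nodes))) {
      nb <- sort(unique(adj[[v]]))
      if (length(nb) < 2L) next
      prs <- utils::combn(nb, 2L)
      for (k in seq_len(ncol(prs))) {
        u <- prs[1L, k]; w <- prs[2L, k]
        qm <- quasi_medians(nodes[u, ], nodes[v, ], nodes[w, ],
                            max_candidates)
        for (r in seq_len(nrow(qm))) {
          m <- qm[r, ]
          cc <- sum(m != nodes[u, ]) + sum(m != nodes[v, ]) +
            sum(m != nodes[w, ])
          cand[[length(cand) + 1L]] <- m
          cost <- c(cost, cc)
        }
      }
    }
    if (length(cand) == 0L) break
    lambda <- min(cost)
    pick <- which(cost <= lambda + epsilon)
    new_seqs <- unique(vapply(cand[pick], paste, "", collapse = ""))
    new_seqs <- sort(setdiff(new_seqs, names(seen)))   # deterministic order
    if (length(new_seqs) == 0L) break
    add <- do.call(rbind, strsplit(new_seqs, ""))
    nodes <- rbind(nodes, add)
    is_median <- c(is_median, rep(TRUE, length(new_seqs)))
    seen <- c(seen, stats::setNames(nrow(nodes) - length(new_seqs) +
                                      seq_along(new_seqs), new_seqs))
  }

  # final network over the full node set, then prune medians/links off all
  # minimal observed-to-observed paths
  D <- hamming_matrix(nodes)
  ed <- msn_edges(D, epsilon)
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(nrow(nodes)))))
  keep_nodes <- rep(FALSE, nrow(nodes))
  keep_nodes[seq_len(n_obs)] <- TRUE
  keep_edge <- rep(FALSE, nrow(ed))
  ekey <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  obs_idx <- seq_len(n_obs)
  for (i in obs_idx) {
    for (j in obs_idx) {
      if (j <= i) next
      sp <- igraph::all_shortest_paths(
        g, from = as.character(i), to = as.character(j),
        weights = igraph::E(g)$weight)$res
      for (p in sp) {
        vp <- as.integer(igraph::as_ids(p))
        keep_nodes[vp] <- TRUE
        if (length(vp) > 1L) {
          kk <- paste(pmin(vp[-length(vp)], vp[-1L]),
                      pmax(vp[-length(vp)], vp[-1L]))
          keep_edge[match(kk, ekey)] <- TRUE
        }
      }
    }
  }
  idx_map <- cumsum(keep_nodes)
  nodes <- nodes[keep_nodes, , drop = FALSE]
  is_median <- is_median[keep_nodes]
  ed <- ed[keep_edge & keep_nodes[ed$from] & keep_nodes[ed$to], , drop = FALSE]
  ed$from <- idx_map[ed$from]; ed$to <- idx_map[ed$to]

  n_med <- sum(is_median)
  ids <- character(nrow(nodes))
  ids[!is_median] <- obs_names
  ids[is_median] <- paste0("mv", seq_len(n_med))
  # reconstruct full-length sequences for all nodes (medians inherit the
  # constant sites of the alignment)
  template <- full[1L, ]
  node_full <- vapply(seq_len(nrow(nodes)), function(i) {
    s <- template
    s[varsites] <- nodes[i, ]
    paste(s, collapse = "")
  }, "")
  nd <- data.frame(
    id = ids, sequence = node_full,
    multiplicity = ifelse(is_median, 0L,
                          mult[match(ids, obs_names)]),
    group = ifelse(is_median, NA_character_, grp[match(ids, obs_names)]),
    is_median = is_median, stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[ed$from], to = ids[ed$to],
                      weight = ed$weight, stringsAsFactors = FALSE)
  structure(list(nodes = nd, edges = edges, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Median-joining network:", sum(!x$nodes$is_median), "haplotypes +",
      sum(x$nodes$is_median), "median vectors;",
      nrow(x$edges), "edges (epsilon =", x$epsilon, ")\n")
  invisible(x)
}

# igraph view of a haplotype_network
network_graph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Minimum substitution count separating two node sets
#'
#' The minimum, over all pairs (a in A, b in B), of the weighted shortest
#' path length through the network — the number of substitutions separating
#' the closest members of two haplogroups, as annotated on network figures.
#'
#' @param net a `haplotype_network`.
#' @param groupA,groupB node-id vectors, or single group labels matched
#'   against the nodes' `group` column.
#' @return minimum substitution count (0 if the sets share a node).
#' @export
group_separation <- function(net, groupA, groupB) {
  resolve <- function(g) {
    if (length(g) == 1L && !(g %in% net$nodes$id) &&
        g %in% net$nodes$group) {
      net$nodes$id[!is.na(net$nodes$group) & net$nodes$group == g]
    } else g
  }
  a <- resolve(groupA); b <- resolve(groupB)
  if (length(a) == 0L || length(b) == 0L) {
    stop("empty node set", call. = FALSE)
  }
  missing <- setdiff(c(a, b), net$nodes$id)
  if (length(missing) > 0L) {
    stop("unknown nodes: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(intersect(a, b)) > 0L) return(0)
  g <- network_graph(net)
  d <- igraph::distances(g, v = a, to = b, weights = igraph::E(g)$weight)
  m <- min(d)
  if (!is.finite(m)) stop("unreachable: node sets are disconnected", call. = FALSE)
  m
}

#' Export a haplotype network
#'
#' @param net a `haplotype_network`.
#' @param path output file path.
#' @param format `"graphml"` (node attributes multiplicity, group,
#'   is_median; edge weights) or `"tsv"` (weighted edge list).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network_graph(net), path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
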