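test_that("two haplotypes give a single edge weighted by their distance", {
  net <- build_mjn(c(h1 = "AAATTT", h2 = "TATTTA"))   # sites 1, 3, 6 differ
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 3)
  expect_false(any(net$nodes$is_median))
})

test_that("the hand-worked triplet gains exactly one central median vector", {
  # binary analogue of 000 / 110 / 011 over {A,T}
  net <- build_mjn(c(a = "AAA", b = "TTA", c = "ATT"))
  med <- net$nodes[net$nodes$is_median, ]
  expect_equal(nrow(med), 1L)
  expect_equal(med$sequence, "ATA")   # majority state per site
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight == 1))
  # star: every edge touches the median
  expect_true(all(med$id %in% net$edges$from | med$id %in% net$edges$to))
})

test_that("a resolved chain stays a path with no median added", {
  net <- build_mjn(c(A = "AA", B = "AT", C = "TT"))
  expect_false(any(net$nodes$is_median))
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(net$edges$weight == 1))
})

test_that("edge weights equal the Hamming distance of their endpoints", {
  seqs <- c(h1 = "AACCGGTT", h2 = "AACCGGTA", h3 = "TACCGGTA",
            h4 = "AATCGCTT", h5 = "CACCGGTT")
  net <- build_mjn(seqs)
  seqof <- stats::setNames(net$nodes$sequence, net$nodes$id)
  for (e in seq_len(nrow(net$edges))) {
    a <- strsplit(seqof[net$edges$from[e]], "")[[1]]
    b <- strsplit(seqof[net$edges$to[e]], "")[[1]]
    expect_equal(net$edges$weight[e], sum(a != b))
    expect_gte(net$edges$weight[e], 1)
  }
})

test_that("shortest network paths never undercut the direct Hamming distance", {
  seqs <- c(h1 = "AAAAAA", h2 = "AAATAA", h3 = "TTAAAA", h4 = "TTATTA")
  net <- build_mjn(seqs)
  g <- crhaplo:::network_graph(net)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      hd <- sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]])
      sp <- igraph::distances(g, names(seqs)[i], names(seqs)[j],
                              weights = igraph::E(g)$weight)[1, 1]
      expect_gte(sp, hd)
    }
  }
})

test_that("the epsilon-0 network contains every minimum spanning tree edge", {
  for (seed in c(3, 8, 15)) {
    seqs <- random_seqs(6, 30, seed = seed)
    seqs <- seqs[!duplicated(seqs)]
    names(seqs) <- paste0("h", seq_along(seqs))
    smat <- do.call(rbind, strsplit(seqs, ""))
    D <- matrix(0, length(seqs), length(seqs))
    for (i in seq_along(seqs)) for (j in seq_along(seqs))
      D[i, j] <- sum(smat[i, ] != smat[j, ])
    mst_union <- oracle_mst_edges(D)
    ed <- crhaplo:::msn_edges(D, 0L)
    msn_keys <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "-")
    expect_true(all(mst_union %in% msn_keys))
  }
})

test_that("duplicate observed haplotypes are rejected; multiplicity is cosmetic", {
  expect_error(build_mjn(c(a = "AAAA", b = "AAAA", c = "AATT")), "duplicate")
  aln1 <- make_aln(c("AAAA", "AATT", "TTTT"))
  aln2 <- make_aln(c("AAAA", "AAAA", "AATT", "TTTT", "TTTT", "TTTT"))
  n1 <- build_mjn(collapse_haplotypes(aln1))
  n2 <- build_mjn(collapse_haplotypes(aln2))
  norm <- function(n) {
    key <- stats::setNames(n$nodes$sequence, n$nodes$id)
    e <- data.frame(a = pmin(key[n$edges$from], key[n$edges$to]),
                    b = pmax(key[n$edges$from], key[n$edges$to]),
                    w = n$edges$weight)
    e[order(e$a, e$b), ]
  }
  expect_equal(norm(n1), norm(n2), ignore_attr = TRUE)
  expect_equal(sort(n2$nodes$multiplicity[!n2$nodes$is_median]),
               c(1L, 2L, 3L))
})

test_that("network topology is invariant to input order", {
  seqs <- c(h1 = "AAAAAA", h2 = "TTAAAA", h3 = "AATTAA", h4 = "AAAATT",
            h5 = "TTTTAA")
  norm <- function(net) {
    key <- stats::setNames(net$nodes$sequence, net$nodes$id)
    e <- data.frame(a = pmin(key[net$edges$from], key[net$edges$to]),
                    b = pmax(key[net$edges$from], key[net$edges$to]),
                    w = net$edges$weight)
    e <- e[order(e$a, e$b, e$w), ]
    rownames(e) <- NULL
    e
  }
  ref <- norm(build_mjn(seqs))
  set.seed(4)
  for (r in 1:5) {
    perm <- sample(seqs)
    expect_equal(norm(build_mjn(perm)), ref)
  }
})

test_that("group separation is the minimum weighted path between node sets", {
  # two groups joined by one weight-5 edge
  net <- build_mjn(c(a = "AAAAA", b = "TTTTT"))
  expect_equal(group_separation(net, "a", "b"), 5)

  # separation through an inferred median: a-mv (1) + mv-c (1) = 2
  net2 <- build_mjn(c(a = "AAA", b = "TTA", c = "ATT"))
  expect_equal(group_separation(net2, "a", "c"), 2)

  # overlap -> zero
  expect_equal(group_separation(net2, c("a", "b"), c("b", "c")), 0)

  # group labels resolve against node attributes
  aln <- make_aln(c(x1 = "AAAA", x2 = "AATA", y1 = "TTTT"),
                  groups = c("gx", "gx", "gy"))
  net3 <- build_mjn(collapse_haplotypes(aln))
  expect_equal(group_separation(net3, "gx", "gy"), 3)

  expect_error(group_separation(net2, "zz", "a"), "empty|unknown")
})

test_that("exports round-trip through GraphML and edge-list TSV", {
  aln <- make_aln(c(a = "AAAA", b = "AATT", c = "TTTT"),
                  groups = c("g1", "g1", "g2"))
  net <- build_mjn(collapse_haplotypes(aln))

  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$weight, net$edges$weight)

  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  expect_setequal(igraph::E(g)$weight, net$edges$weight)
  expect_equal(sum(igraph::V(g)$is_median), sum(net$nodes$is_median))

  expect_error(export_network(net, tempfile(), "dot"), "arg")
})

test_that("haplogroup fixtures separate by the expected substitution count", {
  # two haplogroups around distinct cores, 12 fixed differences between cores
  core1 <- strrep("A", 12)
  core2 <- strrep("T", 12)
  vary <- function(core, pos, to) {
    s <- strsplit(core, "")[[1]]; s[pos] <- to; paste(s, collapse = "")
  }
  seqs <- c(a1 = core1, a2 = vary(core1, 1, "G"),
            b1 = core2, b2 = vary(core2, 12, "C"))
  aln <- make_aln(seqs, groups = c("A", "A", "B", "B"))
  net <- build_mjn(collapse_haplotypes(aln))
  expect_equal(group_separation(net, "A", "B"), 12)
})
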