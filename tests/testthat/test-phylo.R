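test_that("similarity converts to distance and back", {
  ids <- c("a", "b", "c")
  vals <- matrix(c(100, 40, 10, 40, 100, 25, 10, 25, 100), 3,
                 dimnames = list(ids, ids))
  sim <- similarity_matrix(stats::setNames(
    c("ACDEF", "ACDEG", "WYWYW"), ids))  # only for class; values replaced
  sim$values <- vals
  d <- to_distance(sim)
  expect_equal(diag(d$values), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d$values[1L, 3L], 0.9)   # 10% similar -> 0.9
  expect_equal(100 - 100 * d$values, vals, ignore_attr = TRUE)
})

test_that("two-taxon and three-taxon trees solve the closed forms", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))
  expect_equal(write_newick(t2), "(A:0.2,B:0.2);")

  # ultrametric 3-taxon: pendant lengths solve the three-point formulas
  # d(A,B)=0.2, d(A,C)=d(B,C)=0.6 -> a=b=0.1, c=0.5
  ids <- c("A", "B", "C")
  d3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
               dimnames = list(ids, ids))
  t3 <- neighbor_joining(d3)
  pend <- stats::setNames(
    t3$edge.length[match(seq_along(ids), t3$edge[, 2L])], t3$tip.label)
  expect_equal(pend[["A"]], 0.1)
  expect_equal(pend[["B"]], 0.1)
  expect_equal(pend[["C"]], 0.5)
})

test_that("NJ recovers a known 4-taxon topology with exact edge lengths", {
  # quartet ((A,B),(C,D)) with all five edges 0.1
  ids <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.2
  for (x in c("A", "B")) for (y in c("C", "D")) {
    d[x, y] <- d[y, x] <- 0.3
  }
  tr <- neighbor_joining(d)
  expect_equal(unname(as.matrix(stats::cophenetic(tr))[ids, ids]),
               unname(d))
  # AB form a cherry
  cherry <- ape::prop.part(ape::unroot(tr))
  expect_equal(max(abs(as.matrix(stats::cophenetic(tr))[ids, ids] - d)), 0)
})

test_that("NJ is exact on additive matrices from random trees (<= 8 leaves)", {
  set.seed(31)
  for (k in 1:25) {
    n <- sample(4:8, 1L)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    tru <- ape::unroot(tr)
    D <- stats::cophenetic(tru)
    ids <- sort(rownames(D))
    njt <- neighbor_joining(D[ids, ids])
    expect_equal(sort(njt$tip.label), ids)
    expect_equal(ape::dist.topo(ape::unroot(njt), tru), 0,
                 ignore_attr = TRUE)
    C <- as.matrix(stats::cophenetic(njt))[rownames(D), colnames(D)]
    expect_lt(max(abs(C - D)), 1e-8)
  }
})

test_that("NJ validates its input", {
  expect_error(neighbor_joining(matrix(0, 1, 1)), "at least 2")
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("midpoint rooting bisects the longest leaf-to-leaf path", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  r2 <- midpoint_root(neighbor_joining(d2))
  expect_equal(sort(r2$edge.length), c(0.2, 0.2))

  # caterpillar with diameter 1.0 between A and D -> root 0.5 from each
  txt <- "(((A:0.4,B:0.1):0.2,C:0.1):0.2,D:0.2);"
  tr <- ape::unroot(ape::read.tree(text = txt))
  rt <- midpoint_root(tr)
  ntip <- length(rt$tip.label)
  dn <- ape::dist.nodes(rt)
  root <- ntip + 1L
  depths <- stats::setNames(dn[root, seq_len(ntip)], rt$tip.label)
  expect_equal(depths[["A"]], 0.5)
  expect_equal(depths[["D"]], 0.5)
  # root has degree 2 (subdivides an edge)
  expect_equal(sum(rt$edge[, 1L] == root), 2L)
})

test_that("midpoint rooting preserves leaf distances and is idempotent", {
  set.seed(17)
  for (k in 1:10) {
    n <- sample(4:8, 1L)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    tru <- ape::unroot(tr)
    D <- stats::cophenetic(tru)
    r1 <- midpoint_root(tru)
    C1 <- as.matrix(stats::cophenetic(r1))[rownames(D), colnames(D)]
    expect_lt(max(abs(C1 - D)), 1e-8)
    r2 <- midpoint_root(r1)
    C2 <- as.matrix(stats::cophenetic(r2))[rownames(D), colnames(D)]
    expect_lt(max(abs(C2 - C1)), 1e-8)
    # deepest leaf is exactly half the diameter from the root
    dn <- ape::dist.nodes(r2)
    root <- length(r2$tip.label) + 1L
    expect_equal(max(dn[root, seq_len(length(r2$tip.label))]), max(D) / 2,
                 tolerance = 1e-8)
  }
})

test_that("newick output quotes awkward labels and round-trips", {
  ids <- c("p|1", "B", "C")
  d3 <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
               dimnames = list(ids, ids))
  tr <- midpoint_root(neighbor_joining(d3))
  txt <- write_newick(tr)
  expect_match(txt, "'p|1'", fixed = TRUE)
  expect_match(txt, ";$")
  # safe labels round-trip through ape's parser
  set.seed(3)
  tr2 <- ape::rtree(6)
  tr2$edge.length <- round(stats::runif(nrow(tr2$edge), 0.1, 1), 4)
  back <- ape::read.tree(text = write_newick(tr2))
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_equal(as.matrix(stats::cophenetic(back))[tr2$tip.label,
                                                  tr2$tip.label],
               as.matrix(stats::cophenetic(tr2))[tr2$tip.label,
                                                 tr2$tip.label],
               tolerance = 1e-4)
})

test_that("similarity-to-tree pipeline keeps the leaf set", {
  refs <- fixture_refs()
  seqs <- vapply(refs, function(r) r$sequence, character(1L))
  sm <- similarity_matrix(seqs)
  tr <- midpoint_root(neighbor_joining(to_distance(sm)))
  expect_setequal(tr$tip.label, names(seqs))
  expect_true(all(tr$edge.length >= 0))
})
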