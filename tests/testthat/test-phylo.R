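# Complete-deletion masking, supermatrix concatenation, gamma-corrected
# distances, deterministic UPGMA, bootstrap supports, and Newick round trips.

test_that("complete deletion removes exactly the gapped columns", {
  rows <- c(a = "MKVLT", b = "MKVLT", c = "MKVLT")
  expect_equal(ncol(maskCompleteDeletion(rows)), 5L)
  rows2 <- c(a = "MKVLT", b = "MKV-T", c = "MKVLT")
  m <- maskCompleteDeletion(rows2)
  expect_equal(ncol(m), 4L)
  expect_equal(paste(m["a", ], collapse = ""), "MKVT")
  # oracle: per-column scan
  set.seed(61)
  g <- replicate(4, paste(sample(c(LETTERS[1:6], "-"), 30, TRUE),
                          collapse = ""))
  names(g) <- paste0("t", 1:4)
  keep <- !apply(do.call(rbind, strsplit(g, "")), 2,
                 function(col) any(col == "-"))
  expect_equal(ncol(maskCompleteDeletion(g)), sum(keep))
  expect_error(maskCompleteDeletion(c(a = "-", b = "A")), "empty-matrix")
})

test_that("concatenation matches rows by taxon id and records boundaries", {
  a1 <- c(x = "MKVLTAGMKV", y = "MKVLTAGMKV")
  a2 <- c(y = "PPPPPPPPPP", x = "QQQQQQQQQQ")   # permuted taxon order
  sm <- concatenateAlignments(list(g1 = a1, g2 = a2))
  expect_equal(ncol(sm$matrix), 20L)
  expect_equal(paste(sm$matrix["x", 11:20], collapse = ""), a2[["x"]])
  expect_equal(sm$boundaries$gene, c("g1", "g2"))
  expect_equal(sm$boundaries$to, c(10L, 20L))
  # 31 single-column genes -> 31 boundary rows
  singles <- setNames(rep(list(c(x = "A", y = "C")), 31),
                      sprintf("g%02d", 1:31))
  expect_equal(nrow(concatenateAlignments(singles)$boundaries), 31L)
  expect_error(concatenateAlignments(list(g1 = a1, g2 = a2[1])),
               "completeness error")
})

test_that("gamma distances follow the closed form and its Poisson limit", {
  m <- rbind(a = strsplit("AAAAAAAAAA", "")[[1]],
             b = strsplit("AAAAAAAAAA", "")[[1]])
  expect_equal(unname(distanceMatrix(m)["a", "b"]), 0)
  expect_equal(gammaDistance(0.1, 2.25), 2.25 * (0.9^(-1 / 2.25) - 1))
  expect_lt(abs(gammaDistance(0.1, 1e6) - (-log(0.9))) / -log(0.9), 1e-3)
  bad <- rbind(a = c("A", "A"), b = c("C", "C"))
  expect_error(distanceMatrix(bad), "infinite-distance.*a.*b")
})

test_that("UPGMA resolves the forced three-taxon topology with d/2 heights", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(D)
  expect_equal(sort(ape::extract.clade(
    tr, ape::getMRCA(tr, c("A", "B")))$tip.label), c("A", "B"))
  h <- nodeHeights(tr)
  expect_equal(sort(unique(round(h[h > 0], 9))), c(1, 3))
  expect_error(upgmaTree(matrix(c(0, -1, -1, 0), 2)), "matrix error")
})

test_that("UPGMA reconstructs ultrametric matrices exactly", {
  set.seed(63)
  for (i in 1:5) {
    n <- sample(4:12, 1)
    tr0 <- ape::rcoal(n)
    D <- ape::cophenetic.phylo(tr0)
    tr <- upgmaTree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr0)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    # ultrametricity of the result
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    # permuting the input taxa gives the same tree
    p <- sample(n)
    tr2 <- upgmaTree(D[p, p])
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("UPGMA heights agree with average-linkage hclust", {
  set.seed(65)
  n <- 8
  X <- matrix(rnorm(n * 4), n, dimnames = list(paste0("t", 1:n), NULL))
  D <- as.matrix(dist(X))
  tr <- upgmaTree(D)
  hc <- stats::hclust(as.dist(D), method = "average")
  expect_equal(sort(unique(round(nodeHeights(tr)[nodeHeights(tr) > 1e-12],
                                 8))),
               sort(round(hc$height / 2, 8)))
})

test_that("a clade guaranteed by every resample has bootstrap support 100", {
  # rows a and b are identical at every column, so every replicate merges
  # them first; constant columns keep all pairwise p below 1
  inf <- c(a = "A", b = "A", c = "C", d = "T")
  const <- c(a = "G", b = "G", c = "G", d = "G")
  m <- cbind(matrix(rep(inf, 10), 4, dimnames = list(names(inf), NULL)),
             matrix(rep(const, 20), 4, dimnames = list(names(const), NULL)))
  tr <- bootstrapUpgma(m, nReps = 25L, seed = 2L, gammaShape = 2.25)
  node <- ape::getMRCA(tr, c("a", "b"))
  expect_equal(as.numeric(tr$node.label[node - ape::Ntip(tr)]), 100)
})

test_that("a long internal branch earns high support, a star does not", {
  set.seed(67)
  deep <- ape::read.tree(text = "((a:0.05,b:0.05):0.45,(c:0.05,d:0.05):0.45);")
  fams <- makeFamilies(deep, nFamilies = 4L, rootLen = 80L, seed = 3L)
  sm <- concatenateAlignments(fams$families)
  tr <- bootstrapUpgma(sm, nReps = 50L, seed = 5L)
  internal <- as.numeric(tr$node.label)
  internal <- internal[!is.na(internal)]
  expect_gte(max(internal), 95)
  # near-star data: no bipartition should be overwhelmingly supported
  star <- ape::read.tree(text = "((a:0.5,b:0.5):0.0001,(c:0.5,d:0.5):0.0001);")
  hits <- 0L
  for (sd in 1:5) {
    f <- makeFamilies(star, nFamilies = 2L, rootLen = 60L, seed = sd)
    t2 <- bootstrapUpgma(concatenateAlignments(f$families), nReps = 30L,
                         seed = sd)
    lab <- as.numeric(t2$node.label)
    # ignore the root (always present in every rooted replicate)
    if (max(lab[-1], na.rm = TRUE) > 80) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("Newick output round-trips topology, lengths and supports", {
  set.seed(69)
  for (i in 1:5) {
    tr0 <- ape::rcoal(sample(4:10, 1))
    f <- tempfile(fileext = ".nwk")
    writeNewick(tr0, f)
    tr1 <- readNewick(f)
    expect_equal(ape::dist.topo(ape::unroot(tr0), ape::unroot(tr1)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(tr0$edge.length), sort(tr1$edge.length),
                 tolerance = 1e-8)
  }
  tr <- upgmaTree(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
                         dimnames = list(c("A", "B", "C"), NULL)))
  tr$node.label <- c(100, 87.5)
  f <- tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  expect_equal(as.numeric(readNewick(f)$node.label), c(100, 87.5))
})

test_that("dayhoff ML distances are symmetric, zero-diagonal and ordered", {
  set.seed(71)
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2);")
  fams <- makeFamilies(tr, nFamilies = 3L, rootLen = 100L, seed = 11L)
  sm <- concatenateAlignments(fams$families)
  D <- distanceMatrix(sm, model = "dayhoff_ml")
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_lt(D["a", "b"], D["a", "c"])   # within-clade < between-clade
})
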