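# ORF enumeration against a brute-force oracle, minimal-overlap selection,
# anchor numbering, and genome statistics.

test_that("a minimal single-ORF genome yields exactly one candidate", {
  g <- Genome(paste0("ATG", strrep("GCA", 149), "TAA"), topology = "linear")
  e <- enumerateOrfs(g)
  expect_equal(nrow(e$orfs), 1L)
  expect_equal(e$orfs$aa_length, 150L)
  expect_equal(e$orfs$start, 1L)
  expect_equal(e$orfs$end, 453L)
  expect_false(grepl("\\*", e$orfs$protein))
})

test_that("an ORF spanning the circular origin is called with wraps = TRUE", {
  set.seed(8)
  body <- paste0("ATG", strrep("GCA", 60), "TAA")
  L <- 1000L
  bg <- strsplit(strrep("C", L), "")[[1]]
  pos <- ((950:(949 + nchar(body)) - 1) %% L) + 1
  bg[pos] <- strsplit(body, "")[[1]]
  g <- Genome(paste(bg, collapse = ""))
  e <- enumerateOrfs(g)
  expect_equal(nrow(e$orfs), 1L)
  expect_true(e$orfs$wraps)
  expect_equal(e$orfs$start, 950L)
  expect_equal(spanLength(e$orfs$start, e$orfs$end, L), nchar(body))
  expect_error(enumerateOrfs(Genome("AC")), "range error")
})

test_that("enumeration equals the brute-force oracle on random genomes", {
  set.seed(11)
  for (rep in 1:5) {
    g <- Genome(random_dna(2000, at = 0.6))
    called <- enumerateOrfs(g, minAa = 20L)$orfs
    expected <- oracle_orfs(g, minAa = 20L)
    expect_equal(called[, c("start", "end", "strand", "aa_length")],
                 expected, info = paste("seed rep", rep))
  }
  # linear topology too
  g <- Genome(random_dna(3000, at = 0.55), topology = "linear")
  called <- enumerateOrfs(g, minAa = 25L)$orfs
  expect_equal(called[, c("start", "end", "strand", "aa_length")],
               oracle_orfs(g, minAa = 25L))
})

test_that("nucleotide span is 3*(aa+1) and proteins have no internal stop", {
  set.seed(4)
  g <- Genome(random_dna(4000, at = 0.6))
  orfs <- enumerateOrfs(g, minAa = 30L)$orfs
  expect_gt(nrow(orfs), 0L)
  expect_equal(spanLength(orfs$start, orfs$end, 4000L),
               3L * (orfs$aa_length + 1L))
  expect_false(any(grepl("\\*", orfs$protein)))
  expect_equal(nchar(orfs$protein), orfs$aa_length)
})

test_that("the stop-counting flag restores the literal 150-nt threshold", {
  g <- Genome(paste0("ATG", strrep("GCA", 48), "TAA",   # 49 aa, 150 nt
                     strrep("C", 50)), topology = "linear")
  expect_equal(nrow(enumerateOrfs(g, minAa = 50L)$orfs), 0L)
  expect_equal(nrow(enumerateOrfs(g, minAa = 50L,
                                  countStopInMin = TRUE)$orfs), 1L)
})

test_that("minimal-overlap selection keeps disjoint and drops nested ORFs", {
  # two disjoint ORFs
  g <- Genome(paste0("ATG", strrep("GCA", 60), "TAA", strrep("C", 30),
                     "ATG", strrep("GGA", 60), "TAA"), topology = "linear")
  orfs <- enumerateOrfs(g, minAa = 50L)$orfs
  kept <- selectMinimalOverlap(orfs, g)
  expect_equal(nrow(kept), 2L)
  # a 60-aa ORF fully nested (opposite strand) inside a 200-aa ORF
  inner <- paste0("ATG", strrep("GCA", 59), "TAA")
  outer_body <- paste0(strrep("GGA", 30), oracle_revcomp(inner),
                       strrep("GAG", 107))
  stopifnot(nchar(outer_body) %% 3 == 0)
  g2 <- Genome(paste0("ATG", outer_body, "TAA"), topology = "linear")
  orfs2 <- enumerateOrfs(g2, minAa = 50L)$orfs
  outer_key <- paste(1, nchar(genomeSeq(g2)), "+")
  inner_key <- paste(94, 94 + nchar(inner) - 1, "-")
  expect_true(all(c(outer_key, inner_key) %in% orf_key(orfs2)))
  kept2 <- selectMinimalOverlap(orfs2, g2)
  expect_true(outer_key %in% orf_key(kept2))
  expect_false(inner_key %in% orf_key(kept2))
})

test_that("selection recovers exactly the planted ORFs among nested decoys", {
  sim <- small_sim()
  ann_orfs <- selectMinimalOverlap(
    enumerateOrfs(sim$genome)$orfs, sim$genome)
  expect_setequal(orf_key(ann_orfs), orf_key(sim$truth$orfs))
  # overlap feasibility: every retained pair overlaps <= the cap
  L <- genomeLength(sim$genome)
  n <- nrow(ann_orfs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    expect_lte(baculokit:::.circ_overlap(
      ann_orfs$start[i], ann_orfs$end[i],
      ann_orfs$start[j], ann_orfs$end[j], L), 75L)
})

test_that("anchor numbering rotates, reflects, and assigns serials", {
  sim <- small_sim()
  orfs <- selectMinimalOverlap(enumerateOrfs(sim$genome)$orfs, sim$genome)
  # plus-strand anchor already near origin: serials strictly increase
  anchor_plus <- orfs$ID[orfs$strand == "+"][1]
  res <- numberFromAnchor(orfs, sim$genome, anchor_plus)
  expect_equal(res$orfs$start[res$orfs$serial == 1L], 1L)
  expect_equal(res$orfs$strand[res$orfs$serial == 1L], "+")
  expect_equal(res$orfs$serial, seq_len(nrow(orfs)))
  # spans preserved
  L <- genomeLength(sim$genome)
  expect_setequal(spanLength(res$orfs$start, res$orfs$end, L),
                  spanLength(orfs$start, orfs$end, L))
  # minus-strand anchor: reflection; applying the transform again with the
  # (now plus-strand, position-1) anchor is the identity
  anchor_minus <- orfs$ID[orfs$strand == "-"][1]
  r1 <- numberFromAnchor(orfs, sim$genome, anchor_minus)
  a1 <- r1$orfs$ID[r1$orfs$serial == 1L]
  r2 <- numberFromAnchor(r1$orfs, r1$genome, a1)
  expect_identical(genomeSeq(r2$genome), genomeSeq(r1$genome))
  expect_equal(r2$orfs$start, r1$orfs$start[order(r1$orfs$start)])
  expect_error(numberFromAnchor(orfs, sim$genome, "nope"), "lookup error")
})

test_that("reflection of intervals is an involution", {
  set.seed(6)
  L <- 1000L
  df <- data.frame(start = sample(L, 20), end = sample(L, 20),
                   strand = sample(c("+", "-"), 20, TRUE))
  back <- baculokit:::.reflect_features(
    baculokit:::.reflect_features(df, L), L)
  expect_equal(back, df)
})

test_that("genome statistics count coding coverage and strand split", {
  g <- Genome(random_dna(1000), topology = "linear")
  one <- data.frame(start = 101L, end = 400L, strand = "+")
  expect_equal(genomeStats(one, g)$coding_fraction, 0.300)
  two <- rbind(one, data.frame(start = 351L, end = 650L, strand = "-"))
  st <- genomeStats(two, g)
  expect_equal(st$coding_fraction, 0.550)
  expect_equal(st$n_same_strand, 1L)
  expect_equal(st$n_opposite_strand, 1L)
  # monotone non-decreasing as ORFs are added
  three <- rbind(two, data.frame(start = 900L, end = 950L, strand = "+"))
  expect_gte(genomeStats(three, g)$coding_fraction, st$coding_fraction)
})
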