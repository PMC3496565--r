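# Palindrome discovery against a brute-force oracle, hr clustering, conserved
# ends, self-similarity, direct repeats, hairpin energies, and non-hr-ori
# flagging.

test_that("perfect palindromes are found with exact geometry", {
  p <- findPalindromes("AAATTT", minArm = 3, maxLoop = 0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$start, 1L)
  expect_equal(p$end, 6L)
  expect_equal(p$arm, 3L)
  expect_equal(p$mismatches, 0L)
  # poly-A cannot pair with itself: no palindromes possible
  expect_equal(nrow(findPalindromes(strrep("A", 50),
                                    minArm = 12, maxLoop = 5)), 0L)
})

test_that("a planted imperfect palindrome is recovered with its exact span", {
  set.seed(21)
  rec <- genomeRecipe(length = 3000L,
                      hrCassettes = data.frame(n_pal = 1L), seed = 21L)
  sim <- simulateGenome(rec)
  found <- findPalindromes(sim$genome)
  expect_equal(nrow(found), 1L)
  expect_equal(found$start, sim$truth$palindromes$start)
  expect_equal(found$end, sim$truth$palindromes$end)
})

test_that("detection equals the O(n^2) brute-force oracle on random 2-kb", {
  set.seed(33)
  for (rep in 1:3) {
    s <- random_dna(2000, at = 0.62)
    got <- findPalindromes(Genome(s, topology = "linear"),
                           minArm = 10L, maxLoop = 20L,
                           maxMismatchRate = 0.2)
    exp <- oracle_palindromes(s, minArm = 10L, maxLoop = 20L, rate = 0.2)
    expect_equal(got[, c("start", "end", "arm", "loop", "mismatches")],
                 exp, info = paste("rep", rep))
  }
})

test_that("reported palindromes satisfy their mismatch budget on re-check", {
  set.seed(17)
  s <- random_dna(4000, at = 0.7)
  found <- findPalindromes(Genome(s, topology = "linear"),
                           minArm = 10L, maxLoop = 30L)
  ch <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(found))) {
    k <- found$arm[i]
    lefts <- ch[found$start[i] + seq_len(k) - 1L]
    rights <- ch[found$end[i] - seq_len(k) + 1L]
    mm <- sum(comp[lefts] != rights)
    expect_equal(mm, found$mismatches[i])
    expect_lte(mm, ceiling(k * 0.2))
  }
})

test_that("Biostrings cross-checks a planted perfect palindrome", {
  set.seed(19)
  pal <- paste0("GCGAATTCAAGCTTAAGC", strrep("A", 8),
                oracle_revcomp("GCGAATTCAAGCTTAAGC"))
  s <- paste0(random_dna(300, at = 0), pal, random_dna(300, at = 0))
  ours <- findPalindromes(Genome(s, topology = "linear"),
                          minArm = 15, maxLoop = 10, maxMismatchRate = 0)
  bs <- Biostrings::findPalindromes(Biostrings::DNAString(s),
                                    min.armlength = 15, max.looplength = 10,
                                    max.mismatch = 0)
  expect_equal(nrow(ours), 1L)
  expect_equal(length(bs), 1L)
  expect_equal(ours$start, Biostrings::start(bs))
  expect_equal(ours$end, Biostrings::end(bs))
})

test_that("palindromes spanning the circular origin are found once", {
  core <- "TTCGAGTGAGTTTTCAAAATTTTGAAAACTCACTCGAA"   # perfect palindrome
  L <- 1500L
  bg <- strsplit(strrep("A", L), "")[[1]]   # poly-A: self-pairing impossible
  pos <- ((L - 14):(L - 15 + nchar(core)) - 1) %% L + 1
  bg[pos] <- strsplit(core, "")[[1]]
  g <- Genome(paste(bg, collapse = ""))
  found <- findPalindromes(g, minArm = 12, maxLoop = 10)
  expect_equal(nrow(found), 1L)
  expect_true(found$wraps)
  expect_equal(spanLength(found$start, found$end, L), nchar(core))
})

test_that("AT fraction of a loop-free perfect palindrome equals its arm's", {
  set.seed(27)
  for (i in 1:5) {
    arm <- random_dna(15, at = 0.6)
    pal <- paste0(arm, oracle_revcomp(arm))
    p <- findPalindromes(pal, minArm = 10, maxLoop = 0,
                         maxMismatchRate = 0)
    expect_equal(p$at_fraction[1], atFraction(Genome(arm)))
  }
})

test_that("hr clustering is single-linkage with a circular closure", {
  g <- Genome(random_dna(10000))
  pals <- data.frame(start = c(1000L, 1200L, 1350L, 5000L),
                     end = c(1060L, 1260L, 1410L, 5060L),
                     wraps = FALSE)
  hrs <- clusterHrs(pals, g, maxGap = 500L)
  expect_equal(nrow(hrs), 2L)
  expect_equal(hrs$n_palindromes, c(3L, 1L))
  expect_equal(hrs$start[1], 1000L)
  expect_equal(hrs$end[1], 1410L)
  # two palindromes 2 kb apart stay separate
  hrs2 <- clusterHrs(pals[c(1, 4), ], g, maxGap = 500L)
  expect_equal(nrow(hrs2), 2L)
  # cluster count is monotone non-increasing in maxGap
  gaps <- c(100L, 500L, 2000L, 5000L)
  counts <- vapply(gaps, function(mg) nrow(clusterHrs(pals, g, mg)), 0L)
  expect_true(all(diff(counts) <= 0L))
  # adjacency across the origin joins first and last clusters
  palsw <- data.frame(start = c(100L, 9900L), end = c(160L, 9960L),
                      wraps = FALSE)
  hrw <- clusterHrs(palsw, g, maxGap = 300L)
  expect_equal(nrow(hrw), 1L)
  expect_equal(hrw$start, 9900L)
  expect_equal(hrw$end, 160L)
})

test_that("conserved palindrome ends recover the planted flank block", {
  sim <- small_sim()
  pals <- findPalindromes(sim$genome)
  ce <- conservedEnds(pals, sim$genome, blockLen = 15L)
  expect_equal(ce$left, sim$recipe$flankBlock)
  expect_equal(ce$right, revComp(sim$recipe$flankBlock))
  expect_true(ce$palindromic)
  # 13-block is an infix of the 15-block
  ce13 <- conservedEnds(pals, sim$genome, blockLen = 13L)
  expect_true(grepl(ce13$left, ce$left, fixed = TRUE))
  expect_error(conservedEnds(pals[1, ], sim$genome), "insufficient-data")
})

test_that("conserved ends of perfect palindromes are reverse complements", {
  set.seed(29)
  flank <- "GATTACAGATTACAG"
  seqs <- vapply(1:4, function(i) {
    half <- paste0(flank, random_dna(10, at = 0.7))
    paste0(half, oracle_revcomp(half))
  }, "")
  L <- sum(nchar(seqs)) + 5000L
  bg <- strsplit(random_dna(L, at = 0), "")[[1]]
  at <- 1L
  rows <- list()
  for (s in seqs) {
    pos <- at + 1000L
    bg[pos:(pos + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    rows[[length(rows) + 1L]] <- data.frame(start = pos,
                                            end = pos + nchar(s) - 1L)
    at <- pos + nchar(s)
  }
  g <- Genome(paste(bg, collapse = ""), topology = "linear")
  pals <- do.call(rbind, rows)
  pals$wraps <- FALSE
  ce <- conservedEnds(pals, g, blockLen = 15L)
  expect_equal(ce$left, flank)
  expect_equal(ce$right, oracle_revcomp(flank))
  expect_true(ce$palindromic)
})

test_that("self-similarity finds planted duplications and inversions only", {
  set.seed(35)
  unit <- random_dna(120, at = 0.5)
  s <- paste0(random_dna(1500), unit, random_dna(1500), unit,
              random_dna(500))
  hits <- selfSimilarity(s, minLen = 100, minIdentity = 90)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$orientation, "direct")
  expect_gte(hits$length, 120L)
  # inverted copy
  s2 <- paste0(random_dna(1000), unit, random_dna(800),
               oracle_revcomp(unit), random_dna(400))
  hits2 <- selfSimilarity(s2, minLen = 100, minIdentity = 90)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$orientation, "revcomp")
  # repeat-free sequence: empty
  expect_equal(nrow(selfSimilarity(random_dna(3000), minLen = 100)), 0L)
})

test_that("direct repeats are reported with unit lengths and identity", {
  set.seed(37)
  unit <- random_dna(31, at = 0.75)
  region <- paste0(random_dna(40, at = 0.75), unit,
                   random_dna(22, at = 0.75), unit,
                   random_dna(40, at = 0.75))
  g <- Genome(paste0(random_dna(500), region, random_dna(500)),
              topology = "linear")
  dr <- findDirectRepeats(g, 501L, 500L + nchar(region), minUnit = 25L,
                          minIdentity = 90)
  expect_equal(nrow(dr), 1L)
  expect_gte(dr$unit_length1, 31L)
  expect_gte(dr$identity, 90)
  # random 300-bp region holds nothing at these thresholds
  g0 <- Genome(random_dna(1000), topology = "linear")
  expect_equal(nrow(findDirectRepeats(g0, 301L, 600L, minUnit = 25L,
                                      minIdentity = 90)), 0L)
})

test_that("imperfect direct-repeat pairs are found and deduplicated", {
  set.seed(39)
  b1 <- random_dna(79, at = 0.75)
  b2 <- strsplit(substr(b1, 1, 72), "")[[1]]
  for (p in sample(72, 7)) b2[p] <- setdiff(c("A","C","G","T"), b2[p])[1]
  region <- paste0(random_dna(30, at = 0.6), b1, random_dna(25, at = 0.6),
                   paste(b2, collapse = ""), random_dna(30, at = 0.6))
  g <- Genome(paste0(random_dna(400), region, random_dna(400)),
              topology = "linear")
  dr <- findDirectRepeats(g, 401L, 400L + nchar(region), minUnit = 25L,
                          minIdentity = 85)
  expect_equal(nrow(dr), 1L)
  expect_gte(dr$unit_length1, 50L)
  expect_gte(dr$identity, 85)
})

test_that("hairpin energies follow nearest-neighbor expectations", {
  gGC <- Genome(paste0(strrep("G", 10), "AAAA", strrep("C", 10)),
                topology = "linear")
  gAT <- Genome(paste0(strrep("A", 10), "AAAA", strrep("T", 10)),
                topology = "linear")
  dgGC <- hairpinDeltaG(gGC, 1, 24, arm = 10, loop = 4)
  dgAT <- hairpinDeltaG(gAT, 1, 24, arm = 10, loop = 4)
  expect_lt(dgGC, dgAT)         # G:C stems are more stable
  # a mismatch raises the free energy
  mm <- Genome(paste0(strrep("G", 10), "AAAA", strrep("C", 4), "A",
                      strrep("C", 5)), topology = "linear")
  expect_gt(hairpinDeltaG(mm, 1, 24, arm = 10, loop = 4), dgGC)
  expect_error(hairpinDeltaG(gGC, 1, 24, arm = 1, loop = 4),
               "undefined-structure")
})

test_that("stem energies equal a hand-summed nearest-neighbor oracle", {
  nn <- c(AA = -1.00, TT = -1.00, AT = -0.88, TA = -0.58,
          CA = -1.45, TG = -1.45, GT = -1.44, AC = -1.44,
          CT = -1.28, AG = -1.28, GA = -1.30, TC = -1.30,
          CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)
  loop_tab <- function(n) stats::approx(
    c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
    c(3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5, 4.6, 5.0, 5.1, 5.3, 5.5, 5.7,
      6.1, 6.3), xout = n)$y
  set.seed(41)
  for (i in 1:20) {
    k <- sample(4:12, 1)
    loop <- sample(3:20, 1)
    arm <- random_dna(k)
    # naive summation over adjacent pairs of a perfect stem
    ch <- strsplit(arm, "")[[1]]
    expected <- sum(nn[paste0(ch[-k], ch[-1])]) + loop_tab(loop)
    expect_equal(stemDeltaG(arm, oracle_revcomp(arm), loop), expected)
  }
})

test_that("non-hr-ori flagging requires repeats, AT-richness and hr context", {
  sim <- small_sim()   # ori cassette attached to the first hr
  ann <- runAnnotate(genome = sim$genome)
  expect_equal(sum(ann$ori_candidates$tier == 1L), 1L)
  # the flagged hr is the one carrying the planted direct repeats
  dr_mid <- mean(c(sim$truth$ori_region[["start"]],
                   sim$truth$ori_region[["end"]]))
  flagged <- ann$ori_candidates[ann$ori_candidates$tier == 1L, ]
  expect_true(flagged$start <= dr_mid && dr_mid <= flagged$end)
  # a plain hr with a single palindrome and no repeats is not flagged
  plain <- ann$hrs[ann$hrs$n_palindromes == 1L, ]
  expect_false(any(flagged$hr %in% plain$hr))
  # an AT-rich repeat region without hr context lands in tier 2
  set.seed(43)
  unit <- random_dna(31, at = 0.8)
  far <- paste0(unit, random_dna(20, at = 0.8), unit,
                random_dna(25, at = 0.8), unit)
  g2 <- Genome(paste0(random_dna(6000), far, random_dna(6000)))
  hrs_empty <- data.frame(hr = 1L, start = 100L, end = 200L,
                          n_palindromes = 1L)
  t2 <- flagNonHrOri(g2, hrs_empty,
                     extraRegions = data.frame(start = 6001L,
                                               end = 6000L + nchar(far)))
  expect_true(all(t2$tier[is.na(t2$hr)] == 2L))
  expect_gte(nrow(t2[t2$tier == 2L, ]), 1L)
})
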