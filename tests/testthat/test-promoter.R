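# Upstream windows, IUPAC matching against an explicit-alternation oracle,
# and early/late promoter classification.

test_that("upstream windows slice the coding strand, wrapping when circular", {
  set.seed(10)
  g <- Genome(random_dna(600))
  expect_identical(upstreamWindow(g, 151, 400, "+", 150),
                   subSequence(g, 1, 150, "+"))
  # wrap through the origin
  w <- upstreamWindow(g, 10, 200, "+", 150)
  expect_identical(w, subSequence(g, 460, 9, "+"))
  # minus strand: window lies 3' of the interval on the forward strand
  wm <- upstreamWindow(g, 100, 300, "-", 150)
  expect_identical(wm, subSequence(g, 301, 450, "-"))
  # linear truncation
  gl <- Genome(random_dna(300), topology = "linear")
  expect_equal(nchar(upstreamWindow(gl, 51, 200, "+", 150)), 50L)
})

test_that("windows equal independent slices of the doubled sequence", {
  set.seed(12)
  g <- Genome(random_dna(800))
  doubled <- paste0(genomeSeq(g), genomeSeq(g))
  for (i in 1:50) {
    start <- sample(800, 1)
    end <- (start + 3 * sample(20:60, 1) + 2 - 1) %% 800 + 1
    strand <- sample(c("+", "-"), 1)
    w <- upstreamWindow(g, start, end, strand, 150)
    if (strand == "+") {
      from <- (start - 150 - 1) %% 800 + 1
      expect_identical(w, substr(doubled, from, from + 149))
    } else {
      from <- end %% 800 + 1
      expect_identical(w, oracle_revcomp(substr(doubled, from, from + 149)))
    }
  }
})

test_that("IUPAC matching equals the regex-alternation oracle", {
  expect_equal(matchIupac("GTAAGCC", "DTAAG"), 1L)
  expect_equal(matchIupac("TATATAA", "TATAWAW"), 1L)
  expect_error(matchIupac("ACGT", "AXGT"), "pattern error")
  set.seed(14)
  pats <- c("TATAW", "TATAWAW", "TATAWTW", "CAKT", "DTAAG", "WGATAR",
            "WGATAY")
  for (i in 1:200) {
    w <- random_dna(60, at = 0.65)
    for (p in pats)
      expect_identical(matchIupac(w, p), oracle_iupac(w, p),
                       info = paste(w, p))
  }
})

test_that("classification applies the TATA-CAKT spacer and DTAAG rules", {
  pad <- function(n) strrep("C", n)
  early <- paste0(pad(10), "TATAAAT", pad(25), "CATT", pad(60))
  expect_equal(classifyPromoter(early)$call, "early")
  out_of_range <- paste0(pad(10), "TATAAAT", pad(50), "CATT", pad(39))
  expect_equal(classifyPromoter(out_of_range)$call, "none")
  both <- paste0(pad(10), "TATAT", pad(30), "CAGT", pad(20), "ATAAG",
                 pad(40))
  expect_equal(classifyPromoter(both)$call, "both")
  late_only <- paste0(pad(40), "GTAAG", pad(80))
  expect_equal(classifyPromoter(late_only)$call, "late")
  # purity: identical window, identical call
  expect_identical(classifyPromoter(both)$call, classifyPromoter(both)$call)
  # GATA reported but never changes the call
  gata <- paste0(pad(30), "TGATAG", pad(60))
  cl <- classifyPromoter(gata)
  expect_equal(cl$call, "none")
  expect_true("gata" %in% cl$hits$class)
})

test_that("spacer boundaries are inclusive at 20 and 40 intervening nt", {
  # TATAT matches only the 5-letter TATAW variant, pinning the TATA end
  pad <- function(n) strrep("C", n)
  at20 <- paste0(pad(5), "TATAT", pad(20), "CATT", pad(82))
  at40 <- paste0(pad(5), "TATAT", pad(40), "CATT", pad(62))
  at19 <- paste0(pad(5), "TATAT", pad(19), "CATT", pad(83))
  at41 <- paste0(pad(5), "TATAT", pad(41), "CATT", pad(61))
  expect_equal(classifyPromoter(at20)$call, "early")
  expect_equal(classifyPromoter(at40)$call, "early")
  expect_equal(classifyPromoter(at19)$call, "none")
  expect_equal(classifyPromoter(at41)$call, "none")
})

test_that("genome-wide scan counts match the planted promoter classes", {
  sim <- small_sim()
  ann <- runAnnotate(genome = sim$genome)
  truth <- sim$truth$orfs$promoter
  s <- ann$summary$promoters
  expect_equal(s$n_early, sum(truth %in% c("early", "both")))
  expect_equal(s$n_late, sum(truth %in% c("late", "both")))
  expect_equal(s$n_both, sum(truth == "both"))
  expect_lte(s$n_both, min(s$n_early, s$n_late))
  # motif-free genome: all zero
  g0 <- Genome(strrep("C", 2000))
  orfs0 <- data.frame(start = c(500L, 1200L), end = c(700L, 1400L),
                      strand = "+", ID = c("a", "b"))
  s0 <- scanPromoters(g0, orfs0)$summary
  expect_equal(c(s0$n_early, s0$n_late, s0$n_both), c(0L, 0L, 0L))
})
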