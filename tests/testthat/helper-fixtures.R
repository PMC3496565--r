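# Shared fixtures, generated once per test session.

.fixture_env <- new.env(parent = emptyenv())

# small annotated genome: 3 ORFs (one per promoter class mix), 2 hrs, ori
small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    rec <- genomeRecipe(
      length = 20000L,
      orfCassettes = data.frame(aa = c(60L, 120L, 200L),
                                strand = c("+", "-", "+"),
                                promoter = c("early", "late", "both")),
      hrCassettes = data.frame(n_pal = c(2L, 1L)),
      oriCassette = TRUE, seed = 7L)
    .fixture_env$small <- simulateGenome(rec)
  }
  .fixture_env$small
}

# flagship genome emulating the published architecture (119 kb, 40 ORFs,
# 16 hrs / 26 palindromes, non-hr ori); generated once, reused by the
# acceptance blocks
flagship_sim <- function(seed = 1L) {
  key <- paste0("flagship", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulateGenome(epapRecipe(seed = seed))
  .fixture_env[[key]]
}

flagship_annotation <- function(seed = 1L) {
  key <- paste0("flagann", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- runAnnotate(genome = flagship_sim(seed)$genome)
  .fixture_env[[key]]
}

span_key <- function(df) paste(df$start, df$end)
orf_key <- function(df) paste(df$start, df$end, df$strand)
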