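# Independent oracles, implemented from first principles and kept free of the
# package's own code paths.

# ---- alignment oracles -----------------------------------------------------

# Gotoh affine-gap global alignment score; a gap of length L costs
# open + ext * L
oracle_gotoh_score <- function(a, b, sub, open, ext) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub[x[i], y[j]]
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive enumeration of all global alignments (tiny inputs only):
# recursively expand (match | gap-in-a | gap-in-b), scoring affine gaps
oracle_enum_score <- function(a, b, sub, open, ext) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(x) && j > length(y)) return(0)
    best <- -Inf
    if (i <= length(x) && j <= length(y))
      best <- max(best, sub[x[i], y[j]] + rec(i + 1, j + 1, "m"))
    if (i <= length(x)) {
      g <- if (prev == "x") ext else open + ext
      best <- max(best, -g + rec(i + 1, j, "x"))
    }
    if (j <= length(y)) {
      g <- if (prev == "y") ext else open + ext
      best <- max(best, -g + rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

dna_submat <- function() {
  s <- matrix(-1, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                        c("A","C","G","T","N")))
  diag(s) <- 1; s["N", ] <- -1; s[, "N"] <- -1
  s
}

# ---- ORF oracle ------------------------------------------------------------

# brute-force scan: every ATG on either strand is extended codon by codon
# (wrapping on circular genomes) until a stop; canonical = longest ORF per
# stop codon position and strand
oracle_orfs <- function(g, minAa = 50L) {
  L <- genomeLength(g)
  ch <- strsplit(genomeSeq(g), "")[[1]]
  circ <- isCircular(g)
  base_at <- function(p) ch[(p - 1L) %% L + 1L]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  codon <- function(p, strand) {
    if (strand == "+") paste0(base_at(p), base_at(p + 1L), base_at(p + 2L))
    else paste0(comp[base_at(p + 2L)], comp[base_at(p + 1L)], comp[base_at(p)])
  }
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (strand in c("+", "-")) for (i in seq_len(L)) {
    if (!circ && i > L - 2L) next
    if (codon(i, strand) != "ATG") next
    # walk 3' on the coding strand
    p <- i; steps <- 0L; found <- FALSE
    repeat {
      p <- if (strand == "+") p + 3L else p - 3L
      steps <- steps + 1L
      if (circ) {
        if (steps * 3L > L) break
        pw <- (p - 1L) %% L + 1L
      } else {
        if (p < 1L || p > L - 2L) break
        pw <- p
      }
      if (codon(pw, strand) %in% stops) { found <- TRUE; break }
    }
    if (!found) next
    aa <- steps              # Met plus the non-stop codons walked over
    if (aa < minAa) next
    pw <- (p - 1L) %% L + 1L
    if (strand == "+") {
      s0 <- i; e0 <- (pw + 2L - 1L) %% L + 1L
    } else {
      s0 <- pw; e0 <- (i + 2L - 1L) %% L + 1L
    }
    rows[[length(rows) + 1L]] <-
      data.frame(start = s0, end = e0, strand = strand, aa_length = aa,
                 stop_key = paste(if (strand == "+") e0 else s0, strand))
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), aa_length = integer()))
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[, c("start", "end", "strand")]), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$stop_key), function(sel)
    sel[which.max(df$aa_length[sel])]))
  out <- df[sort(keep), c("start", "end", "strand", "aa_length")]
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

# ---- palindrome oracle -----------------------------------------------------

# O(n^2) brute force over every (center, loop) placement of a linear string,
# then the same best-first overlap reduction the detector documents
oracle_palindromes <- function(s, minArm = 15L, maxLoop = 40L, rate = 0.2,
                               maxArm = 100L, reduce = TRUE) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (l in 0:maxLoop) {
      j0 <- i + l + 1L
      if (j0 > n) break
      kmax <- min(i, n - j0 + 1L, maxArm)
      if (kmax < minArm) next
      ks <- seq_len(kmax)
      left <- ch[i - ks + 1L]
      right <- ch[j0 + ks - 1L]
      ok <- !is.na(comp[left]) & comp[left] == right
      m <- cumsum(!ok)
      feas <- ok & m <= ceiling(ks * rate)
      if (!any(feas)) next
      bk <- max(ks[feas])
      if (bk < minArm) next
      rows[[length(rows) + 1L]] <-
        data.frame(start = i - bk + 1L, end = j0 + bk - 1L, arm = bk,
                   loop = l, mismatches = m[bk])
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), arm = integer(),
                      loop = integer(), mismatches = integer()))
  df <- do.call(rbind, rows)
  if (reduce && nrow(df) > 1L) {
    ord <- order(-df$arm, df$mismatches, df$start)
    kept <- integer(0)
    for (i in ord) {
      clash <- any(vapply(kept, function(k)
        df$start[i] <= df$end[k] && df$end[i] >= df$start[k], TRUE))
      if (!clash) kept <- c(kept, i)
    }
    df <- df[sort(kept), , drop = FALSE]
  }
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- IUPAC oracle ----------------------------------------------------------

# expand a degenerate pattern into an explicit regex alternation and find all
# overlapping matches with a lookahead
oracle_iupac <- function(window, pattern) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", N = "[ACGT]",
               R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
               K = "[GT]", M = "[AC]", B = "[CGT]", V = "[ACG]",
               D = "[AGT]", H = "[ACT]")
  rx <- paste(classes[strsplit(toupper(pattern), "")[[1]]], collapse = "")
  m <- gregexpr(paste0("(?=", rx, ")"), toupper(window), perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# ---- misc ------------------------------------------------------------------

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
               replace = TRUE), collapse = "")
}

# reverse complement written independently of the package
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}
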