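# Discovery of imperfect palindromes (inverted repeats), their clustering into
# homologous regions (hrs), conserved palindrome-end consensus, direct-repeat
# pairs, and flagging of non-hr origin-like regions.

#' Find imperfect palindromes (approximate inverted repeats)
#'
#' A palindrome is a pair of equal-length arms, reverse complements of each
#' other up to a mismatch budget, separated by a loop.  At arm length `k` up
#' to `ceil(k * maxMismatchRate)` mismatches are tolerated; the reported arm
#' is maximal (the largest budget-respecting arm ending on a matching pair).
#' Overlapping calls are reduced to the best-scoring one (longest arm, then
#' fewest mismatches, then smallest start).  Circular genomes are scanned on
#' the doubled sequence and calls deduplicated modulo the genome length.
#'
#' Defaults reflect the structures described for tortricid-specific
#' granulovirus hrs: ~58-76 bp imperfect palindromes with conserved 15-bp
#' ends, hence `minArm = 15`.
#'
#' @param g a [Genome-class] or nucleotide string (treated as linear).
#' @param minArm minimum arm length (>= 6).
#' @param maxLoop maximum loop length.
#' @param maxMismatchRate mismatch budget per arm length.
#' @param maxArm arm-length cap for the scan.
#' @param reduce drop overlapping calls, keeping the best (default `TRUE`).
#' @return data.frame: start, end, arm, loop, mismatches, wraps, at_fraction.
#' @export
findPalindromes <- function(g, minArm = 15L, maxLoop = 40L,
                            maxMismatchRate = 0.2, maxArm = 100L,
                            reduce = TRUE) {
  stopifnot(minArm >= 2L)
  if (is.character(g)) g <- Genome(g, topology = "linear")
  L <- genomeLength(g)
  circ <- isCircular(g)
  s <- if (circ) paste0(genomeSeq(g), genomeSeq(g)) else genomeSeq(g)
  df <- .scan_palindromes_cpp(s, as.integer(minArm), as.integer(maxLoop),
                              maxMismatchRate, as.integer(maxArm))
  if (circ && nrow(df)) {
    keep <- df$start <= L & (df$end - df$start + 1L) <= L
    df <- df[keep, , drop = FALSE]
    df$end <- (df$end - 1L) %% L + 1L
  }
  df$wraps <- df$start > df$end
  if (reduce && nrow(df) > 1L) {
    ord <- order(-df$arm, df$mismatches, df$start)
    kept <- integer(0)
    for (i in ord) {
      clash <- FALSE
      for (k in kept) {
        if (.circ_overlap(df$start[i], df$end[i], df$start[k], df$end[k],
                          L) > 0L) { clash <- TRUE; break }
      }
      if (!clash) kept <- c(kept, i)
    }
    df <- df[sort(kept), , drop = FALSE]
  }
  if (nrow(df)) {
    df$at_fraction <- vapply(seq_len(nrow(df)), function(i)
      atFraction(subSequence(g, df$start[i], df$end[i], "+")),
      numeric(1))
  } else df$at_fraction <- numeric(0)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Cluster palindromes into homologous regions (hrs)
#'
#' Single-linkage clustering: palindromes whose spans lie within `maxGap` nt
#' of each other join one hr; the hr interval is the envelope of its members.
#' On circular genomes adjacency across the origin is honored.  hr ids are
#' assigned clockwise.
#'
#' @param pals palindrome table from [findPalindromes()], sorted by start.
#' @param g the [Genome-class].
#' @param maxGap maximum gap between clustered palindromes (default 1000 nt).
#' @return data.frame: hr, start, end, n_palindromes, members (comma-joined
#'   row indices into `pals`).
#' @export
clusterHrs <- function(pals, g, maxGap = 1000L) {
  if (!nrow(pals))
    return(data.frame(hr = integer(), start = integer(), end = integer(),
                      n_palindromes = integer(), members = character()))
  L <- genomeLength(g)
  n <- nrow(pals)
  ord <- order(pals$start)
  p <- pals[ord, , drop = FALSE]
  ends_lin <- ifelse(p$wraps, p$end + L, p$end)   # unwrapped ends
  cluster <- integer(n)
  cl <- 1L
  cluster[1L] <- 1L
  reach <- ends_lin[1L]
  for (i in seq_len(n)[-1L]) {
    if (p$start[i] - reach - 1L <= maxGap) {
      cluster[i] <- cl
      reach <- max(reach, ends_lin[i])
    } else {
      cl <- cl + 1L
      cluster[i] <- cl
      reach <- ends_lin[i]
    }
  }
  # circular closure: merge the last cluster into the first when the gap
  # across the origin is small
  merged_wrap <- FALSE; wrap_sel <- integer(0)
  if (isCircular(g) && cl > 1L) {
    last_sel <- which(cluster == cl)
    gap_wrap <- p$start[1L] + L - max(ends_lin[last_sel]) - 1L
    if (gap_wrap <= maxGap) {
      merged_wrap <- TRUE; wrap_sel <- last_sel
      cluster[last_sel] <- 1L
    }
  }
  ids <- sort(unique(cluster))
  out <- do.call(rbind, lapply(ids, function(id) {
    sel <- which(cluster == id)
    if (merged_wrap && id == 1L) {
      # envelope runs from the late-coordinate members through the origin
      early <- setdiff(sel, wrap_sel)
      start <- min(p$start[wrap_sel])
      end <- (max(ends_lin[early]) - 1L) %% L + 1L
    } else {
      start <- min(p$start[sel])
      end <- (max(ends_lin[sel]) - 1L) %% L + 1L
    }
    data.frame(hr = id, start = start, end = end,
               n_palindromes = length(sel),
               members = paste(ord[sel], collapse = ","))
  }))
  out <- out[order(out$start), , drop = FALSE]
  out$hr <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Consensus of conserved palindrome ends
#'
#' Aligns all palindrome sequences with [progressiveMsa()], extracts the first
#' and last `blockLen` aligned columns, and returns the majority consensus of
#' each flank, the full position-frequency matrix, and whether the left flank
#' is approximately the reverse complement of the right flank.
#'
#' @param pals palindrome table.
#' @param g the [Genome-class].
#' @param blockLen conserved end-block length (default 15, per tortricid GV
#'   hrs; 13 reproduces the cross-species consensus block).
#' @return list: `left`, `right` (consensus strings), `pfm` (from
#'   [columnStats()]), `palindromic` (logical), `msa`.
#' @export
conservedEnds <- function(pals, g, blockLen = 15L) {
  if (nrow(pals) < 3L)
    stop("insufficient-data error: need >= 3 palindromes")
  seqs <- vapply(seq_len(nrow(pals)), function(i)
    subSequence(g, pals$start[i], pals$end[i], "+"), character(1))
  names(seqs) <- sprintf("pal%02d", seq_along(seqs))
  msa <- progressiveMsa(seqs, alignParams("dna"))
  stats <- columnStats(msa)
  nc <- nchar(msa$rows[[1]])
  cons <- strsplit(stats$consensus, "")[[1]]
  left <- paste(cons[seq_len(min(blockLen, nc))], collapse = "")
  right <- paste(cons[seq.int(max(1L, nc - blockLen + 1L), nc)], collapse = "")
  # degenerate consensus positions (N) count as matches for the symmetry check
  rc <- strsplit(revComp(right), "")[[1]]
  lf <- strsplit(left, "")[[1]]
  m <- min(length(rc), length(lf))
  agree <- mean(lf[1:m] == rc[1:m] | lf[1:m] == "N" | rc[1:m] == "N")
  list(left = left, right = right, pfm = stats,
       palindromic = agree >= 0.8, msa = msa)
}

# ---- repeat pairs (direct / inverted) --------------------------------------

# ungapped seed-and-extend self-comparison of a sequence; returns hit pairs
.seed_extend <- function(s1, s2, k, min_len, min_identity, same = FALSE,
                         max_kmer_hits = 50L) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 < k || n2 < k) return(NULL)
  km1 <- substring(s1, seq_len(n1 - k + 1L), seq_len(n1 - k + 1L) + k - 1L)
  km2 <- if (same) km1 else
    substring(s2, seq_len(n2 - k + 1L), seq_len(n2 - k + 1L) + k - 1L)
  idx2 <- split(seq_along(km2), km2)
  idx2 <- idx2[lengths(idx2) <= max_kmer_hits]
  ch1 <- strsplit(s1, "")[[1]]; ch2 <- strsplit(s2, "")[[1]]
  hits <- list()
  seen <- character(0)
  for (i in seq_along(km1)) {
    js <- idx2[[km1[i]]]
    if (is.null(js)) next
    for (j in js) {
      if (same && j <= i) next                     # off-diagonal only
      # extend left
      a <- i; b <- j; mat <- k; len <- k
      while (a > 1L && b > 1L) {
        ok <- ch1[a - 1L] == ch2[b - 1L] & ch1[a - 1L] %in% c("A", "C", "G", "T")
        if ((mat + ok) / (len + 1L) * 100 < min_identity) break
        a <- a - 1L; b <- b - 1L; len <- len + 1L; mat <- mat + ok
      }
      e1 <- i + k - 1L; e2 <- j + k - 1L
      while (e1 < n1 && e2 < n2) {
        ok <- ch1[e1 + 1L] == ch2[e2 + 1L] & ch1[e1 + 1L] %in% c("A", "C", "G", "T")
        if ((mat + ok) / (len + 1L) * 100 < min_identity) break
        e1 <- e1 + 1L; e2 <- e2 + 1L; len <- len + 1L; mat <- mat + ok
      }
      if (len >= min_len && 100 * mat / len >= min_identity) {
        key <- paste(a, b, e1, e2)
        if (!key %in% seen) {
          seen <- c(seen, key)
          hits[[length(hits) + 1L]] <-
            data.frame(start1 = a, end1 = e1, start2 = b, end2 = e2,
                       length = len, identity = 100 * mat / len)
        }
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

# reduce to maximal non-redundant hits: gap-free hits from one repeat pair
# share a diagonal (start2 - start1 for direct matches; start1 + end2 for
# inverted ones, where extension moves the two copies in opposite
# directions); keep the longest per overlapping same-diagonal group, then
# drop hits nested inside longer hits
.nonredundant_hits <- function(df, inverted = FALSE) {
  if (is.null(df) || nrow(df) < 2L) return(df)
  diag_key <- if (inverted) df$start1 + df$end2 else df$start2 - df$start1
  ord <- order(-df$length, df$start1)
  keep <- logical(nrow(df))
  for (i in ord) {
    redundant <- FALSE
    for (j in which(keep)) {
      same_diag <- diag_key[i] == diag_key[j]
      overlaps <- df$start1[i] <= df$end1[j] && df$end1[i] >= df$start1[j]
      nested <- df$start1[i] >= df$start1[j] && df$end1[i] <= df$end1[j] &&
        df$start2[i] >= df$start2[j] && df$end2[i] <= df$end2[j]
      if (nested || (same_diag && overlaps)) { redundant <- TRUE; break }
    }
    if (!redundant) keep[i] <- TRUE
  }
  out <- df[keep, , drop = FALSE]
  out[order(out$start1), , drop = FALSE]
}

#' Genome self-similarity (repeat) scan
#'
#' k-mer-seeded, gap-free extended local matches of the genome against itself
#' (off-diagonal only) and against its reverse complement; the trivial
#' full-length self-match is excluded by construction.
#'
#' @param g a [Genome-class] or string.
#' @param minLen minimum reported hit length (>= 8).
#' @param minIdentity minimum percent identity.
#' @param k seed length.
#' @return data.frame with both intervals, orientation (`"direct"` /
#'   `"revcomp"`), length, identity.
#' @export
selfSimilarity <- function(g, minLen = 50L, minIdentity = 90, k = 12L) {
  stopifnot(minLen >= 8L)
  if (is.character(g)) g <- Genome(g, topology = "linear")
  s <- genomeSeq(g)
  L <- nchar(s)
  dir <- .seed_extend(s, s, k, minLen, minIdentity, same = TRUE)
  if (!is.null(dir)) dir$orientation <- "direct"
  rc <- revComp(s)
  inv <- .seed_extend(s, rc, k, minLen, minIdentity, same = FALSE)
  if (!is.null(inv)) {
    # map revcomp coordinates back to forward coordinates
    s2 <- L - inv$end2 + 1L
    e2 <- L - inv$start2 + 1L
    inv$start2 <- s2; inv$end2 <- e2
    # drop mirror duplicates and self-overlapping palindromic hits
    inv <- inv[inv$start1 < inv$start2, , drop = FALSE]
    if (nrow(inv)) inv$orientation <- "revcomp" else inv <- NULL
  }
  out <- rbind(.nonredundant_hits(dir),
               .nonredundant_hits(inv, inverted = TRUE))
  if (is.null(out))
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      length = integer(), identity = numeric(),
                      orientation = character()))
  rownames(out) <- NULL
  out
}

#' Direct-repeat pairs within a region
#'
#' Same-orientation repeat pairs inside `[start, end]`, maximal and
#' non-redundant, reported with unit lengths and percent identity.
#'
#' @param g a [Genome-class].
#' @param start,end region to scan (1-based inclusive; may wrap).
#' @param minUnit minimum repeat unit length.
#' @param minIdentity minimum percent identity between the two copies.
#' @param k seed length.
#' @return data.frame: start1, end1, start2, end2 (genome coordinates),
#'   unit_length1, unit_length2, identity.
#' @export
findDirectRepeats <- function(g, start, end, minUnit = 25L, minIdentity = 85,
                              k = 10L) {
  region <- subSequence(g, start, end, "+")
  hits <- .seed_extend(region, region, k, minUnit, minIdentity, same = TRUE)
  hits <- .nonredundant_hits(hits)
  if (is.null(hits) || !nrow(hits))
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      unit_length1 = integer(), unit_length2 = integer(),
                      identity = numeric()))
  hits <- hits[hits$end1 < hits$start2, , drop = FALSE]  # non-overlapping pairs
  L <- genomeLength(g)
  tog <- function(p) (start + p - 2L) %% L + 1L          # region -> genome
  data.frame(start1 = tog(hits$start1), end1 = tog(hits$end1),
             start2 = tog(hits$start2), end2 = tog(hits$end2),
             unit_length1 = hits$end1 - hits$start1 + 1L,
             unit_length2 = hits$end2 - hits$start2 + 1L,
             identity = hits$identity)
}

#' Flag candidate non-hr origin-like regions
#'
#' A candidate must (i) contain at least two direct-repeat pairs within
#' `flank` nt of an hr envelope, and (ii) be AT-rich above `atThreshold` over
#' the repeat region (the envelope of the direct-repeat pairs — the ori-like
#' element itself; the hr supplies context, not composition).  Regions
#' supplied via `extraRegions` that satisfy the repeat and AT criteria but
#' lack hr context are reported at tier 2, not as candidates.
#'
#' @param g a [Genome-class].
#' @param hrs hr table from [clusterHrs()].
#' @param atThreshold minimum AT fraction of the evidence region.
#' @param flank how far around each hr envelope to look (default 1000 nt).
#' @param minUnit,minIdentity direct-repeat detection parameters.
#' @param extraRegions optional data.frame (start, end) of AT-rich repeat
#'   regions to evaluate without hr context.
#' @return data.frame: hr (NA for tier 2), start, end, at_fraction,
#'   n_direct_repeat_pairs, tier (1 = candidate non-hr ori, 2 = repeat region
#'   without hr context).
#' @export
flagNonHrOri <- function(g, hrs, atThreshold = 0.65, flank = 1000L,
                         minUnit = 25L, minIdentity = 85,
                         extraRegions = NULL) {
  L <- genomeLength(g)
  out <- list()
  evaluate <- function(ws, we, hr_id, tier) {
    dr <- findDirectRepeats(g, ws, we, minUnit = minUnit,
                            minIdentity = minIdentity)
    if (nrow(dr) < 2L) return(NULL)
    # composition is judged on the repeat region itself
    es <- min(dr$start1)
    ee <- max(dr$end2)
    at <- atFraction(subSequence(g, es, ee, "+"))
    if (at < atThreshold) return(NULL)
    data.frame(hr = hr_id, start = es, end = ee, at_fraction = at,
               n_direct_repeat_pairs = nrow(dr), tier = tier)
  }
  for (i in seq_len(nrow(hrs))) {
    ws <- (hrs$start[i] - flank - 1L) %% L + 1L
    we <- (hrs$end[i] + flank - 1L) %% L + 1L
    out[[length(out) + 1L]] <- evaluate(ws, we, hrs$hr[i], 1L)
  }
  for (i in seq_len(NROW(extraRegions))) {
    near_hr <- any(vapply(seq_len(nrow(hrs)), function(k)
      .circ_overlap((hrs$start[k] - flank - 1L) %% L + 1L,
                    (hrs$end[k] + flank - 1L) %% L + 1L,
                    extraRegions$start[i], extraRegions$end[i], L) > 0L,
      TRUE))
    if (!near_hr)
      out[[length(out) + 1L]] <-
        evaluate(extraRegions$start[i], extraRegions$end[i], NA_integer_, 2L)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(hr = integer(), start = integer(), end = integer(),
                      at_fraction = numeric(),
                      n_direct_repeat_pairs = integer(), tier = integer())
  rownames(out) <- NULL
  out
}
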