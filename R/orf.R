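# ATG-initiated ORF calling on both strands of a (circular) genome, the
# minimal-overlap selection rule, serial numbering from the granulin-style
# anchor, and genome summary statistics.
#
# ORF intervals include the stop codon (GenBank CDS convention), so a protein
# of `aa` residues spans 3*(aa+1) nt.  Frames continue across the circular
# origin: the scan runs on the doubled sequence and calls are deduplicated
# modulo genome length.

.STOPS <- c("TAA", "TAG", "TGA")

# scan one linear strand string; returns candidates in local coordinates
.scan_strand <- function(str, minAa, countStopInMin) {
  n <- nchar(str)
  if (n < 6L) return(NULL)
  ch <- strsplit(str, "")[[1]]
  idx <- seq_len(n - 2L)
  cod <- paste0(ch[idx], ch[idx + 1L], ch[idx + 2L])
  out <- vector("list", 3L)
  for (f in 0:2) {
    pos <- seq.int(1L + f, n - 2L, by = 3L)
    cpos <- cod[pos]
    stops <- pos[cpos %in% .STOPS]
    atgs <- pos[cpos == "ATG"]
    if (!length(stops) || !length(atgs)) next
    nxt <- findInterval(atgs, stops) + 1L          # index of next stop > atg
    ok <- nxt <= length(stops)
    atgs <- atgs[ok]; nxt <- nxt[ok]
    if (!length(atgs)) next
    p <- stops[nxt]
    aa <- (p - atgs) %/% 3L
    min_eff <- if (countStopInMin) minAa - 1L else minAa
    keep <- aa >= min_eff
    if (!any(keep)) next
    atgs <- atgs[keep]; p <- p[keep]; aa <- aa[keep]
    canon <- !duplicated(p)                         # 5'-most ATG per segment
    out[[f + 1L]] <- data.frame(a = atgs, e = p + 2L, aa = aa, canonical = canon)
  }
  do.call(rbind, out)
}

#' Enumerate ATG-initiated ORF candidates
#'
#' All six frames are scanned; on circular genomes frames continue across the
#' origin.  For every stop-to-stop segment the 5'-most ATG (longest variant)
#' is the canonical candidate; shorter in-frame ATG variants are kept in a
#' secondary table.  No candidate contains an internal stop.
#'
#' @param g a [Genome-class].
#' @param minAa minimum protein length in amino acids (Met counted, stop
#'   excluded; default 50).
#' @param countStopInMin if `TRUE`, adopt the literal "150 nt" reading in
#'   which the stop codon counts towards the minimum (i.e. protein >= 49 aa
#'   at the default).
#' @param translate attach protein translations (default `TRUE`).
#' @return list with `orfs` (canonical candidates: start, end, strand, wraps,
#'   aa_length, protein, ID) and `variants` (shorter in-frame starts).
#' @export
enumerateOrfs <- function(g, minAa = 50L, countStopInMin = FALSE,
                          translate = TRUE) {
  L <- genomeLength(g)
  if (L < 3L) stop("range error: genome shorter than one codon")
  circ <- isCircular(g)
  s <- genomeSeq(g)
  fwd <- if (circ) paste0(s, s) else s
  rev <- revComp(fwd)
  n2 <- nchar(fwd)
  res <- list()
  for (strand in c("+", "-")) {
    cand <- .scan_strand(if (strand == "+") fwd else rev, minAa, countStopInMin)
    if (is.null(cand)) next
    if (strand == "+") {
      pa <- cand$a; pe <- cand$e
    } else {  # map reverse-strand local coords back to forward coords
      pa <- n2 + 1L - cand$e; pe <- n2 + 1L - cand$a
    }
    span <- pe - pa + 1L
    if (circ) {
      keep <- span <= L            # drop ORFs longer than the genome
      cand <- cand[keep, , drop = FALSE]; pa <- pa[keep]; pe <- pe[keep]
      start <- (pa - 1L) %% L + 1L
      end <- (pe - 1L) %% L + 1L
    } else {
      start <- pa; end <- pe
    }
    if (!nrow(cand)) next
    res[[strand]] <- data.frame(start = start, end = end, strand = strand,
                                wraps = start > end, aa_length = cand$aa,
                                canonical = cand$canonical,
                                stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, res)
  if (is.null(df) || !nrow(df)) {
    empty <- data.frame(start = integer(), end = integer(),
                        strand = character(), wraps = logical(),
                        aa_length = integer(), protein = character(),
                        ID = character())
    return(list(orfs = empty, variants = empty))
  }
  df <- df[!duplicated(df[, c("start", "end", "strand")]), , drop = FALSE]
  # canonical = longest variant per stop codon (stop at `end` on +, `start`
  # on -); recomputed here because the doubled-sequence scan can truncate the
  # stop-to-stop segment of the copy nearest the origin
  stop_key <- paste(ifelse(df$strand == "+", df$end, df$start), df$strand)
  longest <- stats::ave(df$aa_length, stop_key, FUN = max)
  df$canonical <- df$aa_length == longest
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  if (translate) {
    df$protein <- vapply(seq_len(nrow(df)), function(i)
      translateCds(subSequence(g, df$start[i], df$end[i], df$strand[i])),
      character(1))
  } else df$protein <- NA_character_
  df$ID <- sprintf("orf_%s_%d_%d", ifelse(df$strand == "+", "p", "m"),
                   df$start, df$end)
  orfs <- df[df$canonical, setdiff(names(df), "canonical"), drop = FALSE]
  variants <- df[!df$canonical, setdiff(names(df), "canonical"), drop = FALSE]
  rownames(orfs) <- rownames(variants) <- NULL
  list(orfs = orfs, variants = variants)
}

# circular overlap (nt) between two inclusive intervals on a genome of size L
.circ_overlap <- function(s1, e1, s2, e2, L) {
  pieces <- function(s, e) {
    if (s <= e) list(c(s, e)) else list(c(s, L), c(1L, e))
  }
  p1 <- pieces(s1, e1); p2 <- pieces(s2, e2)
  tot <- 0L
  for (x in p1) for (y in p2)
    tot <- tot + max(0L, min(x[2], y[2]) - max(x[1], y[1]) + 1L)
  tot
}

#' Select a final ORF set under the minimal-overlap rule
#'
#' Greedy longest-first retention: a candidate is kept iff its nucleotide
#' overlap with every already-retained ORF is at most `maxOverlapNt`,
#' regardless of strand.  Length ties are broken by smaller start, then by
#' `+` strand.  The result is sorted by clockwise start.
#'
#' @param orfs candidate table from [enumerateOrfs()]`$orfs`.
#' @param g the [Genome-class] (for circular overlap arithmetic).
#' @param maxOverlapNt maximum tolerated pairwise overlap (default 75 nt).
#' @return filtered ORF table sorted by start.
#' @export
selectMinimalOverlap <- function(orfs, g, maxOverlapNt = 75L) {
  if (!nrow(orfs)) return(orfs)
  L <- genomeLength(g)
  span <- spanLength(orfs$start, orfs$end, L)
  ord <- order(-span, orfs$start, orfs$strand != "+")
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (.circ_overlap(orfs$start[i], orfs$end[i],
                        orfs$start[k], orfs$end[k], L) > maxOverlapNt) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- orfs[sort(kept), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# reflect an interval table for the reverse-complemented genome
.reflect_features <- function(df, L) {
  ns <- L - df$end + 1L
  ne <- L - df$start + 1L
  df$start <- ns; df$end <- ne
  df$strand <- ifelse(df$strand == "+", "-", "+")
  df
}

.rotate_features <- function(df, shift, L) {
  df$start <- (df$start - 1L - shift) %% L + 1L
  df$end <- (df$end - 1L - shift) %% L + 1L
  df
}

#' Rotate/reflect genome and ORFs so an anchor ORF starts at position 1
#'
#' Emulates the granulin convention: coordinates are rotated (and, for a
#' minus-strand anchor, reflected) so the anchor starts at position 1 on the
#' plus strand, and serials 1..n are assigned clockwise by start position.
#'
#' @param orfs ORF table.
#' @param g the [Genome-class].
#' @param anchor `ID` of the anchor ORF (must be present in `orfs`).
#' @return list with rotated `genome`, transformed `orfs` (with `serial`), and
#'   the transform description.
#' @export
numberFromAnchor <- function(orfs, g, anchor) {
  idx <- match(anchor, orfs$ID)
  if (is.na(idx)) stop("lookup error: anchor '", anchor, "' not among ORFs")
  L <- genomeLength(g)
  seqs <- genomeSeq(g)
  df <- orfs
  reflected <- df$strand[idx] == "-"
  if (reflected) {
    seqs <- revComp(seqs)
    df <- .reflect_features(df, L)
  }
  shift <- df$start[idx] - 1L
  if (shift > 0L)
    seqs <- paste0(substr(seqs, shift + 1L, L), substr(seqs, 1L, shift))
  df <- .rotate_features(df, shift, L)
  df$wraps <- df$start > df$end
  df <- df[order(df$start, df$end), , drop = FALSE]
  df$serial <- seq_len(nrow(df))
  rownames(df) <- NULL
  g2 <- Genome(seqs, id = genomeId(g), topology = g@topology)
  list(genome = g2, orfs = df,
       transform = list(reflected = reflected, shift = shift))
}

#' Summary statistics of an annotated genome
#'
#' @param orfs ORF table (start/end/strand, wrap-aware).
#' @param g the [Genome-class].
#' @param anchorStrand strand regarded as "clockwise" (default `"+"`).
#' @return list: `n_orfs`, `coding_fraction` (union of ORF spans / genome
#'   length, overlaps counted once), `n_same_strand` / `n_opposite_strand`
#'   relative to `anchorStrand`, and `at_fraction`.
#' @export
genomeStats <- function(orfs, g, anchorStrand = "+") {
  L <- genomeLength(g)
  covered <- logical(L)
  for (i in seq_len(nrow(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    if (s <= e) covered[s:e] <- TRUE
    else { covered[s:L] <- TRUE; covered[1:e] <- TRUE }
  }
  list(n_orfs = nrow(orfs),
       coding_fraction = mean(covered),
       n_same_strand = sum(orfs$strand == anchorStrand),
       n_opposite_strand = sum(orfs$strand != anchorStrand),
       at_fraction = atFraction(g))
}
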