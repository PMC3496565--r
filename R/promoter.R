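# Early/late baculovirus promoter classification: a 150-bp window upstream of
# each start codon is scanned (coding strand only) for TATA-box variants with
# a CAKT initiator 20-40 nt downstream (early) and for the DTAAG late
# initiator; GATA motifs are reported but never change the call.

#' Default promoter motif set
#'
#' IUPAC one-letter codes (W=A/T, K=G/T, D=A/G/T, R=A/G, Y=C/T).
#'
#' @param spacerMin,spacerMax allowed number of nucleotides between the last
#'   TATA base and the first CAKT base (inclusive bounds, default 20-40).
#' @param window upstream window length in nt (default 150).
#' @param anchor `"tata_end"` (default) or `"tata_start"`: where the spacer is
#'   measured from.
#' @return list describing the motif set.
#' @export
motifSet <- function(spacerMin = 20L, spacerMax = 40L, window = 150L,
                     anchor = c("tata_end", "tata_start")) {
  stopifnot(spacerMin <= spacerMax, window >= 1L)
  list(early_tata = c(TATAWAW = "TATAWAW", TATAWTW = "TATAWTW", TATAW = "TATAW"),
       early_inr = c(CAKT = "CAKT"),
       late_inr = c(DTAAG = "DTAAG"),
       gata = c(WGATAR = "WGATAR", WGATAY = "WGATAY"),
       spacer = c(spacerMin, spacerMax),
       window = window,
       anchor = match.arg(anchor))
}

#' Upstream window of an ORF
#'
#' The `window` nucleotides immediately 5' of the A of the start codon, on the
#' ORF's coding strand.  Offset 1 is the base farthest from the ATG.  Circular
#' genomes wrap through the origin; on linear genomes the window is truncated
#' at the molecule end.
#'
#' @param g a [Genome-class].
#' @param start,end,strand the ORF interval (start codon at `start` for `+`,
#'   at `end` for `-`).
#' @param window window length (default 150).
#' @return nucleotide string (possibly shorter than `window` on linear
#'   genomes).
#' @export
upstreamWindow <- function(g, start, end, strand = "+", window = 150L) {
  stopifnot(window >= 1L)
  L <- genomeLength(g)
  if (isCircular(g)) window <- min(window, L - 1L)  # window cannot lap itself
  if (strand == "+") {
    to <- start - 1L
    from <- start - window
    if (isCircular(g)) {
      from <- (from - 1L) %% L + 1L
      to <- (to - 1L) %% L + 1L
      return(subSequence(g, from, to, "+"))
    }
    if (to < 1L) return("")
    subSequence(g, max(1L, from), to, "+")
  } else {
    from <- end + 1L
    to <- end + window
    if (isCircular(g)) {
      from <- (from - 1L) %% L + 1L
      to <- (to - 1L) %% L + 1L
      return(subSequence(g, from, to, "-"))
    }
    if (from > L) return("")
    subSequence(g, from, min(L, to), "-")
  }
}

#' Match a degenerate IUPAC pattern
#'
#' All (overlapping) match start offsets of `pattern` in `window`; offset 1 is
#' the window base farthest from the ATG.  Coding strand only.
#'
#' @param window nucleotide string.
#' @param pattern IUPAC pattern (e.g. `"DTAAG"`).
#' @return integer vector of 1-based offsets.
#' @export
matchIupac <- function(window, pattern) {
  if (!nzchar(pattern)) stop("pattern error: empty pattern")
  if (grepl("[^ACGTNRYSWKMBDHV]", toupper(pattern)))
    stop("pattern error: invalid IUPAC letter in '", pattern, "'")
  if (nchar(window) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(toupper(pattern),
                                Biostrings::DNAString(toupper(window)),
                                fixed = FALSE)
  as.integer(Biostrings::start(m))
}

#' Classify the promoter content of one upstream window
#'
#' Early requires a TATA variant plus a CAKT initiator whose start lies within
#' the spacer range downstream of the TATA match (measured from the TATA end
#' by default); late requires a DTAAG anywhere in the window.  GATA hits are
#' reported but never affect the call.
#'
#' @param window upstream window (from [upstreamWindow()]).
#' @param motifs a [motifSet()].
#' @return list with `call` (`"early"`, `"late"`, `"both"`, `"none"`) and
#'   `hits` (data.frame motif/offset/match).
#' @export
classifyPromoter <- function(window, motifs = motifSet()) {
  window <- toupper(window)
  hits <- list()
  addhits <- function(patterns, class) {
    for (nm in names(patterns)) {
      off <- matchIupac(window, patterns[[nm]])
      if (length(off))
        hits[[length(hits) + 1L]] <<- data.frame(
          motif = nm, class = class, offset = off,
          match = substring(window, off, off + nchar(patterns[[nm]]) - 1L))
    }
  }
  addhits(motifs$early_tata, "tata")
  addhits(motifs$early_inr, "cakt")
  addhits(motifs$late_inr, "late")
  addhits(motifs$gata, "gata")
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(motif = character(), class = character(),
                          offset = integer(), match = character())
  tata <- hits[hits$class == "tata", , drop = FALSE]
  cakt <- hits[hits$class == "cakt", , drop = FALSE]
  early <- FALSE
  if (nrow(tata) && nrow(cakt)) {
    for (i in seq_len(nrow(tata))) {
      ref <- if (motifs$anchor == "tata_end")
        tata$offset[i] + nchar(tata$match[i]) - 1L else tata$offset[i]
      gap <- cakt$offset - ref - 1L   # nt strictly between TATA end and CAKT
      if (any(gap >= motifs$spacer[1] & gap <= motifs$spacer[2])) {
        early <- TRUE; break
      }
    }
  }
  late <- any(hits$class == "late")
  call <- if (early && late) "both" else if (early) "early"
          else if (late) "late" else "none"
  list(call = call, hits = hits)
}

#' Scan all ORFs for promoter motifs
#'
#' @param g a [Genome-class].
#' @param orfs ORF table (start/end/strand/ID).
#' @param motifs a [motifSet()].
#' @return list with `calls` (per-ORF table), `hits` (all motif hits), and
#'   `summary`: `n_early` (ORFs with an early element, regardless of late),
#'   `n_late` (late element, regardless of early), `n_both`, plus the
#'   exclusive counts `n_early_only` / `n_late_only` / `n_none` so that both
#'   counting conventions are available.
#' @export
scanPromoters <- function(g, orfs, motifs = motifSet()) {
  calls <- character(nrow(orfs))
  allhits <- list()
  for (i in seq_len(nrow(orfs))) {
    w <- upstreamWindow(g, orfs$start[i], orfs$end[i], orfs$strand[i],
                        motifs$window)
    cl <- classifyPromoter(w, motifs)
    calls[i] <- cl$call
    if (nrow(cl$hits)) {
      cl$hits$ID <- orfs$ID[i]
      allhits[[length(allhits) + 1L]] <- cl$hits
    }
  }
  calls_df <- data.frame(ID = orfs$ID, start = orfs$start, end = orfs$end,
                         strand = orfs$strand, call = calls,
                         stringsAsFactors = FALSE)
  summary <- list(
    n_early = sum(calls %in% c("early", "both")),
    n_late = sum(calls %in% c("late", "both")),
    n_both = sum(calls == "both"),
    n_early_only = sum(calls == "early"),
    n_late_only = sum(calls == "late"),
    n_none = sum(calls == "none"))
  list(calls = calls_df,
       hits = if (length(allhits)) do.call(rbind, allhits) else NULL,
       summary = summary)
}
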