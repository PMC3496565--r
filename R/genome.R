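#' Genome: a (possibly circular) nucleotide sequence
#'
#' S4 container for a single viral genome.  The sequence is stored upper-cased
#' over the IUPAC DNA alphabet; `topology` records whether coordinate
#' arithmetic may wrap through the origin.  By convention (the granulin-anchor
#' convention used for granulovirus maps) position 1 is the A of the granulin
#' start codon and "clockwise" is the granulin coding strand; genomes lacking
#' that annotation keep their native origin.
#'
#' @slot id single character identifier.
#' @slot sequence upper-case nucleotide string.
#' @slot topology `"circular"` or `"linear"`.
#'
#' @seealso [readGenomeFasta()], [subSequence()], [atFraction()]
#' @export
setClass("Genome",
         representation(id = "character", sequence = "character",
                        topology = "character"))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (length(object@sequence) != 1L)
    msg <- c(msg, "sequence must be a single string")
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", object@sequence)
  if (nzchar(bad)) {
    pos <- regexpr(sprintf("[^ACGTNRYSWKMBDHV]"), object@sequence)
    msg <- c(msg, sprintf("non-IUPAC character '%s' at position %d",
                          substr(object@sequence, pos, pos), pos))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Genome
#'
#' @param sequence nucleotide string (any case; upper-cased on ingestion).
#' @param id genome identifier.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return a [Genome-class] object.
#' @examples
#' g <- Genome("acgtACGT", id = "toy")
#' genomeLength(g)
#' @export
Genome <- function(sequence, id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  bad <- regexpr("[^ACGTNRYSWKMBDHV]", sequence)
  if (bad > 0L)
    stop(sprintf("format error: non-nucleotide character '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  new("Genome", id = id, sequence = sequence, topology = topology)
}

#' @rdname Genome
#' @param g a `Genome`.
#' @export
genomeId <- function(g) g@id

#' @rdname Genome
#' @export
genomeSeq <- function(g) g@sequence

#' @rdname Genome
#' @export
genomeLength <- function(g) nchar(g@sequence)

#' @rdname Genome
#' @export
isCircular <- function(g) g@topology == "circular"

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome '%s': %s bp, %s\n", object@id,
              format(nchar(object@sequence), big.mark = ","),
              object@topology))
  n <- nchar(object@sequence)
  if (n <= 60) cat(" ", object@sequence, "\n")
  else cat(sprintf("  %s...%s\n", substr(object@sequence, 1, 30),
                   substr(object@sequence, n - 29, n)))
})

#' Read a genome from FASTA
#'
#' @param path FASTA file (single- or multi-record).
#' @param id record to select when the file holds several; default the first.
#' @param topology assumed topology of the molecule (default circular, the
#'   natural state of a baculovirus chromosome).
#' @return a [Genome-class].
#' @export
readGenomeFasta <- function(path, id = NULL,
                            topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("format error: file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("format error: ", conditionMessage(e)))
  if (length(set) == 0L) stop("format error: empty FASTA: ", path)
  if (is.null(id)) idx <- 1L
  else {
    idx <- match(id, sub("\\s.*$", "", names(set)))
    if (is.na(idx)) stop("format error: record '", id, "' not in ", path)
  }
  Genome(as.character(set[[idx]]), id = sub("\\s.*$", "", names(set)[idx]),
         topology = topology)
}

#' Write a genome to FASTA
#'
#' @param g a [Genome-class].
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(g, path, width = 70L) {
  set <- Biostrings::DNAStringSet(setNames(genomeSeq(g), genomeId(g)))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' AT fraction of a genome
#'
#' (#A + #T) / (#A + #C + #G + #T).  `N` and other ambiguity codes are
#' excluded from numerator and denominator.
#'
#' @param g a [Genome-class] or nucleotide string.
#' @return fraction in \[0, 1\].
#' @export
atFraction <- function(g) {
  s <- if (is(g, "Genome")) genomeSeq(g) else toupper(g)
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                     letters = c("A", "C", "G", "T"))
  tot <- sum(cnt)
  if (tot == 0L) stop("undefined-content error: no unambiguous bases")
  unname((cnt[["A"]] + cnt[["T"]]) / tot)
}

# ---- circular coordinate arithmetic ---------------------------------------

#' Span length of a (possibly wrapping) interval
#'
#' Intervals are 1-based inclusive.  On a circular genome `start > end`
#' denotes a feature wrapping the origin.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param genomeLength length of the molecule (required for wraps).
#' @return integer span in bp.
#' @examples
#' spanLength(58352, 58479)  # 128
#' @export
spanLength <- function(start, end, genomeLength = NA_integer_) {
  w <- start > end
  out <- end - start + 1L
  if (any(w)) {
    if (any(is.na(genomeLength)))
      stop("range error: wrapping interval needs genomeLength")
    out[w] <- (genomeLength - start + 1L + end)[w]
  }
  as.integer(out)
}

#' Extract a strand-oriented subsequence
#'
#' Returns the sequence of the interval on the requested strand (reverse
#' complement for `-`).  Wrapping intervals (`start > end`) concatenate the
#' suffix and the prefix of a circular genome.
#'
#' @param g a [Genome-class].
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return nucleotide string.
#' @export
subSequence <- function(g, start, end, strand = "+") {
  L <- genomeLength(g)
  if (start < 1L || end < 1L || start > L || end > L)
    stop("range error: interval outside genome")
  if (start > end) {
    if (!isCircular(g))
      stop("topology error: wrapping interval on a linear genome")
    s <- paste0(substr(genomeSeq(g), start, L), substr(genomeSeq(g), 1L, end))
  } else {
    s <- substr(genomeSeq(g), start, end)
  }
  if (strand == "-") revComp(s) else s
}

#' Translate a CDS
#'
#' Standard genetic code.  Translation stops at the first stop codon; the
#' terminal stop is not part of the protein.  With `strict = TRUE` an internal
#' stop (any stop before the final codon) is an error rather than a silent
#' truncation.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @param strict flag internal stop codons.
#' @return amino-acid string.
#' @examples
#' translateCds("ATGAAATAA")  # "MK"
#' @export
translateCds <- function(cds, strict = FALSE) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("frame error: CDS length ", nchar(cds), " not divisible by 3")
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve",
    no.init.codon = TRUE)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    if (strict && stop_at < nchar(aa))
      stop("internal stop codon at amino-acid position ", stop_at)
    aa <- substr(aa, 1L, stop_at - 1L)
  }
  aa
}
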