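# Feature tables are plain data.frames with 1-based inclusive `start`/`end`,
# `strand` ("+"/"-"), `type`, and `ID`.  On a circular genome start > end marks
# a feature wrapping the origin (GenBank-style coordinates; BED emission
# converts to 0-based half-open).

#' Build a feature table
#'
#' @param start,end 1-based inclusive coordinates (`start > end` = wraps the
#'   origin on a circular genome).
#' @param strand `"+"` or `"-"` per feature.
#' @param type GFF3 feature type (default `"CDS"`).
#' @param ID unique feature identifiers.
#' @param ... further attribute columns, recycled as needed.
#' @return data.frame feature table.
#' @export
featureTable <- function(start, end, strand = "+", type = "CDS",
                         ID = NULL, ...) {
  n <- max(length(start), length(end))
  if (is.null(ID)) ID <- sprintf("feat%03d", seq_len(n))
  data.frame(start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n), type = rep_len(type, n),
             ID = ID, ..., stringsAsFactors = FALSE)
}

# split wrapping rows into linear parts sharing the ID; `part` column 1/2
.split_wraps <- function(features, genomeLength) {
  w <- features$start > features$end
  if (!any(w)) {
    features$part <- 1L
    return(features)
  }
  lin <- features[!w, , drop = FALSE]
  if (nrow(lin)) lin$part <- 1L
  wrap <- features[w, , drop = FALSE]
  p1 <- wrap; p1$end <- rep(genomeLength, nrow(wrap)); p1$part <- 1L
  p2 <- wrap; p2$start <- 1L; p2$part <- 2L
  out <- rbind(lin, p1, p2)
  out[order(out$ID, out$part), , drop = FALSE]
}

.features_to_granges <- function(features, g) {
  parts <- .split_wraps(features, genomeLength(g))
  gr <- GenomicRanges::GRanges(
    seqnames = genomeId(g),
    ranges = IRanges::IRanges(parts$start, parts$end),
    strand = parts$strand)
  S4Vectors::mcols(gr)$type <- parts$type
  S4Vectors::mcols(gr)$ID <- parts$ID
  # CDS rows need a phase for GFF3; parts are emitted in frame
  S4Vectors::mcols(gr)$phase <- ifelse(parts$type == "CDS", 0L, NA_integer_)
  extra <- setdiff(names(parts), c("start", "end", "strand", "type", "ID", "part"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- parts[[col]]
  gr
}

#' Write features to GFF3 or BED
#'
#' GFF3 is written 1-based inclusive; BED 0-based half-open.  Features that
#' wrap the circular origin are split into two parts sharing their `ID`
#' attribute (BED: the name column), so the conversion is lossless — see
#' [readFeatureGff3()].
#'
#' @param features feature table (see [featureTable()]).
#' @param g the [Genome-class] the features live on.
#' @param path output file.
#' @param kind `"gff3"`, `"bed"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(features, g, path, kind = c("gff3", "bed", "tsv")) {
  kind <- match.arg(kind)
  L <- genomeLength(g)
  bad <- features$start < 1L | features$end < 1L |
    features$start > L | features$end > L
  if (any(bad)) stop("range error: feature outside genome: ",
                     paste(features$ID[bad], collapse = ", "))
  if (any(features$start > features$end) && !isCircular(g))
    stop("topology error: wrapping feature on a linear genome")
  if (kind == "tsv") {
    write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gr <- .features_to_granges(features, g)
  if (kind == "gff3") {
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    names(gr) <- S4Vectors::mcols(gr)$ID
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read a GFF3 feature table, reassembling origin-wrapping parts
#'
#' Two parts sharing an `ID` where one ends at the genome's last base and the
#' other starts at base 1 are merged back into a single wrapping feature.
#'
#' @param path GFF3 file.
#' @param genomeLength genome length in bp (needed to recognize wraps).
#' @param types optional filter on feature types (e.g. `"CDS"`).
#' @return feature table data.frame.
#' @export
readFeatureGff3 <- function(path, genomeLength, types = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(S4Vectors::mcols(gr)$type),
                   ID = as.character(S4Vectors::mcols(gr)$ID),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  if (!is.null(types)) df <- df[df$type %in% types, , drop = FALSE]
  if (anyDuplicated(df$ID)) {
    pieces <- split(df, df$ID)
    df <- do.call(rbind, lapply(pieces, function(p) {
      if (nrow(p) == 1L) return(p)
      if (nrow(p) == 2L) {
        hi <- p[which.max(p$start), , drop = FALSE]
        lo <- p[which.min(p$start), , drop = FALSE]
        if (hi$end == genomeLength && lo$start == 1L) {
          hi$end <- lo$end       # reassembled wrap: start > end
          return(hi)
        }
      }
      stop("format error: cannot reassemble parts of feature ", p$ID[1])
    }))
  }
  rownames(df) <- NULL
  df[order(df$start), , drop = FALSE]
}
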