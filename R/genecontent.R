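# Ortholog tables by reciprocal best hit over global protein alignments,
# gene-content classification across genus panels, and composite (fusion)
# gene annotation.

# shared k-mer counts used as an alignment prescreen
.kmer_counts <- function(seqs, k = 4L) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
}

# best-hit table of A vs B: for each protein in A the best-scoring partner
.best_hits <- function(A, B, params, scoreFloor, prescreenK, prescreenTop) {
  kmA <- .kmer_counts(A, prescreenK)
  kmB <- .kmer_counts(B, prescreenK)
  out <- data.frame(query = character(), hit = character(),
                    score = numeric(), identity = numeric())
  for (i in seq_along(A)) {
    shared <- vapply(kmB, function(x) length(intersect(kmA[[i]], x)), 0L)
    cand <- order(-shared)[seq_len(min(prescreenTop, length(B)))]
    cand <- cand[shared[cand] > 0L]
    if (!length(cand)) next
    best <- NULL
    for (j in cand) {
      al <- globalAlign(A[[i]], B[[j]], params)
      pid <- percentIdentity(al, "aligned_columns")
      if (is.null(best) || al$score > best$score ||
          (al$score == best$score &&
           (pid > best$identity ||
            (pid == best$identity && names(B)[j] < best$hit)))) {
        best <- list(hit = names(B)[j], score = al$score, identity = pid)
      }
    }
    if (best$score >= scoreFloor)
      out <- rbind(out, data.frame(query = names(A)[i], hit = best$hit,
                                   score = best$score,
                                   identity = best$identity))
  }
  out
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is kept iff b is a's best-scoring global alignment in B and
#' vice versa, with score >= `scoreFloor`.  Ties break deterministically by
#' identity, then id order.  A shared-k-mer prescreen limits the all-vs-all
#' alignment cost.
#'
#' @param A,B named character vectors (or `AAStringSet`s) of proteins.
#' @param params alignment parameters (default protein BLOSUM62 10/0.1).
#' @param scoreFloor minimum alignment score for a pairing (default 0).
#' @param prescreenK,prescreenTop k-mer prescreen parameters.
#' @return data.frame: idA, idB, score, identity.
#' @export
reciprocalBestHits <- function(A, B, params = NULL, scoreFloor = 0,
                               prescreenK = 4L, prescreenTop = 10L) {
  A <- .as_named_chr(A); B <- .as_named_chr(B)
  stopifnot(length(A) >= 1L, length(B) >= 1L)
  if (is.null(params)) params <- alignParams("protein")
  ab <- .best_hits(A, B, params, scoreFloor, prescreenK, prescreenTop)
  ba <- .best_hits(B, A, params, scoreFloor, prescreenK, prescreenTop)
  key_ab <- paste(ab$query, ab$hit)
  key_ba <- paste(ba$hit, ba$query)
  keep <- key_ab %in% key_ba
  out <- data.frame(idA = ab$query[keep], idB = ab$hit[keep],
                    score = ab$score[keep], identity = ab$identity[keep],
                    stringsAsFactors = FALSE)
  out[order(out$idA), , drop = FALSE]
}

.as_named_chr <- function(x) {
  if (is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (is.null(names(x))) names(x) <- sprintf("p%03d", seq_along(x))
  x
}

#' Ortholog table across several proteomes
#'
#' Families are seeded by the reference proteome (first element); every other
#' genome contributes at most one member per family, by reciprocal best hit
#' against the reference.
#'
#' @param proteomes named list of named protein vectors; first = reference.
#' @param ... passed to [reciprocalBestHits()].
#' @return data.frame: family (reference protein id), one column per genome
#'   holding the member id or `NA`.
#' @export
orthologTable <- function(proteomes, ...) {
  stopifnot(length(proteomes) >= 2L)
  if (is.null(names(proteomes)))
    names(proteomes) <- sprintf("genome%02d", seq_along(proteomes))
  ref <- .as_named_chr(proteomes[[1]])
  tab <- data.frame(family = names(ref), stringsAsFactors = FALSE)
  tab[[names(proteomes)[1]]] <- names(ref)
  for (gi in seq_along(proteomes)[-1]) {
    rbh <- reciprocalBestHits(ref, proteomes[[gi]], ...)
    tab[[names(proteomes)[gi]]] <- rbh$idB[match(tab$family, rbh$idA)]
  }
  tab
}

#' Classify gene families by presence across genus panels
#'
#' @param table ortholog table from [orthologTable()] (family + one member
#'   column per genome).
#' @param panels named list of character vectors assigning genome column
#'   names to genera (e.g. `list(betabaculovirus = ..., alphabaculovirus =
#'   ...)`); panels must partition the genome set.
#' @param focal the focal genome column (default the first genome column).
#' @param gvPanel name of the betabaculovirus panel (defaults to the panel
#'   containing the focal genome).
#' @return the table with a `class` column: `core` (present in every genome of
#'   every panel), `unique` (only the focal genome), `gv_specific` (>= 1
#'   betabaculovirus, none outside that panel), `lepidopteran` (present in all
#'   genomes of the lepidopteran-infecting panels but missing somewhere else),
#'   otherwise `other`.
#' @export
classifyFamilies <- function(table, panels, focal = NULL, gvPanel = NULL) {
  genomes <- setdiff(colnames(table), c("family", "class"))
  if (any(lengths(panels) == 0L)) stop("configuration error: empty panel")
  if (!setequal(unlist(panels), genomes))
    stop("configuration error: panels must partition the genome set")
  if (is.null(focal)) focal <- genomes[1]
  if (is.null(gvPanel))
    gvPanel <- names(panels)[vapply(panels, function(p) focal %in% p, TRUE)][1]
  lep_panels <- intersect(names(panels), c("alphabaculovirus", gvPanel))
  pres <- !is.na(as.matrix(table[, genomes, drop = FALSE]))
  cls <- vapply(seq_len(nrow(table)), function(i) {
    p <- pres[i, ]
    in_panel <- vapply(panels, function(g) any(p[g]), TRUE)
    all_panel <- vapply(panels, function(g) all(p[g]), TRUE)
    if (all(all_panel)) return("core")
    if (sum(p) == 1L && p[[focal]]) return("unique")
    if (in_panel[[gvPanel]] && !any(in_panel[setdiff(names(panels), gvPanel)]))
      return("gv_specific")
    if (length(lep_panels) > 1L && all(all_panel[lep_panels]))
      return("lepidopteran")
    "other"
  }, character(1))
  table$class <- cls
  table
}

#' Locate reference domains within a composite (fusion) protein
#'
#' Each reference domain is globally aligned into the composite protein
#' (global in the domain, local in the protein); segment spans and the
#' unassigned linker are reported.  A domain that cannot be placed above the
#' score floor yields an absent-domain row, not an error.
#'
#' @param protein composite protein sequence.
#' @param domains named character vector of reference domain sequences.
#' @param params alignment parameters (default protein).
#' @param scoreFloor minimum placement score.
#' @return list with `segments` (domain, aa_start, aa_end, length, score,
#'   present), `linker_length` (aa between consecutive placed segments), and
#'   `protein_length`.
#' @export
annotateFusion <- function(protein, domains, params = NULL, scoreFloor = 0) {
  protein <- toupper(protein)
  domains <- .as_named_chr(domains)
  if (is.null(params)) params <- alignParams("protein")
  segs <- lapply(names(domains), function(nm) {
    pa <- Biostrings::pairwiseAlignment(
      toupper(domains[[nm]]), protein, type = "global-local",
      substitutionMatrix = params$submat,
      gapOpening = params$gapOpen, gapExtension = params$gapExtend)
    sc <- Biostrings::score(pa)
    if (sc < scoreFloor)
      return(data.frame(domain = nm, aa_start = NA_integer_,
                        aa_end = NA_integer_, length = NA_integer_,
                        score = sc, present = FALSE))
    rng <- pa@subject@range
    data.frame(domain = nm, aa_start = IRanges::start(rng),
               aa_end = IRanges::end(rng),
               length = IRanges::width(rng), score = sc, present = TRUE)
  })
  segs <- do.call(rbind, segs)
  placed <- segs[segs$present, , drop = FALSE]
  placed <- placed[order(placed$aa_start), , drop = FALSE]
  if (nrow(placed) > 1L &&
      any(placed$aa_start[-1] <= placed$aa_end[-nrow(placed)]))
    warning("placed domains overlap; linker lengths may be negative")
  linker <- if (nrow(placed) > 1L)
    placed$aa_start[-1] - placed$aa_end[-nrow(placed)] - 1L
  else integer(0)
  list(segments = segs, linker_length = linker,
       protein_length = nchar(protein))
}

#' Packaged EpapGV gene-classification table
#'
#' The published per-ORF classification of the EpapGV genome, transcribed from
#' the printed gene lists: the betabaculovirus-specific (GV-exclusive) set,
#' the ORFs unique to EpapGV, and the individually named core genes.  The core
#' list covers the core genes named with serials in the text and is therefore
#' partial; it is shipped for lookup convenience, not as an exhaustive core
#' catalogue.
#'
#' @return data.frame: serial, name, class.
#' @export
epapGeneClasses <- function() {
  path <- system.file("extdata", "epapgv_gene_classes.tsv",
                      package = "baculokit")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
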