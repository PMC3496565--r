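# Gene-parity synteny between genome pairs: ortholog positional indices,
# greedy chaining into colinear blocks (forward or inverted), and an
# inversion report with bp spans.

#' Gene-parity points for a genome pair
#'
#' One point per shared family: the positional index of the member in each
#' genome's clockwise gene order, plus whether the strands agree.
#'
#' @param orderA,orderB data.frames with columns `gene` (family id), `strand`,
#'   and optionally `start`/`end` (bp intervals); rows in clockwise order.
#' @return data.frame: gene, indexA, indexB, strand_agreement.
#' @export
parityPairs <- function(orderA, orderB) {
  shared <- intersect(orderA$gene, orderB$gene)
  if (!length(shared)) {
    warning("no shared families between the two genomes")
    return(data.frame(gene = character(), indexA = integer(),
                      indexB = integer(), strand_agreement = logical()))
  }
  ia <- match(shared, orderA$gene)
  ib <- match(shared, orderB$gene)
  out <- data.frame(gene = shared, indexA = ia, indexB = ib,
                    strand_agreement = orderA$strand[ia] == orderB$strand[ib],
                    stringsAsFactors = FALSE)
  out[order(out$indexA), , drop = FALSE]
}

#' Chain parity points into colinear blocks
#'
#' Points are visited in `indexA` order and chained greedily into monotone
#' runs: `indexB` increasing (forward) or decreasing (inverted), tolerating
#' index gaps up to `maxIndexGap` in both genomes (isolated unshared genes
#' inside a block).  A block's orientation is fixed by its first two points.
#'
#' @param pairs from [parityPairs()].
#' @param maxIndexGap maximum index gap inside a block (default 2).
#' @param orderA,orderB optional gene-order tables with `start`/`end` columns;
#'   when given, bp spans are computed from member intervals.
#' @return data.frame of blocks: orientation, fromA/toA, fromB/toB (index
#'   ranges), n_genes, span_bpA, span_bpB.
#' @export
colinearBlocks <- function(pairs, maxIndexGap = 2L,
                           orderA = NULL, orderB = NULL) {
  if (!nrow(pairs)) stop("no parity points")
  p <- pairs[order(pairs$indexA), , drop = FALSE]
  n <- nrow(p)
  block <- integer(n); orient <- character(n)
  bid <- 1L; block[1L] <- bid
  dirn <- 0L   # 0 = undecided, +1 forward, -1 inverted
  for (i in seq_len(n)[-1L]) {
    gapA <- p$indexA[i] - p$indexA[i - 1L] - 1L
    stepB <- p$indexB[i] - p$indexB[i - 1L]
    gapB <- abs(stepB) - 1L
    want <- sign(stepB)
    compatible <- gapA <= maxIndexGap && gapB <= maxIndexGap &&
      want != 0L && (dirn == 0L || want == dirn)
    if (compatible) {
      block[i] <- bid
      if (dirn == 0L) dirn <- want
    } else {
      bid <- bid + 1L
      block[i] <- bid
      dirn <- 0L
    }
  }
  # label each block by the accumulated direction (singletons = forward)
  blocks <- lapply(split(seq_len(n), block), function(sel) {
    ori <- if (length(sel) >= 2L) {
      if (p$indexB[sel[2L]] > p$indexB[sel[1L]]) "forward" else "inverted"
    } else "forward"
    span_bp <- function(ord, idx) {
      if (is.null(ord) || is.null(ord$start)) return(NA_integer_)
      rows <- range(idx)
      lo <- min(ord$start[rows[1]:rows[2]]); hi <- max(ord$end[rows[1]:rows[2]])
      hi - lo + 1L
    }
    data.frame(orientation = ori,
               fromA = min(p$indexA[sel]), toA = max(p$indexA[sel]),
               fromB = min(p$indexB[sel]), toB = max(p$indexB[sel]),
               n_genes = length(sel),
               span_bpA = span_bp(orderA, range(p$indexA[sel])),
               span_bpB = span_bp(orderB, range(p$indexB[sel])))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Report inverted blocks
#'
#' @param blocks from [colinearBlocks()].
#' @return the inverted blocks sorted by decreasing bp span (gene count when
#'   spans are unavailable).
#' @export
inversionReport <- function(blocks) {
  inv <- blocks[blocks$orientation == "inverted", , drop = FALSE]
  if (!nrow(inv)) return(inv)
  key <- if (all(is.na(inv$span_bpA))) inv$n_genes else inv$span_bpA
  inv <- inv[order(-key), , drop = FALSE]
  rownames(inv) <- NULL
  inv
}
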