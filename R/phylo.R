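# Concatenated core-gene distance phylogeny: complete-deletion column masking,
# supermatrix concatenation, gamma-corrected Poisson (or Dayhoff ML) distances,
# deterministic UPGMA, site bootstrap, Newick I/O.

#' Remove every alignment column containing a gap or missing symbol
#'
#' "Complete deletion" in the distance-phylogenetics sense: a column is kept
#' only if every row holds a residue (`-`, `.`, `?`, `X`/`N` missing symbols
#' excluded).
#'
#' @param rows named character vector of equal-length gapped rows.
#' @param missing characters treated as missing (default gap and `?`).
#' @return character matrix (rows x columns) of retained columns.
#' @export
maskCompleteDeletion <- function(rows, missing = c("-", ".", "?")) {
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  keep <- apply(m, 2, function(col) !any(col %in% missing))
  out <- m[, keep, drop = FALSE]
  if (ncol(out) == 0L) stop("empty-matrix error: all columns masked")
  out
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Rows are matched by taxon name, not position.  Every gene must cover the
#' full taxon set (the definition of a core gene).
#'
#' @param alignments list of named character vectors (gapped rows), one per
#'   gene; names of the list are gene names.
#' @param mask apply [maskCompleteDeletion()] per gene before concatenation.
#' @return list with `matrix` (taxa x columns character matrix) and
#'   `boundaries` (data.frame gene/from/to).
#' @export
concatenateAlignments <- function(alignments, mask = TRUE) {
  if (is.null(names(alignments)))
    names(alignments) <- sprintf("gene%03d", seq_along(alignments))
  taxa <- sort(names(alignments[[1]]))
  mats <- lapply(names(alignments), function(gn) {
    al <- alignments[[gn]]
    if (is.null(names(al)) || !setequal(names(al), taxa))
      stop("completeness error: gene '", gn, "' does not cover the taxon set")
    m <- if (mask) maskCompleteDeletion(al) else {
      mm <- do.call(rbind, strsplit(al, "")); rownames(mm) <- names(al); mm
    }
    m[taxa, , drop = FALSE]
  })
  widths <- vapply(mats, ncol, 0L)
  to <- cumsum(widths)
  list(matrix = do.call(cbind, mats),
       boundaries = data.frame(gene = names(alignments),
                               from = c(1L, head(to, -1) + 1L), to = to))
}

#' Gamma-corrected pairwise distance matrix
#'
#' For each taxon pair the proportion of differing sites `p` is transformed to
#' `d = a * ((1 - p)^(-1/a) - 1)` where `a` is the gamma shape parameter
#' describing among-site rate variation; as `a -> Inf` this tends to the
#' Poisson correction `-log(1 - p)`.  `model = "dayhoff_ml"` instead delegates
#' to [phangorn::dist.ml()] with the Dayhoff rate matrix.
#'
#' @param sm supermatrix from [concatenateAlignments()] (or a character
#'   matrix, taxa x sites).
#' @param model `"gamma_poisson"` (default) or `"dayhoff_ml"`.
#' @param gammaShape gamma shape parameter `a` (default 2.25).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(sm, model = c("gamma_poisson", "dayhoff_ml"),
                           gammaShape = 2.25) {
  model <- match.arg(model)
  m <- if (is.list(sm)) sm$matrix else sm
  if (nrow(m) < 2L || ncol(m) < 1L)
    stop("matrix error: need >= 2 taxa and >= 1 column")
  taxa <- rownames(m)
  if (model == "dayhoff_ml") {
    pd <- phangorn::phyDat(m, type = "AA")
    D <- as.matrix(phangorn::dist.ml(pd, model = "Dayhoff"))
    return(D[taxa, taxa])
  }
  stopifnot(gammaShape > 0)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- mean(m[i, ] != m[j, ])
    if (p >= 1)
      stop("infinite-distance error: taxa ", taxa[i], " and ", taxa[j],
           " share no sites")
    D[i, j] <- D[j, i] <- gammaDistance(p, gammaShape)
  }
  D
}

#' @rdname distanceMatrix
#' @param p proportion of differing sites.
#' @export
gammaDistance <- function(p, gammaShape = 2.25) {
  gammaShape * ((1 - p)^(-1 / gammaShape) - 1)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with merge height `d/2` (ultrametric).
#' Tie-breaks are deterministic: among equal minimal distances the pair with
#' the lexicographically smallest (sorted) label pair is merged first.
#'
#' @param D symmetric non-negative matrix with dimnames, or a `dist`.
#' @return an [ape::phylo] rooted ultrametric tree with branch lengths.
#' @export
upgmaTree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (any(is.na(D)) || any(D < 0)) stop("matrix error: NaN or negative entries")
  if (max(abs(D - t(D))) > 1e-9) stop("matrix error: matrix not symmetric")
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(n >= 2L)
  size <- rep(1L, n)
  height <- rep(0, n)            # current cluster heights
  active <- seq_len(n)
  id <- -seq_len(n)              # hclust convention: negatives = singletons
  key <- labels                  # smallest member label per cluster (sorted key)
  merge <- matrix(0L, n - 1, 2)
  mh <- numeric(n - 1)
  Dw <- D
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL; bestd <- Inf; bestkey <- NULL
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      d <- Dw[a, b]
      pk <- paste(sort(c(key[a], key[b])), collapse = "\r")
      if (d < bestd - 1e-12 ||
          (abs(d - bestd) <= 1e-12 && !is.null(bestkey) && pk < bestkey)) {
        bestd <- d; best <- c(a, b); bestkey <- pk
      }
    }
    a <- best[1]; b <- best[2]
    merge[step, ] <- id[c(a, b)]
    mh[step] <- bestd
    newrow <- (size[a] * Dw[a, ] + size[b] * Dw[b, ]) / (size[a] + size[b])
    keep <- setdiff(seq_len(k), c(a, b))
    Dw <- rbind(cbind(Dw[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    size <- c(size[keep], size[a] + size[b])
    key <- c(key[keep], min(key[a], key[b]))
    id <- c(id[keep], step)
    active <- c(active[keep], 0L)
  }
  hc <- structure(list(merge = merge, height = mh, order = .hc_order(merge),
                       labels = labels, method = "average"),
                  class = "hclust")
  ape::as.phylo(hc)   # edge lengths = height differences / 2 => merge at d/2
}

.hc_order <- function(merge) {
  n <- nrow(merge) + 1L
  rec <- function(i) {
    if (i < 0) return(-i)
    c(rec(merge[i, 1]), rec(merge[i, 2]))
  }
  rec(nrow(merge))
}

#' Node heights of an ultrametric tree
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @return numeric vector of root-to-node distances subtracted from tree
#'   height, named by node number.
#' @export
nodeHeights <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Site-bootstrap supports for the full-data UPGMA tree
#'
#' Columns of the supermatrix are resampled with replacement `nReps` times;
#' each replicate is re-analysed with the same distance model and UPGMA; the
#' support of each internal node of the full-data tree is the percentage of
#' replicates whose tree contains the same clade.
#'
#' @param sm supermatrix (list from [concatenateAlignments()] or matrix).
#' @param nReps number of bootstrap replicates.
#' @param seed integer seed (reproducible).
#' @inheritParams distanceMatrix
#' @return the full-data tree with `node.label` set to supports in \[0, 100\].
#' @export
bootstrapUpgma <- function(sm, nReps = 100L, seed = 1L,
                           model = "gamma_poisson", gammaShape = 2.25) {
  stopifnot(nReps >= 1L)
  m <- if (is.list(sm)) sm$matrix else sm
  full <- upgmaTree(distanceMatrix(m, model = model, gammaShape = gammaShape))
  set.seed(seed)
  boots <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[r]] <- upgmaTree(distanceMatrix(m[, cols, drop = FALSE],
                                           model = model,
                                           gammaShape = gammaShape))
  }
  counts <- ape::prop.clades(full, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  full$node.label <- round(100 * counts / nReps, 1)
  full
}

#' Write / read Newick with supports as internal node labels
#'
#' @param tree [ape::phylo].
#' @param path output file.
#' @return `path` invisibly; `readNewick` returns the parsed tree.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
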