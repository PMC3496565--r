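# Pairwise and progressive alignment used by the repeat, gene-content and
# phylogeny stages.  Pairwise global alignment delegates to Biostrings
# (Needleman-Wunsch with affine gaps, deterministic traceback); the
# progressive aligner merges profiles in UPGMA guide-tree order.

.is_dna <- function(x) all(grepl("^[ACGTN-]*$", toupper(x)))

#' Default alignment parameters
#'
#' DNA: match +1 / mismatch -1 / gap open 2 / gap extend 1 (N scores as a
#' mismatch against everything).  Protein: BLOSUM62, gap open 10 / extend 0.1
#' — the classic pairwise settings for viral protein comparisons.  A gap of
#' length L costs `gapOpen + gapExtend * L`.
#'
#' @param type `"dna"` or `"protein"`.
#' @param matrix optional substitution matrix name (e.g. `"BLOSUM45"`) or an
#'   actual matrix; presets cover the BLOSUM series.
#' @param gapOpen,gapExtend affine gap penalties (non-negative).
#' @return list of parameters for [globalAlign()].
#' @export
alignParams <- function(type = c("protein", "dna"), matrix = NULL,
                        gapOpen = NULL, gapExtend = NULL) {
  type <- match.arg(type)
  if (type == "dna") {
    sub <- matrix(-1, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                            c("A", "C", "G", "T", "N")))
    diag(sub) <- 1
    sub["N", ] <- -1; sub[, "N"] <- -1   # N is always a mismatch
    list(type = "dna", submat = sub,
         gapOpen = if (is.null(gapOpen)) 2 else gapOpen,
         gapExtend = if (is.null(gapExtend)) 1 else gapExtend)
  } else {
    sub <- matrix
    if (is.null(sub)) sub <- "BLOSUM62"
    if (is.character(sub)) {
      e <- new.env()
      utils::data(list = sub, package = "Biostrings", envir = e)
      nm <- sub; sub <- get(nm, envir = e)
      attr(sub, "name") <- nm
    }
    list(type = "protein", submat = sub,
         gapOpen = if (is.null(gapOpen)) 10 else gapOpen,
         gapExtend = if (is.null(gapExtend)) 0.1 else gapExtend)
  }
}

.guess_params <- function(seqs, params) {
  if (!is.null(params)) return(params)
  alignParams(if (.is_dna(seqs)) "dna" else "protein")
}

#' Global pairwise alignment
#'
#' Optimal Needleman-Wunsch alignment under a substitution matrix and affine
#' gap penalties (gap of length L costs `gapOpen + gapExtend * L`).
#'
#' @param a,b sequences (character strings over one alphabet).
#' @param params from [alignParams()]; guessed from the alphabet when `NULL`.
#' @return list with `rows` (two gapped strings, named when inputs are named),
#'   `score`, and `params`.
#' @examples
#' al <- globalAlign("ACGT", "ACGA")
#' al$score
#' @export
globalAlign <- function(a, b, params = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("alphabet error: empty sequence")
  params <- .guess_params(c(a, b), params)
  if (params$type == "dna" && !.is_dna(c(a, b)))
    stop("alphabet error: mixed alphabets (DNA params, non-DNA sequence)")
  pa <- Biostrings::pairwiseAlignment(
    toupper(a), toupper(b), type = "global",
    substitutionMatrix = params$submat,
    gapOpening = params$gapOpen, gapExtension = params$gapExtend)
  rows <- c(as.character(Biostrings::alignedPattern(pa)),
            as.character(Biostrings::alignedSubject(pa)))
  names(rows) <- c(names(a), names(b))
  list(rows = unname_if_empty(rows), score = Biostrings::score(pa),
       params = params)
}

unname_if_empty <- function(x) {
  if (is.null(names(x)) || all(!nzchar(names(x)))) unname(x) else x
}

#' Percent identity of a two-row alignment
#'
#' @param al alignment from [globalAlign()] (or any list with two gapped
#'   `rows`).
#' @param mode denominator: `"aligned_columns"` (columns holding at least one
#'   residue; gap-gap columns never counted) or `"shorter_seq"` (length of the
#'   shorter ungapped input).
#' @return percentage in \[0, 100\].
#' @export
percentIdentity <- function(al, mode = c("aligned_columns", "shorter_seq")) {
  mode <- match.arg(mode)
  rows <- if (is.list(al)) al$rows else al
  if (length(rows) != 2L) stop("arity error: need exactly 2 rows")
  x <- strsplit(rows[[1]], "")[[1]]
  y <- strsplit(rows[[2]], "")[[1]]
  resid <- x != "-" | y != "-"
  matches <- sum(x == y & x != "-")
  denom <- switch(mode,
    aligned_columns = sum(resid),
    shorter_seq = min(sum(x != "-"), sum(y != "-")))
  100 * matches / denom
}

# ---- progressive multiple alignment ---------------------------------------

# profile = list(rows = character vector of gapped strings)
# column score between profiles: average substitution score over residue pairs
.profile_cols <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  m
}

# Gotoh profile-profile alignment; returns merged gapped rows (A rows first)
.profile_align <- function(rowsA, rowsB, params) {
  A <- .profile_cols(rowsA); B <- .profile_cols(rowsB)
  nA <- ncol(A); nB <- ncol(B)
  sub <- params$submat
  alpha <- rownames(sub)
  # per-column residue frequency matrices (gaps dropped)
  colfreq <- function(M) {
    apply(M, 2, function(col) {
      col <- col[col != "-"]
      tab <- table(factor(col, levels = alpha))
      if (sum(tab) == 0) rep(0, length(alpha)) else as.numeric(tab) / sum(tab)
    })
  }
  fA <- colfreq(A); fB <- colfreq(B)         # |alpha| x ncol
  colscore <- crossprod(fA, sub %*% fB)      # nA x nB expected score
  go <- params$gapOpen; ge <- params$gapExtend
  NEG <- -1e9
  M <- matrix(NEG, nA + 1, nB + 1); X <- M; Y <- M
  M[1, 1] <- 0
  X[, 1] <- NEG; Y[1, ] <- NEG
  for (j in seq_len(nB)) Y[1, j + 1] <- -(go + ge * j)
  for (i in seq_len(nA)) X[i + 1, 1] <- -(go + ge * i)
  ptrM <- matrix(0L, nA + 1, nB + 1); ptrX <- ptrM; ptrY <- ptrM
  for (i in seq_len(nA)) {
    Mi1 <- M[i, ]; Xi1 <- X[i, ]; Yi1 <- Y[i, ]
    for (j in seq_len(nB)) {
      best <- max(Mi1[j], Xi1[j], Yi1[j])
      M[i + 1, j + 1] <- best + colscore[i, j]
      ptrM[i + 1, j + 1] <- which.max(c(Mi1[j], Xi1[j], Yi1[j]))
      xo <- M[i, j + 1] - go - ge; xe <- X[i, j + 1] - ge
      X[i + 1, j + 1] <- max(xo, xe)
      ptrX[i + 1, j + 1] <- if (xo >= xe) 1L else 2L
      yo <- M[i + 1, j] - go - ge; ye <- Y[i + 1, j] - ge
      Y[i + 1, j + 1] <- max(yo, ye)
      ptrY[i + 1, j + 1] <- if (yo >= ye) 1L else 2L
    }
  }
  # traceback (ties prefer the match state)
  i <- nA; j <- nB
  state <- which.max(c(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1]))
  opsA <- integer(0); opsB <- integer(0)   # 1 = consume column, 0 = gap
  while (i > 0 || j > 0) {
    if (i == 0L) {                # only gaps-in-A remain
      opsA <- c(0L, opsA); opsB <- c(1L, opsB); j <- j - 1; next
    }
    if (j == 0L) {                # only gaps-in-B remain
      opsA <- c(1L, opsA); opsB <- c(0L, opsB); i <- i - 1; next
    }
    if (state == 1L) {
      st <- ptrM[i + 1, j + 1]
      opsA <- c(1L, opsA); opsB <- c(1L, opsB); i <- i - 1; j <- j - 1
      state <- st
    } else if (state == 2L) {
      st <- ptrX[i + 1, j + 1]
      opsA <- c(1L, opsA); opsB <- c(0L, opsB); i <- i - 1
      state <- if (st == 1L) 1L else 2L
    } else {
      st <- ptrY[i + 1, j + 1]
      opsA <- c(0L, opsA); opsB <- c(1L, opsB); j <- j - 1
      state <- if (st == 1L) 1L else 3L
    }
  }
  expand <- function(M, ops) {
    out <- matrix("-", nrow(M), length(ops))
    out[, ops == 1L] <- M
    setNames(apply(out, 1, paste, collapse = ""), rownames(M))
  }
  c(expand(A, opsA), expand(B, opsB))
}

#' Progressive multiple sequence alignment
#'
#' Pairwise distances (100 - percent identity of global alignments) feed a
#' UPGMA guide tree; profiles are merged bottom-up in guide-tree order via
#' profile-profile Needleman-Wunsch.  Output rows are returned in input order.
#'
#' @param seqs character vector (optionally named) of >= 1 sequences.
#' @param params from [alignParams()]; guessed when `NULL`.
#' @return list with `rows` (gapped, input order), `guide` (merge list), and
#'   `params`.
#' @export
progressiveMsa <- function(seqs, params = NULL) {
  n <- length(seqs)
  if (n == 0L) stop("arity error: no sequences")
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    names(seqs) <- sprintf("seq%03d", seq_len(n))
  params <- .guess_params(seqs, params)
  if (n == 1L) {
    warning("single sequence: returned unchanged")
    return(list(rows = seqs, guide = NULL, params = params))
  }
  if (n == 2L) {
    al <- globalAlign(seqs[1], seqs[2], params)
    names(al$rows) <- names(seqs)
    return(list(rows = al$rows, guide = NULL, params = params))
  }
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- globalAlign(seqs[i], seqs[j], params)
    D[i, j] <- D[j, i] <- 100 - percentIdentity(al, "aligned_columns")
  }
  tree <- upgmaTree(D)   # deterministic guide tree
  merges <- .merge_order(tree, names(seqs))
  profiles <- lapply(seq_len(n), function(i) setNames(seqs[i], names(seqs)[i]))
  for (m in merges) {
    merged <- .profile_align(profiles[[m[1]]], profiles[[m[2]]], params)
    profiles[[m[1]]] <- merged
    profiles[[m[2]]] <- NA    # consumed (keep list indices stable)
  }
  rows <- profiles[[merges[[length(merges)]][1]]]
  rows <- rows[names(seqs)]
  list(rows = rows, guide = merges, params = params)
}

# post-order list of (cluster-representative input-index pairs) from a phylo
.merge_order <- function(tree, input_names) {
  n <- length(tree$tip.label)
  rep_of <- c(match(tree$tip.label, input_names), rep(NA_integer_, tree$Nnode))
  ord <- ape::reorder.phylo(tree, "postorder")
  merges <- list()
  kids <- split(ord$edge[, 2], ord$edge[, 1])
  for (node in unique(ord$edge[, 1])) {
    ch <- kids[[as.character(node)]]
    r <- rep_of[ch]
    for (k in seq_along(r)[-1]) {
      merges[[length(merges) + 1L]] <- c(r[1], r[k])
    }
    rep_of[node] <- r[1]
  }
  # map tip indices back to input order (tip.label = input names order kept)
  merges
}

#' Position frequency matrix and column statistics of an alignment
#'
#' Per-column symbol counts over non-gap residues, the majority consensus
#' (threshold on the fraction of residues; below threshold the column is `N`
#' for DNA, `X` for protein), and per-column information content
#' `log2 |alphabet| + sum p log2 p`.
#'
#' @param al alignment (list with `rows`) or character vector of gapped rows.
#' @param threshold majority-consensus threshold (default 0.5).
#' @return list with `counts` (alphabet x columns), `consensus` (string),
#'   `info_bits` (numeric per column).
#' @export
columnStats <- function(al, threshold = 0.5) {
  rows <- if (is.list(al)) al$rows else al
  if (length(rows) < 2L) stop("arity error: need >= 2 rows")
  m <- .profile_cols(rows)
  dna <- .is_dna(rows)
  alpha <- if (dna) c("A", "C", "G", "T")
           else setdiff(sort(unique(c(m[m != "-"], LETTERS))), c("B", "J", "O", "U", "X", "Z"))
  counts <- apply(m, 2, function(col) {
    table(factor(col[col != "-" & col %in% alpha], levels = alpha))
  })
  counts <- matrix(as.numeric(counts), nrow = length(alpha),
                   dimnames = list(alpha, NULL))
  info <- apply(counts, 2, function(ct) {
    tot <- sum(ct)
    if (tot == 0) return(0)
    p <- ct[ct > 0] / tot
    log2(length(alpha)) + sum(p * log2(p))
  })
  cons <- apply(counts, 2, function(ct) {
    tot <- sum(ct)
    if (tot == 0) return("-")
    top <- which.max(ct)   # ties: first alphabetically
    if (ct[top] / tot >= threshold) alpha[top] else if (dna) "N" else "X"
  })
  list(counts = counts, consensus = paste(cons, collapse = ""),
       info_bits = unname(info))
}
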