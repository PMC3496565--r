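# Hairpin-forming potential of a palindrome: a documented nearest-neighbor
# approximation (unified DNA NN stacking free energies at 37 degC, a hairpin
# loop-initiation size table, and a flat per-mismatch penalty).  This is NOT a
# full secondary-structure prediction: multi-state folding, dangling ends and
# salt corrections are out of scope, so published Mfold values are comparison
# output, never asserted.

# unified NN stacking dG37 (kcal/mol), keyed by the 5'->3' top-strand dimer
.NN_DG <- c(AA = -1.00, TT = -1.00, AT = -0.88, TA = -0.58,
            CA = -1.45, TG = -1.45, GT = -1.44, AC = -1.44,
            CT = -1.28, AG = -1.28, GA = -1.30, TC = -1.30,
            CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)

# hairpin loop initiation dG37 by loop size; extrapolated beyond 30 with a
# Jacobson-Stockmayer term
.LOOP_SIZES <- c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30)
.LOOP_DG <- c(3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5, 4.6, 5.0, 5.1, 5.3,
              5.5, 5.7, 6.1, 6.3)

.loop_penalty <- function(n) {
  n <- max(n, 3L)   # loops < 3 are scored as the minimal loop (cruciform apex)
  if (n <= 30L) stats::approx(.LOOP_SIZES, .LOOP_DG, xout = n)$y
  else .LOOP_DG[length(.LOOP_DG)] + 1.75 * 0.616 * log(n / 30)
}

#' Hairpin free energy of a palindrome (nearest-neighbor approximation)
#'
#' Sums unified nearest-neighbor stacking free energies over consecutive
#' matched stem pairs, adds a hairpin-loop initiation penalty from a loop-size
#' table, and a flat penalty per stem mismatch (a mismatch also interrupts
#' stacking).  More negative is more stable.
#'
#' @param g a [Genome-class].
#' @param start,end palindrome interval.
#' @param arm,loop arm and loop lengths (from [findPalindromes()]).
#' @param mismatchPenalty kcal/mol added per stem mismatch (default +1.0).
#' @return free energy estimate in kcal/mol.
#' @export
hairpinDeltaG <- function(g, start, end, arm, loop,
                          mismatchPenalty = 1.0) {
  if (arm < 2L) stop("undefined-structure error: arm < 2")
  s <- subSequence(g, start, end, "+")
  stemDeltaG(substr(s, 1L, arm),
             substr(s, arm + loop + 1L, 2L * arm + loop),
             loop, mismatchPenalty)
}

#' @rdname hairpinDeltaG
#' @param left,right the two arm sequences (5'->3' on the same strand).
#' @export
stemDeltaG <- function(left, right, loop, mismatchPenalty = 1.0) {
  a <- strsplit(toupper(left), "")[[1]]
  b <- rev(strsplit(toupper(right), "")[[1]])   # pair i of stem: a[i] vs b[i]
  k <- length(a)
  stopifnot(length(b) == k, k >= 2L)
  paired <- .base_pairs(a, b)
  dg <- 0
  for (i in seq_len(k - 1L)) {
    if (paired[i] && paired[i + 1L])
      dg <- dg + .NN_DG[[paste0(a[i], a[i + 1L])]]
  }
  dg + .loop_penalty(loop) + mismatchPenalty * sum(!paired)
}
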