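# Synthetic circular genomes with machine-readable truth tables: AT-rich
# background, ORF cassettes with promoter classes satisfied by construction,
# hr cassettes (clustered imperfect palindromes with conserved 15-bp ends),
# a non-hr-ori cassette (direct-repeat pairs beside an hr), plus protein
# families evolved along a known tree and ortholog orders with planted
# inversions.  The background is "sterilized": spurious ORFs/palindromes that
# arise by chance are broken by point edits outside planted cassettes, so the
# truth table is exact and detector recall/precision can be asserted at 1.0.

# conserved palindrome end block shared by all planted hrs
.DEFAULT_FLANK <- "TTCGAGTGAGTTTTC"

.rand_dna <- function(n, at) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# n random sense-strand codons free of stop codons
.rand_codons <- function(n, at) {
  if (n <= 0L) return("")
  cod <- character(n)
  for (i in seq_len(n)) {
    repeat {
      c3 <- .rand_dna(3L, at)
      if (!c3 %in% .STOPS) break
    }
    cod[i] <- c3
  }
  paste(cod, collapse = "")
}

#' Recipe for a synthetic genome
#'
#' @param length genome length in bp.
#' @param atTarget background AT fraction.
#' @param orfCassettes data.frame with columns `aa` (protein length),
#'   `strand`, `promoter` (`early`/`late`/`both`/`none`); or `NULL`.
#' @param hrCassettes data.frame with columns `n_pal` (palindromes per hr),
#'   and per-palindrome `arm`, `loop`, `mismatches` ranges are drawn from
#'   `armRange`/`loopRange`; or `NULL`.
#' @param oriCassette plant a non-hr-ori block (direct repeats) beside the
#'   first hr (default `FALSE`).
#' @param seed integer; fixes all randomness of [simulateGenome()].
#' @param flankBlock conserved 15-bp palindrome end block.
#' @param armRange,loopRange sampling ranges for palindrome arms/loops.
#' @param detector detector parameters the truth is constructed against
#'   (minAa, maxOverlapNt, minArm, maxLoop, rate, hrMaxGap).
#' @return recipe list for [simulateGenome()].
#' @export
genomeRecipe <- function(length = 20000L, atTarget = 0.585,
                         orfCassettes = NULL, hrCassettes = NULL,
                         oriCassette = FALSE, seed = 1L,
                         flankBlock = .DEFAULT_FLANK,
                         armRange = c(18L, 28L), loopRange = c(6L, 20L),
                         detector = list(minAa = 50L, maxOverlapNt = 75L,
                                         minArm = 15L, maxLoop = 40L,
                                         rate = 0.2, hrMaxGap = 1000L)) {
  stopifnot(nchar(flankBlock) == 15L, length >= 1000L)
  list(length = as.integer(length), atTarget = atTarget,
       orfCassettes = orfCassettes, hrCassettes = hrCassettes,
       oriCassette = oriCassette, seed = as.integer(seed),
       flankBlock = toupper(flankBlock),
       armRange = armRange, loopRange = loopRange, detector = detector)
}

#' Flagship recipe emulating a granulovirus genome architecture
#'
#' 119,082 bp at 58.5% AT; 40 ORF cassettes whose promoter classes follow the
#' published proportions of early-only / late-only / both / none promoters;
#' 16 hr cassettes holding 26 palindromes in total; one non-hr-ori cassette.
#'
#' @param seed integer seed.
#' @return recipe list.
#' @export
epapRecipe <- function(seed = 1L) {
  promoter <- rep(c("early", "late", "both", "none"), c(5L, 16L, 3L, 16L))
  orfs <- data.frame(
    aa = rep(c(60L, 90L, 150L, 250L, 400L), 8L),
    strand = rep(c("+", "-"), 20L),
    promoter = promoter, stringsAsFactors = FALSE)
  hrs <- data.frame(n_pal = c(2L, 1L, 2L, 3L, 1L, 2L, 1L, 2L,
                              1L, 3L, 1L, 2L, 1L, 2L, 1L, 1L))
  genomeRecipe(length = 119082L, atTarget = 0.585, orfCassettes = orfs,
               hrCassettes = hrs, oriCassette = TRUE, seed = seed)
}

# promoter window of a given class, valid by construction (rejection-checked
# against the classifier); the last 3 nt are an in-frame TAA so the planted
# ATG is the 5'-most start of its stop-to-stop segment
.make_window <- function(class, motifs, at, maxTry = 500L) {
  W <- motifs$window
  inst <- function(p) {  # concrete instance of an IUPAC pattern
    map <- list(W = c("A", "T"), K = c("G", "T"), D = c("A", "G", "T"),
                R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T"))
    paste(vapply(strsplit(p, "")[[1]], function(ch)
      if (ch %in% names(map)) sample(map[[ch]], 1L) else ch, ""), collapse = "")
  }
  for (t in seq_len(maxTry)) {
    w <- strsplit(paste0(.rand_dna(W - 3L, at), "TAA"), "")[[1]]
    put <- function(motif, off) {
      w[off:(off + nchar(motif) - 1L)] <<- strsplit(motif, "")[[1]]
    }
    if (class %in% c("early", "both")) {
      tata <- inst(sample(c("TATAWAW", "TATAWTW"), 1L))
      cakt <- inst("CAKT")
      off <- sample(15:60, 1L)
      gap <- sample(24:36, 1L)
      put(tata, off)
      put(cakt, off + nchar(tata) + gap)
    }
    if (class %in% c("late", "both")) {
      off <- sample(115:135, 1L)
      put(inst("DTAAG"), off)
    }
    window <- paste(w, collapse = "")
    if (classifyPromoter(window, motifs)$call == class) return(window)
  }
  stop("packing error: could not build a '", class, "' promoter window")
}

# ORFs a cassette can seed in genome context: scanned with stop codons
# padded onto both ends, so reading frames that would only terminate in the
# surrounding background are visible too.  "TAATTAATTAA" holds a TAA at
# offsets 1/5/9, i.e. a stop in all three frames; its reverse complement
# stops every minus-strand frame on the left.
.cassette_orfs <- function(seqstr, det) {
  pad_r <- "TAATTAATTAA"
  pad_l <- "TTAATTAATTA"   # revComp(pad_r)
  padded <- paste0(pad_l, seqstr, pad_r)
  orfs <- enumerateOrfs(Genome(padded, topology = "linear"),
                        minAa = det$minAa, translate = FALSE)$orfs
  orfs$start <- orfs$start - nchar(pad_l)
  orfs$end <- orfs$end - nchar(pad_l)
  orfs
}

# spurious palindromes inside a cassette (outside the planted spans)
.extra_pals <- function(seqstr, planted_spans, det) {
  found <- findPalindromes(Genome(seqstr, topology = "linear"),
                           minArm = det$minArm, maxLoop = det$maxLoop,
                           maxMismatchRate = det$rate)
  if (!nrow(found)) return(0L)
  key <- paste(planted_spans$start, planted_spans$end)
  sum(!paste(found$start, found$end) %in% key)
}

# one ORF cassette: 150-nt promoter window (ending in-frame TAA) + CDS.
# Cassettes are rejection-sampled so that, in isolation, they contain no
# spurious palindrome and no internal ORF that the minimal-overlap selection
# would retain (anything nested deeper than the overlap cap dies there).
.make_orf_cassette <- function(aa, strand, promoter, motifs, at, det,
                               maxTry = 200L) {
  for (t in seq_len(maxTry)) {
    window <- .make_window(promoter, motifs, at)
    cds <- paste0("ATG", .rand_codons(aa - 1L, at),
                  sample(.STOPS, 1L, prob = c(0.5, 0.25, 0.25)))
    cass <- paste0(window, cds)
    len <- nchar(cass)
    orf_local <- c(start = nchar(window) + 1L, end = len)
    if (strand == "-") {
      cass <- revComp(cass)
      orf_local <- c(start = len - orf_local[["end"]] + 1L,
                     end = len - orf_local[["start"]] + 1L)
    }
    if (.extra_pals(cass, data.frame(start = integer(), end = integer()),
                    det) > 0L) next
    cand <- .cassette_orfs(cass, det)
    planted <- cand$start == orf_local[["start"]] &
      cand$end == orf_local[["end"]] & cand$strand == strand
    # a non-planted internal ORF is tolerable only if the greedy
    # longest-first selection is certain to drop it: it must overlap the
    # planted ORF beyond the cap AND be shorter than the planted ORF
    coexists <- vapply(seq_len(nrow(cand)), function(i)
      .circ_overlap(cand$start[i], cand$end[i], orf_local[["start"]],
                    orf_local[["end"]], len + 1L) <= det$maxOverlapNt, TRUE)
    span <- cand$end - cand$start + 1L
    planted_span <- orf_local[["end"]] - orf_local[["start"]] + 1L
    if (!any(planted) ||
        any(!planted & (coexists | span >= planted_span))) next
    return(list(seq = cass, orf_local = orf_local, aa = aa, strand = strand,
                promoter = promoter))
  }
  stop("packing error: could not build a clean ORF cassette")
}

# one imperfect palindrome with mismatch-guard flanks.  The whole span is a
# perfect palindrome (the loop/core pairs too), then `mismatches`
# substitutions are placed in the right arm; the detector's maximal reading
# absorbs the complementary core into the arms, so the reported span equals
# the planted span exactly (guards block any extension).
.make_palindrome <- function(arm, loop, mismatches, flank, at, rate) {
  stopifnot(arm >= nchar(flank), mismatches <= ceiling(arm * rate))
  S <- 2L * arm + loop
  half <- paste0(flank, .rand_dna(arm - nchar(flank), at),
                 .rand_dna(loop %/% 2L, min(0.9, at + 0.15)))
  center <- if (loop %% 2L == 1L) .rand_dna(1L, 1) else ""
  pal <- paste0(half, center, revComp(half))
  stopifnot(nchar(pal) == S)
  # mismatches go into the right arm between the conserved end block and the
  # core, so the 15-bp flanks stay pristine (they are the conserved feature)
  fl <- nchar(flank)
  avail <- if (S - fl - 1L >= S - arm + 1L) (S - arm + 1L):(S - fl - 1L)
           else integer(0)
  mismatches <- min(mismatches, length(avail))
  if (mismatches > 0L) {
    ch <- strsplit(pal, "")[[1]]
    pos <- sample(avail, mismatches)
    for (p in pos)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    pal <- paste(ch, collapse = "")
  }
  # 12-nt guards whose pairs all mismatch, blocking arm extension
  gR <- strsplit(.rand_dna(12L, at), "")[[1]]
  gL <- vapply(rev(gR), function(b)
    sample(setdiff(c("A", "C", "G", "T"), .complement_map[[b]]), 1L), "")
  list(seq = paste0(paste(gL, collapse = ""), pal, paste(gR, collapse = "")),
       pal_local = c(start = 13L, end = 12L + S),
       arm = arm, loop = loop, mismatches = mismatches)
}

# hr cassette: 1-3 palindromes separated by short AT-rich spacers;
# rejection-sampled until the detector sees exactly the planted spans and no
# internal ORF
.make_hr_cassette <- function(n_pal, flank, at, armRange, loopRange, det,
                              maxTry = 200L) {
  for (t in seq_len(maxTry)) {
    pals <- list(); pieces <- character(0); offsets <- integer(0)
    pos <- 0L
    for (i in seq_len(n_pal)) {
      arm <- sample(armRange[1]:armRange[2], 1L)
      loop <- sample(loopRange[1]:loopRange[2], 1L)
      mm <- sample(0:ceiling(arm * det$rate), 1L)
      p <- .make_palindrome(arm, loop, mm, flank, at, det$rate)
      pieces <- c(pieces, p$seq)
      pals[[i]] <- p
      offsets <- c(offsets, pos)
      pos <- pos + nchar(p$seq)
      if (i < n_pal) {
        sp <- .rand_dna(sample(60:200, 1L), min(0.9, at + 0.1))
        pieces <- c(pieces, sp)
        pos <- pos + nchar(sp)
      }
    }
    cass <- paste(pieces, collapse = "")
    spans <- data.frame(
      start = offsets + vapply(pals, function(p) p$pal_local[["start"]], 0L),
      end = offsets + vapply(pals, function(p) p$pal_local[["end"]], 0L))
    found <- findPalindromes(Genome(cass, topology = "linear"),
                             minArm = det$minArm, maxLoop = det$maxLoop,
                             maxMismatchRate = det$rate)
    exact <- nrow(found) == n_pal &&
      setequal(paste(found$start, found$end), paste(spans$start, spans$end))
    if (exact && nrow(.cassette_orfs(cass, det)) == 0L)
      return(list(seq = cass, pals = pals, offsets = offsets))
  }
  stop("packing error: could not build a clean hr cassette")
}

# non-hr-ori block: two identical 31-bp direct repeats (A1/A2) and an
# imperfect 79/72-bp pair (B1/B2), all AT-rich; rejection-sampled to be free
# of palindromes and internal ORFs
.make_ori_cassette <- function(at, det, maxTry = 200L) {
  atr <- min(0.9, at + 0.2)
  for (t in seq_len(maxTry)) {
    a1 <- .rand_dna(31L, atr)
    b1 <- .rand_dna(79L, atr)
    b2ch <- strsplit(substr(b1, 1L, 72L), "")[[1]]
    for (p in sample(72L, 7L))   # ~90% identity
      b2ch[p] <- sample(setdiff(c("A", "C", "G", "T"), b2ch[p]), 1L)
    gaps <- vapply(1:3, function(i) .rand_dna(sample(15:30, 1L), atr), "")
    parts <- c(a1, gaps[1], a1, gaps[2], b1, gaps[3],
               paste(b2ch, collapse = ""))
    lens <- nchar(parts)
    starts <- cumsum(c(1L, head(lens, -1L)))
    cass <- paste(parts, collapse = "")
    if (.extra_pals(cass, data.frame(start = integer(), end = integer()),
                    det) > 0L) next
    if (nrow(.cassette_orfs(cass, det)) > 0L) next
    return(list(seq = cass,
                units = data.frame(unit = c("A1", "A2", "B1", "B2"),
                                   start = starts[c(1, 3, 5, 7)],
                                   end = starts[c(1, 3, 5, 7)] +
                                     lens[c(1, 3, 5, 7)] - 1L)))
  }
  stop("packing error: could not build a clean ori cassette")
}

# append the non-hr-ori block to an hr cassette; the combined cassette is
# rejection-checked as a whole so the junctions host no spurious feature
.attach_ori <- function(cass, at, det, maxTry = 200L) {
  spans <- data.frame(
    start = cass$offsets + vapply(cass$pals, function(p)
      p$pal_local[["start"]], 0L),
    end = cass$offsets + vapply(cass$pals, function(p)
      p$pal_local[["end"]], 0L))
  for (t in seq_len(maxTry)) {
    ori <- .make_ori_cassette(at, det)
    gap <- .rand_dna(80L, at)
    combined <- paste0(cass$seq, gap, ori$seq)
    if (.extra_pals(combined, spans, det) > 0L) next
    if (nrow(.cassette_orfs(combined, det)) > 0L) next
    ori$units$start <- ori$units$start + nchar(cass$seq) + 80L
    ori$units$end <- ori$units$end + nchar(cass$seq) + 80L
    cass$seq <- combined
    cass$ori_units <- ori$units
    return(cass)
  }
  stop("packing error: could not attach a clean ori cassette")
}

# place cassettes without overlap by rejection sampling; margins keep
# upstream windows and guards clear of each other and of the origin, and give
# hr cassettes enough clearance that distinct hrs never fall within the
# clustering gap of one another
.place_cassettes <- function(L, lens, margins, maxTry = 1000L) {
  occupied <- logical(L)
  m0 <- max(margins)
  occupied[seq_len(m0)] <- TRUE                   # keep the origin clear
  occupied[(L - m0):L] <- TRUE
  starts <- integer(length(lens))
  for (i in order(-lens)) {
    ok <- FALSE
    for (t in seq_len(maxTry)) {
      s <- sample.int(L - lens[i] - margins[i], 1L)
      span <- max(1L, s - margins[i]):min(L, s + lens[i] - 1L + margins[i])
      if (!any(occupied[span])) {
        occupied[span] <- TRUE
        starts[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("packing error: could not place cassette ", i,
                  " after ", maxTry, " tries")
  }
  starts
}

#' Simulate a genome from a recipe
#'
#' Background bases are drawn to the AT target; cassettes are placed without
#' overlap by rejection sampling; ORF cassettes carry valid ATG/stop codons
#' and promoter windows that satisfy the classifier by construction; hr
#' cassettes embed imperfect palindromes with the shared conserved end block.
#' When planted features exist, the background is sterilized so that the
#' corresponding detectors return exactly the planted set (see the methods
#' vignette).  The same recipe and seed give a byte-identical genome.
#'
#' @param recipe from [genomeRecipe()] or [epapRecipe()].
#' @param sterilize break spurious background features (`"auto"` sterilizes a
#'   feature class iff cassettes of that class are planted; `TRUE`/`FALSE`
#'   force).
#' @return list: `genome` ([Genome-class]), `truth` (orfs, palindromes, hrs,
#'   direct_repeats, ori region), `recipe`.
#' @export
simulateGenome <- function(recipe, sterilize = "auto") {
  set.seed(recipe$seed)
  L <- recipe$length
  at <- recipe$atTarget
  det <- recipe$detector
  motifs <- motifSet()
  cassettes <- list()
  if (!is.null(recipe$orfCassettes)) {
    oc <- recipe$orfCassettes
    for (i in seq_len(nrow(oc)))
      cassettes[[length(cassettes) + 1L]] <-
        c(.make_orf_cassette(oc$aa[i], oc$strand[i], oc$promoter[i],
                             motifs, at, det), kind = "orf")
  }
  if (!is.null(recipe$hrCassettes)) {
    hc <- recipe$hrCassettes
    for (i in seq_len(nrow(hc))) {
      cass <- c(.make_hr_cassette(hc$n_pal[i], recipe$flankBlock, at,
                                  recipe$armRange, recipe$loopRange,
                                  det), kind = "hr")
      if (recipe$oriCassette && i == 1L) cass <- .attach_ori(cass, at, det)
      cassettes[[length(cassettes) + 1L]] <- cass
    }
  }
  lens <- vapply(cassettes, function(x) nchar(x$seq), 0L)
  kinds <- vapply(cassettes, function(x) x$kind, "")
  margins <- ifelse(kinds == "hr", det$hrMaxGap %/% 2L + 100L, 250L)
  starts <- if (length(cassettes)) .place_cassettes(L, lens, margins)
            else integer(0)
  bg <- strsplit(.rand_dna(L, at), "")[[1]]
  protected <- logical(L)
  for (i in seq_along(cassettes)) {
    s <- starts[i]; e <- s + lens[i] - 1L
    bg[s:e] <- strsplit(cassettes[[i]]$seq, "")[[1]]
    protected[s:e] <- TRUE
  }
  # ---- truth tables ----
  orfs <- list(); pals <- list(); hrs <- list(); dr <- NULL; ori_region <- NULL
  hr_id <- 0L
  for (i in seq_along(cassettes)) {
    cs <- cassettes[[i]]; s0 <- starts[i]
    if (cs$kind == "orf") {
      orfs[[length(orfs) + 1L]] <- data.frame(
        start = s0 + cs$orf_local[["start"]] - 1L,
        end = s0 + cs$orf_local[["end"]] - 1L,
        strand = cs$strand, aa_length = cs$aa, promoter = cs$promoter)
    } else {
      hr_id <- hr_id + 1L
      pal_rows <- lapply(seq_along(cs$pals), function(k) {
        p <- cs$pals[[k]]
        data.frame(start = s0 + cs$offsets[k] + p$pal_local[["start"]] - 1L,
                   end = s0 + cs$offsets[k] + p$pal_local[["end"]] - 1L,
                   arm = p$arm, loop = p$loop, mismatches = p$mismatches,
                   hr = hr_id)
      })
      pal_rows <- do.call(rbind, pal_rows)
      pals[[length(pals) + 1L]] <- pal_rows
      hrs[[length(hrs) + 1L]] <- data.frame(
        hr = hr_id, start = min(pal_rows$start), end = max(pal_rows$end),
        n_palindromes = nrow(pal_rows))
      if (!is.null(cs$ori_units)) {
        u <- cs$ori_units
        u$start <- u$start + s0 - 1L
        u$end <- u$end + s0 - 1L
        dr <- u
        ori_region <- c(start = min(u$start), end = max(u$end))
      }
    }
  }
  truth <- list(
    orfs = if (length(orfs)) do.call(rbind, orfs) else NULL,
    palindromes = if (length(pals)) do.call(rbind, pals) else NULL,
    hrs = if (length(hrs)) do.call(rbind, hrs) else NULL,
    direct_repeats = dr, ori_region = ori_region)
  g <- Genome(paste(bg, collapse = ""), id = sprintf("synthetic_%d", recipe$seed))
  # ---- sterilize background ----
  do_orf <- if (identical(sterilize, "auto")) !is.null(truth$orfs) else isTRUE(sterilize)
  do_pal <- if (identical(sterilize, "auto")) !is.null(truth$palindromes) else isTRUE(sterilize)
  if (do_orf || do_pal)
    g <- .sterilize(g, truth, protected, det, do_orf, do_pal)
  list(genome = g, truth = truth, recipe = recipe)
}

# break spurious background ORFs/palindromes by point edits at unprotected
# positions; iterate to a fixpoint
.sterilize <- function(g, truth, protected, det, do_orf, do_pal,
                       maxIter = 40L) {
  L <- genomeLength(g)
  ch <- strsplit(genomeSeq(g), "")[[1]]
  pal_region_hits <- integer(0)   # recurring loci, for random-restart escalation
  orf_region_hits <- integer(0)
  truth_orf_key <- if (!is.null(truth$orfs))
    paste(truth$orfs$start, truth$orfs$end, truth$orfs$strand) else character(0)
  truth_pal_key <- if (!is.null(truth$palindromes))
    paste(truth$palindromes$start, truth$palindromes$end) else character(0)
  for (iter in seq_len(maxIter)) {
    g <- Genome(paste(ch, collapse = ""), id = genomeId(g))
    changed <- FALSE
    residual <- 0L
    if (do_orf) {
      called <- selectMinimalOverlap(
        enumerateOrfs(g, minAa = det$minAa, translate = FALSE)$orfs,
        g, det$maxOverlapNt)
      spur <- called[!paste(called$start, called$end, called$strand) %in%
                       truth_orf_key, , drop = FALSE]
      residual <- residual + nrow(spur)
      for (r in seq_len(nrow(spur))) {
        s <- spur$start[r]; e <- spur$end[r]; st <- spur$strand[r]
        posv <- if (s <= e) s:e else c(s:L, 1:e)
        # interior in-frame codons (exclude the ATG and the stop codon);
        # for "+" a codon is posv[o:(o+2)], for "-" it is posv[(o-2):o]
        cods <- if (st == "+") seq(4L, length(posv) - 5L, 3L)
                else seq(length(posv) - 3L, 6L, -3L)
        free <- vapply(cods, function(o) {
          idx <- if (st == "+") posv[o:(o + 2L)] else posv[(o - 2L):o]
          !any(protected[idx])
        }, TRUE)
        key <- as.character(s %/% 200L)
        orf_region_hits[key] <- sum(orf_region_hits[key], 1L, na.rm = TRUE)
        if (orf_region_hits[[key]] >= 3L && any(!protected[posv])) {
          # recurring locus (stop insertions can seed new boundary starts):
          # re-randomize the unprotected span
          freepos <- posv[!protected[posv]]
          ch[freepos] <- sample(c("A", "T", "C", "G"), length(freepos),
                                replace = TRUE)
          changed <- TRUE
        } else if (any(free)) {
          # earliest free codon: the 5' remnant is then too short to call.
          # TAA carries no G/C, so the edit cannot complete an ATG or a
          # minus-strand CAT by itself.
          o <- cods[free][1L]
          idx <- if (st == "+") posv[o:(o + 2L)] else posv[(o - 2L):o]
          stopc <- if (st == "+") c("T", "A", "A") else c("T", "T", "A")
          ch[idx] <- stopc
          changed <- TRUE
        } else {
          # fall back to destroying the start codon itself
          idx <- if (st == "+") posv[1:3] else posv[(length(posv) - 2L):length(posv)]
          mid <- idx[2L]
          if (!protected[mid]) {
            ch[mid] <- if (st == "+") "C" else "G"   # ATG -> ACG
            changed <- TRUE
          }
        }
      }
    }
    if (do_pal) {
      found <- findPalindromes(g, minArm = det$minArm, maxLoop = det$maxLoop,
                               maxMismatchRate = det$rate)
      spur <- found[!paste(found$start, found$end) %in% truth_pal_key, ,
                    drop = FALSE]
      residual <- residual + nrow(spur)
      for (r in seq_len(nrow(spur))) {
        a <- spur$start[r]; b <- spur$end[r]; k <- spur$arm[r]
        posv <- if (a <= b) a:b else c(a:L, 1:b)
        lefts <- posv[seq_len(k)]
        rights <- rev(posv)[seq_len(k)]        # pair i: lefts[i] vs rights[i]
        pairable <- .base_pairs(ch[lefts], ch[rights])
        editable <- which(pairable & (!protected[lefts] | !protected[rights]))
        if (!length(editable)) next
        key <- as.character(a %/% 100L)
        pal_region_hits[key] <- sum(pal_region_hits[key], 1L, na.rm = TRUE)
        if (pal_region_hits[[key]] >= 3L) {
          # recurring locus: mirror edits are cycling through alternative
          # readings here; re-randomize the whole unprotected span instead
          free <- posv[!protected[posv]]
          ch[free] <- sample(c("A", "T", "C", "G"), length(free),
                             replace = TRUE)
        } else {
          # break every editable pair by copying one side onto the other:
          # equal bases never pair, so nearby alternative readings of the
          # same self-complementary stretch die too
          for (i in editable) {
            if (!protected[lefts[i]]) ch[lefts[i]] <- ch[rights[i]]
            else ch[rights[i]] <- ch[lefts[i]]
          }
        }
        changed <- TRUE
      }
    }
    if (residual == 0L) return(g)
    if (!changed) {
      warning("sterilization stuck with ", residual,
              " uneditable spurious feature(s)")
      return(g)
    }
  }
  warning("sterilization did not reach a fixpoint after ", maxIter,
          " iterations; residual background features may remain")
  Genome(paste(ch, collapse = ""), id = genomeId(g))
}

#' Write a truth table as GFF3
#'
#' All planted features (CDS, palindromes, hrs, direct repeats, ori region)
#' with their class carried in the `type` column, so detector output can be
#' diffed against the truth directly.
#'
#' @param sim result of [simulateGenome()].
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
writeTruthGff3 <- function(sim, path) {
  rows <- list()
  t <- sim$truth
  if (!is.null(t$orfs))
    rows[[1]] <- featureTable(t$orfs$start, t$orfs$end, t$orfs$strand,
                              type = "CDS",
                              ID = sprintf("true_orf%03d", seq_len(nrow(t$orfs))))
  if (!is.null(t$palindromes))
    rows[[2]] <- featureTable(t$palindromes$start, t$palindromes$end, "+",
                              type = "inverted_repeat",
                              ID = sprintf("true_pal%03d",
                                           seq_len(nrow(t$palindromes))))
  if (!is.null(t$hrs))
    rows[[3]] <- featureTable(t$hrs$start, t$hrs$end, "+", type = "repeat_region",
                              ID = sprintf("true_hr%02d", t$hrs$hr))
  if (!is.null(t$direct_repeats))
    rows[[4]] <- featureTable(t$direct_repeats$start, t$direct_repeats$end,
                              "+", type = "direct_repeat",
                              ID = paste0("true_", t$direct_repeats$unit))
  df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  writeFeatures(df, sim$genome, path, "gff3")
}

#' Simulate protein families along a known tree
#'
#' Root sequences are random; substitutions accumulate along branches under a
#' Dayhoff model with 4-category discrete-gamma site rates (shape 2.25 by
#' default), via [phangorn::simSeq()].
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param nFamilies number of gene families.
#' @param rootLen protein length per family (split across rate categories).
#' @param gammaShape gamma shape for among-site rate variation.
#' @param seed integer seed.
#' @return list: `families` (list of named character vectors, aligned rows —
#'   the simulation introduces no indels) and `tree`.
#' @export
makeFamilies <- function(tree, nFamilies = 10L, rootLen = 100L,
                         gammaShape = 2.25, seed = 1L) {
  if (sum(tree$edge.length) == 0)
    warning("degenerate input: zero total branch length; all taxa identical")
  set.seed(seed)
  rates <- phangorn::discrete.gamma(gammaShape, 4L)
  chunk <- diff(round(seq(0L, rootLen, length.out = 5L)))
  fams <- lapply(seq_len(nFamilies), function(f) {
    mats <- lapply(seq_along(rates), function(k) {
      if (chunk[k] == 0L) return(NULL)
      as.character(phangorn::simSeq(tree, l = chunk[k], type = "AA",
                                    model = "Dayhoff", rate = rates[k]))
    })
    mats <- mats[!vapply(mats, is.null, TRUE)]
    m <- do.call(cbind, mats)
    setNames(toupper(apply(m, 1L, paste, collapse = "")), rownames(m))
  })
  names(fams) <- sprintf("fam%03d", seq_len(nFamilies))
  list(families = fams, tree = tree)
}

#' Ortholog order pair with planted inversions
#'
#' Genome A carries genes 1..n in order; genome B is identical except that the
#' specified segments are reversed with strands flipped.  Gene lengths in the
#' inverted segment are scaled so its bp span matches the request.
#'
#' @param nGenes number of shared genes.
#' @param inversions list of `list(start, len, span_bp)` (gene index of the
#'   first inverted gene, number of genes, target bp span), or `NULL`.
#' @param seed integer seed.
#' @param gap intergenic gap in bp.
#' @return list: `orderA`, `orderB` (gene/strand/start/end tables in clockwise
#'   order), `truth` (the planted inversions).
#' @export
makeOrthologOrders <- function(nGenes, inversions = NULL, seed = 1L,
                               gap = 100L) {
  set.seed(seed)
  lens <- sample(300:1500, nGenes, replace = TRUE)
  strands <- sample(c("+", "-"), nGenes, replace = TRUE)
  if (!is.null(inversions) && !is.null(inversions$start))
    inversions <- list(inversions)
  for (inv in inversions) {
    sel <- inv$start:(inv$start + inv$len - 1L)
    stopifnot(max(sel) <= nGenes)
    tot <- inv$span_bp - (inv$len - 1L) * gap
    w <- lens[sel] / sum(lens[sel])
    lens[sel] <- pmax(50L, round(tot * w))
    lens[sel[1]] <- lens[sel[1]] + (tot - sum(lens[sel]))  # exact span
  }
  mk <- function(genes, lens, strands) {
    starts <- cumsum(c(1L, head(lens + gap, -1L)))
    data.frame(gene = genes, strand = strands, start = starts,
               end = starts + lens - 1L, stringsAsFactors = FALSE)
  }
  genesA <- sprintf("g%03d", seq_len(nGenes))
  ordA <- mk(genesA, lens, strands)
  perm <- seq_len(nGenes)
  strB <- strands
  for (inv in inversions) {
    sel <- inv$start:(inv$start + inv$len - 1L)
    perm[sel] <- rev(perm[sel])
    strB[sel] <- ifelse(strB[rev(sel)] == "+", "-", "+")
  }
  ordB <- mk(genesA[perm], lens[perm], strB)
  list(orderA = ordA, orderB = ordB,
       truth = list(inversions = inversions))
}
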