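# Orchestration over the analysis stages: single-genome annotation
# (ORFs -> promoters -> repeats) and multi-genome comparison
# (orthologs -> synteny -> phylogeny), with serialized run configuration.

#' Default run configuration
#'
#' All stage parameters in one serializable list; written next to the outputs
#' of every run so a run can be reproduced byte-identically.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
runConfig <- function(...) {
  cfg <- list(
    topology = "circular",
    min_aa = 50L, count_stop_in_min = FALSE, max_overlap_nt = 75L,
    window = 150L, spacer_min = 20L, spacer_max = 40L,
    min_arm = 15L, max_loop = 40L, max_mismatch_rate = 0.2,
    hr_max_gap = 1000L, end_block_len = 15L,
    ori_at_threshold = 0.65, ori_flank = 1000L,
    dr_min_unit = 25L, dr_min_identity = 85,
    gamma_shape = 2.25, bootstrap_reps = 100L,
    max_index_gap = 2L, seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' @rdname runConfig
#' @param cfg configuration list.
#' @param path YAML file.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readConfig <- function(path) {
  cfg <- runConfig()
  over <- yaml::read_yaml(path)
  cfg[names(over)] <- over
  cfg
}

#' Annotate a genome: ORFs, promoters, repeats
#'
#' Runs the ORF caller (or ingests a provided GFF3 annotation instead —
#' published genome-level statistics are properties of a deposited annotation,
#' not of any overlap heuristic), the promoter scan, and the repeat finder,
#' and assembles a summary.  With `outdir` set, writes GFF3/BED/TSV outputs,
#' a JSON summary, and the configuration.
#'
#' @param genome a [Genome-class], or `fasta` path.
#' @param fasta path to a FASTA file (used when `genome` is missing).
#' @param gff optional GFF3 whose CDS features are trusted as the ORF set
#'   (annotation-ingest mode; skips calling).
#' @param config from [runConfig()].
#' @param outdir optional output directory.
#' @return list: `orfs`, `promoters`, `palindromes`, `hrs`, `ori_candidates`,
#'   `summary`.
#' @export
runAnnotate <- function(genome = NULL, fasta = NULL, gff = NULL,
                        config = runConfig(), outdir = NULL) {
  g <- if (!is.null(genome)) genome
       else readGenomeFasta(fasta, topology = config$topology)
  if (!is.null(gff)) {
    feats <- readFeatureGff3(gff, genomeLength(g), types = "CDS")
    orfs <- data.frame(start = feats$start, end = feats$end,
                       strand = feats$strand,
                       wraps = feats$start > feats$end,
                       aa_length = spanLength(feats$start, feats$end,
                                              genomeLength(g)) %/% 3L - 1L,
                       protein = NA_character_, ID = feats$ID,
                       stringsAsFactors = FALSE)
  } else {
    cand <- enumerateOrfs(g, minAa = config$min_aa,
                          countStopInMin = config$count_stop_in_min)
    orfs <- selectMinimalOverlap(cand$orfs, g, config$max_overlap_nt)
  }
  motifs <- motifSet(spacerMin = config$spacer_min,
                     spacerMax = config$spacer_max, window = config$window)
  prom <- scanPromoters(g, orfs, motifs)
  pals <- findPalindromes(g, minArm = config$min_arm,
                          maxLoop = config$max_loop,
                          maxMismatchRate = config$max_mismatch_rate)
  hrs <- clusterHrs(pals, g, maxGap = config$hr_max_gap)
  ori <- flagNonHrOri(g, hrs, atThreshold = config$ori_at_threshold,
                      flank = config$ori_flank, minUnit = config$dr_min_unit,
                      minIdentity = config$dr_min_identity)
  stats <- genomeStats(orfs, g)
  summary <- list(
    genome = genomeId(g), length_bp = genomeLength(g),
    at_percent = round(100 * stats$at_fraction, 1),
    n_orfs = stats$n_orfs,
    coding_fraction = round(stats$coding_fraction, 4),
    strand_split = c(stats$n_same_strand, stats$n_opposite_strand),
    promoters = prom$summary,
    n_palindromes = nrow(pals), n_hrs = nrow(hrs),
    n_ori_candidates = sum(ori$tier == 1L))
  out <- list(genome = g, orfs = orfs, promoters = prom, palindromes = pals,
              hrs = hrs, ori_candidates = ori, summary = summary)
  if (!is.null(outdir)) .write_annotate_bundle(out, config, outdir)
  out
}

.write_annotate_bundle <- function(res, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- res$genome
  p <- function(f) file.path(outdir, f)
  if (nrow(res$orfs)) {
    writeFeatures(featureTable(res$orfs$start, res$orfs$end, res$orfs$strand,
                               type = "CDS", ID = res$orfs$ID), g,
                  p("orfs.gff3"), "gff3")
    prot <- res$orfs$protein
    if (!all(is.na(prot)))
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(setNames(prot, res$orfs$ID)),
        p("proteins.faa"))
  }
  if (nrow(res$palindromes))
    writeFeatures(featureTable(res$palindromes$start, res$palindromes$end,
                               "+", type = "inverted_repeat",
                               ID = sprintf("pal%03d",
                                            seq_len(nrow(res$palindromes)))),
                  g, p("palindromes.bed"), "bed")
  if (nrow(res$hrs))
    writeFeatures(featureTable(res$hrs$start, res$hrs$end, "+",
                               type = "repeat_region",
                               ID = sprintf("hr%02d", res$hrs$hr)),
                  g, p("hrs.bed"), "bed")
  write.table(res$promoters$calls, p("promoter_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeConfig(config, p("config.yaml"))
  invisible(outdir)
}

#' Compare genomes: orthologs, synteny, phylogeny
#'
#' Builds the ortholog table by reciprocal best hits against the first
#' (reference) genome, computes gene-parity blocks for each genome against
#' the reference, and infers a UPGMA tree with bootstrap supports from the
#' families shared by all genomes (aligned per family, complete-deletion
#' masked, concatenated, gamma-corrected distances).
#'
#' @param proteomes named list (>= 2) of named protein vectors or
#'   `AAStringSet`s; first = reference.
#' @param orders optional named list of gene-order tables (gene/strand/
#'   start/end) for the synteny stage; gene ids must match protein ids.
#' @param config from [runConfig()].
#' @param outdir optional output directory.
#' @param alignments optional named list of pre-aligned families (rows named
#'   by genome), bypassing RBH + MSA for the phylogeny stage.
#' @return list: `orthologs`, `blocks` (per non-reference genome),
#'   `inversions`, `tree`, `supermatrix`.
#' @export
runCompare <- function(proteomes = NULL, orders = NULL,
                       config = runConfig(), outdir = NULL,
                       alignments = NULL) {
  if (is.null(proteomes) && is.null(alignments))
    stop("usage error: need proteomes or alignments")
  tab <- NULL; blocks <- NULL; inversions <- NULL
  if (!is.null(proteomes)) {
    if (length(proteomes) < 2L) stop("usage error: need >= 2 genomes")
    tab <- orthologTable(proteomes)
    genomes <- names(proteomes)
    if (!is.null(orders)) {
      blocks <- list(); inversions <- list()
      for (gn in setdiff(genomes, genomes[1])) {
        sub <- tab[!is.na(tab[[gn]]), c(genomes[1], gn)]
        oa <- orders[[genomes[1]]]; ob <- orders[[gn]]
        # map family membership onto gene order indices
        oa2 <- oa; oa2$gene <- oa$gene
        ob2 <- ob
        map <- setNames(sub[[1]], sub[[2]])       # member in gn -> ref family
        ob2$gene <- ifelse(ob$gene %in% names(map), map[ob$gene], ob$gene)
        pp <- parityPairs(oa2, ob2)
        bl <- colinearBlocks(pp, config$max_index_gap, oa2, ob2)
        blocks[[gn]] <- bl
        inversions[[gn]] <- inversionReport(bl)
      }
    }
  }
  tree <- NULL; sm <- NULL
  if (is.null(alignments) && !is.null(tab)) {
    genomes <- names(proteomes)
    shared <- tab[stats::complete.cases(tab[, genomes]), , drop = FALSE]
    if (nrow(shared) >= 1L) {
      alignments <- lapply(seq_len(nrow(shared)), function(i) {
        seqs <- vapply(genomes, function(gn)
          .as_named_chr(proteomes[[gn]])[[shared[[gn]][i]]], "")
        progressiveMsa(seqs, alignParams("protein"))$rows
      })
      names(alignments) <- shared$family
    }
  }
  if (!is.null(alignments)) {
    sm <- concatenateAlignments(alignments)
    tree <- bootstrapUpgma(sm, nReps = config$bootstrap_reps,
                           seed = config$seed,
                           gammaShape = config$gamma_shape)
  }
  res <- list(orthologs = tab, blocks = blocks, inversions = inversions,
              tree = tree, supermatrix = sm)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(tab))
      write.table(tab, file.path(outdir, "orthologs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(blocks))
      for (gn in names(blocks))
        write.table(blocks[[gn]],
                    file.path(outdir, paste0("blocks_", gn, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tree)) writeNewick(tree, file.path(outdir, "tree.nwk"))
    writeConfig(config, file.path(outdir, "config.yaml"))
  }
  res
}
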