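## End-to-end pipeline: split -> fit (classical or unfolded) -> infer codes
## -> enumerate configurations -> rank -> merge -> significance on the
## held-out test set -> MEME + TSV + JSON outputs.

#' Pipeline run configuration
#'
#' Defaults follow the reference configuration (M = 50, l = 8, K = 24,
#' h = 12, alpha = 32, beta = 100, K1 = 6, K2 = 3, q = 3, batch 6, 15 %
#' held-out test fraction, per-position scan p-value 1e-3, significance
#' gate 1e-6, top J = 1000 candidates). The "desk" profile (M = 8, K = 6,
#' h = 6, epochs = 10) is a reduced configuration for CPU-scale runs.
#'
#' @param profile "paper" (reference scale) or "desk" (CPU scale).
#' @param mode "classical" (alternating solver) or "unfolded" (trained
#'   network).
#' @param seed integer seed driving the split, fit and control shuffles.
#' @param testFraction held-out fraction (default 0.15).
#' @param scanPvalue per-position hit p-value (default 1e-3).
#' @param significancePvalue Fisher gate for reporting a motif as
#'   significant (default 1e-6).
#' @param topJ candidate buckets taken from the hash table (default 1000).
#' @param minBucket minimum hash-bucket occupancy for a configuration to
#'   become a motif candidate (default 2: an MSA needs at least two rows to
#'   define an alignment).
#' @param ... overrides for any \code{\link{defaultHyper}} field.
#' @return named list.
#' @export
runConfig <- function(profile = c("paper", "desk"),
                      mode = c("classical", "unfolded"), seed = 1L,
                      testFraction = 0.15, scanPvalue = 1e-3,
                      significancePvalue = 1e-6, topJ = 1000L,
                      minBucket = 2L, ...) {
  profile <- match.arg(profile)
  mode <- match.arg(mode)
  hyper <- if (profile == "desk")
    defaultHyper(M = 8L, K = 6L, h = 6L, epochs = 10L, ...)
  else defaultHyper(...)
  c(hyper, list(profile = profile, mode = mode, seed = as.integer(seed),
                testFraction = testFraction, scanPvalue = scanPvalue,
                significancePvalue = significancePvalue,
                topJ = as.integer(topJ), minBucket = as.integer(minBucket)))
}

#' Discover motifs in a set of DNA sequences
#'
#' Runs the full pipeline: the records are split into training and held-out
#' test sets; the two-level sparse representation is fitted on the training
#' set (alternating classical solver or trained unfolded network); sparse
#' image codes are inferred for all records; spatial configurations of the
#' image-code components are enumerated into the hash table; the top-J
#' buckets become candidate MSAs/PWMs; similar PWMs are merged by ALLR; and
#' each motif is scored for enrichment on the held-out test set against
#' dinucleotide-shuffled controls with Fisher's exact test.
#'
#' @param fasta path to a FASTA file, or a \code{DNAStringSet} / named
#'   character vector of at least 20 sequences.
#' @param config list from \code{\link{runConfig}}.
#' @param outDir output directory; created if needed. Written files:
#'   motifs.meme, report.tsv, run.json, run.log, and (if NULL) nothing is
#'   written.
#' @return a \code{MotifSet}, invisibly when \code{outDir} is given.
#' @export
discoverMotifs <- function(fasta, config = runConfig(), outDir = NULL) {
  records <- if (is.character(fasta) && length(fasta) == 1 &&
                 file.exists(fasta) && is.null(names(fasta)))
    readDnaFasta(fasta) else fasta
  recs <- asRecords(records)
  if (length(recs) < 20) stop("stage input: need at least 20 sequences")
  logLines <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    logLines <<- c(logLines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  cfg <- config
  bg <- rep(0.25, 4)

  note("split: ", length(recs), " records, test fraction ",
       cfg$testFraction)
  sp <- stage("split",
              splitTrainTest(recs, cfg$testFraction, cfg$seed))

  note("fit (", cfg$mode, "): ", length(sp$train), " training sequences")
  fitRes <- stage("fit", {
    if (cfg$mode == "classical") fitClassical(sp$train, cfg, cfg$seed)
    else netTrain(sp$train, cfg, cfg$seed)
  })
  model <- fitRes$model

  note("infer codes: ", length(recs), " records")
  codeSet <- stage("infer", {
    if (cfg$mode == "classical") inferCodes(model, recs, cfg)
    else inferCodes(fitRes$params, recs, cfg)
  })

  note("enumerate: q = ", cfg$q)
  tab <- stage("enumerate", buildMotifTable(codeSet, recs, cfg))
  top <- stage("rank", selectTop(tab, cfg$topJ))
  minB <- if (is.null(cfg$minBucket)) 2L else cfg$minBucket
  top <- top[top$count >= minB, ]
  note("hash table: ", length(unique(tab@entries$key)), " keys; kept ",
       nrow(top), " buckets of occupancy >= ", minB)

  cands <- stage("candidates", {
    out <- vector("list", nrow(top))
    for (i in seq_len(nrow(top))) {
      msa <- extractMsa(tab, recs, top$key[i])
      counts <- msaToCounts(msa)
      if (max(colSums(counts)) == 0) next
      out[[i]] <- list(counts = counts, key = top$key[i],
                       count = top$count[i],
                       msaSize = as.integer(max(colSums(counts))))
    }
    out[!vapply(out, is.null, logical(1))]
  })

  note("merge: ", length(cands), " candidates")
  merged <- stage("merge", mergeSimilar(cands, background = bg))
  ## trim uninformative edge columns so the scored PWM is the conserved core
  merged <- lapply(merged, function(m) {
    m$counts <- trimCountsByIC(m$counts, background = bg)
    m
  })
  note("merged into ", length(merged), " motifs")

  ## one site-refinement pass: re-estimate each motif's counts from its
  ## actual hit sites in the training records, which de-noises MSA rows
  ## contributed by impure buckets (the held-out test set is not touched)
  merged <- stage("refine", lapply(merged, function(m) {
    m$counts <- refineCounts(m$counts, sp$train, cfg$scanPvalue, bg)
    m
  }))

  note("significance: ", length(sp$test), " held-out records")
  ctrl <- stage("controls", shuffleControls(sp$test, cfg$seed + 1000L))
  motifs <- stage("significance", {
    lapply(merged, function(m) {
      pwm <- pwmFromCounts(m$counts, bg)
      ## calibrate so the two-strand per-position background hit rate is
      ## scanPvalue (Bonferroni over the two strand scans)
      thr <- pvalueToScore(pwm, cfg$scanPvalue / 2)
      st <- evaluateSignificance(pwm, sp$test, seed = cfg$seed + 1000L,
                                 threshold = thr, controls = ctrl)
      nInst <- scanHits(pwm, thr, recs)$count
      new("ScoredMotif", key = m$key, counts = m$counts,
          pwm = pwm$logOdds, background = bg, pseudocount = 1,
          threshold = thr,
          stats = c(st, nInstances = nInst, bucketCount = m$count,
                    nMerged = m$nMerged),
          msaSize = m$msaSize)
    })
  })
  ## report order: most significant first (ties: larger bucket, then key)
  if (length(motifs) > 1) {
    pv <- vapply(motifs, function(m) m@stats[["pValue"]], numeric(1))
    bc <- vapply(motifs, function(m) m@stats[["bucketCount"]], numeric(1))
    ky <- vapply(motifs, function(m) m@key, character(1))
    motifs <- motifs[order(pv, -bc, ky)]
  }
  motifSet <- new("MotifSet", motifs = motifs, config = cfg)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage("write", {
      writeMeme(motifSet, file.path(outDir, "motifs.meme"), bg)
      rep <- motifStats(motifSet)
      if (!is.null(rep)) {
        rep <- cbind(motif = sprintf("motif_%d", seq_len(nrow(rep))), rep)
        rep$significant <- rep$pValue < cfg$significancePvalue
      } else {
        rep <- data.frame(motif = character(0))
      }
      utils::write.table(rep, file.path(outDir, "report.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(config = cfg,
             package = as.character(utils::packageVersion("sparsemotif")),
             nRecords = length(recs), nMotifs = length(motifs)),
        file.path(outDir, "run.json"), auto_unbox = TRUE, digits = NA)
      writeLines(logLines, file.path(outDir, "run.log"))
    })
    return(invisible(motifSet))
  }
  motifSet
}

#' Human-readable summary of a pipeline run
#'
#' @param outDir directory written by \code{\link{discoverMotifs}}.
#' @return the report data.frame, invisibly; prints a per-motif summary
#'   (configuration key, width, instances, odds ratio to 3 decimals,
#'   p-value), or an explicit no-significant-motifs line.
#' @export
motifReport <- function(outDir) {
  path <- file.path(outDir, "report.tsv")
  if (!file.exists(path)) stop("no report.tsv under ", outDir)
  rep <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(rep) == 0 || !any(rep$significant)) {
    cat("no significant motifs\n")
  }
  if (nrow(rep) > 0) {
    for (i in seq_len(nrow(rep))) {
      cat(sprintf(
        "%s key=%s width=%d instances=%d oddsRatio=%.3f p=%.3g%s\n",
        rep$motif[i], rep$key[i], rep$width[i], rep$nInstances[i],
        rep$oddsRatio[i], rep$pValue[i],
        if (isTRUE(rep$significant[i])) " *" else ""))
    }
  }
  invisible(rep)
}
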