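## PWM construction, p-value calibrated score thresholds, hit scanning,
## dinucleotide-shuffled controls with Fisher's exact enrichment test, and
## ALLR-based redundancy merging.

#' Log-odds PWM from base counts
#'
#' \code{logOdds[b, j] = log2(((counts[b,j] + pc*bg[b]) / (colTotal + pc))
#' / bg[b])} — the standard pseudocounted log-odds, with the pseudocount
#' distributed by the background so no entry is -Inf.
#'
#' @param counts 4 x w non-negative count matrix (rows A,C,G,T).
#' @param background length-4 background probabilities; default uniform.
#' @param pseudocount total pseudocount per column (default 1).
#' @return list with \code{counts}, \code{logOdds} (4 x w, base 2),
#'   \code{background}, \code{pseudocount}.
#' @export
pwmFromCounts <- function(counts, background = rep(0.25, 4),
                          pseudocount = 1) {
  stopifnot(nrow(counts) == 4, all(counts >= 0), ncol(counts) >= 1)
  tot <- colSums(counts)
  if (any(tot == 0)) stop("zero total count in PWM column ",
                          which(tot == 0)[1])
  num <- counts + pseudocount * background
  freq <- sweep(num, 2, tot + pseudocount, "/")
  lo <- log2(freq / background)
  dimnames(lo) <- list(DNA_BASES, NULL)
  list(counts = counts, logOdds = lo, background = background,
       pseudocount = pseudocount)
}

#' Score threshold for a target p-value
#'
#' Computes the exact tail distribution of the PWM score of a random
#' background word by column-wise dynamic programming over scores
#' discretized at \code{granularity}, and returns the smallest discretized
#' threshold t with P(score >= t) <= pvalue. Together with the scanner's
#' ">= threshold" hit rule this calibrates the per-position hit probability
#' on background to (at most) \code{pvalue}.
#'
#' @param pwm a \code{pwmFromCounts} result, or a 4 x w log-odds matrix.
#' @param pvalue target p-value in (0, 1); default 1e-3.
#' @param granularity score discretization step (default 1e-3).
#' @param background length-4 background; defaults to the pwm's own, or
#'   uniform for a bare matrix.
#' @return numeric score threshold (a multiple of \code{granularity}).
#' @export
pvalueToScore <- function(pwm, pvalue = 1e-3, granularity = 1e-3,
                          background = NULL) {
  if (is.list(pwm)) {
    if (is.null(background)) background <- pwm$background
    pwm <- pwm$logOdds
  }
  if (is.null(background)) background <- rep(0.25, 4)
  stopifnot(pvalue > 0, pvalue < 1, granularity > 0)
  imat <- round(pwm / granularity)
  w <- ncol(imat)
  probs <- 1                          # P(partial score == offLo + i - 1)
  offLo <- 0
  dropTol <- min(pvalue, 1e-9) * 1e-3
  for (j in seq_len(w)) {
    cmin <- min(imat[, j]); cmax <- max(imat[, j])
    newLo <- offLo + cmin
    newP <- numeric(length(probs) + (cmax - cmin))
    for (b in 1:4) {
      sh <- imat[b, j] - cmin
      idx <- seq_along(probs) + sh
      newP[idx] <- newP[idx] + probs * background[b]
    }
    probs <- newP; offLo <- newLo
    ## lump negligible low-score mass into the lowest retained bin; the
    ## upper tail, which sets the threshold, is unaffected beyond dropTol
    if (length(probs) > 4096L) {
      cum <- cumsum(probs)
      cut <- which(cum > dropTol)[1]
      if (!is.na(cut) && cut > 1L) {
        lump <- cum[cut - 1L]
        probs <- probs[cut:length(probs)]
        probs[1L] <- probs[1L] + lump
        offLo <- offLo + cut - 1L
      }
    }
  }
  tail <- rev(cumsum(rev(probs)))
  ## smallest achievable score whose upper tail is within the target
  ok <- which(tail <= pvalue & probs > 0)
  if (length(ok) == 0L) return((offLo + length(probs)) * granularity)
  (offLo + ok[1] - 1L) * granularity
}

## integer base indices of a record; NA for N
baseIndices <- function(s)
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)

## scores of all w-windows of one record under a 4 x w matrix; NA windows
## (containing N) come out NA
windowScores <- function(pwm, idx) {
  w <- ncol(pwm); L <- length(idx)
  P <- L - w + 1L
  if (P < 1L) return(numeric(0))
  sc <- numeric(P)
  for (j in seq_len(w)) sc <- sc + pwm[, j][idx[j:(j + P - 1L)]]
  sc
}

#' Scan records for PWM hits on both strands
#'
#' Slides the PWM over every valid offset of every record; the reverse
#' strand is scanned with the reverse-complemented PWM on the forward text.
#' A position counts once even if both strands score >= threshold; windows
#' containing N never hit.
#'
#' @param pwm \code{pwmFromCounts} result or 4 x w log-odds matrix.
#' @param threshold score threshold (from \code{\link{pvalueToScore}}).
#' @param records \code{DNAStringSet} or character vector.
#' @return list with \code{count} (total hits) and \code{positions}
#'   (per-record integer vectors of 1-based window starts).
#' @export
scanHits <- function(pwm, threshold, records) {
  if (is.list(pwm)) pwm <- pwm$logOdds
  recs <- asRecords(records)
  if (length(recs) == 0L)
    return(list(count = 0L, positions = list()))
  w <- ncol(pwm)
  rc <- reverseComplementFilter(pwm)
  ## scan all records in one pass: join them with w-1 Ns, whose windows
  ## never hit, then split the hit offsets back per record
  sep <- strrep("N", w - 1L)
  joined <- paste(recs, collapse = sep)
  idx <- baseIndices(joined)
  fw <- windowScores(pwm, idx)
  rv <- windowScores(rc, idx)
  starts <- cumsum(c(1L, head(nchar(recs) + (w - 1L), -1L)))
  positions <- vector("list", length(recs))
  names(positions) <- names(recs)
  if (length(fw) > 0L) {
    hit <- which((!is.na(fw) & fw >= threshold) |
                 (!is.na(rv) & rv >= threshold))
    if (length(hit)) {
      rec <- findInterval(hit, starts)
      rel <- hit - starts[rec] + 1L
      keep <- rel <= nchar(recs)[rec] - w + 1L   # inside a record
      sp <- split(rel[keep], factor(rec[keep], levels = seq_along(recs)))
      positions <- lapply(sp, unname)
      names(positions) <- names(recs)
    } else {
      positions <- lapply(recs, function(z) integer(0))
    }
  } else positions <- lapply(recs, function(z) integer(0))
  list(count = sum(lengths(positions)), positions = positions)
}

#' Motif enrichment against dinucleotide-shuffled controls
#'
#' Counts hits of the PWM in the test records (tauH of N_T = sum of record
#' lengths positions) and in a control set built by dinucleotide-preserving
#' shuffling of the same records (seeded), then tests the null hypothesis
#' that the odds ratio (tauH/tauM)/(cH/cM) is one with a two-sided Fisher
#' exact test. A degenerate 2x2 margin gives an NA odds ratio and p = 1.
#'
#' @param pwm \code{pwmFromCounts} result or log-odds matrix.
#' @param testRecords held-out records.
#' @param seed integer seed for the control shuffles.
#' @param threshold score threshold; computed from \code{scanPvalue} if NULL.
#' @param scanPvalue per-position hit p-value for the threshold (default
#'   1e-3).
#' @param controls optional pre-shuffled control records (as produced by
#'   \code{\link{shuffleControls}}); shuffles are generated from \code{seed}
#'   when NULL. Passing them in lets one control set serve many motifs.
#' @return named numeric: tauH, tauM, cH, cM, oddsRatio, pValue.
#' @export
evaluateSignificance <- function(pwm, testRecords, seed = 1L,
                                 threshold = NULL, scanPvalue = 1e-3,
                                 controls = NULL) {
  recs <- asRecords(testRecords)
  stopifnot(length(recs) >= 1)
  if (is.null(threshold)) threshold <- pvalueToScore(pwm, scanPvalue)
  NT <- sum(nchar(recs))
  tauH <- scanHits(pwm, threshold, recs)$count
  tauM <- NT - tauH
  if (is.null(controls)) controls <- shuffleControls(recs, seed)
  cH <- scanHits(pwm, threshold, controls)$count
  cM <- NT - cH
  tab <- matrix(c(tauH, tauM, cH, cM), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    oddsRatio <- NA_real_; pValue <- 1
  } else {
    oddsRatio <- (tauH / tauM) / (cH / cM)
    pValue <- stats::fisher.test(tab)$p.value
  }
  c(tauH = tauH, tauM = tauM, cH = cH, cM = cM,
    oddsRatio = oddsRatio, pValue = pValue)
}

#' Dinucleotide-preserving shuffled controls for a record set
#'
#' One 2-mer-preserving shuffle per record, seeded per record.
#' @param records records to shuffle.
#' @param seed integer seed; record i uses \code{seed + i}.
#' @return character vector of shuffled records.
#' @export
shuffleControls <- function(records, seed = 1L) {
  recs <- asRecords(records)
  vapply(seq_along(recs), function(i)
    dinucleotideShuffle(recs[i], seed + i), character(1))
}

#' Average log-likelihood ratio between two PWM columns
#'
#' \code{allr(a, b) = [sum_b n^a_b log2(f^B_b / bg_b) +
#' sum_b n^b_b log2(f^A_b / bg_b)] / (n^a + n^b)}, where f is the
#' pseudocounted frequency of the opposite column. Positive for columns
#' with matching preferences, negative for clashing ones; symmetric.
#'
#' @param a,b length-4 count vectors.
#' @param background length-4 background probabilities.
#' @param pseudocount total pseudocount (default 1).
#' @return numeric ALLR in bits.
#' @export
allr <- function(a, b, background = rep(0.25, 4), pseudocount = 1) {
  na <- sum(a); nb <- sum(b)
  stopifnot(na > 0, nb > 0)
  fa <- (a + pseudocount * background) / (na + pseudocount)
  fb <- (b + pseudocount * background) / (nb + pseudocount)
  (sum(a * log2(fb / background)) + sum(b * log2(fa / background))) /
    (na + nb)
}

## all pairwise column ALLRs between two count matrices (wa x wb), by the
## same formula as allr() but in three matrix products
allrColumnMatrix <- function(ca, cb, background, pseudocount = 1) {
  na <- colSums(ca); nb <- colSums(cb)
  logFa <- log2(sweep(sweep(ca, 1, pseudocount * background, "+"),
                      2, na + pseudocount, "/") / background)
  logFb <- log2(sweep(sweep(cb, 1, pseudocount * background, "+"),
                      2, nb + pseudocount, "/") / background)
  (crossprod(ca, logFb) + crossprod(logFa, cb)) / outer(na, nb, "+")
}

## best gapless alignment of candidate counts cb against retained counts ca:
## all offsets, both strands, overlap >= minOverlap; returns the best mean
## column ALLR with its offset and strand
bestAllrAlignment <- function(ca, cb, minOverlap, background,
                              pseudocount = 1) {
  wa <- ncol(ca); wb <- ncol(cb)
  best <- list(score = -Inf, offset = 0L, strand = "+")
  for (strand in c("+", "-")) {
    cc <- if (strand == "+") cb else reverseComplementFilter(cb)
    Mal <- allrColumnMatrix(ca, cc, background, pseudocount)
    ## a gapless alignment at offset off uses the diagonal ja - jb = off;
    ## all diagonal means in one pass
    dg <- as.vector(row(Mal) - col(Mal))
    sums <- rowsum(as.vector(Mal), dg)
    lens <- tabulate(dg - min(dg) + 1L)
    offs <- sort(unique(dg))
    keep <- lens >= minOverlap
    if (!any(keep)) next
    means <- sums[keep, 1] / lens[keep]
    i <- which.max(means)
    if (means[i] > best$score)
      best <- list(score = means[i], offset = offs[keep][i],
                   strand = strand)
  }
  best
}

## pseudocounted log2(freq/background) profile of a count matrix, cached
## alongside the pieces the pairwise ALLR matrix needs
allrProfile <- function(counts, background, pseudocount = 1) {
  n <- colSums(counts)
  logF <- log2(sweep(sweep(counts, 1, pseudocount * background, "+"),
                     2, n + pseudocount, "/") / background)
  list(counts = counts, n = n, logF = logF)
}

## best alignment of candidate profile pb (given strand) to retained pa
bestOffsetScore <- function(pa, pb, minOverlap) {
  Mal <- (crossprod(pa$counts, pb$logF) + crossprod(pa$logF, pb$counts)) /
    outer(pa$n, pb$n, "+")
  wa <- nrow(Mal); wb <- ncol(Mal)
  dg <- as.vector(row(Mal) - col(Mal))
  sums <- rowsum(as.vector(Mal), dg)
  lens <- tabulate(dg - (1L - wb) + 1L)
  keep <- lens >= minOverlap
  if (!any(keep)) return(list(score = -Inf, offset = 0L))
  means <- sums[keep, 1] / lens[keep]
  i <- which.max(means)
  list(score = means[i], offset = ((1L - wb):(wa - 1L))[keep][i])
}

#' Merge redundant motif candidates by ALLR similarity
#'
#' Walks the enrichment-ranked candidate list; each candidate is aligned
#' (all gapless offsets, both strands) against every retained motif and
#' merged into the best-matching one when the mean column ALLR over an
#' overlap of at least \code{minOverlap} columns exceeds
#' \code{allrThreshold}; otherwise it is retained as a new motif. Merging
#' sums the aligned candidate counts into the retained motif (its width is
#' kept), so the total number of MSA rows is conserved. Deterministic.
#'
#' @param candidates list of candidates, each a list with \code{counts}
#'   (4 x w), \code{key}, \code{count} (bucket size), \code{msaSize}.
#' @param minOverlap minimum aligned columns; default
#'   \code{max(6, ceiling(w_short / 2))} per pair.
#' @param allrThreshold mean-ALLR merge threshold in bits (default 0).
#' @param background length-4 background.
#' @return list of merged candidates (same structure, plus \code{nMerged}).
#' @export
mergeSimilar <- function(candidates, minOverlap = NULL, allrThreshold = 0,
                         background = rep(0.25, 4)) {
  retained <- list()
  profs <- list()
  for (cand in candidates) {
    pbF <- allrProfile(cand$counts, background)
    pbR <- allrProfile(reverseComplementFilter(cand$counts), background)
    wb <- ncol(cand$counts)
    bestIdx <- 0L; bestScore <- -Inf; bestOff <- 0L; bestStrand <- "+"
    for (i in seq_along(retained)) {
      wa <- ncol(retained[[i]]$counts)
      mo <- if (is.null(minOverlap)) max(6L, ceiling(min(wa, wb) / 2))
            else minOverlap
      mo <- min(mo, wa, wb)
      for (strand in c("+", "-")) {
        al <- bestOffsetScore(profs[[i]],
                              if (strand == "+") pbF else pbR, mo)
        if (al$score > bestScore) {
          bestScore <- al$score; bestIdx <- i
          bestOff <- al$offset; bestStrand <- strand
        }
      }
    }
    if (bestIdx > 0L && bestScore > allrThreshold) {
      r <- retained[[bestIdx]]
      cc <- if (bestStrand == "+") cand$counts
            else reverseComplementFilter(cand$counts)
      wa <- ncol(r$counts)
      ja <- max(1L, bestOff + 1L):min(wa, bestOff + wb)
      r$counts[, ja] <- r$counts[, ja] + cc[, ja - bestOff]
      r$msaSize <- r$msaSize + cand$msaSize
      r$count <- r$count + cand$count
      r$nMerged <- r$nMerged + 1L
      retained[[bestIdx]] <- r
      profs[[bestIdx]] <- allrProfile(r$counts, background)
    } else {
      cand$nMerged <- 1L
      retained[[length(retained) + 1L]] <- cand
      profs[[length(retained)]] <- pbF
    }
  }
  retained
}

#' Trim uninformative edge columns from a count matrix
#'
#' Removes leading and trailing columns whose information content (2 minus
#' the entropy of the pseudocounted column frequencies, in bits) falls
#' below \code{minIC}; internal low-information columns (spacers of gapped
#' motifs) are kept. Returns the input unchanged if no column passes.
#'
#' @param counts 4 x w count matrix.
#' @param minIC minimum edge-column information content in bits
#'   (default 0.25).
#' @param background length-4 background probabilities.
#' @param pseudocount total pseudocount per column.
#' @return trimmed 4 x w' count matrix.
#' @export
trimCountsByIC <- function(counts, minIC = 0.25, background = rep(0.25, 4),
                           pseudocount = 1) {
  tot <- colSums(counts)
  freq <- sweep(counts + pseudocount * background, 2, tot + pseudocount,
                "/")
  ic <- 2 + colSums(freq * log2(freq))
  ## small-sample correction: a random column over n sequences carries
  ## about 3/(2 ln 2 n) bits of apparent information, so the edge
  ## threshold rises accordingly for thin MSAs
  n <- max(stats::median(tot), 1)
  thr <- minIC + 2.16 / n
  keep <- which(ic >= thr)
  if (length(keep) == 0L) return(counts)
  counts[, keep[1]:keep[length(keep)], drop = FALSE]
}

#' Re-estimate motif counts from its hit sites
#'
#' Scans \code{records} with the PWM built from \code{counts} (threshold
#' calibrated to \code{scanPvalue} per strand pair) and rebuilds the count
#' matrix from the hit windows, reverse-complementing windows that score
#' better on the minus strand. One such refinement pass de-noises a PWM
#' assembled from heterogeneous MSA buckets. Returns the input counts
#' unchanged when fewer than \code{minSites} sites are found.
#'
#' @param counts 4 x w count matrix.
#' @param records records to re-estimate from (training set).
#' @param scanPvalue per-position (two-strand) hit p-value.
#' @param background length-4 background.
#' @param minSites minimum number of hit sites (default 5).
#' @return 4 x w count matrix.
#' @export
refineCounts <- function(counts, records, scanPvalue = 1e-3,
                         background = rep(0.25, 4), minSites = 5L) {
  recs <- asRecords(records)
  pwm <- pwmFromCounts(counts, background)
  thr <- pvalueToScore(pwm, scanPvalue / 2)
  hits <- scanHits(pwm, thr, recs)
  if (hits$count < minSites) return(counts)
  w <- ncol(counts)
  rc <- reverseComplementFilter(pwm$logOdds)
  sites <- character(0)
  for (id in names(hits$positions)) {
    ps <- hits$positions[[id]]
    if (length(ps) == 0L) next
    idx <- baseIndices(recs[[id]])
    fw <- windowScores(pwm$logOdds, idx)
    rv <- windowScores(rc, idx)
    for (p in ps) {
      sub <- substr(recs[[id]], p, p + w - 1L)
      if (!is.na(rv[p]) && (is.na(fw[p]) || rv[p] > fw[p]))
        sub <- reverseComplement(sub)
      sites <- c(sites, sub)
    }
  }
  out <- msaToCounts(sites)
  if (max(colSums(out)) < minSites) counts else out
}

#' Write motifs in MEME minimal format
#'
#' @param motifSet a \code{MotifSet}, or a list of \code{ScoredMotif} /
#'   candidate lists with \code{counts}.
#' @param path output file.
#' @param background length-4 background probabilities.
#' @return the path, invisibly.
#' @export
writeMeme <- function(motifSet, path, background = rep(0.25, 4)) {
  ms <- if (methods::is(motifSet, "MotifSet")) motifSet@motifs else motifSet
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background),
                     collapse = " "), ""), con)
  for (i in seq_along(ms)) {
    m <- ms[[i]]
    counts <- if (methods::is(m, "ScoredMotif")) m@counts else m$counts
    key <- if (methods::is(m, "ScoredMotif")) m@key else m$key
    nsites <- max(colSums(counts))
    freq <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
    writeLines(sprintf("MOTIF motif_%d %s", i, key), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(counts), nsites), con)
    writeLines(apply(freq, 2, function(cc)
      paste(sprintf("%.6f", cc), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read back a MEME minimal file written by \code{writeMeme}
#'
#' @param path MEME file path.
#' @return list of motifs, each with \code{name}, \code{key}, \code{freq}
#'   (4 x w letter-probability matrix).
#' @export
readMeme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(s) {
    hdr <- strsplit(lines[s], "\\s+")[[1]]
    wline <- lines[s + 1L]
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", wline))
    block <- lines[(s + 2L):(s + 1L + w)]
    freq <- vapply(block, function(x)
      as.numeric(strsplit(trimws(x), "\\s+")[[1]]), numeric(4),
      USE.NAMES = FALSE)                  # 4 x w
    dimnames(freq) <- list(DNA_BASES, NULL)
    list(name = hdr[2], key = if (length(hdr) > 2) hdr[3] else NA_character_,
         freq = freq)
  })
}
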