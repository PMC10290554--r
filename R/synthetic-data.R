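## Planted-motif synthetic data: background sequences (i.i.d. or first-order
## Markov) with primary, gapped, or embedded motif sites written in at known
## coordinates, plus the ground-truth table for recovery scoring.

#' Sample background DNA sequences
#'
#' i.i.d. uniform bases (order 0) or a first-order Markov chain with a
#' supplied transition matrix. Deterministic given \code{seed}.
#'
#' @param n number of sequences (>= 1).
#' @param L sequence length (>= 1).
#' @param markovOrder 0 or 1.
#' @param seed integer seed.
#' @param transition 4 x 4 row-stochastic matrix (rows/cols A,C,G,T);
#'   required when \code{markovOrder = 1}.
#' @param init length-4 initial base distribution (default uniform).
#' @return named \code{DNAStringSet}.
#' @export
sampleBackground <- function(n, L, markovOrder = 0, seed = 1L,
                             transition = NULL, init = rep(0.25, 4)) {
  stopifnot(n >= 1, L >= 1, markovOrder %in% c(0, 1))
  if (markovOrder == 1) {
    if (is.null(transition) || !all(dim(transition) == c(4, 4)) ||
        any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
      stop("markovOrder = 1 needs a 4 x 4 row-stochastic transition matrix")
  }
  seqs <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      if (markovOrder == 0) {
        paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
      } else {
        b <- integer(L)
        b[1] <- sample.int(4, 1, prob = init)
        if (L > 1) for (j in 2:L)
          b[j] <- sample.int(4, 1, prob = transition[b[j - 1], ])
        paste(DNA_BASES[b], collapse = "")
      }
    }, character(1))
  })
  names(seqs) <- paste0("seq", seq_len(n))
  Biostrings::DNAStringSet(seqs)
}

#' Specification of a motif-planting experiment
#'
#' @param pfms list of 4 x w column-stochastic PFMs to plant (named, or
#'   auto-named motif1, motif2, ...).
#' @param mode "primary" (sites concatenated directly, typically one PFM),
#'   "gapped" (sites joined by a random-background spacer of length drawn
#'   uniformly from \code{spacerRange}) or "embedded" (the first PFM's site
#'   wrapped in fixed flanking consensus sequence, emulating a conserved
#'   long element that embeds a primary site).
#' @param spacerRange integer interval c(lo, hi) of spacer lengths (gapped).
#' @param occurrenceRate probability that a sequence receives a planted
#'   insert.
#' @param strandProb probability that the insert is reverse-complemented.
#' @param flankWidth width of each fixed flank (embedded mode).
#' @param seed integer seed (site sampling, spacers, positions, and the
#'   fixed flanks of embedded mode).
#' @return a plant specification list for \code{\link{plantMotifs}}.
#' @export
plantSpec <- function(pfms, mode = c("primary", "gapped", "embedded"),
                      spacerRange = c(5, 5), occurrenceRate = 0.8,
                      strandProb = 0, flankWidth = 8L, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.list(pfms)) pfms <- list(pfms)
  if (is.null(names(pfms))) names(pfms) <- paste0("motif", seq_along(pfms))
  stopifnot(occurrenceRate >= 0, occurrenceRate <= 1,
            strandProb >= 0, strandProb <= 1,
            spacerRange[1] >= 0, spacerRange[2] >= spacerRange[1])
  for (p in pfms)
    stopifnot(nrow(p) == 4, all(abs(colSums(p) - 1) < 1e-6))
  list(pfms = pfms, mode = mode, spacerRange = as.integer(spacerRange),
       occurrenceRate = occurrenceRate, strandProb = strandProb,
       flankWidth = as.integer(flankWidth), seed = as.integer(seed))
}

sampleSite <- function(pfm) {
  paste(DNA_BASES[apply(pfm, 2, function(p) sample.int(4, 1, prob = p))],
        collapse = "")
}

#' Plant motif sites into background records
#'
#' Per record, with probability \code{occurrenceRate}: a site is sampled
#' from each PFM (per-column multinomial), the sites are joined according
#' to the mode (directly; with a uniform random spacer; or inside fixed
#' consensus flanks), optionally reverse-complemented as a whole, and
#' written over the record at a uniform random valid offset. At most one
#' insert is planted per record, so truth coordinates are unambiguous.
#'
#' @param records background records (\code{DNAStringSet} or character).
#' @param spec a \code{\link{plantSpec}}.
#' @return list with \code{records} (same class layout, modified) and
#'   \code{truth}, a data.frame with columns id, start, end (1-based,
#'   closed), strand, motif, spacer.
#' @export
plantMotifs <- function(records, spec) {
  recs <- asRecords(records)
  out <- withSeed(spec$seed, {
    flanks <- NULL
    if (spec$mode == "embedded")
      flanks <- c(paste(sample(DNA_BASES, spec$flankWidth, TRUE),
                        collapse = ""),
                  paste(sample(DNA_BASES, spec$flankWidth, TRUE),
                        collapse = ""))
    truth <- list()
    for (i in seq_along(recs)) {
      if (stats::runif(1) > spec$occurrenceRate) next
      sites <- vapply(spec$pfms, sampleSite, character(1))
      spacer <- NA_integer_
      insert <- switch(spec$mode,
        primary = paste(sites, collapse = ""),
        gapped = {
          spacer <- if (spec$spacerRange[2] > spec$spacerRange[1])
            sample(spec$spacerRange[1]:spec$spacerRange[2], 1)
          else spec$spacerRange[1]
          gaps <- vapply(seq_len(length(sites) - 1L), function(g)
            paste(sample(DNA_BASES, spacer, TRUE), collapse = ""),
            character(1))
          paste0(paste0(sites[-length(sites)], gaps, collapse = ""),
                 sites[length(sites)])
        },
        embedded = paste0(flanks[1], sites[1], flanks[2]))
      L <- nchar(recs[i]); wi <- nchar(insert)
      if (wi > L) stop("insert of width ", wi,
                       " does not fit a length-", L, " sequence")
      strand <- "+"
      if (stats::runif(1) < spec$strandProb) {
        insert <- reverseComplement(insert)
        strand <- "-"
      }
      pos <- sample.int(L - wi + 1L, 1)
      substr(recs[i], pos, pos + wi - 1L) <- insert
      truth[[length(truth) + 1L]] <- data.frame(
        id = names(recs)[i], start = pos, end = pos + wi - 1L,
        strand = strand, motif = paste(names(spec$pfms), collapse = "+"),
        spacer = spacer)
    }
    list(records = recs, truth = if (length(truth))
      do.call(rbind, truth)
      else data.frame(id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      motif = character(0), spacer = integer(0)))
  })
  out$records <- Biostrings::DNAStringSet(out$records)
  out
}

#' Write a planted-truth table as TSV
#'
#' BED-like but 1-based, closed, with strand, matching the package-wide
#' coordinate convention.
#'
#' @param truth truth data.frame from \code{\link{plantMotifs}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTruthTsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' A sharply peaked random PFM
#'
#' Each column concentrates mass \code{conservation} on one random base and
#' splits the rest evenly; a convenient planted-motif ground truth.
#'
#' @param w width in nt.
#' @param conservation probability of the preferred base per column.
#' @param seed integer seed.
#' @return 4 x w column-stochastic matrix.
#' @export
conservedPfm <- function(w, conservation = 0.9, seed = 1L) {
  withSeed(seed, {
    p <- matrix((1 - conservation) / 3, 4, w,
                dimnames = list(DNA_BASES, NULL))
    for (j in seq_len(w)) p[sample.int(4, 1), j] <- conservation
    p
  })
}
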