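## shared fixture builders; everything is generated in code, seeded

randomDna <- function(L, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else sparsemotif:::withSeed(seed, gen())
}

## tiny hyper configuration for fast solver/net tests
tinyHyper <- function(...) defaultHyper(M = 2L, l = 3L, K = 2L, h = 2L,
                                        alpha = 6L, K1 = 2L, K2 = 2L,
                                        sweeps = 2L, beta = 10, ...)

## mean per-column Pearson correlation of a planted PFM against the best
## gapless alignment (both strands) within a frequency matrix
bestPfmPearson <- function(freq, pfm) {
  w <- ncol(pfm)
  best <- -1
  for (cand in list(freq, reverseComplementFilter(freq))) {
    wa <- ncol(cand)
    if (wa < w) next
    for (off in 0:(wa - w)) {
      cc <- mean(vapply(seq_len(w), function(j)
        suppressWarnings(stats::cor(cand[, off + j], pfm[, j])), numeric(1)))
      if (!is.na(cc) && cc > best) best <- cc
    }
  }
  best
}

countsToFreq <- function(counts)
  sweep(counts, 2, pmax(colSums(counts), 1), "/")
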