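test_that("log-odds PWM construction follows the pseudocount formula", {
  flat <- matrix(5L, 4, 3)
  expect_equal(max(abs(pwmFromCounts(flat)$logOdds)), 0)
  p <- pwmFromCounts(matrix(c(10L, 0L, 0L, 0L), 4, 1), pseudocount = 1)
  expect_equal(unname(p$logOdds[1, 1]), log2((10.25 / 11) / 0.25), tolerance = 1e-12)
  ## scale invariance at zero pseudocount
  c1 <- matrix(c(3L, 1L, 0L, 2L), 4, 1) + 1L
  expect_equal(pwmFromCounts(c1, pseudocount = 0)$logOdds,
               pwmFromCounts(2L * c1, pseudocount = 0)$logOdds)
  expect_error(pwmFromCounts(matrix(0L, 4, 2)), "zero total")
})

test_that("pvalue-to-score threshold matches word enumeration on a
           single column", {
  lo <- matrix(c(2, 1, 0, -1), 4, 1)
  expect_equal(pvalueToScore(lo, 0.25), 2)
  expect_equal(pvalueToScore(lo, 0.5), 1)
})

test_that("pvalue-to-score equals the exhaustive 4^w word oracle", {
  oracle <- function(lo, pvalue, bg, gran = 1e-3) {
    w <- ncol(lo)
    imat <- round(lo / gran)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    sc <- numeric(nrow(words)); pr <- numeric(nrow(words))
    for (i in seq_len(nrow(words))) {
      sc[i] <- sum(imat[cbind(words[i, ], seq_len(w))])
      pr[i] <- prod(bg[words[i, ]])
    }
    cand <- sort(unique(sc))
    for (t in cand) if (sum(pr[sc >= t]) <= pvalue) return(t * gran)
    (max(sc) + 1) * gran
  }
  set.seed(11)
  for (i in 1:50) {
    w <- sample(2:6, 1)
    counts <- matrix(rpois(4 * w, 3) + 1L, 4, w)
    pwm <- pwmFromCounts(counts)
    pv <- runif(1, 0.001, 0.3)
    expect_equal(pvalueToScore(pwm, pv),
                 oracle(pwm$logOdds, pv, pwm$background), tolerance = 1e-9)
  }
})

test_that("pvalue-to-score is monotone in the p-value", {
  set.seed(12)
  pwm <- pwmFromCounts(matrix(rpois(32, 4) + 1L, 4, 8))
  ts <- vapply(c(0.2, 0.05, 0.01, 1e-3, 1e-4), function(p)
    pvalueToScore(pwm, p), numeric(1))
  expect_true(all(diff(ts) >= 0))
})

test_that("scanning finds exact sites on both strands, once per position", {
  ## PWM strongly matching "AC"
  pwm <- pwmFromCounts(matrix(c(20L, 0L, 0L, 0L, 0L, 20L, 0L, 0L), 4, 2))
  thr <- 3                                   # only the exact word scores >= 3
  hits <- scanHits(pwm, thr, c(r = "ACGACT"))
  expect_equal(hits$count, 2)
  expect_equal(hits$positions$r, c(1L, 4L))
  ## reverse-strand site "GT" is found by the rc scan at the same offset
  hits2 <- scanHits(pwm, thr, c(r = "GGGTGG"))
  expect_equal(hits2$positions$r, 3L)
  ## a site hitting on both strands counts once
  pal <- pwmFromCounts(msaToCounts(c("ACGT", "ACGT", "ACGT")))
  thrP <- pvalueToScore(pal, 0.01)
  hp <- scanHits(pal, thrP, c(r = "AAACGTAA"))
  expect_equal(hp$count, length(unique(hp$positions$r)))
  ## empty record set and N windows
  expect_equal(scanHits(pwm, thr, character(0))$count, 0)
  expect_equal(scanHits(pwm, thr, c(r = "ANCANC"))$count, 0)
})

test_that("scanning is strand symmetric", {
  set.seed(13)
  for (i in 1:10) {
    counts <- matrix(rpois(4 * 5, 2) + 1L, 4, 5)
    pwm <- pwmFromCounts(counts)
    thr <- pvalueToScore(pwm, 0.05)
    s <- setNames(randomDna(40), "r")
    rcp <- list(counts = counts, logOdds = reverseComplementFilter(pwm$logOdds),
                background = pwm$background)
    a <- scanHits(pwm, thr, s)$count
    b <- scanHits(rcp, thr, setNames(reverseComplement(unname(s)), "r"))$count
    expect_equal(a, b)
  }
})

test_that("control hit rate on background tracks the scan p-value", {
  set.seed(14)
  counts <- msaToCounts(vapply(1:40, function(i)
    randomDna(8), character(1)))
  pwm <- pwmFromCounts(counts)
  thr <- pvalueToScore(pwm, 1e-3)
  recs <- setNames(vapply(1:40, function(i) randomDna(2500), character(1)),
                   paste0("r", 1:40))
  NT <- sum(nchar(recs))
  rate <- scanHits(pwm, thr, recs)$count / NT
  expect_gte(rate, 0.5e-3 * 0.5)   # binomial tolerance at NT = 1e5,
  expect_lte(rate, 2e-3)           # both-strand scan stays within 2x
})

test_that("Fisher significance matches the hypergeometric example and
           handles degeneracy", {
  ## build a PWM and records so that tauH = 3, tauM = 1, cH = 1, cM = 3
  ## cannot be staged through scanning; check the 2x2 arithmetic directly
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(stats::fisher.test(tab)$p.value, 34 / 70, tolerance = 1e-12)
  or <- (3 / 1) / (1 / 3)
  expect_equal(or, 9)
  ## the full evaluate path: a motif planted in the test set is enriched
  pfmT <- conservedPfm(8, 0.99, seed = 21)
  bg <- sampleBackground(30, 60, seed = 22)
  pl <- plantMotifs(bg, plantSpec(list(m = pfmT), "primary",
                                  occurrenceRate = 1, seed = 23))
  counts <- msaToCounts(vapply(seq_len(nrow(pl$truth)), function(i)
    substr(as.character(pl$records)[pl$truth$id[i]],
           pl$truth$start[i], pl$truth$end[i]), character(1)))
  pwm <- pwmFromCounts(counts)
  st <- evaluateSignificance(pwm, pl$records, seed = 24)
  expect_gte(st[["tauH"]], 25)
  expect_lt(st[["pValue"]], 1e-6)
  expect_equal(st[["tauH"]] + st[["tauM"]], sum(nchar(as.character(pl$records))))
  ## degenerate table: nothing hits anywhere
  never <- pwmFromCounts(matrix(c(50L, 0L, 0L, 0L), 4, 8))
  stD <- evaluateSignificance(never, c(a = "CCCGGGCCCGGG"), seed = 1,
                              threshold = 1e6)
  expect_true(is.na(stD[["oddsRatio"]]))
  expect_equal(stD[["pValue"]], 1)
})

test_that("Fisher p-values equal an independent hypergeometric-sum oracle", {
  hyperOracle <- function(a, b, c, d) {
    ## two-sided Fisher: sum of all table probabilities <= observed
    rs1 <- a + b; rs2 <- c + d; cs1 <- a + c; n <- a + b + c + d
    support <- max(0, cs1 - rs2):min(rs1, cs1)
    pr <- stats::dhyper(support, rs1, rs2, cs1)
    pObs <- stats::dhyper(a, rs1, rs2, cs1)
    sum(pr[pr <= pObs * (1 + 1e-7)])
  }
  set.seed(15)
  for (i in 1:500) {
    a <- rpois(1, 4); b <- rpois(1, 20) + 1
    c <- rpois(1, 4); d <- rpois(1, 20) + 1
    p1 <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
    p2 <- hyperOracle(a, b, c, d)
    expect_lt(abs(p1 - p2) / max(p2, 1e-300), 1e-10)
  }
})

test_that("ALLR sign, symmetry, and merge behavior", {
  strong <- c(18, 1, 1, 1)
  expect_gt(allr(strong, strong), 0)
  expect_lt(allr(strong, rev(strong)), 0)
  set.seed(16)
  for (i in 1:10) {
    a <- rpois(4, 5) + 1; b <- rpois(4, 5) + 1
    expect_equal(allr(a, b), allr(b, a))
  }
  ## the fast pairwise matrix agrees with the scalar op
  ca <- matrix(rpois(12, 5) + 1, 4, 3); cb <- matrix(rpois(8, 5) + 1, 4, 2)
  Mal <- sparsemotif:::allrColumnMatrix(ca, cb, rep(0.25, 4))
  for (j in 1:3) for (i in 1:2)
    expect_equal(Mal[j, i], allr(ca[, j], cb[, i]), tolerance = 1e-12)
})

test_that("merging collapses duplicates and retains dissimilar motifs", {
  msa <- c("ACGTACGT", "ACGTACGT", "ACGAACGT", "ACGTACCT")
  counts <- msaToCounts(msa)
  cand <- list(counts = counts, key = "1:0:2", count = 4L, msaSize = 4L)
  merged <- mergeSimilar(list(cand, cand))
  expect_length(merged, 1)
  expect_equal(merged[[1]]$counts, 2L * counts)
  expect_equal(merged[[1]]$msaSize, 8L)
  ## two clashing conserved motifs are both retained
  m1 <- msaToCounts(rep("AAAAAAAA", 6))
  m2 <- msaToCounts(rep("CGCGCGCG", 6))
  kept <- mergeSimilar(list(
    list(counts = m1, key = "a", count = 6L, msaSize = 6L),
    list(counts = m2, key = "b", count = 6L, msaSize = 6L)))
  expect_length(kept, 2)
  ## determinism and row conservation
  cands <- list(
    list(counts = m1, key = "a", count = 6L, msaSize = 6L),
    list(counts = counts, key = "c", count = 4L, msaSize = 4L),
    list(counts = m2, key = "b", count = 6L, msaSize = 6L))
  r1 <- mergeSimilar(cands); r2 <- mergeSimilar(cands)
  expect_identical(r1, r2)
  expect_equal(sum(vapply(r1, `[[`, numeric(1), "msaSize")), 16)
  ## a reverse-complement duplicate merges onto the original
  rcCand <- list(counts = reverseComplementFilter(counts), key = "d",
                 count = 4L, msaSize = 4L)
  mergedRc <- mergeSimilar(list(cand, rcCand))
  expect_length(mergedRc, 1)
})

test_that("MEME writer round-trips motif frequencies", {
  msa <- c("ACGTAC", "ACGTAC", "ACGAAC", "TCGTAC")
  counts <- msaToCounts(msa)
  sm <- new("ScoredMotif", key = "1:2:3", counts = counts,
            pwm = pwmFromCounts(counts)$logOdds,
            background = rep(0.25, 4), pseudocount = 1, threshold = 0,
            stats = c(tauH = 1, tauM = 1, cH = 1, cM = 1, oddsRatio = 1,
                      pValue = 1, nInstances = 4, bucketCount = 4,
                      nMerged = 1),
            msaSize = 4L)
  tf <- tempfile(fileext = ".meme")
  writeMeme(list(sm), tf)
  back <- readMeme(tf)
  expect_length(back, 1)
  expect_equal(back[[1]]$key, "1:2:3")
  expect_equal(back[[1]]$freq, countsToFreq(counts), tolerance = 1e-5)
  lines <- readLines(tf)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^ALPHABET= ACGT", lines)))
})
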