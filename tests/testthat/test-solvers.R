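test_that("non-negative soft-threshold matches its definition", {
  expect_equal(softThresholdNonneg(c(3, -1, 0.5), 1), c(2, 0, 0))
  v <- c(0, 0.2, 5)
  expect_equal(softThresholdNonneg(v, 0), v)
  set.seed(1)
  for (i in 1:10)
    expect_true(all(softThresholdNonneg(rnorm(20), runif(1)) >= 0))
  expect_error(softThresholdNonneg(1, -1))
})

test_that("top-alpha projection keeps largest magnitudes, index tie-break", {
  expect_equal(projectTopAlpha(c(5, -3, 2, 0.1), 2), c(5, -3, 0, 0))
  v <- c(1, -2, 0, 3)
  expect_equal(projectTopAlpha(v, 10), v)
  expect_equal(projectTopAlpha(c(1, 1, 1), 2), c(1, 1, 0))
  expect_equal(projectTopAlpha(matrix(1:4, 2), 0), matrix(0, 2, 2))
})

test_that("top-alpha projection equals a sort-based oracle", {
  oracle <- function(v, alpha) {
    if (alpha >= length(v)) return(v)
    ord <- order(-abs(v), seq_along(v))
    out <- numeric(length(v))
    out[ord[seq_len(alpha)]] <- v[ord[seq_len(alpha)]]
    out
  }
  set.seed(2)
  for (i in 1:1000) {
    n <- sample(1:30, 1)
    v <- round(rnorm(n), sample(0:2, 1))   # rounding creates magnitude ties
    a <- sample(0:n, 1)
    expect_identical(projectTopAlpha(v, a), oracle(v, a))
  }
})

test_that("single-filter ISTA code step matches a finite-difference oracle", {
  ## 1 filter, L = 6: one step from codes c0 must equal
  ## prox_{lambda*eta}(c0 - eta * numerical gradient of the data term)
  set.seed(3)
  bank <- randomSeqBank(1, 3)
  s <- oneHotEncode("ACGTAC")
  P <- 4
  X0 <- matrix(rexp(P, 2), P, 1); Y0 <- matrix(rexp(P, 2), P, 1)
  eta <- 0.05; lambda <- 0.3
  dataTerm <- function(X, Y)
    0.5 * sum((reconstructSequence(bank, list(X = X, Y = Y)) - s)^2)
  numGradX <- vapply(1:P, function(p) {
    e <- matrix(0, P, 1); e[p] <- 1e-6
    (dataTerm(X0 + e, Y0) - dataTerm(X0 - e, Y0)) / 2e-6
  }, numeric(1))
  upd <- istaCodeStep(list(X = X0, Y = Y0), bank, s, m = 1,
                      eta = eta, lambda = lambda)
  expect_equal(upd$X[, 1], pmax(X0[, 1] - eta * numGradX - lambda * eta, 0),
               tolerance = 1e-6)
  ## y step uses the residual after the x update
  numGradY <- vapply(1:P, function(p) {
    e <- matrix(0, P, 1); e[p] <- 1e-6
    (dataTerm(upd$X, Y0 + e) - dataTerm(upd$X, Y0 - e)) / 2e-6
  }, numeric(1))
  expect_equal(upd$Y[, 1], pmax(Y0[, 1] - eta * numGradY - lambda * eta, 0),
               tolerance = 1e-6)
})

test_that("ISTA code step fixed points and thresholding limits", {
  set.seed(4)
  bank <- randomSeqBank(2, 3)
  ## zero residual (s equals the reconstruction), zero coupling -> unchanged
  X <- matrix(rexp(12), 6, 2); Y <- matrix(0, 6, 2)
  s <- reconstructSequence(bank, list(X = X, Y = Y))
  upd <- istaCodeStep(list(X = X, Y = Y), bank, s, m = 1, eta = 0.01,
                      lambda = 0, rho = 0)
  expect_equal(upd$X, X, tolerance = 1e-12)
  ## huge lambda drives codes to zero
  upd2 <- istaCodeStep(list(X = X, Y = Y), bank, s, m = 1, eta = 0.01,
                       lambda = 1e6)
  expect_equal(sum(upd2$X[, 1]), 0)
})

test_that("ADMM fits an exact 1-sparse synthetic instance", {
  hyper <- defaultHyper(M = 2L, l = 4L, K = 2L, h = 3L, alpha = 4L,
                        lambda = 1e-4, eta = 0.15, rho = 1e-4, sweeps = 3L)
  bank <- withSeed(101, randomSeqBank(2, 4))
  ib <- withSeed(102, randomImageBank(2, 3, 2))
  P <- 17
  X <- matrix(0, P, 2); X[5, 1] <- 1
  s <- reconstructSequence(bank, list(X = X, Y = matrix(0, P, 2)))
  st <- admmSolveCodes(bank, ib, s, hyper, iters = 50)
  rec <- reconstructSequence(bank, list(X = st$X, Y = st$Y))
  expect_lt(sum((rec - s)^2), 1e-3)
})

test_that("ADMM respects the sparsity budget and code positivity", {
  hyper <- tinyHyper()
  bank <- withSeed(11, randomSeqBank(hyper$M, hyper$l))
  ib <- withSeed(12, randomImageBank(hyper$K, hyper$h, hyper$M))
  s <- oneHotEncode(randomDna(25, seed = 13))
  st <- admmSolveCodes(bank, ib, s, hyper, iters = 8)
  expect_lte(sum(st$Z != 0), hyper$alpha)
  expect_true(all(st$X >= 0) && all(st$Y >= 0))
  ## alpha = 0 forces Z to stay zero
  h0 <- tinyHyper(alpha = 0L)
  st0 <- admmSolveCodes(bank, ib, s, h0, iters = 5)
  expect_equal(sum(st0$Z != 0), 0)
})

test_that("ADMM primal residual settles on a fixed random instance", {
  hyper <- defaultHyper(M = 3L, l = 4L, K = 2L, h = 3L, alpha = 8L,
                        rho = 1e-2)
  bank <- withSeed(21, randomSeqBank(3, 4))
  ib <- withSeed(22, randomImageBank(2, 3, 3))
  s <- oneHotEncode(randomDna(40, seed = 23))
  st <- admmSolveCodes(bank, ib, s, hyper, iters = 100)
  last10 <- tail(st$primal, 10)
  expect_true(all(diff(last10) <= 1e-8))
})

test_that("mirror descent keeps columns on the simplex and finds the
           empirical site frequencies on a one-filter toy", {
  set.seed(31)
  l <- 4; L <- 12; P <- L - l + 1; nseq <- 40
  truePfm <- matrix(c(0.7, 0.1, 0.1, 0.1), 4, l)
  seqs <- list(); codes <- list(); siteSum <- matrix(0, 4, l)
  for (i in 1:nseq) {
    site <- paste(c("A", "C", "G", "T")[
      apply(truePfm, 2, function(p) sample(4, 1, prob = p))], collapse = "")
    sq <- randomDna(L)
    substr(sq, 3, 3 + l - 1) <- site
    seqs[[i]] <- oneHotEncode(sq)
    siteSum <- siteSum + oneHotEncode(site)
    Xi <- matrix(0, P, 1); Xi[3, 1] <- 1
    codes[[i]] <- list(X = Xi, Y = matrix(0, P, 1))
  }
  b <- withSeed(32, randomSeqBank(1, l))
  for (it in 1:200) {
    b <- mirrorDescentStepD(b, codes, seqs, step = 2)
    cs <- colSums(pfm(b, 1))
    expect_true(all(abs(cs - 1) < 1e-9) && all(pfm(b, 1) > 0))
  }
  ## analytic optimum of the quadratic: the empirical site frequency
  expect_lt(max(abs(pfm(b, 1) - siteSum / nseq)), 1e-2)
  ## zero gradient (perfect reconstruction, no background) -> fixed point
  perfect <- lapply(codes, function(cc)
    reconstructSequence(b, cc))
  b2 <- mirrorDescentStepD(b, codes, perfect, step = 2)
  expect_equal(seqFilters(b2), seqFilters(b), tolerance = 1e-10)
})

test_that("image-filter ISTA normalizes, stays non-negative, and its
           gradient matches finite differences", {
  set.seed(41)
  K <- 2; h <- 2; M <- 2
  ib <- randomImageBank(K, h, M)
  Z <- matrix(rexp(8), 4, K)
  target <- matrix(rnorm(5 * 2 * M), 5, 2 * M)
  upd <- istaStepF(ib, list(Z), list(target), step = 1e-3, mu = 0, tau = 1)
  fro <- sqrt(apply(imageFilters(upd)^2, 3, sum))
  expect_equal(unname(fro), rep(1, K))
  expect_true(all(imageFilters(upd) >= 0))
  ## finite-difference check of the pre-projection gradient direction
  f0 <- imageFilters(ib)
  obj <- function(f) 0.5 * sum((reconstructImage(f, Z) - target)^2)
  gNum <- array(0, dim(f0))
  for (i in seq_along(f0)) {
    e <- array(0, dim(f0)); e[i] <- 1e-6
    gNum[i] <- (obj(f0 + e) - obj(f0 - e)) / 2e-6
  }
  step <- 1e-3
  pre <- f0 - step * gNum              # tau = 1, mean over 1 sequence
  pre[pre < 0] <- 0
  for (k in 1:K) pre[, , k] <- pre[, , k] / sqrt(sum(pre[, , k]^2))
  expect_equal(imageFilters(upd), pre, tolerance = 1e-6)
  ## a huge mu zeroes every filter and triggers re-initialization
  upd2 <- withSeed(5, istaStepF(ib, list(Z), list(target), step = 1,
                                mu = 1e9, tau = 1))
  fro2 <- sqrt(apply(imageFilters(upd2)^2, 3, sum))
  expect_equal(unname(fro2), rep(1, K))
  expect_gt(max(abs(imageFilters(upd2) - imageFilters(ib))), 0.01)
})

test_that("classical fit is deterministic, respects invariants, and
           decreases its objective on a small planted instance", {
  pfmT <- conservedPfm(6, 0.95, seed = 51)
  bg <- sampleBackground(12, 30, seed = 52)
  pl <- plantMotifs(bg, plantSpec(list(m = pfmT), "primary",
                                  occurrenceRate = 1, seed = 53))
  hyper <- defaultHyper(M = 3L, l = 6L, K = 2L, h = 3L, alpha = 6L,
                        outerRounds = 5L, admmIters = 4L, beta = 1,
                        rho = 0.1)
  fit <- fitClassical(pl$records, hyper, seed = 54)
  fit2 <- fitClassical(pl$records, hyper, seed = 54)
  expect_identical(seqFilters(fit$model@seqBank), seqFilters(fit2$model@seqBank))
  ## all PFM columns on the simplex after the fit
  cs <- apply(seqFilters(fit$model@seqBank), c(2, 3), sum)
  expect_true(all(abs(cs - 1) < 1e-9))
  fro <- sqrt(apply(imageFilters(fit$model@imageBank)^2, 3, sum))
  expect_true(all(abs(fro - 1) < 1e-6))
  ## image codes within budget, all code matrices non-negative
  for (cc in codes(fit$codes)) {
    expect_lte(sum(cc$Z != 0), hyper$alpha)
    expect_true(all(cc$X >= 0) && all(cc$Y >= 0))
  }
  ## objective trace settles: each later round is no worse than the
  ## previous one beyond round-off
  tot <- fit$objective[, "total"]
  expect_true(all(diff(tot[-1]) <= 1e-6))
  ## zero rounds returns the initialization
  h0 <- defaultHyper(M = 3L, l = 6L, K = 2L, h = 3L, outerRounds = 0L)
  fit0 <- fitClassical(pl$records, h0, seed = 54)
  init <- withSeed(54, randomSeqBank(3, 6))
  expect_identical(seqFilters(fit0$model@seqBank), seqFilters(init))
})

test_that("classical fit recovers a strongly planted PFM", {
  pfmT <- conservedPfm(8, 0.97, seed = 61)
  bg <- sampleBackground(30, 40, seed = 62)
  pl <- plantMotifs(bg, plantSpec(list(m = pfmT), "primary",
                                  occurrenceRate = 1, seed = 63))
  hyper <- defaultHyper(M = 3L, l = 8L, K = 2L, h = 3L, alpha = 6L,
                        outerRounds = 20L, admmIters = 5L, lambda = 0.2,
                        eta = 0.02, pi = 2)
  fit <- fitClassical(pl$records, hyper, seed = 65)
  d <- seqFilters(fit$model@seqBank)
  best <- -1
  for (m in seq_len(hyper$M))
    best <- max(best, bestPfmPearson(d[, , m], pfmT))
  expect_gte(best, 0.8)
})
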