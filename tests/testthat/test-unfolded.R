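test_that("parameter count matches the reference configuration", {
  expect_identical(countParameters(defaultHyper()), 30421L)
  ## only the per-layer step sizes scale with depth: 2 scalars per extra
  ## code layer, 2 per extra filter layer
  h <- defaultHyper()
  expect_identical(countParameters(defaultHyper(K1 = 2L * h$K1)) -
                   countParameters(h), 2L * h$K1)
  expect_identical(countParameters(defaultHyper(K2 = h$K2 + 1L)) -
                   countParameters(h), 2L)
  ## filter weights dominate: M*4*l + K*h*2M
  tiny <- defaultHyper(M = 1L, l = 2L, K = 1L, h = 2L, K1 = 1L, K2 = 1L)
  expect_identical(countParameters(tiny), 8L + 4L + 3L + 4L)
})

test_that("forward pass starts from zero codes and honors degenerate depth", {
  hyper <- tinyHyper(K1 = 0L, K2 = 0L)
  seqs <- lapply(1:2, function(i) oneHotEncode(randomDna(12, seed = i)))
  params <- netInit(hyper, seed = 1L)
  fw <- netForward(params, seqs, hyper)
  for (cc in fw$codes) {
    expect_equal(sum(abs(cc$X)) + sum(abs(cc$Y)) + sum(abs(cc$Z)), 0)
  }
  ## zero codes, any filters: loss = mean ||s||^2 = L for one-hot strings
  expect_equal(fw$loss, 12)
  expect_equal(unname(fw$lossTerms["seq"]), 12)
  expect_equal(unname(fw$lossTerms["image"]), 0)
  ## K1 > 0 keeps Z within the sparsity budget
  h2 <- tinyHyper(alpha = 3L)
  fw2 <- netForward(netInit(h2, 1L), seqs, h2)
  for (cc in fw2$codes) expect_lte(sum(cc$Z != 0), 3)
})

test_that("loss is non-negative and vanishes on a constructed fixed point", {
  hyper <- tinyHyper()
  seqs <- lapply(1:3, function(i) oneHotEncode(randomDna(14, seed = 10 + i)))
  params <- netInit(hyper, seed = 2L)
  fw <- netForward(params, seqs, hyper)
  expect_gte(fw$loss, 0)
  ## exact synthetic instance: codes that reproduce both levels exactly
  bank <- withSeed(3, randomSeqBank(2, 3))
  ib <- withSeed(4, randomImageBank(2, 2, 2))
  P <- 8; Q <- 7
  Z <- matrix(0, Q, 2); Z[3, 1] <- 2
  XY <- reconstructImage(ib, Z) / 5       # beta = 5 target met exactly
  codes <- list(list(X = XY[, 1:2], Y = XY[, 3:4], Z = Z))
  s <- reconstructSequence(bank, codes[[1]])
  expect_lt(unname(netLoss(codes, seqFilters(bank), imageFilters(ib),
                           list(s), beta = 5)["loss"]), 1e-10)
})

test_that("forward with shared step sizes is tensor-identical to the
           classical iterates", {
  hyper <- tinyHyper(M = 3L, l = 4L, K = 2L, h = 3L, alpha = 5L, K1 = 4L,
                     K2 = 2L, sweeps = 2L, beta = 100)
  s <- oneHotEncode(randomDna(30, seed = 7))
  params <- netInit(hyper, seed = 3L)
  eff <- sparsemotif:::effectiveParams(params)
  shared <- hyper
  shared$lambda <- eff$lambda; shared$mu <- eff$mu
  shared$rho <- eff$rho; shared$tau <- eff$rho
  shared$eta <- eff$eta[1]; shared$gamma <- eff$gamma[1]
  shared$pi <- eff$piv[1]; shared$omega <- eff$omega[1]
  bank <- SeqFilterBank(params@d)
  ib <- new("ImageFilterBank", filters = params@f)
  ## code phase == ADMM code solve
  st <- admmSolveCodes(bank, ib, s, shared, iters = hyper$K1)
  fw <- netForward(params, list(s), hyper)
  expect_identical(fw$codes[[1]]$X, st$X)
  expect_identical(fw$codes[[1]]$Y, st$Y)
  expect_identical(fw$codes[[1]]$Z, st$Z)
  expect_identical(fw$codes[[1]]$U, st$U)
  ## filter phase == mirror + image-filter ISTA + dual updates
  codes <- list(list(X = st$X, Y = st$Y, Z = st$Z))
  b <- bank; ibb <- ib
  theta <- matrix(0, nrow(st$X), 2 * hyper$M)
  for (t in seq_len(hyper$K2)) {
    b <- mirrorDescentStepD(b, codes, list(s), shared$pi)
    targ <- list(hyper$beta * cbind(st$X, st$Y) - theta)
    ibb <- istaStepF(ibb, list(st$Z), targ, shared$omega, shared$mu,
                     shared$tau)
    theta <- theta + reconstructImage(ibb, st$Z) -
      hyper$beta * cbind(st$X, st$Y)
  }
  expect_identical(fw$dFinal, seqFilters(b))
  expect_identical(fw$fFinal, imageFilters(ibb))
  expect_identical(fw$thetas[[1]], theta)
})

test_that("hand-derived gradients match central finite differences", {
  hyper <- tinyHyper(alpha = 100L)   # identity projection: smooth graph
  seqs <- lapply(1:3, function(i)
    oneHotEncode(randomDna(15, seed = 20 + i)))
  params <- netInit(hyper, seed = 6L)
  gr <- netGradients(params, seqs, hyper)
  lossAt <- function(p) netForward(p, seqs, hyper)$loss
  fd <- function(slot, idx, eps = 1e-4) {
    p1 <- params; p2 <- params
    v <- methods::slot(params, slot)
    v1 <- v; v2 <- v
    v1[idx] <- v[idx] + eps; v2[idx] <- v[idx] - eps
    methods::slot(p1, slot) <- v1; methods::slot(p2, slot) <- v2
    (lossAt(p1) - lossAt(p2)) / (2 * eps)
  }
  set.seed(30)
  checks <- list(list("d", sample(length(params@d), 3)),
                 list("f", sample(length(params@f), 3)),
                 list("logLambda", 1), list("logMu", 1), list("logRho", 1),
                 list("logEta", 1:2), list("logGamma", 1:2),
                 list("logPi", 1:2), list("logOmega", 1:2))
  for (ch in checks) for (idx in ch[[2]]) {
    num <- fd(ch[[1]], idx)
    ana <- gr$grads[[ch[[1]]]][idx]
    ok <- abs(num - ana) / max(abs(num), abs(ana), 1e-8) < 1e-3 ||
      abs(num - ana) < 1e-10
    expect_true(ok, label = paste("gradient of", ch[[1]], "entry", idx))
  }
})

test_that("training runs the expected number of optimizer steps, is
           deterministic, and does not increase the loss on a planted set", {
  pfmT <- conservedPfm(6, 0.95, seed = 41)
  bg <- sampleBackground(12, 24, seed = 42)
  pl <- plantMotifs(bg, plantSpec(list(m = pfmT), "primary",
                                  occurrenceRate = 1, seed = 43))
  hyper <- defaultHyper(M = 2L, l = 6L, K = 2L, h = 2L, alpha = 6L,
                        K1 = 2L, K2 = 1L, sweeps = 1L, epochs = 2L,
                        batchSize = 6L, learningRate = 1e-3)
  tr <- netTrain(pl$records, hyper, seed = 44)
  expect_length(tr$lossHistory, 2)
  ## 12 strings at batch 6: 2 optimizer steps per epoch
  expect_lte(tail(tr$lossHistory, 1), tr$lossHistory[1])
  tr2 <- netTrain(pl$records, hyper, seed = 44)
  expect_identical(tr$params@d, tr2$params@d)
  expect_identical(tr$params@logEta, tr2$params@logEta)
  ## projections hold after training
  cs <- apply(tr$params@d, c(2, 3), sum)
  expect_true(all(abs(cs - 1) < 1e-9))
  fro <- sqrt(apply(tr$params@f^2, 3, sum))
  expect_true(all(abs(fro - 1) < 1e-6))
  expect_error(netTrain(pl$records[1:3], hyper, seed = 1), "batchSize")
})

test_that("code inference is deterministic and respects the budget", {
  hyper <- tinyHyper(alpha = 4L)
  params <- netInit(hyper, seed = 8L)
  recs <- setNames(vapply(1:4, function(i) randomDna(20, seed = 50 + i),
                          character(1)), paste0("r", 1:4))
  cs1 <- inferCodes(params, recs, hyper)
  cs2 <- inferCodes(params, recs, hyper)
  expect_identical(codes(cs1), codes(cs2))
  for (cc in codes(cs1)) expect_lte(sum(cc$Z != 0), 4)
  ## classical-model route
  fit <- fitClassical(recs, tinyHyper(alpha = 4L, outerRounds = 1L),
                      seed = 9L)
  cs3 <- inferCodes(fit$model, recs)
  for (cc in codes(cs3)) expect_lte(sum(cc$Z != 0), 4)
  ## reconstruction from inferred codes tracks an exactly representable
  ## input closely
  bank <- fit$model@seqBank
  X <- matrix(0, 18, 2); X[c(4, 30)] <- 1
  sEx <- reconstructSequence(bank, list(X = X, Y = matrix(0, 18, 2)))
  hEx <- tinyHyper(alpha = 4L, lambda = 1e-4, rho = 1e-4, eta = 0.15,
                   K1 = 40L)
  pEx <- netInit(hEx, seed = 10L)
  pEx@d <- seqFilters(bank)
  csEx <- inferCodes(pEx, list(sEx), hEx)
  rec <- reconstructSequence(bank, codes(csEx, 1))
  expect_lte(sum((rec - sEx)^2) / sum(sEx^2), 0.05)
})

test_that("checkpoints round-trip parameters, hyper and seed", {
  hyper <- tinyHyper()
  params <- netInit(hyper, seed = 11L)
  tf <- tempfile(fileext = ".json")
  writeCheckpoint(params, hyper, 11L, tf)
  back <- readCheckpoint(tf)
  expect_equal(back$seed, 11L)
  expect_equal(back$hyper$M, hyper$M)
  expect_equal(back$hyper$beta, hyper$beta)
  expect_equal(back$params@d, params@d)
  expect_equal(back$params@f, params@f)
  expect_equal(back$params@logOmega, params@logOmega)
  ## a forward pass with restored parameters is identical
  s <- list(oneHotEncode(randomDna(12, seed = 60)))
  expect_equal(netForward(back$params, s, back$hyper)$loss,
               netForward(params, s, hyper)$loss)
})
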