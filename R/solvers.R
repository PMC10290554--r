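## Alternating minimization of the two-level representation:
## ADMM over the codes (non-negative ISTA for X/Y, projected gradient with a
## hard top-alpha projection for Z, scaled dual ascent), mirror descent on
## the PFM filters, non-negative ISTA with Frobenius renormalization on the
## image filters. The same iterates are re-used verbatim as layers of the
## unfolded network.

#' Non-negative soft-threshold operator
#'
#' \code{max(v - t, 0)} elementwise; the proximal operator of the l1 penalty
#' restricted to the non-negative orthant.
#'
#' @param v numeric vector/matrix.
#' @param t threshold, \code{t >= 0}.
#' @return object of the same shape, all entries >= 0.
#' @examples
#' softThresholdNonneg(c(3, -1, 0.5), 1)
#' @export
softThresholdNonneg <- function(v, t) {
  stopifnot(t >= 0)
  out <- v - t
  out[out < 0] <- 0
  out
}

#' Keep the alpha largest-magnitude entries of a matrix
#'
#' Hard sparsity projection: the \code{alpha} entries of largest absolute
#' value are kept, the rest zeroed. Ties are broken by smallest flat
#' (column-major) index.
#'
#' @param Z numeric matrix (or vector).
#' @param alpha integer >= 0.
#' @return object of the same shape with at most alpha non-zeros.
#' @examples
#' projectTopAlpha(c(5, -3, 2, 0.1), 2)
#' @export
projectTopAlpha <- function(Z, alpha) {
  stopifnot(alpha >= 0)
  v <- as.vector(Z)
  if (alpha >= length(v)) return(Z)
  keep <- order(-abs(v), seq_along(v))[seq_len(alpha)]
  out <- Z
  out[] <- 0
  out[keep] <- Z[keep]
  out
}

## one alternating (x-phase then y-phase) Jacobi-in-m ISTA sweep over the
## code pair; W and U are the current image reconstruction and scaled duals
## (both on the image scale, i.e. matching beta*(X, Y)). The coupling term
## rho*(x - (L + Gamma)/beta) maps them back to code scale, so the pull is
## toward the image reconstruction's estimate of the code; at beta = 1 this
## is exactly rho*(x - L - Gamma).
codeSweep <- function(X, Y, DjF, DjR, s, W, U, eta, lambda, rho, beta,
                      keep = FALSE) {
  P <- nrow(X); M <- ncol(X)
  iF <- seq_len(M); iR <- M + iF
  Rx <- seqConv(DjF, X) + seqConv(DjR, Y) - s
  Gx <- seqXcorr(DjF, Rx, P)
  X1 <- softThresholdNonneg(
    X - eta * (Gx + rho * (X - (W[, iF] + U[, iF]) / beta)),
    lambda * eta)
  Ry <- Rx + seqConv(DjF, X1 - X)
  Gy <- seqXcorr(DjR, Ry, P)
  Y1 <- softThresholdNonneg(
    Y - eta * (Gy + rho * (Y - (W[, iR] + U[, iR]) / beta)),
    lambda * eta)
  if (keep)
    list(X = X1, Y = Y1, X0 = X, Y0 = Y, Rx = Rx, Gx = Gx, Ry = Ry, Gy = Gy)
  else list(X = X1, Y = Y1)
}

#' One ISTA update of the code pair for a single sequence filter
#'
#' Updates column m of the forward and reverse codes by one non-negative
#' ISTA step on the reconstruction objective, with the optional ADMM
#' coupling to the image reconstruction (left/right halves \code{W} and
#' scaled duals \code{U}).
#'
#' @param codes list with P x M matrices \code{X} and \code{Y}.
#' @param bank a \code{SeqFilterBank}.
#' @param s 4 x L one-hot matrix.
#' @param m filter index to update.
#' @param eta step size > 0.
#' @param lambda code sparsity weight.
#' @param rho coupling penalty (0 for plain ISTA).
#' @param W P x 2M current image reconstruction (NULL for zero).
#' @param U P x 2M scaled duals (NULL for zero).
#' @param beta image scaling factor.
#' @return list with updated \code{X} and \code{Y}.
#' @export
istaCodeStep <- function(codes, bank, s, m, eta, lambda = 0, rho = 0,
                         W = NULL, U = NULL, beta = 1) {
  stopifnot(eta > 0)
  d <- bank@filters
  M <- dim(d)[3]; P <- nrow(codes$X)
  if (P != ncol(s) - dim(d)[2] + 1L)
    stop("code length does not match sequence and filter width")
  if (is.null(W)) W <- matrix(0, P, 2 * M)
  if (is.null(U)) U <- matrix(0, P, 2 * M)
  DjF <- makeDj(d); DjR <- makeDj(rcArray(d))
  X <- codes$X; Y <- codes$Y
  Rx <- seqConv(DjF, X) + seqConv(DjR, Y) - s
  ## per-m gradient: cross-correlate filter m only
  Djm <- lapply(DjF, function(a) a[, m, drop = FALSE])
  DjmR <- lapply(DjR, function(a) a[, m, drop = FALSE])
  gx <- seqXcorr(Djm, Rx, P)
  xm <- softThresholdNonneg(
    X[, m] - eta * (gx + rho * (X[, m] - (W[, m] + U[, m]) / beta)),
    lambda * eta)
  dx <- xm - X[, m]
  X[, m] <- xm
  Ry <- Rx + seqConv(Djm, matrix(dx, ncol = 1))
  gy <- seqXcorr(DjmR, Ry, P)
  ym <- softThresholdNonneg(
    Y[, m] - eta * (gy + rho * (Y[, m] - (W[, M + m] + U[, M + m]) / beta)),
    lambda * eta)
  Y[, m] <- ym
  list(X = X, Y = Y)
}

#' ADMM solve of the sparse codes of one sequence, filters fixed
#'
#' Loops: (i) \code{sweeps} alternating non-negative ISTA sweeps over the
#' code pair; (ii) one projected-gradient step on the image code Z (gradient
#' of the quadratic coupling penalty, then hard top-alpha projection);
#' (iii) scaled dual update of the coupling constraint
#' \eqn{\sum_k F_k * z_k = \beta(X, Y)}.
#'
#' @param bank \code{SeqFilterBank}; \code{ibank} \code{ImageFilterBank}.
#' @param ibank image filter bank.
#' @param s 4 x L one-hot matrix.
#' @param hyper hyperparameter list (see \code{\link{defaultHyper}}).
#' @param iters number of ADMM iterations (>= 1).
#' @param state optional warm-start state (a previous return value).
#' @return list with X, Y (P x M), Z (Q x K, <= alpha non-zeros), U
#'   (P x 2M scaled duals) and \code{primal}, the trace of the primal
#'   residual norm of the coupling constraint.
#' @export
admmSolveCodes <- function(bank, ibank, s, hyper, iters = hyper$admmIters,
                           state = NULL) {
  stopifnot(iters >= 1)
  d <- bank@filters; f <- ibank@filters
  M <- dim(d)[3]; l <- dim(d)[2]; K <- dim(f)[3]; h <- dim(f)[1]
  L <- ncol(s); P <- L - l + 1L; Q <- P - h + 1L
  if (Q < 1L) stop("sequence too short for the filter sizes")
  DjF <- makeDj(d); DjR <- makeDj(rcArray(d)); Fj <- makeFj(f)
  beta <- hyper$beta; rho <- hyper$rho
  if (is.null(state)) {
    X <- matrix(0, P, M); Y <- matrix(0, P, M)
    Z <- matrix(0, Q, K); U <- matrix(0, P, 2 * M)
  } else {
    X <- state$X; Y <- state$Y; Z <- state$Z; U <- state$U
  }
  primal <- numeric(iters)
  for (it in seq_len(iters)) {
    W <- imgConv(Fj, Z)
    for (sw in seq_len(hyper$sweeps)) {
      upd <- codeSweep(X, Y, DjF, DjR, s, W, U, hyper$eta, hyper$lambda,
                       rho, beta)
      X <- upd$X; Y <- upd$Y
    }
    XY <- beta * cbind(X, Y)
    E <- imgConv(Fj, Z) - XY + U
    Gz <- rho * imgXcorr(Fj, E, Q)
    Z <- projectTopAlpha(Z - hyper$gamma * Gz, hyper$alpha)
    W2 <- imgConv(Fj, Z)
    U <- U + W2 - XY
    primal[it] <- sqrt(sum((W2 - XY)^2))
    if (!all(is.finite(X)) || !all(is.finite(Y)) || !all(is.finite(Z)))
      stop("ADMM diverged (non-finite values) at iteration ", it)
  }
  list(X = X, Y = Y, Z = Z, U = U, primal = primal)
}

#' One mirror-descent update of the PFM filter bank
#'
#' Multiplicative update of every filter column under the negative-entropy
#' mirror map: \code{d <- d * exp(-pi * g)} renormalized to the simplex,
#' where g is the gradient of the sequence reconstruction term (including
#' the chain through the reverse-complement filters). Columns stay strictly
#' inside the simplex whenever they start there.
#'
#' @param bank \code{SeqFilterBank}.
#' @param codes list of per-sequence code lists (X, Y).
#' @param seqs list of 4 x L one-hot matrices.
#' @param step mirror step size pi > 0.
#' @return updated \code{SeqFilterBank}.
#' @export
mirrorDescentStepD <- function(bank, codes, seqs, step) {
  stopifnot(step > 0)
  d <- bank@filters
  M <- dim(d)[3]; l <- dim(d)[2]
  cs <- apply(d, c(2, 3), sum)
  if (any(cs <= 0)) stop("zero column mass in a PFM filter")
  g <- filterGradD(d, codes, seqs)
  SeqFilterBank(mirrorUpdate(d, g, step)$d)
}

## multiplicative (negative-entropy mirror) update of every PFM column:
## d <- d * exp(-step * g), renormalized per column; computed via a shifted
## softmax for stability. Boundary zeros are absorbing. Returns the pieces
## the unfolded network's reverse pass needs.
mirrorUpdate <- function(d, g, step) {
  M <- dim(d)[3]; l <- dim(d)[2]
  t <- log(pmax(d, 1e-300)) - step * g
  dNew <- d
  wKeep <- array(0, dim(d)); sKeep <- matrix(0, l, M)
  eKeep <- array(0, dim(d))
  for (m in seq_len(M)) {
    tm <- matrix(t[, , m], 4, l)
    shift <- apply(tm, 2, max)
    em <- exp(sweep(tm, 2, shift, "-"))
    em[matrix(d[, , m], 4, l) == 0] <- 0
    ssum <- colSums(em)
    dNew[, , m] <- sweep(em, 2, ssum, "/")
    wKeep[, , m] <- em
    sKeep[, m] <- ssum
    ## exp factor alone (w = d * e); clamped for the zero-d boundary
    eKeep[, , m] <- exp(pmin(sweep(-step * matrix(g[, , m], 4, l),
                                   2, shift, "-"), 700))
  }
  list(d = dNew, w = wKeep, s = sKeep, e = eKeep)
}

## gradient of the mean (over sequences) of 0.5*||recon_n - s_n||^2 w.r.t.
## the PFM filters; the per-sequence mean keeps the mirror step size
## meaningful independently of dataset or batch size
filterGradD <- function(d, codes, seqs) {
  l <- dim(d)[2]
  DjF <- makeDj(d); DjR <- makeDj(rcArray(d))
  g <- array(0, dim(d))
  for (n in seq_along(seqs)) {
    R <- seqConv(DjF, codes[[n]]$X) + seqConv(DjR, codes[[n]]$Y) - seqs[[n]]
    g <- g + seqConvFilterGrad(R, codes[[n]]$X, l) +
      rcArray(seqConvFilterGrad(R, codes[[n]]$Y, l))
  }
  g / length(seqs)
}

#' One non-negative ISTA update of the image filter bank
#'
#' Gradient step on the quadratic coupling term, non-negative
#' soft-thresholding with mu*omega, then Frobenius normalization of each
#' filter. A filter zeroed entirely by the threshold is redrawn at random
#' (Frobenius normalization of a zero matrix is undefined).
#'
#' @param ibank \code{ImageFilterBank}.
#' @param zs list of per-sequence image codes Z.
#' @param codeImages list of per-sequence targets \code{beta * (X, Y)}
#'   (P x 2M), optionally plus scaled duals already added by the caller.
#' @param step step size omega > 0.
#' @param mu filter sparsity weight.
#' @param tau coupling penalty weight multiplying the gradient.
#' @return updated \code{ImageFilterBank}.
#' @export
istaStepF <- function(ibank, zs, codeImages, step, mu, tau) {
  stopifnot(step > 0)
  f <- ibank@filters
  h <- dim(f)[1]; K <- dim(f)[3]
  Fj <- makeFj(f)
  g <- array(0, dim(f))
  for (n in seq_along(zs)) {
    E <- imgConv(Fj, zs[[n]]) - codeImages[[n]]
    g <- g + imgConvFilterGrad(E, zs[[n]], h)
  }
  g <- g / length(zs)
  upd <- fStepUpdate(f, g, step, mu, tau)
  fNew <- upd$f
  for (k in seq_len(K)) {
    if (upd$r[k] == 0) {   # fully thresholded filter: redraw
      fk <- array(abs(stats::rnorm(h * dim(f)[2])), c(h, dim(f)[2]))
      fNew[, , k] <- fk / sqrt(sum(fk^2))
    }
  }
  new("ImageFilterBank", filters = fNew)
}

## shared ISTA + Frobenius renormalization update of the image filters;
## a filter zeroed by the threshold stays zero here (r = 0 flags it).
fStepUpdate <- function(f, g, step, mu, tau) {
  Fpre <- f - step * tau * g - mu * step
  Frelu <- Fpre
  Frelu[Frelu < 0] <- 0
  K <- dim(f)[3]
  r <- numeric(K)
  fNew <- Frelu
  for (k in seq_len(K)) {
    r[k] <- sqrt(sum(Frelu[, , k]^2))
    if (r[k] > 0) fNew[, , k] <- Frelu[, , k] / r[k]
  }
  list(f = fNew, Fpre = Fpre, r = r)
}

#' Fit the two-level sparse representation by alternating minimization
#'
#' Alternates, for \code{outerRounds} rounds: an ADMM code solve per
#' sequence (filters fixed, warm-started across rounds), then
#' \code{filterSteps} joint filter updates (mirror descent on the PFM
#' filters, ISTA + renormalization on the image filters, scaled dual update
#' of the coupling constraint). Iteration budgets are fixed, mirroring the
#' unfolded architecture. Deterministic given \code{seed}.
#'
#' @param seqs list of 4 x L one-hot matrices, or a \code{DNAStringSet} /
#'   character vector which is one-hot encoded first.
#' @param hyper hyperparameter list, see \code{\link{defaultHyper}}.
#' @param seed integer seed for the random filter initialization.
#' @return list with \code{model} (a \code{MotifModel}), \code{codes}
#'   (a \code{CodeSet}) and \code{objective} (per-round objective terms).
#' @export
fitClassical <- function(seqs, hyper = defaultHyper(), seed = 1L) {
  if (!is.list(seqs)) seqs <- lapply(asRecords(seqs), oneHotEncode)
  stopifnot(length(seqs) >= 1)
  N <- length(seqs)
  bank <- withSeed(seed, randomSeqBank(hyper$M, hyper$l))
  ibank <- withSeed(seed + 1L, randomImageBank(hyper$K, hyper$h, hyper$M))
  states <- vector("list", N)
  thetas <- vector("list", N)
  objTrace <- NULL
  if (hyper$outerRounds > 0) for (r in seq_len(hyper$outerRounds)) {
    for (n in seq_len(N)) {
      ## warm-start the codes across rounds but reset the scaled duals:
      ## the coupling is infeasible while the filters still move, and
      ## letting the duals integrate that error across rounds drives the
      ## codes to zero through the beta-scaled penalty
      if (!is.null(states[[n]])) states[[n]]$U[] <- 0
      states[[n]] <- admmSolveCodes(bank, ibank, seqs[[n]], hyper,
                                    state = states[[n]])
    }
    zs <- lapply(states, `[[`, "Z")
    codes <- lapply(states, function(st) list(X = st$X, Y = st$Y))
    for (n in seq_len(N)) if (is.null(thetas[[n]]))
      thetas[[n]] <- matrix(0, nrow(states[[n]]$X), 2 * hyper$M)
    for (fs in seq_len(hyper$filterSteps)) {
      bank <- mirrorDescentStepD(bank, codes, seqs, hyper$pi)
      targets <- lapply(seq_len(N), function(n)
        hyper$beta * cbind(states[[n]]$X, states[[n]]$Y) - thetas[[n]])
      ibank <- withSeed(seed + 2L + r * 131L + fs,
        istaStepF(ibank, zs, targets, hyper$omega, hyper$mu, hyper$tau))
      Fj <- makeFj(ibank@filters)
      for (n in seq_len(N))
        thetas[[n]] <- thetas[[n]] + imgConv(Fj, states[[n]]$Z) -
          hyper$beta * cbind(states[[n]]$X, states[[n]]$Y)
    }
    obj <- objectiveTerms(bank, ibank, codes, zs, seqs,
                          hyper$lambda, hyper$mu, hyper$beta)
    objTrace <- rbind(objTrace, obj)
  }
  codes <- lapply(states, function(st)
    if (is.null(st)) NULL else list(X = st$X, Y = st$Y, Z = st$Z, U = st$U))
  model <- new("MotifModel", seqBank = bank, imageBank = ibank,
               hyper = hyper,
               scalars = c(lambda = hyper$lambda, mu = hyper$mu,
                           rho = hyper$rho),
               stepSizes = list(eta = hyper$eta, gamma = hyper$gamma,
                                pi = hyper$pi, omega = hyper$omega),
               mode = "classical", seed = as.integer(seed))
  codeSet <- if (hyper$outerRounds > 0)
    new("CodeSet", codes = codes, alpha = as.integer(hyper$alpha))
  else new("CodeSet", codes = list(), alpha = as.integer(hyper$alpha))
  list(model = model, codes = codeSet, objective = objTrace)
}

#' Default hyperparameters of the two-level representation
#'
#' Structural defaults follow the reference configuration: M = 50 sequence
#' filters of width l = 8 nt, K = 24 image filters of height h = 12 code
#' rows (each covering 12 x 2M pixels), image-code sparsity alpha = 32,
#' image scaling beta = 100, K1 = 6 code layers and K2 = 3 filter layers for
#' the unfolded network, batch size 6, q = 3 components per configuration.
#' Solver defaults (step sizes, penalties, iteration budgets) are this
#' package's own serviceable choices and are all overridable.
#'
#' @param ... named overrides of any field.
#' @return named list of hyperparameters.
#' @export
defaultHyper <- function(...) {
  hyper <- list(M = 50L, l = 8L, K = 24L, h = 12L, alpha = 32L, beta = 100,
                K1 = 6L, K2 = 3L, q = 3L, batchSize = 6L,
                lambda = 0.1, mu = 0.01, rho = 1, tau = 1,
                eta = 2e-2, gamma = 0.1, pi = 0.5, omega = 1e-5,
                sweeps = 3L, admmIters = 6L, outerRounds = 8L,
                filterSteps = 2L, epochs = 20L, learningRate = 1e-3)
  over <- list(...)
  hyper[names(over)] <- over
  hyper
}
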