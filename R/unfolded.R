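## Deep-unfolded network: the classical iterates parameterized as layers.
## 2*K1 code layers (non-negative ISTA sweeps on X/Y interleaved with a
## projected-gradient + hard top-alpha step on Z and a scaled dual update)
## followed by 2*K2 filter layers (mirror descent on the PFM filters
## interleaved with ISTA + Frobenius renormalization on the image filters
## and the coupling dual update). All filters, the sparsity parameters
## lambda/mu, the single coupling penalty rho (shared by both half-problems,
## which is why the parameter count is 4MLl + 2MhK + 3 + 2K1 + 2K2) and all
## per-layer step sizes are trainable. Training is plain reverse-mode
## differentiation of the forward pass, written out by hand below; the hard
## top-alpha projection passes gradients only through the kept entries.

#' Trainable parameters of the unfolded network
#'
#' Filters are stored in their projected form (PFM simplex columns;
#' non-negative unit-Frobenius image filters) and re-projected after every
#' optimizer step. Positive scalars (lambda, mu, rho and all step sizes)
#' are stored as logarithms so backpropagation cannot drive them negative.
#'
#' @slot d numeric 4 x l x M array of PFM sequence filters.
#' @slot f numeric h x 2M x K array of image filters.
#' @slot logLambda,logMu,logRho log of the sparsity and penalty scalars.
#' @slot logEta,logGamma length-K1 log step sizes of the code layers.
#' @slot logPi,logOmega length-K2 log step sizes of the filter layers.
#' @export
setClass("NetParams",
  representation(d = "array", f = "array",
                 logLambda = "numeric", logMu = "numeric", logRho = "numeric",
                 logEta = "numeric", logGamma = "numeric",
                 logPi = "numeric", logOmega = "numeric"))

setMethod("show", "NetParams", function(object) {
  dd <- dim(object@d); df <- dim(object@f)
  cat("NetParams: M =", dd[3], "seq filters (l =", dd[2],
      "), K =", df[3], "image filters (h =", df[1], ")\n")
  cat("  K1 =", length(object@logEta), "code layers, K2 =",
      length(object@logPi), "filter layers\n")
  cat("  lambda =", signif(exp(object@logLambda), 3),
      " mu =", signif(exp(object@logMu), 3),
      " rho =", signif(exp(object@logRho), 3), "\n")
})

#' Initialize unfolded-network parameters
#'
#' Sequence-filter columns are symmetric Dirichlet(1) draws; image filters
#' |N(0,1)| entries, Frobenius-normalized; scalars and per-layer step sizes
#' start at the classical-solver defaults in \code{hyper}.
#'
#' @param hyper hyperparameter list (\code{\link{defaultHyper}}).
#' @param seed integer seed.
#' @return a \code{NetParams}.
#' @export
netInit <- function(hyper, seed = 1L) {
  bank <- withSeed(seed, randomSeqBank(hyper$M, hyper$l))
  ibank <- withSeed(seed + 1L, randomImageBank(hyper$K, hyper$h, hyper$M))
  new("NetParams", d = bank@filters, f = ibank@filters,
      logLambda = log(hyper$lambda), logMu = log(hyper$mu),
      logRho = log(hyper$rho),
      logEta = rep(log(hyper$eta), hyper$K1),
      logGamma = rep(log(hyper$gamma), hyper$K1),
      logPi = rep(log(hyper$pi), hyper$K2),
      logOmega = rep(log(hyper$omega), hyper$K2))
}

effectiveParams <- function(p) {
  list(d = p@d, f = p@f, lambda = exp(p@logLambda), mu = exp(p@logMu),
       rho = exp(p@logRho), eta = exp(p@logEta), gamma = exp(p@logGamma),
       piv = exp(p@logPi), omega = exp(p@logOmega))
}

#' Number of trainable parameters of the unfolded network
#'
#' Filter weights (4*l*M sequence + h*2M*K image), three scalars (lambda,
#' mu, and the single coupling penalty rho shared by the code- and
#' filter-level half-problems of the one coupling constraint), and two step
#' sizes per layer (eta, gamma per code layer; pi, omega per filter layer).
#'
#' @param hyper hyperparameter list with M, l, K, h, K1, K2.
#' @return integer parameter count.
#' @examples
#' countParameters(defaultHyper())  # 30421 at the reference configuration
#' @export
countParameters <- function(hyper) {
  as.integer(hyper$M * 4 * hyper$l + hyper$K * hyper$h * 2 * hyper$M +
             3L + 2L * hyper$K1 + 2L * hyper$K2)
}

## top-alpha projection that also returns the kept-support mask, sharing
## projectTopAlpha's tie-break (largest |value|, ties by smallest flat index)
projTopAlphaMask <- function(Z, alpha) {
  v <- as.vector(Z)
  if (alpha >= length(v))
    return(list(Z = Z, mask = matrix(TRUE, nrow(Z), ncol(Z))))
  keep <- order(-abs(v), seq_along(v))[seq_len(alpha)]
  out <- Z; out[] <- 0; out[keep] <- Z[keep]
  mask <- matrix(FALSE, nrow(Z), ncol(Z)); mask[keep] <- TRUE
  list(Z = out, mask = mask)
}

## ---- forward ----------------------------------------------------------

## code phase for one sequence; identical arithmetic to admmSolveCodes
codePhaseForward <- function(eff, s, hyper, record = FALSE) {
  d <- eff$d; f <- eff$f
  M <- dim(d)[3]; l <- dim(d)[2]; K <- dim(f)[3]; h <- dim(f)[1]
  L <- ncol(s); P <- L - l + 1L; Q <- P - h + 1L
  if (Q < 1L) stop("sequence too short for the filter sizes")
  DjF <- makeDj(d); DjR <- makeDj(rcArray(d)); Fj <- makeFj(f)
  beta <- hyper$beta; rho <- eff$rho
  X <- matrix(0, P, M); Y <- matrix(0, P, M)
  Z <- matrix(0, Q, K); U <- matrix(0, P, 2 * M)
  layers <- if (record) vector("list", hyper$K1) else NULL
  K1 <- hyper$K1
  if (K1 > 0) for (t in seq_len(K1)) {
    Z0 <- Z; U0 <- U
    W <- imgConv(Fj, Z)
    sweeps <- if (record) vector("list", hyper$sweeps) else NULL
    for (sw in seq_len(hyper$sweeps)) {
      upd <- codeSweep(X, Y, DjF, DjR, s, W, U, eff$eta[t], eff$lambda,
                       rho, beta, keep = record)
      X <- upd$X; Y <- upd$Y
      if (record) sweeps[[sw]] <- upd
    }
    XY <- beta * cbind(X, Y)
    E <- W - XY + U
    Gz0 <- imgXcorr(Fj, E, Q)
    pr <- projTopAlphaMask(Z - eff$gamma[t] * (rho * Gz0), hyper$alpha)
    Z <- pr$Z
    W2 <- imgConv(Fj, Z)
    U <- U + W2 - XY
    if (!all(is.finite(X)) || !all(is.finite(Z)) || !all(is.finite(U)))
      stop("non-finite activations at code layer ", t)
    if (record)
      layers[[t]] <- list(Z0 = Z0, U0 = U0, W = W, sweeps = sweeps, E = E,
                          Gz0 = Gz0, mask = pr$mask, Z1 = Z, W2 = W2,
                          Xf = X, Yf = Y)
  }
  list(X = X, Y = Y, Z = Z, U = U, layers = layers, P = P, Q = Q)
}

## filter phase over the whole batch; identical arithmetic to
## mirrorDescentStepD / istaStepF (tau tied to rho, no random redraw of
## zeroed filters inside the differentiable forward)
filterPhaseForward <- function(eff, codes, seqs, hyper, record = FALSE) {
  d <- eff$d; f <- eff$f
  h <- dim(f)[1]
  beta <- hyper$beta
  N <- length(seqs)
  thetas <- lapply(codes, function(cc) matrix(0, nrow(cc$X), 2 * ncol(cc$X)))
  layers <- if (record) vector("list", hyper$K2) else NULL
  K2 <- hyper$K2
  if (K2 > 0) for (t in seq_len(K2)) {
    g <- filterGradD(d, codes, seqs)
    mu_ <- mirrorUpdate(d, g, eff$piv[t])
    Fj <- makeFj(f)
    Es <- vector("list", N)
    gF <- array(0, dim(f))
    for (n in seq_len(N)) {
      XYn <- beta * cbind(codes[[n]]$X, codes[[n]]$Y)
      Es[[n]] <- imgConv(Fj, codes[[n]]$Z) - XYn + thetas[[n]]
      gF <- gF + imgConvFilterGrad(Es[[n]], codes[[n]]$Z, h)
    }
    gF <- gF / N
    fs <- fStepUpdate(f, gF, eff$omega[t], eff$mu, eff$rho)
    Fj1 <- makeFj(fs$f)
    theta0 <- thetas
    for (n in seq_len(N)) {
      XYn <- beta * cbind(codes[[n]]$X, codes[[n]]$Y)
      thetas[[n]] <- thetas[[n]] + imgConv(Fj1, codes[[n]]$Z) - XYn
    }
    if (!all(is.finite(mu_$d)) || !all(is.finite(fs$f)))
      stop("non-finite activations at filter layer ", t)
    if (record)
      layers[[t]] <- list(d0 = d, g = g, w = mu_$w, sK = mu_$s, e = mu_$e,
                          F0 = f, Es = Es, gF = gF, Fpre = fs$Fpre,
                          r = fs$r, F1 = fs$f, theta0 = theta0)
    d <- mu_$d; f <- fs$f
  }
  list(d = d, f = f, thetas = thetas, layers = layers)
}

#' Two-term reconstruction loss of the unfolded network
#'
#' \eqn{(1/N)\sum_n [\|\sum_m d_m * x_{mn} + \tilde d_m * y_{mn} - s_n\|^2
#' + \|\sum_k F_k * z_{kn} - \beta (X_n, Y_n)\|_F^2]} with the codes from
#' the last code layer and the filters from the last filter layer.
#'
#' @param codes list of per-sequence code lists (X, Y, Z).
#' @param dFinal 4 x l x M PFM filter array (or \code{SeqFilterBank}).
#' @param fFinal h x 2M x K image filter array (or \code{ImageFilterBank}).
#' @param seqs list of 4 x L one-hot matrices.
#' @param beta image scaling factor.
#' @return named numeric: seq, image, loss (their mean-normalized sum).
#' @export
netLoss <- function(codes, dFinal, fFinal, seqs, beta) {
  if (methods::is(dFinal, "SeqFilterBank")) dFinal <- dFinal@filters
  if (methods::is(fFinal, "ImageFilterBank")) fFinal <- fFinal@filters
  DjF <- makeDj(dFinal); DjR <- makeDj(rcArray(dFinal))
  Fj <- makeFj(fFinal)
  seqTerm <- 0; imgTerm <- 0
  N <- length(seqs)
  for (n in seq_len(N)) {
    A <- seqConv(DjF, codes[[n]]$X) + seqConv(DjR, codes[[n]]$Y) - seqs[[n]]
    seqTerm <- seqTerm + sum(A^2)
    B <- imgConv(Fj, codes[[n]]$Z) -
      beta * cbind(codes[[n]]$X, codes[[n]]$Y)
    imgTerm <- imgTerm + sum(B^2)
  }
  c(seq = seqTerm / N, image = imgTerm / N,
    loss = (seqTerm + imgTerm) / N)
}

#' Forward pass of the unfolded network
#'
#' Runs K1 code layers per sequence (codes and duals initialized to zero),
#' then K2 filter layers over the batch, and evaluates the two-term loss.
#'
#' @param params a \code{NetParams}.
#' @param seqs list of 4 x L one-hot matrices (lengths may differ),
#'   or a \code{DNAStringSet}/character vector.
#' @param hyper hyperparameter list.
#' @param record keep the intermediates needed by the reverse pass.
#' @return list with \code{codes} (per-sequence X, Y, Z, U), \code{dFinal},
#'   \code{fFinal}, \code{thetas}, \code{lossTerms}, \code{loss}, and the
#'   tapes when \code{record = TRUE}.
#' @export
netForward <- function(params, seqs, hyper, record = FALSE) {
  if (!is.list(seqs)) seqs <- lapply(asRecords(seqs), oneHotEncode)
  stopifnot(length(seqs) >= 1)
  eff <- effectiveParams(params)
  cps <- lapply(seqs, function(s) codePhaseForward(eff, s, hyper, record))
  codes <- lapply(cps, function(cp)
    list(X = cp$X, Y = cp$Y, Z = cp$Z, U = cp$U))
  fp <- filterPhaseForward(eff, codes, seqs, hyper, record)
  lt <- netLoss(codes, fp$d, fp$f, seqs, hyper$beta)
  list(codes = codes, dFinal = fp$d, fFinal = fp$f, thetas = fp$thetas,
       lossTerms = lt[c("seq", "image")], loss = unname(lt["loss"]),
       codeTapes = if (record) cps else NULL,
       filterTape = if (record) fp$layers else NULL)
}

## ---- reverse pass ------------------------------------------------------

netBackward <- function(fw, params, seqs, hyper) {
  if (!is.list(seqs)) seqs <- lapply(asRecords(seqs), oneHotEncode)
  eff <- effectiveParams(params)
  beta <- hyper$beta; rho <- eff$rho; lambda <- eff$lambda
  N <- length(seqs)
  M <- dim(eff$d)[3]; l <- dim(eff$d)[2]
  K <- dim(eff$f)[3]; h <- dim(eff$f)[1]
  iF <- seq_len(M); iR <- M + iF
  K1 <- hyper$K1; K2 <- hyper$K2
  codes <- fw$codes

  dd <- array(0, dim(eff$d)); df <- array(0, dim(eff$f))
  dLambda <- 0; dMu <- 0; dRho <- 0
  dEta <- numeric(max(K1, 0L)); dGamma <- numeric(max(K1, 0L))
  dPi <- numeric(max(K2, 0L)); dOmega <- numeric(max(K2, 0L))

  ## ---- loss seeds -----------------------------------------------------
  dF_ <- fw$dFinal; fF_ <- fw$fFinal
  DjFfin <- makeDj(dF_); DjRfin <- makeDj(rcArray(dF_))
  Fjfin <- makeFj(fF_)
  ddFin <- array(0, dim(eff$d))   # grad w.r.t. filter-phase output d
  dfFin <- array(0, dim(eff$f))
  dXs <- vector("list", N); dYs <- vector("list", N); dZs <- vector("list", N)
  for (n in seq_len(N)) {
    X <- codes[[n]]$X; Y <- codes[[n]]$Y; Z <- codes[[n]]$Z
    P <- nrow(X); Q <- nrow(Z)
    A <- seqConv(DjFfin, X) + seqConv(DjRfin, Y) - seqs[[n]]
    dA <- (2 / N) * A
    ddFin <- ddFin + seqConvFilterGrad(dA, X, l) +
      rcArray(seqConvFilterGrad(dA, Y, l))
    dXs[[n]] <- seqXcorr(DjFfin, dA, P)
    dYs[[n]] <- seqXcorr(DjRfin, dA, P)
    B <- imgConv(Fjfin, Z) - beta * cbind(X, Y)
    dB <- (2 / N) * B
    dfFin <- dfFin + imgConvFilterGrad(dB, Z, h)
    dZs[[n]] <- imgXcorr(Fjfin, dB, Q)
    dXs[[n]] <- dXs[[n]] - beta * dB[, iF, drop = FALSE]
    dYs[[n]] <- dYs[[n]] - beta * dB[, iR, drop = FALSE]
  }

  ## ---- filter phase backward -----------------------------------------
  ddCar <- ddFin; dfCar <- dfFin
  dThetas <- lapply(codes, function(cc) matrix(0, nrow(cc$X), 2 * M))
  if (K2 > 0) for (t in rev(seq_len(K2))) {
    tp <- fw$filterTape[[t]]
    Fj1 <- makeFj(tp$F1); Fj0 <- makeFj(tp$F0)
    ## theta update: theta1 = theta0 + imgConv(F1, Z) - beta XY
    for (n in seq_len(N)) {
      dth <- dThetas[[n]]
      if (any(dth != 0)) {
        Z <- codes[[n]]$Z; Q <- nrow(Z)
        dfCar <- dfCar + imgConvFilterGrad(dth, Z, h)
        dZs[[n]] <- dZs[[n]] + imgXcorr(Fj1, dth, Q)
        dXs[[n]] <- dXs[[n]] - beta * dth[, iF, drop = FALSE]
        dYs[[n]] <- dYs[[n]] - beta * dth[, iR, drop = FALSE]
      }
    }
    ## F step: F1 = normalize(relu(Fpre)); Fpre = F0 - w_t*rho*gF - mu*w_t
    om <- eff$omega[t]
    dFrelu <- array(0, dim(eff$f))
    for (k in seq_len(K)) {
      if (tp$r[k] > 0) {
        dk <- dfCar[, , k]; fk <- tp$F1[, , k]
        dFrelu[, , k] <- (dk - fk * sum(dk * fk)) / tp$r[k]
      }
    }
    dFpre <- dFrelu * (tp$Fpre > 0)
    dOmega[t] <- sum(dFpre * (-rho * tp$gF - eff$mu))
    dRho <- dRho - om * sum(dFpre * tp$gF)
    dMu <- dMu - om * sum(dFpre)
    dgF <- -om * rho * dFpre
    dFj <- makeFj(dgF)
    dfCar2 <- dFpre
    for (n in seq_len(N)) {
      Z <- codes[[n]]$Z; Q <- nrow(Z)
      dE <- imgConv(dFj, Z) / N        # gF averages over sequences
      dZs[[n]] <- dZs[[n]] + imgXcorr(dFj, tp$Es[[n]], Q) / N +
        imgXcorr(Fj0, dE, Q)
      dfCar2 <- dfCar2 + imgConvFilterGrad(dE, Z, h)
      dXs[[n]] <- dXs[[n]] - beta * dE[, iF, drop = FALSE]
      dYs[[n]] <- dYs[[n]] - beta * dE[, iR, drop = FALSE]
      dThetas[[n]] <- dThetas[[n]] + dE
    }
    dfCar <- dfCar2
    ## mirror step: d1[,j,m] = w/s per column, w = d0 * e
    pit <- eff$piv[t]
    d1 <- mirrorUpdate(tp$d0, tp$g, pit)$d  # == forward output, recomputed
    dw <- array(0, dim(eff$d))
    for (m in seq_len(M)) {
      Gm <- matrix(ddCar[, , m], 4, l); Om <- matrix(d1[, , m], 4, l)
      inner <- colSums(Gm * Om)    # d(out)/d(w): (G_i - sum G.out) / s
      dw[, , m] <- sweep(sweep(Gm, 2, inner, "-"), 2, tp$sK[, m], "/")
    }
    dd0 <- dw * tp$e
    dg <- -pit * (tp$w * dw)
    dPi[t] <- -sum(tp$g * tp$w * dw)
    ## g = sum_n seqConvFilterGrad(R_n, X_n) + rc(seqConvFilterGrad(R_n, Y_n))
    dgrc <- rcArray(dg)
    dgDj <- makeDj(dg); dgrcDj <- makeDj(dgrc)
    Dj0 <- makeDj(tp$d0); Dj0R <- makeDj(rcArray(tp$d0))
    for (n in seq_len(N)) {
      X <- codes[[n]]$X; Y <- codes[[n]]$Y; P <- nrow(X)
      Rn <- seqConv(Dj0, X) + seqConv(Dj0R, Y) - seqs[[n]]
      dRn <- (seqConv(dgDj, X) + seqConv(dgrcDj, Y)) / N  # g averages over n
      dXs[[n]] <- dXs[[n]] + seqXcorr(dgDj, Rn, P) / N +
        seqXcorr(Dj0, dRn, P)
      dYs[[n]] <- dYs[[n]] + seqXcorr(dgrcDj, Rn, P) / N +
        seqXcorr(Dj0R, dRn, P)
      dd0 <- dd0 + seqConvFilterGrad(dRn, X, l) +
        rcArray(seqConvFilterGrad(dRn, Y, l))
    }
    ddCar <- dd0
  }

  ## ---- code phase backward (per sequence) -----------------------------
  DjF <- makeDj(eff$d); DjR <- makeDj(rcArray(eff$d))
  Fj <- makeFj(eff$f)
  for (n in seq_len(N)) {
    cp <- fw$codeTapes[[n]]
    P <- cp$P; Q <- cp$Q
    dX <- dXs[[n]]; dY <- dYs[[n]]; dZ <- dZs[[n]]
    dU <- matrix(0, P, 2 * M)
    if (K1 > 0) for (t in rev(seq_len(K1))) {
      tp <- cp$layers[[t]]
      et <- eff$eta[t]; gt <- eff$gamma[t]
      ## dual update: U1 = U0 + W2 - XY1, W2 = imgConv(F, Z1)
      df <- df + imgConvFilterGrad(dU, tp$Z1, h)
      dZ <- dZ + imgXcorr(Fj, dU, Q)
      dX <- dX - beta * dU[, iF, drop = FALSE]
      dY <- dY - beta * dU[, iR, drop = FALSE]
      ## Z step: Z1 = mask o (Z0 - gamma*rho*Gz0)
      dZpre <- dZ * tp$mask
      dGamma[t] <- dGamma[t] - sum(dZpre * (rho * tp$Gz0))
      dRho <- dRho - gt * sum(dZpre * tp$Gz0)
      dGz0 <- -gt * rho * dZpre
      dE <- imgConv(Fj, dGz0)
      df <- df + imgXcorrFilterGrad(dGz0, tp$E, h)
      ## E = W - XY1 + U0
      dW <- dE
      dX <- dX - beta * dE[, iF, drop = FALSE]
      dY <- dY - beta * dE[, iR, drop = FALSE]
      dU <- dU + dE
      dZ0 <- dZpre
      ## sweeps backward
      for (sw in rev(seq_len(hyper$sweeps))) {
        sp <- tp$sweeps[[sw]]
        penY <- rho * (sp$Y0 - (tp$W[, iR] + tp$U0[, iR]) / beta)
        dY1pre <- dY * (sp$Y > 0)
        dY0 <- dY1pre * (1 - et * rho)
        dGy <- -et * dY1pre
        dW[, iR] <- dW[, iR] + (et * rho / beta) * dY1pre
        dU[, iR] <- dU[, iR] + (et * rho / beta) * dY1pre
        dEta[t] <- dEta[t] + sum(dY1pre * (-(sp$Gy + penY) - lambda))
        dLambda <- dLambda - et * sum(dY1pre)
        dRho <- dRho - sum(dY1pre * (et / rho) * penY)
        dRy <- seqConv(DjR, dGy)
        dd <- dd + rcArray(seqXcorrFilterGrad(dGy, sp$Ry, l))
        ## Ry = Rx + seqConv(DjF, X1 - X0)
        dRx <- dRy
        tmp <- seqXcorr(DjF, dRy, P)
        dX <- dX + tmp
        dX0extra <- -tmp
        dd <- dd + seqConvFilterGrad(dRy, sp$X - sp$X0, l)
        ## X branch
        penX <- rho * (sp$X0 - (tp$W[, iF] + tp$U0[, iF]) / beta)
        dX1pre <- dX * (sp$X > 0)
        dX0 <- dX0extra + dX1pre * (1 - et * rho)
        dGx <- -et * dX1pre
        dW[, iF] <- dW[, iF] + (et * rho / beta) * dX1pre
        dU[, iF] <- dU[, iF] + (et * rho / beta) * dX1pre
        dEta[t] <- dEta[t] + sum(dX1pre * (-(sp$Gx + penX) - lambda))
        dLambda <- dLambda - et * sum(dX1pre)
        dRho <- dRho - sum(dX1pre * (et / rho) * penX)
        dRx <- dRx + seqConv(DjF, dGx)
        dd <- dd + seqXcorrFilterGrad(dGx, sp$Rx, l)
        ## Rx = seqConv(DjF, X0) + seqConv(DjR, Y0) - s
        dX0 <- dX0 + seqXcorr(DjF, dRx, P)
        dY0 <- dY0 + seqXcorr(DjR, dRx, P)
        dd <- dd + seqConvFilterGrad(dRx, sp$X0, l) +
          rcArray(seqConvFilterGrad(dRx, sp$Y0, l))
        dX <- dX0; dY <- dY0
      }
      ## W = imgConv(F, Z0)
      dZ0 <- dZ0 + imgXcorr(Fj, dW, Q)
      df <- df + imgConvFilterGrad(dW, tp$Z0, h)
      dZ <- dZ0
    }
  }
  dd <- dd + ddCar; df <- df + dfCar

  list(d = dd, f = df,
       logLambda = dLambda * lambda, logMu = dMu * eff$mu,
       logRho = dRho * rho,
       logEta = dEta * eff$eta, logGamma = dGamma * eff$gamma,
       logPi = dPi * eff$piv, logOmega = dOmega * eff$omega)
}

#' Gradients of the unfolded-network loss
#'
#' Forward pass with recording plus the hand-derived reverse pass; used by
#' training and by the finite-difference gradient checks.
#'
#' @param params \code{NetParams}.
#' @param seqs list of one-hot matrices (or sequences).
#' @param hyper hyperparameter list.
#' @return list with \code{loss} and \code{grads} (named like the
#'   \code{NetParams} slots; scalar/step gradients already on the log scale).
#' @export
netGradients <- function(params, seqs, hyper) {
  if (!is.list(seqs)) seqs <- lapply(asRecords(seqs), oneHotEncode)
  fw <- netForward(params, seqs, hyper, record = TRUE)
  list(loss = fw$loss, grads = netBackward(fw, params, seqs, hyper))
}

## ---- training ---------------------------------------------------------

## Euclidean projection of a vector onto the probability simplex
simplexProject <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(u)
  rhoIdx <- max(which(u - (css - 1) / j > 0))
  theta <- (css[rhoIdx] - 1) / rhoIdx
  pmax(v - theta, 0)
}

projectParams <- function(p) {
  d <- p@d; f <- p@f
  M <- dim(d)[3]; l <- dim(d)[2]
  for (m in seq_len(M)) for (j in seq_len(l))
    d[, j, m] <- simplexProject(d[, j, m])
  for (k in seq_len(dim(f)[3])) {
    fk <- pmax(f[, , k], 0)
    fro <- sqrt(sum(fk^2))
    if (fro == 0) {
      fk <- array(abs(stats::rnorm(length(fk))), dim(f)[1:2])
      fro <- sqrt(sum(fk^2))
    }
    f[, , k] <- fk / fro
  }
  p@d <- d; p@f <- f
  p
}

paramList <- function(p)
  list(d = p@d, f = p@f, logLambda = p@logLambda, logMu = p@logMu,
       logRho = p@logRho, logEta = p@logEta, logGamma = p@logGamma,
       logPi = p@logPi, logOmega = p@logOmega)

paramFromList <- function(x)
  new("NetParams", d = x$d, f = x$f, logLambda = x$logLambda,
      logMu = x$logMu, logRho = x$logRho, logEta = x$logEta,
      logGamma = x$logGamma, logPi = x$logPi, logOmega = x$logOmega)

## AdaBelief: adapts to the variance of the gradient around its EMA
adaBeliefStep <- function(theta, grads, state, lr,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-12) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    diffsq <- (g - state$m[[nm]])^2
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * diffsq + eps
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(theta = theta, state = state)
}

#' Train the unfolded network
#'
#' Minibatch training of all network parameters (filters, lambda, mu, rho,
#' per-layer step sizes) with the AdaBelief update rule on the two-term
#' reconstruction loss. After every optimizer step the filter parameters
#' are re-projected (PFM simplex columns; non-negative unit-Frobenius image
#' filters, with a fully zeroed filter redrawn). Deterministic given
#' \code{seed}.
#'
#' @param seqs training sequences (\code{DNAStringSet}, character, or list
#'   of one-hot matrices); at least \code{hyper$batchSize} of them.
#' @param hyper hyperparameter list (\code{\link{defaultHyper}}); uses
#'   \code{epochs}, \code{learningRate}, \code{batchSize}.
#' @param seed integer seed (initialization and batch order).
#' @return list with \code{model} (a \code{MotifModel}, mode "unfolded"),
#'   \code{params} (the trained \code{NetParams}) and \code{lossHistory}
#'   (per-epoch mean batch loss).
#' @export
netTrain <- function(seqs, hyper = defaultHyper(), seed = 1L) {
  if (!is.list(seqs)) seqs <- lapply(asRecords(seqs), oneHotEncode)
  if (length(seqs) < hyper$batchSize)
    stop("need at least batchSize = ", hyper$batchSize, " sequences")
  params <- netInit(hyper, seed)
  theta <- paramList(params)
  state <- list(t = 0L,
                m = lapply(theta, function(x) x * 0),
                v = lapply(theta, function(x) x * 0))
  lossHistory <- numeric(hyper$epochs)
  withSeed(seed + 7L, {
    if (hyper$epochs > 0) for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(length(seqs))
      batches <- split(ord, ceiling(seq_along(ord) / hyper$batchSize))
      losses <- numeric(length(batches))
      for (b in seq_along(batches)) {
        batch <- seqs[batches[[b]]]
        gr <- netGradients(paramFromList(theta), batch, hyper)
        if (!is.finite(gr$loss)) stop("non-finite loss in epoch ", ep)
        upd <- adaBeliefStep(theta, gr$grads, state, hyper$learningRate)
        theta <- upd$theta; state <- upd$state
        theta <- paramList(projectParams(paramFromList(theta)))
        losses[b] <- gr$loss
      }
      lossHistory[ep] <- mean(losses)
    }
  })
  params <- paramFromList(theta)
  eff <- effectiveParams(params)
  model <- new("MotifModel",
               seqBank = SeqFilterBank(eff$d),
               imageBank = new("ImageFilterBank", filters = eff$f),
               hyper = hyper,
               scalars = c(lambda = eff$lambda, mu = eff$mu, rho = eff$rho),
               stepSizes = list(eta = eff$eta, gamma = eff$gamma,
                                pi = eff$piv, omega = eff$omega),
               mode = "unfolded", seed = as.integer(seed))
  list(model = model, params = params, lossHistory = lossHistory)
}

#' Infer sparse codes for sequences with a fitted model
#'
#' For a trained \code{NetParams} this is a forward pass of the code layers
#' (no gradient bookkeeping); for a classical-mode \code{MotifModel} it is
#' the ADMM code solve with the fitted filters held fixed. Either way the
#' image code of every sequence has at most alpha non-zeros.
#'
#' @param x \code{NetParams} or \code{MotifModel}.
#' @param seqs sequences (\code{DNAStringSet}, character, or list of
#'   one-hot matrices).
#' @param hyper hyperparameter list; defaults to the model's own.
#' @return a \code{CodeSet}.
#' @export
setGeneric("inferCodes", function(x, seqs, hyper) standardGeneric("inferCodes"))

#' @rdname inferCodes
#' @export
setMethod("inferCodes", "NetParams", function(x, seqs, hyper) {
  if (!is.list(seqs)) seqs <- lapply(asRecords(seqs), oneHotEncode)
  eff <- effectiveParams(x)
  out <- lapply(seqs, function(s) {
    cp <- codePhaseForward(eff, s, hyper, record = FALSE)
    list(X = cp$X, Y = cp$Y, Z = cp$Z, U = cp$U)
  })
  new("CodeSet", codes = out, alpha = as.integer(hyper$alpha))
})

#' @rdname inferCodes
#' @export
setMethod("inferCodes", "MotifModel", function(x, seqs, hyper) {
  if (missing(hyper)) hyper <- x@hyper
  if (!is.list(seqs)) seqs <- lapply(asRecords(seqs), oneHotEncode)
  out <- lapply(seqs, function(s) {
    st <- admmSolveCodes(x@seqBank, x@imageBank, s, hyper)
    list(X = st$X, Y = st$Y, Z = st$Z, U = st$U)
  })
  new("CodeSet", codes = out, alpha = as.integer(hyper$alpha))
})

## ---- checkpointing ----------------------------------------------------

#' Save / load a network checkpoint
#'
#' A single JSON file holding the trained parameters, the hyperparameters
#' and the training seed.
#'
#' @param params \code{NetParams}.
#' @param hyper hyperparameter list.
#' @param seed integer seed the parameters were trained under.
#' @param path file path.
#' @return \code{writeCheckpoint}: the path, invisibly;
#'   \code{readCheckpoint}: a list with \code{params}, \code{hyper},
#'   \code{seed}.
#' @export
writeCheckpoint <- function(params, hyper, seed, path) {
  obj <- list(hyper = hyper, seed = seed,
              d = list(dim = dim(params@d), data = as.vector(params@d)),
              f = list(dim = dim(params@f), data = as.vector(params@f)),
              logLambda = params@logLambda, logMu = params@logMu,
              logRho = params@logRho, logEta = params@logEta,
              logGamma = params@logGamma, logPi = params@logPi,
              logOmega = params@logOmega)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hyper <- as.list(obj$hyper)
  intFields <- c("M", "l", "K", "h", "alpha", "K1", "K2", "q", "batchSize",
                 "sweeps", "admmIters", "outerRounds", "filterSteps",
                 "epochs")
  for (nm in intersect(intFields, names(hyper)))
    hyper[[nm]] <- as.integer(hyper[[nm]])
  params <- new("NetParams",
                d = array(obj$d$data, obj$d$dim),
                f = array(obj$f$data, obj$f$dim),
                logLambda = obj$logLambda, logMu = obj$logMu,
                logRho = obj$logRho, logEta = obj$logEta,
                logGamma = obj$logGamma, logPi = obj$logPi,
                logOmega = obj$logOmega)
  list(params = params, hyper = hyper, seed = obj$seed)
}
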