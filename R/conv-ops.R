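## Internal vectorized convolution / correlation primitives.
##
## "Convolution" d * x here is the transposed correlation of Fig-1B-style
## sparse coding: the code indexes valid placement offsets and the filter is
## stamped (not flipped). Each primitive is a sum of small matrix products
## over the filter width, with hand-derived adjoints used by the unfolded
## network's reverse pass.

## slice list: Dj[[j]] = 4 x M matrix of column j of every sequence filter
makeDj <- function(D) {
  l <- dim(D)[2]
  lapply(seq_len(l), function(j) matrix(D[, j, ], nrow = 4))
}

## slice list: Fj[[j]] = K x 2M matrix of row j of every image filter
makeFj <- function(F) {
  h <- dim(F)[1]; w <- dim(F)[2]
  lapply(seq_len(h), function(j) t(matrix(F[j, , ], nrow = w)))
}

rcArray <- function(D) D[4:1, rev(seq_len(dim(D)[2])), , drop = FALSE]

## sum_m sum_p X[p,m] d_m stamped at columns p..p+l-1  -> 4 x L
seqConv <- function(Dj, X) {
  P <- nrow(X); l <- length(Dj); L <- P + l - 1L
  R <- matrix(0, 4, L)
  tX <- t(X)
  for (j in seq_len(l)) {
    cols <- j:(j + P - 1L)
    R[, cols] <- R[, cols] + Dj[[j]] %*% tX
  }
  R
}

## adjoint of seqConv in the code: G[p,m] = sum_j d_m[,j] . R[, p+j-1]  -> P x M
seqXcorr <- function(Dj, R, P) {
  l <- length(Dj)
  G <- matrix(0, P, ncol(Dj[[1]]))
  for (j in seq_len(l)) {
    cols <- j:(j + P - 1L)
    G <- G + crossprod(R[, cols, drop = FALSE], Dj[[j]])
  }
  G
}

## gradient of seqConv w.r.t. the filters: dD[,j,m] += sum_p X[p,m] G[, p+j-1]
seqConvFilterGrad <- function(G, X, l) {
  P <- nrow(X); M <- ncol(X)
  dD <- array(0, c(4, l, M))
  for (j in seq_len(l)) {
    cols <- j:(j + P - 1L)
    dD[, j, ] <- G[, cols, drop = FALSE] %*% X
  }
  dD
}

## gradient of seqXcorr w.r.t. the filters: dD[,j,m] += sum_p G[p,m] R[, p+j-1]
seqXcorrFilterGrad <- function(G, R, l) {
  P <- nrow(G); M <- ncol(G)
  dD <- array(0, c(4, l, M))
  for (j in seq_len(l)) {
    cols <- j:(j + P - 1L)
    dD[, j, ] <- R[, cols, drop = FALSE] %*% G
  }
  dD
}

## sum_k sum_q Z[q,k] F_k stamped at rows q..q+h-1  -> P x 2M
imgConv <- function(Fj, Z) {
  Q <- nrow(Z); h <- length(Fj); P <- Q + h - 1L
  W <- matrix(0, P, ncol(Fj[[1]]))
  for (j in seq_len(h)) {
    rows <- j:(j + Q - 1L)
    W[rows, ] <- W[rows, ] + Z %*% Fj[[j]]
  }
  W
}

## adjoint of imgConv in the code: G[q,k] = sum_j F_k[j,] . E[q+j-1, ] -> Q x K
imgXcorr <- function(Fj, E, Q) {
  h <- length(Fj)
  G <- matrix(0, Q, nrow(Fj[[1]]))
  for (j in seq_len(h)) {
    rows <- j:(j + Q - 1L)
    G <- G + tcrossprod(E[rows, , drop = FALSE], Fj[[j]])
  }
  G
}

## gradient of imgConv w.r.t. the filters (h x 2M x K)
imgConvFilterGrad <- function(G, Z, h) {
  Q <- nrow(Z); K <- ncol(Z)
  dF <- array(0, c(h, ncol(G), K))
  for (j in seq_len(h)) {
    rows <- j:(j + Q - 1L)
    dF[j, , ] <- t(crossprod(Z, G[rows, , drop = FALSE]))
  }
  dF
}

## gradient of imgXcorr w.r.t. the filters (h x 2M x K)
imgXcorrFilterGrad <- function(G, E, h) {
  Q <- nrow(G)
  dF <- array(0, c(h, ncol(E), ncol(G)))
  for (j in seq_len(h)) {
    rows <- j:(j + Q - 1L)
    dF[j, , ] <- t(crossprod(G, E[rows, , drop = FALSE]))
  }
  dF
}
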