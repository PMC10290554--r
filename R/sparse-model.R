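## The two-level representation: PFM-constrained sequence filters, image
## filters, sparse codes and the objective arithmetic.

#' Construct a bank of PFM sequence filters
#'
#' @param filters a 4 x l x M array or a list of 4 x l column-stochastic
#'   matrices.
#' @return a \code{SeqFilterBank}; reverse-complement filters are derived
#'   automatically and kept consistent.
#' @export
SeqFilterBank <- function(filters) {
  if (is.list(filters)) {
    l <- ncol(filters[[1]])
    filters <- array(unlist(filters), c(4, l, length(filters)))
  }
  new("SeqFilterBank", filters = filters, rcFilters = rcArray(filters))
}

#' Construct a bank of image filters
#'
#' @param filters an h x 2M x K array or list of h x 2M matrices; entries
#'   must be non-negative and each filter is Frobenius-normalized on entry.
#' @return an \code{ImageFilterBank}.
#' @export
ImageFilterBank <- function(filters) {
  if (is.list(filters)) {
    h <- nrow(filters[[1]]); w <- ncol(filters[[1]])
    filters <- array(unlist(filters), c(h, w, length(filters)))
  }
  for (k in seq_len(dim(filters)[3])) {
    fro <- sqrt(sum(filters[, , k]^2))
    if (fro > 0) filters[, , k] <- filters[, , k] / fro
  }
  new("ImageFilterBank", filters = filters)
}

#' Reverse complement of a PFM
#'
#' Columns reversed and rows complement-swapped (A<->T, C<->G), so that a
#' filter representing a site on the forward strand represents the same site
#' read from the complementary strand. An involution.
#'
#' @param p 4 x l PFM (rows A,C,G,T).
#' @return 4 x l PFM.
#' @examples
#' reverseComplementFilter(matrix(c(1, 0, 0, 0), 4, 1))
#' @export
reverseComplementFilter <- function(p) {
  stopifnot(nrow(p) == 4)
  out <- p[4:1, rev(seq_len(ncol(p))), drop = FALSE]
  rownames(out) <- rownames(p)
  out
}

#' Random PFM filter bank (symmetric Dirichlet(1) columns)
#'
#' @param M number of filters.
#' @param l filter width (nt).
#' @return a \code{SeqFilterBank}.
#' @export
randomSeqBank <- function(M, l) {
  d <- array(stats::rexp(4 * l * M), c(4, l, M))
  cs <- apply(d, c(2, 3), sum)
  for (m in seq_len(M)) d[, , m] <- sweep(d[, , m, drop = FALSE][, , 1],
                                          2, cs[, m], "/")
  SeqFilterBank(d)
}

#' Random image filter bank (|N(0,1)| entries, unit Frobenius norm)
#'
#' @param K number of image filters.
#' @param h filter height in code rows.
#' @param M number of sequence filters (width is 2M).
#' @return an \code{ImageFilterBank}.
#' @export
randomImageBank <- function(K, h, M) {
  ImageFilterBank(array(abs(stats::rnorm(h * 2 * M * K)), c(h, 2 * M, K)))
}

#' Reconstruct a one-hot sequence from its sparse codes
#'
#' Computes \eqn{\sum_m d_m * x_m + \tilde d_m * y_m}: every non-zero code
#' entry stamps its (forward or reverse-complement) PFM at the corresponding
#' placement offset. Linear in the codes.
#'
#' @param bank a \code{SeqFilterBank}.
#' @param codes list with \code{X} and \code{Y}, each P x M non-negative
#'   (P = L - l + 1 valid offsets).
#' @return 4 x L numeric matrix.
#' @export
reconstructSequence <- function(bank, codes) {
  d <- if (methods::is(bank, "SeqFilterBank")) bank@filters else bank
  M <- dim(d)[3]
  if (ncol(codes$X) != M || ncol(codes$Y) != M || nrow(codes$X) != nrow(codes$Y))
    stop("code shape does not match the filter bank")
  seqConv(makeDj(d), codes$X) + seqConv(makeDj(rcArray(d)), codes$Y)
}

#' Reconstruct a code image from its image code
#'
#' Computes \eqn{\sum_k F_k * z_k}: each non-zero entry of Z stamps image
#' filter k over rows q..q+h-1 at full width.
#'
#' @param bank an \code{ImageFilterBank}.
#' @param Z Q x K image code (Q = P - h + 1 valid offsets).
#' @return P x 2M numeric matrix.
#' @export
reconstructImage <- function(bank, Z) {
  f <- if (methods::is(bank, "ImageFilterBank")) bank@filters else bank
  if (ncol(Z) != dim(f)[3]) stop("image code width must equal K")
  imgConv(makeFj(f), Z)
}

#' Objective terms of the two-level representation
#'
#' Returns the separate terms of the fitting objective: the sequence data
#' term \eqn{\frac12\sum_n\|recon_n - s_n\|^2}, the code l1 penalty
#' \eqn{\lambda\sum(\|x\|_1+\|y\|_1)}, the image-filter l1 penalty
#' \eqn{\mu\sum_k\|F_k\|_1}, and the image coupling residual
#' \eqn{\frac12\sum_n\|\sum_k F_k * z_{kn} - \beta(X_n, Y_n)\|_F^2}, plus
#' their sum. The scaling transform T(M) = beta * M is applied on the
#' image-matching side.
#'
#' @param bank \code{SeqFilterBank}.
#' @param ibank \code{ImageFilterBank}.
#' @param codes list of per-sequence lists with X, Y.
#' @param zs list of per-sequence image codes Z.
#' @param seqs list of 4 x L one-hot matrices.
#' @param lambda,mu non-negative sparsity weights.
#' @param beta image scaling factor.
#' @return named numeric: data, codeL1, filterL1, image, total.
#' @export
objectiveTerms <- function(bank, ibank, codes, zs, seqs,
                           lambda = 0, mu = 0, beta = 1) {
  dataTerm <- 0; codeL1 <- 0; imageTerm <- 0
  f <- if (methods::is(ibank, "ImageFilterBank")) ibank@filters else ibank
  for (n in seq_along(seqs)) {
    rec <- reconstructSequence(bank, codes[[n]])
    dataTerm <- dataTerm + 0.5 * sum((rec - seqs[[n]])^2)
    codeL1 <- codeL1 + sum(codes[[n]]$X) + sum(codes[[n]]$Y)
    W <- imgConv(makeFj(f), zs[[n]])
    imageTerm <- imageTerm +
      0.5 * sum((W - beta * cbind(codes[[n]]$X, codes[[n]]$Y))^2)
  }
  out <- c(data = dataTerm, codeL1 = lambda * codeL1,
           filterL1 = mu * sum(abs(f)), image = imageTerm)
  c(out, total = sum(out))
}
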