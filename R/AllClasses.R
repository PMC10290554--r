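#' Bank of PFM-constrained sequence filters
#'
#' Holds M sequence filters, each a 4 x l position frequency matrix (rows
#' A,C,G,T; every column on the probability simplex), together with their
#' reverse-complement counterparts used to represent the complementary strand.
#'
#' @slot filters numeric array, 4 x l x M; column-stochastic slices.
#' @slot rcFilters numeric array, 4 x l x M; slice m is the reverse complement
#'   (columns reversed, rows complement-swapped) of \code{filters[,,m]}.
#' @export
setClass("SeqFilterBank",
  representation(filters = "array", rcFilters = "array"))

setValidity("SeqFilterBank", function(object) {
  d <- object@filters
  if (length(dim(d)) != 3L || dim(d)[1] != 4L)
    return("filters must be a 4 x l x M array")
  if (any(d < 0)) return("filter entries must be non-negative")
  cs <- apply(d, c(2, 3), sum)
  if (any(abs(cs - 1) > 1e-9)) return("filter columns must sum to 1")
  if (!identical(dim(d), dim(object@rcFilters)))
    return("rcFilters shape must match filters")
  rc <- d[4:1, rev(seq_len(dim(d)[2])), , drop = FALSE]
  if (max(abs(rc - object@rcFilters)) > 1e-12)
    return("rcFilters must equal the reverse complement of filters")
  TRUE
})

#' Bank of non-negative image filters
#'
#' K filters over the code image, each h x 2M (h code rows by the forward and
#' reverse-strand code columns), non-negative with unit Frobenius norm.
#'
#' @slot filters numeric array, h x 2M x K.
#' @export
setClass("ImageFilterBank", representation(filters = "array"))

setValidity("ImageFilterBank", function(object) {
  f <- object@filters
  if (length(dim(f)) != 3L) return("filters must be an h x 2M x K array")
  if (any(f < 0)) return("image filter entries must be non-negative")
  fro <- sqrt(apply(f^2, 3, sum))
  if (any(abs(fro - 1) > 1e-6))
    return("each image filter must have unit Frobenius norm")
  TRUE
})

#' Per-sequence sparse codes of the two-level representation
#'
#' One element per sequence, each a list with the forward code \code{X}
#' (P x M), reverse-complement code \code{Y} (P x M), image code \code{Z}
#' (Q x K, at most alpha non-zeros) and the scaled dual variables \code{U}
#' (P x 2M) of the coupling constraint.
#'
#' @slot codes list of per-sequence code lists.
#' @slot alpha integer sparsity budget of the image code.
#' @export
setClass("CodeSet",
  representation(codes = "list", alpha = "integer"))

setValidity("CodeSet", function(object) {
  for (cc in object@codes) {
    if (!all(c("X", "Y", "Z") %in% names(cc)))
      return("each code element needs X, Y, Z")
    if (min(cc$X, cc$Y) < 0) return("codes must be non-negative")
    if (sum(cc$Z != 0) > object@alpha)
      return("image code exceeds the alpha sparsity budget")
  }
  TRUE
})

#' Fitted two-level sparse representation model
#'
#' @slot seqBank \code{SeqFilterBank} of PFM sequence filters.
#' @slot imageBank \code{ImageFilterBank} of image filters.
#' @slot hyper named list of structural hyperparameters (M, l, K, h, alpha,
#'   beta, K1, K2, sweeps, ...).
#' @slot scalars named numeric: lambda (code sparsity), mu (filter sparsity),
#'   rho (the single ADMM penalty of the coupling constraint).
#' @slot stepSizes named list of per-phase step sizes eta, gamma, pi, omega.
#' @slot mode character, "classical" or "unfolded".
#' @slot seed integer seed the fit was run under.
#' @export
setClass("MotifModel",
  representation(seqBank = "SeqFilterBank", imageBank = "ImageFilterBank",
                 hyper = "list", scalars = "numeric", stepSizes = "list",
                 mode = "character", seed = "integer"))

#' Configuration hash table
#'
#' Maps each spatial configuration key (q image-filter indices sorted by
#' occurrence, with the q-1 inter-component nucleotide distances) to the
#' sequence regions it covers. Regions are stored as coordinates
#' (1-based, closed) so the covered substrings — an MSA per key — can be
#' re-extracted from the records at any time.
#'
#' @slot entries \code{data.table} with columns key, seqid, start, span.
#' @slot h integer image filter height (code rows).
#' @slot l integer sequence filter width (nt).
#' @slot q integer number of components per configuration.
#' @export
setClass("MotifTable",
  representation(entries = "ANY", h = "integer", l = "integer", q = "integer"))

#' A discovered motif with its enrichment statistics
#'
#' @slot key configuration key string ("k1:d1:k2:...:kq"); merged motifs keep
#'   the key of their highest-ranked member.
#' @slot counts 4 x w base count matrix of the MSA.
#' @slot pwm 4 x w log2-odds matrix.
#' @slot background length-4 background probabilities (A,C,G,T).
#' @slot pseudocount pseudocount distributed by background.
#' @slot threshold score threshold calibrated to the scan p-value.
#' @slot stats named numeric: tauH, tauM, cH, cM, oddsRatio, pValue,
#'   nInstances (NA before \code{evaluateSignificance}).
#' @slot msaSize number of MSA rows the counts were built from.
#' @export
setClass("ScoredMotif",
  representation(key = "character", counts = "matrix", pwm = "matrix",
                 background = "numeric", pseudocount = "numeric",
                 threshold = "numeric", stats = "numeric", msaSize = "integer"))

#' An ordered collection of discovered motifs plus run metadata
#'
#' @slot motifs list of \code{ScoredMotif}.
#' @slot config named list echoing the run configuration.
#' @export
setClass("MotifSet", representation(motifs = "list", config = "list"))

## ---- show methods -----------------------------------------------------

setMethod("show", "SeqFilterBank", function(object) {
  d <- dim(object@filters)
  cat("SeqFilterBank:", d[3], "PFM filters of width", d[2], "nt\n")
})

setMethod("show", "ImageFilterBank", function(object) {
  d <- dim(object@filters)
  cat("ImageFilterBank:", d[3], "filters of", d[1], "x", d[2],
      "pixels (non-negative, unit Frobenius norm)\n")
})

setMethod("show", "MotifModel", function(object) {
  h <- object@hyper
  cat("MotifModel (", object@mode, " fit)\n", sep = "")
  cat("  sequence filters: M =", h$M, ", width l =", h$l, "nt\n")
  cat("  image filters:    K =", h$K, ", height h =", h$h, "rows\n")
  cat("  sparsity alpha =", h$alpha, ", scaling beta =", h$beta, "\n")
  cat("  lambda =", signif(object@scalars["lambda"], 3),
      " mu =", signif(object@scalars["mu"], 3),
      " rho =", signif(object@scalars["rho"], 3), "\n")
})

setMethod("show", "MotifTable", function(object) {
  e <- object@entries
  cat("MotifTable: ", length(unique(e$key)), " configuration keys, ",
      nrow(e), " placements (q = ", object@q, ")\n", sep = "")
})

setMethod("show", "ScoredMotif", function(object) {
  cat("ScoredMotif ", object@key, ": width ", ncol(object@counts),
      " nt, ", object@msaSize, " MSA rows\n", sep = "")
  if (!is.na(object@stats["pValue"]))
    cat("  odds ratio ", signif(object@stats["oddsRatio"], 4),
        ", Fisher p = ", format(object@stats["pValue"], digits = 3), "\n",
        sep = "")
})

setMethod("show", "MotifSet", function(object) {
  cat("MotifSet with", length(object@motifs), "motifs\n")
  for (m in head(object@motifs, 5)) show(m)
  if (length(object@motifs) > 5) cat("  ...\n")
})
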