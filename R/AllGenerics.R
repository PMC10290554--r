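#' @name accessors
#' @title Accessors for sparsemotif S4 containers
#' @param x an object.
#' @param m,i index.
#' @description Slot access for the package's S4 classes goes through these
#'   accessors; the slots themselves are internal.
NULL

#' @rdname accessors
#' @export
setGeneric("seqFilters", function(x) standardGeneric("seqFilters"))
#' @rdname accessors
#' @export
setGeneric("imageFilters", function(x) standardGeneric("imageFilters"))
#' @rdname accessors
#' @export
setGeneric("pfm", function(x, m) standardGeneric("pfm"))
#' @rdname accessors
#' @export
setGeneric("nFilters", function(x) standardGeneric("nFilters"))
#' @rdname accessors
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))
#' @rdname accessors
#' @export
setGeneric("codes", function(x, i) standardGeneric("codes"))
#' @rdname accessors
#' @export
setGeneric("motifStats", function(x) standardGeneric("motifStats"))
#' @rdname accessors
#' @export
setGeneric("tableEntries", function(x) standardGeneric("tableEntries"))

#' @rdname accessors
#' @export
setMethod("seqFilters", "SeqFilterBank", function(x) x@filters)
#' @rdname accessors
#' @export
setMethod("seqFilters", "MotifModel", function(x) x@seqBank)
#' @rdname accessors
#' @export
setMethod("imageFilters", "ImageFilterBank", function(x) x@filters)
#' @rdname accessors
#' @export
setMethod("imageFilters", "MotifModel", function(x) x@imageBank)
#' @rdname accessors
#' @export
setMethod("pfm", "SeqFilterBank", function(x, m) x@filters[, , m, drop = TRUE])
#' @rdname accessors
#' @export
setMethod("nFilters", "SeqFilterBank", function(x) dim(x@filters)[3])
#' @rdname accessors
#' @export
setMethod("nFilters", "ImageFilterBank", function(x) dim(x@filters)[3])
#' @rdname accessors
#' @export
setMethod("motifs", "MotifSet", function(x) x@motifs)
#' @rdname accessors
#' @export
setMethod("codes", "CodeSet", function(x, i) {
  if (missing(i)) x@codes else x@codes[[i]]
})
#' @rdname accessors
#' @export
setMethod("motifStats", "ScoredMotif", function(x) x@stats)
#' @rdname accessors
#' @export
setMethod("motifStats", "MotifSet", function(x) {
  do.call(rbind, lapply(x@motifs, function(m)
    data.frame(key = m@key, width = ncol(m@counts), msaSize = m@msaSize,
               as.list(m@stats))))
})
#' @rdname accessors
#' @export
setMethod("tableEntries", "MotifTable", function(x) x@entries)

#' Length of a MotifSet is its number of motifs
#' @param x a \code{MotifSet}.
#' @export
setMethod("length", "MotifSet", function(x) length(x@motifs))

#' Extract one motif from a MotifSet
#' @param x a \code{MotifSet}.
#' @param i index.
#' @export
setMethod("[[", "MotifSet", function(x, i) x@motifs[[i]])
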