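## Enumerating at the image level: q-component configurations of each
## sequence's image code, hashed into a table whose buckets are MSAs.
##
## Coverage convention: an image-code component at row offset p (1-based)
## spans nucleotides [p, p + h + l - 2] (h code rows, each code row placing
## a width-l filter). The distance between neighbouring components is the
## gap in nt between the end of one coverage and the start of the next;
## overlapping components give negative distances and are valid keys.

#' Non-zero components of an image code
#'
#' @param z Q x K image code matrix.
#' @return data.frame with columns \code{k} (filter index), \code{p} (row
#'   offset) and \code{value}, sorted by p then k.
#' @export
nonzeroComponents <- function(z) {
  idx <- which(z != 0)
  if (length(idx) == 0L)
    return(data.frame(k = integer(0), p = integer(0), value = numeric(0)))
  p <- ((idx - 1L) %% nrow(z)) + 1L
  k <- ((idx - 1L) %/% nrow(z)) + 1L
  ord <- order(p, k)
  data.frame(k = k[ord], p = p[ord], value = z[idx][ord])
}

#' Enumerate q-component configurations of an image code
#'
#' Every q-subset of the non-zero components, sorted by spatial occurrence,
#' becomes one configuration: the tuple of filter indices and the q-1
#' inter-component nucleotide distances. With nnz non-zeros this is
#' choose(nnz, q) configurations (at most choose(alpha, q)).
#'
#' @param z Q x K image code matrix.
#' @param q components per configuration (>= 1).
#' @param h image filter height (code rows).
#' @param l sequence filter width (nt).
#' @return \code{data.table} with columns \code{key} ("f1:d1:f2:...:fq"),
#'   \code{start} (smallest covered nt) and \code{span} (covered width in
#'   nt); zero rows when fewer than q components exist.
#' @export
enumerateConfigurations <- function(z, q, h, l) {
  stopifnot(q >= 1)
  comp <- nonzeroComponents(z)
  nnz <- nrow(comp)
  empty <- data.table::as.data.table(
    list(key = character(0), start = integer(0), span = integer(0)))
  if (nnz < q) return(empty)
  cover <- h + l - 1L
  sub <- utils::combn(nnz, q)             # columns are index subsets, sorted
  ks <- matrix(comp$k[sub], nrow = q)
  ps <- matrix(comp$p[sub], nrow = q)
  if (q > 1L) {
    d <- ps[-1L, , drop = FALSE] - ps[-q, , drop = FALSE] - cover
    pieces <- character(2L * q - 1L)
    keyParts <- vector("list", 2L * q - 1L)
    for (i in seq_len(q)) keyParts[[2L * i - 1L]] <- ks[i, ]
    for (i in seq_len(q - 1L)) keyParts[[2L * i]] <- d[i, ]
    key <- do.call(paste, c(keyParts, sep = ":"))
    span <- ps[q, ] - ps[1L, ] + cover
  } else {
    key <- as.character(ks[1L, ])
    span <- rep(cover, ncol(sub))
  }
  data.table::as.data.table(list(key = key, start = as.integer(ps[1L, ]),
                                 span = as.integer(span)))
}

#' Build the configuration hash table over a dataset
#'
#' Enumerates the configurations of every sequence's image code and stores
#' each placement (sequence id, start, span) under its configuration key.
#' Placements whose nucleotide span would overrun the sequence are skipped
#' (under this package's coverage convention they cannot occur, but the
#' guard is kept). Each key's placements define an MSA of equal-length
#' substrings.
#'
#' @param codeSet a \code{CodeSet} (or plain list of per-sequence lists
#'   with element \code{Z}).
#' @param records sequences the codes were inferred from
#'   (\code{DNAStringSet} or named character).
#' @param hyper hyperparameter list providing q, h, l.
#' @return a \code{MotifTable}.
#' @export
buildMotifTable <- function(codeSet, records, hyper) {
  cs <- if (methods::is(codeSet, "CodeSet")) codeSet@codes else codeSet
  recs <- asRecords(records)
  stopifnot(length(cs) == length(recs))
  parts <- vector("list", length(cs))
  for (n in seq_along(cs)) {
    cfg <- enumerateConfigurations(cs[[n]]$Z, hyper$q, hyper$h, hyper$l)
    if (nrow(cfg) == 0L) next
    L <- nchar(recs[n])
    cfg <- cfg[cfg$start >= 1L & cfg$start + cfg$span - 1L <= L, ]
    if (nrow(cfg) == 0L) next
    cfg$seqid <- names(recs)[n]
    parts[[n]] <- cfg
  }
  entries <- data.table::rbindlist(parts[!vapply(parts, is.null, logical(1))])
  if (nrow(entries) == 0L)
    entries <- data.table::as.data.table(
      list(key = character(0), start = integer(0), span = integer(0),
           seqid = character(0)))
  new("MotifTable", entries = entries, h = as.integer(hyper$h),
      l = as.integer(hyper$l), q = as.integer(hyper$q))
}

#' Extract the MSA stored under one configuration key
#'
#' @param table a \code{MotifTable}.
#' @param records the same records the table was built from.
#' @param key configuration key string.
#' @return character vector of equal-length substrings (may contain N;
#'   N-containing rows are dropped at the counting stage).
#' @export
extractMsa <- function(table, records, key) {
  recs <- asRecords(records)
  ent <- table@entries
  sel <- ent$key == key        # plain vector comparison, outside the frame
  e <- ent[sel, ]
  if (nrow(e) == 0L) return(character(0))
  substring(recs[e$seqid], e$start, e$start + e$span - 1L)
}

#' Rank configuration keys by bucket occupancy
#'
#' "Most enriched" at the enumeration stage means largest bucket; the
#' statistical enrichment test comes later. Ties are broken by
#' lexicographic key order.
#'
#' @param table a \code{MotifTable}.
#' @param J maximum number of keys returned (default 1000).
#' @return \code{data.table} with columns \code{key}, \code{count}, ranked.
#' @export
selectTop <- function(table, J = 1000L) {
  stopifnot(J >= 1)
  e <- table@entries
  if (nrow(e) == 0L)
    return(data.table::as.data.table(
      list(key = character(0), count = integer(0))))
  agg <- e[, list(count = .N), by = "key"]
  data.table::setorder(agg, -count, key)
  head(agg, J)
}

#' Base counts of an MSA
#'
#' Column j holds the A,C,G,T counts at position j over the retained
#' strings; strings containing N are excluded so the counts stay integral
#' over the DNA alphabet, and all column sums equal the number retained.
#'
#' @param strings equal-length DNA strings (>= 1).
#' @return 4 x w integer count matrix (rows A,C,G,T).
#' @export
msaToCounts <- function(strings) {
  stopifnot(length(strings) >= 1)
  w <- nchar(strings[1])
  if (any(nchar(strings) != w)) stop("MSA strings must have equal length")
  keep <- !grepl("N", strings, fixed = TRUE)
  counts <- matrix(0L, 4, w, dimnames = list(DNA_BASES, NULL))
  if (!any(keep)) return(counts)
  chars <- matrix(unlist(strsplit(strings[keep], "", fixed = TRUE)),
                  ncol = w, byrow = TRUE)
  for (b in seq_along(DNA_BASES))
    counts[b, ] <- colSums(chars == DNA_BASES[b])
  counts
}
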