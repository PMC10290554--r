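## Sequence I/O, one-hot encoding, shuffles and splits.
## Coordinates are 1-based, closed, forward-strand throughout the package.

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Evaluate an expression under a fixed seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded helpers do not disturb the
#' surrounding random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Coerce DNAStringSet / character to a named uppercase character vector.
asRecords <- function(x) {
  nm <- names(x)                     # as.character/toupper drop attributes
  s <- toupper(as.character(x))
  if (length(s) == 0L) return(setNames(character(0), character(0)))
  names(s) <- if (is.null(nm)) paste0("seq", seq_along(s)) else nm
  s
}

#' Read DNA sequences from a FASTA file
#'
#' Parses a FASTA file into a named \code{DNAStringSet}. Sequences are
#' uppercased and any IUPAC ambiguity code is collapsed to \code{N} (encoded
#' downstream as a uniform 0.25 column, which keeps the reconstruction loss
#' well-defined without discarding reads).
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "ttga"), tf)
#' readDnaFasta(tf)
#' @export
readDnaFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L) stop("empty FASTA input: ", path)
  if (!startsWith(trimws(lines[content[1]]), ">"))
    stop("malformed FASTA at line ", content[1],
         ": expected a '>' header before sequence data")
  ok <- grepl("^[ACGTUacgtuRYSWKMBDHVNryswkmbdhvn]*$", trimws(lines))
  bad <- setdiff(which(!ok & nzchar(trimws(lines))),
                 grep("^>", trimws(lines)))
  if (length(bad))
    stop("malformed FASTA at line ", bad[1], ": invalid characters in '",
         trimws(lines[bad[1]]), "'")
  hasU <- grepl("[Uu]", lines[-grep("^>", trimws(lines))])
  if (any(hasU))
    stop("non-DNA alphabet (found 'U'); RNA input is not supported")
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA input: ", path)
  s <- toupper(as.character(x))
  if (any(!nzchar(s))) stop("FASTA entry with empty sequence: ",
                            names(s)[which(!nzchar(s))[1]])
  s <- vapply(s, function(z)
    chartr(paste(IUPAC_AMBIG, collapse = ""),
           strrep("N", length(IUPAC_AMBIG)), z), character(1))
  ## keep only the first word of each header as the id
  names(s) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  Biostrings::DNAStringSet(s)
}

#' Write DNA sequences to FASTA
#'
#' @param seqs a \code{DNAStringSet} or named character vector.
#' @param path output path; lines wrapped at 80 columns.
#' @return \code{path}, invisibly.
#' @export
writeDnaFasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(asRecords(seqs))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' One-hot encode a DNA string
#'
#' Returns the 4 x L indicator matrix of a DNA string (rows A, C, G, T).
#' Ambiguous bases (\code{N}) become uniform 0.25 columns, so every column
#' sums to 1.
#'
#' @param seq a single DNA string (character) or \code{DNAString}.
#' @return 4 x L numeric matrix with rownames A,C,G,T.
#' @examples
#' oneHotEncode("ACN")
#' @export
oneHotEncode <- function(seq) {
  s <- strsplit(toupper(as.character(seq)[1]), "", fixed = TRUE)[[1]]
  L <- length(s)
  m <- matrix(0, 4, L, dimnames = list(DNA_BASES, NULL))
  idx <- match(s, DNA_BASES)
  known <- !is.na(idx)
  m[cbind(idx[known], which(known))] <- 1
  if (any(!known)) m[, !known] <- 0.25
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Column argmax; uniform columns decode to \code{N}.
#' @param m 4 x L matrix.
#' @return character DNA string.
#' @export
oneHotDecode <- function(m) {
  stopifnot(nrow(m) == 4)
  if (ncol(m) == 0) return("")
  uni <- apply(m, 2, function(cc) max(cc) - min(cc) < 1e-12)
  b <- DNA_BASES[apply(m, 2, which.max)]
  b[uni] <- "N"
  paste(b, collapse = "")
}

#' Reverse complement of plain character DNA strings
#'
#' Method for \code{Biostrings::reverseComplement} on character vectors
#' (alphabet A,C,G,T,N); an involution.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse-complemented strings.
#' @export
#' @importFrom Biostrings reverseComplement
setMethod("reverseComplement", "character", function(x, ...) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANTGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
})

#' Dinucleotide-preserving shuffle
#'
#' Shuffles a DNA string so that its 16-entry dinucleotide count vector is
#' exactly preserved, using the Euler-tour (Altschul-Erickson) construction:
#' the string is a walk on the graph whose edges are its dinucleotides, and a
#' uniformly sampled Eulerian walk with the same start and end vertex is
#' returned. First and last nucleotide are therefore fixed. Deterministic
#' given \code{seed}.
#'
#' @param seq a DNA string of length >= 2.
#' @param seed integer seed.
#' @return shuffled DNA string.
#' @examples
#' dinucleotideShuffle("AAGTCGTAAG", seed = 1)
#' @export
dinucleotideShuffle <- function(seq, seed) {
  s <- strsplit(toupper(as.character(seq)[1]), "", fixed = TRUE)[[1]]
  L <- length(s)
  if (L < 2) stop("sequence must have length >= 2")
  withSeed(seed, {
    verts <- unique(s)
    nv <- length(verts)
    from <- match(s[-L], verts)
    to <- match(s[-1], verts)
    outEdges <- split(to, factor(from, levels = seq_len(nv)))
    last <- match(s[L], verts)
    if (nv > 1L) {
      repeat {
        ## pick a random terminal out-edge for every vertex but the last;
        ## accept when the chosen edges form a tree rooted at the last vertex
        lastEdge <- rep(NA_integer_, nv)
        for (v in seq_len(nv)) {
          if (v == last) next
          ev <- outEdges[[v]]
          lastEdge[v] <- ev[sample.int(length(ev), 1L)]
        }
        ok <- TRUE
        for (v in seq_len(nv)) {
          if (v == last) next
          cur <- v; steps <- 0L
          while (cur != last && steps <= nv) {
            cur <- lastEdge[cur]; steps <- steps + 1L
            if (is.na(cur)) break
          }
          if (is.na(cur) || cur != last) { ok <- FALSE; break }
        }
        if (ok) break
      }
    } else lastEdge <- NA_integer_
    ## shuffle the remaining out-edges, append the chosen terminal edge
    lists <- vector("list", nv)
    for (v in seq_len(nv)) {
      ev <- outEdges[[v]]
      if (v != last && nv > 1L) {
        drop1 <- match(lastEdge[v], ev)
        rest <- ev[-drop1]
        if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
        lists[[v]] <- c(rest, lastEdge[v])
      } else {
        if (length(ev) > 1L) ev <- ev[sample.int(length(ev))]
        lists[[v]] <- ev
      }
    }
    ptr <- rep(1L, nv)
    walk <- integer(L)
    walk[1] <- match(s[1], verts)
    for (i in 2:L) {
      v <- walk[i - 1L]
      walk[i] <- lists[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
    }
    paste(verts[walk], collapse = "")
  })
}

#' Split records into training and held-out test sets
#'
#' A random partition with \code{round(fraction * N)} test records, used so
#' that motif significance is always assessed on sequences the representation
#' was not fitted on.
#'
#' @param records \code{DNAStringSet} or named character vector.
#' @param fraction test fraction in (0, 1); default 0.15.
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test} (same class as the
#'   input subsetting allows), a disjoint partition of the input.
#' @export
splitTrainTest <- function(records, fraction = 0.15, seed = 1L) {
  N <- length(records)
  if (N < 2) stop("need at least 2 records to split")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  nTest <- as.integer(round(fraction * N))
  nTest <- max(min(nTest, N - 1L), if (fraction > 0) 0L else 0L)
  idx <- withSeed(seed, sample.int(N, nTest))
  idx <- sort(idx)
  list(train = records[setdiff(seq_len(N), idx)], test = records[idx])
}

#' Dinucleotide count vector of a DNA string
#'
#' Convenience used by tests and controls: the 16 overlapping 2-mer counts
#' over A,C,G,T (pairs containing other letters are counted under their own
#' labels).
#' @param seq DNA string.
#' @return named integer vector of dinucleotide counts.
#' @export
dinucleotideCounts <- function(seq) {
  s <- strsplit(toupper(as.character(seq)[1]), "", fixed = TRUE)[[1]]
  if (length(s) < 2) return(integer(0))
  table(paste0(s[-length(s)], s[-1]))
}
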