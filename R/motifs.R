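#' Read a motif collection
#'
#' Parses a text file of position-specific matrices into
#' \linkS4class{MotifMatrix} objects. Two dialects are supported:
#' \describe{
#'   \item{jaspar}{JASPAR 2016+ text: a \code{">ID"} header line followed by
#'     four rows \code{A [ 1 2 ... ]}, \code{C [...]}, \code{G [...]},
#'     \code{T [...]} (brackets optional). Values are counts per position.}
#'   \item{plain}{a \code{">ID"} header followed by m whitespace-delimited
#'     rows of 4 numbers (positions x bases A C G T).}
#' }
#' Count matrices are kept as counts; they are normalized only when converted
#' to an energy matrix.
#'
#' @param path path to the motif file.
#' @param format "jaspar" or "plain".
#' @return a list of \linkS4class{MotifMatrix}, in file order.
#' @export
readMotifs <- function(path, format = c("jaspar", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no motif records (no '>' headers) in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    id <- trimws(sub("^>", "", lines[hdr[i]]))
    id <- strsplit(id, "[ \t]+")[[1L]][1L]
    body <- lines[seq(hdr[i] + 1L, length.out = ends[i] - hdr[i])]
    mat <- if (format == "jaspar") parseJasparBlock(id, body)
           else parsePlainBlock(id, body)
    if (nrow(mat) == 0L)
      stop("zero-length motif rejected: '", id, "'")
    if (anyNA(mat))
      stop("malformed motif record '", id, "': non-numeric values")
    if (any(mat < 0))
      stop("malformed motif record '", id, "': negative counts")
    type <- if (all(abs(rowSums(mat) - 1) <= 1e-6)) "frequencies" else "counts"
    out[[i]] <- new("MotifMatrix", id = id, values = mat, type = type)
  }
  out
}

parseJasparBlock <- function(id, body) {
  if (length(body) != 4L)
    stop("malformed motif record '", id, "': expected 4 base rows, got ",
         length(body))
  rows <- lapply(body, function(x) {
    base <- toupper(trimws(substr(trimws(x), 1L, 1L)))
    nums <- gsub("^[ACGTacgt]\\s*", "", trimws(x))
    nums <- gsub("\\[|\\]", " ", nums)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1L]]))
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, `[[`, "", "base")
  if (!setequal(bases, c("A", "C", "G", "T")))
    stop("malformed motif record '", id, "': base rows must be A, C, G, T")
  lens <- vapply(rows, function(r) length(r$vals), 1L)
  if (length(unique(lens)) != 1L)
    stop("malformed motif record '", id, "': unequal row lengths")
  mat <- matrix(0, nrow = lens[1L], ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (r in rows) mat[, r$base] <- r$vals
  mat
}

parsePlainBlock <- function(id, body) {
  vals <- lapply(body, function(x)
    suppressWarnings(as.numeric(strsplit(trimws(x), "\\s+")[[1L]])))
  if (any(vapply(vals, length, 1L) != 4L))
    stop("malformed motif record '", id, "': each row needs 4 values")
  mat <- do.call(rbind, vals)
  colnames(mat) <- c("A", "C", "G", "T")
  mat
}

#' Convert a motif to a binding energy matrix
#'
#' Derives per-position, per-base mismatch energies from a motif using the
#' Berg-von Hippel form
#' \deqn{E_{j,b} = \ln\frac{f_{max,j} + p_0}{f_{b,j} + p_0}}
#' where \eqn{f_{b,j}} is the frequency of base b at position j and
#' \eqn{f_{max,j}} the per-position maximum. The consensus base at every
#' position has energy exactly 0; the pseudocount keeps energies finite when a
#' base was never observed. Count matrices are normalized per position first,
#' so the result is invariant to rescaling counts by a positive constant.
#'
#' @param motif a \linkS4class{MotifMatrix}.
#' @param p0 pseudocount, > 0 (default 0.01).
#' @return an \linkS4class{EnergyMatrix}.
#' @export
toEnergyMatrix <- function(motif, p0 = 0.01) {
  stopifnot(is(motif, "MotifMatrix"))
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0)
    stop("p0 must be a single positive number")
  f <- motif@values
  rs <- rowSums(f)
  if (any(rs <= 0))
    stop("motif '", motif@id, "': position with zero total count")
  f <- f / rs
  fmax <- apply(f, 1L, max)
  e <- log((fmax + p0) / (f + p0))
  # exact 0 at the consensus despite floating-point log
  e <- e - apply(e, 1L, min)
  new("EnergyMatrix", id = motif@id, energies = e, pseudocount = p0)
}

#' Score one binding site against an energy matrix
#'
#' The total binding energy E*S of an m-mer: the sum over positions of the
#' energy of the base at that position. An N contributes the mean of the four
#' energies at its position (the expectation over a uniform resolution).
#'
#' @param E an \linkS4class{EnergyMatrix}.
#' @param site a character string of length m over A, C, G, T, N.
#' @return the site energy (a single non-negative number).
#' @export
siteEnergy <- function(E, site) {
  stopifnot(is(E, "EnergyMatrix"))
  codes <- encodeDNA(site)
  m <- nrow(E@energies)
  if (length(codes) != m)
    stop("site length ", length(codes), " does not match motif length ", m)
  e5 <- energyLookup(E@energies)
  sum(e5[cbind(seq_len(m), codes)])
}

# m x 5 lookup: columns A, C, G, T and (as 5th) the per-position mean for N
energyLookup <- function(e) {
  cbind(e, rowMeans(e))
}

# reverse-complement energy matrix: scoring the forward sequence with this
# matrix equals scoring the reverse complement of the site with the original
revcompEnergies <- function(e) {
  e[rev(seq_len(nrow(e))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

encodeDNA <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  chars <- strsplit(toupper(x), "")[[1L]]
  codes <- match(chars, DNA_BASES5)
  if (anyNA(codes))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(chars[is.na(codes)]), collapse = ","))
  codes
}
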