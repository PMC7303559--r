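#' Chemical potential of the binding-probability model
#'
#' The probability that a TF bound nonspecifically occupies a site of energy E
#' follows a Fermi-Dirac form \eqn{P = 1/(1 + \exp(E - \mu))}, where the
#' chemical potential \eqn{\mu} tracks the protein concentration. When
#' \eqn{\mu = 0} does not apply or the protein concentration is very low, the
#' Maxwell-Boltzmann limit \eqn{P \approx \exp(-E)} is used instead
#' (mode "boltzmann"; \code{mu} is ignored there).
#'
#' @param mode "fermi_dirac" or "boltzmann".
#' @param mu chemical potential (dimensionless, thermal units).
#' @return a ChemicalPotential object (a small classed list).
#' @export
chemicalPotential <- function(mode = c("fermi_dirac", "boltzmann"), mu = 0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  structure(list(mode = mode, mu = mu), class = "ChemicalPotential")
}

#' @rdname chemicalPotential
#' @export
print.ChemicalPotential <- function(x, ...) {
  cat(sprintf("ChemicalPotential: %s%s\n", x$mode,
              if (x$mode == "fermi_dirac") sprintf(" (mu = %g)", x$mu) else ""))
  invisible(x)
}

#' Default chemical potentials for genome scans
#'
#' Fermi-Dirac at mu = 0 and mu = -10: the low-to-median concentration range
#' where the nonspecific affinity signal is informative (it vanishes as mu
#' becomes strongly negative).
#'
#' @return a list of two ChemicalPotential objects.
#' @export
defaultPotentials <- function() {
  list(chemicalPotential("fermi_dirac", 0),
       chemicalPotential("fermi_dirac", -10))
}

potentialLabel <- function(pot) {
  if (pot$mode == "boltzmann") "boltzmann"
  else sprintf("fermi_dirac_mu%g", pot$mu)
}

#' Lay out sliding windows on a sequence
#'
#' Windows of size \code{L} step by \code{st}: starts 0, st, 2st, ... and
#' count \code{k = floor((N - L)/st) + 1}; when \code{N < L} the grid is empty
#' (k = 0), not an error.
#'
#' @param N sequence length.
#' @param L window size in bp (default 50).
#' @param st step size in bp (default 5).
#' @return a \linkS4class{SlidingWindowGrid}.
#' @export
makeGrid <- function(N, L = 50L, st = 5L) {
  N <- as.integer(N); L <- as.integer(L); st <- as.integer(st)
  stopifnot(L >= 1L, st >= 1L, N >= 0L)
  starts <- if (N >= L) as.integer(seq.int(0L, N - L, by = st)) else integer(0)
  new("SlidingWindowGrid", N = N, L = L, st = st, starts = starts)
}

#' Binding probability of a site energy
#'
#' Fermi-Dirac: \eqn{1/(1 + \exp(E - \mu))}; Boltzmann: \eqn{\exp(-E)}.
#' Exponents are clamped at +-700 so extreme energies underflow to 0
#' gracefully instead of overflowing.
#'
#' @param energy numeric vector/matrix of site energies.
#' @param potential a \code{\link{chemicalPotential}}.
#' @return probabilities in (0, 1], same shape as \code{energy}.
#' @export
bindingProbability <- function(energy, potential) {
  stopifnot(inherits(potential, "ChemicalPotential"))
  if (potential$mode == "boltzmann") {
    exp(-pmin(energy, 700))
  } else {
    x <- pmin(pmax(energy - potential$mu, -700), 700)
    1 / (1 + exp(x))
  }
}

#' Binding affinity of a TF on one sliding window
#'
#' \eqn{A = p \sum_{l=1}^{L-m+1} P(E(S_{i,l}))}: the prior times the summed
#' binding probability over every motif offset in the window. By default both
#' strands are scored and their per-offset probabilities summed, since TF
#' binding is strand-symmetric; \code{strands = "forward"} restricts to the
#' given strand. A motif wider than the window gives the empty-sum value 0.
#'
#' @param window character DNA string of length L (A, C, G, T, N).
#' @param E an \linkS4class{EnergyMatrix}.
#' @param potential a \code{\link{chemicalPotential}}.
#' @param p prior binding probability in (0, 1] (default 1).
#' @param strands "both" or "forward".
#' @return the window affinity, a single number >= 0.
#' @export
windowAffinity <- function(window, E, potential, p = 1,
                           strands = c("both", "forward")) {
  strands <- match.arg(strands)
  codes <- encodeDNA(window)
  windowAffinityCodes(codes, E@energies, potential, p, strands == "both")
}

windowAffinityCodes <- function(codes, e, potential, p, both) {
  m <- nrow(e)
  L <- length(codes)
  if (m > L) return(0)
  nOff <- L - m + 1L
  e5f <- energyLookup(e)
  ef <- numeric(nOff)
  for (j in seq_len(m)) ef <- ef + e5f[j, codes[j:(j + nOff - 1L)]]
  tot <- bindingProbability(ef, potential)
  if (both) {
    e5r <- energyLookup(revcompEnergies(e))
    er <- numeric(nOff)
    for (j in seq_len(m)) er <- er + e5r[j, codes[j:(j + nOff - 1L)]]
    tot <- tot + bindingProbability(er, potential)
  }
  p * sum(tot)
}

# deterministic per-(window, motif) sub-seed; kept below 2^31
deriveSeed <- function(seed, windowIndex, motifIndex) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    as.numeric(windowIndex) * 69621 + as.numeric(motifIndex) * 16807
  as.integer(s %% 2147483629) + 1L
}

withSeed <- function(s, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = env)
    else assign(".Random.seed", old, envir = env)
  })
  set.seed(s)
  force(expr)
}

#' Seeded shuffle permutations for one window/motif cell
#'
#' The mononucleotide shuffles behind the background affinity are drawn from a
#' stream seeded by hash(seed, windowIndex, motifIndex), so a scan's result is
#' independent of worker count and motif processing order. Exposing the
#' permutations lets independent re-implementations reproduce the exact
#' background term.
#'
#' @param seed integer master seed.
#' @param windowIndex,motifIndex 1-based indices of the window and motif.
#' @param R number of shuffles.
#' @param L window length.
#' @return an L x R integer matrix; column r permutes the window's bases.
#' @export
shuffleIndices <- function(seed, windowIndex = 1L, motifIndex = 1L,
                           R = 10L, L = 50L) {
  stopifnot(R >= 1L, L >= 1L)
  withSeed(deriveSeed(seed, windowIndex, motifIndex),
           vapply(seq_len(R), function(r) sample.int(L), integer(L)))
}

#' Background affinity over shuffled windows
#'
#' The mean of \code{\link{windowAffinity}} over R mononucleotide shuffles of
#' the window. Shuffles permute the window's own bases, so base composition is
#' preserved exactly; a homopolymer window therefore has background equal to
#' its own affinity.
#'
#' @inheritParams windowAffinity
#' @param R number of shuffles (default 10).
#' @param seed integer master seed.
#' @param windowIndex,motifIndex indices identifying the shuffle stream (see
#'   \code{\link{shuffleIndices}}).
#' @return the mean shuffled affinity.
#' @export
shuffledBackground <- function(window, E, potential, p = 1, R = 10L, seed = 1L,
                               windowIndex = 1L, motifIndex = 1L,
                               strands = c("both", "forward")) {
  strands <- match.arg(strands)
  codes <- encodeDNA(window)
  perms <- shuffleIndices(seed, windowIndex, motifIndex, R, length(codes))
  vals <- vapply(seq_len(R), function(r)
    windowAffinityCodes(codes[perms[, r]], E@energies, potential, p,
                        strands == "both"), 0)
  mean(vals)
}

#' Differential binding affinity of one window
#'
#' dbA = window affinity minus shuffled background; subtracting the
#' composition-matched background removes local sequence bias so affinities
#' are comparable genome-wide.
#'
#' @inheritParams shuffledBackground
#' @return the differential affinity (may be negative).
#' @export
diffBindingAffinity <- function(window, E, potential, p = 1, R = 10L,
                                seed = 1L, windowIndex = 1L, motifIndex = 1L,
                                strands = c("both", "forward")) {
  strands <- match.arg(strands)
  windowAffinity(window, E, potential, p, strands) -
    shuffledBackground(window, E, potential, p, R, seed,
                       windowIndex, motifIndex, strands)
}

#' Scan a sequence for expected nonspecific TF binding affinity
#'
#' Slides windows of size \code{L} (step \code{st}) along the sequence and,
#' for each window and chemical potential, averages the differential binding
#' affinity dbA over the motif ensemble:
#' \deqn{nTBA(S_i) = \frac{1}{n}\sum_{T=1}^{n} (A_{i,T} - A_{i,T,R})}
#' The value is assigned to the window center. The R shuffled variants of a
#' window (the randomly mutated DNA) are generated once per window from a
#' seeded per-window stream and scored by every motif, so results are
#' bit-identical for any \code{workers} and invariant to motif reordering.
#' Windows containing more than L/2 undetermined (N) bases yield NA rather
#' than a spurious value.
#'
#' @param sequence DNA as a character string or Biostrings DNAString.
#' @param motifs list of \linkS4class{EnergyMatrix}; motifs wider than L are
#'   skipped with a warning.
#' @param potentials list of \code{\link{chemicalPotential}} objects.
#' @param L,st window and step size in bp.
#' @param p prior binding probability.
#' @param R number of shuffles per window and motif.
#' @param seed master seed.
#' @param workers number of parallel worker processes (motifs are split
#'   across workers; the result does not depend on this).
#' @param strands "both" (sum of forward and reverse-complement
#'   probabilities) or "forward".
#' @param seqname name recorded in the profile.
#' @return an \linkS4class{AffinityProfile}.
#' @export
ntbaScan <- function(sequence, motifs, potentials = defaultPotentials(),
                     L = 50L, st = 5L, p = 1, R = 10L, seed = 1L,
                     workers = 1L, strands = c("both", "forward"),
                     seqname = "seq") {
  strands <- match.arg(strands)
  both <- strands == "both"
  if (inherits(potentials, "ChemicalPotential")) potentials <- list(potentials)
  stopifnot(length(potentials) >= 1L)
  if (is(motifs, "EnergyMatrix")) motifs <- list(motifs)
  codes <- encodeDNA(sequence)
  grid <- makeGrid(length(codes), L, st)
  L <- grid@L; st <- grid@st
  k <- windowCount(grid)

  widths <- vapply(motifs, motifLength, 1L)
  usable <- which(widths <= L)
  if (length(usable) < length(motifs))
    warning(length(motifs) - length(usable),
            " motif(s) wider than the window (m > L) skipped")
  if (length(usable) == 0L)
    stop("no usable motif: all motif lengths exceed the window size L = ", L)

  potdf <- data.frame(mode = vapply(potentials, `[[`, "", "mode"),
                      mu = vapply(potentials, `[[`, 0, "mu"))
  if (k == 0L)
    return(new("AffinityProfile", seqname = seqname, centers = integer(0),
               values = matrix(0, 0L, length(potentials),
                               dimnames = list(NULL, vapply(potentials, potentialLabel, ""))),
               potentials = potdf, nMotifs = length(usable),
               L = L, st = st))

  starts1 <- grid@starts + 1L
  # windows dominated by N are reported as missing
  isN <- cumsum(codes == 5L)
  nN <- isN[starts1 + L - 1L] - c(0, isN)[starts1]
  mask <- nN > L / 2

  scanOne <- function(ti) {
    scanOneMotif(codes, starts1, mask, L, p, R, seed, ti,
                 motifs[[ti]]@energies, potentials, both)
  }
  pieces <- if (workers > 1L) {
    parallel::mclapply(usable, scanOne, mc.cores = workers)
  } else {
    lapply(usable, scanOne)
  }
  total <- Reduce(`+`, pieces)
  vals <- total / length(usable)
  vals[mask, ] <- NA_real_
  colnames(vals) <- vapply(potentials, potentialLabel, "")
  new("AffinityProfile", seqname = seqname,
      centers = windowCenters(grid), values = vals, potentials = potdf,
      nMotifs = length(usable), L = L, st = st)
}

scanOneMotif <- function(codes, starts1, mask, L, p, R, seed, motifIndex,
                         e, potentials, both) {
  m <- nrow(e)
  nOff <- L - m + 1L
  k <- length(starts1)
  P <- length(potentials)
  e5f <- energyLookup(e)
  e5r <- if (both) energyLookup(revcompEnergies(e)) else NULL

  # foreground: site energies precomputed once for the whole sequence,
  # window sums via cumulative sums
  nSites <- length(codes) - m + 1L
  ef <- numeric(nSites)
  for (j in seq_len(m)) ef <- ef + e5f[j, codes[j:(j + nSites - 1L)]]
  if (both) {
    er <- numeric(nSites)
    for (j in seq_len(m)) er <- er + e5r[j, codes[j:(j + nSites - 1L)]]
  }
  fg <- matrix(0, k, P)
  for (q in seq_len(P)) {
    Pall <- bindingProbability(ef, potentials[[q]])
    if (both) Pall <- Pall + bindingProbability(er, potentials[[q]])
    cs <- c(0, cumsum(Pall))
    fg[, q] <- p * (cs[starts1 + nOff] - cs[starts1])
  }

  # background: R mononucleotide shuffles per window, batched per window
  bg <- matrix(0, k, P)
  for (w in seq_len(k)) {
    if (mask[w]) next
    # shuffled windows are generated once per window (the mutated DNA) and
    # scored by every motif, so profiles are invariant to motif reordering
    perms <- shuffleIndices(seed, w, 1L, R, L)
    wc <- codes[starts1[w]:(starts1[w] + L - 1L)]
    shuf <- matrix(wc[perms], L, R)
    efm <- matrix(0, nOff, R)
    if (both) erm <- matrix(0, nOff, R)
    for (j in seq_len(m)) {
      sub <- shuf[j:(j + nOff - 1L), , drop = FALSE]
      efm <- efm + matrix(e5f[j, sub], nOff, R)
      if (both) erm <- erm + matrix(e5r[j, sub], nOff, R)
    }
    for (q in seq_len(P)) {
      Pm <- bindingProbability(efm, potentials[[q]])
      if (both) Pm <- Pm + bindingProbability(erm, potentials[[q]])
      bg[w, q] <- mean(p * .colSums(Pm, nOff, R))
    }
  }
  fg - bg
}

#' Write / read an affinity profile as a wide TSV
#'
#' Columns: position (0-based window center) and one column per chemical
#' potential; missing values written as "nan". Scan metadata (L, st, motif
#' count, sequence name) is kept in '#'-prefixed header lines so the profile
#' round-trips.
#'
#' @param profile an \linkS4class{AffinityProfile}.
#' @param path output/input file path.
#' @return \code{readProfileTSV} returns an \linkS4class{AffinityProfile};
#'   \code{writeProfileTSV} returns \code{path} invisibly.
#' @export
writeProfileTSV <- function(profile, path) {
  stopifnot(is(profile, "AffinityProfile"))
  hdr <- c(sprintf("#seqname=%s", profile@seqname),
           sprintf("#L=%d", profile@L), sprintf("#st=%d", profile@st),
           sprintf("#nMotifs=%d", profile@nMotifs))
  df <- data.frame(position = profile@centers, profile@values,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  body <- apply(df, 1L, function(r) {
    r[is.na(r)] <- "nan"
    paste(r, collapse = "\t")
  })
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' @rdname writeProfileTSV
#' @export
readProfileTSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^#", key, "="), "", hit[1L]) else default
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", na.strings = "nan",
                           check.names = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  pot <- lapply(colnames(vals), function(nm) {
    if (nm == "boltzmann") chemicalPotential("boltzmann")
    else chemicalPotential("fermi_dirac",
                           as.numeric(sub("^fermi_dirac_mu", "", nm)))
  })
  new("AffinityProfile", seqname = meta("seqname", "seq"),
      centers = as.integer(tab$position), values = vals,
      potentials = data.frame(mode = vapply(pot, `[[`, "", "mode"),
                              mu = vapply(pot, `[[`, 0, "mu")),
      nMotifs = as.integer(meta("nMotifs", "1")),
      L = as.integer(meta("L", "50")), st = as.integer(meta("st", "5")))
}

#' Write an affinity profile as bedGraph files
#'
#' One bedGraph per chemical potential: \code{chrom  center  center+1  value};
#' missing windows are omitted.
#'
#' @param profile an \linkS4class{AffinityProfile}.
#' @param dir output directory.
#' @param prefix file-name prefix (default "ntba").
#' @return paths of the written files, invisibly.
#' @export
writeProfileBedGraph <- function(profile, dir, prefix = "ntba") {
  stopifnot(is(profile, "AffinityProfile"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (q in seq_len(ncol(profile@values))) {
    lab <- colnames(profile@values)[q]
    v <- profile@values[, q]
    keep <- !is.na(v)
    df <- data.frame(chrom = profile@seqname, start = profile@centers[keep],
                     end = profile@centers[keep] + 1L, value = v[keep])
    path <- file.path(dir, sprintf("%s_%s.bedGraph", prefix, lab))
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
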