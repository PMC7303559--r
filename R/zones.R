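#' @importFrom mclust Mclust mclustBIC
NULL

#' Stress curve for choosing the cluster count
#'
#' For each candidate k, a seeded k-means fit gives
#' \deqn{stress(k) = \sqrt{WSS(k)/TSS}}
#' the square root of the within-cluster sum of squares over the total sum of
#' squares around the global centroid; stress(1) = 1 by definition. The
#' selected k is the smallest k whose step to k+1 improves stress by less
#' than \code{elbow} (relative), i.e. the last k before the curve flattens;
#' if the curve never flattens the largest candidate is returned. When
#' reproducing the three-zone classification, k = 3 is forced explicitly by
#' the caller.
#'
#' @param table numeric bins x features matrix.
#' @param ks candidate cluster counts (default 1:6).
#' @param seed integer seed.
#' @param elbow relative-improvement cutoff (default 0.1).
#' @param nstart k-means restarts per k.
#' @return list with \code{stress} (named numeric over ks) and
#'   \code{selected}.
#' @export
stressCurve <- function(table, ks = 1:6, seed = 1L, elbow = 0.1,
                        nstart = 10L) {
  table <- as.matrix(table)
  ks <- sort(unique(as.integer(ks)))
  stopifnot(all(ks >= 1L))
  nDistinct <- nrow(unique(table))
  if (nDistinct < max(ks))
    stop("fewer distinct rows (", nDistinct, ") than clusters (", max(ks), ")")
  tss <- sum(scale(table, scale = FALSE)^2)
  stress <- withSeed(seed, vapply(ks, function(k) {
    if (k == 1L) return(1)
    km <- kmeans(table, centers = k, nstart = nstart, iter.max = 100L)
    sqrt(km$tot.withinss / tss)
  }, 0))
  names(stress) <- ks
  selected <- ks[length(ks)]
  for (idx in seq_len(length(ks) - 1L)) {
    s0 <- stress[idx]; s1 <- stress[idx + 1L]
    if (s0 <= 0 || (s0 - s1) / s0 < elbow) { selected <- ks[idx]; break }
  }
  list(stress = stress, selected = selected)
}

#' Cluster genomic window bins by combined k-means and Gaussian mixture
#'
#' The assignment used for zone classification: (1) a seeded k-means fit
#' gives centroids; (2) each bin's inverse Euclidean distance to every
#' centroid, normalized to sum 1, is a distance-based probability; (3) a
#' Gaussian mixture with the same number of components is fitted to the rows
#' and its posterior gives a second probability, with components matched to
#' the k-means clusters by an optimal centroid-to-mean assignment; (4) the
#' final probability is \code{w * pDist + (1-w) * pMix} and each bin takes
#' the cluster of highest probability (ties to the lower index). A singular
#' mixture fit falls back to diagonal Gaussians estimated from the k-means
#' partition, with variance inflation and a warning.
#'
#' @param table numeric bins x features matrix.
#' @param k number of clusters (default 3).
#' @param w weight on the distance probabilities, in [0, 1] (default 0.5).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return a \linkS4class{ZoneModel}.
#' @export
clusterBins <- function(table, k = 3L, w = 0.5, seed = 1L, nstart = 10L) {
  table <- as.matrix(table)
  k <- as.integer(k)
  stopifnot(k >= 1L, w >= 0, w <= 1)
  n <- nrow(table)
  if (nrow(unique(table)) < k)
    stop("fewer distinct rows than clusters")
  if (k == 1L) {
    ones <- matrix(1, n, 1L)
    return(new("ZoneModel", k = 1L,
               centroids = matrix(colMeans(table), 1L),
               pDist = ones, pMix = ones, w = w, probabilities = ones,
               labels = rep(1L, n)))
  }
  km <- withSeed(seed, kmeans(table, centers = k, nstart = nstart,
                              iter.max = 100L))
  centroids <- km$centers

  # inverse-distance probabilities; epsilon guards bins that sit on a centroid
  d <- vapply(seq_len(k), function(c)
    sqrt(rowSums(sweep(table, 2L, centroids[c, ])^2)), numeric(n))
  inv <- 1 / (1e-12 + d)
  pDist <- inv / rowSums(inv)

  mix <- fitMixture(table, k, km, seed)
  perm <- matchComponents(centroids, mix$means)
  pMix <- mix$z[, perm, drop = FALSE]
  pMix <- pMix / rowSums(pMix)

  prob <- w * pDist + (1 - w) * pMix
  prob <- prob / rowSums(prob)
  labels <- max.col(prob, ties.method = "first")
  new("ZoneModel", k = k, centroids = centroids, pDist = pDist, pMix = pMix,
      w = w, probabilities = prob, labels = as.integer(labels))
}

# Gaussian mixture posterior with a diagonal fallback for singular fits
fitMixture <- function(table, k, km, seed) {
  fit <- withSeed(seed, tryCatch(
    Mclust(table, G = k, verbose = FALSE),
    error = function(e) NULL))
  if (!is.null(fit) && !is.null(fit$z) && !anyNA(fit$z)) {
    means <- t(fit$parameters$mean)       # k x p
    return(list(z = fit$z, means = means))
  }
  warning("singular Gaussian mixture fit; using diagonal components from ",
          "the k-means partition with inflated variances")
  p <- ncol(table)
  means <- km$centers
  vars <- t(vapply(seq_len(k), function(c) {
    rows <- table[km$cluster == c, , drop = FALSE]
    v <- apply(rows, 2L, stats::var)
    v[!is.finite(v) | v < 1e-8] <- 1e-8
    v
  }, numeric(p)))
  wts <- tabulate(km$cluster, k) / nrow(table)
  logd <- vapply(seq_len(k), function(c) {
    rowSums(dnorm(table, mean = matrix(means[c, ], nrow(table), p,
                                       byrow = TRUE),
                  sd = matrix(sqrt(vars[c, ]), nrow(table), p, byrow = TRUE),
                  log = TRUE)) + log(wts[c])
  }, numeric(nrow(table)))
  mx <- apply(logd, 1L, max)
  z <- exp(logd - mx)
  z <- z / rowSums(z)
  list(z = z, means = means)
}

# optimal assignment of mixture components to k-means centroids
# (exhaustive for small k, greedy beyond)
matchComponents <- function(centroids, means) {
  k <- nrow(centroids)
  cost <- vapply(seq_len(k), function(comp)
    sqrt(rowSums(sweep(centroids, 2L, means[comp, ])^2)), numeric(k))
  if (k <= 7L) {
    perms <- permutationsOf(k)
    tot <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(k), p)]))
    perms[which.min(tot), ]
  } else {
    perm <- integer(k)
    left <- seq_len(k)
    for (c in seq_len(k)) {
      best <- left[which.min(cost[c, left])]
      perm[c] <- best
      left <- setdiff(left, best)
    }
    perm
  }
}

permutationsOf <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    cbind(first, rest, deparse.level = 0)
  }))
}

#' Order clusters into zone types by interaction frequency
#'
#' Ranks the k = 3 clusters by the mean intra-chromosomal interaction
#' frequency F_i of their bins, ascending: low, medium and high interaction
#' clusters become types I, II and III — the Inactive, Poised and Active
#' Genomic Zones. An exact tie in mean F_i is broken by the mean F_he over
#' all markers.
#'
#' @param model a \linkS4class{ZoneModel} with k = 3.
#' @param bf the matching \linkS4class{BinFrequencies} (or a numeric F_i
#'   vector).
#' @param cellLine cell-line label.
#' @param resolution bin size in bp recorded on the labels (default 250000).
#' @return a \linkS4class{ZoneLabels}.
#' @export
labelZones <- function(model, bf, cellLine = "NA", resolution = 250000L) {
  stopifnot(is(model, "ZoneModel"))
  if (model@k != 3L) stop("zone labelling requires k = 3 clusters")
  if (is(bf, "BinFrequencies")) {
    fi <- bf@fi
    fheMean <- rowMeans(bf@fhe)
    chrom <- bf@chrom
  } else {
    fi <- as.numeric(bf)
    fheMean <- rep(0, length(fi))
    chrom <- "chr"
  }
  if (length(fi) != length(model@labels))
    stop("F_i must be available for every labeled bin")
  meanFi <- vapply(1:3, function(c) mean(fi[model@labels == c]), 0)
  meanFhe <- vapply(1:3, function(c) mean(fheMean[model@labels == c]), 0)
  ord <- order(meanFi, meanFhe)
  typeOf <- integer(3L)
  typeOf[ord] <- 1:3
  type <- factor(c("I", "II", "III")[typeOf[model@labels]],
                 levels = c("I", "II", "III"))
  new("ZoneLabels", chrom = chrom, resolution = as.integer(resolution),
      type = type, fi = fi, cellLine = cellLine)
}

#' Write zone labels with posterior probabilities
#'
#' BED-like TSV: chrom, start, end (0-based half-open bins), type, zone
#' name, F_i and the per-cluster posterior probabilities.
#'
#' @param zones a \linkS4class{ZoneLabels}.
#' @param model the matching \linkS4class{ZoneModel} (optional).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeZoneTable <- function(zones, model = NULL, path) {
  n <- length(zones@type)
  res <- zones@resolution
  df <- data.frame(chrom = zones@chrom,
                   start = (seq_len(n) - 1L) * res,
                   end = seq_len(n) * res,
                   type = as.character(zones@type),
                   zone = zoneName(zones),
                   fi = zones@fi)
  if (!is.null(model)) {
    pp <- model@probabilities
    colnames(pp) <- paste0("prob", seq_len(ncol(pp)))
    df <- cbind(df, pp)
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
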