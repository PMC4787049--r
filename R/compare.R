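# Comparative proteome analysis: feature scaling, PCA, seeded K-means with
# elbow-based k selection, and per-cluster profiling across organisms.

#' Column-wise z-scaling of a feature matrix
#'
#' Missing cells are imputed as the column mean before scaling (flagged in
#' the \code{"imputed"} attribute); constant columns are dropped with a
#' warning. Sample standard deviation (n - 1) is used.
#'
#' @param x numeric matrix (rows = proteins, columns = features)
#' @return scaled matrix; attributes \code{"center"}, \code{"scale"},
#'   \code{"imputed"} (logical matrix over retained columns)
#' @export
zscale <- function(x) {
  x <- as.matrix(x)
  imputed <- is.na(x)
  for (j in seq_len(ncol(x))) {
    if (any(imputed[, j])) {
      mu <- mean(x[, j], na.rm = TRUE)
      x[imputed[, j], j] <- mu
    }
  }
  sds <- apply(x, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
    imputed <- imputed[, keep, drop = FALSE]
  }
  out <- scale(x)
  res <- out[, , drop = FALSE]
  attr(res, "center") <- attr(out, "scaled:center")
  attr(res, "scale") <- attr(out, "scaled:scale")
  attr(res, "imputed") <- imputed
  res
}

#' Principal component analysis of a scaled feature matrix
#'
#' Eigendecomposition of the sample covariance of the (already centred and
#' scaled) matrix. Components are ordered by decreasing eigenvalue; the sign
#' of each component is fixed so its largest-magnitude loading is positive.
#'
#' @param x scaled matrix (see [zscale()])
#' @return list: \code{scores} (rotated data), \code{loadings},
#'   \code{explained} (variance fractions summing to 1)
#' @export
pcaProps <- function(x) {
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, explained = explained)
}

# k-means++ initial centres (D^2 sampling) from the current RNG stream.
.kmeansPPInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Seeded K-means clustering (k-means++ initialisation, Lloyd iterations)
#'
#' Runs \code{nRestarts} k-means++ initialisations from the stated seed and
#' polishes each with Lloyd iterations (at most \code{maxIter}); the
#' lowest-WCSS restart wins. Nearest-centroid ties resolve to the lowest
#' centroid index. Deterministic given the seed.
#'
#' @param x scaled matrix
#' @param k number of clusters (k <= n)
#' @param seed RNG seed
#' @param nRestarts restarts (default 50)
#' @param maxIter Lloyd iteration cap per restart (default 300)
#' @return list: \code{assignments} (integer per row), \code{centroids},
#'   \code{wcss}
#' @export
kmeansPP <- function(x, k, seed = 42L, nRestarts = 50L, maxIter = 300L) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of rows")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    init <- .kmeansPPInit(x, k)
    init <- init[!duplicated(init), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = maxIter,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(assignments = as.integer(best$cluster),
       centroids = best$centers,
       wcss = best$tot.withinss)
}

#' Choose the number of clusters by the elbow rule
#'
#' With \code{explained(k) = 1 - WCSS(k)/WCSS(1)}, picks the smallest k with
#' \code{explained(k) >= minExplained} and marginal gain
#' \code{explained(k+1) - explained(k) < maxGain}. If no k in range reaches
#' the explained threshold (structureless data), the smallest k whose
#' marginal gain is below \code{maxGain} is returned instead (k = 1 for a
#' single blob); failing both, the largest k in range.
#'
#' @param x scaled matrix
#' @param kRange candidate k values (default 1:8)
#' @param seed RNG seed passed to [kmeansPP()]
#' @param minExplained,maxGain elbow thresholds
#' @return list: \code{k}, \code{explained} (named numeric over the range)
#' @export
chooseKElbow <- function(x, kRange = 1:8, seed = 42L,
                         minExplained = 0.75, maxGain = 0.05) {
  x <- as.matrix(x)
  kRange <- sort(unique(as.integer(kRange)))
  stopifnot(all(kRange >= 1L), max(kRange) <= nrow(x))
  ks <- c(kRange, max(kRange) + 1L)
  ks <- ks[ks <= nrow(x)]
  wcss1 <- sum(scale(x, scale = FALSE)^2)
  wcss <- vapply(ks, function(k) {
    if (k == 1L) wcss1 else kmeansPP(x, k, seed = seed)$wcss
  }, numeric(1))
  explained <- stats::setNames(1 - wcss / wcss1, ks)
  gain <- function(k) {
    i <- match(k, ks)
    if (i + 1L > length(ks)) return(0)
    explained[i + 1L] - explained[i]
  }
  for (k in kRange)
    if (explained[match(k, ks)] >= minExplained && gain(k) < maxGain)
      return(list(k = k, explained = explained[as.character(kRange)]))
  for (k in kRange)
    if (gain(k) < maxGain)
      return(list(k = k, explained = explained[as.character(kRange)]))
  list(k = max(kRange), explained = explained[as.character(kRange)])
}

#' Per-cluster profile report
#'
#' Mean scaled feature values per cluster, organism composition per cluster
#' and cluster distribution per organism.
#'
#' @param assignments integer cluster per row
#' @param x scaled matrix
#' @param organisms organism tag per row
#' @return list: \code{k}, \code{sizes}, \code{featureMeans} (cluster x
#'   feature), \code{organismFractions} (cluster x organism, rows sum to 1),
#'   \code{clusterByOrganism} (organism x cluster, rows sum to 1)
#' @export
clusterProfile <- function(assignments, x, organisms) {
  x <- as.matrix(x)
  stopifnot(length(assignments) == nrow(x),
            length(organisms) == nrow(x))
  ks <- sort(unique(assignments))
  featureMeans <- t(vapply(ks, function(k)
    colMeans(x[assignments == k, , drop = FALSE]), numeric(ncol(x))))
  rownames(featureMeans) <- ks
  tab <- table(assignments, organisms)
  orgFrac <- sweep(tab, 1L, rowSums(tab), `/`)
  byOrg <- sweep(t(tab), 1L, colSums(tab), `/`)
  list(k = length(ks),
       sizes = as.integer(table(factor(assignments, levels = ks))),
       featureMeans = featureMeans,
       organismFractions = as.matrix(orgFrac),
       clusterByOrganism = as.matrix(byOrg))
}

#' Full proteome comparison pipeline
#'
#' z-scales the combined feature matrix, runs PCA, selects k by the elbow
#' rule (unless fixed), clusters with seeded K-means and profiles the
#' clusters by organism.
#'
#' @param x feature matrix with [propertyFeatureNames()] columns
#' @param organisms organism tag per row
#' @param seed RNG seed
#' @param k fixed number of clusters (NULL: elbow-selected)
#' @param kRange candidate range for the elbow rule
#' @return list: \code{scaled}, \code{pca}, \code{k}, \code{assignments},
#'   \code{profile}
#' @export
compareProteomes <- function(x, organisms, seed = 42L, k = NULL,
                             kRange = 1:8) {
  sc <- zscale(x)
  pc <- pcaProps(sc)
  if (is.null(k)) k <- chooseKElbow(sc, kRange = kRange, seed = seed)$k
  km <- kmeansPP(sc, k, seed = seed)
  prof <- clusterProfile(km$assignments, sc, organisms)
  list(scaled = sc, pca = pc, k = k, assignments = km$assignments,
       profile = prof)
}
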