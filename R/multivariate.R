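#' Assemble the autofluorescence shape matrix
#'
#' Truncates each autofluorescence component to a wavelength window
#' (665--775 nm by default, cutting off the divergence of the baseline fit at
#' both spectrum ends) and min-max rescales each spectrum to [0, 1], so that
#' only the *shape* of the emission enters the classification. Constant rows
#' cannot be rescaled and are dropped with a report.
#'
#' @param af_spectra List of [raman_spectrum()] autofluorescence components
#'   on one axis.
#' @param window_nm Length-2 wavelength window in nm.
#' @return Numeric matrix, one row per retained spectrum (rownames are cell
#'   ids); attribute `"dropped"` is a data.frame of rejected rows (or NULL).
#' @export
prepare_af_matrix <- function(af_spectra, window_nm = c(665, 775)) {
  if (!length(af_spectra)) stop("at least one spectrum required")
  ax <- af_spectra[[1L]]$axis
  idx <- axis_window_nm(ax, window_nm)
  if (!length(idx)) stop("window lies outside the axis")
  dropped <- list()
  rows <- list()
  ids <- character(0)
  for (i in seq_along(af_spectra)) {
    s <- af_spectra[[i]]
    if (!axes_identical(ax, s$axis)) stop("spectra must share one axis")
    v <- s$intensities[idx]
    rng <- range(v)
    if (rng[1L] == rng[2L]) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        index = i, cell_id = s$meta$cell_id, reason = "constant spectrum")
      next
    }
    rows[[length(rows) + 1L]] <- (v - rng[1L]) / (rng[2L] - rng[1L])
    ids <- c(ids, s$meta$cell_id)
  }
  if (!length(rows)) stop("all spectra are constant over the window")
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  colnames(m) <- sprintf("%.2f", ax$wavelengths_nm[idx])
  attr(m, "wavelengths_nm") <- ax$wavelengths_nm[idx]
  attr(m, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  m
}

#' Principal component analysis of spectral shapes
#'
#' Mean-centered (unscaled) PCA; rows are already min-max normalized, so no
#' variable scaling is applied.
#'
#' @param m Matrix from [prepare_af_matrix()] (rows = cells).
#' @param n_components Number of components to retain (default 7); clipped
#'   with a warning when it exceeds what the data support.
#' @return List with `scores` (n x k), `loadings` (p x k),
#'   `explained_variance` (fractions, all components), `center`.
#' @export
af_pca <- function(m, n_components = 7L) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("PCA needs at least 2 rows")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k_max <- ncol(pc$x)
  n_components <- as.integer(n_components)
  if (n_components > k_max) {
    warning("n_components clipped from ", n_components, " to ", k_max)
    n_components <- k_max
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance = ev, center = pc$center)
}

# -- X-means ------------------------------------------------------------------

# Lloyd's algorithm with a centroid-movement stop condition
lloyd_kmeans <- function(X, centers, tolerance = 1e-4, max_iter = 200L) {
  k <- nrow(centers)
  n <- nrow(X)
  labels <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist_to_centers(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      in_j <- labels == j
      if (any(in_j)) {
        new_centers[j, ] <- colMeans(X[in_j, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), labels)])
        new_centers[j, ] <- X[far, ]
        labels[far] <- j
      }
    }
    move <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (move < tolerance) break
  }
  d2 <- sq_dist_to_centers(X, centers)
  labels <- max.col(-d2, ties.method = "first")
  list(centers = centers, labels = labels,
       wss = sum(d2[cbind(seq_len(n), labels)]))
}

sq_dist_to_centers <- function(X, centers) {
  # n x k matrix of squared Euclidean distances; clamp the tiny negatives
  # the expansion produces for near-coincident points
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  pmax(outer(xx, cc, `+`) - 2 * X %*% t(centers), 0)
}

# k-means++ seeding
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    for (j in 2:k) {
      d2 <- apply(sq_dist_to_centers(X, centers[seq_len(j - 1L), ,
                                               drop = FALSE]), 1L, min)
      if (sum(d2) == 0) {
        centers[j, ] <- X[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- X[sample.int(n, 1L, prob = d2), ]
      }
    }
  }
  centers
}

# Bayesian information criterion for a spherical-Gaussian k-means model:
# pooled variance sigma^2 = W / (n - k), per-cluster log-likelihood
#   l_j = n_j log n_j - n_j log n - n_j/2 log(2 pi) - n_j d/2 log sigma^2
#         - (n_j - k)/2
# and the parameter penalty p/2 log n charged per cluster, the scoring used
# by the X-means implementations this pipeline emulates; the per-cluster
# penalty is deliberately conservative for smoothly varying spectral shapes
bic_spherical <- function(X, labels, centers) {
  n <- nrow(X)
  d <- ncol(X)
  k <- nrow(centers)
  if (n <= k) return(-Inf)
  W <- sum((X - centers[labels, , drop = FALSE])^2)
  sigma2 <- W / (n - k)
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  nj <- tabulate(labels, nbins = k)
  nj <- nj[nj > 0]
  p <- (k - 1) + k * d + 1
  sum(nj * log(nj) - nj * log(n) - nj / 2 * log(2 * pi) -
        nj * d / 2 * log(sigma2) - (nj - k) / 2) - k * p / 2 * log(n)
}

# deterministic 2-way split seeding: centroid +/- principal direction
split_init <- function(Xj) {
  mu <- colMeans(Xj)
  Xc <- sweep(Xj, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = 1)
  dir <- sv$v[, 1L] * sv$d[1L] / sqrt(nrow(Xj))
  rbind(mu + dir, mu - dir)
}

#' X-means clustering with BIC-scored splitting
#'
#' k-means whose cluster count is chosen by the data: starting from `k_init`
#' clusters, every cluster is tentatively split in two, and a split is kept
#' when the two-cluster Bayesian information criterion (spherical-Gaussian
#' likelihood, Pelleg-Moore formulation) exceeds the one-cluster BIC on that
#' cluster's points. Splitting repeats until no split improves the BIC or
#' `k_max` is reached. Cluster refinement is Lloyd's algorithm with the
#' centroid-movement stop condition `tolerance`.
#'
#' @param scores Numeric matrix of observations (rows), e.g. PC scores.
#' @param k_init Initial cluster count (default 2).
#' @param k_max Maximum cluster count (default 20).
#' @param tolerance Centroid-movement stop condition (default 0.0001).
#' @param seed Optional integer; fixes the k-means++ initialization so the
#'   result is reproducible.
#' @param min_cluster_size Clusters smaller than twice this are never split
#'   (default 2).
#' @return A `cluster_result`: list with `labels` (1..k), `k`, `centroids`,
#'   `bic`, and `params`.
#' @export
xmeans <- function(scores, k_init = 2L, k_max = 20L, tolerance = 1e-4,
                   seed = NULL, min_cluster_size = 2L) {
  X <- as.matrix(scores)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k_init > n) stop("k_init exceeds the number of observations")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  km <- lloyd_kmeans(X, kmeanspp_init(X, k_init), tolerance)
  repeat {
    k <- nrow(km$centers)
    if (k >= k_max) break
    accepted <- list()
    for (j in seq_len(k)) {
      in_j <- km$labels == j
      nj <- sum(in_j)
      if (nj < 2L * min_cluster_size) next
      Xj <- X[in_j, , drop = FALSE]
      parent_bic <- bic_spherical(Xj, rep(1L, nj),
                                  matrix(colMeans(Xj), 1L))
      child <- lloyd_kmeans(Xj, split_init(Xj), tolerance)
      if (length(unique(child$labels)) < 2L) next
      if (min(tabulate(child$labels, 2L)) < min_cluster_size) next
      child_bic <- bic_spherical(Xj, child$labels, child$centers)
      if (child_bic > parent_bic) {
        accepted[[length(accepted) + 1L]] <- child$centers
      } else {
        accepted[[length(accepted) + 1L]] <- km$centers[j, , drop = FALSE]
      }
    }
    # clusters too small to split keep their centroid
    untouched <- setdiff(seq_len(k), which(tabulate(km$labels, k) >=
                                             2L * min_cluster_size))
    centers_new <- do.call(rbind, c(accepted,
                                    lapply(untouched, function(j)
                                      km$centers[j, , drop = FALSE])))
    if (nrow(centers_new) > k_max) {
      centers_new <- centers_new[seq_len(k_max), , drop = FALSE]
    }
    if (nrow(centers_new) == k) break
    km <- lloyd_kmeans(X, centers_new, tolerance)
  }
  structure(
    list(labels = km$labels, k = nrow(km$centers), centroids = km$centers,
         bic = bic_spherical(X, km$labels, km$centers),
         params = list(k_init = k_init, k_max = k_max, tolerance = tolerance,
                       seed = seed, min_cluster_size = min_cluster_size)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, sizes: %s\n", x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Agglomerative hierarchical clustering of spectral shapes
#'
#' Thin wrapper over [stats::hclust()] with validated linkage/metric names
#' and an optional cut.
#'
#' @param m Matrix (rows = observations).
#' @param linkage One of `"ward.D2"`, `"ward.D"`, `"single"`, `"complete"`,
#'   `"average"`, `"mcquitty"`, `"median"`, `"centroid"`.
#' @param metric One of `"euclidean"`, `"maximum"`, `"manhattan"`,
#'   `"canberra"`, `"minkowski"`.
#' @param k Optional number of clusters to cut at.
#' @return List with `hclust` (the dendrogram object), `heights`, and
#'   `labels` (NULL unless `k` given).
#' @export
hcluster <- function(m, linkage = "ward.D2", metric = "euclidean", k = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows")
  linkages <- c("ward.D2", "ward.D", "single", "complete", "average",
                "mcquitty", "median", "centroid")
  metrics <- c("euclidean", "maximum", "manhattan", "canberra", "minkowski")
  if (!linkage %in% linkages) stop("unknown linkage: ", linkage)
  if (!metric %in% metrics) stop("unknown metric: ", metric)
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  list(hclust = hc, heights = hc$height,
       labels = if (!is.null(k)) stats::cutree(hc, k = k) else NULL)
}
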