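#' Pearson correlation distance
#'
#' `d = 1 - r` between rows of a matrix; values lie in [0,2]. Constant rows
#' have no defined correlation and are rejected.
#'
#' @param mat numeric matrix (rows = items, >= 3 columns).
#' @return a `dist` object.
#' @export
pearson_distance <- function(mat) {
  stopifnot(ncol(mat) >= 3L)
  vars <- apply(mat, 1L, stats::var)
  if (any(vars == 0))
    stop(sprintf("zero-variance row(s): %s",
                 paste(rownames(mat)[vars == 0], collapse = ", ")))
  stats::as.dist(1 - stats::cor(t(mat)))
}

#' Hierarchical clustering with Pearson distance and complete linkage
#'
#' @param mat numeric matrix (rows = items).
#' @return an `hclust` tree.
#' @export
hierarchical_cluster <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  stats::hclust(pearson_distance(mat), method = "complete")
}

#' Average silhouette width of a clustering
#'
#' Mean over items of `(b - a) / max(a, b)` where `a` is the mean distance
#' to the item's own cluster and `b` the smallest mean distance to another
#' cluster; singleton clusters contribute 0 for their item.
#'
#' @param labels integer cluster labels.
#' @param d a `dist` object over the same items.
#' @return average silhouette width in [-1, 1].
#' @export
average_silhouette <- function(labels, d) {
  sil <- cluster::silhouette(labels, d)
  mean(sil[, "sil_width"])
}

#' K-means with silhouette-based selection of k
#'
#' Rows are z-scored per transcript by default (clustering expression
#' shapes, not magnitudes). For each candidate k the best of `n_init`
#' k-means starts (squared Euclidean) is kept; the chosen k maximizes the
#' average silhouette width (ties to the smallest k). Deterministic given
#' `seed`.
#'
#' @param mat numeric matrix (rows = items).
#' @param k_range candidate k values within `[2, nrow - 1]`; values with
#'   `k >= nrow(mat)` are skipped with a warning.
#' @param n_init number of random starts per k (default 10).
#' @param seed integer seed.
#' @param standardize z-score rows first (default TRUE).
#' @return list with `k` (chosen), `labels` (for chosen k),
#'   `silhouette` (named vector of average widths per candidate k),
#'   and `centers`.
#' @export
kmeans_silhouette <- function(mat, k_range = 2:8, n_init = 10L, seed = 1L,
                              standardize = TRUE) {
  if (standardize) {
    mat <- t(apply(mat, 1L, function(r) {
      s <- stats::sd(r)
      if (s == 0) stop("zero-variance row cannot be standardized")
      (r - mean(r)) / s
    }))
  }
  keep <- k_range[k_range >= 2L & k_range < nrow(mat)]
  if (length(keep) < length(k_range))
    warning("skipping k values outside [2, nrow - 1]")
  if (length(keep) == 0L) stop("no valid k in k_range")
  d <- stats::dist(mat)
  fits <- list(); widths <- stats::setNames(numeric(length(keep)),
                                            as.character(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    set.seed(seed + k)
    fit <- stats::kmeans(mat, centers = k, nstart = n_init, iter.max = 100L)
    fits[[i]] <- fit
    widths[i] <- average_silhouette(fit$cluster, d)
  }
  best <- which(widths == max(widths))[1L]  # ties -> smallest k
  list(k = keep[best], labels = fits[[best]]$cluster,
       silhouette = widths, centers = fits[[best]]$centers)
}
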