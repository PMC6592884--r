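#' Partition records into thermal regimes by 1-D K-means on WT
#'
#' Lloyd's algorithm on the water-temperature column only, with k-means++
#' seeding and multiple restarts. Clustering is one-dimensional by design:
#' the regimes of interest (diatom, transition, cyanobacteria communities)
#' are defined by non-overlapping WT ranges, and optimal 1-D K-means
#' clusters are contiguous intervals of the sorted values. Iterations run to
#' an assignment fixed point (or `max_iter`); the best of `restarts`
#' initializations by lowest within-cluster sum of squares is kept, and
#' clusters are relabeled so cluster 1 has the lowest centroid.
#'
#' @param data Monitoring table (only the `WT` column is used).
#' @param k Number of clusters (>= 1; at most the number of distinct WT
#'   values).
#' @param seed Integer seed controlling the k-means++ initializations.
#' @param restarts Number of seeded restarts, default 10.
#' @param max_iter Iteration cap per restart, default 300.
#' @return A `wt_partition`: list with `k`, ascending `centroids`, integer
#'   `labels` (one per row), the converged `objective` (within-cluster sum
#'   of squared distances), `sizes`, and `iterations` of the winning
#'   restart.
#' @examples
#' sim <- simulate_monitoring(goryung_config(n_days = 120, seed = 3))
#' part <- kmeans_wt(sim$data, k = 3, seed = 1)
#' tidy(part)
#' @export
kmeans_wt <- function(data, k, seed = 1, restarts = 10, max_iter = 300) {
  x <- if (is.data.frame(data)) data$WT else as.numeric(data)
  if (is.null(x)) {
    stopf("`data` must contain a `WT` column.",
          class = "bloomregime_contract_error")
  }
  k <- as.integer(k)
  n_distinct <- length(unique(x))
  if (k < 1) stopf("`k` must be >= 1.", class = "bloomregime_config_error")
  if (k > n_distinct) {
    stopf("k = %d exceeds the %d distinct WT values: infeasible.",
          k, n_distinct, class = "bloomregime_infeasible_error")
  }

  # Restarts run on the sorted values so the result depends on the data only
  # through its multiset (row order never matters). Restart 0 is a
  # deterministic quantile seeding; the rest are seeded k-means++.
  xs <- sort(x)
  inits <- c(
    list(stats::quantile(xs, probs = (seq_len(k) - 0.5) / k, names = FALSE)),
    lapply(seq_len(restarts), function(r) {
      with_seed(seed + r - 1L, kpp_init(xs, k))
    })
  )
  best <- NULL
  for (centers in inits) {
    fit <- lloyd_1d(xs, centers, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }

  centroids <- sort(best$centers)
  d <- abs(outer(x, centroids, "-"))
  labels <- max.col(-d, ties.method = "first")
  structure(
    list(
      k = k,
      centroids = centroids,
      labels = labels,
      objective = sum((x - centroids[labels])^2),
      sizes = tabulate(labels, nbins = k),
      iterations = best$iterations
    ),
    class = "wt_partition"
  )
}

# k-means++ seeding in 1-D: first centre uniform, then proportional to
# squared distance from the nearest chosen centre.
kpp_init <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(x, function(v) min((v - centers[seq_len(j - 1)])^2),
                   numeric(1))
      if (all(d2 == 0)) {
        centers[j] <- x[sample.int(length(x), 1)]
      } else {
        centers[j] <- x[sample.int(length(x), 1, prob = d2)]
      }
    }
  }
  centers
}

# Lloyd iterations in 1-D with empty-cluster repair: an empty centroid is
# re-seeded at the point farthest from its current assignment's centroid.
lloyd_1d <- function(x, centers, max_iter) {
  k <- length(centers)
  labels <- rep(0L, length(x))
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    d <- abs(outer(x, centers, "-"))
    new_labels <- max.col(-d, ties.method = "first")
    for (j in which(tabulate(new_labels, nbins = k) == 0)) {
      far <- which.max(abs(x - centers[new_labels]))
      new_labels[far] <- j
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    centers <- vapply(seq_len(k), function(j) mean(x[labels == j]), numeric(1))
  }
  list(centers = centers, labels = labels,
       objective = sum((x - centers[labels])^2),
       iterations = iterations)
}

#' Assign water temperatures to the nearest cluster
#'
#' Ties at the exact midpoint of two centroids break toward the lower
#' cluster id (the colder regime).
#'
#' @param partition A `wt_partition` from [kmeans_wt()].
#' @param wt Numeric vector of water temperatures (deg C).
#' @return Integer vector of cluster ids in `1:partition$k`.
#' @export
assign_cluster <- function(partition, wt) {
  stopifnot(inherits(partition, "wt_partition"))
  d <- abs(outer(as.numeric(wt), partition$centroids, "-"))
  max.col(-d, ties.method = "first")
}

#' @export
print.wt_partition <- function(x, ...) {
  cat(sprintf("WT partition: K = %d, objective = %.4g\n", x$k, x$objective))
  cat("centroids (deg C):", paste(sprintf("%.2f", x$centroids), collapse = ", "),
      "\n")
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wt_partition <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    centroid = x$centroids,
    n = x$sizes
  )
}

#' @exportS3Method generics::glance
glance.wt_partition <- function(x, ...) {
  tibble::tibble(k = x$k, objective = x$objective, iterations = x$iterations)
}

#' Serialize / restore a WT partition as JSON
#'
#' @param partition A `wt_partition`.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_partition()` returns the restored object.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(unclass(partition), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(k = as.integer(obj$k), centroids = as.numeric(obj$centroids),
         labels = as.integer(obj$labels), objective = as.numeric(obj$objective),
         sizes = as.integer(obj$sizes), iterations = as.integer(obj$iterations)),
    class = "wt_partition"
  )
}
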