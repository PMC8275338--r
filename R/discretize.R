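#' Binarize real-valued expression by per-gene 2-means clustering
#'
#' Each gene's values across all experiments are partitioned into two
#' clusters by 1-D k-means (k = 2); experiments in the higher-mean cluster
#' are assigned 1 ("on"), the rest 0. Each column is clustered with
#' `restarts` random centroid initializations (centers drawn from the
#' distinct observed values) and the partition with the lowest
#' within-cluster sum of squares is kept; equal-SSE ties break toward the
#' partition with the lower split threshold. Zero-variance genes carry no
#' evidence of activity and map to all-0 (with a warning).
#'
#' @param x an [expression_dataset()] carrying a real-valued matrix, or a
#'   numeric matrix (experiments x genes).
#' @param seed optional integer; controls centroid initialization (the
#'   caller's RNG state is restored afterwards).
#' @param restarts number of random centroid initializations per gene.
#' @return Same shape as the input: a dataset whose `bool` slot is filled
#'   in, or an integer 0/1 matrix.
#' @export
binarize <- function(x, seed = NULL, restarts = 10) {
  if (inherits(x, "expression_dataset")) {
    if (is.null(x$real)) stop("dataset carries no real-valued matrix")
    x$bool <- binarize(x$real, seed = seed, restarts = restarts)
    return(x)
  }
  x <- as.matrix(x)
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty expression matrix")
  if (nrow(x) < 2) stop("need at least two experiments to cluster")
  if (anyNA(x)) stop("missing values are not supported")
  out <- with_seed(seed, {
    apply(x, 2, binarize_column, restarts = restarts)
  })
  out <- matrix(as.integer(out), nrow = nrow(x), dimnames = dimnames(x))
  out
}

binarize_column <- function(v, restarts) {
  ux <- sort(unique(v))
  if (length(ux) == 1) {
    warning("zero-variance gene mapped to all 0")
    return(rep(0L, length(v)))
  }
  if (length(ux) == 2) return(as.integer(v == ux[2]))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- sample(ux, 2)
    km <- tryCatch(
      suppressWarnings(kmeans(v, centers = matrix(sort(centers)), iter.max = 50)),
      error = function(e) NULL)
    if (is.null(km)) next
    hi <- which.max(km$centers)
    bits <- as.integer(km$cluster == hi)
    thr <- max(v[bits == 0L])
    cand <- list(sse = km$tot.withinss, thr = thr, bits = bits)
    if (is.null(best) || cand$sse < best$sse - 1e-12 ||
        (abs(cand$sse - best$sse) <= 1e-12 && cand$thr < best$thr))
      best <- cand
  }
  if (is.null(best)) stop("k-means failed on a column")  # unreachable in practice
  best$bits
}
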