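#' Census of a Vietoris-Rips complex over a point cloud
#'
#' Builds the Vietoris-Rips complex at distance threshold `epsilon` (closed
#' ball: a pair of points is linked when their Euclidean distance is `<=`
#' `epsilon`) and counts the simplexes of each dimension `k = 0, ..., K`.
#' A VR `k`-simplex is exactly a `(k+1)`-clique of the epsilon-neighborhood
#' graph, so the census is a vertex / edge / triangle (and, for `K = 3`,
#' 4-clique) count. Alongside the raw counts `rho_k` the census stores the
#' maxima `rho_k^m = choose(P, k+1)` and the realized fractions
#' `S_k = rho_k / rho_k^m`.
#'
#' Duplicate points are distinct vertices (their distance 0 is always within
#' `epsilon`). Distance comparisons are performed on squared distances, so no
#' square root is taken; ties at exactly `epsilon` are included.
#'
#' @param cloud A [point_cloud][delay_embed] (or a bare numeric matrix of
#'   points, one row per point).
#' @param epsilon Positive, finite distance threshold, in the units of the
#'   points. See [epsilon_from_factor()] to derive it from the source series'
#'   standard deviation.
#' @param K Maximum simplex dimension to count: 1, 2 (default) or 3.
#'
#' @return A `simplex_census` object with fields `P`, `epsilon`, `K`,
#'   `rho` (named numeric, dimensions `0..K`), `rho_max`, and `S`.
#'
#' @examples
#' cl <- delay_embed(rnorm(200), d = 2)
#' vr_census(cl, epsilon = 0.1 * cl$source_sd)
#' @export
vr_census <- function(cloud, epsilon, K = 2) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (is.null(dim(pts)) || nrow(pts) == 0) {
    stop("empty point cloud", call. = FALSE)
  }
  if (length(epsilon) != 1 || !is.finite(epsilon) || epsilon <= 0) {
    stop("invalid epsilon: must be a single finite positive number", call. = FALSE)
  }
  if (!K %in% 1:3) {
    stop("`K` must be 1, 2 or 3", call. = FALSE)
  }
  rho <- .census_counts(pts, epsilon, as.integer(K))
  new_simplex_census(P = nrow(pts), rho = rho, epsilon = epsilon, K = as.integer(K))
}

#' Build a simplex census directly from counts
#'
#' Assembles a `simplex_census` from already-known simplex counts, e.g. a
#' census read off a published figure, without access to the underlying
#' point cloud. Maxima and realized fractions are derived from `P`.
#'
#' @param P Number of points (0-simplexes).
#' @param rho Numeric vector of simplex counts for dimensions `1..K`
#'   (dimension 0 is always `P`).
#' @param epsilon Optional threshold to record; `NA` when unknown.
#'
#' @return A `simplex_census`.
#' @examples
#' census_from_counts(P = 10, rho = c(10, 2))
#' @export
census_from_counts <- function(P, rho, epsilon = NA_real_) {
  K <- length(rho)
  if (K < 1 || K > 3) stop("`rho` must cover dimensions 1..K with K in 1:3", call. = FALSE)
  new_simplex_census(P = P, rho = c(P, rho), epsilon = epsilon, K = K)
}

new_simplex_census <- function(P, rho, epsilon, K) {
  k <- 0:K
  rho <- as.numeric(rho)
  rho_max <- choose(P, k + 1)
  if (any(rho < 0) || any(rho > rho_max)) {
    stop("simplex counts must satisfy 0 <= rho_k <= choose(P, k+1)", call. = FALSE)
  }
  S <- ifelse(rho_max > 0, rho / rho_max, 0)
  names(rho) <- names(rho_max) <- names(S) <- as.character(k)
  structure(
    list(P = P, epsilon = epsilon, K = K, rho = rho, rho_max = rho_max, S = S),
    class = "simplex_census"
  )
}

#' Distance threshold as a factor of the source series' standard deviation
#'
#' The tolerance convention ties `epsilon` to the (population) standard
#' deviation of the original, scale-1 series: `epsilon = factor * SD`. The SD
#' is the one stored in the cloud at embedding time, so coarse-grained
#' subseries inherit the tolerance of the series they came from.
#'
#' @param cloud A [point_cloud][delay_embed].
#' @param factor Positive multiplier (0.1 is the conventional default).
#'
#' @return The absolute threshold `factor * source_sd`.
#' @export
epsilon_from_factor <- function(cloud, factor = 0.1) {
  stopifnot(inherits(cloud, "point_cloud"), is.numeric(factor), factor > 0)
  if (cloud$source_sd <= 0) {
    stop("constant series: epsilon undefined via SD factor", call. = FALSE)
  }
  factor * cloud$source_sd
}

#' @export
print.simplex_census <- function(x, ...) {
  cat(sprintf("<simplex_census> P = %d, epsilon = %.4g, K = %d\n", x$P, x$epsilon, x$K))
  print(tidy(x))
  invisible(x)
}

#' Tidy a simplex census into a tibble
#'
#' @param x A `simplex_census`.
#' @param ... Unused.
#' @return A tibble with columns `k`, `rho`, `rho_max`, `S`.
#' @exportS3Method generics::tidy
#' @export
tidy.simplex_census <- function(x, ...) {
  tibble::tibble(
    k = 0:x$K,
    rho = unname(x$rho),
    rho_max = unname(x$rho_max),
    S = unname(x$S)
  )
}
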