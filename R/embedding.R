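#' Delay-embed a time series into a point cloud
#'
#' Maps a scalar series `x(1), ..., x(N)` to the `d`-dimensional point cloud
#' of consecutive-sample patterns `(x(j), x(j+1), ..., x(j+d-1))` for
#' `j = 1, ..., N - d + 1` (unit lag). The population standard deviation of
#' the input series is stored alongside the points so that distance tolerances
#' can later be expressed as a fraction of it (see [epsilon_from_factor()]).
#'
#' @param x Numeric vector, the time series. All values must be finite.
#' @param d Embedding dimension, a positive integer with `d <= length(x)`.
#'
#' @return A `point_cloud` object: a list with `points` (a
#'   `(N - d + 1) x d` numeric matrix), `d`, and `source_sd` (population SD
#'   of `x`, i.e. divisor `N`).
#'
#' @examples
#' delay_embed(c(1, 2, 3, 4), d = 2)
#' @export
delay_embed <- function(x, d = 2) {
  x <- as.numeric(x)
  if (length(x) == 0 || !all(is.finite(x))) {
    stop("series must be non-empty with all values finite", call. = FALSE)
  }
  if (length(d) != 1 || d < 1 || d != round(d)) {
    stop("`d` must be a single positive integer", call. = FALSE)
  }
  if (length(x) < d) {
    stop("series too short for embedding: N < d", call. = FALSE)
  }
  d <- as.integer(d)
  # stats::embed() returns columns in reverse time order; flip to (x_j, ..., x_{j+d-1})
  pts <- stats::embed(x, dimension = d)[, d:1, drop = FALSE]
  new_point_cloud(pts, d, pop_sd(x))
}

new_point_cloud <- function(points, d, source_sd) {
  structure(
    list(points = points, d = d, source_sd = source_sd),
    class = "point_cloud"
  )
}

# population standard deviation (divisor N, not N-1)
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf(
    "<point_cloud> %d points in %d dimensions (source SD %.4g)\n",
    nrow(x$points), x$d, x$source_sd
  ))
  invisible(x)
}

#' @export
dim.point_cloud <- function(x) dim(x$points)
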