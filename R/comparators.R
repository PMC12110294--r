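#' Sample entropy
#'
#' Classical sample entropy `-ln(A/B)`: `B` counts unordered pairs of
#' distinct length-`m` templates whose Chebyshev (max-norm) distance is
#' within the tolerance, `A` the same for length-`m+1` templates;
#' self-matches are excluded and both counts run over the same `N - m*lag`
#' template start positions. Natural logarithm, following the SampEn
#' convention.
#'
#' @param x Numeric vector, the time series (length > `m + 1`).
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a fraction of the population SD of `x`
#'   (default 0.15); ignored when `tolerance` is given.
#' @param tolerance Absolute tolerance; overrides `r_factor`.
#' @param lag Stride between template elements (default 1; lag `tau` serves
#'   the moving-average multiscale variant).
#'
#' @return The entropy value, or `NA` when no template pairs match at either
#'   length (undefined).
#'
#' @examples
#' sampen(gen_white(300, seed = 1))
#' @export
sampen <- function(x, m = 2, r_factor = 0.15, tolerance = NULL, lag = 1) {
  x <- as.numeric(x)
  stopifnot(m >= 1, lag >= 1)
  if (length(x) < m + 2) stop("series too short", call. = FALSE)
  if (is.null(tolerance)) {
    stopifnot(r_factor > 0)
    tolerance <- r_factor * pop_sd(x)
  }
  if (tolerance <= 0) return(NA_real_)
  cnt <- .sampen_counts(x, as.integer(m), tolerance, as.integer(lag))
  B <- cnt[1]; A <- cnt[2]
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

#' Multiscale entropy (MSE) profile
#'
#' The SampEn-based multiscale baseline: at each scale `tau` the series is
#' reduced to non-overlapping window means (the single offset-1
#' coarse-grained subseries, length `floor(N / tau)`) and SampEn is computed
#' with the tolerance fixed from the scale-1 series' population SD.
#'
#' @inheritParams sampen
#' @param tau_max Largest scale factor (default 20).
#'
#' @return A `scale_profile` (method `"MSE"`, `k = NA`); scales where SampEn
#'   is undefined (no template matches) carry `entropy = NA`.
#'
#' @examples
#' mse(gen_white(1000, seed = 1), tau_max = 5)
#' @export
mse <- function(x, tau_max = 20, m = 2, r_factor = 0.15) {
  x <- as.numeric(x)
  stopifnot(all(is.finite(x)), tau_max >= 1)
  tol <- r_factor * pop_sd(x)
  rows <- purrr::map(seq_len(tau_max), function(tau) {
    sub <- coarse_grain(x, tau)[[1]]
    val <- if (length(sub) >= m + 2) sampen(sub, m = m, tolerance = tol) else NA_real_
    sampen_profile_row(tau, val)
  })
  new_scale_profile(dplyr::bind_rows(rows), method = "MSE",
                    params = list(m = m, r_factor = r_factor,
                                  tau_max = tau_max, n = length(x)))
}

#' Modified multiscale entropy (MMSE) profile
#'
#' The moving-average multiscale baseline: at each scale `tau` the series is
#' smoothed by a stride-1 moving average of window `tau` (length
#' `N - tau + 1`, so the series barely shortens with scale), and SampEn is
#' computed on the smoothed series with templates taken at lag `tau`
#' (`template_lag = "tau"`, the default) or at lag 1, tolerance fixed from
#' the scale-1 SD.
#'
#' @inheritParams mse
#' @param template_lag `"tau"` (default) or `"one"`: stride between SampEn
#'   template elements on the smoothed series.
#'
#' @return A `scale_profile` (method `"MMSE"`, `k = NA`).
#' @export
mmse <- function(x, tau_max = 20, m = 2, r_factor = 0.15,
                 template_lag = c("tau", "one")) {
  x <- as.numeric(x)
  template_lag <- match.arg(template_lag)
  stopifnot(all(is.finite(x)), tau_max >= 1)
  tol <- r_factor * pop_sd(x)
  rows <- purrr::map(seq_len(tau_max), function(tau) {
    sub <- moving_average(x, tau)
    lag <- if (template_lag == "tau") tau else 1L
    val <- if (length(sub) >= m * lag + 2) {
      sampen(sub, m = m, tolerance = tol, lag = lag)
    } else NA_real_
    sampen_profile_row(tau, val)
  })
  new_scale_profile(dplyr::bind_rows(rows), method = "MMSE",
                    params = list(m = m, r_factor = r_factor, tau_max = tau_max,
                                  template_lag = template_lag, n = length(x)))
}

sampen_profile_row <- function(tau, val) {
  tibble::tibble(scale = as.integer(tau), k = NA_integer_, entropy = val,
                 se = NA_real_, n_defined = as.integer(!is.na(val)),
                 n_subseries = 1L, defined = !is.na(val))
}

# stride-1 moving average of window tau; length N - tau + 1
moving_average <- function(x, tau) {
  if (tau == 1) return(x)
  as.numeric(stats::filter(x, rep(1 / tau, tau), sides = 1))[tau:length(x)]
}
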