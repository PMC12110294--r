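#' Composite coarse-graining of a time series
#'
#' For a scale factor `tau`, builds the `tau` coarse-grained subseries
#' `y_r(j) = mean(x((j-1)*tau + r), ..., x(j*tau + r - 1))`, one per window
#' offset r = 1, ..., tau. The index `j` runs while the window fits, so
#' subseries r has `floor((N - r + 1) / tau)` points; every full window of
#' the data is used and each raw sample enters at most one window per offset.
#'
#' @param x Numeric vector, the time series.
#' @param tau Positive integer scale factor, `tau <= length(x)`.
#'
#' @return A list of `tau` numeric vectors (subseries for each offset r),
#'   with attribute `tau`.
#'
#' @examples
#' coarse_grain(c(1, 2, 3, 4), tau = 2)  # list(c(1.5, 3.5), 2.5)
#' @export
coarse_grain <- function(x, tau) {
  x <- as.numeric(x)
  n <- length(x)
  if (length(tau) != 1 || tau < 1 || tau != round(tau)) {
    stop("`tau` must be a single positive integer", call. = FALSE)
  }
  if (tau > n) stop("scale exceeds series length", call. = FALSE)
  tau <- as.integer(tau)
  out <- vector("list", tau)
  for (r in seq_len(tau)) {
    w <- (n - r + 1L) %/% tau
    if (w == 0L) {
      out[[r]] <- numeric(0)
    } else {
      out[[r]] <- colMeans(matrix(x[r:(r + w * tau - 1L)], nrow = tau))
    }
  }
  attr(out, "tau") <- tau
  out
}

#' Multiscale simplicial complex approximate entropy profile
#'
#' Computes the composite multiscale SCAE profile of a series: for each scale
#' `tau = 1, ..., tau_max` the series is coarse-grained into its `tau` offset
#' subseries, each subseries is delay-embedded with dimension `d` and given a
#' Vietoris-Rips census at the tolerance `eps_factor` times the population SD
#' of the *original* scale-1 series, and the scale's entropy is the mean of
#' the `tau` per-subseries SCAE values. Fixing the tolerance from the
#' original series (rather than re-scaling it per subseries) is what lets the
#' profile register the variance loss that coarse-graining inflicts on
#' uncorrelated noise.
#'
#' A scale's mean is undefined (NA, `defined = FALSE`) when any of its
#' subseries yields an undefined entropy — one zero simplex count poisons the
#' averaged log — unless `strict = FALSE`, in which case the mean is taken
#' over the defined subseries only (exploratory use).
#'
#' Long records are split into two non-overlapping leading segments of
#' `segment_length` values when `length(x) >= 2 * segment_length`; per-segment
#' profiles are computed (each with its own scale-1 SD) and their subseries
#' entropies pooled. Set `segment_length = Inf` to disable.
#'
#' @param x Numeric vector, the time series.
#' @param k Simplex dimension(s) of the entropy, a subset of `0:2`;
#'   profiles for all requested `k` are computed from a single census per
#'   subseries. Default `0`.
#' @param tau_max Largest scale factor (default 20).
#' @param d Embedding dimension (default 2).
#' @param eps_factor Tolerance as a fraction of the scale-1 population SD
#'   (default 0.1).
#' @param log_base Base of the entropy logarithm (default 10; see [scae()]).
#' @param segment_length Segment size for the long-record protocol
#'   (default 10000).
#' @param strict If `TRUE` (default) a scale with any undefined subseries is
#'   undefined.
#'
#' @return A `scale_profile`: a tibble with columns `scale`, `k`, `entropy`,
#'   `se` (standard error over subseries), `n_defined`, `n_subseries`,
#'   `defined`; attributes `method = "MS-SCAE"` and `params`.
#'
#' @examples
#' x <- gen_white(512, seed = 1)
#' ms_scae(x, k = 0, tau_max = 5)
#' @export
ms_scae <- function(x, k = 0, tau_max = 20, d = 2, eps_factor = 0.1,
                    log_base = 10, segment_length = 10000, strict = TRUE) {
  x <- as.numeric(x)
  stopifnot(all(is.finite(x)), all(k %in% 0:2), tau_max >= 1, eps_factor > 0)
  if (length(x) < d + tau_max) {
    stop("series too short for the requested tau_max and d", call. = FALSE)
  }
  segs <- split_segments(x, segment_length)
  K <- max(k) + 1L

  rows <- purrr::map(seq_len(tau_max), function(tau) {
    # per-subseries entropy values pooled over segments, one row per k
    vals <- purrr::map(segs, function(seg) {
      sd1 <- pop_sd(seg)
      cg <- coarse_grain(seg, tau)
      purrr::map(cg, function(sub) subseries_scae(sub, k, d, eps_factor * sd1,
                                                  K, log_base, sd1))
    })
    vals <- purrr::flatten(vals) # list over subseries of named numeric per k
    purrr::map(k, function(kk) {
      v <- purrr::map_dbl(vals, kk + 1L)
      summarize_scale(tau, kk, v, strict)
    })
  })
  prof <- dplyr::bind_rows(purrr::flatten(rows))
  new_scale_profile(prof, method = "MS-SCAE",
                    params = list(d = d, eps_factor = eps_factor,
                                  log_base = log_base, tau_max = tau_max,
                                  segment_length = segment_length,
                                  strict = strict, n = length(x),
                                  n_segments = length(segs)))
}

# entropy values (one per k) of a single coarse-grained subseries;
# NA with attr reason when too short, constant source, or zero counts
subseries_scae <- function(sub, k, d, eps, K, log_base, sd1) {
  if (length(sub) < d || sd1 <= 0 || eps <= 0) {
    return(rep(NA_real_, max(k) + 1L))
  }
  cen <- vr_census(delay_embed(sub, d), epsilon = eps, K = K)
  vapply(0:max(k), function(kk) scae_value(cen$S, kk, log_base), numeric(1))
}

summarize_scale <- function(tau, kk, v, strict) {
  n_def <- sum(!is.na(v))
  ent <- if (n_def == 0 || (strict && n_def < length(v))) NA_real_ else mean(v, na.rm = TRUE)
  se <- if (n_def >= 2) stats::sd(v[!is.na(v)]) / sqrt(n_def) else NA_real_
  tibble::tibble(scale = as.integer(tau), k = as.integer(kk), entropy = ent,
                 se = se, n_defined = n_def, n_subseries = length(v),
                 defined = !is.na(ent))
}

split_segments <- function(x, segment_length) {
  n <- length(x)
  if (is.finite(segment_length) && n >= 2 * segment_length) {
    L <- as.integer(segment_length)
    list(x[1:L], x[(L + 1):(2L * L)])
  } else {
    list(x)
  }
}

new_scale_profile <- function(df, method, params) {
  structure(
    tibble::new_tibble(df, method = method, params = params,
                       class = "scale_profile"),
    class = c("scale_profile", class(tibble::tibble())))
}

#' Largest scale at which a profile remains estimable
#'
#' The maximum estimable scale is the largest `tau` such that the profile's
#' mean entropy is defined at *every* scale `1..tau`; `NA` when already
#' undefined at `tau = 1`. For multiscale SCAE this operationalizes "can be
#' estimated" as all subseries having nonzero simplex counts up to that
#' scale; for SampEn-based profiles, as nonzero template-match counts.
#'
#' @param profile A [scale_profile][ms_scae].
#' @param k Simplex dimension to extract when the profile holds several;
#'   defaults to all present.
#'
#' @return A named integer vector, one element per `k` (names are the `k`
#'   values; unnamed scalar when a single `k` is present). `NA` means not
#'   estimable even at scale 1.
#' @export
max_estimable_scale <- function(profile, k = NULL) {
  stopifnot(inherits(profile, "scale_profile"))
  ks <- if (is.null(k)) sort(unique(profile$k), na.last = TRUE) else k
  out <- vapply(ks, function(kk) {
    d <- profile[profile$k %in% kk | (is.na(kk) & is.na(profile$k)), ]
    d <- d[order(d$scale), ]
    ok <- cumprod(as.integer(d$defined))
    if (!any(ok == 1)) NA_integer_ else as.integer(max(d$scale[ok == 1]))
  }, integer(1))
  if (length(ks) == 1) return(unname(out))
  names(out) <- as.character(ks)
  out
}

#' @export
print.scale_profile <- function(x, ...) {
  cat(sprintf("<scale_profile> method %s, scales 1..%d\n",
              attr(x, "method"), max(x$scale)))
  NextMethod()
}

#' Tidy / summarize scale profiles
#'
#' `tidy()` returns the per-scale table as a plain tibble; `glance()` returns
#' a one-row summary with the method, its parameters and the maximum
#' estimable scale per `k`.
#'
#' @param x A `scale_profile`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.scale_profile <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.scale_profile
#' @exportS3Method generics::glance
#' @export
glance.scale_profile <- function(x, ...) {
  p <- attr(x, "params")
  ks <- sort(unique(x$k))
  mes <- max_estimable_scale(x)
  tibble::tibble(
    method = attr(x, "method"),
    tau_max = max(x$scale),
    k = paste(ks, collapse = ","),
    max_estimable_scale = paste(mes, collapse = ","),
    params = list(p)
  )
}

#' Export a scale profile to CSV
#'
#' Writes the per-scale table (columns `scale`, `k`, `entropy`, `se`,
#' `n_defined`, `n_subseries`, `defined`).
#'
#' @param profile A `scale_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(tidy(profile), path, row.names = FALSE)
  invisible(path)
}

#' Export a scale profile to JSON
#'
#' @param profile A `scale_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  obj <- list(method = attr(profile, "method"),
              params = attr(profile, "params"),
              profile = tidy(profile))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
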