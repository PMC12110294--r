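#' Seeded Gaussian white noise
#'
#' I.i.d. standard Gaussian draws; with a `seed`, the generator is a pure
#' function of `(n, seed)` and the global RNG state is left untouched.
#'
#' @param n Series length (`n >= 1`).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_white <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_local_seed(seed, rnorm(n))
}

#' Seeded 1/f (power-law) noise by spectral synthesis
#'
#' Draws complex Gaussian Fourier coefficients, scales the amplitude at
#' frequency `f` by `f^(-beta/2)` (so the power spectral density falls off
#' as `1/f^beta`), zeroes the DC component, enforces Hermitian symmetry,
#' inverse-transforms, and standardizes the result to zero mean and unit
#' population SD. `beta = 1` gives classical 1/f ("pink") noise with
#' long-range correlations; `beta = 0` reduces to white noise.
#'
#' @param n Series length (`n >= 16`).
#' @param beta Spectral exponent (`>= 0`, default 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`, standardized.
#' @export
gen_one_over_f <- function(n, beta = 1, seed = NULL) {
  stopifnot(n >= 16, beta >= 0)
  with_local_seed(seed, {
    half <- n %/% 2
    spec <- complex(real = rep(0, n))
    # positive frequencies 1..half (index k+1 holds frequency k)
    amp <- (1:half)^(-beta / 2)
    re <- rnorm(half) * amp / sqrt(2)
    im <- rnorm(half) * amp / sqrt(2)
    if (n %% 2 == 0) im[half] <- 0  # Nyquist bin must be real
    spec[2:(half + 1)] <- complex(real = re, imaginary = im)
    # Hermitian symmetry for a real-valued inverse transform; DC stays 0
    neg <- (half + 2):n
    spec[neg] <- Conj(spec[n - neg + 2])
    x <- Re(fft(spec, inverse = TRUE)) / n
    (x - mean(x)) / pop_sd(x)
  })
}

#' Shuffled surrogate of a series
#'
#' Uniform random permutation of the values: the value multiset (hence mean,
#' SD, full distribution) is preserved exactly while all temporal
#' correlations are destroyed. Multiscale entropy profiles of surrogates of
#' correlated series collapse onto the white-noise shape.
#'
#' @param x Numeric vector.
#' @param seed Optional integer seed.
#' @return Permuted copy of `x`.
#' @export
shuffle_surrogate <- function(x, seed = NULL) {
  with_local_seed(seed, x[sample.int(length(x))])
}

# run expr under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Read an RR-interval record from a plain-text file
#'
#' Parses interbeat (RR) interval exports: either one interval per line
#' (seconds), or two whitespace-separated columns (beat time, RR interval)
#' of which the second is used. Lines that fail to parse as numbers are
#' dropped with a warning stating their count.
#'
#' @param path Path to the text file.
#' @param format `"auto"` (default; inferred from the first parseable line),
#'   `"plain"` (one column) or `"two_column"`.
#' @return Numeric vector of RR intervals.
#' @export
read_rr <- function(path, format = c("auto", "plain", "two_column")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty RR file: ", path, call. = FALSE)
  tokens <- strsplit(lines, "[ \t,]+")
  if (format == "auto") {
    format <- if (length(tokens[[1]]) >= 2) "two_column" else "plain"
  }
  col <- if (format == "two_column") 2L else 1L
  vals <- vapply(tokens, function(tk) {
    if (length(tk) < col) return(NA_real_)
    suppressWarnings(as.numeric(tk[col]))
  }, numeric(1))
  bad <- sum(is.na(vals))
  if (bad > 0) {
    warning(sprintf("dropped %d unparseable line(s) in %s", bad, path), call. = FALSE)
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no numeric RR values in ", path, call. = FALSE)
  vals
}
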