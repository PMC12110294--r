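# Independent reference implementations used to cross-check the package's
# optimized kernels. Deliberately naive: exhaustive enumeration and matrix
# algebra, no shared code with the implementation under test.

# VR simplex counts by full distance-matrix enumeration (O(P^2)/O(P^3)).
census_oracle <- function(pts, eps, K = 2) {
  D <- as.matrix(dist(pts))
  A <- (D <= eps)
  diag(A) <- FALSE
  P <- nrow(pts)
  rho <- c(P, sum(A) / 2)
  if (K >= 2) {
    A1 <- A * 1
    rho <- c(rho, sum(diag(A1 %*% A1 %*% A1)) / 6) # closed triangle walks
  }
  if (K >= 3) {
    # exhaustive 4-subset check
    n4 <- 0
    if (P >= 4) {
      idx <- utils::combn(P, 4)
      n4 <- sum(apply(idx, 2, function(q) all(A[q, q][upper.tri(diag(4))])))
    }
    rho <- c(rho, n4)
  }
  rho
}

# SampEn by explicit double loop over templates (lag 1).
sampen_oracle <- function(x, m, tol) {
  n <- length(x)
  ntpl <- n - m
  B <- 0; A <- 0
  for (i in 1:(ntpl - 1)) {
    for (j in (i + 1):ntpl) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Exact two-sided Mann-Whitney p by enumerating every group labeling.
mann_whitney_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  labelings <- utils::combn(length(pooled), n1)
  mu <- n1 * length(b) / 2
  us <- apply(labelings, 2, function(sel) u_of(pooled[sel], pooled[-sel]))
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = p)
}

# coarse-graining by direct evaluation of the window-mean formula
coarse_grain_oracle <- function(x, tau) {
  n <- length(x)
  lapply(seq_len(tau), function(r) {
    out <- c()
    j <- 1
    while (j * tau + r - 1 <= n) {
      out <- c(out, mean(x[((j - 1) * tau + r):(j * tau + r - 1)]))
      j <- j + 1
    }
    out
  })
}
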