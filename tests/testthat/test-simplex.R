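test_that("degenerate clouds give the expected counts", {
  # 3 points pairwise farther than epsilon: no edges, no triangles
  far <- matrix(c(0, 10, 20, 0, 0, 0), ncol = 2)
  cen <- vr_census(far, epsilon = 1, K = 2)
  expect_equal(unname(cen$rho), c(3, 0, 0))
  expect_equal(cen$S[["1"]], 0)

  # 4 identical points: complete graph, all fractions 1
  same <- matrix(1, nrow = 4, ncol = 2)
  cen <- vr_census(same, epsilon = 0.5, K = 3)
  expect_equal(unname(cen$rho), c(4, 6, 4, 1))
  expect_equal(unname(cen$S), c(1, 1, 1, 1))
})

test_that("binomial maxima follow choose(P, k+1)", {
  cen <- census_from_counts(P = 10, rho = c(10, 2))
  expect_identical(unname(cen$rho_max), c(10, 45, 120))
  cen3 <- vr_census(matrix(rnorm(24), ncol = 2), epsilon = 0.5, K = 3)
  expect_equal(unname(cen3$rho_max), choose(12, 1:4))
})

test_that("optimized census matches exhaustive enumeration on random clouds", {
  set.seed(11)
  for (rep in 1:20) {
    P <- sample(20:200, 1)
    d <- sample(2:3, 1)
    pts <- matrix(runif(P * d), ncol = d)
    eps <- runif(1, 0.05, 0.4)
    K <- if (P <= 60) 3 else 2
    cen <- vr_census(pts, epsilon = eps, K = K)
    expect_equal(unname(cen$rho), census_oracle(pts, eps, K))
  }
})

test_that("rho_k is monotone in epsilon and S_0 is always 1", {
  set.seed(5)
  pts <- matrix(rnorm(300), ncol = 2)
  eps <- sort(runif(6, 0.01, 1))
  censuses <- lapply(eps, function(e) vr_census(pts, e, K = 2))
  for (cen in censuses) expect_equal(cen$S[["0"]], 1)
  rho <- t(vapply(censuses, function(cen) unname(cen$rho), numeric(3)))
  expect_true(all(diff(rho[, 2]) >= 0))
  expect_true(all(diff(rho[, 3]) >= 0))
})

test_that("every triangle is supported by edges (downward closure, count bound)", {
  set.seed(9)
  for (rep in 1:5) {
    pts <- matrix(rnorm(160), ncol = 2)
    cen <- vr_census(pts, epsilon = 0.5, K = 2)
    # a graph with E edges has at most choose(E, 2) triangles... use the
    # tight clique bound: need at least 3 edges per triangle, edges shared
    expect_true(cen$rho[["2"]] == 0 || cen$rho[["1"]] >= 3)
    # removing below-threshold pairs kills triangles: recount at eps -> 0
    tiny <- vr_census(pts, epsilon = 1e-9, K = 2)
    expect_equal(unname(tiny$rho[c("1", "2")]), c(0, 0))
  }
})

test_that("census is invariant under affine rescaling with SD-tied epsilon", {
  set.seed(13)
  x <- rnorm(400)
  for (a in c(10, -3, 0.2)) {
    cl1 <- delay_embed(x, 2)
    cl2 <- delay_embed(a * x + 5, 2)
    c1 <- vr_census(cl1, epsilon_from_factor(cl1, 0.1), K = 2)
    c2 <- vr_census(cl2, epsilon_from_factor(cl2, 0.1), K = 2)
    expect_equal(c1$rho, c2$rho)
    expect_equal(c1$S, c2$S)
  }
})

test_that("duplicate points are distinct, always-linked vertices", {
  pts <- matrix(c(0, 0, 0, 0, 5, 5), ncol = 2, byrow = TRUE)
  cen <- vr_census(pts, epsilon = 0.1, K = 2)
  expect_equal(unname(cen$rho), c(3, 1, 0))
})

test_that("ties at exactly epsilon are included (closed ball)", {
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  expect_equal(vr_census(pts, epsilon = 1, K = 1)$rho[["1"]], 1)
  expect_equal(vr_census(pts, epsilon = 1 - 1e-9, K = 1)$rho[["1"]], 0)
})

test_that("census input validation", {
  expect_error(vr_census(matrix(numeric(0), ncol = 2), 0.1), "empty")
  pts <- matrix(rnorm(10), ncol = 2)
  expect_error(vr_census(pts, epsilon = Inf), "invalid epsilon")
  expect_error(vr_census(pts, epsilon = -1), "invalid epsilon")
  expect_error(epsilon_from_factor(delay_embed(rep(1, 10), 2), 0.1), "constant")
})
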