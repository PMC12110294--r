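test_that("coarse-graining matches direct evaluation of the window-mean formula", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 1)[[1]], c(1, 2, 3, 4))
  cg2 <- coarse_grain(c(1, 2, 3, 4), 2)
  expect_equal(cg2[[1]], c(1.5, 3.5))
  expect_equal(cg2[[2]], 2.5)
  cg3 <- coarse_grain(1:6, 3)
  expect_equal(cg3[[1]], c(2, 5))
  expect_equal(cg3[[2]], 3)
  expect_equal(cg3[[3]], 4)

  set.seed(21)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    tau <- sample(1:7, 1)
    x <- rnorm(n)
    got <- coarse_grain(x, tau)
    ref <- coarse_grain_oracle(x, tau)
    for (r in seq_len(tau)) expect_equal(got[[r]], ref[[r]])
    # subseries lengths floor((N - r + 1)/tau); total points <= N
    expect_equal(lengths(got), (n - seq_len(tau) + 1) %/% tau)
    expect_lte(sum(lengths(got)), n)
  }
  expect_error(coarse_grain(1:3, 4), "exceeds")
})

test_that("MS-SCAE at tau = 1 reduces to the plain single-series entropy", {
  x <- gen_white(400, seed = 2)
  prof <- ms_scae(x, k = 0:1, tau_max = 1)
  cl <- delay_embed(x, 2)
  cen <- vr_census(cl, epsilon_from_factor(cl, 0.1), K = 2)
  expect_equal(prof$entropy[prof$k == 0], scae(cen, 0)$value)
  expect_equal(prof$entropy[prof$k == 1], scae(cen, 1)$value)
})

test_that("white noise MS-SCAE profile decreases with scale", {
  profs <- lapply(1:5, function(i) ms_scae(gen_white(4000, seed = 30 + i),
                                           k = 0, tau_max = 10))
  mean_prof <- rowMeans(sapply(profs, function(p) p$entropy))
  expect_true(all(diff(mean_prof) < 0))
})

test_that("1/f noise profile is much flatter than the white-noise drop", {
  w <- sapply(1:5, function(i) ms_scae(gen_white(4000, seed = 40 + i),
                                       k = 0, tau_max = 10)$entropy)
  f <- sapply(1:5, function(i) ms_scae(gen_one_over_f(4000, seed = 40 + i),
                                       k = 0, tau_max = 10)$entropy)
  drop_white <- mean(w[1, ]) - mean(w[10, ])
  range_f <- max(rowMeans(f)[2:10]) - min(rowMeans(f)[2:10])
  expect_gt(drop_white, 3 * range_f)
})

test_that("undefined subseries poison a scale under strict averaging only", {
  # short series where large scales have no triangles
  x <- gen_white(60, seed = 1)
  p_strict <- ms_scae(x, k = 1, tau_max = 10, strict = TRUE)
  p_loose <- ms_scae(x, k = 1, tau_max = 10, strict = FALSE)
  expect_true(any(!p_strict$defined))
  strict_def <- p_strict$defined
  loose_def <- p_loose$defined
  expect_true(all(loose_def[strict_def]))  # loose defined wherever strict is
  # strict undefined exactly when some subseries value is missing
  expect_equal(p_strict$defined, p_strict$n_defined == p_strict$n_subseries)
})

test_that("max_estimable_scale returns the last scale of an unbroken defined run", {
  x <- gen_white(60, seed = 1)
  p <- ms_scae(x, k = 0:1, tau_max = 10)
  mes <- max_estimable_scale(p)
  for (kk in 0:1) {
    def <- p$defined[p$k == kk]
    expected <- if (!def[1]) NA_integer_ else max(which(cumprod(def) == 1))
    expect_equal(unname(mes[[as.character(kk)]]), expected)
  }
  # fully defined profile reports tau_max
  pfull <- ms_scae(gen_white(2000, seed = 2), k = 0, tau_max = 5)
  expect_equal(max_estimable_scale(pfull), 5)
})

test_that("long records are split into two segments and pooled", {
  x <- gen_white(2000, seed = 9)
  p <- ms_scae(x, k = 0, tau_max = 3, segment_length = 1000)
  expect_equal(p$n_subseries, c(2L, 4L, 6L))  # tau subseries per segment
  p1 <- ms_scae(x[1:1000], k = 0, tau_max = 3, segment_length = Inf)
  p2 <- ms_scae(x[1001:2000], k = 0, tau_max = 3, segment_length = Inf)
  expect_equal(p$entropy[1], mean(c(p1$entropy[1], p2$entropy[1])))
})

test_that("constant series yields undefined scales via the SD-tied tolerance", {
  p <- ms_scae(rep(1, 100), k = 0, tau_max = 3)
  expect_true(all(!p$defined))
  expect_true(is.na(max_estimable_scale(p)))
})

test_that("profile accessors and exports are coherent", {
  p <- ms_scae(gen_white(300, seed = 4), k = 0:1, tau_max = 4)
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("scale", "k", "entropy", "se", "n_defined",
                     "n_subseries", "defined"))
  expect_equal(nrow(td), 8)
  g <- glance(p)
  expect_equal(g$method, "MS-SCAE")
  f <- tempfile(fileext = ".csv")
  write_profile_csv(p, f)
  expect_equal(nrow(utils::read.csv(f)), 8)
  j <- tempfile(fileext = ".json")
  write_profile_json(p, j)
  expect_equal(jsonlite::read_json(j)$method, "MS-SCAE")
})
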