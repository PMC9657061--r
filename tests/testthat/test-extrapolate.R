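test_that("constant series extrapolate to the constant with zero error", {
  n <- seq(11, 25, 2)
  for (method in c("neville", "bulirsch_stoer")) {
    for (omega in c(0.5, 0.82, 2)) {
      r <- extrapolate_series(n, rep(3.3, 8), omega, method)
      expect_equal(r$value, 3.3, tolerance = 1e-12)
      expect_equal(r$error, 0, tolerance = 1e-12)
    }
  }
})

test_that("series linear in h = N^-omega are recovered at matching omega", {
  n <- seq(11, 25, 2)
  t_true <- 3.7
  vals <- t_true + 2 * n^-0.8
  # the polynomial tableau interpolates a line exactly; the rational
  # recursion (with its zero pre-column) converges to it without being an
  # exact interpolant, so it carries a tiny residual even in exact arithmetic
  expect_equal(extrapolate_series(n, vals, 0.8, "neville")$value, t_true,
               tolerance = 1e-10)
  expect_equal(extrapolate_series(n, vals, 0.8, "bulirsch_stoer")$value,
               t_true, tolerance = 1e-7)
})

test_that("the rational method handles pole-dominated series far better", {
  n <- seq(4, 18, 2)
  h <- n^-0.9
  a <- 2.5; b <- -4.0; cc <- 8.0  # pole at h = -1/8: strongly non-polynomial
  vals <- (a + b * h) / (1 + cc * h)
  bs_err <- abs(extrapolate_series(n, vals, 0.9, "bulirsch_stoer")$value - a)
  nev_err <- abs(extrapolate_series(n, vals, 0.9, "neville")$value - a)
  expect_lt(bs_err, 1e-3)
  expect_gt(nev_err, 10 * bs_err)  # the two recursions genuinely differ
})

test_that("the Neville tableau interpolates through every input point", {
  n <- c(5, 8, 11, 14, 17)
  vals <- 2 + 3 * n^-1.1 + 0.5 * n^-2.2
  omega <- 0.7
  for (i in seq_along(n)) {
    expect_equal(isawtheta:::neville_at(n, vals, omega, n[i]^-omega),
                 vals[i], tolerance = 1e-9)
  }
})

test_that("extrapolation rejects malformed series", {
  expect_error(extrapolate_series(c(3, 3, 5), c(1, 2, 3), 1), "duplicate")
  expect_error(extrapolate_series(c(5, 3), c(1, 2), 1), "increasing")
  expect_error(extrapolate_series(5, 1, 1), "at least two")
  expect_error(extrapolate_series(c(3, 5), c(1, 2), -1), "omega")
})

test_that("tidy and glance expose the tableau and the summary", {
  n <- seq(11, 19, 2)
  r <- extrapolate_series(n, 3 + n^-0.8, 0.8)
  td <- tidy(r)
  expect_equal(nrow(td), 5 + 4 + 3 + 2 + 1)
  expect_equal(td$t[td$j == 0], 3 + n^-0.8)
  gl <- glance(r)
  expect_equal(gl$estimate, r$value)
  expect_equal(gl$n_points, 5L)
})

test_that("the omega scan combines parities and picks the smallest error", {
  # two synthetic parity series converging to the same limit
  n_odd <- seq(11, 25, 2); n_even <- seq(12, 26, 2)
  t_true <- 3.71
  series <- tibble::tibble(
    n = c(n_odd, n_even),
    t_star = t_true - 14 * c(n_odd, n_even)^-0.85,
    parity = rep(c("odd", "even"), each = 8)
  )
  # the polynomial recursion is exact on h-linear data, so the combined
  # error vanishes exactly at the matching omega
  sc <- scan_omega(series, seq(0.5, 1.2, 0.01), method = "neville")
  best <- scan_best(sc)
  expect_equal(best$omega, 0.85, tolerance = 1e-6)
  expect_equal(best$mean, t_true, tolerance = 1e-9)
  expect_equal(sc$mean, (sc$t_odd + sc$t_even) / 2)
  expect_equal(sc$error, sqrt(sc$err_odd^2 + sc$err_even^2) / 2)

  # constant series: every row has zero error, ties break to the smallest omega
  const <- series; const$t_star <- 2.0
  scc <- scan_omega(const, c(0.6, 0.9, 1.5), method = "neville")
  expect_equal(scan_best(scc)$omega, 0.6)
  expect_true(all(scc$error == 0))

  expect_error(scan_omega(series, numeric(0)), "nonempty")
  odd_only <- series[series$parity == "odd", ]
  expect_error(scan_omega(odd_only, 0.8), "both parities")
})

test_that("coarse-to-fine refinement sharpens the scan and the estimate", {
  n_odd <- seq(11, 25, 2); n_even <- seq(12, 26, 2)
  series <- tibble::tibble(
    n = c(n_odd, n_even),
    t_star = 3.71 - 14 * c(n_odd, n_even)^-0.8531,
    parity = rep(c("odd", "even"), each = 8)
  )
  # the error estimator can have accidental near-zeros away from the planted
  # exponent, so the refined omega is not guaranteed to be 0.8531; the
  # refined error must improve on the coarse scan and the extrapolated value
  # must be accurate regardless
  coarse <- scan_best(scan_omega(series, seq(0.3, 1.5, 0.01), "neville"))
  best <- refine_omega(series, method = "neville", lower = 0.3, upper = 1.5)
  expect_lte(best$error, coarse$error)
  expect_equal(best$mean, 3.71, tolerance = 1e-4)
})

test_that("deep tableaus amplify rounding of the input series", {
  # the reference series is printed at 4 decimals; the 8-point rational
  # tableau's sensitivity to a single input exceeds 100, so a 5e-5 rounding
  # perturbation can move the extrapolant by more than 0.005 — which is why
  # extrapolations of the rounded reference series cannot reproduce results
  # computed from full-precision internal values
  ref <- reference_t_star()
  odd <- ref[ref$parity == "odd", ]
  base <- extrapolate_series(odd$n, odd$t_star, 0.820)$value
  eps <- 1e-7
  grad <- vapply(seq_len(8), function(i) {
    v <- odd$t_star
    v[i] <- v[i] + eps
    (extrapolate_series(odd$n, v, 0.820)$value - base) / eps
  }, double(1))
  expect_gt(max(abs(grad)), 100)
})

test_that("phi estimates are invariant to the rms vs mean-square convention", {
  tabs <- lapply(10:13, isaw_table)
  ps <- phi_series(tabs, t_theta = 3.713)
  # recompute using d log <R^2> / dT = 2 d log R / dT: the factor cancels
  for (k in seq_len(nrow(ps))) {
    n <- ps$n[k]
    d_hi <- 2 * dlog_r_dT(isaw_poly(n + 1), 3.713)
    d_lo <- 2 * dlog_r_dT(isaw_poly(n - 1), 3.713)
    expect_equal(log(d_hi / d_lo) / log((n + 1) / (n - 1)), ps$phi[k],
                 tolerance = 1e-12)
  }
  expect_error(phi_series(tabs, t_theta = -2), "positive")
})
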