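t4 <- c(4, 24, 72, 192)

test_that("mono-exponential fit recovers noiseless generators exactly", {
  cases <- list(c(A = 50, lambda = 0.02), c(A = 200, lambda = 0.004),
                c(A = 5, lambda = 0.15))
  for (p in cases) {
    tac <- TimeActivityCurve("o", t4, p[["A"]] * exp(-p[["lambda"]] * t4),
                             7200)
    f <- fitMonoexp(tac)
    expect_true(f@converged)
    expect_lt(relErr(f@parameters[["A"]], p[["A"]]), 1e-6)
    expect_lt(relErr(f@parameters[["lambda"]], p[["lambda"]]), 1e-6)
    expect_lt(relErr(tia(f), p[["A"]] / p[["lambda"]]), 1e-6)
    expect_equal(tiac(f), tia(f) / 7200, tolerance = 1e-15)
    expect_identical(f@goodness, 1)  # exact monotone fit
  }
  # TIAC division oracle from the worked numbers
  f <- fitMonoexp(TimeActivityCurve("o", t4, 50 * exp(-0.02 * t4), 7200))
  expect_equal(tiac(f), 2500 / 7200, tolerance = 1e-6)
})

test_that("two points determine the interpolating exponential", {
  tac <- TimeActivityCurve("o", c(10, 50), c(80, 20), 7200)
  f <- fitMonoexp(tac)
  lam <- log(80 / 20) / 40
  expect_lt(relErr(f@parameters[["lambda"]], lam), 1e-8)
  expect_lt(f@rss, 1e-16)
  expect_error(fitMonoexp(TimeActivityCurve("o", 4, 10, 7200)), "2 points")
})

test_that("non-decaying data are flagged rather than rejected", {
  tac <- TimeActivityCurve("o", t4, c(10, 20, 30, 40), 7200)
  f <- fitMonoexp(tac)
  expect_true("non_decaying" %in% f@flags)
})

test_that("bi-exponential fit recovers a noiseless two-component TAC", {
  a <- 30 * exp(-0.1 * t4) + 20 * exp(-0.005 * t4)
  f <- fitBiexp(TimeActivityCurve("o", t4, a, 7200))
  expect_true(f@converged)
  expect_lt(relErr(tia(f), 30 / 0.1 + 20 / 0.005), 1e-4)
  expect_lt(relErr(f@parameters[["A1"]], 30), 1e-4)
  expect_lt(relErr(f@parameters[["lambda1"]], 0.1), 1e-4)
  expect_lt(relErr(f@parameters[["A2"]], 20), 1e-4)
  expect_lt(relErr(f@parameters[["lambda2"]], 0.005), 1e-4)
  expect_error(fitBiexp(TimeActivityCurve("o", c(4, 24, 72), c(3, 2, 1),
                                          7200)), "4 points")
})

test_that("degenerate equal-rate bi-exponential matches the mono-exp TIA", {
  a <- 50 * exp(-0.02 * t4)
  fb <- fitBiexp(TimeActivityCurve("o", t4, a, 7200))
  fm <- fitMonoexp(TimeActivityCurve("o", t4, a, 7200))
  expect_lt(relErr(tia(fb), tia(fm)), 1e-4)
})

test_that("bi-exponential median TIA stays within 5% under 2% noise", {
  truth <- 30 / 0.1 + 20 / 0.005
  a <- 30 * exp(-0.1 * t4) + 20 * exp(-0.005 * t4)
  set.seed(42)
  tias <- replicate(100, {
    f <- tryCatch(fitBiexp(noisyTac("o", t4, a, 7200, 0.02)),
                  error = function(e) NULL)
    if (is.null(f) || !f@converged) NA_real_ else tia(f)
  })
  expect_lt(relErr(stats::median(tias, na.rm = TRUE), truth), 0.05)
})

test_that("power-exponential nests the mono-exponential family", {
  a <- 50 * exp(-0.02 * t4)
  f <- fitPowerexp(TimeActivityCurve("o", t4, a, 7200))
  expect_true(f@converged)
  expect_lt(relErr(tia(f), f@parameters[["A"]] / f@parameters[["c"]]), 1e-6)
  expect_lt(relErr(tia(f), 2500), 1e-4)
})

test_that("power-exponential recovers its own generator and its quadrature
           matches the closed form", {
  tp <- seq(2, 200, length.out = 6)
  a <- 5 * tp^0.5 * exp(-0.05 * tp)
  f <- fitPowerexp(TimeActivityCurve("o", tp, a, 7200))
  expect_lt(relErr(f@parameters[["A"]], 5), 1e-3)
  expect_lt(relErr(f@parameters[["b"]], 0.5), 1e-3)
  expect_lt(relErr(f@parameters[["c"]], 0.05), 1e-3)
  expect_lt(relErr(f@parameters[["d"]], 1), 1e-3)
  # with d = 1 the TIA integral has the closed form A Gamma(b+1) / c^(b+1)
  closed <- 5 * gamma(1.5) / 0.05^1.5
  expect_lt(relErr(tia(f), closed), 1e-6)
})

test_that("trapezoid with tail reproduces the worked four-point quadrature", {
  tac <- TimeActivityCurve("k", t4, c(90, 70, 40, 10), 7200)
  lam <- log(2) / 159.53
  f <- integrateTrapezoidTail(tac, "zero_line", lam)
  hand <- 0.5 * 4 * 90 + (20 * 160 + 48 * 110 + 120 * 50) / 2 + 10 / lam
  expect_lt(relErr(tia(f), hand), 1e-12)
  expect_equal(tia(f), 180 + 1600 + 2640 + 3000 + 10 / lam,
               tolerance = 1e-12)
  expect_equal(tiac(f), tia(f) / 7200, tolerance = 1e-15)
  # constant head adds exactly half of t1 * A1
  fc <- integrateTrapezoidTail(tac, "constant", lam)
  expect_equal(tia(fc) - tia(f), 180, tolerance = 1e-9)
  # single point: head + tail in closed form
  f1 <- integrateTrapezoidTail(TimeActivityCurve("k", 4, 100, 7200),
                               "constant", lam)
  expect_equal(tia(f1), 400 + 100 / lam, tolerance = 1e-12)
})

test_that("trapezoid part matches an independent piecewise-linear oracle", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    t <- sort(stats::runif(n, 1, 300))
    a <- stats::runif(n, 0, 100)
    tac <- TimeActivityCurve("o", t, a, 1000)
    lam <- stats::runif(1, 0.001, 0.1)
    f <- integrateTrapezoidTail(tac, "zero_line", lam)
    # oracle: antiderivative of the linear interpolant on each segment
    oracle <- 0
    for (s in seq_len(n - 1)) {
      dt <- t[s + 1] - t[s]
      slope <- (a[s + 1] - a[s]) / dt
      oracle <- oracle + a[s] * dt + slope * dt^2 / 2
    }
    expect_lt(relErr(tia(f) - 0.5 * t[1] * a[1] - a[n] / lam, oracle), 1e-12)
    expect_equal(tiac(f) * 1000, tia(f), tolerance = 1e-12)
  }
})

test_that("fine trapezoid sampling converges to the analytic mono-exp TIA", {
  A <- 50; lam <- 0.02
  t <- seq(0.1, 400, by = 0.1)
  tac <- TimeActivityCurve("o", t, A * exp(-lam * t), 7200)
  f <- integrateTrapezoidTail(tac, "zero_line", lam)
  expect_lt(relErr(tia(f), A / lam), 1e-3)
})

test_that("mono-exp TIAC bias stays under 2% across 100 noisy replicates", {
  truthTiac <- 50 / 0.02 / 7200
  a <- 50 * exp(-0.02 * t4)
  set.seed(7)
  tiacs <- replicate(100, tiac(fitMonoexp(noisyTac("o", t4, a, 7200, 0.05))))
  expect_lt(relErr(mean(tiacs), truthTiac), 0.02)
})

test_that("model selection prefers parsimony and falls back sensibly", {
  # pure mono-exponential data: monoexp beats biexp under AICc
  mono <- TimeActivityCurve("o", seq(4, 192, length.out = 8),
                            50 * exp(-0.02 * seq(4, 192, length.out = 8)),
                            7200)
  expect_identical(autoSelect(mono)@model, "monoexp")
  # clearly bi-phasic noiseless data select the bi-exponential
  t7 <- c(1, 4, 12, 24, 48, 96, 192)
  bi <- TimeActivityCurve("o", t7, 40 * exp(-0.3 * t7) + 15 * exp(-0.004 * t7),
                          7200)
  sel <- autoSelect(bi)
  expect_identical(sel@model, "biexp")
  expect_true(is.data.frame(attr(sel, "selection")))
  # a single point leaves only trapezoid integration
  one <- TimeActivityCurve("o", 4, 100, 7200)
  f1 <- autoSelect(one)
  expect_identical(f1@model, "trapezoid_tail")
  expect_true("fallback" %in% f1@flags)
})

test_that("Spearman goodness is 1 for monotone exact fits", {
  tac <- TimeActivityCurve("o", t4, 50 * exp(-0.02 * t4), 7200)
  expect_identical(fitMonoexp(tac)@goodness, 1)
  expect_identical(integrateTrapezoidTail(tac)@goodness, 1)
})
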