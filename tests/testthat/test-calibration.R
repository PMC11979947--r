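# Calibration: residual definitions, self-consistency recovery on toys,
# degenerate cases.

test_that("residuals are zero when targets equal model outputs", {
  net <- toy_chain(1, 2, 1)
  ss <- steady_state(net, tol = 1e-12)
  targets <- data.frame(observable = c("X", "kc_flux"),
                        mean = c(unname(ss$concentrations["X"]), ss$kc_flux),
                        sd = NA_real_, n = 1, lo = NA_real_, hi = NA_real_,
                        type = c("point", "flux"))
  r <- kc_residuals(net, targets, ss = ss)
  expect_equal(unname(as.numeric(r)), c(0, 0), tolerance = 1e-10)
})

test_that("a flux target off by +10% yields residual 0.1 (unit weight)", {
  net <- toy_chain(1, 2, 1)
  ss <- steady_state(net, tol = 1e-12)
  targets <- data.frame(observable = "kc_flux", mean = ss$kc_flux / 1.1,
                        sd = NA_real_, n = 1, lo = NA_real_, hi = NA_real_,
                        type = "flux")
  r <- kc_residuals(net, targets, ss = ss)
  expect_equal(as.numeric(r), 0.1, tolerance = 1e-9)
  # with an SD the residual is weighted by obs/sd
  targets$sd <- targets$mean / 2
  r2 <- kc_residuals(net, targets, ss = ss)
  expect_equal(as.numeric(r2), 0.2, tolerance = 1e-9)
})

test_that("interval targets penalize only outside the interval", {
  net <- toy_chain(1, 2, 1)
  ss <- steady_state(net, tol = 1e-12)
  x <- unname(ss$concentrations["X"])
  t_in <- data.frame(observable = "X", mean = NA_real_, sd = NA_real_, n = NA,
                     lo = x / 2, hi = x * 2, type = "interval")
  expect_equal(as.numeric(kc_residuals(net, t_in, ss = ss)), 0)
  # below the interval: log-scale distance to the lower bound
  t_hi <- t_in; t_hi$lo <- x * 2; t_hi$hi <- x * 4
  expect_equal(as.numeric(kc_residuals(net, t_hi, ss = ss)),
               log(1 / 2), tolerance = 1e-9)
  # above the interval: log-scale distance to the upper bound
  t_lo <- t_in; t_lo$lo <- x / 4; t_lo$hi <- x / 2
  expect_equal(as.numeric(kc_residuals(net, t_lo, ss = ss)),
               log(2), tolerance = 1e-9)
})

test_that("hand-computed residual vector matches on a toy with two targets", {
  net <- toy_chain(1, 2, 1)
  ss <- steady_state(net, tol = 1e-12)
  xs <- unname(ss$concentrations["X"])
  targets <- data.frame(observable = c("X", "kc_flux"),
                        mean = c(0.8, 1.25), sd = c(0.2, NA_real_), n = 1,
                        lo = NA_real_, hi = NA_real_,
                        type = c("point", "flux"))
  r <- as.numeric(kc_residuals(net, targets, ss = ss))
  expect_equal(r[1], (xs - 0.8) / 0.8 * (0.8 / 0.2), tolerance = 1e-9)
  expect_equal(r[2], (ss$kc_flux - 1.25) / 1.25, tolerance = 1e-9)
})

test_that("calibration recovers a known truth on the toy chain", {
  truth <- toy_chain(v0 = 1.3, Vmax = 2.5, Km = 0.7)
  ss <- steady_state(truth, tol = 1e-12)
  targets <- data.frame(observable = c("X", "kc_flux"),
                        mean = c(unname(ss$concentrations["X"]), ss$kc_flux),
                        sd = NA_real_, n = 1, lo = NA_real_, hi = NA_real_,
                        type = c("point", "flux"))
  start <- toy_chain(v0 = 0.6, Vmax = 2.5, Km = 0.7)
  spec <- calibration_spec(
    data.frame(key = "influx.Vc", lower = 0.1, upper = 10, initial = 0.6),
    targets)
  fit <- calibrate(start, spec, seed = 1, n_starts = 2)
  expect_equal(unname(fit$fitted["influx.Vc"]), 1.3, tolerance = 1e-6)
  expect_lt(fit$loss, 1e-10)
})

test_that("two-parameter recovery from exact targets", {
  truth <- toy_chain3()
  truth <- set_params(truth, list("R1.Vmaxf" = 7, "R3.Vmaxf" = 9))
  ss <- steady_state(truth, tol = 1e-12)
  targets <- data.frame(
    observable = c("X", "Y", "kc_flux"),
    mean = c(unname(ss$concentrations["X"]), unname(ss$concentrations["Y"]),
             ss$kc_flux),
    sd = NA_real_, n = 1, lo = NA_real_, hi = NA_real_,
    type = c("point", "point", "flux"))
  spec <- calibration_spec(
    data.frame(key = c("R1.Vmaxf", "R3.Vmaxf"), lower = c(1, 1),
               upper = c(50, 50), initial = c(12, 4)),
    targets)
  fit <- calibrate(toy_chain3(), spec, seed = 2, n_starts = 2)
  expect_equal(unname(fit$fitted["R1.Vmaxf"]), 7, tolerance = 1e-4)
  expect_equal(unname(fit$fitted["R3.Vmaxf"]), 9, tolerance = 1e-4)
})

test_that("zero free parameters returns the input unchanged with its loss", {
  net <- toy_chain(1, 2, 1)
  ss <- steady_state(net, tol = 1e-12)
  targets <- data.frame(observable = "kc_flux", mean = ss$kc_flux * 1.1,
                        sd = NA_real_, n = 1, lo = NA_real_, hi = NA_real_,
                        type = "flux")
  spec <- structure(list(
    free_params = data.frame(key = character(0), lower = numeric(0),
                             upper = numeric(0), initial = numeric(0)),
    targets = targets), class = "kc_calibration_spec")
  fit <- calibrate(net, spec, seed = 1)
  expect_length(fit$fitted, 0)
  r <- kc_residuals(net, targets)
  expect_equal(fit$loss, sum(r^2), tolerance = 1e-9)
})

test_that("more free parameters than targets triggers a warning", {
  net <- toy_chain3()
  targets <- data.frame(observable = "kc_flux", mean = 1, sd = NA_real_,
                        n = 1, lo = NA_real_, hi = NA_real_, type = "flux")
  spec <- calibration_spec(
    data.frame(key = c("R1.Vmaxf", "R2.Vmaxf", "R3.Vmaxf"),
               lower = rep(1, 3), upper = rep(50, 3), initial = c(10, 8, 12)),
    targets)
  expect_warning(calibrate(net, spec, seed = 1, n_starts = 1),
                 "under-determined")
})

test_that("non-convergent states produce penalty residuals, flagged", {
  net <- toy_chain(1, 2, 1)
  targets <- data.frame(observable = "kc_flux", mean = 1, sd = NA_real_,
                        n = 1, lo = NA_real_, hi = NA_real_, type = "flux")
  bad <- integrate_to_steady_state(net, x0 = c(X = 50), t_max = 1e-4,
                                   refine = FALSE)
  r <- kc_residuals(net, targets, ss = bad)
  expect_false(attr(r, "converged"))
  expect_true(all(r == 1e3))
})

test_that("calibration bounds are honoured", {
  truth <- toy_chain(v0 = 1.3, Vmax = 2.5, Km = 0.7)
  ss <- steady_state(truth, tol = 1e-12)
  targets <- data.frame(observable = "kc_flux", mean = ss$kc_flux,
                        sd = NA_real_, n = 1, lo = NA_real_, hi = NA_real_,
                        type = "flux")
  spec <- calibration_spec(
    data.frame(key = "influx.Vc", lower = 0.2, upper = 1.0, initial = 0.5),
    targets)
  fit <- calibrate(toy_chain(0.5, 2.5, 0.7), spec, seed = 1, n_starts = 1)
  expect_lte(unname(fit$fitted["influx.Vc"]), 1.0)
  expect_gte(unname(fit$fitted["influx.Vc"]), 0.2)
})
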