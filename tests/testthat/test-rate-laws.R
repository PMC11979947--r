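# Rate-law unit and property tests. Expected values are either trivial
# (zero numerator / equilibrium), closed-form hand evaluations of the
# denominators, or the printed Vmax saturation limits.

test_that("every mechanism matches its literal-transcription oracle on random points", {
  set.seed(42)
  for (mech in kc_mechanisms()) {
    got <- want <- numeric(1000)
    for (rep in 1:1000) {
      p <- rand_mech_params(mech)
      conc <- rand_conc(mech_nconc[[mech]])
      got[rep] <- do.call(pkg_rate[[mech]], c(list(p), as.list(conc)))
      want[rep] <- do.call(oracle[[mech]], c(list(p), as.list(conc)))
    }
    expect_equal(got, want, tolerance = 1e-12, label = mech)
  }
})

test_that("zero substrates and products give zero rate", {
  set.seed(7)
  for (mech in kc_mechanisms()) {
    p <- rand_mech_params(mech)
    conc <- rep(0, mech_nconc[[mech]])
    expect_identical(do.call(pkg_rate[[mech]], c(list(p), as.list(conc))), 0,
                     label = mech)
  }
})

test_that("reversible laws vanish exactly at the mass-action equilibrium ratio", {
  set.seed(11)
  eq_cases <- list(
    ter_bi = function(p) {
      A <- 0.5; B <- 0.8; C <- 1.2; P <- 0.9
      list(conc = c(A, B, C, P, A * B * C * p$Keq / P))
    },
    random_bi_bi = function(p) {
      A <- 0.5; B <- 0.8; P <- 0.9
      list(conc = c(A, B, P, A * B * p$Keq / P))
    },
    uni_uni = function(p) list(conc = c(0.7, 0.7 * p$Keq)),
    bi_bi = function(p) {
      A <- 0.5; B <- 0.8; P <- 0.9
      list(conc = c(A, B, P, A * B * p$Keq / P))
    },
    bi_bi_inhib = function(p) {
      A <- 0.5; B <- 0.8; P <- 0.9
      list(conc = c(A, B, P, A * B * p$Keq / P, 0.3, 0.2))
    },
    ter_ter = function(p) {
      A <- 0.5; B <- 0.8; C <- 1.2; P <- 0.9; Q <- 0.4
      list(conc = c(A, B, C, P, Q, A * B * C * p$Keq / (P * Q)))
    },
    gr_bi_ter = function(p) {
      A <- 0.5; B <- 0.8; P <- 0.9; Q <- 0.4
      list(conc = c(A, B, P, Q, A * B * p$Keq / (P * Q)))
    },
    uni_uni_2V = function(p)
      list(conc = c(0.7, 0.7 * p$Vmaxf * p$Kp / (p$Ka * p$Vmaxr))),
    bi_bi_2V = function(p) {
      A <- 0.5; B <- 0.8; P <- 0.9
      list(conc = c(A, B, P,
                    (p$Vmaxf * A * B / (p$Ka * p$Kb)) * p$Kp * p$Kq /
                      (p$Vmaxr * P)))
    }
  )
  for (mech in names(eq_cases)) {
    for (rep in 1:25) {
      p <- rand_mech_params(mech)
      conc <- eq_cases[[mech]](p)$conc
      v <- do.call(pkg_rate[[mech]], c(list(p), as.list(conc)))
      expect_lt(abs(v), 1e-10 * p$Vmaxf, label = sprintf("%s rep %d", mech, rep))
    }
  }
})

test_that("half-saturation closed forms hold (denominator hand evaluations)", {
  p <- list(Vmaxf = 26, Ka = 0.21, Kb = 0.014, Kc = 0.34, Kp = 0.05,
            Kq = 0.05, Keq = 1e8)
  # ter-bi at A=Ka, B=Kb, C=Kc, products 0: denominator 1+1+1+1 = 4
  expect_equal(rate_ter_bi(p, p$Ka, p$Kb, p$Kc, 0, 0), 26 / 4)
  # random bi-bi at A=Ka, B=Kb: denominator 1+1+1+1 = 4
  p2 <- list(Vmaxf = 1260, Ka = 0.003, Kb = 0.011, Kp = 0.05, Kq = 1.6,
             Keq = 2.2e6)
  expect_equal(rate_random_bi_bi(p2, p2$Ka, p2$Kb, 0, 0), 1260 / 4)
  # ter-ter at A=Ka, B=Kb, C=Kc: denominator 4
  p3 <- list(Vmaxf = 100, Ka = 0.1, Kb = 0.2, Kc = 0.3, Kp = 1, Kq = 1,
             Kr = 1, Keq = 10)
  expect_equal(rate_ter_ter(p3, 0.1, 0.2, 0.3, 0, 0, 0), 100 / 4)
  # ordered bi-bi at A=Ka, B=Kb: denominator 1+1+1 = 3
  p4 <- list(Vmaxf = 70, Ka = 0.5, Kb = 1.4, Kp = 3, Kq = 0.03, Keq = 34)
  expect_equal(rate_bi_bi(p4, 0.5, 1.4, 0, 0), 70 / 3)
  # bi-ter (GR) at A=Ka, B=Kb: denominator 1+1+1 = 3
  p5 <- list(Vmaxf = 60, Ka = 0.01, Kb = 0.06, Kp = 0.1, Kq = 10, Kr = 10,
             Keq = 5e4)
  expect_equal(rate_gr(p5, 0.01, 0.06, 0, 0, 0), 60 / 3)
})

test_that("saturation limits reach the measured Vmax values within 1%", {
  sat <- function(p, k) 1000 * p[[k]]
  # PDH (HepM): 26
  p <- list(Vmaxf = 26, Ka = 0.21, Kb = 0.014, Kc = 0.34, Kp = 0.05,
            Kq = 0.05, Keq = 1e8 / 2.2)
  expect_equal(rate_ter_bi(p, sat(p, "Ka"), sat(p, "Kb"), sat(p, "Kc"), 0, 0),
               26, tolerance = 0.01)
  # CS (HepM): 1260
  p <- list(Vmaxf = 1260, Ka = 0.003, Kb = 0.011, Kp = 0.05, Kq = 1.6,
            Keq = 2.2e6)
  expect_equal(rate_random_bi_bi(p, sat(p, "Ka"), sat(p, "Kb"), 0, 0),
               1260, tolerance = 0.01)
  # ACO (RHM): 173
  p <- list(Vmaxf = 173, Ka = 0.22, Kp = 0.6, Keq = 2)
  expect_equal(rate_uni_uni(p, sat(p, "Ka"), 0), 173, tolerance = 0.01)
  # FH (HepM): 3356
  p <- list(Vmaxf = 3356, Vmaxr = 340, Ka = 1, Kp = 0.4)
  expect_equal(rate_uni_uni_2V(p, sat(p, "Ka"), 0), 3356, tolerance = 0.01)
  # IDH-NADP (HepM): 587, zero products and inhibitors
  p <- list(Vmaxf = 587, Ka = 0.078, Kb = 0.046, Kp = 2, Kq = 0.036,
            Keq = 2.5e4 / 2.2, Ki_GSH = 3, Ki_NAD = 0.6)
  expect_equal(rate_idh_nadp(p, sat(p, "Ka"), sat(p, "Kb"), 0, 0, 0, 0),
               587, tolerance = 0.01)
  # ME (RHM): 70
  p <- list(Vmaxf = 70, Ka = 0.5, Kb = 1.4, Kp = 3, Kq = 0.03, Keq = 34)
  expect_equal(rate_bi_bi(p, sat(p, "Ka"), sat(p, "Kb"), 0, 0),
               70, tolerance = 0.01)
  # GDH (RHM): 2, forward saturating, reverse zero
  p <- list(Vmaxf = 2, Vmaxr = 19, Ka = 0.53, Kb = 8.8, Kp = 0.08,
            Kq = 0.025, Kr = 1.1, L = 10, n = 4, Ka_ADP = 1, Ki_GTP = 0.2)
  expect_equal(rate_gdh(p, sat(p, "Ka"), sat(p, "Kb"), 0, 0, 1, 0, 1),
               2, tolerance = 0.01)
  # MDH (HepM) reverse: -2074 at saturating OAA/NADH, A=B=0
  p <- list(Vmaxf = 269, Vmaxr = 2074, Ka = 0.11, Kb = 0.45, Kp = 0.007,
            Kq = 0.017)
  expect_equal(rate_bi_bi_2V(p, 0, 0, sat(p, "Kp"), sat(p, "Kq")),
               -2074, tolerance = 0.01)
  # IDH-NAD (HepM): L -> 0 with saturating NAD and Iso approaches 51
  p <- list(Vmaxf = 51, Ka = 0.25, Kb = 5.7, Kp = 1, Kq = 0.05,
            Keq = 2.5e4 / 2.2, L = 1e-12, n = 2.33,
            Ki_NADH_vs_Iso = 0.04, Ki_NADH_vs_NAD = 0.08)
  expect_equal(rate_mwc_idh_nad(p, sat(p, "Ka"), sat(p, "Kb"), 0, 0),
               51, tolerance = 0.01)
})

test_that("rates are bounded by the forward/reverse limiting rates", {
  set.seed(99)
  for (mech in setdiff(kc_mechanisms(), "constant_flux")) {
    excess <- numeric(200)
    for (rep in 1:200) {
      p <- rand_mech_params(mech)
      conc <- rlnorm(mech_nconc[[mech]], 1, 2)
      v <- do.call(pkg_rate[[mech]], c(list(p), as.list(conc)))
      vr <- haldane_vmaxr(p, mech)
      bound <- max(p$Vmaxf, vr, na.rm = TRUE) * (1 + 1e-9)
      excess[rep] <- abs(v) - bound
    }
    expect_lte(max(excess), 0, label = mech)
  }
  # constant flux is bounded by Vc
  p <- list(Vc = 100)
  expect_lte(rate_constant_flux(p, 1e9), 100)
})

test_that("monotone in substrates (non-decreasing) and products/inhibitors (non-increasing)", {
  set.seed(123)
  for (mech in names(mech_substrates)) {
    sub_viol <- prod_viol <- 0
    for (rep in 1:40) {
      p <- rand_mech_params(mech)
      base <- rlnorm(mech_nconc[[mech]], -0.5, 1)
      v0 <- do.call(pkg_rate[[mech]], c(list(p), as.list(base)))
      for (i in mech_substrates[[mech]]) {
        up <- base; up[i] <- up[i] * 1.25
        v1 <- do.call(pkg_rate[[mech]], c(list(p), as.list(up)))
        if (v1 < v0 - 1e-9 * abs(v0)) sub_viol <- sub_viol + 1
      }
      # products/inhibitors push a forward-running rate down; in the reverse
      # regime an inhibitor moves v toward zero (upward), so assert only
      # where the rate runs forward
      if (v0 > 0) for (i in mech_products[[mech]]) {
        up <- base; up[i] <- up[i] * 1.25
        v1 <- do.call(pkg_rate[[mech]], c(list(p), as.list(up)))
        if (v1 > v0 + 1e-9 * abs(v0)) prod_viol <- prod_viol + 1
      }
    }
    expect_identical(sub_viol, 0, label = paste(mech, "substrate"))
    expect_identical(prod_viol, 0, label = paste(mech, "product"))
  }
})

test_that("allosteric NAD-IDH is strictly decreasing in NADH", {
  p <- list(Vmaxf = 51, Ka = 0.25, Kb = 5.7, Kp = 1, Kq = 0.05,
            Keq = 2.5e4 / 2.2, L = 0.64, n = 2.33,
            Ki_NADH_vs_Iso = 0.04, Ki_NADH_vs_NAD = 0.08)
  nadh <- seq(0, 0.1, length.out = 50)
  v <- vapply(nadh, function(q) rate_mwc_idh_nad(p, 0.5, 2, 0.1, q), 0)
  expect_true(all(diff(v) < 0))
  expect_true(all(v <= p$Vmaxf))
})

test_that("GDH effectors act through the MWC gate as activator/inhibitor", {
  p <- list(Vmaxf = 2, Vmaxr = 19, Ka = 0.53, Kb = 8.8, Kp = 0.08,
            Kq = 0.025, Kr = 1.1, L = 10, n = 4, Ka_ADP = 1, Ki_GTP = 0.2)
  # reverse-only conditions: A = B = 0 so v = -Vmaxr * rev * gate
  v_base <- rate_gdh(p, 0, 0, 0.5, 0.5, 1, 0.5, 1)
  v_gtp  <- rate_gdh(p, 0, 0, 0.5, 0.5, 1, 5, 1)     # more GTP
  v_adp  <- rate_gdh(p, 0, 0, 0.5, 0.5, 1, 0.5, 10)  # more ADP
  expect_lt(abs(v_gtp), abs(v_base))  # GTP lowers |reverse term|
  expect_gt(abs(v_adp), abs(v_base))  # ADP raises it
  # ADP -> infinity with GTP = 0 drives L_eff -> 0: pure Hill-like gate
  v_inf <- rate_gdh(p, 0, 0, 0.5, 0.5, 1, 0, 1e9)
  al <- 1 / p$Kr
  gate_hill <- (al * (1 + al)^(p$n - 1)) / (1 + al)^p$n
  rev <- (0.5 * 0.5 / (p$Kp * p$Kq)) /
    (1 + 0.5 / p$Kp + 0.5 * 0.5 / (p$Kp * p$Kq))
  expect_equal(v_inf, -p$Vmaxr * rev * gate_hill, tolerance = 1e-6)
})

test_that("IDH-NADP inhibitors drive the rate down; GSH -> infinity kills it", {
  p <- list(Vmaxf = 587, Ka = 0.078, Kb = 0.046, Kp = 2, Kq = 0.036,
            Keq = 2.5e4 / 2.2, Ki_GSH = 3, Ki_NAD = 0.6)
  v0 <- rate_idh_nadp(p, 0.3, 0.1, 0, 0, 0, 0)
  gsh <- c(1, 10, 100, 1e4, 1e8)
  v <- vapply(gsh, function(g) rate_idh_nadp(p, 0.3, 0.1, 0, 0, g, 0), 0)
  expect_true(all(diff(v) < 0))
  expect_lt(v[length(v)], 1e-3 * v0)
  expect_gt(v[length(v)], 0)
  expect_lt(rate_idh_nadp(p, 0.3, 0.1, 0, 0, 0, 5), v0)  # NAD+ inhibition
})

test_that("constant-flux guard behaves at the boundary", {
  p <- list(Vc = 100)
  expect_identical(rate_constant_flux(p, 0), 0)
  expect_equal(rate_constant_flux(p, 1), 100, tolerance = 1e-4)
  expect_equal(rate_constant_flux(p, KC_FLUX_GUARD_EPS), 50)
})

test_that("parameter validation names the missing constant and enforces positivity", {
  p <- list(Vmaxf = 26, Ka = 0.21, Kb = 0.014, Kc = 0.34, Kp = 0.05,
            Kq = 0.05, Keq = 1e8)
  expect_silent(validate_params(p, "ter_bi", "PDH"))
  expect_error(validate_params(p[-7], "ter_bi", "PDH"), "Keq")
  bad <- p; bad$Ka <- -1
  expect_error(validate_params(bad, "ter_bi", "PDH"), "strictly positive")
  expect_error(validate_params(p, "nonsense", "PDH"), "unknown mechanism")
  pm <- list(Vmaxf = 51, Ka = 0.25, Kb = 5.7, Kp = 1, Kq = 0.05, Keq = 1,
             L = 1, n = 0.5, Ki_NADH_vs_Iso = 0.04, Ki_NADH_vs_NAD = 0.08)
  expect_error(validate_params(pm, "mwc_idh", "IDH"), "n must be >= 1")
})

test_that("Haldane diagnostic matches the reverse plateau for single-Vmax laws", {
  set.seed(5)
  p <- rand_mech_params("bi_bi")
  # reverse plateau: P, Q -> infinity with A = B = 0
  v_rev <- rate_bi_bi(p, 0, 0, 1e9 * p$Kp, 1e9 * p$Kq)
  expect_equal(-v_rev, haldane_vmaxr(p, "bi_bi"), tolerance = 1e-6)
  p <- rand_mech_params("uni_uni")
  v_rev <- rate_uni_uni(p, 0, 1e9 * p$Kp)
  expect_equal(-v_rev, haldane_vmaxr(p, "uni_uni"), tolerance = 1e-6)
})
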