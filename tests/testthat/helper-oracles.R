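# Independent oracles: literal transcriptions of the printed rate equations
# (with the documented denominator corrections), written as flat arithmetic
# with no shared code with the package implementations.

oracle <- list(
  ter_bi = function(p, A, B, C, P, Q)
    (p$Vmaxf / (p$Ka * p$Kb * p$Kc)) * (A * B * C - P * Q / p$Keq) /
      (1 + A / p$Ka + (A * B) / (p$Ka * p$Kb) +
         (A * B * C) / (p$Ka * p$Kb * p$Kc) +
         (P * Q) / (p$Kp * p$Kq) + Q / p$Kq),
  random_bi_bi = function(p, A, B, P, Q)
    (p$Vmaxf / (p$Ka * p$Kb)) * (A * B - P * Q / p$Keq) /
      (1 + A / p$Ka + B / p$Kb + (A * B) / (p$Ka * p$Kb) + P / p$Kp +
         Q / p$Kq + (P * Q) / (p$Kp * p$Kq) + (A * Q) / (p$Ka * p$Kq) +
         (P * B) / (p$Kp * p$Kb)),
  uni_uni = function(p, A, P)
    (p$Vmaxf / p$Ka) * (A - P / p$Keq) / (1 + A / p$Ka + P / p$Kp),
  mwc_idh = function(p, A, B, P, Q) {
    anad <- A / (p$Ka * (1 + Q / p$Ki_NADH_vs_NAD))
    p$Vmaxf * ((anad / (1 + anad)) *
      ((B / p$Kb) * (1 + B / p$Kb)^(p$n - 1)) /
        (p$L * (1 + Q / p$Ki_NADH_vs_Iso)^p$n + (1 + B / p$Kb)^p$n) -
      ((P * Q) / (p$Kp * p$Kq * p$Keq)) /
        (1 + P / p$Kp + Q / p$Kq + (P * Q) / (p$Kp * p$Kq)))
  },
  bi_bi_inhib = function(p, A, B, P, Q, GSH, NAD)
    (p$Vmaxf / (p$Ka * p$Kb)) * (A * B - P * Q / p$Keq) /
      (1 + A / p$Ka + (A * GSH) / (p$Ka * p$Ki_GSH) +
         (A * B) / (p$Ka * p$Kb) + (Q * B) / (p$Kq * p$Kb) +
         (Q * P) / (p$Kq * p$Kp) + Q / p$Kq + NAD / p$Ki_NAD),
  ter_ter = function(p, A, B, C, P, Q, R)
    (p$Vmaxf / (p$Ka * p$Kb * p$Kc)) * (A * B * C - P * Q * R / p$Keq) /
      (1 + A / p$Ka + (A * B) / (p$Ka * p$Kb) +
         (A * B * C) / (p$Ka * p$Kb * p$Kc) +
         (P * Q * R) / (p$Kp * p$Kq * p$Kr) + (Q * R) / (p$Kq * p$Kr) +
         R / p$Kr),
  bi_bi = function(p, A, B, P, Q)
    (p$Vmaxf / (p$Ka * p$Kb)) * (A * B - P * Q / p$Keq) /
      (1 + A / p$Ka + (A * B) / (p$Ka * p$Kb) + (P * Q) / (p$Kp * p$Kq) +
         Q / p$Kq),
  uni_uni_2V = function(p, A, P)
    (p$Vmaxf * A / p$Ka - p$Vmaxr * P / p$Kp) / (1 + A / p$Ka + P / p$Kp),
  bi_bi_2V = function(p, A, B, P, Q)
    (p$Vmaxf * (A * B) / (p$Ka * p$Kb) - p$Vmaxr * (P * Q) / (p$Kp * p$Kq)) /
      (1 + A / p$Ka + (A * B) / (p$Ka * p$Kb) + (P * Q) / (p$Kp * p$Kq) +
         Q / p$Kq),
  gdh_mwc = function(p, A, B, P, Q, R, GTP, ADP)
    p$Vmaxf * ((A * B) / (p$Ka * p$Kb)) /
      (1 + A / p$Ka + (A * B) / (p$Ka * p$Kb)) -
    p$Vmaxr * (((P * Q) / (p$Kp * p$Kq)) /
      (1 + P / p$Kp + (P * Q) / (p$Kp * p$Kq))) *
      ((R / p$Kr) * (1 + R / p$Kr)^(p$n - 1) /
         (p$L * (1 + GTP / p$Ki_GTP)^p$n / (1 + ADP / p$Ka_ADP) +
            (1 + R / p$Kr)^p$n)),
  gr_bi_ter = function(p, A, B, P, Q, R)
    (p$Vmaxf / (p$Ka * p$Kb)) * (A * B - P * Q * R / p$Keq) /
      (1 + A / p$Ka + (A * B) / (p$Ka * p$Kb) +
         (P * Q * R) / (p$Kp * p$Kq * p$Kr) + (Q * R) / (p$Kq * p$Kr) +
         Q / p$Kq + R / p$Kr),
  constant_flux = function(p, S) p$Vc * S / (S + 1e-6)
)

# package entry points with positional concentration arguments, same order
# as the oracles above
pkg_rate <- list(
  ter_bi = rate_ter_bi, random_bi_bi = rate_random_bi_bi,
  uni_uni = rate_uni_uni, mwc_idh = rate_mwc_idh_nad,
  bi_bi_inhib = rate_idh_nadp, ter_ter = rate_ter_ter, bi_bi = rate_bi_bi,
  uni_uni_2V = rate_uni_uni_2V, bi_bi_2V = rate_bi_bi_2V, gdh_mwc = rate_gdh,
  gr_bi_ter = rate_gr, constant_flux = rate_constant_flux
)

# number of concentration arguments per mechanism (same order as oracles)
mech_nconc <- c(ter_bi = 5, random_bi_bi = 4, uni_uni = 2, mwc_idh = 4,
                bi_bi_inhib = 6, ter_ter = 6, bi_bi = 4, uni_uni_2V = 2,
                bi_bi_2V = 4, gdh_mwc = 7, gr_bi_ter = 5, constant_flux = 1)

# substrate / product+inhibitor argument positions for monotonicity checks
mech_substrates <- list(ter_bi = 1:3, random_bi_bi = 1:2, uni_uni = 1,
                        mwc_idh = 1:2, bi_bi_inhib = 1:2, ter_ter = 1:3,
                        bi_bi = 1:2, uni_uni_2V = 1, bi_bi_2V = 1:2,
                        gr_bi_ter = 1:2, constant_flux = 1)
mech_products <- list(ter_bi = 4:5, random_bi_bi = 3:4, uni_uni = 2,
                      mwc_idh = 3:4, bi_bi_inhib = 3:6, ter_ter = 4:6,
                      bi_bi = 3:4, uni_uni_2V = 2, bi_bi_2V = 3:4,
                      gr_bi_ter = 3:5, constant_flux = integer(0))

rand_mech_params <- function(mechanism) {
  p <- list(Vmaxf = rlnorm(1, 3, 1), Vmaxr = rlnorm(1, 3, 1),
            Ka = rlnorm(1, -1, 1), Kb = rlnorm(1, -1, 1),
            Kc = rlnorm(1, -1, 1), Kp = rlnorm(1, -1, 1),
            Kq = rlnorm(1, -1, 1), Kr = rlnorm(1, -1, 1),
            Keq = rlnorm(1, 1, 2), L = runif(1, 0.1, 10),
            n = runif(1, 1, 4),
            Ki_NADH_vs_Iso = rlnorm(1, -2, 0.5),
            Ki_NADH_vs_NAD = rlnorm(1, -2, 0.5),
            Ki_GSH = rlnorm(1, 0, 0.5), Ki_NAD = rlnorm(1, -1, 0.5),
            Ka_ADP = rlnorm(1, 0, 0.5), Ki_GTP = rlnorm(1, -1, 0.5),
            Vc = rlnorm(1, 3, 1))
  p[krebsmca:::.mech_required[[mechanism]]]
}

rand_conc <- function(k) {
  x <- rlnorm(k, -1, 1.5)
  # occasionally zero out entries to probe boundary behaviour
  x[runif(k) < 0.1] <- 0
  x
}

# ---- toy networks ----------------------------------------------------------

# constant influx v0 -> X, Michaelis-Menten consumer (Vmax, Km);
# closed-form steady state X* = Km*w/(Vmax - w), w = v0/(1 + 1e-6)
toy_chain <- function(v0 = 1, Vmax = 2, Km = 1, x0 = 0.1) {
  species <- data.frame(id = c("X", "SRC", "SINK"),
                        role = c("variable", "fixed", "fixed"),
                        conc = c(x0, 1, 0))
  reactions <- list(
    list(id = "influx", mechanism = "constant_flux", roles = c(S = "SRC"),
         stoich = c(X = 1), params = list(Vc = v0), activity = 1),
    list(id = "consumer", mechanism = "uni_uni", roles = c(A = "X", P = "SINK"),
         stoich = c(X = -1),
         params = list(Vmaxf = Vmax, Ka = Km, Kp = 1, Keq = 1e12),
         activity = 1))
  kc_network(species, reactions, tissue = "toy", kc_flux_reaction = "consumer")
}

toy_chain_xstar <- function(v0 = 1, Vmax = 2, Km = 1) {
  w <- v0 / (1 + 1e-6)
  Km * w / (Vmax - w)
}

# fully reversible 3-reaction linear chain SRC -> X -> Y -> SINK with
# distributed flux control (for dual-method MCA checks)
toy_chain3 <- function() {
  species <- data.frame(id = c("X", "Y", "SRC", "SINK"),
                        role = c("variable", "variable", "fixed", "fixed"),
                        conc = c(1, 1, 5, 0.1))
  uni <- function(id, a, p, Vmax, Ka, Kp, Keq, st)
    list(id = id, mechanism = "uni_uni", roles = c(A = a, P = p), stoich = st,
         params = list(Vmaxf = Vmax, Ka = Ka, Kp = Kp, Keq = Keq),
         activity = 1)
  reactions <- list(
    uni("R1", "SRC", "X", 10, 2, 1, 5, c(X = 1)),
    uni("R2", "X", "Y", 8, 0.5, 0.8, 4, c(X = -1, Y = 1)),
    uni("R3", "Y", "SINK", 12, 1.5, 1, 10, c(Y = -1)))
  kc_network(species, reactions, tissue = "toy3", kc_flux_reaction = "R3")
}

# toy with a conserved cofactor pair (T + TH = total), for moiety plumbing;
# three reactions so the only conservation is the cofactor pool
toy_cofactor <- function(total = 2) {
  species <- data.frame(id = c("X", "T", "TH", "SRC", "SINK"),
                        role = c("variable", "variable", "variable",
                                 "fixed", "fixed"),
                        conc = c(0.5, total - 0.5, 0.5, 2, 0.05))
  reactions <- list(
    # SRC + T -> X + TH
    list(id = "load", mechanism = "bi_bi",
         roles = c(A = "SRC", B = "T", P = "X", Q = "TH"),
         stoich = c(T = -1, X = 1, TH = 1),
         params = list(Vmaxf = 5, Ka = 1, Kb = 0.5, Kp = 1, Kq = 0.5,
                       Keq = 10), activity = 1),
    # X -> SINK
    list(id = "consume", mechanism = "uni_uni",
         roles = c(A = "X", P = "SINK"),
         stoich = c(X = -1),
         params = list(Vmaxf = 6, Ka = 0.8, Kp = 2, Keq = 50), activity = 1),
    # TH -> T (reoxidation)
    list(id = "reox", mechanism = "uni_uni",
         roles = c(A = "TH", P = "T"),
         stoich = c(TH = -1, T = 1),
         params = list(Vmaxf = 4, Ka = 0.3, Kp = 1.5, Keq = 30),
         activity = 1))
  kc_network(species, reactions,
             moieties = list(Tpool = list(id = "Tpool",
                                          coef = c(T = 1, TH = 1),
                                          total = total)),
             tissue = "toycof", kc_flux_reaction = "consume")
}

# cached tissue steady states shared across test files (calibrated models)
kc_test_env <- new.env()
tissue_ss <- function(tissue) {
  key <- paste0("ss_", tissue)
  if (is.null(kc_test_env[[key]])) {
    net <- build_model(tissue)
    kc_test_env[[paste0("net_", tissue)]] <- net
    kc_test_env[[key]] <- steady_state(net)
  }
  kc_test_env[[key]]
}
tissue_net <- function(tissue) {
  tissue_ss(tissue)
  kc_test_env[[paste0("net_", tissue)]]
}
tissue_mca <- function(tissue) {
  key <- paste0("mca_", tissue)
  if (is.null(kc_test_env[[key]]))
    kc_test_env[[key]] <- control_analysis(tissue_net(tissue),
                                           tissue_ss(tissue))
  kc_test_env[[key]]
}
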