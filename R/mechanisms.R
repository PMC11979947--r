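#' Kinetic rate laws of the Krebs cycle models
#'
#' Stateless evaluation of every rate equation used by the tissue models:
#' ordered reversible ter-bi / bi-bi / ter-ter and random bi-bi
#' Michaelis-Menten forms, two mono-reactant reversible forms (one with a
#' single Vmax plus Keq, one with independent forward/reverse Vmax),
#' Monod-Wyman-Changeux (MWC) allosteric forms for the NAD-dependent
#' isocitrate dehydrogenase and for glutamate dehydrogenase, an ordered
#' bi-ter form for glutathione reductase, and guarded constant-flux boundary
#' reactions (complex-I NADH consumption, GSH oxidation).
#'
#' Concentrations are in mM, rates in nmol·min^-1·mg^-1 (numerically equal to
#' mM·min^-1 under the default matrix volume of 1 uL per mg protein).
#'
#' @name rate_laws
#' @keywords internal
NULL

#' Guard epsilon for constant-flux boundary reactions (mM)
#'
#' Constant fluxes are multiplied by S/(S + eps) so the ODE system cannot
#' drive the substrate pool (NADH or GSH) negative; eps is far below all
#' physiological concentrations.
#' @export
KC_FLUX_GUARD_EPS <- 1e-6

# required parameter names per mechanism (activity handled at network level)
.mech_required <- list(
  ter_bi        = c("Vmaxf", "Ka", "Kb", "Kc", "Kp", "Kq", "Keq"),
  random_bi_bi  = c("Vmaxf", "Ka", "Kb", "Kp", "Kq", "Keq"),
  uni_uni       = c("Vmaxf", "Ka", "Kp", "Keq"),
  mwc_idh       = c("Vmaxf", "Ka", "Kb", "Kp", "Kq", "Keq", "L", "n",
                    "Ki_NADH_vs_Iso", "Ki_NADH_vs_NAD"),
  bi_bi_inhib   = c("Vmaxf", "Ka", "Kb", "Kp", "Kq", "Keq", "Ki_GSH", "Ki_NAD"),
  ter_ter       = c("Vmaxf", "Ka", "Kb", "Kc", "Kp", "Kq", "Kr", "Keq"),
  bi_bi         = c("Vmaxf", "Ka", "Kb", "Kp", "Kq", "Keq"),
  uni_uni_2V    = c("Vmaxf", "Vmaxr", "Ka", "Kp"),
  bi_bi_2V      = c("Vmaxf", "Vmaxr", "Ka", "Kb", "Kp", "Kq"),
  gdh_mwc       = c("Vmaxf", "Vmaxr", "Ka", "Kb", "Kp", "Kq", "Kr", "L", "n",
                    "Ka_ADP", "Ki_GTP"),
  gr_bi_ter     = c("Vmaxf", "Ka", "Kb", "Kp", "Kq", "Kr", "Keq"),
  constant_flux = c("Vc")
)

#' Known rate-law mechanisms
#' @return character vector of mechanism tags
#' @export
kc_mechanisms <- function() names(.mech_required)

#' Validate a kinetic parameter set against its mechanism
#'
#' Checks that every constant required by the mechanism is present, finite
#' and strictly positive (L >= 0, n >= 1 for allosteric forms).
#'
#' @param p named list of kinetic constants
#' @param mechanism mechanism tag, see [kc_mechanisms()]
#' @param enzyme_id identifier used in error messages
#' @return `p`, invisibly, with class `kc_params`
#' @export
validate_params <- function(p, mechanism, enzyme_id = "enzyme") {
  if (!mechanism %in% names(.mech_required))
    stop("unknown mechanism '", mechanism, "' for ", enzyme_id)
  need <- .mech_required[[mechanism]]
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("configuration error: ", enzyme_id, " (", mechanism,
         ") is missing constant(s): ", paste(miss, collapse = ", "))
  for (nm in need) {
    val <- p[[nm]]
    if (!is.finite(val))
      stop("configuration error: ", enzyme_id, " constant ", nm, " is not finite")
    if (nm == "L") {
      if (val < 0) stop("configuration error: ", enzyme_id, " L must be >= 0")
    } else if (nm == "n") {
      if (val < 1) stop("configuration error: ", enzyme_id, " n must be >= 1")
    } else if (val <= 0) {
      stop("configuration error: ", enzyme_id, " constant ", nm,
           " must be strictly positive (got ", val, ")")
    }
  }
  invisible(structure(p, class = "kc_params", mechanism = mechanism))
}

#' Ordered reversible ter-bi Michaelis-Menten rate (PDH, 2OGDH)
#'
#' v = (Vmaxf/(Ka Kb Kc)) (ABC - PQ/Keq) /
#'     (1 + A/Ka + AB/(Ka Kb) + ABC/(Ka Kb Kc) + PQ/(Kp Kq) + Q/Kq)
#'
#' @param p parameter list with Vmaxf, Ka, Kb, Kc, Kp, Kq, Keq
#' @param A,B,C substrate concentrations (mM)
#' @param P,Q product concentrations (mM)
#' @return rate (nmol·min^-1·mg^-1)
#' @export
rate_ter_bi <- function(p, A, B, C, P, Q) {
  num <- (p$Vmaxf / (p$Ka * p$Kb * p$Kc)) * (A * B * C - P * Q / p$Keq)
  den <- 1 + A / p$Ka + A * B / (p$Ka * p$Kb) + A * B * C / (p$Ka * p$Kb * p$Kc) +
    P * Q / (p$Kp * p$Kq) + Q / p$Kq
  num / den
}

#' Random bi-bi reversible Michaelis-Menten rate (CS)
#'
#' The printed denominator term "\[Q\]Kp" is implemented as Q/Kq (standard
#' random bi-bi form; otherwise Kq would be unused).
#'
#' @inheritParams rate_ter_bi
#' @return rate
#' @export
rate_random_bi_bi <- function(p, A, B, P, Q) {
  num <- (p$Vmaxf / (p$Ka * p$Kb)) * (A * B - P * Q / p$Keq)
  den <- 1 + A / p$Ka + B / p$Kb + A * B / (p$Ka * p$Kb) +
    P / p$Kp + Q / p$Kq + P * Q / (p$Kp * p$Kq) +
    A * Q / (p$Ka * p$Kq) + P * B / (p$Kp * p$Kb)
  num / den
}

#' Mono-reactant reversible Michaelis-Menten rate (ACO, pyruvate transport)
#' @inheritParams rate_ter_bi
#' @return rate
#' @export
rate_uni_uni <- function(p, A, P) {
  (p$Vmaxf / p$Ka) * (A - P / p$Keq) / (1 + A / p$Ka + P / p$Kp)
}

#' MWC allosteric rate for NAD-dependent isocitrate dehydrogenase
#'
#' Concerted-transition (Monod-Wyman-Changeux) term in isocitrate with
#' exclusive binding and NADH as allosteric inhibitor, gated by a Michaelis
#' term in NAD+ (with NADH competitive inhibition versus NAD+), minus a
#' reversible product term. General MWC form with site count n and
#' transition constant L from the fitted kinetics.
#'
#' @param p parameter list (Vmaxf, Ka = Km NAD+, Kb = K0.5 Iso, Kp, Kq, Keq,
#'   L, n, Ki_NADH_vs_Iso, Ki_NADH_vs_NAD)
#' @param NAD,Iso substrate concentrations (mM)
#' @param OXO,NADH product concentrations (mM); NADH also inhibits
#' @return rate
#' @export
rate_mwc_idh_nad <- function(p, NAD, Iso, OXO, NADH) {
  if (p$L <= 0) stop("configuration error: mwc_idh requires L > 0")
  if (p$n < 1) stop("configuration error: mwc_idh requires n >= 1")
  a <- NAD / (p$Ka * (1 + NADH / p$Ki_NADH_vs_NAD))
  gate <- a / (1 + a)
  al <- Iso / p$Kb
  mwc <- (al * (1 + al)^(p$n - 1)) /
    (p$L * (1 + NADH / p$Ki_NADH_vs_Iso)^p$n + (1 + al)^p$n)
  rev <- (OXO * NADH / (p$Kp * p$Kq * p$Keq)) /
    (1 + OXO / p$Kp + NADH / p$Kq + OXO * NADH / (p$Kp * p$Kq))
  p$Vmaxf * (gate * mwc - rev)
}

#' NADP-dependent isocitrate dehydrogenase rate with GSH and NAD+ inhibition
#'
#' Ordered bi-bi reversible form (A = NADP+, B = Iso, P = 2-oxoglutarate,
#' Q = NADPH) with GSH competitive inhibition versus isocitrate and NAD+
#' competitive inhibition versus NADP+.
#'
#' @inheritParams rate_ter_bi
#' @param GSH,NAD inhibitor concentrations (mM)
#' @return rate
#' @export
rate_idh_nadp <- function(p, A, B, P, Q, GSH, NAD) {
  num <- (p$Vmaxf / (p$Ka * p$Kb)) * (A * B - P * Q / p$Keq)
  den <- 1 + A / p$Ka + A * GSH / (p$Ka * p$Ki_GSH) + A * B / (p$Ka * p$Kb) +
    Q * B / (p$Kq * p$Kb) + Q * P / (p$Kq * p$Kp) + Q / p$Kq + NAD / p$Ki_NAD
  num / den
}

#' Ordered ter-ter reversible Michaelis-Menten rate (SCS)
#'
#' Denominator uses AB/(Ka Kb) and QR/(Kq Kr) (dimensionally consistent
#' ordered ter-ter form).
#'
#' @inheritParams rate_ter_bi
#' @param R third product concentration (mM)
#' @return rate
#' @export
rate_ter_ter <- function(p, A, B, C, P, Q, R) {
  num <- (p$Vmaxf / (p$Ka * p$Kb * p$Kc)) * (A * B * C - P * Q * R / p$Keq)
  den <- 1 + A / p$Ka + A * B / (p$Ka * p$Kb) + A * B * C / (p$Ka * p$Kb * p$Kc) +
    P * Q * R / (p$Kp * p$Kq * p$Kr) + Q * R / (p$Kq * p$Kr) + R / p$Kr
  num / den
}

#' Ordered bi-bi reversible Michaelis-Menten rate
#'
#' Used for SDH, AST, ALT, ME and the Mal/Iso, Mal/Suc and Mal/2-oxo
#' exchangers.
#'
#' @inheritParams rate_ter_bi
#' @return rate
#' @export
rate_bi_bi <- function(p, A, B, P, Q) {
  num <- (p$Vmaxf / (p$Ka * p$Kb)) * (A * B - P * Q / p$Keq)
  den <- 1 + A / p$Ka + A * B / (p$Ka * p$Kb) + P * Q / (p$Kp * p$Kq) + Q / p$Kq
  num / den
}

#' Mono-reactant reversible rate with independent Vmaxf/Vmaxr (FH)
#' @inheritParams rate_ter_bi
#' @return rate
#' @export
rate_uni_uni_2V <- function(p, A, P) {
  (p$Vmaxf * A / p$Ka - p$Vmaxr * P / p$Kp) / (1 + A / p$Ka + P / p$Kp)
}

#' Ordered bi-bi reversible rate with independent Vmaxf/Vmaxr (MDH)
#' @inheritParams rate_ter_bi
#' @return rate
#' @export
rate_bi_bi_2V <- function(p, A, B, P, Q) {
  num <- p$Vmaxf * A * B / (p$Ka * p$Kb) - p$Vmaxr * P * Q / (p$Kp * p$Kq)
  den <- 1 + A / p$Ka + A * B / (p$Ka * p$Kb) + P * Q / (p$Kp * p$Kq) + Q / p$Kq
  num / den
}

#' Glutamate dehydrogenase rate (MWC gate on ammonium)
#'
#' Forward Michaelis terms in NADP+ (A) and glutamate (B); reverse term in
#' 2-oxoglutarate (P) and NADPH (Q) gated by a concerted-transition MWC term
#' in NH4+ (R) with GTP inhibition (Ki_GTP) and ADP activation (Ka_ADP)
#' acting on the allosteric transition constant L.
#'
#' @inheritParams rate_ter_bi
#' @param R NH4+ concentration (mM)
#' @param GTP,ADP effector concentrations (mM)
#' @return rate
#' @export
rate_gdh <- function(p, A, B, P, Q, R, GTP, ADP) {
  if (p$L <= 0) stop("configuration error: gdh_mwc requires L > 0")
  fwd <- (A * B / (p$Ka * p$Kb)) / (1 + A / p$Ka + A * B / (p$Ka * p$Kb))
  rev <- (P * Q / (p$Kp * p$Kq)) / (1 + P / p$Kp + P * Q / (p$Kp * p$Kq))
  Leff <- p$L * (1 + GTP / p$Ki_GTP)^p$n / (1 + ADP / p$Ka_ADP)
  al <- R / p$Kr
  gate <- (al * (1 + al)^(p$n - 1)) / (Leff + (1 + al)^p$n)
  p$Vmaxf * fwd - p$Vmaxr * rev * gate
}

#' Glutathione reductase rate (ordered bi-ter; Q and R are both GSH)
#' @inheritParams rate_ter_ter
#' @return rate
#' @export
rate_gr <- function(p, A, B, P, Q, R) {
  num <- (p$Vmaxf / (p$Ka * p$Kb)) * (A * B - P * Q * R / p$Keq)
  den <- 1 + A / p$Ka + A * B / (p$Ka * p$Kb) +
    P * Q * R / (p$Kp * p$Kq * p$Kr) + Q * R / (p$Kq * p$Kr) +
    Q / p$Kq + R / p$Kr
  num / den
}

#' Guarded constant-flux boundary rate (complex-I NADH consumption, GSH oxidation)
#'
#' v = Vc * S/(S + eps) with eps = `KC_FLUX_GUARD_EPS`; numerically constant
#' for S >> eps and exactly zero at S = 0 so the substrate pool cannot be
#' driven negative.
#'
#' @param p parameter list with flux constant Vc
#' @param S substrate concentration (mM)
#' @return rate
#' @export
rate_constant_flux <- function(p, S) {
  p$Vc * S / (S + KC_FLUX_GUARD_EPS)
}

#' Haldane-implied reverse limiting rate for single-Vmax reversible forms
#'
#' For the one-Vmax mechanisms the reverse-direction plateau is
#' Vmaxf * prod(product K's) / (prod(substrate K's) * Keq); reported as a
#' diagnostic (Haldane consistency is not enforced).
#'
#' @param p parameter list
#' @param mechanism mechanism tag
#' @return implied reverse limiting rate, or NA for mechanisms where the
#'   notion does not apply
#' @export
haldane_vmaxr <- function(p, mechanism) {
  switch(mechanism,
    ter_bi       = p$Vmaxf * p$Kp * p$Kq / (p$Ka * p$Kb * p$Kc * p$Keq),
    random_bi_bi = p$Vmaxf * p$Kp * p$Kq / (p$Ka * p$Kb * p$Keq),
    uni_uni      = p$Vmaxf * p$Kp / (p$Ka * p$Keq),
    bi_bi        = p$Vmaxf * p$Kp * p$Kq / (p$Ka * p$Kb * p$Keq),
    bi_bi_inhib  = p$Vmaxf * p$Kp * p$Kq / (p$Ka * p$Kb * p$Keq),
    ter_ter      = p$Vmaxf * p$Kp * p$Kq * p$Kr / (p$Ka * p$Kb * p$Kc * p$Keq),
    gr_bi_ter    = p$Vmaxf * p$Kp * p$Kq * p$Kr / (p$Ka * p$Kb * p$Keq),
    uni_uni_2V   = p$Vmaxr,
    bi_bi_2V     = p$Vmaxr,
    gdh_mwc      = p$Vmaxr,
    mwc_idh      = p$Vmaxf / p$Keq, # supremum of the reverse product term
    constant_flux = NA_real_,
    NA_real_)
}

# generic dispatcher used by the network evaluator: conc is a named numeric
# vector of the bound role concentrations (A,B,C,P,Q,R,S and modifiers)
.rate_dispatch <- function(mechanism, p, conc) {
  switch(mechanism,
    ter_bi        = rate_ter_bi(p, conc[["A"]], conc[["B"]], conc[["C"]], conc[["P"]], conc[["Q"]]),
    random_bi_bi  = rate_random_bi_bi(p, conc[["A"]], conc[["B"]], conc[["P"]], conc[["Q"]]),
    uni_uni       = rate_uni_uni(p, conc[["A"]], conc[["P"]]),
    mwc_idh       = rate_mwc_idh_nad(p, conc[["A"]], conc[["B"]], conc[["P"]], conc[["Q"]]),
    bi_bi_inhib   = rate_idh_nadp(p, conc[["A"]], conc[["B"]], conc[["P"]], conc[["Q"]],
                                  conc[["GSH"]], conc[["NAD"]]),
    ter_ter       = rate_ter_ter(p, conc[["A"]], conc[["B"]], conc[["C"]], conc[["P"]],
                                 conc[["Q"]], conc[["R"]]),
    bi_bi         = rate_bi_bi(p, conc[["A"]], conc[["B"]], conc[["P"]], conc[["Q"]]),
    uni_uni_2V    = rate_uni_uni_2V(p, conc[["A"]], conc[["P"]]),
    bi_bi_2V      = rate_bi_bi_2V(p, conc[["A"]], conc[["B"]], conc[["P"]], conc[["Q"]]),
    gdh_mwc       = rate_gdh(p, conc[["A"]], conc[["B"]], conc[["P"]], conc[["Q"]],
                             conc[["R"]], conc[["GTP"]], conc[["ADP"]]),
    gr_bi_ter     = rate_gr(p, conc[["A"]], conc[["B"]], conc[["P"]], conc[["Q"]], conc[["R"]]),
    constant_flux = rate_constant_flux(p, conc[["S"]]),
    stop("unknown mechanism: ", mechanism))
}

# roles consumed by each mechanism (species bound to these names)
.mech_roles <- list(
  ter_bi        = c("A", "B", "C", "P", "Q"),
  random_bi_bi  = c("A", "B", "P", "Q"),
  uni_uni       = c("A", "P"),
  mwc_idh       = c("A", "B", "P", "Q"),
  bi_bi_inhib   = c("A", "B", "P", "Q", "GSH", "NAD"),
  ter_ter       = c("A", "B", "C", "P", "Q", "R"),
  bi_bi         = c("A", "B", "P", "Q"),
  uni_uni_2V    = c("A", "P"),
  bi_bi_2V      = c("A", "B", "P", "Q"),
  gdh_mwc       = c("A", "B", "P", "Q", "R", "GTP", "ADP"),
  gr_bi_ter     = c("A", "B", "P", "Q", "R"),
  constant_flux = "S"
)

#' Roles required by a mechanism
#' @param mechanism mechanism tag
#' @return character vector of role names
#' @export
mechanism_roles <- function(mechanism) {
  r <- .mech_roles[[mechanism]]
  if (is.null(r)) stop("unknown mechanism: ", mechanism)
  r
}
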