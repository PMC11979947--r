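#' Post-model analyses: respiration stoichiometry and inhibitor titrations
#'
#' Conversion between state-3 oxygen-consumption rates and Krebs-cycle flux
#' (each NADH or FADH2 oxidized consumes half an O2, so one cycle turn on
#' pyruvate/malate consumes 2.5 O2), and in-silico activity titrations of the
#' complex-I NADH-consumption step (rotenone analogue) and of SDH (malonate
#' analogue).
#'
#' @name scenarios
#' @keywords internal
NULL

#' Krebs-cycle flux from a state-3 oxygen-consumption rate
#'
#' flux = O2_rate / (0.5 * (nadh_per_turn + fadh2_per_turn)); for the
#' pyruvate/malate condition 4 NADH (PDH, IDH, 2OGDH, MDH) and 1 FADH2 (SDH)
#' are produced per turn, so one turn consumes 2.5 O2. Exactly linear and
#' invertible: flux * 2.5 recovers the O2 rate.
#'
#' @param state3_rate O2-consumption rate (nmol O2 min^-1 mg^-1)
#' @param nadh_per_turn NADH produced per cycle turn (default 4)
#' @param fadh2_per_turn FADH2 produced per cycle turn (default 1)
#' @return KC flux (nmol min^-1 mg^-1)
#' @export
kc_flux_from_o2 <- function(state3_rate, nadh_per_turn = 4, fadh2_per_turn = 1) {
  state3_rate / (0.5 * (nadh_per_turn + fadh2_per_turn))
}

#' Count reducing equivalents produced per cycle turn
#'
#' Counts the NADH-producing reactions (positive NADH stoichiometry,
#' excluding boundary consumption) and CoQ-reducing (FADH2-linked) reactions
#' on the cycle path for a substrate condition. For pyruvate/malate the full
#' cycle is active: 4 NADH (PDH, IDH-NAD, 2OGDH, MDH) and 1 FADH2 (SDH).
#' IDH-NADP reduces NADP, not NAD, and is not counted.
#'
#' @param net `kc_network`
#' @param condition substrate condition tag (only "Pyr/Mal" is modelled)
#' @return list(nadh, fadh2, nadh_reactions, fadh2_reactions)
#' @export
count_redox_per_turn <- function(net, condition = "Pyr/Mal") {
  if (condition != "Pyr/Mal")
    stop("only the Pyr/Mal condition is modelled")
  S <- net$S
  nadh_rxn <- colnames(S)[S["NADH", ] > 0]
  # CoQ is a fixed species; FADH2-linked steps bind CoQ as substrate role B
  fadh_rxn <- names(Filter(function(r)
    !is.na(r$roles["B"]) && r$roles[["B"]] == "CoQ", net$reactions))
  list(nadh = length(nadh_rxn), fadh2 = length(fadh_rxn),
       nadh_reactions = nadh_rxn, fadh2_reactions = fadh_rxn)
}

#' Titrate a reaction's activity and record the flux-response curve
#'
#' Re-solves the steady state at each activity factor (descending from 1)
#' and reports the reference (KC) flux, normalized to the unperturbed flux.
#' Non-convergent points are flagged and excluded from IC50 interpolation.
#'
#' @param net calibrated `kc_network`
#' @param reaction reaction id to titrate (e.g. "NADH_CONS" or "SDH")
#' @param factors activity factors in (0, 1], sorted descending; default 40
#'   log-spaced factors from 1 to 0.01
#' @param ref_flux reference flux reaction (default the network KC flux)
#' @return `kc_titration` data.frame-backed object with factors, kc_flux,
#'   normalized flux and `flux_ic50`
#' @export
titrate_activity <- function(net, reaction,
                             factors = exp(seq(log(1), log(0.01), length.out = 40)),
                             ref_flux = net$kc_flux_reaction) {
  if (!reaction %in% names(net$reactions)) stop("unknown reaction: ", reaction)
  if (any(factors <= 0 | factors > 1)) stop("factors must lie in (0, 1]")
  if (is.unsorted(rev(factors))) stop("factors must be sorted descending")
  ss0 <- steady_state(net)
  if (!ss0$converged) stop("reference steady state did not converge")
  J0 <- unname(ss0$fluxes[ref_flux])
  flux <- rep(NA_real_, length(factors))
  conv <- logical(length(factors))
  xprev <- ss0$concentrations
  for (i in seq_along(factors)) {
    netp <- net
    netp$reactions[[reaction]]$activity <-
      net$reactions[[reaction]]$activity * factors[i]
    netp <- kc_compile(netp)
    res <- tryCatch(newton_refine(netp, xprev), error = function(e) NULL)
    if (is.null(res) || !res$converged)
      res <- tryCatch(integrate_to_steady_state(netp, xprev),
                      error = function(e) NULL)
    if (!is.null(res) && res$converged) {
      flux[i] <- unname(res$fluxes[ref_flux])
      conv[i] <- TRUE
      xprev <- res$concentrations
    }
  }
  curve <- structure(list(reaction = reaction, ref_flux = ref_flux,
                          factors = factors, kc_flux = flux,
                          normalized = flux / J0, converged = conv, J0 = J0),
                     class = "kc_titration")
  curve$flux_ic50 <- flux_ic50(curve)
  curve
}

#' Activity factor at which the normalized flux crosses one half
#'
#' Linear interpolation in log(activity factor); `NA` if the curve never
#' crosses 0.5 among converged points.
#'
#' @param curve `kc_titration`
#' @return interpolated factor, or NA
#' @export
flux_ic50 <- function(curve) {
  ok <- curve$converged & is.finite(curve$normalized)
  f <- curve$factors[ok]; y <- curve$normalized[ok]
  if (!length(y) || all(y > 0.5) || all(y < 0.5)) return(NA_real_)
  hit <- which(abs(y - 0.5) < 1e-12)
  if (length(hit)) return(f[hit[1]])
  i <- which(diff(sign(y - 0.5)) != 0)[1]
  if (is.na(i)) return(NA_real_)
  lf1 <- log(f[i]); lf2 <- log(f[i + 1])
  exp(lf1 + (0.5 - y[i]) * (lf2 - lf1) / (y[i + 1] - y[i]))
}

#' @export
print.kc_titration <- function(x, ...) {
  cat(sprintf("Titration of %s (reference flux %s): J0 = %.4g\n",
              x$reaction, x$ref_flux, x$J0))
  cat(sprintf("  flux IC50 (activity factor): %s\n",
              if (is.na(x$flux_ic50)) "not crossed" else
                format(x$flux_ic50, digits = 4)))
  invisible(x)
}
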