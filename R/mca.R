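#' Metabolic Control Analysis
#'
#' Scaled elasticities, flux control coefficients (FCC) and concentration
#' control coefficients (CCC) at a solved steady state. The primary method
#' perturbs each reaction's activity by a relative `delta` and re-solves the
#' steady state (finite differences on re-solved states are robust in the
#' presence of conserved moieties); the classical matrix method (elasticities
#' plus link matrix) is available as a cross-check. Activity scaling
#' multiplies Vmaxf and Vmaxr together (and the flux constant of the
#' constant-flux boundary reactions), modelling an enzyme-amount
#' perturbation.
#'
#' @name mca
#' @keywords internal
NULL

#' Scaled elasticity coefficients
#'
#' eps(v, s) = (s/v) dv/ds by central differences with relative step
#' `rel_step`; entries for species that do not appear in a rate law are
#' exactly zero.
#'
#' @param net `kc_network`
#' @param ss `kc_steady_state` (or a state vector)
#' @param rel_step relative finite-difference step (default 1e-5)
#' @return matrix reactions x variable species
#' @export
scaled_elasticities <- function(net, ss, rel_step = 1e-5) {
  x <- if (inherits(ss, "kc_steady_state")) ss$concentrations else ss[net$var_ids]
  v0 <- rate_vector(net, x)
  E <- matrix(0, length(net$reactions), length(net$var_ids),
              dimnames = list(names(net$reactions), net$var_ids))
  for (s in net$var_ids) {
    touched <- vapply(net$reactions, function(r) s %in% r$roles, TRUE)
    if (!any(touched)) next
    h <- rel_step * max(abs(x[s]), 1e-8)
    xp <- x; xp[s] <- x[s] + h
    xm <- x; xm[s] <- max(x[s] - h, 0)
    vp <- rate_vector(net, xp); vm <- rate_vector(net, xm)
    dv <- (vp - vm) / (xp[s] - xm[s])
    E[touched, s] <- dv[touched] * x[s] / v0[touched]
  }
  E
}

# unscaled dv/dx matrix (reactions x variable species)
.kc_dvdx <- function(net, x, rel_step = 1e-6) {
  E <- matrix(0, length(net$reactions), length(net$var_ids),
              dimnames = list(names(net$reactions), net$var_ids))
  for (s in net$var_ids) {
    touched <- vapply(net$reactions, function(r) s %in% r$roles, TRUE)
    if (!any(touched)) next
    h <- max(rel_step * abs(x[s]), 1e-9)
    xp <- x; xp[s] <- x[s] + h
    xm <- x; xm[s] <- max(x[s] - h, 0)
    vp <- rate_vector(net, xp); vm <- rate_vector(net, xm)
    E[touched, s] <- (vp - vm)[touched] / (xp[s] - xm[s])
  }
  E
}

# re-solve the steady state with one reaction's activity scaled by `factor`,
# warm-starting Newton from the reference state
.kc_perturbed_ss <- function(net, ss, rid, factor, tol = 1e-11) {
  netp <- net
  netp$reactions[[rid]]$activity <- netp$reactions[[rid]]$activity * factor
  netp <- kc_compile(netp)
  res <- tryCatch(newton_refine(netp, ss$concentrations, tol = tol),
                  error = function(e) NULL)
  if (is.null(res) || !res$converged)
    res <- tryCatch(integrate_to_steady_state(netp, ss$concentrations,
                                              tol = tol),
                    error = function(e) NULL)
  res
}

# one scaled control coefficient by central difference with adaptive step:
# if the observed relative change leaves the linear regime (> 2%), the
# perturbation is shrunk tenfold (up to twice) — large coefficients on
# knife-edge states would otherwise be badly underestimated
.kc_cc_adaptive <- function(net, ss, rid, delta, extract, ref0) {
  d <- delta
  for (k in 1:3) {
    up <- .kc_perturbed_ss(net, ss, rid, 1 + d)
    dn <- .kc_perturbed_ss(net, ss, rid, 1 - d)
    if (is.null(up) || is.null(dn) || !up$converged || !dn$converged)
      return(NA_real_)
    coef <- (extract(up) - extract(dn)) / (2 * d * ref0)
    if (abs(coef) * d <= 2e-4 || k == 3 || d <= 1e-6) return(coef)
    d <- d / 10
  }
  coef
}

#' Flux control coefficients by steady-state re-solution
#'
#' C^J_i = (a_i/J) dJ/da_i, central difference at activity factors 1 +/-
#' `delta`. For constant-flux reactions the perturbed quantity is the flux
#' constant (activity multiplies it). Non-convergent perturbed solves are
#' flagged `NA`, never silently zero.
#'
#' @param net `kc_network`
#' @param ss solved `kc_steady_state` (must be converged)
#' @param ref_flux reference flux reaction id (default: the network's KC flux
#'   reaction, MDH for the tissue models)
#' @param delta relative activity perturbation (default 1e-3)
#' @return `kc_control` list with fcc vector, fcc_sum, method
#' @export
flux_control_coefficients <- function(net, ss, ref_flux = net$kc_flux_reaction,
                                      delta = 1e-3) {
  stopifnot(inherits(ss, "kc_steady_state"))
  if (!ss$converged) stop("steady state not converged; refuse MCA")
  if (!ref_flux %in% names(net$reactions)) stop("unknown reference flux: ", ref_flux)
  J0 <- unname(ss$fluxes[ref_flux])
  cc <- stats::setNames(rep(NA_real_, length(net$reactions)),
                        names(net$reactions))
  for (rid in names(net$reactions))
    cc[rid] <- .kc_cc_adaptive(net, ss, rid, delta,
                               function(s) unname(s$fluxes[ref_flux]), J0)
  structure(list(fcc = cc, fcc_sum = sum(cc, na.rm = TRUE),
                 ref_flux = ref_flux, delta = delta,
                 method = "finite_difference"), class = "kc_control")
}

#' Concentration control coefficients by steady-state re-solution
#'
#' C^S_i = (a_i/S) dS/da_i with the same perturbation protocol as
#' [flux_control_coefficients()].
#'
#' @inheritParams flux_control_coefficients
#' @param species species whose concentration is controlled (default NADH)
#' @return `kc_control` list with ccc vector and ccc_sum
#' @export
concentration_control_coefficients <- function(net, ss, species = "NADH",
                                               delta = 1e-3) {
  stopifnot(inherits(ss, "kc_steady_state"))
  if (!ss$converged) stop("steady state not converged; refuse MCA")
  if (!species %in% net$var_ids) stop("unknown species: ", species)
  S0 <- unname(ss$concentrations[species])
  cc <- stats::setNames(rep(NA_real_, length(net$reactions)),
                        names(net$reactions))
  for (rid in names(net$reactions))
    cc[rid] <- .kc_cc_adaptive(net, ss, rid, delta,
                               function(s) unname(s$concentrations[species]),
                               S0)
  structure(list(ccc = cc, ccc_sum = sum(cc, na.rm = TRUE),
                 species = species, delta = delta,
                 method = "finite_difference"), class = "kc_control")
}

#' Control coefficients by the matrix method (cross-check)
#'
#' Classical summation-consistent computation from unscaled elasticities and
#' the link matrix of the moiety-reduced system:
#' C_x = -L (N_R Dv L)^{-1} N_R, C_v = I + Dv C_x, then scaled by fluxes and
#' concentrations.
#'
#' @param net `kc_network`
#' @param ss solved steady state
#' @return list(fcc_matrix, ccc_matrix) of scaled control matrices
#'   (rows: controlled flux/species, columns: controlling reaction)
#' @export
control_matrices <- function(net, ss) {
  x <- ss$concentrations
  v <- ss$fluxes
  red <- .kc_reduction(net)
  indep <- red$indep
  # link matrix: x_full = L y + const
  L <- matrix(0, length(net$var_ids), length(indep),
              dimnames = list(net$var_ids, indep))
  L[indep, indep] <- diag(length(indep))
  for (m in net$moieties) {
    bal <- names(m$coef)[1]
    oth <- names(m$coef)[-1]
    L[bal, oth[oth %in% indep]] <-
      -m$coef[oth[oth %in% indep]] / m$coef[[bal]]
  }
  Dv <- .kc_dvdx(net, x)              # r x m
  NR <- net$S[indep, , drop = FALSE]  # independent rows
  M <- NR %*% Dv %*% L
  Cx <- -L %*% solve(M, NR)           # m x r (unscaled)
  Cv <- diag(length(v)) + Dv %*% Cx   # r x r (unscaled)
  fcc <- sweep(sweep(Cv, 2, v, "*"), 1, v, "/")
  ccc <- sweep(sweep(Cx, 2, v, "*"), 1, x, "/")
  dimnames(fcc) <- list(names(v), names(v))
  dimnames(ccc) <- list(names(x), names(v))
  list(fcc_matrix = fcc, ccc_matrix = ccc, method = "matrix")
}

#' Summation-theorem diagnostics
#'
#' Flux control coefficients over all steps sum to 1; concentration control
#' coefficients sum to 0.
#'
#' @param result `kc_control` from [flux_control_coefficients()] or
#'   [concentration_control_coefficients()], or a bare named numeric vector
#'   (interpreted by `type`)
#' @param type "fcc" or "ccc" when a bare vector is supplied
#' @param tol pass tolerance (default 1e-3)
#' @return list(sum, expected, pass, largest) where largest lists the largest
#'   contributors on failure
#' @export
check_summation <- function(result, type = NULL, tol = 1e-3) {
  if (inherits(result, "kc_control")) {
    if (!is.null(result$fcc)) { cc <- result$fcc; expected <- 1 }
    else { cc <- result$ccc; expected <- 0 }
  } else {
    stopifnot(type %in% c("fcc", "ccc"))
    cc <- result
    expected <- if (type == "fcc") 1 else 0
  }
  s <- sum(cc, na.rm = TRUE)
  pass <- abs(s - expected) <= tol
  largest <- if (!pass) sort(abs(cc), decreasing = TRUE)[
    seq_len(min(5, length(cc)))] else NULL
  list(sum = s, expected = expected, pass = pass, largest = largest)
}

#' Full control analysis of a network
#'
#' Convenience wrapper: solves (or accepts) a steady state, computes scaled
#' elasticities, FCCs for a reference flux and CCCs for a species, plus
#' summation diagnostics.
#'
#' @inheritParams flux_control_coefficients
#' @param species species for concentration control (default NADH)
#' @return `kc_control_analysis` list
#' @export
control_analysis <- function(net, ss = NULL, ref_flux = net$kc_flux_reaction,
                             species = "NADH", delta = 1e-3) {
  if (is.null(ss)) ss <- steady_state(net)
  el <- scaled_elasticities(net, ss)
  f <- flux_control_coefficients(net, ss, ref_flux, delta)
  c <- concentration_control_coefficients(net, ss, species, delta)
  structure(list(
    elasticities = el,
    fcc = f$fcc, ccc = c$ccc,
    fcc_sum = f$fcc_sum, ccc_sum = c$ccc_sum,
    ref_flux = ref_flux, species = species,
    summation = list(fcc = check_summation(f), ccc = check_summation(c)),
    steady_state = ss, method = "finite_difference"
  ), class = "kc_control_analysis")
}

#' @export
print.kc_control_analysis <- function(x, ...) {
  cat("Metabolic Control Analysis (", x$method, ")\n", sep = "")
  cat(sprintf("  reference flux: %s; species: %s\n", x$ref_flux, x$species))
  tab <- data.frame(reaction = names(x$fcc),
                    FCC = round(unname(x$fcc), 4),
                    CCC = round(unname(x$ccc), 4))
  print(tab, row.names = FALSE)
  cat(sprintf("  sum FCC = %.6f (theorem: 1); sum CCC = %.6f (theorem: 0)\n",
              x$fcc_sum, x$ccc_sum))
  invisible(x)
}
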