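#' Steady-state solution of the Krebs-cycle ODE system
#'
#' The network defines dx/dt = S v(x) with conserved cofactor moieties
#' (NAD(H), NADP(H), glutathione, CoA esters). No external stiff-ODE solver
#' is assumed: integration to steady state uses an adaptive linearly
#' implicit (backward-Euler / pseudo-transient) scheme with numerical
#' Jacobians, followed by damped Newton refinement on the moiety-reduced
#' system.
#'
#' @name steady_state
#' @keywords internal
NULL

# numerical Jacobian of dx/dt with respect to the variable species
.kc_jacobian <- function(net, x, f0 = NULL) {
  n <- length(x)
  if (is.null(f0)) f0 <- kc_dxdt(net, x)
  J <- matrix(0, n, n, dimnames = list(names(x), names(x)))
  for (i in seq_len(n)) {
    h <- max(1e-7, 1e-6 * abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    J[, i] <- (kc_dxdt(net, xp) - f0) / h
  }
  J
}

#' Integrate the network to steady state
#'
#' Adaptive linearly implicit pseudo-transient integration: each step solves
#' (I/h - J) dx = f(x) and accepts when the new state is non-negative and
#' the step behaves; the step size grows geometrically once progress is
#' smooth. Integration stops when max |dx/dt| < `tol` or `t_max` is reached.
#'
#' @param net `kc_network`
#' @param x0 initial variable-species state (default: network initial state;
#'   must be compatible with the configured moiety totals)
#' @param t_max maximum pseudo-time (min), default 1e6
#' @param tol convergence tolerance on max |dx/dt| (mM/min), default 1e-9
#' @param refine run Newton refinement after integration (default TRUE)
#' @return `kc_steady_state` list: concentrations, fluxes, kc_flux,
#'   residual_norm, converged, moiety_drift, t
#' @export
integrate_to_steady_state <- function(net, x0 = NULL, t_max = 1e6,
                                      tol = 1e-9, refine = TRUE) {
  stopifnot(tol > 0)
  x <- if (is.null(x0)) net$x0 else x0[net$var_ids]
  if (any(x < 0)) stop("solver error: negative initial concentration")
  n <- length(x)
  t <- 0
  h <- 1e-6
  f <- kc_dxdt(net, x)
  J <- NULL
  steps_since_jac <- Inf  # force factorization on first step
  iter <- 0L
  while (max(abs(f)) >= tol && t < t_max && iter < 20000L) {
    iter <- iter + 1L
    if (steps_since_jac > 5) {
      J <- .kc_jacobian(net, x, f)
      steps_since_jac <- 0
    }
    A <- diag(1 / h, n) - J
    dx <- tryCatch(solve(A, f), error = function(e) NULL)
    ok <- !is.null(dx) && all(is.finite(dx))
    if (ok) {
      xn <- x + dx
      if (any(xn < -1e-9)) ok <- FALSE else xn[xn < 0] <- 0
    }
    if (ok) {
      fn <- kc_dxdt(net, xn)
      # reject wildly diverging steps
      if (!all(is.finite(fn)) ||
          (max(abs(fn)) > 10 * max(abs(f)) && max(abs(f)) < 1e6)) ok <- FALSE
    }
    if (ok) {
      x <- xn; f <- fn; t <- t + h
      h <- min(h * 1.8, t_max / 10)
      steps_since_jac <- steps_since_jac + 1
    } else {
      h <- h / 4
      steps_since_jac <- Inf
      if (h < 1e-14) stop("solver error: step size underflow (guard/step failure)")
    }
  }
  res <- .kc_ss_result(net, x, t = t, tol = tol)
  if (refine && res$residual_norm > 0) {
    ref <- tryCatch(newton_refine(net, x, tol = tol), error = function(e) NULL)
    if (!is.null(ref) && ref$residual_norm <= res$residual_norm) {
      ref$t <- t
      res <- ref
    }
  }
  res
}

.kc_ss_result <- function(net, x, t = NA_real_, tol = 1e-9, eig = NULL) {
  f <- kc_dxdt(net, x)
  v <- rate_vector(net, x)
  drift <- if (length(net$moieties))
    max(abs(moiety_totals(net, x) -
            vapply(net$moieties, `[[`, 0, "total"))) else 0
  kcf <- if (!is.null(net$kc_flux_reaction) &&
             net$kc_flux_reaction %in% names(v))
    unname(v[net$kc_flux_reaction]) else NA_real_
  structure(list(
    concentrations = x,
    fluxes = v,
    kc_flux = kcf,
    residual_norm = max(abs(f)),
    converged = max(abs(f)) < tol,
    moiety_drift = drift,
    jacobian_eigenvalues = eig,
    t = t, tol = tol
  ), class = "kc_steady_state")
}

#' @export
print.kc_steady_state <- function(x, ...) {
  cat("Krebs-cycle steady state", if (x$converged) "(converged)" else
    "(NOT converged)", "\n")
  cat(sprintf("  KC flux (MDH): %.4g nmol/min/mg\n", x$kc_flux))
  cat(sprintf("  residual max|dx/dt|: %.3g mM/min; moiety drift: %.3g mM\n",
              x$residual_norm, x$moiety_drift))
  invisible(x)
}

# reduction: independent species = all variable species minus one balancing
# species per moiety (the first member of each coefficient vector)
.kc_reduction <- function(net) {
  dep <- vapply(net$moieties, function(m) names(m$coef)[1], "")
  indep <- setdiff(net$var_ids, dep)
  list(dep = dep, indep = indep)
}

.kc_expand <- function(net, y, red) {
  x <- stats::setNames(numeric(length(net$var_ids)), net$var_ids)
  x[red$indep] <- y
  for (m in net$moieties) {
    bal <- names(m$coef)[1]
    rest <- sum(m$coef[-1] * x[names(m$coef)[-1]])
    x[bal] <- (m$total - rest) / m$coef[[bal]]
  }
  x
}

#' Damped Newton refinement of a near-steady state
#'
#' Operates on the moiety-reduced system (one dependent species per
#' conserved pool eliminated) so the Jacobian is non-singular; the full
#' Jacobian is rank-deficient because of the conservation relations. Steps
#' are damped by halving until the residual norm decreases.
#'
#' @param net `kc_network`
#' @param x state near a steady state
#' @param tol residual tolerance for the converged flag
#' @param max_iter Newton iteration cap
#' @return `kc_steady_state` with reduced-Jacobian eigenvalues reported
#' @export
newton_refine <- function(net, x, tol = 1e-9, max_iter = 60) {
  x <- x[net$var_ids]
  red <- .kc_reduction(net)
  # recompute moiety totals from the entry state so refinement preserves them
  totals_in <- moiety_totals(net, x)
  net_loc <- net
  for (m in names(net_loc$moieties))
    net_loc$moieties[[m]]$total <- unname(totals_in[m])

  gfun <- function(y) {
    xx <- .kc_expand(net_loc, y, red)
    kc_dxdt(net_loc, xx)[red$indep]
  }
  y <- x[red$indep]
  g <- gfun(y)
  m <- length(y)
  # chord Newton: the Jacobian is reused across damped steps and only
  # recomputed when progress stalls (cheap for warm starts)
  jac <- function(y, g) {
    Jr <- matrix(0, m, m)
    for (i in seq_len(m)) {
      h <- max(1e-9, 1e-7 * abs(y[i]))
      yp <- y; yp[i] <- y[i] + h
      Jr[, i] <- (gfun(yp) - g) / h
    }
    Jr
  }
  Jr <- NULL
  fresh <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) < min(tol, 1e-12)) break
    if (is.null(Jr)) { Jr <- jac(y, g); fresh <- TRUE }
    dy <- tryCatch(solve(Jr, -g), error = function(e) NULL)
    if (is.null(dy)) { if (fresh) break; Jr <- NULL; next }
    lam <- 1
    improved <- FALSE
    for (k in 1:30) {
      yn <- y + lam * dy
      if (all(.kc_expand(net_loc, yn, red) >= 0)) {
        gn <- gfun(yn)
        if (all(is.finite(gn)) && max(abs(gn)) < max(abs(g))) {
          y <- yn; g <- gn; improved <- TRUE
          break
        }
      }
      lam <- lam / 2
    }
    if (improved) {
      fresh <- FALSE
    } else {
      if (fresh) break
      Jr <- NULL
    }
  }
  xfin <- .kc_expand(net_loc, y, red)
  eig <- if (!is.null(Jr)) eigen(Jr, only.values = TRUE)$values else NULL
  res <- .kc_ss_result(net, xfin, tol = tol, eig = eig)
  res
}

#' Solve a network to steady state (integration + Newton refinement)
#' @inheritParams integrate_to_steady_state
#' @return `kc_steady_state`
#' @export
steady_state <- function(net, x0 = NULL, t_max = 1e6, tol = 1e-9) {
  integrate_to_steady_state(net, x0 = x0, t_max = t_max, tol = tol,
                            refine = TRUE)
}

#' Fluxes through every reaction at a state
#' @param net `kc_network`
#' @param x variable-species state
#' @return named numeric vector of fluxes (activity scalings applied); the
#'   element for the reference reaction is the KC flux
#' @export
flux_profile <- function(net, x = net$x0) {
  rate_vector(net, x)
}
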