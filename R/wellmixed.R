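#' Parameters of the two-strain killing model
#'
#' Both strains share a basal growth rate `r` and density-dependent
#' mortality `s`, and differ only in their contact-killing rates: strain A
#' kills B at rate `alpha_ba` and strain B kills A at rate `alpha_ab`.
#' `d` is the cell dispersal (diffusion) coefficient used by the spatial
#' model. Defaults are the standard simulation values (r = 2, s = 2,
#' alpha_ab = alpha_ba = 0.5, d = 0.01).
#'
#' @param r Basal growth rate (1/time).
#' @param s Density-dependent mortality coefficient (1/(density time)).
#' @param alpha_ab Rate at which strain B kills strain A.
#' @param alpha_ba Rate at which strain A kills strain B.
#' @param d Cell dispersal coefficient (length^2/time).
#' @return List of class `two_strain_params`.
#' @export
two_strain_params <- function(r = 2, s = 2, alpha_ab = 0.5, alpha_ba = 0.5,
                              d = 0.01) {
  stopifnot(r >= 0, s >= 0, alpha_ab >= 0, alpha_ba >= 0, d >= 0)
  structure(list(r = r, s = s, alpha_ab = alpha_ab, alpha_ba = alpha_ba,
                 d = d),
            class = "two_strain_params")
}

#' Parameters of the public-goods extension
#'
#' Strain A (the cooperator) secretes a diffusible good at rate `rho`,
#' paying a growth-rate cost `c`; the good decays at rate `lambda`,
#' diffuses with coefficient `big_d`, and raises both strains' growth rate
#' by `b` per unit concentration. Killing is symmetric at rate `alpha`
#' (possibly 0). The constraint `s > rho * b / lambda` guarantees a finite
#' cooperator-only equilibrium. Defaults are the standard invasion-scenario
#' values (b = 1.9, c = 0.1, rho = lambda = 100, big_d = 0.1).
#'
#' @inheritParams two_strain_params
#' @param alpha Symmetric killing rate.
#' @param b Growth benefit per unit good concentration.
#' @param c Growth-rate cost of production.
#' @param rho Secretion rate.
#' @param lambda Good decay rate (1/time).
#' @param big_d Good diffusion coefficient (length^2/time).
#' @return List of class `public_goods_params` (also inherits the
#'   two-strain fields with `alpha_ab = alpha_ba = alpha`).
#' @export
public_goods_params <- function(r = 2, s = 2, alpha = 0.5, b = 1.9, c = 0.1,
                                rho = 100, lambda = 100, big_d = 0.1,
                                d = 0.01) {
  stopifnot(r >= 0, s >= 0, alpha >= 0, b >= 0, c >= 0, rho >= 0,
            lambda > 0, big_d >= 0, d >= 0)
  if (s <= rho * b / lambda)
    abort("invariant violated: need s > rho * b / lambda for a finite cooperator equilibrium")
  structure(list(r = r, s = s, alpha = alpha, alpha_ab = alpha,
                 alpha_ba = alpha, b = b, c = c, rho = rho, lambda = lambda,
                 big_d = big_d, d = d),
            class = c("public_goods_params", "two_strain_params"))
}

# Reaction right-hand side of the well-mixed two-strain system.
rhs_wellmixed_two_strain <- function(A, B, p) {
  tot <- A + B
  list(dA = A * (p$r - p$s * tot - p$alpha_ab * B),
       dB = B * (p$r - p$s * tot - p$alpha_ba * A))
}

# Reaction rhs of the well-mixed public-goods system (full 3 variables).
rhs_wellmixed_goods <- function(A, B, S, p) {
  tot <- A + B
  list(dA = A * (p$r - p$c + p$b * S - p$s * tot - p$alpha * B),
       dB = B * (p$r + p$b * S - p$s * tot - p$alpha * A),
       dS = p$rho * A - p$lambda * S)
}

# Quasi-steady-state reduced rhs: S = rho A / lambda.
rhs_wellmixed_goods_qss <- function(A, B, p) {
  S <- p$rho * A / p$lambda
  out <- rhs_wellmixed_goods(A, B, S, p)
  out[c("dA", "dB")]
}

# Central-difference Jacobian of a 2-variable reaction system.
numeric_jacobian <- function(fn, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  f0 <- fn(x)
  for (k in seq_len(n)) {
    h <- eps * max(1, abs(x[k]))
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    J[, k] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

classify_equilibrium <- function(J, tol = 1e-9) {
  tr <- sum(diag(J)); dt <- det(J)
  ev <- Re(eigen(J, only.values = TRUE)$values)
  cls <- if (dt < -tol) "saddle"
  else if (all(ev < -tol)) "stable"
  else if (any(ev > tol)) "unstable"
  else "marginal"
  list(trace = tr, det = dt, classification = cls, eigen = ev)
}

#' Equilibria and stability of the well-mixed two-strain system
#'
#' Returns the four equilibria — extinction (0, 0), the two single-strain
#' states (r/s, 0) and (0, r/s), and the coexistence point
#' `A* = alpha_ab r / (s (alpha_ab + alpha_ba) + alpha_ab alpha_ba)` (and
#' symmetrically for B*) — together with the trace and determinant of the
#' Jacobian and a stability classification from its eigenvalues.
#' With positive killing rates the extinction state is unstable, both
#' single-strain states are stable, and coexistence is a saddle: the
#' well-mixed system always resolves to one strain dominating, with the
#' separatrix at `A/B = alpha_ab / alpha_ba`.
#'
#' @param params A [two_strain_params()].
#' @return A tibble with columns `equilibrium`, `A`, `B`, `trace`, `det`,
#'   `classification`, `residual` (max |rhs| at the point).
#' @examples
#' equilibria_two_strain(two_strain_params())
#' @export
equilibria_two_strain <- function(params) {
  p <- params
  if (p$s == 0) abort("s = 0: single-strain equilibrium undefined")
  denom <- p$s * (p$alpha_ab + p$alpha_ba) + p$alpha_ab * p$alpha_ba
  pts <- list(
    extinction = c(0, 0),
    only_A = c(p$r / p$s, 0),
    only_B = c(0, p$r / p$s),
    coexistence = if (denom > 0)
      c(p$alpha_ab * p$r / denom, p$alpha_ba * p$r / denom) else c(NA, NA)
  )
  fn <- function(x) unlist(rhs_wellmixed_two_strain(x[1], x[2], p),
                           use.names = FALSE)
  rows <- purrr::imap(pts, function(x, nm) {
    if (anyNA(x)) return(NULL)
    cl <- classify_equilibrium(numeric_jacobian(fn, x))
    tibble(equilibrium = nm, A = x[1], B = x[2], trace = cl$trace,
           det = cl$det, classification = cl$classification,
           residual = max(abs(fn(x))))
  })
  dplyr::bind_rows(rows)
}

#' Predicted winner of a well-mixed two-strain contest
#'
#' From the saddle structure of the coexistence equilibrium: strain A
#' eventually dominates iff `A0 / B0 > alpha_ab / alpha_ba`, strain B iff
#' the ratio is below the threshold, and initial conditions exactly on the
#' threshold lie on the separatrix.
#'
#' @param A0,B0 Positive initial densities.
#' @param params A [two_strain_params()].
#' @return `"A"`, `"B"` or `"separatrix"`.
#' @examples
#' domination_outcome(0.6, 0.4, two_strain_params())
#' @export
domination_outcome <- function(A0, B0, params) {
  stopifnot(A0 > 0, B0 > 0)
  thr <- params$alpha_ab / params$alpha_ba
  ratio <- A0 / B0
  if (isTRUE(all.equal(ratio, thr))) "separatrix"
  else if (ratio > thr) "A" else "B"
}

#' Critical killing rate for cooperator stability
#'
#' Under the quasi-steady-state good (`S = rho A / lambda`) the
#' pure-cooperator equilibrium of the killing + public-goods model is
#' stable against rare cheats iff
#' `alpha > c (lambda s - rho b) / (lambda r - lambda c)`.
#'
#' @param params A [public_goods_params()].
#' @return The threshold killing rate.
#' @examples
#' alpha_crit(public_goods_params())  # 1/190
#' @export
alpha_crit <- function(params) {
  p <- params
  p$c * (p$lambda * p$s - p$rho * p$b) / (p$lambda * p$r - p$lambda * p$c)
}

#' Equilibria of the well-mixed cooperator/cheat system
#'
#' Uses the quasi-steady-state reduction `S = rho A / lambda`. The
#' pure-cooperator state sits at `A* = lambda (r - c) / (lambda s - rho b)`
#' and is stable iff `alpha` exceeds [alpha_crit()]; the pure-cheat state
#' `B* = r / s` is always stable; when the threshold is exceeded an
#' interior saddle appears whose A-coordinate exceeds its B-coordinate
#' whenever `c > 0` (the cooperator basin is the smaller one).
#'
#' @param params A [public_goods_params()].
#' @return Tibble as in [equilibria_two_strain()] plus column `S`
#'   (quasi-steady good concentration).
#' @examples
#' cooperator_equilibria(public_goods_params())
#' @export
cooperator_equilibria <- function(params) {
  p <- params
  if (p$s <= p$rho * p$b / p$lambda)
    abort("invariant violated: need s > rho * b / lambda")
  coopA <- p$lambda * (p$r - p$c) / (p$lambda * p$s - p$rho * p$b)
  pts <- list(cooperator = c(coopA, 0), cheat = c(0, p$r / p$s))
  if (p$alpha > alpha_crit(p) && p$alpha > 0) {
    As <- (p$r + p$s * p$c / p$alpha) /
      (2 * p$s + p$alpha - p$b * p$rho / p$lambda)
    Bs <- As - p$c / p$alpha
    if (As > 0 && Bs > 0) pts$saddle <- c(As, Bs)
  }
  fn <- function(x) unlist(rhs_wellmixed_goods_qss(x[1], x[2], p),
                           use.names = FALSE)
  rows <- purrr::imap(pts, function(x, nm) {
    cl <- classify_equilibrium(numeric_jacobian(fn, x))
    tibble(equilibrium = nm, A = x[1], B = x[2],
           S = p$rho * x[1] / p$lambda, trace = cl$trace, det = cl$det,
           classification = cl$classification, residual = max(abs(fn(x))))
  })
  dplyr::bind_rows(rows)
}

#' Per-capita fitness advantage of the cooperator
#'
#' The difference in per-capita growth rate between cooperator and cheat in
#' the well-mixed killing model under the quasi-steady-state good:
#' `w_A - w_B = -c + alpha (A - B)`. The shared good benefit cancels, so
#' the advantage is positive exactly when the cooperator's numerical excess
#' outweighs the production cost — the positive frequency dependence
#' induced by killing.
#'
#' @param A,B Densities (vectorised).
#' @param params A [public_goods_params()].
#' @return Numeric vector `w_A - w_B`.
#' @export
cooperator_advantage <- function(A, B, params) {
  -params$c + params$alpha * (A - B)
}

#' Integrate the well-mixed system
#'
#' Adaptive (lsoda) integration of the two-strain system or, with a
#' [public_goods_params()], the full three-variable cooperator/cheat/good
#' system. Densities are kept non-negative.
#'
#' @param init Named numeric: `A`, `B` and, for public goods, optionally
#'   `S` (default: quasi-steady value).
#' @param params [two_strain_params()] or [public_goods_params()].
#' @param t_end End time.
#' @param n_out Number of equally spaced output times.
#' @return Tibble with columns `time`, `A`, `B` (and `S`), plus `freq_a`.
#' @examples
#' integrate_wellmixed(c(A = 0.55, B = 0.45), two_strain_params(), 50)
#' @export
integrate_wellmixed <- function(init, params, t_end, n_out = 200) {
  goods <- inherits(params, "public_goods_params")
  if (goods && (!("S" %in% names(init)) || is.na(init[["S"]])))
    init["S"] <- params$rho * init[["A"]] / params$lambda
  fn <- function(t, y, parms) {
    y <- pmax(y, 0)
    d <- if (goods) rhs_wellmixed_goods(y[["A"]], y[["B"]], y[["S"]], parms)
    else rhs_wellmixed_two_strain(y[["A"]], y[["B"]], parms)
    list(unlist(d, use.names = FALSE))
  }
  yini <- if (goods) c(A = init[["A"]], B = init[["B"]], S = init[["S"]])
  else c(A = init[["A"]], B = init[["B"]])
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = yini, times = times, func = fn, parms = params)
  out <- as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  out$A <- pmax(out$A, 0); out$B <- pmax(out$B, 0)
  out$freq_a <- ifelse(out$A + out$B > 0, out$A / (out$A + out$B), NA_real_)
  out
}
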