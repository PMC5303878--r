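# Periodic 5-point Laplacian, vectorised. A single-row (or single-column)
# matrix degenerates to a 1-D periodic domain.
laplacian_periodic <- function(f, dx = 1) {
  up <- rbind(f[nrow(f), , drop = FALSE], f[-nrow(f), , drop = FALSE])
  down <- rbind(f[-1, , drop = FALSE], f[1, , drop = FALSE])
  left <- cbind(f[, ncol(f), drop = FALSE], f[, -ncol(f), drop = FALSE])
  right <- cbind(f[, -1, drop = FALSE], f[, 1, drop = FALSE])
  (up + down + left + right - 4 * f) / dx^2
}

#' Right-hand side of the spatial two-strain killing model
#'
#' The well-mixed dynamics extended with dispersal:
#' `dA/dt = A (r - s (A + B) - alpha_ab B) + d lap(A)` and
#' `dB/dt = B (r - s (A + B) - alpha_ba A) + d lap(B)`,
#' with the 5-point finite-difference Laplacian on a periodic grid.
#'
#' @param state A [field_state()] with fields `A` and `B`.
#' @param params A [two_strain_params()].
#' @return List of matrices `dA`, `dB`.
#' @examples
#' st <- field_state(matrix(1, 8, 8), matrix(0, 8, 8))
#' max(abs(rhs_two_strain(st, two_strain_params())$dA))  # ~0 at A = r/s
#' @export
rhs_two_strain <- function(state, params) {
  stopifnot(inherits(state, "field_state"))
  A <- state$A; B <- state$B
  tot <- A + B
  list(dA = A * (params$r - params$s * tot - params$alpha_ab * B) +
         params$d * laplacian_periodic(A, state$dx),
       dB = B * (params$r - params$s * tot - params$alpha_ba * A) +
         params$d * laplacian_periodic(B, state$dx))
}

#' Right-hand side of the spatial public-goods model
#'
#' Adds the cooperator's production cost `c`, the shared growth benefit
#' `b S`, and the good's own reaction-diffusion equation
#' `dS/dt = rho A - lambda S + D lap(S)`.
#'
#' @param state A [field_state()] with fields `A`, `B` and `S`.
#' @param params A [public_goods_params()].
#' @return List of matrices `dA`, `dB`, `dS`.
#' @export
rhs_public_goods <- function(state, params) {
  stopifnot(inherits(state, "field_state"))
  if (is.null(state$S)) abort("public-goods rhs needs an S field")
  A <- state$A; B <- state$B; S <- state$S
  tot <- A + B
  list(dA = A * (params$r - params$c + params$b * S - params$s * tot -
                   params$alpha * B) +
         params$d * laplacian_periodic(A, state$dx),
       dB = B * (params$r + params$b * S - params$s * tot -
                   params$alpha * A) +
         params$d * laplacian_periodic(B, state$dx),
       dS = params$rho * A - params$lambda * S +
         params$big_d * laplacian_periodic(S, state$dx))
}

check_cfl <- function(params, dx, dt) {
  dmax <- max(params$d, if (!is.null(params$big_d)) params$big_d else 0)
  bound <- dx^2 / (4 * max(dmax, .Machine$double.eps))
  if (dt >= bound)
    abort(sprintf(
      "dt = %g violates the diffusive stability bound dt < dx^2/(4 max(d, D)) = %g",
      dt, bound))
  invisible(bound)
}

#' Integrate the spatial model by forward Euler
#'
#' Explicit forward-Euler time stepping on a periodic grid, with the
#' diffusive CFL bound `dt < dx^2 / (4 max(d, D))` checked up front. With a
#' [public_goods_params()] the good's stiff production/decay term
#' (`lambda` of order 100) is advanced by its exact exponential solution
#' (operator splitting), so `dt` is set by the ecology and cell diffusion,
#' not by `lambda`. Fields are clipped at zero; clip events are counted and
#' reported with a warning (they vanish as `dt` decreases).
#'
#' @param state Initial [field_state()] (with `S` for public-goods runs;
#'   a missing `S` starts at its quasi-steady value).
#' @param params [two_strain_params()] or [public_goods_params()].
#' @param t_end End time.
#' @param dt Time step.
#' @param record_at Increasing times at which to record snapshots
#'   (rounded to whole steps; defaults to `t_end`).
#' @return Object of class `pde_run`: list with `states` (list of
#'   [field_state()]), `times`, `clips`, `params`.
#' @export
integrate_fields <- function(state, params, t_end, dt, record_at = NULL) {
  stopifnot(inherits(state, "field_state"))
  goods <- inherits(params, "public_goods_params")
  check_cfl(params, state$dx, dt)
  if (is.null(record_at)) record_at <- t_end
  stopifnot(all(diff(record_at) > 0), max(record_at) <= t_end + 1e-9)
  steps_at <- unique(pmax(0L, round(record_at / dt)))
  if (goods && is.null(state$S))
    state$S <- params$rho * state$A / params$lambda
  p <- params
  if (!goods) p$big_d <- NULL
  plist <- list(r = p$r, s = p$s, alpha_ab = p$alpha_ab,
                alpha_ba = p$alpha_ba, d = p$d)
  if (goods)
    plist <- c(plist, list(b = p$b, c = p$c, rho = p$rho, lambda = p$lambda,
                           big_d = p$big_d))
  states <- list(); times <- numeric(); clips <- 0
  done <- 0L
  A <- state$A; B <- state$B; S <- state$S
  for (target in steps_at) {
    n <- target - done
    if (n > 0) {
      res <- pde_run_cpp(A, B, S, plist, state$dx, dt, n, goods)
      A <- res$A; B <- res$B
      if (goods) S <- res$S
      clips <- clips + res$clips
      done <- target
    }
    st <- field_state(A, B, S = if (goods) S else NULL, dx = state$dx,
                      t = state$t + done * dt)
    states[[length(states) + 1]] <- st
    times <- c(times, st$t)
  }
  if (clips > 0)
    warn(sprintf("clipped %d negative field values at 0 during integration",
                 as.integer(clips)))
  structure(list(states = states, times = times, clips = clips,
                 params = params, dt = dt),
            class = "pde_run")
}

#' Growth rate of a sinusoidal composition perturbation
#'
#' Initialises a 1-D periodic domain at the homogeneous coexistence
#' equilibrium, perturbs the composition by `+a sin(beta x)` for strain A
#' and `-a sin(beta x)` for strain B, integrates briefly, and fits the
#' exponential growth rate of the `sin(beta x)` mode of the composition
#' `phi_A = A / (A + B)` (negative = decay). The domain is an integer
#' number of wavelengths by construction.
#'
#' For the symmetric two-strain model the linearised rate is
#' `alpha A* - d beta^2` (with `A*` the coexistence density), so killing
#' destabilises long wavelengths while dispersal damps short ones; without
#' killing the mode decays diffusively at `-d beta^2`.
#'
#' @param params [two_strain_params()] or [public_goods_params()].
#' @param beta_wave Angular spatial frequency of the perturbation
#'   (1/length).
#' @param amplitude Perturbation amplitude relative to the equilibrium
#'   density (default 1e-3; keep at or below 1e-2 for linearity).
#' @param n_cells Grid cells per wavelength.
#' @param n_waves Number of wavelengths in the domain.
#' @param horizon Integration time for the fit.
#' @param dt Time step (default: safely inside the CFL bound).
#' @return List with `rate` (fitted 1/time), `se`, and the tibble
#'   `amplitudes` (time, mode amplitude).
#' @examples
#' perturbation_growth(two_strain_params(), beta_wave = 1)$rate
#' @export
perturbation_growth <- function(params, beta_wave, amplitude = 1e-3,
                                n_cells = 256, n_waves = 1, horizon = 2,
                                dt = NULL) {
  stopifnot(beta_wave > 0, amplitude >= 0)
  goods <- inherits(params, "public_goods_params")
  wavelength <- 2 * pi / beta_wave
  L <- n_waves * wavelength
  n <- n_cells * n_waves
  dx <- L / n
  eq <- if (goods) coexistence_goods(params) else coexistence_densities(params)
  if (anyNA(eq) || any(eq[1:2] <= 0))
    abort("no positive homogeneous coexistence equilibrium for these parameters")
  x <- (seq_len(n) - 1) * dx
  a <- amplitude * eq[["A"]]
  if (a > 0.01 * eq[["A"]] + 1e-15)
    warn("perturbation amplitude above 1% of the equilibrium density; fit may leave the linear regime")
  A0 <- matrix(eq[["A"]] + a * sin(beta_wave * x), nrow = 1)
  B0 <- matrix(eq[["B"]] - a * sin(beta_wave * x), nrow = 1)
  if (is.null(dt)) {
    dmax <- max(params$d, if (goods) params$big_d else 0)
    dt <- min(0.2 * dx^2 / (4 * max(dmax, 1e-12)), 5e-3)
  }
  st <- field_state(A0, B0,
                    S = if (goods) params$rho * A0 / params$lambda else NULL,
                    dx = dx)
  record_at <- seq(horizon / 10, horizon, length.out = 10)
  run <- integrate_fields(st, params, t_end = horizon, dt = dt,
                          record_at = record_at)
  mode_amp <- function(s) {
    phi <- s$A / (s$A + s$B)
    2 * mean(phi * sin(beta_wave * x))
  }
  amp0 <- 2 * mean((A0 / (A0 + B0)) * sin(beta_wave * x))
  amps <- tibble(time = c(0, run$times),
                 amplitude = c(amp0, vapply(run$states, mode_amp, numeric(1))))
  usable <- amps[abs(amps$amplitude) > 1e-14, ]
  fit <- lm(log(abs(amplitude)) ~ time, data = usable)
  list(rate = unname(coef(fit)[2]),
       se = summary(fit)$coefficients[2, 2],
       amplitudes = amps)
}

# Homogeneous coexistence densities of the two-strain model.
coexistence_densities <- function(p) {
  denom <- p$s * (p$alpha_ab + p$alpha_ba) + p$alpha_ab * p$alpha_ba
  if (denom > 0)
    c(A = p$alpha_ab * p$r / denom, B = p$alpha_ba * p$r / denom)
  else  # no killing: neutral composition; split the carrying capacity
    c(A = p$r / (2 * p$s), B = p$r / (2 * p$s))
}

# Interior (saddle) coexistence of the cooperator/cheat killing model under
# the quasi-steady-state good; used as the base state for perturbations.
coexistence_goods <- function(p) {
  if (p$alpha <= 0) return(c(A = NA_real_, B = NA_real_))
  A <- (p$r + p$s * p$c / p$alpha) /
    (2 * p$s + p$alpha - p$b * p$rho / p$lambda)
  c(A = A, B = A - p$c / p$alpha)
}
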