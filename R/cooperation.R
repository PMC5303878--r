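#' Cooperator-versus-cheat invasion scenarios
#'
#' Runs the cooperation model across the four canonical scenarios
#' (non-spatial or spatial, with or without killing) from a set of initial
#' cooperator frequencies, and returns the global cooperator frequency
#' through time. Together the scenarios map the phase diagram:
#' without killing cheats fix everywhere; non-spatial killing gives
#' bistability with the smaller basin for cooperators; spatial killing
#' drives phase separation that lets cooperators invade from rarity and
#' sweep to fixation.
#'
#' Non-spatial runs integrate the well-mixed three-variable system from
#' total density `r/s` (the cheat carrying capacity) split by the initial
#' frequency. Spatial runs use a 1-D periodic domain seeded with randomly
#' placed founder patches: the domain is divided into patches of
#' `patch_cells` grid cells, and exactly `round(freq * n_patches)` of them
#' start as pure cooperator at total density `r/s` (the continuum analogue
#' of randomly seeding discrete clonal cells, which is the regime whose
#' large-amplitude compositional heterogeneity phase separation feeds on;
#' see the methods vignette). Killing is switched off by setting
#' `alpha = 0` with all other parameters unchanged.
#'
#' @param params A [public_goods_params()].
#' @param init_freqs Initial cooperator frequencies in (0, 1).
#' @param spatial Logical: spatially extended (1-D PDE) or well mixed.
#' @param killing Logical: keep `params$alpha` or set it to 0.
#' @param t_end End time (default 200, a few domain-sweep times at the
#'   default parameters).
#' @param n_cells 1-D grid size for spatial runs.
#' @param dx Grid spacing for spatial runs.
#' @param patch_cells Founder-patch width in grid cells.
#' @param dt Euler step for spatial runs.
#' @param n_record Number of recorded time points.
#' @param seed Seed for the random patch placement.
#' @return Tibble with columns `spatial`, `killing`, `init_freq`, `time`,
#'   `coop_freq`.
#' @examples
#' run_cooperation_scenarios(public_goods_params(), 0.3,
#'                           spatial = FALSE, killing = FALSE, t_end = 20)
#' @export
run_cooperation_scenarios <- function(params, init_freqs = c(0.05, 0.25, 0.5,
                                                             0.75, 0.95),
                                      spatial = FALSE, killing = TRUE,
                                      t_end = 200, n_cells = 1024, dx = 0.1,
                                      patch_cells = 8, dt = 0.002,
                                      n_record = 60, seed = 1) {
  stopifnot(all(init_freqs > 0 & init_freqs < 1))
  p <- params
  if (!killing) {
    p$alpha <- 0; p$alpha_ab <- 0; p$alpha_ba <- 0
  }
  n0 <- p$r / p$s
  record_at <- seq(t_end / n_record, t_end, length.out = n_record)
  one <- function(f, idx) {
    if (!spatial) {
      tr <- integrate_wellmixed(c(A = f * n0, B = (1 - f) * n0), p, t_end,
                                n_out = n_record + 1)
      tibble(init_freq = f, time = tr$time, coop_freq = tr$freq_a)
    } else {
      rng <- make_rng(seed, sprintf("coop-%s-%s-%g", spatial, killing, f))
      n_patch <- n_cells %/% patch_cells
      n_coop <- max(1L, round(f * n_patch))
      coop_patches <- rng$sample(n_patch, n_coop)
      is_coop <- rep(seq_len(n_patch) %in% coop_patches,
                     each = patch_cells, length.out = n_cells)
      A0 <- matrix(ifelse(is_coop, n0, 0), nrow = 1)
      B0 <- matrix(ifelse(is_coop, 0, n0), nrow = 1)
      st <- field_state(A0, B0, S = p$rho * A0 / p$lambda, dx = dx)
      run <- suppressWarnings(
        integrate_fields(st, p, t_end = t_end, dt = dt,
                         record_at = record_at))
      cf <- vapply(run$states, function(s) sum(s$A) / sum(s$A + s$B),
                   numeric(1))
      f_real <- sum(A0) / sum(A0 + B0)
      tibble(init_freq = f,
             time = c(0, run$times), coop_freq = c(f_real, cf))
    }
  }
  out <- dplyr::bind_rows(purrr::imap(init_freqs, one))
  dplyr::mutate(out, spatial = spatial, killing = killing,
                .before = "init_freq")
}
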