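#' Parameters of the individual-based killing model
#'
#' Each time step, a fraction of occupied cells activate their T6SS and kill
#' all 8-neighbours of the opposite strain, and a fraction attempt to
#' reproduce into one adjacent empty site. The defaults (500 x 500 lattice,
#' 5% killers and 5% reproducers per step, equal initial strain frequencies)
#' are the standard study conditions for a fully occupied, randomly seeded
#' mutual-killing population.
#'
#' Killer/reproducer selection is an independent Bernoulli mark per occupied
#' cell (not an exact 5% quota); a cell may carry both marks, and killing is
#' applied before reproduction when the cell is visited. Updates propagate
#' sequentially in row-major order from the top-left corner; cells killed
#' earlier in a sweep do not act.
#'
#' @param width,height Lattice dimensions.
#' @param kill_fraction Per-step probability that an occupied cell kills.
#' @param repro_fraction Per-step probability that it attempts reproduction.
#' @param init_freq_a Initial fraction of strain A (+1) among cells.
#' @param boundary `"closed"` (default; finite colony, no wrap) or
#'   `"periodic"` (cleaner Fourier statistics).
#' @param seed Integer master seed.
#' @return A list of class `ibm_params`.
#' @export
ibm_params <- function(width = 500L, height = 500L, kill_fraction = 0.05,
                       repro_fraction = 0.05, init_freq_a = 0.5,
                       boundary = c("closed", "periodic"), seed = 1L) {
  boundary <- match.arg(boundary)
  stopifnot(width >= 1, height >= 1,
            kill_fraction >= 0, kill_fraction <= 1,
            repro_fraction >= 0, repro_fraction <= 1,
            init_freq_a >= 0, init_freq_a <= 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 kill_fraction = kill_fraction,
                 repro_fraction = repro_fraction,
                 init_freq_a = init_freq_a, boundary = boundary,
                 seed = as.integer(seed)),
            class = "ibm_params")
}

#' Randomly seed a fully occupied two-strain lattice
#'
#' Places exactly `round(W * H * init_freq_a)` cells of strain A (+1) and
#' fills the remainder with strain B (-1); positions are a uniform random
#' permutation under the configured seed. No site is left empty.
#'
#' @param params An [ibm_params()] object.
#' @param rng Optional `rng_stream`; defaults to the `"ibm-init"` substream
#'   of `params$seed`.
#' @return A [cell_lattice()] at step 0.
#' @examples
#' lat <- seed_lattice(ibm_params(width = 10, height = 10, seed = 1))
#' table(lat$grid)
#' @export
seed_lattice <- function(params, rng = NULL) {
  if (is.null(rng)) rng <- make_rng(params$seed, "ibm-init")
  n <- params$width * params$height
  n_a <- round(n * params$init_freq_a)
  cells <- c(rep(1L, n_a), rep(-1L, n - n_a))
  perm <- rng$sample(n, n)
  grid <- matrix(cells[perm], nrow = params$height, ncol = params$width)
  cell_lattice(grid, step = 0L, seed = params$seed, boundary = params$boundary)
}

#' Advance the individual-based model by one step
#'
#' Applies one mark-and-sweep update (see [ibm_params()] for the rule). The
#' optional `killers`/`reproducers` logical matrices force the marks instead
#' of drawing them, which is how the update rule itself is exercised in
#' isolation.
#'
#' @param state A [cell_lattice()].
#' @param params An [ibm_params()].
#' @param rng Optional `rng_stream` supplying the step's randomness; when
#'   `NULL` the current global RNG state is used.
#' @param killers,reproducers Optional logical matrices of forced marks.
#' @return The updated [cell_lattice()] with `step` incremented.
#' @export
step_ibm <- function(state, params, rng = NULL,
                     killers = NULL, reproducers = NULL) {
  stopifnot(inherits(state, "cell_lattice"))
  if (!identical(dim(state$grid), c(params$height, params$width)))
    abort("state dimensions do not match params")
  periodic <- identical(state$boundary, "periodic")
  forced <- !is.null(killers) || !is.null(reproducers)
  if (forced && is.null(killers))
    killers <- matrix(FALSE, nrow(state$grid), ncol(state$grid))
  if (forced && is.null(reproducers))
    reproducers <- matrix(FALSE, nrow(state$grid), ncol(state$grid))
  kernel <- function() ibm_step_cpp(state$grid, params$kill_fraction,
                                    params$repro_fraction, periodic,
                                    killers, reproducers)
  new_grid <- if (!is.null(rng)) rng$with(kernel()) else kernel()
  out <- state
  out$grid <- new_grid
  out$step <- state$step + 1L
  out
}

#' Run the individual-based model
#'
#' @param params An [ibm_params()].
#' @param n_steps Number of update steps.
#' @param record_at Strictly increasing steps at which to keep snapshots
#'   (defaults to `n_steps` only). Step 0 (the seeded lattice) is always
#'   included in the summary.
#' @param out_dir Optional directory; when given, each recorded snapshot is
#'   written via [write_snapshot()] and a `summary.csv` is emitted.
#' @return An object of class `ibm_run`: list with `snapshots` (named list
#'   of [cell_lattice()]), `summary` (tibble: step, n_a, n_b, n_empty,
#'   freq_a) and `params`.
#' @examples
#' run <- run_ibm(ibm_params(width = 32, height = 32, seed = 1), n_steps = 5)
#' run$summary
#' @export
run_ibm <- function(params, n_steps, record_at = NULL, out_dir = NULL) {
  if (is.null(record_at)) record_at <- n_steps
  stopifnot(all(diff(record_at) > 0), max(record_at) <= n_steps)
  rng <- make_rng(params$seed, "ibm")
  state <- seed_lattice(params)
  snapshots <- list()
  summ <- vector("list", n_steps + 1)
  tally <- function(st) {
    g <- st$grid
    n_a <- sum(g == 1L); n_b <- sum(g == -1L); n_e <- sum(g == 0L)
    tibble(step = st$step, n_a = n_a, n_b = n_b, n_empty = n_e,
           freq_a = if (n_a + n_b > 0) n_a / (n_a + n_b) else NA_real_)
  }
  summ[[1]] <- tally(state)
  for (k in seq_len(n_steps)) {
    state <- step_ibm(state, params, rng = rng)
    summ[[k + 1]] <- tally(state)
    if (k %in% record_at) {
      snapshots[[as.character(k)]] <- state
      if (!is.null(out_dir))
        write_snapshot(state, file.path(out_dir, sprintf("ibm_step%06d", k)))
    }
  }
  summary <- dplyr::bind_rows(summ)
  if (!is.null(out_dir))
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  structure(list(snapshots = snapshots, summary = summary, params = params),
            class = "ibm_run")
}

#' Interface density of a two-strain lattice
#'
#' Fraction of 4-neighbour occupied pairs whose members carry opposite
#' labels; a scalar measure of mixing that decreases as domains coarsen.
#'
#' @param state A [cell_lattice()] (or bare label matrix).
#' @return A scalar in `[0, 1]`.
#' @export
interface_density <- function(state) {
  g <- if (inherits(state, "cell_lattice")) state$grid else state
  right <- cbind(g[, -1], NA)
  down <- rbind(g[-1, ], NA)
  opp <- function(a, b) {
    ok <- !is.na(b) & a != 0 & b != 0
    c(sum(ok & a == -b, na.rm = TRUE), sum(ok, na.rm = TRUE))
  }
  h <- opp(g, right); v <- opp(g, down)
  (h[1] + v[1]) / max(1, h[2] + v[2])
}
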