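#' Parameters of the Ising spin model
#'
#' The statistical-mechanics reference point for the killing lattice: a grid
#' of +/-1 spins evolving by stochastic single-spin flips under the
#' 8-neighbour (Moore) Hamiltonian, with no external field and no
#' conservation of magnetisation (Model A / Glauber-type dynamics). One
#' sweep is `width * height` flip attempts at uniformly chosen sites.
#'
#' @param width,height Lattice dimensions.
#' @param beta Inverse temperature in units of 1/(k_B T); the default 1
#'   is the standard coarsening condition.
#' @param seed Integer master seed.
#' @return A list of class `ising_params`.
#' @export
ising_params <- function(width = 500L, height = 500L, beta = 1, seed = 1L) {
  stopifnot(width >= 1, height >= 1, beta > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 beta = beta, seed = as.integer(seed)),
            class = "ising_params")
}

#' Local 8-neighbour Hamiltonian at one site
#'
#' `H = (sum of the 8 nearest neighbours) * (centre spin)`: +8 when the
#' centre agrees with every neighbour, -8 when it opposes all of them.
#' Neighbour lookup is periodic by default.
#'
#' @param spins A [spin_lattice()] or bare +/-1 matrix.
#' @param site Integer vector `(row, col)`, 1-based.
#' @param boundary `"periodic"` (default) or `"closed"`; under a closed
#'   boundary a site on the edge has no full neighbourhood and is an error.
#' @return Integer in `{-8, ..., 8}` with the parity of 8.
#' @examples
#' m <- matrix(1L, 3, 3)
#' local_hamiltonian(m, c(2, 2))  # 8
#' @export
local_hamiltonian <- function(spins, site,
                              boundary = c("periodic", "closed")) {
  boundary <- match.arg(boundary)
  s <- if (inherits(spins, "spin_lattice")) spins$spins else spins
  nr <- nrow(s); nc <- ncol(s)
  i <- site[1]; j <- site[2]
  if (i < 1 || i > nr || j < 1 || j > nc) abort("site out of bounds")
  if (boundary == "closed" && (i == 1 || i == nr || j == 1 || j == nc))
    abort("site on a closed boundary has an incomplete neighbourhood")
  wrap <- function(k, n) ((k - 1) %% n) + 1
  nbrs <- 0L
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbrs <- nbrs + s[wrap(i + di, nr), wrap(j + dj, nc)]
  }
  as.integer(nbrs * s[i, j])
}

#' Attempt a single stochastic spin flip
#'
#' A flip negates the local Hamiltonian, so the energy change is
#' `dE = 2 * H_old`. The spin flips iff `exp(-beta * dE) > u` with
#' `u ~ Uniform[0, 1)`: energetically favourable and neutral moves are
#' always accepted, unfavourable ones with Boltzmann probability.
#'
#' @param spins A [spin_lattice()].
#' @param site `(row, col)` of the candidate spin.
#' @param params An [ising_params()].
#' @param rng Optional `rng_stream`; otherwise the global RNG is used.
#' @return List with the (possibly updated) `spins` lattice and logical
#'   `flipped`.
#' @export
attempt_flip <- function(spins, site, params, rng = NULL) {
  stopifnot(inherits(spins, "spin_lattice"))
  h_old <- local_hamiltonian(spins, site)
  u <- if (!is.null(rng)) rng$runif(1) else stats::runif(1)
  flipped <- exp(-params$beta * 2 * h_old) > u
  if (flipped)
    spins$spins[site[1], site[2]] <- -spins$spins[site[1], site[2]]
  list(spins = spins, flipped = flipped)
}

#' Randomly seed a spin lattice
#'
#' Equal numbers of up (+1) and down (-1) spins in uniformly random
#' positions: the infinite-temperature initial condition.
#'
#' @param params An [ising_params()].
#' @param rng Optional `rng_stream`.
#' @return A [spin_lattice()] at sweep 0.
#' @export
seed_spins <- function(params, rng = NULL) {
  if (is.null(rng)) rng <- make_rng(params$seed, "ising-init")
  n <- params$width * params$height
  n_up <- floor(n / 2) + (n %% 2L) * rng$sample(0:1, 1)
  cells <- c(rep(1L, n_up), rep(-1L, n - n_up))
  grid <- matrix(cells[rng$sample(n, n)], params$height, params$width)
  spin_lattice(grid, sweep = 0L, seed = params$seed)
}

#' Run the Ising model
#'
#' Starts from random spins and performs sweeps of `width * height`
#' uniformly targeted flip attempts; one sweep advances time by 1.
#'
#' @param params An [ising_params()].
#' @param n_sweeps Number of sweeps.
#' @param record_at Strictly increasing sweeps at which to keep snapshots.
#' @param init Optional [spin_lattice()] to start from instead of a random
#'   seeding.
#' @param out_dir Optional output directory (snapshots +
#'   `magnetization.csv`).
#' @return Object of class `ising_run`: `snapshots`, `magnetization`
#'   (tibble: sweep, m, flips) and `params`.
#' @examples
#' run <- run_ising(ising_params(width = 32, height = 32, seed = 1), 3)
#' run$magnetization
#' @export
run_ising <- function(params, n_sweeps, record_at = NULL, init = NULL,
                      out_dir = NULL) {
  if (is.null(record_at)) record_at <- n_sweeps
  stopifnot(all(diff(record_at) > 0), max(record_at) <= n_sweeps)
  state <- if (is.null(init)) seed_spins(params) else init
  attempts <- params$width * params$height
  snapshots <- list()
  mag <- vector("list", n_sweeps + 1)
  mag[[1]] <- tibble(sweep = state$sweep, m = mean(state$spins), flips = NA_real_)
  res <- with_stream_seed(params$seed, "ising", {
    for (k in seq_len(n_sweeps)) {
      sw <- ising_sweep_cpp(state$spins, params$beta, attempts)
      state$spins <- sw$spins
      state$sweep <- state$sweep + 1L
      mag[[k + 1]] <- tibble(sweep = state$sweep, m = mean(state$spins),
                             flips = sw$flips)
      if (k %in% record_at) {
        snapshots[[as.character(k)]] <- state
        if (!is.null(out_dir))
          write_snapshot(state, file.path(out_dir, sprintf("ising_sweep%06d", k)))
      }
    }
    list(snapshots = snapshots, state = state)
  })
  magnetization <- dplyr::bind_rows(mag)
  if (!is.null(out_dir))
    readr::write_csv(magnetization, file.path(out_dir, "magnetization.csv"))
  structure(list(snapshots = res$snapshots, magnetization = magnetization,
                 params = params),
            class = "ising_run")
}
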