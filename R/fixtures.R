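#' Deterministic test patterns with known spatial statistics
#'
#' Generates the standard ground-truth fixtures used to validate the
#' spatial statistics: `"random"` (i.i.d. labels; assortment 0, flat S(q)),
#' `"stripes"` (vertical square wave of the given period; S(q) peak at
#' `2 pi / period`), `"checkerboard"` (maximal anti-assortment),
#' `"halves"` (left/right split; fully phase separated) and `"labyrinth"`
#' (a smoothed-noise threshold pattern with an intermediate length scale).
#'
#' @param kind Pattern name.
#' @param size Side length in cells (at least 32 for Fourier fixtures).
#' @param period Stripe period in pixels (even).
#' @param freq Fraction of +1 labels for `"random"`.
#' @param smooth Smoothing radius (cells) for `"labyrinth"`.
#' @param seed Seed for the stochastic patterns.
#' @return A [cell_lattice()] fully occupied with +1/-1 labels.
#' @examples
#' make_pattern("checkerboard", size = 8)$grid[1:3, 1:3]
#' @export
make_pattern <- function(kind = c("random", "stripes", "checkerboard",
                                  "halves", "labyrinth"),
                         size = 64, period = 16, freq = 0.5, smooth = 3,
                         seed = 1) {
  kind <- match.arg(kind)
  grid <- switch(kind,
    random = {
      rng <- make_rng(seed, paste0("fixture-random-", size))
      matrix(ifelse(rng$runif(size * size) < freq, 1L, -1L), size, size)
    },
    stripes = {
      stopifnot(period %% 2 == 0, size %% period == 0)
      cols <- ifelse(((seq_len(size) - 1) %% period) < period / 2, 1L, -1L)
      matrix(cols, size, size, byrow = TRUE)
    },
    checkerboard = {
      outer(seq_len(size), seq_len(size),
            function(i, j) ifelse((i + j) %% 2 == 0, 1L, -1L))
    },
    halves = {
      cbind(matrix(1L, size, size %/% 2),
            matrix(-1L, size, size - size %/% 2))
    },
    labyrinth = {
      rng <- make_rng(seed, paste0("fixture-labyrinth-", size))
      z <- matrix(rng$rnorm(size * size), size, size)
      # periodic moving-average smoothing to imprint a length scale
      for (k in seq_len(smooth)) {
        z <- (z +
                rbind(z[size, ], z[-size, ]) + rbind(z[-1, ], z[1, ]) +
                cbind(z[, size], z[, -size]) + cbind(z[, -1], z[, 1])) / 5
      }
      ifelse(z > stats::median(z), 1L, -1L)
    })
  cell_lattice(grid, boundary = "periodic")
}

#' Self-similar rescaled copies of one pattern
#'
#' Block-upsamples a base +1/-1 pattern by integer factors. Upsampling by
#' factor `k` compresses the spectrum (`q -> q / k`) and multiplies the
#' per-pixel normalised structure factor by `k^2`, so the series satisfies
#' `S(q_m) ~ q_m^-2` exactly by construction — an oracle for the
#' coarsening-scaling fit that is independent of any simulator.
#'
#' @param base A [cell_lattice()] or label matrix.
#' @param factors Integer upsampling factors (e.g. `c(1, 2, 4)`).
#' @return List of [cell_lattice()]s of increasing size.
#' @export
make_scaled_series <- function(base, factors = c(1L, 2L, 4L)) {
  g <- as_label_matrix(base)
  lapply(factors, function(k)
    cell_lattice(kronecker(g, matrix(1L, k, k)), boundary = "periodic"))
}
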