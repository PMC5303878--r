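# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the assortment oracle enumerates windows
# directly, and the Fourier oracle evaluates the DFT from its definition
# by explicit matrix products rather than stats::fft.

# Brute-force sliding-window assortment (focal strain coded `focal`).
oracle_assortment <- function(I, h, focal = 1) {
  if (inherits(I, "cell_lattice")) I <- I$grid
  nr <- nrow(I); nc <- ncol(I)
  p_vals <- c()
  n_g <- 0; n_o <- 0
  for (i in (h + 1):(nr - h)) for (j in (h + 1):(nc - h)) {
    if (I[i, j] != 0) n_o <- n_o + 1
    if (I[i, j] == focal) n_g <- n_g + 1
  }
  for (i in (h + 1):(nr - h)) for (j in (h + 1):(nc - h)) {
    if (I[i, j] != focal) next
    same <- 0; occ <- 0
    for (di in -h:h) for (dj in -h:h) {
      if (di == 0 && dj == 0) next
      v <- I[i + di, j + dj]
      if (v != 0) occ <- occ + 1
      if (v == focal) same <- same + 1
    }
    if (occ > 0) p_vals <- c(p_vals, same / occ)
  }
  f_g <- n_g / n_o
  (mean(p_vals) - f_g) / (1 - f_g)
}

# Direct DFT power spectrum |F|^2 / N from the definition, via explicit
# complex exponential matrices (no call to fft()).
oracle_power_spectrum <- function(I) {
  I <- I - mean(I)
  nr <- nrow(I); nc <- ncol(I)
  wr <- exp(-2i * pi * outer(0:(nr - 1), 0:(nr - 1)) / nr)
  wc <- exp(-2i * pi * outer(0:(nc - 1), 0:(nc - 1)) / nc)
  F <- wr %*% I %*% wc
  Mod(F)^2 / (nr * nc)
}

# Radial average of a 2-D power spectrum with the same binning convention
# as structure_factor(), reimplemented independently.
oracle_radial_average <- function(S2, dx = 1) {
  nr <- nrow(S2); nc <- ncol(S2)
  kx <- c(0:(nr %/% 2), -((nr - 1) %/% 2):-1)
  ky <- c(0:(nc %/% 2), -((nc - 1) %/% 2):-1)
  qmag <- sqrt(outer((2 * pi * kx / (nr * dx))^2,
                     (2 * pi * ky / (nc * dx))^2, `+`))
  dq <- 2 * pi / (max(nr, nc) * dx)
  bin <- as.integer(round(qmag / dq))
  keep <- bin > 0
  means <- tapply(S2[keep], bin[keep], mean)
  data.frame(q = as.integer(names(means)) * dq, S = as.numeric(means))
}

expect_snapshot_equal <- function(a, b) {
  expect_identical(a$grid %||% a$spins, b$grid %||% b$spins)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
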