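# Extract a numeric matrix from any of the state containers.
as_label_matrix <- function(image) {
  if (inherits(image, "cell_lattice")) return(image$grid)
  if (inherits(image, "spin_lattice")) return(image$spins)
  if (inherits(image, "field_state")) return(image$A - image$B)
  as.matrix(image)
}

# Summed-area table window sums: out[i, j] = sum of M over the
# (2h+1) x (2h+1) window centred at (i, j); valid only for the interior
# i, j in (h+1) .. (n - h).
box_sum <- function(M, h) {
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(0, nr + 1, nc + 1)
  P[-1, -1] <- apply(apply(M, 2, cumsum), 1, cumsum) |> t()
  ri <- (h + 1):(nr - h); cj <- (h + 1):(nc - h)
  P[ri + h + 1, cj + h + 1] - P[ri - h, cj + h + 1] -
    P[ri + h + 1, cj - h] + P[ri - h, cj - h]
}

#' Radially averaged structure factor of a label image
#'
#' Computes `S(q_x, q_y) = |FFT(I - mean(I))|^2 / N` (so that, by
#' Parseval's identity, the non-DC bins of S sum to the image's total
#' centred squared magnitude) and radially averages it into annuli of one
#' fundamental frequency `2 pi / (max(W, H) L)`, dropping the DC bin.
#' A flat curve signals a well-mixed population with no characteristic
#' length scale; coarsening moves power to small `q`.
#'
#' @param image A [cell_lattice()], [spin_lattice()], [field_state()]
#'   (uses `A - B`) or bare numeric matrix. Labels are used as +1/-1 with
#'   empties 0.
#' @param dx Pixel (cell) size `L`; wavenumbers are in units of `1/L`.
#' @param window `"none"` (default; periodic simulation output) or
#'   `"hann"` for closed-boundary or experimental images.
#' @return A tibble of class `sf_curve` with columns `q`, `S`, `n_modes`
#'   and attributes `dx`, `dims`, `band_max` (the axis Nyquist `pi/dx`)
#'   and `total_power`.
#' @examples
#' img <- make_pattern("stripes", size = 64, period = 16)
#' curve <- structure_factor(img)
#' sf_peak(curve)$q_m  # ~ 2*pi/16
#' @export
structure_factor <- function(image, dx = 1, window = c("none", "hann")) {
  window <- match.arg(window)
  I <- as_label_matrix(image)
  storage.mode(I) <- "double"
  if (min(dim(I)) < 32)
    abort("image must be at least 32 x 32")
  if (max(I) == min(I))
    abort("no fluctuations: constant image has S identically 0 after mean removal")
  I <- I - mean(I)
  if (window == "hann") {
    hr <- 0.5 * (1 - cos(2 * pi * (seq_len(nrow(I)) - 1) / (nrow(I) - 1)))
    hc <- 0.5 * (1 - cos(2 * pi * (seq_len(ncol(I)) - 1) / (ncol(I) - 1)))
    I <- I * outer(hr, hc)
    I <- I - mean(I)
  }
  nr <- nrow(I); nc <- ncol(I)
  S2 <- Mod(fft(I))^2 / (nr * nc)
  kx <- c(0:(nr %/% 2), -((nr - 1) %/% 2):-1) # signed mode indices
  ky <- c(0:(nc %/% 2), -((nc - 1) %/% 2):-1)
  qx <- 2 * pi * kx / (nr * dx)
  qy <- 2 * pi * ky / (nc * dx)
  qmag <- sqrt(outer(qx^2, qy^2, `+`))
  dq <- 2 * pi / (max(nr, nc) * dx)
  bin <- as.integer(round(qmag / dq))
  keep <- bin > 0L
  sums <- tapply(S2[keep], bin[keep], sum)
  counts <- tapply(S2[keep], bin[keep], length)
  bins <- as.integer(names(sums))
  out <- tibble(q = bins * dq, S = as.numeric(sums / counts),
                n_modes = as.integer(counts))
  out <- out[order(out$q), ]
  structure(out,
            class = c("sf_curve", class(out)),
            dx = dx, dims = c(nr, nc), band_max = pi / dx,
            total_power = sum(I^2))
}

#' Characteristic wavenumber of a structure-factor curve
#'
#' By default the peak wavenumber is the first moment
#' `q_m = sum(q S(q)) / sum(S(q))` over the retained band (up to the axis
#' Nyquist frequency), a robust estimator for noisy coarsening spectra;
#' `method = "argmax"` returns the location of the maximum of a lightly
#' smoothed curve instead. `S_qm` is the curve linearly interpolated at
#' `q_m`.
#'
#' @param curve An `sf_curve` from [structure_factor()].
#' @param method `"moment"` (default) or `"argmax"`.
#' @param band Upper wavenumber limit of the retained band (default: the
#'   curve's `band_max` attribute).
#' @param smooth Moving-average half-width (bins) applied before the
#'   argmax; 0 (default) keeps sharp single-mode peaks in their bin.
#' @return List with `q_m`, `S_qm`, `band`, `method` and logical
#'   `no_scale` (flagged, with a warning, when the curve is nearly flat,
#'   max/median < 2).
#' @export
sf_peak <- function(curve, method = c("moment", "argmax"), band = NULL,
                    smooth = 0) {
  method <- match.arg(method)
  if (nrow(curve) < 8) abort("need at least 8 structure-factor bins")
  if (is.null(band)) band <- attr(curve, "band_max") %||% max(curve$q)
  cc <- curve[curve$q <= band + 1e-12, ]
  no_scale <- max(cc$S) / stats::median(cc$S) < 2
  if (no_scale)
    warn("no characteristic scale: structure factor is nearly flat")
  if (method == "moment") {
    q_m <- sum(cc$q * cc$S) / sum(cc$S)
  } else {
    s <- cc$S
    if (smooth > 0) {
      k <- 2 * smooth + 1
      sm <- stats::filter(s, rep(1 / k, k), sides = 2)
      s[!is.na(sm)] <- sm[!is.na(sm)]
    }
    q_m <- cc$q[which.max(s)]
  }
  S_qm <- approx(cc$q, cc$S, xout = q_m, rule = 2)$y
  list(q_m = q_m, S_qm = S_qm, band = band, method = method,
       no_scale = no_scale)
}

#' Coarsening scaling fit across a trajectory of snapshots
#'
#' For each snapshot, extracts `(q_m, S(q_m))` from the radially averaged
#' structure factor, then fits least-squares slopes of `log S(q_m)` against
#' `log q_m` and of `log q_m` against `log t`. Non-conserved (Model A)
#' coarsening predicts `S(q_m) ~ q_m^-2` and `q_m ~ t^(-1/2)`. Snapshots in
#' an initial transient (first `transient_frac` of the time span) are
#' dropped (with logarithmically spaced snapshots this removes the earliest
#' snapshot(s), where the pattern has not yet entered the scaling regime);
#' at least 5 usable points are required.
#'
#' @param images List of snapshots (anything [structure_factor()] accepts)
#'   or of precomputed `sf_curve`s.
#' @param times Numeric vector of snapshot times (same length).
#' @param transient_frac Fraction of the snapshot sequence treated as
#'   transient and dropped (default 0.1).
#' @param peak_method Passed to [sf_peak()].
#' @param dx Pixel size, when `images` are raw snapshots.
#' @return Object of class `coarsening_fit` with [tidy()] and [glance()]
#'   methods; elements `table` (time, q_m, s_qm), `slope_sq_qm`,
#'   `se_sq_qm`, `slope_qm_t`, `se_qm_t`.
#' @export
coarsening_fit <- function(images, times, transient_frac = 0.1,
                           peak_method = "moment", dx = 1) {
  stopifnot(length(images) == length(times))
  curves <- lapply(images, function(im)
    if (inherits(im, "sf_curve")) im else structure_factor(im, dx = dx))
  peaks <- lapply(curves, sf_peak, method = peak_method)
  tab <- tibble(time = times,
                q_m = vapply(peaks, `[[`, numeric(1), "q_m"),
                s_qm = vapply(peaks, `[[`, numeric(1), "S_qm"))
  ord <- order(tab$time)
  tab <- tab[ord, ]
  tab <- tab[seq_len(nrow(tab)) > floor(transient_frac * nrow(tab)), ]
  if (nrow(tab) < 5)
    abort("fewer than 5 usable time points past the transient")
  f1 <- lm(log(s_qm) ~ log(q_m), data = tab)
  use_t <- tab[tab$time > 0, ]
  f2 <- lm(log(q_m) ~ log(time), data = use_t)
  structure(list(table = tab,
                 slope_sq_qm = unname(coef(f1)[2]),
                 se_sq_qm = summary(f1)$coefficients[2, 2],
                 slope_qm_t = unname(coef(f2)[2]),
                 se_qm_t = summary(f2)$coefficients[2, 2],
                 r_squared = summary(f1)$r.squared,
                 peak_method = peak_method,
                 transient_frac = transient_frac),
            class = "coarsening_fit")
}

#' @export
print.coarsening_fit <- function(x, ...) {
  cat(sprintf("<coarsening_fit over %d snapshots>\n", nrow(x$table)))
  cat(sprintf("  log S(q_m) ~ log q_m slope: %.3f (se %.3f)\n",
              x$slope_sq_qm, x$se_sq_qm))
  cat(sprintf("  log q_m ~ log t slope:      %.3f (se %.3f)\n",
              x$slope_qm_t, x$se_qm_t))
  invisible(x)
}

#' @rdname coarsening_fit
#' @param x A `coarsening_fit`.
#' @param ... Unused.
#' @export
tidy.coarsening_fit <- function(x, ...) {
  tibble(term = c("log S(q_m) ~ log q_m", "log q_m ~ log t"),
         estimate = c(x$slope_sq_qm, x$slope_qm_t),
         std.error = c(x$se_sq_qm, x$se_qm_t))
}

#' @rdname coarsening_fit
#' @export
glance.coarsening_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = nrow(x$table),
         peak_method = x$peak_method)
}

#' Dynamic-scaling collapse of structure-factor curves
#'
#' Rescales each curve to `(q / q_m, S(q) q_m^2 L^2)`; under dynamic
#' scaling all times fall on one master curve. A collapse-quality score
#' (median pairwise L2 distance between curves interpolated onto a common
#' abscissa grid) is reported for both the rescaled and the raw curves;
#' rescaling should strictly improve (lower) it during self-similar
#' coarsening.
#'
#' @param curves List of `sf_curve`s (or snapshots accepted by
#'   [structure_factor()]).
#' @param times Optional times used to label the output.
#' @param n_grid Size of the common abscissa grid.
#' @param dx Pixel size for raw snapshots.
#' @return Object of class `sf_collapse`: `table` (tibble time, x, y),
#'   `score`, `score_raw`.
#' @export
collapse_curves <- function(curves, times = NULL, n_grid = 50, dx = 1) {
  curves <- lapply(curves, function(im)
    if (inherits(im, "sf_curve")) im else structure_factor(im, dx = dx))
  if (is.null(times)) times <- seq_along(curves)
  L <- vapply(curves, function(cv) attr(cv, "dx") %||% dx, numeric(1))
  qm <- vapply(curves, function(cv) sf_peak(cv)$q_m, numeric(1))
  scaled <- purrr::pmap(list(curves, qm, L, times), function(cv, q_m, l, t)
    tibble(time = t, x = cv$q / q_m, y = cv$S * q_m^2 * l^2))
  tab <- dplyr::bind_rows(scaled)
  pair_score <- function(xs, ys) {
    lo <- max(vapply(xs, min, numeric(1)))
    hi <- min(vapply(xs, max, numeric(1)))
    if (hi <= lo) return(NA_real_)
    grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
    mats <- mapply(function(x, y) approx(x, y, xout = grid)$y, xs, ys)
    k <- ncol(mats)
    if (k < 2) return(0)
    dists <- c()
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      dists <- c(dists, sqrt(mean((log(mats[, i]) - log(mats[, j]))^2,
                                  na.rm = TRUE)))
    stats::median(dists)
  }
  xs <- lapply(scaled, `[[`, "x"); ys <- lapply(scaled, `[[`, "y")
  raw_xs <- lapply(curves, `[[`, "q"); raw_ys <- lapply(curves, `[[`, "S")
  structure(list(table = tab,
                 score = pair_score(xs, ys),
                 score_raw = pair_score(raw_xs, raw_ys)),
            class = "sf_collapse")
}

#' Kin assortment of a two-genotype image at one interaction radius
#'
#' Convolution form of the assortment statistic: with the focal strain
#' coded +1 and the competitor -1, each focal cell's neighbourhood of
#' radius `h` (the `(2h+1)^2 - 1` surrounding positions; equivalently a
#' kernel of ones with centre `-((2h+1)^2 - 1)`) yields the local frequency
#' of the focal strain among occupied neighbours. Averaging over focal
#' cells and normalising against the global focal frequency `f_g` gives
#' `r_g = (p_local - f_g) / (1 - f_g)`, which is 0 under random mixing,
#' approaches 1 under complete segregation at scales much larger than `h`,
#' and is negative under anti-assortment. Borders within `h` are trimmed;
#' empty sites (0) are excluded from the occupied-neighbour counts.
#'
#' @param image A [cell_lattice()] or matrix with entries in `{-1, 0, 1}`.
#' @param h Interaction radius in cells (`1 <= h <= min(W, H) / 4`).
#' @param focal Label of the focal strain `g` (+1 or -1).
#' @return Tibble with columns `h`, `r_g`, `r_c`, `freq_g` (global focal
#'   frequency among occupied cells in the trimmed interior).
#' @examples
#' img <- make_pattern("halves", size = 64)
#' assortment(img, h = 2)
#' @export
assortment <- function(image, h, focal = 1) {
  I <- as_label_matrix(image)
  stopifnot(all(I %in% c(-1, 0, 1)), focal %in% c(-1, 1))
  nr <- nrow(I); nc <- ncol(I)
  if (h < 1 || h > min(nr, nc) / 4)
    abort("h must satisfy 1 <= h <= min(W, H) / 4")
  G <- (I == focal) * 1
  C <- (I == -focal) * 1
  O <- G + C
  winG <- box_sum(G, h)
  winO <- box_sum(O, h)
  core <- function(member, winM) {
    # member: indicator matrix of the strain whose neighbourhoods we average
    Mi <- member[(h + 1):(nr - h), (h + 1):(nc - h)]
    nbr_m <- winM - Mi   # same-strain neighbours (centre excluded)
    nbr_o <- winO - Mi   # occupied neighbours (centre excluded)
    sel <- Mi == 1 & nbr_o > 0
    if (!any(sel)) return(NA_real_)
    mean(nbr_m[sel] / nbr_o[sel])
  }
  Gi <- G[(h + 1):(nr - h), (h + 1):(nc - h)]
  Oi <- O[(h + 1):(nr - h), (h + 1):(nc - h)]
  n_g <- sum(Gi); n_o <- sum(Oi)
  if (n_g == 0 || n_g == n_o)
    abort("assortment undefined: focal strain frequency is 0 or 1")
  f_g <- n_g / n_o
  p_g <- core(G, winG)
  p_c <- core(C, winO - winG)
  tibble(h = as.integer(h),
         r_g = (p_g - f_g) / (1 - f_g),
         r_c = (p_c - (1 - f_g)) / f_g,
         freq_g = f_g)
}

# Brute-force sliding-window assortment; independent oracle for tests.
assortment_direct <- function(image, h, focal = 1) {
  I <- as_label_matrix(image)
  nr <- nrow(I); nc <- ncol(I)
  vals_g <- c(); vals_c <- c()
  n_g <- 0; n_o <- 0
  for (i in (h + 1):(nr - h)) for (j in (h + 1):(nc - h)) {
    if (I[i, j] != 0) n_o <- n_o + 1
    if (I[i, j] == focal) n_g <- n_g + 1
    if (I[i, j] == 0) next
    win <- I[(i - h):(i + h), (j - h):(j + h)]
    win[h + 1, h + 1] <- 0 # exclude centre
    occ <- sum(win != 0)
    if (occ == 0) next
    p <- sum(win == I[i, j]) / occ
    if (I[i, j] == focal) vals_g <- c(vals_g, p) else vals_c <- c(vals_c, p)
  }
  f_g <- n_g / n_o
  tibble(h = as.integer(h),
         r_g = (mean(vals_g) - f_g) / (1 - f_g),
         r_c = (mean(vals_c) - (1 - f_g)) / f_g,
         freq_g = f_g)
}

#' Assortment profile over a range of interaction radii
#'
#' Computes `r_g(h)` and `r_c(h)` for `h = 1 .. h_max` (the standard range
#' is 1-36). Given several images (replicates), returns the mean profile
#' with a 95% confidence band across images.
#'
#' @param image A single image or a list of replicate images.
#' @param h_max Largest interaction radius.
#' @param focal Focal strain label.
#' @return Tibble `(h, r_g, r_c, freq_g)` for a single image; for
#'   replicates, `(h, r_g, r_c, ci_low, ci_high, n)` where the confidence
#'   band is for `r_g`.
#' @export
assortment_profile <- function(image, h_max = 36, focal = 1) {
  one <- function(img) dplyr::bind_rows(
    lapply(seq_len(h_max), function(h) assortment(img, h, focal)))
  if (is.list(image) && !inherits(image, c("cell_lattice", "spin_lattice",
                                           "field_state")) &&
      !is.matrix(image)) {
    prof <- dplyr::bind_rows(lapply(image, one), .id = "replicate")
    prof |>
      dplyr::group_by(.data$h) |>
      dplyr::summarise(
        mean_r_g = mean(.data$r_g), mean_r_c = mean(.data$r_c),
        sd_r_g = sd(.data$r_g), n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(
        ci_low = .data$mean_r_g - qt(0.975, pmax(.data$n - 1, 1)) *
          .data$sd_r_g / sqrt(.data$n),
        ci_high = .data$mean_r_g + qt(0.975, pmax(.data$n - 1, 1)) *
          .data$sd_r_g / sqrt(.data$n)) |>
      dplyr::rename(r_g = "mean_r_g", r_c = "mean_r_c") |>
      dplyr::select("h", "r_g", "r_c", "ci_low", "ci_high", "n")
  } else {
    one(image)
  }
}
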