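#' Lattice and field state containers
#'
#' Three light S3 containers hold simulator state. `cell_lattice` is a
#' W x H grid of +1 (strain A, "red"), -1 (strain B, "blue") and 0 (empty)
#' with a step counter; `spin_lattice` is a grid of +/-1 spins with a sweep
#' counter; `field_state` carries continuous non-negative density fields
#' A and B (and optionally a public-good concentration S) on a periodic grid
#' with spacing `dx` and time `t`.
#'
#' @param grid Integer matrix with entries in `{-1, 0, 1}`.
#' @param step Non-negative integer step counter.
#' @param seed Integer seed recorded for provenance (may be `NA`).
#' @param boundary `"closed"` (no wrap) or `"periodic"`.
#' @return An object of the corresponding class.
#' @export
cell_lattice <- function(grid, step = 0L, seed = NA_integer_,
                         boundary = c("closed", "periodic")) {
  boundary <- match.arg(boundary)
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  if (!all(grid %in% c(-1L, 0L, 1L)))
    abort("cell_lattice entries must be in {-1, 0, +1}")
  if (step < 0) abort("step must be non-negative")
  structure(list(grid = grid, step = as.integer(step),
                 seed = seed, boundary = boundary, meta = list()),
            class = "cell_lattice")
}

#' @rdname cell_lattice
#' @param spins Integer matrix with entries in `{-1, 1}`.
#' @param sweep Non-negative integer sweep counter.
#' @export
spin_lattice <- function(spins, sweep = 0L, seed = NA_integer_) {
  spins <- as.matrix(spins)
  storage.mode(spins) <- "integer"
  if (!all(spins %in% c(-1L, 1L)))
    abort("spin_lattice entries must be in {-1, +1} (no empty state)")
  structure(list(spins = spins, sweep = as.integer(sweep), seed = seed),
            class = "spin_lattice")
}

#' @rdname cell_lattice
#' @param A,B Non-negative numeric matrices (density fields).
#' @param S Optional non-negative matrix (public-good concentration).
#' @param dx Grid spacing (length units).
#' @param t Simulation time.
#' @export
field_state <- function(A, B, S = NULL, dx = 1, t = 0) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B)))
    abort("A and B fields must share one shape")
  if (!is.null(S)) {
    S <- as.matrix(S)
    if (!identical(dim(S), dim(A))) abort("S field must match A/B shape")
    if (any(S < 0)) abort("S must be non-negative")
  }
  if (any(A < 0) || any(B < 0)) abort("density fields must be non-negative")
  stopifnot(dx > 0)
  structure(list(A = A, B = B, S = S, dx = dx, t = t),
            class = "field_state")
}

#' @export
print.cell_lattice <- function(x, ...) {
  n <- table(factor(x$grid, levels = c(1, -1, 0)))
  cat(sprintf("<cell_lattice %d x %d, step %d, %s boundary>\n",
              nrow(x$grid), ncol(x$grid), x$step, x$boundary))
  cat(sprintf("  A (+1): %d   B (-1): %d   empty: %d\n", n[[1]], n[[2]], n[[3]]))
  invisible(x)
}

#' @export
print.spin_lattice <- function(x, ...) {
  cat(sprintf("<spin_lattice %d x %d, sweep %d, m = %.4f>\n",
              nrow(x$spins), ncol(x$spins), x$sweep, mean(x$spins)))
  invisible(x)
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state %d x %d, dx = %g, t = %g%s>\n",
              nrow(x$A), ncol(x$A), x$dx, x$t,
              if (is.null(x$S)) "" else ", with good S"))
  invisible(x)
}

#' Read a two-genotype label image into a cell lattice
#'
#' Entry point for applying the package's spatial statistics to external
#' masks. Accepts an 8-bit greyscale PNG or a whitespace-delimited integer
#' text grid; `mapping` translates every distinct pixel value into the
#' internal alphabet +1 / -1 / 0.
#'
#' @param path Path to a `.png` or text grid file.
#' @param mapping Named numeric vector, names = pixel values as written in
#'   the file (for PNG, 0-255 grey levels), values in `{-1, 0, 1}`.
#' @return A [cell_lattice()] with provenance (`path`, `mapping`) in `$meta`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("1 1", "2 2"), f)
#' read_label_image(f, c("1" = 1, "2" = -1))$grid
#' @export
read_label_image <- function(path, mapping = c("0" = -1, "127" = 0, "255" = 1)) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    raw <- round(img * 255)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
    lens <- lengths(rows)
    if (length(unique(lens)) != 1)
      abort(sprintf("non-rectangular text grid: row lengths %s",
                    paste(unique(lens), collapse = ", ")))
    raw <- do.call(rbind, rows)
  }
  vals <- sort(unique(as.vector(raw)))
  missing <- setdiff(as.character(vals), names(mapping))
  if (length(missing))
    abort(sprintf("unmapped label %s", paste(missing, collapse = ", ")))
  grid <- matrix(unname(mapping[as.character(raw)]), nrow(raw), ncol(raw))
  out <- cell_lattice(grid)
  out$meta <- list(path = path, mapping = mapping)
  out
}

# grey levels used for the PNG rendering of the three-letter alphabet
.png_levels <- c(`-1` = 0L, `0` = 127L, `1` = 255L)

#' Write a simulation state to disk
#'
#' Discrete states are written as an 8-bit greyscale PNG (visualisation) plus
#' a whitespace-delimited text grid (the authoritative lossless form);
#' continuous fields as one CSV of floats per field. A JSON sidecar records
#' step/time, seed and a hash of the written payload.
#'
#' @param state A [cell_lattice()], [spin_lattice()] or [field_state()].
#' @param path Base path without extension; files `path.png`, `path.txt`,
#'   `path.json` (discrete) or `path_A.csv`, `path_B.csv`, ... are created.
#' @return Invisibly, the character vector of files written.
#' @export
write_snapshot <- function(state, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("parent directory does not exist: %s", dir))
  files <- character()
  if (inherits(state, "cell_lattice") || inherits(state, "spin_lattice")) {
    grid <- if (inherits(state, "cell_lattice")) state$grid else state$spins
    txt <- paste0(path, ".txt")
    utils::write.table(grid, txt, row.names = FALSE, col.names = FALSE)
    pngf <- paste0(path, ".png")
    png::writePNG(matrix(.png_levels[as.character(grid)] / 255,
                         nrow(grid), ncol(grid)), pngf)
    counter <- if (inherits(state, "cell_lattice")) state$step else state$sweep
    meta <- list(class = class(state)[1], step = counter, seed = state$seed,
                 shape = dim(grid), hash = unname(tools::md5sum(txt)))
    files <- c(txt, pngf)
  } else if (inherits(state, "field_state")) {
    for (f in c("A", "B", "S")) {
      if (is.null(state[[f]])) next
      csv <- paste0(path, "_", f, ".csv")
      utils::write.table(state[[f]], csv, sep = ",",
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, csv)
    }
    meta <- list(class = "field_state", t = state$t, dx = state$dx,
                 shape = dim(state$A),
                 hash = unname(tools::md5sum(files[1])))
  } else {
    abort("unsupported state class")
  }
  metaf <- paste0(path, ".json")
  jsonlite::write_json(meta, metaf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, metaf))
}

#' Read back the lossless text form of a written snapshot
#'
#' @param path Base path used in [write_snapshot()].
#' @return A [cell_lattice()] or [spin_lattice()] depending on the sidecar.
#' @export
read_snapshot <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- as.matrix(utils::read.table(paste0(path, ".txt")))
  dimnames(grid) <- NULL
  if (identical(meta$class, "spin_lattice"))
    spin_lattice(grid, sweep = meta$step %||% 0L)
  else
    cell_lattice(grid, step = meta$step %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a run configuration
#'
#' A `run_config` bundles the model choice, its parameter block, the record
#' schedule and the mandatory seed. Configurations can be read from YAML
#' with [read_run_config()]; there is no silent wall-clock seeding.
#'
#' @param model One of `"ibm"`, `"ising"`, `"pde"`, `"pde_public_goods"`.
#' @param params Model-specific parameter object or list.
#' @param n_steps Total steps (discrete models) or end time (PDE).
#' @param record_at Strictly increasing vector of steps/times to record.
#' @param seed Integer master seed (required).
#' @param out_dir Optional output directory.
#' @export
run_config <- function(model = c("ibm", "ising", "pde", "pde_public_goods"),
                       params = list(), n_steps, record_at = NULL,
                       seed, out_dir = NULL) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed))
    abort("seed must be explicit in a run_config")
  if (is.null(record_at)) record_at <- n_steps
  if (any(diff(record_at) <= 0))
    abort("record schedule must be strictly increasing")
  structure(list(model = model, params = params, n_steps = n_steps,
                 record_at = record_at, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file with keys `model`, `params`, `n_steps`,
#'   `record_at`, `seed`, `out_dir`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(model = y$model, params = y$params %||% list(),
             n_steps = y$n_steps, record_at = unlist(y$record_at),
             seed = y$seed, out_dir = y$out_dir)
}
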