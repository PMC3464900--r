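#' Interpolate an expression matrix onto a uniform time grid
#'
#' Each gene's series is fitted with a cubic spline over the observed
#' timepoints and evaluated on a uniform grid running from the first to the
#' last observed time at `grid_step_h` spacing. With `spar = 0` (default)
#' the fit is an exact interpolating natural cubic spline, so values at
#' observed timepoints are reproduced; with `spar` in (0, 1] a smoothing
#' spline ([stats::smooth.spline()]) is used instead. Fits are per gene and
#' per condition, and deterministic.
#'
#' @param m an [expression_matrix()].
#' @param grid_step_h grid spacing in hours (> 0).
#' @param spar spline smoothing parameter; see Details.
#' @return An `expr_matrix` on the uniform grid.
#' @export
interpolate_to_grid <- function(m, grid_step_h, spar = 0) {
  stopifnot(inherits(m, "expr_matrix"), grid_step_h > 0)
  t_in <- m$timepoints_h
  if (length(t_in) < 4) {
    stop("at least 4 timepoints are required for cubic spline interpolation")
  }
  n_steps <- floor((max(t_in) - min(t_in)) / grid_step_h + 1e-9)
  grid <- min(t_in) + grid_step_h * (0:n_steps)
  out <- matrix(NA_real_, nrow = nrow(m$values), ncol = length(grid))
  for (i in seq_len(nrow(m$values))) {
    y <- m$values[i, ]
    if (spar > 0) {
      fit <- stats::smooth.spline(t_in, y, spar = spar)
      out[i, ] <- stats::predict(fit, grid)$y
    } else {
      f <- stats::splinefun(t_in, y, method = "natural")
      out[i, ] <- f(grid)
    }
  }
  expression_matrix(out, grid, condition = m$condition, gene_ids = m$gene_ids)
}

#' Segment a uniform time grid into overlapping analysis frames
#'
#' The first frame spans the start of the grid; every subsequent frame is a
#' `frame_h`-hour window starting at a light/dark transition and ending on
#' or before the end of the grid. A transition frame whose end coincides
#' with the first frame's end would duplicate it and is dropped. Blending
#' weights for recombining per-frame results are triangular (peaking at the
#' frame centre, falling to a small floor at the edges) and are renormalised
#' so that at every grid timepoint the weights of the covering frames sum
#' to one.
#'
#' @param grid_times_h uniform time grid in hours.
#' @param config a [priism_config()] supplying the frame layout (or explicit
#'   `frame_boundaries` override).
#' @return An object of class `frame_set`: list with `frames` (data frame of
#'   `index`, `start_h`, `end_h`), `weights` (frames x timepoints matrix,
#'   columns summing to 1) and `grid_times_h`.
#' @export
make_frames <- function(grid_times_h, config = priism_config()) {
  grid <- as.numeric(grid_times_h)
  step <- diff(grid)
  if (length(grid) < 2 || any(abs(step - step[1]) > 1e-9)) {
    stop("grid_times_h must be a uniform grid")
  }
  tol <- 1e-9
  g0 <- grid[1]
  gend <- grid[length(grid)]

  if (!is.null(config$frame_boundaries)) {
    bounds <- lapply(config$frame_boundaries, as.numeric)
  } else {
    if (gend - g0 < config$first_frame_h - tol) {
      stop("grid (", gend - g0, " h) is shorter than the first frame (",
           config$first_frame_h, " h)")
    }
    first_end <- g0 + config$first_frame_h
    bounds <- list(c(g0, first_end))
    for (tt in light_dark_transitions(g0, gend, config)) {
      fr_end <- tt + config$frame_h
      if (fr_end > gend + tol) next
      if (abs(fr_end - first_end) < tol) next  # duplicates frame 1's end
      bounds <- c(bounds, list(c(tt, fr_end)))
    }
    bounds <- unique(bounds)
    ord <- order(vapply(bounds, `[`, numeric(1), 1L))
    bounds <- bounds[ord]
  }

  frames <- data.frame(
    index = seq_along(bounds),
    start_h = vapply(bounds, `[`, numeric(1), 1L),
    end_h = vapply(bounds, `[`, numeric(1), 2L)
  )
  if (any(frames$end_h <= frames$start_h)) stop("frame end must exceed start")
  on_grid <- function(x) vapply(x, function(v) any(abs(grid - v) < tol), logical(1))
  if (!all(on_grid(frames$start_h)) || !all(on_grid(frames$end_h))) {
    stop("frame boundaries must lie on the uniform grid")
  }

  w <- matrix(0, nrow = nrow(frames), ncol = length(grid))
  for (f in seq_len(nrow(frames))) {
    s <- frames$start_h[f]; e <- frames$end_h[f]
    inside <- grid >= s - tol & grid <= e + tol
    centre <- (s + e) / 2
    halfw <- (e - s) / 2
    tri <- pmax(1 - abs(grid[inside] - centre) / halfw, config$edge_floor)
    w[f, inside] <- tri
  }
  covered <- colSums(w) > 0
  if (!all(covered)) {
    stop("frames leave grid timepoints uncovered, starting at t = ",
         grid[which(!covered)[1]], " h")
  }
  w <- sweep(w, 2, colSums(w), "/")
  structure(list(frames = frames, weights = w, grid_times_h = grid),
            class = "frame_set")
}

# light/dark transition times inside (g0, gend], given the photoperiod and
# the zeitgeber time of g0
light_dark_transitions <- function(g0, gend, config) {
  period <- config$light_h + config$dark_h
  zt <- config$zt_at_t0 %% period
  in_light <- zt < config$light_h
  t_next <- if (in_light) config$light_h - zt else period - zt
  cur <- g0 + t_next
  out <- numeric(0)
  while (cur <= gend + 1e-9) {
    out <- c(out, cur)
    in_light <- !in_light
    cur <- cur + if (in_light) config$light_h else config$dark_h
  }
  out
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames on %d grid timepoints\n",
              nrow(x$frames), length(x$grid_times_h)))
  for (f in seq_len(nrow(x$frames))) {
    cat(sprintf("  frame %d: [%g, %g] h\n", f, x$frames$start_h[f],
                x$frames$end_h[f]))
  }
  invisible(x)
}

# indices of grid timepoints falling inside frame f
frame_grid_indices <- function(fs, f) {
  s <- fs$frames$start_h[f]; e <- fs$frames$end_h[f]
  which(fs$grid_times_h >= s - 1e-9 & fs$grid_times_h <= e + 1e-9)
}

#' Shift the mean of a framed series to zero
#'
#' Removing the mean before the Fourier transform zeroes the DC coefficient,
#' which would otherwise dominate the spectrum and bias dominant-frequency
#' detection towards frequency zero. The removed mean is retained so it can
#' be redistributed over the reconstructed components later.
#'
#' @param x numeric vector: one gene's expression values within one frame.
#' @return A list of class `mean_shifted`: `samples` (zero-mean values) and
#'   `removed_mean`.
#' @export
mean_shift <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("cannot mean-shift an empty series")
  m <- mean(x)
  structure(list(samples = x - m, removed_mean = m), class = "mean_shifted")
}

#' Blend per-frame series back into one series by weighted averaging
#'
#' @param per_frame_series list with one numeric vector per frame, each
#'   covering exactly that frame's grid timepoints.
#' @param fs a `frame_set` from [make_frames()].
#' @return Numeric vector on the full grid: at each timepoint the
#'   weight-averaged value over the frames covering it.
#' @export
blend_frames <- function(per_frame_series, fs) {
  stopifnot(inherits(fs, "frame_set"))
  n_frames <- nrow(fs$frames)
  if (length(per_frame_series) != n_frames) {
    stop("need one series per frame (", n_frames, "), got ",
         length(per_frame_series))
  }
  out <- numeric(length(fs$grid_times_h))
  for (f in seq_len(n_frames)) {
    idx <- frame_grid_indices(fs, f)
    v <- per_frame_series[[f]]
    if (is.null(v)) stop("missing series for frame ", f)
    if (length(v) != length(idx)) {
      stop("frame ", f, " series has length ", length(v), ", expected ",
           length(idx))
    }
    out[idx] <- out[idx] + fs$weights[f, idx] * v
  }
  out
}
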