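#' Dominant frequency bins of an amplitude spectrum
#'
#' A bin is dominant when its relative amplitude exceeds the threshold
#' (default 0.7, i.e. roughly half-maximal spectral power). Bin 0 is never a
#' candidate: the series is mean-shifted before transforming, so the DC bin
#' carries no signal.
#'
#' @param a an [amplitude_spectrum()].
#' @param threshold relative-amplitude cutoff in (0, 1).
#' @return Integer vector of 0-based dominant bin indices (possibly empty).
#' @export
dominant_frequencies <- function(a, threshold = 0.7) {
  stopifnot(inherits(a, "amplitude_spectrum"), threshold > 0, threshold < 1)
  if (a$degenerate) return(integer(0))
  a$bins[a$bins >= 1L & a$relative_amplitudes > threshold]
}

#' Circadian clock frequency range (CCFR)
#'
#' The union of the dominant frequency bins of the core clock genes'
#' amplitude spectra defines the clock band; its lowest and highest bins
#' bound a closed, contiguous bin interval used for band filtering even if
#' interior bins were dominant for no gene.
#'
#' @param clock_amp_spectra list of [amplitude_spectrum()] objects, one per
#'   core clock gene.
#' @param threshold relative-amplitude cutoff for dominance.
#' @return Integer vector `c(c_min, c_max)` of 0-based bin indices.
#' @export
ccfr <- function(clock_amp_spectra, threshold = 0.7) {
  if (length(clock_amp_spectra) == 0) stop("need at least one clock gene spectrum")
  dom <- unlist(lapply(clock_amp_spectra, dominant_frequencies,
                       threshold = threshold))
  if (length(dom) == 0) {
    stop(structure(
      class = c("priism_no_dominant_bins", "error", "condition"),
      list(message = paste(
             "no clock gene has a dominant frequency bin;",
             "fall back to the configured default clock band",
             "(see fallback_center_cpd in priism_config())"),
           call = sys.call(-1))))
  }
  c(min(dom), max(dom))
}

#' Clock-band weight vector from core clock gene spectra
#'
#' Per CCFR bin n, the power of the core clock genes is summed,
#' \eqn{P_n = \sum_m |G_{mn}|^2}, and min-max normalised across the band:
#' \eqn{w_n = (P_n - \min P) / (\max P - \min P)}. The resulting weights in
#' \[0, 1\] are the gain-frequency response of a tapering band-pass filter.
#' When the band has a single bin (or all bins carry equal power) the
#' normalisation is 0/0 and all weights are set to 1 so the band still
#' passes its components.
#'
#' @param clock_spectra list of `priism_spectrum` objects, one per clock
#'   gene, all of equal length N.
#' @param c_min,c_max 0-based CCFR bin bounds, `1 <= c_min <= c_max <= N/2`.
#' @param condition,frame_index labels carried along for reporting.
#' @return Object of class `clock_vector`: `c_min`, `c_max`, `weights`,
#'   `summed_power`, `condition`, `frame_index`, `N`, `sample_interval_h`.
#' @export
clock_weights <- function(clock_spectra, c_min, c_max,
                          condition = NA_character_, frame_index = NA_integer_) {
  if (length(clock_spectra) == 0) stop("need at least one clock gene spectrum")
  ns <- vapply(clock_spectra, function(s) s$N, numeric(1))
  if (length(unique(ns)) != 1) stop("clock spectra must share one length N")
  n <- ns[1]
  if (!(c_min >= 1 && c_min <= c_max && c_max <= floor(n / 2))) {
    stop("CCFR bins must satisfy 1 <= c_min <= c_max <= floor(N/2)")
  }
  band <- c_min:c_max
  p <- vapply(band, function(b) {
    sum(vapply(clock_spectra, function(s) Mod(s$coefficients[b + 1L])^2,
               numeric(1)))
  }, numeric(1))
  rng <- range(p)
  w <- if (diff(rng) <= 0) rep(1, length(p)) else (p - rng[1]) / diff(rng)
  structure(
    list(c_min = c_min, c_max = c_max, weights = w, summed_power = p,
         condition = condition, frame_index = frame_index, N = n,
         sample_interval_h = clock_spectra[[1]]$sample_interval_h),
    class = "clock_vector"
  )
}

#' @export
print.clock_vector <- function(x, ...) {
  cpd <- 24 / (x$N * x$sample_interval_h)
  cat(sprintf(
    "<clock_vector> %s frame %s: bins %d..%d (%.2f..%.2f cycles/day), weights %s\n",
    x$condition, x$frame_index, x$c_min, x$c_max,
    x$c_min * cpd, x$c_max * cpd,
    paste(signif(x$weights, 3), collapse = " ")))
  invisible(x)
}

# clock vector for one condition x frame: mean-shift + transform each clock
# gene within the frame, take the dominant-bin union, then Eq.-style weights;
# falls back (with a warning) to a band of one bin either side of
# fallback_center_cpd when no gene has a dominant bin.
clock_vector_for_frame <- function(em, fs, f, config) {
  idx <- frame_grid_indices(fs, f)
  t_step <- config$grid_step_h
  present <- intersect(config$clock_genes, em$gene_ids)
  if (length(present) == 0) {
    stop("none of the configured clock genes are present in the ",
         em$condition, " matrix")
  }
  if (length(present) < length(config$clock_genes)) {
    warning("clock genes missing from ", em$condition, " matrix: ",
            paste(setdiff(config$clock_genes, present), collapse = ", "))
  }
  spectra <- lapply(present, function(g) {
    dft(mean_shift(em$values[g, idx]), t_step)
  })
  band <- tryCatch(
    ccfr(lapply(spectra, amplitude_spectrum),
         threshold = config$rel_amp_threshold),
    priism_no_dominant_bins = function(e) {
      n <- spectra[[1]]$N
      centre <- round(config$fallback_center_cpd * n * t_step / 24)
      lo <- max(1L, centre - 1L)
      hi <- min(floor(n / 2), centre + 1L)
      warning("no dominant clock bins in ", em$condition, " frame ", f,
              "; using fallback band ", lo, "..", hi, call. = FALSE)
      c(lo, hi)
    })
  clock_weights(spectra, band[1], band[2],
                condition = em$condition, frame_index = f)
}

#' Tabulate clock vectors for inspection and plotting
#'
#' One row per condition x frame, with the band boundaries converted to
#' cycles per day and the tapering weights serialised alongside. The
#' per-frame differences between conditions visualise treatment-induced
#' clock disruption (damping, phase shifts, period lengthening move and
#' reshape the band).
#'
#' @param vectors list of `clock_vector` objects.
#' @return A data frame with columns `condition`, `frame_index`, `c_min`,
#'   `c_max`, `f_min_cpd`, `f_max_cpd`, `n_bins`, `weights` (comma-joined).
#' @export
clock_vector_report <- function(vectors) {
  stopifnot(length(vectors) > 0)
  rows <- lapply(vectors, function(v) {
    cpd <- 24 / (v$N * v$sample_interval_h)
    data.frame(
      condition = v$condition, frame_index = v$frame_index,
      c_min = v$c_min, c_max = v$c_max,
      f_min_cpd = v$c_min * cpd, f_max_cpd = v$c_max * cpd,
      n_bins = v$N,
      weights = paste(signif(v$weights, 6), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
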