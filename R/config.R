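#' Pipeline configuration
#'
#' Bundles every tunable parameter of the decomposition pipeline. Defaults
#' describe a 58-hour course sampled under a 16 h light / 8 h dark cycle
#' that starts 14 h after dawn (ZT14), the layout for which the default
#' frame geometry (a 26-hour first frame followed by 24-hour frames aligned
#' to light/dark transitions) was designed.
#'
#' @param grid_step_h uniform grid spacing in hours used for interpolation.
#' @param first_frame_h length of the first analysis frame, hours.
#' @param frame_h length of every subsequent frame, hours.
#' @param light_h,dark_h photoperiod: hours of light and of dark per cycle.
#' @param zt_at_t0 zeitgeber time (hours since dawn) at the first timepoint.
#' @param frame_boundaries optional explicit override: a list of
#'   `c(start_h, end_h)` pairs. When given, the photoperiod-derived layout
#'   is ignored.
#' @param edge_floor floor for the triangular frame blending weights at the
#'   frame edges (weights are renormalised per timepoint); keeps timepoints
#'   covered only by frame edges from receiving zero total weight.
#' @param spline_spar smoothing parameter for grid interpolation; `0` (the
#'   default) requests an exact interpolating cubic spline, values in
#'   (0, 1] are passed to [stats::smooth.spline()] as `spar`.
#' @param clock_genes identifiers of the core circadian clock genes used to
#'   locate the clock frequency band. Defaults to the eight canonical
#'   Arabidopsis core clock genes.
#' @param rel_amp_threshold relative-amplitude cutoff above which a
#'   frequency bin counts as dominant (0.7 corresponds to half-maximal
#'   spectral power).
#' @param fallback_center_cpd centre, in cycles/day, of the fallback clock
#'   band (centre bin plus/minus one bin) used with a warning when no clock
#'   gene has any dominant frequency in a frame.
#' @return A list of class `priism_config`.
#' @export
priism_config <- function(grid_step_h = 2,
                          first_frame_h = 26,
                          frame_h = 24,
                          light_h = 16,
                          dark_h = 8,
                          zt_at_t0 = 14,
                          frame_boundaries = NULL,
                          edge_floor = 0.05,
                          spline_spar = 0,
                          clock_genes = c("CCA1", "LHY", "PRR7", "PRR9",
                                          "ELF4", "GI", "LUX", "TOC1"),
                          rel_amp_threshold = 0.7,
                          fallback_center_cpd = 1) {
  stopifnot(grid_step_h > 0, first_frame_h > 0, frame_h > 0,
            light_h > 0, dark_h > 0, zt_at_t0 >= 0,
            edge_floor >= 0, edge_floor < 1,
            rel_amp_threshold > 0, rel_amp_threshold < 1,
            fallback_center_cpd > 0)
  structure(
    list(grid_step_h = grid_step_h, first_frame_h = first_frame_h,
         frame_h = frame_h, light_h = light_h, dark_h = dark_h,
         zt_at_t0 = zt_at_t0, frame_boundaries = frame_boundaries,
         edge_floor = edge_floor, spline_spar = spline_spar,
         clock_genes = clock_genes,
         rel_amp_threshold = rel_amp_threshold,
         fallback_center_cpd = fallback_center_cpd),
    class = "priism_config"
  )
}

#' Read a pipeline configuration from a YAML (or JSON) file
#'
#' Keys missing from the file keep their [priism_config()] defaults.
#' `frame_boundaries`, if present, is a list of two-element `[start, end]`
#' arrays in hours.
#'
#' @param path path to a YAML/JSON config file.
#' @return A `priism_config`.
#' @export
read_priism_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(priism_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
    raw <- raw[intersect(names(raw), known)]
  }
  if (!is.null(raw$frame_boundaries)) {
    raw$frame_boundaries <- lapply(raw$frame_boundaries, as.numeric)
  }
  do.call(priism_config, raw)
}
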