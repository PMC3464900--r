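#' Partition spectrum bins into treatment, clock and noise bands
#'
#' The treatment band is `[0, c_min-1]`, the clock band `[c_min, c_max]`,
#' and the noise band everything above `c_max`, each closed under the
#' conjugate mirror `n -> N - n` so that filtered spectra stay
#' conjugate-symmetric and reconstructions real. The three sets are
#' pairwise disjoint and exhaustive ("coarse graining": no bin belongs to
#' two bands). The Nyquist bin (even N) falls in the noise band unless the
#' CCFR reaches it.
#'
#' @param N spectrum length.
#' @param c_min,c_max 0-based clock band bounds, `1 <= c_min <= c_max <= N/2`.
#' @return Object of class `band_partition`: integer vectors `treatment`,
#'   `clock`, `noise` of 0-based bins, plus `N`, `c_min`, `c_max`.
#' @export
partition_bands <- function(N, c_min, c_max) {
  stopifnot(N >= 4, c_min >= 1, c_min <= c_max, c_max <= floor(N / 2))
  mirror <- function(n) (N - n) %% N
  treat <- 0:(c_min - 1L)
  clock <- c_min:c_max
  treatment <- sort(unique(c(treat, mirror(treat))))
  clockb <- sort(unique(c(clock, mirror(clock))))
  noise <- setdiff(0:(N - 1L), c(treatment, clockb))
  structure(list(treatment = treatment, clock = clockb, noise = noise,
                 N = N, c_min = c_min, c_max = c_max),
            class = "band_partition")
}

mask_spectrum <- function(sp, keep_bins) {
  co <- sp$coefficients
  keep <- rep(FALSE, sp$N)
  keep[keep_bins + 1L] <- TRUE
  co[!keep] <- 0 + 0i
  new_spectrum_like(sp, co)
}

#' Ideal low-pass filter retaining the treatment band
#'
#' A brick-wall mask: coefficients in the treatment band (and mirrors) pass
#' unchanged, all others are zeroed. The steep cutoff keeps the bands
#' exactly disjoint.
#'
#' @param sp a `priism_spectrum`.
#' @param p a [partition_bands()] result with matching N.
#' @return Filtered `priism_spectrum`.
#' @export
filter_treatment <- function(sp, p) {
  check_partition(sp, p)
  mask_spectrum(sp, p$treatment)
}

#' Tapering band-pass filter for the clock band
#'
#' Each clock-band coefficient (and its conjugate mirror) is multiplied by
#' its clock-vector weight, \eqn{\hat G_c = w_c G_c}; every bin outside the
#' band is zeroed. The taper suppresses band edges with little summed clock
#' power, reducing noise and discontinuity artefacts relative to a
#' rectangular mask.
#'
#' @param sp a `priism_spectrum`.
#' @param p a [partition_bands()] result.
#' @param cv a [clock_weights()] vector whose band equals the partition's.
#' @return Filtered `priism_spectrum`.
#' @export
filter_clock <- function(sp, p, cv) {
  check_partition(sp, p)
  if (cv$c_min != p$c_min || cv$c_max != p$c_max || cv$N != p$N) {
    stop("clock vector band does not match the partition")
  }
  co <- rep(0 + 0i, sp$N)
  for (j in seq_along(cv$weights)) {
    b <- cv$c_min + j - 1L
    mb <- (sp$N - b) %% sp$N
    co[b + 1L] <- cv$weights[j] * sp$coefficients[b + 1L]
    co[mb + 1L] <- cv$weights[j] * sp$coefficients[mb + 1L]
  }
  new_spectrum_like(sp, co)
}

#' Ideal high-pass filter retaining the noise band
#'
#' @param sp a `priism_spectrum`.
#' @param p a [partition_bands()] result with matching N.
#' @return Filtered `priism_spectrum`.
#' @export
filter_noise <- function(sp, p) {
  check_partition(sp, p)
  mask_spectrum(sp, p$noise)
}

check_partition <- function(sp, p) {
  stopifnot(inherits(sp, "priism_spectrum"), inherits(p, "band_partition"))
  if (sp$N != p$N) stop("partition length ", p$N, " != spectrum length ", sp$N)
  invisible(TRUE)
}

#' Redistribute the removed mean over the reconstructed components
#'
#' The mean removed before transforming is added back to the three
#' reconstructed series in proportion to each band's share of the original
#' (unshifted) spectrum's power. The DC bin of the unshifted spectrum,
#' \eqn{|G_0| = K \bar g}, belongs to the treatment band, so for typical
#' log-scale expression (large mean, modest oscillation) nearly the whole
#' baseline returns to the treatment component and the clock and noise
#' components stay close to zero-mean — a constant gene is all trend. The
#' three offsets always sum to the removed mean exactly.
#'
#' @param components list with zero-mean reconstructions `treatment`,
#'   `clock`, `noise` (from [idft()] of the filtered spectra).
#' @param removed_mean the frame mean removed by [mean_shift()].
#' @param sp the unfiltered `priism_spectrum` of the mean-shifted series.
#' @param p the [partition_bands()] used for filtering.
#' @return Object of class `component_set`: the three offset series plus
#'   `band_power_fractions`, `restored_means` and `removed_mean`.
#' @export
redistribute_mean <- function(components, removed_mean, sp, p) {
  check_partition(sp, p)
  pw <- Mod(sp$coefficients)^2
  # mean shift only changes bin 0: restore the unshifted DC power |K*mean|^2
  pw[1L] <- (sp$N * removed_mean)^2
  band_pw <- c(treatment = sum(pw[p$treatment + 1L]),
               clock = sum(pw[p$clock + 1L]),
               noise = sum(pw[p$noise + 1L]))
  total <- sum(band_pw)
  frac <- if (total <= 0) c(treatment = 1, clock = 0, noise = 0) else band_pw / total
  offsets <- removed_mean * frac
  structure(
    list(treatment = components$treatment + offsets[["treatment"]],
         clock = components$clock + offsets[["clock"]],
         noise = components$noise + offsets[["noise"]],
         band_power_fractions = frac,
         restored_means = offsets,
         removed_mean = removed_mean),
    class = "component_set"
  )
}

#' Decompose one gene's series into treatment, clock and noise components
#'
#' Per frame: mean-shift, transform, split the spectrum into the three
#' bands (ideal low-pass, tapering clock band-pass, ideal high-pass),
#' inverse-transform each band and redistribute the removed mean in
#' proportion to band power. The per-frame component series are then
#' blended across frames with the frame-set weights. By linearity and mean
#' conservation the three full-grid components sum to the original series.
#'
#' @param samples numeric vector: the gene's values on the full uniform grid.
#' @param fs a `frame_set` from [make_frames()].
#' @param vectors list of `clock_vector` objects, one per frame, for the
#'   gene's condition.
#' @param grid_step_h grid spacing in hours.
#' @return List of class `gene_components`: full-grid `treatment`, `clock`,
#'   `noise` series and `per_frame` (the per-frame `component_set`s).
#' @export
decompose_gene <- function(samples, fs, vectors, grid_step_h) {
  stopifnot(inherits(fs, "frame_set"))
  n_frames <- nrow(fs$frames)
  if (length(vectors) != n_frames) {
    stop("need one clock vector per frame (", n_frames, ")")
  }
  per_frame <- vector("list", n_frames)
  parts <- list(treatment = vector("list", n_frames),
                clock = vector("list", n_frames),
                noise = vector("list", n_frames))
  for (f in seq_len(n_frames)) {
    idx <- frame_grid_indices(fs, f)
    ms <- mean_shift(samples[idx])
    sp <- dft(ms, grid_step_h)
    cv <- vectors[[f]]
    if (cv$N != sp$N) {
      stop("clock vector for frame ", f, " was computed on a different grid")
    }
    p <- partition_bands(sp$N, cv$c_min, cv$c_max)
    comp <- list(treatment = idft(filter_treatment(sp, p)),
                 clock = idft(filter_clock(sp, p, cv)),
                 noise = idft(filter_noise(sp, p)))
    cs <- redistribute_mean(comp, ms$removed_mean, sp, p)
    per_frame[[f]] <- cs
    parts$treatment[[f]] <- cs$treatment
    parts$clock[[f]] <- cs$clock
    parts$noise[[f]] <- cs$noise
  }
  structure(
    list(treatment = blend_frames(parts$treatment, fs),
         clock = blend_frames(parts$clock, fs),
         noise = blend_frames(parts$noise, fs),
         per_frame = per_frame),
    class = "gene_components"
  )
}
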