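#' Configuration for the synthetic diel-expression generator
#'
#' Describes a paired control/treatment experiment over a multi-day course:
#' log-scale baselines, ~24-h sinusoidal clock components with gene-specific
#' amplitude and phase, a low-frequency treatment-response trend planted in
#' a responder subset of the treatment condition, treatment-induced clock
#' disruption (amplitude damping, phase shift, period lengthening) applied
#' to every gene's oscillation in the treatment condition, and additive
#' Gaussian noise. Defaults emulate a 58-hour course sampled every 2 hours
#' with 200 genes, 8 strongly rhythmic core clock genes, 30 responders with
#' a 2 log2-unit upregulation and noise sd 0.3.
#'
#' @param n_genes total gene count.
#' @param n_clock_genes number of core clock genes (strong oscillators); up
#'   to eight receive the canonical Arabidopsis core clock names.
#' @param n_responders number of treatment-responder genes.
#' @param t_start,t_end,t_step time grid in hours.
#' @param baseline_range range of per-gene baseline means (log2 units).
#' @param clock_period_h oscillation period in the control condition.
#' @param clock_amp_range amplitude range for non-clock genes (log2 units).
#' @param clock_gene_amp amplitude of the core clock genes.
#' @param treatment_period_h lengthened oscillation period under treatment.
#' @param damping multiplicative amplitude damping under treatment.
#' @param phase_shift_h additive phase shift under treatment, hours.
#' @param effect_size responder upregulation plateau (log2 units).
#' @param onset_h logistic midpoint of the responder trend, hours.
#' @param rise_h logistic time scale of the responder trend, hours.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed RNG seed; fixed seed gives bit-reproducible output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, n_clock_genes = 8, n_responders = 30,
                       t_start = 0, t_end = 58, t_step = 2,
                       baseline_range = c(6, 10),
                       clock_period_h = 24,
                       clock_amp_range = c(0.5, 1.5),
                       clock_gene_amp = 2,
                       treatment_period_h = 28,
                       damping = 0.6,
                       phase_shift_h = 3,
                       effect_size = 2,
                       onset_h = 26,
                       rise_h = 4,
                       noise_sd = 0.3,
                       seed = 1) {
  if (n_clock_genes < 1 || n_responders < 0 ||
      n_clock_genes + n_responders > n_genes) {
    stop("need n_clock_genes >= 1, n_responders >= 0 and ",
         "n_clock_genes + n_responders <= n_genes")
  }
  stopifnot(t_end > t_start, t_step > 0, clock_period_h > 0,
            treatment_period_h > 0, damping >= 0, noise_sd >= 0, rise_h > 0)
  structure(as.list(environment()), class = "sim_config")
}

core_clock_names <- c("CCA1", "LHY", "PRR7", "PRR9", "ELF4", "GI", "LUX", "TOC1")

#' Simulate paired control/treatment expression matrices with ground truth
#'
#' Control series are `baseline + amplitude * sin(2*pi*t/period + phase) +
#' noise`. Treatment series use a damped amplitude, shifted phase and
#' lengthened period for every gene's oscillation, and responders
#' additionally receive a logistic upregulation trend
#' `effect / (1 + exp(-(t - onset)/rise))`. Clock genes are strong-amplitude
#' oscillators named after the core clock genes so the clock-band detection
#' works out of the box. The returned ground truth holds each planted part
#' per condition; the planted parts sum to the emitted values exactly.
#'
#' @param cfg a [sim_config()].
#' @return Object of class `sim_result`: `control` and `treatment`
#'   ([expression_matrix()]s) and `truth` (list with `clock_genes`,
#'   `responders`, `times_h`, `baseline`, and per-condition `trend`,
#'   `sinusoid`, `noise` matrices).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)
  t <- seq(cfg$t_start, cfg$t_end, by = cfg$t_step)
  nt <- length(t)
  ng <- cfg$n_genes

  n_named <- min(cfg$n_clock_genes, length(core_clock_names))
  clock_ids <- c(core_clock_names[seq_len(n_named)],
                 if (cfg$n_clock_genes > n_named)
                   sprintf("CLOCK_%02d", seq_len(cfg$n_clock_genes - n_named)))
  resp_ids <- if (cfg$n_responders > 0) sprintf("RESP_%03d", seq_len(cfg$n_responders))
  other_ids <- sprintf("GENE_%03d", seq_len(ng - cfg$n_clock_genes - cfg$n_responders))
  ids <- c(clock_ids, resp_ids, other_ids)

  baseline <- stats::runif(ng, cfg$baseline_range[1], cfg$baseline_range[2])
  phase <- stats::runif(ng, 0, 2 * pi)
  amp <- stats::runif(ng, cfg$clock_amp_range[1], cfg$clock_amp_range[2])
  amp[seq_len(cfg$n_clock_genes)] <- cfg$clock_gene_amp

  sin_ctrl <- outer(seq_len(ng), seq_len(nt), function(i, j) {
    amp[i] * sin(2 * pi * t[j] / cfg$clock_period_h + phase[i])
  })
  phase_t <- phase + 2 * pi * cfg$phase_shift_h / cfg$clock_period_h
  sin_trt <- outer(seq_len(ng), seq_len(nt), function(i, j) {
    cfg$damping * amp[i] * sin(2 * pi * t[j] / cfg$treatment_period_h + phase_t[i])
  })
  trend_trt <- matrix(0, ng, nt)
  if (cfg$n_responders > 0) {
    resp_rows <- cfg$n_clock_genes + seq_len(cfg$n_responders)
    rise <- cfg$effect_size / (1 + exp(-(t - cfg$onset_h) / cfg$rise_h))
    trend_trt[resp_rows, ] <- matrix(rise, cfg$n_responders, nt, byrow = TRUE)
  }
  noise_ctrl <- matrix(stats::rnorm(ng * nt, sd = cfg$noise_sd), ng, nt)
  noise_trt <- matrix(stats::rnorm(ng * nt, sd = cfg$noise_sd), ng, nt)

  vals_ctrl <- baseline + sin_ctrl + noise_ctrl
  vals_trt <- baseline + trend_trt + sin_trt + noise_trt

  truth <- list(
    clock_genes = clock_ids,
    responders = as.character(resp_ids),
    times_h = t,
    baseline = stats::setNames(baseline, ids),
    control = list(trend = matrix(0, ng, nt, dimnames = list(ids, NULL)),
                   sinusoid = `rownames<-`(sin_ctrl, ids),
                   noise = `rownames<-`(noise_ctrl, ids)),
    treatment = list(trend = `rownames<-`(trend_trt, ids),
                     sinusoid = `rownames<-`(sin_trt, ids),
                     noise = `rownames<-`(noise_trt, ids))
  )
  structure(
    list(control = expression_matrix(vals_ctrl, t, "control", ids),
         treatment = expression_matrix(vals_trt, t, "treatment", ids),
         truth = truth, config = cfg),
    class = "sim_result"
  )
}

#' Write a simulated dataset to disk
#'
#' Emits `control.tsv` and `treatment.tsv` (tab-delimited expression
#' matrices), `gold.txt` (one responder id per line: the gold-standard list
#' for evaluation) and `truth.json` (planted components, full precision).
#'
#' @param sim a [simulate_expression()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$control, file.path(dir, "control.tsv"))
  write_expression(sim$treatment, file.path(dir, "treatment.tsv"))
  writeLines(sim$truth$responders, file.path(dir, "gold.txt"))
  truth <- sim$truth
  truth$baseline <- as.list(truth$baseline)  # keep gene names in JSON
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(dir)
}

#' Reload the ground truth written by [write_fixture()]
#'
#' @param path path to `truth.json`.
#' @return The truth list, with component matrices restored.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  tr$baseline <- unlist(tr$baseline)
  ids <- names(tr$baseline)
  for (cond in c("control", "treatment")) {
    tr[[cond]] <- lapply(tr[[cond]], function(m) {
      m <- as.matrix(m)
      rownames(m) <- ids
      m
    })
  }
  tr
}
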