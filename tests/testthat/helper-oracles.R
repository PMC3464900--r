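# Independent brute-force oracles, deliberately naive: these re-derive the
# quantities the package computes via library routines, straight from the
# defining sums.

# forward transform, O(N^2) summation
naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(m) {
    sum(x * exp(-2i * pi * m * (0:(n - 1)) / n))
  }, complex(1))
}

# inverse transform, O(N^2) summation
naive_idft <- function(co) {
  n <- length(co)
  vapply(0:(n - 1), function(k) {
    sum(co * exp(2i * pi * (0:(n - 1)) * k / n)) / n
  }, complex(1))
}

# cumulative TP/FP walk down a ranking
naive_roc_walk <- function(ranked_ids, gold) {
  tp <- 0L; fp <- 0L
  out <- matrix(0L, nrow = length(ranked_ids), ncol = 2,
                dimnames = list(NULL, c("tp", "fp")))
  for (r in seq_along(ranked_ids)) {
    if (ranked_ids[r] %in% gold) tp <- tp + 1L else fp <- fp + 1L
    out[r, ] <- c(tp, fp)
  }
  out
}

# a spectrum object built directly from coefficients (for filter tests)
fake_spectrum <- function(co, sample_interval_h = 2) {
  n <- length(co)
  structure(
    list(coefficients = as.complex(co), N = n,
         sample_interval_h = sample_interval_h,
         frequencies = (0:(n - 1)) / (n * sample_interval_h)),
    class = "priism_spectrum"
  )
}

# conjugate-symmetric random spectrum of length n (real underlying signal)
random_real_spectrum <- function(n, sample_interval_h = 2) {
  fake_spectrum(stats::fft(stats::rnorm(n)), sample_interval_h)
}

# small well-formed expression matrix on an uneven diel sampling
tiny_matrix <- function(n_genes = 3, times = c(0, 2, 6, 10, 14), seed = 42,
                        condition = "control") {
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_genes * length(times), mean = 8),
                 nrow = n_genes)
  expression_matrix(vals, times, condition = condition,
                    gene_ids = sprintf("G%02d", seq_len(n_genes)))
}

default_grid_58h <- seq(0, 58, by = 2)

# internal helpers exercised directly by tests
ranked_list <- function(...) priism:::ranked_list(...)
frame_grid_indices <- function(...) priism:::frame_grid_indices(...)
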