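# Independent oracles and small fixtures, built in code at test time.

# O(n*m) brute-force two-sample KS statistic: for every pooled value,
# compare the ECDFs by direct counting.
ks_brute <- function(a, b) {
  vals <- c(a, b)
  m <- 0
  for (x in vals) {
    d <- abs(mean(a <= x) - mean(b <= x))
    if (d > m) m <- d
  }
  m
}

# pixel cloud of nonnegative two-stain mixtures with exclusive-stain tails,
# for extraction tests with a known mixing matrix
make_pixel_cloud <- function(v_hem, v_dab, n = 5000, frac_hem = 0.45,
                             frac_dab = 0.25, noise_sd = 0.003, seed = 1) {
  v_hem <- v_hem / sqrt(sum(v_hem^2))
  v_dab <- v_dab / sqrt(sum(v_dab^2))
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    cls <- sample.int(3L, n, replace = TRUE,
                      prob = c(frac_hem, frac_dab, 1 - frac_hem - frac_dab))
    ch <- ifelse(cls != 2L, 0.05 + rgamma(n, 2, scale = 0.25), 0)
    cd <- ifelse(cls != 1L, 0.05 + rgamma(n, 2, scale = 0.30), 0)
    pmax(ch %o% v_hem + cd %o% v_dab + matrix(rnorm(3 * n, 0, noise_sd), n, 3), 0)
  })
}

# small synthetic reference for pipeline-level tests
small_spec <- function(seed = 1, n_cores = 16L, tile_px = 80L, ...) {
  synthetic_spec(n_cores = n_cores, tile_px = tile_px, seed = seed, ...)
}

white_bg <- function() sda_background(c(1, 1, 1))

max_axis_error <- function(basis, spec) {
  max(angle_deg(basis$a, spec$v_hem), angle_deg(basis$b, spec$v_dab))
}
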