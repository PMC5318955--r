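# internal helpers shared across modules

vnorm <- function(x) sqrt(sum(x^2))

unitize <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  x / n
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Angle between two vectors in degrees
#'
#' Convenience for assessing stain-axis recovery: the unsigned angle between
#' two 3-vectors, in degrees.
#'
#' @param u,v numeric vectors of equal length.
#' @return angle in degrees, in `[0, 180]`.
#' @export
angle_deg <- function(u, v) {
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, ct))) * 180 / pi
}

# run code with a local RNG state so library calls do not disturb the
# caller's random stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# quantiles at probabilities (i - 0.5)/n, linearly interpolating order
# statistics (stats::quantile type 5, whose plateau convention matches
# these probabilities).  Every quantile computation in the package routes
# through here so QC numbers are reproducible under one fixed rule.
mid_probs <- function(n) (seq_len(n) - 0.5) / n

sample_quantiles <- function(x, n_quantiles) {
  stats::quantile(x, probs = mid_probs(n_quantiles), type = 5, names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
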