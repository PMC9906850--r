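# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a stream-specific 32-bit seed from a base seed; keeps independent
# stages decoupled while remaining reproducible from one integer
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483L + 1L
}

km <- function(m) m / 1000

dist2d <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

# split-Rhat (Gelman et al.) for a draws matrix [iterations x chains]
split_rhat <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

log_dhalfnorm <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) - log(scale) + dnorm(x / scale, log = TRUE))
}

# log density of centered bivariate normal with SDs (s1, s2), correlation r
log_dbvn <- function(a, b, s1, s2, r) {
  q <- (a / s1)^2 - 2 * r * (a / s1) * (b / s2) + (b / s2)^2
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log1p(-r^2) - q / (2 * (1 - r^2))
}

# draws from a centered bivariate normal via Cholesky
rbvn <- function(n, s1, s2, r) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(s1 * z1, s2 * (r * z1 + sqrt(1 - r^2) * z2))
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x == floor(x)
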