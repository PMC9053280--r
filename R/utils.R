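# shared internal helpers

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. seed = NULL leaves the stream alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

ppm_diff <- function(observed, theoretical) {
  abs(observed - theoretical) / theoretical * 1e6
}

within_ppm <- function(mz, target, ppm) {
  abs(mz - target) <= target * ppm * 1e-6
}

# lognormal sdlog giving coefficient of variation `cv`
cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

# multiplicative lognormal noise with unit mean and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- cv_to_sdlog(cv)
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# trapezoidal integral of y(t)
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# min-max scale to [0, 1]; an all-equal vector maps to a stated constant
minmax_scale <- function(x, constant = 0.5) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(constant, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Euclidean cross-distance matrix between rows of A (n x p) and B (m x p)
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Spearman rank correlation with a two-sided p-value from the t reference
# distribution on (n - 2) df (midranks for ties). Returns c(rho, p).
spearman_rho_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4 || sd(x) == 0 || sd(y) == 0) return(c(rho = NA_real_, p = NA_real_))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(-abs(tt), df = n - 2))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) stop(sprintf("`%s` must be finite", name), call. = FALSE)
  invisible(x)
}
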