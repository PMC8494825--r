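# von Mises primitives: density, sampling, ML concentration, plug-in bandwidth.
# These underpin the kernel density estimator and the smoothed bootstrap.

#' Wrap angles onto [0, 2*pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return Angles reduced modulo `2*pi` into `[0, 2*pi)`.
#' @export
wrap_angle <- function(theta) {
  theta %% (2 * pi)
}

#' von Mises density
#'
#' Density of the von Mises distribution with mean direction `mu` and
#' concentration `kappa`. Evaluated with exponentially scaled Bessel
#' functions so large concentrations do not overflow.
#'
#' @param theta angles in radians.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0); `kappa = 0` is the circular uniform.
#' @return Density values.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) {
    return(rep(1 / (2 * pi), length(theta)))
  }
  # exp(kappa*cos(d)) / (2*pi*I0(kappa)) == exp(kappa*(cos(d)-1)) / (2*pi*I0.scaled)
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` falls back to the circular
#' uniform. Draws depend only on the R random number stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0).
#' @return `n` angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    nk <- sum(keep)
    if (nk > 0) {
      u3 <- stats::runif(nk)
      out[(got + 1):(got + nk)] <- sign(u3 - 0.5) * acos(f[keep])
      got <- got + nk
    }
  }
  wrap_angle(out + mu)
}

# Ratio A1(kappa) = I1(kappa)/I0(kappa); scaled Bessels cancel the exp factor.
.A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Mean resultant length of a circular sample
#'
#' @param theta angles in radians.
#' @return Scalar in `[0, 1]`.
#' @export
mean_resultant_length <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

#' Maximum-likelihood von Mises concentration
#'
#' Solves A(kappa) = Rbar, where A is the ratio of modified Bessel functions
#' I1/I0 and Rbar the mean resultant length, by bracketed root-finding.
#' Perfectly dispersed samples (Rbar near 0) give kappa = 0; numerically
#' coincident samples (Rbar near 1) are capped at `kappa_max` with a warning
#' because the MLE diverges.
#'
#' @param theta angles in radians, `length(theta) >= 2`.
#' @param kappa_max cap for degenerate (all-coincident) samples.
#' @return Estimated concentration `kappa >= 0`.
#' @export
kappa_ml <- function(theta, kappa_max = 500) {
  stopifnot(length(theta) >= 2)
  rbar <- mean_resultant_length(theta)
  if (rbar < 1e-12) return(0)
  if (rbar >= .A1(kappa_max)) {
    warning("sample is (numerically) concentrated at a point; capping kappa at ",
            kappa_max)
    return(kappa_max)
  }
  stats::uniroot(function(k) .A1(k) - rbar,
                 lower = 1e-10, upper = kappa_max, tol = 1e-10)$root
}

#' Plug-in bandwidth for the von Mises kernel
#'
#' Concentration of the smoothing kernel, chosen by the plug-in rule
#' `kappa = (3 n k^2 I2(2k) / (4 sqrt(pi) I1(k)^2))^(2/5)` with `k` the
#' maximum-likelihood von Mises concentration of the sample, then scaled by
#' `adjust`. Computed on the log scale so large `k` does not overflow the
#' Bessel functions. Dispersed samples for which the rule collapses to zero
#' are floored at `bw_floor`.
#'
#' @param theta angles in radians, `length(theta) >= 2`.
#' @param adjust multiplier on the plug-in value (0.8 pairs with the Dhat1
#'   overlap estimator, 1.0 with Dhat4).
#' @param bw_floor minimum returned concentration.
#' @param kappa_max passed to [kappa_ml()].
#' @return Kernel concentration (> 0).
#' @export
plugin_bandwidth <- function(theta, adjust = 1, bw_floor = 0.01, kappa_max = 500) {
  stopifnot(length(theta) >= 2, adjust > 0)
  k <- kappa_ml(theta, kappa_max = kappa_max)
  if (k < 1e-10) return(bw_floor)
  n <- length(theta)
  log_i2 <- log(besselI(2 * k, 2, expon.scaled = TRUE)) + 2 * k
  log_i1 <- log(besselI(k, 1, expon.scaled = TRUE)) + k
  log_arg <- log(3) + log(n) + 2 * log(k) + log_i2 -
    log(4) - 0.5 * log(pi) - 2 * log_i1
  max(adjust * exp(0.4 * log_arg), bw_floor)
}

# Density of a von Mises mixture given component data.frames/lists with
# mean, kappa, weight. Used by the synthetic generator's ground truth.
dvm_mixture <- function(theta, mixture) {
  dens <- numeric(length(theta))
  for (i in seq_len(nrow(mixture))) {
    dens <- dens + mixture$weight[i] *
      dvonmises(theta, mixture$mean[i], mixture$kappa[i])
  }
  dens
}

rvm_mixture <- function(n, mixture) {
  if (n == 0) return(numeric(0))
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  out <- numeric(n)
  for (i in unique(comp)) {
    idx <- comp == i
    out[idx] <- rvonmises(sum(idx), mixture$mean[i], mixture$kappa[i])
  }
  out
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
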