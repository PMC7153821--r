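# Internal helpers: angle arithmetic, seeded RNG scoping, von Mises sampling.

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrapped angular difference a - b in degrees, result in (-180, 180].
angle_diff <- function(a, b) wrap_angle(a - b)

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG
# stream; seeds must stay below 2^31 (R integers).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; the circular analogue of a Gaussian
#' with mean direction `mu` and concentration `kappa` (variance ~ 1/kappa for
#' large kappa). Used as the per-angle emission model of the synthetic torsion
#' generator.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, > 0.
#' @return n draws in radians, in (-pi, pi] relative to zero (absolute, i.e.
#'   already shifted by `mu` and wrapped).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa > 0, n >= 0)
  if (n == 0) return(numeric(0))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      u3 <- stats::runif(k)
      theta <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      out[(filled + 1L):(filled + k)] <- theta
      filled <- filled + k
    }
  }
  th <- out + mu
  th - 2 * pi * ceiling((th - pi) / (2 * pi))
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left Perron eigenvector of `T`, normalized to sum to one.
#'
#' @param T row-stochastic transition matrix.
#' @return stationary probability vector pi with pi %*% T = pi.
#' @export
stationary_distribution <- function(T) {
  stopifnot(is.matrix(T), nrow(T) == ncol(T))
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("no non-negative stationary vector; is T stochastic?")
  pmax(v, 0) / sum(pmax(v, 0))
}

check_stochastic <- function(P, tol = 1e-12) {
  if (any(P < 0)) stop("jump/transition matrix has negative entries")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol)) {
    stop(sprintf("matrix rows must sum to 1 (max deviation %.3g)", max(abs(rs - 1))))
  }
  invisible(TRUE)
}
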