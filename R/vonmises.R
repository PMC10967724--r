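#' Sample headings from a von Mises distribution
#'
#' Draws angles (degrees, clockwise from upward) from the von Mises
#' distribution with mean direction `mu_deg` and concentration `kappa`.
#' `kappa = 0` is the uniform circular distribution; large `kappa`
#' concentrates all mass near `mu_deg`. Uses the Best-Fisher (1979)
#' wrapped-Cauchy envelope rejection sampler.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration parameter, >= 0.
#' @return numeric vector of `n` angles in `[0, 360)`.
#' @examples
#' set.seed(1)
#' mean(cos(rvonmises_deg(5000, 0, 2) * pi / 180))  # ~ I1(2)/I0(2) = 0.698
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  stopifnot(length(n) == 1, n >= 0, is.finite(kappa), kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)

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
    c_ <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    nok <- sum(ok)
    if (nok > 0) {
      u3 <- stats::runif(nok)
      theta <- sign(u3 - 0.5) * acos(f[ok]) + mu
      out[(got + 1L):(got + nok)] <- theta
      got <- got + nok
    }
  }
  wrap360(rad2deg(out))
}

#' Theoretical mean resultant length of a von Mises distribution
#'
#' The population value that the empirical r-value of a large von Mises
#' sample converges to: the Bessel-function ratio I1(kappa)/I0(kappa).
#'
#' @param kappa concentration parameter, >= 0.
#' @return mean resultant length in `[0, 1)`.
#' @export
vonmises_rho <- function(kappa) {
  stopifnot(all(kappa >= 0))
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}
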