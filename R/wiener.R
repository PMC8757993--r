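#' Analytic two-boundary Wiener first-passage solution
#'
#' Closed-form choice probabilities and first-passage-time densities for a
#' Wiener process with drift `mu`, diffusion SD `sigma`, absorbing boundaries
#' at 0 and `B`, and starting point `z0`. Used as an independent oracle for
#' validating the Euler simulator in its no-variability limit.
#'
#' @param mu Drift rate (evidence/s).
#' @param sigma Diffusion coefficient (evidence/sqrt(s)); must be positive.
#' @param B Upper boundary (> 0); lower boundary at 0.
#' @param z0 Starting point, strictly inside `(0, B)`.
#' @return `wiener_choice_prob`: probability of absorption at the upper
#'   boundary.
#' @export
#' @examples
#' wiener_choice_prob(0, 0.1, 1, 0.5)  # 0.5 by symmetry
wiener_choice_prob <- function(mu, sigma, B, z0) {
  if (sigma <= 0) stop("sigma must be positive")
  if (z0 <= 0 || z0 >= B) stop("z0 must lie strictly inside (0, B)")
  if (abs(mu) < 1e-12) return(z0 / B)
  a <- -2 * mu / sigma^2
  # guard large exponents
  expm1r <- function(x) expm1(x)
  (expm1r(a * z0)) / (expm1r(a * B))
}

#' @rdname wiener_choice_prob
#' @param t Vector of times (s) at which to evaluate the density.
#' @param boundary `"upper"` or `"lower"`: which absorption the density
#'   refers to (defective density; integrates to that boundary's choice
#'   probability).
#' @param tol Series truncation tolerance; terms are added until the bound on
#'   the remainder falls below `tol`. Default `1e-12`.
#' @return `wiener_fpt_density`: the defective first-passage density at `t`.
#' @export
wiener_fpt_density <- function(t, mu, sigma, B, z0,
                               boundary = c("upper", "lower"), tol = 1e-12) {
  boundary <- match.arg(boundary)
  if (sigma <= 0) stop("sigma must be positive")
  if (z0 <= 0 || z0 >= B) stop("z0 must lie strictly inside (0, B)")
  # density at the LOWER boundary of a process started at z:
  #   f(t) = (pi s2 / B^2) exp(-z mu / s2 - mu^2 t / (2 s2)) *
  #          sum_k k sin(k pi z / B) exp(-k^2 pi^2 s2 t / (2 B^2))
  if (boundary == "upper") {
    z <- B - z0
    mu <- -mu
  } else {
    z <- z0
  }
  s2 <- sigma^2
  out <- numeric(length(t))
  pos <- t > 0
  tv <- t[pos]
  if (length(tv)) {
    pref <- (pi * s2 / B^2) * exp(-z * mu / s2 - mu^2 * tv / (2 * s2))
    lam <- pi^2 * s2 / (2 * B^2)
    acc <- numeric(length(tv))
    for (k in seq_len(10000L)) {
      term <- k * sin(k * pi * z / B) * exp(-k^2 * lam * tv)
      acc <- acc + term
      # |remaining terms| bounded by geometric-like tail in exp(-k^2 lam t)
      if (all(k * exp(-k^2 * lam * tv) < tol)) break
    }
    out[pos] <- pmax(pref * acc, 0)
  }
  out
}

#' @rdname wiener_choice_prob
#' @param t_grid Increasing time grid starting near 0 over which to integrate.
#' @return `wiener_fpt_cdf`: the defective first-passage CDF on `t_grid`
#'   (trapezoidal integration of the density).
#' @export
wiener_fpt_cdf <- function(t_grid, mu, sigma, B, z0,
                           boundary = c("upper", "lower"), tol = 1e-12) {
  boundary <- match.arg(boundary)
  f <- wiener_fpt_density(t_grid, mu, sigma, B, z0, boundary, tol)
  dt <- diff(t_grid)
  c(0, cumsum(dt * (f[-1] + f[-length(f)]) / 2))
}
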