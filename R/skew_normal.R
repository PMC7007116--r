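# Skew-normal distribution: density, CDF, quantile, sampler, and the
# quantile-matching fit used to turn a reported (median, 95% interval)
# into a sampling law for percentage iron change.
#
# Parameterisation: location xi, scale omega > 0, shape alpha; alpha = 0
# recovers Normal(xi, omega). CDF via Owen's T function, evaluated by
# fixed-order Gauss-Legendre quadrature (nodes from pracma), with the
# standard reduction to |a| <= 1 so the integrand stays well resolved.

.ferro_gl <- new.env(parent = emptyenv())

gl_nodes <- function() {
  if (is.null(.ferro_gl$x)) {
    gl <- pracma::gaussLegendre(64, 0, 1)
    .ferro_gl$x <- gl$x
    .ferro_gl$w <- gl$w
  }
  .ferro_gl
}

#' Owen's T function
#'
#' \eqn{T(h, a) = \frac{1}{2\pi}\int_0^a \frac{e^{-h^2(1+x^2)/2}}{1+x^2}dx},
#' the ingredient of the skew-normal CDF. Vectorised over `h`.
#'
#' @param h Numeric vector.
#' @param a Scalar slope parameter.
#' @return Numeric vector of `T(h, a)` values.
#' @export
owen_t <- function(h, a) {
  if (length(a) != 1) stop_domain("owen_t: a must be a scalar")
  if (a == 0) return(rep(0, length(h)))
  if (a < 0) return(-owen_t(h, -a))
  h <- abs(h)  # T(-h, a) = T(h, a)
  if (a > 1) {
    # T(h, a) = (Phi(h) + Phi(ah))/2 - Phi(h)Phi(ah) - T(ah, 1/a)
    ah <- a * h
    return(0.5 * (pnorm(h) + pnorm(ah)) - pnorm(h) * pnorm(ah) - owen_t(ah, 1 / a))
  }
  gl <- gl_nodes()
  x <- a * gl$x          # nodes on [0, a]
  w <- a * gl$w
  # outer product: rows follow h, columns follow quadrature nodes
  integrand <- exp(-0.5 * outer(h^2, 1 + x^2)) / rep(1 + x^2, each = length(h))
  as.numeric(integrand %*% w) / (2 * pi)
}

#' The skew-normal distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the three-parameter skew-normal law with location `xi`, scale
#' `omega` and shape `alpha`. With `alpha = 0` all four reduce to the
#' normal distribution.
#'
#' @param x,q,p Numeric vectors of values / probabilities.
#' @param n Number of draws.
#' @param xi Location parameter.
#' @param omega Scale parameter, `> 0`.
#' @param alpha Shape parameter; negative values skew left.
#' @return `dskewnorm`, `pskewnorm`, `qskewnorm` return numeric vectors;
#'   `rskewnorm` returns `n` random deviates.
#' @export
dskewnorm <- function(x, xi = 0, omega = 1, alpha = 0) {
  if (omega <= 0) stop_domain("omega must be > 0")
  z <- (x - xi) / omega
  2 / omega * dnorm(z) * pnorm(alpha * z)
}

#' @rdname dskewnorm
#' @export
pskewnorm <- function(q, xi = 0, omega = 1, alpha = 0) {
  if (omega <= 0) stop_domain("omega must be > 0")
  z <- (q - xi) / omega
  pmin(pmax(pnorm(z) - 2 * owen_t(z, alpha), 0), 1)
}

#' @rdname dskewnorm
#' @export
qskewnorm <- function(p, xi = 0, omega = 1, alpha = 0) {
  if (omega <= 0) stop_domain("omega must be > 0")
  if (any(p <= 0 | p >= 1)) stop_domain("p must lie in (0, 1)")
  vapply(p, function(pp) {
    f <- function(z) pskewnorm(z, 0, 1, alpha) - pp
    # the standard skew-normal has sub-gaussian tails: |z| < 10 covers
    # any probability representable in double precision here
    z <- uniroot(f, interval = c(-10, 10), extendInt = "upX", tol = 1e-12)$root
    xi + omega * z
  }, numeric(1))
}

#' @rdname dskewnorm
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  if (omega <= 0) stop_domain("omega must be > 0")
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n)
  u1 <- rnorm(n)
  xi + omega * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

#' @rdname dskewnorm
#' @return `skewnorm_mean()` returns the analytic expectation
#'   \eqn{\xi + \omega\delta\sqrt{2/\pi}} with
#'   \eqn{\delta = \alpha/\sqrt{1+\alpha^2}}.
#' @export
skewnorm_mean <- function(xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  xi + omega * delta * sqrt(2 / pi)
}

#' Fit a skew-normal law to a reported median and 95% interval
#'
#' Finds `(xi, omega, alpha)` such that the law's median equals
#' `median_pct` and its 2.5% / 97.5% quantiles equal `ci_lo` / `ci_hi`.
#' The shape is identified first: the asymmetry ratio
#' `(q97.5 - median) / (median - q2.5)` of the standard law is a strictly
#' increasing function of `alpha` alone, so a one-dimensional root search
#' pins `alpha`, after which scale and location follow by linear
#' quantile arithmetic.
#'
#' The attainable ratio is bounded (the half-normal limits as
#' `alpha -> +-Inf`): triples more asymmetric than that admit no
#' skew-normal law and raise a fit error reporting the residuals.
#'
#' @param median_pct The target median (the reported central estimate).
#' @param ci_lo,ci_hi The reported 95% interval, read as the 2.5% and
#'   97.5% quantiles; requires `ci_lo < median_pct < ci_hi`.
#' @param tol Root-finding tolerance on quantile residuals.
#' @return A list with elements `xi`, `omega`, `alpha`.
#' @export
fit_skew_normal <- function(median_pct, ci_lo, ci_hi, tol = 1e-9) {
  if (!(ci_lo < ci_hi)) stop_domain("ci_lo must be < ci_hi")
  if (!(ci_lo < median_pct && median_pct < ci_hi)) {
    stop_fit(paste0("median ", median_pct, " outside interval (", ci_lo,
                    ", ", ci_hi, "): no skew-normal law matches"))
  }
  target_ratio <- (ci_hi - median_pct) / (median_pct - ci_lo)
  std_q <- function(alpha) qskewnorm(c(0.025, 0.5, 0.975), 0, 1, alpha)
  ratio_of <- function(alpha) {
    z <- std_q(alpha)
    (z[3] - z[2]) / (z[2] - z[1])
  }
  if (abs(log(target_ratio)) < 1e-12) {
    alpha <- 0
  } else {
    # the ratio is monotone in alpha; bracket outward from 0
    f <- function(a) log(ratio_of(a)) - log(target_ratio)
    lo <- -1; hi <- 1
    while (f(hi) < 0 && hi < 60) hi <- hi * 2
    while (f(lo) > 0 && lo > -60) lo <- lo * 2
    if (f(hi) < 0 || f(lo) > 0) {
      stop_fit(paste0("interval asymmetry ratio ", signif(target_ratio, 6),
                      " outside the skew-normal attainable range; ",
                      "residual at alpha=", ifelse(f(hi) < 0, hi, lo), ": ",
                      signif(ifelse(f(hi) < 0, f(hi), f(lo)), 6)))
    }
    alpha <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  z <- std_q(alpha)
  omega <- (ci_hi - ci_lo) / (z[3] - z[1])
  xi <- median_pct - omega * z[2]
  fitted <- qskewnorm(c(0.025, 0.5, 0.975), xi, omega, alpha)
  resid <- fitted - c(ci_lo, median_pct, ci_hi)
  if (max(abs(resid)) > max(tol, 1e-7 * (ci_hi - ci_lo))) {
    stop_fit(paste0("quantile residuals exceed tolerance: ",
                    paste(signif(resid, 4), collapse = ", ")))
  }
  list(xi = xi, omega = omega, alpha = alpha)
}
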