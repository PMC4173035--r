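#' Fixed point of the clock model
#'
#' The steady state of the delay system does not depend on the delays: it is
#' the unique solution of
#' \deqn{\alpha_m / (1 + (P^*/P_0)^n) = \mu_m M^*, \quad \alpha_p M^* = \mu_p P^*.}
#' Eliminating \eqn{M^*} gives a scalar equation in \eqn{P^*} whose left side
#' is strictly decreasing and right side strictly increasing, so exactly one
#' root exists; it is found by bracketing and bisection refined to a relative
#' residual below 1e-10.
#'
#' @param params A [clock_params] object.
#' @return Named numeric vector `c(mrna = M*, protein = P*)`.
#' @examples
#' steady_state(clock_params())
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "clock_params"))
  am <- params$mrna_synthesis_max
  mm <- params$mrna_degradation
  ap <- params$protein_synthesis
  mp <- params$protein_degradation
  p0 <- params$repression_threshold
  n  <- params$hill_coefficient

  # decoupled limits: a zero synthesis rate pins part of the fixed point
  if (am == 0) return(c(mrna = 0, protein = 0))
  if (ap == 0) return(c(mrna = am / mm, protein = 0))

  # g(P) = am*ap*repression(P) - mm*mp*P : strictly decreasing, g(0) > 0
  g <- function(P) am * ap / (1 + (P / p0)^n) - mm * mp * P
  upper <- am * ap / (mm * mp)  # g(upper) < 0 since repression < 1
  root <- stats::uniroot(g, c(0, upper), tol = .Machine$double.eps^0.9,
                         maxiter = 2000L)$root
  # bisection polish to push the relative residual below 1e-10
  lo <- max(root * (1 - 1e-6), 0); hi <- root * (1 + 1e-6)
  if (g(lo) < 0 || g(hi) > 0) { lo <- 0; hi <- upper }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * max(hi, 1)) break
  }
  Pstar <- (lo + hi) / 2
  Mstar <- mp * Pstar / ap
  c(mrna = Mstar, protein = Pstar)
}

#' Hopf critical delay of the clock model
#'
#' Linearizing about the fixed point gives the characteristic equation
#' \deqn{(\lambda + \mu_m)(\lambda + \mu_p) = -K e^{-\lambda \tau}}
#' with feedback gain
#' \eqn{K = \alpha_p \, |d(\alpha_m \, h(P))/dP|_{P^*}} evaluated at the fixed
#' point, where \eqn{h} is the Hill repression function. Setting
#' \eqn{\lambda = i\omega} yields the crossing frequency
#' \deqn{\omega^2 = \frac{-(\mu_m^2+\mu_p^2) + \sqrt{(\mu_m^2-\mu_p^2)^2 + 4K^2}}{2}}
#' which is real and positive iff \eqn{K > \mu_m \mu_p}, and the smallest
#' destabilizing delay
#' \deqn{\tau_c = \frac{\pi - \arctan(\omega/\mu_m) - \arctan(\omega/\mu_p)}{\omega}.}
#' For total delay above \eqn{\tau_c} the fixed point is unstable and a limit
#' cycle (sustained oscillation) appears.
#'
#' @param params A [clock_params] object. The delay stored in `params` is
#'   ignored; the returned value is the threshold against which it can be
#'   compared.
#' @return The critical total delay in minutes, or `Inf` (sentinel: no finite
#'   threshold) when the gain is too weak to destabilize the fixed point
#'   (`K <= mu_m * mu_p`). The crossing angular frequency (rad/min) is
#'   attached as attribute `"omega"` when finite.
#' @examples
#' critical_delay(clock_params())
#' @export
critical_delay <- function(params) {
  stopifnot(inherits(params, "clock_params"))
  mm <- params$mrna_degradation
  mp <- params$protein_degradation
  K <- feedback_gain(params)
  if (K <= mm * mp) return(Inf)
  disc <- sqrt((mm^2 - mp^2)^2 + 4 * K^2)
  omega2 <- (-(mm^2 + mp^2) + disc) / 2
  omega <- sqrt(omega2)
  tau_c <- (pi - atan(omega / mm) - atan(omega / mp)) / omega
  structure(tau_c, omega = omega)
}

#' @export
summary.clock_params <- function(object, ...) {
  print(object)
  ss <- steady_state(object)
  tc <- critical_delay(object)
  cat(sprintf("  fixed point:    M* = %.4g, P* = %.4g\n",
              ss["mrna"], ss["protein"]))
  if (is.finite(tc))
    cat(sprintf("  critical delay: %.2f min (total delay %.2f min -> %s)\n",
                tc, object$delay$total_min,
                if (object$delay$total_min > tc) "oscillatory"
                else "stable fixed point"))
  else
    cat("  critical delay: none (gain below destabilization bound)\n")
  invisible(list(steady_state = ss, critical_delay = tc))
}

# Feedback gain K = alpha_p * alpha_m * |h'(P*)| at the fixed point.
feedback_gain <- function(params) {
  ss <- steady_state(params)
  p0 <- params$repression_threshold
  n  <- params$hill_coefficient
  P <- ss[["protein"]]
  x <- (P / p0)^n
  # |d/dP 1/(1+(P/p0)^n)| = n P^(n-1) / p0^n / (1+x)^2, finite at P = 0
  hprime <- n * P^(n - 1) / p0^n / (1 + x)^2
  params$protein_synthesis * params$mrna_synthesis_max * hprime
}
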