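#' Minimum sample size for a 1:c frequency-matched case-control study
#'
#' Computes the minimum number of cases `n1` (and controls `n2 = c * n1`)
#' needed to detect an allele-frequency odds ratio `OR` against a
#' control-group risk-allele frequency `p0`, with `c` controls per case,
#' a two-sided type-I error `alpha` and power `1 - beta`.
#'
#' The case frequency is derived as `p1 = p0 * OR / (1 + p0 * (OR - 1))`
#' and the pooled frequency as `p_bar = (p1 + c * p0) / (1 + c)`.  Two
#' variance forms are available:
#'
#' * `"pooled"`: `n1 = (1 + 1/c) * p_bar * q_bar * (z_a + z_b)^2 / (p1 - p0)^2`
#' * `"unpooled"` (default):
#'   `n1 = (z_a * sqrt((1 + 1/c) * p_bar * q_bar) + z_b * sqrt(p1*q1 + p0*q0/c))^2 / (p1 - p0)^2`
#'
#' where `z_a` is the standard-normal quantile for two-sided `alpha` and
#' `z_b` the quantile for the target power.  `n1` is rounded up to the
#' next integer before multiplying by `c` ("minimum" semantics).  The
#' two forms can differ by a few cases; both are exposed so the choice
#' is explicit.
#'
#' @param p0 Control-group risk-allele frequency, in (0, 1).
#' @param or Assumed odds ratio, positive and different from 1.
#' @param c Controls per case, a positive integer (default 2).
#' @param alpha Two-sided type-I error, in (0, 1).
#' @param power Target power `1 - beta`, in (0, 1).
#' @param variance_form `"unpooled"` (default) or `"pooled"`.
#' @return An object of class `sample_size`: a list with all formula
#'   symbols (`p1`, `p_bar`, `q_bar`, `z_alpha`, `z_beta`), the raw
#'   (unrounded) `n1_raw`, and the integer requirements `n1`, `n2`.
#' @examples
#' required_sample_size(p0 = 0.2, or = 2, c = 2)
#' @export
required_sample_size <- function(p0, or, c = 2L, alpha = 0.05, power = 0.8,
                                 variance_form = c("unpooled", "pooled")) {
  variance_form <- match.arg(variance_form)
  stopifnot(is.numeric(p0), length(p0) == 1L, is.numeric(or), length(or) == 1L)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)")
  if (or <= 0) stop("or must be positive")
  if (or == 1) stop("or = 1 gives a zero denominator: no effect to detect")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie strictly in (0, 1)")
  c <- as.integer(c)
  if (is.na(c) || c < 1L) stop("c must be a positive integer")

  p1 <- p0 * or / (1 + p0 * (or - 1))
  p_bar <- (p1 + c * p0) / (1 + c)
  q_bar <- 1 - p_bar
  z_alpha <- qnorm(1 - alpha / 2)
  z_beta <- qnorm(power)

  denom <- (p1 - p0)^2
  n1_raw <- switch(variance_form,
    pooled = (1 + 1 / c) * p_bar * q_bar * (z_alpha + z_beta)^2 / denom,
    unpooled = (z_alpha * sqrt((1 + 1 / c) * p_bar * q_bar) +
                z_beta * sqrt(p1 * (1 - p1) + p0 * (1 - p0) / c))^2 / denom
  )
  n1 <- ceiling(n1_raw - 1e-12)
  if (n1 <= .Machine$integer.max) n1 <- as.integer(n1)

  structure(list(
    p0 = p0, or = or, c = c, alpha = alpha, power = power,
    variance_form = variance_form,
    p1 = p1, p_bar = p_bar, q_bar = q_bar,
    z_alpha = z_alpha, z_beta = z_beta,
    n1_raw = n1_raw, n1 = n1, n2 = c * n1
  ), class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  cat(sprintf("1:%d frequency-matched design (%s variance)\n", x$c,
              x$variance_form))
  cat(sprintf("  p0 = %.4f, p1 = %.4f, OR = %.2f, alpha = %.3f, power = %.2f\n",
              x$p0, x$p1, x$or, x$alpha, x$power))
  cat(sprintf("  n1 = %.0f cases, n2 = %.0f controls (raw n1 = %.2f)\n",
              x$n1, x$n2, x$n1_raw))
  invisible(x)
}
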