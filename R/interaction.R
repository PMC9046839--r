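# Additive-scale gene-environment interaction: joint-exposure recoding,
# the indicator-parameterized logistic model, RERI / AP / SI with
# delta-method and stratified-bootstrap confidence intervals, and the
# multiplicative product-term test.

#' Joint gene x environment exposure table
#'
#' Cross-classifies participants by a binary genotype recode (recessive:
#' risk homozygote vs others; dominant: any risk allele vs none) and
#' migrant status, within cases and controls.  Cell order is (gene,
#' env) = (0,0), (1,0), (0,1), (1,1).
#'
#' @inheritParams adjusted_association
#' @param coding `"recessive"` (default) or `"dominant"` genotype recode.
#' @return An object of class `joint_exposure_table` with `case` and
#'   `control` count vectors.
#' @export
joint_exposure_table <- function(records, marker,
                                 coding = c("recessive", "dominant")) {
  coding <- match.arg(coding)
  y <- is_case(records)
  g <- drop(encode_inheritance(records[[genotype_column(marker)]], coding))
  e <- as.numeric(as.character(records$migration) == "migrant")
  cell <- factor(paste0(g, e), levels = c("00", "10", "01", "11"))
  tab <- table(case = y, cell)
  out <- structure(list(
    marker = marker$name, coding = coding,
    case = setNames(as.integer(tab["1", ]), c("n00", "n10", "n01", "n11")),
    control = setNames(as.integer(tab["0", ]), c("n00", "n10", "n01", "n11"))
  ), class = "joint_exposure_table")
  out
}

#' @export
print.joint_exposure_table <- function(x, ...) {
  cat(sprintf("%s (%s coding), joint gene x migration table\n", x$marker,
              x$coding))
  m <- rbind(case = x$case, control = x$control)
  colnames(m) <- c("g0e0", "g1e0", "g0e1", "g1e1")
  print(m)
  invisible(x)
}

joint_indicators <- function(records, marker, coding) {
  g <- drop(encode_inheritance(records[[genotype_column(marker)]], coding))
  e <- as.numeric(as.character(records$migration) == "migrant")
  cbind(I10 = as.numeric(g == 1 & e == 0),
        I01 = as.numeric(g == 0 & e == 1),
        I11 = as.numeric(g == 1 & e == 1))
}

#' Joint-exposure logistic model
#'
#' Fits the indicator parameterization: three dummies I10, I01, I11
#' against the doubly-unexposed reference, plus optional covariates, so
#' `OR10 = exp(b1)`, `OR01 = exp(b2)`, `OR11 = exp(b3)` map directly to
#' the joint-exposure odds-ratio grid.
#'
#' @inheritParams joint_exposure_table
#' @param covariates Covariate columns to adjust for (dummy-coded).
#' @return A [fit_logistic()] result with terms `I10`, `I01`, `I11`.
#' @export
fit_joint_model <- function(records, marker,
                            coding = c("recessive", "dominant"),
                            covariates = character()) {
  coding <- match.arg(coding)
  jt <- joint_exposure_table(records, marker, coding)
  occupancy <- jt$case + jt$control
  if (any(occupancy == 0L)) {
    empty <- c("(0,0)", "(1,0)", "(0,1)", "(1,1)")[occupancy == 0L]
    stop("joint-exposure category ", paste(empty, collapse = ", "),
         " is empty; the model is not identifiable")
  }
  y <- is_case(records)
  ind <- joint_indicators(records, marker, coding)
  cx <- covariate_design(records, covariates)
  fit_logistic(y, cbind(`(Intercept)` = 1, ind, cx))
}

#' Additive-scale interaction measures
#'
#' From the joint-exposure odds-ratio grid: relative excess risk due to
#' interaction `RERI = OR11 - OR10 - OR01 + 1`, attributable proportion
#' `AP = RERI / OR11`, and synergy index
#' `SI = (OR11 - 1) / ((OR10 - 1) + (OR01 - 1))`.  Under the additive
#' null RERI = 0, AP = 0, SI = 1.  SI is undefined (returned `NA` and
#' flagged) when `OR10 + OR01 = 2`.
#'
#' @param or10,or01,or11 Positive odds ratios against the (0,0) reference.
#' @return A list with `reri`, `ap`, `si`, `si_defined`.
#' @examples
#' additive_measures(2.86, 2.54, 10.80)  # RERI 6.40, AP 0.59, SI 2.88
#' @export
additive_measures <- function(or10, or01, or11) {
  ors <- c(or10, or01, or11)
  if (any(!is.finite(ors)) || any(ors <= 0)) {
    stop("all odds ratios must be positive and finite")
  }
  reri <- or11 - or10 - or01 + 1
  ap <- reri / or11
  denom <- (or10 - 1) + (or01 - 1)
  si_defined <- denom != 0
  si <- if (si_defined) (or11 - 1) / denom else NA_real_
  list(reri = reri, ap = ap, si = si, si_defined = si_defined)
}

# Gradients of the three measures with respect to (b1, b2, b3), the log
# odds ratios.  ln SI is handled on the log scale.
reri_gradient <- function(b1, b2, b3) c(-exp(b1), -exp(b2), exp(b3))
ap_gradient <- function(b1, b2, b3) {
  c(-exp(b1 - b3), -exp(b2 - b3), exp(b1 - b3) + exp(b2 - b3) - exp(-b3))
}
lnsi_gradient <- function(b1, b2, b3) {
  d <- exp(b1) + exp(b2) - 2
  c(-exp(b1) / d, -exp(b2) / d, exp(b3) / (exp(b3) - 1))
}

#' Delta-method confidence intervals for RERI, AP and SI
#'
#' First-order propagation of the covariance of the joint-indicator
#' coefficients (b1, b2, b3) through each measure.  RERI and AP get
#' symmetric intervals `estimate +/- z * sqrt(g' Sigma g)`; SI is
#' handled on the log scale (`ln SI = ln(e^b3 - 1) - ln(e^b1 + e^b2 - 2)`)
#' and the interval exponentiated, which matches the asymmetric SI
#' intervals conventional in this literature.  The SI interval is
#' undefined and flagged when `OR11 <= 1` or `OR10 + OR01 <= 2`.
#'
#' @param fit A [fit_joint_model()] result (or any `logit_fit`).
#' @param terms Names of the three joint-indicator coefficients, in the
#'   order (gene-only, env-only, joint); default `c("I10","I01","I11")`.
#' @param conf Confidence level.
#' @return A data frame with rows `reri`, `ap`, `si`: `estimate`, `se`
#'   (on the measure scale; for SI, of ln SI), `ci_low`, `ci_high`,
#'   `defined`.
#' @export
delta_ci <- function(fit, terms = c("I10", "I01", "I11"), conf = 0.95) {
  stopifnot(inherits(fit, "logit_fit"), length(terms) == 3L)
  if (!all(terms %in% names(fit$coef))) {
    stop("terms not all present in the fitted model")
  }
  b <- fit$coef[terms]
  sigma <- fit$vcov[terms, terms]
  z <- qnorm(1 - (1 - conf) / 2)
  m <- additive_measures(exp(b[1]), exp(b[2]), exp(b[3]))

  g_reri <- reri_gradient(b[1], b[2], b[3])
  se_reri <- sqrt(drop(t(g_reri) %*% sigma %*% g_reri))
  g_ap <- ap_gradient(b[1], b[2], b[3])
  se_ap <- sqrt(drop(t(g_ap) %*% sigma %*% g_ap))

  si_ci_defined <- exp(b[3]) > 1 && (exp(b[1]) + exp(b[2])) > 2
  if (si_ci_defined) {
    g_si <- lnsi_gradient(b[1], b[2], b[3])
    se_lnsi <- sqrt(drop(t(g_si) %*% sigma %*% g_si))
    lnsi <- log(m$si)
    si_lo <- exp(lnsi - z * se_lnsi)
    si_hi <- exp(lnsi + z * se_lnsi)
  } else {
    se_lnsi <- NA_real_; si_lo <- NA_real_; si_hi <- NA_real_
  }

  data.frame(
    measure = c("reri", "ap", "si"),
    estimate = c(m$reri, m$ap, m$si),
    se = c(se_reri, se_ap, se_lnsi),
    ci_low = c(m$reri - z * se_reri, m$ap - z * se_ap, si_lo),
    ci_high = c(m$reri + z * se_reri, m$ap + z * se_ap, si_hi),
    defined = c(TRUE, TRUE, si_ci_defined),
    row.names = c("reri", "ap", "si"), stringsAsFactors = FALSE
  )
}

#' Stratified-bootstrap percentile CIs for RERI, AP and SI
#'
#' Resamples individuals with replacement within case and control
#' strata (preserving both group sizes), refits the joint-exposure
#' model per replicate, and takes empirical 2.5 / 97.5 percentiles of
#' each measure.  Replicates with an empty joint category or a
#' non-convergent fit are dropped and counted; more than 20% dropped
#' attaches a warning.
#'
#' @inheritParams fit_joint_model
#' @param b Number of bootstrap replicates (>= 200; default 2000).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param conf Confidence level.
#' @return A list with `ci` (data frame rows reri/ap/si), `b`,
#'   `n_dropped`, `replicates` (matrix of retained measure draws).
#' @export
bootstrap_ci <- function(records, marker, coding = c("recessive", "dominant"),
                         covariates = character(), b = 2000L, seed = 1L,
                         conf = 0.95) {
  coding <- match.arg(coding)
  b <- as.integer(b)
  if (b < 200L) stop("b must be at least 200")
  y <- is_case(records)
  idx_case <- which(y == 1L)
  idx_ctrl <- which(y == 0L)
  draws <- with_seed(substream_seed(seed, 777L), {
    out <- matrix(NA_real_, nrow = b, ncol = 3,
                  dimnames = list(NULL, c("reri", "ap", "si")))
    for (i in seq_len(b)) {
      take <- c(sample(idx_case, length(idx_case), replace = TRUE),
                sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
      rep_fit <- tryCatch(
        suppressWarnings(fit_joint_model(records[take, , drop = FALSE],
                                         marker, coding, covariates)),
        error = function(e) NULL)
      if (is.null(rep_fit) || !rep_fit$converged) next
      bb <- rep_fit$coef[c("I10", "I01", "I11")]
      m <- additive_measures(exp(bb[1]), exp(bb[2]), exp(bb[3]))
      out[i, ] <- c(m$reri, m$ap, if (m$si_defined) m$si else NA_real_)
    }
    out
  })
  ok <- !is.na(draws[, "reri"])
  n_dropped <- sum(!ok)
  if (n_dropped > 0.2 * b) {
    warning(sprintf("%d of %d bootstrap replicates dropped (empty category or non-convergence)",
                    n_dropped, b))
  }
  alpha <- (1 - conf) / 2
  qfun <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    quantile(v, c(alpha, 1 - alpha), names = FALSE)
  }
  qs <- apply(draws[ok, , drop = FALSE], 2, qfun)
  ci <- data.frame(
    measure = c("reri", "ap", "si"),
    ci_low = qs[1, ], ci_high = qs[2, ],
    row.names = c("reri", "ap", "si"), stringsAsFactors = FALSE
  )
  list(ci = ci, b = b, n_dropped = n_dropped,
       replicates = draws[ok, , drop = FALSE])
}

#' Multiplicative interaction (product-term) test
#'
#' Fits main effects of the coded genotype and migrant status plus
#' their product, with optional covariates, and Wald-tests the product
#' coefficient.  In the covariate-free model the product OR equals
#' `OR11 / (OR10 * OR01)` exactly.
#'
#' @inheritParams fit_joint_model
#' @return A list with `or`, `ci_low`, `ci_high`, `p` for the product
#'   term, and the underlying `fit`.
#' @export
multiplicative_test <- function(records, marker,
                                coding = c("recessive", "dominant"),
                                covariates = character()) {
  coding <- match.arg(coding)
  jt <- joint_exposure_table(records, marker, coding)
  if (any(jt$case + jt$control == 0L)) {
    stop("empty joint-exposure category; product-term model not identifiable")
  }
  y <- is_case(records)
  g <- drop(encode_inheritance(records[[genotype_column(marker)]], coding))
  e <- as.numeric(as.character(records$migration) == "migrant")
  cx <- covariate_design(records, covariates)
  x <- cbind(`(Intercept)` = 1, G = g, E = e, `G:E` = g * e, cx)
  fit <- fit_logistic(y, x)
  w <- wald_or(fit, "G:E")
  list(or = w$or, ci_low = w$ci_low, ci_high = w$ci_high, p = w$p, fit = fit)
}

#' Full additive + multiplicative interaction analysis for one marker
#'
#' Runs the joint-exposure model, Wald ORs for the grid, RERI/AP/SI
#' with delta and (optionally) bootstrap intervals, the product-term
#' test, and the conventional significance rule: an additive
#' interaction is declared when the RERI and AP intervals exclude 0 and
#' the SI interval excludes 1.
#'
#' @inheritParams fit_joint_model
#' @param bootstrap_b Bootstrap replicates (0 disables the bootstrap).
#' @param seed Seed for the bootstrap.
#' @return An object of class `interaction_result`.
#' @export
interaction_analysis <- function(records, marker,
                                 coding = c("recessive", "dominant"),
                                 covariates = character(),
                                 bootstrap_b = 2000L, seed = 1L) {
  coding <- match.arg(coding)
  jt <- joint_exposure_table(records, marker, coding)
  fit <- fit_joint_model(records, marker, coding, covariates)
  grid <- do.call(rbind, lapply(c("I10", "I01", "I11"), function(tm) {
    w <- wald_or(fit, tm)
    data.frame(term = tm, or = w$or, ci_low = w$ci_low, ci_high = w$ci_high,
               p = w$p, stringsAsFactors = FALSE)
  }))
  delta <- delta_ci(fit)
  boot <- if (bootstrap_b > 0L) {
    bootstrap_ci(records, marker, coding, covariates, b = bootstrap_b,
                 seed = seed)
  } else NULL
  mult <- multiplicative_test(records, marker, coding, covariates)
  sig <- c(
    reri = delta["reri", "ci_low"] > 0 || delta["reri", "ci_high"] < 0,
    ap = delta["ap", "ci_low"] > 0 || delta["ap", "ci_high"] < 0,
    si = isTRUE(delta["si", "defined"]) &&
      (delta["si", "ci_low"] > 1 || delta["si", "ci_high"] < 1)
  )
  structure(list(
    marker = marker$name, coding = coding, covariates = covariates,
    table = jt, fit = fit, or_grid = grid,
    measures = additive_measures(grid$or[1], grid$or[2], grid$or[3]),
    delta = delta, bootstrap = boot, multiplicative = mult,
    significant = sig, additive_interaction = all(sig)
  ), class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("%s x migration, %s coding\n", x$marker, x$coding))
  labels <- c("OR10 (gene only)", "OR01 (migrant only)", "OR11 (both)")
  cat("  OR00 (reference)         1.00\n")
  for (i in 1:3) {
    cat(sprintf("  %-24s %s  p = %s\n", labels[i],
                fmt_or_ci(x$or_grid$or[i], x$or_grid$ci_low[i],
                          x$or_grid$ci_high[i]), fmt_p(x$or_grid$p[i])))
  }
  d <- x$delta
  cat(sprintf("  RERI %.2f (%.2f-%.2f)  AP %.2f (%.2f-%.2f)  SI %s\n",
              d["reri", "estimate"], d["reri", "ci_low"], d["reri", "ci_high"],
              d["ap", "estimate"], d["ap", "ci_low"], d["ap", "ci_high"],
              if (isTRUE(d["si", "defined"]))
                sprintf("%.2f (%.2f-%.2f)", d["si", "estimate"],
                        d["si", "ci_low"], d["si", "ci_high"])
              else "undefined"))
  cat(sprintf("  product-term OR %s  p = %s\n",
              fmt_or_ci(x$multiplicative$or, x$multiplicative$ci_low,
                        x$multiplicative$ci_high), fmt_p(x$multiplicative$p)))
  cat(sprintf("  additive interaction present (delta rule): %s\n",
              if (x$additive_interaction) "yes" else "no"))
  invisible(x)
}
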