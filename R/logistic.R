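# Maximum-likelihood unconditional logistic regression via iteratively
# reweighted least squares, with Wald inference.  This is the engine
# behind adjusted associations and the joint-exposure interaction
# models; it exposes the iteration trace, convergence and separation
# flags that downstream inference relies on.

logistic_loglik <- function(y, eta) {
  # numerically stable: log(1 + exp(eta)) via log1p on the right branch
  sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

#' Fit a logistic regression by IRLS
#'
#' Newton/IRLS maximum likelihood with step-halving, run to
#' `|delta loglik| < 1e-8` or 100 iterations.  The covariance is the
#' inverse observed information at the optimum.  Complete or
#' quasi-complete separation is flagged (never silently returned) when
#' any coefficient exceeds 15 on the log-odds scale.
#'
#' @param y Binary response vector (0/1); both classes must be present.
#' @param x Design matrix including the intercept column.
#' @return An object of class `logit_fit`: `coef` (named, log-odds
#'   scale), `vcov`, `loglik`, `loglik_trace`, `converged`,
#'   `iterations`, `separation`, `n`.
#' @export
fit_logistic <- function(y, x) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)")
  if (any(is.na(y)) || any(is.na(x))) stop("missing values in response or design")
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L) stop("response has a single class; model is not identifiable")
  if (any(colSums(abs(x)) == 0)) stop("design contains a constant-zero column")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  p <- ncol(x)
  beta <- numeric(p)
  ll <- logistic_loglik(y, drop(x %*% beta))
  trace <- ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(x, x * w)
    score <- crossprod(x, y - mu)
    step <- tryCatch(solve(info, score),
                     error = function(e) stop("information matrix is singular: ",
                                              conditionMessage(e)))
    # step-halving keeps the log-likelihood monotone non-decreasing
    lambda <- 1
    repeat {
      cand <- beta + lambda * drop(step)
      ll_new <- logistic_loglik(y, drop(x %*% cand))
      if (ll_new >= ll - 1e-12 || lambda < 2^-30) break
      lambda <- lambda / 2
    }
    beta <- cand
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < 1e-8) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  vcov <- solve(crossprod(x, x * w))
  dimnames(vcov) <- list(colnames(x), colnames(x))
  separation <- any(abs(beta) > 15)
  if (separation) {
    warning("possible separation: a coefficient exceeds 15 on the log-odds scale")
  }
  structure(list(
    coef = setNames(drop(beta), colnames(x)), vcov = vcov,
    loglik = ll, loglik_trace = trace, converged = converged && !separation,
    iterations = iter, separation = separation, n = length(y)
  ), class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> n = %d, loglik = %.4f, %d iterations%s%s\n",
              x$n, x$loglik, x$iterations,
              if (x$converged) ", converged" else ", NOT converged",
              if (x$separation) ", separation flagged" else ""))
  se <- sqrt(diag(x$vcov))
  print(data.frame(coef = x$coef, se = se, row.names = names(x$coef)))
  invisible(x)
}

#' Wald odds ratio for one model term
#'
#' `OR = exp(b)` with 95% CI `exp(b +/- z * se)` and a two-sided normal
#' p-value on `b / se`.  A zero standard error yields a degenerate CI
#' and is flagged.
#'
#' @param fit A [fit_logistic()] result.
#' @param term Name of the coefficient.
#' @param conf Confidence level (default 0.95).
#' @return A list with `term`, `coef`, `se`, `or`, `ci_low`, `ci_high`,
#'   `p`, `degenerate`.
#' @export
wald_or <- function(fit, term, conf = 0.95) {
  stopifnot(inherits(fit, "logit_fit"))
  if (!term %in% names(fit$coef)) {
    stop("term '", term, "' is not in the fitted model")
  }
  b <- fit$coef[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- qnorm(1 - (1 - conf) / 2)
  degenerate <- se == 0
  if (degenerate) warning("zero standard error for '", term, "': degenerate CI")
  p <- if (degenerate) NA_real_ else 2 * pnorm(-abs(b / se))
  list(term = term, coef = b, se = se, or = exp(b),
       ci_low = exp(b - z * se), ci_high = exp(b + z * se),
       p = p, degenerate = degenerate)
}

# Dummy-coded covariate design (first listed category = reference).
# Constant covariates are dropped with a warning; `age` may be used
# continuously in place of the default age_group bands.
covariate_design <- function(records, covariates) {
  if (length(covariates) == 0L) {
    return(matrix(numeric(0), nrow = nrow(records), ncol = 0))
  }
  blocks <- list()
  for (cv in covariates) {
    if (!cv %in% names(records)) stop("covariate '", cv, "' not found in records")
    if (cv %in% c("age", "bmi")) {
      blocks[[cv]] <- matrix(as.numeric(records[[cv]]), ncol = 1,
                             dimnames = list(NULL, cv))
      next
    }
    lv <- .participant_levels[[cv]]
    if (is.null(lv)) lv <- sort(unique(as.character(records[[cv]])))
    f <- factor(as.character(records[[cv]]), levels = lv)
    if (anyNA(f)) stop("covariate '", cv, "' has values outside its level set")
    present <- lv[lv %in% unique(as.character(f))]
    if (length(present) < 2L) {
      warning("covariate '", cv, "' is constant in this subset; dropped")
      next
    }
    m <- vapply(present[-1L],
                function(l) as.numeric(f == l), numeric(nrow(records)))
    m <- matrix(m, nrow = nrow(records),
                dimnames = list(NULL, paste0(cv, ".", present[-1L])))
    blocks[[cv]] <- m
  }
  if (length(blocks) == 0L) {
    return(matrix(numeric(0), nrow = nrow(records), ncol = 0))
  }
  do.call(cbind, blocks)
}

#' Adjusted genotype-obesity association under an inheritance model
#'
#' Builds a design of intercept + inheritance-coded genotype +
#' dummy-coded covariates, fits the unconditional logistic model with
#' obesity (vs normal weight) as outcome, and returns per-genotype-term
#' odds ratios with Wald CIs.
#'
#' @param records Participant data frame (cases obese, controls normal;
#'   no overweight rows, no missing genotypes).
#' @param marker A [marker()].
#' @param model Inheritance model, see [encode_inheritance()].
#' @param covariates Character vector of record columns to adjust for
#'   (categorical columns are dummy-coded against their first level;
#'   `"age"` enters continuously, `"age_group"` as decade-band dummies).
#' @return An object of class `association_result` with one row per
#'   genotype term (`or`, `ci_low`, `ci_high`, `p`) plus the underlying
#'   `fit`.
#' @export
adjusted_association <- function(records, marker,
                                 model = c("dominant", "recessive",
                                           "codominant", "additive"),
                                 covariates = character()) {
  model <- match.arg(model)
  y <- is_case(records)
  g <- records[[genotype_column(marker)]]
  gx <- encode_inheritance(g, model)
  colnames(gx) <- paste0(marker$name, ".", colnames(gx))
  cx <- covariate_design(records, covariates)
  x <- cbind(`(Intercept)` = 1, gx, cx)
  fit <- fit_logistic(y, x)
  terms <- colnames(gx)
  est <- do.call(rbind, lapply(terms, function(tm) {
    w <- wald_or(fit, tm)
    data.frame(term = tm, or = w$or, ci_low = w$ci_low, ci_high = w$ci_high,
               p = w$p, stringsAsFactors = FALSE)
  }))
  structure(list(marker = marker$name, model = model,
                 covariates = covariates, estimates = est, fit = fit),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s, %s model (adjusted for: %s)\n", x$marker, x$model,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "nothing"))
  e <- x$estimates
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-24s OR %s  p = %s\n", e$term[i],
                fmt_or_ci(e$or[i], e$ci_low[i], e$ci_high[i]), fmt_p(e$p[i])))
  }
  invisible(x)
}
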