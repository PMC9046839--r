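# Study-design operations: case selection, eligibility exclusions and
# 1:c frequency matching of controls on age group and sex.

#' Select the case group
#'
#' All obese participants (weight class `"obese"`), in input order.
#'
#' @param records Participant data frame with `weight_class` populated.
#' @return The obese subset.
#' @export
select_cases <- function(records) {
  if (anyNA(records$weight_class)) stop("weight_class must be populated")
  records[records$weight_class == "obese", , drop = FALSE]
}

#' Frequency-match controls to cases
#'
#' For each stratum of the matching factors (default joint age group x
#' sex), draws `ratio` controls per case by seeded simple random
#' sampling without replacement from the eligible (normal-weight)
#' controls in that stratum.  A stratum with fewer eligible controls
#' than its target is handled by `shortfall_policy`: take all and warn
#' (default), or fail.
#'
#' @param cases Case records (from [select_cases()]).
#' @param eligible_controls Normal-weight candidate records; ids must
#'   not overlap the cases.
#' @param ratio Controls per case (default 2).
#' @param strata Record columns defining matching strata.
#' @param seed Integer seed for the stratum-wise sampling.
#' @param shortfall_policy `"take_all_and_warn"` or `"fail"`.
#' @return A list: `controls` (the selected records) and `diagnostics`
#'   (per-stratum data frame with `stratum`, `n_cases`, `target`,
#'   `eligible`, `achieved`, `deficit`).
#' @export
frequency_match_controls <- function(cases, eligible_controls, ratio = 2L,
                                     strata = c("age_group", "sex"),
                                     seed = 1L,
                                     shortfall_policy = c("take_all_and_warn",
                                                          "fail")) {
  shortfall_policy <- match.arg(shortfall_policy)
  ratio <- as.integer(ratio)
  if (ratio < 1L) stop("ratio must be a positive integer")
  if (!all(strata %in% names(cases)) || !all(strata %in% names(eligible_controls))) {
    stop("matching strata columns missing from records")
  }
  if (nrow(eligible_controls) > 0 &&
      any(eligible_controls$weight_class != "normal")) {
    stop("eligible controls must all have normal weight")
  }
  if (length(intersect(cases$id, eligible_controls$id)) > 0L) {
    stop("case and control ids overlap")
  }
  if (nrow(cases) == 0L) {
    warning("empty case set: no controls selected")
    return(list(controls = eligible_controls[0, , drop = FALSE],
                diagnostics = data.frame(stratum = character(0),
                                         n_cases = integer(0),
                                         target = integer(0),
                                         eligible = integer(0),
                                         achieved = integer(0),
                                         deficit = integer(0))))
  }
  stratum_key <- function(df) {
    do.call(paste, c(lapply(strata, function(s) as.character(df[[s]])),
                     sep = "|"))
  }
  case_key <- stratum_key(cases)
  ctrl_key <- stratum_key(eligible_controls)
  strata_levels <- sort(unique(case_key))

  picked <- integer(0)
  diag_rows <- vector("list", length(strata_levels))
  with_seed(substream_seed(seed, 42L), {
    for (i in seq_along(strata_levels)) {
      s <- strata_levels[i]
      n_cases <- sum(case_key == s)
      target <- ratio * n_cases
      pool <- which(ctrl_key == s)
      if (length(pool) < target && shortfall_policy == "fail") {
        stop("stratum '", s, "' has only ", length(pool),
             " eligible controls for a target of ", target)
      }
      take <- if (length(pool) <= target) pool else sample(pool, target)
      if (length(pool) < target) {
        warning("stratum '", s, "' short by ", target - length(pool),
                " controls; taking all ", length(pool))
      }
      picked <- c(picked, take)
      diag_rows[[i]] <- data.frame(
        stratum = s, n_cases = n_cases, target = target,
        eligible = length(pool), achieved = length(take),
        deficit = max(0L, target - length(take)), stringsAsFactors = FALSE)
    }
  })
  list(controls = eligible_controls[sort(picked), , drop = FALSE],
       diagnostics = do.call(rbind, diag_rows))
}

#' Apply analysis exclusions
#'
#' Drops overweight participants (ineligible in a design that contrasts
#' obese cases with normal-weight controls) and participants missing a
#' genotype for any required marker, with a per-reason exclusion log.
#'
#' @param records Participant data frame.
#' @param require_markers List of [marker()] objects whose genotypes
#'   must be non-missing.
#' @return A list: `records` (retained rows) and `log` (data frame with
#'   `reason`, `n`).
#' @export
apply_exclusions <- function(records, require_markers = list()) {
  n0 <- nrow(records)
  keep <- records$weight_class != "overweight"
  n_overweight <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  n_missing <- 0L
  for (mk in require_markers) {
    col <- genotype_column(mk)
    if (!col %in% names(records)) stop("no genotype column for ", mk$name)
    miss <- is.na(records[[col]])
    n_missing <- n_missing + sum(miss)
    records <- records[!miss, , drop = FALSE]
  }
  log <- data.frame(
    reason = c("overweight (ineligible)", "missing genotype"),
    n = c(n_overweight, n_missing), stringsAsFactors = FALSE)
  if (nrow(records) == 0L && n0 > 0L) {
    message("all ", n0, " records excluded: ",
            paste(sprintf("%s = %d", log$reason, log$n), collapse = ", "))
  }
  list(records = records, log = log)
}
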