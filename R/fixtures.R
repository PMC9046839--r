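# Fixture builder: reconstruct individual-level records from published
# stratified genotype counts, so tabulation-level results can be
# reproduced exactly without the original (undeposited) survey data.

#' Rebuild participant records from printed genotype counts
#'
#' Expands a case/control x farmer/migrant x genotype count table for
#' one marker into one record per counted unit, with deterministic ids.
#' Tabulating the output recovers the input counts exactly.  Covariates,
#' sex and age are placeholder categories (first level of each set,
#' age 40); the records carry `attr(, "synthetic") = TRUE` and are only
#' meaningful for genotype-level and joint-exposure analyses.
#'
#' @param marker A [marker()].
#' @param counts Nested list `counts[[status]][[group]]`, with `status`
#'   in `c("case", "control")` and `group` in `c("farmer", "migrant")`,
#'   each a nonnegative integer 3-vector of genotype counts
#'   (risk-allele count 0, 1, 2).
#' @return A participant data frame; cases get BMI 30 (obese), controls
#'   BMI 22 (normal weight).
#' @examples
#' cts <- mc4r_example_counts()$rs17782313
#' fx <- fixture_from_printed_counts(marker("rs17782313", "T", "C"), cts)
#' table(fx$weight_class)
#' @export
fixture_from_printed_counts <- function(marker, counts) {
  stopifnot(inherits(marker, "marker"))
  statuses <- c("case", "control")
  groups <- c("farmer", "migrant")
  if (!all(statuses %in% names(counts))) {
    stop("counts must have 'case' and 'control' components")
  }
  rows <- list()
  for (st in statuses) {
    if (!all(groups %in% names(counts[[st]]))) {
      stop("counts[['", st, "']] must have 'farmer' and 'migrant' components")
    }
    for (gr in groups) {
      v <- counts[[st]][[gr]]
      if (length(v) != 3L || any(is.na(v)) || any(v < 0) ||
          any(v != floor(v))) {
        stop("counts[['", st, "']][['", gr, "']] must be 3 nonnegative integers")
      }
      total <- sum(v)
      if (total == 0L) next
      g <- rep(0:2, times = v)
      bmi <- if (st == "case") 30 else 22
      rec <- data.frame(
        id = sprintf("%s_%s_%s_%05d", marker$name, st, gr, seq_len(total)),
        migration = gr,
        sex = "woman",
        age = 40,
        age_group = age_group_from_age(rep(40, total)),
        bmi = bmi,
        weight_class = weight_class_from_bmi(rep(bmi, total)),
        education = "illiterate",
        income = "low",
        smoking = "never",
        drinking = "never",
        occupational_pa = "light",
        leisure_exercise = "light",
        stringsAsFactors = FALSE
      )
      rec[[genotype_column(marker)]] <- as.integer(g)
      rows[[paste(st, gr)]] <- rec
    }
  }
  if (length(rows) == 0L) {
    out <- empty_participants(marker$name)
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  attr(out, "synthetic") <- TRUE
  out
}

#' Published example counts and odds ratios for two MC4R-region SNPs
#'
#' Genotype counts for rs17782313 and rs12970134, stratified by case
#' status (obese case / normal-weight control) and residence group
#' (rural farmer / rural-to-urban migrant), from a published 1:2
#' frequency-matched case-control study of obesity (322 cases, 643
#' genotyped controls).  Used as the built-in fixture for examples and
#' for reproducing the published tabulation-level results.
#'
#' @return A named list with one component per marker, each suitable as
#'   the `counts` argument of [fixture_from_printed_counts()].
#' @export
mc4r_example_counts <- function() {
  list(
    rs17782313 = list(
      case = list(farmer = c(76L, 43L, 7L), migrant = c(117L, 63L, 16L)),
      control = list(farmer = c(317L, 132L, 13L), migrant = c(131L, 46L, 4L))
    ),
    rs12970134 = list(
      case = list(farmer = c(82L, 35L, 9L), migrant = c(124L, 59L, 13L)),
      control = list(farmer = c(325L, 124L, 13L), migrant = c(133L, 45L, 3L))
    )
  )
}

#' @rdname mc4r_example_counts
#' @details `mc4r_example_adjusted_ors()` returns the covariate-adjusted
#'   joint-exposure odds ratios (recessive genotype coding x migrant
#'   status, reference = unexposed on both) reported by the same study:
#'   `or10` (genotype only), `or01` (migration only), `or11` (both).
#'   They are inputs for interaction-measure arithmetic when the
#'   individual-level covariate data behind them are unavailable.
#' @export
mc4r_example_adjusted_ors <- function() {
  list(
    rs17782313 = c(or10 = 2.02, or01 = 2.46, or11 = 10.03),
    rs12970134 = c(or10 = 2.86, or01 = 2.54, or11 = 10.80)
  )
}
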