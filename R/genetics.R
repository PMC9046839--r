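# Genotype tabulation, allele frequencies, Hardy-Weinberg testing and
# case-control chi-square comparisons for a diallelic marker.

#' Genotype counts
#'
#' Container for the three genotype classes of a diallelic marker,
#' ordered by risk-allele count: `n0` (common homozygotes), `n1`
#' (heterozygotes), `n2` (risk homozygotes).
#'
#' @param n0,n1,n2 Nonnegative integer counts.
#' @return An object of class `genotype_counts`.
#' @export
genotype_counts <- function(n0, n1, n2) {
  v <- c(n0 = n0, n1 = n1, n2 = n2)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
    stop("genotype counts must be nonnegative integers")
  }
  structure(list(n0 = as.integer(n0), n1 = as.integer(n1),
                 n2 = as.integer(n2), n = as.integer(n0 + n1 + n2)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> n0 = %d, n1 = %d, n2 = %d (n = %d)\n",
              x$n0, x$n1, x$n2, x$n))
  invisible(x)
}

as_counts_vector <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  c(counts$n0, counts$n1, counts$n2)
}

#' Tabulate genotypes for a marker
#'
#' Exact genotype counts over a subset of participant records.  Missing
#' genotypes are an error: exclusions must happen upstream (see
#' [apply_exclusions()]).
#'
#' @param records Participant data frame.
#' @param marker A [marker()].
#' @param subset Optional logical vector selecting rows.
#' @return A [genotype_counts()] object.
#' @export
tabulate_genotypes <- function(records, marker, subset = NULL) {
  col <- genotype_column(marker)
  if (!col %in% names(records)) stop("no genotype column for ", marker$name)
  g <- records[[col]]
  if (!is.null(subset)) g <- g[subset]
  if (any(is.na(g))) {
    stop("missing genotypes present for ", marker$name,
         "; apply exclusions first")
  }
  genotype_counts(sum(g == 0L), sum(g == 1L), sum(g == 2L))
}

#' Risk-allele frequency from genotype counts
#'
#' @param counts A [genotype_counts()] with `n > 0`.
#' @return A list with `risk_count` (`n1 + 2 n2`), `total_alleles`
#'   (`2 n`) and `frequency`.
#' @examples
#' allele_frequency(genotype_counts(193, 106, 23))  # 152 / 644 = 0.2360
#' @export
allele_frequency <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$n == 0L) stop("cannot compute allele frequency from zero genotypes")
  risk <- counts$n1 + 2L * counts$n2
  total <- 2L * counts$n
  list(risk_count = risk, total_alleles = total, frequency = risk / total)
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson goodness-of-fit chi-square (1 df, no continuity correction)
#' of observed genotype counts against the proportions q^2, 2pq, p^2
#' implied by the sample risk-allele frequency p.  Conventionally run on
#' the control group as a genotyping quality check.
#'
#' @param counts A [genotype_counts()]; both alleles must be present.
#' @return An object of class `hwe_result` with fields `chi2`, `df`,
#'   `p`, `risk_allele_freq`, `observed`, `expected`.
#' @examples
#' hwe_test(genotype_counts(448, 178, 17))  # p = 0.8919
#' @export
hwe_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$n == 0L) stop("empty sample is untestable")
  p <- allele_frequency(counts)$frequency
  if (p == 0 || p == 1) {
    stop("monomorphic sample: Hardy-Weinberg equilibrium is untestable")
  }
  q <- 1 - p
  expected <- counts$n * c(q^2, 2 * p * q, p^2)
  observed <- as_counts_vector(counts)
  chi2 <- sum((observed - expected)^2 / expected)
  structure(list(
    chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1L, lower.tail = FALSE),
    risk_allele_freq = p, observed = observed, expected = expected
  ), class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f (df = 1), p = %s, risk-allele freq = %.4f\n",
              x$chi2, fmt_p(x$p), x$risk_allele_freq))
  invisible(x)
}

# Shared Pearson chi-square wrapper with expected-cell policy: error on
# a zero expected cell (naming it), warn below 5.
pearson_chi2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  zero <- which(expected == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    stop(sprintf("expected cell [%d, %d] is zero; test undefined",
                 zero[1, 1], zero[1, 2]))
  }
  if (any(expected < 5)) {
    warning("some expected cell counts are below 5; chi-square approximation may be poor")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(chi2 = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, table = tab), class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4f (df = %d), p = %s\n",
              x$chi2, x$df, fmt_p(x$p)))
  invisible(x)
}

#' Case-control genotype-distribution test
#'
#' Pearson chi-square (no continuity correction) on the 2 x 3 table of
#' genotype counts in cases versus controls (df = 2).
#'
#' @param case,control [genotype_counts()] objects.
#' @return A `chi2_result` with `chi2`, `df`, `p` and the tested table.
#' @export
genotype_case_control_test <- function(case, control) {
  tab <- rbind(case = as_counts_vector(case), control = as_counts_vector(control))
  colnames(tab) <- c("g0", "g1", "g2")
  pearson_chi2(tab)
}

#' Case-control allele-frequency test
#'
#' Pearson chi-square (no continuity correction) on the 2 x 2 table of
#' allele counts (common vs risk) in cases versus controls (df = 1).
#'
#' @inheritParams genotype_case_control_test
#' @return A `chi2_result`.
#' @export
allele_case_control_test <- function(case, control) {
  row_alleles <- function(cts) {
    af <- allele_frequency(cts)
    c(common = af$total_alleles - af$risk_count, risk = af$risk_count)
  }
  tab <- rbind(case = row_alleles(case), control = row_alleles(control))
  pearson_chi2(tab)
}
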