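# Synthetic cohort generator: two-group (farmer / migrant) cohorts with
# two diallelic markers drawn from haplotype frequencies (HWE within
# marker; LD only through the haplotype distribution) and obesity from a
# logistic disease model with additive joint-indicator parameterization.

#' Default two-marker set used by the simulator and examples
#'
#' Two MC4R-region SNPs: rs17782313 (T > C, risk allele C) and
#' rs12970134 (G > A, risk allele A).
#'
#' @return A list of two [marker()] objects.
#' @export
default_markers <- function() {
  list(marker("rs17782313", "T", "C"),
       marker("rs12970134", "G", "A"))
}

# Per-group covariate category probabilities for the generator defaults,
# patterned on the control-group distributions of a rural/urban migrant
# cohort: farmers are less educated, lower income, more heavy
# occupational activity; migrants the reverse.
.default_covariate_probs <- list(
  farmer = list(
    sex = c(man = 0.35, woman = 0.65),
    age_group = c(`20-29` = 0.07, `30-39` = 0.22, `40-49` = 0.36,
                  `50-59` = 0.22, `60-80` = 0.13),
    education = c(illiterate = 0.72, primary_middle = 0.26, high_plus = 0.02),
    income = c(low = 0.78, high = 0.22),
    smoking = c(never = 0.65, former = 0.02, current = 0.33),
    drinking = c(never = 0.66, former = 0.08, current = 0.26),
    occupational_pa = c(light = 0.28, moderate = 0.06, heavy = 0.66),
    leisure_exercise = c(light = 0.94, moderate = 0.02, heavy = 0.04)
  ),
  migrant = list(
    sex = c(man = 0.28, woman = 0.72),
    age_group = c(`20-29` = 0.05, `30-39` = 0.20, `40-49` = 0.29,
                  `50-59` = 0.25, `60-80` = 0.21),
    education = c(illiterate = 0.42, primary_middle = 0.37, high_plus = 0.21),
    income = c(low = 0.19, high = 0.81),
    smoking = c(never = 0.69, former = 0.03, current = 0.28),
    drinking = c(never = 0.71, former = 0.07, current = 0.22),
    occupational_pa = c(light = 0.75, moderate = 0.16, heavy = 0.09),
    leisure_exercise = c(light = 0.45, moderate = 0.25, heavy = 0.30)
  )
)

#' Configuration for the synthetic cohort generator
#'
#' Defines group sizes, per-group haplotype frequencies for the two
#' markers, covariate category probabilities, and the logistic disease
#' model.  Obesity is assigned with probability
#' `plogis(b0_group + log(or_g) I(G=1, E=0) + log(or_e) I(G=0, E=1) +
#' log(or_ge) I(G=1, E=1) + covariate terms)`, where `G` is the coded
#' genotype of `disease_marker` (recessive by default) and `E` indicates
#' migrant status, so `or_ge` is the joint odds ratio against the
#' doubly-unexposed reference (not a product term).
#'
#' @param n Named integer vector `c(farmer = ..., migrant = ...)`.
#' @param markers List of two [marker()] objects.
#' @param haplotype_freqs Named list with one 4-vector per group over
#'   haplotypes (common,common), (common,risk2), (risk1,common),
#'   (risk1,risk2) of the two markers; each must sum to 1.  The default
#'   uses independent haplotypes (no LD) with risk-allele frequencies
#'   0.165 and 0.16 in both groups; these are illustrative values.
#' @param covariate_probs Named list (`farmer`, `migrant`) of per-group
#'   category probability vectors for sex, age_group, education, income,
#'   smoking, drinking, occupational_pa, leisure_exercise.
#' @param baseline_logodds Named numeric `c(farmer = ..., migrant = ...)`
#'   baseline log-odds of obesity for genotype-unexposed members of each
#'   group; the migrant entry is ignored by the disease model above
#'   (migration enters through `or_e` / `or_ge`) but is kept for
#'   explicitness and must equal the farmer entry.
#' @param disease_coding `"recessive"` or `"dominant"` coding of
#'   `disease_marker` in the disease model.
#' @param disease_marker Index (1 or 2) of the marker driving disease.
#' @param or_g,or_e,or_ge Target odds ratios for genotype alone, migrant
#'   status alone, and the joint exposure, all positive.
#' @param covariate_effects Optional named list of per-level log-odds
#'   offsets, e.g. `list(income = c(low = 0, high = 0.3))`; default none,
#'   so covariates are independent of outcome given group.
#' @param overweight_fraction Fraction of non-obese participants
#'   assigned to the overweight class (ineligible as controls).
#' @param seed Master integer seed; all stochastic stages derive
#'   substreams from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n = c(farmer = 2000L, migrant = 1000L),
                              markers = default_markers(),
                              haplotype_freqs = NULL,
                              covariate_probs = .default_covariate_probs,
                              baseline_logodds = c(farmer = qlogis(0.08),
                                                   migrant = qlogis(0.08)),
                              disease_coding = c("recessive", "dominant"),
                              disease_marker = 1L,
                              or_g = 2, or_e = 2.5, or_ge = 10,
                              covariate_effects = NULL,
                              overweight_fraction = 0.30,
                              seed = 20150701L) {
  disease_coding <- match.arg(disease_coding)
  stopifnot(length(markers) == 2L,
            all(vapply(markers, inherits, logical(1), "marker")))
  if (is.null(haplotype_freqs)) {
    p1 <- 0.165; p2 <- 0.16   # illustrative: independent haplotypes
    hf <- c((1 - p1) * (1 - p2), (1 - p1) * p2, p1 * (1 - p2), p1 * p2)
    haplotype_freqs <- list(farmer = hf, migrant = hf)
  }
  n <- setNames(as.integer(n), names(n))
  if (!all(c("farmer", "migrant") %in% names(n))) {
    stop("n must be named with 'farmer' and 'migrant'")
  }
  if (any(n < 0L)) stop("group sizes must be nonnegative")
  for (g in c("farmer", "migrant")) {
    f <- haplotype_freqs[[g]]
    if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      stop("haplotype_freqs[['", g, "']] must be 4 nonnegative values summing to 1")
    }
  }
  if (any(c(or_g, or_e, or_ge) <= 0)) stop("all odds ratios must be positive")
  if (overweight_fraction < 0 || overweight_fraction > 1) {
    stop("overweight_fraction must lie in [0, 1]")
  }
  structure(list(
    n = n, markers = markers, haplotype_freqs = haplotype_freqs,
    covariate_probs = covariate_probs, baseline_logodds = baseline_logodds,
    disease_coding = disease_coding, disease_marker = as.integer(disease_marker),
    or_g = or_g, or_e = or_e, or_ge = or_ge,
    covariate_effects = covariate_effects,
    overweight_fraction = overweight_fraction, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Sample two-marker genotypes from haplotype frequencies
#'
#' Each individual receives two independent haplotype draws (random
#' mating), so per-marker genotype frequencies converge to the
#' Hardy-Weinberg proportions p^2, 2pq, q^2 and any between-marker
#' correlation is induced solely by the haplotype distribution.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param hap_freqs Numeric 4-vector over haplotypes (0,0), (0,1),
#'   (1,0), (1,1) (risk-allele indicator at marker 1, marker 2); must be
#'   nonnegative and sum to 1 within 1e-9.
#' @param n Number of individuals.
#' @return An `n x 2` integer matrix of risk-allele counts.
#' @export
sample_genotypes <- function(hap_freqs, n) {
  stopifnot(is.numeric(hap_freqs), length(hap_freqs) == 4L)
  if (any(hap_freqs < 0)) stop("haplotype frequencies must be nonnegative")
  if (abs(sum(hap_freqs) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  n <- as.integer(n)
  if (n == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("m1", "m2"))))
  }
  # haplotype -> risk-allele contribution at each marker
  risk1 <- c(0L, 0L, 1L, 1L)
  risk2 <- c(0L, 1L, 0L, 1L)
  hap <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = hap_freqs),
                ncol = 2L)
  cbind(m1 = risk1[hap[, 1]] + risk1[hap[, 2]],
        m2 = risk2[hap[, 1]] + risk2[hap[, 2]])
}

sample_category <- function(probs, n) {
  if (abs(sum(probs) - 1) > 1e-6) stop("category probabilities must sum to 1")
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Simulate a two-group cohort
#'
#' Generates one participant record per individual: group, demographics
#' and lifestyle covariates from the configured per-group category
#' probabilities, genotypes from the group haplotype frequencies, and
#' obesity from the configured logistic disease model.  Non-obese
#' individuals are split into normal / overweight classes by
#' `overweight_fraction`; BMI is set to a class-representative value
#' (22, 26, 30) so `weight_class` stays a deterministic function of it.
#' Identical configurations (including seed) give identical output.
#'
#' @param config A [simulation_config()].
#' @return A data frame of participant records, one row per individual.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  groups <- c("farmer", "migrant")
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    grp <- groups[k]
    ng <- config$n[[grp]]
    if (ng == 0L) {
      warning("group '", grp, "' has size zero; emitting no records")
      next
    }
    out[[k]] <- with_seed(substream_seed(config$seed, k), {
      geno <- sample_genotypes(config$haplotype_freqs[[grp]], ng)
      cp <- config$covariate_probs[[grp]]
      age_group <- sample_category(cp$age_group, ng)
      lo <- c(`20-29` = 20, `30-39` = 30, `40-49` = 40, `50-59` = 50,
              `60-80` = 60)
      span <- c(`20-29` = 10, `30-39` = 10, `40-49` = 10, `50-59` = 10,
                `60-80` = 21)
      age <- lo[age_group] + floor(runif(ng) * span[age_group])

      rec <- data.frame(
        id = sprintf("%s_%06d", grp, seq_len(ng)),
        migration = grp,
        sex = sample_category(cp$sex, ng),
        age = as.numeric(age),
        age_group = age_group,
        bmi = NA_real_,
        weight_class = NA_character_,
        education = sample_category(cp$education, ng),
        income = sample_category(cp$income, ng),
        smoking = sample_category(cp$smoking, ng),
        drinking = sample_category(cp$drinking, ng),
        occupational_pa = sample_category(cp$occupational_pa, ng),
        leisure_exercise = sample_category(cp$leisure_exercise, ng),
        stringsAsFactors = FALSE
      )
      for (j in 1:2) {
        rec[[genotype_column(config$markers[[j]])]] <- as.integer(geno[, j])
      }

      g_raw <- geno[, config$disease_marker]
      g <- if (config$disease_coding == "recessive") {
        as.numeric(g_raw == 2L)
      } else {
        as.numeric(g_raw >= 1L)
      }
      e <- as.numeric(grp == "migrant")
      eta <- config$baseline_logodds[["farmer"]] +
        log(config$or_g) * (g == 1 & e == 0) +
        log(config$or_e) * (g == 0 & e == 1) +
        log(config$or_ge) * (g == 1 & e == 1)
      if (!is.null(config$covariate_effects)) {
        for (nm in names(config$covariate_effects)) {
          eff <- config$covariate_effects[[nm]]
          eta <- eta + unname(eff[rec[[nm]]])
        }
      }
      obese <- rbinom(ng, 1L, plogis(eta)) == 1L
      over <- !obese & (runif(ng) < config$overweight_fraction)
      rec$bmi <- ifelse(obese, 30, ifelse(over, 26, 22))
      rec$weight_class <- weight_class_from_bmi(rec$bmi)
      rec
    })
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(empty_participants(vapply(config$markers, `[[`, "", "name")))
  }
  do.call(rbind, out)
}

empty_participants <- function(marker_names = character()) {
  cols <- .participant_columns(marker_names)
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (nm in c("age", "bmi")) df[[nm]] <- numeric(0)
  for (nm in paste0(marker_names, "_genotype")) df[[nm]] <- integer(0)
  df
}
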