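# Internal helpers: category dictionaries, seeding, formatting.

# Canonical category levels for participant records.  First level of each
# set is the reference level in dummy-coded regression designs.
.participant_levels <- list(
  migration       = c("farmer", "migrant"),
  sex             = c("man", "woman"),
  age_group       = c("20-29", "30-39", "40-49", "50-59", "60-80"),
  weight_class    = c("normal", "overweight", "obese"),
  education       = c("illiterate", "primary_middle", "high_plus"),
  income          = c("low", "high"),
  smoking         = c("never", "former", "current"),
  drinking        = c("never", "former", "current"),
  occupational_pa = c("light", "moderate", "heavy"),
  leisure_exercise = c("light", "moderate", "heavy")
)

.participant_columns <- function(markers = character()) {
  c("id", "migration", "sex", "age", "age_group", "bmi", "weight_class",
    "education", "income", "smoking", "drinking", "occupational_pa",
    "leisure_exercise",
    if (length(markers)) paste0(markers, "_genotype") else character(0))
}

#' Weight class from BMI
#'
#' Deterministic classification used throughout the package: normal
#' (BMI < 24), overweight (24 <= BMI < 28), obese (BMI >= 28 kg/m^2),
#' the adult cutoffs of the Working Group on Obesity in China.
#'
#' @param bmi Numeric vector of body-mass indices (kg/m^2).
#' @return Character vector in `c("normal", "overweight", "obese")`.
#' @export
weight_class_from_bmi <- function(bmi) {
  stopifnot(is.numeric(bmi))
  ifelse(bmi >= 28, "obese", ifelse(bmi >= 24, "overweight", "normal"))
}

#' Age group from age
#'
#' Decade bands 20-29, 30-39, 40-49, 50-59 and a pooled 60-80 band.
#'
#' @param age Numeric vector of ages in years (20-80).
#' @return Character vector of age-band labels.
#' @export
age_group_from_age <- function(age) {
  stopifnot(is.numeric(age))
  if (any(!is.na(age) & (age < 20 | age > 80))) {
    stop("age must lie in [20, 80]")
  }
  bands <- .participant_levels$age_group
  idx <- pmin(findInterval(age, c(20, 30, 40, 50, 60)), 5L)
  bands[idx]
}

# Derive a deterministic 32-bit substream seed from a master seed and an
# integer stream index, so independent stages never share a stream.
substream_seed <- function(seed, stream) {
  seed <- as.numeric(seed)
  stream <- as.numeric(stream)
  as.integer((abs(seed) %% 46337) * 46337 + (abs(stream) %% 46337)) %% 2147483647L
}

# Evaluate `code` under `set.seed(seed)` while preserving the caller's
# global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Rendering conventions: percentages and ORs to 2 decimals, p-values to 4.
fmt_count_pct <- function(n, total) {
  pct <- if (total > 0) 100 * n / total else 0
  sprintf("%d (%.2f)", as.integer(n), pct)
}

fmt_p <- function(p) {
  ifelse(p < 0.0001, "<0.0001", sprintf("%.4f", p))
}

fmt_or_ci <- function(or, lo, hi) sprintf("%.2f (%.2f-%.2f)", or, lo, hi)

factorize_participants <- function(records) {
  for (nm in names(.participant_levels)) {
    if (nm %in% names(records)) {
      records[[nm]] <- factor(records[[nm]], levels = .participant_levels[[nm]])
    }
  }
  records
}

is_case <- function(records) {
  wc <- as.character(records$weight_class)
  if (any(wc == "overweight")) {
    stop("records contain overweight participants; run apply_exclusions() first")
  }
  as.integer(wc == "obese")
}
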