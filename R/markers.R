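#' Define a diallelic marker
#'
#' A marker is a named SNP with a common allele and a risk allele.
#' Genotypes are stored internally as risk-allele counts (0, 1, 2);
#' allele-pair strings are an I/O concern only.
#'
#' @param name Marker name, e.g. `"rs17782313"`.
#' @param common_allele Single-character common-allele symbol.
#' @param risk_allele Single-character risk-allele symbol; must differ
#'   from `common_allele`.
#' @return An object of class `marker`.
#' @examples
#' marker("rs17782313", "T", "C")
#' @export
marker <- function(name, common_allele, risk_allele) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(common_allele), nchar(common_allele) == 1L)
  stopifnot(is.character(risk_allele), nchar(risk_allele) == 1L)
  if (identical(common_allele, risk_allele)) {
    stop("common_allele and risk_allele must differ")
  }
  structure(list(name = name, common_allele = common_allele,
                 risk_allele = risk_allele), class = "marker")
}

#' @export
print.marker <- function(x, ...) {
  cat(sprintf("<marker> %s (%s > %s), risk allele %s\n",
              x$name, x$common_allele, x$risk_allele, x$risk_allele))
  invisible(x)
}

genotype_column <- function(marker) paste0(marker$name, "_genotype")

#' Inheritance-model design coding
#'
#' Encodes risk-allele counts under one of the four standard inheritance
#' models: dominant (any risk allele vs none), recessive (risk
#' homozygote vs others), additive (per-allele count) and codominant
#' (separate indicators for heterozygote and risk homozygote).
#'
#' @param genotype Integer vector of risk-allele counts in `{0, 1, 2}`;
#'   missing values are not allowed.
#' @param model One of `"dominant"`, `"recessive"`, `"additive"`,
#'   `"codominant"`.
#' @return A numeric matrix with one column (two for codominant), one
#'   row per genotype.
#' @examples
#' encode_inheritance(c(0, 1, 2), "recessive")
#' encode_inheritance(c(0, 1, 2), "codominant")
#' @export
encode_inheritance <- function(genotype,
                               model = c("dominant", "recessive",
                                         "codominant", "additive")) {
  model <- match.arg(model)
  if (any(is.na(genotype))) stop("genotype contains missing values")
  if (!all(genotype %in% 0:2)) stop("genotype values must be 0, 1 or 2")
  g <- as.numeric(genotype)
  switch(model,
    dominant  = matrix(as.numeric(g >= 1), ncol = 1,
                       dimnames = list(NULL, "dom")),
    recessive = matrix(as.numeric(g == 2), ncol = 1,
                       dimnames = list(NULL, "rec")),
    additive  = matrix(g, ncol = 1, dimnames = list(NULL, "add")),
    codominant = cbind(het = as.numeric(g == 1), hom = as.numeric(g == 2))
  )
}
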