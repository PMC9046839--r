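test_that("degenerate haplotype frequencies give all-reference genotypes", {
  geno <- sample_genotypes(c(1, 0, 0, 0), 10)
  expect_equal(dim(geno), c(10L, 2L))
  expect_true(all(geno == 0L))
})

test_that("genotype draws converge to Hardy-Weinberg proportions", {
  p <- 0.165
  hf <- c((1 - p) * 0.84, (1 - p) * 0.16, p * 0.84, p * 0.16)
  set.seed(401)
  geno <- sample_genotypes(hf, 100000)
  hom_frac <- mean(geno[, 1] == 2L)
  mc_se <- sqrt(p^2 * (1 - p^2) / 100000)
  expect_lt(abs(hom_frac - p^2), 3 * mc_se)
  # heterozygote fraction too
  expect_lt(abs(mean(geno[, 1] == 1L) - 2 * p * (1 - p)),
            3 * sqrt(2 * p * (1 - p) * (1 - 2 * p * (1 - p)) / 100000))
})

test_that("independent haplotypes leave the two markers uncorrelated", {
  p1 <- 0.3; p2 <- 0.2
  hf <- c((1 - p1) * (1 - p2), (1 - p1) * p2, p1 * (1 - p2), p1 * p2)
  set.seed(402)
  geno <- sample_genotypes(hf, 50000)
  expect_lt(abs(cor(geno[, 1], geno[, 2])), 3 / sqrt(50000))
})

test_that("invalid haplotype frequencies are rejected", {
  expect_error(sample_genotypes(c(0.5, 0.5, 0.1, -0.1), 10), "nonnegative")
  expect_error(sample_genotypes(c(0.5, 0.5, 0.5, 0.5), 10), "sum to 1")
})

test_that("null disease model reproduces the baseline prevalence", {
  cfg <- simulation_config(n = c(farmer = 20000L, migrant = 20000L),
                           baseline_logodds = c(farmer = qlogis(0.3),
                                                migrant = qlogis(0.3)),
                           or_g = 1, or_e = 1, or_ge = 1, seed = 403L)
  coh <- simulate_cohort(cfg)
  frac <- mean(coh$weight_class == "obese")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 40000))
})

test_that("crude odds ratios from the realized table recover the targets", {
  cfg <- simulation_config(n = c(farmer = 200000L, migrant = 200000L),
                           or_g = 2, or_e = 2.5, or_ge = 10, seed = 404L)
  coh <- simulate_cohort(cfg)
  excl <- apply_exclusions(coh, default_markers())
  jt <- joint_exposure_table(excl$records, mk1, "recessive")
  grid <- crude_grid(jt)
  targets <- log(c(2, 2.5, 10))
  for (j in 1:3) {
    expect_lt(abs(grid["logor", j] - targets[j]), 3 * grid["se", j])
  }
})

test_that("identical seeds give byte-identical cohorts", {
  cfg <- simulation_config(n = c(farmer = 500L, migrant = 500L), seed = 405L)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- simulation_config(n = c(farmer = 500L, migrant = 500L), seed = 406L)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("zero-size group warns and yields no records for it", {
  cfg <- simulation_config(n = c(farmer = 50L, migrant = 0L), seed = 407L)
  expect_warning(coh <- simulate_cohort(cfg), "size zero")
  expect_true(all(coh$migration == "farmer"))
  expect_equal(nrow(coh), 50L)
})

test_that("generated genotypes pass the package HWE test at the nominal rate", {
  p <- 0.3
  hf <- c((1 - p)^2, 0, 2 * p * (1 - p), p^2)  # marker 1 freq p, marker 2 irrelevant
  hf <- hf / sum(hf)
  set.seed(408)
  reject <- logical(500)
  for (r in seq_len(500)) {
    g <- sample_genotypes(hf, 1000)[, 1]
    cts <- genotype_counts(sum(g == 0), sum(g == 1), sum(g == 2))
    reject[r] <- hwe_test(cts)$p < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("crude RERI is centered on zero under the additive null", {
  # OR_GE = OR_G + OR_E - 1 with dominant coding for stable cells
  set.seed(409)
  reri <- numeric(200)
  for (r in seq_len(200)) {
    cfg <- simulation_config(n = c(farmer = 2000L, migrant = 2000L),
                             disease_coding = "dominant",
                             or_g = 2, or_e = 2, or_ge = 3,
                             seed = 500000L + r)
    coh <- simulate_cohort(cfg)
    jt <- joint_exposure_table(coh[coh$weight_class != "overweight", ],
                               mk1, "dominant")
    ors <- exp(crude_grid(jt)["logor", ])
    reri[r] <- additive_measures(ors[1], ors[2], ors[3])$reri
  }
  expect_lt(abs(mean(reri)), 3 * sd(reri) / sqrt(200))
})

test_that("fixture reconstruction is the exact inverse of tabulation", {
  cts <- mc4r_example_counts()
  fx <- fixture_mk1()
  expect_equal(nrow(fx), 965L)
  expect_true(isTRUE(attr(fx, "synthetic")))
  cases <- fx[fx$weight_class == "obese", ]
  ctrls <- fx[fx$weight_class == "normal", ]
  expect_equal(nrow(cases), 322L)
  expect_equal(nrow(ctrls), 643L)
  cc <- tabulate_genotypes(fx, mk1, fx$weight_class == "obese")
  expect_equal(c(cc$n0, cc$n1, cc$n2), c(193L, 106L, 23L))
  # per-stratum identity on counts, both markers
  for (nm in names(cts)) {
    mk <- if (nm == "rs17782313") mk1 else mk2
    f <- fixture_from_printed_counts(mk, cts[[nm]])
    for (st in c("case", "control")) {
      wc <- if (st == "case") "obese" else "normal"
      for (gr in c("farmer", "migrant")) {
        sub <- tabulate_genotypes(f, mk, f$weight_class == wc & f$migration == gr)
        expect_equal(c(sub$n0, sub$n1, sub$n2), as.integer(cts[[nm]][[st]][[gr]]),
                     info = paste(nm, st, gr))
      }
    }
  }
})

test_that("recessive recode of the fixture reproduces the joint case counts", {
  fx <- fixture_mk1()
  jt <- joint_exposure_table(fx, mk1, "recessive")
  expect_equal(unname(jt$case), c(119L, 7L, 180L, 16L))
  expect_equal(unname(jt$control), c(449L, 13L, 177L, 4L))
})

test_that("all-zero printed counts give an empty collection", {
  zero <- list(case = list(farmer = c(0, 0, 0), migrant = c(0, 0, 0)),
               control = list(farmer = c(0, 0, 0), migrant = c(0, 0, 0)))
  fx <- fixture_from_printed_counts(mk1, zero)
  expect_equal(nrow(fx), 0L)
  expect_error(fixture_from_printed_counts(mk1, list(case = list(
    farmer = c(-1, 0, 0), migrant = c(0, 0, 0)),
    control = zero$control)), "nonnegative")
})
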