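test_that("joint-exposure recoding reproduces the published table cells", {
  fx <- fixture_mk1()
  jt <- joint_exposure_table(fx, mk1, "recessive")
  expect_equal(unname(jt$case), c(119L, 7L, 180L, 16L))
  expect_equal(unname(jt$control), c(449L, 13L, 177L, 4L))
  expect_equal(sum(jt$case) + sum(jt$control), nrow(fx))
  dom <- joint_exposure_table(fx, mk1, "dominant")
  expect_equal(sum(dom$case[c("n10", "n11")]), 106L + 23L)
  farmers <- fx[fx$migration == "farmer", ]
  jt_f <- joint_exposure_table(farmers, mk1, "recessive")
  expect_equal(unname(jt_f$case[c("n01", "n11")]), c(0L, 0L))
})

test_that("crude joint-model ORs equal the 2x2 cross-product ratios", {
  fx <- fixture_mk1()
  fit <- fit_joint_model(fx, mk1, "recessive")
  jt <- joint_exposure_table(fx, mk1, "recessive")
  cp <- function(cell) {
    (jt$case[[cell]] * jt$control[["n00"]]) /
      (jt$control[[cell]] * jt$case[["n00"]])
  }
  expect_equal(exp(fit$coef[["I10"]]), cp("n10"), tolerance = 1e-6)
  expect_equal(exp(fit$coef[["I01"]]), cp("n01"), tolerance = 1e-6)
  expect_equal(exp(fit$coef[["I11"]]), cp("n11"), tolerance = 1e-6)
  expect_equal(exp(fit$coef[["I11"]]), 16 * 449 / (4 * 119), tolerance = 1e-6)
  # same property on a simulated cohort
  coh <- small_cohort(seed = 71L)
  coh <- coh[coh$weight_class != "overweight", ]
  fit2 <- fit_joint_model(coh, mk1, "dominant")
  jt2 <- joint_exposure_table(coh, mk1, "dominant")
  cp2 <- (jt2$case[["n11"]] * jt2$control[["n00"]]) /
    (jt2$control[["n11"]] * jt2$case[["n00"]])
  expect_equal(exp(fit2$coef[["I11"]]), cp2, tolerance = 1e-6)
})

test_that("an empty joint category is a named error", {
  fx <- fixture_mk1()
  farmers <- fx[fx$migration == "farmer", ]
  expect_error(fit_joint_model(farmers, mk1, "recessive"), "\\(0,1\\)")
})

test_that("additive measures reproduce the published arithmetic", {
  m <- additive_measures(2.86, 2.54, 10.80)
  expect_equal(m$reri, 6.40, tolerance = 1e-9)
  expect_equal(m$ap, 6.40 / 10.80, tolerance = 1e-9)
  expect_equal(m$si, 9.80 / 3.40, tolerance = 1e-9)
  m2 <- additive_measures(2.02, 2.46, 10.03)
  expect_equal(round(m2$reri, 2), 6.55)
  expect_equal(round(m2$ap, 2), 0.65)
  expect_equal(round(m2$si, 2), 3.64)
  # additive null
  m0 <- additive_measures(1.7, 2.3, 1.7 + 2.3 - 1)
  expect_equal(m0$reri, 0, tolerance = 1e-12)
  expect_equal(m0$ap, 0, tolerance = 1e-12)
  expect_equal(m0$si, 1, tolerance = 1e-12)
  expect_error(additive_measures(-1, 2, 3), "positive")
  und <- additive_measures(1.5, 0.5, 3)  # OR10 + OR01 = 2
  expect_false(und$si_defined)
  expect_true(is.na(und$si))
})

test_that("AP * OR11 = RERI and the SI consistency identity hold everywhere", {
  set.seed(72)
  for (i in 1:50) {
    ors <- exp(rnorm(3, 0, 1))
    m <- additive_measures(ors[1], ors[2], ors[3])
    expect_equal(m$ap * ors[3], m$reri, tolerance = 1e-9)
    if (m$si_defined && abs(ors[1] + ors[2] - 2) > 1e-6) {
      expect_equal(m$si * (ors[1] + ors[2] - 2), ors[3] - 1, tolerance = 1e-9)
    }
  }
})

fake_fit <- function(b, sigma) {
  names(b) <- c("I10", "I01", "I11")
  dimnames(sigma) <- list(names(b), names(b))
  structure(list(coef = b, vcov = sigma), class = "logit_fit")
}

test_that("zero covariance collapses the delta CIs to the point estimates", {
  d <- delta_ci(fake_fit(log(c(2, 3, 8)), matrix(0, 3, 3)))
  expect_equal(d$ci_low, d$estimate, tolerance = 1e-12)
  expect_equal(d$ci_high, d$estimate, tolerance = 1e-12)
})

test_that("delta variances match a central-finite-difference gradient oracle", {
  set.seed(73)
  measures <- list(
    reri = function(b) exp(b[3]) - exp(b[1]) - exp(b[2]) + 1,
    ap = function(b) (exp(b[3]) - exp(b[1]) - exp(b[2]) + 1) / exp(b[3]),
    lnsi = function(b) log(exp(b[3]) - 1) - log(exp(b[1]) + exp(b[2]) - 2)
  )
  for (i in 1:25) {
    # coefficients guaranteeing SI is defined: both ORs above 1
    b <- c(runif(2, 0.1, 1.5), runif(1, 0.2, 2.5))
    b[3] <- max(b[3], 0.3)
    a <- matrix(rnorm(9, sd = 0.3), 3)
    sigma <- crossprod(a) + diag(1e-4, 3)
    d <- delta_ci(fake_fit(b, sigma))
    h <- 1e-6
    for (nm in names(measures)) {
      f <- measures[[nm]]
      g <- vapply(1:3, function(j) {
        e <- numeric(3); e[j] <- h
        (f(b + e) - f(b - e)) / (2 * h)
      }, numeric(1))
      var_fd <- drop(t(g) %*% sigma %*% g)
      row <- if (nm == "lnsi") "si" else nm
      expect_equal(d[row, "se"]^2, var_fd, tolerance = 1e-6,
                   info = paste(nm, i))
    }
  }
})

test_that("the SI interval is flagged undefined outside its domain", {
  d <- delta_ci(fake_fit(log(c(0.7, 0.9, 0.8)), diag(0.01, 3)))
  expect_false(d["si", "defined"])
  expect_true(is.na(d["si", "ci_low"]))
  # RERI and AP intervals still produced
  expect_true(all(is.finite(d[c("reri", "ap"), "ci_low"])))
})

test_that("delta CI half-widths track the empirical sampling spread of RERI", {
  cfg0 <- simulation_config(n = c(farmer = 4000L, migrant = 4000L),
                            disease_coding = "dominant",
                            or_g = 2, or_e = 2, or_ge = 6, seed = 1L)
  reri <- numeric(300); se <- numeric(300)
  for (r in seq_len(300)) {
    cfg <- cfg0; cfg$seed <- 730000L + r
    coh <- simulate_cohort(cfg)
    coh <- coh[coh$weight_class != "overweight", ]
    fit <- fit_joint_model(coh, mk1, "dominant")
    d <- delta_ci(fit)
    reri[r] <- d["reri", "estimate"]
    se[r] <- d["reri", "se"]
  }
  expect_lt(abs(mean(se) - sd(reri)) / sd(reri), 0.10)
})

test_that("bootstrap CIs are seeded, reproducible and consistent with delta", {
  cfg <- simulation_config(n = c(farmer = 8000L, migrant = 8000L),
                           disease_coding = "dominant",
                           or_g = 2, or_e = 2, or_ge = 6, seed = 74L)
  coh <- simulate_cohort(cfg)
  coh <- coh[coh$weight_class != "overweight", ]
  b1 <- bootstrap_ci(coh, mk1, "dominant", b = 300L, seed = 75L)
  b2 <- bootstrap_ci(coh, mk1, "dominant", b = 300L, seed = 75L)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_ci(coh, mk1, "dominant", b = 300L, seed = 76L)
  expect_false(identical(b1$ci, b3$ci))
  expect_error(bootstrap_ci(coh, mk1, "dominant", b = 2L), "at least 200")
  # cross-method agreement of RERI interval half-widths at large n
  fit <- fit_joint_model(coh, mk1, "dominant")
  d <- delta_ci(fit)
  hw_delta <- (d["reri", "ci_high"] - d["reri", "ci_low"]) / 2
  hw_boot <- (b1$ci["reri", "ci_high"] - b1$ci["reri", "ci_low"]) / 2
  expect_lt(abs(hw_boot - hw_delta) / hw_delta, 0.15)
})

test_that("crude product-term model equals the closed-form OR ratio", {
  fx <- fixture_mk1()
  mt <- multiplicative_test(fx, mk1, "recessive")
  jt <- joint_exposure_table(fx, mk1, "recessive")
  cp <- function(cell) (jt$case[[cell]] * jt$control[["n00"]]) /
    (jt$control[[cell]] * jt$case[["n00"]])
  expect_equal(log(mt$or), log(cp("n11") / (cp("n10") * cp("n01"))),
               tolerance = 1e-6)
})

test_that("the product-term test sees multiplicative structure correctly", {
  # multiplicative null: OR_GE = OR_G * OR_E
  cfg <- simulation_config(n = c(farmer = 20000L, migrant = 20000L),
                           disease_coding = "dominant",
                           or_g = 2, or_e = 2.5, or_ge = 5, seed = 77L)
  coh <- simulate_cohort(cfg)
  coh <- coh[coh$weight_class != "overweight", ]
  mt <- multiplicative_test(coh, mk1, "dominant")
  b <- log(mt$or)
  se <- (log(mt$ci_high) - b) / qnorm(0.975)
  expect_lt(abs(b), 3 * se)
  # strong super-multiplicative interaction is detected
  cfg2 <- simulation_config(n = c(farmer = 20000L, migrant = 20000L),
                            disease_coding = "dominant",
                            or_g = 2, or_e = 2.5, or_ge = 25, seed = 78L)
  coh2 <- simulate_cohort(cfg2)
  coh2 <- coh2[coh2$weight_class != "overweight", ]
  mt2 <- multiplicative_test(coh2, mk1, "dominant")
  expect_lt(mt2$p, 0.001)
  expect_gt(mt2$or, 1)
})

test_that("interaction_analysis assembles a coherent result", {
  fx <- fixture_mk1()
  suppressWarnings(ia <- interaction_analysis(fx, mk1, "recessive",
                                              bootstrap_b = 200L, seed = 79L))
  expect_s3_class(ia, "interaction_result")
  expect_equal(ia$or_grid$or[3], 15.0924, tolerance = 1e-4)
  expect_equal(ia$measures$ap * ia$or_grid$or[3], ia$measures$reri,
               tolerance = 1e-9)
  expect_named(ia$significant, c("reri", "ap", "si"))
  expect_equal(ia$additive_interaction, all(ia$significant))
  expect_true(is.finite(ia$bootstrap$ci["reri", "ci_low"]))
  out <- capture.output(print(ia))
  expect_true(any(grepl("RERI", out)))
})
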