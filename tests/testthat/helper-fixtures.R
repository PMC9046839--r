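# Shared fixtures: the two example markers and the published-count
# reconstruction, plus a small deterministic cohort for design tests.

mk1 <- marker("rs17782313", "T", "C")
mk2 <- marker("rs12970134", "G", "A")

fixture_mk1 <- function() {
  fixture_from_printed_counts(mk1, mc4r_example_counts()$rs17782313)
}

fixture_mk2 <- function() {
  fixture_from_printed_counts(mk2, mc4r_example_counts()$rs12970134)
}

small_cohort <- function(n = c(farmer = 800L, migrant = 400L), seed = 11L,
                         ...) {
  simulate_cohort(simulation_config(n = n, seed = seed, ...))
}

# Crude log-OR grid and Wald SEs from a joint-exposure count table;
# independent of the model-fitting path.
crude_grid <- function(jt) {
  ref_case <- as.numeric(jt$case[["n00"]]); ref_ctrl <- as.numeric(jt$control[["n00"]])
  sapply(c("n10", "n01", "n11"), function(cell) {
    a <- as.numeric(jt$case[[cell]]); b <- as.numeric(jt$control[[cell]])
    c(logor = log(a * ref_ctrl / (b * ref_case)),
      se = sqrt(1 / a + 1 / b + 1 / ref_case + 1 / ref_ctrl))
  })
}
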