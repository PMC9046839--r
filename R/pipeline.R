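# Pipeline orchestration: simulate/load -> match -> QC -> associate ->
# interact, with seeded determinism, per-stage logging to stderr, and
# rendering of the three standard report tables.

#' Pipeline configuration
#'
#' @param source Input source: one of
#'   `list(type = "simulate", config = simulation_config(...))`,
#'   `list(type = "csv", path = "participants.csv")`, or
#'   `list(type = "fixture", marker = marker(...), counts = ...)` (see
#'   [fixture_from_printed_counts()]; fixture input is already a
#'   matched case-control set, so the matching stage is skipped).
#' @param markers Markers to analyse (defaults to [default_markers()];
#'   for a fixture source, the fixture marker).
#' @param match_ratio Controls per case for frequency matching.
#' @param match_strata Matching factors (default age group x sex).
#' @param covariates Covariates for adjusted models.
#' @param codings Genotype recodes for the interaction stage.
#' @param bootstrap_b Bootstrap replicates (0 disables).
#' @param seed Master seed.
#' @param out_dir Optional output directory for persisted artifacts
#'   (participant CSV, results JSON, rendered tables).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(source,
                            markers = NULL,
                            match_ratio = 2L,
                            match_strata = c("age_group", "sex"),
                            covariates = c("age_group", "sex", "education",
                                           "income", "smoking", "drinking",
                                           "occupational_pa",
                                           "leisure_exercise"),
                            codings = c("recessive", "dominant"),
                            bootstrap_b = 0L,
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(is.list(source), !is.null(source$type))
  if (!source$type %in% c("simulate", "csv", "fixture")) {
    stop("source$type must be 'simulate', 'csv' or 'fixture'")
  }
  if (source$type == "csv" && !file.exists(source$path)) {
    stop("input file does not exist: ", source$path)
  }
  if (is.null(markers)) {
    markers <- if (source$type == "fixture") list(source$marker)
               else default_markers()
  }
  if (length(markers) == 0L) stop("markers must be non-empty")
  structure(list(source = source, markers = markers,
                 match_ratio = as.integer(match_ratio),
                 match_strata = match_strata, covariates = covariates,
                 codings = codings, bootstrap_b = as.integer(bootstrap_b),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes input acquisition, case selection, frequency matching,
#' exclusions, genotype/allele/HWE QC, adjusted association models
#' under the four inheritance modes, and the interaction analysis for
#' each configured genotype recode.  Identical configuration and seed
#' give identical bundles.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return An object of class `report_bundle` with components
#'   `participants`, `match_diagnostics`, `exclusion_log`, `table1`,
#'   `table2`, `associations`, `interactions`, and `run_info`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  markers <- config$markers

  participants <- run_stage("input", switch(config$source$type,
    simulate = simulate_cohort(config$source$config),
    csv = read_participants(config$source$path),
    fixture = fixture_from_printed_counts(config$source$marker,
                                          config$source$counts)
  ))
  stage_log(verbose, "input", "%d participants", nrow(participants))

  if (config$source$type == "fixture") {
    analysed <- participants
    match_diag <- NULL
  } else {
    cases <- run_stage("select_cases", select_cases(participants))
    eligible <- participants[participants$weight_class == "normal", ,
                             drop = FALSE]
    matched <- run_stage("match",
      frequency_match_controls(cases, eligible, ratio = config$match_ratio,
                               strata = config$match_strata,
                               seed = config$seed))
    match_diag <- matched$diagnostics
    analysed <- rbind(cases, matched$controls)
    stage_log(verbose, "match", "%d cases, %d controls", nrow(cases),
              nrow(matched$controls))
  }

  excl <- run_stage("exclusions", apply_exclusions(analysed, markers))
  analysed <- excl$records
  stage_log(verbose, "exclusions", "%d records retained", nrow(analysed))

  y <- is_case(analysed)
  table1 <- run_stage("table1", characteristics_table(analysed, y))

  # A result that cannot be computed on a degenerate cohort (empty
  # joint category, monomorphic marker, single-class outcome in a tiny
  # run) is reported as a warning and dropped; structural stage
  # failures still abort above.
  fit_or_warn <- function(label, expr) {
    tryCatch(suppressWarnings(expr), error = function(e) {
      warning(sprintf("%s could not be computed: %s", label,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }

  table2 <- run_stage("qc", {
    res <- lapply(markers, function(mk) {
      fit_or_warn(paste0(mk$name, " QC"), {
        cc <- tabulate_genotypes(analysed, mk, subset = y == 1L)
        ct <- tabulate_genotypes(analysed, mk, subset = y == 0L)
        list(marker = mk$name,
             case_counts = as_counts_vector(cc),
             control_counts = as_counts_vector(ct),
             case_allele = allele_frequency(cc),
             control_allele = allele_frequency(ct),
             genotype_test = genotype_case_control_test(cc, ct),
             allele_test = allele_case_control_test(cc, ct),
             hwe_controls = hwe_test(ct))
      })
    })
    res[!vapply(res, is.null, logical(1))]
  })

  associations <- run_stage("assoc", {
    res <- list()
    for (mk in markers) {
      for (mod in c("dominant", "recessive", "codominant", "additive")) {
        key <- paste(mk$name, mod, sep = ".")
        res[[key]] <- fit_or_warn(key,
          adjusted_association(analysed, mk, mod, config$covariates))
      }
    }
    res[!vapply(res, is.null, logical(1))]
  })

  interactions <- run_stage("interact", {
    res <- list()
    for (mk in markers) {
      for (cd in config$codings) {
        key <- paste(mk$name, cd, sep = ".")
        res[[key]] <- fit_or_warn(key,
          interaction_analysis(analysed, mk, cd, config$covariates,
                               bootstrap_b = config$bootstrap_b,
                               seed = config$seed))
      }
    }
    res[!vapply(res, is.null, logical(1))]
  })

  bundle <- structure(list(
    participants = analysed, match_diagnostics = match_diag,
    exclusion_log = excl$log, table1 = table1, table2 = table2,
    associations = associations, interactions = interactions,
    run_info = list(seed = config$seed, source = config$source$type,
                    markers = vapply(markers, `[[`, "", "name"),
                    package_version = as.character(utils::packageVersion("gxematch")))
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_participants(analysed, file.path(config$out_dir, "participants.csv"))
    jsonlite::write_json(bundle_json(bundle),
                         file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(render_tables(bundle), file.path(config$out_dir, "tables.md"))
  }
  bundle
}

characteristics_table <- function(records, y) {
  vars <- c("sex", "age_group", "education", "income", "smoking", "drinking",
            "occupational_pa", "leisure_exercise")
  lapply(setNames(vars, vars), function(v) {
    lv <- .participant_levels[[v]]
    f <- factor(as.character(records[[v]]), levels = lv)
    tab <- table(f, case = y)
    case <- as.integer(tab[, "1"])
    ctrl <- as.integer(tab[, "0"])
    p <- if (all(rowSums(tab) > 0) && length(unique(y)) == 2L) {
      keep <- rowSums(tab) > 0
      tryCatch(suppressWarnings(chisq.test(tab[keep, , drop = FALSE],
                                           correct = FALSE)$p.value),
               error = function(e) NA_real_)
    } else NA_real_
    list(levels = lv, case = case, control = ctrl, p = p)
  })
}

# Machine-readable mirror of the bundle; every rendered number is
# traceable to a field here.
bundle_json <- function(bundle) {
  list(
    run_info = bundle$run_info,
    exclusions = bundle$exclusion_log,
    table1 = bundle$table1,
    table2 = lapply(bundle$table2, function(t2) list(
      marker = t2$marker,
      case_counts = t2$case_counts, control_counts = t2$control_counts,
      case_allele_freq = t2$case_allele$frequency,
      control_allele_freq = t2$control_allele$frequency,
      genotype_test = list(chi2 = t2$genotype_test$chi2,
                           df = t2$genotype_test$df, p = t2$genotype_test$p),
      allele_test = list(chi2 = t2$allele_test$chi2,
                         df = t2$allele_test$df, p = t2$allele_test$p),
      hwe_controls = list(chi2 = t2$hwe_controls$chi2, p = t2$hwe_controls$p)
    )),
    associations = lapply(bundle$associations, function(a)
      list(marker = a$marker, model = a$model, estimates = a$estimates)),
    interactions = lapply(bundle$interactions, function(ix) list(
      marker = ix$marker, coding = ix$coding,
      case_counts = ix$table$case, control_counts = ix$table$control,
      or_grid = ix$or_grid,
      reri = ix$measures$reri, ap = ix$measures$ap, si = ix$measures$si,
      delta_ci = ix$delta,
      bootstrap_ci = if (!is.null(ix$bootstrap)) ix$bootstrap$ci else NULL,
      multiplicative = ix$multiplicative[c("or", "ci_low", "ci_high", "p")],
      significant = as.list(ix$significant)
    ))
  )
}

#' Render report tables
#'
#' Produces markdown text tables mirroring the standard presentation:
#' characteristics (counts with percentages to 2 decimals and
#' chi-square p-values to 4), genotype/allele/HWE comparison, and the
#' joint-exposure interaction table with its OR 1.00 reference row.
#' Every rendered number comes from a field of the bundle's
#' machine-readable form.
#'
#' @param bundle A [run_pipeline()] result.
#' @return Character vector of markdown lines.
#' @export
render_tables <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  y <- is_case(bundle$participants)
  n_case <- sum(y == 1L); n_ctrl <- sum(y == 0L)
  out <- c("# Analysis report", "",
           sprintf("Cases: %d, controls: %d (seed %d)", n_case, n_ctrl,
                   bundle$run_info$seed), "")

  out <- c(out, "## Table 1. Characteristics of cases and controls", "",
           "| Characteristic | Level | Case | Control | P |",
           "|---|---|---|---|---|")
  for (v in names(bundle$table1)) {
    t1 <- bundle$table1[[v]]
    for (i in seq_along(t1$levels)) {
      out <- c(out, sprintf("| %s | %s | %s | %s | %s |",
                            if (i == 1) v else "", t1$levels[i],
                            fmt_count_pct(t1$case[i], n_case),
                            fmt_count_pct(t1$control[i], n_ctrl),
                            if (i == 1 && !is.na(t1$p)) fmt_p(t1$p) else ""))
    }
  }

  out <- c(out, "", "## Table 2. Genotype and allele frequencies and HWE", "",
           "| Marker | Row | Case | Control | P | HWE P |",
           "|---|---|---|---|---|---|")
  for (t2 in bundle$table2) {
    gl <- c("g0", "g1", "g2")
    out <- c(out, sprintf("| %s | Genotype | | | %s | %s |", t2$marker,
                          fmt_p(t2$genotype_test$p), fmt_p(t2$hwe_controls$p)))
    for (i in 1:3) {
      out <- c(out, sprintf("| | %s | %s | %s | | |", gl[i],
                            fmt_count_pct(t2$case_counts[i], sum(t2$case_counts)),
                            fmt_count_pct(t2$control_counts[i],
                                          sum(t2$control_counts))))
    }
    out <- c(out, sprintf("| | Allele | | | %s | |", fmt_p(t2$allele_test$p)))
    ca <- t2$case_allele; cta <- t2$control_allele
    out <- c(out, sprintf("| | risk | %s | %s | | |",
                          fmt_count_pct(ca$risk_count, ca$total_alleles),
                          fmt_count_pct(cta$risk_count, cta$total_alleles)))
  }

  out <- c(out, "", "## Table 3. Additive gene x migration interaction", "",
           "| Marker/coding | Gene | Migration | Case | Control | OR (95%CI) | P |",
           "|---|---|---|---|---|---|---|")
  for (ix in bundle$interactions) {
    lab <- sprintf("%s (%s)", ix$marker, ix$coding)
    ge <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
    for (i in 1:4) {
      orcell <- if (i == 1) "1.00" else {
        j <- i - 1
        fmt_or_ci(ix$or_grid$or[j], ix$or_grid$ci_low[j], ix$or_grid$ci_high[j])
      }
      pcell <- if (i == 1) "-" else fmt_p(ix$or_grid$p[i - 1])
      out <- c(out, sprintf("| %s | %d | %d | %s | %s | %s | %s |",
                            if (i == 1) lab else "", ge[i, 1], ge[i, 2],
                            fmt_count_pct(ix$table$case[i], sum(ix$table$case)),
                            fmt_count_pct(ix$table$control[i],
                                          sum(ix$table$control)),
                            orcell, pcell))
    }
    d <- ix$delta
    out <- c(out, sprintf("| | | | | RERI | %.2f (%.2f-%.2f) | |",
                          d["reri", "estimate"], d["reri", "ci_low"],
                          d["reri", "ci_high"]))
    out <- c(out, sprintf("| | | | | AP | %.2f (%.2f-%.2f) | |",
                          d["ap", "estimate"], d["ap", "ci_low"],
                          d["ap", "ci_high"]))
    out <- c(out, if (isTRUE(d["si", "defined"])) {
      sprintf("| | | | | SI | %.2f (%.2f-%.2f) | |", d["si", "estimate"],
              d["si", "ci_low"], d["si", "ci_high"])
    } else "| | | | | SI | undefined | |")
  }
  out
}
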