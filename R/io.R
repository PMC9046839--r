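# Participant CSV I/O with a fixed column dictionary and row-level
# validation.  Missing genotype cells are parsed as missing, never 0.

#' Read a participant CSV
#'
#' Columns must be exactly the fixed dictionary: id, migration, sex,
#' age, age_group, bmi, weight_class, education, income, smoking,
#' drinking, occupational_pa, leisure_exercise, plus one
#' `<marker>_genotype` integer column per marker (empty or `NA` cells
#' become missing genotypes).  Unknown columns are an error listing
#' them; malformed or out-of-range numeric values are collected into
#' row-level validation errors.
#'
#' @param path CSV file path.
#' @return A participant data frame.
#' @export
read_participants <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = character(0))
  geno_cols <- grep("_genotype$", names(raw), value = TRUE)
  base_cols <- .participant_columns()
  unknown <- setdiff(names(raw), c(base_cols, geno_cols))
  if (length(unknown) > 0L) {
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(base_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }

  errors <- character(0)
  parse_num <- function(col, lo, hi) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    for (i in bad) {
      errors <<- c(errors, sprintf("row %d, column %s: '%s' is not numeric",
                                   i, col, raw[[col]][i]))
    }
    oor <- which(!is.na(v) & (v < lo | v > hi))
    for (i in oor) {
      errors <<- c(errors, sprintf("row %d, column %s: %s outside [%s, %s]",
                                   i, col, raw[[col]][i], lo, hi))
    }
    v
  }
  out <- raw
  out$age <- parse_num("age", 20, 80)
  out$bmi <- parse_num("bmi", 10, 80)
  for (col in geno_cols) {
    v <- raw[[col]]
    g <- suppressWarnings(as.integer(v))
    g[v %in% c("", "NA")] <- NA_integer_
    bad <- which(is.na(g) & !(v %in% c("", "NA")))
    for (i in bad) {
      errors <- c(errors, sprintf("row %d, column %s: '%s' is not a genotype",
                                  i, col, v[i]))
    }
    oor <- which(!is.na(g) & !(g %in% 0:2))
    for (i in oor) {
      errors <- c(errors, sprintf("row %d, column %s: genotype %s not in {0,1,2}",
                                  i, col, v[i]))
    }
    out[[col]] <- g
  }
  for (nm in names(.participant_levels)) {
    bad <- which(!(out[[nm]] %in% .participant_levels[[nm]]))
    for (i in bad) {
      errors <- c(errors, sprintf("row %d, column %s: '%s' is not a valid category",
                                  i, nm, out[[nm]][i]))
    }
  }
  if (length(errors) > 0L) {
    stop("validation errors in ", path, ":\n  ",
         paste(errors, collapse = "\n  "))
  }
  out
}

#' Write a participant CSV
#'
#' Inverse of [read_participants()]: writing then reading returns
#' identical records.  Missing genotypes are written as empty cells.
#'
#' @param records Participant data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
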