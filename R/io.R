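#' Read and write long-format concentration records
#'
#' The canonical interchange CSV is tidy/long with one measured
#' concentration per row and columns `compound`, `matrix` (`"SW"` surface
#' water or `"PW"` porewater), `sampler` (`"A"`..`"D"` for PW rows, blank
#' for SW), `flume`, `day`, `concentration` (ug/L) and `below_loq`
#' (`TRUE` where the raw value was below the limit of quantification and
#' the stored value is the substituted `LOQ * 2^-0.5`). A leading comment
#' line declares the units (`ug/L`, days); times are converted to hours at
#' this I/O boundary only.
#'
#' @param path CSV file path.
#' @return `read_concentrations()`: a validated data frame of records.
#' @export
read_concentrations <- function(path) {
  records <- utils::read.csv(path, comment.char = "#",
                             colClasses = c(compound = "character",
                                            matrix = "character",
                                            sampler = "character"))
  validate_concentration_records(records)
}

#' @rdname read_concentrations
#' @param records a data frame of concentration records.
#' @export
write_concentrations <- function(records, path) {
  records <- validate_concentration_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: concentration = ug/L, day = d since injection", con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_concentrations
#' @export
validate_concentration_records <- function(records) {
  needed <- c("compound", "matrix", "sampler", "flume", "day",
              "concentration", "below_loq")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  records$sampler[is.na(records$sampler)] <- ""
  bad <- function(cond, what) {
    if (any(cond))
      stop(sprintf("%s in rows: %s", what,
                   paste(which(cond), collapse = ", ")))
  }
  bad(!records$matrix %in% c("SW", "PW"), "matrix must be SW or PW")
  bad(records$matrix == "PW" & !records$sampler %in% c("A", "B", "C", "D"),
      "PW records require a sampler A-D")
  bad(records$matrix == "SW" & records$sampler != "",
      "SW records must have a blank sampler")
  bad(records$day < 0, "negative day")
  bad(records$concentration < 0, "negative concentration")
  key <- paste(records$compound, records$matrix, records$sampler,
               records$flume, records$day)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  bad(dup, "duplicate (compound, matrix, sampler, flume, day) key")
  records$below_loq <- as.logical(records$below_loq)
  records
}

#' Convert a synthetic dataset to/from concentration records
#'
#' `records_from_dataset()` flattens a [simulate_dataset()] result into the
#' long CSV schema (surface water as `matrix = "SW"`, porewater samplers
#' `A`..`D` mapped from flowpaths `a`..`d`); `dataset_from_records()`
#' rebuilds the nested observation/boundary structure, converting days to
#' hours and recovering each compound's LOQ from its censored rows (the
#' substitution rule makes `LOQ = value * sqrt(2)`; compounds with no
#' censored rows get `LOQ = 0`).
#'
#' @param dataset a `synthetic_dataset` (see [simulate_dataset()]).
#' @return A data frame of records / a list with `observations`,
#'   `boundaries`, `flowpaths`.
#' @export
records_from_dataset <- function(dataset) {
  rows <- list()
  for (cmp in names(dataset$boundaries)) {
    b <- dataset$boundaries[[cmp]]
    rows[[length(rows) + 1L]] <- data.frame(
      compound = cmp, matrix = "SW", sampler = "", flume = 1L,
      day = b$times / 24, concentration = b$concentrations,
      below_loq = FALSE)
  }
  for (cmp in names(dataset$observations)) {
    for (fp in names(dataset$observations[[cmp]])) {
      o <- dataset$observations[[cmp]][[fp]]
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp, matrix = "PW", sampler = toupper(fp), flume = 1L,
        day = o$times / 24, concentration = o$concentrations,
        below_loq = o$censored)
    }
  }
  validate_concentration_records(do.call(rbind, rows))
}

#' @rdname records_from_dataset
#' @param records a validated record data frame.
#' @param flowpaths named list of [flowpath_geometry()]s keyed by
#'   lower-case sampler letters.
#' @export
dataset_from_records <- function(records, flowpaths = default_flowpaths()) {
  records <- validate_concentration_records(records)
  observations <- list(); boundaries <- list()
  for (cmp in unique(records$compound)) {
    sw <- records[records$compound == cmp & records$matrix == "SW", ]
    if (nrow(sw) == 0L) stop("no SW boundary record for compound ", cmp)
    sw <- sw[order(sw$day), ]
    boundaries[[cmp]] <- boundary_series(sw$day * 24, sw$concentration)
    pw <- records[records$compound == cmp & records$matrix == "PW", ]
    if (nrow(pw) == 0L) next
    observations[[cmp]] <- list()
    for (smp in sort(unique(pw$sampler))) {
      sub <- pw[pw$sampler == smp, ]
      sub <- sub[order(sub$day), ]
      loq <- if (any(sub$below_loq))
        sub$concentration[sub$below_loq][1] * sqrt(2) else 0
      observations[[cmp]][[tolower(smp)]] <- observation_set(
        cmp, tolower(smp), sub$day * 24, sub$concentration,
        loq = loq, censored = sub$below_loq)
    }
  }
  list(observations = observations, boundaries = boundaries,
       flowpaths = flowpaths)
}
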