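# Plain-CSV serialisation of worker and day tables. Numeric cells are
# written with %.17g so a write -> read round trip reproduces the doubles
# exactly; missing values are empty cells, never zeros.

.worker_numeric_cols <- function()
  c("age", "work_hours", "bmi", "exertion", "pain_regions",
    "pain_intensity", "pain_interference", "influence", "support",
    "n_children", "worker_child_ratio", "staff_ratio",
    "ilr1", "ilr2", "sb", "lpa", "mvpa")

.day_numeric_cols <- function()
  c("day", "work_hours", "sb_hours", "lpa_hours", "mvpa_hours")

.write_table <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    col <- out[[nm]]
    out[[nm]] <- if (is.numeric(col)) {
      ifelse(is.na(col), "", sprintf("%.17g", col))
    } else {
      ifelse(is.na(col), "", as.character(col))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

.read_table <- function(path, numeric_cols, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("malformed header in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (nm in intersect(numeric_cols, names(df))) {
    raw <- df[[nm]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                   raw[bad[1]], nm, bad[1], basename(path)))
    df[[nm]] <- val
  }
  df
}

#' Write / read a worker table as CSV
#'
#' The worker table holds one row per worker: hierarchy ids
#' (`institution`, `team`, `worker`), the 15 determinants, and (when
#' present) ilr coordinates and the aggregated behaviour composition.
#' Missing determinant values round-trip as empty cells.
#'
#' @param workers Worker data frame.
#' @param path File path.
#' @return `writeWorkers` returns the path invisibly; `readWorkers` the
#'   data frame. Reading fails with an informative error on a malformed
#'   header, a non-numeric cell (naming row and column) or a duplicated
#'   worker id.
#' @export
writeWorkers <- function(workers, path) {
  stopifnot(all(c("institution", "team", "worker") %in% names(workers)))
  .write_table(workers, path)
}

#' @rdname writeWorkers
#' @export
readWorkers <- function(path) {
  df <- .read_table(path, .worker_numeric_cols(),
                    required = c("institution", "team", "worker"))
  dup <- unique(df$worker[duplicated(df$worker)])
  if (length(dup))
    stop("duplicated worker id(s) in ", basename(path), ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  team_inst <- unique(df[, c("institution", "team")])
  if (anyDuplicated(team_inst$team))
    stop("team id(s) appear under more than one institution in ",
         basename(path))
  df
}

#' Write / read a per-day record table as CSV
#'
#' One row per measured worker-day: `worker`, `day`, total `work_hours`
#' and the hours spent in each behaviour (`sb_hours`, `lpa_hours`,
#' `mvpa_hours`).
#'
#' @param days Day-record data frame.
#' @param path File path.
#' @return `writeDays` returns the path invisibly; `readDays` the data
#'   frame.
#' @export
writeDays <- function(days, path) {
  stopifnot(all(c("worker", "day", "work_hours") %in% names(days)))
  .write_table(days, path)
}

#' @rdname writeDays
#' @export
readDays <- function(path) {
  df <- .read_table(path, .day_numeric_cols(),
                    required = c("worker", "day", "work_hours",
                                 "sb_hours", "lpa_hours", "mvpa_hours"))
  if (anyDuplicated(df[, c("worker", "day")]))
    stop("duplicated worker/day pair(s) in ", basename(path))
  df
}

#' Write / read a simulated study as a two-file CSV dataset
#'
#' Serialises a study (or any list with `workers` and `days` data frames)
#' to `workers.csv` and `days.csv` in a directory.
#'
#' @param study A `codatime_study` or list with `workers` and `days`.
#' @param dir Directory (created if needed).
#' @return `writeDataset` returns `dir` invisibly; `readDataset` a list
#'   with `workers` and `days`.
#' @export
writeDataset <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeWorkers(study$workers, file.path(dir, "workers.csv"))
  writeDays(study$days, file.path(dir, "days.csv"))
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  list(workers = readWorkers(file.path(dir, "workers.csv")),
       days = readDays(file.path(dir, "days.csv")))
}
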