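# From daily accelerometer records to one analysis row per worker:
# validity filtering, per-day closure and zero replacement, compositional
# aggregation, and complete-case filtering on the determinants.

#' Keep only valid measurement days
#'
#' A workday is valid if it contains at least `min_work_hours` hours of
#' work-time measurement (closed bound: a day of exactly the threshold is
#' kept). Workers whose days are all invalid are reported in the
#' `excluded_workers` attribute rather than silently dropped.
#'
#' @param days Day-record data frame (see [readDays()]).
#' @param min_work_hours Validity threshold in hours (default 4, must be
#'   positive).
#' @return The retained day records, with attributes `n_dropped` (days
#'   removed) and `excluded_workers` (ids left with zero valid days).
#' @export
filterValidDays <- function(days, min_work_hours = 4) {
  if (!is.numeric(min_work_hours) || min_work_hours <= 0)
    stop("min_work_hours must be positive")
  keep <- days$work_hours >= min_work_hours
  out <- days[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "excluded_workers") <- setdiff(days$worker, out$worker)
  out
}

#' Aggregate daily records into one composition per worker
#'
#' Each valid day's behaviour hours are closed to a composition (after
#' multiplicative zero replacement across the day table), and days are
#' averaged per worker. The default aggregation is the compositional
#' (geometric-mean) centre of the daily compositions; an arithmetic mean
#' of the closed daily compositions is available for sensitivity
#' analysis.
#'
#' @param days Valid day records.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return Data frame with one row per worker: `worker`, `n_days`,
#'   `work_hours_gm` (geometric-mean daily work duration), the aggregated
#'   composition `sb`, `lpa`, `mvpa`, and its ilr coordinates `ilr1`,
#'   `ilr2`.
#' @export
aggregateWorkers <- function(days, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (nrow(days) == 0L) stop("no valid days to aggregate")
  comp <- closeComposition(cbind(sb = days$sb_hours, lpa = days$lpa_hours,
                                  mvpa = days$mvpa_hours))
  comp <- replaceZeros(comp)
  ids <- unique(days$worker)
  agg <- t(vapply(ids, function(w) {
    rows <- comp[days$worker == w, , drop = FALSE]
    if (method == "geometric") geometricMeanComposition(rows)
    else closeComposition(colMeans(rows))
  }, numeric(3)))
  colnames(agg) <- behaviourParts()
  n_days <- as.vector(table(factor(days$worker, levels = ids)))
  hours_gm <- vapply(ids, function(w)
    exp(mean(log(days$work_hours[days$worker == w]))), numeric(1))
  data.frame(worker = ids, n_days = n_days, work_hours_gm = hours_gm,
             agg, ilrTransform(agg), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Complete-case filter on required determinants
#'
#' Retains only workers with observed values for every required
#' determinant, as the association models need. The number of rows lost
#' to each determinant is attached for attrition logging.
#'
#' @param workers Worker table.
#' @param required Character vector of determinant columns that must be
#'   non-missing (default: all 15 from [determinantCatalogue()]).
#' @return The complete-case rows, with attribute `n_missing` (named
#'   count of missing values per required determinant) and `n_dropped`.
#' @export
completeCaseFilter <- function(workers,
                               required = determinantCatalogue()$name) {
  absent <- setdiff(required, names(workers))
  if (length(absent))
    stop("required determinant(s) not present in the worker table: ",
         paste(absent, collapse = ", "))
  miss <- vapply(required, function(nm) sum(is.na(workers[[nm]])),
                 integer(1))
  keep <- !Reduce(`|`, lapply(required, function(nm) is.na(workers[[nm]])))
  out <- workers[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no complete cases remain; relax the required determinant set")
  rownames(out) <- NULL
  attr(out, "n_missing") <- miss
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Preprocess a study into analysis-ready worker records
#'
#' Chains the full preprocessing path: validity filtering of days,
#' per-day closure with zero replacement, per-worker compositional
#' aggregation, and a join back onto the worker determinant table.
#' Workers without any valid day are excluded (and reported).
#'
#' @param workers Worker table (hierarchy ids + determinants).
#' @param days Day records for those workers.
#' @param min_work_hours Validity threshold in hours (default 4).
#' @param aggregation `"geometric"` (default) or `"arithmetic"`.
#' @return Worker table restricted to workers with valid days, with the
#'   aggregated `sb`, `lpa`, `mvpa`, `ilr1`, `ilr2`, `n_days` and
#'   `work_hours_gm` columns replaced by the day-derived values.
#'   Attributes `n_days_dropped` and `excluded_workers` carry the
#'   attrition counts.
#' @export
preprocessStudy <- function(workers, days, min_work_hours = 4,
                            aggregation = c("geometric", "arithmetic")) {
  aggregation <- match.arg(aggregation)
  valid <- filterValidDays(days, min_work_hours)
  agg <- aggregateWorkers(valid, aggregation)
  drop_cols <- intersect(names(workers),
                         c("sb", "lpa", "mvpa", "ilr1", "ilr2",
                           "n_days", "work_hours_gm"))
  base <- workers[, setdiff(names(workers), drop_cols), drop = FALSE]
  out <- merge(base, agg, by = "worker", sort = FALSE)
  out <- out[order(match(out$worker, workers$worker)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_days_dropped") <- attr(valid, "n_dropped")
  attr(out, "excluded_workers") <-
    setdiff(workers$worker, agg$worker)
  out
}
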