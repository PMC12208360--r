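#' Determinant catalogue for the simulated study
#'
#' Metadata for the 15 determinants measured at the worker, team and
#' institution levels: the organisational level, the variable kind
#' (continuous or binary), the target marginal mean and SD (continuous) or
#' event probability (binary), and the admissible range. Continuous
#' determinants are simulated from truncated normal distributions whose
#' parameters are moment-matched so the realised mean equals the target
#' mean within its range; binary determinants are Bernoulli draws encoded
#' as two-level factors.
#'
#' @return A data frame with one row per determinant: `name`, `level`,
#'   `kind`, `mean`, `sd`, `lower`, `upper`, `prob`, `level1`, `level2`
#'   (factor levels; `level1` is the reference).
#' @export
determinantCatalogue <- function() {
  d <- function(name, level, kind, mean = NA, sd = NA, lower = NA,
                upper = NA, prob = NA, level1 = NA, level2 = NA)
    data.frame(name = name, level = level, kind = kind, mean = mean,
               sd = sd, lower = lower, upper = upper, prob = prob,
               level1 = level1, level2 = level2,
               stringsAsFactors = FALSE)
  rbind(
    d("age",                "worker", "continuous", 36.5, 11.7, 18, 70),
    d("sex",                "worker", "binary", prob = 0.843,
      level1 = "male", level2 = "female"),
    d("work_hours",         "worker", "continuous", 35.0, 2.6, 20, 45),
    d("job_type",           "worker", "binary", prob = 0.433,
      level1 = "pedagogue", level2 = "non-pedagogue"),
    d("bmi",                "worker", "continuous", 25.3, 5.3, 16, 50),
    d("exertion",           "worker", "continuous", 5.9, 1.8, 0, 10),
    d("pain_regions",       "worker", "continuous", 2.5, 1.8, 0, 8),
    d("pain_intensity",     "worker", "continuous", 5.6, 2.5, 0, 10),
    d("pain_interference",  "worker", "continuous", 3.5, 6.6, 0, 28),
    d("influence",          "worker", "continuous", 69.8, 14.9, 0, 100),
    d("support",            "worker", "continuous", 70.8, 14.3, 0, 100),
    d("n_children",         "team",   "continuous", 12.0, 0.9, 6, 18),
    d("worker_child_ratio", "team",   "continuous", 0.3, 0.09, 0.05, 1),
    d("institution_type",   "institution", "binary", prob = 0.625,
      level1 = "private", level2 = "public"),
    d("staff_ratio",        "institution", "continuous", 0.3, 0.2, 0, 1.5)
  )
}

# truncated-normal moments on [a, b] for underlying N(mu, sigma^2),
# by quadrature against the in-range renormalised density: accurate even
# when [a, b] sits far in the tail, where the Mills-ratio formulas fail
.tn_moments <- function(mu, sigma, a, b) {
  x0 <- min(max(mu, a), b) # density maximum within the range
  f0 <- function(x) exp((((x0 - mu) / sigma)^2 - ((x - mu) / sigma)^2) / 2)
  Z <- stats::integrate(f0, a, b, rel.tol = 1e-12)$value
  m <- stats::integrate(function(x) x * f0(x), a, b,
                        rel.tol = 1e-12)$value / Z
  v <- stats::integrate(function(x) (x - m)^2 * f0(x), a, b,
                        rel.tol = 1e-12)$value / Z
  c(mean = m, sd = sqrt(max(v, 0)))
}

# choose (mu, sigma) so the truncated mean hits `mean` exactly and the
# truncated sd is as close to `sd` as the family allows on [a, b]
.match_truncnorm <- function(mean, sd, a, b) {
  if (!is.finite(sd) || sd <= 0) return(c(mu = mean, sigma = 0))
  stopifnot(mean > a, mean < b)
  solve_mu <- function(sigma) {
    stats::uniroot(function(mu) .tn_moments(mu, sigma, a, b)["mean"] - mean,
                   lower = a - 15 * sigma, upper = b + 15 * sigma,
                   tol = 1e-10)$root
  }
  obj <- function(lsig) {
    sigma <- exp(lsig)
    mu <- solve_mu(sigma)
    (.tn_moments(mu, sigma, a, b)["sd"] - sd)^2
  }
  opt <- stats::optimize(obj, interval = log(c(0.2 * sd, 5 * sd)))
  sigma <- exp(opt$minimum)
  c(mu = solve_mu(sigma), sigma = sigma)
}

# sample() treats a scalar first argument as 1:x; guard against that
.sample_counts <- function(x, n, prob = NULL) {
  if (length(x) == 1L) rep(x, n)
  else sample(x, n, replace = TRUE, prob = prob)
}

# inverse-CDF truncated normal sampler (mirrored for numerical stability)
.rtruncnorm <- function(n, mu, sigma, a, b) {
  if (sigma == 0) return(rep(mu, n))
  u <- stats::runif(n)
  if (mu < (a + b) / 2) { # mirror so qnorm works in the precise tail
    lo <- stats::pnorm((-b + mu) / sigma)
    hi <- stats::pnorm((-a + mu) / sigma)
    -(stats::qnorm(lo + u * (hi - lo)) * sigma - mu)
  } else {
    lo <- stats::pnorm((a - mu) / sigma)
    hi <- stats::pnorm((b - mu) / sigma)
    stats::qnorm(lo + u * (hi - lo)) * sigma + mu
  }
}

#' Simulation configuration for a hierarchical time-use study
#'
#' Defines the study conditions the generator emulates: a multi-site
#' occupational study with 16 institutions, about 73 teams and about 178
#' workers, daily accelerometer records over 1 to 5 workdays, nested
#' random intercepts on the ilr scale, and determinant marginals from the
#' catalogue in [determinantCatalogue()].
#'
#' @param n_institutions Number of institutions (default 16).
#' @param teams_per_institution Integer vector of candidate team counts
#'   per institution, sampled uniformly (default `4:5`, giving ~73 teams
#'   over 16 institutions).
#' @param workers_per_team Candidate worker counts per team
#'   (default `2:4`) with sampling probabilities `workers_per_team_prob`
#'   (default `c(0.60, 0.35, 0.05)`, mean 2.45, giving ~178 workers).
#' @param var_worker,var_team,var_institution Random-intercept variances
#'   per ilr coordinate at each level (defaults 0.079, 0.0017, 0.0021).
#' @param beta Named list of fixed effects: each element a length-2 vector
#'   `c(ilr1, ilr2)` giving the per-unit effect of a determinant on the
#'   two ilr coordinates. Defaults: exertion `c(-0.03, 0)`, pain
#'   intensity `c(0.03, 0)`, all others 0. Binary determinants act
#'   through their non-reference level indicator.
#' @param grand_mean_composition Population centre of the behaviour
#'   composition (default `c(0.4767, 0.4000, 0.1233)`).
#' @param days_per_worker Candidate numbers of measured workdays
#'   (default `1:5`) with probabilities `days_per_worker_prob`
#'   (default `c(0.10, 0.15, 0.25, 0.35, 0.15)`, mean 3.3 days).
#' @param work_hours_gm Geometric-mean daily work duration in hours
#'   (default 6.61); daily hours are lognormal with `work_hours_sdlog`
#'   (default 0.25) so a small share of days falls under the 4-hour
#'   validity threshold.
#' @param day_sd Day-level SD around the worker's ilr value, per
#'   coordinate (default 0.1).
#' @param missing_rate Per-determinant probability that a worker-level
#'   questionnaire value is missing (default 0.0125, so roughly 87% of
#'   workers are complete cases, mirroring the attrition from 178 to
#'   about 155 analysable workers).
#' @param seed Default random seed used by [simulateStudy()] when no seed
#'   is passed explicitly.
#' @return An object of class `codatime_config` (a validated list, with
#'   truncated-normal parameters resolved for every continuous
#'   determinant).
#' @export
simConfig <- function(n_institutions = 16,
                      teams_per_institution = 4:5,
                      workers_per_team = 2:4,
                      workers_per_team_prob = c(0.60, 0.35, 0.05),
                      var_worker = 0.079,
                      var_team = 0.0017,
                      var_institution = 0.0021,
                      beta = NULL,
                      grand_mean_composition = c(0.4767, 0.4000, 0.1233),
                      days_per_worker = 1:5,
                      days_per_worker_prob = c(0.10, 0.15, 0.25, 0.35, 0.15),
                      work_hours_gm = 6.61,
                      work_hours_sdlog = 0.25,
                      day_sd = 0.1,
                      missing_rate = 0.0125,
                      seed = 1L) {
  cat_ <- determinantCatalogue()
  if (n_institutions < 1) stop("infeasible config: need at least 1 institution")
  if (any(teams_per_institution < 1)) stop("infeasible config: zero teams")
  if (any(workers_per_team < 1)) stop("infeasible config: zero workers per team")
  if (length(workers_per_team_prob) != length(workers_per_team) ||
      any(workers_per_team_prob < 0))
    stop("workers_per_team_prob must be non-negative, one per candidate count")
  if (length(days_per_worker_prob) != length(days_per_worker) ||
      any(days_per_worker_prob < 0))
    stop("days_per_worker_prob must be non-negative, one per candidate count")
  if (any(c(var_worker, var_team, var_institution) < 0))
    stop("variances must be non-negative")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (day_sd < 0) stop("day_sd must be non-negative")
  gm <- closeComposition(grand_mean_composition)

  full_beta <- stats::setNames(
    rep(list(c(0, 0)), nrow(cat_)), cat_$name)
  if (!is.null(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% cat_$name))
      stop("beta names must be determinant names: ",
           paste(setdiff(names(beta), cat_$name), collapse = ", "))
    for (nm in names(beta)) {
      b <- beta[[nm]]
      if (length(b) == 1L) b <- c(b, 0)
      stopifnot(length(b) == 2L, all(is.finite(b)))
      full_beta[[nm]] <- as.numeric(b)
    }
  } else {
    full_beta[["exertion"]] <- c(-0.03, 0)
    full_beta[["pain_intensity"]] <- c(0.03, 0)
  }

  tn <- lapply(seq_len(nrow(cat_)), function(i) {
    if (cat_$kind[i] != "continuous") return(NULL)
    .match_truncnorm(cat_$mean[i], cat_$sd[i], cat_$lower[i], cat_$upper[i])
  })
  names(tn) <- cat_$name

  structure(list(
    n_institutions = as.integer(n_institutions),
    teams_per_institution = as.integer(teams_per_institution),
    workers_per_team = as.integer(workers_per_team),
    workers_per_team_prob = workers_per_team_prob / sum(workers_per_team_prob),
    var_worker = var_worker, var_team = var_team,
    var_institution = var_institution,
    beta = full_beta,
    grand_mean_composition = gm,
    grand_mean_ilr = ilrTransform(gm),
    days_per_worker = as.integer(days_per_worker),
    days_per_worker_prob = days_per_worker_prob / sum(days_per_worker_prob),
    work_hours_gm = work_hours_gm,
    work_hours_sdlog = work_hours_sdlog,
    day_sd = day_sd,
    missing_rate = missing_rate,
    catalogue = cat_,
    truncnorm = tn,
    seed = as.integer(seed)
  ), class = "codatime_config")
}

#' @export
print.codatime_config <- function(x, ...) {
  cat("Hierarchical time-use simulation configuration\n")
  cat(sprintf("  institutions: %d; teams/institution: %s; workers/team: %s\n",
              x$n_institutions,
              paste(range(x$teams_per_institution), collapse = "-"),
              paste(range(x$workers_per_team), collapse = "-")))
  cat(sprintf("  ilr variances (worker/team/institution): %.4g / %.4g / %.4g\n",
              x$var_worker, x$var_team, x$var_institution))
  nz <- Filter(function(b) any(b != 0), x$beta)
  cat("  nonzero fixed effects:",
      if (length(nz)) paste(names(nz), collapse = ", ") else "none", "\n")
  cat(sprintf("  grand-mean composition: %.4f / %.4f / %.4f (sb/lpa/mvpa)\n",
              x$grand_mean_composition[1], x$grand_mean_composition[2],
              x$grand_mean_composition[3]))
  invisible(x)
}

#' Sample the institution/team/worker skeleton
#'
#' Draws the nested population structure: each institution receives a
#' number of teams drawn uniformly from the configured candidates, and
#' each team a number of workers from the configured count distribution.
#' Every worker belongs to exactly one team and every team to exactly one
#' institution (ids encode the nesting).
#'
#' @param config A [simConfig()] object.
#' @return Data frame with columns `institution`, `team`, `worker`.
#' @export
sampleHierarchy <- function(config) {
  stopifnot(inherits(config, "codatime_config"))
  n_teams <- .sample_counts(config$teams_per_institution,
                            config$n_institutions)
  inst_ids <- sprintf("i%02d", seq_len(config$n_institutions))
  team_inst <- rep(inst_ids, n_teams)
  team_ids <- sprintf("%s_t%d", team_inst,
                      unlist(lapply(n_teams, seq_len), use.names = FALSE))
  n_workers <- .sample_counts(config$workers_per_team, length(team_ids),
                              prob = config$workers_per_team_prob)
  data.frame(
    institution = rep(team_inst, n_workers),
    team = rep(team_ids, n_workers),
    worker = sprintf("w%04d", seq_len(sum(n_workers))),
    stringsAsFactors = FALSE
  )
}

#' Sample determinants onto a population skeleton
#'
#' Fills in the 15 determinants at their proper level: worker-level values
#' are drawn per worker, team-level per team (shared by the team's
#' workers) and institution-level per institution. Continuous determinants
#' come from moment-matched truncated normals within their admissible
#' range; binary determinants are Bernoulli draws returned as character
#' values (reference level first in the catalogue).
#'
#' @param skeleton Output of [sampleHierarchy()].
#' @param config A [simConfig()] object.
#' @return The skeleton with one column per determinant appended.
#' @export
sampleDeterminants <- function(skeleton, config) {
  stopifnot(inherits(config, "codatime_config"))
  cat_ <- config$catalogue
  out <- skeleton
  for (i in seq_len(nrow(cat_))) {
    nm <- cat_$name[i]
    unit <- switch(cat_$level[i],
                   worker = skeleton$worker,
                   team = skeleton$team,
                   institution = skeleton$institution)
    uu <- unique(unit)
    vals <- if (cat_$kind[i] == "continuous") {
      p <- config$truncnorm[[nm]]
      .rtruncnorm(length(uu), p["mu"], p["sigma"], cat_$lower[i], cat_$upper[i])
    } else {
      ifelse(stats::runif(length(uu)) < cat_$prob[i], cat_$level2[i],
             cat_$level1[i])
    }
    out[[nm]] <- vals[match(unit, uu)]
  }
  out
}

# model matrix of determinant effects, centred at the configured marginal
# means/probabilities so the grand-mean composition is the population centre
.determinant_design <- function(workers, config) {
  cat_ <- config$catalogue
  X <- matrix(0, nrow(workers), nrow(cat_),
              dimnames = list(NULL, cat_$name))
  for (i in seq_len(nrow(cat_))) {
    nm <- cat_$name[i]
    X[, i] <- if (cat_$kind[i] == "continuous") {
      workers[[nm]] - cat_$mean[i]
    } else {
      (workers[[nm]] == cat_$level2[i]) - cat_$prob[i]
    }
  }
  X
}

#' Simulate behaviour outcomes for a determinant-filled population
#'
#' Generates each worker's latent ilr coordinates as
#' `grand-mean ilr + X beta + u_institution + u_team + e_worker`, with
#' mean-zero Gaussian random intercepts at the configured variances
#' (independently per coordinate), then draws 1-5 daily records per
#' worker: day-level Gaussian noise around the worker value, lognormal
#' daily work hours, and behaviour durations obtained by mapping the day's
#' ilr through the inverse transformation and multiplying by the day's
#' work hours.
#'
#' @param workers Output of [sampleDeterminants()].
#' @param config A [simConfig()] object.
#' @return List with `workers` (input plus latent `ilr1`, `ilr2` and the
#'   worker-level composition `sb`, `lpa`, `mvpa`) and `days` (one row
#'   per worker-day: `worker`, `day`, `work_hours`, `sb_hours`,
#'   `lpa_hours`, `mvpa_hours`).
#' @export
sampleOutcomes <- function(workers, config) {
  stopifnot(inherits(config, "codatime_config"))
  n <- nrow(workers)
  X <- .determinant_design(workers, config)
  B <- do.call(rbind, config$beta) # determinants x 2
  fixed <- X %*% B

  u_i <- matrix(stats::rnorm(2 * length(unique(workers$institution)),
                             sd = sqrt(config$var_institution)), ncol = 2)
  u_t <- matrix(stats::rnorm(2 * length(unique(workers$team)),
                             sd = sqrt(config$var_team)), ncol = 2)
  e_w <- matrix(stats::rnorm(2 * n, sd = sqrt(config$var_worker)), ncol = 2)

  ilr <- matrix(config$grand_mean_ilr, n, 2, byrow = TRUE) + fixed +
    u_i[match(workers$institution, unique(workers$institution)), ] +
    u_t[match(workers$team, unique(workers$team)), ] + e_w
  colnames(ilr) <- c("ilr1", "ilr2")

  comp <- inverseIlr(ilr)
  out_workers <- cbind(workers, ilr, comp)

  n_days <- .sample_counts(config$days_per_worker, n,
                           prob = config$days_per_worker_prob)
  idx <- rep(seq_len(n), n_days)
  day_ilr <- ilr[idx, , drop = FALSE] +
    matrix(stats::rnorm(2 * length(idx), sd = config$day_sd), ncol = 2)
  hours <- stats::rlnorm(length(idx), meanlog = log(config$work_hours_gm),
                         sdlog = config$work_hours_sdlog)
  day_comp <- inverseIlr(day_ilr)
  days <- data.frame(
    worker = workers$worker[idx],
    day = unlist(lapply(n_days, seq_len), use.names = FALSE),
    work_hours = hours,
    sb_hours = day_comp[, "sb"] * hours,
    lpa_hours = day_comp[, "lpa"] * hours,
    mvpa_hours = day_comp[, "mvpa"] * hours,
    stringsAsFactors = FALSE
  )
  list(workers = out_workers, days = days)
}

# knock out worker-level questionnaire determinants at the configured rate
.add_missingness <- function(workers, config) {
  if (config$missing_rate <= 0) return(workers)
  cat_ <- config$catalogue
  for (nm in cat_$name[cat_$level == "worker"]) {
    hit <- stats::runif(nrow(workers)) < config$missing_rate
    workers[[nm]][hit] <- NA
  }
  workers
}

#' Simulate a complete hierarchical time-use study
#'
#' Runs the full generator: hierarchy, determinants, outcomes and daily
#' records, then masks a small fraction of worker-level determinant
#' values as missing (questionnaire non-response). The same seed and
#' configuration always reproduce the identical dataset.
#'
#' @param config A [simConfig()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List of class `codatime_study` with elements `workers`,
#'   `days`, `config` and `seed`.
#' @export
simulateStudy <- function(config = simConfig(), seed = config$seed) {
  stopifnot(inherits(config, "codatime_config"))
  set.seed(as.integer(seed))
  skel <- sampleHierarchy(config)
  workers <- sampleDeterminants(skel, config)
  sim <- sampleOutcomes(workers, config)
  sim$workers <- .add_missingness(sim$workers, config)
  structure(list(workers = sim$workers, days = sim$days,
                 config = config, seed = as.integer(seed)),
            class = "codatime_study")
}

#' @export
print.codatime_study <- function(x, ...) {
  cat(sprintf(
    "Simulated time-use study (seed %d): %d workers, %d teams, %d institutions, %d worker-days\n",
    x$seed, nrow(x$workers), length(unique(x$workers$team)),
    length(unique(x$workers$institution)), nrow(x$days)))
  invisible(x)
}
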