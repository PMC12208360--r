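# Multilevel analysis of the ilr-transformed behaviour composition:
# variance components across institution/team/worker, association models
# for the whole composition (both ilr coordinates) and for each
# behaviour's dominance (pivot models), and back-transformed prediction
# curves. REML fitting is delegated to lme4; the compositional outcome
# construction, coordinate stacking, joint tests and percentage-change
# translation live here.

.require_ilr <- function(workers) {
  if (!all(c("ilr1", "ilr2") %in% names(workers))) {
    comp <- replaceZeros(closeComposition(
      workers[, behaviourParts(), drop = FALSE]))
    workers[, c("ilr1", "ilr2")] <- ilrTransform(comp)
  }
  workers
}

.check_hierarchy <- function(workers) {
  for (col in c("institution", "team", "worker"))
    if (!col %in% names(workers)) stop("missing hierarchy column: ", col)
  if (length(unique(workers$institution)) < 2L)
    stop("degenerate design: need at least 2 institutions")
  workers_per_team <- table(workers$team)
  if (max(workers_per_team) == 1L)
    stop("degenerate design: every team has a single worker, so the ",
         "team component is confounded with worker-level variance")
  teams_per_inst <- tapply(workers$team, workers$institution,
                           function(x) length(unique(x)))
  if (max(teams_per_inst) == 1L)
    stop("degenerate design: every institution has a single team, so the ",
         "team and institution components are confounded")
  invisible(TRUE)
}

.lmer_quiet <- function(formula, data) {
  # bobyqa with a tight end trust-region radius: reproduces closed-form
  # ANOVA variance components on balanced designs to ~1e-8
  ctl <- lme4::lmerControl(optimizer = "bobyqa",
                           calc.derivs = FALSE,
                           check.conv.singular = "ignore",
                           optCtrl = list(rhoend = 1e-10))
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(formula, data = data, REML = TRUE, control = ctl),
             error = function(e) stop("mixed-model fit failed: ",
                                      conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("conv", conditionMessage(w), ignore.case = TRUE))
        invokeRestart("muffleWarning")
    })
  fit
}

#' Variance component analysis of the behaviour composition
#'
#' Decomposes the total variance of the ilr-transformed composition into
#' contributions from the institution, team-within-institution and worker
#' levels. The two ilr coordinates are stacked as repeated outcomes
#' sharing one variance parameter per level (a coordinate-specific fixed
#' mean, and independent random intercepts per coordinate at the
#' institution and team levels), so the decomposition yields a single
#' estimate per organisational level; worker-level variance is the
#' residual. Estimation is by REML; negative components are truncated at
#' zero by the non-negativity constraint of the fit.
#'
#' @param workers Analysis-ready worker table with hierarchy ids and
#'   either `ilr1`/`ilr2` or a strictly positive `sb`/`lpa`/`mvpa`
#'   composition.
#' @return An object of class `codatime_vca`: variance `estimates` and
#'   percentage `contributions` per level (worker, team, institution),
#'   the `total`, a `per_coordinate` diagnostic decomposition, and the
#'   sample sizes.
#' @export
fitVca <- function(workers) {
  workers <- .require_ilr(workers)
  .check_hierarchy(workers)
  n <- nrow(workers)
  long <- data.frame(
    y = c(workers$ilr1, workers$ilr2),
    coord = rep(c("ilr1", "ilr2"), each = n),
    institution = rep(workers$institution, 2L),
    team = rep(workers$team, 2L),
    stringsAsFactors = FALSE
  )
  long$inst_c <- interaction(long$institution, long$coord, drop = TRUE)
  long$team_c <- interaction(long$team, long$coord, drop = TRUE)
  fit <- .lmer_quiet(y ~ 0 + coord + (1 | inst_c) + (1 | team_c), long)
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- c(
    worker = vc$vcov[vc$grp == "Residual"],
    team = vc$vcov[vc$grp == "team_c"],
    institution = vc$vcov[vc$grp == "inst_c"]
  )
  total <- sum(est)
  per_coord <- vapply(c("ilr1", "ilr2"), function(cc) {
    sub <- workers
    sub$y <- if (cc == "ilr1") workers$ilr1 else workers$ilr2
    f <- .lmer_quiet(y ~ 1 + (1 | institution) + (1 | institution:team), sub)
    v <- as.data.frame(lme4::VarCorr(f))
    c(worker = v$vcov[v$grp == "Residual"],
      team = v$vcov[v$grp == "institution:team"],
      institution = v$vcov[v$grp == "institution"])
  }, numeric(3))
  structure(list(
    estimates = est,
    contributions = 100 * est / total,
    total = total,
    per_coordinate = per_coord,
    n = c(workers = n, teams = length(unique(workers$team)),
          institutions = length(unique(workers$institution))),
    REMLcrit = stats::deviance(fit, REML = TRUE)
  ), class = "codatime_vca")
}

#' @export
print.codatime_vca <- function(x, ...) {
  cat(sprintf(
    "Variance components of the ilr-transformed behaviour composition\n(%d workers, %d teams, %d institutions)\n\n",
    x$n["workers"], x$n["teams"], x$n["institutions"]))
  tab <- data.frame(
    Level = c("Worker", "Team", "Institution", "Total"),
    Estimate = signif(c(x$estimates, x$total), 3),
    `Contribution (%)` = sprintf("%.1f",
      c(x$contributions, 100)), check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

# ---- association models ------------------------------------------------

.prep_model_data <- function(workers, determinants) {
  workers <- .require_ilr(workers)
  .check_hierarchy(workers)
  cat_ <- determinantCatalogue()
  cat_ <- cat_[cat_$name %in% determinants, , drop = FALSE]
  absent <- setdiff(determinants, names(workers))
  if (length(absent))
    stop("determinant(s) not present: ", paste(absent, collapse = ", "))
  nmiss <- vapply(determinants, function(nm) sum(is.na(workers[[nm]])),
                  integer(1))
  if (any(nmiss > 0))
    stop("missing determinant values (",
         paste(sprintf("%s: %d", names(nmiss)[nmiss > 0],
                       nmiss[nmiss > 0]), collapse = ", "),
         "); apply completeCaseFilter() first")
  for (i in seq_len(nrow(cat_)))
    if (cat_$kind[i] == "binary") {
      nm <- cat_$name[i]
      workers[[nm]] <- factor(workers[[nm]],
                              levels = c(cat_$level1[i], cat_$level2[i]))
      if (anyNA(workers[[nm]]))
        stop("unknown level in binary determinant '", nm, "'")
    }
  rhs <- paste(determinants, collapse = " + ")
  fixed <- stats::as.formula(paste("~", rhs))
  mm <- stats::model.matrix(fixed, workers)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; collinear or constant column(s): ",
         paste(bad, collapse = ", "))
  }
  list(data = workers, rhs = rhs, fixed = fixed, mm = mm,
       catalogue = cat_, determinants = determinants)
}

# map each determinant to its fixed-effect coefficient name
.term_coef_map <- function(mm, determinants) {
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(stats::as.formula(
    paste("~", paste(determinants, collapse = "+")))), "term.labels")
  stats::setNames(lapply(seq_along(labels), function(i)
    colnames(mm)[asgn == i]), labels)
}

.coef_row <- function(fit, coef_name) {
  est <- lme4::fixef(fit)[coef_name]
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[coef_name])
  z <- est / se
  c(estimate = unname(est), se = unname(se),
    ci_lower = unname(est - stats::qnorm(0.975) * se),
    ci_upper = unname(est + stats::qnorm(0.975) * se),
    p = unname(2 * stats::pnorm(abs(z), lower.tail = FALSE)))
}

#' Whole-composition association model (both ilr coordinates)
#'
#' Fits the primary association model: each ilr coordinate regressed on
#' all determinants as fixed effects, with nested random intercepts for
#' institutions and teams within institutions, by REML. Determinants
#' enter on their raw scales (per-unit effects); reference levels are
#' male (sex), pedagogue (job type) and private (institution type). Each
#' determinant's single composition-level p-value is a 2-degree-of-
#' freedom joint Wald test of its coefficients across the two
#' coordinates (treated as independent fits); per-coordinate Wald-z
#' statistics and 95% CIs are always reported alongside.
#'
#' @param workers Complete-case analysis-ready worker table.
#' @param determinants Character vector of determinant columns (default:
#'   the full 15-variable catalogue).
#' @return Object of class `codatime_model1`: a `coefficients` data
#'   frame (per determinant and coordinate: estimate, SE, 95% CI, p;
#'   plus the joint 2-df chi-square and p), the two `lme4` fits, the
#'   model data, and sample sizes.
#' @export
fitModel1 <- function(workers, determinants = determinantCatalogue()$name) {
  prep <- .prep_model_data(workers, determinants)
  dat <- prep$data
  fits <- lapply(c("ilr1", "ilr2"), function(cc)
    .lmer_quiet(stats::as.formula(paste(
      cc, "~", prep$rhs, "+ (1 | institution) + (1 | institution:team)")),
      dat))
  names(fits) <- c("ilr1", "ilr2")
  cmap <- .term_coef_map(prep$mm, determinants)
  rows <- lapply(names(cmap), function(det) {
    cn <- cmap[[det]]
    r1 <- .coef_row(fits$ilr1, cn)
    r2 <- .coef_row(fits$ilr2, cn)
    chi2 <- (r1["estimate"] / r1["se"])^2 + (r2["estimate"] / r2["se"])^2
    data.frame(
      determinant = det,
      level = prep$catalogue$level[prep$catalogue$name == det],
      estimate_ilr1 = r1["estimate"], se_ilr1 = r1["se"],
      ci_lower_ilr1 = r1["ci_lower"], ci_upper_ilr1 = r1["ci_upper"],
      p_ilr1 = r1["p"],
      estimate_ilr2 = r2["estimate"], se_ilr2 = r2["se"],
      ci_lower_ilr2 = r2["ci_lower"], ci_upper_ilr2 = r2["ci_upper"],
      p_ilr2 = r2["p"],
      chi2_joint = unname(chi2),
      p_joint = unname(stats::pchisq(chi2, df = 2, lower.tail = FALSE)),
      row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(list(
    coefficients = do.call(rbind, rows),
    fits = fits,
    data = dat,
    determinants = determinants,
    n = c(workers = nrow(dat), teams = length(unique(dat$team)),
          institutions = length(unique(dat$institution))),
    REMLcrit = vapply(fits, stats::deviance, numeric(1), REML = TRUE)
  ), class = "codatime_model1")
}

#' @export
print.codatime_model1 <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Whole-composition mixed model (%d workers, %d teams, %d institutions)\n\n",
    x$n["workers"], x$n["teams"], x$n["institutions"]))
  co <- x$coefficients
  tab <- data.frame(
    Determinant = co$determinant,
    `ilr1 b (95% CI)` = sprintf("%.*f (%.*f, %.*f)", digits,
      co$estimate_ilr1, digits, co$ci_lower_ilr1, digits, co$ci_upper_ilr1),
    `ilr2 b (95% CI)` = sprintf("%.*f (%.*f, %.*f)", digits,
      co$estimate_ilr2, digits, co$ci_lower_ilr2, digits, co$ci_upper_ilr2),
    `joint p` = sprintf("%.3f", co$p_joint), check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Behaviour-dominance models via pivot coordinates
#'
#' Fits one mixed model per behaviour, using as outcome the first pivot
#' coordinate that contrasts that behaviour against the geometric mean of
#' the other two, with the same fixed and random structure as the
#' whole-composition model. Each coefficient is translated into the
#' percentage change in the pivot behaviour, relative to the remaining
#' behaviours, per unit of the determinant (see [percentChange()]).
#'
#' @inheritParams fitModel1
#' @param pivots Which behaviours to pivot (default all three).
#' @return Object of class `codatime_pivot_fits`: one element per pivot
#'   with a coefficient table (estimate, SE, CI, Wald-z p, percent
#'   change) and the underlying `lme4` fit.
#' @export
fitPivotModels <- function(workers,
                           determinants = determinantCatalogue()$name,
                           pivots = behaviourParts()) {
  stopifnot(all(pivots %in% behaviourParts()))
  prep <- .prep_model_data(workers, determinants)
  dat <- prep$data
  comp <- replaceZeros(closeComposition(
    dat[, behaviourParts(), drop = FALSE]))
  cmap <- .term_coef_map(prep$mm, determinants)
  out <- lapply(pivots, function(pv) {
    dat$.pivot1 <- pivotCoordinates(comp, pv)[, 1]
    fit <- .lmer_quiet(stats::as.formula(paste(
      ".pivot1 ~", prep$rhs,
      "+ (1 | institution) + (1 | institution:team)")), dat)
    rows <- lapply(names(cmap), function(det) {
      r <- .coef_row(fit, cmap[[det]])
      data.frame(determinant = det,
                 level = prep$catalogue$level[prep$catalogue$name == det],
                 estimate = r["estimate"], se = r["se"],
                 ci_lower = r["ci_lower"], ci_upper = r["ci_upper"],
                 p = r["p"],
                 percent_change = percentChange(r[["estimate"]]),
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    list(pivot = pv, coefficients = do.call(rbind, rows), fit = fit)
  })
  names(out) <- pivots
  structure(list(models = out,
                 n = c(workers = nrow(dat),
                       teams = length(unique(dat$team)),
                       institutions = length(unique(dat$institution)))),
            class = "codatime_pivot_fits")
}

#' @export
print.codatime_pivot_fits <- function(x, ...) {
  cat(sprintf(
    "Behaviour-dominance pivot models (%d workers, %d teams, %d institutions)\n",
    x$n["workers"], x$n["teams"], x$n["institutions"]))
  for (m in x$models) {
    cat(sprintf("\nPivot: %s (vs geometric mean of the others)\n",
                toupper(m$pivot)))
    co <- m$coefficients
    tab <- data.frame(
      Determinant = co$determinant,
      `b (95% CI)` = sprintf("%.2f (%.2f, %.2f)", co$estimate,
                             co$ci_lower, co$ci_upper),
      p = sprintf("%.3f", co$p),
      `% change` = sprintf("%+.1f", co$percent_change),
      check.names = FALSE)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Predicted composition along a determinant gradient
#'
#' Evaluates the whole-composition model along a grid of values of one
#' determinant, holding all other determinants at their sample mean
#' (continuous) or most frequent level (binary) and random effects at
#' zero, and maps the predicted ilr coordinates back to behaviour shares.
#' The resulting long table (determinant value, sb, lpa, mvpa) is ready
#' for ternary plotting.
#'
#' @param fit A [fitModel1()] object.
#' @param determinant Name of the determinant to vary.
#' @param grid Numeric grid of determinant values (default: 25 points
#'   over the observed range). Values outside the observed range trigger
#'   a warning, not an error.
#' @return Data frame with columns `determinant`, `value`, `ilr1`,
#'   `ilr2`, `sb`, `lpa`, `mvpa`; the shares sum to 1 on every row.
#' @export
predictCompositionCurve <- function(fit, determinant, grid = NULL) {
  stopifnot(inherits(fit, "codatime_model1"))
  dat <- fit$data
  if (!determinant %in% fit$determinants)
    stop("'", determinant, "' is not a model determinant")
  if (is.factor(dat[[determinant]]))
    stop("prediction curves are defined for continuous determinants")
  obs <- range(dat[[determinant]])
  if (is.null(grid)) grid <- seq(obs[1], obs[2], length.out = 25L)
  if (any(grid < obs[1] | grid > obs[2]))
    warning("grid extends outside the observed range of '",
            determinant, "' [", signif(obs[1], 3), ", ",
            signif(obs[2], 3), "]")
  newdata <- dat[rep(1L, length(grid)), fit$determinants, drop = FALSE]
  for (nm in fit$determinants) {
    newdata[[nm]] <- if (is.factor(dat[[nm]])) {
      tab <- table(dat[[nm]])
      factor(rep(names(tab)[which.max(tab)], length(grid)),
             levels = levels(dat[[nm]]))
    } else rep(mean(dat[[nm]]), length(grid))
  }
  newdata[[determinant]] <- grid
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(fit$determinants, collapse = "+"))),
    newdata)
  z <- cbind(ilr1 = drop(mm %*% lme4::fixef(fit$fits$ilr1)),
             ilr2 = drop(mm %*% lme4::fixef(fit$fits$ilr2)))
  comp <- inverseIlr(z)
  data.frame(determinant = determinant, value = grid, z, comp,
             row.names = NULL, stringsAsFactors = FALSE)
}
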