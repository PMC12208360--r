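# Fixtures built in code: random compositions, balanced hierarchies and
# small day tables used across the test files.

# n strictly positive random 3-part compositions (rows sum to 1)
random_compositions <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rgamma(3 * n, shape = 2), ncol = 3)
  m <- m / rowSums(m)
  colnames(m) <- behaviourParts()
  m
}

# balanced institution/team/worker skeleton
balanced_skeleton <- function(n_inst, teams_per_inst, workers_per_team) {
  inst <- rep(sprintf("i%02d", seq_len(n_inst)),
              each = teams_per_inst * workers_per_team)
  team <- rep(sprintf("i%02d_t%d", rep(seq_len(n_inst), each = teams_per_inst),
                      rep(seq_len(teams_per_inst), times = n_inst)),
              each = workers_per_team)
  data.frame(institution = inst, team = team,
             worker = sprintf("w%04d", seq_along(inst)),
             stringsAsFactors = FALSE)
}

# balanced three-level dataset with known ilr variance components and no
# fixed effects; same per-level variance on both coordinates
balanced_vca_data <- function(n_inst = 8, teams_per_inst = 4,
                              workers_per_team = 5,
                              var_inst = 0.8, var_team = 0.4,
                              var_worker = 1, seed = 11) {
  set.seed(seed)
  sk <- balanced_skeleton(n_inst, teams_per_inst, workers_per_team)
  draw <- function() {
    ui <- stats::rnorm(n_inst, sd = sqrt(var_inst))
    ut <- stats::rnorm(n_inst * teams_per_inst, sd = sqrt(var_team))
    e <- stats::rnorm(nrow(sk), sd = sqrt(var_worker))
    0.3 + ui[match(sk$institution, unique(sk$institution))] +
      ut[match(sk$team, unique(sk$team))] + e
  }
  sk$ilr1 <- draw()
  sk$ilr2 <- draw()
  sk
}

# closed-form expected-mean-squares variance component estimators for a
# balanced nested design, applied to the two stacked ilr coordinates with
# a fixed mean per coordinate (the independent oracle for fitVca)
anova_varcomp_oracle <- function(d) {
  I <- length(unique(d$institution))
  T_ <- length(unique(d$team)) / I
  W <- nrow(d) / (I * T_)
  y <- c(d$ilr1, d$ilr2)
  cc <- rep(1:2, each = nrow(d))
  gi <- paste(cc, rep(d$institution, 2))
  gt <- paste(cc, rep(d$team, 2))
  ybar_c <- stats::ave(y, cc)
  ybar_ci <- stats::ave(y, gi)
  ybar_cit <- stats::ave(y, gt)
  MSi <- sum((ybar_ci - ybar_c)^2) / (2 * (I - 1))
  MSt <- sum((ybar_cit - ybar_ci)^2) / (2 * I * (T_ - 1))
  MSe <- sum((y - ybar_cit)^2) / (2 * I * T_ * (W - 1))
  c(worker = MSe, team = (MSt - MSe) / W,
    institution = (MSi - MSt) / (T_ * W))
}

# small day table for one or more workers: behaviour fractions x hours
make_days <- function(worker, hours, fractions) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1)
  data.frame(worker = worker, day = seq_along(hours), work_hours = hours,
             sb_hours = fractions[, 1] * hours,
             lpa_hours = fractions[, 2] * hours,
             mvpa_hours = fractions[, 3] * hours,
             stringsAsFactors = FALSE)
}

# analysis-ready worker table from the generator, small and fast
small_study_workers <- function(seed = 5, ...) {
  cfg <- simConfig(...)
  st <- simulateStudy(cfg, seed = seed)
  preprocessStudy(st$workers, st$days)
}
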