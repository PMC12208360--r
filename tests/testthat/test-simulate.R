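# Hierarchical synthetic-data generator: structure, determinant
# marginals, outcome model and determinism.

test_that("config validation rejects infeasible settings", {
  expect_error(simConfig(teams_per_institution = 0), "zero teams")
  expect_error(simConfig(var_worker = -1), "non-negative")
  expect_error(simConfig(missing_rate = 2), "missing_rate")
  expect_error(simConfig(beta = list(nonsense = 0.1)), "determinant names")
  expect_error(simConfig(grand_mean_composition = c(0, 0, 0)))
})

test_that("hierarchy skeleton matches the configured study structure", {
  cfg <- simConfig()
  set.seed(1)
  sk <- sampleHierarchy(cfg)
  expect_length(unique(sk$institution), 16)
  nt <- length(unique(sk$team))
  expect_gte(nt, 60)
  expect_lte(nt, 90)
  # every worker in exactly one team, every team in one institution
  expect_false(anyDuplicated(sk$worker) > 0)
  expect_equal(nrow(unique(sk[, c("institution", "team")])),
               length(unique(sk$team)))
  # degenerate one-worker-one-team config collapses to n_institutions
  cfg1 <- simConfig(teams_per_institution = 1, workers_per_team = 1,
                    workers_per_team_prob = 1)
  set.seed(2)
  expect_equal(nrow(sampleHierarchy(cfg1)), 16)
  # determinism
  set.seed(9); a <- sampleHierarchy(cfg)
  set.seed(9); b <- sampleHierarchy(cfg)
  expect_identical(a, b)
})

test_that("determinant marginals converge to their target values", {
  cfg <- simConfig(n_institutions = 850, teams_per_institution = 4,
                   workers_per_team = 3, workers_per_team_prob = 1,
                   missing_rate = 0)
  set.seed(7)
  sk <- sampleHierarchy(cfg)
  expect_gte(nrow(sk), 10000)
  d <- sampleDeterminants(sk, cfg)
  expect_lt(abs(mean(d$age) - 36.5), 0.5)
  cat_ <- determinantCatalogue()
  for (i in which(cat_$kind == "continuous" & cat_$level == "worker")) {
    nm <- cat_$name[i]
    se <- cat_$sd[i] / sqrt(nrow(d))
    expect_lt(abs(mean(d[[nm]]) - cat_$mean[i]), 3 * se + 1e-9)
    expect_true(all(d[[nm]] >= cat_$lower[i] & d[[nm]] <= cat_$upper[i]))
  }
  # binary proportions (3 SE of a binomial proportion)
  p_se <- function(p) 3 * sqrt(p * (1 - p) / nrow(d))
  expect_lt(abs(mean(d$sex == "female") - 0.843), p_se(0.843))
  expect_lt(abs(mean(d$job_type == "pedagogue") - 0.567), p_se(0.567))
  inst <- d[!duplicated(d$institution), ]
  expect_lt(abs(mean(inst$institution_type == "public") - 0.625),
            3 * sqrt(0.625 * 0.375 / nrow(inst)))
})

test_that("degenerate spread collapses a determinant to its mean", {
  # direct check of the truncated-normal sampler contract
  expect_equal(codatime:::.rtruncnorm(50, 5, 0, 0, 10), rep(5, 50))
})

test_that("outcome model follows grand mean + effects + nested intercepts", {
  # no variance, no effects: everyone sits at the grand-mean composition
  cfg0 <- simConfig(var_worker = 0, var_team = 0, var_institution = 0,
                    beta = list(age = 0), day_sd = 0, missing_rate = 0)
  st0 <- simulateStudy(cfg0, seed = 3)
  for (p in behaviourParts())
    expect_equal(st0$workers[[p]],
                 rep(cfg0$grand_mean_composition[[p]], nrow(st0$workers)),
                 tolerance = 1e-12)
  # deterministic limit: +1 exertion shifts ilr1 by exactly beta
  cfgb <- simConfig(var_worker = 0, var_team = 0, var_institution = 0,
                    beta = list(exertion = c(-0.03, 0)), day_sd = 0,
                    missing_rate = 0)
  stb <- simulateStudy(cfgb, seed = 4)
  w <- stb$workers
  fit <- stats::lm(ilr1 ~ exertion, data = w)
  expect_equal(unname(stats::coef(fit)["exertion"]), -0.03,
               tolerance = 1e-10)
  expect_equal(stats::sd(stats::residuals(fit)), 0, tolerance = 1e-10)
})

test_that("simulated ilr variance matches the configured worker variance", {
  cfg <- simConfig(n_institutions = 170, teams_per_institution = 4,
                   workers_per_team = 3, workers_per_team_prob = 1,
                   var_worker = 0.079, var_team = 0, var_institution = 0,
                   beta = list(age = 0), missing_rate = 0)
  st <- simulateStudy(cfg, seed = 8)
  expect_gte(nrow(st$workers), 2000)
  expect_true(stats::var(st$workers$ilr1) > 0.070 &&
                stats::var(st$workers$ilr1) < 0.088)
  expect_true(stats::var(st$workers$ilr2) > 0.070 &&
                stats::var(st$workers$ilr2) < 0.088)
})

test_that("day records are consistent and the study is reproducible", {
  cfg <- simConfig()
  st <- simulateStudy(cfg, seed = 5)
  # behaviour hours sum to the day's work duration
  tot <- with(st$days, sb_hours + lpa_hours + mvpa_hours)
  expect_lt(max(abs(tot - st$days$work_hours)), 1e-9)
  expect_true(all(st$days$work_hours > 0))
  # day counts within the configured 1-5 range
  nd <- table(st$days$worker)
  expect_true(all(nd >= 1 & nd <= 5))
  # identical seed + config reproduce the dataset exactly
  st2 <- simulateStudy(cfg, seed = 5)
  expect_identical(st$workers, st2$workers)
  expect_identical(st$days, st2$days)
  st3 <- simulateStudy(cfg, seed = 6)
  expect_false(identical(st$workers, st3$workers))
})

test_that("missingness masks worker determinants at the configured rate", {
  cfg <- simConfig(missing_rate = 0.2)
  st <- simulateStudy(cfg, seed = 10)
  worker_dets <- determinantCatalogue()
  worker_dets <- worker_dets$name[worker_dets$level == "worker"]
  miss <- vapply(worker_dets, function(nm) mean(is.na(st$workers[[nm]])),
                 numeric(1))
  expect_true(all(miss > 0.05 & miss < 0.4))
  # team/institution determinants stay complete
  expect_false(anyNA(st$workers$n_children))
  expect_false(anyNA(st$workers$staff_ratio))
})
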