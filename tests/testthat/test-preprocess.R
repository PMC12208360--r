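# Day-validity filtering, compositional aggregation and complete-case
# filtering.

test_that("the 4-hour validity rule is a closed bound", {
  d <- make_days("w1", c(3.9, 4.0), rbind(c(0.5, 0.3, 0.2),
                                          c(0.5, 0.3, 0.2)))
  kept <- filterValidDays(d, 4)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$work_hours, 4.0)
  expect_equal(attr(kept, "n_dropped"), 1L)
  expect_error(filterValidDays(d, 0), "positive")
})

test_that("filtering drops exactly the short days and is idempotent", {
  hours <- c(7, 3, 6.5, 2, 8, 5, 3.5, 7.2, 6, 4.4)
  d <- make_days(sprintf("w%d", rep(1:5, each = 2)), hours,
                 matrix(rep(c(0.5, 0.3, 0.2), 10), ncol = 3, byrow = TRUE))
  kept <- filterValidDays(d)
  expect_equal(nrow(kept), 7L)
  again <- filterValidDays(kept)
  expect_equal(again$work_hours, kept$work_hours)
  expect_equal(attr(again, "n_dropped"), 0L)
  # all valid: identity
  allv <- filterValidDays(d[d$work_hours >= 4, ])
  expect_equal(nrow(allv), 7L)
  # a worker with no valid day is flagged, not silently lost
  d2 <- make_days("w9", 3, c(0.5, 0.3, 0.2))
  expect_equal(attr(filterValidDays(d2), "excluded_workers"), "w9")
})

test_that("worker aggregation is the compositional mean over days", {
  # single day: that day's closed composition
  d1 <- make_days("w1", 6, c(0.5, 0.3, 0.2))
  a1 <- aggregateWorkers(d1)
  expect_equal(unname(unlist(a1[, behaviourParts()])), c(0.5, 0.3, 0.2),
               tolerance = 1e-12)
  # two identical days: unchanged
  d2 <- make_days("w1", c(6, 8), rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)))
  a2 <- aggregateWorkers(d2)
  expect_equal(unname(unlist(a2[, behaviourParts()])), c(0.5, 0.3, 0.2),
               tolerance = 1e-12)
  # two distinct days: closed part-wise geometric mean
  d3 <- make_days("w1", c(6, 6), rbind(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2)))
  a3 <- aggregateWorkers(d3)
  expect_equal(unname(unlist(a3[, behaviourParts()])),
               c(0.39739345, 0.39739345, 0.20521310), tolerance = 1e-7)
  # permutation invariance over days and unit sum
  d4 <- make_days("w1", c(5, 6, 7), random_compositions(3, seed = 31))
  a4 <- aggregateWorkers(d4)
  a4r <- aggregateWorkers(d4[3:1, ])
  expect_equal(unlist(a4[, behaviourParts()]),
               unlist(a4r[, behaviourParts()]))
  expect_equal(sum(a4[, behaviourParts()]), 1, tolerance = 1e-12)
  # arithmetic aggregation differs but still closes
  a5 <- aggregateWorkers(d3, method = "arithmetic")
  expect_equal(unname(unlist(a5[, behaviourParts()])), c(0.4, 0.4, 0.2),
               tolerance = 1e-12)
})

test_that("aggregation applies zero replacement to zero-MVPA days", {
  d <- make_days("w1", c(6, 6), rbind(c(0.5, 0.5, 0), c(0.4, 0.4, 0.2)))
  a <- aggregateWorkers(d)
  expect_true(all(a[, behaviourParts()] > 0))
  expect_equal(sum(a[, behaviourParts()]), 1, tolerance = 1e-12)
})

test_that("complete-case filter reproduces study-style attrition", {
  set.seed(41)
  w <- small_study_workers(seed = 41, missing_rate = 0)
  w <- w[seq_len(min(178, nrow(w))), ]
  n <- nrow(w)
  # knock out determinants in exactly 23 rows
  hit <- sample(n, 23)
  w$exertion[hit[1:10]] <- NA
  w$bmi[hit[11:18]] <- NA
  w$influence[hit[19:23]] <- NA
  cc <- completeCaseFilter(w)
  expect_equal(nrow(cc), n - 23)
  expect_equal(attr(cc, "n_dropped"), 23L)
  expect_equal(unname(attr(cc, "n_missing")["exertion"]), 10L)
  # no missing values: identity
  cc2 <- completeCaseFilter(cc)
  expect_equal(nrow(cc2), nrow(cc))
  # unknown required column
  expect_error(completeCaseFilter(w, required = c("age", "shoe_size")),
               "shoe_size")
  # everything missing
  w$age <- NA_real_
  expect_error(completeCaseFilter(w, required = "age"), "no complete cases")
})

test_that("preprocessStudy joins day aggregates onto worker records", {
  st <- simulateStudy(simConfig(), seed = 42)
  w <- preprocessStudy(st$workers, st$days)
  expect_true(all(c("sb", "lpa", "mvpa", "ilr1", "ilr2", "n_days",
                    "work_hours_gm") %in% names(w)))
  expect_true(all(abs(rowSums(w[, behaviourParts()]) - 1) < 1e-12))
  # aggregated ilr differs from the latent worker ilr by day-level noise
  expect_false(isTRUE(all.equal(w$ilr1,
                                st$workers$ilr1[match(w$worker,
                                                      st$workers$worker)])))
  # workers with no valid days are excluded and reported
  days_all_short <- st$days
  days_all_short$work_hours[days_all_short$worker == w$worker[1]] <- 1
  w2 <- preprocessStudy(st$workers, days_all_short)
  expect_true(w$worker[1] %in% attr(w2, "excluded_workers"))
  expect_false(w$worker[1] %in% w2$worker)
})
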