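# Compositional algebra: closure, geometric-mean centre, ilr and pivot
# coordinates, percentage-change translation.

test_that("closure rescales durations to unit-sum compositions", {
  # geometric-mean behaviour hours of a full study day
  expect_equal(unname(closeComposition(c(3.17, 2.66, 0.82))),
               c(47.67, 40.00, 12.33) / 100, tolerance = 1e-4)
  expect_equal(unname(closeComposition(c(1, 1, 1))), rep(1 / 3, 3))
  expect_equal(unname(closeComposition(c(2, 0.5, 0.5))),
               c(2 / 3, 1 / 6, 1 / 6))
  m <- closeComposition(random_compositions(200, seed = 1) * 7.3)
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  expect_error(closeComposition(c(0, 0, 0)), "degenerate")
  expect_error(closeComposition(c(-1, 1, 1)), "non-negative")
})

test_that("geometric-mean composition is the closed part-wise centre", {
  x <- c(sb = 0.5, lpa = 0.3, mvpa = 0.2)
  expect_equal(geometricMeanComposition(rbind(x, x, x)), x)
  got <- geometricMeanComposition(rbind(c(0.6, 0.3, 0.1),
                                        c(0.1, 0.3, 0.6)))
  expect_equal(unname(got), c(0.31010205, 0.37979590, 0.31010205),
               tolerance = 1e-7)
  # permutation invariance over samples
  m <- random_compositions(10, seed = 2)
  expect_equal(geometricMeanComposition(m),
               geometricMeanComposition(m[sample(10), ]))
  expect_error(geometricMeanComposition(m[0, ]), "empty")
})

test_that("ilr coordinates follow the sequential binary partition", {
  expect_equal(unname(ilrTransform(c(1, 1, 1) / 3)), c(0, 0))
  # hand-evaluated against the closed-form log-ratio formulas
  expect_equal(unname(ilrTransform(c(0.4767, 0.4000, 0.1233))),
               c(0.6237, 0.8322), tolerance = 1e-4)
  # antisymmetry of the LPA/MVPA contrast
  z1 <- ilrTransform(c(0.4, 0.5, 0.1))
  z2 <- ilrTransform(c(0.4, 0.1, 0.5))
  expect_equal(z1[["ilr2"]], -z2[["ilr2"]])
  expect_equal(z1[["ilr1"]], z2[["ilr1"]])
  expect_error(ilrTransform(c(0.5, 0.5, 0)), "positive")
})

test_that("ilr is scale invariant and inverts exactly", {
  m <- random_compositions(1000, seed = 3)
  z <- ilrTransform(m)
  expect_equal(ilrTransform(m * 24), z)
  back <- inverseIlr(z)
  expect_lt(max(abs(back - m)), 1e-10)
  expect_lt(max(abs(ilrTransform(inverseIlr(z)) - z)), 1e-10)
  expect_equal(unname(inverseIlr(c(0, 0))), rep(1 / 3, 3))
  expect_equal(unname(inverseIlr(c(0.6237, 0.8322))),
               c(0.4767, 0.4000, 0.1233), tolerance = 1e-4)
  expect_error(inverseIlr(c(Inf, 0)), "finite")
})

test_that("ilr is an isometry for the Aitchison distance", {
  a <- random_compositions(100, seed = 4)
  b <- random_compositions(100, seed = 5)
  for (i in seq_len(100)) {
    d_ilr <- sqrt(sum((ilrTransform(a[i, ]) - ilrTransform(b[i, ]))^2))
    expect_equal(aitchisonDistance(a[i, ], b[i, ]), d_ilr,
                 tolerance = 1e-10)
  }
})

test_that("pivot coordinates rotate each behaviour into first position", {
  m <- random_compositions(100, seed = 6)
  # SB is already first in the basic partition
  z_sb <- pivotCoordinates(m, "sb")
  expect_equal(unname(z_sb[, 1]), unname(ilrTransform(m)[, "ilr1"]))
  # equal parts map to the origin under any pivot
  for (pv in behaviourParts())
    expect_equal(unname(pivotCoordinates(c(1, 1, 1) / 3, pv)), c(0, 0),
                 ignore_attr = TRUE)
  # the rotation is an isometry: squared norm free of the pivot choice
  n_sb <- rowSums(pivotCoordinates(m, "sb")^2)
  n_lpa <- rowSums(pivotCoordinates(m, "lpa")^2)
  n_mvpa <- rowSums(pivotCoordinates(m, "mvpa")^2)
  expect_lt(max(abs(n_sb - n_mvpa)), 1e-10)
  expect_lt(max(abs(n_sb - n_lpa)), 1e-10)
  # first coordinate is the pivot-vs-rest contrast
  x <- c(0.2, 0.5, 0.3)
  expect_equal(pivotCoordinates(x, "mvpa")[[1]],
               sqrt(2 / 3) * log(0.3 / sqrt(0.2 * 0.5)))
  expect_error(pivotCoordinates(x, "sleep"))
})

test_that("percentage-change translation matches its closed form", {
  expect_equal(percentChange(0.03), 3.7, tolerance = 0.02)
  expect_equal(percentChange(-0.03), -3.6, tolerance = 0.02)
  expect_equal(percentChange(0.01), 1.2, tolerance = 0.03)
  expect_equal(percentChange(0), 0)
  # strictly increasing in beta
  b <- seq(-0.5, 0.5, by = 0.01)
  expect_true(all(diff(percentChange(b)) > 0))
  expect_error(percentChange(0.1, D = 1), "D must")
  expect_error(percentChange(NA_real_), "finite")
})

test_that("multiplicative zero replacement keeps closure and positivity", {
  m <- rbind(c(0.7, 0.3, 0), c(0.5, 0.3, 0.2), c(0.6, 0.4, 0),
             c(0.88, 0.1, 0.02))
  colnames(m) <- behaviourParts()
  r <- replaceZeros(m)
  expect_true(all(r > 0))
  expect_true(all(abs(rowSums(r) - 1) < 1e-12))
  # delta is half the smallest observed nonzero fraction of that part
  expect_equal(unname(r[1, "mvpa"]), 0.01)
  # untouched rows stay identical
  expect_equal(r[2, ], m[2, ])
  expect_error(replaceZeros(c(0, 0, 0)), "degenerate|zero")
})
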