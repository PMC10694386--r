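test_that("discretization partitions every value exactly once", {
  expect_equal(as.integer(discretize_factor(c(1, 2, 3, 4), "quantile", 2)),
               c(1, 1, 2, 2))
  expect_equal(nlevels(discretize_factor(c(0, 10), "equal-interval", 2)), 2)
  for (method in c("quantile", "equal-interval", "natural-breaks")) {
    x <- withr::with_seed(41, stats::rnorm(300))
    f <- discretize_factor(x, method, 5)
    expect_equal(length(f), 300)
    expect_false(anyNA(f))
    expect_true(nlevels(f) >= 2)
    # labels are ordered with the values
    mids <- tapply(x, f, mean)
    expect_true(all(diff(mids) > 0))
  }
  expect_error(discretize_factor(rep(1, 10), "quantile", 3), "constant")
})

test_that("factor q reproduces hand-worked micro examples", {
  expect_equal(factor_q(c(1, 1, 2, 2), c("a", "a", "b", "b"),
                        significance = "none")$q, 1)
  expect_equal(factor_q(c(1, 2, 1, 2), c("a", "a", "b", "b"),
                        significance = "none")$q, 0)
  expect_equal(factor_q(c(0, 0, 1, 1, 1, 3), rep(c("a", "b"), each = 3),
                        significance = "none")$q, 4 / 9, tolerance = 1e-12)
})

test_that("factor q matches the two-pass loop oracle on random samples", {
  for (s in 1:20) {
    n <- withr::with_seed(s, sample(10:100, 1))
    y <- withr::with_seed(s + 100, stats::rnorm(n))
    strata <- random_strata(n, sample(2:6, 1), seed = s + 200)
    expect_equal(factor_q(y, strata, significance = "none")$q,
                 oracle_q(y, strata), tolerance = 1e-12)
  }
})

test_that("q is invariant to affine response transforms and label renaming", {
  y <- withr::with_seed(51, stats::rnorm(80))
  strata <- random_strata(80, 4, seed = 52)
  q0 <- factor_q(y, strata, significance = "none")$q
  expect_equal(factor_q(3.7 * y - 11, strata, significance = "none")$q, q0,
               tolerance = 1e-12)
  relabeled <- factor(strata, labels = c("w", "x", "y", "z"))
  expect_equal(factor_q(y, relabeled, significance = "none")$q, q0)
})

test_that("degenerate q inputs are explicit errors", {
  expect_error(factor_q(rep(2, 6), rep(c("a", "b"), 3), significance = "none"),
               "constant")
  expect_error(factor_q(c(1, 2, 3), c("a", "a", "a"), significance = "none"),
               "2 nonempty strata")
  # singleton strata are kept and contribute zero within-variance
  q <- factor_q(c(1, 2, 5), c("a", "a", "b"), significance = "none")$q
  expect_equal(q, oracle_q(c(1, 2, 5), c("a", "a", "b")), tolerance = 1e-12)
  expect_equal(q, 1 - 0.5 / (78 / 9), tolerance = 1e-12)
})

test_that("permutation p-values are deterministic, bounded away from 0", {
  y <- withr::with_seed(61, stats::rnorm(40))
  strata <- random_strata(40, 4, seed = 62)
  r1 <- factor_q(y, strata, n_perm = 199, seed = 7)
  r2 <- factor_q(y, strata, n_perm = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  # perfect separation reports the smoothed lower bound
  p <- factor_q(c(1, 1, 2, 2), c("a", "a", "b", "b"), n_perm = 999)$p_value
  expect_equal(p, 1 / 1000)
})

test_that("permutation and noncentral-F agree on a strong effect", {
  tab <- generate_zonal_table(zonal_design(200, 4, 0.8, seed = 63))
  rp <- factor_q(tab$y, tab$x1, significance = "permutation", n_perm = 999,
                 seed = 1)
  rf <- factor_q(tab$y, tab$x1, significance = "noncentral-F")
  expect_lt(rp$p_value, 0.05)
  expect_lt(rf$p_value, 0.05)
})

test_that("interaction detector handles identity, XOR and refinement", {
  y <- withr::with_seed(71, stats::rnorm(60))
  s1 <- random_strata(60, 3, seed = 72)
  r_id <- interaction_detect(y, s1, s1)
  expect_equal(r_id$q12, r_id$q1, tolerance = 1e-12)
  # XOR: individually useless, jointly decisive
  f1 <- rep(c("a", "a", "b", "b"), 25)
  f2 <- rep(c("a", "b", "a", "b"), 25)
  yx <- as.numeric(f1 != f2)
  rx <- interaction_detect(yx, f1, f2)
  expect_equal(rx$q1, 0)
  expect_equal(rx$q2, 0)
  expect_equal(rx$q12, 1)
  expect_equal(rx$category, "nonlinear-enhance")
  # y fully determined by the pair -> q12 = 1 with partial singles
  f3 <- rep(c("a", "a", "b", "b"), 25)
  f4 <- rep(c("u", "v", "u", "v"), 25)
  yd <- c(1, 2, 3, 5)[as.integer(interaction(factor(f3), factor(f4)))]
  rd <- interaction_detect(yd, f3, f4)
  expect_lt(rd$q1, 1)
  expect_equal(rd$q12, 1)
})

test_that("overlay q dominates both marginals on random inputs", {
  for (s in 1:50) {
    n <- 60
    y <- withr::with_seed(s + 300, stats::rnorm(n))
    s1 <- random_strata(n, 4, seed = s + 400)
    s2 <- random_strata(n, 3, seed = s + 500)
    r <- interaction_detect(y, s1, s2)
    expect_gte(r$q12, max(r$q1, r$q2) - 1e-12)
    expect_false(r$category %in% c("nonlinear-weaken", "uni-weaken"))
  }
})

test_that("ecological detector follows its F definition", {
  y <- withr::with_seed(81, stats::rnorm(200))
  s1 <- random_strata(200, 4, seed = 82)
  r_same <- ecological_detect(y, s1, s1)
  expect_equal(r_same$F, 1)
  expect_false(r_same$significant)
  # same y on both sides: F reduces to SSW1/SSW2
  s2 <- random_strata(200, 5, seed = 83)
  r <- ecological_detect(y, s1, s2)
  expect_equal(r$F, r$ssw_x1 / r$ssw_x2, tolerance = 1e-12)
  # a near-perfect factor vs a random factor is significant
  tab <- generate_zonal_table(zonal_design(200, 4, 0.9, noise_sd = 0.05,
                                           seed = 84))
  rnd <- random_strata(200, 4, seed = 85)
  expect_true(ecological_detect(tab$y, tab$x1, rnd)$significant)
  # zero SSW on the denominator side is an explicit error
  expect_error(ecological_detect(c(1, 1, 2, 2), c("a", "b", "a", "b"),
                                 c("a", "a", "b", "b")), "undefined")
})

test_that("run_detectors recovers design q and ignores row order", {
  tab <- generate_zonal_table(zonal_design(3000, c(4, 3), c(.45, .2),
                                           seed = 91))
  rep <- run_detectors(tab, response = "y", n_perm = 99, seed = 5)
  expect_lt(abs(rep$factor$q[rep$factor$factor == "x1"] - 0.45), 0.05)
  expect_lt(abs(rep$factor$q[rep$factor$factor == "x2"] - 0.2), 0.05)
  expect_equal(nrow(rep$interaction), 1)
  expect_equal(nrow(rep$ecological), 1)
  shuffled <- tab[withr::with_seed(92, sample(nrow(tab))), ]
  rep2 <- run_detectors(shuffled, response = "y", n_perm = 99, seed = 5)
  expect_equal(rep2$factor$q, rep$factor$q, tolerance = 1e-12)
  expect_equal(rep2$interaction$q12, rep$interaction$q12, tolerance = 1e-12)
})

test_that("run_detectors discretizes continuous factors and validates columns", {
  tab <- tibble::tibble(unit = 1:100,
                        y = withr::with_seed(93, stats::rnorm(100)),
                        elev = withr::with_seed(94, stats::runif(100)))
  rep <- run_detectors(tab, response = "y", n_bins = 4, n_perm = 49)
  expect_equal(rep$factor$L, 4)
  expect_equal(nrow(rep$interaction), 0)  # single factor: no pairs
  expect_error(run_detectors(tab, response = "nope"), "response")
  expect_error(run_detectors(tab, response = "y", factors = "slope"),
               "slope")
})

test_that("tidiers expose detector results as tibbles", {
  tab <- generate_zonal_table(zonal_design(200, c(3, 3), c(.4, .1), seed = 95))
  rep <- run_detectors(tab, response = "y", n_perm = 49)
  expect_s3_class(tidy(rep), "tbl_df")
  g <- glance(rep)
  expect_equal(g$n_factors, 2)
  expect_equal(g$best_factor, "x1")
  fq <- factor_q(tab$y, tab$x1, significance = "none")
  expect_named(tidy(fq), c("q", "p_value", "L", "n", "method"))
})
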