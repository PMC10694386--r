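toy_params <- function() {
  threats <- threat_table(tibble::tibble(
    threat = "road", code = 9L, max_dist_km = 2, weight = 1, decay = "linear"))
  sens <- sensitivity_table(tibble::tibble(
    lucode = c(1L, 9L), name = c("habitat", "road"),
    habitat = c(0.8, 0), road = c(0.5, 0)))
  list(threats = threats, sens = sens)
}

test_that("decay factors hit their boundary and analytic values", {
  expect_equal(decay_factor(0, 7, "linear"), 1)
  expect_equal(decay_factor(0, 7, "exponential"), 1)
  expect_equal(decay_factor(7, 7, "linear"), 0)
  expect_equal(decay_factor(7, 7, "exponential"), exp(-2.99), tolerance = 1e-15)
  # clamped beyond the maximum distance, monotone within it
  expect_equal(decay_factor(7.001, 7, "exponential"), 0)
  d <- seq(0, 7, by = 0.1)
  expect_true(all(diff(decay_factor(d, 7, "linear")) <= 0))
  expect_true(all(diff(decay_factor(d, 7, "exponential")) < 0))
  expect_error(decay_factor(-1, 7, "linear"), ">= 0")
})

test_that("threat presence layers count sources correctly", {
  p <- toy_params()
  lu <- lu_raster(matrix(c(1L, 1L, 9L, 1L, 9L, 1L, 1L, 1L, 1L), 3, 3), 1000)
  layers <- extract_threat_layers(lu, p$threats)
  expect_equal(layers$road$n_sources, 2)
  expect_equal(sum(layers$road$presence), 2)
  expect_equal(which(layers$road$presence == 1), which(lu$codes == 9L))
  none <- lu_raster(matrix(1L, 3, 3), 1000)
  expect_equal(extract_threat_layers(none, p$threats)$road$n_sources, 0)
})

test_that("single-source degradation reproduces the hand evaluation", {
  p <- toy_params()
  # source and habitat cell 1 km apart; d_max 2 km, linear => i = 0.5
  lu <- lu_raster(matrix(c(9L, 1L), 1, 2), cell_size = 1000)
  D <- compute_degradation(lu, p$threats, p$sens)
  expect_equal(D$values[1, 2], 0.5 * 0.5, tolerance = 1e-12)  # i * S
  expect_equal(D$values[1, 1], 0)  # source class is insensitive to itself
})

test_that("two sources at d = 0 and d = d_max sum to S * (1 + 0)", {
  threats <- threat_table(tibble::tibble(
    threat = "t", code = 2L, max_dist_km = 1, weight = 1, decay = "linear"))
  sens <- sensitivity_table(tibble::tibble(
    lucode = 2L, name = "dual", habitat = 0.3, t = 1))
  # 1x2 grid, cell 1000 m: cell 1 is a source AND habitat; cell 2 a source
  # exactly d_max away
  lu <- lu_raster(matrix(c(2L, 2L), 1, 2), cell_size = 1000)
  D <- compute_degradation(lu, threats, sens)
  expect_equal(D$values[1, 1], 1, tolerance = 1e-12)
})

test_that("cells insensitive to every threat have zero degradation", {
  p <- toy_params()
  sens0 <- p$sens
  sens0$road <- c(0, 0)
  lu <- random_poyang_landscape(15, 15, seed = 4)
  lu$codes[lu$codes > 2L] <- 1L  # legend {1, 9} only
  lu$codes[lu$codes == 2L] <- 9L
  D <- compute_degradation(lu, p$threats, sensitivity_table(sens0))
  expect_true(all(D$values == 0))
})

test_that("kernel engine matches the brute-force oracle, with beta and mean mode", {
  th <- poyang_threats(); se <- poyang_sensitivity()
  lu <- random_poyang_landscape(30, 30, cell_size = 500, seed = 9)
  D <- compute_degradation(lu, th, se)
  expect_lt(max(abs(D$values - oracle_degradation(lu, th, se))), 1e-9)
  # accessibility raster scales everything
  beta <- value_raster(matrix(runif(900), 30, 30), 500)
  Db <- compute_degradation(lu, th, se, access = beta)
  expect_lt(max(abs(Db$values - oracle_degradation(lu, th, se, beta$values))),
            1e-9)
  # mean-over-sources mode
  Dm <- compute_degradation(lu, th, se, per_source_mean = TRUE)
  expect_lt(max(abs(Dm$values -
                      oracle_degradation(lu, th, se, per_source_mean = TRUE))),
            1e-9)
})

test_that("the per-source oracle agrees with a fully scalar quadruple loop", {
  th <- poyang_threats(); se <- poyang_sensitivity()
  lu <- random_poyang_landscape(8, 8, cell_size = 500, seed = 13)
  expect_equal(oracle_degradation(lu, th, se),
               oracle_degradation_scalar(lu, th, se), tolerance = 1e-12)
})

test_that("nodata propagates through degradation and quality", {
  th <- poyang_threats(); se <- poyang_sensitivity()
  m <- matrix(3L, 5, 5); m[2, 2] <- NA; m[1, 5] <- 10L
  lu <- lu_raster(m, 500)
  D <- compute_degradation(lu, th, se)
  expect_true(is.na(D$values[2, 2]))
  expect_equal(sum(is.na(D$values)), 1)
  Q <- compute_quality(D, lu, se)
  expect_true(is.na(Q$values[2, 2]))
})

test_that("quality transform has its analytic fixed points", {
  se <- poyang_sensitivity()
  lu <- lu_raster(matrix(c(3L, 7L, 6L), 1, 3), 500)  # forest, urban, water
  D <- value_raster(matrix(c(0, 0.3, 0.5), 1, 3), 500)
  Q <- compute_quality(D, lu, se, k = 0.5)
  expect_equal(Q$values[1, 1], 1)        # D = 0 -> Q = H = 1
  expect_equal(Q$values[1, 2], 0)        # H = 0 (urban) -> Q = 0
  expect_equal(Q$values[1, 3], 0.5)      # D = k -> Q = H/2
  # auto mode: k = max(D)/2
  Qa <- compute_quality(D, lu, se, k = "auto")
  expect_equal(attr(Qa, "k"), 0.25)
  # degradation-free map falls back to k = 0.5
  Q0 <- compute_quality(value_raster(matrix(0, 1, 3), 500), lu, se, k = "auto")
  expect_equal(attr(Q0, "k"), 0.5)
})

test_that("quality is bounded by suitability and decreasing in degradation", {
  th <- poyang_threats(); se <- poyang_sensitivity()
  lu <- random_poyang_landscape(25, 25, cell_size = 500, seed = 17)
  D <- compute_degradation(lu, th, se)
  Q <- compute_quality(D, lu, se)
  H <- matrix(se$habitat[match(lu$codes, se$lucode)], 25, 25)
  expect_true(all(Q$values >= 0 & Q$values <= 1))
  expect_true(all(Q$values <= H + 1e-12))
  expect_true(all(D$values >= 0))
  # monotone: same H, larger D, smaller Q
  lu1 <- lu_raster(matrix(3L, 1, 2), 500)
  Dm <- value_raster(matrix(c(0.2, 0.4), 1, 2), 500)
  Qm <- compute_quality(Dm, lu1, se)
  expect_gt(Qm$values[1, 1], Qm$values[1, 2])
})

test_that("a threat-free landscape keeps Q = H everywhere", {
  th <- poyang_threats(); se <- poyang_sensitivity()
  lu <- lu_raster(matrix(sample(c(3L, 4L, 5L, 6L), 100, TRUE), 10, 10), 500)
  D <- compute_degradation(lu, th, se)
  expect_true(all(D$values == 0))
  Q <- compute_quality(D, lu, se)
  H <- matrix(se$habitat[match(lu$codes, se$lucode)], 10, 10)
  expect_equal(Q$values, H)
})

test_that("grade classification covers the grid and conserves area", {
  v <- value_raster(matrix(c(0.85, 0.05, 0.3, 0.75, 0.6, 1.0), 2, 3), 1000,
                    what = "quality")
  g <- classify_raster(v, quality_grades())
  labels <- g$levels[g$grades]
  expect_equal(labels[1], "excellent")   # 0.85
  expect_equal(labels[2], "awful")       # 0.05
  expect_equal(labels[6], "excellent")   # 1.0 (top interval closed)
  expect_equal(sum(g$areas$share_pct), 100, tolerance = 1e-6)
  expect_equal(sum(g$areas$area_km2), 6 * 1)  # 6 cells of 1 km^2
  # uniform raster -> one grade holds everything
  gu <- classify_raster(value_raster(matrix(0.9, 3, 3), 1000), quality_grades())
  expect_equal(max(gu$areas$share_pct), 100)
  # out-of-range values are an error
  expect_error(classify_raster(value_raster(matrix(1.5, 1, 1), 30),
                               quality_grades()), "outside")
})

test_that("grade schemes validate their intervals", {
  expect_error(grade_scheme(c("a", "b"), c(0, 0.5)), "one longer")
  expect_error(grade_scheme(c("a", "b"), c(0, 0.6, 0.5)), "increasing")
  expect_equal(nrow(equal_interval_grades(10)), 10)
})

test_that("landuse cross-tab rows sum to 100% and match hand counts", {
  se <- poyang_sensitivity()
  # checkerboard of forest and urban
  m <- matrix(rep(c(3L, 7L), 8), 4, 4)
  lu <- lu_raster(m, 1000)
  D <- value_raster(matrix(0, 4, 4), 1000)
  Q <- compute_quality(D, lu, se)
  g <- classify_raster(Q, quality_grades())
  xt <- summarize_by_landuse(g, lu)
  shares <- tidyr::pivot_wider(xt[, c("lucode", "grade", "share_pct")],
                               names_from = "grade", values_from = "share_pct")
  expect_equal(sum(xt$share_pct[xt$lucode == 3]), 100)
  expect_equal(sum(xt$share_pct[xt$lucode == 7]), 100)
  # urban (H = 0) is forced into the lowest grade
  expect_equal(xt$share_pct[xt$lucode == 7 & xt$grade == "awful"], 100)
  expect_equal(xt$share_pct[xt$lucode == 3 & xt$grade == "excellent"], 100)
})

test_that("parameter tables are validated", {
  expect_error(threat_table(tibble::tibble(
    threat = "t", code = 1L, max_dist_km = 5, weight = 1.5, decay = "linear")),
    "\\(0, 1\\]")
  expect_error(threat_table(tibble::tibble(
    threat = "t", code = 1L, max_dist_km = 5, weight = 1, decay = "gauss")),
    "decay")
  expect_error(sensitivity_table(tibble::tibble(
    lucode = 1L, name = "a", habitat = 1.2)), "\\[0, 1\\]")
  th <- poyang_threats()
  expect_error(
    sensitivity_table(poyang_sensitivity()[, -4], threats = th),
    "Paddy field")
  # degradation demands a sensitivity row for every observed code
  lu <- lu_raster(matrix(c(1L, 99L), 1, 2), 500)
  expect_error(compute_degradation(lu, th, poyang_sensitivity()), "99")
})
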