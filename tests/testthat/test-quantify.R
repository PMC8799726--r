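test_that("pool normalization divides by the pool-average total", {
  ct <- tibble::tibble(
    sample_id = rep(c("A", "B"), each = 2),
    species = rep(c("0-0", "GUSB"), 2),
    raw_count = as.integer(c(80, 20, 250, 50)))
  pools <- tibble::tibble(sample_id = c("A", "B"), pool_id = "p1")
  out <- pool_normalize(ct, pools)
  # totals 100 and 300 -> divisor 200 for both samples
  expect_equal(out$normalized_count, c(80, 20, 250, 50) / 200)
  # uniform totals: divisor is the shared total
  ct2 <- dplyr::mutate(ct, raw_count = as.integer(c(80, 20, 70, 30)))
  expect_equal(pool_normalize(ct2, pools)$normalized_count,
               c(80, 20, 70, 30) / 100)
  expect_error(pool_normalize(ct, pools[1, ]), "without a pool")
  expect_error(
    pool_normalize(dplyr::mutate(ct, raw_count = 0L), pools), "zero total")
})

test_that("pool normalization makes samples comparable across pools", {
  # a species at 1% of reads in each sample, pools of different depth
  ct <- tibble::tibble(
    sample_id = c("A", "A", "B", "B"),
    species = rep(c("M-L", "0-0"), 2),
    raw_count = as.integer(c(10, 990, 40, 3960)))
  pools <- tibble::tibble(sample_id = c("A", "B"), pool_id = c("p1", "p2"))
  out <- pool_normalize(ct, pools)
  ml <- out$normalized_count[out$species == "M-L"]
  expect_equal(ml[1], ml[2]) # total = pool mean in both pools
})

test_that("control normalization rescales by the spiked volume fraction", {
  ct <- tibble::tibble(sample_id = "S1",
                       species = c("0-0", "GUSB"),
                       raw_count = c(50L, 100L))
  expect_equal(control_normalize(ct)$value, 0.5)
  # control observed at 10% volume: 10 observed reads -> effective 100
  ct2 <- tibble::tibble(sample_id = "S1",
                        species = c("0-0", "GUSB"),
                        raw_count = c(50L, 10L))
  expect_equal(
    control_normalize(ct2, control_volume_fraction = 0.10)$value, 0.5)
  # zero control: undefined (NA), never zero
  ct3 <- tibble::tibble(sample_id = "S1",
                        species = c("0-0", "GUSB"),
                        raw_count = c(50L, 0L))
  out3 <- control_normalize(ct3)
  expect_true(is.na(out3$value))
  expect_true(out3$control_missing)
})

test_that("control normalization is scale-invariant per sample", {
  ct <- tibble::tibble(sample_id = "S1",
                       species = c("0-0", "M-0", "GUSB"),
                       raw_count = c(60L, 30L, 10L))
  a <- control_normalize(ct)
  b <- control_normalize(dplyr::mutate(ct, raw_count = raw_count * 13L))
  expect_equal(a$value, b$value)
})

test_that("the Poisson partition estimator matches its closed form", {
  # exactly half the droplets positive: lambda = ln 2
  w <- tibble::tibble(well_id = "w1", channel = "t",
                      n_positive = 10000L, n_total = 20000L,
                      droplet_volume_nl = 0.85)
  out <- ddpcr_concentration(w)
  expect_equal(out$lambda, log(2))
  expect_equal(out$concentration, log(2) / (0.85e-3))
  expect_equal(out$lambda_se, sqrt((exp(log(2)) - 1) / 20000))
  # no positives: zero with the below-LOD flag
  w0 <- dplyr::mutate(w, n_positive = 0L)
  out0 <- ddpcr_concentration(w0)
  expect_equal(out0$concentration, 0)
  expect_true(out0$below_lod)
  # saturation is an error unless flagged
  ws <- dplyr::mutate(w, n_positive = 20000L)
  expect_error(ddpcr_concentration(ws), "aturated")
  expect_true(is.na(ddpcr_concentration(ws, on_saturated = "flag")$lambda))
})

test_that("the estimator is strictly increasing in the positive count", {
  w <- tibble::tibble(well_id = sprintf("w%d", 1:1999), channel = "t",
                      n_positive = as.integer(seq(10, 19990, by = 10)),
                      n_total = 20000L, droplet_volume_nl = 0.85)
  conc <- ddpcr_concentration(w)$concentration
  expect_true(all(diff(conc) > 0))
})

test_that("simulated wells recover lambda within 3 standard errors", {
  for (lam in c(0.1, 1, 3)) {
    conc <- lam / (0.85e-3)
    w <- simulate_droplets(conc, n_droplets = 20000, seed = round(100 * lam))
    est <- ddpcr_concentration(w)
    expect_lt(abs(est$lambda - lam), 3 * sqrt((exp(lam) - 1) / 20000))
  }
})

test_that("ddPCR expression ratios behave and flag degenerate controls", {
  w <- tibble::tibble(well_id = "t", channel = "t", n_positive = 5000L,
                      n_total = 20000L, droplet_volume_nl = 0.85)
  out <- ddpcr_normalized_expression(w, w)
  expect_equal(out$value, 1)
  expect_equal(out$log2_value, 0)
  expect_equal(out$flag, "ok")
  # target lambda about twice control lambda in the small-lambda regime
  t2 <- simulate_droplets(0.2 / 0.85e-3, n_droplets = 20000, seed = 8)
  c1 <- simulate_droplets(0.1 / 0.85e-3, n_droplets = 20000, seed = 9)
  r <- ddpcr_normalized_expression(t2, c1)
  expect_lt(abs(r$value - 2), 0.2)
  # saturated control is flagged, not computed
  ws <- dplyr::mutate(w, n_positive = 20000L)
  expect_equal(ddpcr_normalized_expression(w, ws)$flag, "control_saturated")
  w0 <- dplyr::mutate(w, n_positive = 0L)
  expect_equal(ddpcr_normalized_expression(w, w0)$flag, "control_below_lod")
})

test_that("group fold changes match direct computation on both scales", {
  expr <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                         value = c(1, 4, 2, 8))
  grouping <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                             group = c("A", "A", "B", "B"))
  expect_equal(group_fold_change(expr, grouping)$fold_change, 2)
  expect_equal(group_fold_change(expr, grouping,
                                 scale = "arithmetic")$fold_change, 2)
  # identical groups: 1; doubling: 2
  expr2 <- dplyr::mutate(expr, value = c(3, 5, 3, 5))
  expect_equal(group_fold_change(expr2, grouping)$fold_change, 1)
  # reciprocal property on the geometric scale
  fc_ab <- group_fold_change(expr, grouping, ref = "A")$fold_change
  fc_ba <- group_fold_change(expr, grouping, ref = "B")$fold_change
  expect_equal(fc_ab * fc_ba, 1)
  # errors
  expect_error(group_fold_change(expr, grouping[1:2, ]), "two")
  expect_error(group_fold_change(dplyr::mutate(expr, value = c(-1, 4, 2, 8)),
                                 grouping), "positive")
})

test_that("Spearman concordance uses average ranks and drops NA pairs", {
  x <- c(1, 2, 3, 4)
  expect_equal(concordance(x, x)$estimate, 1)
  expect_equal(concordance(x, rev(x))$estimate, -1)
  expect_equal(concordance(x, c(1, 3, 2, 4))$estimate, 0.8)
  out <- concordance(c(x, NA), c(1, 3, 2, 4, 5))
  expect_equal(out$n, 4L)
  expect_error(concordance(c(1, 2, NA), c(1, NA, 3)), "at least 3")
})
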