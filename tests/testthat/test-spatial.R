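test_that("nearest distances are exact centroid-to-boundary measurements", {
  st <- matrix(FALSE, 100, 100); st[50, 50] <- TRUE
  tg <- matrix(FALSE, 100, 100); tg[50, 50] <- TRUE
  expect_equal(nearest_distance(st, tg, 0.5), 0)

  # centroid 30 px from a straight boundary at 0.5 um/px reads 15 um
  tg2 <- matrix(FALSE, 100, 100); tg2[1:20, ] <- TRUE
  expect_lt(abs(nearest_distance(st, tg2, 0.5) - 15), 0.5)

  expect_true(is.na(nearest_distance(st, matrix(FALSE, 100, 100), 0.5)))
  expect_error(nearest_distance(matrix(FALSE, 10, 10), tg2[1:10, 1:10], 0.5),
               "empty structure")
})

test_that("distance normalization subtracts the caliber radius and floors at zero", {
  expect_equal(normalize_distance(15, 10), 10)
  expect_equal(normalize_distance(2, 10), 0)
  expect_equal(normalize_distance(7.3, 0), 7.3)
  expect_error(normalize_distance(-1, 2), "non-negative")

  # order-preserving in the raw distance for fixed caliber; never negative
  d <- sort(stats::runif(50, 0, 30))
  nd <- normalize_distance(d, 8)
  expect_true(all(diff(nd) >= 0))
  expect_true(all(nd >= 0))
  expect_true(all(nd <= d))
})

test_that("bone co-occurrence testing matches printed-style marginals", {
  # printed proportions: 45.7% of 268 capillary FOVs include bone, against
  # arteries/arterioles at ~28.8% of 155
  grp <- rep(c(TRUE, FALSE), c(122, 146))
  rest <- rep(c(TRUE, FALSE), c(45, 110))
  res <- cooccurrence_test(grp, rest)
  expect_equal(res$proportion_group, 45.5)
  expect_equal(res$direction, "higher")
  expect_lt(res$p, 0.005)

  same <- cooccurrence_test(rep(c(TRUE, FALSE), 20), rep(c(TRUE, FALSE), 25))
  expect_gt(same$p, 0.99)

  res2 <- cooccurrence_test(rep(TRUE, 20), rep(FALSE, 20))
  expect_lt(res2$p, 1e-6)

  expect_error(cooccurrence_test(rep(TRUE, 5), rep(TRUE, 5)), "degenerate")
})

test_that("skewness z-score matches a brute-force moment oracle", {
  set.seed(12)
  for (n in c(5, 14, 123, 300, 10000)) {
    x <- stats::rlnorm(n, 0, 0.8)
    res <- skewness_z(x)
    # independent oracle: explicit moment sums
    m <- sum(x) / n
    m2 <- sum((x - m)^2) / n
    m3 <- sum((x - m)^3) / n
    g1 <- (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
    se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
    expect_equal(res$g1, g1, tolerance = 1e-12)
    expect_equal(res$z, g1 / se, tolerance = 1e-12)
  }
  expect_equal(skewness_z(c(-2, -1, 0, 1, 2))$z, 0)
  expect_error(skewness_z(rep(1, 10)), "zero variance")
  expect_error(skewness_z(c(1, 2, 3)), "at least 5")
})

test_that("published skewness/sample-size pairs round-trip to the printed integers", {
  pairs <- list(c(1.734, 123, 8), c(1.539, 31, 4), c(1.095, 96, 4),
                c(0.274, 300, 2), c(0.939, 14, 2), c(0.715, 23, 1))
  for (p in pairs)
    expect_equal(skewness_zscore(p[1], p[2])$z_rounded, p[3])
})

test_that("normality diagnostics are location-invariant with sound Q-Q ordinates", {
  set.seed(5)
  x <- stats::rnorm(80, 10, 2)
  d1 <- normality_diagnostics(x)
  d2 <- normality_diagnostics(x + 500)
  expect_equal(d1$W, d2$W, tolerance = 1e-10)
  expect_equal(nrow(d1$qq), 80)
  # a normal fit leaves small de-trended ordinates relative to the spread
  expect_lt(max(abs(d1$qq$detrended)), 3 * stats::sd(x))

  # windowing restricts the series
  dw <- normality_diagnostics(c(x, 1000), window = c(0, 100))
  expect_equal(dw$n, 80)
  expect_error(normality_diagnostics(c(1, 2), NULL), "at least 3")

  # power against a strongly right-skewed alternative at the study n
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    d <- normality_diagnostics(stats::rexp(123, 1 / 20))
    d$p_sw < 0.001 && d$z > 3
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("clustering verdicts follow the stated decision rules", {
  set.seed(6)
  rec <- rbind(
    data.frame(structure_id = 1:150, class = "NCLT", target_kind = "bone",
               d_raw_um = stats::rexp(150, 1 / 15), ic_um = 0),
    data.frame(structure_id = 1:60, class = "A", target_kind = "bone",
               d_raw_um = stats::qnorm((1:60 - 0.5) / 60, 60, 12), ic_um = 0),
    data.frame(structure_id = 1:2, class = "EA", target_kind = "bone",
               d_raw_um = c(4, 8), ic_um = 0))
  out <- clustering_inference(rec, analysis_config())
  ov <- out[out$segment == "overall", ]
  expect_equal(ov$verdict[ov$class == "NCLT"], "right-skewed")
  expect_equal(ov$verdict[ov$class == "A"], "normal")
  expect_equal(ov$verdict[ov$class == "EA"], "insufficient-n")
  # the bone split threshold segments exist for each class
  expect_true(all(c("le_10_um", "gt_10_um") %in%
                    out$segment[out$class == "NCLT"]))
})

test_that("marker-proximity association switches tests and catches degeneracies", {
  # complete separation at n = 12: Fisher p = 2 / choose(12, 6)
  marker <- rep(c(TRUE, FALSE), each = 6)
  dist <- c(stats::runif(6, 0, 8), stats::runif(6, 20, 40))
  res <- marker_proximity_association(marker, dist, 10)
  expect_equal(res$test, "Fisher exact")
  expect_lt(res$p, 0.01)

  expect_error(marker_proximity_association(c(TRUE, TRUE, FALSE), 1:3, 5),
               "at least 4")
  expect_error(marker_proximity_association(rep(TRUE, 6), stats::runif(6), 5),
               "both marker states")

  # large balanced sample uses the chi-square branch
  set.seed(7)
  res2 <- marker_proximity_association(stats::runif(200) < 0.5,
                                       stats::runif(200, 0, 40), 20)
  expect_match(res2$test, "chi-square")
})

test_that("window configuration enforces ordering and positivity", {
  cfg <- analysis_config()
  expect_equal(cfg$endosteal_window_um, 40)
  expect_equal(cfg$perivascular_window_um, 20)
  expect_equal(cfg$bone_contact_window_um, 10)
  expect_error(analysis_config(perivascular_window_um = 50), "ordered")
  expect_error(analysis_config(bone_contact_window_um = -1), "positive")
})
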