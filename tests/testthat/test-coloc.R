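test_that("pearson correlation behaves on self, anti and mixed channels", {
  set.seed(1)
  g <- matrix(stats::runif(2500, 10, 200), 50)
  expect_equal(pearson_coloc(channel_pair(g, g)), 1)
  expect_equal(pearson_coloc(channel_pair(g, max(g) + 1 - g)), -1)

  # bivariate mixing at rho = 0.5: R within 3/sqrt(n) of the target
  n <- 100L
  set.seed(2)
  a <- matrix(stats::rnorm(n^2), n); b <- matrix(stats::rnorm(n^2), n)
  rho <- 0.5
  g2 <- a + 100; r2 <- rho * a + sqrt(1 - rho^2) * b + 100
  R <- pearson_coloc(channel_pair(pmax(g2, 0), pmax(r2, 0)))
  expect_lt(abs(R - rho), 3 / n)

  expect_error(pearson_coloc(channel_pair(g, g), g > max(g)), "fewer than 3")
  const <- matrix(5, 50, 50)
  expect_error(pearson_coloc(channel_pair(g, const)), "zero variance")

  # invariance under positive affine rescaling of either channel
  p1 <- channel_pair(pmax(g2, 0), pmax(r2, 0))
  p2 <- channel_pair(pmax(g2, 0) * 3 + 7, pmax(r2, 0))
  expect_equal(pearson_coloc(p1), pearson_coloc(p2), tolerance = 1e-12)
})

test_that("costes thresholds lie on the regression line and match degenerate cases", {
  g <- matrix(seq(0, 100, length.out = 1024), 32)
  th <- costes_thresholds(channel_pair(g, 2 * g))
  expect_equal(th$slope, 2, tolerance = 1e-10)
  expect_equal(th$intercept, 0, tolerance = 1e-8)
  expect_equal(th$T_red, th$intercept + th$slope * th$T_green)

  expect_error(costes_thresholds(channel_pair(matrix(1, 10, 10) * 0 + 5,
                                              matrix(stats::runif(100), 10))),
               "distinct intensity")
})

test_that("costes scan equals the exhaustive per-level oracle", {
  for (s in 1:12) {
    pr <- mk_quantized_pair(s)
    th <- costes_thresholds(pr)
    or <- oracle_costes(pr)
    expect_identical(th$T_green, or$T_green)
    expect_identical(th$flagged, or$flagged)
  }
  # anti-correlated channels exercise the non-monotone scan path
  set.seed(9)
  g <- round(matrix(stats::runif(1024, 0, 255), 32))
  r <- pmax(round(255 - g + matrix(stats::rnorm(1024, 0, 5), 32)), 0)
  pr <- channel_pair(g, r)
  expect_identical(costes_thresholds(pr)$T_green, oracle_costes(pr)$T_green)
})

test_that("independent noise drives the threshold towards the top of the scan", {
  high_or_flagged <- vapply(1:10, function(s) {
    set.seed(s)
    g <- round(matrix(stats::runif(4096, 0, 255), 64))
    r <- round(matrix(stats::runif(4096, 0, 255), 64))
    th <- costes_thresholds(channel_pair(g, r))
    th$flagged || mean(g <= th$T_green) >= 0.5
  }, logical(1))
  expect_gte(sum(high_or_flagged), 8)
})

test_that("manders coefficients measure co-occurring intensity fractions", {
  set.seed(3)
  g <- matrix(stats::runif(2500, 1, 100), 50)
  expect_equal(manders(channel_pair(g, g), 0, 0), list(M1 = 1, M2 = 1))

  # disjoint supports
  g2 <- matrix(0, 40, 40); g2[1:20, ] <- stats::runif(800, 50, 100)
  r2 <- matrix(0, 40, 40); r2[21:40, ] <- stats::runif(800, 50, 100)
  m <- manders(channel_pair(g2, r2), 10, 10)
  expect_equal(m$M1, 0); expect_equal(m$M2, 0)

  # rendered offset rings: coefficients equal a direct pixel-count oracle
  p <- render_vessel("NCLT", 6, marker_offset_px = 4L, um_per_px = 0.5)
  pr <- channel_pair(p$channels$nestin, p$channels$endo)
  Tg <- 0.2 * max(p$channels$nestin); Tr <- 0.2 * max(p$channels$endo)
  m2 <- manders(pr, Tg, Tr)
  expect_equal(m2$M1,
               sum(p$channels$endo[p$channels$nestin > Tg]) / sum(p$channels$endo),
               tolerance = 1e-12)

  # invariance to positive channel scaling with rescaled thresholds
  m3 <- manders(channel_pair(p$channels$nestin * 2.5, p$channels$endo * 0.7),
                Tg * 2.5, Tr * 0.7)
  expect_equal(m3$M1, m2$M1, tolerance = 1e-12)
  expect_equal(m3$M2, m2$M2, tolerance = 1e-12)

  expect_error(manders(channel_pair(g2, matrix(0, 40, 40)), 0, 0), "zero total")
})

test_that("translated control crops to the overlap and inverts cleanly", {
  p <- simulate_coloc_pair(seed = 2, dim = c(160L, 160L), n_vessels = 3L,
                           control_offsets = c(40L, 40L))
  expect_identical(translated_control(p, 0, 0)$ch_green, p$ch_green)
  tc <- translated_control(p, 40, 40)
  expect_equal(dim(tc$ch_green), c(120L, 120L))
  back <- translated_control(tc, -40, -40)
  expect_identical(back$ch_green, p$ch_green[41:120, 41:120])
  expect_identical(back$ch_red, p$ch_red[41:120, 41:120])
  expect_error(translated_control(p, 160, 0), "offset")
})

test_that("segregated supports yield no co-occurrence and non-positive correlation", {
  res <- coloc_analysis(simulate_coloc_pair(seed = 3, segregated = TRUE),
                        offsets = c(60L, 60L))
  expect_lt(res$M1, 0.05)
  expect_lte(res$R, 0)
})

test_that("control coefficients fall below the paired originals on correlated fields", {
  rs <- t(vapply(1:10, function(s) {
    x <- coloc_analysis(simulate_coloc_pair(seed = s))
    c(x$R, x$tR)
  }, numeric(2)))
  expect_true(all(rs[, 2] < rs[, 1]))
})

test_that("group comparison reproduces an independent Dunn computation", {
  groups <- list(a = c(1.1, 2.3, 2.3, 3.1, 4.0),
                 b = c(2.0, 2.3, 3.7, 4.1, 5.5, 5.0),
                 c = c(5.1, 6.2, 6.2, 7.0))
  res <- compare_groups(groups)
  # reference values computed independently (rank formulas, scipy cross-check)
  expect_equal(res$H, 8.6127327327, tolerance = 1e-9)
  expect_equal(res$p, 0.0134824510, tolerance = 1e-8)
  expect_equal(res$dunn$z, c(-1.0138866544, -2.8962922001, -2.0588051580),
               tolerance = 1e-9)
  expect_equal(res$dunn$p_adj, c(0.9319105204, 0.0113280188, 0.1185387221),
               tolerance = 1e-8)
})

test_that("group comparison flags no effect for identical groups and finds shifts", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  res <- compare_groups(g)
  expect_lt(res$H, 1e-10)
  expect_gt(res$p, 0.99)
  expect_true(compare_groups(list(a = rep(1, 5), b = rep(1, 4)))$degenerate)

  # power: N(0,1) vs N(3,1) at n = 30 rejects at 0.001 nearly always
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    compare_groups(list(a = stats::rnorm(30), b = stats::rnorm(30, 3)))$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # large shift in one of three groups: Dunn flags exactly the two
  # contrasts involving the shifted group
  set.seed(17)
  res3 <- compare_groups(list(a = stats::rnorm(30), b = stats::rnorm(30),
                              c = stats::rnorm(30, 10)))
  sig <- res3$dunn$p_adj < 0.05
  involved <- res3$dunn$group1 == "c" | res3$dunn$group2 == "c"
  expect_identical(sig, involved)
})
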