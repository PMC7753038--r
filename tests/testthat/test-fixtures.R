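test_that("rendered vessel geometry follows the requested caliber and offsets", {
  # degenerate no-lumen case: filled body, empty lumen mask
  p0 <- render_vessel("NC", 0, um_per_px = 0.5)
  expect_false(any(p0$lumen_mask))
  expect_gt(sum(p0$channels$nestin > 0), 0)

  # unit conversion: 10 um lumen at 0.5 um/px spans 20 px (within 1)
  pA <- render_vessel("A", 10, has_pericytes = TRUE, um_per_px = 0.5)
  ext <- diff(range(which(pA$lumen_mask, arr.ind = TRUE)[, 1])) + 1
  expect_lte(abs(ext - 20), 1)
  # wall positive in cytoskeletal channel, pericyte ring only peri channel
  expect_true(all(pA$channels$nestin[pA$wall_mask] > 0))
  expect_equal(sum(pA$channels$peri[pA$wall_mask | pA$lumen_mask]), 0)

  # membrane ring displaced radially: thin rings at offset 3 barely overlap
  pr <- render_vessel("NCLT", 6, marker_offset_px = 3L, um_per_px = 0.5,
                      wall_um = 1, membrane_um = 1)
  gm <- pr$channels$nestin > 0.5 * max(pr$channels$nestin)
  rm_ <- pr$channels$endo > 0.5 * max(pr$channels$endo)
  expect_lt(sum(gm & rm_) / min(sum(gm), sum(rm_)), 0.5)
  # but the rings stay within a few pixels of each other
  gi <- which(gm, arr.ind = TRUE); ri <- which(rm_, arr.ind = TRUE)
  nearest <- vapply(seq_len(nrow(ri)), function(k)
    sqrt(min((gi[, 1] - ri[k, 1])^2 + (gi[, 2] - ri[k, 2])^2)), numeric(1))
  expect_lte(max(nearest), 5)

  expect_error(render_vessel("A", 50, patch_px = 40), "patch")
  expect_error(render_vessel("NC", 0, has_pericytes = TRUE))
})

test_that("imHC placement follows the uniform and exponential-shell laws", {
  # point target (imperceptible lumen): no exclusion-zone truncation
  vt <- data.frame(id = 1L, class = "NCLT", row_px = 96, col_px = 96,
                   lumen_r_px = 0)
  # pure shell: mean distance to the target within 3 SE of the decay scale
  pts <- place_imhcs(500L, vt, c(192L, 192L), 0.5, mode = "shell",
                     shell_decay_um = 5, clustered_fraction = 1, seed = 31L)
  expect_lt(abs(mean(pts$d_target_um) - 5), 3 * 5 / sqrt(500))

  # uniform placement: nearest-vessel distances match an independently
  # simulated uniform null (two-sample KS, alpha = 0.01)
  u1 <- place_imhcs(600L, vt, c(192L, 192L), 0.5, mode = "uniform", seed = 7L)
  u2 <- place_imhcs(600L, vt, c(192L, 192L), 0.5, mode = "uniform", seed = 8L)
  ks <- suppressWarnings(stats::ks.test(u1$d_nearest_vessel_um,
                                        u2$d_nearest_vessel_um))
  expect_gt(ks$p.value, 0.01)

  # half-and-half mixture: median between the two pure-mode medians
  mx <- place_imhcs(600L, vt, c(192L, 192L), 0.5, mode = "shell",
                    shell_decay_um = 5, clustered_fraction = 0.5, seed = 9L)
  pure_c <- place_imhcs(600L, vt, c(192L, 192L), 0.5, mode = "shell",
                        shell_decay_um = 5, clustered_fraction = 1, seed = 10L)
  med <- stats::median(mx$d_nearest_vessel_um)
  expect_gt(med, stats::median(pure_c$d_nearest_vessel_um))
  expect_lt(med, stats::median(u1$d_nearest_vessel_um))

  # no eligible target is an error
  expect_error(place_imhcs(5L, vt[0, ], c(192L, 192L), 0.5, mode = "shell",
                           clustered_fraction = 1),
               "at least one vessel")

  # exclusion zones: never inside bone or a lumen
  bone <- matrix(FALSE, 192, 192); bone[1:40, ] <- TRUE
  vt2 <- data.frame(id = 1L, class = "NCLT", row_px = 96, col_px = 96,
                    lumen_r_px = 2)
  pb <- place_imhcs(300L, vt2, c(192L, 192L), 0.5, mode = "uniform",
                    bone_mask = bone, seed = 11L)
  expect_true(all(round(pb$row_px) > 40))
  expect_true(all((pb$row_px - 96)^2 + (pb$col_px - 96)^2 >= 4))
})

test_that("dataset generation is deterministic with self-consistent ground truth", {
  cfg <- small_fixture_config()
  ds1 <- generate_dataset(cfg, keep_images = TRUE)
  ds2 <- generate_dataset(cfg, keep_images = TRUE)
  expect_identical(ds1$truth, ds2$truth)
  expect_identical(ds1$images[[3]]$channels, ds2$images[[3]]$channels)

  vt <- ds1$truth$vessel_table
  expect_equal(nrow(vt), sum(cfg$n_vessels_per_class))
  expect_equal(unname(table(vt$class)[c("A", "EA", "cEA", "NCLT", "NC")]),
               unname(cfg$n_vessels_per_class[c("A", "EA", "cEA", "NCLT", "NC")]),
               ignore_attr = TRUE)

  # imHC nearest-vessel distances recomputable from points + vessel table
  im <- ds1$truth$imhc_points
  if (nrow(im)) {
    for (k in seq_len(nrow(im))) {
      v <- vt[vt$image_id == im$image_id[k], ]
      d <- sqrt((v$row_px - im$row_px[k])^2 + (v$col_px - im$col_px[k])^2) *
        cfg$um_per_px
      expect_equal(im$d_nearest_vessel_um[k], d, tolerance = 1e-10)
    }
  }

  # ground truth recomputable from rendered masks: caliber within 1 px-ish,
  # centroid of the wall within 2 px of the recorded centre
  for (i in seq_len(nrow(vt))) {
    img <- ds1$images[[vt$image_id[i]]]
    ic_meas <- measure_inner_caliber(img$masks$lumen > 0, cfg$um_per_px)
    expect_lt(abs(ic_meas - vt$true_ic_um[i]),
              max(2 * cfg$um_per_px, 0.15 * vt$true_ic_um[i]))
    ctr <- colMeans(which(img$masks$wall > 0, arr.ind = TRUE))
    expect_lt(sqrt(sum((ctr - c(vt$row_px[i], vt$col_px[i]))^2)), 2)
  }

  # bone distance truth matches an independent recomputation from the mask
  with_bone <- which(vt$bone_in_fov)
  for (i in with_bone) {
    img <- ds1$images[[vt$image_id[i]]]
    d <- nearest_distance(img$masks$wall > 0, img$masks$bone, cfg$um_per_px)
    expect_lt(abs(d - vt$d_bone_raw_um[i]), 2 * cfg$um_per_px)
  }
})

test_that("bone-free configurations flag all bone distances as missing", {
  cfg <- small_fixture_config(bone_fraction = 0)
  ds <- generate_dataset(cfg, keep_images = FALSE)
  expect_true(all(is.na(ds$truth$distance_table$d_raw_um)))
  expect_false(any(ds$truth$vessel_table$bone_in_fov))
})

test_that("per-class inner-caliber distribution recovers its log-normal parameters", {
  cfg <- fixture_config(image_size_px = c(96L, 96L),
                        n_vessels_per_class = c(A = 0L, EA = 0L, cEA = 0L,
                                                NCLT = 250L, NC = 0L),
                        ic_lognormal_params = list(
                          A = c(log(10), 0.2), EA = c(log(6), 0.1),
                          cEA = c(log(4), 0.2), NCLT = c(log(3), 0.25)),
                        ic_trunc_um = list(A = c(8, 18), EA = c(5, 8),
                                           cEA = c(2, 6), NCLT = c(0.5, 15)),
                        zero_lumen_prob = c(A = 0, EA = 0, cEA = 0, NCLT = 0,
                                            NC = 1),
                        imhc_placement = list(mode = "uniform",
                                              mean_per_image = 0),
                        bone_fraction = 0, seed = 21L)
  ds <- generate_dataset(cfg, keep_images = FALSE)
  ic <- ds$truth$vessel_table$true_ic_um
  fit_meanlog <- mean(log(ic)); fit_sdlog <- stats::sd(log(ic))
  expect_lt(abs(fit_meanlog - log(3)) / log(3), 0.10)
  expect_lt(abs(fit_sdlog - 0.25) / 0.25, 0.10)
})

test_that("micrograph sets round-trip through the TIFF interface", {
  cfg <- small_fixture_config()
  ds <- generate_dataset(cfg, keep_images = TRUE)
  dir <- withr::local_tempdir()
  files <- write_micrograph_set(ds$images[[1]], dir, "img1")
  expect_true(all(file.exists(files)))
  g <- read_channel_tiff(file.path(dir, "img1_nestin.tif"))
  expect_equal(dim(g), dim(ds$images[[1]]$channels$nestin))
  # 16-bit storage quantizes to integers on the 0..65535 scale
  expect_lt(max(abs(g - round(ds$images[[1]]$channels$nestin))), 1 + 1e-6)
})
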