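# Shared fixture builders; everything is generated in code at test time.

# Quantized (8-bit) 64x64 channel pair: common structure + independent noise.
mk_quantized_pair <- function(seed) {
  set.seed(seed)
  common <- matrix(stats::rgamma(64 * 64, 2, scale = 30), 64)
  g <- pmax(pmin(round(common + matrix(stats::rnorm(64 * 64, 40, 15), 64)), 255), 0)
  r <- pmax(pmin(round(0.8 * common + matrix(stats::rnorm(64 * 64, 30, 12), 64)), 255), 0)
  channel_pair(g, r)
}

# Naive exhaustive Costes oracle: regression once, then a from-scratch
# below-set evaluation at every distinct green level.
oracle_costes <- function(pair) {
  g <- as.numeric(pair$ch_green[pair$roi_mask])
  r <- as.numeric(pair$ch_red[pair$roi_mask])
  slope <- stats::cov(g, r) / stats::var(g)
  intercept <- mean(r) - slope * mean(g)
  for (L in sort(unique(g), decreasing = TRUE)) {
    sel <- g < L & r < intercept + slope * L
    nb <- sum(sel)
    ok <- if (nb == 0) TRUE else if (nb < 3) FALSE else {
      gg <- g[sel]; rr <- r[sel]
      vg <- nb * sum(gg^2) - sum(gg)^2
      vr <- nb * sum(rr^2) - sum(rr)^2
      if (vg <= 0 || vr <= 0) FALSE
      else (nb * sum(gg * rr) - sum(gg) * sum(rr)) <= 0
    }
    if (ok) return(list(T_green = L, flagged = FALSE))
  }
  list(T_green = min(g), flagged = TRUE)
}

# Pooled imHC nearest-vessel distance series over vessel-centred FOVs,
# without rendering (placement geometry only).
sim_imhc_series <- function(seed, mode, n_img = 150, mean_per_image = 2,
                            clustered_fraction = 0.6, shell_decay_um = 8,
                            dim_px = 192L, um_per_px = 0.5) {
  set.seed(seed)
  d <- c()
  for (i in seq_len(n_img)) {
    vt <- data.frame(id = 1L, class = "NCLT",
                     row_px = stats::runif(1, dim_px * 0.375, dim_px * 0.625),
                     col_px = stats::runif(1, dim_px * 0.375, dim_px * 0.625),
                     lumen_r_px = 3)
    n <- stats::rpois(1, mean_per_image)
    if (n > 0)
      d <- c(d, place_imhcs(n, vt, c(dim_px, dim_px), um_per_px, mode = mode,
                            shell_center = "NCLT",
                            shell_decay_um = shell_decay_um,
                            clustered_fraction = clustered_fraction)$d_nearest_vessel_um)
  }
  d
}

# Generate the full classification fixture and measure every inner caliber
# from the rendered lumen masks (streamed; images are not retained).
measured_classification_run <- function(seed = 1L, image_size = c(192L, 192L)) {
  cfg <- fixture_config(image_size_px = image_size, seed = seed)
  meas <- numeric(sum(cfg$n_vessels_per_class))
  ds <- generate_dataset(cfg, keep_images = FALSE, per_image = function(s)
    meas[s$meta$image_id] <<- measure_inner_caliber(s$masks$lumen > 0,
                                                    s$meta$um_per_px))
  vt <- ds$truth$vessel_table
  list(config = cfg, dataset = ds,
       records = data.frame(id = vt$id, class = vt$class, ic_um = meas[vt$id],
                            has_pericytes = vt$has_pericytes,
                            tubular = vt$tubular, compressed = vt$compressed,
                            bone_in_fov = vt$bone_in_fov))
}

small_fixture_config <- function(seed = 5L, ...) {
  fixture_config(image_size_px = c(128L, 128L),
                 n_vessels_per_class = c(A = 2L, EA = 2L, cEA = 1L,
                                         NCLT = 4L, NC = 1L),
                 seed = seed, ...)
}
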