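#' Configuration for the synthetic micrograph generator
#'
#' Builds and validates the parameter set controlling synthetic bone-marrow
#' micrographs: one field of view (FOV) per NESTIN+ structure, rendered as an
#' annular vessel cross-section in a cytoskeletal (NESTIN) channel, a radially
#' offset endothelial-membrane channel (CD34/CD31), an optional perivascular
#' channel (CD146/aSMA), and a nuclei channel, plus label masks (lumen, wall,
#' bone) and ground-truth tables.
#'
#' Defaults encode the study conditions the downstream analysis assumes:
#' class marginals 268 NCLT / 58 EA / 39 cEA / 58 A / 64 NC (487 structures),
#' 163 of the NCLT with imperceptible (zero) lumens, per-class log-normal
#' inner calibers whose pooled non-zero quartiles fall near 3.2 / 4.5 / 7.6
#' micrometres, 0.5 micrometre pixels (a 1000x confocal FOV of ~0.25 mm on a
#' ~512 px frame), and immature-haematopoietic-cell (imHC) point patterns that
#' are a mixture of a uniform component and an exponential shell around the
#' target structures.
#'
#' @param image_size_px integer length-2, FOV size in pixels (rows, cols).
#' @param um_per_px micrometres per pixel (> 0).
#' @param n_vessels_per_class named integer vector over classes
#'   `A, EA, cEA, NCLT, NC`.
#' @param ic_lognormal_params named list; per class a numeric
#'   `c(meanlog, sdlog)` on the log-micrometre scale (ignored for `NC`).
#' @param ic_trunc_um named list; per class a numeric `c(lo, hi)` truncation
#'   window in micrometres for the drawn inner caliber.
#' @param zero_lumen_prob named numeric; per-class probability of an
#'   imperceptible lumen (IC = 0).
#' @param pericyte_ring list with `has` (named logical per class) and
#'   `thickness_um` (named numeric per class).
#' @param compressed_axis_ratio minor/major axis ratio applied to compressed
#'   (cEA) lumens, in (0, 1].
#' @param wall_um endothelial wall (cytoskeletal ring) thickness, micrometres.
#' @param membrane_um membrane-marker ring thickness, micrometres.
#' @param marker_offset_px non-negative integer radial offset between the
#'   cytoskeletal and membrane channels (sub-cellular displacement).
#' @param bone_fraction area fraction of the FOV occupied by the trabecula
#'   polygon when bone is present, in [0, 1].
#' @param bone_prob named numeric; per-class probability that the FOV
#'   contains bone.
#' @param imhc_placement list: `mode` ("uniform" or "shell"), `shell_center`
#'   (a vessel class or "bone"), `shell_decay_um` (> 0), `clustered_fraction`
#'   in [0, 1], and `mean_per_image` (Poisson mean imHC count per FOV).
#' @param noise numeric `c(poisson_scale, gaussian_sd, background_level)`.
#' @param amplitude peak signal intensity (16-bit scale).
#' @param crosstalk channel crosstalk mixing coefficient in [0, 1).
#' @param seed integer master seed.
#'
#' @return A validated list of class `fixture_config`.
#' @export
fixture_config <- function(image_size_px = c(512L, 512L),
                           um_per_px = 0.5,
                           n_vessels_per_class = c(A = 58L, EA = 58L, cEA = 39L,
                                                   NCLT = 268L, NC = 64L),
                           ic_lognormal_params = list(
                             A    = c(meanlog = log(10.5), sdlog = 0.18),
                             EA   = c(meanlog = log(6.6),  sdlog = 0.12),
                             cEA  = c(meanlog = log(4.1),  sdlog = 0.20),
                             NCLT = c(meanlog = log(3.25), sdlog = 0.18)),
                           ic_trunc_um = list(
                             A    = c(8.6, 18),
                             EA   = c(4.9, 8.1),
                             cEA  = c(2.2, 5.6),
                             NCLT = c(2.4, 3.9)),
                           zero_lumen_prob = c(A = 0, EA = 0, cEA = 0,
                                               NCLT = 163 / 268, NC = 1),
                           pericyte_ring = list(
                             has = c(A = TRUE, EA = TRUE, cEA = TRUE,
                                     NCLT = FALSE, NC = FALSE),
                             thickness_um = c(A = 3.5, EA = 1.5, cEA = 1.5,
                                              NCLT = 0, NC = 0)),
                           compressed_axis_ratio = 0.45,
                           wall_um = 2.5,
                           membrane_um = 1,
                           marker_offset_px = 2L,
                           bone_fraction = 0.25,
                           bone_prob = c(A = 0.241, EA = 0.316, cEA = 0.316,
                                         NCLT = 0.457, NC = 0.437),
                           imhc_placement = list(mode = "shell",
                                                 shell_center = "NCLT",
                                                 shell_decay_um = 8,
                                                 clustered_fraction = 0.6,
                                                 mean_per_image = 2),
                           noise = c(poisson_scale = 0.05, gaussian_sd = 5,
                                     background_level = 10),
                           amplitude = 4000,
                           crosstalk = 0.02,
                           seed = 1L) {
  cfg <- list(image_size_px = as.integer(image_size_px), um_per_px = um_per_px,
              n_vessels_per_class = n_vessels_per_class,
              ic_lognormal_params = ic_lognormal_params,
              ic_trunc_um = ic_trunc_um, zero_lumen_prob = zero_lumen_prob,
              pericyte_ring = pericyte_ring,
              compressed_axis_ratio = compressed_axis_ratio,
              wall_um = wall_um, membrane_um = membrane_um,
              marker_offset_px = as.integer(marker_offset_px),
              bone_fraction = bone_fraction, bone_prob = bone_prob,
              imhc_placement = imhc_placement, noise = noise,
              amplitude = amplitude, crosstalk = crosstalk,
              seed = as.integer(seed))
  validate_fixture_config(cfg)
}

vessel_classes <- function() c("A", "EA", "cEA", "NCLT", "NC")

#' Validate a fixture configuration
#'
#' All violations are collected and reported in a single error.
#'
#' @param cfg a list with the fields of [fixture_config()].
#' @return The config, classed `fixture_config`, invisibly usable downstream.
#' @export
validate_fixture_config <- function(cfg) {
  ce <- collect_errors()
  cls <- vessel_classes()
  ce$check(length(cfg$image_size_px) == 2L && all(cfg$image_size_px >= 32L),
           "image_size_px must be two integers >= 32")
  ce$check(is_scalar_num(cfg$um_per_px) && cfg$um_per_px > 0,
           "um_per_px must be a positive number")
  ce$check(all(cls %in% names(cfg$n_vessels_per_class)) &&
             all(vapply(cfg$n_vessels_per_class, is_count, TRUE)),
           "n_vessels_per_class must give a non-negative count per class A/EA/cEA/NCLT/NC")
  for (cl in setdiff(cls, "NC")) {
    p <- cfg$ic_lognormal_params[[cl]]
    ce$check(is.numeric(p) && length(p) == 2L && p[2] >= 0,
             paste0("ic_lognormal_params$", cl, " must be c(meanlog, sdlog), sdlog >= 0"))
    tr <- cfg$ic_trunc_um[[cl]]
    ce$check(is.numeric(tr) && length(tr) == 2L && tr[1] > 0 && tr[2] > tr[1],
             paste0("ic_trunc_um$", cl, " must be an increasing positive pair"))
  }
  ce$check(all(cls %in% names(cfg$zero_lumen_prob)) &&
             all(cfg$zero_lumen_prob >= 0 & cfg$zero_lumen_prob <= 1),
           "zero_lumen_prob must be probabilities in [0,1] per class")
  ce$check(is.list(cfg$pericyte_ring) &&
             all(cls %in% names(cfg$pericyte_ring$has)) &&
             all(cls %in% names(cfg$pericyte_ring$thickness_um)) &&
             all(cfg$pericyte_ring$thickness_um >= 0),
           "pericyte_ring must give has (logical) and thickness_um (>= 0) per class")
  ce$check(is_scalar_num(cfg$compressed_axis_ratio) &&
             cfg$compressed_axis_ratio > 0 && cfg$compressed_axis_ratio <= 1,
           "compressed_axis_ratio must lie in (0, 1]")
  ce$check(is_scalar_num(cfg$wall_um) && cfg$wall_um > 0, "wall_um must be > 0")
  ce$check(is_scalar_num(cfg$membrane_um) && cfg$membrane_um > 0,
           "membrane_um must be > 0")
  ce$check(is_count(cfg$marker_offset_px), "marker_offset_px must be a non-negative integer")
  ce$check(is_scalar_num(cfg$bone_fraction) && cfg$bone_fraction >= 0 &&
             cfg$bone_fraction <= 1, "bone_fraction must lie in [0,1]")
  ce$check(all(cls %in% names(cfg$bone_prob)) &&
             all(cfg$bone_prob >= 0 & cfg$bone_prob <= 1),
           "bone_prob must be probabilities in [0,1] per class")
  pl <- cfg$imhc_placement
  ce$check(is.list(pl) && pl$mode %in% c("uniform", "shell"),
           "imhc_placement$mode must be 'uniform' or 'shell'")
  ce$check(is.null(pl$shell_center) || pl$shell_center %in% c(cls, "bone"),
           "imhc_placement$shell_center must be a vessel class or 'bone'")
  ce$check(is_scalar_num(pl$shell_decay_um %||% 1) && (pl$shell_decay_um %||% 1) > 0,
           "imhc_placement$shell_decay_um must be > 0")
  cf <- pl$clustered_fraction %||% 0
  ce$check(is_scalar_num(cf) && cf >= 0 && cf <= 1,
           "imhc_placement$clustered_fraction must lie in [0,1]")
  ce$check(is_scalar_num(pl$mean_per_image %||% 0) && (pl$mean_per_image %||% 0) >= 0,
           "imhc_placement$mean_per_image must be >= 0")
  ce$check(length(cfg$noise) == 3L && all(cfg$noise >= 0),
           "noise must be c(poisson_scale, gaussian_sd, background_level), all >= 0")
  ce$check(is_scalar_num(cfg$amplitude) && cfg$amplitude > 0, "amplitude must be > 0")
  ce$check(is_scalar_num(cfg$crosstalk) && cfg$crosstalk >= 0 && cfg$crosstalk < 1,
           "crosstalk must lie in [0,1)")
  ce$check(is_count(cfg$seed), "seed must be a non-negative integer")
  ce$fail_if_any("invalid fixture_config")
  structure(cfg, class = "fixture_config")
}
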