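#' Generate a synthetic micrograph dataset with ground truth
#'
#' Produces one field of view per NESTIN+ structure (the unit of analysis:
#' each confocal microphotograph is centred on one structure), with rendered
#' channels, label masks and ground-truth tables. Under a fixed config and
#' seed the output is bit-identical across runs.
#'
#' @param config a [fixture_config()].
#' @param keep_images logical; retain the rendered `micrograph_set`s in the
#'   returned object. Defaults to TRUE for datasets of at most 24 images,
#'   FALSE otherwise (images can still be consumed via `per_image`).
#' @param per_image optional function called with each rendered
#'   `micrograph_set` as it is produced (streaming use for large datasets).
#'
#' @return list of class `micrograph_dataset` with elements `config`,
#'   `truth` (`vessel_table`, `imhc_points`, `distance_table`) and `images`
#'   (list of `micrograph_set` or NULL). `vessel_table` has one row per
#'   rendered structure; `distance_table` carries the true centroid-to-bone
#'   distances (raw and IC-normalized, NA when no trabecula is in the FOV).
#' @export
generate_dataset <- function(config, keep_images = NULL, per_image = NULL) {
  cfg <- validate_fixture_config(config)
  counts <- cfg$n_vessels_per_class[vessel_classes()]
  n_total <- sum(counts)
  if (is.null(keep_images)) keep_images <- n_total <= 24

  set.seed(cfg$seed)
  classes <- sample(rep(names(counts), counts))      # shuffled image order
  # Imperceptible-lumen counts are fixed marginals (round(n * p) per class,
  # randomly allocated), not binomial draws: the no-lumen band is a stated
  # property of the emulated material, not a sampling fluctuation.
  ics <- vapply(classes, function(cl) draw_ic(cl, cfg), numeric(1))
  for (cl in names(counts)) {
    idx <- which(classes == cl)
    n_zero <- round(length(idx) * cfg$zero_lumen_prob[[cl]])
    if (n_zero > 0 && length(idx))
      ics[sample(idx, n_zero)] <- 0
  }
  peri <- unname(cfg$pericyte_ring$has[classes])
  tubular <- classes != "NC"
  compressed <- classes == "cEA"
  bone_here <- stats::runif(n_total) < unname(cfg$bone_prob[classes]) &
    cfg$bone_fraction > 0
  img_seeds <- vapply(seq_len(n_total), function(i) derive_seed(cfg$seed, i),
                      integer(1))

  H <- cfg$image_size_px[1]; W <- cfg$image_size_px[2]
  vrows <- vector("list", n_total)
  irows <- vector("list", n_total)
  images <- if (keep_images) vector("list", n_total) else NULL

  for (i in seq_len(n_total)) {
    set.seed(img_seeds[i])
    cl <- classes[i]
    patch <- render_vessel(cl, ics[i], has_pericytes = peri[i],
                           compressed = compressed[i],
                           axis_ratio = cfg$compressed_axis_ratio,
                           marker_offset_px = cfg$marker_offset_px,
                           um_per_px = cfg$um_per_px, wall_um = cfg$wall_um,
                           membrane_um = cfg$membrane_um,
                           pericyte_um = cfg$pericyte_ring$thickness_um[[cl]],
                           amplitude = cfg$amplitude)
    bone <- if (bone_here[i]) render_bone(c(H, W), cfg$bone_fraction, cfg$um_per_px)
            else matrix(FALSE, H, W)

    # The structure is framed near the FOV centre (micrographs are taken
    # centred on the vessel of interest), with modest jitter.
    half <- patch$dim[1] / 2
    for (try in 1:200) {
      r0 <- round(stats::runif(1, max(half + 1, H / 2 - H / 8),
                               min(H - half, H / 2 + H / 8)))
      c0 <- round(stats::runif(1, max(half + 1, W / 2 - W / 8),
                               min(W - half, W / 2 + W / 8)))
      if (!bone[r0, c0]) break
    }
    ch <- list(nestin = matrix(0, H, W), endo = matrix(0, H, W),
               peri = matrix(0, H, W))
    rows <- (r0 - patch$center[1] + 1):(r0 - patch$center[1] + patch$dim[1])
    cols <- (c0 - patch$center[2] + 1):(c0 - patch$center[2] + patch$dim[2])
    for (nm in names(ch)) ch[[nm]][rows, cols] <- patch$channels[[nm]]
    lumen <- matrix(FALSE, H, W); lumen[rows, cols] <- patch$lumen_mask
    wall <- matrix(FALSE, H, W); wall[rows, cols] <- patch$wall_mask
    # bone never overwrites the vessel body
    bone[wall | lumen] <- FALSE

    vt_img <- data.frame(id = i, class = cl, row_px = r0, col_px = c0,
                         lumen_r_px = ics[i] / (2 * cfg$um_per_px))
    pl <- cfg$imhc_placement
    n_imhc <- stats::rpois(1L, pl$mean_per_image %||% 0)
    eligible <- !identical(pl$mode, "shell") ||
      (identical(pl$shell_center, "bone") && any(bone)) ||
      identical(pl$shell_center, cl)
    pts <- place_imhcs(n_imhc, vt_img, c(H, W), cfg$um_per_px,
                       mode = if (eligible && identical(pl$mode, "shell"))
                         "shell" else "uniform",
                       shell_center = pl$shell_center %||% "NCLT",
                       shell_decay_um = pl$shell_decay_um %||% 8,
                       clustered_fraction = pl$clustered_fraction %||% 0,
                       bone_mask = bone)
    if (nrow(pts)) pts <- cbind(image_id = i, vessel_class = cl, pts)

    # nuclei channel: imHC nuclei plus sparse stromal nuclei
    nuc <- matrix(0, H, W)
    nuc_pts <- rbind(as.matrix(pts[, c("row_px", "col_px"), drop = FALSE]),
                     cbind(stats::runif(8, 1, H), stats::runif(8, 1, W)))
    for (k in seq_len(nrow(nuc_pts)))
      nuc <- nuc + disk_stamp(c(H, W), nuc_pts[k, 1], nuc_pts[k, 2],
                              2.5 / cfg$um_per_px) * cfg$amplitude / 2

    ch$nuclei <- nuc
    ch <- apply_noise(ch, cfg$noise, cfg$crosstalk)

    d_bone <- if (any(bone))
      point_to_mask_um(vt_img$row_px, vt_img$col_px, bone, cfg$um_per_px)
    else NA_real_

    vrows[[i]] <- cbind(vt_img[, c("id", "class", "row_px", "col_px")],
                        true_ic_um = ics[i], has_pericytes = peri[i],
                        tubular = tubular[i], compressed = compressed[i],
                        bone_in_fov = any(bone), d_bone_raw_um = d_bone,
                        image_id = i)
    irows[[i]] <- if (nrow(pts)) pts else NULL

    set_i <- list(channels = ch,
                  masks = list(lumen = lumen * i, wall = wall * i, bone = bone),
                  meta = list(image_id = i, vessel_id = i, class = cl,
                              um_per_px = cfg$um_per_px, seed = img_seeds[i]))
    class(set_i) <- "micrograph_set"
    if (!is.null(per_image)) per_image(set_i)
    if (keep_images) images[[i]] <- set_i
  }

  vessel_table <- do.call(rbind, vrows)
  imhc_points <- do.call(rbind, irows) %||%
    data.frame(image_id = integer(), vessel_class = character(),
               row_px = numeric(), col_px = numeric(), component = character(),
               target_id = integer(), d_target_um = numeric(),
               d_nearest_vessel_um = numeric())
  distance_table <- data.frame(
    structure_id = vessel_table$id, class = vessel_table$class,
    target_kind = "bone", d_raw_um = vessel_table$d_bone_raw_um,
    ic_um = vessel_table$true_ic_um,
    d_norm_um = ifelse(is.na(vessel_table$d_bone_raw_um), NA_real_,
                       pmax(0, vessel_table$d_bone_raw_um -
                              vessel_table$true_ic_um / 2)))
  structure(list(config = cfg, truth = list(vessel_table = vessel_table,
                                            imhc_points = imhc_points,
                                            distance_table = distance_table),
                 images = images),
            class = "micrograph_dataset")
}

# Truncated log-normal inner-caliber draw (zero-lumen allocation is done
# at the dataset level with fixed per-class counts).
draw_ic <- function(class, cfg) {
  if (cfg$zero_lumen_prob[[class]] >= 1) return(0)
  p <- cfg$ic_lognormal_params[[class]]
  tr <- cfg$ic_trunc_um[[class]]
  for (i in 1:10000) {
    x <- stats::rlnorm(1, p[1], p[2])
    if (x >= tr[1] && x <= tr[2]) return(x)
  }
  stop("inner-caliber truncation window too narrow for class ", class)
}

disk_stamp <- function(dim, r0, c0, radius) {
  grid <- coord_grid(dim, r0, c0)
  (grid$dx^2 + grid$dy^2) < radius^2
}

# Exact minimum Euclidean distance (micrometres) from a point to a mask.
point_to_mask_um <- function(r0, c0, mask, um_per_px) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NA_real_)
  sqrt(min((idx[, 1] - r0)^2 + (idx[, 2] - c0)^2)) * um_per_px
}

#' Write a micrograph set to disk
#'
#' One 16-bit grayscale TIFF per channel (`<basename>_<channel>.tif`), 16-bit
#' label TIFFs for the masks, and a JSON sidecar with the calibration.
#'
#' @param set a `micrograph_set`.
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @return invisibly, the vector of files written.
#' @export
write_micrograph_set <- function(set, dir, basename = "set") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(set$channels)) {
    f <- file.path(dir, paste0(basename, "_", nm, ".tif"))
    tiff::writeTIFF(pmin(set$channels[[nm]], 65535) / 65535, f,
                    bits.per.sample = 16L)
    files <- c(files, f)
  }
  for (nm in names(set$masks)) {
    f <- file.path(dir, paste0(basename, "_mask_", nm, ".tif"))
    tiff::writeTIFF(pmin(set$masks[[nm]] * 1, 65535) / 65535, f,
                    bits.per.sample = 16L)
    files <- c(files, f)
  }
  meta <- file.path(dir, paste0(basename, "_meta.json"))
  jsonlite::write_json(set$meta, meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta))
}

#' Read a single-channel TIFF as an intensity matrix
#'
#' Values are returned on the stored integer scale (0..65535 for 16-bit).
#'
#' @param path TIFF file path.
#' @return numeric matrix.
#' @export
read_channel_tiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}
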