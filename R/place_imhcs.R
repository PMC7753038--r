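#' Place immature haematopoietic cells (imHCs) in a synthetic field of view
#'
#' Generates imHC centroids that are either uniform over the marrow area or a
#' mixture in which a `clustered_fraction` of cells sits in an exponential
#' shell around target structures: for each clustered cell a target is chosen
#' at random among the eligible structures (vessels of class `shell_center`,
#' or the bone surface), a distance is drawn from Exponential(mean =
#' `shell_decay_um`), and the cell is placed at that distance in a random
#' direction. Cells never fall inside the bone mask or a vessel lumen
#' (rejection sampling, which re-draws distance and direction together so the
#' accepted radial law stays exponential).
#'
#' @param n number of cells to place.
#' @param vessel_table data.frame with columns `id`, `class`, `row_px`,
#'   `col_px` (1-based pixel centroids) and optionally `lumen_r_px`.
#' @param image_size_px integer (rows, cols).
#' @param um_per_px micrometres per pixel.
#' @param mode `"uniform"` or `"shell"`.
#' @param shell_center vessel class or `"bone"`; targets of the shell.
#' @param shell_decay_um mean of the exponential shell, micrometres.
#' @param clustered_fraction fraction of cells drawn from the shell component.
#' @param bone_mask optional logical matrix; cells are excluded from bone.
#' @param seed optional integer; when given, placement is deterministic.
#'
#' @return data.frame, one row per cell: `row_px`, `col_px` (continuous,
#'   1-based), `component` ("clustered"/"uniform"), `target_id`,
#'   `d_target_um` (distance to the chosen target; NA for uniform cells) and
#'   `d_nearest_vessel_um` (distance to the nearest vessel centroid).
#' @export
place_imhcs <- function(n, vessel_table, image_size_px, um_per_px,
                        mode = c("shell", "uniform"), shell_center = "NCLT",
                        shell_decay_um = 8, clustered_fraction = 0.6,
                        bone_mask = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is_count(n), um_per_px > 0, shell_decay_um > 0,
            clustered_fraction >= 0, clustered_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "uniform") clustered_fraction <- 0

  targets <- NULL
  if (clustered_fraction > 0) {
    if (identical(shell_center, "bone")) {
      if (is.null(bone_mask) || !any(bone_mask))
        stop("clustered placement around bone requires a non-empty bone_mask")
      surf <- which(bone_surface(bone_mask), arr.ind = TRUE)
      targets <- data.frame(row_px = surf[, 1], col_px = surf[, 2])
    } else {
      targets <- vessel_table[vessel_table$class == shell_center, , drop = FALSE]
      if (nrow(targets) == 0L)
        stop("clustered placement requires at least one vessel of class ",
             shell_center)
    }
  }

  lum_r <- vessel_table$lumen_r_px %||% rep(0, nrow(vessel_table))
  inside_excluded <- function(r, c) {
    if (!is.null(bone_mask)) {
      ri <- round(r); ci <- round(c)
      if (ri >= 1 && ri <= nrow(bone_mask) && ci >= 1 && ci <= ncol(bone_mask) &&
          bone_mask[ri, ci]) return(TRUE)
    }
    if (nrow(vessel_table)) {
      d2 <- (vessel_table$row_px - r)^2 + (vessel_table$col_px - c)^2
      if (any(d2 < lum_r^2)) return(TRUE)
    }
    FALSE
  }

  n_clu <- stats::rbinom(1L, n, clustered_fraction)
  out <- vector("list", n)
  H <- image_size_px[1]; W <- image_size_px[2]
  for (i in seq_len(n)) {
    clustered <- i <= n_clu
    for (try in seq_len(10000L)) {
      if (clustered) {
        k <- sample.int(nrow(targets), 1L)
        d_um <- stats::rexp(1L, rate = 1 / shell_decay_um)
        th <- stats::runif(1L, 0, 2 * pi)
        r <- targets$row_px[k] + sin(th) * d_um / um_per_px
        c <- targets$col_px[k] + cos(th) * d_um / um_per_px
        tid <- if (identical(shell_center, "bone")) NA else targets$id[k]
      } else {
        r <- stats::runif(1L, 0.5, H + 0.5)
        c <- stats::runif(1L, 0.5, W + 0.5)
        d_um <- NA_real_; tid <- NA
      }
      if (r >= 0.5 && r <= H + 0.5 && c >= 0.5 && c <= W + 0.5 &&
          !inside_excluded(r, c)) break
      if (try == 10000L) stop("imHC placement failed: no admissible location found")
    }
    dnv <- if (nrow(vessel_table))
      sqrt(min((vessel_table$row_px - r)^2 + (vessel_table$col_px - c)^2)) * um_per_px
    else NA_real_
    out[[i]] <- data.frame(row_px = r, col_px = c,
                           component = if (clustered) "clustered" else "uniform",
                           target_id = tid, d_target_um = d_um,
                           d_nearest_vessel_um = dnv)
  }
  if (n == 0L)
    return(data.frame(row_px = numeric(), col_px = numeric(),
                      component = character(), target_id = integer(),
                      d_target_um = numeric(), d_nearest_vessel_um = numeric()))
  do.call(rbind, out)
}

# Surface (boundary) pixels of a mask: mask pixels with a 4-neighbour outside.
bone_surface <- function(mask) {
  m <- mask
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
  mask & !(up & dn & lf & rt)
}
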