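# Geometric rendering of vessel cross-sections.
#
# A vessel is drawn as nested ellipses around a common centre. Normalised
# radius q(y, x) = sqrt((dx/a)^2 + (dy/b)^2) so that q < 1 is the lumen
# interior; annuli are bands in "axis-offset" space: the band between offsets
# (o1, o2) contains pixels with ellipse(a + o1, b + o1) <= . < ellipse(a + o2,
# b + o2). Circles are the a == b special case. Pixel-centre inclusion is
# strict (< outer, >= inner), which makes the rasterised lumen extent equal
# to the true diameter within one pixel.

norm_radius <- function(grid, a, b) {
  if (a <= 0 || b <= 0) return(matrix(Inf, nrow(grid$dy), ncol(grid$dy)))
  sqrt((grid$dx / a)^2 + (grid$dy / b)^2)
}

ellipse_band <- function(grid, a, b, o1, o2) {
  inner <- if (a + o1 <= 0 || b + o1 <= 0) NULL else norm_radius(grid, a + o1, b + o1)
  outer <- norm_radius(grid, a + o2, b + o2)
  m <- outer < 1
  if (!is.null(inner)) m <- m & (inner >= 1)
  m
}

#' Render one vessel cross-section patch
#'
#' Draws a single NESTIN+ structure as a noiseless multi-channel patch: the
#' cytoskeletal (NESTIN) channel fills the endothelial wall annulus, the
#' membrane channel (CD34/CD31) is a thinner ring displaced radially outward
#' by `marker_offset_px` (sub-cellular displacement: co-occurrence without
#' pixel-wise coincidence), and, when present, a perivascular (CD146/aSMA)
#' ring lies strictly outside the wall. Compressed lumens are rendered as
#' ellipses with minor axis `ic_um` and axis ratio `axis_ratio`.
#'
#' @param class one of `A`, `EA`, `cEA`, `NCLT`, `NC`.
#' @param ic_um inner caliber (minor axis of the lumen) in micrometres;
#'   0 renders an imperceptible lumen (filled body, empty lumen mask).
#' @param has_pericytes logical, draw the perivascular ring.
#' @param compressed logical, render an elliptical (compressed) lumen.
#' @param axis_ratio minor/major ratio for compressed lumens.
#' @param marker_offset_px radial offset (pixels) of the membrane ring.
#' @param um_per_px micrometres per pixel.
#' @param wall_um,membrane_um,pericyte_um ring thicknesses in micrometres.
#' @param amplitude peak intensity of the rendered rings.
#' @param patch_px optional patch side in pixels; computed from the geometry
#'   when `NULL`. An `ic_um` too large for the requested patch is an error.
#'
#' @return list with `channels` (matrices `nestin`, `endo`, `peri`),
#'   `lumen_mask`, `wall_mask` (logical matrices), `dim` and `center`
#'   (row, col of the vessel centre).
#' @export
render_vessel <- function(class, ic_um, has_pericytes = FALSE,
                          compressed = FALSE, axis_ratio = 0.45,
                          marker_offset_px = 2L, um_per_px = 0.5,
                          wall_um = 2.5, membrane_um = 1, pericyte_um = 1.5,
                          amplitude = 4000, patch_px = NULL) {
  stopifnot(class %in% vessel_classes(), is_scalar_num(ic_um), ic_um >= 0,
            um_per_px > 0)
  if (class == "NC" && has_pericytes)
    stop("non-tubular single cells (NC) carry no perivascular ring")

  b <- ic_um / (2 * um_per_px)                      # lumen semi-minor, px
  a <- if (compressed && b > 0) b / axis_ratio else b
  wall_px <- max(wall_um / um_per_px, 1)
  memb_px <- max(membrane_um / um_per_px, 1)
  peri_px <- max(pericyte_um / um_per_px, 1)
  off <- as.numeric(marker_offset_px)

  reach <- a + max(wall_px, off + memb_px,
                   if (has_pericytes) wall_px + 1 + peri_px else 0)
  need <- ceiling(2 * reach) + 5L
  if (need %% 2L == 0L) need <- need + 1L          # odd side: integer centre
  n <- if (is.null(patch_px)) need else as.integer(patch_px)
  if (n < need) stop("ic_um too large for the requested patch size")

  ctr <- (n + 1) / 2
  grid <- coord_grid(c(n, n), ctr, ctr)

  # Graded (Gaussian) radial intensity profiles: fluorescence falls off
  # smoothly across a stained layer rather than as a binary band. `tpx` is
  # the signed radial distance (pixels) outward from the lumen boundary.
  if (b > 0) {
    q <- norm_radius(grid, a, b)
    tpx <- (q - 1) * sqrt(a * b)
    lumen <- q < 1
    nestin_m <- ellipse_band(grid, a, b, 0, wall_px)
    endo_m <- ellipse_band(grid, a, b, off, off + memb_px)
  } else {
    # Imperceptible lumen: solid cytoskeletal body, membrane at its surface.
    body <- wall_px
    d <- sqrt(grid$dx^2 + grid$dy^2)
    tpx <- d - body + wall_px              # body interior maps onto the wall
    lumen <- matrix(FALSE, n, n)
    nestin_m <- d < body
    endo_m <- ellipse_band(grid, body - memb_px, body - memb_px, off, off + memb_px)
  }
  nestin_i <- amplitude * exp(-0.5 * ((tpx - wall_px / 2) / (wall_px / 2.2))^2)
  endo_i <- amplitude * exp(-0.5 * ((tpx - (off + memb_px / 2)) / (memb_px / 1.5))^2)
  nestin_i[nestin_i < amplitude * 0.01] <- 0
  endo_i[endo_i < amplitude * 0.01] <- 0
  if (b == 0) {                            # solid body: flat-topped core
    d <- sqrt(grid$dx^2 + grid$dy^2)
    nestin_i <- pmax(nestin_i, amplitude * (d < wall_px / 2))
  }

  peri_m <- matrix(FALSE, n, n)
  peri_i <- matrix(0, n, n)
  if (has_pericytes) {
    peri_m <- ellipse_band(grid, a, b, wall_px + 1, wall_px + 1 + peri_px)
    peri_i <- amplitude *
      exp(-0.5 * ((tpx - (wall_px + 1 + peri_px / 2)) / (peri_px / 1.5))^2)
    peri_i[peri_i < amplitude * 0.01] <- 0
    peri_i[nestin_m | lumen] <- 0          # strictly sub-endothelial
  }

  list(channels = list(nestin = nestin_i, endo = endo_i, peri = peri_i),
       lumen_mask = lumen, wall_mask = nestin_m,
       dim = c(n, n), center = c(ctr, ctr))
}

# Smoothed random polygon entering from one image edge, covering roughly
# `fraction` of the frame: mimics a trabecula crossing a trephine FOV.
render_bone <- function(dim, fraction, um_per_px) {
  if (fraction <= 0) return(matrix(FALSE, dim[1], dim[2]))
  edge <- sample.int(4L, 1L)
  n_long <- if (edge <= 2L) dim[2] else dim[1]
  # random smooth depth profile along the edge
  k <- 6L
  knots <- stats::runif(k, 0.5, 1.5)
  prof <- stats::spline(seq(0, 1, length.out = k), knots,
                        xout = seq(0, 1, length.out = n_long))$y
  prof <- pmax(prof, 0.05)
  depth0 <- fraction * (if (edge <= 2L) dim[1] else dim[2])
  depth <- prof * depth0 / mean(prof)
  m <- matrix(FALSE, dim[1], dim[2])
  if (edge == 1L) for (j in seq_len(dim[2])) m[seq_len(min(dim[1], max(1, round(depth[j])))), j] <- TRUE
  if (edge == 2L) for (j in seq_len(dim[2])) m[dim[1] - seq_len(min(dim[1], max(1, round(depth[j])))) + 1L, j] <- TRUE
  if (edge == 3L) for (i in seq_len(dim[1])) m[i, seq_len(min(dim[2], max(1, round(depth[i]))))] <- TRUE
  if (edge == 4L) for (i in seq_len(dim[1])) m[i, dim[2] - seq_len(min(dim[2], max(1, round(depth[i])))) + 1L] <- TRUE
  m
}

# Fluorescence noise model: crosstalk mixing between the cytoskeletal and
# membrane channels, additive background, Poisson photon noise at
# `poisson_scale` photons per intensity unit, then Gaussian read noise.
apply_noise <- function(channels, noise, crosstalk) {
  ps <- noise[[1]]; gsd <- noise[[2]]; bg <- noise[[3]]
  if (crosstalk > 0) {
    ne <- channels$nestin + crosstalk * channels$endo
    en <- channels$endo + crosstalk * channels$nestin
    channels$nestin <- ne
    channels$endo <- en
  }
  lapply(channels, function(ch) {
    ch <- ch + bg
    if (ps > 0) ch <- matrix(stats::rpois(length(ch), ch * ps) / ps, nrow(ch))
    if (gsd > 0) ch <- ch + matrix(stats::rnorm(length(ch), 0, gsd), nrow(ch))
    pmax(ch, 0)
  })
}
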