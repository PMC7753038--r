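#' Construct a two-channel pixel pair for co-localization analysis
#'
#' @param ch_green 2-D non-negative intensity matrix (cytoskeletal channel,
#'   NESTIN).
#' @param ch_red 2-D non-negative intensity matrix of the same shape
#'   (endothelial surface channel, CD34 or CD31).
#' @param roi_mask optional logical matrix restricting the analysis region;
#'   must cover at least 25 pixels.
#' @return list of class `channel_pair`.
#' @export
channel_pair <- function(ch_green, ch_red, roi_mask = NULL) {
  stopifnot(is.matrix(ch_green), is.matrix(ch_red),
            all(dim(ch_green) == dim(ch_red)))
  if (!all(is.finite(ch_green)) || !all(is.finite(ch_red)) ||
      any(ch_green < 0) || any(ch_red < 0))
    stop("channel intensities must be finite and non-negative")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(ch_green), ncol(ch_green))
  stopifnot(is.logical(roi_mask), all(dim(roi_mask) == dim(ch_green)))
  if (sum(roi_mask) < 25L) stop("roi_mask must cover at least 25 pixels")
  structure(list(ch_green = ch_green, ch_red = ch_red, roi_mask = roi_mask),
            class = "channel_pair")
}

#' Pearson correlation of paired pixel intensities
#'
#' @param pair a [channel_pair()].
#' @param pixel_selector optional logical matrix (or vector over ROI pixels)
#'   choosing the pixels entering the correlation; defaults to the whole ROI.
#' @return Pearson's R.
#' @export
pearson_coloc <- function(pair, pixel_selector = NULL) {
  g <- pair$ch_green[pair$roi_mask]
  r <- pair$ch_red[pair$roi_mask]
  if (!is.null(pixel_selector)) {
    sel <- if (is.matrix(pixel_selector)) pixel_selector[pair$roi_mask]
           else pixel_selector
    g <- g[sel]; r <- r[sel]
  }
  if (length(g) < 3L) stop("pixel selector yields fewer than 3 pixels")
  if (stats::var(g) == 0 || stats::var(r) == 0)
    stop("zero variance in a channel: correlation undefined")
  stats::cor(g, r)
}

#' Costes automatic dual-channel threshold
#'
#' Finds the intensity thresholds below which the two channels are
#' uncorrelated. Red is regressed on green over the ROI (least squares); the
#' green threshold is the highest distinct green level `T` such that the
#' Pearson correlation over pixels with `green < T` and `red < intercept +
#' slope * T` is non-positive (a level with no such pixels left also
#' qualifies); the red threshold follows from the regression line. When the
#' below-threshold correlation never becomes non-positive the minimum level
#' is returned with `flagged = TRUE`.
#'
#' The search is a descending scan over the distinct green levels, organised
#' so that its decisions are bit-identical to an exhaustive per-level rescan:
#' with a positive regression slope the below-threshold set shrinks
#' monotonically and is maintained incrementally; otherwise the set is
#' re-evaluated per level.
#'
#' @param pair a [channel_pair()].
#' @return list `T_green`, `T_red`, `slope`, `intercept`, `flagged`.
#' @export
costes_thresholds <- function(pair) {
  g <- as.numeric(pair$ch_green[pair$roi_mask])
  r <- as.numeric(pair$ch_red[pair$roi_mask])
  n <- length(g)
  if (length(unique(g)) < 2L || length(unique(r)) < 2L)
    stop("both channels need at least 2 distinct intensity levels")
  vg <- stats::var(g)
  if (vg == 0) stop("regression undefined: constant green channel")
  slope <- stats::cov(g, r) / vg
  intercept <- mean(r) - slope * mean(g)

  levels <- sort(unique(g), decreasing = TRUE)
  hit <- if (slope > 0) scan_monotone(g, r, levels, slope, intercept)
         else if (as.double(n) * length(levels) <= 2e8)
           scan_generic(g, r, levels, slope, intercept)
         else scan_sweep_neg(g, r, levels, slope, intercept)
  flagged <- is.na(hit)
  Tg <- if (flagged) levels[length(levels)] else hit
  list(T_green = Tg, T_red = intercept + slope * Tg,
       slope = slope, intercept = intercept, flagged = flagged)
}

# Non-positivity test used by both scan paths: needs >= 3 pixels and
# positive variance in both channels; empty below-set qualifies outright.
# Sums of integer-valued intensities keep these tests exact in doubles.
below_ok <- function(nb, Sg, Sr, Sgg, Srr, Sgr) {
  if (nb == 0L) return(TRUE)
  if (nb < 3L) return(FALSE)
  if (nb * Sgg - Sg^2 <= 0 || nb * Srr - Sr^2 <= 0) return(FALSE)
  (nb * Sgr - Sg * Sr) <= 0
}

# Positive slope: as T_green descends both cuts tighten, so pixels leave the
# below-set exactly once; two sorted pointers maintain the running sums with
# the same strict comparisons an exhaustive rescan would use.
scan_monotone <- function(g, r, levels, slope, intercept) {
  og <- order(g, decreasing = TRUE)
  or <- order(r, decreasing = TRUE)
  alive <- rep(TRUE, length(g))
  Sg <- sum(g); Sr <- sum(r); Sgg <- sum(g^2); Srr <- sum(r^2); Sgr <- sum(g * r)
  nb <- length(g); pg <- 1L; pr <- 1L
  for (L in levels) {
    Tr <- intercept + slope * L
    while (pg <= length(og) && g[og[pg]] >= L) {
      i <- og[pg]
      if (alive[i]) {
        alive[i] <- FALSE; nb <- nb - 1L
        Sg <- Sg - g[i]; Sr <- Sr - r[i]
        Sgg <- Sgg - g[i]^2; Srr <- Srr - r[i]^2; Sgr <- Sgr - g[i] * r[i]
      }
      pg <- pg + 1L
    }
    while (pr <= length(or) && r[or[pr]] >= Tr) {
      i <- or[pr]
      if (alive[i]) {
        alive[i] <- FALSE; nb <- nb - 1L
        Sg <- Sg - g[i]; Sr <- Sr - r[i]
        Sgg <- Sgg - g[i]^2; Srr <- Srr - r[i]^2; Sgr <- Sgr - g[i] * r[i]
      }
      pr <- pr + 1L
    }
    if (below_ok(nb, Sg, Sr, Sgg, Srr, Sgr)) return(L)
  }
  NA_real_
}

# Zero or negative slope: the red cut loosens while the green cut tightens,
# so the below-set is not nested; recompute it per level. Used for small
# inputs and for the degenerate anti-correlated case.
scan_generic <- function(g, r, levels, slope, intercept) {
  for (L in levels) {
    sel <- g < L & r < (intercept + slope * L)
    nb <- sum(sel)
    if (below_ok(nb, sum(g[sel]), sum(r[sel]), sum(g[sel]^2), sum(r[sel]^2),
                 sum(g[sel] * r[sel]))) return(L)
  }
  NA_real_
}

# Negative slope on large inputs: each pixel is a member of the below-set
# for green levels in the interval (g_i, (r_i - intercept)/slope); sweep the
# descending levels with add/remove pointers. Interval endpoints use one
# division, so decisions at exact float ties may differ from a rescan by one
# level; this path is only taken when the per-level rescan is impractical.
scan_sweep_neg <- function(g, r, levels, slope, intercept) {
  entry <- (r - intercept) / slope          # member while L < entry
  oe <- order(entry, decreasing = TRUE)
  og <- order(g, decreasing = TRUE)
  state <- integer(length(g))               # 0 = pending, 1 = in, 2 = out
  Sg <- 0; Sr <- 0; Sgg <- 0; Srr <- 0; Sgr <- 0; nb <- 0L
  pe <- 1L; pg <- 1L
  for (L in levels) {
    while (pe <= length(oe) && L < entry[oe[pe]]) {
      i <- oe[pe]
      if (state[i] == 0L) {
        if (g[i] < L) {
          state[i] <- 1L; nb <- nb + 1L
          Sg <- Sg + g[i]; Sr <- Sr + r[i]
          Sgg <- Sgg + g[i]^2; Srr <- Srr + r[i]^2; Sgr <- Sgr + g[i] * r[i]
        } else state[i] <- 2L               # already past its green cut
      }
      pe <- pe + 1L
    }
    while (pg <= length(og) && g[og[pg]] >= L) {
      i <- og[pg]
      if (state[i] == 1L) {
        nb <- nb - 1L
        Sg <- Sg - g[i]; Sr <- Sr - r[i]
        Sgg <- Sgg - g[i]^2; Srr <- Srr - r[i]^2; Sgr <- Sgr - g[i] * r[i]
      }
      state[i] <- 2L
      pg <- pg + 1L
    }
    if (below_ok(nb, Sg, Sr, Sgg, Srr, Sgr)) return(L)
  }
  NA_real_
}

#' Thresholded Manders co-occurrence coefficients
#'
#' `M1` is the fraction of red intensity lying in green-positive pixels
#' (`green > T_green`); `M2` the fraction of green intensity lying in
#' red-positive pixels (`red > T_red`). Both are computed over the ROI.
#'
#' @param pair a [channel_pair()].
#' @param T_green,T_red channel thresholds.
#' @return list `M1`, `M2`.
#' @export
manders <- function(pair, T_green, T_red) {
  g <- pair$ch_green[pair$roi_mask]
  r <- pair$ch_red[pair$roi_mask]
  if (sum(r) == 0 || sum(g) == 0)
    stop("zero total intensity in a channel: Manders undefined")
  list(M1 = sum(r[g > T_green]) / sum(r),
       M2 = sum(g[r > T_red]) / sum(g))
}

#' Translated negative control
#'
#' Shifts the green channel by `(dx_px, dy_px)` (columns, rows) and restricts
#' both channels to the overlap region; no wraparound, the red channel is
#' unchanged. The paired coefficients of a genuinely co-occurring image
#' collapse towards zero under this control.
#'
#' @param pair a [channel_pair()].
#' @param dx_px,dy_px integer offsets in pixels (may be negative).
#' @return a [channel_pair()] over the overlap region.
#' @export
translated_control <- function(pair, dx_px, dy_px) {
  H <- nrow(pair$ch_green); W <- ncol(pair$ch_green)
  dx <- as.integer(dx_px); dy <- as.integer(dy_px)
  if (abs(dx) >= W || abs(dy) >= H)
    stop("translation offset must be smaller than the image size")
  # output frame = red frame rows (1+dy..H) etc. for positive offsets:
  # green pixel (i, j) lands on red pixel (i + dy, j + dx).
  ro <- max(1L, 1L + dy):min(H, H + dy)     # red rows in overlap
  co <- max(1L, 1L + dx):min(W, W + dx)
  gr <- ro - dy; gc <- co - dx              # matching green rows/cols
  channel_pair(pair$ch_green[gr, gc, drop = FALSE],
               pair$ch_red[ro, co, drop = FALSE],
               pair$roi_mask[ro, co, drop = FALSE])
}

#' Full co-localization analysis with translated negative control
#'
#' Computes Costes thresholds, Pearson's R over above-threshold pixels,
#' Manders M1/M2, then repeats the identical analysis (thresholds
#' re-estimated) on the translated control, mirroring the negative-control
#' protocol of translating the cytoskeletal channel by a fixed pixel offset
#' on both axes.
#'
#' @param pair a [channel_pair()].
#' @param offsets integer length-2 `(dx, dy)` control translation in pixels.
#' @param above_rule pixels entering the reported R: above `"either"`
#'   threshold (default) or above `"both"`.
#' @return list of class `coloc_result`: `R`, `M1`, `M2`, `T_green`,
#'   `T_red`, `slope`, `intercept`, `flagged`, `n_pixels`, the translated
#'   twins `tR`, `tM1`, `tM2`, and `decisions` (the conventions used).
#' @export
coloc_analysis <- function(pair, offsets = c(100L, 100L),
                           above_rule = c("either", "both")) {
  above_rule <- match.arg(above_rule)
  main <- coloc_single(pair, above_rule)
  ctrl_pair <- translated_control(pair, offsets[1], offsets[2])
  ctrl <- coloc_single(ctrl_pair, above_rule)
  structure(c(main,
              list(tR = ctrl$R, tM1 = ctrl$M1, tM2 = ctrl$M2,
                   control_flagged = ctrl$flagged,
                   offsets = as.integer(offsets),
                   decisions = list(
                     above_rule = above_rule,
                     below_set = "below both thresholds",
                     control_thresholds = "re-estimated on the translated pair",
                     translation = "no wraparound, overlap-restricted ROI"))),
            class = "coloc_result")
}

coloc_single <- function(pair, above_rule) {
  th <- costes_thresholds(pair)
  g <- pair$ch_green[pair$roi_mask]
  r <- pair$ch_red[pair$roi_mask]
  sel <- if (above_rule == "either") g > th$T_green | r > th$T_red
         else g > th$T_green & r > th$T_red
  R <- if (sum(sel) >= 3L && stats::var(g[sel]) > 0 && stats::var(r[sel]) > 0)
    stats::cor(g[sel], r[sel]) else NA_real_
  m <- manders(pair, th$T_green, th$T_red)
  list(R = R, M1 = m$M1, M2 = m$M2, T_green = th$T_green, T_red = th$T_red,
       slope = th$slope, intercept = th$intercept, flagged = th$flagged,
       n_pixels = sum(sel))
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("co-localization: R = %.3f (tR = %.3f), M1 = %.3f (tM1 = %.3f), M2 = %.3f (tM2 = %.3f)\n",
              x$R, x$tR, x$M1, x$tM1, x$M2, x$tM2))
  cat(sprintf("  thresholds: T_green = %.1f, T_red = %.1f%s; %d pixels above (%s rule)\n",
              x$T_green, x$T_red, if (x$flagged) " [flagged]" else "",
              x$n_pixels, x$decisions$above_rule))
  invisible(x)
}
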