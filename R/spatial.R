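#' Spatial analysis window configuration
#'
#' The endosteal region is conventionally the marrow within 40 micrometres
#' of the bone surface; the perivascular shell of interest around
#' capillaries is 20 micrometres; bone contact is scored below 10
#' micrometres.
#'
#' @param endosteal_window_um,perivascular_window_um,bone_contact_window_um
#'   window widths in micrometres; must satisfy
#'   `bone_contact < perivascular < endosteal`.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(endosteal_window_um = 40,
                            perivascular_window_um = 20,
                            bone_contact_window_um = 10) {
  ce <- collect_errors()
  ce$check(is_scalar_num(endosteal_window_um) && endosteal_window_um > 0,
           "endosteal_window_um must be a positive number")
  ce$check(is_scalar_num(perivascular_window_um) && perivascular_window_um > 0,
           "perivascular_window_um must be a positive number")
  ce$check(is_scalar_num(bone_contact_window_um) && bone_contact_window_um > 0,
           "bone_contact_window_um must be a positive number")
  if (!length(ce$messages()))
    ce$check(bone_contact_window_um < perivascular_window_um &&
               perivascular_window_um < endosteal_window_um,
             "windows must be ordered: bone_contact < perivascular < endosteal")
  ce$fail_if_any("invalid analysis_config")
  structure(list(endosteal_window_um = endosteal_window_um,
                 perivascular_window_um = perivascular_window_um,
                 bone_contact_window_um = bone_contact_window_um,
                 verdict_rules = paste(
                   "right-skewed iff p_sw < 0.05 and z >= 2;",
                   "normal iff p_sw >= 0.05; otherwise symmetric non-normal;",
                   "insufficient-n below 5 values")),
            class = "analysis_config")
}

#' Distance from a structure centroid to the nearest target pixel
#'
#' Exact minimum Euclidean distance, in micrometres, from the centroid of
#' `structure_mask` to the target set (its boundary, when approached from
#' outside). An empty target (no trabecula in the field of view) yields a
#' flagged missing value, `NA`.
#'
#' @param structure_mask,target_mask logical matrices of equal size.
#' @param um_per_px micrometres per pixel.
#' @return distance in micrometres, or `NA` when the target is empty.
#' @export
nearest_distance <- function(structure_mask, target_mask, um_per_px) {
  stopifnot(all(dim(structure_mask) == dim(target_mask)), um_per_px > 0)
  idx <- which(structure_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty structure mask")
  ctr <- colMeans(idx)
  point_to_mask_um(ctr[1], ctr[2], target_mask != 0, um_per_px)
}

#' Normalize a distance by the vessel inner caliber
#'
#' Converts a centre-referenced distance to a surface-referenced one by
#' subtracting half of the inner caliber; negative results mean contact and
#' are floored at zero.
#'
#' @param d_raw_um raw centroid distance(s), micrometres.
#' @param ic_um inner caliber(s), micrometres.
#' @return normalized distance(s), micrometres.
#' @export
normalize_distance <- function(d_raw_um, ic_um) {
  if (any(d_raw_um < 0, na.rm = TRUE) || any(ic_um < 0, na.rm = TRUE))
    stop("distances and calibers must be non-negative")
  pmax(0, d_raw_um - ic_um / 2)
}

#' Bone co-occurrence test between a vessel group and the rest
#'
#' 2 x 2 Pearson chi-square (no continuity correction) of the
#' bone-in-field-of-view flags, group versus rest, with Fisher's exact test
#' substituted when any expected count falls below 5.
#'
#' @param flags_group,flags_rest logical vectors.
#' @return list: `proportion_group`, `proportion_rest` (percent, one
#'   decimal), `direction`, `p`, `test`.
#' @export
cooccurrence_test <- function(flags_group, flags_rest) {
  stopifnot(length(flags_group) >= 1L, length(flags_rest) >= 1L)
  tb <- rbind(group = c(sum(flags_group), sum(!flags_group)),
              rest = c(sum(flags_rest), sum(!flags_rest)))
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop("degenerate margins in the co-occurrence table")
  expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tb)$p.value
    test <- "Fisher exact"
  } else {
    p <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))$p.value
    test <- "Pearson chi-square, no continuity correction"
  }
  pg <- mean(flags_group) * 100; pr <- mean(flags_rest) * 100
  list(proportion_group = round(pg, 1), proportion_rest = round(pr, 1),
       direction = if (pg > pr) "higher" else if (pg < pr) "lower" else "equal",
       p = p, test = test)
}

#' Sample skewness and its z-score
#'
#' Adjusted Fisher-Pearson sample skewness
#' `G1 = m3 / m2^(3/2) * sqrt(n (n-1)) / (n - 2)` with its exact
#' finite-sample standard error
#' `SE = sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))` and the z-score `G1 / SE`,
#' reported raw and rounded to the nearest integer (the convention of the
#' descriptive output this reproduces).
#'
#' @param values numeric vector, n >= 5.
#' @return list `g1`, `se_g1`, `z`, `z_rounded`, `n`.
#' @export
skewness_z <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 5L) stop("need at least 5 values for the skewness z-score")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("zero variance: skewness undefined")
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5 * sqrt(n * (n - 1)) / (n - 2)
  se <- skewness_se(n)
  list(g1 = g1, se_g1 = se, z = g1 / se, z_rounded = round(g1 / se), n = n)
}

#' Standard error of the sample skewness
#'
#' `sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))`, the exact normal-theory standard
#' error of the adjusted Fisher-Pearson skewness G1.
#'
#' @param n sample size (>= 5).
#' @return the standard error.
#' @export
skewness_se <- function(n) {
  stopifnot(n >= 5)
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

#' Skewness z-score from a reported skewness and sample size
#'
#' For reproducing published skewness/z pairs: `z = g1 / SE(g1)` with the
#' exact finite-sample standard error, rounded to the nearest integer as in
#' the descriptive reports.
#'
#' @param g1 sample skewness (adjusted Fisher-Pearson).
#' @param n sample size.
#' @return list `z`, `z_rounded`, `se_g1`.
#' @export
skewness_zscore <- function(g1, n) {
  se <- skewness_se(n)
  list(z = g1 / se, z_rounded = round(g1 / se), se_g1 = se)
}

#' Distribution diagnostics for a distance series
#'
#' Shapiro-Wilk normality test, skewness z-score and de-trended Q-Q
#' ordinates (sorted values minus the normal line fitted by sample mean and
#' SD, against standard normal quantiles at plotting positions
#' `(i - 0.5)/n`, or Blom's `(i - 3/8)/(n + 1/4)`).
#'
#' @param values numeric distance series, micrometres.
#' @param window optional `c(lo, hi)`; values outside are dropped first.
#' @param plotting_positions `"halfstep"` (default) or `"blom"`.
#' @return list of class `dist_diag`: `n`, `W`, `p_sw`, `g1`, `se_g1`, `z`,
#'   `z_rounded`, `qq` (data.frame `theoretical`, `detrended`), `window`.
#' @export
normality_diagnostics <- function(values, window = NULL,
                                  plotting_positions = c("halfstep", "blom")) {
  plotting_positions <- match.arg(plotting_positions)
  x <- values[!is.na(values)]
  if (!is.null(window)) x <- x[x >= window[1] & x <= window[2]]
  n <- length(x)
  if (n < 3L) stop("need at least 3 values after windowing")
  sw <- stats::shapiro.test(x)
  sk <- if (n >= 5L && stats::var(x) > 0) skewness_z(x)
        else list(g1 = NA_real_, se_g1 = NA_real_, z = NA_real_,
                  z_rounded = NA_integer_)
  xs <- sort(x)
  pp <- if (plotting_positions == "halfstep") (seq_len(n) - 0.5) / n
        else (seq_len(n) - 3 / 8) / (n + 1 / 4)
  theo <- stats::qnorm(pp)
  fit <- mean(x) + stats::sd(x) * theo
  structure(list(n = n, W = unname(sw$statistic), p_sw = sw$p.value,
                 g1 = sk$g1, se_g1 = sk$se_g1, z = sk$z,
                 z_rounded = sk$z_rounded,
                 qq = data.frame(theoretical = theo, detrended = xs - fit),
                 window = window, plotting_positions = plotting_positions),
            class = "dist_diag")
}

verdict_of <- function(n, p_sw, z) {
  if (is.na(p_sw) || n < 5L) return("insufficient-n")
  if (p_sw < 0.05 && !is.na(z) && z >= 2) return("right-skewed")
  if (p_sw >= 0.05) return("normal")
  "symmetric non-normal"
}

#' Distribution-based spatial clustering inference
#'
#' For each vessel class and target kind, characterises the normalized
#' distance distribution overall, inside the endosteal window, and split at
#' the perivascular (imHC targets) or bone-contact (bone targets)
#' threshold. A series is called "right-skewed" (excess of short distances,
#' the signature of spatial condensation near the target) when
#' Shapiro-Wilk rejects normality and the skewness z-score is at least 2;
#' "normal" when Shapiro-Wilk does not reject; otherwise "symmetric
#' non-normal". Series shorter than 5 are "insufficient-n".
#'
#' @param records data.frame with columns `structure_id`, `class`,
#'   `target_kind` ("bone" or "imHC"), `d_raw_um`, `ic_um` (and optionally
#'   `d_norm_um`, recomputed when absent).
#' @param config an [analysis_config()].
#' @return data.frame, one row per class x target x segment: `class`,
#'   `target_kind`, `segment`, `n`, `W`, `p_sw`, `g1`, `z`, `verdict`.
#' @export
clustering_inference <- function(records, config = analysis_config()) {
  stopifnot(is.data.frame(records),
            all(c("class", "target_kind", "d_raw_um", "ic_um") %in% names(records)))
  if (is.null(records$d_norm_um))
    records$d_norm_um <- normalize_distance(records$d_raw_um, records$ic_um)
  records <- records[!is.na(records$d_norm_um), , drop = FALSE]
  out <- list()
  for (tk in unique(records$target_kind)) {
    split_at <- if (tk == "imHC") config$perivascular_window_um
                else config$bone_contact_window_um
    for (cl in unique(records$class[records$target_kind == tk])) {
      d <- records$d_norm_um[records$class == cl & records$target_kind == tk]
      segs <- list(overall = d,
                   endosteal = d[d <= config$endosteal_window_um],
                   below_split = d[d <= split_at],
                   above_split = d[d > split_at])
      names(segs) <- c("overall",
                       sprintf("within_%g_um", config$endosteal_window_um),
                       sprintf("le_%g_um", split_at),
                       sprintf("gt_%g_um", split_at))
      for (sg in names(segs)) {
        x <- segs[[sg]]
        row <- data.frame(class = cl, target_kind = tk, segment = sg,
                          n = length(x), W = NA_real_, p_sw = NA_real_,
                          g1 = NA_real_, z = NA_real_,
                          verdict = "insufficient-n")
        if (length(x) >= 5L && stats::var(x) > 0) {
          dg <- normality_diagnostics(x)
          row$W <- dg$W; row$p_sw <- dg$p_sw; row$g1 <- dg$g1; row$z <- dg$z
          row$verdict <- verdict_of(dg$n, dg$p_sw, dg$z)
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "verdict_rules") <- config$verdict_rules
  res
}

#' Association between a binary marker and proximity to a target
#'
#' 2 x 2 table of marker status against within/beyond a distance threshold,
#' tested by Pearson chi-square, or Fisher's exact test when any expected
#' count is below 5.
#'
#' @param marker_flags logical vector (marker positive).
#' @param distances numeric distances, micrometres.
#' @param threshold_um proximity threshold, micrometres.
#' @return list `table`, `p`, `test`.
#' @export
marker_proximity_association <- function(marker_flags, distances, threshold_um) {
  ok <- !is.na(marker_flags) & !is.na(distances)
  marker_flags <- marker_flags[ok]; distances <- distances[ok]
  if (length(marker_flags) < 4L) stop("need at least 4 complete observations")
  if (length(unique(marker_flags)) < 2L)
    stop("both marker states must be present")
  within <- distances <= threshold_um
  tb <- table(marker = marker_flags, within = within)
  if (ncol(tb) < 2L) tb <- cbind(tb, `TRUE` = c(0, 0))
  expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  if (any(expected < 5)) {
    list(table = tb, p = stats::fisher.test(tb)$p.value, test = "Fisher exact")
  } else {
    list(table = tb,
         p = suppressWarnings(stats::chisq.test(tb, correct = FALSE))$p.value,
         test = "Pearson chi-square, no continuity correction")
  }
}
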