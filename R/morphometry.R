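#' Measure the inner caliber of a lumen mask
#'
#' The inner caliber (IC) is the minor-axis length of the best-fit ellipse of
#' the largest connected lumen component, estimated from the second moments
#' of the pixel coordinates (minor axis = 4 sqrt(lambda_min), with the 1/12
#' per-pixel quantization variance removed), converted to micrometres. The
#' minor axis is robust to the compression artifact of sectioned vessels.
#' An empty mask is an imperceptible lumen and returns 0.
#'
#' @param lumen_mask binary (logical or 0/1) matrix.
#' @param um_per_px micrometres per pixel.
#' @param method `"minor_axis"` (default) or `"equivalent_diameter"`
#'   (diameter of the circle with the component's area).
#' @return inner caliber in micrometres.
#' @export
measure_inner_caliber <- function(lumen_mask, um_per_px,
                                  method = c("minor_axis", "equivalent_diameter")) {
  method <- match.arg(method)
  stopifnot(um_per_px > 0)
  if (is.logical(lumen_mask)) lumen_mask <- lumen_mask * 1
  if (!is.matrix(lumen_mask) || !all(lumen_mask %in% c(0, 1)))
    stop("lumen_mask must be a binary matrix")
  if (!any(lumen_mask == 1)) return(0)
  lab <- EBImage::bwlabel(lumen_mask)
  sizes <- tabulate(lab[lab > 0])
  idx <- which(lab == which.max(sizes), arr.ind = TRUE)
  if (method == "equivalent_diameter")
    return(2 * sqrt(nrow(idx) / pi) * um_per_px)
  if (nrow(idx) == 1L) return(um_per_px)   # single-pixel lumen: one pixel wide
  cv <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
  lmin <- min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
  4 * sqrt(max(lmin - 1 / 12, 0)) * um_per_px
}

#' Quartile cut-offs of inner-caliber values
#'
#' Empirical 25th/50th/75th percentiles with linear interpolation between
#' order statistics ([stats::quantile()] type 7). Zero-IC (imperceptible
#' lumen) structures are excluded from the cut-off estimation by default:
#' they form their own band of the classification and would otherwise drag
#' the lower percentiles to zero.
#'
#' @param ic_values numeric vector of inner calibers, micrometres.
#' @param exclude_zero drop IC == 0 values before computing the percentiles.
#' @return list of class `quartile_cutoffs`: `q25`, `q50`, `q75`.
#' @export
compute_quartiles <- function(ic_values, exclude_zero = TRUE) {
  stopifnot(is.numeric(ic_values), all(ic_values >= 0, na.rm = TRUE))
  x <- ic_values[!is.na(ic_values)]
  if (exclude_zero) x <- x[x > 0]
  if (length(x) < 4L) stop("need at least 4 inner-caliber values")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  structure(list(q25 = q[1], q50 = q[2], q75 = q[3]), class = "quartile_cutoffs")
}

#' Classify NESTIN+ structures
#'
#' Applies the extended morphological classification in rule order:
#' non-tubular structures are single cells (`NC`); tubular structures
#' without perivascular cells are capillary-like tubes (`NCLT`); tubular
#' pericyte-bearing structures are compressed arterioles (`cEA`) when
#' flagged compressed with IC at or below the median cut-off, endosteal
#' arterioles (`EA`) for IC in the (q50, q75] band, and arteries (`A`)
#' above q75. A pericyte-bearing tubular structure with small IC but no
#' compression flag is assigned `cEA` with a warning flag (the residual
#' category of apparently small arterioles).
#'
#' @param records data.frame with columns `ic_um`, `has_pericytes`,
#'   `tubular` and optionally `compressed` (FALSE when absent).
#' @param cutoffs a [compute_quartiles()] result.
#' @return `records` with `assigned_class` (factor over A/EA/cEA/NCLT/NC)
#'   and `class_warning` (logical, residual-rule applications) appended.
#' @export
classify_structure <- function(records, cutoffs) {
  stopifnot(is.data.frame(records),
            all(c("ic_um", "has_pericytes", "tubular") %in% names(records)),
            inherits(cutoffs, "quartile_cutoffs"))
  if (is.null(records$compressed)) records$compressed <- FALSE
  stopifnot(all(records$ic_um >= 0))
  if (any(!records$tubular & records$has_pericytes))
    warning("pericyte-bearing non-tubular records present (excluded column)")
  cls <- character(nrow(records))
  warn <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    cls[i] <- if (!r$tubular) "NC"
    else if (!r$has_pericytes) "NCLT"
    else if (r$compressed && r$ic_um <= cutoffs$q50) "cEA"
    else if (r$ic_um > cutoffs$q75) "A"
    else if (r$ic_um > cutoffs$q50) "EA"
    else { warn[i] <- TRUE; "cEA" }      # residual: small-IC pericyte vessel
  }
  records$assigned_class <- factor(cls, levels = vessel_classes())
  records$class_warning <- warn
  records
}

#' Class percentages among tubular vessels
#'
#' Percentages of arteries, endosteal arterioles (reported jointly with the
#' compressed sub-type and separately) and capillary-like tubes, with the
#' non-tubular structures (NC) excluded from the denominator.
#'
#' @param x either a classified records data.frame (column `assigned_class`)
#'   or a named vector of class counts.
#' @return list: `counts`, `denominator` (tubular total), `percent` (exact)
#'   and `percent_1dp` (one-decimal report values) over
#'   `A`, `EA`, `cEA`, `EA_plus_cEA`, `NCLT`.
#' @export
class_percentages <- function(x) {
  counts <- if (is.data.frame(x)) table(x$assigned_class)
            else x
  counts <- vapply(vessel_classes(), function(cl)
    if (cl %in% names(counts)) as.numeric(counts[[cl]]) else 0, numeric(1))
  denom <- sum(counts[c("A", "EA", "cEA", "NCLT")])
  if (denom == 0) stop("no tubular records: percentages undefined")
  pct <- c(A = counts[["A"]], EA = counts[["EA"]], cEA = counts[["cEA"]],
           EA_plus_cEA = counts[["EA"]] + counts[["cEA"]],
           NCLT = counts[["NCLT"]]) / denom * 100
  list(counts = counts, denominator = denom, percent = pct,
       percent_1dp = round(pct, 1))
}

#' Build the 5 x 3 caliber-by-complexity contingency table
#'
#' Rows are the caliber bands (no lumen, <= q25, (q25, q50], (q50, q75],
#' > q75); columns the complexity states (pericytes & tubular, no pericytes
#' & tubular, non-tubular). The pericytes & non-tubular column is kept in
#' the full table but excluded from analysis by default.
#'
#' @param records data.frame with `ic_um`, `has_pericytes`, `tubular`.
#' @param cutoffs a [compute_quartiles()] result.
#' @return list of class `contingency_table`: `table` (5 x 4 counts),
#'   `excluded_columns`, `cutoffs`.
#' @export
build_contingency <- function(records, cutoffs) {
  stopifnot(nrow(records) >= 1L, inherits(cutoffs, "quartile_cutoffs"))
  band <- cut(records$ic_um,
              breaks = c(-Inf, 0, cutoffs$q25, cutoffs$q50, cutoffs$q75, Inf),
              labels = c("no_lumen", "le_q25", "q25_q50", "q50_q75", "gt_q75"))
  col <- ifelse(records$tubular & records$has_pericytes, "pericytes_tubular",
         ifelse(records$tubular, "no_pericytes_tubular",
         ifelse(records$has_pericytes, "pericytes_nontubular", "nontubular")))
  col <- factor(col, levels = c("pericytes_tubular", "no_pericytes_tubular",
                                "nontubular", "pericytes_nontubular"))
  structure(list(table = table(band, col), excluded_columns = "pericytes_nontubular",
                 cutoffs = cutoffs),
            class = "contingency_table")
}

#' Chi-square test of the caliber-by-complexity table
#'
#' Pearson chi-square on the analyzed cells: excluded columns are dropped,
#' as are rows/columns with zero marginals (with a warning).
#'
#' @param ct a [build_contingency()] result.
#' @return list `statistic`, `df`, `p`, `table_analyzed`.
#' @export
chi_square_table <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  tb <- ct$table[, setdiff(colnames(ct$table), ct$excluded_columns), drop = FALSE]
  keep_r <- rowSums(tb) > 0; keep_c <- colSums(tb) > 0
  if (!all(keep_r) || !all(keep_c))
    warning("dropping zero-marginal rows/columns from the chi-square test")
  tb <- tb[keep_r, keep_c, drop = FALSE]
  if (nrow(tb) < 2L || ncol(tb) < 2L)
    stop("degenerate contingency table: need >= 2 rows and columns with counts")
  ch <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
  list(statistic = unname(ch$statistic), df = unname(ch$parameter),
       p = ch$p.value, table_analyzed = tb)
}
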