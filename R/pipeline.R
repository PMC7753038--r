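#' Build and validate a pipeline run configuration
#'
#' One configuration drives the full analysis: synthetic input (a
#' [fixture_config()]) or user-supplied tables, stage selection, module
#' settings and the master seed. Validation collects every problem and
#' reports them all at once.
#'
#' @param raw a (possibly partial) list: fields `mode` ("synthetic" or
#'   "tables"), `fixture` (fixture_config arguments), `tables` (named list
#'   of data.frames: `vessels`, `distances` for mode "tables"), `stages`
#'   (subset of "fixtures", "coloc", "morphometry", "spatial"), `analysis`
#'   (analysis_config arguments), `coloc` (`offsets`, `above_rule`,
#'   `n_images`), `seed`. An empty list yields the synthetic-mode defaults.
#'   May also be a path to a YAML or JSON file.
#' @return list of class `run_config`.
#' @export
validate_run_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- if (grepl("\\.json$", raw)) jsonlite::read_json(raw, simplifyVector = TRUE)
           else yaml::read_yaml(raw)
    raw <- raw %||% list()
  }
  ce <- collect_errors()
  known <- c("mode", "fixture", "tables", "stages", "analysis", "coloc", "seed")
  unknown <- setdiff(names(raw), known)
  ce$check(length(unknown) == 0,
           paste("unknown config keys:", paste(unknown, collapse = ", ")))

  mode <- raw$mode %||% "synthetic"
  ce$check(length(mode) == 1L && mode %in% c("synthetic", "tables"),
           "mode must be exactly one of 'synthetic' or 'tables'")
  seed <- raw$seed %||% 1L
  ce$check(is_count(seed), "seed must be a non-negative integer")

  stages <- raw$stages %||% c("fixtures", "coloc", "morphometry", "spatial")
  ce$check(all(stages %in% c("fixtures", "coloc", "morphometry", "spatial")),
           "stages must be a subset of fixtures/coloc/morphometry/spatial")

  fixture <- NULL
  if (identical(mode, "synthetic")) {
    fixture <- tryCatch(
      do.call(fixture_config, c(raw$fixture %||% list(),
                                if (is.null((raw$fixture %||% list())$seed))
                                  list(seed = derive_seed(seed, 1L)))),
      error = function(e) { ce$check(FALSE, conditionMessage(e)); NULL })
  } else {
    ce$check(is.list(raw$tables) && length(raw$tables) > 0,
             "mode 'tables' requires a non-empty tables list")
  }
  analysis <- tryCatch(do.call(analysis_config, raw$analysis %||% list()),
                       error = function(e) { ce$check(FALSE, conditionMessage(e)); NULL })
  coloc <- raw$coloc %||% list()
  coloc$offsets <- coloc$offsets %||% c(100L, 100L)
  coloc$above_rule <- coloc$above_rule %||% "either"
  coloc$n_images <- coloc$n_images %||% 4L
  ce$check(length(coloc$offsets) == 2L && all(coloc$offsets == round(coloc$offsets)),
           "coloc$offsets must be two integers")
  ce$check(coloc$above_rule %in% c("either", "both"),
           "coloc$above_rule must be 'either' or 'both'")
  ce$fail_if_any("invalid run configuration")
  structure(list(mode = mode, fixture = fixture, tables = raw$tables,
                 stages = stages, analysis = analysis, coloc = coloc,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full micro-vessel analysis pipeline
#'
#' Executes the enabled stages in dependency order — synthetic data
#' generation (or table intake), co-localization, morphometry, spatial
#' inference — and assembles a reproducible report: per-module outputs, the
#' conventions (decision toggles) actually used, seeds and payload
#' checksums. Identical config and seed give identical payloads.
#'
#' @param config a [validate_run_config()] result (or the raw list/path,
#'   validated on the fly).
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` plus CSV tables.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  report <- list(seed = config$seed, mode = config$mode,
                 package_version = as.character(utils::packageVersion("marrowmorph")),
                 stages = config$stages)
  decisions <- list(
    percentile_method = "linear interpolation (type 7), zero-IC excluded from cut-offs",
    ic_operator = "minor axis of largest lumen component",
    coloc_above_rule = config$coloc$above_rule,
    coloc_below_set = "below both thresholds",
    coloc_control = "thresholds re-estimated on translated pair, no wraparound",
    dunn_adjustment = "Bonferroni",
    distance_normalization = "max(0, d_raw - IC/2), centroid-referenced",
    qq_plotting_positions = "(i - 0.5)/n",
    cooccurrence_test = "Pearson chi-square without continuity correction, Fisher fallback",
    verdict_rules = config$analysis$verdict_rules,
    cutoff_discrepancy_note = paste(
      "figure caption cut-offs 7.2/4.6 um differ from the text values",
      "7.6/4.5 um; the text values are the reference"))

  ds <- NULL
  vessels <- distances <- imhcs <- NULL
  if (identical(config$mode, "synthetic") && "fixtures" %in% config$stages) {
    ds <- generate_dataset(config$fixture, keep_images = FALSE,
                           per_image = NULL)
    vessels <- ds$truth$vessel_table
    vessels$ic_um <- vessels$true_ic_um
    distances <- ds$truth$distance_table
    imhcs <- ds$truth$imhc_points
    report$fixtures <- list(n_structures = nrow(vessels),
                            n_imhcs = nrow(imhcs),
                            class_counts = as.list(table(vessels$class)),
                            seed = config$fixture$seed)
  } else if (identical(config$mode, "tables")) {
    vessels <- config$tables$vessels
    distances <- config$tables$distances
    imhcs <- config$tables$imhcs
  }

  if ("coloc" %in% config$stages && identical(config$mode, "synthetic")) {
    report$coloc <- tryCatch(
      pipeline_coloc_stage(config), error = function(e) list(error = conditionMessage(e)))
  }

  if ("morphometry" %in% config$stages && !is.null(vessels)) {
    report$morphometry <- tryCatch({
      cuts <- compute_quartiles(vessels$ic_um)
      cl <- classify_structure(vessels, cuts)
      ct <- build_contingency(cl, cuts)
      chi <- chi_square_table(ct)
      pct <- class_percentages(cl)
      acc <- if (!is.null(cl$class)) mean(as.character(cl$assigned_class) == cl$class)
             else NULL
      list(cutoffs_um = unclass(cuts), class_counts = as.list(table(cl$assigned_class)),
           percent_of_tubular = as.list(pct$percent_1dp),
           contingency = unclass(ct$table), chi_square = chi[c("statistic", "df", "p")],
           recovery = acc)
    }, error = function(e) list(error = conditionMessage(e)))
  }

  if ("spatial" %in% config$stages && !is.null(distances)) {
    report$spatial <- tryCatch({
      bone_rec <- distances[distances$target_kind == "bone", , drop = FALSE]
      res <- list()
      if (nrow(bone_rec)) {
        res$bone_verdicts <- clustering_inference(bone_rec, config$analysis)
        if (!is.null(vessels$bone_in_fov)) {
          grp <- vessels$class == "NCLT"
          res$bone_cooccurrence <- cooccurrence_test(
            vessels$bone_in_fov[grp], vessels$bone_in_fov[!grp])
        }
      }
      if (!is.null(imhcs) && nrow(imhcs)) {
        im_rec <- data.frame(structure_id = seq_len(nrow(imhcs)),
                             class = imhcs$vessel_class, target_kind = "imHC",
                             d_raw_um = imhcs$d_nearest_vessel_um, ic_um = 0)
        res$imhc_verdicts <- clustering_inference(im_rec, config$analysis)
      }
      res
    }, error = function(e) list(error = conditionMessage(e)))
  }

  report$decisions <- decisions
  report$checksums <- lapply(
    report[intersect(c("fixtures", "coloc", "morphometry", "spatial"),
                     names(report))],
    payload_checksum)
  report <- structure(report, class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

# Co-localization stage on a handful of capillary-like synthetic pairs.
pipeline_coloc_stage <- function(config) {
  n_img <- config$coloc$n_images
  seeds <- vapply(seq_len(n_img), function(i) derive_seed(config$seed, 100L + i),
                  integer(1))
  res <- lapply(seeds, function(s) {
    pair <- simulate_coloc_pair(seed = s)
    coloc_analysis(pair, offsets = config$coloc$offsets,
                   above_rule = config$coloc$above_rule)
  })
  coefs <- data.frame(R = vapply(res, `[[`, 1, "R"),
                      M1 = vapply(res, `[[`, 1, "M1"),
                      M2 = vapply(res, `[[`, 1, "M2"),
                      tR = vapply(res, `[[`, 1, "tR"),
                      tM1 = vapply(res, `[[`, 1, "tM1"),
                      tM2 = vapply(res, `[[`, 1, "tM2"))
  list(n_images = n_img, coefficients = coefs,
       means = as.list(round(colMeans(coefs), 4)))
}

payload_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(file.path(out_dir, "report.json"))
}

#' Simulate one capillary-like two-channel field for co-localization work
#'
#' Renders several capillary cross-sections (thick cytoskeletal annuli with
#' radially offset thinner membrane rings) into a frame with background,
#' crosstalk and noise — the co-occurrence-without-coincidence configuration
#' of a cytoskeletal and a surface marker in the same cells.
#'
#' @param seed integer seed.
#' @param dim frame size in pixels.
#' @param n_vessels number of cross-sections.
#' @param marker_offset_px radial membrane displacement, pixels.
#' @param um_per_px micrometres per pixel.
#' @param noise,crosstalk,amplitude as in [fixture_config()].
#' @param segregated render the membrane ring far outside the cytoskeletal
#'   annulus instead (disjoint supports), for negative-control fixtures.
#' @param control_offsets integer `(dx, dy)`; vessel centres are kept clear
#'   of each other's positions shifted by this translation, so the
#'   translated negative control has genuinely independent structure (no
#'   accidental ring alignment), as the control protocol assumes.
#' @return a [channel_pair()].
#' @export
simulate_coloc_pair <- function(seed, dim = c(256L, 256L), n_vessels = 8L,
                                marker_offset_px = 4L, um_per_px = 0.5,
                                noise = c(poisson_scale = 0.05,
                                          gaussian_sd = 5,
                                          background_level = 10),
                                crosstalk = 0, amplitude = 4000,
                                segregated = FALSE,
                                control_offsets = c(100L, 100L)) {
  set.seed(seed)
  H <- dim[1]; W <- dim[2]
  ch <- list(nestin = matrix(0, H, W), endo = matrix(0, H, W))
  centers <- matrix(numeric(0), ncol = 2)
  dx <- control_offsets[1]; dy <- control_offsets[2]
  for (k in seq_len(n_vessels)) {
    ic <- stats::runif(1, 2, 4.5)
    off <- if (segregated) marker_offset_px + 12L else marker_offset_px
    p <- render_vessel("NCLT", ic, marker_offset_px = off,
                       um_per_px = um_per_px,
                       amplitude = amplitude * stats::runif(1, 0.55, 1.3))
    n <- p$dim[1]; half <- n %/% 2
    for (try in 1:500) {
      r0 <- round(stats::runif(1, half + 8, H - half - 8))
      c0 <- round(stats::runif(1, half + 8, W - half - 8))
      cand <- rbind(c(r0, c0), c(r0 + dy, c0 + dx), c(r0 - dy, c0 - dx))
      ok <- nrow(centers) == 0 ||
        min(sqrt(outer(cand[, 1], centers[, 1], "-")^2 +
                   outer(cand[, 2], centers[, 2], "-")^2)) > n + 4
      if (ok) break
    }
    centers <- rbind(centers, c(r0, c0))
    rows <- (r0 - p$center[1] + 1):(r0 - p$center[1] + n)
    cols <- (c0 - p$center[2] + 1):(c0 - p$center[2] + n)
    ch$nestin[rows, cols] <- pmax(ch$nestin[rows, cols], p$channels$nestin)
    ch$endo[rows, cols] <- pmax(ch$endo[rows, cols], p$channels$endo)
  }
  ch <- apply_noise(ch, noise, crosstalk)
  # quantized to a 16-bit-like integer scale: keeps threshold scans exact
  channel_pair(round(ch$nestin), round(ch$endo))
}
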