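#' Week-series summary of quantification reports
#'
#' Mean and SD of every metric per week, matching the mean +- SD layout
#' of the reference week-series table.
#'
#' @param reports Tibble of [quant_report()] rows (each must carry a
#'   `week` tag).
#' @return Long tibble of class `week_series`: `week`, `metric`, `mean`,
#'   `sd`, `n`, ordered by week.
#' @export
week_summary <- function(reports) {
  stopifnot(is.data.frame(reports))
  if (!"week" %in% names(reports) || anyNA(reports$week)) {
    stop("missing week tag on one or more reports", call. = FALSE)
  }
  metrics <- setdiff(
    names(reports)[vapply(reports, is.numeric, logical(1))], "week"
  )
  out <- reports |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$week, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$week, .data$metric)
  class(out) <- c("week_series", class(out))
  out
}

#' Linear trend of a metric over weeks
#'
#' Ordinary least squares of the per-replicate metric on the week index;
#' `r` is the Pearson correlation and the p-value is the two-sided test
#' of a nonzero slope.  A constant metric yields r = 0 with a degenerate
#' flag (p = 1); zero variance in the weeks is an error.
#'
#' @param values Numeric metric values (one per replicate), or a data
#'   frame of reports (then `metrics` selects columns and `week_col`
#'   supplies the weeks).
#' @param weeks Week of each value (when `values` is a vector).
#' @param metrics Character vector of metric columns (data-frame input);
#'   defaults to all numeric columns except the week.
#' @param week_col Name of the week column.
#' @return Tibble of class `trend_result`: `metric`, `r`, `p_value`,
#'   `n`, `degenerate`.
#' @examples
#' linear_trend(c(1, 2, 3, 5), weeks = 1:4)
#' @export
linear_trend <- function(values, weeks = NULL, metrics = NULL,
                         week_col = "week") {
  if (is.data.frame(values)) {
    stopifnot(week_col %in% names(values))
    metrics <- metrics %||% setdiff(
      names(values)[vapply(values, is.numeric, logical(1))], week_col
    )
    out <- dplyr::bind_rows(lapply(metrics, function(m) {
      .trend_one(values[[m]], values[[week_col]], m)
    }))
  } else {
    stopifnot(is.numeric(values), length(values) == length(weeks))
    out <- .trend_one(values, weeks, "value")
  }
  class(out) <- c("trend_result", class(out))
  out
}

.trend_one <- function(y, w, name) {
  ok <- is.finite(y) & is.finite(w)
  y <- y[ok]; w <- w[ok]
  if (length(y) < 3 || length(unique(w)) < 2) {
    if (stats::var(w) == 0 || length(unique(w)) < 2) {
      stop("zero variance in weeks", call. = FALSE)
    }
    stop("need at least 3 points spanning at least 2 weeks", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    return(tibble::tibble(metric = name, r = 0, p_value = 1,
                          n = length(y), degenerate = TRUE))
  }
  fit <- stats::lm(y ~ w)
  p <- suppressWarnings(summary(fit))$coefficients["w", "Pr(>|t|)"]
  tibble::tibble(
    metric = name, r = stats::cor(w, y), p_value = unname(p),
    n = length(y), degenerate = FALSE
  )
}

#' @method glance trend_result
#' @export
glance.trend_result <- function(x, ...) {
  tibble::tibble(
    n_metrics = nrow(x),
    min_p = min(x$p_value),
    all_significant = all(x$p_value < 0.05)
  )
}

#' @method tidy trend_result
#' @export
tidy.trend_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @method tidy week_series
#' @export
tidy.week_series <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

.default_pipeline_config <- function() {
  list(
    phantom = list(weeks = 1:4, grid_n = 64, voxel_um = 9, seed = 1,
                   replicates = 1),
    optics = list(energy_kev = 15, distance_m = 1, n_angles = 200,
                  photons = 1e4),
    recon = list(filter = "ramlak"),
    quant = list(method = "otsu", polarity = "dark", min_voxels = 8),
    contrast = list(window = 15),
    output = list(write_volumes = FALSE)
  )
}

# recursive config merge (user over defaults)
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full simulation-to-report pipeline
#'
#' Executes phantom generation, acquisition, reconstruction, vessel
#' quantification, projection contrast analysis and week-series
#' reporting end to end, writing CSV tables, a ground-truth versus
#' recovered JSON comparison, a parameter log, and (optionally) TIFF
#' volumes to `out_dir`.  Fully deterministic for a fixed config: a
#' rerun reproduces the outputs bit for bit.
#'
#' @param config Nested list (see `ilxpct:::.default_pipeline_config()`
#'   for the schema and defaults) or path to an equivalent YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-replicate `reports` tibble,
#'   the `week_series` summary, `trend` fits, `contrast` table and the
#'   paths written.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  grid_n <- cfg$phantom$grid_n
  domain <- rep(grid_n * cfg$phantom$voxel_um / 1000, 3)
  geom <- beam_geometry(
    energy_kev = cfg$optics$energy_kev, distance_m = cfg$optics$distance_m,
    pixel_um = cfg$phantom$voxel_um, n_angles = cfg$optics$n_angles,
    photons = cfg$optics$photons
  )

  reports <- list(); contrasts <- list(); gt_rows <- list()
  for (rep_i in seq_len(cfg$phantom$replicates)) {
    seed_r <- cfg$phantom$seed + 1000L * (rep_i - 1L)
    base_spec <- stage("phantom", phantom_spec(
      week_stage = 1, domain_mm = domain, voxel_um = cfg$phantom$voxel_um,
      seed = seed_r
    ))
    series <- stage("phantom",
                    stage_series(base_spec, seed = seed_r,
                                 weeks = cfg$phantom$weeks))
    for (k in seq_along(series)) {
      ph <- series[[k]]
      w <- ph$spec$week_stage
      sino <- stage("optics",
                    acquire_sinogram(ph, geom, seed = seed_r + 10L * w))
      vol <- stage("recon",
                   reconstruct_volume(sino, filter = cfg$recon$filter))
      rep_row <- stage("vesselquant", quantify_specimen(
        vol, ph$masks$tumor, week = w,
        suture_mask = dilate_mask(ph$masks$suture, 2),
        method = cfg$quant$method, polarity = cfg$quant$polarity,
        min_voxels = cfg$quant$min_voxels
      ))
      rep_row$replicate <- rep_i
      reports[[length(reports) + 1]] <- rep_row
      gt <- tidy.phantom_volume(ph)
      gt$replicate <- rep_i
      gt_rows[[length(gt_rows) + 1]] <- gt

      proj <- stage("optics", fresnel_propagate(
        complex_transmission(ph, 0, geom), geometry = geom
      ))
      tm <- apply(ph$masks$tumor, c(1, 3), any)
      lm_ <- apply(ph$masks$liver & !ph$masks$tumor, c(1, 3), any) & !tm
      ctr <- stage("contrast", tumor_vs_liver_contrast(
        proj$intensity, tm, lm_, w = cfg$contrast$window
      ))
      ctr$week <- w; ctr$replicate <- rep_i
      contrasts[[length(contrasts) + 1]] <- ctr

      if (isTRUE(cfg$output$write_volumes)) {
        stage("report", write_volume_tiff(
          vol, file.path(out_dir, sprintf("recon_w%d_r%d.tif", w, rep_i))
        ))
      }
    }
  }

  reports <- dplyr::bind_rows(reports)
  gt_tbl <- dplyr::bind_rows(gt_rows)
  contrasts <- dplyr::bind_rows(contrasts)
  ws <- stage("report", week_summary(
    dplyr::select(reports, -"replicate", -"sub_resolution")
  ))
  tr <- if (nrow(reports) >= 3 && length(unique(reports$week)) >= 2) {
    stage("report", linear_trend(
      dplyr::select(reports, "week", "tumor_volume_mm3",
                    "vascular_volume_mm3")
    ))
  } else {
    structure(tibble::tibble(metric = character(), r = numeric(),
                             p_value = numeric(), n = integer(),
                             degenerate = logical()),
              class = c("trend_result", class(tibble::tibble())))
  }

  paths <- c(
    reports = file.path(out_dir, "quant_reports.csv"),
    week_summary = file.path(out_dir, "week_summary.csv"),
    trend = file.path(out_dir, "trend.csv"),
    contrast = file.path(out_dir, "contrast.csv"),
    comparison = file.path(out_dir, "ground_truth_vs_recovered.json"),
    params = file.path(out_dir, "params.json")
  )
  utils::write.csv(reports, paths[["reports"]], row.names = FALSE)
  utils::write.csv(as.data.frame(ws), paths[["week_summary"]],
                   row.names = FALSE)
  utils::write.csv(tidy.trend_result(tr), paths[["trend"]],
                   row.names = FALSE)
  utils::write.csv(contrasts, paths[["contrast"]], row.names = FALSE)
  comparison <- dplyr::left_join(
    dplyr::select(gt_tbl, "week", "replicate",
                  true_density_pct = "vascular_density_pct",
                  true_tumor_mm3 = "tumor_volume_mm3"),
    dplyr::select(reports, "week", "replicate",
                  recovered_density_pct = "vascular_density_pct",
                  recovered_tumor_mm3 = "tumor_volume_mm3"),
    by = c("week", "replicate")
  )
  jsonlite::write_json(comparison, paths[["comparison"]], digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(cfg, paths[["params"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(reports = reports, week_series = ws, trend = tr,
                 contrast = contrasts, comparison = comparison,
                 paths = paths))
}
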