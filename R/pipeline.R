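# Configuration, shared readers/writers, and the end-to-end driver that
# binds the modules: audio -> spectral features; WSS -> OSI summary;
# ultrasound -> BFV; joined visit table -> cohort statistics.

#' Pipeline configuration
#'
#' Collects every tunable setting of the end-to-end analysis. Defaults are
#' the study settings: 4-s trim, 4th-order 50 Hz high-pass, 100-250 /
#' 500-700 Hz bands, OSI threshold 0.1, type-7 quantiles, Student t-test,
#' 1000 bootstrap replicates.
#'
#' @param trim_duration_s,cutoff_hz,filter_order Audio preprocessing.
#' @param low_band,high_band Band edges (Hz), length-2 each.
#' @param osi_threshold OSI cutoff for the high-OSI area fraction.
#' @param t_test_var_equal Pooled-variance t-test if `TRUE`.
#' @param n_boot,seed Bootstrap replicates and seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(trim_duration_s = 4, cutoff_hz = 50,
                            filter_order = 4, low_band = c(100, 250),
                            high_band = c(500, 700), osi_threshold = 0.1,
                            t_test_var_equal = TRUE, n_boot = 1000,
                            seed = 1) {
  stopifnot(trim_duration_s > 0, cutoff_hz > 0, filter_order >= 1,
            length(low_band) == 2, length(high_band) == 2,
            low_band[1] < low_band[2], high_band[1] < high_band[2],
            osi_threshold >= 0, osi_threshold <= 0.5,
            n_boot >= 1, is.finite(seed))
  structure(list(trim_duration_s = trim_duration_s, cutoff_hz = cutoff_hz,
                 filter_order = filter_order, low_band = low_band,
                 high_band = high_band, osi_threshold = osi_threshold,
                 t_test_var_equal = t_test_var_equal,
                 n_boot = n_boot, seed = seed),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as a flat key-value file
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config` returns a `pipeline_config` equal to the
#'   one written.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- vapply(config, function(v) paste(v, collapse = ","), "")
  writeLines(paste0(names(flat), " = ", flat), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  kv <- read.dcf(textConnection(gsub(" = ", ": ", readLines(path))))
  g <- function(k) as.numeric(strsplit(kv[1, k], ",")[[1]])
  pipeline_config(trim_duration_s = g("trim_duration_s"),
                  cutoff_hz = g("cutoff_hz"),
                  filter_order = g("filter_order"),
                  low_band = g("low_band"), high_band = g("high_band"),
                  osi_threshold = g("osi_threshold"),
                  t_test_var_equal = as.logical(kv[1, "t_test_var_equal"]),
                  n_boot = g("n_boot"), seed = g("seed"))
}

#' Read / write a WSS field in the plain CSV dialect
#'
#' Long-format exchange table with columns `element_id`, `area`, `t`,
#' `tx`, `ty`, `tz`: one row per element per time sample.
#'
#' @param path CSV path.
#' @param roi_mask Optional per-element ROI flag (element order).
#' @return `read_wss_csv` returns a `wss_field`.
#' @export
read_wss_csv <- function(path, roi_mask = NULL) {
  d <- utils::read.csv(path)
  need <- c("element_id", "area", "t", "tx", "ty", "tz")
  if (!all(need %in% names(d)))
    stop(path, ": missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "))
  elems <- sort(unique(d$element_id))
  times <- sort(unique(d$t))
  d <- d[order(match(d$element_id, elems), match(d$t, times)), ]
  ne <- length(elems); nt <- length(times)
  if (nrow(d) != ne * nt) stop(path, ": ragged element/time grid")
  tau <- array(0, dim = c(ne, nt, 3))
  tau[, , 1] <- matrix(d$tx, ne, nt, byrow = TRUE)
  tau[, , 2] <- matrix(d$ty, ne, nt, byrow = TRUE)
  tau[, , 3] <- matrix(d$tz, ne, nt, byrow = TRUE)
  areas <- d$area[seq(1, nrow(d), by = nt)]
  wss_field(times, tau, areas, roi_mask)
}

#' @rdname read_wss_csv
#' @param field A `wss_field` to write.
#' @export
write_wss_csv <- function(field, path) {
  stopifnot(inherits(field, "wss_field"))
  ne <- dim(field$tau)[1]; nt <- dim(field$tau)[2]
  d <- data.frame(
    element_id = rep(seq_len(ne), each = nt),
    area = rep(field$element_areas, each = nt),
    t = rep(field$times, ne),
    tx = as.vector(t(field$tau[, , 1])),
    ty = as.vector(t(field$tau[, , 2])),
    tz = as.vector(t(field$tau[, , 3])))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end pipeline on a file manifest
#'
#' Consumes a manifest of input files, runs each module, joins the
#' results into a visit-level table and computes the cohort statistics.
#' Output files (`features.csv`, `osi_summary.json`, `bfv.csv`,
#' `visits.csv`, `stats.json`, `provenance.json`) go to `out_dir`, which
#' must be empty or absent unless `overwrite = TRUE` — partial results are
#' never silently overwritten.
#'
#' @param config A `pipeline_config`.
#' @param manifest `data.frame` with columns `kind` (`"audio"`, `"wss"`
#'   or `"us"`), `path`, `patient_id`, `visit` (`us` rows may leave
#'   patient/visit empty: the US table carries its own).
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with `features`, `osi_summary`, `bfv`,
#'   `visits`, `stats`.
#' @export
run_pipeline <- function(config, manifest, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(manifest) == 0) stop("empty manifest: nothing to do")
  need <- c("kind", "path", "patient_id", "visit")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  missing <- which(!file.exists(manifest$path))
  if (length(missing))
    stop("manifest line(s) ", paste(missing, collapse = ", "),
         ": file not found (", paste(manifest$path[missing], collapse = ", "), ")")
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory ", out_dir,
         " is not empty; pass overwrite = TRUE to replace its contents")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  features <- NULL; osi_summary <- NULL; bfv <- NULL
  a_rows <- which(manifest$kind == "audio")
  if (length(a_rows)) {
    features <- do.call(rbind, lapply(a_rows, function(i) {
      rec <- read_wav(manifest$path[i])
      cbind(patient_id = manifest$patient_id[i], visit = manifest$visit[i],
            analyze_recording(rec,
                              duration_s = config$trim_duration_s,
                              cutoff_hz = config$cutoff_hz,
                              order = config$filter_order,
                              low = config$low_band, high = config$high_band))
    }))
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
  }
  w_rows <- which(manifest$kind == "wss")
  if (length(w_rows)) {
    osi_summary <- do.call(rbind, lapply(w_rows, function(i) {
      field <- read_wss_csv(manifest$path[i])
      osi <- compute_osi(field)
      data.frame(patient_id = manifest$patient_id[i],
                 visit = manifest$visit[i],
                 osi_area_percent =
                   high_osi_area_percent(osi, field, config$osi_threshold),
                 roi_area_mm2 = sum(field$element_areas[field$roi_mask]))
    }))
    jsonlite::write_json(osi_summary, file.path(out_dir, "osi_summary.json"),
                         dataframe = "rows", digits = NA)
  }
  u_rows <- which(manifest$kind == "us")
  if (length(u_rows)) {
    bfv <- do.call(rbind, lapply(u_rows, function(i)
      flow_metrics_table(utils::read.csv(manifest$path[i]))))
    utils::write.csv(bfv, file.path(out_dir, "bfv.csv"), row.names = FALSE)
  }

  visits <- .join_visits(features, osi_summary, bfv)
  utils::write.csv(visits, file.path(out_dir, "visits.csv"), row.names = FALSE)

  stats_out <- list()
  if (!is.null(visits$osi_area_percent) &&
      sum(!is.na(visits$hlpr) & !is.na(visits$osi_area_percent)) >= 4) {
    sc <- median_split_comparison(visits, var_equal = config$t_test_var_equal)
    stats_out$median_split <- list(
      threshold = sc$threshold,
      high = sc$high[c("n", "median", "q1", "q3")],
      low = sc$low[c("n", "median", "q1", "q3")],
      t_statistic = sc$t_statistic, p_value = sc$p_value)
  }
  ok <- !is.null(visits$brachial_bfv_ml_min) &&
    sum(!is.na(visits$max_peak_amplitude) &
          !is.na(visits$brachial_bfv_ml_min)) >= 4
  if (ok && length(unique(visits$patient_id)) >= 2) {
    fit <- fit_random_intercept_model(visits$max_peak_amplitude,
                                      visits$brachial_bfv_ml_min,
                                      visits$patient_id,
                                      n_boot = config$n_boot,
                                      seed = config$seed)
    stats_out$amplitude_vs_bfv <- fit[c("slope", "intercept",
                                        "p_value_slope", "ci_low", "ci_high",
                                        "patient_intercept_sd", "residual_sd",
                                        "n_obs", "n_patients")]
  }
  if (length(stats_out))
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)

  prov <- list(package = "avfsound",
               version = as.character(utils::packageVersion("avfsound")),
               config = unclass(config),
               inputs = data.frame(path = manifest$path,
                                   md5 = unname(tools::md5sum(manifest$path))),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(list(features = features, osi_summary = osi_summary, bfv = bfv,
                 visits = visits, stats = stats_out))
}

# Join the per-module outputs into one row per patient-visit.
.join_visits <- function(features, osi_summary, bfv) {
  key <- function(d) paste(d$patient_id, d$visit, sep = "\r")
  keys <- unique(c(if (!is.null(features)) key(features),
                   if (!is.null(osi_summary)) key(osi_summary),
                   if (!is.null(bfv)) key(bfv)))
  if (!length(keys)) return(data.frame())
  parts <- do.call(rbind, strsplit(keys, "\r"))
  out <- data.frame(patient_id = parts[, 1], visit = parts[, 2],
                    hlpr = NA_real_, max_peak_amplitude = NA_real_,
                    osi_area_percent = NA_real_,
                    brachial_bfv_ml_min = NA_real_,
                    venous_bfv_ml_min = NA_real_)
  if (!is.null(features)) {
    i <- match(key(out), key(features))
    out$hlpr <- features$hlpr[i]
    out$max_peak_amplitude <- features$max_peak_amplitude[i]
  }
  if (!is.null(osi_summary))
    out$osi_area_percent <- osi_summary$osi_area_percent[
      match(key(out), key(osi_summary))]
  if (!is.null(bfv)) {
    ba <- bfv[bfv$vessel == "BA", ]; ven <- bfv[bfv$vessel == "VEN", ]
    out$brachial_bfv_ml_min <- ba$bfv_ml_min[match(key(out), key(ba))]
    out$venous_bfv_ml_min <- ven$bfv_ml_min[match(key(out), key(ven))]
  }
  out[order(out$patient_id, match(out$visit, VISIT_LEVELS)), , drop = FALSE]
}
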