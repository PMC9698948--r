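#' Write a pulse record to CSV with a JSON sidecar
#'
#' The waveform goes to a two-column CSV (`sample_index`, `pressure`;
#' sample indices 0-based for interchange) and the metadata — subject,
#' regime, sampling rate, and when present the ground-truth onsets
#' (0-based) and beat labels — to `<basename>.json` next to it.
#'
#' @param record a `pulse_record`.
#' @param dir output directory (created if missing).
#' @param basename file stem; defaults to `<subject>_<regime>`.
#' @return Invisibly, the CSV path.
#' @seealso [read_waveform_csv()], [write_cohort()]
#' @export
write_record <- function(record, dir, basename = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(basename))
    basename <- paste0(record$subject_id, "_", record$regime)
  csv <- file.path(dir, paste0(basename, ".csv"))
  df <- data.frame(sample_index = seq_along(record$samples) - 1L,
                   pressure = record$samples)
  write.table(df, csv, sep = ",", row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = record$subject_id, regime = record$regime,
               sampling_rate_hz = record$sampling_rate)
  if (!is.null(record$truth_onsets)) {
    meta$truth_onsets <- record$truth_onsets - 1L
    meta$truth_beat_labels <- record$truth_beat_labels
  }
  jsonlite::write_json(meta, file.path(dir, paste0(basename, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Write a cohort and its manifest
#'
#' Writes every record via [write_record()] plus a tab-separated manifest
#' (`path`, `subject`, `regime`).
#'
#' @param cohort a `pulse_cohort` or list of `pulse_record`s.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  paths <- vapply(cohort, write_record, character(1), dir = dir)
  manifest <- data.frame(
    path = basename(paths),
    subject = vapply(cohort, `[[`, character(1), "subject_id"),
    regime = vapply(cohort, `[[`, character(1), "regime"))
  mp <- file.path(dir, "manifest.tsv")
  write.table(manifest, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Read a waveform CSV into a pulse record
#'
#' Accepts a single pressure column or `sample_index,pressure` pairs, with
#' or without a header row (both dialects parse identically). If a JSON
#' sidecar `<stem>.json` exists its metadata (subject, regime, sampling
#' rate, ground truth) is attached; 0-based on-disk onsets are converted
#' to the package's 1-based in-memory convention.
#'
#' @param path CSV path.
#' @param sampling_rate sampling rate in Hz; overrides the sidecar value.
#'   Required when no sidecar is present.
#' @return A `pulse_record`.
#' @export
read_waveform_csv <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty waveform file: ", path)
  first <- strsplit(lines[1L], ",")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- if (has_header) lines[-1L] else lines
  if (!length(body)) stop("empty waveform file (header only): ", path)
  parts <- strsplit(body, ",")
  ncol <- lengths(parts)
  if (any(ncol != ncol[1L]))
    stop("ragged rows in ", path, " (line ",
         which(ncol != ncol[1L])[1L] + has_header, ")")
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = ncol[1L], byrow = TRUE))
  if (anyNA(vals))
    stop("non-numeric value in ", path, " at line ",
         which(apply(is.na(vals), 1L, any))[1L] + has_header)
  pressure <- vals[, ncol(vals)]

  meta <- list()
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fs <- if (!is.null(sampling_rate)) sampling_rate else meta$sampling_rate_hz
  if (is.null(fs)) stop("'sampling_rate' required (no JSON sidecar found)")
  rec <- list(subject_id = if (!is.null(meta$subject_id)) meta$subject_id else
                sub("\\.[^.]*$", "", basename(path)),
              regime = if (!is.null(meta$regime)) meta$regime else NA_character_,
              sampling_rate = fs, samples = pressure)
  if (!is.null(meta$truth_onsets)) {
    rec$truth_onsets <- as.integer(meta$truth_onsets) + 1L
    rec$truth_beat_labels <- as.character(meta$truth_beat_labels)
  }
  structure(rec, class = "pulse_record")
}

#' Write / read a feature table as TSV
#'
#' @param features a [build_feature_table()] result.
#' @param path TSV path.
#' @return `write_feature_table()` returns the path invisibly;
#'   `read_feature_table()` returns a `pulse_features` data frame.
#' @export
write_feature_table <- function(features, path) {
  write.table(features, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(c("subject", "regime", "beat_index", "label",
                       feature_names()), names(df))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  structure(df, class = c("pulse_features", "data.frame"))
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run — simulation, segmentation,
#' feature windowing, classifier methods, evaluation protocols and the
#' master seed — into one object that round-trips losslessly through its
#' JSON serialization ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param sim a [sim_config()].
#' @param min_hr,max_hr segmentation heart-rate gate, beats/min.
#' @param window feature variability window (`"record"` or odd integer).
#' @param normalization amplitude-proportion normalization.
#' @param methods classifier methods (`"all"` or subset).
#' @param protocols evaluation protocols to run.
#' @param seed master seed (propagated to the simulation when it differs).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            min_hr = 30, max_hr = 240,
                            window = "record",
                            normalization = "total",
                            methods = "all",
                            protocols = c("threefold", "loso"),
                            seed = sim$seed) {
  protocols <- match.arg(protocols, c("threefold", "loso", "holdout"),
                         several.ok = TRUE)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, min_hr = min_hr, max_hr = max_hr,
                 window = window, normalization = normalization,
                 methods = methods, protocols = protocols,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- config
  ser$sim$regimes <- lapply(ser$sim$regimes, unclass)
  ser$sim$regimes <- lapply(ser$sim$regimes, function(r) {
    r$template <- unclass(r$template); r
  })
  ser$sim <- unclass(ser$sim)
  jsonlite::write_json(unclass(ser), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  regs <- lapply(raw$sim$regimes, function(r) {
    regime_spec(label = r$label,
                template = harmonic_template(r$template$dc_level,
                                             r$template$amplitudes,
                                             r$template$phases),
                amplitude_jitter_cv = r$amplitude_jitter_cv,
                phase_jitter_sd = r$phase_jitter_sd,
                artifact_rate = r$artifact_rate,
                artifact_model = r$artifact_model)
  })
  sim <- sim_config(n_subjects = raw$sim$n_subjects,
                    hr_mean = raw$sim$hr_mean, hr_sd = raw$sim$hr_sd,
                    duration = raw$sim$duration,
                    sampling_rate = raw$sim$sampling_rate,
                    regimes = regs,
                    clean_fraction_appropriate = raw$sim$clean_fraction_appropriate,
                    lowq_fraction_higher = raw$sim$lowq_fraction_higher,
                    seed = raw$sim$seed)
  pipeline_config(sim = sim, min_hr = raw$min_hr, max_hr = raw$max_hr,
                  window = if (is.character(raw$window)) raw$window
                           else as.integer(raw$window),
                  normalization = raw$normalization,
                  methods = raw$methods, protocols = raw$protocols,
                  seed = raw$seed)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full simulation-to-evaluation pipeline
#'
#' Executes simulate -> segment -> featurize -> evaluate -> compare and
#' writes `features.tsv`, `results.json`, `comparison.tsv`, `config.json`
#' and `run.log` (seed, package version, config MD5) into `out_dir`.
#' Segmentation uses detected onsets; beat labels fall back to the
#' generator's ground truth matched by onset proximity (or to
#' `annotations` when supplied).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param annotations optional per-beat annotation table (see
#'   [build_feature_table()]).
#' @return Invisibly, a list with the cohort, the feature table, the
#'   `pulse_eval` results per protocol, and the 40-index group comparison.
#' @export
run_pipeline <- function(config, out_dir, annotations = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  cfg_md5 <- unname(tools::md5sum(cfg_path))

  cohort <- pipeline_stage("simulate", generate_cohort(config$sim))
  features <- pipeline_stage("features", suppressMessages(
    build_feature_table(cohort, window = config$window,
                        normalization = config$normalization,
                        use_truth = FALSE, annotations = annotations,
                        min_hr = config$min_hr, max_hr = config$max_hr)))
  write_feature_table(features, file.path(out_dir, "features.tsv"))

  results <- lapply(config$protocols, function(pr) {
    pipeline_stage(pr, quality_eval(features, protocol = pr,
                                    methods = config$methods,
                                    seed = config$seed))
  })
  names(results) <- config$protocols
  res_json <- lapply(results, function(r)
    list(protocol = r$protocol, unit = r$unit, n_units = r$n_units,
         metrics = r$metrics))
  jsonlite::write_json(list(config_md5 = cfg_md5, results = res_json),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  comparison <- pipeline_stage("compare", compare_indices(features, by = "regime"))
  write.table(cbind(config_md5 = cfg_md5, comparison),
              file.path(out_dir, "comparison.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  writeLines(c(sprintf("pulseqc %s", as.character(utils::packageVersion("pulseqc"))),
               sprintf("seed: %d", config$seed),
               sprintf("config_md5: %s", cfg_md5),
               sprintf("records: %d", length(cohort)),
               sprintf("beats: %d", nrow(features))),
             file.path(out_dir, "run.log"))

  invisible(list(cohort = cohort, features = features, results = results,
                 comparison = comparison, config_md5 = cfg_md5))
}
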