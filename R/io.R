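#' Recording and result input/output
#'
#' Recordings round-trip through a BrainVision-style triplet: an INI-style
#' header (`.vhdr`), a marker file (`.vmrk`), and a binary signal file
#' (`.eeg`, IEEE float32, multiplexed channel order, microvolts). Ground
#' truths, feature tables and reports serialize to TSV.
#'
#' @name io
NULL

#' Write a recording as a BrainVision-style triplet
#'
#' @param rec An `eeg_recording`.
#' @param basepath Path without extension; writes `basepath.vhdr`,
#'   `basepath.vmrk`, `basepath.eeg`.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basepath) {
  base <- basename(basepath)
  vhdr <- paste0(basepath, ".vhdr")
  vmrk <- paste0(basepath, ".vmrk")
  eegf <- paste0(basepath, ".eeg")
  n_ch <- nrow(rec$signal)
  header <- c(
    "BrainVision-style Data Header",
    "",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_ch),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), rec$labels)
  )
  writeLines(header, vhdr, useBytes = TRUE)
  markers <- c(
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    if (nrow(rec$events) > 0) {
      sprintf("Mk%d=Stimulus,%s,%d,1,0",
              seq_len(nrow(rec$events)) + 1L, rec$events$code, rec$events$sample)
    }
  )
  writeLines(markers, vmrk)
  con <- file(eegf, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$signal), con, size = 4, endian = "little")
  invisible(vhdr)
}

.parse_ini <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[kv[1]]] <- paste(kv[-1], collapse = "=")
    }
  }
  out
}

#' Read a BrainVision-style triplet
#'
#' @param vhdr_path Path to the `.vhdr` header.
#' @param press_codes Marker codes mapped to press events.
#' @return An `eeg_recording` (signal in microvolts).
#' @export
read_brainvision <- function(vhdr_path, press_codes = "press") {
  ini <- .parse_ini(readLines(vhdr_path, encoding = "UTF-8"))
  common <- ini[["Common Infos"]]
  if (is.null(common)) abort("header has no [Common Infos] section")
  n_ch <- as.integer(common$NumberOfChannels)
  fs <- 1e6 / as.numeric(common$SamplingInterval)
  if (!identical(toupper(common$DataOrientation %||% "MULTIPLEXED"), "MULTIPLEXED")) {
    abort("DataOrientation: only MULTIPLEXED is supported")
  }
  bin_fmt <- ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32"
  if (!identical(toupper(bin_fmt), "IEEE_FLOAT_32")) {
    abort(sprintf("BinaryFormat '%s' not supported (IEEE_FLOAT_32 only)", bin_fmt))
  }
  chinfo <- ini[["Channel Infos"]]
  labels <- unname(vapply(chinfo[sprintf("Ch%d", seq_len(n_ch))], function(v) {
    strsplit(v, ",", fixed = TRUE)[[1]][1]
  }, character(1)))
  if (anyNA(labels)) abort("NumberOfChannels inconsistent with [Channel Infos] entries")
  dir <- dirname(vhdr_path)
  eegf <- file.path(dir, common$DataFile)
  nbytes <- file.size(eegf)
  n_vals <- nbytes / 4
  if (n_vals %% n_ch != 0) {
    abort(sprintf("binary size (%d samples) inconsistent with NumberOfChannels = %d",
                  n_vals, n_ch))
  }
  con <- file(eegf, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n_vals, size = 4, endian = "little")
  signal <- matrix(vals, nrow = n_ch, dimnames = list(labels, NULL))
  events <- tibble::tibble(sample = integer(), code = character())
  vmrk <- file.path(dir, common$MarkerFile %||% "")
  if (nzchar(common$MarkerFile %||% "") && file.exists(vmrk)) {
    mlines <- grep("^Mk[0-9]+=", readLines(vmrk), value = TRUE)
    if (length(mlines) > 0) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",", fixed = TRUE)
      type <- vapply(parts, `[[`, character(1), 1)
      code <- vapply(parts, function(p) p[2] %||% "", character(1))
      smp <- vapply(parts, function(p) as.integer(p[3]), integer(1))
      keep <- type == "Stimulus" & code %in% press_codes
      events <- tibble::tibble(sample = smp[keep], code = code[keep])
    }
  }
  eeg_recording(signal, fs, labels, events)
}

#' Write / read ground-truth hotspots
#'
#' TSV with columns `subject`, `hand`, `x`, `y`, `z` (cm, Cz-origin frame).
#'
#' @param truths Tibble of truths.
#' @param path File path.
#' @return `read_hotspots()` returns the tibble; `write_hotspots()` the path.
#' @export
write_hotspots <- function(truths, path) {
  utils::write.table(tibble::as_tibble(truths)[, c("subject", "hand", "x", "y", "z")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hotspots
#' @export
read_hotspots <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Default run configuration
#'
#' All pipeline parameters in one serializable list: cohort generation,
#' preprocessing, bands, network, cross-validation, study selection and
#' seeds. [read_run_config()] merges a YAML file over these defaults.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    study = "band-study",
    seed = 1,
    out_dir = "hotspotr-run",
    cohort = list(n_subjects = 10, hands = c("left", "right"),
                  hotspot_jitter_sd = 1, n_trials = 30, fs = 1000),
    preprocess = list(target_fs = 200, lo = 0.5, hi = 50.5, artifacts = "none"),
    bands = eeg_bands()$band,
    band = "gamma",
    channel_set = "Ch_Set1",
    channel_sets_file = NULL,
    set_names = paste0("Ch_Set", 1:5),
    model = list(n_hidden = 40, input = "relative_power", max_epochs = 1000,
                 patience = 50, val_fraction = 0.15, learn_rate = 0.05,
                 weight_decay = 1e-3, n_networks = 3),
    n_folds = 10
  )
}

#' Read a run configuration
#'
#' @param path YAML file; keys override [default_run_config()].
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- modifyList(default_run_config(), yaml::read_yaml(path))
  known_bands <- eeg_bands()$band
  bad <- setdiff(c(cfg$bands, cfg$band), known_bands)
  if (length(bad) > 0) {
    abort(paste0("unknown band(s) in config: ", paste(bad, collapse = ", ")))
  }
  if (!cfg$study %in% c("band-study", "ablation", "erp")) {
    abort(sprintf("unknown study '%s' (band-study, ablation, erp)", cfg$study))
  }
  cfg
}

#' Run the end-to-end pipeline from a configuration
#'
#' Simulates the configured cohort, runs the selected study, and writes
#' TSV/JSON artifacts plus a provenance record (config, seeds, package
#' version) under `out_dir`.
#'
#' @param config Configuration list (see [default_run_config()]) or a YAML
#'   path.
#' @return The study result, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  montage <- default_montage()
  sets <- if (!is.null(cfg$channel_sets_file)) {
    read_channel_sets(cfg$channel_sets_file)
  } else default_channel_sets()

  cspec <- do.call(cohort_spec, cfg$cohort)
  cohort <- simulate_cohort(cspec, seed = cfg$seed, montage = montage)
  write_hotspots(cohort_truths(cohort), file.path(cfg$out_dir, "hotspots_truth.tsv"))
  spec <- do.call(mlp_spec, c(cfg$model, list(seed = cfg$seed)))

  result <- switch(
    cfg$study,
    "band-study" = run_band_study(cohort, bands = cfg$bands,
                                  set_name = cfg$channel_set, montage = montage,
                                  sets = sets, n_folds = cfg$n_folds,
                                  spec = spec, seed = cfg$seed,
                                  artifacts = cfg$preprocess$artifacts),
    "ablation" = run_channel_ablation(cohort, set_names = cfg$set_names,
                                      band = cfg$band, montage = montage,
                                      sets = sets, n_folds = cfg$n_folds,
                                      spec = spec, seed = cfg$seed,
                                      artifacts = cfg$preprocess$artifacts),
    "erp" = run_erp_study(cohort, artifacts = cfg$preprocess$artifacts)
  )

  if (inherits(result, "hotspot_report")) {
    utils::write.table(result$trial_errors, file.path(cfg$out_dir, "trial_errors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$summary, file.path(cfg$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stats_json <- list(
      summary = result$summary,
      anova = lapply(result$anova, function(a) {
        a[c("F", "df1", "df2", "p", "epsilon_gg", "p_gg", "ordering")]
      }),
      hand_tests = result$hand_tests
    )
    jsonlite::write_json(stats_json, file.path(cfg$out_dir, "statistics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else if (inherits(result, "hotspot_erp_study")) {
    for (h in names(result)) {
      utils::write.table(result[[h]]$erp, file.path(cfg$out_dir, sprintf("erp_%s.tsv", h)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(result[[h]]$peaks, file.path(cfg$out_dir, sprintf("erp_peaks_%s.tsv", h)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  provenance <- list(
    package = "hotspotr",
    version = as.character(utils::packageVersion("hotspotr")),
    r_version = R.version.string,
    config = cfg,
    config_hash = rlang::hash(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}
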