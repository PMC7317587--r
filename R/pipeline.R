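#' Pipeline configuration
#'
#' Collects every tunable option of the analysis stages, validated against
#' the stage preconditions up front.
#'
#' @param ar_order AR order of the HRV spectral step
#' @param fs_interp tachogram resampling rate (Hz)
#' @param segment_s SDNNi segment length (s)
#' @param window_s,overlap,taper coherence windowing options
#' @param bands band table (see \code{\link{eeg_bands}})
#' @param transform edge length transform for graph metrics
#' @param amp_threshold optional artifact-rejection amplitude threshold
#' @param alpha significance level of the statistical layer
#' @param covariates covariate columns for group contrasts
#' @param seed integer seed recorded for stochastic stages
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(ar_order = 16, fs_interp = 4, segment_s = 50,
                            window_s = 2, overlap = 0.75, taper = "hann",
                            bands = eeg_bands(), transform = "inverse",
                            amp_threshold = NULL, alpha = 0.05,
                            covariates = "IQ", seed = NULL) {
  stop_if_not(ar_order >= 2, "ar_order must be at least 2")
  stop_if_not(fs_interp > 0.8, "fs_interp must exceed twice the HF edge")
  stop_if_not(window_s >= 2, "window_s must be at least 2 s")
  stop_if_not(overlap >= 0 && overlap <= 0.95, "overlap must be in [0, 0.95]")
  stop_if_not(all(c("band", "low", "high") %in% names(bands)),
              "bands needs band/low/high columns")
  structure(list(ar_order = ar_order, fs_interp = fs_interp,
                 segment_s = segment_s, window_s = window_s,
                 overlap = overlap, taper = taper, bands = bands,
                 transform = transform, amp_threshold = amp_threshold,
                 alpha = alpha, covariates = covariates, seed = seed),
            class = "pipeline_config")
}

#' Analyse one subject's R-R series and EEG recording
#'
#' Runs the HRV chain on the R-R series and the coherence-network chain on
#' the EEG, returning the subject's flat feature row: HR, LF, HF, SDNN,
#' SDNNi, RMSSD, pNN50 plus per-band \code{cpl_*} and \code{cc_*}.
#'
#' @param rr raw R-R intervals (ms vector, \code{rr_series} or
#'   \code{r_peaks})
#' @param eeg an \code{eeg_recording} (or NULL to skip network features)
#' @param config a \code{\link{pipeline_config}}
#' @return one-row data.frame
#' @export
analyze_subject <- function(rr, eeg, config = pipeline_config()) {
  row <- hrv_summary(rr, ar_order = config$ar_order,
                     fs_interp = config$fs_interp,
                     segment_s = config$segment_s)
  if (!is.null(eeg)) {
    if (!is.null(config$amp_threshold))
      eeg <- reject_artifacts(eeg, config$amp_threshold, config$window_s)
    sp <- windowed_spectra(eeg, window_s = config$window_s,
                           overlap = config$overlap, taper = config$taper,
                           max_freq = max(config$bands$high) + 5)
    cms <- band_adjacency(sp, config$bands)
    gm <- metrics_for_bands(cms, transform = config$transform)
    for (i in seq_len(nrow(gm))) {
      row[[paste0("cpl_", gm$band[i])]] <- gm$cpl[i]
      row[[paste0("cc_", gm$band[i])]] <- gm$avg_cc[i]
    }
  }
  row
}

#' Analyse a whole cohort end to end
#'
#' Builds the subject feature table with \code{\link{analyze_subject}},
#' screens it for outliers, runs IQ-adjusted group contrasts on every HRV
#' and network variable, and computes per-group FDR-corrected Spearman
#' correlation networks over the HRV and path-length variables.
#'
#' @param cohort output of \code{\link{generate_cohort}}, or a list with a
#'   \code{subjects} element of the same shape
#' @param config a \code{\link{pipeline_config}}
#' @param screen_outliers logical; run \code{\link{remove_outliers}} first
#' @return list: \code{subject_table}, \code{outlier_log},
#'   \code{contrasts} (one row per variable), \code{correlations}
#'   (per-group edge list)
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(),
                           screen_outliers = TRUE) {
  rows <- lapply(cohort$subjects, function(s) {
    cbind(data.frame(id = s$id, group = s$group),
          analyze_subject(s$rr, s$eeg, config))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(cohort$truth) && "IQ" %in% names(cohort$truth))
    tab$IQ <- cohort$truth$IQ[match(tab$id, cohort$truth$id)]
  feat <- setdiff(names(tab), c("id", "group", "IQ"))
  olog <- NULL
  if (screen_outliers && nrow(tab) < 10) {
    message("fewer than 10 subjects: outlier screening skipped")
    screen_outliers <- FALSE
  }
  if (screen_outliers) {
    sc <- remove_outliers(tab, feat, alpha = config$alpha)
    tab <- sc$table
    olog <- sc$log
  }
  contrasts <- do.call(rbind, lapply(feat, function(v) {
    tryCatch(group_contrast(tab, v, covariates = config$covariates),
             error = function(e)
               data.frame(variable = v, model = NA_character_,
                          t = NA_real_, p = NA_real_, eta_p_sq = NA_real_,
                          df = NA_real_, n_1 = NA_integer_,
                          n_2 = NA_integer_))
  }))
  corr_vars <- intersect(c("HR", "HF", "SDNNi",
                           paste0("cpl_", config$bands$band)), names(tab))
  correlations <- spearman_fdr(tab, corr_vars, by_group = TRUE,
                               alpha = config$alpha)
  list(subject_table = tab, outlier_log = olog,
       contrasts = contrasts, correlations = correlations)
}

#' Write a synthetic cohort to disk
#'
#' One R-R CSV per subject, one EEG file per subject (EDF by default), a
#' \code{subjects.csv} roster (id, group, IQ) and the latent ground-truth
#' table \code{truth.tsv}.
#'
#' @param spec a \code{\link{cohort_spec}}
#' @param out_dir output directory (created if needed)
#' @param eeg_format \code{"edf"} or \code{"csv"}
#' @param overwrite allow writing into a non-empty directory
#' @return invisibly, the cohort object that was written
#' @export
simulate_cohort_files <- function(spec, out_dir,
                                  eeg_format = c("edf", "csv"),
                                  overwrite = FALSE) {
  eeg_format <- match.arg(eeg_format)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE)",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec)
  for (s in cohort$subjects) {
    write.csv(data.frame(rr_ms = s$rr$intervals),
              file.path(out_dir, paste0(s$id, "_rr.csv")),
              row.names = FALSE)
    if (eeg_format == "edf") {
      write_edf(s$eeg$data, s$eeg$fs,
                file.path(out_dir, paste0(s$id, "_eeg.edf")))
    } else {
      csv_path <- file.path(out_dir, paste0(s$id, "_eeg.csv"))
      write.csv(as.data.frame(s$eeg$data), csv_path, row.names = FALSE)
      writeLines(as.character(s$eeg$fs), paste0(csv_path, ".fs"))
    }
  }
  roster <- cohort$truth[, c("id", "group", "IQ")]
  write.csv(roster, file.path(out_dir, "subjects.csv"), row.names = FALSE)
  write_tsv(cohort$truth, file.path(out_dir, "truth.tsv"))
  invisible(cohort)
}

#' Run the full analysis pipeline over a directory of subject files
#'
#' Expects the layout written by \code{\link{simulate_cohort_files}}:
#' \code{subjects.csv} plus per-subject \code{<id>_rr.csv} and
#' \code{<id>_eeg.edf} (or \code{.csv}).  Subjects with unreadable or
#' missing modalities are skipped with a logged reason.  Writes
#' \code{subject_table.tsv}, \code{contrasts.tsv},
#' \code{correlations.tsv} and \code{outlier_log.tsv} (numeric cells fixed
#' to 6 decimals, so reruns are byte-identical) and a JSON sidecar of the
#' configuration.
#'
#' @param in_dir input directory
#' @param out_dir output directory (created if needed)
#' @param config a \code{\link{pipeline_config}}
#' @return invisibly, the \code{\link{analyze_cohort}} result, plus a
#'   \code{skipped} data.frame
#' @export
run_pipeline <- function(in_dir, out_dir, config = pipeline_config()) {
  roster_path <- file.path(in_dir, "subjects.csv")
  stop_if_not(file.exists(roster_path), "subjects.csv not found in in_dir")
  roster <- read.csv(roster_path, stringsAsFactors = FALSE)
  subjects <- list()
  skipped <- list()
  for (i in seq_len(nrow(roster))) {
    id <- roster$id[i]
    rr_path <- file.path(in_dir, paste0(id, "_rr.csv"))
    eeg_edf <- file.path(in_dir, paste0(id, "_eeg.edf"))
    eeg_csv <- file.path(in_dir, paste0(id, "_eeg.csv"))
    res <- tryCatch({
      stop_if_not(file.exists(rr_path), "missing RR file")
      rr <- read.csv(rr_path)[[1]]
      eeg <- if (file.exists(eeg_edf)) {
        e <- read_edf(eeg_edf)
        as_eeg_recording(e$data, e$fs)
      } else if (file.exists(eeg_csv)) {
        as_eeg_recording(as.matrix(read.csv(eeg_csv, check.names = FALSE)),
                         guess_eeg_fs(eeg_csv))
      } else stop("missing EEG file")
      list(id = id, group = roster$group[i], rr = rr, eeg = eeg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping subject ", id, ": ", conditionMessage(res))
      skipped[[length(skipped) + 1]] <-
        data.frame(id = id, reason = conditionMessage(res))
    } else {
      subjects[[length(subjects) + 1]] <- res
    }
  }
  stop_if_not(length(subjects) >= 4, "fewer than 4 readable subjects")
  truth <- data.frame(id = roster$id, IQ = roster$IQ)
  out <- analyze_cohort(list(subjects = subjects, truth = truth), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(out$subject_table, file.path(out_dir, "subject_table.tsv"))
  write_tsv(out$contrasts, file.path(out_dir, "contrasts.tsv"))
  write_tsv(out$correlations, file.path(out_dir, "correlations.tsv"))
  if (!is.null(out$outlier_log))
    write_tsv(out$outlier_log, file.path(out_dir, "outlier_log.tsv"))
  cfg <- unclass(config)
  cfg$bands <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  out$skipped <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(id = character(), reason = character())
  invisible(out)
}

# EEG CSVs carry no sampling rate; a sidecar "<file>.fs" holds it, else 250
guess_eeg_fs <- function(path) {
  side <- paste0(path, ".fs")
  if (file.exists(side)) as.numeric(readLines(side, n = 1)) else 250
}

# TSV writer with fixed 6-decimal formatting for byte-stable reruns
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], format = "f", digits = 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
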