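#' Write a recording to CSV with header metadata
#'
#' All trace types share one on-disk format: `# key=value` metadata lines
#' followed by a regular CSV table whose column names carry units
#' (`time_s`, `current_pA`, ...).
#'
#' @param x A `single_channel_recording`, `ramp_sweep`, `flux_assay_record`
#'   or `imaging_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  if (inherits(x, "single_channel_recording")) {
    kind <- "single_channel"
    df <- data.frame(time_s = (seq_along(x$samples) - 1) / x$sample_rate,
                     current_pA = x$samples)
    meta <- list(sample_rate_Hz = x$sample_rate,
                 filter_cutoff_Hz = x$filter_cutoff, voltage_mV = x$voltage,
                 permeant_ion = x$permeant_ion, genotype = x$genotype)
  } else if (inherits(x, "ramp_sweep")) {
    kind <- "ramp"
    df <- data.frame(time_s = x$time, voltage_mV = x$voltage,
                     current_pA = x$current)
    meta <- c(list(capacitance_pF = x$capacitance), x$condition)
  } else if (inherits(x, "flux_assay_record")) {
    kind <- "flux"
    df <- data.frame(time_s = x$time_s, F_ca_ex = x$F_ca_ex,
                     F_fura340 = x$F_fura340, F_fura380 = x$F_fura380,
                     F_tmrm_num = x$F_tmrm_num, F_tmrm_den = x$F_tmrm_den)
    meta <- list(ca_added_uM = x$ca_added_uM, protein_mg_ml = x$protein_mg_ml)
  } else if (inherits(x, "imaging_trace")) {
    kind <- "imaging"
    df <- data.frame(time_s = x$time_s, F340 = x$f340, F380 = x$f380,
                     F_cepia = x$f_cepia)
    meta <- list(frame_interval_s = x$frame_interval_s,
                 stim_time_s = x$stim_time_s, cell_id = x$cell_id,
                 dish_id = x$dish_id)
  } else stop("unsupported object for trace CSV export")
  meta <- c(list(kind = kind), meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    if (!is.null(meta[[k]]) && !is.na(meta[[k]]))
      writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 15)), con)
  writeLines(paste(names(df), collapse = ","), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' Validates the `# key=value` metadata header, the expected columns for the
#' trace kind, strictly increasing time, and the absence of missing values,
#' then rebuilds the module-appropriate object.
#'
#' @param path Input file.
#' @param kind Expected kind ("single_channel", "ramp", "flux", "imaging")
#'   or "auto" to take it from the metadata.
#' @return The reconstructed recording object.
#' @export
read_trace_csv <- function(path, kind = "auto") {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trace file: ", path)
  is_meta <- grepl("^#", lines)
  header <- sub("^#\\s*", "", lines[is_meta])
  meta <- list()
  for (h in header) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed metadata line: ", h)
    meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!is_meta]
  if (length(body) < 2) stop("trace file has no data rows: ", path)
  df <- read.csv(text = paste(body, collapse = "\n"))
  file_kind <- meta$kind
  if (kind == "auto") {
    if (is.null(file_kind)) stop("no kind metadata; pass `kind` explicitly")
    kind <- file_kind
  } else if (!is.null(file_kind) && file_kind != kind) {
    stop("file declares kind '", file_kind, "' but '", kind, "' was requested")
  }
  need <- switch(kind,
    single_channel = c("time_s", "current_pA"),
    ramp = c("time_s", "voltage_mV", "current_pA"),
    flux = c("time_s", "F_ca_ex", "F_fura340", "F_fura380", "F_tmrm_num",
             "F_tmrm_den"),
    imaging = c("time_s", "F340", "F380", "F_cepia"),
    stop("unknown trace kind: ", kind))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyNA(df[need])) stop("trace contains missing values")
  if (any(diff(df$time_s) <= 0)) stop("time column is not strictly increasing")
  num <- function(key, default = NA_real_)
    if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
  switch(kind,
    single_channel = single_channel_recording(
      df$current_pA,
      sample_rate = num("sample_rate_Hz",
                        1 / median(diff(df$time_s))),
      filter_cutoff = num("filter_cutoff_Hz"),
      voltage = num("voltage_mV"),
      permeant_ion = meta$permeant_ion %||% "Ca",
      genotype = meta$genotype %||% "WT"),
    ramp = ramp_sweep(df$time_s, df$voltage_mV, df$current_pA,
                      capacitance = num("capacitance_pF", 1),
                      condition = meta[setdiff(names(meta),
                                               c("kind", "capacitance_pF"))]),
    flux = structure(list(time_s = df$time_s, F_ca_ex = df$F_ca_ex,
                          F_fura340 = df$F_fura340, F_fura380 = df$F_fura380,
                          F_tmrm_num = df$F_tmrm_num,
                          F_tmrm_den = df$F_tmrm_den,
                          ca_added_uM = num("ca_added_uM"),
                          protein_mg_ml = num("protein_mg_ml")),
                     class = "flux_assay_record"),
    imaging = structure(list(time_s = df$time_s, f340 = df$F340,
                             f380 = df$F380, f_cepia = df$F_cepia,
                             frame_interval_s = num("frame_interval_s",
                                                    median(diff(df$time_s))),
                             stim_time_s = num("stim_time_s"),
                             cell_id = meta$cell_id %||% "cell1",
                             dish_id = meta$dish_id %||% "dish1"),
                        class = "imaging_trace"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a seeded end-to-end demonstration pipeline
#'
#' Executes one of three reproducible stage chains driven entirely by the
#' package's generators and analyses, logging parameters as it goes:
#'
#' * `"single_channel"`: simulate WT and MICU1-KO ensembles, resample at
#'   2.5 kHz, fit and Viterbi-idealize each trace, and compare open
#'   probabilities between genotypes.
#' * `"flux"`: simulate uptake assays over a range of calcium boluses and
#'   recover the chord conductance for each.
#' * `"imaging"`: simulate WT-like and MICU1-KO-like dishes, detect each
#'   cell's uptake threshold, and run the dish-level group statistics.
#'
#' Identical `config` (including `seed`) gives identical results.
#'
#' @param config List with `pipeline` (one of the above), `seed`, and
#'   optional sizes: `n_per_group`, `trace_duration`, `ca_added_uM`,
#'   `cells_per_dish`, `n_dishes`. Alternatively a path to a JSON file with
#'   those fields.
#' @param out Optional path for a JSON results file.
#' @return A list with `config`, `log` (character) and `results`.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$pipeline)) stop("config$pipeline is required")
  if (is.null(config$seed)) stop("config$seed is required: all stochastic steps are seeded")
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("pipeline=%s seed=%d", config$pipeline, config$seed)
  results <- switch(config$pipeline,
    single_channel = {
      n <- config$n_per_group %||% 4
      dur <- config$trace_duration %||% 20
      note("simulating %d traces per genotype, %g s each", n, dur)
      wt <- gating_model()
      ko <- set_open_probability(wt, open_probability(wt) / 2.5)
      run1 <- function(model, seed) {
        sim <- simulate_single_channel(model, duration = dur, seed = seed)
        rec <- resample(sim$recording, 2500)
        fit <- baum_welch_fit(rec, K = 4, seed = seed)
        channel_stats(viterbi_idealize(rec, fit$model), fit$model)
      }
      stats_wt <- lapply(seq_len(n), function(i) run1(wt, config$seed + i))
      stats_ko <- lapply(seq_len(n), function(i) run1(ko, config$seed + 100 + i))
      cmp <- compare_genotypes(stats_wt, stats_ko, stat = "p_open")
      note("Po ratio WT/KO = %.3f (p = %.3g)", cmp$ratio, cmp$p_value)
      list(po_wt = cmp$mean[1], po_ko = cmp$mean[2], po_ratio = cmp$ratio,
           p_value = cmp$p_value)
    },
    flux = {
      ca <- config$ca_added_uM %||% c(1, 2, 5, 10, 20)
      note("simulating %d flux assays", length(ca))
      points <- lapply(seq_along(ca), function(i) {
        buf <- protocol_buffers("auto", ca[i])
        cal <- fluo4_calibration(if (ca[i] <= 3) 1 else 2)
        model <- flux_model(buffers = buf, indicator = cal)
        rec <- simulate_flux_assay(model, ca[i], seed = config$seed + i)
        cp <- recover_conductance(rec, cal, buf, model$matrix_fura,
                                  model$protein_mg_ml,
                                  tmrm_table = tmrm_calibration_table(model))
        data.frame(ca_added_uM = ca[i], ca_i_free_uM = cp$ca_i_free_uM,
                   G_nS = cp$G_nS)
      })
      do.call(rbind, points)
    },
    imaging = {
      nd <- config$n_dishes %||% 3
      nc <- config$cells_per_dish %||% 5
      note("simulating %d dishes x %d cells per genotype", nd, nc)
      cal <- indicator_calibration(kd = 224, r_min = 0.3, r_max = 3, beta = 4)
      rows <- list()
      k <- 0
      for (gt in c("WT", "MICU1KO")) {
        for (d in seq_len(nd)) for (cell in seq_len(nc)) {
          k <- k + 1
          thr <- if (gt == "WT") 400 else 100
          m <- imaging_model(threshold_ca_nM = thr)
          tr <- simulate_imaging(m, seed = config$seed + k,
                                 cell_id = sprintf("c%d", cell),
                                 dish_id = sprintf("%s_d%d", gt, d))
          res <- analyze_imaging_trace(tr, cal)
          rows[[k]] <- data.frame(genotype = gt, dish_id = tr$dish_id,
                                  cell_id = tr$cell_id,
                                  threshold_ca_nM = res$threshold_ca_nM)
        }
      }
      df <- do.call(rbind, rows)
      batch <- batch_thresholds(df)
      note("ANOVA p = %.3g", batch$anova_p)
      list(cells = df, group_summary = batch$group_summary,
           anova_p = batch$anova_p)
    },
    stop("unknown pipeline: ", config$pipeline))
  bundle <- list(config = config, log = log, results = results)
  if (!is.null(out))
    jsonlite::write_json(bundle, out, auto_unbox = TRUE, digits = 10,
                         dataframe = "rows")
  bundle
}
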