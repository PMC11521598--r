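#' Pipeline configuration
#'
#' Assembles and validates the configuration for an end-to-end run:
#' simulate -> preprocess -> synchrony -> indices -> model. Unknown keys
#' are rejected so that config typos fail loudly. The configuration
#' round-trips through YAML unchanged.
#'
#' @param n_dyads Number of dyads to simulate (default 6).
#' @param stages Character subset of
#'   `c("simulate", "preprocess", "synchrony", "indices", "model")`.
#' @param sim Named list overriding [dyad_sim_config()] fields (e.g.
#'   `list(coupling = 0.6, duration_s = 120)`).
#' @param wtc Named list overriding [wtc_config()] fields.
#' @param synchrony_channel Channel for the synchrony stage: `"ibi"`,
#'   `"rsp"`, or `"sc"`.
#' @param synchrony_band Band for the synchrony stage.
#' @param baseline_correct Apply [neutral_baseline_correct()] before
#'   modelling (default `TRUE`).
#' @param seed Master seed.
#' @param out Output root directory.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_dyads = 6,
                            stages = c("simulate", "preprocess", "synchrony",
                                       "indices", "model"),
                            sim = list(), wtc = list(),
                            synchrony_channel = "ibi",
                            synchrony_band = "full",
                            baseline_correct = TRUE,
                            seed = 1L, out = tempfile("dyadsync_run_"),
                            log_level = c("info", "quiet")) {
  stages <- match.arg(stages, several.ok = TRUE)
  log_level <- match.arg(log_level)
  ok_sim <- names(formals(dyad_sim_config))
  bad <- setdiff(names(sim), ok_sim)
  if (length(bad)) stop("unknown sim config keys: ", paste(bad, collapse = ", "))
  ok_wtc <- names(formals(wtc_config))
  bad <- setdiff(names(wtc), ok_wtc)
  if (length(bad)) stop("unknown wtc config keys: ", paste(bad, collapse = ", "))
  structure(
    list(n_dyads = n_dyads, stages = stages, sim = sim, wtc = wtc,
         synchrony_channel = synchrony_channel,
         synchrony_band = synchrony_band,
         baseline_correct = baseline_correct,
         seed = as.integer(seed), out = out, log_level = log_level),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ok <- names(formals(pipeline_config))
  bad <- setdiff(names(y), ok)
  if (length(bad)) stop("unknown pipeline config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

log_line <- function(config, stage, msg, ...) {
  if (config$log_level == "quiet") return(invisible())
  entry <- jsonlite::toJSON(
    c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage,
           msg = sprintf(msg, ...))),
    auto_unbox = TRUE)
  message(entry)
}

#' Run the dyadic synchrony pipeline
#'
#' Executes the enabled stages in order on simulated sessions, writing
#' per-dyad session directories, preprocessing outputs (`artifacts.json`,
#' per-channel derived series), `synchrony.csv`, `dyad_indices.csv` (and
#' the baseline-corrected variant), `model_fit.json` and
#' `selection_trace.json`, plus a run manifest with per-file digests so
#' reruns can be verified bit-for-bit.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_manifest`: `config`, `seeds`, `files`
#'   (named md5 digests), `timestamps`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  sessions <- list()

  if ("simulate" %in% config$stages) {
    log_line(config, "simulate", "simulating %d dyads", config$n_dyads)
    for (d in seq_len(config$n_dyads)) {
      sim_args <- config$sim
      sim_args$seed <- derive_seed(config$seed, "dyad", d)
      scfg <- do.call(dyad_sim_config, sim_args)
      sessions[[d]] <- simulate_dyad_session(scfg)
      write_session(sessions[[d]], file.path(out, sprintf("dyad%02d", d)))
    }
  }

  individual <- NULL
  if ("preprocess" %in% config$stages) {
    log_line(config, "preprocess", "preprocessing %d dyads", length(sessions))
    dir.create(file.path(out, "preproc"), showWarnings = FALSE)
    individual <- sessions_to_individual_table(sessions, physio = TRUE)
    rsp_recs <- list(); sc_recs <- list()
    pid <- 0L
    for (d in seq_along(sessions)) {
      for (m in 1:2) {
        pid <- pid + 1L
        vids <- sessions[[d]]$members[[m]]$videos
        rsp_recs[[pid]] <- lapply(vids, `[[`, "rsp")
        sc_recs[[pid]] <- lapply(vids, `[[`, "sc")
        for (v in 1:3) {
          ibi <- vids[[v]]$ibi
          utils::write.csv(
            data.frame(peak_times_s = ibi$peak_times,
                       ibi_ms = c(NA, ibi$ibis_ms)),
            file.path(out, "preproc",
                      sprintf("dyad%02d_member%d_video%d_ibi.csv", d, m, v)),
            row.names = FALSE)
          write_signal_csv(
            extract_phasic_sc(vids[[v]]$sc),
            file.path(out, "preproc",
                      sprintf("dyad%02d_member%d_video%d_sc_phasic.csv",
                              d, m, v)))
        }
      }
    }
    reports <- list(rsp = flag_rsp_artifacts(rsp_recs),
                    sc = flag_sc_artifacts(sc_recs))
    jsonlite::write_json(reports, file.path(out, "artifacts.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  if ("synchrony" %in% config$stages) {
    log_line(config, "synchrony", "computing %s synchrony", config$synchrony_channel)
    wcfg <- do.call(wtc_config, config$wtc)
    rows <- list()
    for (d in seq_along(sessions)) {
      for (v in 1:3) {
        vids1 <- sessions[[d]]$members[[1]]$videos[[v]]
        vids2 <- sessions[[d]]$members[[2]]$videos[[v]]
        tr <- switch(config$synchrony_channel,
          ibi = list(x = vids1$ibi$interp_trace, y = vids2$ibi$interp_trace,
                     fs = vids1$ibi$interp_fs),
          rsp = list(x = vids1$rsp$samples, y = vids2$rsp$samples,
                     fs = vids1$rsp$fs),
          sc = list(x = extract_phasic_sc(vids1$sc)$samples,
                    y = extract_phasic_sc(vids2$sc)$samples,
                    fs = vids1$sc$fs))
        n <- min(length(tr$x), length(tr$y))
        map <- wavelet_coherence(tr$x[seq_len(n)], tr$y[seq_len(n)], tr$fs, wcfg)
        sync <- average_synchrony(map, config$synchrony_band)
        rows[[length(rows) + 1L]] <- data.frame(
          dyad = d, channel = config$synchrony_channel, video = v,
          valence = vids1$valence, band = sync$band, method = sync$method,
          value = sync$value)
      }
    }
    sync_tab <- do.call(rbind, rows)
    utils::write.csv(sync_tab, file.path(out, "synchrony.csv"), row.names = FALSE)
  }

  if ("indices" %in% config$stages) {
    log_line(config, "indices", "building dyad index table")
    if (is.null(individual)) {
      individual <- sessions_to_individual_table(sessions, physio = TRUE)
    }
    tab <- build_dyad_table(individual)
    if (file.exists(file.path(out, "synchrony.csv"))) {
      sync_tab <- utils::read.csv(file.path(out, "synchrony.csv"))
      sync_col <- paste0("synchrony_", config$synchrony_channel)
      tab[[sync_col]] <- sync_tab$value[match(paste(tab$dyad, tab$video),
                                              paste(sync_tab$dyad, sync_tab$video))]
    }
    utils::write.csv(tab, file.path(out, "dyad_indices.csv"), row.names = FALSE)
    if (config$baseline_correct) {
      corr <- neutral_baseline_correct(tab)
      utils::write.csv(corr, file.path(out, "dyad_indices_corrected.csv"),
                       row.names = FALSE)
    }
  }

  if ("model" %in% config$stages) {
    log_line(config, "model", "fitting mixed model with backward selection")
    path <- file.path(out, if (config$baseline_correct)
      "dyad_indices_corrected.csv" else "dyad_indices.csv")
    tab <- utils::read.csv(path)
    phys <- intersect(c("dyadic_mean_ibi", "dyadic_mean_rsp_rate",
                        "dyadic_mean_sc_level"), names(tab))
    tab <- standardize_predictors(tab, phys)
    fixed <- c(phys, "attention",
               if ("dyadic_mean_sc_level" %in% phys) "dyadic_mean_sc_level:attention")
    spec <- model_spec("mutual_connectedness", fixed = fixed,
                       random_intercepts = "dyad", estimation = "ML")
    sel <- backward_stepwise(spec, tab)
    fit <- sel$final_fit
    jsonlite::write_json(
      list(coefficients = fit$coefficients, logLik = fit$logLik,
           sigma2 = fit$sigma2, tau00 = as.list(fit$tau00), icc = fit$icc,
           r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional,
           n_obs = fit$n_obs, converged = fit$converged,
           singular = fit$singular),
      file.path(out, "model_fit.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(
      list(trace = sel$trace, final_fixed = sel$final_spec$fixed),
      file.path(out, "selection_trace.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  digests <- tools::md5sum(files)
  names(digests) <- substring(files, nchar(out) + 2)
  manifest <- structure(
    list(config = unclass(config), seed = config$seed,
         files = as.list(digests),
         started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
         finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate a session directory against the expected layout
#'
#' Checks channel-file presence for each member and video, the
#' `# fs=... units=...` headers, strictly increasing time columns, and
#' unit labels. Violations are collected, not thrown.
#'
#' @param path Session directory (as written by [write_session()]).
#' @param n_videos Expected number of videos (default 3).
#' @return A list with `valid` (logical) and `violations` (character
#'   vector naming each offending file/row).
#' @export
validate_session_dir <- function(path, n_videos = 3) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  violations <- character(0)
  expect_units <- c(ecg = "mV", rsp = "mcV", sc = "uS")
  for (m in 1:2) {
    for (v in seq_len(n_videos)) {
      for (ch in c("ecg", "rsp", "sc")) {
        f <- file.path(path, sprintf("member%d_video%d_%s.csv", m, v, ch))
        if (!file.exists(f)) {
          violations <- c(violations,
                          sprintf("missing %s file for member %d video %d", ch, m, v))
          next
        }
        header <- readLines(f, n = 1L)
        if (!grepl("^#\\s*fs=[0-9.eE+-]+\\s+units=\\S+", header)) {
          violations <- c(violations, sprintf("%s: malformed header", basename(f)))
          next
        }
        units <- sub(".*units=(\\S+).*", "\\1", header)
        if (units != expect_units[[ch]]) {
          violations <- c(violations,
                          sprintf("%s: units %s, expected %s", basename(f),
                                  units, expect_units[[ch]]))
        }
        dat <- utils::read.csv(f, comment.char = "#")
        bad <- which(diff(dat$time_s) <= 0)
        if (length(bad)) {
          violations <- c(violations,
                          sprintf("%s: non-monotone time column at row %d",
                                  basename(f), bad[1] + 1L))
        }
      }
    }
  }
  for (f in c("ratings.csv", "session.json")) {
    if (!file.exists(file.path(path, f))) {
      violations <- c(violations, paste("missing", f))
    }
  }
  list(valid = length(violations) == 0L, violations = violations)
}
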