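#' Trace serialization
#'
#' Traces are written as plain CSV (one row per time-point, full numeric
#' precision) with the run configuration in a JSON sidecar
#' (`<path>.json`), so a round-trip reproduces the trace exactly.
#'
#' @param trace an `"al_trace"`.
#' @param path CSV output path.
#' @return `path` invisibly; `read_trace` returns the `"al_trace"`.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  fmt <- vapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col),
    character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  utils::write.table(fmt, path, sep = ",", quote = FALSE, row.names = FALSE)
  cfg <- attr(trace, "config")
  if (!is.null(cfg))
    jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df[] <- lapply(df, function(col) if (is.integer(col)) as.numeric(col) else col)
  need <- c("round", "n_observed", "fraction", "accuracy")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed trace file %s: missing columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  df <- df[order(df$round), , drop = FALSE]
  rownames(df) <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(df, "config") <- jsonlite::read_json(side, simplifyVector = TRUE)
  class(df) <- c("al_trace", "data.frame")
  df
}

pipeline_defaults <- function() {
  list(
    out_dir = "dtal-run",
    seed = 1L,
    grid = list(u_values = c(0.3, 0.5, 0.7), r_values = c(0.2, 0.4),
                noise_values = 0, n_seeds = 1L, N = 20L, M = 20L),
    trace = list(strategy = "uncertainty", init = "random",
                 batch_fraction = 0.05, R = 10L, iterations = 50L,
                 tol = 1e-4, stop_fraction = 0.95, max_rounds = Inf),
    predictor = list(folds = 11L),
    calibration = list(bin_width = 0.05, folds = 11L)
  )
}

validate_config <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop(sprintf("unknown configuration keys: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (grp in c("grid", "trace", "predictor", "calibration")) {
    bad <- setdiff(names(config[[grp]]), names(defaults[[grp]]))
    if (length(bad) > 0L)
      stop(sprintf("unknown keys in '%s': %s", grp,
                   paste(bad, collapse = ", ")), call. = FALSE)
    defaults[[grp]][names(config[[grp]])] <- config[[grp]]
  }
  for (key in setdiff(names(config), c("grid", "trace", "predictor", "calibration")))
    defaults[[key]] <- config[[key]]
  defaults
}

#' Run the end-to-end simulation pipeline
#'
#' Orchestrates simulate -> traces -> accuracy predictor -> calibration:
#' realises every scenario in the configured grid (writing `Y`, `Kd`, `Kt`
#' as tab-delimited files), runs one uncertainty-sampling trace per
#' scenario (written as CSV + JSON sidecar), fits the trajectory-grouped
#' lasso accuracy regressor on all traces (written as JSON), computes the
#' cross-validated exceedance calibration (CSV), and writes a scenario
#' manifest.  Identical configuration and seed reproduce every output
#' bit-identically; all outputs carry the configuration's MD5 hash.
#'
#' @param config nested list overriding the defaults (see
#'   `dtal:::pipeline_defaults()`): `out_dir`, `seed`, and groups `grid`
#'   (`u_values`, `r_values`, `noise_values`, `n_seeds`, `N`, `M`),
#'   `trace` (`strategy`, `init`, `batch_fraction`, `R`, `iterations`,
#'   `tol`, `stop_fraction`, `max_rounds`), `predictor` (`folds`),
#'   `calibration` (`bin_width`, `folds`).  Unknown keys are rejected
#'   before any computation.  A YAML file path is accepted when the yaml
#'   package is installed.
#' @param quiet suppress per-stage progress messages.
#' @return the output directory, invisibly, with the manifest data.frame
#'   as attribute `"manifest"`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  ## hash the scientific configuration only, not the output location
  tmp <- tempfile()
  jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")], tmp,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scen_dir <- file.path(cfg$out_dir, "scenarios")
  trace_dir <- file.path(cfg$out_dir, "traces")
  dir.create(scen_dir, showWarnings = FALSE)
  dir.create(trace_dir, showWarnings = FALSE)

  g <- cfg$grid
  grid <- build_grid(g$u_values, g$r_values, g$noise_values,
                     n_seeds = g$n_seeds, N = g$N, M = g$M,
                     base_seed = cfg$seed)
  say("stage simulate: %d scenarios (%d x %d)", nrow(grid), g$N, g$M)

  tr_cfg <- cfg$trace
  batch <- ceiling(tr_cfg$batch_fraction * g$N * g$M)
  traces <- vector("list", nrow(grid))
  manifest <- grid
  manifest$scenario_id <- sprintf("s%04d", seq_len(nrow(grid)))
  manifest$u_achieved <- NA_real_
  manifest$r_achieved <- NA_real_
  manifest$config_hash <- cfg_hash

  for (i in seq_len(nrow(grid))) {
    sid <- manifest$scenario_id[i]
    sc <- tryCatch(
      simulate_scenario(grid$u_target[i], grid$r_target[i], grid$noise[i],
                        N = g$N, M = g$M, seed = grid$seed[i]),
      error = function(e) stop(sprintf("stage simulate failed for %s: %s",
                                       sid, conditionMessage(e)), call. = FALSE))
    manifest$u_achieved[i] <- sc$u
    manifest$r_achieved[i] <- sc$r
    write_interaction_matrix(sc$Y, file.path(scen_dir, paste0(sid, "_Y.tsv")))
    write_kernel(sc$Kd, file.path(scen_dir, paste0(sid, "_Kd.tsv")))
    write_kernel(sc$Kt, file.path(scen_dir, paste0(sid, "_Kt.tsv")))

    tr <- tryCatch(
      run_trace(sc$Y, sc$Kd, sc$Kt, strategy = tr_cfg$strategy,
                init = tr_cfg$init, batch = batch, R = tr_cfg$R,
                iterations = tr_cfg$iterations, tol = tr_cfg$tol,
                seed = grid$seed[i], stop_fraction = tr_cfg$stop_fraction,
                max_rounds = tr_cfg$max_rounds),
      error = function(e) stop(sprintf("stage run-al failed for %s: %s",
                                       sid, conditionMessage(e)), call. = FALSE))
    attr(tr, "config")$config_hash <- cfg_hash
    write_trace(tr, file.path(trace_dir, paste0(sid, ".csv")))
    traces[[i]] <- tr
    say("stage run-al: %s done (%d rounds, final accuracy %.3f)",
        sid, nrow(tr), tr$accuracy[nrow(tr)])
  }
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)

  pf <- min(cfg$predictor$folds, length(traces))
  say("stage train-predictor: %d traces, %d-fold grouped CV", length(traces), pf)
  predictor <- fit_accuracy_regressor(traces, folds = pf, seed = cfg$seed)
  write_predictor(predictor, file.path(cfg$out_dir, "predictor.json"))

  cf <- max(3L, min(cfg$calibration$folds, floor(length(traces) / 2)))
  say("stage calibrate: %d-fold trajectory CV", cf)
  calib <- cv_calibrate(traces, folds = cf,
                        bin_width = cfg$calibration$bin_width,
                        seed = cfg$seed)
  utils::write.csv(cbind(as.data.frame(calib), config_hash = cfg_hash),
                   file.path(cfg$out_dir, "calibration.csv"),
                   row.names = FALSE)

  invisible(structure(cfg$out_dir, manifest = manifest))
}
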