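# Run configuration (YAML), result tables (TSV with unit-bearing
# headers), and run logs. An empty config file yields the full baseline
# model; unknown keys are rejected by name.

.run_config_keys <- list(
  model = c("cm", "gbar", "erev", "coupling_c", "kca_fixed_ca",
            "h_act_v_half"),
  calcium = c("tau_ca", "f", "ca_base", "ca_out", "temperature", "z",
              "log_base"),
  stimulus = c("kind", "amplitude", "onset", "width", "lambda", "seed"),
  analysis = c("levels", "lambda_grid", "seeds", "percents", "duration",
               "transient", "threshold", "min_isi", "channel",
               "gbar_values"),
  run = c("out_dir", "seed")
)

#' Load a run configuration
#'
#' Reads a YAML configuration with sections `model`, `calcium`,
#' `stimulus`, `analysis` and `run`; every field is optional and falls
#' back to the baseline model defaults. Unknown sections or keys are
#' errors naming the offender; invariant violations (negative
#' conductances, non-positive time constants) are errors naming the
#' field.
#'
#' @param path path to a YAML file (or a list already parsed)
#' @return a list of class `run_config` with elements `config` (a
#'   [neuron_config()]), `stimulus` (a `stimulus_protocol`), `analysis`
#'   (a list of analysis settings) and `run`
#' @export
load_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), names(.run_config_keys))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    unk <- setdiff(names(raw[[sec]]), .run_config_keys[[sec]])
    if (length(unk)) stop("unknown key(s) in section '", sec, "': ",
                          paste(unk, collapse = ", "))
  }
  m <- raw$model
  ca <- raw$calcium
  cal_args <- if (is.null(ca)) list() else
    ca[intersect(names(ca), .run_config_keys$calcium)]
  calcium <- do.call(calcium_config, cal_args)
  gbar <- if (!is.null(m$gbar)) unlist(m$gbar)
  if (!is.null(gbar) && any(gbar < 0))
    stop("negative conductance for channel(s): ",
         paste(names(gbar)[gbar < 0], collapse = ", "))
  specs <- default_channels()
  if (!is.null(m$h_act_v_half))
    specs$h <- shift_activation(specs$h, m$h_act_v_half)
  config <- neuron_config(
    gbar = gbar,
    erev = if (!is.null(m$erev)) unlist(m$erev),
    cm = if (!is.null(m$cm)) m$cm else 0.6,
    calcium = calcium, specs = specs,
    coupling_c = if (!is.null(m$coupling_c)) m$coupling_c else 1,
    kca_fixed_ca = if (!is.null(m$kca_fixed_ca)) m$kca_fixed_ca
                   else NA_real_)
  s <- raw$stimulus
  stimulus <- if (is.null(s) || is.null(s$kind) ||
                  identical(s$kind, "zero")) zero_stimulus()
  else if (identical(s$kind, "tonic"))
    tonic_current(if (!is.null(s$amplitude)) s$amplitude else 0,
                  onset = if (!is.null(s$onset)) s$onset else 0)
  else if (identical(s$kind, "synaptic"))
    synaptic_train(s$lambda, seed = if (!is.null(s$seed)) s$seed else 1L,
                   amplitude = if (!is.null(s$amplitude)) s$amplitude
                               else 0.75,
                   width = if (!is.null(s$width)) s$width else 2)
  else stop("unknown stimulus kind: ", s$kind)
  analysis <- utils::modifyList(
    list(levels = seq(0, 2, length.out = 21),
         lambda_grid = c(30, 20, 12, 8, 5, 3, 2, 1, 0.5),
         seeds = 1:5, percents = c(70, 85, 100, 115, 130),
         duration = 12000, transient = 2000,
         threshold = -10, min_isi = 4),
    if (is.null(raw$analysis)) list() else raw$analysis)
  run <- utils::modifyList(list(out_dir = ".", seed = 1L),
                           if (is.null(raw$run)) list() else raw$run)
  structure(list(config = config, stimulus = stimulus,
                 analysis = analysis, run = run, raw = raw),
            class = "run_config")
}

#' Serialize a run configuration back to YAML
#'
#' Writes the raw configuration (as loaded) so that
#' `load_run_config(write_run_config(cfg))` round-trips.
#'
#' @param rc a `run_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_run_config <- function(rc, path) {
  yaml::write_yaml(rc$raw, path)
  invisible(path)
}

#' Write a result table as tab-separated values
#'
#' @param table a data frame whose column names carry units
#' @param path output path
#' @return `path`, invisibly
#' @export
write_results <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a simulated trace as tab-separated values
#'
#' Columns: `time_ms`, `V_mV`, `Ca_uM`, one current column per channel
#' (`I_<name>_uAcm2`, outward positive) and the stimulus current.
#'
#' @param trace a `neuron_trace`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  names(df) <- c("time_ms", "V_mV", "Ca_uM",
                 paste0("I_", colnames(trace$currents), "_uAcm2"),
                 "I_stim_uAcm2")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run log
#'
#' Records what a run needs to be reproduced: a hash of the model
#' configuration, solver tolerances, seeds, and package version.
#'
#' @param path output path (JSON)
#' @param config the `neuron_config` used
#' @param seed the global seed
#' @param extra named list of additional fields
#' @return `path`, invisibly
#' @export
write_run_log <- function(path, config, seed = NA_integer_,
                          extra = list()) {
  payload <- c(list(
    config_hash = config_hash(config),
    rtol = 1e-7, atol = 1e-9, seed = seed,
    package_version = as.character(utils::packageVersion("neurogain")),
    timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Stable hash of a model configuration
#'
#' @param config a `neuron_config`
#' @return a short hexadecimal digest
#' @export
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  # rolling polynomial hash of the serialized payload; enough to
  # identify a configuration in run logs
  h <- 0
  for (b in as.integer(raw)) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
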