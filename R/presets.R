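#' Generative parameters of a simulated experimental condition
#'
#' A `ConditionPreset` bundles the generative parameters of one simulated
#' imaging condition: the probability that a cell responds to the withdrawal
#' stimulus, Poisson event rates in the initiation and maintenance phases,
#' the per-event amplitude distribution, the transient kernel time constants
#' and the measurement-noise level. Named presets encode the experimental
#' conditions the simulator emulates, calibrated to the reported responder
#' fractions (e.g. ~50 % for withdrawal of all essential amino acids, ~42 %
#' for arginine alone, ~27 % for essential amino acids without arginine, 0 %
#' for mock withdrawal).
#'
#' @param name Either the name of a built-in preset (see [listPresets()]) or
#'   a free label when the remaining parameters are given explicitly.
#' @param responder_prob Probability in \[0,1\] that a cell is a responder.
#' @param init_event_rate Event rate (events/s) during the initiation phase,
#'   the first 240 s after stimulus.
#' @param maint_event_rate Event rate (events/s) during the maintenance phase
#'   (from stimulus + 240 s to the end of the recording), before scaling.
#' @param maint_multiplier Unitless >= 0 factor on the maintenance-phase
#'   event rate; 0 models a full block of transient maintenance.
#' @param amp_log_mean,amp_log_sd Log-normal meanlog/sdlog of the per-event
#'   peak amplitude in dF/F units.
#' @param tau_rise_s,tau_decay_s Rise and decay time constants (s) of the
#'   difference-of-exponentials transient kernel; must satisfy
#'   `tau_rise_s < tau_decay_s`.
#' @param noise_sd Gaussian measurement-noise SD as a fraction of each
#'   cell's baseline fluorescence.
#' @param bleach_rate Per-second exponential photobleaching constant >= 0.
#'
#' @return A list of class `ConditionPreset`.
#' @export
#' @examples
#' conditionPreset("mock")
#' conditionPreset("eaa-withdrawal")
conditionPreset <- function(name = "custom",
                            responder_prob = 0.5,
                            init_event_rate = 0.025,
                            maint_event_rate = 0.015,
                            maint_multiplier = 1,
                            amp_log_mean = log(3),
                            amp_log_sd = 0.25,
                            tau_rise_s = 4,
                            tau_decay_s = 30,
                            noise_sd = 0.05,
                            bleach_rate = 0) {
  if (length(name) == 1L && missing(responder_prob) && name %in% names(.presets)) {
    args <- .presets[[name]]
    return(do.call(conditionPreset, c(list(name = name), args)))
  }
  p <- list(name = name, responder_prob = responder_prob,
            init_event_rate = init_event_rate,
            maint_event_rate = maint_event_rate,
            maint_multiplier = maint_multiplier,
            amp_log_mean = amp_log_mean, amp_log_sd = amp_log_sd,
            tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
            noise_sd = noise_sd, bleach_rate = bleach_rate)
  for (fld in c("responder_prob", "init_event_rate", "maint_event_rate",
                "maint_multiplier", "amp_log_sd", "tau_rise_s",
                "tau_decay_s", "noise_sd", "bleach_rate")) {
    v <- p[[fld]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("invalid preset parameter '%s': must be a single finite number >= 0", fld))
    }
  }
  if (p$responder_prob > 1) {
    stop("invalid preset parameter 'responder_prob': must lie in [0, 1]")
  }
  if (p$tau_rise_s >= p$tau_decay_s) {
    stop("invalid preset parameters 'tau_rise_s'/'tau_decay_s': rise must be faster than decay")
  }
  structure(p, class = "ConditionPreset")
}

# responder probabilities follow the reported fractions per condition;
# maintenance presets use responder_prob = 1 because phase AUC is quantified
# on responding cells.
.presets <- list(
  "mock"                 = list(responder_prob = 0),
  "eaa-withdrawal"       = list(responder_prob = 0.5),
  "arginine-withdrawal"  = list(responder_prob = 0.42),
  "eaa-minus-arginine"   = list(responder_prob = 0.27),
  "maintenance-control"  = list(responder_prob = 1, maint_multiplier = 1),
  "maintenance-block"    = list(responder_prob = 1, maint_multiplier = 0)
)

#' @describeIn conditionPreset Names of the built-in presets.
#' @export
listPresets <- function() names(.presets)

#' @export
print.ConditionPreset <- function(x, ...) {
  cat(sprintf("ConditionPreset '%s'\n", x$name))
  flds <- setdiff(names(x), "name")
  cat(paste0("  ", flds, " = ", vapply(x[flds], format, ""), collapse = "\n"), "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles a [conditionPreset()] with the recording geometry: number of cells
#' and preparations, frame interval (4 s by default, the acquisition interval
#' of the imaging protocol), recording duration (600 s), stimulus time (60 s)
#' and the log-normal baseline-fluorescence distribution. A seed is
#' mandatory: unseeded simulation is an error, so every simulated dataset is
#' reproducible.
#'
#' @param n_cells Number of cells (>= 1).
#' @param preset A `ConditionPreset` or the name of a built-in preset.
#' @param seed Integer RNG seed (required).
#' @param n_preps Number of preparations cells are assigned to (round-robin).
#' @param frame_interval_s Frame spacing in seconds.
#' @param duration_s Recording duration in seconds; frames run 0..duration.
#' @param stim_time_s Stimulus (withdrawal) time in seconds.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-cell baseline fluorescence (arbitrary units).
#' @param hemisegment_probs Optional named probability vector over the 12
#'   hemisegment labels ([hemisegmentLevels()]); default uniform.
#'
#' @return A list of class `SimConfig`.
#' @export
#' @examples
#' cfg <- simConfig(n_cells = 10, preset = "mock", seed = 1)
simConfig <- function(n_cells, preset, seed, n_preps = 5,
                      frame_interval_s = 4, duration_s = 600,
                      stim_time_s = 60,
                      baseline_log_mean = log(100), baseline_log_sd = 0.2,
                      hemisegment_probs = NULL) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("a numeric 'seed' is required: unseeded simulation is not allowed")
  }
  if (is.character(preset)) preset <- conditionPreset(preset)
  if (!inherits(preset, "ConditionPreset")) {
    stop("'preset' must be a ConditionPreset or the name of one")
  }
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (frame_interval_s <= 0) stop("'frame_interval_s' must be > 0")
  if (stim_time_s >= duration_s) stop("'stim_time_s' must precede 'duration_s'")
  if (!is.null(hemisegment_probs)) {
    if (!setequal(names(hemisegment_probs), hemisegmentLevels())) {
      stop("'hemisegment_probs' must be named by the 12 hemisegment labels")
    }
    hemisegment_probs <- hemisegment_probs[hemisegmentLevels()]
  }
  structure(list(n_cells = as.integer(n_cells), preset = preset,
                 seed = as.integer(seed), n_preps = as.integer(n_preps),
                 frame_interval_s = frame_interval_s, duration_s = duration_s,
                 stim_time_s = stim_time_s,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 hemisegment_probs = hemisegment_probs),
            class = "SimConfig")
}
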