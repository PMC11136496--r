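## FRAP trace simulator. Inverts the analysis model: normalized post-bleach
## signal m + (1 - m) A (1 - exp(-t tau)) with floor m at the bleach frame,
## mapped back to raw ROI/background counts so the full normalization chain
## is exercised. The five-phase acquisition design gives, at the default
## settings, 30 pre-bleach samples (30 s at 1 Hz), 180 fast samples (3 min at
## 1 Hz, bleach frame included) and 21 slow samples (7 min at one frame per
## 20 s).

#' Configuration for the FRAP simulator
#'
#' @param A_true mobile fraction(s) in [0, 1]; recycled over traces.
#' @param tau_true recovery rate(s), 1/s, > 0.
#' @param noise_sd Gaussian noise SD as a fraction of the pre-bleach level.
#' @param n_traces number of traces.
#' @param bleach_floor normalized intensity right after the bleach. The
#'   default 0 (complete bleach) makes the post-bleach signal exactly
#'   `A_true * (1 - exp(-t tau))` on the normalized scale, so the fit
#'   recovers the generating parameters exactly on noise-free traces.
#' @param phases list of `c(duration, interval)` (seconds) for `prebleach`,
#'   `fast` and `slow`.
#' @param background,prebleach_intensity raw background level and pre-bleach
#'   ROI amplitude above background (arbitrary counts).
#' @param junction_type,condition labels stamped on every trace.
#' @param seed RNG seed.
#' @return List of class `frap_sim_config`.
#' @export
frap_sim_config <- function(A_true = 0.5, tau_true = 0.01, noise_sd = 0.05,
                            n_traces = 1L, bleach_floor = 0,
                            phases = list(prebleach = c(duration = 30, interval = 1),
                                          fast = c(duration = 180, interval = 1),
                                          slow = c(duration = 420, interval = 20)),
                            background = 50, prebleach_intensity = 1000,
                            junction_type = "EC-EC", condition = "control",
                            seed = 1L) {
  if (any(A_true < 0 | A_true > 1)) {
    eht_stop("eht_config_error", "A_true must lie in [0, 1]")
  }
  if (any(tau_true <= 0)) eht_stop("eht_config_error", "tau_true must be > 0")
  stopifnot_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  stopifnot_fraction(bleach_floor, "bleach_floor")
  for (p in c("prebleach", "fast", "slow")) {
    if (any(phases[[p]] <= 0)) {
      eht_stop("eht_config_error", sprintf("%s durations/intervals must be > 0", p))
    }
  }
  cfg <- as.list(environment())
  class(cfg) <- "frap_sim_config"
  cfg
}

#' Simulate a FRAP dataset with known ground truth
#'
#' @param cfg a [frap_sim_config()].
#' @return List: `traces` (list of [frap_trace()]), `truth` data.frame
#'   (trace, A_true, tau_true, bleach_floor).
#' @export
make_frap_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "frap_sim_config"))
  with_seed(cfg$seed, {
    ph <- cfg$phases
    n_pre <- floor(ph$prebleach["duration"] / ph$prebleach["interval"])
    t_pre <- -rev(seq_len(n_pre)) * ph$prebleach["interval"]
    n_fast <- floor(ph$fast["duration"] / ph$fast["interval"])
    t_fast <- (seq_len(n_fast) - 1) * ph$fast["interval"]  # bleach frame at t = 0
    n_slow <- floor(ph$slow["duration"] / ph$slow["interval"])
    t_slow <- max(t_fast) + seq_len(n_slow) * ph$slow["interval"]
    A <- rep_len(cfg$A_true, cfg$n_traces)
    tau <- rep_len(cfg$tau_true, cfg$n_traces)
    traces <- vector("list", cfg$n_traces)
    for (i in seq_len(cfg$n_traces)) {
      t_post <- c(t_fast, t_slow)
      m <- cfg$bleach_floor
      norm_true <- c(rep(1, n_pre), m + (1 - m) * A[i] * (1 - exp(-t_post * tau[i])))
      roi <- cfg$background + cfg$prebleach_intensity * norm_true
      if (cfg$noise_sd > 0) {
        roi <- roi + stats::rnorm(length(roi), 0,
                                  cfg$noise_sd * cfg$prebleach_intensity)
      }
      traces[[i]] <- frap_trace(
        times = c(t_pre, t_post), roi = roi,
        background = rep(cfg$background, length(roi)),
        phase = c(rep("prebleach", n_pre), rep("fast", n_fast),
                  rep("slow", n_slow)),
        junction_type = cfg$junction_type, condition = cfg$condition)
    }
    list(traces = traces,
         truth = data.frame(trace = seq_len(cfg$n_traces), A_true = A,
                            tau_true = tau, bleach_floor = cfg$bleach_floor,
                            junction_type = cfg$junction_type,
                            condition = cfg$condition))
  })
}
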