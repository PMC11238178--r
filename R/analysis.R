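#' Virtual local field potential of a neuron class
#'
#' The model surrogate for the LFP: the pointwise mean of the synaptic
#' currents `s(t)` over all neurons of a class (or LN subclass), as recorded
#' by [run_simulation()] with `record_lfp = TRUE`.
#'
#' @param rec a `sim_recording`.
#' @param cls class or LN subclass name.
#' @return an object of class `lfp_trace`: list with `lfp` (numeric
#'   series), `fs` (sampling rate, Hz), and `group`.
#' @export
virtual_lfp <- function(rec, cls) {
  if (is.null(rec$lfp)) stop("recording has no LFP data (record_lfp = FALSE)",
                             call. = FALSE)
  if (!cls %in% colnames(rec$lfp)) {
    stop("class ", cls, " was not recorded; available: ",
         paste(colnames(rec$lfp), collapse = ", "), call. = FALSE)
  }
  out <- list(lfp = unname(rec$lfp[, cls]), fs = 1 / rec$dt, group = cls)
  class(out) <- "lfp_trace"
  out
}

#' Welch power spectrum of an LFP trace
#'
#' Mean-removed Welch estimate with Hann-windowed segments (default 1 s)
#' and 50% overlap. The peak frequency and power are taken over the
#' analysis band (default 5-100 Hz).
#'
#' @param lfp an `lfp_trace`, or a numeric vector (then give `fs`).
#' @param fs sampling rate in Hz (taken from the trace if omitted).
#' @param seg_sec segment length in seconds (default 1).
#' @param overlap fractional segment overlap (default 0.5).
#' @param band analysis band in Hz (default `c(5, 100)`).
#' @return an object of class `power_spectrum`: list with `freqs`, `power`,
#'   `peak_freq`, `peak_power`.
#' @export
power_spectrum <- function(lfp, fs = NULL, seg_sec = 1, overlap = 0.5,
                           band = c(5, 100)) {
  if (inherits(lfp, "lfp_trace")) {
    fs <- lfp$fs
    x <- lfp$lfp
  } else {
    x <- as.numeric(lfp)
  }
  stopifnot(!is.null(fs), fs > 0)
  nseg <- round(seg_sec * fs)
  if (length(x) < nseg) {
    stop("series (", length(x), " samples) shorter than one segment (",
         nseg, " samples)", call. = FALSE)
  }
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1)) # Hann
  wnorm <- sum(win^2)
  acc <- numeric(nseg)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  acc <- acc / (length(starts) * wnorm * fs)
  n_half <- floor(nseg / 2)
  freqs <- (seq_len(n_half) - 1) * fs / nseg
  power <- acc[seq_len(n_half)]
  power[-1] <- 2 * power[-1] # fold negative frequencies
  in_band <- freqs >= band[1] & freqs <= band[2]
  pk <- which.max(ifelse(in_band, power, -Inf))
  out <- list(freqs = freqs, power = power,
              peak_freq = freqs[pk], peak_power = power[pk], band = band)
  class(out) <- "power_spectrum"
  out
}

#' Windowed firing-frequency time course
#'
#' Counts spikes in tumbling windows (default 50 ms) and converts to Hz.
#' Several trials can be averaged by passing a list of spike-time vectors.
#'
#' @param spike_times numeric vector of spike times (seconds), or a list of
#'   such vectors (one per trial, aligned to the same reference).
#' @param window window length in seconds (default 0.05).
#' @param t_range analysis interval `c(t0, t1)` in seconds.
#' @return a `data.frame` with `t` (window start, s) and `rate` (Hz;
#'   trial-averaged when a list was given).
#' @export
firing_frequency <- function(spike_times, window = 0.05, t_range) {
  stopifnot(window > 0, length(t_range) == 2, t_range[2] > t_range[1])
  edges <- seq(t_range[1], t_range[2], by = window)
  if (utils::tail(edges, 1) < t_range[2]) edges <- c(edges, t_range[2])
  one <- function(st) {
    st <- st[st >= t_range[1] & st < utils::tail(edges, 1)]
    counts <- graphics::hist(st, breaks = edges, plot = FALSE)$counts
    counts / diff(edges)
  }
  rates <- if (is.list(spike_times)) {
    Reduce(`+`, lapply(spike_times, one)) / length(spike_times)
  } else {
    one(spike_times)
  }
  data.frame(t = utils::head(edges, -1), rate = rates)
}

#' Spike counts of one neuron within scheduled odor windows
#'
#' @param rec a `sim_recording`.
#' @param id neuron id.
#' @param windows `data.frame` with `odorant`, `onset`, `duration` (s).
#' @return named integer vector of spike counts, one per window row.
#' @export
window_spike_counts <- function(rec, id, windows) {
  st <- rec$spikes$t_ms[rec$spikes$id == id] / 1000
  counts <- vapply(seq_len(nrow(windows)), function(r) {
    sum(st >= windows$onset[r] & st < windows$onset[r] + windows$duration[r])
  }, integer(1))
  names(counts) <- windows$odorant
  counts
}

#' Trial success criterion for associative learning
#'
#' A trial succeeds when the readout neuron responds solely to the learned
#' odor: its spike count reaches `threshold` in the learned odor's window
#' and stays below `threshold` in every other window. No response anywhere
#' is a failure.
#'
#' @param counts named spike counts, one per odor window.
#' @param learned name of the learned odorant.
#' @param threshold minimum spike count constituting a response (default 1).
#' @return logical.
#' @export
is_trial_success <- function(counts, learned, threshold = 1) {
  stopifnot(learned %in% names(counts))
  all(counts[names(counts) == learned] >= threshold) &&
    all(counts[names(counts) != learned] < threshold)
}

#' Run the associative-learning experiment
#'
#' One experiment set: after the homeostatic warmup (kind-1 stimulation),
#' the target odorant is presented once and a reward is delivered
#' `reward_delay` seconds after odor onset, depressing the MBON-alpha1
#' synapses of the KCs that fired within the eligibility window. Then
#' `n_trials` test trials follow; in each, all six odorants are applied
#' sequentially (1 s every 5 s) in a fresh random order, and the trial
#' succeeds if SMP354 spikes only in the learned odor's window. Several
#' sets rerun the whole procedure (fresh naive weights) with different
#' random input.
#'
#' @param net network topology (list `neurons`, `W`).
#' @param or_table an [or_response_table()].
#' @param learned learned odorant name.
#' @param odorants odor panel (default [odor_panel()]); must contain
#'   `learned`.
#' @param n_sets number of experiment sets (default 1).
#' @param n_trials trials per set (default 10).
#' @param warmup homeostatic warmup duration in seconds (default 300).
#' @param reward_delay reward latency after target odor onset (default 4 s,
#'   i.e. 3 s after the 1-s odor ends).
#' @param ltd logical: deliver the reward (TRUE) or run the unrewarded
#'   control (FALSE).
#' @param params,scaling,seed,... forwarded to [run_simulation()].
#' @return an object of class `learning_outcome`: list with `learned`,
#'   `trials` (`data.frame`: set, trial, success), `counts` (list of
#'   per-trial named count vectors), `success_rate`, and `W_final` of the
#'   last set.
#' @export
run_learning_experiment <- function(net, or_table, learned,
                                    odorants = odor_panel(),
                                    n_sets = 1, n_trials = 10,
                                    warmup = 300, reward_delay = 4,
                                    ltd = TRUE,
                                    params = default_neuron_params(),
                                    scaling = scaling_table(),
                                    seed = NULL, ...) {
  stopifnot(learned %in% odorants, length(odorants) == 6)
  if (!is.null(seed)) set.seed(seed)
  trials <- list(); counts_all <- list(); W_last <- NULL
  for (set_i in seq_len(n_sets)) {
    sched <- learning_schedule(learned, odorants, warmup, n_trials)
    rec <- run_simulation(net, sched$schedule, or_table,
                          params = params, scaling = scaling,
                          reward_times = if (ltd) warmup + reward_delay else numeric(0),
                          record_lfp = FALSE, ...)
    W_last <- rec$W_final
    for (tr in seq_len(n_trials)) {
      win <- sched$trial_windows[[tr]]
      cnt <- window_spike_counts(rec, "SMP354", win)
      counts_all[[length(counts_all) + 1L]] <- cnt
      trials[[length(trials) + 1L]] <- data.frame(
        set = set_i, trial = tr,
        success = is_trial_success(cnt, learned))
    }
  }
  trials <- if (length(trials)) do.call(rbind, trials) else
    data.frame(set = integer(0), trial = integer(0), success = logical(0))
  out <- list(learned = learned, trials = trials, counts = counts_all,
              success_rate = if (nrow(trials)) mean(trials$success) else NaN,
              W_final = W_last)
  class(out) <- "learning_outcome"
  out
}

# Schedule: warmup (kind-1 cycling), one target presentation, then
# n_trials blocks of all six odors in random order (1 s every 5 s).
learning_schedule <- function(learned, odorants, warmup, n_trials) {
  base <- build_protocol(1, odorants, warmup = warmup, n_cycles = 0)
  warm <- base[base$phase == "warmup", , drop = FALSE]
  target <- data.frame(odorant = learned, onset = warmup, duration = 1,
                       phase = "main", stringsAsFactors = FALSE)
  trial_windows <- vector("list", n_trials)
  rows <- list(target)
  t0 <- warmup + 5 # trials start after the rewarded presentation
  for (tr in seq_len(n_trials)) {
    order_tr <- sample(odorants)
    win <- data.frame(odorant = order_tr,
                      onset = t0 + 5 * (seq_along(order_tr) - 1),
                      duration = 1, phase = "main",
                      stringsAsFactors = FALSE)
    trial_windows[[tr]] <- win
    rows[[length(rows) + 1L]] <- win
    t0 <- t0 + 5 * length(odorants)
  }
  schedule <- rbind(warm, do.call(rbind, rows))
  attr(schedule, "horizon") <- t0
  list(schedule = schedule, trial_windows = trial_windows)
}

#' @export
print.learning_outcome <- function(x, ...) {
  cat("<learning_outcome> learned odor: ", x$learned, "\n", sep = "")
  cat("  ", nrow(x$trials), " trials, success rate ",
      sprintf("%.1f%%", 100 * x$success_rate), "\n", sep = "")
  invisible(x)
}

#' Peak oscillation power per neuron class over repeated odor presentations
#'
#' Runs one continuous simulation in which the odorant is presented
#' `n_repeats` times for 10 s every 20 s (after the warmup), computes the
#' virtual-LFP Welch spectrum of each requested group inside every odor
#' window, and averages the peak power per group over presentations. With
#' `no_odor = TRUE` the windows are quiet periods instead, giving the
#' odor-free control.
#'
#' @param net,or_table,params,scaling,seed,... as in [run_simulation()].
#' @param odorant odorant to present.
#' @param n_repeats number of 10-s presentations (default 5).
#' @param groups classes / LN subclasses to analyze (default PN, LN, KC and
#'   the four LN subclasses).
#' @param inactivate class or subclass names to inactivate.
#' @param warmup warmup duration in seconds (default 300).
#' @param no_odor logical: analyze odor-free windows instead.
#' @param band spectral analysis band in Hz (default `c(5, 100)`); use the
#'   oscillation band (e.g. `c(20, 30)`) to quantify attenuation of the
#'   odor-evoked rhythm specifically.
#' @return `data.frame` with `group`, `peak_power` (mean over windows),
#'   `sd`, `peak_freq` (mean).
#' @export
peak_power_experiment <- function(net, or_table, odorant, n_repeats = 5,
                                  groups = c("PN", "LN", "KC", ln_subclasses()),
                                  inactivate = character(0), warmup = 300,
                                  no_odor = FALSE, band = c(5, 100),
                                  params = default_neuron_params(),
                                  scaling = scaling_table(),
                                  seed = NULL, ...) {
  proto <- build_protocol(2, odorant, warmup = warmup, n_cycles = n_repeats)
  if (no_odor) {
    main <- proto$phase == "main"
    proto <- proto[!main, , drop = FALSE]
    attr(proto, "horizon") <- warmup + 20 * n_repeats
  }
  rec <- run_simulation(net, proto, or_table, params = params,
                        scaling = scaling, inactivate = inactivate,
                        seed = seed, ...)
  onsets <- warmup + 20 * (seq_len(n_repeats) - 1)
  res <- lapply(groups, function(g) {
    lfp <- virtual_lfp(rec, g)
    pk <- vapply(onsets, function(t0) {
      i0 <- round(t0 / rec$dt) + 1
      i1 <- min(round((t0 + 10) / rec$dt), rec$n_steps)
      ps <- power_spectrum(lfp$lfp[i0:i1], fs = lfp$fs, band = band)
      c(ps$peak_power, ps$peak_freq)
    }, numeric(2))
    data.frame(group = g, peak_power = mean(pk[1, ]), sd = stats::sd(pk[1, ]),
               peak_freq = mean(pk[2, ]), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fraction of neurons in a class activated per odor
#'
#' For each odorant, the fraction of neurons of the class whose firing rate
#' inside that odorant's presentation windows exceeds their rate elsewhere
#' by `min_extra` Hz; the fractions are averaged over odorants. This is the
#' quantity that shrinks along the ORN to PN to KC pathway (response
#' sparsening).
#'
#' @param rec a `sim_recording`.
#' @param cls neuron class.
#' @param windows `data.frame` with `odorant`, `onset`, `duration` (s).
#' @param min_extra minimum odor-minus-baseline rate difference in Hz
#'   (default 5).
#' @return mean fraction in `[0, 1]`.
#' @export
fraction_responding <- function(rec, cls, windows, min_extra = 5) {
  ids <- rec$neurons$id[rec$neurons$class == cls]
  spk <- rec$spikes[rec$spikes$class == cls, ]
  ts_by_id <- split(spk$t_ms / 1000, factor(spk$id, levels = ids))
  t_all <- sum(windows$duration)
  per_odor <- vapply(unique(windows$odorant), function(o) {
    win <- windows[windows$odorant == o, , drop = FALSE]
    t_in <- sum(win$duration)
    t_out <- rec$horizon - t_all
    mean(vapply(ts_by_id, function(ts) {
      inw <- rep(FALSE, length(ts))
      for (r in seq_len(nrow(win))) {
        inw <- inw | (ts >= win$onset[r] & ts < win$onset[r] + win$duration[r])
      }
      any_w <- rep(FALSE, length(ts))
      for (r in seq_len(nrow(windows))) {
        any_w <- any_w |
          (ts >= windows$onset[r] & ts < windows$onset[r] + windows$duration[r])
      }
      rate_in <- sum(inw) / t_in
      rate_out <- sum(!any_w) / t_out
      (rate_in - rate_out) >= min_extra
    }, logical(1)))
  }, numeric(1))
  mean(per_odor)
}
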