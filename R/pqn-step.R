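#' Create a zero-initialized neuron population state
#'
#' All dynamical variables start at zero. Which fields are present depends on
#' the model variant: single-compartment neurons carry `v`, `n`, `q`;
#' two-compartment neurons carry `v`, `n`, `v_s`; the homeostatic PN variant
#' additionally carries the gain `u`, the measured firing frequency `F` (Hz)
#' and the spike counter of the running one-second window.
#'
#' @param n_neurons number of neurons in the population.
#' @param variant `"single"`, `"two_comp"`, or `"pn"`.
#' @param u0 initial homeostatic gain for the `"pn"` variant (default 0, in
#'   `[0, 1]`).
#' @return an object of class `pqn_state`.
#' @export
pqn_state <- function(n_neurons, variant = c("single", "two_comp", "pn"), u0 = 0) {
  variant <- match.arg(variant)
  z <- numeric(n_neurons)
  st <- list(v = z, n = z, variant = variant,
             spiked = logical(n_neurons))
  if (variant == "single") {
    st$q <- z
  } else {
    st$v_s <- z
  }
  if (variant == "pn") {
    stopifnot(u0 >= 0, u0 <= 1)
    st$u <- rep(u0, n_neurons)
    st$F <- z
    st$spike_count_window <- integer(n_neurons)
  }
  class(st) <- "pqn_state"
  st
}

check_finite_state <- function(v, t = NULL) {
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop("numeric overflow in PQN state for neuron index ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (!is.null(t)) paste0(" at t=", t, " s"),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Spike detection by threshold crossing
#'
#' A spike is registered when the membrane potential crosses zero from below:
#' the old value is negative and the new value is zero or greater.
#'
#' @param v_old,v_new membrane potential before and after one update
#'   (vectorized).
#' @return logical vector.
#' @export
detect_spike <- function(v_old, v_new) {
  v_old < 0 & v_new >= 0
}

#' One explicit-Euler step of the single-compartment PQN model
#'
#' Advances membrane potential `v`, recovery variable `n`, and slow variable
#' `q` by one time step. All right-hand sides are evaluated at the pre-step
#' state (synchronous update), so results do not depend on neuron ordering.
#'
#' @param state a `pqn_state` with variant `"single"`.
#' @param p a `pqn_params` with variant `"single"`.
#' @param I stimulus current (scalar or per-neuron vector).
#' @param dt time step in seconds.
#' @param Q optional quantizer function applied at arithmetic stage
#'   boundaries (fixed-point backend); `NULL` for double precision.
#' @return the updated state; `state$spiked` flags threshold crossings.
#' @export
step_single <- function(state, p, I, dt, Q = NULL) {
  stopifnot(state$variant == "single", p$variant == "single", dt >= 0)
  v <- state$v; n <- state$n; q <- state$q
  m <- transform_input(I, p)
  if (is.null(Q)) {
    v_new <- v + dt * (p$phi / p$tau) * (pqn_f(v, p) - n - q + p$I_b0 + m)
    n_new <- n + dt * (1 / p$tau) * (pqn_g(v, p) - n)
    q_new <- q + dt * (p$epsilon / p$tau) * (pqn_h(v, p) - q)
  } else {
    m <- Q(m)
    v_new <- Q(v + Q(Q(dt * p$phi / p$tau) * Q(Q(pqn_f_q(v, p, Q)) - n - q + p$I_b0 + m)))
    n_new <- Q(n + Q(Q(dt / p$tau) * Q(Q(pqn_g_q(v, p, Q)) - n)))
    q_new <- Q(q + Q(Q(dt * p$epsilon / p$tau) * Q(Q(pqn_h_q(v, p, Q)) - q)))
  }
  check_finite_state(v_new)
  state$spiked <- detect_spike(v, v_new)
  state$v <- v_new; state$n <- n_new; state$q <- q_new
  state
}

#' One explicit-Euler step of the two-compartment PQN model
#'
#' The axonal compartment (`v`, `n`) generates spikes; the somatic
#' compartment `v_s` is a linear leaky integrator coupled to the axon by the
#' internal current \eqn{I_c = k_0 (v - v_s)}. Synaptic input enters the
#' axonal compartment through `I`; current injected directly into the soma
#' enters through `I_r`.
#'
#' @inheritParams step_single
#' @param I_r current injected into the somatic compartment.
#' @export
step_two_comp <- function(state, p, I, dt, I_r = 0, Q = NULL) {
  stopifnot(state$variant %in% c("two_comp", "pn"),
            p$variant %in% c("two_comp", "pn"), dt >= 0)
  drive <- transform_input(I, p)
  if (state$variant == "pn") drive <- state$u * drive
  step_two_comp_core(state, p, drive, dt, I_r, Q)
}

step_two_comp_core <- function(state, p, drive, dt, I_r, Q = NULL) {
  v <- state$v; n <- state$n; v_s <- state$v_s
  if (is.null(Q)) {
    I_c <- p$k_0 * (v - v_s)
    v_new <- v + dt * (p$phi / p$tau) * (pqn_f(v, p) - n + p$I_b0 + drive - I_c)
    n_new <- n + dt * (1 / p$tau) * (pqn_g(v, p) - n)
    vs_new <- v_s + dt * (p$theta / p$tau) *
      (-p$alpha_leak * v_s + p$I_b1 + I_c + p$k_r * I_r)
  } else {
    drive <- Q(drive)
    I_c <- Q(p$k_0 * Q(v - v_s))
    v_new <- Q(v + Q(Q(dt * p$phi / p$tau) * Q(Q(pqn_f_q(v, p, Q)) - n + p$I_b0 + drive - I_c)))
    n_new <- Q(n + Q(Q(dt / p$tau) * Q(Q(pqn_g_q(v, p, Q)) - n)))
    vs_new <- Q(v_s + Q(Q(dt * p$theta / p$tau) *
      Q(Q(-p$alpha_leak * v_s) + p$I_b1 + I_c + Q(p$k_r * I_r))))
  }
  check_finite_state(v_new)
  state$spiked <- detect_spike(v, v_new)
  state$v <- v_new; state$n <- n_new; state$v_s <- vs_new
  state
}

#' One step of the homeostatic projection-neuron variant
#'
#' Identical to [step_two_comp()] except that the transformed synaptic drive
#' is gated by the homeostatic gain `u` (the term is `u * m(I)`). `u` itself
#' is only changed by [update_homeostasis()], once per simulated second.
#' Spikes increment the one-second window counter.
#'
#' @inheritParams step_two_comp
#' @export
step_pn <- function(state, p, I, dt, I_r = 0, Q = NULL) {
  stopifnot(state$variant == "pn", p$variant == "pn", dt >= 0)
  drive <- state$u * transform_input(I, p)
  state <- step_two_comp_core(state, p, drive, dt, I_r, Q)
  state$spike_count_window <- state$spike_count_window + as.integer(state$spiked)
  state
}

#' Once-per-second homeostatic gain update
#'
#' Sets the measured firing frequency `F` to the spike count of the completed
#' one-second window, moves the gain `u` by `(kappa / tau) * (F_t - F)` (Euler
#' over one second), clamps `u` to `[0, 1]`, and resets the window counter.
#' Call exactly once per simulated second, after the second completes.
#'
#' @param state a `pqn_state` with variant `"pn"`.
#' @param p matching `pqn_params`.
#' @export
update_homeostasis <- function(state, p) {
  stopifnot(state$variant == "pn", p$variant == "pn")
  state$F <- as.numeric(state$spike_count_window)
  u <- state$u + (p$kappa / p$tau) * (p$F_t - state$F)
  state$u <- pmin(pmax(u, 0), 1)
  state$spike_count_window <- integer(length(state$v))
  state
}

#' Simulate a single neuron's response to a current time series
#'
#' Deterministic explicit-Euler integration of one PQN neuron from the
#' all-zero initial state. For two-compartment variants the input series is
#' routed to the somatic injection `I_r`, matching current-clamp protocols in
#' which the electrode sits in the soma; set `route = "axon"` to drive the
#' synaptic input `I` instead. The PN variant keeps `u` fixed at `u0`
#' (homeostasis operates on the slow time scale of network runs).
#'
#' @param p a `pqn_params` object.
#' @param I_series numeric vector of input current, one entry per step.
#' @param dt time step in seconds (default 1 ms).
#' @param route `"soma"` (default, two-compartment variants only) or `"axon"`.
#' @param u0 homeostatic gain held fixed for the PN variant (default 1).
#' @param fmt optional [fxp_format()] for the fixed-point backend.
#' @return a data.frame with columns `t_ms`, `v`, `spike`, plus `v_s` for
#'   two-compartment variants.
#' @export
simulate_trace <- function(p, I_series, dt = 1e-3, route = c("soma", "axon"),
                           u0 = 1, fmt = NULL) {
  route <- match.arg(route)
  stopifnot(all(is.finite(I_series)))
  n_steps <- length(I_series)
  Q <- if (is.null(fmt)) NULL else fxp_quantizer(fmt)
  if (!is.null(Q)) p <- quantize_params(p, fmt)
  st <- pqn_state(1L, p$variant, u0 = if (p$variant == "pn") u0 else 0)
  two <- p$variant %in% c("two_comp", "pn")
  v <- numeric(n_steps); vs <- if (two) numeric(n_steps) else NULL
  spike <- logical(n_steps)
  for (k in seq_len(n_steps)) {
    Ik <- I_series[k]
    if (p$variant == "single") {
      st <- step_single(st, p, Ik, dt, Q)
    } else {
      I_ax <- if (route == "axon") Ik else 0
      I_som <- if (route == "soma") Ik else 0
      if (p$variant == "pn") {
        st <- step_pn(st, p, I_ax, dt, I_r = I_som, Q = Q)
      } else {
        st <- step_two_comp(st, p, I_ax, dt, I_r = I_som, Q = Q)
      }
    }
    v[k] <- st$v; spike[k] <- st$spiked
    if (two) vs[k] <- st$v_s
  }
  out <- data.frame(t_ms = seq_len(n_steps) * dt * 1000, v = v, spike = spike)
  if (two) out$v_s <- vs
  out
}

#' Count spikes in a stored voltage trace
#'
#' Post-hoc scan for negative-to-nonnegative crossings; the reference oracle
#' for spike counts produced during stepping.
#'
#' @param v numeric voltage trace.
#' @param v_init value preceding the first sample (default 0).
#' @return integer spike count.
#' @export
count_spikes_in_trace <- function(v, v_init = 0) {
  prev <- c(v_init, v[-length(v)])
  sum(detect_spike(prev, v))
}
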