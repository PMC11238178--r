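#' Create a bank of kinetic synapse state variables
#'
#' Each presynaptic neuron owns one synaptic activation `s` in `[0, 1]`.
#' Chemical synapses of modeled neurons rise toward 1 while the presynaptic
#' membrane potential is suprathreshold and decay exponentially otherwise;
#' ORN synapses (spike-driven input terminals) jump to 1 on a spike and decay
#' between spikes. With the default rates and a 1 ms step the decay time
#' constant is `1/beta` s, about 5 ms, matching measured cholinergic and
#' GABAergic synaptic decay.
#'
#' @param n number of presynaptic neurons.
#' @param alpha rise rate (1/s, default 250).
#' @param beta decay rate (1/s, default 203.125).
#' @param is_orn logical; spike-driven (ORN) semantics instead of
#'   voltage-driven.
#' @return an object of class `synapse_bank`.
#' @export
synapse_bank <- function(n, alpha = 250, beta = 203.125, is_orn = FALSE) {
  stopifnot(n >= 0, alpha >= 0, beta >= 0)
  b <- list(s = numeric(n), alpha = alpha, beta = beta, is_orn = is_orn)
  class(b) <- "synapse_bank"
  b
}

#' Advance chemical synapses one Euler step
#'
#' `s` rises by `dt * alpha * (1 - s)` where the presynaptic potential is
#' `>= 0`, and decays by `dt * beta * s` elsewhere. `s` remains in `[0, 1]`
#' whenever `alpha * dt <= 1` and `beta * dt <= 1`.
#'
#' @param bank a [synapse_bank()] with `is_orn = FALSE`.
#' @param v_pre presynaptic membrane potentials, one per synapse slot.
#' @param dt time step (seconds).
#' @param Q optional fixed-point quantizer.
#' @export
step_chemical_synapse <- function(bank, v_pre, dt, Q = NULL) {
  stopifnot(!bank$is_orn, length(v_pre) == length(bank$s))
  on <- v_pre >= 0
  if (is.null(Q)) {
    bank$s <- ifelse(on,
                     bank$s + dt * bank$alpha * (1 - bank$s),
                     bank$s - dt * bank$beta * bank$s)
  } else {
    up <- Q(bank$s + Q(Q(dt * bank$alpha) * Q(1 - bank$s)))
    down <- Q(bank$s - Q(Q(dt * bank$beta) * bank$s))
    bank$s <- ifelse(on, up, down)
  }
  bank
}

#' Advance spike-driven (ORN) synapses one Euler step
#'
#' `s` is set to 1 for terminals whose ORN spiked this step; all others decay
#' by `dt * beta * s`.
#'
#' @param bank a [synapse_bank()] with `is_orn = TRUE`.
#' @param spike logical vector, one per terminal.
#' @inheritParams step_chemical_synapse
#' @export
step_orn_synapse <- function(bank, spike, dt, Q = NULL) {
  stopifnot(bank$is_orn, length(spike) == length(bank$s))
  if (is.null(Q)) {
    decayed <- bank$s - dt * bank$beta * bank$s
  } else {
    decayed <- Q(bank$s - Q(Q(dt * bank$beta) * bank$s))
  }
  bank$s <- ifelse(spike, 1, decayed)
  bank
}

#' Class-pair synaptic scaling table
#'
#' The synaptic input of a postsynaptic neuron is the weighted sum of
#' presynaptic activations, scaled by one constant per (presynaptic class,
#' postsynaptic class) pair. The sign of each constant encodes the polarity
#' of the presynaptic class: ORN, PN, KC, and MBON_a3 are excitatory
#' (positive); LN, APL, and MBON_a1 are inhibitory (negative). The four LN
#' subclasses share a single value per postsynaptic class.
#'
#' @param values named numeric vector; names are `"PRE>POST"` class pairs,
#'   e.g. `"PN>KC"`. Defaults to the package's tuned table (see the methods
#'   vignette); the PN-to-KC value 1.03125 is the reference operating point.
#' @return an object of class `scaling_table` (named numeric vector).
#' @export
scaling_table <- function(values = NULL) {
  if (is.null(values)) values <- default_scaling_values()
  stopifnot(is.numeric(values), !is.null(names(values)))
  validate_scaling_signs(values)
  class(values) <- "scaling_table"
  values
}

excitatory_classes <- function() c("ORN", "PN", "KC", "MBON_a3")
inhibitory_classes <- function() c("LN", "APL", "MBON_a1")

validate_scaling_signs <- function(values) {
  pre <- sub(">.*$", "", names(values))
  bad_pos <- pre %in% excitatory_classes() & values < 0
  bad_neg <- pre %in% inhibitory_classes() & values > 0
  if (any(bad_pos | bad_neg)) {
    stop("scaling table sign mismatch for pair(s): ",
         paste(names(values)[bad_pos | bad_neg], collapse = ", "),
         " (excitatory presynaptic classes must be positive, inhibitory negative)",
         call. = FALSE)
  }
  invisible(values)
}

#' Look up the scaling constant for a class pair
#'
#' @param tbl a [scaling_table()].
#' @param pre,post presynaptic and postsynaptic class names (vectorized).
#' @return numeric vector of scaling constants.
#' @export
scaling_value <- function(tbl, pre, post) {
  key <- paste0(pre, ">", post)
  v <- unclass(tbl)[key]
  if (anyNA(v)) {
    stop("no scaling entry for class pair(s): ",
         paste(unique(key[is.na(v)]), collapse = ", "), call. = FALSE)
  }
  unname(v)
}

#' Accumulate synaptic input currents
#'
#' Computes the input current of every postsynaptic neuron as
#' \eqn{I_i = \sum_j w_{ji} s_j p_{x(j), y(i)}}: the sparse weight matrix
#' entry times the presynaptic activation times the class-pair scaling
#' constant.
#'
#' @param W sparse weight matrix (pre x post), as built by
#'   [build_network()] or [build_from_connectome()].
#' @param s numeric vector of presynaptic activations (length `nrow(W)`).
#' @param classes character vector of neuron class names, one per neuron
#'   (row/col order of `W`).
#' @param p a [scaling_table()].
#' @return numeric vector of input currents, one per postsynaptic neuron.
#' @export
accumulate_input <- function(W, s, classes, p) {
  W_eff <- effective_weights(W, classes, p)
  as.numeric(Matrix::crossprod(W_eff, s))
}

#' Fold the class-pair scaling into the weight matrix
#'
#' Returns `W_eff[j, i] = W[j, i] * p[class(j), class(i)]` so the per-step
#' accumulation is a single sparse matrix-vector product. Errors if an edge
#' exists for a class pair missing from the table.
#'
#' @inheritParams accumulate_input
#' @return a sparse matrix of effective weights.
#' @export
effective_weights <- function(W, classes, p) {
  W <- methods::as(W, "CsparseMatrix")
  if (length(W@x) == 0) return(W)
  # column index per nonzero from the CSC column pointer
  j_col <- rep(seq_len(ncol(W)), diff(W@p))
  i_row <- W@i + 1L
  W@x <- W@x * scaling_value(p, classes[i_row], classes[j_col])
  W
}

#' Rescale class-pair constants for a reduced network
#'
#' The default [scaling_table()] is calibrated for the full-size network, in
#' which each postsynaptic class receives a characteristic number of
#' convergent inputs (e.g. about 24 ORNs per PN, 1337 ORNs per LN, 1884 KCs
#' onto APL and the MBONs). When simulating a size-reduced network the raw
#' input sums shrink with the in-degree; this helper multiplies each
#' class-pair constant by (reference in-degree) / (actual in-degree) so the
#' summed drive per postsynaptic neuron is preserved. Pairs with no
#' reference entry, and the PN-to-KC pair (whose in-degree the synthetic
#' generator holds at its target independently of size), are returned
#' unchanged.
#'
#' @param scaling a [scaling_table()].
#' @param net network (list `neurons`, `W`) whose in-degrees to match.
#' @return a rescaled [scaling_table()].
#' @export
rescale_scaling <- function(scaling, net) {
  ref <- c("ORN>PN" = 24.0, "ORN>LN" = 1337.4, "PN>LN" = 88.9,
           "LN>PN" = 140.3, "LN>LN" = 190, "PN>APL" = 121,
           "KC>APL" = 1884, "KC>MBON_a1" = 1884, "KC>MBON_a3" = 1884)
  st <- topology_stats(net$W, net$neurons)
  vals <- unclass(scaling)
  for (r in seq_len(nrow(st))) {
    key <- paste0(st$pre_class[r], ">", st$post_class[r])
    if (key %in% names(ref) && key %in% names(vals) && st$mean_in[r] > 0) {
      vals[key] <- vals[key] * ref[key] / st$mean_in[r]
    }
  }
  scaling_table(vals)
}

#' Eligibility buffer for reward-driven depression
#'
#' Tracks, per Kenyon cell, the time of its most recent spike. A KC is
#' eligible for depression when a reward arrives within `window` seconds of
#' that spike (boundary inclusive).
#'
#' @param kc_ids identifiers of the Kenyon cells.
#' @param window eligibility window in seconds (default 5).
#' @return an object of class `eligibility_buffer`.
#' @export
eligibility_buffer <- function(kc_ids, window = 5) {
  b <- list(kc_ids = kc_ids,
            last_spike_time = stats::setNames(rep(-Inf, length(kc_ids)), kc_ids),
            window = window)
  class(b) <- "eligibility_buffer"
  b
}

#' Record Kenyon-cell spikes into the eligibility buffer
#'
#' @param buf an [eligibility_buffer()].
#' @param spikes logical vector aligned with `buf$kc_ids`.
#' @param t current time (seconds); must be nondecreasing across calls.
#' @export
record_kc_spikes <- function(buf, spikes, t) {
  stopifnot(length(spikes) == length(buf$kc_ids))
  buf$last_spike_time[spikes] <- t
  buf
}

#' Apply a reward: depress eligible KC-to-MBON-alpha1 weights
#'
#' Every KC whose last spike lies in `[t_reward - window, t_reward]` has its
#' synaptic weight onto MBON-alpha1 set to 0.25 (long-term depression).
#' The assignment is absolute and idempotent -- weights take only the values
#' 1 (naive) or 0.25 (depressed), as in a two-bit hardware weight store.
#' No other entries of the weight matrix change.
#'
#' @param W sparse weight matrix (pre x post) with dimnames carrying neuron
#'   ids.
#' @param buf an [eligibility_buffer()].
#' @param t_reward reward time (seconds).
#' @param mbon_id identifier of the MBON-alpha1 neuron (default
#'   `"MBON_a1"`-classed column found by name `attr(W, "mbon_a1")`, or pass
#'   explicitly).
#' @return the updated weight matrix.
#' @export
apply_reward <- function(W, buf, t_reward, mbon_id) {
  eligible <- names(buf$last_spike_time)[
    buf$last_spike_time >= t_reward - buf$window &
      buf$last_spike_time <= t_reward]
  if (!length(eligible)) return(W)
  stopifnot(mbon_id %in% colnames(W))
  rows <- match(eligible, rownames(W))
  stopifnot(!anyNA(rows))
  col <- match(mbon_id, colnames(W))
  has_syn <- which(W[rows, col] != 0)
  if (length(has_syn)) W[rows[has_syn], col] <- 0.25
  W
}
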