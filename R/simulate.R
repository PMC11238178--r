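#' Run a full network simulation
#'
#' Composes the PQN neuron populations, kinetic synapses, Poisson ORN input
#' and (optionally) reward-driven depression into one explicit-Euler loop on
#' a 1 ms grid. Per step: ORN spikes are drawn, ORN synaptic terminals
#' updated, input currents accumulated through the scaled weight matrix,
#' every neuron class advanced synchronously, chemical synapses updated from
#' the freshly committed membrane potentials, and KC spikes recorded into
#' the eligibility buffer. Once per simulated second the PN homeostatic
#' gains are updated. Inactivating a class (or LN subclass) forces its
#' accumulated input current to zero.
#'
#' @param net a list with `neurons` (a [neuron_table()]) and `W` (sparse
#'   pre x post weight matrix), e.g. from [generate_synthetic_topology()].
#' @param protocol a stimulus schedule (see [build_protocol()]).
#' @param or_table an [or_response_table()].
#' @param params named list of [pqn_params()] per class / LN subclass
#'   (default [default_neuron_params()]).
#' @param scaling a [scaling_table()].
#' @param dt time step in seconds (default 1 ms).
#' @param horizon simulation end time (s); defaults to the protocol horizon.
#' @param inactivate character vector of class or LN-subclass names whose
#'   stimulus input is forced to zero.
#' @param reward_times times (s) at which a reward signal triggers LTD of
#'   eligible KC-to-MBON-alpha1 synapses; empty disables learning.
#' @param record list of optional recording selectors: `v`, `v_s`, `s`
#'   (character vectors of neuron ids) and `u` (logical: record PN gains
#'   once per second).
#' @param record_lfp logical: record the per-class (and per-LN-subclass)
#'   mean synaptic current at every step (default `TRUE`).
#' @param seed integer seed for the ORN spike draws; `NULL` uses the
#'   current RNG state.
#' @param fixed_point logical: run every state variable and arithmetic
#'   stage in the 18-bit/10-fraction fixed-point format (default `FALSE`).
#' @param alpha,beta kinetic synapse rise and decay rates shared by all
#'   synapses (defaults 250 and 203.125).
#' @param eligibility_window KC eligibility window for LTD in seconds
#'   (default 5).
#' @return an object of class `sim_recording`: a list with `spikes`
#'   (`data.frame` of `t_ms`, `id`, `class`), `lfp` (steps x groups matrix
#'   of mean synaptic currents), `traces`, `u` (per-second PN gain matrix),
#'   `W_final`, `n_steps`, `dt`, and the call configuration.
#' @export
run_simulation <- function(net, protocol, or_table,
                           params = default_neuron_params(),
                           scaling = scaling_table(),
                           dt = 1e-3, horizon = NULL,
                           inactivate = character(0),
                           reward_times = numeric(0),
                           record = list(),
                           record_lfp = TRUE,
                           seed = NULL, fixed_point = FALSE,
                           alpha = 250, beta = 203.125,
                           eligibility_window = 5) {
  neurons <- net$neurons
  W <- net$W
  ids <- neurons$id
  N <- length(ids)
  stopifnot(identical(rownames(W), ids), identical(colnames(W), ids))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(horizon)) {
    horizon <- attr(protocol, "horizon") %||%
      (max(protocol$onset + protocol$duration) + 1)
  }
  n_steps <- as.integer(round(horizon / dt))
  steps_per_sec <- as.integer(round(1 / dt))

  fmt <- if (fixed_point) fxp_format() else NULL
  Q <- if (fixed_point) fxp_quantizer(fmt) else NULL

  cls <- neurons$class
  sub <- neurons$ln_subclass
  # dynamics blocks: one per LN subclass, one per other non-ORN class
  block_key <- ifelse(cls == "LN", sub, cls)
  block_names <- intersect(
    c("PN", "KC", "APL", "MBON_a1", "MBON_a3", "SMP354", ln_subclasses()),
    unique(block_key))
  missing_par <- setdiff(block_names, names(params))
  if (length(missing_par)) {
    stop("no parameter set for block(s): ", paste(missing_par, collapse = ", "),
         call. = FALSE)
  }
  blocks <- lapply(block_names, function(b) {
    idx <- which(block_key == b)
    p <- params[[b]]
    if (fixed_point) p <- quantize_params(p, fmt)
    list(name = b, idx = idx, p = p, n = length(idx))
  })
  names(blocks) <- block_names

  # Fused per-neuron coefficient vectors over the modeled (non-ORN)
  # neurons. Single-compartment neurons take k_0 = theta = 0 so the
  # somatic terms vanish exactly and one uniform update covers all
  # variants; two-compartment neurons take epsilon = 0 so q stays 0.
  mod_idx <- unlist(lapply(blocks, `[[`, "idx"), use.names = FALSE)
  M <- length(mod_idx)
  eng <- local({
    fields <- c("phi", "tau", "epsilon", "I_b0", "k_I", "m0", "m1",
                "a_fn", "b_fn", "c_fn", "a_fp", "b_fp", "c_fp",
                "a_gn", "b_gn", "c_gn", "a_gp", "b_gp", "c_gp", "r_g",
                "a_hn", "b_hn", "c_hn", "a_hp", "b_hp", "c_hp", "r_h",
                "theta", "alpha_leak", "I_b1", "k_0", "k_r")
    e <- list()
    for (f in fields) e[[f]] <- numeric(M)
    e$is_pn <- logical(M)
    pos <- 0L
    for (bl in blocks) {
      sel <- pos + seq_len(bl$n)
      p <- bl$p
      for (f in fields) {
        val <- p[[f]]
        if (is.null(val) || !is.finite(val)) val <- 0
        e[[f]][sel] <- val
      }
      if (p$variant == "single") {
        e$theta[sel] <- 0; e$k_0[sel] <- 0; e$alpha_leak[sel] <- 0
        e$I_b1[sel] <- 0; e$k_r[sel] <- 0
      } else {
        e$epsilon[sel] <- 0
      }
      if (p$variant == "pn") e$is_pn[sel] <- TRUE
      pos <- pos + bl$n
    }
    e$dphi <- dt * e$phi / e$tau
    e$dn <- dt / e$tau
    e$deps <- dt * e$epsilon / e$tau
    e$dth <- dt * e$theta / e$tau
    if (fixed_point) {
      for (f in c("dphi", "dn", "deps", "dth")) e[[f]] <- Q(e[[f]])
    }
    e
  })
  pn_sel <- which(eng$is_pn)
  # state vectors (all zero-initialized)
  v <- numeric(M); n_v <- numeric(M); q <- numeric(M); v_s <- numeric(M)
  u <- numeric(M); spike_cnt <- integer(length(pn_sel))
  kc_block <- blocks[["KC"]]
  kc_sel <- if (!is.null(kc_block)) match(kc_block$idx, mod_idx) else integer(0)

  # effective weights: fold class-pair scaling into the sparse matrix
  W_eff <- effective_weights(W, cls, scaling)
  if (fixed_point) W_eff@x <- fxp_quantize(W_eff@x, fmt)

  # ORN input machinery
  orn_idx <- which(cls == "ORN")
  n_orn <- length(orn_idx)
  act <- active_odorant_steps(protocol, horizon, dt)
  rates <- cbind(rep(or_table$r_spo, n_orn),
                 if (length(act$levels))
                   vapply(act$levels,
                          function(o) orn_rate(neurons$or_type[orn_idx], o, or_table),
                          numeric(n_orn)))
  pr <- pmin(rates * dt, 1)
  act_idx <- c(act$index, rep(0L, max(0, n_steps - length(act$index))))

  # inactivation: match classes and LN subclasses
  inact_idx <- which(cls %in% inactivate | (!is.na(sub) & sub %in% inactivate))

  # LFP groups
  lfp_groups <- c(setdiff(unique(cls), character(0)),
                  intersect(ln_subclasses(), unique(sub)))
  lfp_groups <- unique(lfp_groups)
  group_idx <- lapply(lfp_groups, function(g) {
    if (g %in% ln_subclasses()) which(!is.na(sub) & sub == g) else which(cls == g)
  })
  names(group_idx) <- lfp_groups
  group_inv <- vapply(group_idx, function(ix) 1 / max(1L, length(ix)), numeric(1))
  lfp_mat <- if (record_lfp) matrix(0, n_steps, length(lfp_groups),
                                    dimnames = list(NULL, lfp_groups)) else NULL

  # trace recording
  tr_sel <- list(v = match(record$v %||% character(0), ids),
                 v_s = match(record$v_s %||% character(0), ids),
                 s = match(record$s %||% character(0), ids))
  tr_mats <- lapply(tr_sel, function(ix)
    if (length(ix)) matrix(0, n_steps, length(ix)) else NULL)
  rec_u <- isTRUE(record$u)
  pn_block <- blocks[["PN"]]
  u_mat <- if (rec_u && !is.null(pn_block))
    matrix(0, ceiling(horizon), pn_block$n) else NULL

  # plasticity bookkeeping
  kc_idx <- which(cls == "KC")
  buf <- eligibility_buffer(ids[kc_idx], window = eligibility_window)
  reward_steps <- sort(unique(as.integer(round(reward_times / dt))))
  mbon_col <- match("MBON_a1", ids)
  if (length(reward_steps) && is.na(mbon_col)) {
    stop("reward given but network has no MBON_a1 neuron", call. = FALSE)
  }

  s <- numeric(N)              # synaptic activation per presynaptic neuron
  v_all <- numeric(N)          # committed membrane potentials (0 for ORN)
  vs_all <- numeric(N)
  spk_t <- vector("list", 2048); spk_i <- vector("list", 2048); spk_n <- 0L

  ad <- dt * alpha; bd <- dt * beta
  if (fixed_point) { ad <- fxp_quantize(ad, fmt); bd <- fxp_quantize(bd, fmt) }
  # integration-rate coefficients, associated exactly as in the step_*
  # operations so fused and per-block updates agree bit-for-bit
  if (fixed_point) {
    c_v <- Q(dt * eng$phi / eng$tau)
    c_n <- Q(dt / eng$tau)
    c_q <- Q(dt * eng$epsilon / eng$tau)
    c_s <- Q(dt * eng$theta / eng$tau)
  } else {
    c_v <- dt * (eng$phi / eng$tau)
    c_n <- dt * (1 / eng$tau)
    c_q <- dt * (eng$epsilon / eng$tau)
    c_s <- dt * (eng$theta / eng$tau)
  }
  quadv <- function(vv, r, an, bn, cn, ap, bp, cp) {
    neg <- vv < r
    a <- ap; b <- bp; cc <- cp
    a[neg] <- an[neg]; b[neg] <- bn[neg]; cc[neg] <- cn[neg]
    if (fixed_point) {
      d <- Q(vv - b)
      Q(Q(a * Q(d * d)) + cc)
    } else {
      a * (vv - b)^2 + cc
    }
  }
  zero_r <- numeric(M)
  kap_tau <- if (!is.null(blocks[["PN"]]))
    blocks[["PN"]]$p$kappa / blocks[["PN"]]$p$tau else 0
  F_t_pn <- if (!is.null(blocks[["PN"]])) blocks[["PN"]]$p$F_t else 0

  for (k in seq_len(n_steps)) {
    t_now <- k * dt
    # 1. ORN spikes and their synaptic terminals
    orn_spk <- stats::runif(n_orn) < pr[, act_idx[k] + 1L]
    s_orn <- s[orn_idx]
    s_orn <- if (fixed_point) Q(s_orn - Q(bd * s_orn)) else s_orn - bd * s_orn
    s_orn[orn_spk] <- 1
    s[orn_idx] <- s_orn
    # 2. accumulate input currents
    I <- as.numeric(Matrix::crossprod(W_eff, s))
    if (fixed_point) I <- Q(I)
    if (length(inact_idx)) I[inact_idx] <- 0
    # 3. synchronous neuron update (all modeled neurons at once)
    Im <- I[mod_idx]
    mI <- eng$k_I * pmin(pmax(Im, eng$m0), eng$m1)
    if (fixed_point) mI <- Q(mI)
    drive <- mI
    if (length(pn_sel)) drive[pn_sel] <- u[pn_sel] * mI[pn_sel]
    if (fixed_point) drive <- Q(drive)
    fq <- quadv(v, zero_r, eng$a_fn, eng$b_fn, eng$c_fn,
                eng$a_fp, eng$b_fp, eng$c_fp)
    gq <- quadv(v, eng$r_g, eng$a_gn, eng$b_gn, eng$c_gn,
                eng$a_gp, eng$b_gp, eng$c_gp)
    hq <- quadv(v, eng$r_h, eng$a_hn, eng$b_hn, eng$c_hn,
                eng$a_hp, eng$b_hp, eng$c_hp)
    if (fixed_point) {
      I_c <- Q(eng$k_0 * Q(v - v_s))
      v_new <- Q(v + Q(c_v * Q(fq - n_v - q + eng$I_b0 + drive - I_c)))
      n_new <- Q(n_v + Q(c_n * Q(gq - n_v)))
      q_new <- Q(q + Q(c_q * Q(hq - q)))
      vs_new <- Q(v_s + Q(c_s * Q(Q(-eng$alpha_leak * v_s) + eng$I_b1 + I_c)))
    } else {
      I_c <- eng$k_0 * (v - v_s)
      v_new <- v + c_v * (fq - n_v - q + eng$I_b0 + drive - I_c)
      n_new <- n_v + c_n * (gq - n_v)
      q_new <- q + c_q * (hq - q)
      vs_new <- v_s + c_s * (-eng$alpha_leak * v_s + eng$I_b1 + I_c)
    }
    if (anyNA(v_new) || any(is.infinite(v_new))) {
      check_finite_state(v_new, t = t_now)
    }
    spiked <- v < 0 & v_new >= 0
    v <- v_new; n_v <- n_new; q <- q_new; v_s <- vs_new
    v_all[mod_idx] <- v
    if (length(pn_sel)) {
      spike_cnt <- spike_cnt + as.integer(spiked[pn_sel])
    }
    # spike bookkeeping
    if (any(spiked) || any(orn_spk)) {
      hits <- c(mod_idx[spiked], orn_idx[orn_spk])
      spk_n <- spk_n + 1L
      if (spk_n > length(spk_t)) {
        length(spk_t) <- 2L * length(spk_t); length(spk_i) <- 2L * length(spk_i)
      }
      spk_t[[spk_n]] <- rep.int(t_now, length(hits))
      spk_i[[spk_n]] <- hits
    }
    # 4. chemical synapses from the committed potentials
    s_mod <- s[mod_idx]
    if (fixed_point) {
      s_new <- Q(s_mod - Q(bd * s_mod))
      on <- which(v >= 0)
      if (length(on)) s_new[on] <- Q(s_mod[on] + Q(ad * Q(1 - s_mod[on])))
    } else {
      s_new <- s_mod - bd * s_mod
      on <- which(v >= 0)
      if (length(on)) s_new[on] <- s_mod[on] + ad * (1 - s_mod[on])
    }
    s[mod_idx] <- s_new
    # 5. eligibility
    if (length(kc_sel)) {
      kc_spk <- spiked[kc_sel]
      if (any(kc_spk)) buf$last_spike_time[kc_spk] <- t_now
    }
    # 6. once-per-second homeostasis
    if (length(pn_sel) && k %% steps_per_sec == 0L) {
      F_now <- as.numeric(spike_cnt)
      u_new <- u[pn_sel] + kap_tau * (F_t_pn - F_now)
      u_new <- pmin(pmax(u_new, 0), 1)
      if (fixed_point) u_new <- Q(u_new)
      u[pn_sel] <- u_new
      spike_cnt <- integer(length(pn_sel))
      if (rec_u) u_mat[k %/% steps_per_sec, ] <- u_new
    }
    # 7. reward-driven LTD
    if (length(reward_steps) && k %in% reward_steps) {
      W <- apply_reward(W, buf, t_now, mbon_id = "MBON_a1")
      nz <- which(W[, mbon_col] != 0)
      W_eff[nz, mbon_col] <- W[nz, mbon_col] *
        scaling_value(scaling, cls[nz], "MBON_a1")
      if (fixed_point) W_eff@x <- fxp_quantize(W_eff@x, fmt)
    }
    # 8. recordings
    if (record_lfp) {
      for (g in seq_along(group_idx)) {
        lfp_mat[k, g] <- sum(s[group_idx[[g]]]) * group_inv[g]
      }
    }
    if (!is.null(tr_mats$v)) tr_mats$v[k, ] <- v_all[tr_sel$v]
    if (!is.null(tr_mats$v_s)) {
      vs_all[mod_idx] <- v_s
      tr_mats$v_s[k, ] <- vs_all[tr_sel$v_s]
    }
    if (!is.null(tr_mats$s)) tr_mats$s[k, ] <- s[tr_sel$s]
  }

  spike_idx <- unlist(spk_i[seq_len(spk_n)]) %||% integer(0)
  spikes <- data.frame(
    t_ms = (unlist(spk_t[seq_len(spk_n)]) %||% numeric(0)) * 1000,
    id = ids[spike_idx],
    class = cls[spike_idx],
    stringsAsFactors = FALSE)
  ord <- order(spikes$t_ms)
  spikes <- spikes[ord, , drop = FALSE]
  rownames(spikes) <- NULL

  out <- list(spikes = spikes,
              lfp = lfp_mat, lfp_groups = lfp_groups,
              traces = tr_mats,
              trace_ids = list(v = record$v, v_s = record$v_s, s = record$s),
              u = u_mat,
              W_final = W,
              neurons = neurons,
              n_steps = n_steps, dt = dt, horizon = horizon,
              inactivate = inactivate, seed = seed,
              fixed_point = fixed_point,
              pn_state = if (length(pn_sel))
                list(ids = ids[mod_idx[pn_sel]], v = v[pn_sel],
                     v_s = v_s[pn_sel], u = u[pn_sel]) else NULL)
  class(out) <- "sim_recording"
  out
}

#' @export
print.sim_recording <- function(x, ...) {
  cat("<sim_recording> ", x$horizon, " s at dt=", x$dt * 1000, " ms, ",
      nrow(x$spikes), " spikes",
      if (x$fixed_point) ", fixed-point backend", "\n", sep = "")
  if (nrow(x$spikes)) {
    print(table(x$spikes$class))
  }
  invisible(x)
}
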