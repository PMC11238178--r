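#' Names of the six-odorant panel
#'
#' Labels for the default odor panel used by the cycling stimulus protocols.
#' @return character vector of length 6.
#' @export
odor_panel <- function() {
  c("3-octanol", "cis-3-hexenol", "cyclohexanone",
    "2,3-butanedione", "2-hexanol", "ethyl butyrate")
}

#' Construct an OR-by-odorant response table
#'
#' Holds the response intensity `r_ij` of each olfactory receptor to each
#' odorant (values in `[0, 1]`, DoOR-style), per-odorant concentration
#' scalars `k_j` in `[0, 1]`, the gain `c` and the spontaneous firing rate.
#' With the defaults (`c = 192`, `r_spo = 8` Hz) the firing rate at maximal
#' response and concentration is 200 Hz.
#'
#' @param response numeric matrix, ORs x odorants, entries in `[0, 1]`;
#'   rownames are OR types, colnames odorant names.
#' @param k per-odorant concentration scalars in `[0, 1]` (default 1).
#' @param c gain constant (default 192).
#' @param r_spo spontaneous firing rate in Hz (default 8).
#' @return an object of class `or_response_table`.
#' @export
or_response_table <- function(response, k = NULL, c = 192, r_spo = 8) {
  stopifnot(is.matrix(response), all(response >= 0), all(response <= 1),
            !is.null(rownames(response)), !is.null(colnames(response)))
  if (is.null(k)) k <- stats::setNames(rep(1, ncol(response)), colnames(response))
  stopifnot(all(k >= 0), all(k <= 1),
            setequal(names(k), colnames(response)))
  tbl <- list(response = response, k = k[colnames(response)],
              c = c, r_spo = r_spo)
  class(tbl) <- "or_response_table"
  tbl
}

#' ORN firing rate for an OR / odorant pair
#'
#' `r = c * k_j * r_ij + r_spo`; with no active odorant the rate is the
#' spontaneous rate `r_spo`.
#'
#' @param or_type OR type (row of the table); vectorized.
#' @param odorant odorant name, or `NA` for no odor.
#' @param table an [or_response_table()].
#' @return firing rate(s) in Hz.
#' @export
orn_rate <- function(or_type, odorant, table) {
  if (length(odorant) == 1 && is.na(odorant)) {
    return(rep(table$r_spo, length(or_type)))
  }
  stopifnot(all(or_type %in% rownames(table$response)),
            all(odorant %in% colnames(table$response)))
  r_ij <- table$response[cbind(or_type, odorant)]
  unname(table$c * table$k[odorant] * r_ij + table$r_spo)
}

#' Generate a synthetic OR response table
#'
#' Stands in for a measured odorant-response database. Each odorant drives a
#' distinct, randomly chosen subset of the ORs: a fraction `sparsity` of ORs
#' responds at full intensity (1), the rest at 0. Sparse, odorant-specific
#' tuning is what lets odors be represented by small, distinct KC
#' populations downstream.
#'
#' @param or_types character vector of OR type names.
#' @param odorants character vector of odorant names (default the
#'   six-odorant panel).
#' @param sparsity fraction of ORs responding strongly per odorant
#'   (default 0.25).
#' @param background fraction of the remaining ORs that respond weakly
#'   (default 0.3); weak intensities are uniform on `(0, weak_max]`.
#'   Broad weak tuning recruits many ORNs while leaving their projection
#'   neurons subthreshold, the first stage of response sparsening.
#' @param weak_max maximum weak response intensity (default 0.3).
#' @param k per-odorant concentration scalars (default 1).
#' @return an [or_response_table()]. Uses the current RNG state.
#' @export
generate_synthetic_or_table <- function(or_types, odorants = odor_panel(),
                                        sparsity = 0.25, background = 0.3,
                                        weak_max = 0.3, k = NULL) {
  stopifnot(length(or_types) >= 1, sparsity >= 0, sparsity <= 1,
            background >= 0, background <= 1)
  n_or <- length(or_types)
  resp <- matrix(0, n_or, length(odorants),
                 dimnames = list(or_types, odorants))
  n_strong <- round(sparsity * n_or)
  # draw strong ORs from a shuffled pool without replacement so odorant
  # tuning sets are disjoint whenever the receptor repertoire allows
  pool <- sample(n_or)
  for (j in seq_along(odorants)) {
    if (n_strong == 0) next
    take <- integer(0)
    while (length(take) < n_strong) {
      if (!length(pool)) pool <- sample(n_or)
      k_take <- min(n_strong - length(take), length(pool))
      take <- c(take, pool[seq_len(k_take)])
      pool <- pool[-seq_len(k_take)]
    }
    resp[take, j] <- 1
    rest <- setdiff(seq_len(n_or), take)
    n_weak <- round(background * length(rest))
    if (n_weak > 0) {
      weak <- sample(rest, n_weak)
      resp[weak, j] <- stats::runif(n_weak, 0, weak_max)
    }
  }
  or_response_table(resp, k = k)
}

#' Build a stimulus protocol
#'
#' Three protocol kinds: (1) six odorants applied in turn for 1 s every 5 s;
#' (2) a single odorant applied for 10 s every 20 s; (3) six odorants in turn
#' for 10 s every 20 s. Every protocol is preceded by `warmup` seconds of
#' kind-1 stimulation (default 300 s), during which PN homeostasis settles.
#'
#' @param kind 1, 2 or 3.
#' @param odorants odorant names: six for kinds 1 and 3, one for kind 2.
#'   For kind 2 the warmup cycles a six-odor panel given in
#'   `warmup_odorants`.
#' @param warmup warmup duration in seconds (default 300).
#' @param n_cycles number of post-warmup presentations (kind 1: per odorant
#'   cycles through the panel; kinds 2 and 3: presentations).
#' @param warmup_odorants odor panel used during the warmup (default
#'   `odorants` for kinds 1 and 3; required for kind 2 unless the default
#'   [odor_panel()] applies).
#' @return an object of class `stimulus_protocol`: a `data.frame` with
#'   columns `odorant`, `onset` (s), `duration` (s), `phase`
#'   (`"warmup"`/`"main"`), with attributes `kind`, `warmup`, `horizon`.
#' @export
build_protocol <- function(kind, odorants, warmup = 300, n_cycles = 1,
                           warmup_odorants = NULL) {
  stopifnot(kind %in% 1:3)
  if (kind == 2) {
    if (length(odorants) != 1) stop("kind 2 takes exactly one odorant", call. = FALSE)
    if (is.null(warmup_odorants)) warmup_odorants <- odor_panel()
  } else {
    if (length(odorants) != 6) stop("kinds 1 and 3 take exactly six odorants", call. = FALSE)
    if (is.null(warmup_odorants)) warmup_odorants <- odorants
  }
  sched_warm <- if (warmup > 0) {
    n_pres <- floor(warmup / 5)
    data.frame(odorant = rep(warmup_odorants, length.out = n_pres),
               onset = 5 * (seq_len(n_pres) - 1),
               duration = rep(1, n_pres),
               phase = rep("warmup", n_pres), stringsAsFactors = FALSE)
  } else {
    data.frame(odorant = character(0), onset = numeric(0),
               duration = numeric(0), phase = character(0))
  }
  period <- if (kind == 1) 5 else 20
  dur <- if (kind == 1) 1 else 10
  n_pres <- if (kind == 2) n_cycles else 6 * n_cycles
  odo <- if (kind == 2) rep(odorants, n_pres) else rep(odorants, length.out = n_pres)
  sched_main <- data.frame(odorant = odo,
                           onset = warmup + period * (seq_len(n_pres) - 1),
                           duration = rep(dur, n_pres),
                           phase = rep("main", n_pres),
                           stringsAsFactors = FALSE)
  sched <- rbind(sched_warm, sched_main)
  stopifnot(all(diff(sched$onset) >= 0),
            all(utils::head(sched$onset + sched$duration, -1) <= sched$onset[-1]))
  attr(sched, "kind") <- kind
  attr(sched, "warmup") <- warmup
  attr(sched, "horizon") <- max(sched$onset + period)
  class(sched) <- c("stimulus_protocol", "data.frame")
  sched
}

# Which odorant (or NA) is active on each time step of a dt grid covering
# [0, horizon). Returns an integer index into `levels` (0 = none).
active_odorant_steps <- function(schedule, horizon, dt) {
  n_steps <- ceiling(horizon / dt)
  act <- integer(n_steps)
  odors <- unique(schedule$odorant)
  for (r in seq_len(nrow(schedule))) {
    i0 <- floor(schedule$onset[r] / dt) + 1
    i1 <- min(ceiling((schedule$onset[r] + schedule$duration[r]) / dt), n_steps)
    if (i0 <= n_steps) act[i0:i1] <- match(schedule$odorant[r], odors)
  }
  list(index = act, levels = odors)
}

#' Generate ORN spike trains for a stimulus protocol
#'
#' Bernoulli approximation of a Poisson process: at every time step each ORN
#' spikes with probability `r * dt`, where `r` is the [orn_rate()] of the
#' currently active odorant, or the spontaneous rate between presentations.
#' Probabilities above 1 are clipped (with a warning).
#'
#' @param protocol a [build_protocol()] schedule (or any data.frame with
#'   `odorant`, `onset`, `duration`).
#' @param table an [or_response_table()].
#' @param or_types OR type per ORN.
#' @param horizon simulation end time in seconds (default: protocol horizon).
#' @param dt time step in seconds (default 1 ms).
#' @return a `data.frame` raster with columns `t_ms` (spike time) and `orn`
#'   (ORN index). Uses the current RNG state.
#' @export
generate_orn_spikes <- function(protocol, table, or_types,
                                horizon = NULL, dt = 1e-3) {
  if (is.null(horizon)) horizon <- attr(protocol, "horizon") %||%
      max(protocol$onset + protocol$duration)
  act <- active_odorant_steps(protocol, horizon, dt)
  n_orn <- length(or_types)
  # rate per ORN per odorant (column 1 = no odor)
  rates <- cbind(rep(table$r_spo, n_orn),
                 vapply(act$levels, function(o) orn_rate(or_types, o, table),
                        numeric(n_orn)))
  pr <- rates * dt
  if (any(pr > 1)) {
    warning("spike probability r*dt exceeds 1 for some ORN; clipped")
    pr <- pmin(pr, 1)
  }
  t_out <- vector("list", length(act$index))
  id_out <- vector("list", length(act$index))
  for (k in seq_along(act$index)) {
    spiking <- which(stats::runif(n_orn) < pr[, act$index[k] + 1L])
    if (length(spiking)) {
      t_out[[k]] <- rep(k * dt * 1000, length(spiking))
      id_out[[k]] <- spiking
    }
  }
  data.frame(t_ms = unlist(t_out) %||% numeric(0),
             orn = unlist(id_out) %||% integer(0))
}
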