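#' Construct a PQN parameter set
#'
#' The piecewise quadratic neuron (PQN) model is a qualitative spiking neuron
#' model whose nullclines are built from pairs of parabolic branches, chosen so
#' that the model can be computed with additions and multiplications only.
#' A parameter set holds the time-scale constants, the nullcline coefficients
#' of the three piecewise functions \eqn{f}, \eqn{g}, \eqn{h}, the input
#' transform, and (depending on the variant) the somatic-compartment and
#' homeostasis constants.
#'
#' The coefficients of the right-hand ("p") branches of \eqn{f}, \eqn{g} and
#' \eqn{h} other than their curvatures are not free: they are derived by
#' [derive_dependent_params()] so that each function is continuous and
#' once-differentiable at its branch point (\eqn{v = 0} for \eqn{f},
#' \eqn{v = r_g} for \eqn{g}, \eqn{v = r_h} for \eqn{h}).
#'
#' @param tau time-scale constant shared by all state variables (seconds).
#' @param phi time-scale factor of the membrane potential \eqn{v}.
#' @param epsilon time-scale factor of the slow variable \eqn{q}
#'   (single-compartment variant only).
#' @param I_b0 bias constant added to the \eqn{v} equation.
#' @param k_I input scale applied inside the input transform \eqn{m(I)}.
#' @param m0,m1 lower and upper clamp of the input transform (`m0 <= m1`).
#' @param a_fn,b_fn,c_fn coefficients of the left branch of \eqn{f}.
#' @param a_fp curvature of the right branch of \eqn{f} (nonzero).
#' @param a_gn,b_gn,c_gn coefficients of the left branch of \eqn{g}.
#' @param a_gp curvature of the right branch of \eqn{g} (nonzero).
#' @param r_g branch point of \eqn{g}.
#' @param a_hn,b_hn,c_hn coefficients of the left branch of \eqn{h}.
#' @param a_hp curvature of the right branch of \eqn{h} (nonzero).
#' @param r_h branch point of \eqn{h}.
#' @param variant one of `"single"`, `"two_comp"`, `"pn"`. Two-compartment
#'   variants have no slow variable \eqn{q}; the `"pn"` variant adds
#'   homeostatic gating of the synaptic drive.
#' @param theta somatic time-scale factor (two-compartment variants).
#' @param alpha_leak somatic leak constant (two-compartment variants).
#' @param I_b1 somatic bias constant (two-compartment variants).
#' @param k_0 axon-to-soma coupling gain (two-compartment variants).
#' @param k_r scale of the current injected directly into the soma.
#' @param kappa homeostasis rate constant (`"pn"` variant).
#' @param F_t target firing frequency in Hz (`"pn"` variant).
#' @param label optional class label carried along for error messages.
#'
#' @return An object of class `pqn_params`: a named list with all independent
#'   and derived coefficients.
#' @examples
#' p <- pqn_params(
#'   tau = 0.02, phi = 4, epsilon = 0.1, I_b0 = 0, k_I = 1, m0 = -2, m1 = 2,
#'   a_fn = 1, b_fn = -1, c_fn = 0, a_fp = -1,
#'   a_gn = 2, b_gn = -1.25, c_gn = 0, a_gp = 2, r_g = 0,
#'   a_hn = 0.5, b_hn = -1, c_hn = 0, a_hp = 0.5, r_h = 0
#' )
#' p$b_fp # derived so that f is smooth at v = 0
#' @export
pqn_params <- function(tau, phi, epsilon = 0, I_b0, k_I, m0, m1,
                       a_fn, b_fn, c_fn, a_fp,
                       a_gn, b_gn, c_gn, a_gp, r_g,
                       a_hn = 0, b_hn = 0, c_hn = 0, a_hp = 1, r_h = 0,
                       variant = c("single", "two_comp", "pn"),
                       theta = NA_real_, alpha_leak = NA_real_,
                       I_b1 = NA_real_, k_0 = NA_real_, k_r = NA_real_,
                       kappa = NA_real_, F_t = NA_real_,
                       label = NULL) {
  variant <- match.arg(variant)
  p <- list(
    tau = tau, phi = phi, epsilon = epsilon, I_b0 = I_b0, k_I = k_I,
    m0 = m0, m1 = m1,
    a_fn = a_fn, b_fn = b_fn, c_fn = c_fn, a_fp = a_fp,
    a_gn = a_gn, b_gn = b_gn, c_gn = c_gn, a_gp = a_gp, r_g = r_g,
    a_hn = a_hn, b_hn = b_hn, c_hn = c_hn, a_hp = a_hp, r_h = r_h,
    variant = variant,
    theta = theta, alpha_leak = alpha_leak, I_b1 = I_b1,
    k_0 = k_0, k_r = k_r, kappa = kappa, F_t = F_t,
    label = label
  )
  class(p) <- "pqn_params"
  p <- derive_dependent_params(p)
  validate_pqn_params(p)
  p
}

#' Fill in the derived nullcline coefficients
#'
#' Computes `b_fp`, `c_fp`, `b_gp`, `c_gp`, `b_hp`, `c_hp` from the
#' independent coefficients so that \eqn{f}, \eqn{g}, \eqn{h} are continuous
#' and have continuous first derivatives at their branch points.
#'
#' @param p a `pqn_params` object (derived fields may be absent or stale).
#' @return `p` with the six derived coefficients recomputed.
#' @export
derive_dependent_params <- function(p) {
  if (any(c(p$a_fp, p$a_gp, p$a_hp) == 0)) {
    stop("invalid PQN parameters", if (!is.null(p$label)) paste0(" (", p$label, ")"),
         ": a_fp, a_gp and a_hp must be nonzero", call. = FALSE)
  }
  p$b_fp <- p$a_fn * p$b_fn / p$a_fp
  p$c_fp <- p$a_fn * p$b_fn^2 + p$c_fn - p$a_fp * p$b_fp^2
  p$b_gp <- p$r_g - p$a_gn * (p$r_g - p$b_gn) / p$a_gp
  p$c_gp <- p$a_gn * (p$r_g - p$b_gn)^2 + p$c_gn - p$a_gp * (p$r_g - p$b_gp)^2
  p$b_hp <- p$r_h - p$a_hn * (p$r_h - p$b_hn) / p$a_hp
  p$c_hp <- p$a_hn * (p$r_h - p$b_hn)^2 + p$c_hn - p$a_hp * (p$r_h - p$b_hp)^2
  p
}

validate_pqn_params <- function(p) {
  who <- if (!is.null(p$label)) paste0(" (", p$label, ")") else ""
  if (p$m0 > p$m1) {
    stop("invalid PQN parameters", who, ": m0 must be <= m1", call. = FALSE)
  }
  num <- c("tau", "phi", "I_b0", "k_I", "m0", "m1",
           "a_fn", "b_fn", "c_fn", "a_fp", "a_gn", "b_gn", "c_gn", "a_gp",
           "r_g", "a_hn", "b_hn", "c_hn", "a_hp", "r_h")
  bad <- num[!vapply(p[num], function(x) is.numeric(x) && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("invalid PQN parameters", who, ": non-finite field(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$tau <= 0) stop("invalid PQN parameters", who, ": tau must be positive", call. = FALSE)
  if (p$variant %in% c("two_comp", "pn")) {
    extra <- c("theta", "alpha_leak", "I_b1", "k_0", "k_r")
    miss <- extra[!vapply(p[extra], function(x) is.numeric(x) && is.finite(x), logical(1))]
    if (length(miss)) {
      stop("invalid PQN parameters", who, ": two-compartment variant requires ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  if (p$variant == "pn") {
    extra <- c("kappa", "F_t")
    miss <- extra[!vapply(p[extra], function(x) is.numeric(x) && is.finite(x), logical(1))]
    if (length(miss)) {
      stop("invalid PQN parameters", who, ": pn variant requires ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  invisible(p)
}

#' Evaluate one of the piecewise-parabolic nullcline functions
#'
#' @param which `"f"`, `"g"`, or `"h"`.
#' @param v membrane potential (vectorized).
#' @param p a `pqn_params` object with derived coefficients present.
#' @return numeric vector of function values. At the branch point the
#'   right-hand branch is used; by construction both branches agree there.
#' @export
eval_piecewise <- function(which = c("f", "g", "h"), v, p) {
  which <- match.arg(which)
  switch(which,
    f = pqn_f(v, p),
    g = pqn_g(v, p),
    h = pqn_h(v, p)
  )
}

pqn_f <- function(v, p) {
  ifelse(v < 0,
         p$a_fn * (v - p$b_fn)^2 + p$c_fn,
         p$a_fp * (v - p$b_fp)^2 + p$c_fp)
}

pqn_g <- function(v, p) {
  ifelse(v < p$r_g,
         p$a_gn * (v - p$b_gn)^2 + p$c_gn,
         p$a_gp * (v - p$b_gp)^2 + p$c_gp)
}

pqn_h <- function(v, p) {
  ifelse(v < p$r_h,
         p$a_hn * (v - p$b_hn)^2 + p$c_hn,
         p$a_hp * (v - p$b_hp)^2 + p$c_hp)
}

#' Nonlinear input transform m(I)
#'
#' Scales the stimulus current by `k_I` and clamps its dynamic range to
#' `[m0, m1]` before scaling: returns `k_I * m0` for `I < m0`, `k_I * I`
#' inside the range, and `k_I * m1` above it. `k_I` is applied exactly once;
#' model variants that gate the synaptic drive multiply the result of this
#' function, never re-apply `k_I`.
#'
#' @param I stimulus current (vectorized).
#' @param p a `pqn_params` object.
#' @return transformed current, same length as `I`.
#' @export
transform_input <- function(I, p) {
  p$k_I * pmin(pmax(I, p$m0), p$m1)
}

#' @export
print.pqn_params <- function(x, ...) {
  cat("<pqn_params>", if (!is.null(x$label)) paste0(" ", x$label),
      " variant=", x$variant, "\n", sep = "")
  cat(sprintf("  tau=%g phi=%g epsilon=%g I_b0=%g k_I=%g m0=%g m1=%g\n",
              x$tau, x$phi, x$epsilon, x$I_b0, x$k_I, x$m0, x$m1))
  cat(sprintf("  f: a=(%g,%g) b=(%g,%g) c=(%g,%g)\n",
              x$a_fn, x$a_fp, x$b_fn, x$b_fp, x$c_fn, x$c_fp))
  cat(sprintf("  g: a=(%g,%g) b=(%g,%g) c=(%g,%g) r_g=%g\n",
              x$a_gn, x$a_gp, x$b_gn, x$b_gp, x$c_gn, x$c_gp, x$r_g))
  cat(sprintf("  h: a=(%g,%g) b=(%g,%g) c=(%g,%g) r_h=%g\n",
              x$a_hn, x$a_hp, x$b_hn, x$b_hp, x$c_hn, x$c_hp, x$r_h))
  if (x$variant %in% c("two_comp", "pn")) {
    cat(sprintf("  soma: theta=%g alpha=%g I_b1=%g k_0=%g k_r=%g\n",
                x$theta, x$alpha_leak, x$I_b1, x$k_0, x$k_r))
  }
  if (x$variant == "pn") {
    cat(sprintf("  homeostasis: kappa=%g F_t=%g Hz\n", x$kappa, x$F_t))
  }
  invisible(x)
}
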