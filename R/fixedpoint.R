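#' Fixed-point number format
#'
#' Describes a signed two's-complement fixed-point representation with
#' `total_bits` bits of which `frac_bits` are fractional. The default 18/10
#' format represents the range \eqn{[-128, 128 - 2^{-10}]} with resolution
#' \eqn{2^{-10}}, the format used by the hardware implementation of the PQN
#' engine.
#'
#' @param total_bits total word width (default 18).
#' @param frac_bits fractional bits (default 10).
#' @return an object of class `fxp_format`.
#' @export
fxp_format <- function(total_bits = 18L, frac_bits = 10L) {
  stopifnot(total_bits > frac_bits, frac_bits >= 0)
  scale <- 2^frac_bits
  max_int <- 2^(total_bits - 1) - 1 # in raw integer units
  fmt <- list(total_bits = as.integer(total_bits),
              frac_bits = as.integer(frac_bits),
              scale = scale,
              lo = -2^(total_bits - 1) / scale,
              hi = max_int / scale,
              eps = 1 / scale)
  class(fmt) <- "fxp_format"
  fmt
}

#' Quantize to a fixed-point grid
#'
#' Rounds to the nearest representable value (ties to even, matching IEEE
#' round-half-even) and saturates at the format range limits. Idempotent and
#' monotone.
#'
#' @param x numeric vector.
#' @param fmt an [fxp_format()].
#' @return quantized numeric vector on the grid `k * 2^-frac_bits`.
#' @export
fxp_quantize <- function(x, fmt = fxp_format()) {
  q <- round(x * fmt$scale) / fmt$scale
  pmin(pmax(q, fmt$lo), fmt$hi)
}

# Returns a closure quantizing in a fixed format; used as the `Q` hook of the
# step functions.
fxp_quantizer <- function(fmt = fxp_format()) {
  force(fmt)
  function(x) fxp_quantize(x, fmt)
}

#' Quantize all numeric coefficients of a PQN parameter set
#'
#' Derived coefficients are quantized after derivation, mirroring hardware
#' where the stored constants themselves live in the fixed-point format.
#'
#' @param p a `pqn_params` object.
#' @param fmt an [fxp_format()].
#' @return `pqn_params` with every numeric field on the fixed-point grid.
#' @export
quantize_params <- function(p, fmt = fxp_format()) {
  fields <- c("tau", "phi", "epsilon", "I_b0", "k_I", "m0", "m1",
              "a_fn", "b_fn", "c_fn", "a_fp", "b_fp", "c_fp",
              "a_gn", "b_gn", "c_gn", "a_gp", "b_gp", "c_gp", "r_g",
              "a_hn", "b_hn", "c_hn", "a_hp", "b_hp", "c_hp", "r_h",
              "theta", "alpha_leak", "I_b1", "k_0", "k_r", "kappa", "F_t")
  for (f in fields) {
    if (!is.null(p[[f]]) && is.numeric(p[[f]]) && is.finite(p[[f]])) {
      p[[f]] <- fxp_quantize(p[[f]], fmt)
    }
  }
  p
}

# Stage-quantized evaluation of the piecewise parabolas: the squared
# deviation and the coefficient product are quantized at register
# boundaries, as in the pipelined hardware datapath.
pqn_piece_q <- function(v, a_n, b_n, c_n, a_p, b_p, c_p, r, Q) {
  neg <- v < r
  d <- Q(v - ifelse(neg, b_n, b_p))
  sq <- Q(d * d)
  Q(Q(ifelse(neg, a_n, a_p) * sq) + ifelse(neg, c_n, c_p))
}

pqn_f_q <- function(v, p, Q) pqn_piece_q(v, p$a_fn, p$b_fn, p$c_fn, p$a_fp, p$b_fp, p$c_fp, 0, Q)
pqn_g_q <- function(v, p, Q) pqn_piece_q(v, p$a_gn, p$b_gn, p$c_gn, p$a_gp, p$b_gp, p$c_gp, p$r_g, Q)
pqn_h_q <- function(v, p, Q) pqn_piece_q(v, p$a_hn, p$b_hn, p$c_hn, p$a_hp, p$b_hp, p$c_hp, p$r_h, Q)

#' Decompose a coefficient into signed right-shift terms
#'
#' Multiplication by a constant is realized in hardware as a sum of
#' right-shifted copies of the operand: a coefficient `c` is written as
#' \eqn{\sum_i \pm 2^{-k_i}}. For example `0.021484375 = 2^-6 + 2^-8 + 2^-9`,
#' giving shifts \{6, 8, 9\}. Shifts may be negative (left shifts) for
#' coefficient magnitudes of 2 or more.
#'
#' @param coef coefficient; must be exactly representable in `fmt`.
#' @param fmt an [fxp_format()].
#' @return an object of class `shift_add_plan`: a data.frame with columns
#'   `shift` (right-shift amount) and `sign` (+1/-1). Zero gives an empty
#'   plan.
#' @export
plan_shift_add <- function(coef, fmt = fxp_format()) {
  q <- fxp_quantize(coef, fmt)
  if (q != coef) {
    stop("coefficient ", coef, " is not representable in the ",
         fmt$total_bits, ".", fmt$frac_bits,
         " format; nearest representable value is ", q, call. = FALSE)
  }
  # binary expansion of the scaled integer: one shift per set bit
  k <- round(coef * fmt$scale)
  sgn <- if (k < 0) -1L else 1L
  k <- abs(k)
  shifts <- integer(0)
  pos <- 0L
  while (k != 0) {
    if (k %% 2 == 1) shifts <- c(shifts, fmt$frac_bits - pos)
    k <- k %/% 2
    pos <- pos + 1L
  }
  shifts <- sort(shifts)
  plan <- data.frame(shift = shifts,
                     sign = rep(sgn, length(shifts)))
  attr(plan, "coef") <- coef
  attr(plan, "fmt") <- fmt
  class(plan) <- c("shift_add_plan", "data.frame")
  plan
}

#' Apply a shift-add plan to a value
#'
#' Computes the constant multiplication as the signed sum of right-shifted
#' copies of `x`, then quantizes the result; equal to
#' `fxp_quantize(coef * x, fmt)` for `x` on the grid.
#'
#' @param plan a [plan_shift_add()] result.
#' @param x numeric vector (should be on the format grid).
#' @return numeric vector.
#' @export
apply_shift_add <- function(plan, x) {
  fmt <- attr(plan, "fmt")
  if (nrow(plan) == 0) return(rep(0, length(x)))
  acc <- 0
  for (i in seq_len(nrow(plan))) {
    acc <- acc + plan$sign[i] * x * 2^(-plan$shift[i])
  }
  fxp_quantize(acc, fmt)
}
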