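# Default PQN parameter sets per neuron class.
#
# All values are dimensionless model units on a 1 ms integration grid
# (time constants in seconds). The sets were hand-tuned to the qualitative
# electrophysiology of each class: repetitive spiking over a bounded input
# window for LNs, PNs, KCs, MBONs and SMP354 (the input transform m(I)
# saturates the drive below the depolarization-block point), a slow graded
# non-spiking response for APL, two-compartment soma filtering for PN, KC
# and MBON, and homeostatic synaptic scaling for PN. See the methods
# vignette for the tuning rationale.

spiking_axon_base <- function(variant, phi = 3, tau = 0.008, epsilon = 0.05,
                              I_b0 = 1.5, k_I = 1, m0 = -2, m1 = 2.5,
                              theta = NA, alpha_leak = NA, I_b1 = NA,
                              k_0 = NA, k_r = NA, kappa = NA, F_t = NA,
                              label = NULL) {
  pqn_params(tau = tau, phi = phi,
             epsilon = if (variant == "single") epsilon else 0,
             I_b0 = I_b0, k_I = k_I, m0 = m0, m1 = m1,
             a_fn = 1, b_fn = -1, c_fn = 0, a_fp = -1,
             a_gn = 0.25, b_gn = -4, c_gn = 0, a_gp = 0.25, r_g = 0,
             a_hn = 0, b_hn = 0, c_hn = 0, a_hp = 0.5, r_h = 0.5,
             variant = variant, theta = theta, alpha_leak = alpha_leak,
             I_b1 = I_b1, k_0 = k_0, k_r = k_r, kappa = kappa, F_t = F_t,
             label = label)
}

#' Default PQN parameter sets for every neuron class
#'
#' Returns the tuned parameter set of each modeled class: the four LN
#' subclasses, PN, KC, APL, the two MBONs, and SMP354. LNs, APL and SMP354
#' are single-compartment; PN, KC and MBONs are two-compartment; PN adds
#' homeostatic scaling of its synaptic drive. Individual entries can be
#' replaced to explore parameter changes; [run_simulation()] accepts any
#' named list with these elements.
#'
#' @return named list of [pqn_params()] objects with elements
#'   `Krasavietz_class1`, `Krasavietz_class2`, `NP1227_class1`,
#'   `NP2426_class1`, `PN`, `KC`, `APL`, `MBON_a1`, `MBON_a3`, `SMP354`.
#' @export
default_neuron_params <- function() {
  list(
    # LN subclasses: shared geometry, excitability ordered so that
    # NP2426_class1 is the most responsive oscillator and NP1227_class1 the
    # least (its inactivation barely changes PN oscillations).
    Krasavietz_class1 = spiking_axon_base("single", phi = 3, tau = 0.035,
                                          I_b0 = 1.3, k_I = 0.42, m1 = 4,
                                          label = "Krasavietz_class1"),
    Krasavietz_class2 = spiking_axon_base("single", phi = 2.5, tau = 0.035,
                                          I_b0 = 1.2, k_I = 0.42, m1 = 4,
                                          label = "Krasavietz_class2"),
    NP1227_class1 = spiking_axon_base("single", phi = 2, tau = 0.035,
                                      I_b0 = 1.1, k_I = 0.5, m1 = 4,
                                      label = "NP1227_class1"),
    NP2426_class1 = spiking_axon_base("single", phi = 3, tau = 0.035,
                                      I_b0 = 1.8, k_I = 1.0, m1 = 4,
                                      label = "NP2426_class1"),
    PN = spiking_axon_base("pn", phi = 3, tau = 0.012, I_b0 = 1.3, k_I = 0.35, m0 = -8,
                           m1 = 8, theta = 0.1, alpha_leak = 1, I_b1 = 0,
                           k_0 = 0.2, k_r = 1, kappa = 2.4e-5, F_t = 4,
                           label = "PN"),
    KC = spiking_axon_base("two_comp", phi = 3, I_b0 = 0.8, k_I = 1,
                           m0 = -4, m1 = 3.5, theta = 0.1, alpha_leak = 1,
                           I_b1 = 0, k_0 = 0.2, k_r = 1, label = "KC"),
    APL = pqn_params(tau = 0.1, phi = 0.4, epsilon = 0, I_b0 = 0.09,
                     k_I = 1, m0 = 0, m1 = 1.2,
                     a_fn = 0.25, b_fn = -1, c_fn = 0, a_fp = 0.25,
                     a_gn = 0.5, b_gn = -1, c_gn = 0, a_gp = 0.5, r_g = 0,
                     a_hn = 0, b_hn = 0, c_hn = 0, a_hp = 1, r_h = 0,
                     variant = "single", label = "APL"),
    MBON_a1 = spiking_axon_base("two_comp", phi = 3, I_b0 = 1.2, k_I = 1,
                                m0 = -4, m1 = 3, theta = 0.1, alpha_leak = 1,
                                I_b1 = 0, k_0 = 0.2, k_r = 1,
                                label = "MBON_a1"),
    MBON_a3 = spiking_axon_base("two_comp", phi = 3, I_b0 = 1.2, k_I = 1,
                                m0 = -4, m1 = 3, theta = 0.1, alpha_leak = 1,
                                I_b1 = 0, k_0 = 0.2, k_r = 1,
                                label = "MBON_a3"),
    SMP354 = spiking_axon_base("single", phi = 3, I_b0 = 1.1, k_I = 1,
                               m0 = -4, m1 = 3, label = "SMP354")
  )
}

# default class-pair synaptic scaling constants (sign = presynaptic
# polarity); the PN>KC value 1.03125 is the reference operating point,
# the rest are tuned at the network level.
default_scaling_values <- function() {
  c("ORN>PN" = 1.0, "ORN>LN" = 0.02,
    "LN>PN" = -0.3, "LN>LN" = -0.1,
    "PN>LN" = 1.0, "PN>KC" = 1.03125, "PN>APL" = 0.005,
    "KC>APL" = 0.05, "KC>MBON_a1" = 0.035, "KC>MBON_a3" = 0.035,
    "APL>KC" = -1.5, "APL>MBON_a1" = -1.0, "APL>MBON_a3" = -1.0,
    "MBON_a1>SMP354" = -8.0, "MBON_a3>SMP354" = 4.0)
}
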