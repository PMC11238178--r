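# Shared fixtures built in code.

# A well-behaved spiking single-compartment parameter set (repetitive firing
# for drives between about 1 and 3, stable rest below).
spiking_params <- function(variant = "single", ...) {
  pqn_params(tau = 0.008, phi = 3, epsilon = 0.05, I_b0 = 1.5, k_I = 1,
             m0 = -2, m1 = 2.5,
             a_fn = 1, b_fn = -1, c_fn = 0, a_fp = -1,
             a_gn = 0.25, b_gn = -4, c_gn = 0, a_gp = 0.25, r_g = 0,
             a_hn = 0, b_hn = 0, c_hn = 0, a_hp = 0.5, r_h = 0.5,
             variant = variant, ...)
}

two_comp_params <- function(theta = 0.1, alpha_leak = 1, I_b1 = 0,
                            k_0 = 0.2, k_r = 1, ...) {
  spiking_params(variant = "two_comp", theta = theta,
                 alpha_leak = alpha_leak, I_b1 = I_b1, k_0 = k_0,
                 k_r = k_r, ...)
}

# random valid parameter draws for property-style tests
random_pqn_params <- function() {
  nz <- function() sample(c(-1, 1), 1) * stats::runif(1, 0.1, 3)
  pqn_params(tau = stats::runif(1, 0.005, 0.05), phi = stats::runif(1, 0.5, 4),
             epsilon = stats::runif(1, 0, 0.2),
             I_b0 = stats::runif(1, -2, 2), k_I = stats::runif(1, 0.1, 2),
             m0 = stats::runif(1, -3, 0), m1 = stats::runif(1, 0, 3),
             a_fn = nz(), b_fn = stats::runif(1, -2, 2), c_fn = stats::runif(1, -1, 1),
             a_fp = nz(),
             a_gn = nz(), b_gn = stats::runif(1, -2, 2), c_gn = stats::runif(1, -1, 1),
             a_gp = nz(), r_g = stats::runif(1, -1, 1),
             a_hn = nz(), b_hn = stats::runif(1, -2, 2), c_hn = stats::runif(1, -1, 1),
             a_hp = nz(), r_h = stats::runif(1, -1, 1),
             variant = "single")
}

# a small synthetic network shared across network-level tests; cached per
# session to keep the suite fast
small_net_cache <- new.env(parent = emptyenv())

small_network <- function() {
  if (is.null(small_net_cache$net)) {
    withr::with_seed(101, {
      cfg <- synthetic_config(n_orn = 384, n_pn = 16, n_ln = 40, n_kc = 250,
                              n_glomeruli = 16)
      net <- generate_synthetic_topology(cfg)
      ort <- generate_synthetic_or_table(
        paste0("OR_", unique(net$neurons$glomerulus[net$neurons$class == "ORN"])),
        sparsity = 0.125, background = 0.15, weak_max = 0.15)
      sc <- rescale_scaling(scaling_table(), net)
    })
    small_net_cache$net <- list(net = net, or_table = ort, scaling = sc)
  }
  small_net_cache$net
}
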