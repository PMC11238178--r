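# Topology construction: connectome thresholding, LN subclass assignment,
# glomerular innervation, OR assignment, synthetic generator calibration.

test_that("connectome edges need more than ten synapses", {
  neurons <- neuron_table(c("a", "b", "c", "d"), c("ORN", "PN", "PN", "LN"),
                          glomerulus = c("DA1", "DA1", "G02", NA))
  edges <- data.frame(pre_id = c("a", "a", "a"),
                      post_id = c("b", "c", "b"),
                      synapse_count = c(11, 10, 0))
  W <- build_from_connectome(neurons, edges)
  expect_equal(W["a", "b"], 1) # 11 synapses: kept
  expect_equal(W["a", "c"], 0) # exactly 10: dropped (strictly more than ten)
  expect_equal(sum(W), 1)
})

test_that("connectome LN edges are ignored and unknown ids rejected", {
  neurons <- neuron_table(c("a", "b", "l"), c("ORN", "PN", "LN"))
  edges <- data.frame(pre_id = c("a", "l", "a"), post_id = c("l", "b", "b"),
                      synapse_count = c(50, 50, 50))
  W <- build_from_connectome(neurons, edges)
  expect_equal(sum(W[, "l"]) + sum(W["l", ]), 0)
  expect_equal(W["a", "b"], 1)
  bad <- data.frame(pre_id = "zz", post_id = "b", synapse_count = 20)
  expect_error(build_from_connectome(neurons, bad), "unknown neuron id")
})

test_that("connectome build is invariant to edge-table row order", {
  withr::with_seed(21, {
    neurons <- neuron_table(paste0("n", 1:20), rep(c("ORN", "PN"), 10))
    edges <- data.frame(pre_id = sample(neurons$id, 60, TRUE),
                        post_id = sample(neurons$id, 60, TRUE),
                        synapse_count = sample(0:30, 60, TRUE))
    W1 <- build_from_connectome(neurons, edges)
    W2 <- build_from_connectome(neurons, edges[sample(nrow(edges)), ])
    expect_equal(W1, W2)
  })
})

test_that("191 LNs split into 48/48/48/47 with NP2426_class1 shorted", {
  withr::with_seed(2, {
    labels <- assign_ln_subclasses(191)
    counts <- table(labels)
    expect_equal(unname(counts["NP2426_class1"]), 47)
    expect_equal(unname(counts["Krasavietz_class1"]), 48)
    expect_equal(unname(counts["Krasavietz_class2"]), 48)
    expect_equal(unname(counts["NP1227_class1"]), 48)
    # balanced splits
    expect_equal(sort(as.vector(table(assign_ln_subclasses(4)))), rep(1L, 4))
    expect_equal(sort(as.vector(table(assign_ln_subclasses(8)))), rep(2L, 4))
    expect_error(assign_ln_subclasses(3), "at least 4")
  })
})

test_that("innervation sampling follows the subclass probabilities", {
  gl <- c("DA1", "G02")
  probs <- default_innervation_probs(gl)
  expect_equal(probs["NP1227_class1", "DA1"], 0.75)
  withr::with_seed(4, {
    # probability 1 and 0 edge cases
    p10 <- matrix(c(1, 0), 1, 2, dimnames = list("NP2426_class1", gl))
    inn <- sample_ln_innervation(rep("NP2426_class1", 50), p10)
    expect_true(all(inn[, "DA1"]))
    expect_false(any(inn[, "G02"]))
    # the printed 75% recovered over many draws within binomial CI
    n <- 10000
    inn75 <- sample_ln_innervation(rep("NP1227_class1", n), probs)
    frac <- mean(inn75[, "DA1"])
    se <- sqrt(0.75 * 0.25 / n)
    expect_lt(abs(frac - 0.75), 3 * se)
  })
  expect_error(sample_ln_innervation("made_up_class", probs), "no innervation")
})

test_that("LN edges follow the shared-glomerulus rule", {
  neurons <- rbind(
    neuron_table(paste0("o", 1:3), "ORN", glomerulus = "DA1"),
    neuron_table(paste0("p", 1:2), "PN", glomerulus = "DA1"),
    neuron_table("p3", "PN", glomerulus = "G02"),
    neuron_table(c("l1", "l2"), "LN"))
  inn <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2,
                dimnames = list(c("l1", "l2"), c("DA1", "G02")))
  edges <- derive_ln_edges(inn, neurons)
  # l1 innervates DA1 only: 3 ORN->LN, 2 PN->LN, 2 LN->PN edges
  expect_equal(sum(edges$post_id == "l1" & grepl("^o", edges$pre_id)), 3)
  expect_equal(sum(edges$post_id == "l1" & grepl("^p", edges$pre_id)), 2)
  expect_equal(sum(edges$pre_id == "l1" & grepl("^p", edges$post_id)), 2)
  # l2 innervates nothing
  expect_equal(sum(edges$pre_id == "l2" | edges$post_id == "l2"), 0)
  # two LNs sharing a glomerulus gain reciprocal edges
  inn2 <- matrix(TRUE, 2, 1, dimnames = list(c("l1", "l2"), "DA1"))
  e2 <- derive_ln_edges(inn2, neurons)
  expect_true(any(e2$pre_id == "l1" & e2$post_id == "l2"))
  expect_true(any(e2$pre_id == "l2" & e2$post_id == "l1"))
  expect_false(any(e2$pre_id == e2$post_id))
})

test_that("OR assignment resolves multi-OR glomeruli by uniform choice", {
  neurons <- neuron_table(paste0("o", 1:400), "ORN",
                          glomerulus = rep(c("DA1", "G02"), each = 200))
  map <- list(DA1 = "Or67d", G02 = c("OrA", "OrB"))
  withr::with_seed(6, {
    out <- assign_or_types(neurons, map)
    expect_true(all(out$or_type[out$glomerulus == "DA1"] == "Or67d"))
    mix <- table(out$or_type[out$glomerulus == "G02"])
    expect_gt(min(mix), 60) # roughly 50/50 of 200
  })
  expect_error(assign_or_types(neurons, list(DA1 = "Or67d")), "G02")
  # determinism under a fixed seed
  a <- withr::with_seed(8, assign_or_types(neurons, map))
  b <- withr::with_seed(8, assign_or_types(neurons, map))
  expect_identical(a, b)
})

test_that("synthetic topology hits the printed connectivity averages", {
  withr::with_seed(31, {
    net <- generate_synthetic_topology(synthetic_config())
  })
  st <- topology_stats(net$W, net$neurons)
  g <- function(pre, post, col) st[[col]][st$pre_class == pre & st$post_class == post]
  # each PN receives input from about 24.0 ORNs; each ORN drives 1.6 PNs
  expect_equal(g("ORN", "PN", "mean_in"), 24.0, tolerance = 0.01)
  expect_equal(g("ORN", "PN", "mean_out"), 1.6, tolerance = 0.01)
  # each KC receives input from about 4.2 PNs
  expect_equal(g("PN", "KC", "mean_in"), 4.2, tolerance = 0.1)
  # each LN pools over a thousand ORNs and inhibits most PNs
  expect_gt(g("ORN", "LN", "mean_in"), 1000)
  expect_gt(g("LN", "PN", "mean_out"), 70)
  # every ORN projects to all PNs of its own glomerulus
  orn <- net$neurons[net$neurons$class == "ORN", ]
  pn <- net$neurons[net$neurons$class == "PN", ]
  some <- orn[sample(nrow(orn), 20), ]
  for (i in seq_len(nrow(some))) {
    targets <- colnames(net$W)[net$W[some$id[i], ] != 0]
    pn_targets <- intersect(targets, pn$id)
    expect_setequal(pn_targets, pn$id[pn$glomerulus == some$glomerulus[i]])
  }
  # APL is wired to and from the whole mushroom body
  expect_equal(g("KC", "APL", "mean_out"), 1)
  expect_equal(g("APL", "KC", "mean_in"), 1)
})

test_that("default class counts match the modeled system", {
  withr::with_seed(32, net <- generate_synthetic_topology(synthetic_config()))
  counts <- table(net$neurons$class)
  expect_equal(unname(counts["PN"]), 121L)
  expect_equal(unname(counts["LN"]), 191L)
  expect_equal(unname(counts["ORN"]), 1815L)
  expect_equal(unname(counts[c("APL", "MBON_a1", "MBON_a3", "SMP354")]),
               rep(1L, 4), ignore_attr = TRUE)
  subs <- table(net$neurons$ln_subclass)
  expect_equal(unname(subs["NP2426_class1"]), 47L)
})

test_that("infeasible synthetic configurations error out", {
  expect_error(synthetic_config(n_kc = 0), "KC")
  expect_error(synthetic_config(n_pn = 10, n_glomeruli = 20), "glomeruli")
})

test_that("topology is reproducible under a fixed seed", {
  cfg <- synthetic_config(n_orn = 60, n_pn = 10, n_ln = 8, n_kc = 30,
                          n_glomeruli = 5)
  a <- withr::with_seed(9, generate_synthetic_topology(cfg))
  b <- withr::with_seed(9, generate_synthetic_topology(cfg))
  expect_identical(a$W, b$W)
  expect_identical(a$neurons, b$neurons)
})

test_that("degree summaries are permutation-invariant and handle empty matrices", {
  withr::with_seed(12, {
    cfg <- synthetic_config(n_orn = 60, n_pn = 10, n_ln = 8, n_kc = 30,
                            n_glomeruli = 5)
    net <- generate_synthetic_topology(cfg)
    st1 <- topology_stats(net$W, net$neurons)
    perm <- sample(nrow(net$W))
    Wp <- net$W[perm, perm]
    np <- net$neurons[perm, ]
    st2 <- topology_stats(Wp, np)
    expect_equal(st1, st2)
  })
  ids <- c("x", "y")
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(2, 2), dimnames = list(ids, ids))
  st <- topology_stats(empty, neuron_table(ids, c("PN", "KC")))
  expect_equal(nrow(st), 0)
})

test_that("neuron/edge/weight tables round-trip through CSV", {
  withr::with_seed(14, {
    cfg <- synthetic_config(n_orn = 30, n_pn = 5, n_ln = 4, n_kc = 10,
                            n_glomeruli = 3)
    net <- generate_synthetic_topology(cfg)
  })
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_weight_csv(net$W, tmp)
  W2 <- read_weight_csv(tmp, net$neurons$id)
  expect_equal(as.matrix(net$W), as.matrix(W2), ignore_attr = TRUE)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(net$neurons, tmp2, row.names = FALSE)
  n2 <- read_neuron_table(tmp2)
  expect_equal(n2$id, net$neurons$id)
  expect_equal(n2$class, net$neurons$class)
})
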