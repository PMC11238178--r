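#' Neuron class and LN subclass names
#'
#' @return character vector of the neuron classes (`neuron_classes()`) or of
#'   the four electrophysiological LN subclasses (`ln_subclasses()`).
#' @export
neuron_classes <- function() {
  c("ORN", "PN", "LN", "KC", "APL", "MBON_a1", "MBON_a3", "SMP354")
}

#' @rdname neuron_classes
#' @export
ln_subclasses <- function() {
  c("Krasavietz_class1", "Krasavietz_class2", "NP1227_class1", "NP2426_class1")
}

#' Assemble a neuron table
#'
#' @param id character neuron identifiers (unique).
#' @param class neuron class, one of [neuron_classes()].
#' @param glomerulus glomerulus name for ORNs, PNs and (via innervation) LNs;
#'   `NA` otherwise.
#' @param ln_subclass LN subclass label (`NA` for non-LNs).
#' @param or_type olfactory receptor type (ORNs only).
#' @return a `data.frame` with one row per neuron.
#' @export
neuron_table <- function(id, class, glomerulus = NA_character_,
                         ln_subclass = NA_character_, or_type = NA_character_) {
  stopifnot(!anyDuplicated(id), all(class %in% neuron_classes()))
  data.frame(id = as.character(id), class = class,
             glomerulus = glomerulus, ln_subclass = ln_subclass,
             or_type = or_type, stringsAsFactors = FALSE)
}

#' Build a weight matrix from a connectome-style edge table
#'
#' Connections with more than ten synapses are assumed strong enough to
#' matter and get weight 1; all others are dropped (weight 0). Edges whose
#' presynaptic or postsynaptic neuron is an LN are ignored here: LN
#' connectivity is regenerated from glomerular innervation probabilities via
#' [sample_ln_innervation()] and [derive_ln_edges()].
#'
#' @param neurons a [neuron_table()].
#' @param edges a `data.frame` with columns `pre_id`, `post_id`,
#'   `synapse_count`.
#' @param threshold minimum synapse count, exclusive (default 10).
#' @return sparse pre x post weight matrix with neuron ids as dimnames.
#' @export
build_from_connectome <- function(neurons, edges, threshold = 10) {
  stopifnot(all(c("pre_id", "post_id", "synapse_count") %in% names(edges)),
            all(edges$synapse_count >= 0))
  unknown <- setdiff(unique(c(edges$pre_id, edges$post_id)), neurons$id)
  if (length(unknown)) {
    stop("edge table references unknown neuron id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  ln_ids <- neurons$id[neurons$class == "LN"]
  keep <- edges$synapse_count > threshold &
    !(edges$pre_id %in% ln_ids) & !(edges$post_id %in% ln_ids)
  edges <- edges[keep, , drop = FALSE]
  edge_list_to_matrix(edges[, c("pre_id", "post_id")], neurons$id)
}

edge_list_to_matrix <- function(edges, ids, weight = 1) {
  n <- length(ids)
  if (nrow(edges) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n), dimnames = list(ids, ids)))
  }
  i <- match(edges$pre_id, ids)
  j <- match(edges$post_id, ids)
  stopifnot(!anyNA(i), !anyNA(j))
  w <- if ("weight" %in% names(edges)) edges$weight else rep(weight, nrow(edges))
  m <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n),
                            dimnames = list(ids, ids))
  # duplicate edges collapse to weight 1, not sums
  m@x <- pmin(m@x, max(w))
  m
}

#' Assign the four LN subclasses as evenly as possible
#'
#' For 191 LNs the counts are 48 Krasavietz_class1, 48 Krasavietz_class2,
#' 48 NP1227_class1, and 47 NP2426_class1. In general, counts are the most
#' even split of `n_ln` over the four subclasses, with the shortfall taken
#' from NP2426_class1 first (then NP1227_class1, then Krasavietz_class2).
#' Which individual LN receives which label is a random permutation.
#'
#' @param n_ln number of LNs (at least 4).
#' @return character vector of subclass labels, length `n_ln`, in random
#'   order (uses the current RNG state).
#' @export
assign_ln_subclasses <- function(n_ln) {
  if (n_ln < 4) stop("need at least 4 LNs to cover the four subclasses", call. = FALSE)
  subs <- ln_subclasses()
  counts <- rep(ceiling(n_ln / 4), 4)
  excess <- sum(counts) - n_ln
  k <- 4L
  while (excess > 0) {
    counts[k] <- counts[k] - 1L
    k <- k - 1L
    excess <- excess - 1L
  }
  labels <- rep(subs, times = counts)
  sample(labels)
}

#' Default glomerular innervation probabilities (synthetic)
#'
#' Probability that an LN of each subclass innervates each glomerulus. The
#' measured probability table is summarized here by one value per subclass,
#' chosen so that (i) the NP1227_class1 x DA1 entry equals the printed 75%,
#' (ii) the subclass-average probability is about 0.74, reproducing the
#' reported mean LN in-degree (about 1337 ORNs of 1815) and out-degree
#' (about 91 PNs of 121), and (iii) NP2426_class1 innervates broadly while
#' NP1227_class1 is sparse, consistent with their reported roles in
#' antennal-lobe oscillations. This table is a synthetic stand-in; supply a
#' measured table via the `probs` arguments to override it.
#'
#' @param glomeruli character vector of glomerulus names (must contain
#'   `"DA1"` for the printed entry to apply).
#' @return numeric matrix, subclasses x glomeruli, entries in `[0, 1]`.
#' @export
default_innervation_probs <- function(glomeruli) {
  base <- c(Krasavietz_class1 = 0.80, Krasavietz_class2 = 0.75,
            NP1227_class1 = 0.45, NP2426_class1 = 0.95)
  m <- matrix(base, nrow = 4, ncol = length(glomeruli),
              dimnames = list(names(base), glomeruli))
  if ("DA1" %in% glomeruli) m["NP1227_class1", "DA1"] <- 0.75
  m
}

#' Sample which LN innervates which glomerulus
#'
#' Independent Bernoulli draw per (LN, glomerulus) with the innervation
#' probability of the LN's subclass.
#'
#' @param labels subclass label per LN (names become LN ids if present).
#' @param probs matrix of probabilities, subclasses x glomeruli.
#' @return logical matrix, LNs x glomeruli.
#' @export
sample_ln_innervation <- function(labels, probs) {
  missing_rows <- setdiff(unique(labels), rownames(probs))
  if (length(missing_rows)) {
    stop("no innervation probability row for subclass(es): ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  }
  if (any(probs < 0 | probs > 1)) {
    stop("innervation probabilities must lie in [0, 1]", call. = FALSE)
  }
  pm <- probs[labels, , drop = FALSE]
  draws <- matrix(stats::runif(length(pm)) < pm, nrow = nrow(pm))
  dimnames(draws) <- list(names(labels) %||% seq_along(labels), colnames(probs))
  draws
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive LN edges from shared glomerular innervation
#'
#' An ORN or PN synapses onto every LN innervating its glomerulus; the same
#' shared-glomerulus rule generates the LN's inhibitory output onto the PNs
#' of its glomeruli and reciprocal LN-LN edges between LNs sharing at least
#' one glomerulus (no self-edges).
#'
#' @param innervation logical matrix LNs x glomeruli with LN ids as rownames.
#' @param neurons a [neuron_table()] providing ORN/PN glomeruli.
#' @return a `data.frame` of edges (`pre_id`, `post_id`).
#' @export
derive_ln_edges <- function(innervation, neurons) {
  ln_ids <- rownames(innervation)
  orn <- neurons[neurons$class == "ORN", ]
  pn <- neurons[neurons$class == "PN", ]
  pre <- character(0); post <- character(0)
  for (g in colnames(innervation)) {
    lns_g <- ln_ids[innervation[, g]]
    if (!length(lns_g)) next
    orn_g <- orn$id[orn$glomerulus == g]
    pn_g <- pn$id[pn$glomerulus == g]
    if (length(orn_g)) {
      pre <- c(pre, rep(orn_g, each = length(lns_g)))
      post <- c(post, rep(lns_g, times = length(orn_g)))
    }
    if (length(pn_g)) {
      pre <- c(pre, rep(pn_g, each = length(lns_g)),
               rep(lns_g, times = length(pn_g)))
      post <- c(post, rep(lns_g, times = length(pn_g)),
                rep(pn_g, each = length(lns_g)))
    }
    if (length(lns_g) > 1) {
      pairs <- expand.grid(a = lns_g, b = lns_g, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$b, ]
      pre <- c(pre, pairs$a)
      post <- c(post, pairs$b)
    }
  }
  unique(data.frame(pre_id = pre, post_id = post, stringsAsFactors = FALSE))
}

#' Assign an olfactory receptor type to every ORN
#'
#' Uses a glomerulus-to-OR correspondence map; when a glomerulus maps to
#' several ORs, one is chosen uniformly at random per ORN.
#'
#' @param neurons a [neuron_table()].
#' @param glom_or_map named list: glomerulus name -> character vector of OR
#'   types.
#' @return `neurons` with the `or_type` column filled for ORNs.
#' @export
assign_or_types <- function(neurons, glom_or_map) {
  is_orn <- neurons$class == "ORN"
  gloms <- neurons$glomerulus[is_orn]
  unmapped <- setdiff(unique(gloms), names(glom_or_map))
  if (length(unmapped)) {
    stop("no OR mapping for glomerulus/glomeruli: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (any(!lengths(glom_or_map[unique(gloms)]))) {
    stop("empty OR list for a mapped glomerulus", call. = FALSE)
  }
  neurons$or_type[is_orn] <- vapply(gloms, function(g) {
    ors <- glom_or_map[[g]]
    if (length(ors) == 1) ors else sample(ors, 1)
  }, character(1))
  neurons
}

#' Configuration for the synthetic topology generator
#'
#' Defaults reproduce the modeled olfactory system: 1815 ORNs, 121 PNs,
#' 191 LNs, 1884 KCs (bringing the modeled-neuron total to about 2,200),
#' one APL, one MBON-alpha1, one MBON-alpha3, one SMP354, and 51 glomeruli.
#' `pn_in_degree` (mean ORNs per PN, 24.0) and `kc_in_degree` (mean PNs per
#' KC, 4.2) are the calibration targets of the generator.
#'
#' @param n_orn,n_pn,n_ln,n_kc,n_glomeruli population sizes.
#' @param pn_in_degree target mean number of ORN inputs per PN.
#' @param kc_in_degree target mean number of PN inputs per KC.
#' @return a named list.
#' @export
synthetic_config <- function(n_orn = 1815, n_pn = 121, n_ln = 191,
                             n_kc = 1884, n_glomeruli = 51,
                             pn_in_degree = 24.0, kc_in_degree = 4.2) {
  if (n_kc < 1) stop("need at least one KC", call. = FALSE)
  if (n_glomeruli > n_pn) {
    stop("infeasible counts: more glomeruli than PNs", call. = FALSE)
  }
  if (n_orn < n_glomeruli) {
    stop("infeasible counts: fewer ORNs than glomeruli", call. = FALSE)
  }
  list(n_orn = n_orn, n_pn = n_pn, n_ln = n_ln, n_kc = n_kc,
       n_glomeruli = n_glomeruli, pn_in_degree = pn_in_degree,
       kc_in_degree = kc_in_degree)
}

glomerulus_names <- function(n) {
  c("DA1", sprintf("G%02d", seq_len(n))[-1])[seq_len(n)]
}

# Allocate PNs and ORNs to glomeruli so that (i) every glomerulus has >= 1
# PN, (ii) each ORN projects to all PNs of its glomerulus, and (iii) the
# resulting mean ORN-input count per PN matches the target. Works by placing
# extra PNs on a tail group of glomeruli and solving for how many ORNs sit
# on single-PN glomeruli.
allocate_glomeruli <- function(cfg) {
  n_g <- cfg$n_glomeruli
  npn <- rep(1L, n_g)
  leftover <- cfg$n_pn - n_g
  # extra PNs go to a tail group of glomeruli so single-PN glomeruli remain
  # available for the ORN-allocation calibration below
  tail_n <- max(1L, min(n_g - 1L, ceiling(n_g * 0.4)))
  tail_set <- seq(n_g - tail_n + 1L, n_g)
  k_pos <- 1L
  while (leftover > 0) {
    npn[tail_set[k_pos]] <- npn[tail_set[k_pos]] + 1L
    k_pos <- if (k_pos == tail_n) 1L else k_pos + 1L
    leftover <- leftover - 1L
  }
  target_edges <- round(cfg$n_pn * cfg$pn_in_degree)
  A <- which(npn == 1L)
  B <- which(npn > 1L)
  norn <- rep(1L, n_g)
  rest <- cfg$n_orn - n_g
  if (!length(B)) {
    # every glomerulus has one PN: out-degree forced to 1
    norn <- norn + diff_round(rest * rep(1 / n_g, n_g))
  } else {
    mB <- mean(npn[B])
    xA <- (cfg$n_orn * mB - target_edges) / (mB - 1)
    xA <- min(max(xA, length(A)), cfg$n_orn - length(B))
    extraA <- diff_round((xA - length(A)) * rep(1 / length(A), length(A)))
    extraB <- diff_round((cfg$n_orn - xA - length(B)) * rep(1 / length(B), length(B)))
    norn[A] <- norn[A] + extraA
    norn[B] <- norn[B] + extraB
  }
  list(glomeruli = glomerulus_names(n_g), n_pn_per_glom = npn,
       n_orn_per_glom = norn)
}

# round a vector of nonnegative reals to integers preserving the total
diff_round <- function(x) {
  f <- floor(x)
  need <- round(sum(x)) - sum(f)
  if (need > 0) {
    idx <- order(x - f, decreasing = TRUE)[seq_len(need)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

#' Generate a calibrated synthetic olfactory-network topology
#'
#' Stands in for a connectome export. Construction rules: every ORN projects
#' to all PNs of its glomerulus (glomerular sizes are solved so the mean
#' ORN-input count per PN hits `pn_in_degree`); each KC independently draws
#' its PN inputs with in-degree ~ Binomial(n_pn, `kc_in_degree`/n_pn),
#' minimum 1; LN wiring follows [assign_ln_subclasses()],
#' [sample_ln_innervation()] and [derive_ln_edges()]; APL receives from all
#' KCs and PNs and inhibits all KCs and both MBONs; every KC excites both
#' MBONs; MBON-alpha3 (excitatory) and MBON-alpha1 (inhibitory) converge on
#' SMP354.
#'
#' @param cfg a [synthetic_config()].
#' @param probs innervation probability matrix (default
#'   [default_innervation_probs()]).
#' @param glom_or_map glomerulus-to-OR map (default: one OR per glomerulus,
#'   named after it).
#' @return a list with elements `neurons` (a [neuron_table()]) and `W`
#'   (sparse pre x post weight matrix). Uses the current RNG state; seed with
#'   `set.seed()` for reproducibility.
#' @export
generate_synthetic_topology <- function(cfg = synthetic_config(),
                                        probs = NULL, glom_or_map = NULL) {
  alloc <- allocate_glomeruli(cfg)
  gl <- alloc$glomeruli
  orn_glom <- rep(gl, times = alloc$n_orn_per_glom)
  pn_glom <- rep(gl, times = alloc$n_pn_per_glom)
  ids <- list(
    orn = sprintf("ORN_%04d", seq_len(cfg$n_orn)),
    pn = sprintf("PN_%03d", seq_len(cfg$n_pn)),
    ln = sprintf("LN_%03d", seq_len(cfg$n_ln)),
    kc = sprintf("KC_%04d", seq_len(cfg$n_kc))
  )
  neurons <- rbind(
    neuron_table(ids$orn, "ORN", glomerulus = orn_glom),
    neuron_table(ids$pn, "PN", glomerulus = pn_glom),
    neuron_table(ids$ln, "LN"),
    neuron_table(ids$kc, "KC"),
    neuron_table("APL", "APL"),
    neuron_table("MBON_a1", "MBON_a1"),
    neuron_table("MBON_a3", "MBON_a3"),
    neuron_table("SMP354", "SMP354")
  )
  labels <- assign_ln_subclasses(cfg$n_ln)
  names(labels) <- ids$ln
  neurons$ln_subclass[match(ids$ln, neurons$id)] <- labels
  if (is.null(glom_or_map)) {
    glom_or_map <- stats::setNames(as.list(paste0("OR_", gl)), gl)
  }
  neurons <- assign_or_types(neurons, glom_or_map)
  if (is.null(probs)) probs <- default_innervation_probs(gl)

  # ORN -> PN: all PNs of the ORN's glomerulus
  orn_pn <- do.call(rbind, lapply(gl, function(g) {
    o <- ids$orn[orn_glom == g]; p <- ids$pn[pn_glom == g]
    if (!length(o) || !length(p)) return(NULL)
    expand.grid(pre_id = o, post_id = p, stringsAsFactors = FALSE)
  }))
  # PN -> KC: random in-degree, minimum 1
  kc_deg <- pmax(stats::rbinom(cfg$n_kc, cfg$n_pn, cfg$kc_in_degree / cfg$n_pn), 1L)
  pn_kc <- data.frame(
    pre_id = unlist(lapply(kc_deg, function(d) sample(ids$pn, d))),
    post_id = rep(ids$kc, times = kc_deg), stringsAsFactors = FALSE)
  # LN wiring from glomerular innervation
  innervation <- sample_ln_innervation(labels, probs)
  ln_edges <- derive_ln_edges(innervation, neurons)
  # mushroom body
  mb <- rbind(
    data.frame(pre_id = ids$kc, post_id = "APL", stringsAsFactors = FALSE),
    data.frame(pre_id = ids$pn, post_id = "APL", stringsAsFactors = FALSE),
    data.frame(pre_id = "APL", post_id = ids$kc, stringsAsFactors = FALSE),
    data.frame(pre_id = "APL", post_id = c("MBON_a1", "MBON_a3"),
               stringsAsFactors = FALSE),
    data.frame(pre_id = ids$kc, post_id = "MBON_a1", stringsAsFactors = FALSE),
    data.frame(pre_id = ids$kc, post_id = "MBON_a3", stringsAsFactors = FALSE),
    data.frame(pre_id = c("MBON_a1", "MBON_a3"), post_id = "SMP354",
               stringsAsFactors = FALSE)
  )
  edges <- rbind(orn_pn, pn_kc, ln_edges, mb)
  W <- edge_list_to_matrix(edges, neurons$id)
  list(neurons = neurons, W = W, innervation = innervation)
}

#' Degree summary per class pair
#'
#' Mean in- and out-degrees for every (presynaptic class, postsynaptic
#' class) pair present in the weight matrix. Invariant under neuron
#' relabeling.
#'
#' @param W sparse pre x post weight matrix.
#' @param neurons matching [neuron_table()].
#' @return a `data.frame` with columns `pre_class`, `post_class`, `n_edges`,
#'   `mean_out` (edges per presynaptic neuron of that class) and `mean_in`
#'   (edges per postsynaptic neuron of that class).
#' @export
topology_stats <- function(W, neurons) {
  cls <- neurons$class[match(rownames(W), neurons$id)]
  idx <- Matrix::which(W != 0, arr.ind = TRUE)
  pre_cls <- cls[idx[, 1]]
  post_cls <- cls[idx[, 2]]
  n_by_class <- table(cls)
  pairs <- unique(data.frame(pre_class = pre_cls, post_class = post_cls,
                             stringsAsFactors = FALSE))
  if (nrow(pairs) == 0) {
    return(data.frame(pre_class = character(0), post_class = character(0),
                      n_edges = integer(0), mean_out = numeric(0),
                      mean_in = numeric(0)))
  }
  pairs <- pairs[order(pairs$pre_class, pairs$post_class), , drop = FALSE]
  pairs$n_edges <- mapply(function(a, b) sum(pre_cls == a & post_cls == b),
                          pairs$pre_class, pairs$post_class)
  pairs$mean_out <- pairs$n_edges / as.numeric(n_by_class[pairs$pre_class])
  pairs$mean_in <- pairs$n_edges / as.numeric(n_by_class[pairs$post_class])
  rownames(pairs) <- NULL
  pairs
}
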