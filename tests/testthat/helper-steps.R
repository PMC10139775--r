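# Shared fixtures: a small configuration and parameter set so tests run in
# seconds. All fixtures are generated in code; nothing is read from disk.

small_cfg <- function(...) {
  steps_config(
    list(
      hidden_dim = 8L, layers = 2L,
      rbf = list(n_centers = 4L, gamma = 10),
      seq_encoder = list(type = "standin", dim = 5L, window = 5L),
      binning = list(T = 30L, d_min = 2, d_max = 20),
      train = list(
        epochs_pretrain = 2L, epochs_finetune = 5L, batch_size = 4L, seed = 0L,
        lr_finetune = 1e-4, adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8
      )
    ),
    ...
  )
}

small_graphs <- function(n = 3, len = c(6, 10), classes = 3, seed = 1,
                         cfg = small_cfg()) {
  ds <- make_toy_dataset(n, len, class_count = classes, seed = seed)
  lapply(ds$structures, build_residue_graph, threshold = cfg$threshold)
}

# zero out every numeric in a parameter structure (uniform predictors)
par_zero <- function(p) {
  if (is.list(p)) {
    out <- lapply(p, par_zero)
    attributes(out) <- attributes(p)
    out
  } else {
    p * 0
  }
}

# random rigid motion (proper rotation + translation), seeded
random_rigid <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(p, rt) as.vector(rt$R %*% p + rt$t)

# a hand-built minimal residue graph (bypasses build_residue_graph) for
# toy message-passing checks: n nodes, given adjacency and dihedral table
fake_graph <- function(A, phi = NULL, psi = NULL, sequence = NULL) {
  L <- nrow(A)
  dih <- list(
    phi = phi %||% rep(0, L), psi = psi %||% rep(0, L),
    phi_valid = c(FALSE, rep(TRUE, L - 1)),
    psi_valid = c(rep(TRUE, L - 1), FALSE)
  )
  class(dih) <- "dihedral_table"
  structure(
    list(
      n_nodes = L, distance_matrix = ifelse(A > 0, 1 / sqrt(A), 0),
      edges = which(upper.tri(A) & A > 0, arr.ind = TRUE),
      edge_weight = A[upper.tri(A) & A > 0],
      adjacency = A, dihedrals = dih,
      sequence = paste(rep("A", L), collapse = ""), id = "fake"
    ),
    class = "residue_graph"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
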