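# Self-supervised objectives: pairwise distance-bin classification and masked
# dihedral-angle regression, plus their joint loss.

#' Sample the set of angle-masked residues
#'
#' Draws `max(1, round(fraction * L))` residues uniformly without replacement
#' from the residues whose phi AND psi are both defined (termini and
#' chain-break neighbours are never maskable), capped at the number of such
#' residues. Deterministic given the seed.
#'
#' @param g A [build_residue_graph()] result.
#' @param fraction Masking fraction; default 0.15.
#' @param seed Integer RNG seed.
#' @return List of class `mask_spec` with `masked` (integer node indices,
#'   1-based), `fraction`, `seed`.
#' @export
sample_mask <- function(g, fraction = 0.15, seed = 0L) {
  valid <- which(g$dihedrals$phi_valid & g$dihedrals$psi_valid)
  if (!length(valid)) {
    cond <- structure(
      class = c("steps_skip_protein", "error", "condition"),
      list(message = "no residue with both dihedrals defined; protein skipped for the angle task", call = NULL)
    )
    stop(cond)
  }
  m_target <- max(1L, round(fraction * g$n_nodes))
  m <- min(length(valid), m_target)
  masked <- with_seed(seed, sort(valid[sample.int(length(valid), m)]))
  structure(list(masked = masked, fraction = fraction, seed = seed), class = "mask_spec")
}

#' Initialize the two prediction heads (parameter group alpha)
#'
#' Both heads are two fully connected layers with a ReLU in the middle: the
#' distance head maps `hidden -> hidden -> T` logits, the angle head
#' `hidden -> hidden -> 2` (normalized phi, psi). A single-output regression
#' head for the distance-as-regression ablation is included.
#'
#' @param hidden_dim Hidden width (input to both heads).
#' @param T Number of distance classes.
#' @param seed RNG seed.
#' @return Nested list `list(dis, ang, reg)`, each `list(W1, b1, W2, b2)`.
#' @export
init_head_params <- function(hidden_dim, T = 30L, seed = 0L) {
  with_seed(seed + 2L, {
    mk <- function(nout) {
      list(
        W1 = glorot(hidden_dim, hidden_dim), b1 = numeric(hidden_dim),
        W2 = glorot(hidden_dim, nout), b2 = numeric(nout)
      )
    }
    list(dis = mk(T), ang = mk(2L), reg = mk(1L))
  })
}

head_apply <- function(h, head) {
  z <- ad_relu(ad_add_bias(ad_mm(h, head$W1), head$b1))
  ad_add_bias(ad_mm(z, head$W2), head$b2)
}

#' Predicted distance-bin distribution for a residue pair
#'
#' Applies the distance head to the representation difference `h_i - h_j` and
#' softmaxes the logits into a distribution over the T bins.
#'
#' @param h_i,h_j Hidden vectors (length `hidden_dim`).
#' @param heads [init_head_params()] structure.
#' @return Numeric probability vector of length T (sums to 1).
#' @export
distance_logits <- function(h_i, h_j, heads) {
  u <- matrix(as.numeric(h_i) - as.numeric(h_j), nrow = 1)
  if (ncol(u) != nrow(heads$dis$W1)) stop("distance_logits: dimension mismatch", call. = FALSE)
  z <- ad_value(head_apply(u, heads$dis))
  e <- exp(z - max(z))
  as.vector(e / sum(e))
}

# ordered off-diagonal index pairs of 1..L
ordered_pairs <- function(L) {
  ii <- rep(seq_len(L), each = L)
  jj <- rep(seq_len(L), times = L)
  keep <- ii != jj
  cbind(ii[keep], jj[keep])
}

#' Distance-classification loss for one protein
#'
#' Mean cross-entropy of the predicted bin distribution against the binned
#' true C-alpha distance, over all ordered residue pairs i != j (the
#' degenerate diagonal pairs are excluded, so the normalizer is L^2 - L).
#'
#' @param h L x hidden node representations (numeric or autodiff node).
#' @param D L x L distance matrix (angstrom).
#' @param b A [distance_binning()].
#' @param heads [init_head_params()] structure (numeric or leaves).
#' @return Scalar loss (node if inputs are nodes).
#' @export
distance_loss <- function(h, D, b, heads) {
  L <- nrow(D)
  if (L < 2) stop("distance_loss: need at least 2 residues", call. = FALSE)
  pr <- ordered_pairs(L)
  labels <- bin_distance(D[pr], b) + 1L
  U <- ad_sub(ad_rows(h, pr[, 1]), ad_rows(h, pr[, 2]))
  logits <- head_apply(U, heads$dis)
  ad_softmax_ce(logits, labels)
}

#' Distance regression loss (ablation variant)
#'
#' Single-output head on `h_i - h_j`, mean squared error against the raw
#' distance d_ij over all ordered pairs i != j.
#'
#' @inheritParams distance_loss
#' @return Scalar loss (node if inputs are nodes).
#' @export
distance_loss_regression <- function(h, D, heads) {
  L <- nrow(D)
  if (L < 2) stop("distance_loss_regression: need at least 2 residues", call. = FALSE)
  pr <- ordered_pairs(L)
  U <- ad_sub(ad_rows(h, pr[, 1]), ad_rows(h, pr[, 2]))
  pred <- head_apply(U, heads$reg)
  err <- ad_sub(pred, matrix(D[pr], ncol = 1))
  ad_mean(ad_hadamard(err, err))
}

#' Predict the masked dihedral pair for one residue
#'
#' @param h_i Hidden vector of an angle-masked residue.
#' @param heads [init_head_params()] structure.
#' @return Numeric length-2 vector `(phi_bar, psi_bar)` on the normalized
#'   `[-1, 1]` scale (unconstrained outputs).
#' @export
angle_prediction <- function(h_i, heads) {
  u <- matrix(as.numeric(h_i), nrow = 1)
  if (ncol(u) != nrow(heads$ang$W1)) stop("angle_prediction: dimension mismatch", call. = FALSE)
  as.vector(ad_value(head_apply(u, heads$ang)))
}

#' Masked-angle reconstruction loss
#'
#' Sum over the masked set of the squared errors of both normalized angles:
#' `sum_i (phi_i - phi_bar_i)^2 + (psi_i - psi_bar_i)^2` (a sum, not a mean).
#'
#' @param predictions |M| x 2 matrix (numeric or node).
#' @param truths |M| x 2 matrix of normalized true angles.
#' @return Scalar loss (node if `predictions` is one).
#' @export
angle_loss <- function(predictions, truths) {
  if (!identical(dim(ad_value(predictions)), dim(truths))) {
    stop("angle_loss: prediction/truth shapes differ", call. = FALSE)
  }
  err <- ad_sub(predictions, truths)
  ad_sum(ad_hadamard(err, err))
}

# Full forward pass for one protein: sequence encoding, masked node features,
# GNN, fusion. Returns representations needed by every objective.
protein_forward <- function(g, params, cfg, mask = NULL) {
  rbf <- rbf_spec(cfg$rbf$n_centers, cfg$rbf$gamma)
  h_raw <- seq_encode(g$sequence, params$theta, id = g$id)
  X <- init_node_features(g, h_raw, mask = mask, rbf = rbf)
  gnn <- gnn_forward(g, X, params$omega)
  h_s <- project_seq(h_raw, params$theta)
  list(
    h_raw = h_raw, h_s = h_s,
    h_node = gnn$node, h_graph = gnn$graph,
    h_fused = fuse(h_s, gnn$node)
  )
}

# normalized (phi, psi) truth rows for the masked residues
masked_angle_truths <- function(g, mask) {
  cbind(
    normalize_angle(g$dihedrals$phi[mask$masked]),
    normalize_angle(g$dihedrals$psi[mask$masked])
  )
}

#' Joint self-supervised loss over a batch of proteins
#'
#' One masked forward pass per protein feeds both objectives: the distance
#' task sees the angle-masked node features (edge weights intact) and the
#' angle head reads the fused representations of the masked residues. Each
#' loss is averaged over the batch's proteins and the total is their sum;
#' ablation flags in `cfg$ablations` zero out either term or switch the
#' distance task to regression. Proteins with no maskable residue contribute
#' only to the distance term.
#'
#' @param graphs List of [build_residue_graph()] results.
#' @param params List with parameter groups `theta`, `omega`, `alpha`
#'   (numeric or autodiff leaves).
#' @param cfg A [steps_config()].
#' @param masks Optional list of [sample_mask()] results (one per protein);
#'   sampled with `seed` when `NULL`.
#' @param seed Seed for mask sampling when `masks` is `NULL`.
#' @return List with scalar `l_dis`, `l_angle`, `total` (nodes if params are
#'   leaves) and the `masks` used.
#' @export
ssl_loss <- function(graphs, params, cfg = steps_config(), masks = NULL, seed = 0L) {
  if (!length(graphs)) stop("ssl_loss: empty batch", call. = FALSE)
  b <- distance_binning(cfg$binning$T, cfg$binning$d_min, cfg$binning$d_max)
  if (is.null(masks)) {
    masks <- lapply(seq_along(graphs), function(i) {
      tryCatch(
        sample_mask(graphs[[i]], cfg$mask_fraction, seed = seed + i),
        steps_skip_protein = function(c) NULL
      )
    })
  }
  dis_terms <- list()
  ang_terms <- list()
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    fw <- protein_forward(g, params, cfg, mask = masks[[i]])
    if (!cfg$ablations$no_distance) {
      dis_terms[[length(dis_terms) + 1L]] <- if (cfg$ablations$distance_regression) {
        distance_loss_regression(fw$h_fused, g$distance_matrix, params$alpha)
      } else {
        distance_loss(fw$h_fused, g$distance_matrix, b, params$alpha)
      }
    }
    if (!cfg$ablations$no_angle && !is.null(masks[[i]])) {
      hm <- ad_rows(fw$h_fused, masks[[i]]$masked)
      pred <- head_apply(hm, params$alpha$ang)
      ang_terms[[length(ang_terms) + 1L]] <-
        angle_loss(pred, masked_angle_truths(g, masks[[i]]))
    }
  }
  mean_terms <- function(terms) {
    if (!length(terms)) return(0)
    acc <- terms[[1]]
    for (t in terms[-1]) acc <- ad_add(acc, t)
    ad_scale(acc, 1 / length(terms))
  }
  l_dis <- mean_terms(dis_terms)
  l_angle <- mean_terms(ang_terms)
  total <- ad_add(l_dis, l_angle)
  list(l_dis = l_dis, l_angle = l_angle, total = total, masks = masks)
}

#' Held-out metrics for the self-supervised tasks
#'
#' Runs the same masked forward pass as training on each protein and reports
#' (i) the fraction of ordered residue pairs whose argmax predicted distance
#' bin equals the true bin and (ii) the mean squared error of the masked
#' normalized angle predictions (mean over masked residues and both angles).
#'
#' @param graphs List of [build_residue_graph()] results.
#' @param params List with groups `theta`, `omega`, `alpha` (numeric).
#' @param cfg A [steps_config()].
#' @param seed Seed for mask sampling.
#' @return List with `dis_accuracy` and `angle_mse`.
#' @export
ssl_metrics <- function(graphs, params, cfg = steps_config(), seed = 0L) {
  b <- distance_binning(cfg$binning$T, cfg$binning$d_min, cfg$binning$d_max)
  n_ok <- 0
  n_pairs <- 0
  sse <- 0
  n_ang <- 0
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    mask <- tryCatch(sample_mask(g, cfg$mask_fraction, seed = seed + i),
      steps_skip_protein = function(c) NULL
    )
    fw <- protein_forward(g, params, cfg, mask = mask)
    pr <- ordered_pairs(g$n_nodes)
    labels <- bin_distance(g$distance_matrix[pr], b) + 1L
    U <- fw$h_fused[pr[, 1], , drop = FALSE] - fw$h_fused[pr[, 2], , drop = FALSE]
    logits <- head_apply(U, params$alpha$dis)
    n_ok <- n_ok + sum(max.col(logits, ties.method = "first") == labels)
    n_pairs <- n_pairs + length(labels)
    if (!is.null(mask)) {
      pred <- head_apply(fw$h_fused[mask$masked, , drop = FALSE], params$alpha$ang)
      err <- pred - masked_angle_truths(g, mask)
      sse <- sse + sum(err^2)
      n_ang <- n_ang + length(err)
    }
  }
  list(
    dis_accuracy = n_ok / n_pairs,
    angle_mse = if (n_ang) sse / n_ang else NA_real_
  )
}
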