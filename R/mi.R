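# Jensen-Shannon mutual information between sequence- and structure-level
# protein representations, and the pseudo bi-level coupling: the sequence
# encoder (theta) is perturbed by one inner gradient-ascent step on I for the
# outer gradient computation, but never persisted.

#' Initialize the MI discriminator (parameter group beta)
#'
#' Two towers (sequence side and structure side), each a three-layered fully
#' connected network with skip connections and ReLU activations; the score
#' T_beta is the dot product of the two tower outputs.
#'
#' @param hidden_dim Width of the protein-level representations.
#' @param seed RNG seed.
#' @return Nested list `list(seq = ..., str = ...)` of layer weights.
#' @export
init_discriminator <- function(hidden_dim, seed = 0L) {
  with_seed(seed + 3L, {
    mk <- function() {
      list(
        W1 = glorot(hidden_dim, hidden_dim), b1 = numeric(hidden_dim),
        W2 = glorot(hidden_dim, hidden_dim), b2 = numeric(hidden_dim),
        W3 = glorot(hidden_dim, hidden_dim), b3 = numeric(hidden_dim)
      )
    }
    list(seq = mk(), str = mk())
  })
}

tower_apply <- function(x, tw) {
  z1 <- ad_relu(ad_add_bias(ad_mm(x, tw$W1), tw$b1))
  z2 <- ad_add(ad_relu(ad_add_bias(ad_mm(z1, tw$W2), tw$b2)), z1)
  ad_add(ad_add_bias(ad_mm(z2, tw$W3), tw$b3), z2)
}

#' Discriminator scores for paired protein-level representations
#'
#' @param S,G B x hidden matrices of sequence-side / structure-side vectors.
#' @param beta [init_discriminator()] structure (numeric or leaves).
#' @return B x 1 matrix of scalar scores (node if inputs are nodes).
#' @export
discriminator_score <- function(S, G, beta) {
  ad_rowdot(tower_apply(S, beta$seq), tower_apply(G, beta$str))
}

#' Protein-level sequence and structure representations
#'
#' For each protein: `s_x` is the mean over residues of the projected
#' sequence representation and `g_x` is the GNN mean readout. Computed on the
#' unmasked structure.
#'
#' @param graphs List of [build_residue_graph()] results.
#' @param params List with groups `theta` and `omega` (numeric or leaves).
#' @param cfg A [steps_config()].
#' @return List with `S` and `G`, B x hidden matrices (nodes if params are
#'   leaves), rows in batch order.
#' @export
protein_level_reps <- function(graphs, params, cfg = steps_config()) {
  if (!length(graphs)) stop("protein_level_reps: empty batch", call. = FALSE)
  srows <- vector("list", length(graphs))
  grows <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    fw <- protein_forward(graphs[[i]], params, cfg, mask = NULL)
    srows[[i]] <- ad_colmeans(fw$h_s)
    grows[[i]] <- fw$h_graph
  }
  list(S = ad_rbind(srows), G = ad_rbind(grows))
}

# seeded derangement (permutation with no fixed point) for negative pairing
sample_derangement <- function(n, seed = 0L) {
  if (n < 2) stop("derangement requires n >= 2", call. = FALSE)
  with_seed(seed, {
    repeat {
      p <- sample.int(n)
      if (all(p != seq_len(n))) return(p)
    }
  })
}

#' Jensen-Shannon mutual-information estimate for a batch
#'
#' `I = E[-sp(-T(s_x, g_x))] - E[sp(T(s_x, g_xtilde))]` with `sp` the
#' softplus; positives pair each protein's sequence vector with its own
#' structure vector, negatives pair it with a different protein's structure
#' vector via a seeded within-batch derangement. A zero discriminator gives
#' exactly `-2 log 2`.
#'
#' @param graphs List of at least two [build_residue_graph()] results.
#' @param params List with groups `theta`, `omega`, `beta` (numeric or leaves).
#' @param cfg A [steps_config()].
#' @param seed Seed for the negative-sampling derangement.
#' @return Scalar estimate (node if params are leaves).
#' @export
mi_estimate <- function(graphs, params, cfg = steps_config(), seed = 0L) {
  if (length(graphs) < 2) {
    stop("mi_estimate: need a batch of >= 2 proteins for negative pairs", call. = FALSE)
  }
  reps <- protein_level_reps(graphs, params, cfg)
  perm <- sample_derangement(length(graphs), seed)
  pos <- discriminator_score(reps$S, reps$G, params$beta)
  neg <- discriminator_score(reps$S, ad_rows(reps$G, perm), params$beta)
  ad_sub(
    ad_scale(ad_mean(ad_softplus(ad_scale(pos, -1))), -1),
    ad_mean(ad_softplus(neg))
  )
}

# gradients of I with respect to every group; returns value and grads
mi_grads <- function(theta, omega, beta, graphs, cfg, seed,
                     wrt = c("theta", "omega", "beta")) {
  groups <- list(theta = theta, omega = omega, beta = beta)
  leaves <- groups
  for (nm in wrt) leaves[[nm]] <- params_to_leaves(groups[[nm]])
  node <- mi_estimate(graphs, leaves, cfg, seed = seed)
  ad_backward(node)
  out <- list(value = ad_value(node))
  for (nm in wrt) out[[nm]] <- leaves_grads(leaves[[nm]])
  out
}

#' One inner gradient-ascent step on the sequence encoder
#'
#' Computes `theta(omega) = theta + eta * dI/dtheta` on the given batch. The
#' returned perturbed copy is used only to evaluate the outer objective;
#' `theta` itself is never modified (the pseudo contract).
#'
#' @param theta,omega,beta Parameter groups (numeric).
#' @param graphs Batch of residue graphs (>= 2).
#' @param eta Inner learning rate (>= 0); default from `cfg`.
#' @param cfg A [steps_config()].
#' @param seed Negative-sampling seed.
#' @return List with `theta_new` (the perturbed copy), `grad_theta`, `mi`
#'   (the estimate at the unperturbed theta).
#' @export
inner_step <- function(theta, omega, beta, graphs, eta = NULL,
                       cfg = steps_config(), seed = 0L) {
  if (is.null(eta)) eta <- cfg$bilevel$inner_lr
  if (eta < 0) stop("inner_step: eta must be >= 0", call. = FALSE)
  g <- mi_grads(theta, omega, beta, graphs, cfg, seed, wrt = "theta")
  list(
    theta_new = par_axpy(theta, g$theta, eta),
    grad_theta = g$theta,
    mi = g$value
  )
}

# gradients of the joint SSL loss at given parameter values
ssl_grads <- function(theta, omega, alpha, graphs, cfg, masks,
                      wrt = c("theta", "omega", "alpha")) {
  leaves <- list(theta = theta, omega = omega, alpha = alpha)
  for (nm in wrt) leaves[[nm]] <- params_to_leaves(leaves[[nm]])
  ls <- ssl_loss(graphs, leaves, cfg, masks = masks)
  ad_backward(ls$total)
  out <- list(
    l_dis = ad_value(ls$l_dis), l_angle = ad_value(ls$l_angle),
    total = ad_value(ls$total)
  )
  for (nm in wrt) out[[nm]] <- leaves_grads(leaves[[nm]])
  out
}

#' One outer optimization step of the pseudo bi-level scheme
#'
#' Computes the gradients that the pretraining loop feeds to Adam:
#' * mode `"off"` (or MI disabled, or a singleton batch): plain gradients of
#'   the joint SSL loss at the unperturbed theta.
#' * mode `"first_order"`: the loss is evaluated at the perturbed
#'   `theta(omega)` but the perturbation is treated as constant in omega.
#' * mode `"second_order"` (default): adds the mixed second-derivative term
#'   `eta * d2I/(domega dtheta) . dL/dtheta`, obtained with a central
#'   finite-difference Hessian-vector product.
#'
#' The discriminator gradient ascends I. `theta` is returned untouched and is
#' byte-identical before and after.
#'
#' @param params List of groups `theta`, `omega`, `alpha`, `beta`.
#' @param graphs Batch of residue graphs.
#' @param cfg A [steps_config()].
#' @param masks Optional mask list (sampled from `seed` when `NULL`).
#' @param seed Seed for mask sampling and negative pairing.
#' @return List with `grads` (`omega`, `alpha`, `beta`; `beta` is `NULL`
#'   when MI is off), `logs` (`l_dis`, `l_angle`, `total`, `mi`), and the
#'   untouched `theta`.
#' @export
outer_step <- function(params, graphs, cfg = steps_config(), masks = NULL, seed = 0L) {
  if (is.null(masks)) {
    masks <- lapply(seq_along(graphs), function(i) {
      tryCatch(sample_mask(graphs[[i]], cfg$mask_fraction, seed = seed + i),
        steps_skip_protein = function(c) NULL
      )
    })
  }
  mode <- cfg$bilevel$mode
  use_mi <- isTRUE(cfg$mi$enabled) && length(graphs) >= 2
  mi_val <- NA_real_
  grad_beta <- NULL
  theta_eval <- params$theta
  gI <- NULL
  if (use_mi) {
    gI <- mi_grads(params$theta, params$omega, params$beta, graphs, cfg, seed,
      wrt = if (mode == "second_order") c("theta", "omega", "beta") else c("theta", "beta")
    )
    mi_val <- gI$value
    grad_beta <- par_map2(gI$beta, gI$beta, function(x, y) -x) # ascend I
    if (mode != "off") {
      theta_eval <- par_axpy(params$theta, gI$theta, cfg$bilevel$inner_lr)
    }
  }
  gL <- ssl_grads(theta_eval, params$omega, params$alpha, graphs, cfg, masks,
    wrt = c("theta", "omega", "alpha")
  )
  grad_omega <- gL$omega
  if (use_mi && mode == "second_order") {
    # finite-difference Hessian-vector product for the mixed term
    v <- gL$theta
    vn <- sqrt(sum(par_flatten(v)^2))
    if (vn > 0) {
      eps <- cfg$bilevel$fd_eps / max(1, vn)
      gp <- mi_grads(par_axpy(params$theta, v, eps), params$omega, params$beta,
        graphs, cfg, seed, wrt = "omega"
      )
      gm <- mi_grads(par_axpy(params$theta, v, -eps), params$omega, params$beta,
        graphs, cfg, seed, wrt = "omega"
      )
      hvp <- par_map2(gp$omega, gm$omega, function(a, b) (a - b) / (2 * eps))
      grad_omega <- par_axpy(grad_omega, hvp, cfg$bilevel$inner_lr)
    }
  }
  if (!all(is.finite(par_flatten(grad_omega))) ||
      !all(is.finite(par_flatten(gL$alpha)))) {
    stop("outer_step: non-finite gradient; aborting step", call. = FALSE)
  }
  list(
    grads = list(omega = grad_omega, alpha = gL$alpha, beta = grad_beta),
    logs = list(l_dis = gL$l_dis, l_angle = gL$l_angle, total = gL$total, mi = mi_val),
    theta = params$theta
  )
}
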