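# Node features, the edge-weighted GNN, and the pluggable sequence encoder.

#' Radial basis function specification
#'
#' `n_centers` Gaussian kernels with centers evenly spaced on `[-1, 1]` and
#' shape parameter `gamma`, used to expand normalized scalar angles into
#' feature vectors.
#'
#' @param n_centers Number of centers (>= 2); default 16.
#' @param gamma Kernel shape (> 0); default 10.
#' @return An object of class `rbf_spec`.
#' @export
rbf_spec <- function(n_centers = 16L, gamma = 10.0) {
  if (n_centers < 2) stop("rbf_spec: n_centers must be >= 2", call. = FALSE)
  if (gamma <= 0) stop("rbf_spec: gamma must be > 0", call. = FALSE)
  structure(
    list(
      n_centers = as.integer(n_centers), gamma = gamma,
      centers = seq(-1, 1, length.out = n_centers)
    ),
    class = "rbf_spec"
  )
}

#' Expand a normalized scalar through Gaussian radial basis functions
#'
#' Component j equals `exp(-gamma * (x - u_j)^2)`; all components lie in
#' `(0, 1]` and component j reaches 1 exactly at its center.
#'
#' @param x Numeric scalar or vector (normally in `[-1, 1]`).
#' @param spec An [rbf_spec()].
#' @return For scalar `x` a numeric vector of length `n_centers`; otherwise a
#'   `length(x) x n_centers` matrix.
#' @export
rbf_expand <- function(x, spec = rbf_spec()) {
  out <- exp(-spec$gamma * outer(x, spec$centers, "-")^2)
  if (length(x) == 1) as.vector(out) else out
}

#' Normalize an angle in radians to `(-1, 1]`
#'
#' @param angle Radians in `(-pi, pi]`.
#' @return `angle / pi`.
#' @export
normalize_angle <- function(angle) {
  tol <- 1e-9
  if (any(angle <= -pi - tol | angle > pi + tol, na.rm = TRUE)) {
    stop("normalize_angle: angle must lie in (-pi, pi]", call. = FALSE)
  }
  angle / pi
}

#' Assemble initial node features
#'
#' Per-node feature `X_v = [seq_emb || RBF(phi/pi) || RBF(psi/pi) || mask]`.
#' Residues in the mask have both RBF blocks zeroed and mask flag 1 (their
#' sequence embedding is untouched); residues whose phi or psi is undefined
#' (termini, chain breaks) get a zero block for that angle with flag 0, so the
#' flag channel distinguishes "masked" from "undefined".
#'
#' @param g A [build_residue_graph()] result.
#' @param seq_emb L x E matrix of per-residue sequence embeddings (numeric or
#'   autodiff node).
#' @param mask A [sample_mask()] result or `NULL` for no masking.
#' @param rbf An [rbf_spec()].
#' @return L x (E + 2 n_centers + 1) feature matrix (node if `seq_emb` is one).
#' @export
init_node_features <- function(g, seq_emb, mask = NULL, rbf = rbf_spec()) {
  L <- g$n_nodes
  if (nrow(ad_value(seq_emb)) != L) {
    stop("init_node_features: seq_emb rows must equal the node count", call. = FALSE)
  }
  dh <- g$dihedrals
  C <- rbf$n_centers
  phi_block <- matrix(0, L, C)
  psi_block <- matrix(0, L, C)
  ok_phi <- which(dh$phi_valid)
  ok_psi <- which(dh$psi_valid)
  if (length(ok_phi)) phi_block[ok_phi, ] <- rbf_expand(normalize_angle(dh$phi[ok_phi]), rbf)
  if (length(ok_psi)) psi_block[ok_psi, ] <- rbf_expand(normalize_angle(dh$psi[ok_psi]), rbf)
  flag <- matrix(0, L, 1)
  if (!is.null(mask) && length(mask$masked)) {
    phi_block[mask$masked, ] <- 0
    psi_block[mask$masked, ] <- 0
    flag[mask$masked, 1] <- 1
  }
  ad_cbind(seq_emb, phi_block, psi_block, flag)
}

#' Dimensionality of the node feature vector
#' @param cfg A [steps_config()].
#' @return Integer input dimension `E_seq + 2 n_centers + 1`.
#' @export
node_feature_dim <- function(cfg) {
  as.integer(cfg$seq_encoder$dim + 2L * cfg$rbf$n_centers + 1L)
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize GNN parameters (parameter group omega)
#'
#' Layer 1 maps the raw feature dimension to `hidden_dim`; later layers are
#' `hidden_dim` to `hidden_dim`. Each layer is a single linear map (the
#' COMBINE step); there is no nonlinearity between layers by default.
#'
#' @param input_dim Raw node-feature dimension.
#' @param hidden_dim Hidden width.
#' @param layers Number of message-passing layers K (>= 1).
#' @param seed RNG seed.
#' @return Nested list `list(layers = list(list(W, b), ...))`.
#' @export
init_gnn_params <- function(input_dim, hidden_dim, layers = 2L, seed = 0L) {
  with_seed(seed, {
    dims <- c(input_dim, rep(hidden_dim, layers))
    list(layers = lapply(seq_len(layers), function(k) {
      list(W = glorot(dims[k], dims[k + 1]), b = numeric(dims[k + 1]))
    }))
  })
}

#' Edge-weighted GNN forward pass
#'
#' Message passing with sum aggregation weighted by the inverse-square
#' distance edge features: `a_i = sum_{v in N(i)} e_iv h_v`, followed by the
#' linear COMBINE `h_i <- W_k (h_i + a_i) + b_k` at each layer (no activation
#' unless `activation = TRUE`). The graph representation is the mean over the
#' final-layer node representations.
#'
#' @param g A [build_residue_graph()] result.
#' @param X Node features from [init_node_features()] (numeric or node).
#' @param params [init_gnn_params()] structure (numeric or leaves).
#' @param activation If TRUE apply ReLU between layers; default FALSE.
#' @return List with `node` (L x hidden) and `graph` (1 x hidden mean readout).
#' @export
gnn_forward <- function(g, X, params, activation = FALSE) {
  if (nrow(ad_value(X)) != g$n_nodes) {
    stop("gnn_forward: feature rows must equal the node count", call. = FALSE)
  }
  A <- g$adjacency
  h <- X
  nl <- length(params$layers)
  for (k in seq_len(nl)) {
    ly <- params$layers[[k]]
    if (ncol(ad_value(h)) != nrow(ad_value(ly$W))) {
      stop("gnn_forward: feature/parameter dimension mismatch at layer ", k, call. = FALSE)
    }
    z <- ad_add(h, ad_mm(A, h))
    h <- ad_add_bias(ad_mm(z, ly$W), ly$b)
    if (activation && k < nl) h <- ad_relu(h)
  }
  list(node = h, graph = ad_colmeans(h))
}

# --- sequence encoder (parameter group theta) ------------------------------

# Symmetric sliding-window averaging operator, truncated and renormalized at
# the chain ends; fixed (non-trainable) mixing for the stand-in encoder.
smoothing_matrix <- function(L, window = 5L) {
  half <- (window - 1L) %/% 2L
  S <- matrix(0, L, L)
  for (i in seq_len(L)) {
    lo <- max(1L, i - half)
    hi <- min(L, i + half)
    S[i, lo:hi] <- 1 / (hi - lo + 1L)
  }
  S
}

#' Initialize the stand-in sequence encoder (parameter group theta)
#'
#' The stand-in protein language model is a learned per-amino-acid embedding
#' table followed by a fixed symmetric 5-residue sliding-window average, plus
#' a linear projection from the embedding dimension to the hidden dimension.
#' It is deliberately lightweight: the framework treats the sequence encoder
#' as a pluggable component whose parameters merely need to be differentiable
#' (externally precomputed embeddings can be swapped in instead).
#'
#' @param cfg A [steps_config()].
#' @param seed RNG seed.
#' @param embeddings Optional named list of precomputed L x E matrices keyed
#'   by protein id (external mode; the embedding table is then unused).
#' @return Nested list `list(embed, proj = list(W, b))` with attribute `type`.
#' @export
init_seq_encoder <- function(cfg, seed = 0L, embeddings = NULL) {
  E <- cfg$seq_encoder$dim
  H <- cfg$hidden_dim
  p <- with_seed(seed + 1L, {
    list(
      embed = glorot(length(AA21), E),
      proj = list(W = glorot(E, H), b = numeric(H))
    )
  })
  attr(p, "type") <- if (is.null(embeddings)) "standin" else "external"
  attr(p, "window") <- cfg$seq_encoder$window
  attr(p, "embeddings") <- embeddings
  p
}

#' Per-residue sequence embeddings
#'
#' Stand-in mode: embedding-table lookup followed by the fixed sliding-window
#' average. External mode: returns the precomputed embedding for `id`. The raw
#' (pre-projection) output feeds the node features; [project_seq()] maps it to
#' the hidden dimension for fusion.
#'
#' @param sequence One-letter amino-acid string.
#' @param params [init_seq_encoder()] structure (numeric or leaves).
#' @param id Protein id (required in external mode).
#' @return L x E matrix (autodiff node if `params$embed` is a leaf).
#' @export
seq_encode <- function(sequence, params, id = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% AA21)) {
    stop("seq_encode: sequence contains illegal characters", call. = FALSE)
  }
  if (identical(attr(params, "type"), "external")) {
    embs <- attr(params, "embeddings")
    if (is.null(id) || is.null(embs[[id]])) {
      stop("seq_encode: no external embedding for protein id ", id %||% "<missing>", call. = FALSE)
    }
    emb <- embs[[id]]
    if (nrow(emb) != length(chars)) {
      stop("seq_encode: external embedding length does not match the sequence", call. = FALSE)
    }
    return(emb)
  }
  idx <- match(chars, AA21)
  S <- smoothing_matrix(length(chars), attr(params, "window") %||% 5L)
  ad_mm(S, ad_rows(params$embed, idx))
}

#' Project raw sequence embeddings to the hidden dimension
#' @param h_raw L x E matrix from [seq_encode()].
#' @param params [init_seq_encoder()] structure.
#' @return L x hidden matrix.
#' @export
project_seq <- function(h_raw, params) {
  ad_add_bias(ad_mm(h_raw, params$proj$W), params$proj$b)
}

#' Fuse sequence and structure representations
#'
#' Elementwise sum `h_i = h_i^s + h_i^(K)` of the projected sequence
#' representation and the final GNN node representation.
#'
#' @param h_s,h_k L x hidden matrices (numeric or nodes).
#' @return Their elementwise sum.
#' @export
fuse <- function(h_s, h_k) {
  if (!identical(dim(ad_value(h_s)), dim(ad_value(h_k)))) {
    stop("fuse: representations must have identical shapes", call. = FALSE)
  }
  ad_add(h_s, h_k)
}

#' Load external per-residue embeddings from a TSV file
#'
#' Expected columns: `protein_id` then one numeric column per embedding
#' dimension; one row per residue, rows of a protein contiguous and in
#' residue order.
#'
#' @param path TSV path.
#' @return Named list of L x E matrices keyed by protein id.
#' @export
load_embeddings_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"protein_id" %in% names(df)) {
    stop("load_embeddings_tsv: file must have a protein_id column", call. = FALSE)
  }
  ids <- df$protein_id
  vals <- as.matrix(df[setdiff(names(df), "protein_id")])
  lapply(split(seq_len(nrow(df)), factor(ids, levels = unique(ids))), function(rr) {
    unname(vals[rr, , drop = FALSE])
  })
}
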