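# Pretraining loop, finetuning harness, checkpointing, logging.

#' Cosine learning-rate decay
#'
#' `lr(step) = lr0 * (1 + cos(pi * step / total)) / 2`: `lr(0) = lr0` and the
#' rate reaches exactly 0 after a full cycle (`step = total`). The training
#' loops evaluate it at the number of completed steps, so the first step runs
#' at `lr0` and the last at a small positive rate.
#'
#' @param step Completed steps (0-based).
#' @param total Total steps in the schedule.
#' @param lr0 Initial learning rate.
#' @return The decayed learning rate.
#' @export
cosine_lr <- function(step, total, lr0) {
  lr0 * 0.5 * (1 + cos(pi * pmin(step, total) / total))
}

#' Initialize all four parameter groups
#'
#' @param cfg A [steps_config()].
#' @param seed Master RNG seed (sub-seeds are derived per group).
#' @param embeddings Optional external embeddings (see [init_seq_encoder()]).
#' @return List with groups `theta` (sequence encoder), `omega` (GNN),
#'   `alpha` (prediction heads), `beta` (MI discriminator).
#' @export
init_steps_params <- function(cfg = steps_config(), seed = 0L, embeddings = NULL) {
  list(
    theta = init_seq_encoder(cfg, seed, embeddings = embeddings),
    omega = init_gnn_params(node_feature_dim(cfg), cfg$hidden_dim, cfg$layers, seed),
    alpha = init_head_params(cfg$hidden_dim, cfg$binning$T, seed),
    beta = init_discriminator(cfg$hidden_dim, seed)
  )
}

adam_init <- function(params) {
  n <- length(par_flatten(params))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  g <- par_flatten(grads)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  x <- par_flatten(params) - lr * mhat / (sqrt(vhat) + eps)
  list(params = par_unflatten(x, params), state = state)
}

derive_seed <- function(seed, epoch, batch) {
  as.integer((as.numeric(seed) * 7919 + epoch * 104729 + batch * 1299709) %% 2^30)
}

log_record <- function(con, rec) {
  if (!is.null(con)) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
}

#' Pretrain the structure encoder with the joint self-supervised objective
#'
#' Runs the pseudo bi-level loop: per batch, one [outer_step()] computes the
#' gradients of the joint SSL loss (through the perturbed sequence encoder
#' when bi-level coupling is on) and Adam updates the persistent groups
#' (omega, alpha, beta) under a cosine-decayed learning rate. The sequence
#' encoder theta is frozen throughout. Deterministic given the seed.
#'
#' @param dataset A `steps_dataset` or plain list of [protein_structure()].
#' @param cfg A [steps_config()].
#' @param params Optional initial parameter groups; default
#'   [init_steps_params()] from `cfg$train$seed`.
#' @param epochs Number of epochs; default `cfg$train$epochs_pretrain`.
#' @param log_path Optional path for a JSON-lines per-step log.
#' @param verbose Print one line per epoch.
#' @return A `steps_checkpoint`: parameter groups, config, epoch count and a
#'   per-step `history` data frame (epoch, step, lr, l_dis, l_angle, total, mi).
#' @export
pretrain <- function(dataset, cfg = steps_config(), params = NULL,
                     epochs = NULL, log_path = NULL, verbose = FALSE) {
  structures <- if (inherits(dataset, "steps_dataset")) dataset$structures else dataset
  if (!length(structures)) stop("pretrain: empty dataset", call. = FALSE)
  if (is.null(epochs)) epochs <- cfg$train$epochs_pretrain
  seed <- cfg$train$seed
  if (is.null(params)) params <- init_steps_params(cfg, seed)
  theta0 <- params$theta
  graphs <- lapply(structures, build_residue_graph, threshold = cfg$threshold)
  n <- length(graphs)
  bs <- max(1L, min(cfg$train$batch_size, n))
  n_batches <- ceiling(n / bs)
  total_steps <- epochs * n_batches
  opt <- list(
    omega = adam_init(params$omega),
    alpha = adam_init(params$alpha),
    beta = adam_init(params$beta)
  )
  con <- if (!is.null(log_path)) file(log_path, open = "wt") else NULL
  on.exit(if (!is.null(con)) close(con))
  history <- vector("list", total_steps)
  done <- 0L
  last_good <- params
  b1 <- cfg$train$adam_beta1
  b2 <- cfg$train$adam_beta2
  ae <- cfg$train$adam_eps
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, epoch, 0L), sample.int(n))
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * bs + 1L):min(bi * bs, n)]
      lr <- cosine_lr(done, total_steps, cfg$bilevel$outer_lr)
      step_seed <- derive_seed(seed, epoch, bi)
      st <- tryCatch(
        outer_step(params, graphs[idx], cfg, seed = step_seed),
        error = function(e) e
      )
      if (inherits(st, "error")) {
        warning("pretrain: step failed (", conditionMessage(st),
          "); returning last good checkpoint",
          call. = FALSE
        )
        params <- last_good
        history <- history[seq_len(done)]
        return(make_checkpoint(params, cfg, epoch - 1L, do.call(rbind, history)))
      }
      up <- adam_step(params$omega, st$grads$omega, opt$omega, lr, b1, b2, ae)
      params$omega <- up$params
      opt$omega <- up$state
      up <- adam_step(params$alpha, st$grads$alpha, opt$alpha, lr, b1, b2, ae)
      params$alpha <- up$params
      opt$alpha <- up$state
      if (!is.null(st$grads$beta)) {
        up <- adam_step(params$beta, st$grads$beta, opt$beta, lr, b1, b2, ae)
        params$beta <- up$params
        opt$beta <- up$state
      }
      params$theta <- st$theta # untouched by construction
      done <- done + 1L
      rec <- data.frame(
        epoch = epoch, step = done, lr = lr,
        l_dis = st$logs$l_dis, l_angle = st$logs$l_angle,
        total = st$logs$total, mi = st$logs$mi
      )
      history[[done]] <- rec
      log_record(con, as.list(rec))
    }
    last_good <- params
    if (verbose) {
      ep <- do.call(rbind, history[(done - n_batches + 1L):done])
      message(sprintf(
        "epoch %d: l_dis %.4f l_angle %.4f mi %.4f",
        epoch, mean(ep$l_dis), mean(ep$l_angle), mean(ep$mi)
      ))
    }
  }
  stopifnot(identical(params$theta, theta0)) # the pseudo contract
  make_checkpoint(params, cfg, epochs, do.call(rbind, history))
}

make_checkpoint <- function(params, cfg, epoch, history) {
  structure(
    list(
      omega = params$omega, alpha = params$alpha, beta = params$beta,
      theta = params$theta, cfg = cfg, epoch = epoch, history = history
    ),
    class = "steps_checkpoint"
  )
}

#' @export
print.steps_checkpoint <- function(x, ...) {
  cat(sprintf(
    "<steps_checkpoint> %d epoch(s), hidden_dim %d, %d GNN layer(s)\n",
    x$epoch, x$cfg$hidden_dim, x$cfg$layers
  ))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Checkpoints are written with [saveRDS()] so a reload reproduces forward
#' passes bit-identically on the same platform.
#'
#' @param ckpt A `steps_checkpoint`.
#' @param path File path.
#' @return `path` invisibly / the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "steps_checkpoint")) stop("not a steps checkpoint: ", path, call. = FALSE)
  ckpt
}

# classification loss/grads for finetuning: linear head over mean-pooled
# fused residue representations
classify_forward <- function(graphs, theta, omega, head, cfg) {
  rows <- lapply(graphs, function(g) {
    fw <- protein_forward(g, list(theta = theta, omega = omega), cfg, mask = NULL)
    ad_colmeans(fw$h_fused)
  })
  R <- ad_rbind(rows)
  ad_add_bias(ad_mm(R, head$W), head$b)
}

#' Finetune a pretrained checkpoint for protein-level classification
#'
#' Attaches a purely linear head over the mean-pooled fused residue
#' representations and trains with Adam under cosine decay (initial rate
#' `cfg$train$lr_finetune`, `cfg$train$epochs_finetune` epochs). `mode
#' = "full"` finetunes the GNN (omega) together with the head; `mode =
#' "head_only"` freezes omega. The sequence encoder theta is frozen in both
#' modes.
#'
#' @param ckpt A `steps_checkpoint`.
#' @param dataset A `steps_dataset` (or list of structures) with `labels`.
#' @param labels Integer labels in `[0, C)`; defaults to `dataset$labels`.
#' @param mode `"full"` or `"head_only"`.
#' @param n_classes Number of classes C; default `max(labels) + 1`.
#' @param epochs,seed Optional overrides of the config values.
#' @return A `steps_classifier`: `head`, `omega`, `theta`, `cfg`, `mode`,
#'   `n_classes`, and the per-step loss `history`.
#' @export
finetune <- function(ckpt, dataset, labels = NULL, mode = c("full", "head_only"),
                     n_classes = NULL, epochs = NULL, seed = NULL) {
  mode <- match.arg(mode)
  cfg <- ckpt$cfg
  structures <- if (inherits(dataset, "steps_dataset")) dataset$structures else dataset
  if (is.null(labels)) labels <- dataset$labels
  if (length(labels) != length(structures)) {
    stop("finetune: one label per protein required", call. = FALSE)
  }
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  if (any(labels < 0 | labels >= n_classes)) {
    stop("finetune: labels must lie in [0, n_classes)", call. = FALSE)
  }
  if (is.null(epochs)) epochs <- cfg$train$epochs_finetune
  if (is.null(seed)) seed <- cfg$train$seed
  graphs <- lapply(structures, build_residue_graph, threshold = cfg$threshold)
  # zero-initialized linear probe: argmax is then driven by learned signal
  # rather than a random projection
  head <- list(W = matrix(0, cfg$hidden_dim, n_classes), b = numeric(n_classes))
  omega <- ckpt$omega
  n <- length(graphs)
  bs <- max(1L, min(cfg$train$batch_size, n))
  n_batches <- ceiling(n / bs)
  total_steps <- epochs * n_batches
  opt_head <- adam_init(head)
  opt_omega <- adam_init(omega)
  history <- numeric(0)
  done <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, epoch, 0L) + 1L, sample.int(n))
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * bs + 1L):min(bi * bs, n)]
      lr <- cosine_lr(done, total_steps, cfg$train$lr_finetune)
      head_l <- params_to_leaves(head)
      omega_l <- if (mode == "full") params_to_leaves(omega) else omega
      logits <- classify_forward(graphs[idx], ckpt$theta, omega_l, head_l, cfg)
      loss <- ad_softmax_ce(logits, labels[idx] + 1L)
      ad_backward(loss)
      up <- adam_step(head, leaves_grads(head_l), opt_head, lr,
        cfg$train$adam_beta1, cfg$train$adam_beta2, cfg$train$adam_eps
      )
      head <- up$params
      opt_head <- up$state
      if (mode == "full") {
        up <- adam_step(omega, leaves_grads(omega_l), opt_omega, lr,
          cfg$train$adam_beta1, cfg$train$adam_beta2, cfg$train$adam_eps
        )
        omega <- up$params
        opt_omega <- up$state
      }
      done <- done + 1L
      history[done] <- ad_value(loss)
    }
  }
  structure(
    list(
      head = head, omega = omega, theta = ckpt$theta, cfg = cfg,
      mode = mode, n_classes = n_classes, history = history
    ),
    class = "steps_classifier"
  )
}

#' Predict class probabilities for protein structures
#'
#' @param classifier A `steps_classifier` from [finetune()].
#' @param structures List of [protein_structure()] (or a `steps_dataset`).
#' @return List with `prob` (B x C matrix) and `label` (argmax, 0-based).
#' @export
steps_predict <- function(classifier, structures) {
  if (inherits(structures, "steps_dataset")) structures <- structures$structures
  cfg <- classifier$cfg
  graphs <- lapply(structures, build_residue_graph, threshold = cfg$threshold)
  logits <- classify_forward(graphs, classifier$theta, classifier$omega, classifier$head, cfg)
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  list(prob = p, label = max.col(p, ties.method = "first") - 1L)
}

#' Mean classification accuracy on a labelled dataset
#'
#' @param classifier A `steps_classifier`.
#' @param dataset A `steps_dataset` (or list of structures).
#' @param labels Integer labels; default `dataset$labels`.
#' @return Fraction of argmax-correct predictions.
#' @export
evaluate <- function(classifier, dataset, labels = NULL) {
  structures <- if (inherits(dataset, "steps_dataset")) dataset$structures else dataset
  if (is.null(labels)) labels <- dataset$labels
  if (!length(structures)) stop("evaluate: empty dataset", call. = FALSE)
  pred <- steps_predict(classifier, structures)
  mean(pred$label == labels)
}
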