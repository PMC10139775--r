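# Nested configuration with full-scale defaults.

#' Default configuration
#'
#' Returns the full nested configuration, optionally overridden by a nested
#' list (as from [read_config()]) and/or `...` top-level entries. Defaults:
#' hidden dimension 1280, 2 GNN layers, 7 angstrom contact threshold, 30
#' distance bins over 2-20 angstrom, 16 RBF centers with gamma 10, 15% angle
#' masking, Adam (beta1 0.9, beta2 0.999) with cosine learning-rate decay,
#' outer learning rate 1e-3, inner (sequence-encoder perturbation) rate 5e-5,
#' finetune rate 1e-4, 10 pretrain / 5 finetune epochs, batch size 8.
#'
#' @param overrides Nested list merged over the defaults.
#' @param ... Named top-level overrides merged last.
#' @return A nested list of class `steps_config`.
#' @export
steps_config <- function(overrides = list(), ...) {
  cfg <- list(
    hidden_dim = 1280L,
    layers = 2L,
    threshold = 7.0,
    binning = list(T = 30L, d_min = 2.0, d_max = 20.0),
    rbf = list(n_centers = 16L, gamma = 10.0),
    seq_encoder = list(type = "standin", dim = 32L, window = 5L),
    mask_fraction = 0.15,
    ablations = list(no_angle = FALSE, no_distance = FALSE, distance_regression = FALSE),
    mi = list(enabled = TRUE),
    bilevel = list(mode = "second_order", inner_lr = 5e-5, outer_lr = 1e-3, fd_eps = 1e-3),
    train = list(
      epochs_pretrain = 10L, epochs_finetune = 5L,
      lr_finetune = 1e-4, batch_size = 8L,
      adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8,
      seed = 0L
    )
  )
  cfg <- utils::modifyList(cfg, overrides)
  cfg <- utils::modifyList(cfg, list(...))
  stopifnot(
    cfg$hidden_dim >= 1, cfg$layers >= 1, cfg$threshold >= 0,
    cfg$bilevel$mode %in% c("second_order", "first_order", "off"),
    cfg$bilevel$inner_lr >= 0, cfg$bilevel$outer_lr > 0,
    cfg$mask_fraction > 0, cfg$mask_fraction <= 1
  )
  class(cfg) <- c("steps_config", "list")
  cfg
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected at the top level; the result is merged over
#' [steps_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `steps_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_config requires the 'yaml' package", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known <- names(steps_config())
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  steps_config(raw)
}
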