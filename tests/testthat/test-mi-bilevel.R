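test_that("protein-level representations: pooling and invariances", {
  cfg <- small_cfg()
  graphs <- small_graphs(2, c(6, 8), classes = 2, seed = 1, cfg = cfg)
  params <- init_steps_params(cfg, seed = 1)
  reps <- protein_level_reps(graphs, params, cfg)
  expect_identical(dim(reps$S), c(2L, cfg$hidden_dim))
  # identical proteins give identical rows
  reps2 <- protein_level_reps(list(graphs[[1]], graphs[[1]]), params, cfg)
  expect_equal(reps2$S[1, ], reps2$S[2, ])
  expect_equal(reps2$G[1, ], reps2$G[2, ])
  # a single-residue mean is the residue's projected embedding itself: the
  # sequence-side pooling of a length-2 homopolymer with identical windows
  # equals either residue's projected row
  hs <- project_seq(seq_encode("AA", params$theta), params$theta)
  g2 <- build_residue_graph(build_chain(backbone_spec(2, 0, 0)))
  r2 <- protein_level_reps(list(g2), params, cfg)
  expect_equal(c(r2$S), hs[1, ])
})

test_that("zero discriminator gives I = -2 ln 2 exactly; saturation approaches 0", {
  cfg <- small_cfg()
  graphs <- small_graphs(3, c(6, 8), classes = 3, seed = 2, cfg = cfg)
  params <- init_steps_params(cfg, seed = 1)
  params$beta <- par_zero(params$beta)
  expect_equal(mi_estimate(graphs, params, cfg, seed = 1), -2 * log(2), tolerance = 1e-12)
  # saturated toy: large positive scores on positives, negative on negatives
  big <- 50
  expect_equal(-steps:::softplus(-big) - steps:::softplus(-big), 0, tolerance = 1e-9)
  expect_error(mi_estimate(graphs[1], params, cfg), ">= 2")
})

test_that("mi_estimate is symmetric in identical proteins", {
  cfg <- small_cfg()
  g <- small_graphs(1, c(7, 7), classes = 1, seed = 3, cfg = cfg)[[1]]
  params <- init_steps_params(cfg, seed = 2)
  a <- mi_estimate(list(g, g), params, cfg, seed = 5)
  b <- mi_estimate(list(g, g), params, cfg, seed = 9)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("inner step: identity at eta 0, exact linearity, ascent property", {
  cfg <- small_cfg()
  graphs <- small_graphs(2, c(6, 8), classes = 2, seed = 4, cfg = cfg)
  params <- init_steps_params(cfg, seed = 3)
  i0 <- inner_step(params$theta, params$omega, params$beta, graphs,
    eta = 0, cfg = cfg, seed = 1
  )
  expect_equal(i0$theta_new, params$theta)
  i1 <- inner_step(params$theta, params$omega, params$beta, graphs,
    eta = 1e-6, cfg = cfg, seed = 1
  )
  i2 <- inner_step(params$theta, params$omega, params$beta, graphs,
    eta = 2e-6, cfg = cfg, seed = 1
  )
  # doubling eta doubles the applied displacement eta * grad exactly
  expect_identical(
    i2$theta_new,
    steps:::par_axpy(params$theta, i1$grad_theta, 2e-6)
  )
  d1 <- steps:::par_flatten(i1$theta_new) - steps:::par_flatten(params$theta)
  d2 <- steps:::par_flatten(i2$theta_new) - steps:::par_flatten(params$theta)
  expect_equal(d2, 2 * d1, tolerance = 1e-6)
  # ascent: I at the perturbed theta is no smaller (tiny eta)
  p2 <- params
  p2$theta <- i1$theta_new
  expect_gte(
    mi_estimate(graphs, p2, cfg, seed = 1),
    mi_estimate(graphs, params, cfg, seed = 1) - 1e-12
  )
})

test_that("training the discriminator alone monotonically increases I", {
  cfg <- small_cfg()
  graphs <- small_graphs(4, c(6, 9), classes = 2, seed = 5, cfg = cfg)
  params <- init_steps_params(cfg, seed = 4)
  lr <- 1e-3
  prev <- -Inf
  first <- NA_real_
  for (step in 1:50) {
    g <- steps:::mi_grads(params$theta, params$omega, params$beta, graphs, cfg,
      seed = 11, wrt = "beta"
    )
    expect_gte(g$value, prev - 1e-8)
    if (step == 1) first <- g$value
    prev <- g$value
    params$beta <- steps:::par_axpy(params$beta, g$beta, lr)
  }
  expect_gt(prev, first)
})

test_that("trained I separates matched from shuffled pairings", {
  cfg <- small_cfg()
  # sequence identity determines structure class: helix sequences vs strand
  ds <- make_toy_dataset(6, c(8, 10), class_count = 2, seed = 6)
  graphs <- lapply(ds$structures, build_residue_graph, threshold = cfg$threshold)
  params <- init_steps_params(cfg, seed = 5)
  for (step in 1:60) {
    g <- steps:::mi_grads(params$theta, params$omega, params$beta, graphs, cfg,
      seed = 21, wrt = "beta"
    )
    params$beta <- steps:::par_axpy(params$beta, g$beta, 1e-2)
  }
  matched <- mi_estimate(graphs, params, cfg, seed = 21)
  # shuffled pairing: rotate the structure side so positives are mismatched
  reps <- protein_level_reps(graphs, params, cfg)
  rot <- c(2:6, 1)
  pos <- discriminator_score(reps$S, reps$G[rot, ], params$beta)
  neg <- discriminator_score(reps$S, reps$G[c(3:6, 1:2), ], params$beta)
  shuffled <- mean(-steps:::softplus(-pos)) - mean(steps:::softplus(neg))
  expect_gt(matched, shuffled)
})

test_that("outer step in mode off equals a hand-rolled plain gradient pass", {
  cfg <- small_cfg(
    bilevel = list(mode = "off", inner_lr = 5e-5, outer_lr = 1e-3, fd_eps = 1e-3),
    mi = list(enabled = FALSE)
  )
  graphs <- small_graphs(3, c(6, 9), classes = 3, seed = 7, cfg = cfg)
  params <- init_steps_params(cfg, seed = 6)
  masks <- lapply(seq_along(graphs), function(i) sample_mask(graphs[[i]], 0.15, seed = i))
  st <- outer_step(params, graphs, cfg, masks = masks, seed = 0)
  # hand-rolled: wrap leaves, build the joint loss, backpropagate
  leaves <- list(
    theta = params$theta,
    omega = steps:::params_to_leaves(params$omega),
    alpha = steps:::params_to_leaves(params$alpha)
  )
  ls <- ssl_loss(graphs, leaves, cfg, masks = masks)
  ad_backward(ls$total)
  expect_equal(
    steps:::par_flatten(st$grads$omega),
    steps:::par_flatten(steps:::leaves_grads(leaves$omega)),
    tolerance = 1e-12
  )
  expect_equal(
    steps:::par_flatten(st$grads$alpha),
    steps:::par_flatten(steps:::leaves_grads(leaves$alpha)),
    tolerance = 1e-12
  )
  expect_identical(st$theta, params$theta)
  expect_null(st$grads$beta)
})

test_that("second-order outer gradient matches the finite-difference oracle", {
  cfg <- steps_config(list(
    hidden_dim = 2L, layers = 1L,
    rbf = list(n_centers = 2L, gamma = 10),
    seq_encoder = list(type = "standin", dim = 2L, window = 3L),
    binning = list(T = 5L, d_min = 2, d_max = 20),
    bilevel = list(mode = "second_order", inner_lr = 0.5, outer_lr = 1e-3, fd_eps = 1e-3)
  ))
  ds <- make_toy_dataset(2, c(4, 5), class_count = 2, seed = 3)
  graphs <- lapply(ds$structures, build_residue_graph, threshold = cfg$threshold)
  params <- init_steps_params(cfg, seed = 7)
  masks <- lapply(seq_along(graphs), function(i) sample_mask(graphs[[i]], 0.15, seed = i))
  expect_lte(length(steps:::par_flatten(params$omega)), 50)
  st <- outer_step(params, graphs, cfg, masks = masks, seed = 11)
  gw <- steps:::par_flatten(st$grads$omega)
  Lfun <- function(wvec) {
    p <- params
    p$omega <- steps:::par_unflatten(wvec, params$omega)
    inn <- inner_step(p$theta, p$omega, p$beta, graphs,
      eta = cfg$bilevel$inner_lr, cfg = cfg, seed = 11
    )
    ssl_loss(graphs, list(theta = inn$theta_new, omega = p$omega, alpha = p$alpha),
      cfg,
      masks = masks
    )$total
  }
  w0 <- steps:::par_flatten(params$omega)
  fd <- vapply(seq_along(w0), function(k) {
    h <- 1e-5 * max(1, abs(w0[k]))
    wp <- w0
    wm <- w0
    wp[k] <- wp[k] + h
    wm[k] <- wm[k] - h
    (Lfun(wp) - Lfun(wm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(fd - gw)) / max(abs(fd)), 1e-4)
  # and the first-order mode demonstrably misses the mixed term here
  cfg1 <- cfg
  cfg1$bilevel$mode <- "first_order"
  st1 <- outer_step(params, graphs, cfg1, masks = masks, seed = 11)
  expect_gt(max(abs(fd - steps:::par_flatten(st1$grads$omega))) / max(abs(fd)), 1e-3)
})

test_that("theta is byte-identical across outer steps in every mode", {
  for (mode in c("second_order", "first_order", "off")) {
    cfg <- small_cfg(bilevel = list(mode = mode, inner_lr = 5e-5, outer_lr = 1e-3, fd_eps = 1e-3))
    graphs <- small_graphs(3, c(6, 9), classes = 3, seed = 8, cfg = cfg)
    params <- init_steps_params(cfg, seed = 8)
    st <- outer_step(params, graphs, cfg, seed = 1)
    expect_identical(st$theta, params$theta)
  }
})
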