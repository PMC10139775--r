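test_that("mask size follows max(1, round(fraction * L)) over valid residues", {
  cfg <- small_cfg()
  g20 <- build_residue_graph(make_random_coil(20, 1))
  m <- sample_mask(g20, 0.15, seed = 0)
  expect_identical(length(m$masked), 3L)
  expect_true(all(g20$dihedrals$phi_valid[m$masked] & g20$dihedrals$psi_valid[m$masked]))
  g3 <- build_residue_graph(make_random_coil(3, 1))
  expect_identical(length(sample_mask(g3, 0.15, seed = 0)$masked), 1L)
  expect_identical(sample_mask(g20, 0.15, seed = 7), sample_mask(g20, 0.15, seed = 7))
  # a 2-residue chain has no residue with both angles -> skip signal
  s2 <- build_chain(backbone_spec(2, 0.5, 0.5))
  g2 <- build_residue_graph(s2)
  expect_error(sample_mask(g2), class = "steps_skip_protein")
})

test_that("distance head produces a distribution; zero weights give uniform", {
  heads <- init_head_params(6, T = 30, seed = 1)
  h <- rnorm(6)
  p <- distance_logits(h, rnorm(6), heads)
  expect_length(p, 30)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(distance_logits(h, h, heads), distance_logits(rnorm(6) * 0, rep(0, 6), heads))
  z <- par_zero(heads)
  expect_equal(distance_logits(rnorm(6), rnorm(6), z), rep(1 / 30, 30))
})

test_that("uniform predictor gives l_dis = ln T exactly; perfect predictor ~ 0", {
  cfg <- small_cfg()
  g <- small_graphs(1, c(10, 10), classes = 3, seed = 5, cfg = cfg)[[1]]
  heads <- par_zero(init_head_params(4, T = 30, seed = 1))
  h <- matrix(rnorm(g$n_nodes * 4), g$n_nodes, 4)
  b <- distance_binning(30, 2, 20)
  expect_equal(distance_loss(h, g$distance_matrix, b, heads), log(30), tolerance = 1e-12)
  # hand-built perfect predictor on the 3-collinear-Ca toy: each ordered pair
  # gets a one-hot difference feature, and W2 routes that feature's mass onto
  # the pair's true bin, so the cross-entropy approaches its lower bound 0
  D <- matrix(c(0, 5, 10, 5, 0, 5, 10, 5, 0), 3, 3)
  labels <- bin_distance(D, b)
  pairs <- steps:::ordered_pairs(3)
  perfect <- list(dis = list(
    W1 = diag(6), b1 = rep(0, 6),
    W2 = matrix(0, 6, 30), b2 = rep(0, 30)
  ))
  for (r in seq_len(nrow(pairs))) {
    perfect$dis$W2[r, labels[pairs[r, 1], pairs[r, 2]] + 1] <- 2
  }
  U <- diag(6) * 50 # engineered pair features: 100 logits on the true bin
  logits <- steps:::head_apply(U, perfect$dis)
  pl <- exp(logits - apply(logits, 1, max))
  pl <- pl / rowSums(pl)
  truth <- labels[pairs] + 1
  expect_true(all(max.col(logits) == truth))
  expect_lt(mean(-log(pl[cbind(1:6, truth)])), 1e-6)
})

test_that("l_dis matches a naive double-loop oracle on random instances", {
  cfg <- small_cfg()
  b <- distance_binning(30, 2, 20)
  for (seed in 1:4) {
    g <- small_graphs(1, c(5, 12), classes = 3, seed = seed, cfg = cfg)[[1]]
    heads <- init_head_params(6, T = 30, seed = seed)
    h <- matrix(rnorm(g$n_nodes * 6), g$n_nodes, 6)
    got <- distance_loss(h, g$distance_matrix, b, heads)
    acc <- 0
    n <- 0
    for (i in seq_len(g$n_nodes)) {
      for (j in seq_len(g$n_nodes)) {
        if (i == j) next
        p <- distance_logits(h[i, ], h[j, ], heads)
        lab <- bin_distance(g$distance_matrix[i, j], b) + 1
        acc <- acc - log(p[lab])
        n <- n + 1
      }
    }
    expect_equal(got, acc / n, tolerance = 1e-9)
    expect_identical(n, g$n_nodes^2 - g$n_nodes) # diagonal excluded
  }
})

test_that("L = 2 distance loss equals the single-pair loss by symmetry", {
  s2 <- build_chain(backbone_spec(2, 0.5, 0.5))
  D <- ca_distance_matrix(s2)
  heads <- init_head_params(3, T = 30, seed = 2)
  h <- matrix(rnorm(6), 2, 3)
  b <- distance_binning()
  got <- distance_loss(h, D, b, heads)
  p12 <- distance_logits(h[1, ], h[2, ], heads)
  p21 <- distance_logits(h[2, ], h[1, ], heads)
  lab <- bin_distance(D[1, 2], b) + 1
  expect_equal(got, (-log(p12[lab]) - log(p21[lab])) / 2, tolerance = 1e-12)
})

test_that("angle head and loss: zero head, hand arithmetic, additivity", {
  heads <- par_zero(init_head_params(4, seed = 1))
  expect_equal(angle_prediction(rnorm(4), heads), c(0, 0))
  truth <- matrix(c(0.5, -0.25), 1, 2)
  expect_equal(angle_loss(matrix(0, 1, 2), truth), 0.3125)
  expect_equal(angle_loss(truth, truth), 0)
  # doubling the masked set with identical errors doubles the loss
  t2 <- rbind(truth, truth)
  expect_equal(angle_loss(matrix(0, 2, 2), t2), 2 * 0.3125)
  h <- rnorm(4)
  heads_r <- init_head_params(4, seed = 3)
  expect_identical(angle_prediction(h, heads_r), angle_prediction(h, heads_r))
})

test_that("distance regression ablation: zero predictor on the collinear toy", {
  s <- make_ideal_helix(3, 1)
  s$coords_CA <- matrix(c(0, 0, 0, 5, 0, 0, 10, 0, 0), 3, 3, byrow = TRUE)
  D <- ca_distance_matrix(s)
  heads <- par_zero(init_head_params(4, seed = 1))
  h <- matrix(rnorm(12), 3, 4)
  expect_equal(distance_loss_regression(h, D, heads), 50) # mean(25,25,100 x2)
  # symmetric in pair order: permuting nodes leaves the loss unchanged
  perm <- c(3, 1, 2)
  expect_equal(
    distance_loss_regression(h[perm, ], D[perm, perm], heads),
    distance_loss_regression(h, D, heads),
    tolerance = 1e-12
  )
})

test_that("joint loss composes the closed forms and honours ablations", {
  cfg <- small_cfg()
  graphs <- small_graphs(1, c(10, 10), classes = 3, seed = 6, cfg = cfg)
  params <- init_steps_params(cfg, seed = 1)
  params$alpha <- par_zero(params$alpha)
  masks <- list(sample_mask(graphs[[1]], cfg$mask_fraction, seed = 3))
  ls <- ssl_loss(graphs, params, cfg, masks = masks)
  truth <- steps:::masked_angle_truths(graphs[[1]], masks[[1]])
  expect_equal(ls$l_dis, log(30), tolerance = 1e-12)
  expect_equal(ls$l_angle, sum(truth^2), tolerance = 1e-12)
  expect_equal(ls$total, ls$l_dis + ls$l_angle)
  cfg_na <- small_cfg(ablations = list(no_angle = TRUE, no_distance = FALSE, distance_regression = FALSE))
  expect_equal(ssl_loss(graphs, params, cfg_na, masks = masks)$total, log(30), tolerance = 1e-12)
  cfg_nd <- small_cfg(ablations = list(no_angle = FALSE, no_distance = TRUE, distance_regression = FALSE))
  expect_equal(ssl_loss(graphs, params, cfg_nd, masks = masks)$total, sum(truth^2), tolerance = 1e-12)
})

test_that("loss gradients w.r.t. the heads are nonzero for generic inputs", {
  cfg <- small_cfg()
  graphs <- small_graphs(2, c(8, 10), classes = 3, seed = 8, cfg = cfg)
  params <- init_steps_params(cfg, seed = 2)
  g <- steps:::ssl_grads(params$theta, params$omega, params$alpha, graphs, cfg,
    masks = NULL, wrt = "alpha"
  )
  expect_gt(max(abs(steps:::par_flatten(g$alpha))), 0)
})
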