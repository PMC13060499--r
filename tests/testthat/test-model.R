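# Model assembly, losses, training mechanics, evaluation, protograms.

test_that("per-depth logits are identical across depths at initialization", {
  m <- psn_model(toy_config(D = 12L, P = 6L))
  set.seed(20)
  sb <- sequence_batch(array(rnorm(2 * 5 * 3 * 29 * 129, -5, 6),
                             dim = c(2, 5, 3, 29, 129)))
  fw <- psn_forward(m, sb, mode = "eval")
  expect_lt(max(abs(fw$depth_logits[[1]] - fw$depth_logits[[2]])), 1e-5)
  expect_lt(max(abs(fw$depth_logits[[1]] - fw$depth_logits[[3]])), 1e-5)
  # probabilities normalized at every head
  for (pr in fw$depth_probs) expect_equal(rowSums(pr), rep(1, nrow(pr)))
})

test_that("forward passes are deterministic (eval always, train given the seed)", {
  m <- psn_model(toy_config())
  set.seed(21)
  sb <- sequence_batch(array(rnorm(2 * 5 * 3 * 29 * 129, -5, 6),
                             dim = c(2, 5, 3, 29, 129)))
  e1 <- psn_forward(m, sb, mode = "eval")
  e2 <- psn_forward(m, sb, mode = "eval")
  expect_identical(e1$depth_logits, e2$depth_logits)
  t1 <- psn_forward(m, sb, mode = "train", seed = 7L)
  t2 <- psn_forward(m, sb, mode = "train", seed = 7L)
  expect_identical(t1$depth_logits, t2$depth_logits)
  expect_identical(t1$mask$selector, t2$mask$selector)
  expect_error(psn_forward(m, sequence_batch(array(0, dim = c(1, 5, 3, 20, 129)))),
               "does not match config")
})

test_that("total loss closed forms hold", {
  n <- 10L; K <- 5L
  lab <- rep(1:5, 2)
  perfect <- matrix(-1e3, n, K)
  perfect[cbind(1:n, lab)] <- 1e3
  tl <- total_loss(list(perfect, perfect, perfect), lab, commit_loss = 2,
                   commit_weight = 0)
  expect_equal(tl$total, 0, tolerance = 1e-8)
  uniform <- matrix(0, n, K)
  tl2 <- total_loss(list(uniform), lab)
  expect_equal(tl2$ce, log(5), tolerance = 1e-9)
  set.seed(22)
  lg <- lapply(1:3, function(i) matrix(rnorm(n * K), n, K))
  a <- total_loss(lg, lab, commit_loss = 1.5, depth_weights = c(1, 1, 1))
  b <- total_loss(lg, lab, commit_loss = 1.5, depth_weights = c(2, 2, 2))
  expect_equal(b$total - b$commit * 0.25, 2 * (a$total - a$commit * 0.25))
  expect_error(total_loss(lg, c(lab[-1], 9L)), "out of range")
})

test_that("training learns separable two-class data and zero lr is a no-op", {
  sh <- shared_trained_model()
  ev <- psn_evaluate(sh$model, sh$data$batch)
  expect_gt(ev$accuracy, 0.9)
  expect_true(sh$model$state$vq_active)
  # zero learning rate: parameters unchanged
  m0 <- psn_model(toy_config(lr = 0))
  m1 <- psn_train(m0, sh$data$batch, epochs = 1L, batch_size = 16L)
  expect_equal(m1$params, m0$params)
  # divergence guard message path exists
  expect_error(psn_train(psn_model(toy_config()), sequence_batch(
    array(0, dim = c(0, 5, 3, 29, 129)), matrix(integer(0), 0, 5))), "nonempty")
})

test_that("training is reproducible and checkpoints round-trip", {
  d <- two_class_data(duration_epochs = 60L, seed = 14L)
  m1 <- train_toy_model(d, epochs = 3L)
  m2 <- train_toy_model(d, epochs = 3L)
  expect_equal(m1$params, m2$params)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m1, path)
  m3 <- load_checkpoint(path)
  expect_equal(m3$params, m1$params)
  expect_equal(m3$state$updates, m1$state$updates)
  fw1 <- psn_forward(m1, d$batch, mode = "eval")
  fw3 <- psn_forward(m3, d$batch, mode = "eval")
  expect_identical(fw1$depth_logits, fw3$depth_logits)
})

test_that("quantized inference depends on the embedding only through codebook rows", {
  sh <- shared_trained_model()
  m <- sh$model
  fw <- psn_forward(m, sh$data$batch, mode = "eval", collect_cache = TRUE)
  # manual recomputation: replace the mixed embedding by its selected
  # prototype before the sequence encoder
  LD <- codebook_matrix(psn_codebook(m))
  X2 <- LD[fw$quant$indices, , drop = FALSE]
  B <- dim(sh$data$batch$values)[1]; L <- m$config$L
  se <- sleepproto:::temporal_conv_fwd(array(X2, dim = c(B, L, m$config$D)),
                                       m$params$U, m$params$Wo,
                                       m$params$gamma_se, m$config$se_window)
  lg <- sweep(matrix(se$out, nrow = B * L) %*% m$params$Wh, 2L, m$params$bh, "+")
  expect_equal(lg, fw$depth_logits[[3]])
})

test_that("Cohen's kappa matches the contingency formula and its fixed points", {
  # perfect predictor
  conf <- diag(c(5, 8, 2, 4, 6))
  expect_equal(cohen_kappa(conf), 1)
  # constant single-class predictor: kappa 0
  confc <- matrix(0, 5, 5)
  confc[, 2] <- c(10, 20, 5, 5, 10)
  expect_equal(cohen_kappa(confc), 0)
  set.seed(23)
  for (i in 1:20) {
    cf <- matrix(rpois(25, 8), 5, 5)
    expect_equal(cohen_kappa(cf), kappa_bruteforce(cf), tolerance = 1e-12)
  }
})

test_that("evaluation reports match predictions and occlusion setups are validated", {
  sh <- shared_trained_model()
  ev <- psn_evaluate(sh$model, sh$data$batch)
  expect_equal(sum(ev$confusion), length(sh$data$batch$labels))
  support <- table(factor(stage_levels()[as.vector(sh$data$batch$labels)],
                          levels = stage_levels()))
  expect_equal(as.vector(rowSums(ev$confusion)), as.vector(support))
  expect_gte(ev$cohen_kappa, -1); expect_lte(ev$cohen_kappa, 1)
  expect_error(psn_evaluate(sh$model, sh$data$batch, setup = "bogus"), "unknown")
  # full-EEG occlusion hurts at least as much as no occlusion
  ev_eeg <- psn_evaluate(sh$model, sh$data$batch, setup = "eeg")
  expect_lte(ev_eeg$accuracy, ev$accuracy + 1e-9)
})

test_that("light random occlusion retains at least the agreement of heavy occlusion", {
  sh <- shared_trained_model()
  k25 <- mean(vapply(1:3, function(s) {
    psn_evaluate(sh$model, sh$data$batch, setup = "random25", seed = s)$cohen_kappa
  }, numeric(1)))
  k50 <- mean(vapply(1:3, function(s) {
    psn_evaluate(sh$model, sh$data$batch, setup = "random50", seed = s)$cohen_kappa
  }, numeric(1)))
  expect_gte(k25, k50)
})

test_that("protograms have one index per epoch and are deterministic", {
  sh <- shared_trained_model()
  et <- sh$data$epochs
  pg <- compute_protogram(sh$model, et, subject_id = "s1")
  expect_length(pg$indices, dim(et$values)[1])
  expect_true(all(pg$indices >= 1L & pg$indices <= sh$model$config$P))
  pg2 <- compute_protogram(sh$model, et)
  expect_identical(pg$indices, pg2$indices)
  # identical epochs map to a constant prototype sequence
  one <- et$values[1, , , ]
  rep10 <- epoch_tensor(aperm(array(one, dim = c(dim(one), 10)), c(4, 1, 2, 3)),
                        rep("W", 10))
  pg3 <- compute_protogram(sh$model, rep10)
  expect_equal(length(unique(pg3$indices)), 1L)
})
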