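# Explanation framework: baselines, integrated relevance, reconstructions,
# MMD metrics, feature occlusion and rules.

explain_model <- function(seed = 2L) {
  m <- psn_model(toy_config(seed = seed))
  m$params$gamma_cm <- 0.3  # make the encoder nontrivial beyond the mean
  m
}

test_that("the baseline is the per-cell mean and respects linearity", {
  vals <- random_epoch_batch(6, seed = 30L)
  et <- epoch_tensor(vals, rep("N2", 6))
  bl <- compute_baseline(et)
  expect_equal(bl$values, apply(vals, c(2, 3, 4), mean))
  expect_equal(compute_baseline(vals[1, , , , drop = FALSE])$values,
               array(vals[1, , , ], dim = dim(vals)[-1]))
  expect_equal(compute_baseline(abind_rows(vals[1:3, , , , drop = FALSE],
                                           -vals[1:3, , , , drop = FALSE]))$values,
               array(0, dim = dim(vals)[-1]))
  # mean of partition means equals the global mean (equal-size parts)
  m1 <- compute_baseline(vals[1:3, , , , drop = FALSE])$values
  m2 <- compute_baseline(vals[4:6, , , , drop = FALSE])$values
  expect_equal((m1 + m2) / 2, bl$values)
  expect_error(compute_baseline(vals[0, , , , drop = FALSE]), "nonempty")
})

test_that("relevance of the baseline itself is zero with zero gap", {
  m <- explain_model()
  vals <- random_epoch_batch(5, seed = 31L)
  bl <- compute_baseline(epoch_tensor(vals, rep("W", 5)))
  rm_ <- local_relevance(m, bl$values, 1L, bl, steps = 8L)
  expect_true(all(rm_$values == 0))
  expect_equal(rm_$completeness_gap, 0)
})

test_that("completeness gap shrinks with the step count and is tiny at 512", {
  m <- explain_model()
  vals <- random_epoch_batch(4, seed = 32L)
  bl <- compute_baseline(epoch_tensor(vals, rep("W", 4)))
  s <- array(vals[1, , , ], dim = dim(vals)[-1])
  gaps <- vapply(c(8L, 64L, 512L), function(st) {
    local_relevance(m, s, 2L, bl, steps = st)$completeness_gap
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-3)
})

test_that("the path gradient matches finite differences of the similarity", {
  m <- explain_model()
  vals <- random_epoch_batch(2, seed = 33L)
  s <- array(vals[1, , , ], dim = dim(vals)[-1])
  sg <- sleepproto:::sim_and_grad(m, s, 3L)
  fd_at <- function(ci, ti, fi) {
    eps <- 1e-4
    s2 <- s; s2[ci, ti, fi] <- s2[ci, ti, fi] + eps
    s3 <- s; s3[ci, ti, fi] <- s3[ci, ti, fi] - eps
    (sleepproto:::sim_and_grad(m, s2, 3L, fixed_mask = sg$mask, grad = FALSE)$sim -
       sleepproto:::sim_and_grad(m, s3, 3L, fixed_mask = sg$mask, grad = FALSE)$sim) /
      (2 * eps)
  }
  for (probe in list(c(1, 5, 10), c(2, 17, 60), c(3, 29, 129))) {
    expect_equal(sg$grad[probe[1], probe[2], probe[3]],
                 fd_at(probe[1], probe[2], probe[3]), tolerance = 1e-4)
  }
})

test_that("data-driven reconstruction ranks epochs exactly like a similarity sort", {
  m <- explain_model()
  vals <- random_epoch_batch(200, seed = 34L)
  et <- epoch_tensor(vals, rep(stage_levels(), 40))
  rd <- reconstruct_data_driven(m, et, 2L, k = 10L)
  sims <- fidelity(m, vals, prototype_id = 2L)
  expect_equal(rd$provenance, order(sims, decreasing = TRUE)[1:10])
  expect_equal(rd$fidelity, sort(sims, decreasing = TRUE)[1:10])
  # k = N returns everything sorted; k > N warns and clips
  rall <- reconstruct_data_driven(m, et, 2L, k = 200L)
  expect_equal(rall$provenance, order(sims, decreasing = TRUE))
  expect_warning(rclip <- reconstruct_data_driven(m, et, 2L, k = 500L), "k >")
  expect_equal(dim(rclip$values)[1], 200L)
})

test_that("optimized reconstruction never loses fidelity and beats the data-driven start", {
  m <- explain_model()
  vals <- random_epoch_batch(40, seed = 35L)
  et <- epoch_tensor(vals, rep(stage_levels(), 8))
  for (pid in 1:2) {
    rd <- reconstruct_data_driven(m, et, pid, k = 4L)
    ro <- reconstruct_optimized(m, rd, pid, iters = 30L)
    expect_identical(ro$strategy, "hybrid")
    expect_true(all(ro$fidelity >= rd$fidelity - 1e-12))
    rn <- reconstruct_optimized(m, noise_init(m, 4L, seed = pid), pid, iters = 30L)
    expect_identical(rn$strategy, "model_driven")
    expect_true(all(rn$fidelity >= fidelity(m, noise_init(m, 4L, seed = pid),
                                            prototype_id = pid) - 1e-12))
  }
})

test_that("the MMD estimate equals the O(n^2) double sum and its basic identities", {
  set.seed(36)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- matrix(rnorm(50 * 4, mean = 1), 50, 4)
  bw <- 2.5
  expect_equal(mmd(x, y, bandwidth = bw), mmd_bruteforce(x, y, bw), tolerance = 1e-10)
  expect_equal(mmd(x, y, bandwidth = bw, biased = TRUE),
               mmd_bruteforce(x, y, bw, biased = TRUE), tolerance = 1e-10)
  expect_equal(mmd(x, y), mmd(y, x))                 # symmetry
  expect_equal(mmd(x, x, biased = TRUE), 0)          # identical multisets
  expect_warning(m1 <- mmd(x[1, , drop = FALSE], y), "singleton")
  expect_true(is.finite(m1))
})

test_that("plausibility is zero for the data-driven strategy and grows with offsets", {
  set.seed(37)
  base <- matrix(rnorm(80 * 6), 80, 6)
  expect_equal(mmd(base, base, biased = TRUE), 0)
  sdv <- stats::sd(base)
  shifts <- vapply(c(0, 1, 2), function(k) {
    mmd(base + k * sdv, base, biased = TRUE)
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("stability reduces to pairwise MMD and is permutation invariant", {
  set.seed(38)
  b1 <- matrix(rnorm(30 * 4), 30, 4)
  b2 <- matrix(rnorm(30 * 4, 0.5), 30, 4)
  b3 <- matrix(rnorm(30 * 4, 1), 30, 4)
  expect_equal(stability(list(b1, b1)), 0)
  expect_equal(stability(list(b1, b2)), mmd(b1, b2, biased = TRUE))
  expect_equal(stability(list(b1, b2, b3)), stability(list(b3, b1, b2)))
  expect_error(stability(list(b1)), "at least 2")
})

test_that("feature groups cover the stated bands and occlusion respects them", {
  gr <- feature_groups()
  nm <- vapply(gr, `[[`, "", "name")
  expect_setequal(nm, c("delta", "theta", "alpha", "sigma", "beta", "gamma",
                        "SEMs", "blinks", "REMs", "EOG>5Hz", "EMG_tone"))
  freqs <- (0:128) * 100 / 256
  delta <- gr[[which(nm == "delta")]]
  expect_true(all(freqs[delta$bins] >= 0.5 & freqs[delta$bins] <= 4))
  m <- explain_model()
  vals <- random_epoch_batch(4, seed = 39L)
  bl <- compute_baseline(epoch_tensor(vals, rep("W", 4)))
  # reconstruction equal to the baseline: every relevance is exactly 0
  rel0 <- feature_occlusion_relevance(
    m, array(bl$values, dim = c(1, dim(bl$values))), gr, bl, prototype_id = 1L)
  expect_true(all(rel0$relevance == 0))
})

test_that("an encoder sensitive only to delta cells yields delta-only relevance and rules", {
  m <- explain_model()
  gr <- feature_groups()
  nm <- vapply(gr, `[[`, "", "name")
  vals <- random_epoch_batch(6, seed = 40L)
  bl <- compute_baseline(epoch_tensor(vals, rep("W", 6)))
  # instance differing from the baseline only in EEG delta cells: occluding
  # any other group patches identical values, so only delta can be relevant
  delta <- gr[[which(nm == "delta")]]
  x <- bl$values
  x[1, , delta$bins] <- x[1, , delta$bins] + 8
  rel <- feature_occlusion_relevance(m, array(x, dim = c(1, dim(x))), gr, bl,
                                     prototype_id = 2L)
  expect_true(abs(rel$relevance[nm == "delta"]) > 0)
  expect_true(all(rel$relevance[nm != "delta"] == 0))
  rule <- generate_rules(rel, array(x, dim = c(1, dim(x))), bl, gr,
                         threshold = min(abs(rel$relevance[nm == "delta"]), 0.05) / 2)
  expect_equal(rule$table$feature[1], "delta")
  expect_identical(rule$table$direction[1], "\u2191")
  # thresholding: no clause below the threshold, ordered by |relevance|
  expect_true(all(abs(rule$table$relevance) >= rule$threshold))
  expect_true(!is.unsorted(rev(abs(rule$table$relevance))))
  # all-below-threshold: explicit empty sentence
  none <- generate_rules(rel, array(x, dim = c(1, dim(x))), bl, gr, threshold = 10)
  expect_match(none$text, "no salient features")
  expect_equal(nrow(none$table), 0L)
})
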