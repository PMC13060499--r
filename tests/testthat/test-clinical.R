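# Prototype-gram features, Monte-Carlo CV and group statistics.

make_protogram <- function(indices, P, id = "s", cond = "healthy") {
  structure(list(indices = indices, P = P, subject_id = id, condition = cond),
            class = "protogram")
}

test_that("time-in-prototype converts counts to hours and fractions", {
  pg <- make_protogram(c(1L, 1L, 2L), 3L)
  expect_equal(time_in_prototype(pg), c(1 / 60, 1 / 120, 0))
  fr <- time_in_prototype(pg, as_fraction = TRUE)
  expect_equal(sum(fr), 1)
  expect_equal(fr, c(2 / 3, 1 / 3, 0))
  expect_equal(time_in_prototype(make_protogram(rep(2L, 7), 4L),
                                 as_fraction = TRUE), c(0, 1, 0, 0))
  expect_error(time_in_prototype(make_protogram(integer(0), 3L)), "empty")
  # occupancy conservation: total time equals the recording duration
  set.seed(50)
  pg2 <- make_protogram(sample(1:5, 240, TRUE), 5L)
  expect_equal(sum(time_in_prototype(pg2)), 240 * 30 / 3600)
  ts <- time_in_stage(hypnogram(rep(c("W", "R"), 10)))
  expect_equal(unname(ts[c("W", "R")]), c(10, 10) * 30 / 3600)
})

test_that("separable features classify perfectly; permuted labels are at chance", {
  set.seed(51)
  mk <- function(cond, n, p) t(vapply(seq_len(n), function(i) {
    as.vector(stats::rmultinom(1, 200, p)) / 200
  }, numeric(4)))
  X <- rbind(mk("a", 14, c(0.7, 0.1, 0.1, 0.1)), mk("b", 14, c(0.1, 0.7, 0.1, 0.1)))
  ft <- feature_table(X, rep(c("a", "b"), each = 14))
  cv <- monte_carlo_cv(ft, n_test_per_class = 4L, repeats = 10L, seed = 3L)
  expect_true(all(cv$auc == 1))
  expect_equal(mean(cv$accuracy), 1)
  # permuted labels: mean AUC near chance
  set.seed(52)
  ftp <- feature_table(X, sample(rep(c("a", "b"), each = 14)))
  cvp <- monte_carlo_cv(ftp, n_test_per_class = 4L, repeats = 20L, seed = 4L)
  expect_gt(mean(cvp$auc), 0.35)
  expect_lt(mean(cvp$auc), 0.65)
  # feature scaling leaves the standardized fit and AUC unchanged
  cv2 <- monte_carlo_cv(feature_table(X * 37, rep(c("a", "b"), each = 14)),
                        n_test_per_class = 4L, repeats = 10L, seed = 3L)
  expect_equal(cv2$auc, cv$auc)
  expect_error(monte_carlo_cv(ft, n_test_per_class = 14L), "more than")
})

test_that("CV reports have the declared shape and valid ranges", {
  set.seed(53)
  X <- matrix(runif(60 * 3), 60, 3)
  ft <- feature_table(X, rep(c("h", "ad", "pd"), each = 20))
  cv <- monte_carlo_cv(ft, n_test_per_class = 5L, repeats = 6L, seed = 9L)
  expect_equal(dim(cv$auc), c(6L, 3L))
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  expect_length(cv$accuracy, 6L)
  expect_equal(nrow(cv$summary), 5L)
})

test_that("Mann-Whitney tests match exact enumeration and correction is monotone", {
  # (1,2,3) vs (4,5,6): U = 0, exact two-sided p = 2 * 1/20 = 0.1
  ft <- feature_table(matrix(1:6, ncol = 1), rep(c("a", "b"), each = 3))
  gt <- groupwise_tests(ft, "a", "b")
  expect_equal(gt$U, 0)
  expect_equal(gt$p, 0.1)
  # identical groups: nothing significant
  ft2 <- feature_table(matrix(rep(1:5, 4), ncol = 2), rep(c("a", "b"), each = 5))
  gt2 <- groupwise_tests(ft2, "a", "b")
  expect_false(any(gt2$significant))
  expect_true(all(gt2$tied | gt2$p_adj >= gt2$p))
  set.seed(54)
  ft3 <- feature_table(matrix(rnorm(40 * 6), 40, 6), rep(c("a", "b"), 20))
  gt3 <- groupwise_tests(ft3, "a", "b")
  expect_true(all(gt3$p_adj >= gt3$p - 1e-15))
  # all-tied feature: p = 1 with tie note
  ft4 <- feature_table(matrix(1, 10, 1), rep(c("a", "b"), 5))
  gt4 <- groupwise_tests(ft4, "a", "b")
  expect_true(gt4$tied)
  expect_equal(gt4$p, 1)
})

test_that("per-group profiles are symmetric for identical groups and flag planted shifts", {
  set.seed(55)
  subjects <- function(cond, delta_shift) {
    do.call(rbind, lapply(1:8, function(i) {
      data.frame(subject_id = paste0(cond, i), condition = cond,
                 prototype = rep(1:2, each = 2),
                 feature = rep(c("delta", "beta"), 2),
                 power = c(6 + delta_shift + rnorm(1, 0, 0.3), -8 + rnorm(1, 0, 0.3),
                           2 + rnorm(1, 0, 0.3), -4 + rnorm(1, 0, 0.3)))
    }))
  }
  prof <- rbind(subjects("healthy", 0), subjects("disease", -4))
  stage_df <- expand.grid(condition = c("healthy", "disease"), prototype = 1:2,
                          stage = stage_levels())
  stage_df$count <- 10L
  out <- per_group_prototype_profile(prof, stage_df, reference = "healthy")
  # stage confidence rows sum to 100%
  tot <- stats::aggregate(confidence_pct ~ condition + prototype,
                          data = out$stage_confidence, FUN = sum)
  expect_true(all(abs(tot$confidence_pct - 100) < 1e-9))
  # suppressed delta in the disease group is flagged; beta is not
  dtest <- out$tests[out$tests$feature == "delta" & out$tests$prototype == 1, ]
  expect_true(dtest$significant)
  btest <- out$tests[out$tests$feature == "beta", ]
  expect_false(any(btest$significant))
  # identical groups: no flags
  prof0 <- rbind(subjects("healthy", 0),
                 transform(subjects("healthy", 0), condition = "disease",
                           subject_id = paste0("d", 1:32)))
  out0 <- per_group_prototype_profile(prof0, stage_df, reference = "healthy")
  expect_false(any(out0$tests$significant))
  expect_error(per_group_prototype_profile(prof, stage_df, reference = "nope"),
               "missing reference")
})

test_that("protogram CSV round trip preserves indices and conditions", {
  pgs <- list(make_protogram(c(1L, 3L, 2L), 4L, "s1", "healthy"),
              make_protogram(c(4L, 4L), 4L, "s2", "disease"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_protograms(pgs, path)
  back <- read_protograms(path, P = 4L)
  expect_equal(back$s1$indices, c(1L, 3L, 2L))
  expect_equal(as.character(back$s2$condition), "disease")
})

test_that("sub-stage spectral effects are visible to prototypes but not stages", {
  # the condition morphs N3 spectra toward N2 while the stage chain (and so
  # the hypnogram-level macro-structure) is distributionally identical:
  # time-in-prototype features must discriminate better than time-in-stage
  three_chain <- function() {
    P3 <- matrix(0, 5, 5, dimnames = list(stage_levels(), stage_levels()))
    P3["W", c("W", "N2", "N3")] <- c(0.7, 0.2, 0.1)
    P3["N2", c("W", "N2", "N3")] <- c(0.1, 0.7, 0.2)
    P3["N3", c("W", "N2", "N3")] <- c(0.1, 0.2, 0.7)
    P3[c("N1", "R"), ] <- 0.2
    P3 / rowSums(P3)
  }
  cfg0 <- synthetic_config(transition_matrix = three_chain(),
                           duration_epochs = 360L, seed = 5L)
  rh <- generate_recording(cfg0)
  et <- epoch_and_spectrogram(preprocess_signals(rh$recording), rh$hypnogram)
  m <- psn_train(psn_model(toy_config(P = 6L)), make_sequences(et, L = 5L),
                 epochs = 40L, batch_size = 8L)
  tmpl_dis <- default_stage_templates()
  tmpl_dis$N3$eeg_band_powers <- default_stage_templates()$N2$eeg_band_powers
  mk_cohort <- function(tmpl, cond, n, seed0) lapply(seq_len(n), function(i) {
    cfg <- synthetic_config(stage_templates = tmpl,
                            transition_matrix = three_chain(),
                            duration_epochs = 100L, seed = seed0 + i)
    c(generate_recording(cfg), list(condition = cond,
                                    subject_id = paste0(cond, i)))
  })
  coh <- c(mk_cohort(default_stage_templates(), "healthy", 10L, 500L),
           mk_cohort(tmpl_dis, "disease", 10L, 600L))
  pgs <- lapply(coh, function(s) {
    e2 <- epoch_and_spectrogram(preprocess_signals(s$recording), s$hypnogram)
    compute_protogram(m, e2, subject_id = s$subject_id, condition = s$condition)
  })
  ftp <- protogram_features(pgs)
  fts <- feature_table(t(vapply(coh, function(s) {
    time_in_stage(s$hypnogram, as_fraction = TRUE)
  }, numeric(5))), vapply(coh, `[[`, "", "condition"))
  cvp <- monte_carlo_cv(ftp, n_test_per_class = 3L, repeats = 10L, seed = 1L)
  cvs <- monte_carlo_cv(fts, n_test_per_class = 3L, repeats = 10L, seed = 1L)
  expect_gt(mean(cvp$auc), mean(cvs$auc))
  expect_gt(mean(cvp$auc), 0.9)
})
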