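# Downstream clinical analysis of prototype-grams.
#
# Per-subject time-in-prototype features feed a multinomial logistic
# classifier (L2-penalized, standardized features) under Monte-Carlo
# cross-validation with a fixed number of held-out subjects per condition,
# and per-prototype occupancy is compared between groups with Mann-Whitney U
# tests under Benjamini-Hochberg correction.

#' Time-in-prototype features of a protogram
#'
#' @param pg A `protogram` (or integer index vector with attribute `P`).
#' @param P Prototype count (taken from `pg` when absent).
#' @param as_fraction Return occupancy fractions (sum to 1) instead of hours.
#' @param epoch_len_s Epoch length in seconds.
#' @return Numeric vector of length `P` (hours, or fractions).
#' @export
time_in_prototype <- function(pg, P = NULL, as_fraction = FALSE, epoch_len_s = 30) {
  idx <- if (inherits(pg, "protogram")) pg$indices else pg
  P <- P %||% if (inherits(pg, "protogram")) pg$P else max(idx)
  if (length(idx) == 0L) stop("empty protogram")
  counts <- tabulate(idx, nbins = P)
  if (as_fraction) counts / sum(counts) else counts * epoch_len_s / 3600
}

#' Time-in-stage features of a hypnogram
#'
#' The macro-structure analogue of [time_in_prototype()]: occupancy of the
#' five stages.
#'
#' @param hyp A `hypnogram` (or stage factor).
#' @param as_fraction Fractions instead of hours.
#' @param epoch_len_s Epoch length in seconds.
#' @return Numeric vector of length 5 named by [stage_levels()].
#' @export
time_in_stage <- function(hyp, as_fraction = FALSE, epoch_len_s = 30) {
  lab <- if (inherits(hyp, "hypnogram")) hyp$labels else as_stage_factor(hyp)
  counts <- as.integer(table(lab))
  out <- if (as_fraction) counts / sum(counts) else counts * epoch_len_s / 3600
  names(out) <- stage_levels()
  out
}

#' Build a per-subject feature table from protograms
#'
#' @param protograms List of `protogram` objects (with conditions attached).
#' @param as_fraction Use occupancy fractions.
#' @return Object of class `feature_table`: `features` matrix (subjects x P),
#'   `condition` factor, `subject_id`.
#' @export
protogram_features <- function(protograms, as_fraction = TRUE) {
  P <- protograms[[1]]$P
  feats <- t(vapply(protograms, time_in_prototype, numeric(P),
                    P = P, as_fraction = as_fraction))
  colnames(feats) <- paste0("proto", seq_len(P))
  structure(list(features = feats,
                 condition = factor(vapply(protograms, function(p) as.character(p$condition), "")),
                 subject_id = vapply(protograms, `[[`, "", "subject_id")),
            class = "feature_table")
}

#' Feature table from arbitrary per-subject features
#'
#' @param features Numeric matrix (subjects x features).
#' @param condition Per-subject condition labels.
#' @param subject_id Per-subject identifiers.
#' @return A `feature_table`.
#' @export
feature_table <- function(features, condition, subject_id = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(condition))
  structure(list(features = features, condition = factor(condition),
                 subject_id = subject_id %||% paste0("s", seq_len(nrow(features)))),
            class = "feature_table")
}

# One-vs-rest AUC from scores (probability of the positive class).
auc_ovr <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Monte-Carlo cross-validated condition classification
#'
#' Per repeat: a stratified test set of `n_test_per_class` subjects per
#' condition is drawn, a multinomial logistic classifier with L2 penalty is
#' fit on the standardized remaining subjects, and one-vs-rest AUC per
#' condition, overall accuracy and macro-F1 are computed on the test set.
#' No subject appears in both train and test within a repeat.
#'
#' @param ft A `feature_table`.
#' @param n_test_per_class Held-out subjects per condition (default 8).
#' @param repeats Monte-Carlo repeats (default 20).
#' @param decay L2 penalty strength (default 1).
#' @param seed Seed making the repeat draws reproducible.
#' @return Object of class `cv_report`: `auc` (repeats x conditions),
#'   `accuracy`, `macro_f1` (per repeat), `summary` (means and sds),
#'   `n_test_per_class`, `repeats`.
#' @export
monte_carlo_cv <- function(ft, n_test_per_class = 8L, repeats = 20L,
                           decay = 1, seed = 1L) {
  stopifnot(inherits(ft, "feature_table"))
  cond <- ft$condition
  classes <- levels(cond)
  ns <- table(cond)
  if (any(ns <= n_test_per_class)) {
    stop("every condition needs more than ", n_test_per_class, " subjects (have: ",
         paste(ns, collapse = ", "), ")")
  }
  X <- ft$features
  aucs <- matrix(NA_real_, repeats, length(classes),
                 dimnames = list(NULL, classes))
  acc <- mf1 <- numeric(repeats)
  test_sets <- vector("list", repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      test_idx <- unlist(lapply(classes, function(cl) {
        sample(which(cond == cl), n_test_per_class)
      }))
      train_idx <- setdiff(seq_len(nrow(X)), test_idx)
      stopifnot(length(intersect(train_idx, test_idx)) == 0L)  # leakage guard
      test_sets[[r]] <- sort(test_idx)
      mu <- colMeans(X[train_idx, , drop = FALSE])
      sg <- apply(X[train_idx, , drop = FALSE], 2L, stats::sd)
      sg[sg < 1e-12] <- 1
      Z <- scale(X, center = mu, scale = sg)
      df_tr <- data.frame(y = cond[train_idx], Z[train_idx, , drop = FALSE])
      fit <- nnet::multinom(y ~ ., data = df_tr, decay = decay,
                            trace = FALSE, maxit = 200)
      pr <- predict(fit, newdata = data.frame(Z[test_idx, , drop = FALSE]),
                    type = "probs")
      if (is.null(dim(pr))) {  # two-class: vector of P(second level)
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- fit$lev
      }
      pr <- pr[, classes[classes %in% colnames(pr)], drop = FALSE]
      truth <- cond[test_idx]
      pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                     levels = classes)
      acc[r] <- mean(pred == truth)
      conf <- table(truth, pred)
      mf1[r] <- macro_f1(as.matrix(conf))
      for (cl in classes) {
        aucs[r, cl] <- auc_ovr(pr[, cl], truth == cl)
      }
    }
  })
  sm <- data.frame(metric = c(paste0("auc_", classes), "accuracy", "macro_f1"),
                   mean = c(colMeans(aucs), mean(acc), mean(mf1)),
                   sd = c(apply(aucs, 2L, stats::sd), stats::sd(acc), stats::sd(mf1)))
  structure(list(auc = aucs, accuracy = acc, macro_f1 = mf1, summary = sm,
                 test_sets = test_sets,
                 n_test_per_class = n_test_per_class, repeats = repeats),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$repeats, " repeats, ", x$n_test_per_class,
      " test subjects/condition\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Group-wise Mann-Whitney tests on prototype occupancy
#'
#' Two-sided Mann-Whitney U test per feature column between two conditions,
#' with multiplicity correction across features (Benjamini-Hochberg by
#' default). Exact p-values when the combined group size is <= 20 and there
#' are no ties; normal approximation with tie correction otherwise.
#'
#' @param ft A `feature_table`.
#' @param group_a,group_b Condition labels to compare.
#' @param alpha Significance level after correction.
#' @param method Correction method for [stats::p.adjust()].
#' @return `data.frame` with `feature`, `U`, `p`, `p_adj`, `significant`,
#'   `tied` (all values tied; p reported as 1).
#' @export
groupwise_tests <- function(ft, group_a, group_b, alpha = 0.05, method = "BH") {
  stopifnot(inherits(ft, "feature_table"))
  ia <- ft$condition == group_a
  ib <- ft$condition == group_b
  if (!any(ia) || !any(ib)) stop("both groups must be nonempty")
  nf <- ncol(ft$features)
  U <- p <- numeric(nf)
  tied <- logical(nf)
  for (j in seq_len(nf)) {
    a <- ft$features[ia, j]; b <- ft$features[ib, j]
    if (length(unique(c(a, b))) == 1L) {
      U[j] <- length(a) * length(b) / 2; p[j] <- 1; tied[j] <- TRUE
      next
    }
    exact <- (length(a) + length(b)) <= 20 && !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    U[j] <- unname(wt$statistic)
    p[j] <- wt$p.value
  }
  p_adj <- stats::p.adjust(p, method = method)
  data.frame(feature = colnames(ft$features) %||% paste0("f", seq_len(nf)),
             U = U, p = p, p_adj = p_adj,
             significant = p_adj < alpha, tied = tied)
}

#' Per-group prototype profiles
#'
#' Summarizes, per condition group and prototype: mean feature powers (dB)
#' of per-subject reconstructions, the empirical stage-confidence
#' distribution of the epochs assigned to the prototype, and per-feature
#' between-group Mann-Whitney tests against the reference group.
#'
#' @param profile_df `data.frame` with columns `subject_id`, `condition`,
#'   `prototype`, `feature`, `power` (per-subject reconstruction feature
#'   powers, dB).
#' @param stage_df `data.frame` with columns `condition`, `prototype`,
#'   `stage`, `count` (epoch counts of stage labels among epochs assigned to
#'   each prototype).
#' @param reference Condition treated as the reference group.
#' @param alpha Significance level. @param method Correction method.
#' @return List with `feature_means` (condition x prototype x feature mean
#'   powers, long `data.frame`), `stage_confidence` (percentages summing to
#'   100 per condition x prototype), `tests` (per prototype x feature vs the
#'   reference).
#' @export
per_group_prototype_profile <- function(profile_df, stage_df, reference,
                                        alpha = 0.05, method = "BH") {
  need <- c("subject_id", "condition", "prototype", "feature", "power")
  if (!all(need %in% names(profile_df))) {
    stop("profile_df needs columns: ", paste(need, collapse = ", "))
  }
  if (!reference %in% profile_df$condition) stop("missing reference group: ", reference)
  fm <- stats::aggregate(power ~ condition + prototype + feature,
                         data = profile_df, FUN = mean)
  names(fm)[names(fm) == "power"] <- "mean_power_db"

  sc <- stats::aggregate(count ~ condition + prototype + stage,
                         data = stage_df, FUN = sum)
  tot <- stats::aggregate(count ~ condition + prototype, data = sc, FUN = sum)
  names(tot)[3] <- "total"
  sc <- merge(sc, tot)
  sc$confidence_pct <- 100 * sc$count / sc$total

  tests <- NULL
  others <- setdiff(unique(profile_df$condition), reference)
  for (cond in others) {
    for (pt in unique(profile_df$prototype)) {
      for (ft in unique(profile_df$feature)) {
        a <- profile_df$power[profile_df$condition == reference &
                                profile_df$prototype == pt & profile_df$feature == ft]
        b <- profile_df$power[profile_df$condition == cond &
                                profile_df$prototype == pt & profile_df$feature == ft]
        if (length(a) == 0L || length(b) == 0L) next
        pv <- if (length(unique(c(a, b))) == 1L) 1 else {
          suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
        }
        tests <- rbind(tests, data.frame(condition = cond, prototype = pt,
                                         feature = ft, p = pv))
      }
    }
  }
  if (!is.null(tests)) {
    tests$p_adj <- stats::p.adjust(tests$p, method = method)
    tests$significant <- tests$p_adj < alpha
  }
  list(feature_means = fm, stage_confidence = sc, tests = tests)
}

#' Write / read protograms as CSV
#'
#' Long format: `subject_id`, `epoch_index` (0-based), `prototype_id`
#' (1-based), `condition`.
#'
#' @param protograms List of `protogram` objects. @param path CSV path.
#' @return `path` (write) or the list of protograms (read).
#' @export
write_protograms <- function(protograms, path) {
  rows <- do.call(rbind, lapply(protograms, function(p) {
    data.frame(subject_id = p$subject_id,
               epoch_index = seq_along(p$indices) - 1L,
               prototype_id = p$indices, condition = p$condition)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protograms
#' @param P Prototype count for the restored objects.
#' @export
read_protograms <- function(path, P) {
  tab <- utils::read.csv(path)
  lapply(split(tab, tab$subject_id), function(d) {
    d <- d[order(d$epoch_index), ]
    structure(list(indices = d$prototype_id, P = P,
                   subject_id = d$subject_id[1], condition = d$condition[1]),
              class = "protogram")
  })
}
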