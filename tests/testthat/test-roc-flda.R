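two_group_labels <- function(npos, nneg)
  c(rep("therapy", npos), rep("control", nneg))

test_that("ROC curves reproduce concordance-counting AUCs", {
  # perfectly separated
  roc <- roc_curve(c(5, 6, 7, 1, 2), two_group_labels(3, 2),
                   "greater_is_positive")
  expect_equal(roc$auc, 1.0)
  # tie across groups: (3 wins + 0.5 tie) / 4
  roc2 <- roc_curve(c(0.9, 0.7, 0.7, 0.1), two_group_labels(2, 2),
                    "greater_is_positive")
  expect_equal(roc2$auc, 0.875)
  # score negation flips the AUC on tie-free data
  withr::with_seed(10, s <- rnorm(12))
  lab <- two_group_labels(6, 6)
  a1 <- roc_curve(s, lab, "greater_is_positive")$auc
  a2 <- roc_curve(-s, lab, "greater_is_positive")$auc
  expect_equal(a1 + a2, 1)
  # direction reversal is equivalent to negation
  expect_equal(roc_curve(s, lab, "less_is_positive")$auc, a2)
  expect_error(roc_curve(1:3, rep("therapy", 3)),
               class = "dwi_validation_error")
})

test_that("AUC equals the tie-corrected Mann-Whitney statistic on random data", {
  withr::with_seed(11, {
    for (i in 1:100) {
      npos <- sample(3:12, 1); nneg <- sample(3:12, 1)
      # mix of continuous and heavily tied scores
      s <- if (i %% 2) rnorm(npos + nneg) else sample(1:4, npos + nneg, TRUE)
      lab <- two_group_labels(npos, nneg)
      roc <- roc_curve(s, lab, "greater_is_positive")
      expect_equal(roc$auc, rank_auc(s[lab == "therapy"],
                                     s[lab != "therapy"]),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    for (i in 1:20) {
      s <- rnorm(23); lab <- two_group_labels(12, 11)
      mine <- roc_curve(s, lab, "greater_is_positive")$auc
      ref <- suppressMessages(pROC::auc(pROC::roc(
        response = lab, predictor = s, levels = c("control", "therapy"),
        direction = "<")))
      expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
    }
  })
})

test_that("optimal threshold maximizes Youden J with the stated tie-breaks", {
  roc <- roc_curve(c(0.5, 0.9, 0.1, 0.3), two_group_labels(2, 2),
                   "greater_is_positive")
  opt <- optimal_threshold(roc)
  expect_equal(opt$threshold, 0.4)
  expect_equal(opt$sens, 1); expect_equal(opt$spec, 1)
  expect_equal(opt$accuracy, 1); expect_equal(opt$youden_j, 1)

  # identical score multisets: J = 0 everywhere, tie-break lands on the
  # highest-specificity sentinel
  roc0 <- roc_curve(c(1, 2, 1, 2), two_group_labels(2, 2),
                    "greater_is_positive")
  opt0 <- optimal_threshold(roc0)
  expect_equal(opt0$youden_j, 0)
  expect_equal(opt0$spec, 1)
  expect_equal(opt0$threshold, Inf)

  # confusion counts TP=11 FN=1 TN=11 FP=0 at a 12-vs-11 design
  scores <- c(seq(2, 13), seq(14, 24))          # therapy low, control high
  scores[1] <- 30                                # one therapy animal misclassified
  roc3 <- roc_curve(scores, two_group_labels(12, 11), "less_is_positive")
  opt3 <- optimal_threshold(roc3)
  expect_equal(opt3$sens, 11 / 12)
  expect_equal(opt3$spec, 1)
  expect_equal(opt3$accuracy, 22 / 23)
  expect_equal(100 * round(opt3$sens, 3), 91.7)
  expect_equal(100 * round(opt3$accuracy, 3), 95.7)
})

test_that("optimal threshold equals an exhaustive scan oracle", {
  withr::with_seed(13, {
    for (i in 1:25) {
      s <- round(rnorm(20), 2)                  # ties likely
      lab <- two_group_labels(10, 10)
      dir <- if (i %% 2) "greater_is_positive" else "less_is_positive"
      roc <- roc_curve(s, lab, dir)
      opt <- optimal_threshold(roc)
      # oracle: evaluate J over every candidate threshold directly
      pos <- s[lab == "therapy"]; neg <- s[lab != "therapy"]
      j_of <- function(t) {
        if (dir == "greater_is_positive") mean(pos > t) + mean(neg <= t) - 1
        else mean(pos < t) + mean(neg >= t) - 1
      }
      best_j <- max(vapply(roc$thresholds, j_of, numeric(1)))
      expect_equal(opt$youden_j, best_j, tolerance = 1e-12)
      expect_equal(j_of(opt$threshold), best_j, tolerance = 1e-12)
    }
  })
})

test_that("DeLong test is null for self-comparison and matches pROC", {
  withr::with_seed(14, s <- rnorm(23))
  lab <- two_group_labels(12, 11)
  self <- delong_test(s, s, lab)
  expect_equal(self$p_value, 1.0)
  expect_equal(self$auc_a, self$auc_b)

  skip_if_not_installed("pROC")
  withr::with_seed(15, {
    for (i in 1:10) {
      a <- rnorm(23); b <- rnorm(23) + 0.3 * a
      mine <- delong_test(a, b, lab)
      ra <- suppressMessages(pROC::roc(lab, a, levels = c("control", "therapy"),
                                       direction = "<"))
      rb <- suppressMessages(pROC::roc(lab, b, levels = c("control", "therapy"),
                                       direction = "<"))
      ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("single-AUC variance from placement values matches pROC on a worked example", {
  skip_if_not_installed("pROC")
  pos <- c(0.8, 0.9, 0.6); neg <- c(0.4, 0.7, 0.3)
  pl <- dwiresponse:::placement_values(pos, neg)
  var_mine <- stats::var(pl$v10) / 3 + stats::var(pl$v01) / 3
  r <- suppressMessages(pROC::roc(two_group_labels(3, 3), c(pos, neg),
                                  levels = c("control", "therapy"),
                                  direction = "<"))
  expect_equal(pl$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  expect_equal(var_mine, as.numeric(pROC::var(r, method = "delong")),
               tolerance = 1e-12)
})

test_that("FLDA recovers the closed-form pooled-scatter direction", {
  feats <- rbind(c(2, 0), c(0, 0), c(1, 1), c(1, -1),      # therapy
                 c(1, 2), c(-1, 2), c(0, 3), c(0, 1))      # control
  labs <- c(rep("therapy", 4), rep("control", 4))
  m <- fit_flda(feats, labs)
  # pooled scatter is proportional to identity, so the direction is
  # parallel to the mean difference (-1, 2); orientation puts control higher
  w <- c(m$w_dvol, m$w_dadc)
  expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-12)
  expect_equal(abs(sum(w * c(2, 1)) / sqrt(5)), 0, tolerance = 1e-12)
  scores <- project_flda(m, feats)
  expect_gt(mean(scores[labs == "control"]), mean(scores[labs == "therapy"]))
  expect_equal(w, c(-1, 2) / sqrt(5), tolerance = 1e-12)
})

test_that("FLDA direction agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  withr::with_seed(16, {
    coh <- random_cohort(17)
    X <- cbind(coh$d_vol_pct, coh$d_adc)
    m <- fit_flda(X, coh$group)
    ref <- MASS::lda(x = X, grouping = coh$group)
    w_ref <- as.numeric(ref$scaling)
    w <- c(m$w_dvol, m$w_dadc)
    # directions are parallel (defined up to scale)
    cosine <- sum(w * w_ref) / sqrt(sum(w^2) * sum(w_ref^2))
    expect_equal(abs(cosine), 1, tolerance = 1e-9)
  })
})

test_that("FLDA degenerate inputs raise errors", {
  feats <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  labs <- c("therapy", "therapy", "control", "control")
  expect_error(fit_flda(feats, labs), class = "dwi_degenerate_error")
  expect_error(fit_flda(feats[1:3, ], labs[1:3]),
               class = "dwi_validation_error")
  # collinear features: singular pooled scatter
  feats2 <- cbind(c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 8, 10, 12))
  labs2 <- c(rep("therapy", 3), rep("control", 3))
  expect_error(fit_flda(feats2, labs2), class = "dwi_degenerate_error")
})

test_that("FLDA scores and ROC are invariant under affine feature rescaling", {
  coh <- random_cohort(18)
  X <- cbind(coh$d_vol_pct, coh$d_adc)
  m1 <- fit_flda(X, coh$group)
  s1 <- project_flda(m1, X)
  # invertible diagonal rescaling plus per-feature offsets
  X2 <- cbind(3.7 * X[, 1] + 12, 0.02 * X[, 2] - 5)
  m2 <- fit_flda(X2, coh$group)
  s2 <- project_flda(m2, X2)
  # projected scores agree up to positive affine transformation
  expect_equal(cor(s1, s2), 1, tolerance = 1e-9)
  r1 <- roc_curve(s1, coh$group, "less_is_positive")
  r2 <- roc_curve(s2, coh$group, "less_is_positive")
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$sens, r2$sens, tolerance = 1e-12)
})

test_that("projection and rescaling follow the reported-weight convention", {
  m <- structure(list(w_dvol = 0.0033, w_dadc = -1.0366, threshold = 0.1,
                      scaling = "unit_norm"), class = "flda_model")
  expect_equal(project_flda(m, cbind(33.30, 0.10)),
               0.0033 * 33.30 - 1.0366 * 0.10)
  expect_equal(project_flda(m, cbind(0, 0)), 0)
  # with a negative dADC weight, increasing dADC strictly decreases the score
  s_low <- project_flda(m, cbind(50, 0.1))
  s_high <- project_flda(m, cbind(50, 0.3))
  expect_lt(s_high, s_low)

  coh <- random_cohort(19)
  fit <- fit_flda(cbind(coh$d_vol_pct, coh$d_adc), coh$group)
  resc <- rescale_flda(fit, -1.0366)
  expect_equal(resc$w_dadc, -1.0366)
  expect_equal(resc$w_dvol / resc$w_dadc, fit$w_dvol / fit$w_dadc,
               tolerance = 1e-12)
  expect_error(rescale_flda(fit, -sign(fit$w_dadc) * 2),
               class = "dwi_validation_error")
})
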