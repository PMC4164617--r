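## Empirical ROC analysis. Threshold candidates are the midpoints between
## consecutive distinct scores plus -Inf/+Inf sentinels — the convention
## under which printed "optimal thresholds" (e.g. a volume-change cutoff of
## 61.35% between two observed animals) are reproducible. AUC is the
## trapezoidal area under the empirical curve, identical to the
## tie-corrected Mann-Whitney concordance statistic.

#' Empirical ROC curve
#'
#' @param scores Numeric vector of classifier scores, finite.
#' @param labels Group labels; exactly two classes must be present.
#' @param direction `"greater_is_positive"` (a case is called positive when
#'   its score exceeds the threshold) or `"less_is_positive"`.
#' @param positive_label The class treated as positive (default
#'   `"therapy"`).
#' @return A list of class `roc_result` with `thresholds`, `sens`, `spec`,
#'   `auc`, `direction`, `positive_label`, and the input `scores`/`labels`.
#' @export
roc_curve <- function(scores, labels,
                      direction = c("greater_is_positive",
                                    "less_is_positive"),
                      positive_label = "therapy") {
  direction <- match.arg(direction)
  if (!all(is.finite(scores)))
    stop_validation("scores must be finite")
  labels <- as.character(labels)
  if (length(unique(labels)) != 2 || !positive_label %in% labels)
    stop_validation("labels must contain exactly two classes incl. '%s'",
                    positive_label)
  pos <- scores[labels == positive_label]
  neg <- scores[labels != positive_label]
  v <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, Inf)
  if (direction == "greater_is_positive") {
    sens <- vapply(thresholds, function(t) mean(pos > t), numeric(1))
    spec <- vapply(thresholds, function(t) mean(neg <= t), numeric(1))
  } else {
    sens <- vapply(thresholds, function(t) mean(pos < t), numeric(1))
    spec <- vapply(thresholds, function(t) mean(neg >= t), numeric(1))
  }
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(thresholds = thresholds, sens = sens, spec = spec,
                 auc = auc, direction = direction,
                 positive_label = positive_label,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s, positive = %s): AUC = %.4f over %d thresholds\n",
              x$direction, x$positive_label, x$auc, length(x$thresholds)))
  invisible(x)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Selects the threshold maximizing Youden's `J = sens + spec - 1`; ties are
#' broken in favour of higher specificity, then of the lower threshold.
#' Accuracy is `(TP + TN) / N` from the raw confusion counts at that
#' threshold.
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @return A list with `threshold`, `sens`, `spec`, `accuracy`, `youden_j`.
#' @export
optimal_threshold <- function(roc) {
  j <- roc$sens + roc$spec - 1
  ord <- order(-j, -roc$spec, roc$thresholds)
  i <- ord[1]
  npos <- sum(roc$labels == roc$positive_label)
  nneg <- sum(roc$labels != roc$positive_label)
  tp <- roc$sens[i] * npos
  tn <- roc$spec[i] * nneg
  list(threshold = roc$thresholds[i], sens = roc$sens[i], spec = roc$spec[i],
       accuracy = (tp + tn) / (npos + nneg), youden_j = j[i])
}

## placement values (structural components): per-case conditional
## concordance probabilities; their means give the AUC
placement_values <- function(pos, neg) {
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two classifiers scored on the same cases (paired
#' design), using the structural-component (placement-value) estimate of the
#' covariance matrix of the two AUCs; the difference is referred to a
#' two-sided z-test. Scores with `"less_is_positive"` direction are negated
#' internally so that both AUCs are oriented the same way.
#'
#' @param scores_a,scores_b Score vectors of the two classifiers on the
#'   same cases.
#' @param labels Group labels shared by both classifiers.
#' @param directions Length-2 character vector of per-classifier directions
#'   (`"greater_is_positive"` or `"less_is_positive"`).
#' @param positive_label The positive class.
#' @return A list with `statistic` (z), `p_value`, `auc_a`, `auc_b`,
#'   `method`, `exact`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        directions = c("greater_is_positive",
                                       "greater_is_positive"),
                        positive_label = "therapy") {
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels))
    stop_validation("both classifiers must score the same cases")
  directions <- rep(directions, length.out = 2)
  sa <- if (directions[1] == "less_is_positive") -scores_a else scores_a
  sb <- if (directions[2] == "less_is_positive") -scores_b else scores_b
  ispos <- labels == positive_label
  if (!any(ispos) || all(ispos))
    stop_validation("both classes must be present")
  pa <- placement_values(sa[ispos], sa[!ispos])
  pb <- placement_values(sb[ispos], sb[!ispos])
  m <- sum(ispos); n <- sum(!ispos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  dauc <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(dauc) < 1e-12) {
      out <- test_result(0, 1, "DeLong AUC comparison", exact = FALSE)
    } else {
      stop_degenerate("zero variance with unequal AUCs")
    }
  } else {
    z <- dauc / sqrt(var_diff)
    out <- test_result(z, 2 * stats::pnorm(-abs(z)), "DeLong AUC comparison",
                       exact = FALSE)
  }
  out$auc_a <- pa$auc
  out$auc_b <- pb$auc
  out
}
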