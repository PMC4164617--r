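## Two-class Fisher linear discriminant combining the volume change
## (percent) and the ADC change (1e-3 mm^2/s). The Fisher direction is
## defined only up to positive scale; the canonical model is unit-norm and
## oriented so that the control group scores higher (therapy falls below
## the decision threshold). For comparison with externally reported weights
## the model can be rescaled so that one weight is pinned.

#' Fit a two-class Fisher linear discriminant on (dVOL, dADC)
#'
#' The weight direction is the inverse pooled within-class covariance
#' (denominator `n1 + n2 - 2`) applied to the difference of class means.
#' The canonical scaling is unit Euclidean norm, oriented so that the
#' control group mean score exceeds the therapy group mean score; the
#' decision threshold is then the Youden-optimal cut of the resubstitution
#' ROC with `"less_is_positive"` for therapy.
#'
#' @param features Numeric matrix/data frame with two columns in the order
#'   `(d_vol_pct, d_adc)`, one row per animal.
#' @param labels Group labels ("therapy"/"control"), >= 2 animals each.
#' @return A list of class `flda_model` with `w_dvol`, `w_dadc`, `scaling`
#'   (`"unit_norm"`), `threshold`, `orientation`
#'   (`"therapy_scores_lower"`) and the training `roc` summary.
#' @export
fit_flda <- function(features, labels) {
  X <- as.matrix(features)
  if (ncol(X) != 2)
    stop_validation("features must have two columns (d_vol_pct, d_adc)")
  labels <- as.character(labels)
  it <- labels == "therapy"; ic <- labels == "control"
  if (sum(it) < 2 || sum(ic) < 2)
    stop_validation("need at least 2 animals per group")
  n1 <- sum(it); n2 <- sum(ic)
  sp <- ((n1 - 1) * stats::cov(X[it, , drop = FALSE]) +
           (n2 - 1) * stats::cov(X[ic, , drop = FALSE])) / (n1 + n2 - 2)
  dmean <- colMeans(X[ic, , drop = FALSE]) - colMeans(X[it, , drop = FALSE])
  if (all(abs(dmean) < 1e-12))
    stop_degenerate("identical group means: discriminant direction undefined")
  w <- tryCatch(solve(sp, dmean),
                error = function(e)
                  stop_degenerate("singular pooled within-class scatter"))
  if (all(abs(w) < 1e-15))
    stop_degenerate("zero discriminant direction")
  w <- w / sqrt(sum(w^2))
  scores <- as.numeric(X %*% w)
  if (mean(scores[ic]) < mean(scores[it])) {
    w <- -w
    scores <- -scores
  }
  roc <- roc_curve(scores, labels, direction = "less_is_positive",
                   positive_label = "therapy")
  opt <- optimal_threshold(roc)
  structure(list(w_dvol = unname(w[1]), w_dadc = unname(w[2]),
                 scaling = "unit_norm", threshold = opt$threshold,
                 orientation = "therapy_scores_lower",
                 roc = roc, optimal = opt),
            class = "flda_model")
}

#' @export
print.flda_model <- function(x, ...) {
  cat(sprintf("FLDA: score = %.4f * dVOL[%%] %+.4f * dADC[1e-3 mm^2/s]\n",
              x$w_dvol, x$w_dadc))
  cat(sprintf("  scaling %s, threshold %.4g (%s), training AUC %.4f\n",
              x$scaling, x$threshold, x$orientation, x$roc$auc))
  invisible(x)
}

#' Project animals onto a fitted discriminant
#'
#' `score = w_dvol * d_vol_pct + w_dadc * d_adc`; lower scores indicate
#' therapy under the canonical orientation, so the scores feed
#' [roc_curve()] with `"less_is_positive"`.
#'
#' @param model An `flda_model`.
#' @param features Two-column matrix `(d_vol_pct, d_adc)`.
#' @return Numeric score vector.
#' @export
project_flda <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != 2)
    stop_validation("features must have two columns (d_vol_pct, d_adc)")
  as.numeric(X %*% c(model$w_dvol, model$w_dadc))
}

#' Rescale a discriminant to a pinned dADC weight
#'
#' Fisher weights are defined up to positive scale; this reparameterizes the
#' model so that `w_dadc` equals a caller-given value (for comparison with
#' weights reported on another scale). The requested value must have the
#' same sign as the canonical weight, since a sign flip would reverse the
#' classifier's orientation.
#'
#' @param model An `flda_model`.
#' @param w_dadc Target dADC weight (same sign as `model$w_dadc`).
#' @return A rescaled `flda_model` with `scaling = "pinned_w_dadc"`.
#' @export
rescale_flda <- function(model, w_dadc) {
  k <- w_dadc / model$w_dadc
  if (!is.finite(k) || k <= 0)
    stop_validation("target w_dadc must be finite and of the canonical sign")
  model$w_dvol <- model$w_dvol * k
  model$w_dadc <- w_dadc
  model$threshold <- model$threshold * k
  model$scaling <- "pinned_w_dadc"
  model
}
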