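## Voxelwise monoexponential ADC estimation: S(b) = S0 * exp(-b * ADC),
## fitted by unweighted nonlinear least squares over S0 > 0 and
## ADC in [0, adc_max]. ADC is handled in units of 1e-3 mm^2/s throughout
## (so free water is about 3 and the default cap is 10).
##
## The solver profiles S0 out analytically (variable projection): for fixed
## ADC the optimal S0 is sum(S*w)/sum(w^2) with w = exp(-b*ADC), leaving a
## one-dimensional maximization of u(A)^2/v(A). That profile function is
## seeded on a coarse grid (together with the log-linear initial estimate)
## and polished by a bracketed, bisection-safeguarded Newton iteration,
## vectorized over all voxels of a map.

#' Average trace diffusion-weighted images
#'
#' Voxelwise arithmetic mean of images acquired with diffusion gradients in
#' three orthogonal directions, removing directional dependence before ADC
#' fitting.
#'
#' @param direction_images List of exactly three equally sized numeric
#'   arrays.
#' @return An array of the same dimensions.
#' @export
trace_average <- function(direction_images) {
  if (!is.list(direction_images) || length(direction_images) != 3L)
    stop_validation("trace_average expects a list of exactly 3 images")
  dims <- lapply(direction_images, function(x) as.integer(dim(x)))
  if (length(unique(dims)) != 1L)
    stop_validation("direction images must share dimensions")
  (direction_images[[1]] + direction_images[[2]] + direction_images[[3]]) / 3
}

#' Fit the monoexponential diffusion model to one voxel
#'
#' Minimizes `sum_b (S(b) - S0 * exp(-b * ADC))^2` over `S0 > 0` and
#' `ADC` in `[0, adc_max]`. The search is initialized from the log-linear
#' least-squares line through `(b, log(max(S, tiny)))` and from a coarse
#' profile-function grid, then refined to machine precision. A voxel where
#' at least half the signals are non-positive (or where the profiled S0 is
#' not positive) is reported as not converged rather than raising an error.
#'
#' @param signal Numeric vector of signal intensities, one per b-value.
#' @param bvalues Numeric vector of b-values in s/mm^2, length >= 2.
#' @param adc_max Upper ADC bound, units 1e-3 mm^2/s (default 10). Fits
#'   landing on a bound still count as converged.
#' @return A list with `adc` (1e-3 mm^2/s), `s0` (signal units),
#'   `residual_norm` (root-mean-square residual) and `converged`.
#' @export
fit_voxel <- function(signal, bvalues, adc_max = 10) {
  if (length(bvalues) < 2L)
    stop_validation("at least 2 b-values are required")
  if (length(signal) != length(bvalues))
    stop_validation("signal and bvalues must have equal length")
  if (!all(is.finite(signal)))
    stop_validation("signal must be finite")
  fit <- fit_adc_series(matrix(signal, nrow = 1), bvalues, adc_max = adc_max)
  list(adc = fit$adc[1], s0 = fit$s0[1],
       residual_norm = fit$residual_norm[1], converged = fit$converged[1])
}

#' Fit many voxels at once
#'
#' Vectorized backend of [fit_voxel()]: each row of `signals` is one voxel's
#' signal over the b-values.
#'
#' @param signals Numeric matrix, voxels in rows, b-values in columns.
#' @inheritParams fit_voxel
#' @return A list of vectors `adc`, `s0`, `residual_norm`, `converged`.
#' @export
fit_adc_series <- function(signals, bvalues, adc_max = 10) {
  signals <- as.matrix(signals)
  nb <- length(bvalues)
  stopifnot(ncol(signals) == nb, nb >= 2)
  bk <- as.numeric(bvalues) / 1000          # ADC unit: 1e-3 mm^2/s
  nv <- nrow(signals)

  fittable <- rowSums(signals <= 0) < nb / 2
  adc <- rep(NA_real_, nv); s0 <- rep(NA_real_, nv)
  rss <- rep(NA_real_, nv); conv <- rep(FALSE, nv)
  if (!any(fittable))
    return(list(adc = adc, s0 = s0, residual_norm = rss, converged = conv))

  S <- signals[fittable, , drop = FALSE]
  ssq <- rowSums(S^2)

  # profile function phi(A) = u^2/v (u > 0), maximized over A
  profile_uv <- function(A) {
    W <- exp(-outer(A, bk))                 # nvox x nb
    u <- rowSums(S * W)
    list(u = u,
         u1 = -rowSums(S * W * rep(bk, each = length(A))),
         u2 = rowSums(S * W * rep(bk^2, each = length(A))),
         v = rowSums(W^2),
         v1 = -2 * rowSums(W^2 * rep(bk, each = length(A))),
         v2 = 4 * rowSums(W^2 * rep(bk^2, each = length(A))))
  }
  phi_only <- function(A) {
    W <- exp(-outer(A, bk))
    u <- pmax(rowSums(S * W), 0)
    u^2 / rowSums(W^2)
  }

  # seed: coarse grid plus per-voxel log-linear slope
  grid <- seq(0, adc_max, length.out = 161L)
  Wg <- exp(-outer(bk, grid))               # nb x ngrid
  Ug <- pmax(S %*% Wg, 0)
  vg <- colSums(Wg^2)
  Qg <- sweep(Ug^2, 2, vg, "/")
  best <- max.col(Qg, ties.method = "first")
  step <- grid[2] - grid[1]

  logS <- log(pmax(S, .Machine$double.xmin))
  bc <- bk - mean(bk)
  slope <- (logS %*% bc) / sum(bc^2)
  a_ll <- pmin(pmax(-as.numeric(slope), 0), adc_max)
  better <- phi_only(a_ll) > Qg[cbind(seq_len(nrow(S)), best)]
  A <- ifelse(better, a_ll, grid[best])
  lo <- pmax(pmin(A, grid[pmax(best - 1L, 1L)]), 0)
  hi <- pmin(pmax(A, grid[pmin(best + 1L, length(grid))]), adc_max)

  # bracketed Newton on phi'(A) = 0 with bisection fallback
  for (iter in 1:100) {
    p <- profile_uv(A)
    upos <- pmax(p$u, 0)
    phi1 <- 2 * upos * p$u1 / p$v - upos^2 * p$v1 / p$v^2
    phi2 <- 2 * (p$u1^2 + upos * p$u2) / p$v - 4 * upos * p$u1 * p$v1 / p$v^2 -
      upos^2 * p$v2 / p$v^2 + 2 * upos^2 * p$v1^2 / p$v^3
    lo <- ifelse(phi1 > 0, A, lo)
    hi <- ifelse(phi1 > 0, hi, A)
    newton <- A - phi1 / phi2
    use_newton <- is.finite(newton) & phi2 < 0 & newton > lo & newton < hi
    A_new <- ifelse(use_newton, newton, (lo + hi) / 2)
    done <- (hi - lo) < 1e-13 * pmax(1, A) | abs(A_new - A) < 1e-15 * pmax(1, A)
    A <- A_new
    if (all(done)) break
  }
  # boundary optima: keep the bound if the profile is best there
  A <- ifelse(phi_only(pmin(A, adc_max)) >= phi_only(A), pmin(A, adc_max), A)
  at0 <- phi_only(rep(0, length(A))) >= phi_only(A)
  A <- ifelse(at0, 0, A)
  A <- pmin(pmax(A, 0), adc_max)

  pf <- profile_uv(A)
  s0f <- pf$u / pf$v
  # residual evaluated directly (the profile identity ssq - u^2/v cancels
  # catastrophically when the fit is near-exact)
  Wf <- exp(-outer(A, bk))
  res <- rowSums((S - s0f * Wf)^2)
  ok <- is.finite(A) & is.finite(s0f) & s0f > 0
  adc[fittable] <- ifelse(ok, A, NA_real_)
  s0[fittable] <- ifelse(ok, s0f, NA_real_)
  rss[fittable] <- ifelse(ok, sqrt(pmax(res, 0) / nb), NA_real_)
  conv[fittable] <- ok
  list(adc = adc, s0 = s0, residual_norm = rss, converged = conv)
}

#' Compute a voxelwise ADC map for a study
#'
#' Applies [fit_voxel()] to every voxel (or only those inside `mask`) of a
#' registered study. Voxels where the fit does not converge — in particular
#' voxels where at least half the signals are non-positive, such as
#' background air — are flagged invalid and excluded from all downstream
#' statistics.
#'
#' @param study A [dwi_study()], already registered if motion is present.
#' @param mask Optional [voi_mask()] restricting the fit; must share the
#'   study's grid dimensions.
#' @param adc_max Upper ADC bound in 1e-3 mm^2/s.
#' @return An [adc_map()] sharing the study's geometry.
#' @export
compute_adc_map <- function(study, mask = NULL, adc_max = 10) {
  stopifnot(inherits(study, "dwi_study"))
  d <- dim(study$volumes)
  nvox <- prod(d[1:3])
  sel <- if (is.null(mask)) rep(TRUE, nvox) else {
    if (!identical(dim(mask$mask), d[1:3]))
      stop_validation("mask dimensions do not match study")
    as.vector(mask$mask)
  }
  S <- matrix(study$volumes, nrow = nvox)[sel, , drop = FALSE]
  fit <- fit_adc_series(S, study$bvalues, adc_max = adc_max)
  values <- rep(NA_real_, nvox); s0 <- rep(NA_real_, nvox)
  valid <- rep(FALSE, nvox)
  values[sel] <- fit$adc; s0[sel] <- fit$s0; valid[sel] <- fit$converged
  adc_map(array(values, d[1:3]), array(s0, d[1:3]), array(valid, d[1:3]),
          voxel_size = study$voxel_size,
          slice_thickness = study$slice_thickness,
          slice_gap = study$slice_gap)
}
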