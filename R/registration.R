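## Translation-only alignment of the DWI series along the b-value dimension.
## The estimator is phase correlation (spectrally whitened Fourier
## cross-correlation) with quadratic sub-voxel refinement; resampling uses a
## Fourier phase ramp, so boundary semantics are circular throughout.

#' Circularly shift a 2D image by a (possibly fractional) displacement
#'
#' Positive `dy`/`dx` move image content towards higher indices along the
#' first/second array axis. Integer displacements are applied by exact
#' index rolling; fractional ones by band-limited Fourier interpolation
#' (phase ramp in the frequency domain).
#'
#' @param img 2D numeric matrix.
#' @param dy,dx Displacement in voxels along axes 1 and 2.
#' @return The shifted matrix.
#' @export
shift_image <- function(img, dy, dx) {
  n <- nrow(img); m <- ncol(img)
  if (dy == round(dy) && dx == round(dx)) {
    i <- ((seq_len(n) - 1 - round(dy)) %% n) + 1
    j <- ((seq_len(m) - 1 - round(dx)) %% m) + 1
    return(img[i, j, drop = FALSE])
  }
  ky <- fft_freqs(n); kx <- fft_freqs(m)
  ramp <- exp(-2i * pi * (outer(ky * dy / n, kx * dx / m, `+`)))
  Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE)) / (n * m)
}

## signed DFT frequency indices 0,1,...,-1 (Nyquist mapped to -n/2)
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ((k + floor(n / 2)) %% n) - floor(n / 2)
}

#' Estimate the in-plane displacement between two images
#'
#' Phase correlation: the cross-power spectrum of the two images is
#' normalized to unit magnitude and inverted; its peak locates the
#' translation. Sub-voxel refinement evaluates the correlation surface on an
#' upsampled grid (step 0.01 voxel) within half a voxel of the integer peak
#' by a local matrix DFT, so integer displacements of periodic images are
#' recovered exactly and symmetric peaks stay centred. The returned
#' displacement is the shift that maps `reference` onto `moving`, i.e.
#' applying the negated estimate to `moving` aligns it with `reference`.
#'
#' @param reference,moving 2D matrices of equal size, neither constant.
#' @param upsample Sub-voxel grid refinement factor (default 100, i.e.
#'   0.01-voxel resolution).
#' @return A list with `dy`, `dx` (voxels, fractional) and `peak_score`
#'   (normalized correlation-peak height in `[0, 1]`).
#' @export
estimate_shift <- function(reference, moving, upsample = 100L) {
  if (!identical(dim(reference), dim(moving)))
    stop_validation("reference and moving images must have equal dimensions")
  if (near_constant(reference) || near_constant(moving))
    stop_degenerate("cannot register a constant image")
  n <- nrow(reference); m <- ncol(reference)
  fr <- stats::fft(reference)
  fm <- stats::fft(moving)
  cps <- fr * Conj(fm)
  mag <- Mod(cps)
  eps <- .Machine$double.eps * max(mag)
  R <- cps / (mag + eps)
  surf <- Re(stats::fft(R, inverse = TRUE)) / (n * m)
  p <- arrayInd(which.max(surf), dim(surf)) - 1L    # 0-based peak
  py <- signed_index(p[1], n)
  px <- signed_index(p[2], m)
  # local DFT evaluation of the surface around the integer peak
  dg <- seq(-0.5, 0.5, by = 1 / upsample)
  ky <- fft_freqs(n); kx <- fft_freqs(m)
  ay <- exp(2i * pi * outer(py + dg, ky) / n)       # |dg| x n
  bx <- exp(2i * pi * outer(kx, px + dg) / m)       # m x |dg|
  S <- Re(ay %*% R %*% bx) / (n * m)
  q <- arrayInd(which.max(S), dim(S))
  list(dy = -(py + dg[q[1]]), dx = -(px + dg[q[2]]),
       peak_score = min(max(max(S), 0), 1))
}

signed_index <- function(p, n) ((p + floor(n / 2)) %% n) - floor(n / 2)

## featureless up to floating-point ripple (e.g. a Fourier-shifted constant)
near_constant <- function(x) {
  s <- stats::sd(x)
  s == 0 || s <= 1e-9 * mean(abs(x))
}

#' Register a DWI series along the b-value dimension
#'
#' Each slice of each volume is aligned to the matching slice of the
#' reference volume (by default the lowest b-value, which has the highest
#' signal-to-noise ratio) using [estimate_shift()]; the negated estimate is
#' then applied with [shift_image()]. Volumes whose estimated shift is zero
#' are passed through untouched, so a motion-free series is returned
#' bit-identically. Registration is translation-only and in-plane.
#'
#' @param study A [dwi_study()].
#' @param reference_index Index (in ascending-b order) of the reference
#'   volume; default 1, the lowest b-value.
#' @return A list with `study` (the registered [dwi_study()]) and `shifts`,
#'   a data frame with columns `bvalue`, `slice`, `dy`, `dx`, `peak_score`.
#' @export
register_series <- function(study, reference_index = 1L) {
  stopifnot(inherits(study, "dwi_study"))
  nb <- length(study$bvalues)
  if (reference_index < 1 || reference_index > nb)
    stop_validation("reference_index out of range")
  d <- dim(study$volumes)
  out <- study$volumes
  rows <- vector("list", nb * d[3])
  r <- 0L
  for (bi in seq_len(nb)) {
    for (sl in seq_len(d[3])) {
      r <- r + 1L
      if (bi == reference_index) {
        rows[[r]] <- data.frame(bvalue = study$bvalues[bi], slice = sl,
                                dy = 0, dx = 0, peak_score = 1)
        next
      }
      ref_sl <- study$volumes[, , sl, reference_index]
      mov_sl <- study$volumes[, , sl, bi]
      if (near_constant(ref_sl) && near_constant(mov_sl)) {
        # two featureless slices carry no motion information and shifting a
        # constant image is the identity: zero is the correct alignment
        rows[[r]] <- data.frame(bvalue = study$bvalues[bi], slice = sl,
                                dy = 0, dx = 0,
                                peak_score = as.numeric(isTRUE(
                                  all.equal(ref_sl, mov_sl))))
        next
      }
      est <- tryCatch(
        estimate_shift(ref_sl, mov_sl),
        dwi_degenerate_error = function(e)
          stop_degenerate("b = %g, slice %d: %s",
                          study$bvalues[bi], sl, conditionMessage(e)))
      if (abs(est$dy) > 1e-9 || abs(est$dx) > 1e-9)
        out[, , sl, bi] <- shift_image(study$volumes[, , sl, bi],
                                       -est$dy, -est$dx)
      rows[[r]] <- data.frame(bvalue = study$bvalues[bi], slice = sl,
                              dy = est$dy, dx = est$dx,
                              peak_score = est$peak_score)
    }
  }
  registered <- study
  registered$volumes <- out
  list(study = registered, shifts = do.call(rbind, rows))
}
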