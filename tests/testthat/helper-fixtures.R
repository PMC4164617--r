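# Fixtures shared across test files; everything is generated in code.

paper_bvalues <- c(10, 25, 50, 80, 130, 200, 350, 550, 800)

# small phantom whose tumor spans every slice, so all slices are registrable
small_phantom_config <- function(...) {
  phantom_config(dims = c(32, 28, 5), center = c(16.5, 14.5, 3),
                 semi_axes = c(9, 7, 2), ...)
}

# smooth test image: Gaussian blob plus low-level texture, away from edges
blob_image <- function(n = 32, m = 32, seed = 1) {
  withr::with_seed(seed, {
    g <- outer(stats::dnorm(seq(-3, 3, length.out = n)),
               stats::dnorm(seq(-3, 3, length.out = m)))
    g + matrix(stats::rnorm(n * m, 0, 1e-4), n, m)
  })
}

# brute-force argmax of the circular cross-correlation over integer shifts
brute_force_shift <- function(reference, moving) {
  n <- nrow(reference); m <- ncol(reference)
  best <- c(0, 0); best_cc <- -Inf
  for (dy in seq_len(n) - 1 - floor(n / 2)) {
    for (dx in seq_len(m) - 1 - floor(m / 2)) {
      cc <- sum(reference * shift_image(moving, -dy, -dx))
      if (cc > best_cc) { best_cc <- cc; best <- c(dy, dx) }
    }
  }
  best
}

# exact two-sided signed-rank p by enumeration of all 2^n sign assignments
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# exact two-sided Mann-Whitney p by enumeration of all group labelings
enum_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  u_all <- apply(combs, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# tie-aware concordance AUC via ranks (Mann-Whitney identity oracle)
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

random_cohort <- function(seed) {
  generate_cohort(cohort_config(seed = seed))
}
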