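# Fixtures are built in code: a minimal hand-laid landmark scene whose
# feature values are known analytically, plus small cohort configurations.

# A flat image with a given RGB color, 0-255 scale.
flat_image <- function(size, rgb) {
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Hand-constructed landmark set on a flat image: circular disc of radius
# 60 at the centre of a 768 image, fovea 300 px temporal (image-left),
# crossings on the 104 px-radius measurement circle at known angles.
hand_landmarks <- function(angles = c(ST_RA = 60, IT_RA = 55,
                                      ST_VA = 70, IT_VA = 65),
                           disc_center = c(400, 384),
                           fovea = c(100, 384),
                           disc_radius = 60) {
  t <- seq(0, 2 * pi, length.out = 33)[-33]
  boundary <- cbind(disc_center[1] + disc_radius * cos(t),
                    disc_center[2] + disc_radius * sin(t))
  r <- 104
  cross <- lapply(names(angles), function(v) {
    a <- angles[[v]] * pi / 180
    up <- if (grepl("^ST", v)) -1 else 1     # image y grows downward
    disc_center + r * c(-cos(a), up * sin(a))
  })
  names(cross) <- names(angles)
  list(disc_center = disc_center, fovea = fovea,
       disc_boundary = boundary, crossings = cross)
}

# Small cohort configuration helpers
null_config <- function(n = 400, seed = 1) {
  cohort_config(n_subjects = n, seed = seed,
                feature_effect_sizes = rep(0, 33),
                target_oracle_auc = NULL)
}

small_cohort <- function(n = 120, seed = 42, ...) {
  simulate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
}

# Independent ridge objective used by oracle tests (no shared code with
# the fitter beyond R primitives).
toy_objective <- function(X, y, b, lambda) {
  eta <- drop(X %*% b)
  sum(y * eta - log1p(exp(eta))) - lambda * sum(b^2)
}

# Exhaustive grid maximizer of the penalized log-likelihood over a box,
# staged coarse-to-fine (valid because the objective is strictly concave
# for lambda > 0): a 0.01-step scan of the full box, then a 0.001-step
# scan of the surrounding 0.05-box, equals the full 0.001-step argmax.
grid_oracle <- function(X, y, lambda, box = 5, steps = c(0.01, 0.001)) {
  eval_grid <- function(g1, g2) {
    B <- as.matrix(expand.grid(b1 = g1, b2 = g2))
    eta <- X %*% t(B)                        # n x n_grid
    val <- colSums(y * eta - log1p(exp(eta))) - lambda * rowSums(B^2)
    B[which.max(val), ]
  }
  g <- seq(-box, box, by = steps[1])
  best <- eval_grid(g, g)
  g1 <- seq(best[1] - 5 * steps[1], best[1] + 5 * steps[1], by = steps[2])
  g2 <- seq(best[2] - 5 * steps[1], best[2] + 5 * steps[1], by = steps[2])
  eval_grid(g1, g2)
}
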