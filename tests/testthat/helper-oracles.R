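# Independent oracles and small fixture builders shared across test files.

# O(n^2) pair-enumeration AUC: P(score+ > score-) + 0.5 P(equal).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Naive generalized-Procrustes oracle: alternating minimization where each
# per-shape similarity fit is solved as a plain linear least-squares problem
# in (a, b, tx, ty) with [x', y'] = [a x - b y + tx, b x + a y + ty].
procrustes_oracle <- function(shapes, iters = 200) {
  norm1 <- function(p) {
    p <- sweep(p, 2, colMeans(p))
    p / sqrt(mean(rowSums(p^2)))
  }
  fit_one <- function(from, to) {
    n <- nrow(from)
    A <- rbind(cbind(from[, 1], -from[, 2], 1, 0),
               cbind(from[, 2],  from[, 1], 0, 1))
    y <- c(to[, 1], to[, 2])
    beta <- solve(crossprod(A), crossprod(A, y))
    cbind(beta[1] * from[, 1] - beta[2] * from[, 2] + beta[3],
          beta[2] * from[, 1] + beta[1] * from[, 2] + beta[4])
  }
  mean_shape <- norm1(shapes[[1]])
  for (i in seq_len(iters)) {
    aligned <- lapply(shapes, fit_one, to = mean_shape)
    new_mean <- norm1(Reduce(`+`, aligned) / length(aligned))
    if (sqrt(mean((new_mean - mean_shape)^2)) < 1e-12) break
    mean_shape <- new_mean
  }
  mean_shape
}

# Shapes drawn from a known two-mode linear generator around the PA
# template: returns the shapes plus the true modes and eigenvalues.
two_mode_shapes <- function(n, eig = c(9, 1), amp = 1e-3, seed = 1) {
  base <- kneestudy:::normalize_shape(knee_template("PA")$points)
  d <- length(base)
  set.seed(seed)
  u1 <- rnorm(d); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- rnorm(d); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  b1 <- rnorm(n, 0, sqrt(eig[1]) * amp)
  b2 <- rnorm(n, 0, sqrt(eig[2]) * amp)
  shapes <- lapply(seq_len(n), function(i) {
    matrix(as.vector(base) + b1[i] * u1 + b2[i] * u2, ncol = 2)
  })
  list(shapes = shapes, modes = cbind(u1, u2), eigenvalues = eig * amp^2)
}

# Principal angles (degrees) between column spaces.
principal_angles_deg <- function(U, V) {
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  s <- svd(crossprod(qu, qv))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

# Render a small set of PA knees and return images + landmarks.
render_set <- function(n, seed, image_size = 160) {
  cfg <- cohort_config(n_subjects = 1, image_size = image_size)
  set.seed(seed)
  out <- lapply(rnorm(n), function(s) render_knee(s, "PA", cfg))
  list(images = lapply(out, `[[`, "image"),
       landmarks = lapply(out, `[[`, "landmarks"),
       config = cfg)
}
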