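# Shared test utilities: batch-mean standard errors for autocorrelated MC
# series, and an independent naive-move Metropolis sampler used as an
# oracle for the crankshaft kernel.

batch_se <- function(v, n_batches = 50) {
  bm <- tapply(v, cut(seq_along(v), n_batches), mean)
  stats::sd(bm) / sqrt(n_batches)
}

ring_joint_angles <- function(p) {
  n <- nrow(p)
  a <- p - p[c(n, 1:(n - 1)), , drop = FALSE]
  b <- p[c(2:n, 1), , drop = FALSE] - p
  dot <- rowSums(a * b)
  crs <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  atan2(sqrt(rowSums(crs^2)), dot)
}

# Independent sampler on a uniform ring (all bonds length 1, uniform
# kappa): perturb one node with an isotropic Gaussian step, re-project it
# onto the circle where both incident bonds keep length 1, and accept or
# reject by Metropolis on the total bending energy.  A different move set
# from the crankshaft kernel, sampling the same constrained ensemble.
naive_ring_sampler <- function(n, kappa, n_steps, sigma = 0.5,
                               record_interval = 100, seed = 1) {
  set.seed(seed)
  g <- build_ring(n, 1, kappa)
  p <- cbind(g$nodes$x, g$nodes$y, g$nodes$z)
  nm <- c(n, 1:(n - 1))
  np <- c(2:n, 1)
  energy_of <- function(pp) sum(0.5 * kappa * ring_joint_angles(pp)^2)
  e_cur <- energy_of(p)
  rec <- numeric(n_steps %/% record_interval)
  acc <- 0L
  for (i in seq_len(n_steps)) {
    u <- sample.int(n, 1)
    A <- p[nm[u], ]
    B <- p[np[u], ]
    q <- p[u, ] + rnorm(3, 0, sigma)
    ab <- B - A
    abn <- sqrt(sum(ab^2))
    if (abn < 2) {
      nhat <- ab / abn
      cen <- (A + B) / 2
      rc <- sqrt(1 - abn^2 / 4)
      w <- q - cen
      w <- w - sum(w * nhat) * nhat
      wn <- sqrt(sum(w^2))
      if (wn > 1e-12) {
        trial <- p
        trial[u, ] <- cen + rc * w / wn
        e_new <- energy_of(trial)
        if (e_new - e_cur <= 0 || runif(1) < exp(-(e_new - e_cur))) {
          p <- trial
          e_cur <- e_new
          acc <- acc + 1L
        }
      }
    }
    if (i %% record_interval == 0) rec[i / record_interval] <- e_cur
  }
  list(energies = rec, acceptance = acc / n_steps, positions = p)
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
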