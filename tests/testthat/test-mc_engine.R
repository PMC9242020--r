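test_that("crankshaft move is the identity at 0 and 2*pi and preserves bonds", {
  g <- build_loop(params = sim_params())
  p0 <- cbind(g$nodes$x, g$nodes$y, g$nodes$z)

  g_id <- crankshaft_move(g, 12, 0)
  expect_equal(cbind(g_id$nodes$x, g_id$nodes$y, g_id$nodes$z), p0)

  g_full <- crankshaft_move(g, 12, 2 * pi)
  expect_lt(max(abs(cbind(g_full$nodes$x, g_full$nodes$y,
                          g_full$nodes$z) - p0)), 1e-9)

  set.seed(5)
  for (i in 1:20) {
    node <- sample.int(38, 1)
    g2 <- crankshaft_move(g, node, runif(1, -pi, pi))
    expect_equal(attr(g2, "status"), "ok")
    expect_lt(max(abs(realized_bond_lengths(g2) - g2$bond_lengths)), 1e-9)
    # only the moved node changes
    moved <- which(g2$nodes$x != g$nodes$x | g2$nodes$y != g$nodes$y |
                     g2$nodes$z != g$nodes$z)
    expect_true(all(moved == node))
  }
})

test_that("a degenerate rotation axis is flagged and leaves the geometry alone", {
  # fold-back square: node 2's neighbours (1 and 3) are distinct, but node
  # 3's neighbours (2 and 4) coincide after collapsing 4 onto 2
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1, 0, 0))
  g <- loop_geometry(pos, rep("rigid", 4), rep(1, 4), rep(1, 4))
  g2 <- crankshaft_move(g, 3, 1)
  expect_equal(attr(g2, "status"), "degenerate_axis")
  expect_equal(g2$nodes$x, g$nodes$x)
})

test_that("Metropolis acceptance follows min(1, exp(-dE))", {
  # dE < 0 is always accepted
  expect_true(all(vapply(1:50, function(i) methbend:::metropolis_accept(-1),
                         logical(1))))
  # dE = +1 kT accepted with probability 1/e (binomial 3-sigma band)
  set.seed(31)
  n <- 1e5
  acc <- mean(vapply(seq_len(n), function(i)
    methbend:::metropolis_accept(1), logical(1)))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("incremental energy change matches full recomputation", {
  set.seed(77)
  g <- build_loop(params = sim_params(kink = kink_spec()))
  params <- sim_params()
  worst <- 0
  n_acc <- 0
  for (i in 1:600) {
    e_before <- bending_energy(g)$total_energy_kT
    st <- metropolis_step(g, params)
    if (st$accepted) {
      e_after <- bending_energy(st$geometry)$total_energy_kT
      worst <- max(worst, abs((e_after - e_before) - st$delta_E))
      n_acc <- n_acc + 1
    }
    g <- st$geometry
  }
  expect_gt(n_acc, 100)
  expect_lt(worst, 1e-8)
})

test_that("run_simulation is reproducible from its seed and bonds do not drift", {
  p <- sim_params(seed = 91, n_equil = 1e4, n_sample = 2e4)
  t1 <- run_simulation(p)
  t2 <- run_simulation(p)
  expect_identical(t1$energy_ds_kT, t2$energy_ds_kT)
  expect_identical(t1$dye_distance_nm, t2$dye_distance_nm)
  t3 <- run_simulation(sim_params(seed = 92, n_equil = 1e4, n_sample = 2e4))
  expect_false(identical(t1$energy_ds_kT, t3$energy_ds_kT))

  # zero-step run: valid empty trajectory
  t0 <- run_simulation(sim_params(seed = 1, n_equil = 0, n_sample = 0))
  expect_equal(nrow(t0), 0)

  # no bond-length drift over 1e6 moves
  tl <- run_simulation(sim_params(seed = 9, n_equil = 0, n_sample = 1e6))
  gf <- attr(tl, "final_geometry")
  expect_lt(max(abs(realized_bond_lengths(gf) - gf$bond_lengths)), 1e-8)
})

test_that("Boltzmann average energy is bounded below by the rigid-limit minimum", {
  # uniform ring: ground state is the regular polygon, 2 pi^2 kappa / N
  g <- build_ring(8, 1, 500)
  tr <- run_simulation(sim_params(seed = 3, n_equil = 5e4, n_sample = 1e5),
                       geom = g, dye_nodes = NULL)
  expect_gt(mean(tr$energy_total_kT), 2 * pi^2 * 500 / 8)
})

test_that("sampled joint-angle distribution matches exact Boltzmann weights on a square ring", {
  # moves restricted to nodes 2 and 4 keep the diagonal |p1 - p3| fixed;
  # the reachable shapes are parameterized by the azimuths of nodes 2 and
  # 4 about the p1-p3 axis, where uniform-angle crankshaft proposals are
  # symmetric, so the stationary law of dpsi = psi2 - psi4 is
  # proportional to exp(-E(dpsi)).  Compare the sampled joint angle at
  # node 1 with dense numerical integration of that density.
  d <- sqrt(2)
  r <- sqrt(1 - d^2 / 4)
  shape <- function(dpsi) {
    rbind(c(0, 0, 0), c(r * cos(dpsi), r * sin(dpsi), d / 2),
          c(0, 0, d), c(r, 0, d / 2))
  }
  grid <- seq(1e-3, 2 * pi - 1e-3, length.out = 4000)
  E <- vapply(grid, function(a) sum(0.5 * ring_joint_angles(shape(a))^2), 1)
  TH <- vapply(grid, function(a) ring_joint_angles(shape(a))[1], 1)
  w <- exp(-E)
  o <- order(TH)
  F_exact <- stats::approxfun(TH[o], cumsum(w[o]) / sum(w), yleft = 0,
                              yright = 1, rule = 2, ties = "ordered")

  set.seed(99)
  g <- build_ring(4, 1, 1)
  p <- cbind(g$nodes$x, g$nodes$y, g$nodes$z)
  energy_of <- function(pp) sum(0.5 * ring_joint_angles(pp)^2)
  e_cur <- energy_of(p)
  n_samp <- 8000
  thin <- 20
  samp <- numeric(n_samp)
  gg <- g
  for (i in seq_len(n_samp * thin)) {
    node <- if (runif(1) < 0.5) 2L else 4L
    trial <- crankshaft_move(gg, node, runif(1, -pi, pi))
    pt <- cbind(trial$nodes$x, trial$nodes$y, trial$nodes$z)
    e_new <- energy_of(pt)
    if (e_new - e_cur <= 0 || runif(1) < exp(-(e_new - e_cur))) {
      gg <- trial
      e_cur <- e_new
    }
    if (i %% thin == 0) samp[i / thin] <- joint_angle(gg, 1)
  }
  D <- max(abs(F_exact(sort(samp)) - seq_len(n_samp) / n_samp))
  expect_lt(D, 1.63 / sqrt(n_samp))  # 1% Kolmogorov-Smirnov critical value
})

test_that("energy series is stationary after equilibration", {
  tr <- run_simulation(sim_params(seed = 12, n_equil = 2e5, n_sample = 2e5))
  e <- tr$energy_ds_kT
  h <- length(e) %/% 2
  first <- e[1:h]
  second <- e[(h + 1):(2 * h)]
  se <- sqrt(batch_se(first, 20)^2 + batch_se(second, 20)^2)
  expect_lt(abs(mean(first) - mean(second)), 3 * se)
})

test_that("a kink with the rigid modulus is indistinguishable from no kink", {
  # degenerate kink: denatured joints get exactly the dsDNA modulus
  base <- sim_params(seed = 55, n_equil = 1e5, n_sample = 1e5,
                     kink = kink_spec(modulus = 50 / 0.34))
  sw <- sweep_persistence_length(base, L_P_grid = 50, replicates = 4)
  nk <- sw[sw$form == "non-kink", ]
  kk <- sw[sw$form == "kink", ]
  se <- sqrt(nk$se_energy_ds_kT^2 + kk$se_energy_ds_kT^2)
  expect_lt(abs(nk$mean_energy_ds_kT - kk$mean_energy_ds_kT), 3 * se)
})

test_that("local-stiffness multiplier 1 reproduces the plain kinked run", {
  base <- sim_params(seed = 21, n_equil = 2e4, n_sample = 2e4,
                     kink = kink_spec())
  sw <- sweep_local_stiffness(base, multiplier_grid = 1, replicates = 2)
  # replicate seeds count up from the base seed; multiplier 1 leaves the
  # geometry untouched, so the sweep must reproduce plain kinked runs
  means <- vapply(0:1, function(k) {
    p <- base
    p$seed <- base$seed + k
    mean(run_simulation(p, watch_joints = c(15L, 16L))$watch_angle)
  }, numeric(1))
  expect_equal(sw$mean_kink_angle_rad[1], mean(means), tolerance = 1e-12)
})

test_that("stiffening the non-kink region straightens it while the kink stays the hinge", {
  base <- sim_params(seed = 70, n_equil = 1e5, n_sample = 1e5,
                     kink = kink_spec())
  sw <- sweep_local_stiffness(base, multiplier_grid = c(1, 100),
                              replicates = 3)
  # stiff limit: non-kink joints straighter than baseline
  expect_lt(sw$mean_nonkink_angle_rad[2], sw$mean_nonkink_angle_rad[1])
  # the denatured joints carry substantially more bending than the stiff ones
  expect_gt(sw$mean_kink_angle_rad[1], 2 * sw$mean_nonkink_angle_rad[1])
})

test_that("single-point dye-distance sweep equals the plain trajectory mean", {
  base <- sim_params(seed = 14, n_equil = 2e4, n_sample = 2e4,
                     kink = kink_spec())
  sw <- mean_dye_distance_vs_stiffness(base, L_P_grid = 50, replicates = 2)
  p1 <- base
  p1$seed <- base$seed  # first replicate seed is the base seed
  tr <- run_simulation(p1)
  p2 <- base
  p2$seed <- base$seed + 1L
  tr2 <- run_simulation(p2)
  expect_equal(sw$mean_dye_distance_nm,
               mean(c(mean(tr$dye_distance_nm), mean(tr2$dye_distance_nm))),
               tolerance = 1e-12)
})
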