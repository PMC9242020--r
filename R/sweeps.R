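#' Replicate seeds derived from a base seed
#'
#' Seeds are assigned by a running counter (`seed`, `seed + 1`, ...) so a
#' sweep is reproducible end to end from its base seed.
#' @noRd
seed_counter <- function(base) {
  i <- 0L
  function() {
    i <<- i + 1L
    as.integer(base + i - 1L)
  }
}

run_replicates <- function(params, replicates, next_seed, geom = NULL,
                           watch_joints = NULL, watch_joints2 = NULL) {
  purrr::map(seq_len(replicates), function(r) {
    p <- params
    p$seed <- next_seed()
    run_simulation(p, geom = geom, watch_joints = watch_joints,
                   watch_joints2 = watch_joints2)
  })
}

rep_stats <- function(values) {
  list(mean = mean(values), se = sd(values) / sqrt(length(values)))
}

#' Sweep the dsDNA persistence length for kink and non-kink forms
#'
#' For each persistence length on the grid, runs `replicates` independent
#' simulations of the loop with and without a denatured kink (independent
#' seeds counted up from `base_params$seed`) and summarises the mean dsDNA
#' bending energy and mean dye-to-dye distance per form, with standard
#' errors across replicates.
#'
#' @param base_params a [sim_params()]; its `kink` (or the default
#'   [kink_spec()]) defines the kink arm of the sweep.
#' @param L_P_grid strictly increasing dsDNA persistence lengths, nm.
#' @param replicates independent runs per grid point per form (>= 2).
#' @return A tibble of class `pl_sweep`: columns `L_Pds`, `form`
#'   ("non-kink"/"kink"), `mean_energy_ds_kT`, `se_energy_ds_kT`,
#'   `mean_dye_distance_nm`, `se_dye_distance_nm`, `replicates`.
#' @export
sweep_persistence_length <- function(base_params = sim_params(),
                                     L_P_grid = c(30, 50, 70),
                                     replicates = 5) {
  stopifnot(length(L_P_grid) >= 1, all(diff(L_P_grid) > 0), replicates >= 2)
  kink <- base_params$kink
  if (is.null(kink)) kink <- kink_spec()
  next_seed <- seed_counter(base_params$seed)
  grid <- tidyr::expand_grid(L_Pds = L_P_grid,
                             form = c("non-kink", "kink"))
  out <- purrr::pmap(grid, function(L_Pds, form) {
    p <- base_params
    p$L_Pds <- L_Pds
    p$kink <- if (form == "kink") kink else NULL
    runs <- run_replicates(p, replicates, next_seed)
    e <- rep_stats(purrr::map_dbl(runs, ~ mean(.x$energy_ds_kT)))
    d <- rep_stats(purrr::map_dbl(runs, ~ mean(.x$dye_distance_nm)))
    tibble(L_Pds = L_Pds, form = form,
           mean_energy_ds_kT = e$mean, se_energy_ds_kT = e$se,
           mean_dye_distance_nm = d$mean, se_dye_distance_nm = d$se,
           replicates = replicates)
  })
  structure(dplyr::bind_rows(out),
            class = c("pl_sweep", class(tibble())))
}

#' @export
autoplot.pl_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$L_Pds, y = .data$mean_energy_ds_kT,
                               colour = .data$form)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_energy_ds_kT - .data$se_energy_ds_kT,
      ymax = .data$mean_energy_ds_kT + .data$se_energy_ds_kT)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dsDNA persistence length (nm)",
                  y = "mean dsDNA bending energy (kT)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Sweep the local stiffness of the non-kink dsDNA region
#'
#' With a kink present, scales the bending modulus of every non-denatured
#' joint strictly inside the rigid segment by each multiplier and records
#' the mean bending angle of the denatured (kink) joints — a curvature
#' proxy for the kinked region — and of the non-kink rigid joints.
#'
#' @param base_params a [sim_params()]; a kink is required (the default
#'   [kink_spec()] is used when absent).
#' @param multiplier_grid positive stiffness multipliers.
#' @param replicates independent runs per multiplier.
#' @return A tibble of class `stiffness_sweep`: `multiplier`,
#'   `mean_kink_angle_rad`, `se_kink_angle_rad`, `mean_nonkink_angle_rad`,
#'   `se_nonkink_angle_rad`, `replicates`.
#' @export
sweep_local_stiffness <- function(base_params = sim_params(),
                                  multiplier_grid = c(1, 2, 4),
                                  replicates = 5) {
  stopifnot(all(multiplier_grid > 0), replicates >= 2)
  p0 <- base_params
  if (is.null(p0$kink)) p0$kink <- kink_spec()
  kj <- kink_joints(p0$kink, p0$n_rigid)
  nonkink <- setdiff(seq.int(2L, p0$n_rigid - 1L), kj)
  next_seed <- seed_counter(p0$seed)
  out <- purrr::map(multiplier_grid, function(m) {
    geom <- build_loop(params = p0)
    geom$joint_kappa[nonkink] <- geom$joint_kappa[nonkink] * m
    runs <- run_replicates(p0, replicates, next_seed, geom = geom,
                           watch_joints = kj, watch_joints2 = nonkink)
    a <- rep_stats(purrr::map_dbl(runs, ~ mean(.x$watch_angle)))
    b <- rep_stats(purrr::map_dbl(runs, ~ mean(.x$watch2_angle)))
    tibble(multiplier = m,
           mean_kink_angle_rad = a$mean, se_kink_angle_rad = a$se,
           mean_nonkink_angle_rad = b$mean, se_nonkink_angle_rad = b$se,
           replicates = replicates)
  })
  structure(dplyr::bind_rows(out),
            class = c("stiffness_sweep", class(tibble())))
}

#' Mean dye-to-dye distance of the kink form versus dsDNA stiffness
#'
#' Runs the kinked loop across a persistence-length grid and reports the
#' mean distance between the dye-carrying nodes, with replicate standard
#' errors.  In the kinked equilibrium the dye separation is expected to be
#' insensitive to the dsDNA stiffness.
#'
#' @inheritParams sweep_persistence_length
#' @return A tibble of class `dye_sweep`: `L_Pds`, `mean_dye_distance_nm`,
#'   `se_dye_distance_nm`, `replicates`.
#' @export
mean_dye_distance_vs_stiffness <- function(base_params = sim_params(),
                                           L_P_grid = c(30, 50, 70),
                                           replicates = 5) {
  stopifnot(replicates >= 2)
  p0 <- base_params
  if (is.null(p0$kink)) p0$kink <- kink_spec()
  next_seed <- seed_counter(p0$seed)
  out <- purrr::map(L_P_grid, function(L) {
    p <- p0
    p$L_Pds <- L
    runs <- run_replicates(p, replicates, next_seed)
    d <- rep_stats(purrr::map_dbl(runs, ~ mean(.x$dye_distance_nm)))
    tibble(L_Pds = L, mean_dye_distance_nm = d$mean,
           se_dye_distance_nm = d$se, replicates = replicates)
  })
  structure(dplyr::bind_rows(out),
            class = c("dye_sweep", class(tibble())))
}
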