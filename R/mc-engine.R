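#' Crankshaft move: rotate one node about the axis through its neighbours
#'
#' The selected node is rotated by `angle` about the line joining its two
#' neighbours on the loop.  Distances to the axis are preserved, so the two
#' incident bond lengths are unchanged and every other node is untouched.
#' If the two neighbours coincide the rotation axis is degenerate and the
#' move is returned as a flagged no-op.
#'
#' @param geom a [loop_geometry()].
#' @param node 1-based node index.
#' @param angle rotation angle, radians.
#' @return A `loop_geometry` with attribute `"status"` set to `"ok"` or
#'   `"degenerate_axis"`.
#' @export
crankshaft_move <- function(geom, node, angle) {
  n <- nrow(geom$nodes)
  stopifnot(node >= 1, node <= n, is.finite(angle))
  p <- loop_positions(geom)
  um <- if (node == 1) n else node - 1L
  up <- if (node == n) 1L else node + 1L
  ax <- p[up, ] - p[um, ]
  an <- sqrt(sum(ax^2))
  if (an < 1e-12) {
    attr(geom, "status") <- "degenerate_axis"
    return(geom)
  }
  ax <- ax / an
  v <- p[node, ] - p[um, ]
  rot <- v * cos(angle) +
    c(ax[2] * v[3] - ax[3] * v[2],
      ax[3] * v[1] - ax[1] * v[3],
      ax[1] * v[2] - ax[2] * v[1]) * sin(angle) +
    ax * sum(ax * v) * (1 - cos(angle))
  newp <- p[um, ] + rot
  geom$nodes$x[node] <- newp[1]
  geom$nodes$y[node] <- newp[2]
  geom$nodes$z[node] <- newp[3]
  attr(geom, "status") <- "ok"
  geom
}

# Metropolis acceptance rule at kT = 1
metropolis_accept <- function(delta_E) {
  delta_E <= 0 || runif(1) < exp(-delta_E)
}

# joints whose angle changes when `node` moves (itself and both neighbours)
touched_joints <- function(node, n) {
  j <- c(node - 1L, node, node + 1L)
  ((j - 1L) %% n) + 1L
}

local_joint_energy <- function(geom, joints) {
  th <- joint_angles(geom)[joints]
  sum(0.5 * geom$joint_kappa[joints] * th^2)
}

#' One Metropolis step of the crankshaft sampler
#'
#' Proposes a crankshaft rotation of a uniformly random node with angle
#' uniform in `[-max_pivot_angle, +max_pivot_angle]` and accepts with
#' probability `min(1, exp(-delta_E))` (energies in kT).  `delta_E` is
#' computed incrementally from the three joints the move touches; the
#' kernel-level equivalence with a full-energy recomputation is pinned by
#' the test suite.
#'
#' @param geom a [loop_geometry()].
#' @param params a [sim_params()] (only `max_pivot_angle` is used).
#' @return A list: `geometry` (new or unchanged), `accepted` (logical),
#'   `delta_E` (kT, of the proposal), `node`, `angle`, `status`.
#' @export
metropolis_step <- function(geom, params = sim_params()) {
  n <- nrow(geom$nodes)
  node <- sample.int(n, 1L)
  angle <- runif(1, -params$max_pivot_angle, params$max_pivot_angle)
  trial <- crankshaft_move(geom, node, angle)
  if (attr(trial, "status") == "degenerate_axis") {
    return(list(geometry = geom, accepted = FALSE, delta_E = NA_real_,
                node = node, angle = angle, status = "degenerate_axis"))
  }
  joints <- touched_joints(node, n)
  dE <- local_joint_energy(trial, joints) - local_joint_energy(geom, joints)
  acc <- metropolis_accept(dE)
  list(geometry = if (acc) trial else geom, accepted = acc, delta_E = dE,
       node = node, angle = angle, status = "ok")
}

#' Run a crankshaft Monte Carlo simulation of the loop
#'
#' Builds the loop from `params` (or uses `geom` if supplied), performs
#' `n_equil` unrecorded equilibration steps from the circular initial
#' configuration, then `n_sample` sampling steps recording the dsDNA
#' bending energy, total bending energy and dye-to-dye distance every
#' `record_interval` steps.  Runs are fully reproducible from
#' `params$seed`.
#'
#' @param params a [sim_params()].
#' @param geom optional pre-built [loop_geometry()] (e.g. a uniform ring
#'   or a geometry with rescaled moduli); when supplied, `n_rigid`,
#'   `n_flexible` and the kink in `params` are ignored.
#' @param watch_joints,watch_joints2 optional joint index vectors whose
#'   mean bending angle is recorded alongside the energies (used by the
#'   local-stiffness sweep to monitor the kink and non-kink regions).
#' @param dye_nodes the two nodes whose distance is recorded, or `NULL`
#'   to skip (recorded as `NA`).
#' @return A `loop_trajectory`: a tibble with columns `step`,
#'   `energy_ds_kT`, `energy_total_kT`, `dye_distance_nm` and (when
#'   watched) `watch_angle`, `watch2_angle`; attributes `params`,
#'   `acceptance_rate`, `final_geometry`.
#' @export
#' @examples
#' tr <- run_simulation(sim_params(n_equil = 1e4, n_sample = 1e4, seed = 7))
#' glance(tr)
run_simulation <- function(params = sim_params(), geom = NULL,
                           watch_joints = NULL, watch_joints2 = NULL,
                           dye_nodes = c(4L, 27L)) {
  if (is.null(geom)) geom <- build_loop(params = params)
  n <- nrow(geom$nodes)
  if (!is.null(dye_nodes) && geom$n_rigid < max(dye_nodes)) dye_nodes <- NULL
  dsj <- ds_internal_joints(geom)
  set.seed(params$seed)
  res <- .mc_run_cpp(
    loop_positions(geom), geom$joint_kappa,
    as.integer(dsj - 1L),
    if (is.null(dye_nodes)) -1L else as.integer(dye_nodes[1] - 1L),
    if (is.null(dye_nodes)) -1L else as.integer(dye_nodes[2] - 1L),
    if (is.null(watch_joints)) integer(0) else as.integer(watch_joints - 1L),
    if (is.null(watch_joints2)) integer(0) else as.integer(watch_joints2 - 1L),
    params$n_equil, params$n_sample, params$record_interval,
    params$max_pivot_angle)
  n_rec <- length(res$energy_ds)
  out <- tibble(
    step = if (n_rec) seq_len(n_rec) * params$record_interval else integer(0),
    energy_ds_kT = res$energy_ds,
    energy_total_kT = res$energy_total,
    dye_distance_nm = res$dye_distance,
    watch_angle = res$watch1_angle,
    watch2_angle = res$watch2_angle)
  final <- geom
  final$nodes$x <- res$positions[, 1]
  final$nodes$y <- res$positions[, 2]
  final$nodes$z <- res$positions[, 3]
  structure(out,
            params = params,
            acceptance_rate = if (res$proposals > 0)
              res$accepted / res$proposals else NA_real_,
            final_geometry = final,
            class = c("loop_trajectory", class(out)))
}

#' @export
tidy.loop_trajectory <- function(x, ...) {
  as_tibble(unclass_trajectory(x))
}

unclass_trajectory <- function(x) {
  class(x) <- setdiff(class(x), "loop_trajectory")
  attr(x, "params") <- NULL
  attr(x, "acceptance_rate") <- NULL
  attr(x, "final_geometry") <- NULL
  x
}

#' @export
glance.loop_trajectory <- function(x, ...) {
  tibble(
    n_records = nrow(x),
    mean_energy_ds_kT = mean(x$energy_ds_kT),
    mean_energy_total_kT = mean(x$energy_total_kT),
    mean_dye_distance_nm = mean(x$dye_distance_nm),
    acceptance_rate = attr(x, "acceptance_rate"))
}

#' @export
autoplot.loop_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$energy_ds_kT)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.3) +
    ggplot2::labs(x = "MC step", y = "dsDNA bending energy (kT)") +
    ggplot2::theme_minimal()
}

#' Write a trajectory as delimited text
#'
#' Columns `step`, `energy_ds_kT`, `energy_total_kT`, `dye_distance_nm`;
#' the run manifest (parameters, seed, acceptance rate) goes to
#' `<path>.json` when `jsonlite` is available.
#'
#' @param traj a `loop_trajectory`.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_tsv(tidy(traj)[, c("step", "energy_ds_kT",
                                  "energy_total_kT", "dye_distance_nm")],
                   path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- attr(traj, "params")
    manifest <- list(
      params = p[setdiff(names(p), "kink")],
      kink = !is.null(p$kink),
      acceptance_rate = attr(traj, "acceptance_rate"))
    jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
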