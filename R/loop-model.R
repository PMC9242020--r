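#' Simulation parameters for the coarse-grained D-shaped DNA loop
#'
#' Bundles the physical and sampling parameters of the discrete
#' worm-like-chain model: a closed loop of `n_rigid` nodes standing for the
#' base pairs of the dsDNA portion (spacing `a_ds` = 0.34 nm) and
#' `n_flexible` nodes standing for the nucleotides of the ssDNA string
#' (spacing `a_ss` = 0.7 nm).  Joint bending moduli are dimensionless
#' stiffnesses in units of kT/rad^2, set from the persistence lengths as
#' `L_Pds / a_ds` (dsDNA joints) and `L_Pss / a_ss` (ssDNA joints).
#'
#' The default step counts are desk-scale (2e5 equilibration + 2e5
#' sampling); `full_scale = TRUE` selects the 2e7 + 2e7 preset used for
#' production-quality averages.
#'
#' @param L_Pds dsDNA persistence length, nm.
#' @param L_Pss ssDNA persistence length, nm.
#' @param a_ds,a_ss node spacings, nm (dsDNA rise per bp, ssDNA per nt).
#' @param n_rigid,n_flexible node counts of the two segments.
#' @param n_equil,n_sample Monte Carlo step counts for equilibration and
#'   sampling.
#' @param record_interval steps between recorded observations.
#' @param max_pivot_angle half-width of the uniform crankshaft proposal,
#'   radians.  The default 2.0 rad gives roughly 50% acceptance for the
#'   reference loop at `L_Pds` = 50 nm.
#' @param seed integer RNG seed.
#' @param kink a [kink_spec()] or `NULL` for the non-kink form.
#' @param full_scale if `TRUE`, override step counts with the production
#'   preset `n_equil = n_sample = 2e7`.
#'
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' sim_params(L_Pds = 50, seed = 1)
sim_params <- function(L_Pds = 50, L_Pss = 3, a_ds = 0.34, a_ss = 0.7,
                       n_rigid = 30, n_flexible = 8,
                       n_equil = 2e5, n_sample = 2e5,
                       record_interval = 100, max_pivot_angle = 2,
                       seed = 1L, kink = NULL, full_scale = FALSE) {
  if (full_scale) {
    n_equil <- 2e7
    n_sample <- 2e7
  }
  stopifnot(L_Pds > 0, L_Pss > 0, a_ds > 0, a_ss > 0,
            n_rigid >= 3, n_flexible >= 0,
            n_equil >= 0, n_sample >= 0, record_interval >= 1,
            max_pivot_angle > 0, max_pivot_angle <= pi)
  if (!is.null(kink) && !inherits(kink, "kink_spec")) {
    abort("`kink` must be NULL or a kink_spec object.")
  }
  structure(
    list(L_Pds = L_Pds, L_Pss = L_Pss, a_ds = a_ds, a_ss = a_ss,
         n_rigid = as.integer(n_rigid), n_flexible = as.integer(n_flexible),
         n_equil = n_equil, n_sample = n_sample,
         record_interval = as.integer(record_interval),
         max_pivot_angle = max_pivot_angle, seed = as.integer(seed),
         kink = kink),
    class = "sim_params")
}

#' Kink specification: locally denatured dsDNA joints
#'
#' A kink is modelled as a few rigid-segment joints whose base pairs are
#' transiently denatured, so they bend with single-stranded flexibility
#' while keeping the double-stranded rise.  By default the two central
#' joints of the rigid segment are denatured and assigned the modulus
#' `L_Pss / a_ds` (ssDNA persistence length over dsDNA node spacing).
#'
#' @param denatured_joints integer indices (1-based, within the rigid
#'   segment) of the denatured joints, or `NULL` to centre `n_denatured`
#'   joints in the rigid segment at build time.
#' @param n_denatured number of denatured joints when `denatured_joints`
#'   is `NULL`.
#' @param modulus optional explicit modulus (kT/rad^2) for the denatured
#'   joints; the default `NULL` means `L_Pss / a_ds` from the simulation
#'   parameters.
#'
#' @return A list of class `kink_spec`.
#' @export
kink_spec <- function(denatured_joints = NULL, n_denatured = 2,
                      modulus = NULL) {
  if (!is.null(denatured_joints)) {
    denatured_joints <- as.integer(denatured_joints)
    if (length(denatured_joints) == 0) {
      abort("A kink_spec must denature at least one joint.")
    }
  } else if (n_denatured < 1) {
    abort("A kink_spec must denature at least one joint.")
  }
  structure(list(denatured_joints = denatured_joints,
                 n_denatured = as.integer(n_denatured),
                 modulus = modulus),
            class = "kink_spec")
}

kink_joints <- function(kink, n_rigid) {
  if (is.null(kink$denatured_joints)) {
    k <- kink$n_denatured
    start <- floor((n_rigid - k) / 2) + 1L
    joints <- seq.int(start, length.out = k)
  } else {
    joints <- kink$denatured_joints
  }
  if (any(joints < 1L | joints > n_rigid)) {
    abort("Denatured joints must lie within the rigid segment.")
  }
  joints
}

#' Construct a loop geometry from explicit components
#'
#' Low-level constructor used by [build_loop()] and by tests that need
#' bespoke rings.  Checks the closed-polygon invariants: one edge per node,
#' realized edge lengths equal to the declared bond lengths within 1e-9 nm,
#' and non-negative joint moduli.
#'
#' @param positions numeric matrix, nodes x 3, nm.
#' @param node_class character vector, one of "rigid"/"flexible" per node.
#' @param bond_lengths declared length (nm) of edge i (node i to node i+1,
#'   wrapping).
#' @param joint_kappa bending modulus (kT/rad^2) of the joint at each node.
#' @return An object of class `loop_geometry`: a list with a `nodes`
#'   tibble (`node`, `class`, `x`, `y`, `z`) plus `bond_lengths`,
#'   `joint_kappa`, `n_rigid`, `n_flexible`.
#' @export
loop_geometry <- function(positions, node_class, bond_lengths, joint_kappa) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, length(node_class) == n,
            length(bond_lengths) == n, length(joint_kappa) == n)
  if (any(joint_kappa < 0)) abort("Joint moduli must be >= 0.")
  if (!all(node_class %in% c("rigid", "flexible"))) {
    abort("node_class entries must be 'rigid' or 'flexible'.")
  }
  geom <- structure(
    list(nodes = tibble(node = seq_len(n), class = node_class,
                        x = positions[, 1], y = positions[, 2],
                        z = positions[, 3]),
         bond_lengths = as.numeric(bond_lengths),
         joint_kappa = as.numeric(joint_kappa),
         n_rigid = sum(node_class == "rigid"),
         n_flexible = sum(node_class == "flexible")),
    class = "loop_geometry")
  err <- max(abs(realized_bond_lengths(geom) - geom$bond_lengths))
  if (err > 1e-9) {
    abort(sprintf(
      "Realized edge lengths deviate from declared bonds by %.3g nm.", err))
  }
  geom
}

loop_positions <- function(geom) {
  cbind(geom$nodes$x, geom$nodes$y, geom$nodes$z)
}

#' Realized edge lengths of a loop
#'
#' @param geom a `loop_geometry`.
#' @return numeric vector: length of edge i = |p\[i+1\] - p\[i\]| (wrapping).
#' @export
realized_bond_lengths <- function(geom) {
  p <- loop_positions(geom)
  d <- p[c(seq_len(nrow(p))[-1], 1L), , drop = FALSE] - p
  sqrt(rowSums(d^2))
}

#' Build the coarse-grained D-shaped DNA loop
#'
#' Places `n_rigid + n_flexible` nodes on a common circle whose radius is
#' solved so that the chord-subtended angles of all declared bond lengths
#' sum to 2*pi, giving a closed planar polygon with exact bond lengths.
#' Edges between consecutive rigid nodes get the dsDNA spacing `a_ds`; all
#' other edges (flexible-flexible and the two rigid/flexible junctions,
#' which are single-stranded backbone) get `a_ss`.  Joint moduli:
#' `L_Pds/a_ds` where both incident edges are double-stranded, `L_Pss/a_ss`
#' otherwise (junction joints are treated as single-stranded), and any
#' denatured kink joints are overridden per the [kink_spec()].
#'
#' @param n_rigid number of rigid (dsDNA) nodes, >= 3.
#' @param n_flexible number of flexible (ssDNA) nodes, >= 0.
#' @param params a [sim_params()] supplying spacings, persistence lengths
#'   and the optional kink.
#' @return A [loop_geometry()].
#' @export
#' @examples
#' geom <- build_loop(30, 8, sim_params())
#' range(realized_bond_lengths(geom) - geom$bond_lengths)
build_loop <- function(n_rigid = NULL, n_flexible = NULL,
                       params = sim_params()) {
  if (is.null(n_rigid)) n_rigid <- params$n_rigid
  if (is.null(n_flexible)) n_flexible <- params$n_flexible
  stopifnot(n_rigid >= 3, n_flexible >= 0)
  n <- n_rigid + n_flexible
  cls <- c(rep("rigid", n_rigid), rep("flexible", n_flexible))
  # edge i joins node i and i+1; double-stranded iff both endpoints rigid
  nxt <- c(seq_len(n)[-1], 1L)
  edge_ds <- cls == "rigid" & cls[nxt] == "rigid"
  bonds <- ifelse(edge_ds, params$a_ds, params$a_ss)

  pos <- circle_polygon(bonds)

  prv <- c(n, seq_len(n)[-n])
  joint_ds <- edge_ds[prv] & edge_ds  # both incident edges double-stranded
  kappa <- ifelse(joint_ds, params$L_Pds / params$a_ds,
                  params$L_Pss / params$a_ss)
  if (!is.null(params$kink)) {
    kj <- kink_joints(params$kink, n_rigid)
    km <- params$kink$modulus
    if (is.null(km)) km <- params$L_Pss / params$a_ds
    kappa[kj] <- km
  }
  loop_geometry(pos, cls, bonds, kappa)
}

# Closed polygon inscribed in a circle: solve R so the chord angles
# 2*asin(L/2R) sum to 2*pi, then lay nodes at the cumulative angles.
circle_polygon <- function(bonds) {
  if (max(bonds) >= sum(bonds) - max(bonds)) {
    abort("Bond lengths cannot close a polygon (one bond >= sum of the rest).")
  }
  f <- function(R) sum(2 * asin(pmin(1, bonds / (2 * R)))) - 2 * pi
  lo <- max(bonds) / 2 * (1 + 1e-12)
  hi <- sum(bonds)
  if (f(lo) < 0) {
    abort("No circumscribing circle with the centre inside the polygon.")
  }
  R <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  ang <- cumsum(c(0, 2 * asin(bonds / (2 * R))))[seq_along(bonds)]
  cbind(R * cos(ang), R * sin(ang), 0)
}

#' Build a uniform closed ring
#'
#' Convenience constructor for test systems: `n` rigid nodes on a circle
#' with equal bond lengths and a single bending modulus at every joint.
#'
#' @param n number of nodes (>= 3).
#' @param bond_length edge length, nm.
#' @param kappa joint bending modulus, kT/rad^2.
#' @return A [loop_geometry()].
#' @export
build_ring <- function(n, bond_length = 1, kappa = 1) {
  stopifnot(n >= 3, bond_length > 0, kappa >= 0)
  pos <- circle_polygon(rep(bond_length, n))
  loop_geometry(pos, rep("rigid", n), rep(bond_length, n), rep(kappa, n))
}

#' Angle between adjacent tangent vectors at a joint
#'
#' The bending angle theta_i at node i is the angle in \[0, pi\] between
#' the bond vector entering node i and the bond vector leaving it; 0 means
#' locally straight.
#'
#' @param geom a `loop_geometry`.
#' @param i joint index (joint i sits at node i), or omit to get all.
#' @return Radians (scalar for `joint_angle`, length-n vector for
#'   `joint_angles`).
#' @export
joint_angle <- function(geom, i) {
  n <- nrow(geom$nodes)
  if (i < 1 || i > n) abort("Joint index out of bounds.")
  joint_angles(geom)[i]
}

#' @rdname joint_angle
#' @export
joint_angles <- function(geom) {
  p <- loop_positions(geom)
  n <- nrow(p)
  a <- p - p[c(n, seq_len(n)[-n]), , drop = FALSE]  # incoming bond
  b <- p[c(seq_len(n)[-1], 1L), , drop = FALSE] - p # outgoing bond
  dot <- rowSums(a * b)
  crs <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  atan2(sqrt(rowSums(crs^2)), dot)
}

# joints strictly inside the rigid segment (both incident edges ds):
# nodes 2..(n_rigid - 1) under the canonical rigid-first layout
ds_internal_joints <- function(geom) {
  if (geom$n_rigid < 3) return(integer(0))
  seq.int(2L, geom$n_rigid - 1L)
}

#' Discrete worm-like-chain bending energy of a loop
#'
#' Each joint contributes `(kappa_i / 2) * theta_i^2` kT.  The dsDNA
#' bending energy sums the joints strictly inside the rigid segment (both
#' incident edges double-stranded); the total sums every joint.
#'
#' @param geom a `loop_geometry`.
#' @return An object of class `energy_profile`: list with `per_joint`
#'   (tibble: `joint`, `kappa`, `theta`, `energy_kT`), `dsdna_energy_kT`
#'   and `total_energy_kT`.
#' @export
#' @examples
#' prof <- bending_energy(build_loop(30, 8, sim_params()))
#' prof$dsdna_energy_kT
bending_energy <- function(geom) {
  th <- joint_angles(geom)
  e <- 0.5 * geom$joint_kappa * th^2
  dsj <- ds_internal_joints(geom)
  structure(
    list(per_joint = tibble(joint = seq_along(e), kappa = geom$joint_kappa,
                            theta = th, energy_kT = e),
         dsdna_energy_kT = sum(e[dsj]),
         total_energy_kT = sum(e)),
    class = "energy_profile")
}

#' Dye-to-dye distance of the loop
#'
#' Distance between the rigid nodes carrying the FRET donor and acceptor
#' (the 4th and 27th base pairs of the dsDNA portion by default).
#'
#' @param geom a `loop_geometry`.
#' @param dye_nodes two 1-based indices within the rigid segment.
#' @return Euclidean distance in nm.
#' @export
dye_distance <- function(geom, dye_nodes = c(4L, 27L)) {
  if (geom$n_rigid < max(dye_nodes)) {
    abort("Rigid segment too short for the requested dye nodes.")
  }
  p <- loop_positions(geom)
  sqrt(sum((p[dye_nodes[1], ] - p[dye_nodes[2], ])^2))
}

#' @export
print.loop_geometry <- function(x, ...) {
  cat(sprintf("<loop_geometry> %d nodes (%d rigid + %d flexible)\n",
              nrow(x$nodes), x$n_rigid, x$n_flexible))
  cat(sprintf("  bending energy: %.3f kT (dsDNA portion %.3f kT)\n",
              bending_energy(x)$total_energy_kT,
              bending_energy(x)$dsdna_energy_kT))
  invisible(x)
}

#' Write / read a loop geometry snapshot
#'
#' Plain-text XYZ-like table: `node`, `class`, `x`, `y`, `z` (nm).
#' Bond lengths and moduli are not stored; [read_geometry()] re-derives
#' bond lengths from positions and takes moduli from `params`.
#'
#' @param geom a `loop_geometry`.
#' @param path file path.
#' @export
write_geometry <- function(geom, path) {
  readr::write_tsv(geom$nodes, path)
  invisible(path)
}

#' @rdname write_geometry
#' @param params a [sim_params()] used to reassign joint moduli.
#' @export
read_geometry <- function(path, params = sim_params()) {
  nd <- readr::read_tsv(path, show_col_types = FALSE)
  pos <- cbind(nd$x, nd$y, nd$z)
  n <- nrow(pos)
  d <- pos[c(seq_len(n)[-1], 1L), , drop = FALSE] - pos
  bonds <- sqrt(rowSums(d^2))
  cls <- nd$class
  nxt <- c(seq_len(n)[-1], 1L)
  prv <- c(n, seq_len(n)[-n])
  edge_ds <- cls == "rigid" & cls[nxt] == "rigid"
  joint_ds <- edge_ds[prv] & edge_ds
  kappa <- ifelse(joint_ds, params$L_Pds / params$a_ds,
                  params$L_Pss / params$a_ss)
  loop_geometry(pos, cls, bonds, kappa)
}

#' @export
autoplot.loop_geometry <- function(object, ...) {
  nd <- dplyr::bind_rows(object$nodes, object$nodes[1, ])
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", colour = NULL,
                  title = "Coarse-grained D-shaped DNA loop") +
    ggplot2::theme_minimal()
}
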