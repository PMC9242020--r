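#' Entropic force model of the ssDNA string
#'
#' Parameters of the force-extension relation used to turn a construct's
#' ssDNA string into a bending force on the dsDNA portion.  Two pluggable
#' strategies are provided: the worm-like-chain interpolation formula
#' (`"wlc"`, the default) and a freely-jointed-chain alternative
#' (`"fjc"`, Kuhn length `2 * L_Pss`).
#'
#' @param L_Pss ssDNA persistence length, nm.
#' @param a_ss contour length per nucleotide, nm.
#' @param kT thermal energy, pN nm (4.114 at 25 C).
#' @param reference_string_length string length (nt) of the reference
#'   construct where dsDNA bending begins (70 nt).
#' @param type `"wlc"` or `"fjc"`.
#' @return A list of class `force_model`.
#' @export
force_model <- function(L_Pss = 3, a_ss = 0.7, kT = 4.114,
                        reference_string_length = 70, type = c("wlc", "fjc")) {
  type <- match.arg(type)
  stopifnot(L_Pss > 0, a_ss > 0, kT > 0, reference_string_length > 0)
  structure(list(L_Pss = L_Pss, a_ss = a_ss, kT = kT,
                 reference_string_length = reference_string_length,
                 type = type),
            class = "force_model")
}

#' Convert FRET efficiency to donor-acceptor distance
#'
#' Inverts the Forster relation `E = 1 / (1 + (R/R0)^6)`:
#' `R = R0 * (1/E - 1)^(1/6)`.
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param R0 Forster radius, nm (6.5 nm default for the ATTO 550 /
#'   ATTO 647N pair).
#' @return Distance in nm (vectorised over `E`).
#' @export
#' @examples
#' fret_to_distance(0.5, 6.5)  # == R0
fret_to_distance <- function(E, R0 = 6.5) {
  stopifnot(R0 > 0)
  if (any(!is.finite(E) | E <= 0 | E >= 1)) {
    abort("FRET efficiencies must lie strictly inside (0, 1).")
  }
  R0 * (1 / E - 1)^(1 / 6)
}

#' Entropic stretching force of the ssDNA string
#'
#' Worm-like-chain interpolation:
#' `F = (kT / L_Pss) * (1 / (4 (1 - x/Lc)^2) - 1/4 + x/Lc)` with contour
#' length `Lc = n_nt * a_ss`.  The freely-jointed-chain alternative
#' inverts the Langevin function `x/Lc = coth(F b / kT) - kT / (F b)`
#' numerically with Kuhn length `b = 2 * L_Pss`.
#'
#' @param extension end-to-end extension of the string, nm; must satisfy
#'   `0 <= extension < Lc`.
#' @param n_nt string length in nucleotides.
#' @param model a [force_model()].
#' @return Force in pN (vectorised over `extension`/`n_nt`).
#' @export
#' @examples
#' ssdna_force(7, 22)
ssdna_force <- function(extension, n_nt, model = force_model()) {
  k <- pmax(length(extension), length(n_nt))
  extension <- rep_len(extension, k)
  n_nt <- rep_len(n_nt, k)
  Lc <- n_nt * model$a_ss
  if (any(extension < 0 | extension >= Lc)) {
    abort("Extension must lie in [0, contour length).")
  }
  xr <- extension / Lc
  if (model$type == "wlc") {
    (model$kT / model$L_Pss) * (1 / (4 * (1 - xr)^2) - 0.25 + xr)
  } else {
    b <- 2 * model$L_Pss
    langevin <- function(u) ifelse(u < 1e-6, u / 3, 1 / tanh(u) - 1 / u)
    vapply(xr, function(r) {
      if (r == 0) return(0)
      u <- uniroot(function(u) langevin(u) - r, c(1e-9, 1e6),
                   tol = 1e-12)$root
      u * model$kT / b
    }, numeric(1))
  }
}

#' Bending-force increments and end-to-end distance reductions
#'
#' For each methylation group, takes the construct with the reference
#' string length (70 nt, where dsDNA bending begins) as the zero point and
#' computes, per construct, the reduction in dsDNA end-to-end distance
#' `delta_R = R_ref - R` (from [fret_to_distance()]) and the bending-force
#' increment `delta_F = F - F_ref`, where each force is [ssdna_force()]
#' evaluated at that construct's own FRET-derived extension (force-balance
#' proxy: the string's ends coincide with the dsDNA ends).  The
#' dye-to-dye distance is rescaled to the full dsDNA end-to-end distance
#' by `end_to_end_scale` (29/23: the dyes sit on the 4th and 27th of 30
#' base pairs, spanning 23 of the 29 base steps).
#'
#' @param measurements data frame with columns `label`, `string_length`
#'   (nt), `mean_E`, `methylation_sites`.  Constructs with
#'   `string_length = 0` (linear controls, no string to pull) are dropped.
#' @param R0 Forster radius, nm.
#' @param model a [force_model()]; its `reference_string_length` keys the
#'   reference construct, which must be present in every group.
#' @param end_to_end_scale dye-to-dye to end-to-end rescaling factor.
#' @return Tibble: `label`, `methylation_sites`, `string_length`,
#'   `delta_F_pN`, `delta_R_nm`.
#' @export
delta_R_delta_F <- function(measurements, R0 = 6.5, model = force_model(),
                            end_to_end_scale = 29 / 23) {
  m <- as_tibble(measurements)
  stopifnot(all(c("string_length", "mean_E", "methylation_sites") %in%
                  names(m)))
  if (!"label" %in% names(m)) m$label <- sprintf("construct_%d", seq_len(nrow(m)))
  m <- m[m$string_length > 0, , drop = FALSE]
  ref_len <- model$reference_string_length
  groups <- split(m, m$methylation_sites)
  out <- purrr::map(groups, function(g) {
    ref <- g[g$string_length == ref_len, , drop = FALSE]
    if (nrow(ref) == 0) {
      abort(sprintf(
        "Methylation group %s lacks the %d nt reference construct.",
        g$methylation_sites[1], ref_len))
    }
    E_ref <- mean(ref$mean_E)
    R_ref <- fret_to_distance(E_ref, R0)
    F_ref <- ssdna_force(R_ref * end_to_end_scale, ref_len, model)
    R <- fret_to_distance(g$mean_E, R0)
    F_c <- ssdna_force(R * end_to_end_scale, g$string_length, model)
    tibble(label = g$label, methylation_sites = g$methylation_sites,
           string_length = g$string_length,
           delta_F_pN = F_c - F_ref, delta_R_nm = R_ref - R)
  })
  dplyr::bind_rows(out)
}

#' Origin-constrained least-squares slope
#'
#' Slope of `y = s * x` through the origin: `s = sum(x y) / sum(x^2)`.
#'
#' @param points data frame with `delta_F_pN` and `delta_R_nm` columns
#'   (y regressed on x), or a two-column matrix/data frame `(x, y)`.
#' @return Numeric slope (nm/pN).
#' @export
#' @examples
#' fit_origin_slope(data.frame(delta_F_pN = 1:3, delta_R_nm = 0.86 * (1:3)))
fit_origin_slope <- function(points) {
  if (all(c("delta_F_pN", "delta_R_nm") %in% names(points))) {
    x <- points$delta_F_pN
    y <- points$delta_R_nm
  } else {
    x <- points[[1]]
    y <- points[[2]]
  }
  stopifnot(length(x) >= 1, length(x) == length(y))
  if (all(x == 0)) abort("Cannot fit a slope: all abscissae are zero.")
  sum(x * y) / sum(x^2)
}

#' Relative stiffness increase from bending-compliance slopes
#'
#' The slope of the origin-constrained delta_R vs delta_F line is a
#' bending compliance, inversely proportional to dsDNA stiffness; the
#' stiffness increase of a methylated group relative to the unmethylated
#' one is therefore `100 * (slope_unmeth / slope_meth - 1)` percent.
#'
#' @param slope_unmeth,slope_meth positive slopes (nm/pN).
#' @return Percent stiffness increase.
#' @export
#' @examples
#' relative_stiffness(0.86, 0.80)
#' relative_stiffness(0.86, 0.73)
relative_stiffness <- function(slope_unmeth, slope_meth) {
  if (any(slope_unmeth <= 0) || any(slope_meth <= 0)) {
    abort("Slopes must be positive.")
  }
  100 * (slope_unmeth / slope_meth - 1)
}

#' Extrapolate stiffness change to a genomic methylation density
#'
#' Linear-density model: a per-site stiffness increase measured on a
#' 30 bp construct scales with the number of methylatable sites per
#' 500 bp as `percent_per_site * sites_per_500bp * 30 / 500`.
#'
#' @param percent_per_site_per_30bp percent stiffness increase per
#'   methylation site on 30 bp of dsDNA.
#' @param sites_per_500bp methylatable (e.g. CpG) sites per 500 bp.
#' @return Percent stiffness increase (vectorised).
#' @export
#' @examples
#' extrapolate_by_density(8, c(7, 39))
extrapolate_by_density <- function(percent_per_site_per_30bp,
                                   sites_per_500bp) {
  stopifnot(all(percent_per_site_per_30bp >= 0), all(sites_per_500bp >= 0))
  percent_per_site_per_30bp * sites_per_500bp * 30 / 500
}

#' Full stiffness inference from construct measurements
#'
#' Chains [delta_R_delta_F()], [fit_origin_slope()] per methylation group
#' and [relative_stiffness()] against the unmethylated group.
#'
#' @inheritParams delta_R_delta_F
#' @return A tibble of class `stiffness_result`: `methylation_sites`,
#'   `n_constructs`, `slope_nm_per_pN`, `percent_increase`.
#' @export
#' @examples
#' tbl <- generate_stiffness_table(true_percent_per_site = 8, seed = 1)
#' stiffness_analysis(tbl)
stiffness_analysis <- function(measurements, R0 = 6.5,
                               model = force_model(),
                               end_to_end_scale = 29 / 23) {
  pts <- delta_R_delta_F(measurements, R0, model, end_to_end_scale)
  slopes <- dplyr::bind_rows(purrr::map(
    split(pts, pts$methylation_sites),
    function(g) tibble(methylation_sites = g$methylation_sites[1],
                       n_constructs = nrow(g),
                       slope_nm_per_pN = fit_origin_slope(g))))
  slopes <- dplyr::arrange(slopes, .data$methylation_sites)
  if (!0 %in% slopes$methylation_sites) {
    abort("No unmethylated (0-site) group to reference against.")
  }
  s0 <- slopes$slope_nm_per_pN[slopes$methylation_sites == 0]
  slopes$percent_increase <- relative_stiffness(s0, slopes$slope_nm_per_pN)
  structure(slopes, class = c("stiffness_result", class(tibble())))
}

#' @export
autoplot.stiffness_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$methylation_sites),
                               y = .data$percent_increase)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "methylation sites per 30 bp",
                  y = "stiffness increase (%)") +
    ggplot2::theme_minimal()
}
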