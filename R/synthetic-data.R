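#' Species in a synthetic ALEX burst mixture
#'
#' One molecular species crossing the confocal volume: a dual-labelled
#' molecule at FRET efficiency `true_E`, a donor-only molecule, or an
#' acceptor-only molecule.  Photon statistics follow the standard
#' shot-noise model: Poisson total photons per excitation channel,
#' binomial donor/acceptor colour split with probability `true_E`.
#'
#' @param true_E true FRET efficiency (ignored for single-label species).
#' @param label_state `"dual"`, `"donor_only"` or `"acceptor_only"`.
#' @param abundance fraction of bursts drawn from this species.
#' @param mean_total_photons mean donor-excitation photons per ms.
#' @param mean_acceptor_photons mean acceptor-excitation photons per ms
#'   (defaults to `mean_total_photons`).
#' @param duration_model `"fixed"` or `"exponential"` burst durations.
#' @param mean_duration_ms mean burst duration, ms.
#' @return A list of class `species_spec`.
#' @export
species_spec <- function(true_E = NA_real_,
                         label_state = c("dual", "donor_only",
                                         "acceptor_only"),
                         abundance = 1, mean_total_photons = 100,
                         mean_acceptor_photons = mean_total_photons,
                         duration_model = c("fixed", "exponential"),
                         mean_duration_ms = 1) {
  label_state <- match.arg(label_state)
  duration_model <- match.arg(duration_model)
  if (label_state == "dual" && (!is.finite(true_E) || true_E < 0 ||
                                true_E > 1)) {
    abort("A dual species needs true_E in [0, 1].")
  }
  stopifnot(abundance >= 0, mean_total_photons > 0, mean_duration_ms > 0)
  structure(list(true_E = true_E, label_state = label_state,
                 abundance = abundance,
                 mean_total_photons = mean_total_photons,
                 mean_acceptor_photons = mean_acceptor_photons,
                 duration_model = duration_model,
                 mean_duration_ms = mean_duration_ms),
            class = "species_spec")
}

#' Scenario preset: a named burst mixture
#'
#' Bundles a species mixture with correction factors, a burst count and a
#' seed.  [alex_presets()] returns the built-in D-shaped-DNA scenarios
#' with the construct FRET efficiencies and burst counts of the reference
#' experiment: linear 30 bp dsDNA (E = 0.18, 4120 bursts), weakly bent
#' D30-S22 (E = 0.43, 3236 bursts), strongly bent D30-S8 as a two-state
#' kink/end-melting mixture (E = 0.45 / 0.95, 3350 bursts), nicked
#' D30-S22 (E = 0.53) and nicked D30-S22 with a methylation site beside
#' the nick (E = 0.47).  Each preset also carries a 15% donor-only
#' fraction so stoichiometry selection is exercised.
#'
#' @param name preset label.
#' @param species list of [species_spec()]s; abundances must sum to 1.
#' @param corrections a [correction_factors()].
#' @param n_bursts number of bursts to draw.
#' @param seed RNG seed.
#' @return A list of class `scenario_preset`.
#' @export
scenario_preset <- function(name, species,
                            corrections = correction_factors(),
                            n_bursts = 3000, seed = 1L) {
  ab <- sum(purrr::map_dbl(species, "abundance"))
  if (abs(ab - 1) > 1e-8) abort("Species abundances must sum to 1.")
  structure(list(name = name, species = species,
                 corrections = corrections,
                 n_bursts = as.integer(n_bursts), seed = as.integer(seed)),
            class = "scenario_preset")
}

#' @rdname scenario_preset
#' @param donor_only_fraction donor-only abundance mixed into each preset.
#' @export
alex_presets <- function(donor_only_fraction = 0.15) {
  dual <- function(E, frac) species_spec(E, "dual", abundance = frac)
  donly <- species_spec(label_state = "donor_only",
                        abundance = donor_only_fraction)
  f <- 1 - donor_only_fraction
  list(
    `linear` = scenario_preset("linear", list(dual(0.18, f), donly),
                               n_bursts = 4120, seed = 101L),
    `D30-S22` = scenario_preset("D30-S22", list(dual(0.43, f), donly),
                                n_bursts = 3236, seed = 102L),
    `D30-S8` = scenario_preset(
      "D30-S8",
      list(dual(0.45, f * 0.5), dual(0.95, f * 0.5), donly),
      n_bursts = 3350, seed = 103L),
    `nicked-D30-S22` = scenario_preset(
      "nicked-D30-S22", list(dual(0.53, f), donly),
      n_bursts = 3236, seed = 104L),
    `nicked-D30-S22-M1` = scenario_preset(
      "nicked-D30-S22-M1", list(dual(0.47, f), donly),
      n_bursts = 3236, seed = 105L))
}

#' Generate a synthetic ALEX burst table
#'
#' Forward model of the measurement.  Per burst: draw the species by
#' abundance and the duration; draw the donor-excitation photon total
#' `N_D ~ Poisson(mean * duration)` and split it binomially into `I_DA`
#' (probability `true_E`) vs `I_DD`; draw `I_AA ~ Poisson` for
#' acceptor-carrying species.  The observed counts are then corrupted
#' consistently with the correction factors: the donor channel is thinned
#' by `1/gamma` (gamma >= 1), leakage adds `Binomial(I_DD, l)` counts to
#' `I_DA`, and direct excitation adds `Binomial(I_AA, d)` counts, so
#' processing with [compute_es()] under the same factors recovers the true
#' efficiencies up to shot noise.
#'
#' @param preset a [scenario_preset()].
#' @param seed RNG seed (defaults to the preset's).
#' @return A tibble: `burst_id`, `duration_ms`, `I_DD`, `I_DA`, `I_AA`,
#'   plus ground-truth columns `true_species`, `true_E`.
#' @export
#' @examples
#' b <- generate_bursts(alex_presets()[["D30-S22"]])
#' head(b)
generate_bursts <- function(preset, seed = preset$seed) {
  set.seed(seed)
  n <- preset$n_bursts
  sp <- preset$species
  ab <- purrr::map_dbl(sp, "abundance")
  which_sp <- sample.int(length(sp), n, replace = TRUE, prob = ab)
  corr <- preset$corrections
  rows <- purrr::map(seq_len(n), function(i) {
    s <- sp[[which_sp[i]]]
    dur <- if (s$duration_model == "fixed") s$mean_duration_ms else
      stats::rexp(1, 1 / s$mean_duration_ms)
    has_donor <- s$label_state != "acceptor_only"
    has_acceptor <- s$label_state != "donor_only"
    N_D <- if (has_donor) rpois(1, s$mean_total_photons * dur) else 0L
    p_E <- if (s$label_state == "dual") s$true_E else 0
    I_DA_true <- rbinom(1, N_D, p_E)
    I_DD_true <- N_D - I_DA_true
    I_AA <- if (has_acceptor) rpois(1, s$mean_acceptor_photons * dur) else 0L
    I_DD <- if (corr$gamma >= 1) rbinom(1, I_DD_true, 1 / corr$gamma) else
      I_DD_true + rpois(1, (1 / corr$gamma - 1) * I_DD_true)
    leak <- rbinom(1, I_DD, corr$leakage)
    dex <- rbinom(1, I_AA, corr$direct_excitation)
    tibble(burst_id = i, duration_ms = dur, I_DD = I_DD,
           I_DA = I_DA_true + leak + dex, I_AA = I_AA,
           true_species = s$label_state,
           true_E = if (s$label_state == "dual") s$true_E else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Generate a two-state kink/non-kink burst mixture
#'
#' Two dual-labelled species at `E_low` (weakly bent, end-melting form)
#' and `E_high` (kink form, default 0.95) with abundances
#' `(1 - fraction_kink, fraction_kink)`.
#'
#' @param fraction_kink true kink fraction in \[0, 1\].
#' @param E_low,E_high component FRET efficiencies.
#' @param n_bursts number of bursts.
#' @param seed RNG seed.
#' @param corrections a [correction_factors()].
#' @return Burst tibble as from [generate_bursts()].
#' @export
generate_kink_mixture <- function(fraction_kink, E_low = 0.45,
                                  E_high = 0.95, n_bursts = 3350,
                                  seed = 1L,
                                  corrections = correction_factors()) {
  stopifnot(fraction_kink >= 0, fraction_kink <= 1)
  species <- list()
  if (fraction_kink < 1) {
    species <- c(species, list(species_spec(E_low, "dual",
                                            abundance = 1 - fraction_kink)))
  }
  if (fraction_kink > 0) {
    species <- c(species, list(species_spec(E_high, "dual",
                                            abundance = fraction_kink)))
  }
  preset <- scenario_preset(sprintf("kink-mixture-%.2f", fraction_kink),
                            species, corrections, n_bursts, seed)
  generate_bursts(preset)
}

#' Generate a synthetic high-resolution melting curve
#'
#' Logistic fluorescence decay with inflection at `Tm` plus i.i.d.
#' Gaussian noise, on the instrument grid (60-95 C, 0.1 C steps by
#' default).
#'
#' @param Tm melting temperature, C (inside the grid).
#' @param width transition width, C.
#' @param noise_sd Gaussian noise s.d. on the normalized signal.
#' @param grid `c(from, to, by)` in C.
#' @param seed RNG seed.
#' @return A [melting_curve()].
#' @export
#' @examples
#' melting_temperature(generate_melting_curve(75, seed = 1))
generate_melting_curve <- function(Tm, width = 1.5, noise_sd = 0,
                                   grid = c(60, 95, 0.1), seed = 1L) {
  tc <- seq(grid[1], grid[2], by = grid[3])
  stopifnot(Tm > grid[1], Tm < grid[2], width > 0, noise_sd >= 0)
  set.seed(seed)
  fl <- 1 / (1 + exp((tc - Tm) / width)) + rnorm(length(tc), 0, noise_sd)
  melting_curve(tc, fl)
}

#' Generate a synthetic construct table for stiffness inference
#'
#' Inverse of the stiffness pipeline.  An assumed per-site stiffness
#' increase `p` sets the bending-compliance slope of each methylation
#' group to `base_slope / (1 + m p / 100)`; for every string length the
#' construct's end-to-end distance is solved from the self-consistent
#' balance `R_ref - R = slope * (F(R) - F_ref)` (forces from
#' [ssdna_force()] at the construct's own extension) and converted to a
#' mean FRET efficiency through the Forster relation.  Optional Gaussian
#' noise is added to the efficiencies.
#'
#' @param true_percent_per_site assumed stiffness increase per
#'   methylation site, percent.
#' @param string_lengths non-reference string lengths, nt.
#' @param meth_counts methylation-site counts (groups) to generate.
#' @param base_slope unmethylated compliance slope, nm/pN.
#' @param E_reference mean FRET efficiency of the 70 nt reference
#'   construct (insensitive to methylation).
#' @param R0 Forster radius, nm.
#' @param model a [force_model()].
#' @param end_to_end_scale dye-to-dye to end-to-end rescaling (29/23).
#' @param noise_sd_E Gaussian noise s.d. on mean_E.
#' @param seed RNG seed.
#' @return Tibble: `label`, `string_length`, `mean_E`,
#'   `methylation_sites`.
#' @export
#' @examples
#' stiffness_analysis(generate_stiffness_table(8, seed = 1))
generate_stiffness_table <- function(true_percent_per_site = 8,
                                     string_lengths = c(34, 26, 22),
                                     meth_counts = 0:2,
                                     base_slope = 0.86, E_reference = 0.20,
                                     R0 = 6.5, model = force_model(),
                                     end_to_end_scale = 29 / 23,
                                     noise_sd_E = 0, seed = 1L) {
  stopifnot(true_percent_per_site >= 0, base_slope > 0,
            E_reference > 0, E_reference < 1)
  set.seed(seed)
  ref_len <- model$reference_string_length
  R_ref <- fret_to_distance(E_reference, R0)
  F_ref <- ssdna_force(R_ref * end_to_end_scale, ref_len, model)
  rows <- purrr::map(meth_counts, function(m) {
    slope <- base_slope / (1 + m * true_percent_per_site / 100)
    E <- purrr::map_dbl(string_lengths, function(len) {
      g <- function(R) {
        (R_ref - R) - slope *
          (ssdna_force(R * end_to_end_scale, len, model) - F_ref)
      }
      hi <- min(R_ref, len * model$a_ss / end_to_end_scale * 0.999)
      R <- uniroot(g, c(1e-6, hi), tol = 1e-12)$root
      1 / (1 + (R / R0)^6)
    })
    tibble(
      label = c(sprintf("D30-S%d-M%d", ref_len, m),
                sprintf("D30-S%d-M%d", string_lengths, m)),
      string_length = c(ref_len, string_lengths),
      mean_E = c(E_reference, E),
      methylation_sites = m)
  })
  out <- dplyr::bind_rows(rows)
  if (noise_sd_E > 0) {
    out$mean_E <- pmin(0.999, pmax(1e-3,
                                   out$mean_E + rnorm(nrow(out), 0,
                                                      noise_sd_E)))
  }
  out
}
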