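#' ALEX intensity correction factors
#'
#' The three standard corrections for alternating-laser-excitation burst
#' data: the detection-efficiency ratio between acceptor and donor
#' channels (`gamma`), the fraction of donor emission leaking into the
#' acceptor detection channel (`leakage`), and the fraction of acceptor
#' emission excited directly by the donor laser (`direct_excitation`).
#'
#' @param gamma detection-efficiency ratio, > 0.
#' @param leakage leakage fraction in \[0, 1).
#' @param direct_excitation direct-excitation fraction in \[0, 1).
#' @return A list of class `correction_factors`.
#' @export
correction_factors <- function(gamma = 1, leakage = 0,
                               direct_excitation = 0) {
  stopifnot(gamma > 0, leakage >= 0, leakage < 1,
            direct_excitation >= 0, direct_excitation < 1)
  structure(list(gamma = gamma, leakage = leakage,
                 direct_excitation = direct_excitation),
            class = "correction_factors")
}

#' FRET efficiency and stoichiometry from burst intensities
#'
#' For each burst the corrected acceptor signal under donor excitation is
#' `F = I_DA - l * I_DD - d * I_AA`; then the FRET efficiency is
#' `E = F / (gamma * I_DD + F)` and the stoichiometry is
#' `S = (gamma * I_DD + F) / (gamma * I_DD + F + I_AA)`.  `E` reports the
#' donor-acceptor distance, `S` the labelling status (near 1 for
#' donor-only, near 0 for acceptor-only molecules).  Bursts with a zero
#' denominator are flagged invalid (`es_valid = FALSE`, `E`/`S` set `NA`)
#' and excluded by [select_bursts()].
#'
#' @param bursts a data frame with integer columns `I_DD`, `I_DA`, `I_AA`
#'   (photon counts: donor emission under donor excitation, acceptor
#'   emission under donor excitation, acceptor emission under acceptor
#'   excitation).
#' @param corr a [correction_factors()].
#' @return The input as a tibble with columns `E`, `S`, `es_valid` added.
#' @export
#' @examples
#' compute_es(tibble::tibble(I_DD = 60, I_DA = 40, I_AA = 50))
compute_es <- function(bursts, corr = correction_factors()) {
  bursts <- as_tibble(bursts)
  stopifnot(all(c("I_DD", "I_DA", "I_AA") %in% names(bursts)))
  f <- bursts$I_DA - corr$leakage * bursts$I_DD -
    corr$direct_excitation * bursts$I_AA
  den_e <- corr$gamma * bursts$I_DD + f
  den_s <- den_e + bursts$I_AA
  ok <- is.finite(den_e) & den_e != 0 & is.finite(den_s) & den_s != 0
  bursts$E <- ifelse(ok, f / den_e, NA_real_)
  bursts$S <- ifelse(ok, den_e / den_s, NA_real_)
  bursts$es_valid <- ok
  bursts
}

#' Select analysable dual-labelled bursts
#'
#' Keeps bursts whose total photon rate exceeds `min_rate` counts per
#' millisecond and whose stoichiometry lies strictly inside
#' `(s_min, s_max)` — the window that excludes donor-only (S near 1) and
#' acceptor-only (S near 0) species.  Order is preserved; the counts
#' removed by each criterion are attached as attribute `"filter_counts"`.
#'
#' @param bursts output of [compute_es()]; needs a `duration_ms` column.
#' @param min_rate photon-rate threshold, counts/ms (kept if strictly
#'   above).
#' @param s_min,s_max open stoichiometry window.
#' @return Filtered tibble.
#' @export
select_bursts <- function(bursts, min_rate = 30, s_min = 0.2, s_max = 0.8) {
  bursts <- as_tibble(bursts)
  stopifnot(all(c("duration_ms", "E", "S") %in% names(bursts)))
  rate <- (bursts$I_DD + bursts$I_DA + bursts$I_AA) / bursts$duration_ms
  valid <- !is.na(bursts$es_valid) & bursts$es_valid
  keep_rate <- rate > min_rate
  keep_s <- !is.na(bursts$S) & bursts$S > s_min & bursts$S < s_max
  keep <- valid & keep_rate & keep_s
  out <- bursts[keep, , drop = FALSE]
  attr(out, "filter_counts") <- c(
    invalid = sum(!valid),
    rate = sum(valid & !keep_rate),
    stoichiometry = sum(valid & keep_rate & !keep_s))
  out
}

#' 1D FRET-efficiency histogram
#'
#' Bins are half-open `[lo, hi)` except the last, which is closed, so a
#' value exactly on an internal edge falls in the right-hand bin.  Values
#' outside the break range are dropped.
#'
#' @param E numeric FRET efficiencies, or a data frame with column `E`.
#' @param breaks bin edges; default 50 bins over \[-0.1, 1.1\].
#' @return A tibble of class `fret_histogram`: `bin_lo`, `bin_hi`, `mid`,
#'   `count`.
#' @export
histogram_1d <- function(E, breaks = seq(-0.1, 1.1, length.out = 51)) {
  if (is.data.frame(E)) E <- E$E
  E <- E[is.finite(E)]
  if (length(E) == 0) abort("No finite FRET efficiencies to histogram.")
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  idx <- findInterval(E, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  idx <- idx[idx >= 1L & idx <= nb]
  counts <- tabulate(idx, nbins = nb)
  structure(
    tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
           mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
           count = counts),
    class = c("fret_histogram", class(tibble())))
}

#' @export
autoplot.fret_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_lo[1:2]), fill = "grey70") +
    ggplot2::labs(x = "FRET efficiency E", y = "bursts") +
    ggplot2::theme_minimal()
}

gauss_bump <- function(x, A, c, s) A * exp(-(x - c)^2 / (2 * s^2))

weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(p, function(pp) x[o][which(cw >= pp)[1]], numeric(1))
}

# Starting values from the tallest well-separated histogram peaks (min 3
# bins apart); falls back to the 25th/90th weighted percentiles when the
# histogram shows fewer peaks than components.
peak_init <- function(x, y, n_components, binw) {
  sm <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  n <- length(y)
  is_peak <- vapply(seq_len(n), function(i) {
    y[i] > 0 &&
      sm[i] >= (if (i > 1) sm[i - 1] else -Inf) &&
      sm[i] >= (if (i < n) sm[i + 1] else -Inf)
  }, logical(1))
  cand <- order(sm, decreasing = TRUE)
  cand <- cand[is_peak[cand]]
  picked <- integer(0)
  for (i in cand) {
    if (length(picked) == n_components) break
    if (all(abs(i - picked) >= 3)) picked <- c(picked, i)
  }
  centers <- x[picked]
  if (length(centers) < n_components) {
    q <- weighted_quantile(x, y, c(0.25, 0.90))
    extra <- q[vapply(q, function(cc) all(abs(cc - centers) > 3 * binw),
                      logical(1))]
    centers <- c(centers, extra)[seq_len(n_components)]
  }
  centers <- sort(centers)
  amplitudes <- pmax(1, y[vapply(centers, function(cc)
    which.min(abs(x - cc)), integer(1))])
  list(centers = centers, widths = rep(2 * binw, n_components),
       amplitudes = amplitudes)
}

#' Fit one or two Gaussian components to a FRET histogram
#'
#' Least-squares fit of a sum of Gaussian bumps
#' `A_k * exp(-(E - c_k)^2 / (2 w_k^2))` to the bin counts
#' (Levenberg-Marquardt via \pkg{minpack.lm}).  Components are ordered by
#' ascending centre; weights are component areas normalised to unit total.
#' Widths are bounded below at one bin width — a fit pressed against that
#' floor is flagged `width_at_floor`.  Two-component fits initialise the
#' centres at the two tallest well-separated histogram peaks, falling
#' back to the 25th/90th weighted percentiles for unimodal-looking
#' histograms, unless `init` is given.
#'
#' @param hist a [histogram_1d()] result (or tibble with `mid`, `count`).
#' @param n_components 1 or 2.
#' @param init optional list with numeric vectors `centers`, `widths`,
#'   `amplitudes` of length `n_components`.
#' @return An object of class `gaussian_mixture_fit`: list with
#'   `n_components`, `centers`, `widths`, `weights`, `amplitudes`,
#'   `center_stderr` (from the fit covariance), `rss`, `width_at_floor`,
#'   `histogram`, `fitted`.
#' @export
#' @examples
#' set.seed(1)
#' h <- histogram_1d(rnorm(5000, 0.43, 0.1))
#' fit_gaussian_mixture(h, 1)
fit_gaussian_mixture <- function(hist, n_components = 1, init = NULL) {
  stopifnot(n_components %in% c(1, 2))
  x <- hist$mid
  y <- hist$count
  if (sum(y > 0) < 3 * n_components) {
    abort("Histogram has too few non-empty bins for the requested fit.")
  }
  binw <- min(diff(x))
  if (is.null(init)) {
    if (n_components == 1) {
      mu <- sum(x * y) / sum(y)
      sdw <- sqrt(sum(y * (x - mu)^2) / sum(y))
      centers <- mu
      widths <- max(binw, sdw)
      amplitudes <- max(y)
    } else {
      ini <- peak_init(x, y, n_components, binw)
      centers <- ini$centers
      widths <- ini$widths
      amplitudes <- ini$amplitudes
    }
  } else {
    centers <- init$centers
    widths <- pmax(init$widths, binw)
    amplitudes <- init$amplitudes
  }
  start <- as.list(setNames(
    c(amplitudes, centers, widths),
    c(paste0("A", seq_len(n_components)),
      paste0("c", seq_len(n_components)),
      paste0("s", seq_len(n_components)))))
  form <- if (n_components == 1) {
    count ~ gauss_bump(mid, A1, c1, s1)
  } else {
    count ~ gauss_bump(mid, A1, c1, s1) + gauss_bump(mid, A2, c2, s2)
  }
  lower <- c(rep(0, n_components), rep(min(x), n_components),
             rep(binw, n_components))
  upper <- c(rep(Inf, n_components), rep(max(x), n_components),
             rep(diff(range(x)), n_components))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = hist, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort(sprintf("Gaussian mixture fit failed to converge: %s",
                    conditionMessage(e)))
    })
  cf <- stats::coef(fit)
  A <- cf[paste0("A", seq_len(n_components))]
  cc <- cf[paste0("c", seq_len(n_components))]
  ss <- cf[paste0("s", seq_len(n_components))]
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[paste0("c", seq_len(n_components))],
                 error = function(e) rep(NA_real_, n_components))
  o <- order(cc)
  A <- A[o]; cc <- cc[o]; ss <- ss[o]; se <- se[o]
  area <- A * ss * sqrt(2 * pi)
  at_floor <- ss <= binw * 1.0001
  if (any(at_floor)) {
    warn("Fitted width constrained at one bin width for a component.")
  }
  structure(
    list(n_components = n_components,
         centers = unname(cc), widths = unname(ss),
         weights = unname(area / sum(area)), amplitudes = unname(A),
         center_stderr = unname(se),
         rss = sum(stats::residuals(fit)^2),
         width_at_floor = unname(at_floor),
         histogram = hist,
         fitted = stats::fitted(fit)),
    class = "gaussian_mixture_fit")
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("<gaussian_mixture_fit> %d component(s)\n", x$n_components))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.gaussian_mixture_fit <- function(x, ...) {
  tibble(component = seq_len(x$n_components), center = x$centers,
         width = x$widths, weight = x$weights, amplitude = x$amplitudes,
         center_stderr = x$center_stderr)
}

#' @export
glance.gaussian_mixture_fit <- function(x, ...) {
  tibble(n_components = x$n_components, rss = x$rss,
         kink_fraction = kink_fraction(x),
         width_at_floor = any(x$width_at_floor))
}

#' @export
autoplot.gaussian_mixture_fit <- function(object, ...) {
  h <- object$histogram
  grid <- tibble(mid = seq(min(h$bin_lo), max(h$bin_hi), length.out = 400))
  curves <- purrr::map(seq_len(object$n_components), function(k) {
    tibble(mid = grid$mid, component = factor(k),
           count = gauss_bump(grid$mid, object$amplitudes[k],
                              object$centers[k], object$widths[k]))
  })
  autoplot(h) +
    ggplot2::geom_line(data = dplyr::bind_rows(curves),
                       ggplot2::aes(colour = .data$component),
                       linewidth = 0.8) +
    ggplot2::labs(colour = "component")
}

#' Kink fraction from a mixture fit
#'
#' The kinked subpopulation is read off as the total weight of mixture
#' components whose centre lies above `threshold_E`; the sharply bent kink
#' form shows a much higher FRET efficiency (near 0.95) than the weakly
#' bent form.
#'
#' @param fit a [fit_gaussian_mixture()] result.
#' @param threshold_E classification cutoff on the component centre.
#' @return Fraction in \[0, 1\].
#' @export
kink_fraction <- function(fit, threshold_E = 0.7) {
  sum(fit$weights[fit$centers > threshold_E])
}

#' Standard error of a fitted FRET-histogram centre
#'
#' The statistical precision of a Gaussian centre estimated from
#' `n_bursts` bursts is `width / sqrt(n_bursts)`.
#'
#' @param fit a [fit_gaussian_mixture()] result, or numeric width(s).
#' @param n_bursts number of bursts behind the histogram.
#' @return Standard error(s) in E units, one per component.
#' @export
#' @examples
#' center_standard_error(0.11, 3236)
center_standard_error <- function(fit, n_bursts) {
  stopifnot(n_bursts > 1)
  widths <- if (inherits(fit, "gaussian_mixture_fit")) fit$widths else fit
  widths / sqrt(n_bursts)
}
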