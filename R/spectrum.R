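#' Gaussian broadening and spectral assembly
#'
#' Stick transitions (wavenumber, oscillator strength) are convolved
#' with normalized Gaussians of fixed half-width at half-maximum (the
#' workflow default is 600 cm^-1), with the band area of each transition
#' fixed by the standard molar-absorptivity convention
#' \deqn{\int \epsilon(\tilde\nu) d\tilde\nu = f / 4.319\times 10^{-9}}
#' (epsilon in 1/(M cm), wavenumber in 1/cm).
#'
#' @param transitions data frame with columns \code{wavenumber_cm1} and
#'   \code{oscillator_strength}
#' @param hwhm half-width at half-maximum, cm^-1 (default 600)
#' @param grid_nm wavelength grid, nm (default 200 to 800 by 0.1)
#' @param weight overall multiplicative weight (used when several frames
#'   contribute; default 1)
#' @return object of class \code{"spectrum"}: \code{grid_nm},
#'   \code{epsilon}, \code{lambda_max}, \code{epsilon_max}, \code{hwhm}
#' @export
broaden <- function(transitions, hwhm = 600,
                    grid_nm = seq(200, 800, by = 0.1), weight = 1) {
  if (hwhm <= 0) stop("broaden: hwhm must be > 0")
  eps <- numeric(length(grid_nm))
  if (nrow(transitions) == 0) {
    warning("broaden: no transitions; returning zero spectrum")
  } else {
    sigma <- hwhm / sqrt(2 * log(2))
    nu_grid <- nm_to_wavenumber(grid_nm)
    for (t in seq_len(nrow(transitions))) {
      nu0 <- transitions$wavenumber_cm1[t]
      f <- transitions$oscillator_strength[t]
      area <- weight * f * OSC_TO_BAND_AREA
      eps <- eps + area * exp(-(nu_grid - nu0)^2 / (2 * sigma^2)) /
        (sigma * sqrt(2 * pi))
    }
  }
  imax <- which.max(eps)
  structure(list(grid_nm = grid_nm, epsilon = eps,
                 lambda_max = grid_nm[imax], epsilon_max = eps[imax],
                 hwhm = hwhm),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum: lambda_max = %.1f nm, epsilon_max = %.3g M^-1 cm^-1 (HWHM %.0f cm^-1)\n",
              x$lambda_max, x$epsilon_max, x$hwhm))
  invisible(x)
}

#' Average spectra over a trajectory's PMM transitions
#'
#' Each frame contributes with weight 1/n_frames, so the result is the
#' frame-averaged band.
#'
#' @param pmm_result data frame from \code{\link{pmm_trajectory}}
#' @inheritParams broaden
#' @return a \code{spectrum}
#' @export
spectrum_from_pmm <- function(pmm_result, hwhm = 600,
                              grid_nm = seq(200, 800, by = 0.1)) {
  nf <- length(unique(pmm_result$frame))
  broaden(pmm_result, hwhm = hwhm, grid_nm = grid_nm, weight = 1 / nf)
}

#' Weighted pointwise average of spectra on a common grid
#'
#' @param spectra list of \code{spectrum} objects sharing one grid
#' @param weights fractions summing to 1 (within 0.01)
#' @return a \code{spectrum} with lambda_max recomputed on the average
#' @export
average_spectra <- function(spectra, weights) {
  if (length(spectra) != length(weights)) stop("average_spectra: length mismatch")
  if (abs(sum(weights) - 1) > 0.01) stop("average_spectra: weights must sum to 1")
  grid <- spectra[[1]]$grid_nm
  for (s in spectra) {
    if (length(s$grid_nm) != length(grid) || any(s$grid_nm != grid)) {
      stop("average_spectra: spectra must share a common grid")
    }
  }
  eps <- Reduce(`+`, Map(function(s, w) w * s$epsilon, spectra, weights))
  imax <- which.max(eps)
  structure(list(grid_nm = grid, epsilon = eps,
                 lambda_max = grid[imax], epsilon_max = eps[imax],
                 hwhm = spectra[[1]]$hwhm),
            class = "spectrum")
}

#' Composition rule for per-cluster absorption maxima
#'
#' Combines the five per-cluster band positions into the total:
#' collective-frame position, plus the QM-solvent correction (centroid
#' with minus without explicit QM solvent molecules), plus the vibronic
#' correction (vibrationally resolved minus bare perturbed position):
#' total = lambda_cf + (lambda_c2qm - lambda_c0qm) +
#' (lambda_pmm_vib - lambda_pmm). Reported at 0.1 nm.
#'
#' @param lambda_cf collective-frame maximum, nm
#' @param lambda_c2qm centroid maximum with explicit QM solvent, nm
#' @param lambda_c0qm centroid maximum without QM solvent, nm
#' @param lambda_pmm_vib vibrationally resolved perturbed maximum, nm
#' @param lambda_pmm perturbed maximum, nm
#' @param digits reporting precision (default 1 decimal)
#' @return composed maximum, nm
#' @export
compose_total <- function(lambda_cf, lambda_c2qm, lambda_c0qm,
                          lambda_pmm_vib, lambda_pmm, digits = 1) {
  vals <- c(lambda_cf, lambda_c2qm, lambda_c0qm, lambda_pmm_vib, lambda_pmm)
  if (any(!is.finite(vals))) stop("compose_total: non-finite input")
  round(lambda_cf + (lambda_c2qm - lambda_c0qm) +
          (lambda_pmm_vib - lambda_pmm), digits)
}

#' Cluster-weighted average of band positions
#'
#' @param values per-cluster values, nm
#' @param weights cluster weights, fractions summing to 1 (within 0.01)
#' @param digits reporting precision (default 1 decimal)
#' @return weighted average, nm
#' @export
weighted_average <- function(values, weights, digits = 1) {
  if (length(values) != length(weights)) stop("weighted_average: length mismatch")
  if (abs(sum(weights) - 1) > 0.01) stop("weighted_average: weights must sum to 1")
  round(sum(values * weights), digits)
}

#' Solvatochromic shifts relative to a reference solvent
#'
#' @param averages named numeric vector of per-solvent band positions, nm
#' @param reference name of the reference solvent
#' @return named shifts (value minus reference); the reference maps to 0
#' @export
shift_vs_reference <- function(averages, reference) {
  if (!(reference %in% names(averages))) {
    stop("shift_vs_reference: reference solvent '", reference, "' not present")
  }
  averages - averages[[reference]]
}
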