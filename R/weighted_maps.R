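# Phase-spread weighted electron-density maps.  Downweighting a reflection
# amplitude is treated as a simulation of phase-angle uncertainty: the
# amplitude downweight d_k = exp(-(sigmaF/F)^2) is converted through a
# lookup table into an equivalent Gaussian phase spread sigma_phi, and the
# map is synthesized as the sum of 25 Fourier transforms with the
# reflection phase stepped across +-2 sigma_phi at Gaussian weights.

#' Amplitude downweighting from measurement error
#'
#' `s_k = sigmaF / F_obs`, `d_k = exp(-s_k^2)`, which lies in (0, 1].
#'
#' @param f_obs observed amplitudes (> 0; non-positive entries give `NA`).
#' @param sig_f amplitude standard errors.
#' @return list with `s` and `d` vectors.
#' @export
compute_downweight <- function(f_obs, sig_f) {
  s <- ifelse(f_obs > 0, sig_f / f_obs, NA_real_)
  list(s = s, d = exp(-s^2))
}

#' Phase-spread lookup table
#'
#' For each Gaussian phase-angle spread sigma_phi between 0 and 6.27
#' radians (about 2 pi) in steps of 0.01, the centroid radius of the unit
#' circle weighted by `exp(-phi^2 / (2 sigma_phi^2))` over the full circle
#' (`phi` in `[-pi, pi]`) is computed by numerical integration.  The
#' table is strictly decreasing from 1 (at sigma_phi = 0), so it can be
#' used in reverse to assign a phase spread to a given amplitude
#' downweight.
#'
#' @param step sigma_phi tabulation step, radians.
#' @param sigma_max largest tabulated spread, radians.
#' @return data frame with columns `sigma` and `d`.
#' @export
build_phase_spread_table <- function(step = 0.01, sigma_max = 6.27) {
  key <- sprintf("pst_%g_%g", step, sigma_max)
  if (!is.null(.pkgenv[[key]])) return(.pkgenv[[key]])
  sigma <- seq(0, sigma_max, by = step)
  phi <- seq(-pi, pi, length.out = 4001)
  d <- vapply(sigma, function(s) {
    if (s == 0) return(1)                      # point mass at phi = 0
    w <- exp(-phi^2 / (2 * s^2))
    sqrt(sum(w * cos(phi))^2 + sum(w * sin(phi))^2) / sum(w)
  }, 0)
  tab <- data.frame(sigma = sigma, d = d)
  .pkgenv[[key]] <- tab
  tab
}

#' Phase spread for a given downweight
#'
#' Reverse lookup in the phase-spread table by linear interpolation;
#' downweights below the tabulated minimum clamp to the maximum spread
#' (6.27 radians).
#'
#' @param d downweight value(s) in (0, 1].
#' @return sigma_phi in radians.
#' @export
sigma_from_downweight <- function(d) {
  tab <- build_phase_spread_table()
  out <- stats::approx(tab$d, tab$sigma, xout = pmin(d, 1), rule = 2)$y
  out[d <= min(tab$d)] <- max(tab$sigma)
  out
}

# fill a Hermitian reciprocal grid from coefficients on unique reflections
.coeff_grid <- function(hkl, coeff, dims) {
  F <- array(0 + 0i, dims)
  i <- (hkl[, 1] %% dims[1]) + 1
  j <- (hkl[, 2] %% dims[2]) + 1
  k <- (hkl[, 3] %% dims[3]) + 1
  F[cbind(i, j, k)] <- coeff
  im <- ((-hkl[, 1]) %% dims[1]) + 1
  jm <- ((-hkl[, 2]) %% dims[2]) + 1
  km <- ((-hkl[, 3]) %% dims[3]) + 1
  F[cbind(im, jm, km)] <- Conj(coeff)
  F
}

#' Synthesize the phase-spread weighted electron-density map
#'
#' Each working reflection enters at an amplitude of `2 Fo - Fc` (or
#' `Fo - Fc` for the difference map) at its calculated phase; 25
#' phase-shifted copies spanning -2 sigma_phi to +2 sigma_phi at
#' normalized Gaussian weights are summed (by linearity, as a single
#' transform of the weight-attenuated coefficients).  Reflections in the
#' free set, with unphased F_calc or non-positive F_obs are omitted; with
#' all sigma_phi = 0 the synthesis equals the plain map exactly.
#'
#' @param refl a `bondflex_reflections` object.
#' @param f_calc complex calculated structure factors on `refl$data`.
#' @param dims unit-cell grid dimensions.
#' @param type `"2FoFc"` (refinement target) or `"FoFc"` (difference map).
#' @param n_steps number of phase-shifted transforms (25).
#' @return a unit-cell `bondflex_grid` with attributes `n_used` and
#'   `n_excluded`.
#' @export
synthesize_weighted_map <- function(refl, f_calc, dims, type = c("2FoFc",
                                                                 "FoFc"),
                                    n_steps = 25) {
  type <- match.arg(type)
  dat <- refl$data
  stopifnot(length(f_calc) == nrow(dat))
  if (any(is.na(f_calc) & !dat$free)) stop("unphased working reflections")
  keep <- !dat$free & !is.na(f_calc) & dat$fobs > 0
  n_exc <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  fc <- f_calc[keep]
  dw <- compute_downweight(dat$fobs, dat$sigf)
  sig <- sigma_from_downweight(dw$d)
  u <- seq(-2, 2, length.out = n_steps)
  w <- exp(-u^2 / 2)
  # per-reflection attenuation: normalized sum of the 25 phase-shifted,
  # Gaussian-weighted contributions (real by symmetry of the steps)
  atten <- vapply(sig, function(s) sum(w * cos(u * s)) / sum(w), 0)
  amp <- if (type == "2FoFc") 2 * dat$fobs - Mod(fc) else dat$fobs - Mod(fc)
  coeff <- amp * atten * exp(1i * Arg(fc))
  F <- .coeff_grid(as.matrix(dat[, c("h", "k", "l")]), coeff, dims)
  g <- grid_from_structure_factors(F, refl$cell)
  attr(g, "n_used") <- nrow(dat)
  attr(g, "n_excluded") <- n_exc
  g
}

#' R factors
#'
#' `R = sum |F_obs - |F_calc|| / sum F_obs` over the working and free
#' reflection sets.
#'
#' @param f_obs observed amplitudes.
#' @param f_calc_amp calculated amplitudes (scale already applied).
#' @param free logical free-set flags.
#' @return list with `r_work` and `r_free` (`NA` if no free reflections).
#' @export
compute_r_factors <- function(f_obs, f_calc_amp, free = rep(FALSE,
                                                            length(f_obs))) {
  work <- !free
  if (!any(work)) stop("empty working set")
  rw <- sum(abs(f_obs[work] - f_calc_amp[work])) / sum(f_obs[work])
  rf <- if (any(free))
    sum(abs(f_obs[free] - f_calc_amp[free])) / sum(f_obs[free]) else NA_real_
  list(r_work = rw, r_free = rf)
}
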