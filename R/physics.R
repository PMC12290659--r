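#' 3D-PLI physical signal model
#'
#' A birefringent tissue voxel observed between a rotating linear polarizer
#' and a circular analyzer produces, at polarizer angle \eqn{\rho}, the
#' transmitted intensity
#' \deqn{I_\rho = \frac{I_T}{2}\,(1 + \sin(2\rho - 2\varphi)\,\sin\delta)}
#' with transmittance \eqn{I_T = I_0 e^{-t\mu}} (Bouguer-Lambert) and phase
#' retardation \eqn{\delta \approx 2\pi t \Delta n \cos^2\alpha / \lambda},
#' where \eqn{\varphi} is the in-plane fiber direction, \eqn{\alpha} the
#' out-of-plane inclination, \eqn{t} the cumulative birefringent thickness,
#' \eqn{\mu} the attenuation coefficient, \eqn{\Delta n} the birefringence
#' and \eqn{\lambda} the light wavelength.
#'
#' @name physics
NULL

#' Per-pixel fiber and optics parameters for the forward model
#'
#' @param phi in-plane direction matrix, radians (wrapped mod pi).
#' @param alpha inclination matrix, radians in \code{[0, pi/2]}.
#' @param thickness cumulative birefringent thickness, micrometers, >= 0.
#' @param attenuation attenuation coefficient, 1/micrometer, >= 0.
#' @param I0 incident intensity, > 0.
#' @param birefringence dimensionless birefringence \eqn{\Delta n}.
#' @param wavelength light wavelength in nanometers (default 550).
#' @return a list of class \code{"FiberField"}.
#' @export
fiberField <- function(phi, alpha, thickness, attenuation,
                       I0 = 1, birefringence = 1.5e-3, wavelength = 550) {
  phi <- as.matrix(phi); alpha <- as.matrix(alpha)
  thickness <- as.matrix(thickness); attenuation <- as.matrix(attenuation)
  if (any(alpha < -1e-12 | alpha > pi / 2 + 1e-12))
    stop("inclination must lie in [0, pi/2]")
  if (any(thickness < 0)) stop("thickness must be non-negative")
  if (any(attenuation < 0)) stop("attenuation must be non-negative")
  if (I0 <= 0) stop("I0 must be positive")
  structure(list(phi = wrapDirection(phi), alpha = alpha,
                 thickness = thickness, attenuation = attenuation,
                 I0 = I0, birefringence = birefringence,
                 wavelength = wavelength),
            class = "FiberField")
}

#' Phase retardation delta of a fiber field
#'
#' \eqn{\delta = 2\pi t \Delta n \cos^2\alpha / \lambda}, with t in
#' micrometers and lambda converted from nanometers.
#'
#' @param field a \code{\link{fiberField}}.
#' @return matrix of phase retardation in radians.
#' @export
phaseRetardation <- function(field) {
  lambda_um <- field$wavelength / 1000
  2 * pi * field$thickness * field$birefringence *
    cos(field$alpha)^2 / lambda_um
}

#' Simulate the 9-angle intensity series of a fiber field
#'
#' Evaluates the sinusoidal signal model at the nine polarizer rotation
#' angles: mean \eqn{I_T/2}, amplitude \eqn{(I_T/2)|\sin\delta|}, phase set
#' by the fiber direction.
#'
#' @param field a \code{\link{fiberField}}.
#' @param pixelSize pixel size in micrometers for the resulting series.
#' @return a \linkS4class{PLISeries}.
#' @export
forwardProfiles <- function(field, pixelSize = 1.3) {
  stopifnot(inherits(field, "FiberField"))
  IT <- field$I0 * exp(-field$thickness * field$attenuation)
  delta <- phaseRetardation(field)
  rho <- rhoAngles()
  d <- dim(field$phi)
  out <- array(0, c(d[1], d[2], 9L))
  for (k in seq_len(9L))
    out[, , k] <- IT / 2 * (1 + sin(2 * rho[k] - 2 * field$phi) * sin(delta))
  PLISeries(out, pixelSize = pixelSize)
}

#' Evaluate the signal model directly from parameter maps
#'
#' Convenience forward evaluation when transmittance, direction and
#' retardation (rather than microscopic fiber parameters) are given:
#' \eqn{I_\rho = (I_T/2)(1 + \sin(2\rho - 2\varphi)\, r)}.
#'
#' @param maps a \linkS4class{PLIMaps} object.
#' @return a \linkS4class{PLISeries}.
#' @export
profilesFromMaps <- function(maps) {
  rho <- rhoAngles()
  IT <- transmittance(maps); phi <- direction(maps); r <- retardation(maps)
  d <- dim(IT)
  out <- array(0, c(d[1], d[2], 9L))
  for (k in seq_len(9L))
    out[, , k] <- IT / 2 * (1 + sin(2 * rho[k] - 2 * phi) * r)
  PLISeries(out, pixelSize = pixelSize(maps))
}

#' Retrieve parameter maps from a 9-angle series by harmonic analysis
#'
#' Discrete Fourier analysis of the per-pixel sinusoid at the nine
#' equidistant rotation angles: transmittance is twice the profile mean,
#' retardation is the relative amplitude of the second harmonic in
#' \eqn{2\rho}, and direction is half the phase,
#' \eqn{\varphi = \frac{1}{2}\,\mathrm{atan2}(-a, b) \bmod \pi} for Fourier
#' coefficients \eqn{a} (cosine) and \eqn{b} (sine). The round trip with
#' \code{\link{forwardProfiles}} is exact on noiseless input.
#'
#' Pixels with zero mean intensity have undefined retardation and
#' direction; they are returned as 0 and flagged in the \code{undefined}
#' slot.
#'
#' @param series a \linkS4class{PLISeries}.
#' @param I0 incident intensity recorded with the resulting maps.
#' @return a \linkS4class{PLIMaps}.
#' @export
retrieveParameters <- function(series, I0 = 1) {
  x <- intensities(series)
  rho <- rhoAngles()
  n <- length(rho)
  IT <- 2 * apply(x, c(1, 2), mean)
  cos2 <- cos(2 * rho); sin2 <- sin(2 * rho)
  a <- matrix(0, dim(x)[1], dim(x)[2])
  b <- matrix(0, dim(x)[1], dim(x)[2])
  for (k in seq_len(n)) {
    a <- a + x[, , k] * cos2[k]
    b <- b + x[, , k] * sin2[k]
  }
  a <- 2 * a / n
  b <- 2 * b / n
  undef <- IT <= 0
  amp <- sqrt(a^2 + b^2)
  r <- ifelse(undef, 0, amp / (IT / 2))
  r <- pmin(pmax(r, 0), 1)
  phi <- wrapDirection(0.5 * atan2(-a, b))
  phi[undef] <- 0
  PLIMaps(IT, phi, r, pixelSize = pixelSize(series), I0 = I0,
          undefined = undef)
}

#' Estimate fiber inclination from parameter maps (simplified inversion)
#'
#' Approximate inversion of the signal model under the assumption of
#' spatially uniform attenuation: tissue thickness is first estimated from
#' transmittance via Bouguer-Lambert,
#' \eqn{\hat t = -\ln(I_T/I_0)/\mu_{\mathrm{ref}}}, then
#' \eqn{\cos^2\alpha = \arcsin(r)\,\lambda / (2\pi \hat t \Delta n)}
#' (clipped to \code{[0, 1]}) yields the inclination
#' \eqn{\alpha \in [0, \pi/2]}. This deliberately simple inversion assumes
#' \eqn{\delta \le \pi/2}; it is intended for simulation round trips and
#' qualitative maps, not quantitative fiber reconstruction.
#'
#' @param maps a \linkS4class{PLIMaps}.
#' @param muRef reference attenuation coefficient (1/um).
#' @param birefringence birefringence \eqn{\Delta n}.
#' @param wavelength wavelength in nm.
#' @return list with matrices \code{alpha} (radians, NA where transmittance
#'   is zero or I0 is exceeded) and \code{thickness} (micrometers).
#' @export
estimateInclination <- function(maps, muRef = 0.01, birefringence = 1.5e-3,
                                wavelength = 550) {
  IT <- transmittance(maps); r <- retardation(maps)
  I0 <- incidentIntensity(maps)
  bad <- IT <= 0
  frac <- pmin(IT / I0, 1)
  t_hat <- ifelse(bad, NA_real_, -log(frac) / muRef)
  lambda_um <- wavelength / 1000
  denom <- 2 * pi * t_hat * birefringence
  cos2a <- ifelse(bad | t_hat <= 0, NA_real_,
                  asin(pmin(pmax(r, 0), 1)) * lambda_um / denom)
  cos2a <- pmin(pmax(cos2a, 0), 1)
  alpha <- acos(sqrt(cos2a))
  list(alpha = alpha, thickness = t_hat)
}

#' Stack parameter maps into the 3-channel network input encoding
#'
#' Encodes the circular direction jointly with retardation as
#' \eqn{x = (I_T,\; r\cos 2\varphi,\; r\sin 2\varphi)}, which is continuous
#' across the 0/pi direction wrap and invertible wherever r > 0.
#'
#' @param maps a \linkS4class{PLIMaps}.
#' @return numeric array (H, W, 3).
#' @export
channelEncode <- function(maps) {
  IT <- transmittance(maps); phi <- direction(maps); r <- retardation(maps)
  out <- array(0, c(nrow(IT), ncol(IT), 3L))
  out[, , 1] <- IT
  out[, , 2] <- r * cos(2 * phi)
  out[, , 3] <- r * sin(2 * phi)
  out
}

#' Invert the 3-channel encoding back to parameter maps
#'
#' @param x (H, W, 3) array as produced by \code{\link{channelEncode}}.
#' @param pixelSize,I0 metadata for the reconstructed maps.
#' @return a \linkS4class{PLIMaps}; direction is 0 where r = 0.
#' @export
channelDecode <- function(x, pixelSize = 1.3, I0 = 1) {
  r <- sqrt(x[, , 2]^2 + x[, , 3]^2)
  phi <- wrapDirection(0.5 * atan2(x[, , 3], x[, , 2]))
  phi[r == 0] <- 0
  PLIMaps(x[, , 1], phi, pmin(r, 1), pixelSize = pixelSize, I0 = I0)
}
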