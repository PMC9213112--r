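#' Optical configuration of the Brillouin microscope
#'
#' Bundles the instrument constants needed to interpret a measured Brillouin
#' frequency shift: the incident wavelength \eqn{\lambda_0}, the scattering
#' angle \eqn{\theta}, and the water reference shift \eqn{\nu_B^{water}} used
#' to form the dimensionless elastic contrast. Defaults correspond to a
#' 780.24 nm diode laser in backscattering geometry, for which the water
#' reference is 5.066 GHz.
#'
#' @param lambda0_nm Incident wavelength in nanometres. Must be positive.
#' @param theta_deg Scattering angle in degrees, in (0, 180]. Backscattering
#'   (the default, 180) gives \eqn{\sin(\theta/2) = 1}.
#' @param water_shift_ghz Brillouin frequency shift of water in GHz, the
#'   normalization reference of the elastic contrast. Must be positive.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' shift_to_contrast(5.3193, cfg)
#' @export
optical_config <- function(lambda0_nm = 780.24, theta_deg = 180,
                           water_shift_ghz = 5.066) {
  stopifnot(is.numeric(lambda0_nm), length(lambda0_nm) == 1L,
            is.numeric(theta_deg), length(theta_deg) == 1L,
            is.numeric(water_shift_ghz), length(water_shift_ghz) == 1L)
  if (!is.finite(lambda0_nm) || lambda0_nm <= 0)
    stop("`lambda0_nm` must be a positive finite wavelength", call. = FALSE)
  if (!is.finite(theta_deg) || theta_deg <= 0 || theta_deg > 180)
    stop("`theta_deg` must lie in (0, 180]", call. = FALSE)
  if (!is.finite(water_shift_ghz) || water_shift_ghz <= 0)
    stop("`water_shift_ghz` must be a positive finite frequency",
         call. = FALSE)
  structure(list(lambda0_nm = lambda0_nm, theta_deg = theta_deg,
                 water_shift_ghz = water_shift_ghz),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config> lambda0 =", x$lambda0_nm, "nm, theta =",
      x$theta_deg, "deg, water shift =", x$water_shift_ghz, "GHz\n")
  invisible(x)
}

#' Material state of the probed specimen
#'
#' Refractive index and mass density of the specimen, and optionally its
#' shear modulus \eqn{G'}. These enter the conversion between the Brillouin
#' frequency shift and the longitudinal modulus; the elastic-contrast
#' operations never need them.
#'
#' @param n Refractive index (dimensionless), `n >= 1`.
#' @param rho_kg_m3 Mass density in kg m^-3, positive.
#' @param G_prime_pa Optional shear modulus in Pa (`NULL` if unknown).
#' @return An object of class `material_state`.
#' @export
material_state <- function(n, rho_kg_m3, G_prime_pa = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L,
            is.numeric(rho_kg_m3), length(rho_kg_m3) == 1L)
  if (!is.finite(n) || n < 1)
    stop("refractive index `n` must be finite and >= 1", call. = FALSE)
  if (!is.finite(rho_kg_m3) || rho_kg_m3 <= 0)
    stop("density `rho_kg_m3` must be positive", call. = FALSE)
  if (!is.null(G_prime_pa)) {
    stopifnot(is.numeric(G_prime_pa), length(G_prime_pa) == 1L)
    if (!is.finite(G_prime_pa) || G_prime_pa < 0)
      stop("shear modulus `G_prime_pa` must be >= 0", call. = FALSE)
  }
  structure(list(n = n, rho_kg_m3 = rho_kg_m3, G_prime_pa = G_prime_pa),
            class = "material_state")
}

#' Brillouin frequency shift to elastic contrast
#'
#' The dimensionless Brillouin elastic contrast normalizes a measured shift
#' by the water reference: \eqn{\bar\nu_B = \nu_B / \nu_B^{water} - 1}. The
#' contrast carries the same information as the shift but is independent of
#' the incident wavelength, easing comparison across instruments.
#'
#' @param shift_ghz Numeric vector of Brillouin frequency shifts in GHz, all
#'   positive.
#' @param config An [optical_config()].
#' @return Numeric vector of elastic contrast values (dimensionless).
#' @export
shift_to_contrast <- function(shift_ghz, config = optical_config()) {
  stopifnot(inherits(config, "optical_config"), is.numeric(shift_ghz))
  if (any(!is.finite(shift_ghz)) || any(shift_ghz <= 0))
    stop("`shift_ghz` must contain finite positive values", call. = FALSE)
  shift_ghz / config$water_shift_ghz - 1
}

#' Elastic contrast back to Brillouin frequency shift
#'
#' Inverse of [shift_to_contrast()]: \eqn{\nu_B = (1 + \bar\nu_B)\,
#' \nu_B^{water}}.
#'
#' @param contrast Numeric vector of elastic contrast values, all > -1.
#' @inheritParams shift_to_contrast
#' @return Numeric vector of shifts in GHz.
#' @export
contrast_to_shift <- function(contrast, config = optical_config()) {
  stopifnot(inherits(config, "optical_config"), is.numeric(contrast))
  if (any(!is.finite(contrast)) || any(contrast <= -1))
    stop("`contrast` must contain finite values > -1", call. = FALSE)
  (contrast + 1) * config$water_shift_ghz
}

# sin(theta/2) with the exact backscattering special case
.sin_half_theta <- function(config) {
  if (config$theta_deg == 180) return(1)
  s <- sin(config$theta_deg * pi / 360)
  if (s <= 0)
    stop("scattering geometry has sin(theta/2) = 0", call. = FALSE)
  s
}

#' Brillouin frequency shift to longitudinal modulus
#'
#' Inverts the Brillouin scattering relation
#' \eqn{\nu_B = (2 n / \lambda_0)\sqrt{M'/\rho}\,\sin(\theta/2)} for the
#' longitudinal storage modulus:
#' \eqn{M' = \rho\,(\nu_B \lambda_0 / (2 n \sin(\theta/2)))^2}.
#' Units are tracked internally in SI: the hypersonic phase velocity
#' \eqn{v = \nu_B \lambda_0 / (2 n \sin(\theta/2))} is formed in m/s from
#' GHz and nm, and \eqn{M' = \rho v^2} in Pa.
#'
#' @param shift_ghz Numeric vector of shifts in GHz, positive.
#' @param material A [material_state()].
#' @inheritParams shift_to_contrast
#' @return Longitudinal modulus \eqn{M'} in Pa.
#' @examples
#' # water: n = 1.33, rho = 1000 kg m^-3 -> about 2.21 GPa
#' shift_to_longitudinal_modulus(5.066, material_state(1.33, 1000))
#' @export
shift_to_longitudinal_modulus <- function(shift_ghz, material,
                                          config = optical_config()) {
  stopifnot(inherits(material, "material_state"),
            inherits(config, "optical_config"), is.numeric(shift_ghz))
  if (any(!is.finite(shift_ghz)) || any(shift_ghz <= 0))
    stop("`shift_ghz` must contain finite positive values", call. = FALSE)
  s <- .sin_half_theta(config)
  # GHz * nm = 1e9 Hz * 1e-9 m -> m/s, so the prefactors cancel exactly
  v_m_s <- shift_ghz * config$lambda0_nm / (2 * material$n * s)
  material$rho_kg_m3 * v_m_s^2
}

#' Longitudinal modulus to Brillouin frequency shift
#'
#' Forward form of the scattering relation; exact inverse of
#' [shift_to_longitudinal_modulus()].
#'
#' @param M_prime_pa Longitudinal modulus in Pa, positive.
#' @inheritParams shift_to_longitudinal_modulus
#' @return Shift in GHz.
#' @export
modulus_to_shift <- function(M_prime_pa, material, config = optical_config()) {
  stopifnot(inherits(material, "material_state"),
            inherits(config, "optical_config"), is.numeric(M_prime_pa))
  if (any(!is.finite(M_prime_pa)) || any(M_prime_pa <= 0))
    stop("`M_prime_pa` must contain finite positive values", call. = FALSE)
  s <- .sin_half_theta(config)
  v_m_s <- sqrt(M_prime_pa / material$rho_kg_m3)
  2 * material$n * s * v_m_s / config$lambda0_nm
}

#' Longitudinal modulus to longitudinal compressibility
#'
#' The longitudinal compressibility is the reciprocal modulus,
#' \eqn{\kappa_L = 1/M'}; a stiffer (higher \eqn{M'}) tissue is less
#' compressible.
#'
#' @param M_prime_pa Longitudinal modulus in Pa, positive.
#' @return Compressibility in Pa^-1.
#' @export
longitudinal_to_compressibility <- function(M_prime_pa) {
  stopifnot(is.numeric(M_prime_pa))
  if (any(!is.finite(M_prime_pa)) || any(M_prime_pa <= 0))
    stop("`M_prime_pa` must contain finite positive values", call. = FALSE)
  1 / M_prime_pa
}

#' Bulk modulus from longitudinal and shear moduli
#'
#' For an isotropic sample \eqn{M' = K' + \frac{4}{3} G'}, so
#' \eqn{K' = M' - \frac{4}{3} G'}.
#'
#' @param M_prime_pa Longitudinal modulus in Pa.
#' @param G_prime_pa Shear modulus in Pa, with `0 <= 4/3 * G' <= M'`.
#' @return Bulk modulus \eqn{K'} in Pa.
#' @export
bulk_from_longitudinal <- function(M_prime_pa, G_prime_pa) {
  stopifnot(is.numeric(M_prime_pa), is.numeric(G_prime_pa))
  if (any(!is.finite(M_prime_pa)) || any(!is.finite(G_prime_pa)) ||
      any(G_prime_pa < 0))
    stop("moduli must be finite and `G_prime_pa` >= 0", call. = FALSE)
  K <- M_prime_pa - 4 / 3 * G_prime_pa
  if (any(K < 0))
    stop("inconsistent moduli: M' < 4/3 G' gives a negative bulk modulus",
         call. = FALSE)
  K
}
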