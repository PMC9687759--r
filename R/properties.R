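# ---------------------------------------------------------------------------
# Constitutive models: static material constants, sigmoidal temperature-
# dependent dielectrics, tissue water content, effective / vaporization heat
# capacities. All temperatures in degrees Celsius, SI units otherwise.
# ---------------------------------------------------------------------------

#' Static thermal constants of a material region
#'
#' Bundles density, thermal conductivity and specific heat for one of the
#' registered material regions of the simulation domain.
#'
#' @param name material label, one of `"healthy_liver"`, `"tumor"`,
#'   `"blood"`, `"antenna_dielectric"`, `"antenna_metal"`.
#' @param density kg/m^3, strictly positive.
#' @param thermal_conductivity W/(m C), strictly positive.
#' @param specific_heat J/(kg C), strictly positive.
#' @return An object of class `material_constants`.
#' @export
material_constants <- function(name, density, thermal_conductivity, specific_heat) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(density = density, thermal_conductivity = thermal_conductivity,
            specific_heat = specific_heat)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical material constants must be strictly positive and finite")
  structure(list(name = name, density = density,
                 thermal_conductivity = thermal_conductivity,
                 specific_heat = specific_heat),
            class = "material_constants")
}

#' @export
print.material_constants <- function(x, ...) {
  cat(sprintf("<material_constants> %s: rho = %g kg/m^3, k = %g W/(m C), c = %g J/(kg C)\n",
              x$name, x$density, x$thermal_conductivity, x$specific_heat))
  invisible(x)
}

# Registry of thermal constants for liver tissue, tumoral tissue and blood,
# plus the antenna materials (PTFE-like dielectric, copper-like metal; the
# antenna interior is excluded from the thermal solve, so the metal entries
# only matter for completeness of the lookup).
.material_table <- list(
  healthy_liver      = list(density = 1079, thermal_conductivity = 0.52, specific_heat = 3540),
  tumor              = list(density = 1040, thermal_conductivity = 0.57, specific_heat = 3960),
  blood              = list(density = 1060, thermal_conductivity = 0.50, specific_heat = 3600),
  antenna_dielectric = list(density = 2200, thermal_conductivity = 0.25, specific_heat = 1050),
  antenna_metal      = list(density = 8700, thermal_conductivity = 400,  specific_heat = 385)
)

#' Look up the static constants of a registered material
#'
#' Thermal constants for healthy liver tissue (1079 kg/m^3, 0.52 W/(m C),
#' 3540 J/(kg C)), tumoral liver tissue (1040, 0.57, 3960) and blood
#' (1060, 0.50, 3600; baseline temperature 37 C), plus the antenna
#' construction materials.
#'
#' @param name material label.
#' @return A [material_constants] object.
#' @export
#' @examples
#' material_lookup("healthy_liver")$density
material_lookup <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(match(name, names(.material_table))))
    stop("unknown material: ", paste(name, collapse = ", "),
         " (registered: ", paste(names(.material_table), collapse = ", "), ")")
  m <- .material_table[[name]]
  material_constants(name, m$density, m$thermal_conductivity, m$specific_heat)
}

#' Baseline (core) blood temperature, degrees C
#' @export
blood_core_temperature <- function() 37

#' Sigmoidal temperature-dependent dielectric coefficients
#'
#' Coefficients of the sigmoidal models
#' \deqn{\varepsilon_r(T) = s_1 (1 - 1/(1 + e^{s_2 - s_3 T})), \qquad
#'       \sigma(T) = r_1 (1 - 1/(1 + e^{r_2 - r_3 T}))}
#' describing the collapse of tissue permittivity and conductivity as water
#' is driven off during heating. `s1` (dimensionless) and `r1` (S/m) are the
#' low-temperature plateaus, `s2`/`r2` (dimensionless) and `s3`/`r3` (1/C)
#' locate and scale the transition.
#'
#' The numeric defaults are not package inventions at 37 C: healthy-liver
#' values come from published sigmoidal fits to measured liver dielectric
#' data at 2.45 GHz (external provenance), and tumor values scale the
#' healthy plateaus by the reported 24% permittivity and 11% conductivity
#' contrast of tumoral versus healthy liver.
#'
#' @param s1,s2,s3 permittivity sigmoid coefficients.
#' @param r1,r2,r3 conductivity sigmoid coefficients.
#' @return An object of class `sigmoid_dielectric`.
#' @export
sigmoid_dielectric <- function(s1, s2, s3, r1, r2, r3) {
  if (!(s1 > 0 && r1 > 0 && s3 > 0 && r3 > 0))
    stop("sigmoid coefficients must satisfy s1 > 0, r1 > 0, s3 > 0, r3 > 0 ",
         "(dielectric properties decrease with heating)")
  structure(list(s1 = s1, s2 = s2, s3 = s3, r1 = r1, r2 = r2, r3 = r3),
            class = "sigmoid_dielectric")
}

#' @export
print.sigmoid_dielectric <- function(x, ...) {
  cat(sprintf("<sigmoid_dielectric> eps_r: s = (%g, %g, %g); sigma: r = (%g, %g, %g)\n",
              x$s1, x$s2, x$s3, x$r1, x$r2, x$r3))
  invisible(x)
}

#' Default dielectric coefficient sets
#'
#' @param material `"healthy_liver"`, `"tumor"` or `"antenna_dielectric"`
#'   (the latter: lossless PTFE-like, constant eps_r = 2.03 represented as a
#'   plateau with transition far above operating temperatures).
#' @return A [sigmoid_dielectric] object.
#' @export
default_dielectric <- function(material = c("healthy_liver", "tumor", "antenna_dielectric")) {
  material <- match.arg(material)
  switch(material,
    healthy_liver = sigmoid_dielectric(48.391, 6.286, 0.0764, 2.173, 5.324, 0.0607),
    tumor         = sigmoid_dielectric(60.005, 6.286, 0.0764, 2.412, 5.324, 0.0607),
    antenna_dielectric = sigmoid_dielectric(2.03, 500, 0.01, 1e-12, 500, 0.01))
}

#' Relative permittivity at temperature T
#'
#' @param T temperature, degrees C (vectorized).
#' @param coeffs a [sigmoid_dielectric].
#' @return dimensionless relative permittivity, strictly decreasing in `T`.
#' @export
#' @examples
#' relative_permittivity(37, default_dielectric("healthy_liver"))
relative_permittivity <- function(T, coeffs) {
  coeffs$s1 * (1 - 1 / (1 + exp(coeffs$s2 - coeffs$s3 * T)))
}

#' Electrical conductivity at temperature T
#'
#' @inheritParams relative_permittivity
#' @return conductivity in S/m, strictly decreasing in `T`.
#' @export
electrical_conductivity <- function(T, coeffs) {
  coeffs$r1 * (1 - 1 / (1 + exp(coeffs$r2 - coeffs$r3 * T)))
}

# --- water content -----------------------------------------------------------

#' Tissue water content by mass as a function of temperature
#'
#' Piecewise model of the mass fraction of water in liver tissue during
#' heating: a near-constant plateau of about 0.778 below the onset of
#' evaporation, a steep linear drop across the 100-104 C vaporization band,
#' and an exponential tail above 104 C. Below 70 C the model is extended as
#' the constant plateau value (steady-state water content). The three
#' branches are continuous at 100 C and 104 C.
#'
#' @param T temperature, degrees C (vectorized).
#' @return water mass fraction in `[0, 0.778]`.
#' @export
#' @examples
#' water_content(c(37, 70, 100, 104, 130))
water_content <- function(T) {
  w <- ifelse(T < 100,
              0.778 * (1 - exp((pmax(T, 70) - 106) / 3.42)),
              ifelse(T < 104,
                     7.053 - 0.064096 * T,
                     0.778 * exp(-(T - 80) / 34.37)))
  pmin(pmax(w, 0), 0.778)
}

#' Branchwise analytic derivative dW/dT of the water-content model
#'
#' At the branch joins (70, 100 and 104 C) the left-limit derivative is
#' returned, keeping the effective specific heat finite and deterministic.
#'
#' @inheritParams water_content
#' @return dW/dT in 1/C (non-positive everywhere).
#' @export
water_content_deriv <- function(T) {
  ifelse(T <= 70, 0,
         ifelse(T <= 100, -(0.778 / 3.42) * exp((T - 106) / 3.42),
                ifelse(T <= 104, -0.064096,
                       -(0.778 / 34.37) * exp(-(T - 80) / 34.37))))
}

#' Latent heat constant for the effective-specific-heat model, J/kg
#' @export
latent_heat_alpha <- function() 2.26e6

#' Effective specific heat including vaporization
#'
#' Folds the latent heat of the water being driven off into the specific
#' heat: `c' = c - alpha * dW/dT` with `W` the water mass fraction and
#' `alpha` the latent heat constant (2.26e6 J/kg). Since `W` is
#' non-increasing, `c' >= c` everywhere. An alternative reading that
#' divides the latent term by density is selectable via `per_density`.
#'
#' @param T temperature, degrees C (vectorized).
#' @param mat a [material_constants] object.
#' @param alpha latent heat constant, J/kg.
#' @param per_density if `TRUE`, use `c' = c - (alpha/rho) * dW/dT` instead.
#' @return effective specific heat, J/(kg C).
#' @export
effective_specific_heat <- function(T, mat, alpha = latent_heat_alpha(),
                                    per_density = FALSE) {
  scale <- if (per_density) alpha / mat$density else alpha
  mat$specific_heat - scale * water_content_deriv(T)
}

# --- vaporization (enthalpy-method) constants --------------------------------

#' Constants for the enthalpy-method vaporization model
#'
#' The enthalpy method represents vaporization as a narrow spike in the
#' volumetric heat capacity between 99 and 100 C: below the spike the
#' liquid-phase product `(rho*c)_l` applies, within it
#' `h_fg * C_w / Delta_T`, and above it the gas-phase product
#' `rho_g * c_g`.
#'
#' @param h_fg latent heat of vaporization times water density at 100 C,
#'   J/m^3 (default 2.26e6 J/kg x 958 kg/m^3).
#' @param C_w_tissue,C_w_blood water content mass fractions of tissue and
#'   blood.
#' @param rho_g,c_g gas-phase density (kg/m^3) and specific heat
#'   (J/(kg C)).
#' @param delta_T width of the vaporization band, C (must be positive).
#' @return An object of class `vaporization_constants`.
#' @export
vaporization_constants <- function(h_fg = 2.26e6 * 958,
                                   C_w_tissue = 0.778, C_w_blood = 0.79,
                                   rho_g = 370, c_g = 2160, delta_T = 1) {
  if (delta_T <= 0) stop("vaporization band width delta_T must be positive")
  vals <- c(h_fg, C_w_tissue, C_w_blood, rho_g, c_g)
  if (any(vals <= 0)) stop("all vaporization constants must be positive")
  obj <- structure(list(h_fg = h_fg, C_w_tissue = C_w_tissue,
                        C_w_blood = C_w_blood, rho_g = rho_g, c_g = c_g,
                        delta_T = delta_T),
                   class = "vaporization_constants")
  # sanity: steam must carry less sensible heat per volume than liquid tissue
  liq <- material_lookup("healthy_liver")
  if (rho_g * c_g >= liq$density * liq$specific_heat)
    stop("gas-phase heat capacity product must be below the liquid-phase product")
  obj
}

#' Volumetric heat capacity with the enthalpy vaporization spike
#'
#' Three-branch piecewise volumetric heat capacity `(rho*c)(T)`: liquid
#' product below 99 C, `h_fg * C_w / delta_T` across the 99-100 C band, gas
#' product above 100 C.
#'
#' @param T temperature, degrees C (vectorized), must exceed 0 C.
#' @param phase `"tissue"` or `"blood"`.
#' @param consts a [vaporization_constants] object.
#' @param mat liquid-phase [material_constants]; defaults to healthy liver
#'   for tissue and blood constants for blood.
#' @return volumetric heat capacity, J/(m^3 C).
#' @export
vaporization_rho_c <- function(T, phase = c("tissue", "blood"),
                               consts = vaporization_constants(), mat = NULL) {
  phase <- match.arg(phase)
  if (any(T <= 0)) stop("vaporization_rho_c is defined for T > 0 C")
  if (is.null(mat))
    mat <- material_lookup(if (phase == "tissue") "healthy_liver" else "blood")
  C_w <- if (phase == "tissue") consts$C_w_tissue else consts$C_w_blood
  liq <- mat$density * mat$specific_heat
  spike <- consts$h_fg * C_w / consts$delta_T
  gas <- consts$rho_g * consts$c_g
  ifelse(T <= 100 - consts$delta_T, liq, ifelse(T <= 100, spike, gas))
}
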