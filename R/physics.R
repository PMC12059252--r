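# Nuclear-spin constants and thermal polarization.

# Planck and Boltzmann constants (SI, 2019 redefinition; exact).
.PLANCK_H <- 6.62607015e-34
.BOLTZMANN_K <- 1.380649e-23

# Built-in gyromagnetic ratios, |gamma|/2pi in MHz/T (CODATA / standard NMR
# tables). Magnitudes are stored; the sign of gamma never enters the SNR
# arithmetic here.
.default_nuclei <- list(
  "1H"  = list(gamma_MHz_per_T = 42.577478, spins_per_molecule = 1),
  "2H"  = list(gamma_MHz_per_T = 6.535902,  spins_per_molecule = 1),
  "13C" = list(gamma_MHz_per_T = 10.708399, spins_per_molecule = 1),
  "15N" = list(gamma_MHz_per_T = 4.316726,  spins_per_molecule = 1),
  "19F" = list(gamma_MHz_per_T = 40.077572, spins_per_molecule = 1)
)

#' Define a nucleus
#'
#' Creates a nucleus descriptor carrying the gyromagnetic ratio
#' (\eqn{|\gamma|/2\pi} in MHz/T) and the number of equivalent spins per
#' molecule, used to convert molecular to spin concentration (e.g. 2 for the
#' protons of H2O).
#'
#' Common nuclei (1H, 2H, 13C, 15N, 19F) are available by name alone; the
#' built-in ratio can be overridden or a new nucleus defined by supplying
#' `gamma_MHz_per_T` explicitly.
#'
#' @param name Text label, e.g. `"13C"`.
#' @param gamma_MHz_per_T Gyromagnetic ratio over \eqn{2\pi}, MHz per tesla.
#'   Looked up from the built-in registry when `NULL`.
#' @param spins_per_molecule Number of equivalent spins contributing per
#'   molecule (>= 1).
#' @return An object of class `"nucleus"`.
#' @examples
#' nucleus("13C")
#' nucleus("H2O-1H", gamma_MHz_per_T = 42.577478, spins_per_molecule = 2)
#' @export
nucleus <- function(name, gamma_MHz_per_T = NULL, spins_per_molecule = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  reg <- .default_nuclei[[name]]
  if (is.null(gamma_MHz_per_T)) {
    if (is.null(reg)) {
      stop("unknown nucleus '", name,
           "'; supply gamma_MHz_per_T explicitly", call. = FALSE)
    }
    gamma_MHz_per_T <- reg$gamma_MHz_per_T
  }
  if (is.null(spins_per_molecule)) {
    spins_per_molecule <- if (is.null(reg)) 1 else reg$spins_per_molecule
  }
  if (!is.numeric(gamma_MHz_per_T) || gamma_MHz_per_T <= 0) {
    stop("gamma_MHz_per_T must be a positive number", call. = FALSE)
  }
  if (!is.numeric(spins_per_molecule) || spins_per_molecule < 1) {
    stop("spins_per_molecule must be >= 1", call. = FALSE)
  }
  structure(
    list(name = name,
         gamma_MHz_per_T = as.numeric(gamma_MHz_per_T),
         spins_per_molecule = as.numeric(spins_per_molecule)),
    class = "nucleus"
  )
}

#' @export
print.nucleus <- function(x, ...) {
  cat(sprintf("<nucleus %s: gamma/2pi = %.6g MHz/T, %g spin(s)/molecule>\n",
              x$name, x$gamma_MHz_per_T, x$spins_per_molecule))
  invisible(x)
}

#' List the built-in nucleus registry
#'
#' @return A data frame with one row per registered nucleus: name,
#'   gamma_MHz_per_T, spins_per_molecule.
#' @export
nucleus_registry <- function() {
  data.frame(
    name = names(.default_nuclei),
    gamma_MHz_per_T = vapply(.default_nuclei, `[[`, 0, "gamma_MHz_per_T"),
    spins_per_molecule = vapply(.default_nuclei, `[[`, 0,
                                "spins_per_molecule"),
    row.names = NULL
  )
}

#' Larmor frequency
#'
#' @param nucleus A [nucleus()] object.
#' @param field Static field in tesla (>= 0).
#' @return Resonance frequency in MHz.
#' @examples
#' larmor_frequency(nucleus("13C"), 9.4) # ~100.7 MHz
#' @export
larmor_frequency <- function(nucleus, field) {
  stopifnot(inherits(nucleus, "nucleus"))
  if (!is.numeric(field) || any(field < 0)) {
    stop("field must be >= 0 tesla", call. = FALSE)
  }
  nucleus$gamma_MHz_per_T * field
}

#' Thermal (Boltzmann) nuclear polarization
#'
#' Spin-1/2 equilibrium polarization
#' \eqn{P = \tanh(h \nu / (2 k_B T))} at the Larmor frequency \eqn{\nu}.
#' The spin-1/2 form is used for every registered nucleus, including the
#' spin-1 deuteron: at the fields and temperatures of interest the argument
#' of tanh is ~1e-5, the polarization is linear in \eqn{\gamma B / T}, and
#' only polarization *ratios* against a measured reference enter downstream,
#' so the distinction between Zeeman-manifold conventions is immaterial here.
#'
#' @param nucleus A [nucleus()] object.
#' @param field Static field in tesla (>= 0).
#' @param temperature Sample temperature in kelvin (> 0); default 298 K.
#' @return Polarization as a fraction in \[0, 1).
#' @examples
#' thermal_polarization(nucleus("1H"), 9.4, 298) # ~3.2e-5
#' @export
thermal_polarization <- function(nucleus, field, temperature = 298) {
  stopifnot(inherits(nucleus, "nucleus"))
  if (!is.numeric(field) || any(field < 0)) {
    stop("field must be >= 0 tesla", call. = FALSE)
  }
  if (!is.numeric(temperature) || any(temperature <= 0)) {
    stop("temperature must be > 0 kelvin", call. = FALSE)
  }
  nu_hz <- larmor_frequency(nucleus, field) * 1e6
  tanh(.PLANCK_H * nu_hz / (2 * .BOLTZMANN_K * temperature))
}
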