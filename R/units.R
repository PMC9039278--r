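# Unit conversion layer.  All physics inside the solvers is SI
# (Pa, m, m^3/s, Pa.s/m^3); mmHg, mm and mL/s exist only at the API
# boundary, and cardiac output alone is quoted in L/min.

.PA_PER_MMHG <- 133.322

mmHg_to_Pa <- function(p) p * .PA_PER_MMHG
Pa_to_mmHg <- function(p) p / .PA_PER_MMHG

mm_to_m <- function(x) x * 1e-3

mls_to_m3s <- function(q) q * 1e-6
m3s_to_mls <- function(q) q * 1e6

lmin_to_mls <- function(q) q * 1000 / 60

# resistance: mmHg.s/mL <-> Pa.s/m^3
Rmmhg_to_si <- function(r) r * .PA_PER_MMHG / 1e-6
Rsi_to_mmhg <- function(r) r * 1e-6 / .PA_PER_MMHG

#' Blood material properties
#'
#' Blood is treated as an incompressible Newtonian fluid.  The defaults are
#' the values conventionally used for coronary CFD: density 1050 kg/m^3 and
#' dynamic viscosity 0.0035 Pa s.
#'
#' @param density Mass density in kg/m^3.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return An object of class `blood_properties`.
#' @export
#' @examples
#' blood_properties()
blood_properties <- function(density = 1050, viscosity = 0.0035) {
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("blood density must be a single positive number (kg/m^3)")
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0)
    stop("blood viscosity must be a single positive number (Pa s)")
  structure(list(density = density, viscosity = viscosity),
            class = "blood_properties")
}
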