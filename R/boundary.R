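# Patient-specific boundary conditions.  Inlet: mean aortic pressure from
# the cuff-pressure formula.  Outlets: microcirculatory resistances sized
# so the healthy (stenosis-free) tree carries a coronary flow budget of 4%
# of cardiac output, split across outlets by Murray's law; hyperemia scales
# every coronary resistance to 24% of its resting value.  The systemic
# circulation is one lumped resistance Rdoa = Pa / (0.96 CO).

#' Boundary-condition configuration
#'
#' @param murray_exponent Radius exponent of the outlet flow split
#'   (default 3, the classical Murray value).
#' @param coronary_co_fraction Fraction of cardiac output perfusing the
#'   coronary tree at rest (default 0.04; the complement drives the
#'   systemic outlet).
#' @param venous_pressure_mmHg Reference pressure behind every outlet
#'   resistance (default 0).
#' @param hyperemia_factor Ratio of hyperemic to resting microcirculatory
#'   resistance (default 0.24).
#' @param inductance Empirical inertance of each outlet branch
#'   (default 0.05); it has no effect on a steady solution and is carried
#'   for fidelity of the lumped model only.
#' @return A list of class `bc_config`.
#' @export
bc_config <- function(murray_exponent = 3, coronary_co_fraction = 0.04,
                      venous_pressure_mmHg = 0, hyperemia_factor = 0.24,
                      inductance = 0.05) {
  stopifnot(murray_exponent > 0,
            coronary_co_fraction > 0, coronary_co_fraction < 1,
            venous_pressure_mmHg >= 0,
            hyperemia_factor > 0, inductance >= 0)
  structure(list(murray_exponent = murray_exponent,
                 coronary_co_fraction = coronary_co_fraction,
                 venous_pressure_mmHg = venous_pressure_mmHg,
                 hyperemia_factor = hyperemia_factor,
                 inductance = inductance),
            class = "bc_config")
}

#' Mean aortic pressure from cuff pressure
#'
#' Heart-rate-corrected cuff estimate of the mean arterial pressure:
#' `Pa = DBP + (1/3 + 0.0012 HR) (SBP - DBP)` (mmHg).  Strictly between
#' DBP and SBP at physiological heart rates.
#'
#' @param params A [patient_parameters()] object.
#' @return Mean aortic pressure in mmHg.
#' @export
#' @examples
#' mean_aortic_pressure(patient_parameters(128, 85, 72, 5.26))
mean_aortic_pressure <- function(params) {
  stopifnot(inherits(params, "patient_params"))
  params$dbp + (1 / 3 + params$hr * 0.0012) * (params$sbp - params$dbp)
}

#' Total resting coronary flow
#'
#' The coronary circulation is allotted a fixed fraction of cardiac output
#' (default 4%) at rest; the remainder perfuses the systemic circulation.
#'
#' @param params A [patient_parameters()] object.
#' @param coronary_fraction Coronary share of CO (default 0.04).
#' @return Resting coronary flow in mL/s.
#' @export
total_coronary_flow <- function(params, coronary_fraction = 0.04) {
  stopifnot(inherits(params, "patient_params"),
            coronary_fraction > 0, coronary_fraction < 1)
  lmin_to_mls(coronary_fraction * params$co)
}

#' Murray's-law flow split across coronary outlets
#'
#' Distributes a flow budget over the coronary outlets in proportion to
#' the cube (configurable exponent) of each outlet's terminal radius.
#'
#' @param tree A `coronary_tree`.
#' @param q_total Flow budget (any consistent unit; typically mL/s).
#' @param exponent Radius exponent (default 3).
#' @return Named numeric vector (outlet node -> flow) summing to `q_total`.
#' @export
murray_flow_split <- function(tree, q_total, exponent = 3) {
  stopifnot(inherits(tree, "coronary_tree"), q_total > 0)
  outs <- coronary_outlets(tree)
  if (!length(outs)) stop("tree has no coronary outlets")
  w <- outlet_radii(tree, outs)^exponent
  q <- q_total * w / sum(w)
  stats::setNames(q, outs)
}

#' Resting microcirculatory resistance of one outlet
#'
#' `R = P / Q`, the Ohm analogy between perfusion pressure and the resting
#' branch flow.
#'
#' @param p Perfusion pressure (mmHg).
#' @param q Resting branch flow (mL/s); must be positive.
#' @return Resistance in mmHg s/mL.
#' @export
resting_resistance <- function(p, q) {
  if (!is.numeric(q) || any(q <= 0))
    stop("resting_resistance: flow q must be positive")
  if (any(p < 0)) stop("resting_resistance: pressure p must be >= 0")
  p / q
}

#' Hyperemic microcirculatory resistance
#'
#' Maximal adenosine vasodilation is modelled as the microcirculatory
#' resistance falling to 24% of its resting value.
#'
#' @param r_resting Resting resistance (mmHg s/mL); must be positive.
#' @param factor Hyperemia factor (default 0.24).
#' @return Hyperemic resistance in the same units.
#' @export
#' @examples
#' hyperemic_resistance(100) # 24
hyperemic_resistance <- function(r_resting, factor = 0.24) {
  if (!is.numeric(r_resting) || any(r_resting <= 0))
    stop("hyperemic_resistance: r_resting must be positive")
  factor * r_resting
}

#' Systemic (descending-aorta) outlet resistance
#'
#' `Rdoa = Pa / (0.96 CO)`: the systemic circulation, taking 96% of
#' cardiac output, lumped into one resistance.
#'
#' @param pa Mean aortic pressure (mmHg).
#' @param co Cardiac output in mL/s.
#' @param systemic_fraction Systemic share of CO (default 0.96).
#' @return Resistance in mmHg s/mL.
#' @export
aorta_outlet_resistance <- function(pa, co, systemic_fraction = 0.96) {
  if (!is.numeric(co) || any(co <= 0))
    stop("aorta_outlet_resistance: cardiac output must be positive")
  stopifnot(systemic_fraction > 0, systemic_fraction < 1)
  pa / (systemic_fraction * co)
}

#' Build the lumped-parameter outlet model for a tree
#'
#' Composes the full boundary-condition chain: mean aortic pressure ->
#' resting coronary flow budget -> Murray split across outlets -> per-outlet
#' resting resistance `(Pa - Pv)/Q_i` -> optional hyperemia transform; the
#' systemic outlet receives `Rdoa`.  Resistances are derived from the
#' healthy-tree flow budget and never from a stenosed solve, so the model
#' is independent of lesion burden.
#'
#' @param tree A `coronary_tree`.
#' @param params A [patient_parameters()] object.
#' @param hyperemia Logical: size the model for maximal hyperemia
#'   (default TRUE; FFR is defined under hyperemia).
#' @param config A [bc_config()].
#' @return An object of class `lpm` with elements `outlets` (data.frame:
#'   `outlet_node`, `r_resting`, `r_hyperemia`, `inductance`,
#'   `venous_pressure`), `r_doa`, `state` (`"hyperemia"` or `"resting"`),
#'   `inlet_pressure` (mmHg) and `config`.
#' @export
build_lpm <- function(tree, params, hyperemia = TRUE, config = bc_config()) {
  stopifnot(inherits(tree, "coronary_tree"),
            inherits(params, "patient_params"),
            inherits(config, "bc_config"))
  pa <- mean_aortic_pressure(params)
  pv <- config$venous_pressure_mmHg
  if (pa <= pv) stop("mean aortic pressure must exceed venous pressure")
  q_cor <- total_coronary_flow(params, config$coronary_co_fraction)
  q_split <- murray_flow_split(tree, q_cor, config$murray_exponent)
  r_rest <- resting_resistance(pa - pv, q_split)
  outlets <- data.frame(outlet_node = names(q_split),
                        r_resting = unname(r_rest),
                        r_hyperemia = unname(hyperemic_resistance(
                          r_rest, config$hyperemia_factor)),
                        inductance = config$inductance,
                        venous_pressure = pv,
                        stringsAsFactors = FALSE)
  co_mls <- lmin_to_mls(params$co)
  structure(list(outlets = outlets,
                 r_doa = aorta_outlet_resistance(
                   pa, co_mls, 1 - config$coronary_co_fraction),
                 state = if (hyperemia) "hyperemia" else "resting",
                 inlet_pressure = pa, config = config),
            class = "lpm")
}

#' @export
print.lpm <- function(x, ...) {
  cat(sprintf("Lumped-parameter outlet model (%s state)\n", x$state))
  cat(sprintf("  inlet Pa = %.4g mmHg, Rdoa = %.4g mmHg s/mL, %d coronary outlets\n",
              x$inlet_pressure, x$r_doa, nrow(x$outlets)))
  invisible(x)
}

# resistance actually in force per outlet, given the model state
active_outlet_resistances <- function(lpm) {
  if (lpm$state == "hyperemia") lpm$outlets$r_hyperemia
  else lpm$outlets$r_resting
}
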