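#' Patient physiological parameters
#'
#' Bundle of the four measurements that drive the boundary conditions:
#' systolic and diastolic cuff pressure, heart rate and cardiac output.
#' Myocardial mass may be carried along as metadata; it enters no equation.
#'
#' @param sbp Systolic blood pressure (mmHg).
#' @param dbp Diastolic blood pressure (mmHg).
#' @param hr Heart rate (beats/min).
#' @param co Cardiac output (L/min).
#' @param myocardial_mass Optional myocardial mass (g), metadata only.
#' @return An object of class `patient_params`.
#' @export
#' @examples
#' patient_parameters(sbp = 128, dbp = 85, hr = 72, co = 5.26)
patient_parameters <- function(sbp, dbp, hr, co, myocardial_mass = NULL) {
  for (nm in c("sbp", "dbp", "hr", "co")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("patient parameter '", nm, "' must be a single finite number")
  }
  if (dbp <= 0) stop("dbp must be positive, got ", dbp)
  if (sbp <= dbp) stop("sbp (", sbp, ") must exceed dbp (", dbp, ")")
  if (hr <= 0) stop("hr must be positive, got ", hr)
  if (co <= 0) stop("co must be positive, got ", co)
  if (!is.null(myocardial_mass)) {
    if (!is.numeric(myocardial_mass) || length(myocardial_mass) != 1L ||
        myocardial_mass <= 0)
      stop("myocardial_mass must be a single positive number (g)")
  }
  structure(list(sbp = sbp, dbp = dbp, hr = hr, co = co,
                 myocardial_mass = myocardial_mass),
            class = "patient_params")
}

#' @export
print.patient_params <- function(x, ...) {
  cat(sprintf("Patient parameters: SBP/DBP %.4g/%.4g mmHg, HR %.4g bpm, CO %.4g L/min\n",
              x$sbp, x$dbp, x$hr, x$co))
  if (!is.null(x$myocardial_mass))
    cat(sprintf("  myocardial mass %.4g g (metadata)\n", x$myocardial_mass))
  invisible(x)
}

#' Read / write patient parameters as JSON
#'
#' The on-disk form is a flat JSON object with explicit units in the key
#' names: `{sbp_mmHg, dbp_mmHg, hr_bpm, co_L_min, myocardial_mass_g?}`.
#'
#' @param path File path.
#' @return `read_patient` returns a [patient_parameters()] object.
#' @export
read_patient <- function(path) {
  if (!file.exists(path)) stop("patient file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("sbp_mmHg", "dbp_mmHg", "hr_bpm", "co_L_min")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("patient file ", path, " is missing field(s): ",
         paste(miss, collapse = ", "))
  patient_parameters(sbp = obj$sbp_mmHg, dbp = obj$dbp_mmHg,
                     hr = obj$hr_bpm, co = obj$co_L_min,
                     myocardial_mass = obj$myocardial_mass_g)
}

#' @rdname read_patient
#' @param params A [patient_parameters()] object.
#' @export
write_patient <- function(params, path) {
  stopifnot(inherits(params, "patient_params"))
  obj <- list(sbp_mmHg = params$sbp, dbp_mmHg = params$dbp,
              hr_bpm = params$hr, co_L_min = params$co)
  if (!is.null(params$myocardial_mass))
    obj$myocardial_mass_g <- params$myocardial_mass
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Draw plausible patient parameters
#'
#' Samples SBP, DBP, HR and CO from independent normal distributions with
#' the population means and standard deviations of a stable-angina cohort
#' (SBP 128 +/- 10, DBP 85 +/- 9 mmHg; HR 72 +/- 12.76 bpm; CO 5.26 +/- 2.6
#' L/min, truncated below at 2 L/min; myocardial mass 126 +/- 34.08 g as
#' metadata).  Draws violating sbp > dbp > 0, hr > 0 are rejected and
#' redrawn, so every returned object passes [patient_parameters()]
#' validation.  Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n Number of patients to draw (default 1).
#' @return A `patient_params` object, or a list of them when `n > 1`.
#' @export
#' @examples
#' sample_patient_parameters(seed = 1)
sample_patient_parameters <- function(seed, n = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  set.seed(as.integer(seed))
  draw_one <- function() {
    repeat {
      sbp <- stats::rnorm(1, 128, 10)
      dbp <- stats::rnorm(1, 85, 9)
      hr  <- stats::rnorm(1, 72, 12.76)
      co  <- stats::rnorm(1, 5.26, 2.6)
      mm  <- stats::rnorm(1, 126, 34.08)
      if (sbp > dbp && dbp > 0 && hr > 0 && co >= 2 && mm > 0)
        return(patient_parameters(sbp, dbp, hr, co, myocardial_mass = mm))
    }
  }
  if (n == 1) draw_one() else replicate(n, draw_one(), simplify = FALSE)
}
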