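# FFR field: Pd/Pa at every node of a converged solution, plus per-outlet
# distal values and per-lesion values sampled distal to each stenosis.

#' Compute the FFR field of a converged solution
#'
#' `FFR(node) = P(node) / Pa`, the ratio of local to inlet (aortic mean)
#' pressure; clinically meaningful under maximal hyperemia.  Per-lesion
#' values are sampled, by default, at the distal node of the stenosed
#' segment; `lesion_offset_mm` instead samples the within-segment pressure
#' a fixed distance beyond the end of the lesion (capped at the distal
#' node).
#'
#' @param sol A converged `flow_solution` (from [couple()] or
#'   [solve_monolithic()]).
#' @param inlet_pressure The aortic mean pressure Pa (mmHg) used to drive
#'   the solve.
#' @param lesion_offset_mm Optional sampling distance (mm) distal to each
#'   lesion; `NULL` (default) samples at the host segment's distal node.
#' @param threshold Ischemia threshold passed to [classify_ischemia()]
#'   (default 0.80).
#' @param blood,kt Loss-model parameters; must match those of the solve
#'   when `lesion_offset_mm` is used.
#' @return An object of class `ffr_field`: `node_ffr` (named numeric),
#'   `outlet_ffr` and `lesion_ffr` data.frames, `inlet_pressure_used`.
#' @export
compute_ffr <- function(sol, inlet_pressure, lesion_offset_mm = NULL,
                        threshold = 0.80, blood = blood_properties(),
                        kt = 1.52) {
  stopifnot(inherits(sol, "flow_solution"))
  if (!isTRUE(sol$converged))
    stop("compute_ffr requires a converged flow solution")
  tree <- sol$tree
  pa <- inlet_pressure
  stopifnot(pa > 0)
  node_ffr <- sol$node_pressures / pa
  outs <- coronary_outlets(tree)
  seg <- tree$segments
  outlet_ffr <- data.frame(
    outlet_node = outs,
    branch = seg$branch[match(outs, seg$distal)],
    distal_ffr = unname(node_ffr[outs]),
    stringsAsFactors = FALSE)

  lesion_rows <- list()
  for (i in seq_len(nrow(seg))) {
    st <- seg$stenoses[[i]]
    if (!nrow(st)) next
    for (j in seq_len(nrow(st))) {
      if (is.null(lesion_offset_mm)) {
        p_sample <- sol$node_pressures[[seg$distal[i]]]
      } else {
        s_mm <- min(st$position[j] * seg$length_mm[i] + st$length_mm[j] +
                      lesion_offset_mm, seg$length_mm[i])
        p_sample <- pressure_along_segment(sol, seg[i, ], s_mm, blood, kt)
      }
      lesion_rows[[length(lesion_rows) + 1L]] <- data.frame(
        segment_id = seg$id[i], branch = seg$branch[i],
        severity = st$severity[j], position = st$position[j],
        lesion_ffr = p_sample / pa,
        ischemic = classify_ischemia(p_sample / pa, threshold),
        stringsAsFactors = FALSE)
    }
  }
  lesion_ffr <- if (length(lesion_rows)) do.call(rbind, lesion_rows) else
    data.frame(segment_id = character(0), branch = character(0),
               severity = numeric(0), position = numeric(0),
               lesion_ffr = numeric(0), ischemic = logical(0))
  structure(list(node_ffr = node_ffr, outlet_ffr = outlet_ffr,
                 lesion_ffr = lesion_ffr, inlet_pressure_used = pa),
            class = "ffr_field")
}

# pressure (mmHg) at arc-length s_mm inside one segment of a solved tree:
# proximal pressure minus the viscous drop over [0, s] and the losses of
# every lesion whose throat ends proximal to s
pressure_along_segment <- function(sol, seg, s_mm, blood, kt) {
  q <- sol$segment_flows[[seg$id]]
  frac <- s_mm / seg$length_mm
  sub <- list(length_mm = s_mm, r_prox_mm = seg$r_prox_mm,
              r_dist_mm = seg$r_prox_mm +
                (seg$r_dist_mm - seg$r_prox_mm) * frac)
  dp <- Pa_to_mmHg(segment_viscous_resistance(sub, blood) * mls_to_m3s(q))
  st <- seg$stenoses[[1]]
  if (nrow(st)) {
    for (j in seq_len(nrow(st))) {
      if (st$position[j] * seg$length_mm + st$length_mm[j] <= s_mm + 1e-9)
        dp <- dp + stenosis_pressure_drop(st[j, ], seg, q, blood, kt)
    }
  }
  sol$node_pressures[[seg$proximal]] - dp
}

#' Classify a stenosis as ischemia-causing
#'
#' Inclusive threshold: `FFR <= threshold` (default 0.80) is positive.
#'
#' @param ffr_value FFR value in (0, 1.5].
#' @param threshold Diagnostic cut-off (default 0.80).
#' @return Logical.
#' @export
#' @examples
#' classify_ischemia(0.80) # TRUE: the threshold itself is positive
#' classify_ischemia(0.81) # FALSE
classify_ischemia <- function(ffr_value, threshold = 0.80) {
  stopifnot(all(ffr_value > 0), all(ffr_value <= 1.5))
  ffr_value <= threshold
}

#' @export
print.ffr_field <- function(x, ...) {
  cat(sprintf("FFR field (Pa = %.4g mmHg): %d nodes\n",
              x$inlet_pressure_used, length(x$node_ffr)))
  cat("Per-outlet distal FFR:\n")
  print(x$outlet_ffr, row.names = FALSE)
  if (nrow(x$lesion_ffr)) {
    cat("Per-lesion FFR:\n")
    print(x$lesion_ffr, row.names = FALSE)
  }
  invisible(x)
}

#' Flatten an FFR field to a results table
#'
#' One row per coronary outlet and one per lesion, the layout written by
#' [cmd_compute()].
#'
#' @param field An `ffr_field`.
#' @param threshold Ischemia threshold (default 0.80).
#' @return A data.frame with columns `id`, `kind`, `branch`, `severity`,
#'   `distal_ffr`, `lesion_ffr`, `ischemic`.
#' @export
ffr_results_table <- function(field, threshold = 0.80) {
  stopifnot(inherits(field, "ffr_field"))
  out <- data.frame(id = field$outlet_ffr$outlet_node, kind = "outlet",
                    branch = field$outlet_ffr$branch, severity = NA_real_,
                    distal_ffr = field$outlet_ffr$distal_ffr,
                    lesion_ffr = NA_real_,
                    ischemic = classify_ischemia(
                      field$outlet_ffr$distal_ffr, threshold),
                    stringsAsFactors = FALSE)
  if (nrow(field$lesion_ffr)) {
    les <- data.frame(id = field$lesion_ffr$segment_id, kind = "lesion",
                      branch = field$lesion_ffr$branch,
                      severity = field$lesion_ffr$severity,
                      distal_ffr = NA_real_,
                      lesion_ffr = field$lesion_ffr$lesion_ffr,
                      ischemic = field$lesion_ffr$ischemic,
                      stringsAsFactors = FALSE)
    out <- rbind(out, les)
  }
  out
}
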