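# Steady reduced-order vascular-domain solver and the partitioned 0D <->
# domain coupling.  The domain replaces a transient 3D CFD solve behind
# the same interface contract: inlet pressure and outlet pressures in,
# interface flows out.  A monolithic solver (outlet resistances folded
# into the network) provides an independent fixed point for verification.

#' Viscous (Poiseuille) resistance of a tapered segment
#'
#' Integrates `8 mu / (pi r(s)^4)` along the segment with the radius
#' varying linearly from `r_prox_mm` to `r_dist_mm`; the integral has the
#' closed form `8 mu L (r0^-3 - r1^-3) / (3 pi (r1 - r0))`, reducing to
#' `8 mu L / (pi r^4)` for a uniform tube.
#'
#' @param seg A list or one-row data.frame with `length_mm`, `r_prox_mm`,
#'   `r_dist_mm`.
#' @param blood A [blood_properties()] object.
#' @return Resistance in SI units (Pa s/m^3).
#' @export
#' @examples
#' seg <- list(length_mm = 10, r_prox_mm = 2, r_dist_mm = 2)
#' segment_viscous_resistance(seg, blood_properties()) # ~5.57e6 Pa s/m^3
segment_viscous_resistance <- function(seg, blood = blood_properties()) {
  L <- mm_to_m(seg$length_mm)
  r0 <- mm_to_m(seg$r_prox_mm)
  r1 <- mm_to_m(seg$r_dist_mm)
  stopifnot(L > 0, r0 > 0, r1 > 0)
  mu <- blood$viscosity
  if (isTRUE(all.equal(r0, r1)))
    return(8 * mu * L / (pi * r0^4))
  8 * mu * L * (r0^-3 - r1^-3) / (3 * pi * (r1 - r0))
}

# SI loss coefficients of one stenosis on its host segment:
# list(A = throat Poiseuille resistance, B = expansion-loss coefficient)
stenosis_loss_coeffs <- function(sten, seg, blood, kt = 1.52) {
  if (sten$severity >= 1) stop("stenosis severity must be < 1")
  r_loc <- mm_to_m(seg$r_prox_mm +
                     (seg$r_dist_mm - seg$r_prox_mm) * sten$position)
  a0 <- pi * r_loc^2
  r_throat <- r_loc * (1 - sten$severity)
  lt <- mm_to_m(sten$length_mm)
  A <- 8 * blood$viscosity * lt / (pi * r_throat^4)
  area_ratio <- 1 / (1 - sten$severity)^2  # A0/As
  B <- kt * (blood$density / 2) * (area_ratio - 1)^2 / a0^2
  list(A = A, B = B)
}

#' Pressure drop across a focal stenosis
#'
#' Empirical viscous + turbulent-expansion loss:
#' `dP = Rv q + Kt (rho/2) (A0/As - 1)^2 q |q| / A0^2`, where `Rv` is the
#' Poiseuille resistance of the throat, `A0` the local reference lumen
#' area, `As = A0 (1 - severity)^2` the throat area and `Kt` an empirical
#' constant (default 1.52).  Odd in `q`; zero for a vanishing lesion.
#'
#' @param sten A one-row stenosis data.frame or list (`position`,
#'   `severity`, `length_mm`).
#' @param seg The host segment (list with `length_mm`, `r_prox_mm`,
#'   `r_dist_mm`).
#' @param q Flow through the lesion in mL/s (any sign).
#' @param blood A [blood_properties()] object.
#' @param kt Empirical expansion-loss constant (default 1.52).
#' @return Pressure drop in mmHg, with the sign of `q`.
#' @export
stenosis_pressure_drop <- function(sten, seg, q, blood = blood_properties(),
                                   kt = 1.52) {
  cf <- stenosis_loss_coeffs(sten, seg, blood, kt)
  q_si <- mls_to_m3s(q)
  Pa_to_mmHg(cf$A * q_si + cf$B * q_si * abs(q_si))
}

# edges of the vascular domain (SI): one edge per segment, stenosis losses
# folded into the segment's (A, B)
domain_edges <- function(tree, blood, kt = 1.52) {
  seg <- tree$segments
  n <- nrow(seg)
  A <- numeric(n); B <- numeric(n)
  for (i in seq_len(n)) {
    A[i] <- segment_viscous_resistance(seg[i, ], blood)
    st <- seg$stenoses[[i]]
    if (nrow(st)) {
      for (j in seq_len(nrow(st))) {
        cf <- stenosis_loss_coeffs(st[j, ], seg[i, ], blood, kt)
        A[i] <- A[i] + cf$A
        B[i] <- B[i] + cf$B
      }
    }
  }
  data.frame(from = seg$proximal, to = seg$distal, A = A, B = B,
             id = seg$id, stringsAsFactors = FALSE)
}

# wrap a solve_network() result into the user-facing solution object
make_flow_solution <- function(tree, net, edges, converged = TRUE,
                               coupling_trace = NULL, state = NULL) {
  real_nodes <- names(tree$nodes)
  node_p <- Pa_to_mmHg(net$pressures[real_nodes])
  seg_idx <- match(tree$segments$id, edges$id)
  seg_q <- stats::setNames(m3s_to_mls(net$flows[seg_idx]),
                           tree$segments$id)
  outs <- c(coronary_outlets(tree), tree$systemic_outlet)  # NULL drops
  term_seg <- match(outs, tree$segments$distal)
  interface_q <- stats::setNames(unname(seg_q[tree$segments$id[term_seg]]),
                                 outs)
  inlet_segs <- tree$segments$id[tree$segments$proximal == tree$inlet]
  structure(list(node_pressures = node_p, segment_flows = seg_q,
                 interface_flows = interface_q,
                 inlet_flow = sum(seg_q[inlet_segs]),
                 mass_residual = net$residual_rel,
                 converged = converged, coupling_trace = coupling_trace,
                 state = state, tree = tree),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Flow solution: %d nodes, %d segments, inlet flow %.4g mL/s\n",
              length(x$node_pressures), length(x$segment_flows),
              x$inlet_flow))
  cat(sprintf("  converged: %s; mass-balance residual %.3g (relative)\n",
              x$converged, x$mass_residual))
  if (!is.null(x$coupling_trace))
    cat(sprintf("  coupling iterations: %d (final residual %.3g)\n",
                max(x$coupling_trace$iteration),
                x$coupling_trace$residual[nrow(x$coupling_trace)]))
  invisible(x)
}

#' Solve the vascular domain with prescribed boundary pressures
#'
#' Steady flow in the tree with the inlet held at `inlet_pressure` and
#' every outlet (coronary and systemic) held at the given pressure; each
#' segment obeys its viscous + stenosis pressure-drop law and mass is
#' balanced at every interior node (damped Newton iteration).
#'
#' @param tree A `coronary_tree`.
#' @param inlet_pressure Inlet pressure (mmHg).
#' @param outlet_pressures Named numeric (mmHg) covering every coronary
#'   outlet and the systemic outlet.
#' @param blood A [blood_properties()] object.
#' @param kt Stenosis expansion-loss constant (default 1.52).
#' @return A `flow_solution` with node pressures (mmHg), segment flows
#'   (mL/s, positive proximal to distal) and per-interface flows.
#' @export
solve_domain <- function(tree, inlet_pressure, outlet_pressures,
                         blood = blood_properties(), kt = 1.52) {
  outs <- c(coronary_outlets(tree), tree$systemic_outlet)
  miss <- setdiff(outs, names(outlet_pressures))
  if (length(miss))
    stop("outlet_pressures missing node(s): ", paste(miss, collapse = ", "))
  edges <- domain_edges(tree, blood, kt)
  fixed <- c(stats::setNames(mmHg_to_Pa(inlet_pressure), tree$inlet),
             mmHg_to_Pa(outlet_pressures[outs]))
  net <- solve_network(edges, fixed)
  make_flow_solution(tree, net, edges)
}

#' Evaluate the 0D outlet models for given interface flows
#'
#' Each outlet returns `P = Pv + R Q` with `R` the resting or hyperemic
#' resistance according to the model state (the inertance contributes
#' nothing at steady state, `dQ/dt = 0`); the systemic outlet uses `Rdoa`.
#'
#' @param lpm An `lpm` from [build_lpm()].
#' @param interface_flows Named numeric (mL/s) covering every outlet of the
#'   model, including the systemic outlet node.
#' @param systemic_outlet Node id of the systemic outlet.
#' @return Named numeric of outlet pressures (mmHg).
#' @export
solve_0d <- function(lpm, interface_flows, systemic_outlet = NULL) {
  stopifnot(inherits(lpm, "lpm"))
  outs <- c(lpm$outlets$outlet_node, systemic_outlet)
  miss <- setdiff(outs, names(interface_flows))
  if (length(miss))
    stop("interface_flows missing outlet(s): ", paste(miss, collapse = ", "))
  has_sys <- !is.null(systemic_outlet)
  r <- c(active_outlet_resistances(lpm), if (has_sys) lpm$r_doa)
  pv <- c(lpm$outlets$venous_pressure, if (has_sys) 0)
  stats::setNames(pv + r * unname(interface_flows[outs]), outs)
}

#' Coupling-loop configuration
#'
#' @param epsilon Relative convergence tolerance on the exchanged interface
#'   pressures and flows (default 1e-4).
#' @param max_iterations Iteration cap (default 200).
#' @param relaxation Initial under-relaxation factor in (0, 1] applied to
#'   the exchanged outlet pressures (default 0.5); subsequently adapted
#'   per interface by Aitken's secant rule.
#' @return A list of class `coupling_config`.
#' @export
coupling_config <- function(epsilon = 1e-4, max_iterations = 200,
                            relaxation = 0.5) {
  stopifnot(epsilon > 0, epsilon < 1, max_iterations >= 1,
            relaxation > 0, relaxation <= 1)
  structure(list(epsilon = epsilon, max_iterations = max_iterations,
                 relaxation = relaxation), class = "coupling_config")
}

#' Partitioned 0D-domain coupling iteration
#'
#' Alternates the vascular-domain solve (given the current outlet
#' pressures) with the 0D outlet evaluation (given the freshly computed
#' interface flows), under-relaxing the exchanged pressures.  Because the
#' microcirculatory resistances dominate the vessel resistances, the plain
#' relaxed fixed point is stiff; the update is therefore accelerated by
#' Anderson mixing of the exchanged pressure vector (history depth =
#' number of interfaces + 2), with
#' `cfg$relaxation` as the mixing/damping factor, which recovers the
#' quasi-Newton secant behaviour partitioned couplings need.  Convergence
#' is declared when the largest relative change across interfaces of both
#' pressure and flow falls below `cfg$epsilon` (flow floor 1e-6 mL/s
#' guards the division).
#'
#' @param tree A `coronary_tree`.
#' @param lpm An `lpm` from [build_lpm()].
#' @param inlet_pressure Inlet pressure (mmHg); typically
#'   `lpm$inlet_pressure`.
#' @param cfg A [coupling_config()].
#' @param blood A [blood_properties()] object.
#' @param kt Stenosis expansion-loss constant (default 1.52).
#' @return A converged `flow_solution` whose `coupling_trace` records one
#'   row per iteration (residuals and per-interface P/Q).
#' @export
couple <- function(tree, lpm, inlet_pressure = lpm$inlet_pressure,
                   cfg = coupling_config(), blood = blood_properties(),
                   kt = 1.52) {
  stopifnot(inherits(tree, "coronary_tree"), inherits(lpm, "lpm"),
            inherits(cfg, "coupling_config"))
  outs <- c(coronary_outlets(tree), tree$systemic_outlet)
  if (!setequal(lpm$outlets$outlet_node, coronary_outlets(tree)))
    stop("lpm outlets do not match the tree's coronary outlets")
  q_floor <- 1e-6   # mL/s
  p_floor <- 1e-3   # mmHg
  # Anderson history must span the interface dimension to act as a full
  # secant model of the (strongly cross-coupled) interface map
  m_depth <- length(outs) + 2L
  beta <- cfg$relaxation
  p_out <- stats::setNames(rep(0.9 * inlet_pressure, length(outs)), outs)
  q_prev <- NULL
  x_hist <- list(); r_hist <- list()
  trace <- vector("list", cfg$max_iterations)
  for (it in seq_len(cfg$max_iterations)) {
    dom <- solve_domain(tree, inlet_pressure, p_out, blood, kt)
    q_if <- dom$interface_flows[outs]
    p_new <- solve_0d(lpm, q_if, tree$systemic_outlet)[outs]
    r <- p_new - p_out
    res_p <- max(abs(r) / pmax(abs(p_new), p_floor))
    res_q <- if (is.null(q_prev)) Inf else
      max(abs(q_if - q_prev) / pmax(abs(q_if), q_floor))
    res <- max(res_p, res_q)
    trace[[it]] <- data.frame(iteration = it, residual = res,
                              residual_p = res_p, residual_q = res_q,
                              interface = outs,
                              p_mmHg = unname(p_out),
                              q_mls = unname(q_if),
                              row.names = NULL)
    if (res < cfg$epsilon) {
      tr <- do.call(rbind, trace[seq_len(it)])
      sol <- dom
      sol$coupling_trace <- tr
      sol$state <- lpm$state
      sol$converged <- TRUE
      return(sol)
    }
    x_hist <- c(x_hist, list(unname(p_out)))
    r_hist <- c(r_hist, list(unname(r)))
    if (length(x_hist) > m_depth + 1L) {
      x_hist <- x_hist[-1L]; r_hist <- r_hist[-1L]
    }
    k <- length(x_hist)
    if (k >= 2L) {
      dr <- vapply(2:k, function(j) r_hist[[j]] - r_hist[[j - 1L]],
                   numeric(length(outs)))
      dx <- vapply(2:k, function(j) x_hist[[j]] - x_hist[[j - 1L]],
                   numeric(length(outs)))
      dr <- matrix(dr, nrow = length(outs))
      dx <- matrix(dx, nrow = length(outs))
      # column-normalized rank-filtered least squares keeps the secant
      # model well conditioned as the history becomes collinear
      cn <- sqrt(colSums(dr^2)); cn[cn == 0] <- 1
      drn <- sweep(dr, 2, cn, "/")
      z <- tryCatch(qr.coef(qr(drn, tol = 1e-6), unname(r)),
                    error = function(e) rep(0, ncol(dr)))
      z[!is.finite(z)] <- 0
      gamma <- z / cn
      p_next <- unname(p_out) + beta * unname(r) -
        drop((dx + beta * dr) %*% gamma)
    } else {
      p_next <- unname(p_out) + beta * unname(r)
    }
    if (!all(is.finite(p_next))) {  # degenerate history: damped restart
      p_next <- unname(p_out) + beta * unname(r)
      x_hist <- list(); r_hist <- list()
    }
    p_out <- stats::setNames(p_next, outs)
    q_prev <- q_if
  }
  stop("coupling failed to converge in ", cfg$max_iterations,
       " iterations (last residual ", format(res), ")")
}

#' Monolithic verification solver
#'
#' Folds every outlet resistance into the flow network as an extra linear
#' edge to its venous reference pressure and solves the whole system in a
#' single Newton pass.  Shares the fixed point of [couple()] without any
#' partitioning, so it serves as an independent oracle for the coupling
#' loop.
#'
#' @inheritParams couple
#' @return A `flow_solution` (no coupling trace).
#' @export
solve_monolithic <- function(tree, lpm, inlet_pressure = lpm$inlet_pressure,
                             blood = blood_properties(), kt = 1.52) {
  stopifnot(inherits(tree, "coronary_tree"), inherits(lpm, "lpm"))
  edges <- domain_edges(tree, blood, kt)
  outs <- c(coronary_outlets(tree), tree$systemic_outlet)
  has_sys <- !is.null(tree$systemic_outlet)
  r_si <- Rmmhg_to_si(c(active_outlet_resistances(lpm),
                        if (has_sys) lpm$r_doa))
  pv <- mmHg_to_Pa(c(lpm$outlets$venous_pressure, if (has_sys) 0))
  gnd <- paste0(".gnd_", outs)
  out_edges <- data.frame(from = outs, to = gnd, A = r_si, B = 0,
                          id = paste0(".R_", outs), stringsAsFactors = FALSE)
  fixed <- c(stats::setNames(mmHg_to_Pa(inlet_pressure), tree$inlet),
             stats::setNames(pv, gnd))
  net <- solve_network(rbind(edges, out_edges), fixed)
  make_flow_solution(tree, net, rbind(edges, out_edges),
                     state = lpm$state)
}
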