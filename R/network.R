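# Internal steady nonlinear flow-network solver (SI units throughout).
#
# Each edge obeys  dp = A q + B q |q|  with A > 0 (viscous) and B >= 0
# (stenosis expansion loss), a strictly increasing dp(q), so the network
# problem -- nodal mass balance with some node pressures prescribed -- has
# a unique solution.  It is solved by damped Newton iteration on the free
# nodal pressures; the Jacobian is a weighted graph Laplacian (an
# M-matrix).

# invert dp = A q + B q |q| in closed form
edge_flow <- function(dp, A, B) {
  q <- dp / A
  nl <- B > 0
  if (any(nl)) {
    s <- sign(dp[nl]); ad <- abs(dp[nl])
    q[nl] <- s * 2 * ad / (A[nl] + sqrt(A[nl]^2 + 4 * B[nl] * ad))
  }
  q
}

# dq/d(dp) at the current flow
edge_conductance <- function(q, A, B) 1 / (A + 2 * B * abs(q))

# edges: data.frame(from, to, A, B); fixed_p: named numeric (Pa)
# returns list(pressures, flows, residual_rel, converged)
solve_network <- function(edges, fixed_p, tol = 1e-12, max_iter = 100) {
  nodes <- unique(c(edges$from, edges$to))
  free <- setdiff(nodes, names(fixed_p))
  nfree <- length(free)
  p <- stats::setNames(numeric(length(nodes)), nodes)
  p[names(fixed_p)] <- fixed_p

  iu <- match(edges$from, nodes)
  iv <- match(edges$to, nodes)
  fu <- match(edges$from, free)   # NA when the node is fixed
  fv <- match(edges$to, free)

  # nodal mass-balance residual at the free nodes
  accum <- function(q) {
    r <- numeric(nfree)
    for (e in seq_along(q)) {
      if (!is.na(fu[e])) r[fu[e]] <- r[fu[e]] - q[e]  # flow leaves 'from'
      if (!is.na(fv[e])) r[fv[e]] <- r[fv[e]] + q[e]  # flow enters 'to'
    }
    r
  }

  # linear (B = 0) initial guess for the free pressures
  if (nfree > 0) {
    K <- matrix(0, nfree, nfree)
    b <- numeric(nfree)
    g0 <- 1 / edges$A
    for (e in seq_len(nrow(edges))) {
      u <- fu[e]; v <- fv[e]; g <- g0[e]
      if (!is.na(u)) K[u, u] <- K[u, u] + g
      if (!is.na(v)) K[v, v] <- K[v, v] + g
      if (!is.na(u) && !is.na(v)) {
        K[u, v] <- K[u, v] - g
        K[v, u] <- K[v, u] - g
      }
      if (!is.na(u) && is.na(v)) b[u] <- b[u] + g * p[iv[e]]
      if (is.na(u) && !is.na(v)) b[v] <- b[v] + g * p[iu[e]]
    }
    p[free] <- solve(K, b)
  }

  q <- edge_flow(p[iu] - p[iv], edges$A, edges$B)
  if (nfree == 0)
    return(list(pressures = p, flows = unname(q), residual_rel = 0,
                converged = TRUE))

  qscale <- function(q) max(abs(q), 1e-12)
  r <- accum(q)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) <= tol * qscale(q)) { converged <- TRUE; break }
    g <- edge_conductance(q, edges$A, edges$B)
    J <- matrix(0, nfree, nfree)
    for (e in seq_len(nrow(edges))) {
      u <- fu[e]; v <- fv[e]; ge <- g[e]
      if (!is.na(u)) J[u, u] <- J[u, u] - ge
      if (!is.na(v)) J[v, v] <- J[v, v] - ge
      if (!is.na(u) && !is.na(v)) {
        J[u, v] <- J[u, v] + ge
        J[v, u] <- J[v, u] + ge
      }
    }
    step <- tryCatch(solve(J, -r), error = function(e)
      stop("network solver: singular Jacobian (", conditionMessage(e), ")"))
    # backtracking on the mass-balance norm
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:40) {
      p_try <- p
      p_try[free] <- p[free] + alpha * step
      q_try <- edge_flow(p_try[iu] - p_try[iv], edges$A, edges$B)
      r_try <- accum(q_try)
      if (max(abs(r_try)) < max(abs(r))) {
        p <- p_try; q <- q_try; r <- r_try; accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break  # at rounding level; final residual checked below
  }
  res_rel <- max(abs(r)) / qscale(q)
  # 1e-9 relative is the conservation guarantee; below it the solution is
  # accepted even when rounding stops further Newton progress
  if (!converged && res_rel > 1e-9)
    stop("network solver: Newton failed to converge; ",
         "relative mass-balance residual ", format(res_rel))
  list(pressures = p, flows = unname(q), residual_rel = res_rel,
       converged = TRUE)
}
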