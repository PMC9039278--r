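# Synthetic coronary-tree generator.  Emulates CTA-derived left/right
# coronary trees: a short wide aortic stub, main branches (LAD, LCX, RCA)
# tapering distally, and bifurcations whose daughter radii satisfy
# Murray's law r_parent^3 = r_left^3 + r_right^3 exactly by construction.

#' Generate a synthetic coronary tree
#'
#' Builds a rooted tree consisting of an aortic stub (inlet -> junction ->
#' systemic outlet) and up to three coronary branch trees off the junction.
#' `n_generations` controls how much of the arterial tree is present:
#' `1` gives a single LAD segment, `2` adds the LCX, `3` (the default) adds
#' the RCA and yields 7 coronary outlets.  Within each branch the LAD
#' receives `n_generations - 1` bifurcation levels, the LCX one fewer and
#' the RCA two fewer.  Daughter proximal radii are drawn by splitting the
#' parent's distal cube `r^3` with a random flow fraction in \[0.35, 0.5\],
#' so every bifurcation is Murray-compatible; segments taper by a factor
#' drawn from \[0.87, 0.93\] and have length 8-14 parent radii.
#'
#' Focal stenoses are placed on the root segment of the named branch.
#' Severities at or above 0.95 (near-occlusion, outside the loss-model
#' validity) are rejected.
#'
#' @param n_generations Number of branch generations (>= 1, default 3).
#' @param stenosis_spec Optional data.frame (or list of lists) with columns
#'   `branch`, `severity` and optionally `position` (default 0.5).
#' @param seed Integer seed; output is deterministic per seed.
#' @return A validated `coronary_tree`.
#' @export
#' @examples
#' tree <- generate_synthetic_tree(3, seed = 1)
#' coronary_outlets(tree)
generate_synthetic_tree <- function(n_generations = 3, stenosis_spec = NULL,
                                    seed = 1) {
  stopifnot(n_generations >= 1)
  sten <- normalize_stenosis_spec(stenosis_spec)
  if (nrow(sten) && any(sten$severity >= 0.95))
    stop("stenosis severity >= 0.95 rejected: near-occlusion lies outside ",
         "the pressure-loss model's validity")
  if (nrow(sten) && any(sten$severity < 0))
    stop("stenosis severity must be non-negative")
  set.seed(as.integer(seed))

  env <- new.env()
  env$segs <- list()
  env$node_n <- 0L
  env$seg_n <- 0L
  new_node <- function(prefix = "n") {
    env$node_n <- env$node_n + 1L
    paste0(prefix, env$node_n)
  }
  add_seg <- function(proximal, distal, length_mm, r_prox, r_dist, branch) {
    env$seg_n <- env$seg_n + 1L
    env$segs[[env$seg_n]] <- list(
      id = sprintf("s%02d", env$seg_n), proximal = proximal,
      distal = distal, length_mm = length_mm, r_prox_mm = r_prox,
      r_dist_mm = r_dist, branch = branch, stenoses = empty_stenoses())
    env$seg_n
  }
  grow <- function(prox_node, r_prox, depth, branch) {
    taper <- stats::runif(1, 0.87, 0.93)
    r_dist <- r_prox * taper
    len <- r_prox * stats::runif(1, 8, 14)
    dist_node <- new_node()
    add_seg(prox_node, dist_node, len, r_prox, r_dist, branch)
    if (depth > 0) {
      a <- stats::runif(1, 0.35, 0.5)  # flow fraction of first daughter
      grow(dist_node, r_dist * a^(1 / 3), depth - 1L, branch)
      grow(dist_node, r_dist * (1 - a)^(1 / 3), depth - 1L, branch)
    }
    invisible(NULL)
  }

  inlet <- "AO_IN"; junction <- "AO_J"; sys_out <- "AO_OUT"
  add_seg(inlet, junction, 20, 10.0, 9.9, "AORTA")
  add_seg(junction, sys_out, 30, 9.9, 9.7, "AORTA")
  grow(junction, stats::runif(1, 1.8, 2.0), n_generations - 1L, "LAD")
  if (n_generations >= 2)
    grow(junction, stats::runif(1, 1.5, 1.8), n_generations - 2L, "LCX")
  if (n_generations >= 3)
    grow(junction, stats::runif(1, 1.7, 1.9), max(n_generations - 3L, 0L),
         "RCA")

  segments <- data.frame(
    id = vapply(env$segs, `[[`, character(1), "id"),
    proximal = vapply(env$segs, `[[`, character(1), "proximal"),
    distal = vapply(env$segs, `[[`, character(1), "distal"),
    length_mm = vapply(env$segs, `[[`, numeric(1), "length_mm"),
    r_prox_mm = vapply(env$segs, `[[`, numeric(1), "r_prox_mm"),
    r_dist_mm = vapply(env$segs, `[[`, numeric(1), "r_dist_mm"),
    branch = vapply(env$segs, `[[`, character(1), "branch"),
    stringsAsFactors = FALSE)
  segments$stenoses <- lapply(env$segs, `[[`, "stenoses")

  if (nrow(sten)) {
    for (i in seq_len(nrow(sten))) {
      b <- sten$branch[i]
      hit <- which(segments$branch == b)[1L]
      if (is.na(hit))
        stop("stenosis_spec names branch '", b,
             "' which is absent at n_generations = ", n_generations)
      host_len <- segments$length_mm[hit]
      segments$stenoses[[hit]] <- rbind(
        segments$stenoses[[hit]],
        data.frame(position = sten$position[i], severity = sten$severity[i],
                   length_mm = min(8, 0.4 * host_len)))
    }
  }

  nodes <- stats::setNames(
    vector("list", length(unique(c(segments$proximal, segments$distal)))),
    unique(c(segments$proximal, segments$distal)))
  coronary_tree(nodes, segments, inlet = inlet, systemic_outlet = sys_out)
}

normalize_stenosis_spec <- function(spec) {
  if (is.null(spec))
    return(data.frame(branch = character(0), severity = numeric(0),
                      position = numeric(0)))
  if (is.data.frame(spec)) {
    df <- spec
  } else {
    df <- do.call(rbind, lapply(spec, function(x)
      data.frame(branch = x$branch, severity = x$severity,
                 position = if (is.null(x$position)) NA_real_ else x$position)))
  }
  if (is.null(df$position)) df$position <- NA_real_
  df$position[is.na(df$position)] <- 0.5
  if (!all(c("branch", "severity") %in% names(df)))
    stop("stenosis_spec needs columns 'branch' and 'severity'")
  df
}
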