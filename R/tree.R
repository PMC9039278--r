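# Coronary tree data model: a directed rooted tree of tapered centerline
# segments with focal stenosis descriptors.  Geometry is centerline +
# radius only; node coordinates are optional metadata.  Units: mm.

.TREE_SCHEMA <- "coro-ffrss-tree/1"
.BRANCH_LEVELS <- c("AORTA", "LAD", "LCX", "RCA", "OTHER")
.MIN_CORONARY_RADIUS_MM <- 0.5  # mirrors the >= 1 mm diameter retention rule

#' Construct a coronary tree
#'
#' @param nodes Named list: node id -> `NULL` or numeric xyz (mm).  Nodes
#'   referenced by segments but absent here are added without coordinates.
#' @param segments A data.frame with columns `id`, `proximal`, `distal`,
#'   `length_mm`, `r_prox_mm`, `r_dist_mm`, `branch` and a list-column
#'   `stenoses` (each element a data.frame with `position`, `severity`,
#'   `length_mm`, possibly zero rows).
#' @param inlet Node id of the aortic inlet.
#' @param systemic_outlet Node id of the descending-aorta (systemic) outlet.
#' @param validate Run [validate_tree()] (default TRUE).
#' @return An object of class `coronary_tree`.
#' @export
coronary_tree <- function(nodes, segments, inlet, systemic_outlet,
                          validate = TRUE) {
  if (is.null(segments$stenoses))
    segments$stenoses <- replicate(nrow(segments), empty_stenoses(),
                                   simplify = FALSE)
  referenced <- unique(c(segments$proximal, segments$distal))
  missing_ids <- setdiff(referenced, names(nodes))
  if (length(missing_ids)) {
    extra <- stats::setNames(vector("list", length(missing_ids)), missing_ids)
    nodes <- c(nodes, extra)
  }
  tree <- structure(list(nodes = nodes, segments = segments,
                         inlet = inlet, systemic_outlet = systemic_outlet),
                    class = "coronary_tree")
  if (validate) validate_tree(tree)
  tree
}

empty_stenoses <- function() {
  data.frame(position = numeric(0), severity = numeric(0),
             length_mm = numeric(0))
}

#' Validate a coronary tree
#'
#' Checks the structural invariants: positive lengths and radii, stenosis
#' descriptors inside their host segment, a connected acyclic topology
#' rooted at the single inlet, every outlet reachable from the inlet, and
#' at least one coronary outlet.  Coronary radii below 0.5 mm raise a
#' warning (not an error) so that sub-resolution synthetic stress trees can
#' still be solved.
#'
#' @param tree A `coronary_tree`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "coronary_tree")) stop("not a coronary_tree object")
  seg <- tree$segments
  need <- c("id", "proximal", "distal", "length_mm", "r_prox_mm",
            "r_dist_mm", "branch", "stenoses")
  miss <- setdiff(need, names(seg))
  if (length(miss))
    stop("segments table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(seg) < 1L) stop("tree has no segments")
  if (anyDuplicated(seg$id))
    stop("duplicate segment id: ", seg$id[duplicated(seg$id)][1L])
  bad_branch <- setdiff(unique(seg$branch), .BRANCH_LEVELS)
  if (length(bad_branch))
    stop("segment branch label not in {",
         paste(.BRANCH_LEVELS, collapse = ", "), "}: ", bad_branch[1L])
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (!is.finite(s$length_mm) || s$length_mm <= 0)
      stop("segment ", s$id, ": length_mm must be > 0")
    if (!is.finite(s$r_prox_mm) || s$r_prox_mm <= 0 ||
        !is.finite(s$r_dist_mm) || s$r_dist_mm <= 0)
      stop("segment ", s$id, ": radii must be > 0")
    st <- seg$stenoses[[i]]
    if (nrow(st)) {
      if (any(st$position < 0 | st$position > 1))
        stop("segment ", s$id, ": stenosis position must lie in [0, 1]")
      if (any(st$severity < 0 | st$severity >= 1))
        stop("segment ", s$id, ": stenosis severity must lie in [0, 1)")
      if (any(st$length_mm <= 0 | st$length_mm > s$length_mm))
        stop("segment ", s$id,
             ": stenosis length must be positive and <= segment length")
    }
  }
  # topology
  if (!tree$inlet %in% c(seg$proximal))
    stop("inlet node ", tree$inlet, " is not proximal to any segment")
  g <- igraph::graph_from_data_frame(
    data.frame(from = seg$proximal, to = seg$distal),
    directed = TRUE, vertices = names(tree$nodes))
  if (!igraph::is_dag(g)) stop("tree topology contains a cycle")
  indeg <- igraph::degree(g, mode = "in")
  roots <- names(indeg)[indeg == 0]
  if (!identical(sort(roots), sort(tree$inlet)))
    stop("exactly one root (the inlet) is allowed; found in-degree-0 nodes: ",
         paste(roots, collapse = ", "))
  reach <- igraph::subcomponent(g, tree$inlet, mode = "out")
  if (length(reach) != length(names(tree$nodes)))
    stop("node(s) not reachable from the inlet: ",
         paste(setdiff(names(tree$nodes), names(reach)), collapse = ", "))
  outdeg <- igraph::degree(g, mode = "out")
  terminals <- names(outdeg)[outdeg == 0]
  if (!is.null(tree$systemic_outlet) &&
      !tree$systemic_outlet %in% terminals)
    stop("systemic_outlet ", tree$systemic_outlet,
         " is not a terminal node of the tree")
  cor_out <- setdiff(terminals, tree$systemic_outlet)
  if (!length(cor_out)) stop("tree has no coronary outlet")
  # retention-rule warning for sub-resolution coronary vessels
  is_cor <- seg$branch != "AORTA"
  small <- is_cor & (pmin(seg$r_prox_mm, seg$r_dist_mm) <
                       .MIN_CORONARY_RADIUS_MM)
  if (any(small))
    warning("coronary segment(s) below the 0.5 mm radius retention rule: ",
            paste(seg$id[small], collapse = ", "))
  invisible(TRUE)
}

#' Coronary outlet nodes of a tree
#'
#' Terminal nodes (out-degree zero) other than the systemic outlet, in
#' segment order.
#'
#' @param tree A `coronary_tree`.
#' @return Character vector of node ids.
#' @export
coronary_outlets <- function(tree) {
  seg <- tree$segments
  terminals <- setdiff(seg$distal, seg$proximal)
  setdiff(terminals, tree$systemic_outlet)
}

# radius (mm) of the terminal segment feeding each outlet node
outlet_radii <- function(tree, outlets = coronary_outlets(tree)) {
  seg <- tree$segments
  vapply(outlets, function(o) seg$r_dist_mm[match(o, seg$distal)],
         numeric(1))
}

#' @export
print.coronary_tree <- function(x, ...) {
  cat(sprintf("Coronary tree: %d segments, %d nodes, %d coronary outlets\n",
              nrow(x$segments), length(x$nodes),
              length(coronary_outlets(x))))
  nst <- sum(vapply(x$segments$stenoses, nrow, integer(1)))
  cat(sprintf("  inlet %s, systemic outlet %s, %d stenosis descriptor(s)\n",
              x$inlet,
              if (is.null(x$systemic_outlet)) "<none>" else x$systemic_outlet,
              nst))
  invisible(x)
}

#' Read a coronary tree from its JSON file
#'
#' The file format is versioned (`"schema": "coro-ffrss-tree/1"`); geometry
#' is in mm.  The returned tree has passed [validate_tree()].
#'
#' @param path File path.
#' @return A `coronary_tree`.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse tree JSON ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(obj$schema) || !identical(obj$schema, .TREE_SCHEMA))
    stop("tree file ", path, ": field 'schema' must be \"", .TREE_SCHEMA,
         "\"")
  for (k in c("nodes", "segments", "inlet"))
    if (is.null(obj[[k]])) stop("tree file ", path, ": missing field '",
                                k, "'")
  # systemic_outlet is optional: coronary-only trees carry none
  nodes <- lapply(obj$nodes, function(v) {
    if (is.null(v)) return(NULL)
    v <- unlist(v)
    if (length(v) != 3L || !is.numeric(v))
      stop("tree file ", path, ": field 'nodes' entries must be null or ",
           "numeric [x, y, z]")
    as.numeric(v)
  })
  seg_list <- obj$segments
  if (!length(seg_list)) stop("tree file ", path,
                              ": field 'segments' is empty")
  parse_seg <- function(s) {
    for (k in c("id", "proximal", "distal", "length_mm", "r_prox_mm",
                "r_dist_mm", "branch"))
      if (is.null(s[[k]]))
        stop("tree file ", path, ": segment missing field '", k, "'")
    st <- s$stenoses
    st_df <- if (is.null(st) || !length(st)) empty_stenoses() else {
      do.call(rbind, lapply(st, function(x) {
        for (k in c("position", "severity", "length_mm"))
          if (is.null(x[[k]]))
            stop("tree file ", path, ": stenosis in segment ", s$id,
                 " missing field '", k, "'")
        data.frame(position = as.numeric(x$position),
                   severity = as.numeric(x$severity),
                   length_mm = as.numeric(x$length_mm))
      }))
    }
    list(id = as.character(s$id), proximal = as.character(s$proximal),
         distal = as.character(s$distal),
         length_mm = as.numeric(s$length_mm),
         r_prox_mm = as.numeric(s$r_prox_mm),
         r_dist_mm = as.numeric(s$r_dist_mm),
         branch = as.character(s$branch), stenoses = st_df)
  }
  parsed <- lapply(seg_list, parse_seg)
  segments <- data.frame(
    id = vapply(parsed, `[[`, character(1), "id"),
    proximal = vapply(parsed, `[[`, character(1), "proximal"),
    distal = vapply(parsed, `[[`, character(1), "distal"),
    length_mm = vapply(parsed, `[[`, numeric(1), "length_mm"),
    r_prox_mm = vapply(parsed, `[[`, numeric(1), "r_prox_mm"),
    r_dist_mm = vapply(parsed, `[[`, numeric(1), "r_dist_mm"),
    branch = vapply(parsed, `[[`, character(1), "branch"),
    stringsAsFactors = FALSE)
  segments$stenoses <- lapply(parsed, `[[`, "stenoses")
  coronary_tree(nodes, segments, inlet = as.character(obj$inlet),
                systemic_outlet = if (is.null(obj$systemic_outlet)) NULL
                                  else as.character(obj$systemic_outlet))
}

#' Write a coronary tree to JSON
#'
#' Round-trip lossless: `read_tree(write_tree(tree, f))` reproduces every
#' field to 15 significant digits (the serialization precision), and a
#' second write is byte-identical.  The tree is validated before anything
#' is written.
#'
#' @param tree A `coronary_tree`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  seg <- tree$segments
  seg_json <- lapply(seq_len(nrow(seg)), function(i) {
    st <- seg$stenoses[[i]]
    out <- list(id = seg$id[i], proximal = seg$proximal[i],
                distal = seg$distal[i], length_mm = seg$length_mm[i],
                r_prox_mm = seg$r_prox_mm[i], r_dist_mm = seg$r_dist_mm[i],
                branch = seg$branch[i])
    out$stenoses <- lapply(seq_len(nrow(st)), function(j)
      list(position = st$position[j], severity = st$severity[j],
           length_mm = st$length_mm[j]))
    out
  })
  obj <- list(schema = .TREE_SCHEMA, nodes = tree$nodes,
              segments = seg_json, inlet = tree$inlet)
  if (!is.null(tree$systemic_outlet))
    obj$systemic_outlet <- tree$systemic_outlet
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
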