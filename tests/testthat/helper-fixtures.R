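# Fixture builders used across the suite.  All geometry is constructed in
# code; nothing is read from disk except files the tests themselves write.

# A single uniform coronary tube off the inlet, plus a very short, very
# wide systemic stub so the closed-form tube flow is unaffected by it.
tube_tree <- function(r_mm = 2, length_mm = 10, severity = NULL,
                      sten_len_mm = 2, sten_pos = 0.5) {
  sten <- if (is.null(severity)) empty_stenoses_df() else
    data.frame(position = sten_pos, severity = severity,
               length_mm = sten_len_mm)
  segments <- data.frame(
    id = c("sys", "tube"), proximal = c("AO_IN", "AO_IN"),
    distal = c("SYS", "OUT"), length_mm = c(2, length_mm),
    r_prox_mm = c(10, r_mm), r_dist_mm = c(10, r_mm),
    branch = c("AORTA", "LAD"), stringsAsFactors = FALSE)
  segments$stenoses <- list(empty_stenoses_df(), sten)
  coronary_tree(nodes = stats::setNames(vector("list", 3),
                                        c("AO_IN", "SYS", "OUT")),
                segments = segments, inlet = "AO_IN",
                systemic_outlet = "SYS")
}

empty_stenoses_df <- function() {
  data.frame(position = numeric(0), severity = numeric(0),
             length_mm = numeric(0))
}

# Two coronary outlets of chosen terminal radii behind a common stem.
two_outlet_tree <- function(r1 = 2, r2 = 1) {
  segments <- data.frame(
    id = c("sys", "stem", "d1", "d2"),
    proximal = c("AO_IN", "AO_IN", "J", "J"),
    distal = c("SYS", "J", "O1", "O2"),
    length_mm = c(2, 5, 10, 10),
    r_prox_mm = c(10, 4, r1, r2), r_dist_mm = c(10, 4, r1, r2),
    branch = c("AORTA", "LAD", "LAD", "LCX"), stringsAsFactors = FALSE)
  segments$stenoses <- replicate(4, empty_stenoses_df(), simplify = FALSE)
  coronary_tree(nodes = stats::setNames(vector("list", 5),
                                        c("AO_IN", "SYS", "J", "O1", "O2")),
                segments = segments, inlet = "AO_IN",
                systemic_outlet = "SYS")
}

# Hand-assembled lumped-parameter model with chosen resistances
# (mmHg s/mL); bypasses build_lpm so solver tests control R directly.
make_lpm <- function(outlet_nodes, r_resting, r_doa = 1,
                     state = "hyperemia", venous_pressure = 0,
                     inlet_pressure = 100) {
  structure(list(
    outlets = data.frame(outlet_node = outlet_nodes,
                         r_resting = r_resting,
                         r_hyperemia = 0.24 * r_resting,
                         inductance = 0.05,
                         venous_pressure = venous_pressure,
                         stringsAsFactors = FALSE),
    r_doa = r_doa, state = state, inlet_pressure = inlet_pressure,
    config = bc_config()), class = "lpm")
}

# viscous resistance of a uniform tube in mmHg s/mL
tube_R_mmhg <- function(r_mm, length_mm, blood = blood_properties()) {
  coroffr:::Rsi_to_mmhg(segment_viscous_resistance(
    list(length_mm = length_mm, r_prox_mm = r_mm, r_dist_mm = r_mm), blood))
}

# split segment `seg_id` into k equal sub-segments (linear radius interp)
subdivide_segment <- function(tree, seg_id, k) {
  seg <- tree$segments
  i <- match(seg_id, seg$id)
  s <- seg[i, ]
  stopifnot(nrow(s$stenoses[[1]]) == 0)  # refinement test: plain segments
  bounds <- seq(0, 1, length.out = k + 1)
  radii <- s$r_prox_mm + (s$r_dist_mm - s$r_prox_mm) * bounds
  mids <- paste0(s$distal, "_sub", seq_len(k - 1))
  nds <- c(s$proximal, mids, s$distal)
  sub <- data.frame(
    id = paste0(s$id, "_part", seq_len(k)),
    proximal = nds[seq_len(k)], distal = nds[-1],
    length_mm = rep(s$length_mm / k, k),
    r_prox_mm = radii[seq_len(k)], r_dist_mm = radii[-1],
    branch = rep(s$branch, k), stringsAsFactors = FALSE)
  sub$stenoses <- replicate(k, empty_stenoses_df(), simplify = FALSE)
  segments <- rbind(seg[-i, ], sub)
  nodes <- tree$nodes
  for (nd in mids) nodes[nd] <- list(NULL)
  coronary_tree(nodes, segments, tree$inlet, tree$systemic_outlet)
}

# random paired FFR table with correlated computed values
random_paired_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  ref <- pmin(pmax(stats::rnorm(n, 0.82, 0.10), 0.3), 1.0)
  comp <- pmin(pmax(ref + stats::rnorm(n, 0.01, 0.05), 0.3), 1.0)
  paired_ffr_table(sprintf("v%02d", seq_len(n)), ref, comp)
}

# relative difference helper
rel_diff <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-300))
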