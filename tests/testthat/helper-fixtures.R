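# fixtures built in code: tiny networks, waveforms and cohorts

const_wave <- function(value, n = 32, period = 1, units = "mL/min") {
  sampled_waveform(rep(value, n), period, units)
}

# single straight tube: one inlet, one outlet
tube_network <- function(length_mm = 100, diameter_mm = 4) {
  vascular_network(
    data.frame(id = "T1", from = "A", to = "B", length_mm = length_mm,
               diameter_mm = diameter_mm, name = "tube"),
    inlets = c(A = "LICA"), outlets = c(B = "left_middle"))
}

# symmetric Y: parent splits into two equal daughters in different regions
y_network <- function(d_parent = 4, d_daughter = 3) {
  vascular_network(
    data.frame(id = c("P", "D1", "D2"),
               from = c("A", "B", "B"), to = c("B", "C1", "C2"),
               length_mm = c(50, 30, 30),
               diameter_mm = c(d_parent, d_daughter, d_daughter),
               name = c("parent", "d1", "d2")),
    inlets = c(A = "LICA"),
    outlets = c(C1 = "left_middle", C2 = "right_middle"))
}

# random tree (optionally with extra loop edges) rooted at one inlet
random_network <- function(seed, n_nodes = 7, loops = 0) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(n_nodes))
  seg <- data.frame(
    id = paste0("S", 2:n_nodes),
    # the root keeps exactly one child so the inlet node has one segment
    from = nodes[vapply(2:n_nodes, function(k)
      if (k == 2) 1L else sample(2:(k - 1), 1), integer(1))],
    to = nodes[2:n_nodes],
    length_mm = stats::runif(n_nodes - 1, 5, 50),
    diameter_mm = stats::runif(n_nodes - 1, 1.5, 5),
    name = paste0("S", 2:n_nodes), stringsAsFactors = FALSE)
  # loop edges only between interior (non-leaf, non-root) candidate pairs so
  # boundary nodes keep exactly one attached segment
  interior <- intersect(unique(seg$from), nodes[-1])
  if (loops > 0 && length(interior) >= 2) {
    for (k in seq_len(loops)) {
      pair <- sample(interior, 2)
      seg <- rbind(seg, data.frame(
        id = paste0("L", k), from = pair[1], to = pair[2],
        length_mm = stats::runif(1, 5, 50),
        diameter_mm = stats::runif(1, 1.5, 5), name = paste0("L", k)))
    }
  }
  leaves <- setdiff(nodes, c(seg$from, nodes[1]))
  if (length(leaves) == 0) return(NULL)
  regions <- rep(c("left_middle", "right_middle", "anterior",
                   "left_posterior", "right_posterior", "cerebellum",
                   "ophthalmic"), length.out = length(leaves))
  outlets <- structure(regions, names = leaves)
  vascular_network(seg, inlets = c(N1 = "LICA"), outlets = outlets)
}

# region table covering exactly the regions present in a network
table_for_network <- function(net, seed = 1) {
  regs <- unique(unname(net$outlets))
  set.seed(seed)
  f <- stats::runif(length(regs), 0.5, 1.5)
  f <- f / sum(f)
  f[length(f)] <- 1 - sum(f[-length(f)])   # exact unit sum
  region_table(structure(f, names = regs))
}

# pulsatile inflow, strictly positive
pulsatile_wave <- function(mean_flow = 300, n = 32, period = 0.9) {
  ph <- seq(0, 1, length.out = n + 1)[-(n + 1)]
  sampled_waveform(mean_flow * (1 + 0.5 * sin(2 * pi * ph)), period, "mL/min")
}

# hand-built cohort from metric values: f(participant, condition, source)
# must return c(systolic, time_averaged, end_diastolic); tcbf_f(p, cond)
make_metric_cohort <- function(n, value_f, tcbf_f,
                               conds = c("rest", "hypercapnia", "exercise")) {
  lapply(seq_len(n), function(i) {
    conditions <- lapply(conds, function(cd) {
      mk <- function(src) {
        v <- value_f(i, cd, src)
        structure(c(systolic = v[1], time_averaged = v[2],
                    end_diastolic = v[3]), class = "velocity_metrics")
      }
      list(cfd = mk("cfd"), tcd = mk("tcd"), tcbf = tcbf_f(i, cd))
    })
    names(conditions) <- conds
    list(id = paste0("P", i), conditions = conditions)
  })
}

# nodal conservation residual of a solution, recomputed from the solution's
# segment flows and the prescribed boundary flows (independent of the
# solver's internal bookkeeping)
nodal_residual <- function(sol, net, inlet_flows, splits) {
  np <- length(sol$phase)
  inj <- matrix(0, length(sol$node_names), np,
                dimnames = list(sol$node_names, NULL))
  for (node in names(net$inlets)) {
    w <- resample_waveform(inlet_flows[[net$inlets[[node]]]], np)
    inj[node, ] <- inj[node, ] + w$values
  }
  for (node in names(splits$flows)) {
    w <- resample_waveform(splits$flows[[node]], np)
    inj[node, ] <- inj[node, ] - w$values
  }
  bal <- inj
  for (s in seq_len(nrow(sol$segments))) {
    bal[sol$segments$from[s], ] <- bal[sol$segments$from[s], ] - sol$flow[s, ]
    bal[sol$segments$to[s], ] <- bal[sol$segments$to[s], ] + sol$flow[s, ]
  }
  max(abs(bal)) / max(abs(inj))
}
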