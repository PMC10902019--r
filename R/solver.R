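#' Network solver configuration
#'
#' @param density fluid density, kg/m^3 (default 1050).
#' @param n_phase phase samples per cardiac cycle the boundary waveforms are
#'   resampled to before solving (default 200, minimum 16).
#' @param fp_tolerance relative tolerance on the viscosity fixed-point update
#'   (default 1e-10).
#' @param max_iterations fixed-point iteration cap per phase point.
#' @param reference_node node whose pressure is pinned to 0 Pa (default: the
#'   network's first node; segment flows do not depend on this choice).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(density = 1050, n_phase = 200L, fp_tolerance = 1e-10,
                          max_iterations = 200L, reference_node = NULL) {
  if (density <= 0) stop("density must be positive")
  n_phase <- as.integer(n_phase)
  if (n_phase < 16L) stop("n_phase must be at least 16")
  if (fp_tolerance <= 0) stop("fp_tolerance must be positive")
  structure(list(density = density, n_phase = n_phase,
                 fp_tolerance = fp_tolerance,
                 max_iterations = as.integer(max_iterations),
                 reference_node = reference_node),
            class = "solver_config")
}

#' Solve pulsatile network flow as a quasi-steady nonlinear Poiseuille circuit
#'
#' Reduced-order surrogate for a 3D finite-volume solver: at each phase point
#' an independent steady linear nodal-pressure system is solved with segment
#' conductances \eqn{G = \pi D^4 / (128 \mu_{eff} L)} and prescribed boundary
#' flow injections (inlets positive, outlets negative). The effective
#' viscosity of each segment is the Carreau-Yasuda viscosity at the
#' characteristic Poiseuille wall shear rate \eqn{\dot\gamma = 8 |\bar v| / D}
#' and is updated by Aitken-accelerated fixed-point iteration (with damping
#' of oscillating updates) until the largest relative viscosity change falls
#' below `fp_tolerance`. Walls are rigid with no-slip;
#' the flow regime is laminar; fluid inertia between phase points is
#' neglected (no Womersley effects), so the solution is phase-local.
#'
#' @param net a [vascular_network()].
#' @param inlet_flows named list (by artery label) of inflow waveforms, mL/min.
#' @param splits an `outlet_split` from [build_outlet_splits()]; boundary
#'   flows must conserve mass globally at every phase point.
#' @param rheology a [rheology_params()].
#' @param cfg a [solver_config()].
#' @return an object of class `network_solution`: per-segment matrices
#'   (segments x phase) `flow` (mL/min, signed from `from` to `to`), `v_mean`
#'   and `v_max` (cm/s), `wss` (Pa), `mu` (Pa s); per-node matrix `pressure`
#'   (Pa, relative to the reference node); plus `phase`, `period`, `segments`,
#'   `node_names`, `max_residual` and `iterations`.
#' @export
solve_network <- function(net, inlet_flows, splits,
                          rheology = rheology_params(),
                          cfg = solver_config()) {
  if (!inherits(net, "vascular_network")) stop("net must be a vascular_network")
  if (!inherits(splits, "outlet_split")) stop("splits must be an outlet_split")
  np <- cfg$n_phase
  nodes <- net$nodes
  nn <- length(nodes)
  seg <- net$segments
  m <- nrow(seg)
  from <- match(seg$from, nodes)
  to <- match(seg$to, nodes)
  D <- seg$diameter_mm * 1e-3
  L <- seg$length_mm * 1e-3
  A <- pi * D^2 / 4
  geom <- pi * D^4 / (128 * L)          # conductance = geom / mu

  # oriented incidence matrix (segments x nodes)
  B <- matrix(0, m, nn)
  B[cbind(seq_len(m), from)] <- 1
  B[cbind(seq_len(m), to)] <- -1

  # boundary injections (m^3/s), nodes x phase
  inj <- matrix(0, nn, np)
  period <- NULL
  for (node in names(net$inlets)) {
    w <- inlet_flows[[net$inlets[[node]]]]
    if (is.null(w)) stop("no inlet flow for artery ", net$inlets[[node]])
    stopifnot_waveform(w, units = "mL/min", what = "inlet flow")
    w <- resample_waveform(w, np)
    period <- w$period
    inj[match(node, nodes), ] <- inj[match(node, nodes), ] + w$values * 1e-6 / 60
  }
  for (node in names(splits$flows)) {
    w <- resample_waveform(splits$flows[[node]], np)
    inj[match(node, nodes), ] <- inj[match(node, nodes), ] - w$values * 1e-6 / 60
  }
  scale_in <- max(colSums(abs(inj)))
  imbalance <- max(abs(colSums(inj))) / max(scale_in, .Machine$double.eps)
  if (imbalance > 1e-9)
    stop("boundary flows do not conserve mass (relative imbalance ",
         format(imbalance, digits = 3), ")")

  ref <- if (is.null(cfg$reference_node)) 1L else match(cfg$reference_node, nodes)
  if (is.na(ref)) stop("reference_node not found in network")
  keep <- setdiff(seq_len(nn), ref)
  clamp <- function(x) { x[x < eta_inf] <- eta_inf; x[x > eta_0] <- eta_0; x }
  eta_0 <- rheology$eta_0

  newtonian <- rheology$eta_0 == rheology$eta_inf
  eta_inf <- rheology$eta_inf
  d_eta <- rheology$eta_0 - eta_inf
  lam_cy <- rheology$lambda; a_cy <- rheology$a; pow_cy <- (rheology$n - 1) / rheology$a
  cy <- function(gdot) eta_inf + d_eta * (1 + (lam_cy * gdot)^a_cy)^pow_cy

  flow <- v_mean <- wss <- mu_out <- matrix(NA_real_, m, np)
  pressure <- matrix(NA_real_, nn, np)
  iters <- integer(np)
  max_resid <- 0
  mu <- rep(rheology$eta_0, m)          # warm-started across phase points

  for (p in seq_len(np)) {
    b <- inj[, p]
    # one linear circuit solve at the current viscosity estimate; returns the
    # pressures, segment flows and the raw fixed-point viscosity update
    solve_at <- function(mu) {
      G <- geom / mu
      Lap <- crossprod(B, B * G)        # t(B) %*% diag(G) %*% B
      pr <- numeric(nn)
      pr[keep] <- solve(Lap[keep, keep, drop = FALSE], b[keep])
      Q <- G * drop(B %*% pr)           # m^3/s, from -> to
      delta <- if (newtonian) numeric(m) else cy(8 * abs(Q / A) / D) - mu
      list(pr = pr, Q = Q, delta = delta)
    }
    it <- 0L
    repeat {
      # Steffensen acceleration: two raw fixed-point evaluations followed by
      # a per-segment Aitken jump, clamped to the physical viscosity range.
      # The raw iteration alternates around the solution, so the jump
      # converges in a handful of circuit solves.
      s1 <- solve_at(mu); it <- it + 1L
      if (max(abs(s1$delta) / mu) < cfg$fp_tolerance) break
      mu1 <- clamp(mu + s1$delta)
      s2 <- solve_at(mu1); it <- it + 1L
      if (max(abs(s2$delta) / mu1) < cfg$fp_tolerance) { mu <- mu1; s1 <- s2; break }
      den <- s2$delta - s1$delta
      # the Aitken jump is unreliable where the two updates nearly coincide
      # (denominator ~ 0) or once it has failed to settle (segments with
      # near-zero flow, where the shear-thinning map is non-Lipschitz);
      # fall back to a damped plain update there
      ok <- abs(den) > 1e-3 * abs(s1$delta) & it < 40L
      mu_j <- mu - s1$delta^2 / den
      mu_j[!ok] <- mu1[!ok] + 0.5 * s2$delta[!ok]
      mu <- clamp(mu_j)
      if (it >= cfg$max_iterations)
        stop("viscosity fixed point did not converge within ",
             cfg$max_iterations, " iterations at phase index ", p)
    }
    pr <- s1$pr; Q <- s1$Q
    iters[p] <- it
    resid <- max(abs(drop(crossprod(B, Q)) - b)) /
      max(max(abs(b)), .Machine$double.eps)
    max_resid <- max(max_resid, resid)
    flow[, p] <- Q / 1e-6 * 60
    v_mean[, p] <- Q / A * 100
    wss[, p] <- 32 * mu * Q / (pi * D^3)
    mu_out[, p] <- mu
    pressure[, p] <- pr
  }

  if (is.null(period)) period <- splits$total_inflow$period
  structure(list(segments = seg,
                 node_names = nodes,
                 phase = seq(0, 1, length.out = np + 1L)[-(np + 1L)],
                 period = period,
                 flow = flow, v_mean = v_mean, v_max = 2 * v_mean,
                 wss = wss, mu = mu_out, pressure = pressure,
                 max_residual = max_resid, iterations = iters,
                 rheology = rheology, config = cfg),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf("<network_solution> %d segments, %d nodes, %d phase points, period %.3f s\n",
              nrow(x$segments), length(x$node_names), length(x$phase), x$period))
  cat(sprintf("  max nodal conservation residual %.2e; fixed-point iterations %d-%d\n",
              x$max_residual, min(x$iterations), max(x$iterations)))
  invisible(x)
}

#' @export
summary.network_solution <- function(object, ...) {
  seg <- object$segments
  out <- data.frame(
    id = seg$id, name = seg$name, diameter_mm = seg$diameter_mm,
    mean_flow_ml_min = rowMeans(object$flow),
    peak_v_max_cm_s = apply(object$v_max, 1, max),
    mean_wss_pa = rowMeans(object$wss),
    mean_mu_pa_s = rowMeans(object$mu))
  class(out) <- c("summary.network_solution", "data.frame")
  out
}

#' Extract one segment's waveform from a solution
#'
#' @param sol a `network_solution`.
#' @param segment_id segment id.
#' @param quantity one of `"flow"`, `"v_mean"`, `"v_max"`, `"wss"`, `"mu"`.
#' @return a [sampled_waveform()].
#' @export
segment_waveform <- function(sol, segment_id,
                             quantity = c("flow", "v_mean", "v_max", "wss", "mu")) {
  quantity <- match.arg(quantity)
  i <- match(segment_id, sol$segments$id)
  if (is.na(i)) stop("unknown segment id: ", segment_id)
  units <- c(flow = "mL/min", v_mean = "cm/s", v_max = "cm/s",
             wss = "Pa", mu = "Pa.s")[[quantity]]
  sampled_waveform(sol[[quantity]][i, ], sol$period, units)
}

#' Export a network solution to CSV files
#'
#' One CSV per segment (`phase,flow_ml_min,v_mean_cm_s,v_max_cm_s,wss_pa,
#' mu_pa_s`) plus `pressures.csv` in long form (`phase,node,p_pa`).
#'
#' @param sol a `network_solution`.
#' @param dir output directory (created if needed).
#' @export
export_solution_csv <- function(sol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(sol$segments))) {
    utils::write.csv(
      data.frame(phase = sol$phase, flow_ml_min = sol$flow[i, ],
                 v_mean_cm_s = sol$v_mean[i, ], v_max_cm_s = sol$v_max[i, ],
                 wss_pa = sol$wss[i, ], mu_pa_s = sol$mu[i, ]),
      file.path(dir, paste0("segment_", sol$segments$id[i], ".csv")),
      row.names = FALSE)
  }
  long <- data.frame(
    phase = rep(sol$phase, each = length(sol$node_names)),
    node = rep(sol$node_names, times = length(sol$phase)),
    p_pa = as.vector(sol$pressure))
  utils::write.csv(long, file.path(dir, "pressures.csv"), row.names = FALSE)
  invisible(dir)
}
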