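#' Run the flow-conserving simulation for one participant-condition
#'
#' End-to-end pipeline from duplex recordings to TCD-comparable metrics:
#' ensemble-average each artery's envelope cycles, convert to volumetric flow
#' under the Poiseuille assumption, sum to tCBF, distribute the inflow over
#' the network outlets (regional table then Murray split), solve the
#' quasi-steady nonlinear Poiseuille circuit, and extract the station-averaged
#' maximal-velocity envelope and its metrics in the right M1 segment.
#'
#' @param recordings named list (by artery label) of [duplex_recording()]s
#'   covering every network inlet.
#' @param net a [vascular_network()].
#' @param table a [region_table()].
#' @param rheology a [rheology_params()].
#' @param split_cfg a [split_config()].
#' @param solver_cfg a [solver_config()].
#' @param n_points phase samples for the ensemble grid (defaults to the
#'   solver's `n_phase`).
#' @param alignment_phase systolic-peak alignment phase (default 0.25).
#' @param envelope_factor envelope-to-mean velocity factor (default 0.5).
#' @param m1_segment_ids M1 segment ids for metric extraction
#'   (default `"R_MCA_M1"`, the conventional right-M1 insonation target).
#' @param station_fractions M1 station positions (default 0.25/0.50/0.75).
#' @return list with `ensembles`, `flows` (per artery), `tcbf`, `splits`,
#'   `solution`, `m1_envelope` and `metrics`.
#' @export
simulate_condition <- function(recordings, net, table = default_region_table(),
                               rheology = rheology_params(),
                               split_cfg = split_config(),
                               solver_cfg = solver_config(),
                               n_points = solver_cfg$n_phase,
                               alignment_phase = 0.25,
                               envelope_factor = 0.5,
                               m1_segment_ids = "R_MCA_M1",
                               station_fractions = c(0.25, 0.50, 0.75)) {
  need <- unname(net$inlets)
  missing_r <- setdiff(need, names(recordings))
  if (length(missing_r) > 0)
    stop("missing recordings for arteries: ", paste(missing_r, collapse = ", "))

  ensembles <- lapply(recordings[need], function(rec)
    ensemble_average(rec$cycles, n_points = n_points,
                     alignment_phase = alignment_phase))
  flows <- mapply(function(ens, rec)
    poiseuille_flow(ens, rec$diameter_mm, envelope_factor),
    ensembles, recordings[need], SIMPLIFY = FALSE)

  splits <- build_outlet_splits(net, flows, table, split_cfg)
  sol <- solve_network(net, flows, splits, rheology, solver_cfg)
  env <- m1_envelope(sol, m1_segment_ids, station_fractions)

  list(ensembles = ensembles, flows = flows, tcbf = total_cbf(flows),
       splits = splits, solution = sol, m1_envelope = env,
       metrics = extract_metrics(env))
}
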