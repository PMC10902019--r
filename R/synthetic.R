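#' Deterministic sub-stream seed derivation
#'
#' Hashes the master seed together with an arbitrary path of labels into a
#' 31-bit integer seed, giving every participant/artery/condition its own
#' reproducible random sub-stream: changing one sub-stream's draws cannot
#' perturb any other.
#'
#' @param master master integer seed.
#' @param ... labels (coerced to character) identifying the sub-stream.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  s <- paste(c(master, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Synthetic-cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: per-artery
#' time-averaged inflows (mean +/- SD, mL/min) and heart rates under rest,
#' hypercapnia and submaximal exercise taken from the measured cohort table;
#' a triphasic-like carotid envelope shape (truncated Fourier series);
#' and a multiplicative TCD-vs-CFD envelope bias that is constant within a
#' participant across conditions, larger in diastole than in systole
#' (defaults 1.5 systolic / 1.9 end-diastolic, within the reported ranges of
#' 33-73% and 85-106% excess; these are calibration defaults, not ground
#' truth). Between-participant bias spread and measurement noise are
#' log-normal.
#'
#' @param n_participants cohort size (default 12, minimum 3).
#' @param flow_mean,flow_sd artery x condition matrices of time-averaged flow
#'   (mL/min); rows LICA/RICA/LVA/RVA, columns rest/hypercapnia/exercise.
#' @param hr_mean,hr_sd per-condition heart rate (bpm).
#' @param typical_velocity per-artery typical time-averaged envelope velocity
#'   (cm/s), used once per participant to size the vessel diameter.
#' @param pulsatility (peak - min)/mean of the envelope shape (default 1.2).
#' @param n_harmonics Fourier harmonics in the envelope shape (default 4).
#' @param n_cycles cardiac cycles per duplex recording (default 3).
#' @param samples_per_cycle envelope samples per recorded cycle (default 80).
#' @param cycle_noise_cv multiplicative cycle-to-cycle sample noise CV.
#' @param bias_mean named per-metric mean TCD/CFD bias factors (`systolic`,
#'   `time_averaged`, `end_diastolic`); the envelope bias interpolates
#'   between the systolic and end-diastolic factors (the time-averaged bias
#'   is emergent).
#' @param bias_cv between-participant CV of the bias factors (log-normal).
#' @param noise_cv multiplicative TCD measurement-noise CV per sample.
#' @param response_correlation between-condition correlation of a
#'   participant's flow deviates (default 0.5).
#' @param jitter_cv log-normal CV of network diameter jitter (default 0.05).
#' @param n_phase phase samples used for ensembles and the network solver.
#' @param seed master seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 12L,
                          flow_mean = NULL, flow_sd = NULL,
                          hr_mean = NULL, hr_sd = NULL,
                          typical_velocity = NULL,
                          pulsatility = 1.2, n_harmonics = 4L,
                          n_cycles = 3L, samples_per_cycle = 80L,
                          cycle_noise_cv = 0.02,
                          bias_mean = c(systolic = 1.5, time_averaged = 1.7,
                                        end_diastolic = 1.9),
                          bias_cv = 0.10, noise_cv = 0.05,
                          response_correlation = 0.5, jitter_cv = 0.05,
                          n_phase = 200L, seed = 1L) {
  arteries <- c("LICA", "RICA", "LVA", "RVA")
  conds <- c("rest", "hypercapnia", "exercise")
  if (is.null(flow_mean))
    flow_mean <- matrix(c(268.9, 374.6, 272.8,
                          218.8, 308.6, 262.9,
                          74.2, 119.4, 79.7,
                          56.2, 97.0, 68.4),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(arteries, conds))
  if (is.null(flow_sd))
    flow_sd <- matrix(c(63.3, 79.3, 67.2,
                        74.2, 79.3, 50.3,
                        26.4, 30.9, 27.1,
                        18.3, 32.3, 34.0),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(arteries, conds))
  if (is.null(hr_mean)) hr_mean <- c(rest = 68.7, hypercapnia = 74.1, exercise = 120.4)
  if (is.null(hr_sd)) hr_sd <- c(rest = 9.5, hypercapnia = 8.1, exercise = 21.3)
  if (is.null(typical_velocity))
    typical_velocity <- c(LICA = 40, RICA = 40, LVA = 30, RVA = 30)
  if (n_participants < 3L) stop("n_participants must be at least 3")
  if (any(flow_mean <= 0)) stop("flow means must be positive")
  if (any(flow_sd < 0) || bias_cv < 0 || noise_cv < 0 || cycle_noise_cv < 0 ||
      jitter_cv < 0) stop("all SDs/CVs must be non-negative")
  if (any(bias_mean <= 0)) stop("bias means must be positive")
  if (abs(response_correlation) > 1) stop("response_correlation must be in [-1, 1]")
  structure(list(n_participants = as.integer(n_participants),
                 arteries = arteries, conditions = colnames(flow_mean),
                 flow_mean = flow_mean, flow_sd = flow_sd,
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 typical_velocity = typical_velocity,
                 pulsatility = pulsatility, n_harmonics = as.integer(n_harmonics),
                 n_cycles = as.integer(n_cycles),
                 samples_per_cycle = as.integer(samples_per_cycle),
                 cycle_noise_cv = cycle_noise_cv,
                 bias_mean = bias_mean, bias_cv = bias_cv, noise_cv = noise_cv,
                 response_correlation = response_correlation,
                 jitter_cv = jitter_cv, n_phase = as.integer(n_phase),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Canonical arterial envelope shape: a systolic Gaussian pulse plus a
# dicrotic bump, wrapped periodically, truncated to `n_harmonics` Fourier
# harmonics, then scaled to unit mean and the requested pulsatility
# (max - min)/mean. Peak sits near phase 0.22.
envelope_shape <- function(phase, pulsatility = 1.2, n_harmonics = 4L) {
  nf <- 256L
  fine <- seq(0, 1, length.out = nf + 1L)[-(nf + 1L)]
  pulse <- function(x) exp(-0.5 * ((x - 0.22) / 0.095)^2) +
    0.35 * exp(-0.5 * ((x - 0.45) / 0.12)^2)
  g <- pulse(fine) + pulse(fine - 1) + pulse(fine + 1)
  co <- stats::fft(g) / nf
  eval_series <- function(x) {
    s <- rep(Re(co[1]), length(x))
    for (k in seq_len(n_harmonics))
      s <- s + 2 * (Re(co[k + 1]) * cos(2 * pi * k * x) -
                    Im(co[k + 1]) * sin(2 * pi * k * x))
    s
  }
  base_fine <- eval_series(fine)
  mu <- mean(base_fine)
  beta <- pulsatility * mu / (max(base_fine) - min(base_fine))
  s <- 1 + beta * (eval_series(phase) / mu - 1)
  if (any(s <= 0)) stop("pulsatility too large: envelope shape not positive")
  s
}

#' Synthetic complete Circle-of-Willis network
#'
#' Builds the template complete-CoW topology (paired ICAs feeding MCA, ACA
#' and ophthalmic branches; VAs merging into the basilar artery feeding
#' cerebellar branches and the PCAs; anterior and posterior communicating
#' arteries closing the circle; at least one region-labelled outlet per
#' cerebral territory) and applies log-normal diameter jitter around the
#' template values, deterministically per seed.
#'
#' @param seed integer seed.
#' @param jitter_cv coefficient of variation of the diameter jitter
#'   (0 returns the template exactly).
#' @return a [vascular_network()]; the right M1 segment has id `"R_MCA_M1"`.
#' @export
synth_network <- function(seed = 1L, jitter_cv = 0.05) {
  if (jitter_cv < 0) stop("jitter_cv must be >= 0")
  seg <- cow_template_segments()
  if (jitter_cv > 0) {
    set.seed(seed)
    seg$diameter_mm <- seg$diameter_mm * rlnorm_cv(nrow(seg), jitter_cv)
  }
  vascular_network(
    seg,
    inlets = c(LICA_in = "LICA", RICA_in = "RICA", LVA_in = "LVA", RVA_in = "RVA"),
    outlets = c(L_SCA_out = "cerebellum", R_SCA_out = "cerebellum",
                L_PCA_out = "left_posterior", R_PCA_out = "right_posterior",
                L_OA_out = "ophthalmic", R_OA_out = "ophthalmic",
                L_M2s_out = "left_middle", L_M2i_out = "left_middle",
                R_M2s_out = "right_middle", R_M2i_out = "right_middle",
                L_ACA_out = "anterior", R_ACA_out = "anterior"))
}

cow_template_segments <- function() {
  s <- function(id, from, to, L, D) data.frame(
    id = id, from = from, to = to, length_mm = L, diameter_mm = D, name = id,
    stringsAsFactors = FALSE)
  rbind(
    s("L_ICA", "LICA_in", "L_ICA_term", 25, 4.5),
    s("R_ICA", "RICA_in", "R_ICA_term", 25, 4.5),
    s("L_VA", "LVA_in", "BA_jct", 20, 3.4),
    s("R_VA", "RVA_in", "BA_jct", 20, 3.4),
    s("BA", "BA_jct", "BA_top", 25, 3.2),
    s("L_SCA", "BA_top", "L_SCA_out", 15, 1.5),
    s("R_SCA", "BA_top", "R_SCA_out", 15, 1.5),
    s("L_PCA_P1", "BA_top", "L_PCA_jct", 8, 2.1),
    s("R_PCA_P1", "BA_top", "R_PCA_jct", 8, 2.1),
    s("L_PCoA", "L_ICA_term", "L_PCA_jct", 15, 1.4),
    s("R_PCoA", "R_ICA_term", "R_PCA_jct", 15, 1.4),
    s("L_PCA_P2", "L_PCA_jct", "L_PCA_out", 30, 2.0),
    s("R_PCA_P2", "R_PCA_jct", "R_PCA_out", 30, 2.0),
    s("L_OA", "L_ICA_term", "L_OA_out", 20, 1.3),
    s("R_OA", "R_ICA_term", "R_OA_out", 20, 1.3),
    s("L_MCA_M1", "L_ICA_term", "L_MCA_bif", 20, 2.9),
    s("R_MCA_M1", "R_ICA_term", "R_MCA_bif", 20, 2.9),
    s("L_MCA_M2s", "L_MCA_bif", "L_M2s_out", 25, 2.2),
    s("L_MCA_M2i", "L_MCA_bif", "L_M2i_out", 25, 2.2),
    s("R_MCA_M2s", "R_MCA_bif", "R_M2s_out", 25, 2.2),
    s("R_MCA_M2i", "R_MCA_bif", "R_M2i_out", 25, 2.2),
    s("L_ACA_A1", "L_ICA_term", "ACoA_L", 13, 2.3),
    s("R_ACA_A1", "R_ICA_term", "ACoA_R", 13, 2.3),
    s("ACoA", "ACoA_L", "ACoA_R", 3, 1.5),
    s("L_ACA_A2", "ACoA_L", "L_ACA_out", 25, 2.0),
    s("R_ACA_A2", "ACoA_R", "R_ACA_out", 25, 2.0))
}

#' Synthetic duplex recording at one inflow artery
#'
#' Draws a participant time-averaged flow from the configured truncated
#' normal (unless supplied), builds a periodic envelope from the canonical
#' harmonic shape at the configured pulsatility, adds small multiplicative
#' cycle-to-cycle noise over `n_cycles` cycles, and sizes the lumen diameter
#' so that [poiseuille_flow()] applied to the envelope recovers the drawn
#' flow.
#'
#' @param artery artery label (`LICA`, `RICA`, `LVA`, `RVA`).
#' @param condition condition name present in the config flow table.
#' @param cfg a [cohort_config()].
#' @param seed integer seed for this recording's sub-stream.
#' @param mean_flow optional pre-drawn time-averaged flow (mL/min).
#' @param diameter_mm optional fixed lumen diameter (mm); when supplied the
#'   envelope is scaled so the flow target is still met.
#' @param period optional cardiac period (s); drawn from the condition's
#'   heart-rate distribution if missing.
#' @return a [duplex_recording()].
#' @export
synth_inlet_recording <- function(artery, condition, cfg = cohort_config(),
                                  seed = 1L, mean_flow = NULL,
                                  diameter_mm = NULL, period = NULL) {
  set.seed(seed)
  if (is.null(mean_flow)) {
    repeat {
      mean_flow <- stats::rnorm(1, cfg$flow_mean[artery, condition],
                                cfg$flow_sd[artery, condition])
      if (mean_flow > 0) break
    }
  }
  if (is.null(period)) {
    repeat {
      hr <- stats::rnorm(1, cfg$hr_mean[[condition]], cfg$hr_sd[[condition]])
      if (hr > 30) break
    }
    period <- 60 / hr
  }
  if (is.null(diameter_mm)) {
    v_ta <- cfg$typical_velocity[[artery]]
    diameter_mm <- 20 * sqrt(mean_flow / (30 * pi * v_ta))
  } else {
    v_ta <- mean_flow / (30 * pi * (diameter_mm / 20)^2)
  }
  n <- cfg$samples_per_cycle
  phase <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
  shape <- envelope_shape(phase, cfg$pulsatility, cfg$n_harmonics)
  cycles <- lapply(seq_len(cfg$n_cycles), function(k) {
    v <- v_ta * shape * rlnorm_cv(n, cfg$cycle_noise_cv)
    p <- period * (1 + stats::rnorm(1, 0, 0.01))
    sampled_waveform(v, p, "cm/s")
  })
  duplex_recording(artery, cycles, diameter_mm)
}

#' Apply a TCD-style multiplicative bias to a simulated envelope
#'
#' Emulates the systematic excess of TCD envelope velocities over simulated
#' maximal velocities: the per-participant bias factor is interpolated
#' smoothly across the cycle between the systolic-phase factor (applied where
#' the envelope is at its maximum) and the diastolic-phase factor (applied at
#' its minimum), then multiplicative log-normal measurement noise is added.
#' With a uniform bias factor and zero noise the output metrics are exactly
#' the input metrics scaled by that factor.
#'
#' @param sim_envelope simulated maximal-velocity waveform (cm/s).
#' @param bias_factors named vector with elements `systolic` and
#'   `end_diastolic` (a single unnamed number is used uniformly).
#' @param noise_cv multiplicative noise CV per sample (0 for none).
#' @param seed integer seed.
#' @return a [sampled_waveform()] on the same phase grid.
#' @export
synth_tcd_envelope <- function(sim_envelope, bias_factors, noise_cv = 0,
                               seed = 1L) {
  stopifnot_waveform(sim_envelope, units = "cm/s", what = "sim_envelope")
  if (is.null(names(bias_factors))) {
    if (length(bias_factors) != 1L)
      stop("unnamed bias_factors must be a single uniform factor")
    b_sys <- b_ed <- bias_factors
  } else {
    b_sys <- bias_factors[["systolic"]]
    b_ed <- bias_factors[["end_diastolic"]]
  }
  if (any(c(b_sys, b_ed) <= 0)) stop("bias factors must be positive")
  v <- sim_envelope$values
  rng <- max(v) - min(v)
  w <- if (rng > 0) (v - min(v)) / rng else rep(1, length(v))
  bias <- b_ed + (b_sys - b_ed) * w
  set.seed(seed)
  noise <- rlnorm_cv(length(v), noise_cv)
  sampled_waveform(v * bias * noise, sim_envelope$period, "cm/s")
}

#' Generate a reproducible synthetic cohort and run the pipeline on it
#'
#' For each participant: a jittered complete-CoW network, per-participant
#' TCD bias factors held constant across conditions, correlated per-artery
#' flow draws across conditions, duplex recordings for the four inflow
#' arteries per condition, the full flow-conserving simulation
#' ([simulate_condition()]), and a biased, noisy TCD envelope derived from
#' the simulated right-M1 envelope. Fully deterministic under the master
#' seed, with independent sub-streams per participant, artery and condition.
#'
#' @param cfg a [cohort_config()].
#' @param table a [region_table()] (default [default_region_table()]).
#' @param rheology a [rheology_params()].
#' @param split_cfg a [split_config()].
#' @return list of participants, each a list with `id`, `network`,
#'   `bias_factors`, `recordings` and `conditions` (per condition: `tcbf`,
#'   `cfd_envelope`, `tcd_envelope`, `cfd`, `tcd` metrics), directly
#'   consumable by [run_study()]; ground truth is in `bias_factors` and
#'   `drawn_flows`.
#' @export
synth_cohort <- function(cfg = cohort_config(), table = default_region_table(),
                         rheology = rheology_params(),
                         split_cfg = split_config()) {
  master <- cfg$seed
  conds <- cfg$conditions
  solver_cfg <- solver_config(n_phase = cfg$n_phase)
  lapply(seq_len(cfg$n_participants), function(i) {
    net <- synth_network(derive_seed(master, "network", i), cfg$jitter_cv)

    set.seed(derive_seed(master, "bias", i))
    bias <- cfg$bias_mean * rlnorm_cv(length(cfg$bias_mean), cfg$bias_cv)
    names(bias) <- names(cfg$bias_mean)

    rho <- cfg$response_correlation
    flows <- matrix(NA_real_, length(cfg$arteries), length(conds),
                    dimnames = list(cfg$arteries, conds))
    for (a in cfg$arteries) {
      set.seed(derive_seed(master, "flow", i, a))
      repeat {
        z0 <- stats::rnorm(1)
        z <- vapply(conds, function(cd)
          if (cd == "rest") z0 else rho * z0 + sqrt(1 - rho^2) * stats::rnorm(1),
          numeric(1))
        f <- cfg$flow_mean[a, conds] + cfg$flow_sd[a, conds] * z
        if (all(f > 0)) break
      }
      flows[a, ] <- f
    }
    diam <- vapply(cfg$arteries, function(a)
      20 * sqrt(flows[a, "rest"] / (30 * pi * cfg$typical_velocity[[a]])),
      numeric(1))

    recordings <- list()
    conditions <- list()
    for (cd in conds) {
      set.seed(derive_seed(master, "hr", i, cd))
      repeat {
        hr <- stats::rnorm(1, cfg$hr_mean[[cd]], cfg$hr_sd[[cd]])
        if (hr > 30) break
      }
      recs <- lapply(cfg$arteries, function(a)
        synth_inlet_recording(a, cd, cfg,
                              seed = derive_seed(master, "rec", i, a, cd),
                              mean_flow = flows[a, cd],
                              diameter_mm = diam[[a]], period = 60 / hr))
      names(recs) <- cfg$arteries
      recordings[[cd]] <- recs

      sim <- simulate_condition(recs, net, table = table, rheology = rheology,
                                split_cfg = split_cfg, solver_cfg = solver_cfg,
                                n_points = cfg$n_phase)
      tcd_env <- synth_tcd_envelope(sim$m1_envelope, bias, cfg$noise_cv,
                                    seed = derive_seed(master, "tcd", i, cd))
      conditions[[cd]] <- list(
        tcbf = sim$tcbf,
        cfd_envelope = sim$m1_envelope,
        tcd_envelope = tcd_env,
        cfd = sim$metrics,
        tcd = extract_metrics(tcd_env))
    }
    list(id = sprintf("P%02d", i), network = net, bias_factors = bias,
         drawn_flows = flows, diameters_mm = diam,
         recordings = recordings, conditions = conditions)
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes per-participant duplex envelope/diameter CSVs, network JSONs, TCD
#' envelope CSVs, the region table JSON, and `ground_truth.json` holding the
#' per-participant bias factors, drawn flows and the master seed.
#'
#' @param cohort output of [synth_cohort()].
#' @param cfg the [cohort_config()] used.
#' @param dir output directory.
#' @param table the [region_table()] used.
#' @export
write_cohort <- function(cohort, cfg, dir, table = default_region_table()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_region_table_json(table, file.path(dir, "regions.json"))
  gt <- list(seed = cfg$seed,
             participants = lapply(cohort, function(p)
               list(id = p$id, bias_factors = as.list(p$bias_factors),
                    drawn_flows = as.data.frame(p$drawn_flows),
                    diameters_mm = as.list(p$diameters_mm))))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (p in cohort) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    write_network_json(p$network, file.path(pdir, "network.json"))
    env_rows <- dia_rows <- NULL
    for (cd in names(p$recordings)) for (a in names(p$recordings[[cd]])) {
      rec <- p$recordings[[cd]][[a]]
      for (k in seq_along(rec$cycles)) {
        cy <- rec$cycles[[k]]
        env_rows <- rbind(env_rows, data.frame(
          artery = a, condition = cd, cycle = k,
          t_seconds = cy$phase * cy$period, velocity_cm_s = cy$values))
      }
      dia_rows <- rbind(dia_rows, data.frame(
        artery = a, condition = cd, diameter_mm = rec$diameter_mm))
    }
    utils::write.csv(env_rows, file.path(pdir, "duplex_envelopes.csv"),
                     row.names = FALSE)
    utils::write.csv(dia_rows, file.path(pdir, "duplex_diameters.csv"),
                     row.names = FALSE)
    for (cd in names(p$conditions))
      write_waveform_csv(p$conditions[[cd]]$tcd_envelope,
                         file.path(pdir, paste0("tcd_", cd, ".csv")))
  }
  invisible(dir)
}
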