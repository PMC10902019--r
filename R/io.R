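#' Read duplex recordings from long-form CSV
#'
#' Expects columns `artery,condition,cycle,t_seconds,velocity_cm_s` and a
#' companion diameter table with columns `artery,condition,diameter_mm`.
#' Samples within a cycle must be uniformly spaced in time; the cycle period
#' is taken as `n * dt` (the sample spacing extended one step past the last
#' sample, since the grid covers `[0, T)`).
#'
#' @param envelope_csv path to the long-form envelope CSV.
#' @param diameter_csv path to the diameter CSV.
#' @return nested list: `recordings[[condition]][[artery]]` of
#'   [duplex_recording()] objects.
#' @export
read_duplex_csv <- function(envelope_csv, diameter_csv) {
  env <- utils::read.csv(envelope_csv, stringsAsFactors = FALSE)
  need <- c("artery", "condition", "cycle", "t_seconds", "velocity_cm_s")
  if (!all(need %in% names(env)))
    stop("envelope CSV must have columns ", paste(need, collapse = ","))
  dia <- utils::read.csv(diameter_csv, stringsAsFactors = FALSE)
  if (!all(c("artery", "condition", "diameter_mm") %in% names(dia)))
    stop("diameter CSV must have columns artery,condition,diameter_mm")

  out <- list()
  for (cond in unique(env$condition)) {
    out[[cond]] <- list()
    for (art in unique(env$artery[env$condition == cond])) {
      sub <- env[env$condition == cond & env$artery == art, ]
      cycles <- lapply(split(sub, sub$cycle), function(cy) {
        cy <- cy[order(cy$t_seconds), ]
        dt <- diff(cy$t_seconds)
        if (length(dt) < 2L || max(abs(dt - mean(dt))) > 1e-6 * mean(dt))
          stop("cycle samples must be uniformly spaced in time")
        sampled_waveform(cy$velocity_cm_s, period = mean(dt) * nrow(cy),
                         units = "cm/s")
      })
      d <- dia$diameter_mm[dia$condition == cond & dia$artery == art]
      if (length(d) != 1L)
        stop("need exactly one diameter for ", art, "/", cond)
      out[[cond]][[art]] <- duplex_recording(art, unname(cycles), d)
    }
  }
  out
}

#' Write a waveform to CSV with metadata header
#'
#' Writes `phase,value` rows preceded by comment lines `# units=`,
#' `# period_s=` and (when known) `# n_cycles=`.
#'
#' @param w a [sampled_waveform()] or `ensemble_waveform`.
#' @param path output file path.
#' @export
write_waveform_csv <- function(w, path) {
  n_cycles <- NA
  if (inherits(w, "ensemble_waveform")) {
    n_cycles <- w$n_cycles
    w <- w$waveform
  }
  stopifnot_waveform(w)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units=%s", w$units), con)
  writeLines(sprintf("# period_s=%.10g", w$period), con)
  if (!is.na(n_cycles)) writeLines(sprintf("# n_cycles=%d", n_cycles), con)
  writeLines("phase,value", con)
  writeLines(sprintf("%.10g,%.10g", w$phase, w$values), con)
}

#' Read a waveform written by [write_waveform_csv()]
#'
#' @param path CSV file path.
#' @return a [sampled_waveform()].
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m) == 0L) NA_character_ else sub(paste0("^# ", key, "="), "", m[1])
  }
  units <- get("units")
  period <- as.numeric(get("period_s"))
  if (is.na(units) || is.na(period))
    stop("waveform CSV is missing '# units=' or '# period_s=' header lines")
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  sampled_waveform(body$value[order(body$phase)], period, units)
}

#' Export solver boundary conditions for an external 3D solver
#'
#' Writes one CSV per boundary (`phase,flow_ml_min,massflow_kg_s`) plus a
#' `manifest.csv` listing each boundary's role, artery or region label,
#' diameter and inlet/outlet extrusion length.
#'
#' @param net a [vascular_network()].
#' @param inlet_flows named list (by artery label) of inflow waveforms, mL/min.
#' @param splits an `outlet_split` from [build_outlet_splits()].
#' @param dir output directory (created if needed).
#' @param density density used for the mass-flow conversion, kg/m^3.
#' @param extrusion_multiplier diameter multiple for boundary extrusions.
#' @return invisibly, the manifest data frame.
#' @export
export_boundary_conditions <- function(net, inlet_flows, splits, dir,
                                       density = 1050,
                                       extrusion_multiplier = 11) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  write_bc <- function(node, w, role, label, diameter) {
    m <- to_mass_flow(w, density)
    utils::write.csv(
      data.frame(phase = w$phase, flow_ml_min = w$values,
                 massflow_kg_s = m$values),
      file.path(dir, paste0("bc_", node, ".csv")), row.names = FALSE)
    data.frame(node = node, role = role, label = label,
               diameter_mm = diameter,
               extrusion_mm = extrusion_length(diameter, extrusion_multiplier))
  }
  for (node in names(net$inlets)) {
    art <- net$inlets[[node]]
    w <- inlet_flows[[art]]
    if (is.null(w)) stop("no inlet flow supplied for artery ", art)
    manifest <- rbind(manifest,
                      write_bc(node, w, "inlet", art, boundary_diameter(net, node)))
  }
  for (i in seq_len(nrow(splits$outlets))) {
    node <- splits$outlets$node[i]
    manifest <- rbind(manifest,
                      write_bc(node, splits$flows[[node]], "outlet",
                               splits$outlets$region[i],
                               splits$outlets$diameter_mm[i]))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
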