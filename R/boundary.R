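#' Murray-split configuration
#'
#' @param split_exponent exponent of the diameter-power flow split
#'   (default 2.33).
#' @return an object of class `split_config`.
#' @export
split_config <- function(split_exponent = 2.33) {
  if (!is.finite(split_exponent) || split_exponent <= 0)
    stop("split_exponent must be positive")
  structure(list(split_exponent = split_exponent), class = "split_config")
}

#' Distribute total inflow across cerebral regions
#'
#' Pointwise multiplication of the total inflow waveform by each regional
#' fraction; the regional waveforms sum back to the total exactly.
#'
#' @param total_inflow total cerebral inflow waveform, mL/min.
#' @param table a [region_table()].
#' @return named list (by region) of [sampled_waveform()] objects.
#' @export
walnut_distribute <- function(total_inflow, table) {
  stopifnot_waveform(total_inflow, units = "mL/min", what = "total_inflow")
  if (!inherits(table, "region_table")) table <- region_table(table)
  out <- lapply(as.numeric(table), function(f)
    sampled_waveform(f * total_inflow$values, total_inflow$period, "mL/min"))
  names(out) <- names(unclass(table))
  out
}

#' Murray's-law diameter-power split fractions
#'
#' Fraction to outlet i is \eqn{d_i^n / \sum_j d_j^n}. Diameters are
#' normalised by their maximum before exponentiation so extreme exponents do
#' not overflow; fractions are invariant to uniform diameter rescaling.
#'
#' @param diameters outlet diameters in mm (all > 0).
#' @param split_exponent exponent n (> 0, default 2.33).
#' @return numeric vector of fractions summing to 1.
#' @export
murray_fractions <- function(diameters, split_exponent = 2.33) {
  if (length(diameters) == 0L) stop("need at least one outlet diameter")
  if (any(!is.finite(diameters) | diameters <= 0))
    stop("all outlet diameters must be positive")
  w <- (diameters / max(diameters))^split_exponent
  w / sum(w)
}

#' Split a regional inflow among its outlets by Murray's law
#'
#' @param region_inflow regional inflow waveform, mL/min.
#' @param outlet_diameters outlet diameters in mm.
#' @param cfg a [split_config()].
#' @return list of per-outlet flow waveforms, with the split fractions in
#'   attribute `"fractions"`.
#' @export
murray_split <- function(region_inflow, outlet_diameters, cfg = split_config()) {
  stopifnot_waveform(region_inflow, units = "mL/min", what = "region_inflow")
  fr <- murray_fractions(outlet_diameters, cfg$split_exponent)
  flows <- lapply(fr, function(f)
    sampled_waveform(f * region_inflow$values, region_inflow$period, "mL/min"))
  attr(flows, "fractions") <- fr
  flows
}

#' Build per-outlet flow boundary conditions for a network
#'
#' Sums the measured inlet flows to a total inflow, distributes it across
#' regions with [walnut_distribute()], and splits each regional flow among
#' that region's outlets with [murray_split()] using the diameters of the
#' segments attached to the outlet nodes. Global mass conservation (sum of
#' outlet flows equals sum of inlet flows at every phase point) holds by
#' construction and is verified to 1e-9 relative.
#'
#' @param net a [vascular_network()].
#' @param inlet_flows named list (by artery label) of inflow waveforms in
#'   mL/min, all on the same phase grid. Every network inlet must have a flow.
#' @param table a [region_table()]; every region with positive fraction must
#'   own at least one outlet, and every outlet's region must be in the table.
#' @param cfg a [split_config()].
#' @return an object of class `outlet_split`: list with `outlets` (data frame
#'   `node,region,diameter_mm,fraction`), `flows` (named list of per-outlet
#'   waveforms) and `total_inflow`.
#' @export
build_outlet_splits <- function(net, inlet_flows, table = default_region_table(),
                                cfg = split_config()) {
  if (!inherits(net, "vascular_network")) stop("net must be a vascular_network")
  if (!inherits(table, "region_table")) table <- region_table(table)
  missing_fl <- setdiff(unname(net$inlets), names(inlet_flows))
  if (length(missing_fl) > 0)
    stop("no inlet flow supplied for arteries: ", paste(missing_fl, collapse = ", "))

  used <- inlet_flows[unname(net$inlets)]
  lapply(used, stopifnot_waveform, units = "mL/min", what = "each inlet flow")
  ns <- unique(vapply(used, function(w) length(w$values), integer(1)))
  if (length(ns) != 1L) stop("inlet flows must share one phase grid")
  total <- sampled_waveform(Reduce(`+`, lapply(used, `[[`, "values")),
                            mean(vapply(used, `[[`, numeric(1), "period")),
                            "mL/min")

  fr_tab <- unclass(table)
  outlet_regions <- net$outlets
  bad <- setdiff(unique(outlet_regions), names(fr_tab))
  if (length(bad) > 0)
    stop("outlet region(s) missing from the region table: ",
         paste(bad, collapse = ", "))
  empty <- setdiff(names(fr_tab), unique(outlet_regions))
  if (length(empty) > 0)
    stop("region(s) with positive fraction but no outlets: ",
         paste(empty, collapse = ", "))

  regional <- walnut_distribute(total, table)
  outlets <- data.frame(node = names(outlet_regions),
                        region = unname(outlet_regions),
                        stringsAsFactors = FALSE)
  outlets$diameter_mm <- vapply(outlets$node, boundary_diameter,
                                numeric(1), net = net)
  outlets$fraction <- NA_real_
  flows <- vector("list", nrow(outlets))
  names(flows) <- outlets$node
  for (reg in unique(outlets$region)) {
    i <- which(outlets$region == reg)
    fr <- murray_fractions(outlets$diameter_mm[i], cfg$split_exponent)
    outlets$fraction[i] <- fr * fr_tab[[reg]]
    for (k in seq_along(i))
      flows[[outlets$node[i[k]]]] <- sampled_waveform(
        outlets$fraction[i[k]] * total$values, total$period, "mL/min")
  }

  resid <- max(abs(Reduce(`+`, lapply(flows, `[[`, "values")) - total$values)) /
    max(max(abs(total$values)), .Machine$double.eps)
  if (resid > 1e-9)
    stop("internal error: outlet flows do not conserve inflow (residual ",
         format(resid), ")")

  structure(list(outlets = outlets, flows = flows, total_inflow = total,
                 split_exponent = cfg$split_exponent),
            class = "outlet_split")
}

#' @export
print.outlet_split <- function(x, ...) {
  cat(sprintf("<outlet_split> %d outlets, exponent %.3g, mean total inflow %.1f mL/min\n",
              nrow(x$outlets), x$split_exponent, time_average(x$total_inflow)))
  print(x$outlets, row.names = FALSE)
  invisible(x)
}

#' Boundary extrusion length
#'
#' Straight extrusion prescribed at each boundary so that flow can develop
#' before entering the anatomical domain; the default is 11 boundary
#' diameters. In the reduced network solver extrusions are export metadata
#' only (the quasi-steady circuit needs no development length).
#'
#' @param boundary_diameter diameter in mm (> 0).
#' @param multiplier diameter multiple (default 11; 0 disables extrusions).
#' @return extrusion length in mm.
#' @export
extrusion_length <- function(boundary_diameter, multiplier = 11) {
  if (any(!is.finite(boundary_diameter) | boundary_diameter <= 0))
    stop("boundary_diameter must be positive")
  if (multiplier < 0) stop("multiplier must be >= 0")
  multiplier * boundary_diameter
}
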