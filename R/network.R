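#' Seven-region cerebral outflow vocabulary
#'
#' Region labels used to assign Circle-of-Willis outlets to cerebral
#' territories: left/right posterior, left/right middle, anterior,
#' cerebellum and ophthalmic.
#'
#' @export
COW_REGIONS <- c("left_posterior", "right_posterior", "left_middle",
                 "right_middle", "anterior", "cerebellum", "ophthalmic")

#' Vascular network of cylindrical segments
#'
#' A connected graph of uniform cylindrical segments. Boundary nodes are
#' tagged either as inlets (carrying the artery label whose measured flow is
#' prescribed there) or outlets (carrying one of the seven region labels).
#' Tapering vessels are represented by subdividing them into shorter
#' segments in the network description.
#'
#' @param segments data frame with columns `id`, `from`, `to`, `length_mm`,
#'   `diameter_mm`, `name`.
#' @param inlets named character vector: boundary node -> artery label
#'   (labels must be unique).
#' @param outlets named character vector: boundary node -> region label from
#'   [COW_REGIONS].
#' @return an object of class `vascular_network`.
#' @export
vascular_network <- function(segments, inlets, outlets) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need <- c("id", "from", "to", "length_mm", "diameter_mm", "name")
  if (!all(need %in% names(segments)))
    stop("segments must have columns ", paste(need, collapse = ","))
  if (anyDuplicated(segments$id)) stop("segment ids must be unique")
  if (any(segments$length_mm <= 0)) stop("all segment lengths must be > 0")
  if (any(segments$diameter_mm <= 0)) stop("all segment diameters must be > 0")
  inlets <- unlist(inlets)
  outlets <- unlist(outlets)
  if (anyDuplicated(inlets)) stop("inlet artery labels must be unique")
  bad <- setdiff(unique(outlets), COW_REGIONS)
  if (length(bad) > 0)
    stop("unknown outlet region label(s): ", paste(bad, collapse = ", "))
  nodes <- unique(c(segments$from, segments$to))
  missing_b <- setdiff(c(names(inlets), names(outlets)), nodes)
  if (length(missing_b) > 0)
    stop("boundary node(s) not in graph: ", paste(missing_b, collapse = ", "))

  net <- structure(list(nodes = nodes, segments = segments,
                        inlets = inlets, outlets = outlets),
                   class = "vascular_network")
  if (!network_connected(net)) stop("network graph must be connected")
  net
}

# breadth-first connectivity check
network_connected <- function(net) {
  nodes <- net$nodes
  adj <- split(c(net$segments$to, net$segments$from),
               c(net$segments$from, net$segments$to))
  seen <- structure(logical(length(nodes)), names = nodes)
  queue <- nodes[1]
  seen[queue] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
  }
  all(seen)
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf("<vascular_network> %d nodes, %d segments, %d inlet(s), %d outlet(s)\n",
              length(x$nodes), nrow(x$segments), length(x$inlets), length(x$outlets)))
  cat("  inlets: ", paste(x$inlets, collapse = ", "), "\n")
  cat("  outlet regions: ",
      paste(sort(unique(x$outlets)), collapse = ", "), "\n")
  invisible(x)
}

# diameter of the single segment attached to a boundary node
boundary_diameter <- function(net, node) {
  seg <- net$segments[net$segments$from == node | net$segments$to == node, ]
  if (nrow(seg) != 1L)
    stop("boundary node ", node, " must have exactly one attached segment")
  seg$diameter_mm
}

#' Read a vascular network from JSON
#'
#' Schema: `{"segments":[{"id","from","to","length_mm","diameter_mm","name"}],
#' "inlets":{node:artery}, "outlets":{node:region}}`.
#'
#' @param path JSON file path.
#' @return a [vascular_network()].
#' @export
read_network_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  vascular_network(j$segments, unlist(j$inlets), unlist(j$outlets))
}

#' Write a vascular network to JSON
#'
#' @param net a [vascular_network()].
#' @param path output path.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(
    list(nodes = net$nodes, segments = net$segments,
         inlets = as.list(net$inlets), outlets = as.list(net$outlets)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Regional outflow-fraction table
#'
#' Fractions of total cerebral outflow assigned to cerebral territories
#' before the per-outlet Murray split. Names must come from [COW_REGIONS]
#' (a subset is allowed for reduced test networks); fractions must be
#' positive and sum to 1 within 1e-12.
#'
#' @param fractions named numeric vector of regional fractions.
#' @return an object of class `region_table`.
#' @export
region_table <- function(fractions) {
  fractions <- unlist(fractions)
  bad <- setdiff(names(fractions), COW_REGIONS)
  if (length(bad) > 0)
    stop("unknown region name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(fractions))) stop("duplicated region names")
  if (any(fractions <= 0)) stop("all regional fractions must be > 0")
  if (abs(sum(fractions) - 1) > 1e-12)
    stop("regional fractions must sum to 1 (got ", format(sum(fractions), digits = 15), ")")
  structure(fractions, class = "region_table")
}

#' Provisional default regional fraction table
#'
#' The regional fractions used by the original outflow-distribution scheme
#' are not public; this provisional table (anterior 0.18, each middle 0.25,
#' each posterior 0.10, cerebellum 0.09, ophthalmic 0.03) is a plausible
#' physiological split used by the synthetic cohort and the test-suite. For
#' real analyses supply a participant-specific table.
#'
#' @return a [region_table()].
#' @export
default_region_table <- function() {
  region_table(c(left_posterior = 0.10, right_posterior = 0.10,
                 left_middle = 0.25, right_middle = 0.25,
                 anterior = 0.18, cerebellum = 0.09, ophthalmic = 0.03))
}

#' Read a region table from JSON (`{region: fraction}`)
#'
#' @param path JSON file path.
#' @return a [region_table()].
#' @export
read_region_table_json <- function(path) {
  region_table(unlist(jsonlite::fromJSON(path)))
}

#' Write a region table to JSON
#'
#' @param table a [region_table()].
#' @param path output path.
#' @export
write_region_table_json <- function(table, path) {
  jsonlite::write_json(as.list(unclass(table)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
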