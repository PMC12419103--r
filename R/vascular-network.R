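#' Anatomical variant of the Circle of Willis
#'
#' Describes the common anatomical variants of the Circle of Willis as
#' presence flags for the communicating arteries and hypoplasia scale factors
#' in (0, 1] for the A1/P1 ring segments and the internal carotid arteries.
#' The completeness of the circle governs collateral capacity, so these
#' variants are first-class inputs to every simulation.
#'
#' @param acom_present Is the anterior communicating artery present?
#' @param pcom_left_present,pcom_right_present Posterior communicating
#'   arteries present?
#' @param a1_left_factor,a1_right_factor Radius scale factor for the A1
#'   segments, in (0, 1]; values < 1 model hypoplasia.
#' @param p1_left_factor,p1_right_factor Radius scale factor for the P1
#'   segments, in (0, 1].
#' @param ica_left_factor,ica_right_factor Radius scale factor for the
#'   internal carotid arteries, in (0, 1].
#' @return A list of class `cow_variant`.
#' @export
anatomical_variant <- function(acom_present = TRUE,
                               pcom_left_present = TRUE,
                               pcom_right_present = TRUE,
                               a1_left_factor = 1, a1_right_factor = 1,
                               p1_left_factor = 1, p1_right_factor = 1,
                               ica_left_factor = 1, ica_right_factor = 1) {
  fac <- c(a1_left_factor, a1_right_factor, p1_left_factor, p1_right_factor,
           ica_left_factor, ica_right_factor)
  if (any(!is.finite(fac)) || any(fac <= 0) || any(fac > 1)) {
    abort("Variant scale factors must lie in (0, 1].",
          class = "cowflow_invalid_input")
  }
  structure(list(acom_present = isTRUE(acom_present),
                 pcom_left_present = isTRUE(pcom_left_present),
                 pcom_right_present = isTRUE(pcom_right_present),
                 a1_left_factor = a1_left_factor,
                 a1_right_factor = a1_right_factor,
                 p1_left_factor = p1_left_factor,
                 p1_right_factor = p1_right_factor,
                 ica_left_factor = ica_left_factor,
                 ica_right_factor = ica_right_factor),
            class = "cow_variant")
}

#' Default Circle-of-Willis segment dimensions
#'
#' Editable geometry table of literature-typical radii and lengths for the
#' canonical Circle-of-Willis template: extracranial inlets (ICA, VA),
#' vertebrobasilar trunk (V4, BA), the M1/A1/P1 ring with both communicating
#' arteries, and A2/P2/M1-terminal outlets. Imaging-derived per-patient
#' geometry replaces these values in clinical use; here they make simulations
#' runnable without any imaging.
#'
#' @return A tibble with columns `name`, `from`, `to`, `length_m`, `radius_m`,
#'   `role`.
#' @export
cow_geometry_defaults <- function() {
  g <- utils::read.csv(system.file("extdata", "cow_geometry.csv",
                            package = "cowflow"),
                stringsAsFactors = FALSE)
  as_tibble(g)
}

#' Build the canonical Circle-of-Willis network
#'
#' Constructs the template Circle-of-Willis graph: 2 ICA + 2 VA inlets, the
#' basilar artery from the vertebral confluence, the M1/A1/P1 ring connected
#' by the anterior and both posterior communicating arteries, and six outlets
#' (terminal MCA, A2, P2 on both sides). Variant flags delete communicating
#' arteries; hypoplasia factors shrink radii. Optional superior cerebellar
#' outlets off the distal basilar artery are disabled by default.
#'
#' The network is topological: a graph of cylindrical segments with one
#' length and radius each; no 3D embedding is needed for flow.
#'
#' @param variant An [anatomical_variant()].
#' @param scale Global size factor applied to all radii and lengths.
#' @param geometry Geometry table as in [cow_geometry_defaults()].
#' @param cerebellar_outlets Add a pair of small superior cerebellar outlets
#'   off the distal basilar artery?
#' @return A `cow_network` object: `list(segments = <tibble>, variant)`.
#' @export
#' @examples
#' net <- build_cow_template()
#' validate_network(net)
build_cow_template <- function(variant = anatomical_variant(), scale = 1,
                               geometry = cow_geometry_defaults(),
                               cerebellar_outlets = FALSE) {
  stopifnot(inherits(variant, "cow_variant"))
  check_number(scale, "scale", min = 0, strict_min = TRUE)
  seg <- geometry
  if (!cerebellar_outlets) seg <- seg[!grepl("^SCA", seg$name), ]
  seg$length_m <- seg$length_m * scale
  seg$radius_m <- seg$radius_m * scale

  fac <- function(name, f) {
    seg$radius_m[seg$name == name] <<- seg$radius_m[seg$name == name] * f
  }
  fac("ACA_A1_L", variant$a1_left_factor)
  fac("ACA_A1_R", variant$a1_right_factor)
  fac("PCA_P1_L", variant$p1_left_factor)
  fac("PCA_P1_R", variant$p1_right_factor)
  fac("ICA_L", variant$ica_left_factor)
  fac("ICA_R", variant$ica_right_factor)
  fac("ICA_intracranial_L", variant$ica_left_factor)
  fac("ICA_intracranial_R", variant$ica_right_factor)

  drop <- character(0)
  if (!variant$acom_present) drop <- c(drop, "AComm")
  if (!variant$pcom_left_present) drop <- c(drop, "PComm_L")
  if (!variant$pcom_right_present) drop <- c(drop, "PComm_R")
  seg <- seg[!seg$name %in% drop, ]

  seg$id <- seg$name
  net <- structure(list(segments = as_tibble(seg[, c("id", "name", "from",
                                                     "to", "length_m",
                                                     "radius_m", "role")]),
                        variant = variant),
                   class = "cow_network")
  rep <- validate_network(net)
  bad <- rep$violation[grepl("unreachable", rep$violation)]
  if (length(bad) > 0) {
    abort(paste0("Variant disconnects the network: ",
                 paste(bad, collapse = "; ")),
          class = "cowflow_validation_error")
  }
  net
}

#' @export
print.cow_network <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<cow_network> %d segments, %d nodes, %d inlets, %d outlets\n",
              nrow(s), length(network_nodes(x)),
              sum(s$role == "inlet"), sum(s$role == "outlet")))
  invisible(x)
}

network_nodes <- function(network) {
  unique(c(network$segments$from, network$segments$to))
}

# undirected reachability from a set of start nodes
reachable_nodes <- function(segments, start) {
  nodes <- unique(c(segments$from, segments$to))
  seen <- stats::setNames(nodes %in% start, nodes)
  repeat {
    hit <- seen[segments$from] | seen[segments$to]
    new <- seen
    new[segments$from[hit]] <- TRUE
    new[segments$to[hit]] <- TRUE
    if (identical(new, seen)) break
    seen <- new
  }
  names(seen)[seen]
}

#' Validate a vascular network
#'
#' Automated anatomical plausibility check (the stand-in for an expert review
#' of a reconstructed model): connectivity, inlet/outlet counts, positivity of
#' radii and lengths, reachability of every outlet from the inlet set, and
#' dangling internal nodes. Pure function; returns a report and mutates
#' nothing.
#'
#' @param network A `cow_network`.
#' @return A tibble of violations with columns `check` and `violation`
#'   (zero rows when the network is valid).
#' @export
validate_network <- function(network) {
  s <- network$segments
  v <- list()
  add <- function(check, msg) v[[length(v) + 1]] <<- tibble(check = check,
                                                            violation = msg)
  bad_r <- s$id[!is.finite(s$radius_m) | s$radius_m <= 0]
  for (id in bad_r) add("radius", sprintf("segment %s has non-positive radius", id))
  bad_l <- s$id[!is.finite(s$length_m) | s$length_m <= 0]
  for (id in bad_l) add("length", sprintf("segment %s has non-positive length", id))

  inlets <- s[s$role == "inlet", ]
  if (nrow(inlets) < 1) add("inlets", "network has no inlet")
  if (nrow(inlets) > 4) add("inlets", "network has more than 4 inlets")
  ok_in <- inlets$name %in% c("ICA_L", "ICA_R", "VA_L", "VA_R")
  for (id in inlets$id[!ok_in]) {
    add("inlets", sprintf("segment %s may not be an inlet", id))
  }
  outlets <- s[s$role == "outlet", ]
  if (nrow(outlets) < 1) add("outlets", "network has no outlet")
  ok_out <- grepl("^(MCA|ACA_A2|PCA_P2|SCA)", outlets$name)
  for (id in outlets$id[!ok_out]) {
    add("outlets", sprintf("segment %s may not be an outlet", id))
  }

  inlet_nodes <- s$from[s$role == "inlet"]
  reach <- reachable_nodes(s, inlet_nodes)
  un <- s$id[s$role == "outlet" & !(s$to %in% reach)]
  for (id in un) add("connectivity", sprintf("outlet %s unreachable from inlets", id))

  deg <- table(c(s$from, s$to))
  boundary <- c(s$from[s$role == "inlet"], s$to[s$role == "outlet"])
  dangling <- names(deg)[deg == 1 & !(names(deg) %in% boundary)]
  for (nd in dangling) add("topology", sprintf("internal node %s is dangling", nd))

  if (length(v) == 0) {
    return(tibble(check = character(0), violation = character(0)))
  }
  dplyr::bind_rows(v)
}

#' Randomly perturb network geometry
#'
#' Applies independent lognormal multiplicative factors with log-scale
#' standard deviation `relative_sd` to every radius and length, emulating
#' inter-patient anatomical variability around the template. Deterministic
#' under `seed`.
#'
#' @param network A `cow_network`.
#' @param relative_sd Log-scale standard deviation of the lognormal factors,
#'   in `[0, 0.3]`.
#' @param seed Integer seed.
#' @return A perturbed `cow_network`.
#' @export
perturb_geometry <- function(network, relative_sd, seed) {
  check_number(relative_sd, "relative_sd", min = 0, max = 0.3)
  if (relative_sd == 0) return(network)
  s <- network$segments
  withr::with_seed(as.integer(seed), {
    s$radius_m <- s$radius_m * exp(rnorm(nrow(s), 0, relative_sd))
    s$length_m <- s$length_m * exp(rnorm(nrow(s), 0, relative_sd))
  })
  network$segments <- s
  network
}

#' Read and write vascular networks as JSON
#'
#' Versioned JSON schema:
#' `{schema, nodes:[{id}], segments:[{id, name, from, to, length_m, radius_m,
#' role}], variant:{...}}`. A write/read round trip reproduces the graph
#' exactly (ids and dimensions to full precision).
#'
#' @param network A `cow_network`.
#' @param path File path.
#' @return `read_network_json()` returns a `cow_network`;
#'   `write_network_json()` returns `path` invisibly.
#' @export
write_network_json <- function(network, path) {
  doc <- list(
    schema = "cowflow/network/v1",
    nodes = lapply(network_nodes(network), function(n) list(id = n)),
    segments = lapply(seq_len(nrow(network$segments)), function(i) {
      as.list(network$segments[i, ])
    }),
    variant = unclass(network$variant)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "cowflow/network/v1")) {
    abort("Unrecognised network schema.", class = "cowflow_invalid_input")
  }
  seg <- dplyr::bind_rows(lapply(doc$segments, as_tibble))
  var <- doc$variant
  variant <- anatomical_variant(
    acom_present = var$acom_present,
    pcom_left_present = var$pcom_left_present,
    pcom_right_present = var$pcom_right_present,
    a1_left_factor = var$a1_left_factor,
    a1_right_factor = var$a1_right_factor,
    p1_left_factor = var$p1_left_factor,
    p1_right_factor = var$p1_right_factor,
    ica_left_factor = var$ica_left_factor,
    ica_right_factor = var$ica_right_factor)
  structure(list(segments = seg, variant = variant), class = "cow_network")
}
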