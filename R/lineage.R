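#' Bundle annotations: the lineage seed geometry
#'
#' A bundle annotation anchors one lineage tract: the entry portal (a point
#' and unit plane normal where the tract enters the neuropil from the
#' cortical rind), seed fiber positions on the portal plane (digitised from
#' the annotated fiber bundle), a capture radius, and optionally the soma
#' cluster centre used for tie-breaking.
#'
#' @param lineage_id Lineage name (e.g. `"BAmv1"`, `"CP2d"`).
#' @param portal_point 3-vector (nm) on the portal plane.
#' @param portal_normal Plane normal (normalised internally), oriented from
#'   the soma side into the neuropil.
#' @param seed_fibers n x 3 matrix of seed fiber positions; must lie on the
#'   portal plane (within 1 nm).
#' @param capture_radius Capture radius in nm (> 0).
#' @param soma_center Optional 3-vector: soma cluster centre.
#' @return A list of class `bundle_annotation`.
#' @export
bundle_annotation <- function(lineage_id, portal_point, portal_normal,
                              seed_fibers, capture_radius,
                              soma_center = NULL) {
  portal_normal <- unit_vector(portal_normal)
  seed_fibers <- as_point_matrix(seed_fibers)
  dimnames(seed_fibers) <- NULL
  if (capture_radius <= 0) stop("capture_radius must be > 0")
  off <- abs(sweep(seed_fibers, 2, portal_point) %*% portal_normal)
  if (any(off > 1)) {
    stop("bundle ", lineage_id, ": seed fibers must lie on the portal ",
         "plane (max offset ", format(max(off)), " nm)")
  }
  structure(list(lineage_id = lineage_id,
                 portal_point = as.numeric(portal_point),
                 portal_normal = portal_normal,
                 seed_fibers = seed_fibers,
                 capture_radius = capture_radius,
                 soma_center = if (is.null(soma_center)) NULL
                               else as.numeric(soma_center)),
            class = "bundle_annotation")
}

#' Read / write bundle annotations (JSON)
#'
#' Schema: an array of `{lineage_id, portal: {point, normal},
#' seeds: [[x,y,z], ...], capture_radius_nm, soma_center}`.
#'
#' @param path JSON path.
#' @return [read_bundles()]: a named list of [bundle_annotation()]s.
#' @export
read_bundles <- function(path) {
  if (!file.exists(path)) stop("bundle JSON not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  bundles <- lapply(raw, function(b) {
    bundle_annotation(
      lineage_id = b$lineage_id,
      portal_point = as.numeric(unlist(b$portal$point)),
      portal_normal = as.numeric(unlist(b$portal$normal)),
      seed_fibers = do.call(rbind, lapply(b$seeds, as.numeric)),
      capture_radius = b$capture_radius_nm,
      soma_center = if (is.null(b$soma_center)) NULL
                    else as.numeric(unlist(b$soma_center))
    )
  })
  names(bundles) <- vapply(bundles, `[[`, "", "lineage_id")
  bundles
}

#' @rdname read_bundles
#' @param bundles Named list of [bundle_annotation()]s.
#' @export
write_bundles <- function(bundles, path) {
  out <- lapply(unname(bundles), function(b) {
    list(lineage_id = b$lineage_id,
         portal = list(point = b$portal_point, normal = b$portal_normal),
         seeds = apply(b$seed_fibers, 1, as.numeric, simplify = FALSE),
         capture_radius_nm = b$capture_radius,
         soma_center = b$soma_center)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' First crossing of a polyline through a portal plane
#'
#' Traverses the polyline in order (soma side first) and returns the first
#' point where it crosses the portal plane, linearly interpolated between
#' the bracketing vertices. A vertex exactly on the plane counts as a
#' crossing. Polylines that never reach the plane return `NULL`.
#'
#' @param path_xyz n x 3 matrix of nm coordinates, ordered from the soma
#'   side.
#' @param portal_point,portal_normal Plane definition (normal normalised
#'   internally).
#' @return 3-vector of the crossing point, or `NULL`.
#' @export
portal_crossing <- function(path_xyz, portal_point, portal_normal) {
  pts <- as_point_matrix(path_xyz)
  if (nrow(pts) == 0L) return(NULL)
  n <- unit_vector(portal_normal)
  s <- as.vector(sweep(pts, 2, portal_point) %*% n)
  on_plane <- which(s == 0)
  cross <- which(s[-length(s)] * s[-1] < 0)
  first_on <- if (length(on_plane)) on_plane[1L] else Inf
  first_cr <- if (length(cross)) cross[1L] else Inf
  if (is.infinite(first_on) && is.infinite(first_cr)) return(NULL)
  if (first_on <= first_cr) return(as.numeric(pts[first_on, ]))
  i <- first_cr
  t <- s[i] / (s[i] - s[i + 1L])
  as.numeric(pts[i, ] + t * (pts[i + 1L, ] - pts[i, ]))
}

#' Assign one neuron to a lineage bundle
#'
#' For each candidate bundle, the tract's crossing point through that
#' bundle's portal plane is compared against the bundle's seed fibers; the
#' bundle with the smallest crossing-to-seed distance `d` wins if
#' `d <= capture_radius` (method `PORTAL`). Tracts that cross no portal fall
#' back to the mean tract-to-seed distance (method `TRAJECTORY`). Exact
#' distance ties are broken by soma-to-soma-cluster distance, then
#' lexicographically by lineage id. Neurons captured by no bundle are
#' `UNASSIGNED`. The assignment score is `exp(-d / capture_radius)`.
#'
#' @param path_xyz Backbone main path, soma side first
#'   (see [backbone_main_path()]).
#' @param soma_position 3-vector (nm) used for tie-breaking.
#' @param bundles Named list of [bundle_annotation()]s.
#' @param neuron_id Identifier carried into the output row.
#' @return One-row data.frame: `neuron_id`, `lineage`, `score`, `method`.
#' @export
assign_lineage <- function(path_xyz, soma_position, bundles,
                           neuron_id = NA_character_) {
  unassigned <- data.frame(neuron_id = neuron_id, lineage = NA_character_,
                           score = NA_real_, method = "UNASSIGNED",
                           stringsAsFactors = FALSE)
  pts <- as_point_matrix(path_xyz)
  if (nrow(pts) == 0L || length(bundles) == 0L) return(unassigned)

  seed_min_dist <- function(p, seeds) {
    min(sqrt((seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2 +
               (seeds[, 3] - p[3])^2))
  }
  d_portal <- vapply(bundles, function(b) {
    cp <- portal_crossing(pts, b$portal_point, b$portal_normal)
    if (is.null(cp)) NA_real_ else seed_min_dist(cp, b$seed_fibers)
  }, 0)

  method <- "PORTAL"
  d <- d_portal
  if (all(is.na(d))) {
    method <- "TRAJECTORY"
    d <- vapply(bundles, function(b) {
      mean(vapply(seq_len(nrow(pts)), function(i) {
        seed_min_dist(pts[i, ], b$seed_fibers)
      }, 0))
    }, 0)
  }
  radius <- vapply(bundles, `[[`, 0, "capture_radius")
  ok <- !is.na(d) & d <= radius
  if (!any(ok)) return(unassigned)
  dmin <- min(d[ok])
  cand <- which(!is.na(d) & d == dmin & ok)
  if (length(cand) > 1L && !is.null(soma_position)) {
    soma_d <- vapply(cand, function(i) {
      ctr <- bundles[[i]]$soma_center
      if (is.null(ctr)) Inf else sqrt(sum((soma_position - ctr)^2))
    }, 0)
    cand <- cand[soma_d == min(soma_d)]
  }
  if (length(cand) > 1L) {
    ids <- vapply(bundles[cand], `[[`, "", "lineage_id")
    cand <- cand[order(ids)][1L]
  }
  b <- bundles[[cand[1L]]]
  data.frame(neuron_id = neuron_id, lineage = b$lineage_id,
             score = exp(-d[cand[1L]] / b$capture_radius), method = method,
             stringsAsFactors = FALSE)
}

#' Assign many neurons to lineages
#'
#' Extracts each neuron's backbone and assigns it to a bundle; optionally
#' splits each assigned lineage into two hemilineage groups by the widest
#' principal direction of the portal-crossing positions.
#'
#' @param skeletons Named list of [skeleton()]s.
#' @param connectors A [connector_table()] or `NULL`.
#' @param bundles Named list of [bundle_annotation()]s.
#' @param params A [backbone_params()].
#' @param split_hemilineages Add a `hemilineage` column (`"<lineage>_a"` /
#'   `"<lineage>_b"`) by a 1-D split of crossing positions (default
#'   `FALSE`).
#' @return A lineage catalog data.frame: `neuron_id`, `lineage`,
#'   `hemilineage`, `score`, `method`.
#' @export
assign_lineages <- function(skeletons, connectors = NULL, bundles,
                            params = backbone_params(),
                            split_hemilineages = FALSE) {
  rows <- vector("list", length(skeletons))
  crossings <- matrix(NA_real_, nrow = length(skeletons), ncol = 3)
  for (i in seq_along(skeletons)) {
    skel <- skeletons[[i]]
    bb <- suppressWarnings(extract_backbone(skel, connectors, params))
    soma_id <- skel$soma_node
    soma <- as.numeric(skel$nodes[match(soma_id, skel$nodes$node_id),
                                  c("x", "y", "z")])
    path <- backbone_main_path(bb, soma_position = soma)
    row <- assign_lineage(path, soma, bundles, neuron_id = skel$neuron_id)
    if (!is.na(row$lineage) && row$method == "PORTAL") {
      b <- bundles[[row$lineage]]
      cp <- portal_crossing(path, b$portal_point, b$portal_normal)
      if (!is.null(cp)) crossings[i, ] <- cp
    }
    rows[[i]] <- row
  }
  catalog <- do.call(rbind, rows)
  catalog$hemilineage <- NA_character_
  if (split_hemilineages) {
    for (lin in unique(stats::na.omit(catalog$lineage))) {
      idx <- which(!is.na(catalog$lineage) & catalog$lineage == lin &
                     !is.na(crossings[, 1]))
      if (length(idx) < 2L) next
      catalog$hemilineage[idx] <- paste0(
        lin, "_", split_crossings(crossings[idx, , drop = FALSE]))
    }
  }
  rownames(catalog) <- NULL
  catalog[, c("neuron_id", "lineage", "hemilineage", "score", "method")]
}

# 1-D split of crossing positions along their widest principal direction;
# returns "a" (lower half) / "b" (upper half), mirroring paired
# dorsal/ventral hemilineage tracts
split_crossings <- function(xyz) {
  ctr <- colMeans(xyz)
  centered <- sweep(xyz, 2, ctr)
  pc1 <- eigen(crossprod(centered) / nrow(xyz), symmetric = TRUE)$vectors[, 1]
  proj <- as.vector(centered %*% pc1)
  ifelse(proj <= stats::median(proj), "a", "b")
}

#' CX large-field catalog inclusion filter
#'
#' The published inclusion rule for the central-complex large-field catalog:
#' a neuron is listed if it (1) innervates any CX compartment (has at least
#' one connector there), (2) forms strictly more than `min_cx_synapses`
#' T-bars plus PSDs in those compartments, and (3) forms at least one output
#' connection onto a single neuron with strength strictly greater than
#' `min_single_connection` synapses.
#'
#' @param min_cx_synapses Strict lower bound on total CX T-bars + PSDs
#'   (default 15).
#' @param min_single_connection Strict lower bound on the strongest
#'   single-partner output connection (default 5).
#' @param cx_regions Names of the CX compartments (parent names; annular /
#'   layer subregions are rolled up when a model is supplied).
#' @return A list of class `cx_filter_params`.
#' @export
cx_filter_params <- function(min_cx_synapses = 15,
                             min_single_connection = 5,
                             cx_regions = c("PB", "EB", "FB", "NO", "AB")) {
  stopifnot(min_cx_synapses >= 0, min_single_connection >= 0)
  structure(list(min_cx_synapses = min_cx_synapses,
                 min_single_connection = min_single_connection,
                 cx_regions = cx_regions),
            class = "cx_filter_params")
}

#' Filter a lineage catalog to CX large-field neurons
#'
#' Applies [cx_filter_params()] to the neurons of a catalog using their
#' connector records. Connection strength is the summed synapse weight per
#' ordered (pre, post) neuron pair, in any compartment.
#'
#' @param catalog Lineage catalog data.frame with a `neuron_id` column.
#' @param connectors A [connector_table()] with compartment labels.
#' @param params A [cx_filter_params()].
#' @param model Optional [compartment_model()]; when given, connector
#'   compartments are rolled up to parents before matching `cx_regions`.
#' @return The catalog rows passing the filter.
#' @export
filter_cx_largefield <- function(catalog, connectors,
                                 params = cx_filter_params(),
                                 model = NULL) {
  comp <- connectors$compartment
  if (!is.null(model)) comp <- parent_region(comp, model)
  in_cx <- !is.na(comp) & comp %in% params$cx_regions

  keep <- vapply(catalog$neuron_id, function(n) {
    mine_cx <- in_cx & (connectors$pre == n | connectors$post == n)
    if (!any(mine_cx)) return(FALSE)                                  # (1)
    if (sum(connectors$weight[mine_cx]) <= params$min_cx_synapses) {  # (2)
      return(FALSE)
    }
    out <- connectors$pre == n
    if (!any(out)) return(FALSE)
    strengths <- tapply(connectors$weight[out], connectors$post[out], sum)
    max(strengths) > params$min_single_connection                      # (3)
  }, logical(1))
  catalog[keep, , drop = FALSE]
}

#' Neuron counts per lineage and compartment
#'
#' A neuron counts towards a compartment if it has at least one connector
#' there; neurons innervating several compartments count once in each.
#' Both hemispheres are summed (compartments are named bilaterally).
#'
#' @param catalog Lineage catalog (typically post-filter) with `neuron_id`
#'   and `lineage` columns.
#' @param connectors A [connector_table()] with compartment labels.
#' @param model Optional [compartment_model()] to roll subregions up to
#'   parent compartments.
#' @param compartments Optional character vector fixing the column order;
#'   defaults to the compartments observed.
#' @return An integer matrix, lineages x compartments.
#' @export
count_by_lineage_and_compartment <- function(catalog, connectors,
                                             model = NULL,
                                             compartments = NULL) {
  comp <- connectors$compartment
  if (!is.null(model)) comp <- parent_region(comp, model)
  if (is.null(compartments)) {
    compartments <- sort(unique(comp[!is.na(comp) & comp != "unassigned"]))
  }
  lineages <- sort(unique(catalog$lineage[!is.na(catalog$lineage)]))
  counts <- matrix(0L, nrow = length(lineages), ncol = length(compartments),
                   dimnames = list(lineages, compartments))
  for (i in seq_len(nrow(catalog))) {
    n <- catalog$neuron_id[i]
    lin <- catalog$lineage[i]
    if (is.na(lin) || !lin %in% lineages) next
    mine <- connectors$pre == n | connectors$post == n
    present <- unique(comp[mine])
    present <- present[present %in% compartments]
    counts[lin, present] <- counts[lin, present] + 1L
  }
  counts
}
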