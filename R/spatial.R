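#' Fit a torus axis model to a point cloud
#'
#' The ellipsoid body is modelled as a torus: its ring symmetry axis is the
#' direction of least variance of the synapse/skeleton cloud, the centre is
#' the centroid, and the ring radius is the mean distance of the points from
#' the axis line. The axis sign is fixed towards a reference direction so
#' the fit is deterministic.
#'
#' @param points n x 3 matrix (nm), n >= 10.
#' @param orient Reference direction for the axis sign (default `c(0,1,0)`,
#'   the anterior config axis).
#' @return A list of class `torus_axis_model`: `center`, `axis` (unit),
#'   `ring_radius`.
#' @export
fit_torus_axis <- function(points, orient = c(0, 1, 0)) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 10L) stop("need at least 10 points to fit a torus axis")
  center <- colMeans(pts)
  centered <- sweep(pts, 2, center)
  ev <- eigen(crossprod(centered) / nrow(pts), symmetric = TRUE)
  if (ev$values[2] < 1e-9 * max(ev$values[1], 1)) {
    stop("degenerate (collinear) point cloud: torus axis undefined")
  }
  axis <- ev$vectors[, 3]  # least-variance direction
  if (sum(axis * orient) < 0) axis <- -axis
  v <- as.vector(centered %*% axis)
  radial <- centered - outer(v, axis)
  ring_radius <- mean(sqrt(rowSums(radial^2)))
  if (ring_radius <= 0) stop("degenerate point cloud: zero ring radius")
  structure(list(center = center, axis = axis, ring_radius = ring_radius),
            class = "torus_axis_model")
}

#' Torus axis model from known geometry
#'
#' @param center,axis,ring_radius Ring centre (nm), symmetry axis
#'   (normalised internally) and ring radius (nm).
#' @return A `torus_axis_model`.
#' @export
torus_axis_model <- function(center, axis, ring_radius) {
  stopifnot(ring_radius > 0)
  structure(list(center = as.numeric(center), axis = unit_vector(axis),
                 ring_radius = ring_radius),
            class = "torus_axis_model")
}

#' Circular (azimuth-collapsing) projection onto the tube cross-section
#'
#' Collapses the ring's cross sections onto a single plane: each 3-D point
#' maps to `u` (distance from the ring axis minus the ring radius) and `v`
#' (signed offset along the axis); the azimuth around the ring is
#' discarded. Point count and total weight are conserved exactly.
#'
#' @param points n x 3 matrix (nm).
#' @param model A `torus_axis_model`.
#' @param weight Optional non-negative weights (default 1 per point).
#' @return A data.frame `u`, `v`, `weight` with one row per input point.
#' @export
circular_project <- function(points, model, weight = NULL) {
  pts <- as_point_matrix(points)
  if (is.null(weight)) weight <- rep(1, nrow(pts))
  stopifnot(length(weight) == nrow(pts), all(weight >= 0))
  uv <- torus_uv(pts, model$center, model$axis, model$ring_radius)
  data.frame(u = uv[, "u"], v = uv[, "v"], weight = weight)
}

#' Weighted density profile of projected points
#'
#' Weighted histogram along the `u` (radial) or `v` (axial) coordinate; the
#' total bin mass equals the total weight (points outside the break range
#' are clamped into the edge bins so mass is conserved).
#'
#' @param projected A [circular_project()] data.frame.
#' @param axis `"u"` or `"v"`.
#' @param bins Number of bins (>= 1) or a vector of break points.
#' @return A data.frame `lower`, `upper`, `mass`.
#' @export
density_profile <- function(projected, axis = c("u", "v"), bins = 20) {
  axis <- match.arg(axis)
  x <- projected[[axis]]
  w <- projected$weight
  if (length(x) == 0L) {
    breaks <- if (length(bins) > 1L) bins else seq(0, 1, length.out = bins + 1L)
    return(data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                      mass = 0))
  }
  if (length(bins) == 1L) {
    stopifnot(bins >= 1)
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    breaks <- sort(bins)
  }
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- vapply(seq_len(length(breaks) - 1L), function(b) {
    sum(w[idx == b])
  }, 0)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             mass = mass)
}

#' Synapse occupancy per neuron group and compartment domain
#'
#' Output-synapse counts (T-bar rows of the group's neurons, weight-summed)
#' per domain of a compartment model — e.g. which annular EB domains or FB
#' layers a lineage's output targets. Totals are conserved: the matrix sum
#' equals the group-filtered connector weight in the listed domains.
#'
#' @param connectors A [connector_table()].
#' @param model A [compartment_model()] (positions are re-looked-up, so
#'   domain-level names are used even if rows carry parent labels).
#' @param grouping Named character vector neuron_id -> group.
#' @param domains Domains (columns); default: all region names in the model.
#' @param kinds Connector kinds counted (default `"TBAR"`: output synapses).
#' @return Numeric matrix, groups x domains.
#' @export
domain_occupancy <- function(connectors, model, grouping, domains = NULL,
                             kinds = "TBAR") {
  if (is.null(domains)) {
    domains <- vapply(model$regions, `[[`, "", "name")
  }
  rows <- connectors[connectors$kind %in% kinds &
                       connectors$pre %in% names(grouping), , drop = FALSE]
  dom <- region_of(as.matrix(rows[, c("x", "y", "z")]), model)
  groups <- sort(unique(unname(grouping)))
  m <- matrix(0, nrow = length(groups), ncol = length(domains),
              dimnames = list(groups, domains))
  keep <- dom %in% domains
  if (any(keep)) {
    g <- unname(grouping[rows$pre[keep]])
    agg <- tapply(rows$weight[keep],
                  list(factor(g, levels = groups),
                       factor(dom[keep], levels = domains)), sum)
    agg[is.na(agg)] <- 0
    m[] <- agg
  }
  m
}

#' Modal output layer of each neuron
#'
#' The layer (among `layer_regions`, ordered ventral to dorsal) containing
#' the plurality of a neuron's output synapses; ties resolve to the lower
#' layer index. Neurons with no output synapse in any layer get `NA`.
#'
#' @param connectors A [connector_table()] with compartment labels at
#'   domain resolution.
#' @param neuron_set Neuron ids.
#' @param layer_regions Ordered character vector of layer region names
#'   (index 1 = first element).
#' @return Named integer vector of layer indices.
#' @export
modal_output_layer <- function(connectors, neuron_set, layer_regions) {
  rows <- connectors[connectors$kind == "TBAR" &
                       connectors$compartment %in% layer_regions, ,
                     drop = FALSE]
  vapply(neuron_set, function(n) {
    mine <- rows[rows$pre == n, , drop = FALSE]
    if (nrow(mine) == 0L) return(NA_integer_)
    counts <- vapply(layer_regions, function(r) {
      sum(mine$weight[mine$compartment == r])
    }, 0)
    which.max(counts)  # first max = lower layer index on ties
  }, NA_integer_)
}

#' Topography statistic: dendrite position versus output layer
#'
#' For each neuron: the centroid of its dendritic (PSD-side) synapses
#' outside the excluded compartments, projected onto a configured
#' anatomical axis, against the index of the layer holding the plurality of
#' its output synapses. Returns the Spearman rank correlation per lineage
#' and pooled; lineages with fewer than `min_n` informative neurons are
#' reported as `NA`.
#'
#' @param catalog Lineage catalog with `neuron_id`, `lineage`.
#' @param connectors A [connector_table()] with domain-level compartments.
#' @param layer_regions Ordered layer names (see [modal_output_layer()]).
#' @param axis Anatomical unit vector the dendrite centroid is projected on
#'   (e.g. the posterior direction).
#' @param exclude_regions Compartments excluded from the dendrite centroid
#'   (default: the layer regions themselves).
#' @param min_n Minimum informative neurons per lineage (default 3).
#' @return A list: `per_neuron` data.frame (`neuron_id`, `lineage`,
#'   `centroid_coord`, `layer`), `by_lineage` data.frame (`lineage`, `rho`,
#'   `n`), `rho` (pooled), `n`.
#' @export
topography_correlation <- function(catalog, connectors, layer_regions,
                                   axis, exclude_regions = layer_regions,
                                   min_n = 3) {
  axis <- unit_vector(axis)
  neurons <- catalog$neuron_id
  layer <- modal_output_layer(connectors, neurons, layer_regions)
  dend <- connectors[connectors$kind == "PSD" &
                       connectors$post %in% neurons &
                       (is.na(connectors$compartment) |
                          !connectors$compartment %in% exclude_regions), ,
                     drop = FALSE]
  coord <- vapply(neurons, function(n) {
    mine <- dend[dend$post == n, , drop = FALSE]
    if (nrow(mine) == 0L) return(NA_real_)
    ctr <- c(
      stats::weighted.mean(mine$x, mine$weight),
      stats::weighted.mean(mine$y, mine$weight),
      stats::weighted.mean(mine$z, mine$weight)
    )
    sum(ctr * axis)
  }, 0)
  per_neuron <- data.frame(neuron_id = neurons, lineage = catalog$lineage,
                           centroid_coord = unname(coord),
                           layer = unname(layer), row.names = NULL)
  ok <- !is.na(per_neuron$centroid_coord) & !is.na(per_neuron$layer)
  spearman <- function(x, y) {
    if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y, method = "spearman")
  }
  by_lineage <- do.call(rbind, lapply(
    sort(unique(stats::na.omit(per_neuron$lineage))), function(lin) {
      sel <- ok & !is.na(per_neuron$lineage) & per_neuron$lineage == lin
      data.frame(
        lineage = lin,
        rho = if (sum(sel) < min_n) NA_real_ else
          spearman(per_neuron$centroid_coord[sel], per_neuron$layer[sel]),
        n = sum(sel)
      )
    }))
  list(per_neuron = per_neuron, by_lineage = by_lineage,
       rho = spearman(per_neuron$centroid_coord[ok], per_neuron$layer[ok]),
       n = sum(ok))
}
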