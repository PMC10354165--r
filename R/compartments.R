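#' Construct a compartment model
#'
#' A compartment model is an ordered list of named analytic volumes giving a
#' total point-to-region membership function: every point maps to exactly one
#' region name or `"unassigned"`. Regions are closed (boundary points belong
#' to the region) and overlaps are resolved by priority: the first region in
#' the list that contains a point wins.
#'
#' Supported primitives:
#' \describe{
#'   \item{box}{`center` (3-vector nm), `half` (3-vector of half-extents nm).}
#'   \item{sphere}{`center`, `radius` (nm).}
#'   \item{slab}{`normal` (unit 3-vector), `range` (`c(min, max)` of the
#'     signed offset `<p, normal>` in nm), optional `clip` box
#'     (`list(center, half)`) bounding the slab laterally.}
#'   \item{torus_sector}{`center`, `axis` (unit 3-vector, ring symmetry
#'     axis), `ring_radius`, `tube_radius` (nm), optional `u_range` /
#'     `v_range` restricting the tube cross-section (u = distance from axis
#'     minus ring radius, v = signed offset along the axis).}
#' }
#'
#' Each region may carry a `parent` (e.g. annular domains `EBa`..`EBop`
#' roll up to `EB`) and a logical `mirror` flag: mirrored regions also
#' contain the reflection of a point across the midline plane, giving
#' bilateral compartments a single name.
#'
#' @param regions List of region definitions (`list(name =, primitive =,
#'   ...)`) in priority order.
#' @param midline Midline plane as `list(point =, normal =)`; defaults to
#'   the x = 0 plane.
#' @return An object of class `compartment_model`.
#' @export
compartment_model <- function(regions,
                              midline = list(point = c(0, 0, 0),
                                             normal = c(1, 0, 0))) {
  stopifnot(is.list(regions))
  for (r in regions) {
    if (is.null(r$name) || is.null(r$primitive)) {
      stop("each region needs a name and a primitive")
    }
    if (!r$primitive %in% c("box", "sphere", "slab", "torus_sector")) {
      stop("unknown primitive '", r$primitive, "' in region ", r$name)
    }
  }
  midline$normal <- unit_vector(midline$normal)
  structure(list(regions = regions, midline = midline),
            class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf("<compartment_model> %d regions: %s\n", length(x$regions),
              paste(vapply(x$regions, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

# membership of points (n x 3 matrix) in a single region primitive
region_contains <- function(region, pts, midline) {
  inside <- primitive_contains(region, pts)
  if (isTRUE(region$mirror)) {
    inside <- inside | primitive_contains(region, reflect_points(pts, midline))
  }
  inside
}

primitive_contains <- function(region, pts) {
  switch(region$primitive,
    box = {
      c0 <- region$center; h <- region$half
      abs(pts[, 1] - c0[1]) <= h[1] &
        abs(pts[, 2] - c0[2]) <= h[2] &
        abs(pts[, 3] - c0[3]) <= h[3]
    },
    sphere = {
      c0 <- region$center
      (pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2 +
        (pts[, 3] - c0[3])^2 <= region$radius^2
    },
    slab = {
      n <- unit_vector(region$normal)
      s <- pts %*% n
      ok <- s >= region$range[1] & s <= region$range[2]
      if (!is.null(region$clip)) {
        cl <- region$clip
        ok <- ok &
          abs(pts[, 1] - cl$center[1]) <= cl$half[1] &
          abs(pts[, 2] - cl$center[2]) <= cl$half[2] &
          abs(pts[, 3] - cl$center[3]) <= cl$half[3]
      }
      as.vector(ok)
    },
    torus_sector = {
      uv <- torus_uv(pts, region$center, unit_vector(region$axis),
                     region$ring_radius)
      ok <- uv[, "u"]^2 + uv[, "v"]^2 <= region$tube_radius^2
      if (!is.null(region$u_range)) {
        ok <- ok & uv[, "u"] >= region$u_range[1] & uv[, "u"] <= region$u_range[2]
      }
      if (!is.null(region$v_range)) {
        ok <- ok & uv[, "v"] >= region$v_range[1] & uv[, "v"] <= region$v_range[2]
      }
      ok
    }
  )
}

#' Map points to compartment names
#'
#' Deterministic point-to-region lookup: the first (highest-priority) region
#' containing a point names it; points in no region are `"unassigned"`.
#' Region boundaries are inclusive.
#'
#' @param points A 3-vector or an n x 3 matrix of nm coordinates.
#' @param model A [compartment_model()].
#' @return Character vector of region names.
#' @export
region_of <- function(points, model) {
  pts <- as_point_matrix(points)
  out <- rep("unassigned", nrow(pts))
  todo <- rep(TRUE, nrow(pts))
  for (region in model$regions) {
    if (!any(todo)) break
    hit <- region_contains(region, pts[todo, , drop = FALSE], model$midline)
    out[todo][hit] <- region$name
    todo[todo] <- !hit
  }
  out
}

#' Roll region names up to their parent compartments
#'
#' E.g. the annular EB domains `EBa`..`EBop` aggregate to `EB`, the nine FB
#' layer slabs to `FB`. Names without a declared parent are returned as-is.
#'
#' @param region_names Character vector of region names.
#' @param model A [compartment_model()].
#' @return Character vector of parent compartment names.
#' @export
parent_region <- function(region_names, model) {
  parents <- vapply(model$regions, function(r) {
    if (is.null(r$parent)) r$name else r$parent
  }, character(1))
  names(parents) <- vapply(model$regions, `[[`, "", "name")
  hit <- region_names %in% names(parents)
  region_names[hit] <- parents[region_names[hit]]
  region_names
}

#' Region names belonging to a parent compartment
#'
#' @param parent Parent compartment name (e.g. `"EB"`).
#' @param model A [compartment_model()].
#' @return Character vector of region names whose parent (or own name)
#'   matches.
#' @export
child_regions <- function(parent, model) {
  nm <- vapply(model$regions, `[[`, "", "name")
  pa <- vapply(model$regions, function(r) {
    if (is.null(r$parent)) r$name else r$parent
  }, character(1))
  nm[pa %in% parent | nm %in% parent]
}

#' Hemisphere of points relative to the midline plane
#'
#' The hemisphere is the sign of the coordinate normal to the declared
#' midline plane: positive offsets are `RIGHT`, negative `LEFT`, points on
#' the plane `UNKNOWN`.
#'
#' @param points 3-vector or n x 3 matrix (nm).
#' @param model A [compartment_model()] (supplies the midline plane).
#' @return Character vector in `{"LEFT","RIGHT","UNKNOWN"}`.
#' @export
hemisphere_of <- function(points, model) {
  pts <- as_point_matrix(points)
  s <- sweep(pts, 2, model$midline$point) %*% model$midline$normal
  out <- rep("UNKNOWN", nrow(pts))
  out[s > 0] <- "RIGHT"
  out[s < 0] <- "LEFT"
  out
}

#' Read / write compartment models as JSON
#'
#' @param path JSON path.
#' @return [read_compartments()]: a [compartment_model()].
#' @export
read_compartments <- function(path) {
  if (!file.exists(path)) stop("compartment JSON not found: ", path)
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  regions <- lapply(spec$regions, function(r) {
    for (f in c("center", "half", "normal", "axis", "range", "u_range",
                "v_range")) {
      if (!is.null(r[[f]])) r[[f]] <- as.numeric(unlist(r[[f]]))
    }
    if (!is.null(r$clip)) {
      r$clip$center <- as.numeric(unlist(r$clip$center))
      r$clip$half <- as.numeric(unlist(r$clip$half))
    }
    r
  })
  midline <- list(point = as.numeric(unlist(spec$midline$point)),
                  normal = as.numeric(unlist(spec$midline$normal)))
  compartment_model(regions, midline)
}

#' @rdname read_compartments
#' @param model A [compartment_model()].
#' @export
write_compartments <- function(model, path) {
  jsonlite::write_json(list(midline = model$midline, regions = model$regions),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# --- small geometry helpers -------------------------------------------------

unit_vector <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalised")
  v / n
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 3)
  storage.mode(pts) <- "double"
  pts
}

reflect_points <- function(pts, midline) {
  n <- midline$normal
  s <- as.vector(sweep(pts, 2, midline$point) %*% n)
  pts - 2 * outer(s, n)
}

# (u, v) tube cross-section coordinates relative to a torus axis model:
# v = signed offset along the axis, u = distance from the axis minus the
# ring radius.  Azimuth is deliberately not computed.
torus_uv <- function(pts, center, axis, ring_radius) {
  w <- sweep(as_point_matrix(pts), 2, center)
  v <- as.vector(w %*% axis)
  radial <- w - outer(v, axis)
  d <- sqrt(rowSums(radial^2))
  cbind(u = d - ring_radius, v = v)
}
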