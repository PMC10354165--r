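#' Construct a neuron skeleton
#'
#' A skeleton is a rooted tree of 3-D nodes in nanometres, the unit consumed
#' by the backbone-extraction algorithm. Exactly one node is the root
#' (`parent_id` is `NA`); every other node's parent must resolve and the
#' parent relation must be acyclic.
#'
#' @param neuron_id Identifier of the neuron (coerced to character).
#' @param nodes A data.frame with columns `node_id` (integer), `parent_id`
#'   (integer, `NA` for the root), `x`, `y`, `z` (nm), `radius` (nm, >= 0).
#' @param soma_node Optional `node_id` of the soma; defaults to the root.
#' @param validate Run structural validation (default `TRUE`).
#' @return An object of class `skeleton`: a list with elements `neuron_id`,
#'   `nodes` and `soma_node`.
#' @export
skeleton <- function(neuron_id, nodes, soma_node = NULL, validate = TRUE) {
  required <- c("node_id", "parent_id", "x", "y", "z", "radius")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("skeleton nodes missing columns: ", paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  obj <- structure(
    list(neuron_id = as.character(neuron_id), nodes = nodes,
         soma_node = soma_node),
    class = "skeleton"
  )
  if (validate) validate_skeleton(obj)
  if (is.null(obj$soma_node) && nrow(nodes) > 0L) {
    obj$soma_node <- nodes$node_id[is.na(nodes$parent_id)][1L]
  }
  obj
}

#' Validate skeleton structure
#'
#' Checks the tree invariants: unique node ids, exactly one root, parent
#' references resolve, no cycles, finite coordinates and non-negative radii.
#' Errors name the offending node so malformed SWC exports are diagnosable.
#'
#' @param skel A [skeleton()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_skeleton <- function(skel) {
  nodes <- skel$nodes
  if (nrow(nodes) == 0L) return(invisible(TRUE))
  if (anyDuplicated(nodes$node_id)) {
    dup <- nodes$node_id[duplicated(nodes$node_id)][1L]
    stop("duplicate node id ", dup)
  }
  roots <- nodes$node_id[is.na(nodes$parent_id)]
  if (length(roots) == 0L) stop("no root node (parent -1) found")
  if (length(roots) > 1L) {
    stop("multiple roots: nodes ", paste(roots, collapse = ", "))
  }
  has_parent <- !is.na(nodes$parent_id)
  pidx <- match(nodes$parent_id[has_parent], nodes$node_id)
  if (anyNA(pidx)) {
    bad <- nodes$parent_id[has_parent][is.na(pidx)][1L]
    stop("dangling parent ", bad)
  }
  # cycle check: follow parents from every node; a tree visits the root in
  # <= n steps.  Vectorised pointer-jumping keeps this O(n log n).
  parent_of <- rep(NA_integer_, nrow(nodes))
  parent_of[has_parent] <- pidx
  reach <- parent_of
  for (step in seq_len(ceiling(log2(nrow(nodes))) + 1L)) {
    nxt <- reach
    ok <- !is.na(nxt)
    nxt[ok] <- reach[nxt[ok]]
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  if (any(!is.na(reach))) {
    # some node never reached the root: its parent chain loops
    bad <- nodes$node_id[which(!is.na(reach))[1L]]
    stop("cycle detected involving node ", bad)
  }
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    bad <- nodes$node_id[!stats::complete.cases(nodes[, c("x", "y", "z")]) |
                           !is.finite(nodes$x) | !is.finite(nodes$y) | !is.finite(nodes$z)][1L]
    stop("non-finite coordinate at node ", bad)
  }
  if (any(nodes$radius < 0, na.rm = TRUE)) {
    stop("negative radius at node ", nodes$node_id[which(nodes$radius < 0)[1L]])
  }
  if (!is.null(skel$soma_node) && !skel$soma_node %in% nodes$node_id) {
    stop("soma node ", skel$soma_node, " not present in skeleton")
  }
  invisible(TRUE)
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> neuron %s: %d nodes, cable %.0f nm\n",
              x$neuron_id, nrow(x$nodes), skeleton_cable_length(x)))
  invisible(x)
}

#' Total cable length of a skeleton (nm)
#'
#' Sum of Euclidean parent-child edge lengths.
#'
#' @param skel A [skeleton()].
#' @return Cable length in nm.
#' @export
skeleton_cable_length <- function(skel) {
  nodes <- skel$nodes
  has_parent <- !is.na(nodes$parent_id)
  if (!any(has_parent)) return(0)
  pidx <- match(nodes$parent_id[has_parent], nodes$node_id)
  dx <- nodes$x[has_parent] - nodes$x[pidx]
  dy <- nodes$y[has_parent] - nodes$y[pidx]
  dz <- nodes$z[has_parent] - nodes$z[pidx]
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' Read a skeleton from an SWC file
#'
#' SWC is the standard whitespace-delimited skeleton format with columns
#' `id type x y z r parent` (`#` comments). Coordinates are converted to the
#' package's internal nanometre scale: micrometre files are scaled by 1000
#' and voxel-indexed exports (e.g. 8 nm isotropic EM voxels) by
#' `voxel_size_nm`.
#'
#' @param path Path to an SWC file.
#' @param units Units of the file's coordinates: `"nm"` or `"um"`.
#' @param voxel_size_nm Multiplier applied after unit conversion for
#'   voxel-indexed exports (default 1; use 8 for 8 nm voxel grids).
#' @param neuron_id Neuron identifier; defaults to the file name sans
#'   extension.
#' @return A validated [skeleton()] in nm.
#' @export
read_swc <- function(path, units = c("nm", "um"), voxel_size_nm = 1,
                     neuron_id = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("SWC file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("node_id", "type", "x", "y", "z",
                                         "radius", "parent_id"),
                           colClasses = c("integer", "integer", "numeric",
                                          "numeric", "numeric", "numeric",
                                          "integer"))
  scale <- (if (units == "um") 1000 else 1) * voxel_size_nm
  tab$x <- tab$x * scale
  tab$y <- tab$y * scale
  tab$z <- tab$z * scale
  tab$radius <- tab$radius * scale
  tab$parent_id[tab$parent_id < 0L] <- NA_integer_
  if (is.null(neuron_id)) {
    neuron_id <- sub("\\.swc$", "", basename(path), ignore.case = TRUE)
  }
  soma <- tab$node_id[tab$type == 1L]
  soma <- if (length(soma) >= 1L) soma[1L] else NULL
  skel <- skeleton(neuron_id, tab[, c("node_id", "parent_id", "x", "y", "z",
                                      "radius")],
                   soma_node = soma)
  attr(skel, "swc_type") <- tab$type
  skel
}

#' Write a skeleton to an SWC file
#'
#' Inverse of [read_swc()]; coordinates are written in the requested units.
#'
#' @param skel A [skeleton()].
#' @param path Output path.
#' @param units `"nm"` (default) or `"um"`.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(skel, path, units = c("nm", "um")) {
  units <- match.arg(units)
  scale <- if (units == "um") 1 / 1000 else 1
  nodes <- skel$nodes
  type <- attr(skel, "swc_type")
  if (is.null(type) || length(type) != nrow(nodes)) {
    type <- rep(0L, nrow(nodes))
    if (!is.null(skel$soma_node)) {
      type[match(skel$soma_node, nodes$node_id)] <- 1L
    }
  }
  out <- data.frame(
    id = nodes$node_id, type = type,
    x = nodes$x * scale, y = nodes$y * scale, z = nodes$z * scale,
    r = nodes$radius * scale,
    parent = ifelse(is.na(nodes$parent_id), -1L, nodes$parent_id)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC (%s) neuron %s", units, skel$neuron_id), con)
  utils::write.table(format(out, trim = TRUE, digits = 15, scientific = FALSE),
                     con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read every SWC file in a directory
#'
#' @param dir Directory containing `*.swc` files.
#' @inheritParams read_swc
#' @return A named list of [skeleton()] objects keyed by neuron id.
#' @export
read_swc_dir <- function(dir, units = c("nm", "um"), voxel_size_nm = 1) {
  units <- match.arg(units)
  files <- sort(list.files(dir, pattern = "\\.swc$", ignore.case = TRUE,
                           full.names = TRUE))
  skels <- lapply(files, read_swc, units = units,
                  voxel_size_nm = voxel_size_nm)
  names(skels) <- vapply(skels, function(s) s$neuron_id, character(1))
  skels
}

# --- internal skeleton topology helpers ------------------------------------

# parent index (position, not id) per node; NA at root
skel_parent_index <- function(nodes) {
  idx <- rep(NA_integer_, nrow(nodes))
  has <- !is.na(nodes$parent_id)
  idx[has] <- match(nodes$parent_id[has], nodes$node_id)
  idx
}

# undirected degree per node (parent edge + child edges)
skel_degree <- function(nodes) {
  pidx <- skel_parent_index(nodes)
  deg <- tabulate(pidx, nbins = nrow(nodes))
  deg + as.integer(!is.na(pidx))
}

# drop the given node ids, keeping the remaining nodes' parent pointers
# valid (only ever used to remove whole terminal twigs, so no re-rooting
# is needed)
skel_drop_nodes <- function(skel, drop_ids) {
  nodes <- skel$nodes
  keep <- !(nodes$node_id %in% drop_ids)
  nodes <- nodes[keep, , drop = FALSE]
  nodes$parent_id[!(nodes$parent_id %in% nodes$node_id)] <- NA_integer_
  # removing terminal branches never orphans interior nodes; the only NA
  # parents after the filter are the original root
  skel$nodes <- nodes
  if (!is.null(attr(skel, "swc_type"))) {
    attr(skel, "swc_type") <- attr(skel, "swc_type")[keep]
  }
  skel
}
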