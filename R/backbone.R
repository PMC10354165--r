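#' Parameters of the tract-backbone extraction
#'
#' Defaults follow the published rule set: terminal twigs below 15 nodes
#' (about 120 nm at 8 nm node spacing) are pruned unless they carry a
#' connector; fragments above 2500 nm of cable are kept outright; smaller
#' fragments survive only if longer than 80 nm with fewer connectors than 1%
#' of the numerical value of their cable length in nm; surviving small
#' fragments shorter than the largest fragment's length divided by 2.5 are
#' dropped; and fragments more than 5000 nm from both ends of the largest
#' fragment are trimmed away.
#'
#' @param twig_node_max Terminal branches with fewer nodes than this are
#'   pruning candidates (default 15 nodes, about 120 nm).
#' @param large_fragment_min_len Cable length (nm) above which a fragment is
#'   kept unconditionally (default 2500).
#' @param small_fragment_min_len Minimum cable length (nm) for a small
#'   fragment to be considered at all (default 80).
#' @param connector_density_max Maximum connectors per nm of cable for small
#'   fragments (default 0.01, i.e. "1% of the numerical value of the cable
#'   length" in nm).
#' @param relative_length_factor Small fragments shorter than
#'   `largest / relative_length_factor` are discarded (default 2.5).
#' @param distal_trim_distance Fragments farther than this (nm) from both
#'   endpoints of the largest fragment are discarded (default 5000).
#' @param connector_map_radius Connectors are mapped to their nearest
#'   skeleton node within this radius (nm, default 250); farther connectors
#'   are ignored.
#' @param relative_rule `"ratio"` (default) discards small fragments with
#'   `length < largest / relative_length_factor`; `"literal"` applies the
#'   rule text verbatim (`length < relative_length_factor * largest`), which
#'   discards every non-largest small fragment.
#' @return A list of class `backbone_params`.
#' @export
backbone_params <- function(twig_node_max = 15,
                            large_fragment_min_len = 2500,
                            small_fragment_min_len = 80,
                            connector_density_max = 0.01,
                            relative_length_factor = 2.5,
                            distal_trim_distance = 5000,
                            connector_map_radius = 250,
                            relative_rule = c("ratio", "literal")) {
  relative_rule <- match.arg(relative_rule)
  p <- list(twig_node_max = twig_node_max,
            large_fragment_min_len = large_fragment_min_len,
            small_fragment_min_len = small_fragment_min_len,
            connector_density_max = connector_density_max,
            relative_length_factor = relative_length_factor,
            distal_trim_distance = distal_trim_distance,
            connector_map_radius = connector_map_radius,
            relative_rule = relative_rule)
  num <- p[1:7]
  if (any(unlist(num) <= 0)) stop("all backbone parameters must be > 0")
  if (connector_density_max >= 1) {
    stop("connector_density_max must be < 1 connector per nm")
  }
  class(p) <- "backbone_params"
  p
}

#' Map connectors onto skeleton nodes
#'
#' Each connector touching the neuron (as pre or post) is attached to the
#' nearest skeleton node within `connector_map_radius`; connectors with no
#' node in range are left unmapped and ignored by the pruning rules.
#'
#' @param skel A [skeleton()].
#' @param connectors A [connector_table()] (may cover many neurons).
#' @param map_radius Search radius in nm.
#' @return Integer vector of mapped connector counts, one per skeleton node
#'   (weights summed).
#' @export
map_connectors_to_nodes <- function(skel, connectors, map_radius = 250) {
  nodes <- skel$nodes
  counts <- integer(nrow(nodes))
  if (is.null(connectors) || nrow(connectors) == 0L || nrow(nodes) == 0L) {
    return(counts)
  }
  mine <- connectors$pre == skel$neuron_id | connectors$post == skel$neuron_id
  if (!any(mine)) return(counts)
  cpts <- as.matrix(connectors[mine, c("x", "y", "z")])
  w <- connectors$weight[mine]
  npts <- as.matrix(nodes[, c("x", "y", "z")])
  for (i in seq_len(nrow(cpts))) {
    d2 <- (npts[, 1] - cpts[i, 1])^2 + (npts[, 2] - cpts[i, 2])^2 +
      (npts[, 3] - cpts[i, 3])^2
    j <- which.min(d2)
    if (d2[j] <= map_radius^2) counts[j] <- counts[j] + w[i]
  }
  counts
}

#' Prune connector-free terminal twigs
#'
#' Iteratively removes terminal branches (the run of nodes from a tip up to,
#' but excluding, the nearest branch point) that have fewer than
#' `twig_node_max` nodes and no mapped connector, until no further branch
#' qualifies. Skeletons that are a single unbranched path are returned
#' unchanged (there is no branch to isolate).
#'
#' @param skel A [skeleton()].
#' @param connectors A [connector_table()] or `NULL`.
#' @param params A [backbone_params()].
#' @param node_connectors Optional precomputed per-node connector counts
#'   (from [map_connectors_to_nodes()]); computed if missing.
#' @return The pruned [skeleton()].
#' @export
prune_twigs <- function(skel, connectors = NULL, params = backbone_params(),
                        node_connectors = NULL) {
  if (nrow(skel$nodes) == 0L) return(skel)
  if (is.null(node_connectors)) {
    node_connectors <- map_connectors_to_nodes(skel, connectors,
                                               params$connector_map_radius)
  }
  names(node_connectors) <- as.character(skel$nodes$node_id)
  repeat {
    nodes <- skel$nodes
    deg <- skel_degree(nodes)
    if (!any(deg >= 3L)) break  # unbranched: nothing to isolate
    tips <- which(deg == 1L)
    pidx <- skel_parent_index(nodes)
    children <- lapply(seq_len(nrow(nodes)), function(i) integer(0))
    for (i in which(!is.na(pidx))) {
      children[[pidx[i]]] <- c(children[[pidx[i]]], i)
    }
    drop_ids <- integer(0)
    for (tip in tips) {
      twig <- integer(0)
      cur <- tip
      repeat {
        if (deg[cur] >= 3L) break  # branch point: twig ends before it
        twig <- c(twig, cur)
        # step to the unique neighbour not yet visited
        nbrs <- c(pidx[cur], children[[cur]])
        nbrs <- nbrs[!is.na(nbrs) & !(nbrs %in% twig)]
        if (length(nbrs) == 0L) { twig <- integer(0); break }  # whole path
        cur <- nbrs[1L]
      }
      if (length(twig) > 0L && length(twig) < params$twig_node_max) {
        twig_ids <- nodes$node_id[twig]
        if (sum(node_connectors[as.character(twig_ids)]) == 0L) {
          drop_ids <- c(drop_ids, twig_ids)
        }
      }
    }
    if (length(drop_ids) == 0L) break
    skel <- skel_drop_nodes(skel, unique(drop_ids))
    node_connectors <- node_connectors[as.character(skel$nodes$node_id)]
  }
  skel
}

#' Cut a skeleton into unbranched fragments
#'
#' Neurons are cut at each branch point (undirected degree >= 3): fragments
#' are the maximal paths containing no internal branch node. Branch-point
#' nodes are duplicated into each incident fragment, so fragments partition
#' the edge set.
#'
#' @param skel A [skeleton()].
#' @param node_connectors Optional per-node connector counts; fragments then
#'   carry a `connector_count` (branch-point connectors count in every
#'   incident fragment).
#' @return List of fragments; each is a list with `node_ids` (ordered path),
#'   `cable_length` (nm) and `connector_count`.
#' @export
fragment_at_branchpoints <- function(skel, node_connectors = NULL) {
  nodes <- skel$nodes
  n <- nrow(nodes)
  if (n <= 1L) return(list())
  if (is.null(node_connectors)) node_connectors <- integer(n)
  pidx <- skel_parent_index(nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (i in which(!is.na(pidx))) {
    adj[[i]] <- c(adj[[i]], pidx[i])
    adj[[pidx[i]]] <- c(adj[[pidx[i]]], i)
  }
  deg <- lengths(adj)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  frags <- list()
  visited_edge <- new.env(hash = TRUE)
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  starts <- which(deg != 2L)  # tips and branch points
  if (length(starts) == 0L) starts <- 1L  # cycle-free guarantee: unreachable
  for (s in starts) {
    for (first in adj[[s]]) {
      if (!is.null(visited_edge[[edge_key(s, first)]])) next
      path <- c(s, first)
      assign(edge_key(s, first), TRUE, envir = visited_edge)
      prev <- s; cur <- first
      while (deg[cur] == 2L) {
        nxt <- setdiff(adj[[cur]], prev)
        assign(edge_key(cur, nxt), TRUE, envir = visited_edge)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      seg <- xyz[path, , drop = FALSE]
      steps <- sqrt(rowSums((seg[-1, , drop = FALSE] -
                               seg[-nrow(seg), , drop = FALSE])^2))
      frags[[length(frags) + 1L]] <- list(
        node_ids = nodes$node_id[path],
        cable_length = sum(steps),
        connector_count = sum(node_connectors[path])
      )
    }
  }
  frags
}

#' Select tract fragments by the length / connector-density rules
#'
#' Fragments longer than `large_fragment_min_len` are kept unconditionally.
#' Smaller fragments are kept only if longer than `small_fragment_min_len`
#' and carrying fewer connectors than `connector_density_max` per nm of
#' cable; of these, fragments failing the relative-length rule against the
#' largest fragment are then discarded.
#'
#' @param frags Fragment list from [fragment_at_branchpoints()].
#' @param params A [backbone_params()].
#' @return The retained fragments.
#' @export
select_fragments <- function(frags, params = backbone_params()) {
  if (length(frags) == 0L) return(frags)
  len <- vapply(frags, `[[`, 0, "cable_length")
  ncon <- vapply(frags, `[[`, 0, "connector_count")
  large <- len > params$large_fragment_min_len
  small_ok <- !large &
    len > params$small_fragment_min_len &
    ncon < params$connector_density_max * len
  largest <- max(len)
  cutoff <- if (params$relative_rule == "ratio") {
    largest / params$relative_length_factor
  } else {
    params$relative_length_factor * largest
  }
  small_ok <- small_ok & len >= cutoff
  frags[large | small_ok]
}

#' Trim fragments distal to the largest fragment
#'
#' Keeps the largest fragment and every fragment whose minimum node-to-point
#' distance to at least one endpoint of the largest fragment is within
#' `distal_trim_distance`. This removes terminal-arbor fragments that the
#' length rules occasionally admit.
#'
#' @param frags Fragment list (post-selection).
#' @param skel The parent [skeleton()] (for node coordinates).
#' @param params A [backbone_params()].
#' @return The retained fragments.
#' @export
trim_distal_fragments <- function(frags, skel, params = backbone_params()) {
  if (length(frags) <= 1L) return(frags)
  len <- vapply(frags, `[[`, 0, "cable_length")
  imax <- which.max(len)
  nodes <- skel$nodes
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(xyz) <- as.character(nodes$node_id)
  ends <- frags[[imax]]$node_ids[c(1L, length(frags[[imax]]$node_ids))]
  epts <- xyz[as.character(ends), , drop = FALSE]
  keep <- vapply(seq_along(frags), function(i) {
    if (i == imax) return(TRUE)
    fp <- xyz[as.character(frags[[i]]$node_ids), , drop = FALSE]
    dmin <- min(vapply(seq_len(nrow(epts)), function(e) {
      min(sqrt((fp[, 1] - epts[e, 1])^2 + (fp[, 2] - epts[e, 2])^2 +
                 (fp[, 3] - epts[e, 3])^2))
    }, 0))
    dmin <= params$distal_trim_distance
  }, logical(1))
  frags[keep]
}

#' Extract the lineage-tract backbone of a neuron
#'
#' Composition of the four cleaning steps: connector-aware twig pruning,
#' cutting at branch points, fragment selection by the length and
#' connector-density rules, and distal trimming relative to the largest
#' fragment. The result is the neuron's tract backbone.
#'
#' @param skel A [skeleton()].
#' @param connectors A [connector_table()] or `NULL`.
#' @param params A [backbone_params()].
#' @return A list of class `backbone`: `neuron_id`, `fragments` (see
#'   [fragment_at_branchpoints()]), `node_ids` (union, in skeleton order),
#'   `skeleton` (the pruned skeleton). Neurons whose fragments all fail the
#'   rules yield an empty backbone with a warning.
#' @export
extract_backbone <- function(skel, connectors = NULL,
                             params = backbone_params()) {
  node_connectors <- map_connectors_to_nodes(skel, connectors,
                                             params$connector_map_radius)
  names(node_connectors) <- as.character(skel$nodes$node_id)
  pruned <- prune_twigs(skel, params = params,
                        node_connectors = node_connectors)
  nc <- node_connectors[as.character(pruned$nodes$node_id)]
  frags <- fragment_at_branchpoints(pruned, node_connectors = nc)
  frags <- select_fragments(frags, params)
  frags <- trim_distal_fragments(frags, pruned, params)
  ids <- unique(unlist(lapply(frags, `[[`, "node_ids")))
  if (length(ids) == 0L) {
    warning("neuron ", skel$neuron_id, ": no fragment passed the backbone ",
            "rules; backbone is empty")
  }
  structure(list(neuron_id = skel$neuron_id, fragments = frags,
                 node_ids = skel$nodes$node_id[skel$nodes$node_id %in% ids],
                 skeleton = pruned),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> neuron %s: %d fragment(s), %d nodes\n",
              x$neuron_id, length(x$fragments), length(x$node_ids)))
  invisible(x)
}

#' Ordered coordinates of the backbone's main path
#'
#' The main path is the largest (longest-cable) fragment, oriented with the
#' end nearest the soma first — the polyline used for portal crossings.
#'
#' @param backbone A [extract_backbone()] result.
#' @param soma_position Optional 3-vector; defaults to the pruned skeleton's
#'   soma/root node position.
#' @return An n x 3 matrix of nm coordinates (0 rows if the backbone is
#'   empty).
#' @export
backbone_main_path <- function(backbone, soma_position = NULL) {
  if (length(backbone$fragments) == 0L) {
    return(matrix(numeric(0), ncol = 3))
  }
  len <- vapply(backbone$fragments, `[[`, 0, "cable_length")
  frag <- backbone$fragments[[which.max(len)]]
  nodes <- backbone$skeleton$nodes
  xyz <- as.matrix(nodes[match(frag$node_ids, nodes$node_id),
                         c("x", "y", "z")])
  if (is.null(soma_position)) {
    soma_id <- backbone$skeleton$soma_node
    if (is.null(soma_id) || !soma_id %in% nodes$node_id) {
      soma_id <- nodes$node_id[is.na(nodes$parent_id)][1L]
    }
    soma_position <- as.numeric(nodes[match(soma_id, nodes$node_id),
                                      c("x", "y", "z")])
  }
  d_first <- sum((xyz[1L, ] - soma_position)^2)
  d_last <- sum((xyz[nrow(xyz), ] - soma_position)^2)
  if (d_last < d_first) xyz <- xyz[rev(seq_len(nrow(xyz))), , drop = FALSE]
  unname(xyz)
}

#' Per-fragment report of the backbone rules
#'
#' One row per fragment of the pruned skeleton, with its cable length,
#' connector count, whether it was kept, and the first rule that decided its
#' fate — the audit trail for the cleaning procedure.
#'
#' @inheritParams extract_backbone
#' @return A data.frame with columns `neuron_id`, `fragment_id`,
#'   `length_nm`, `n_connectors`, `kept`, `rule`.
#' @export
backbone_fragment_report <- function(skel, connectors = NULL,
                                     params = backbone_params()) {
  node_connectors <- map_connectors_to_nodes(skel, connectors,
                                             params$connector_map_radius)
  names(node_connectors) <- as.character(skel$nodes$node_id)
  pruned <- prune_twigs(skel, params = params,
                        node_connectors = node_connectors)
  nc <- node_connectors[as.character(pruned$nodes$node_id)]
  frags <- fragment_at_branchpoints(pruned, node_connectors = nc)
  if (length(frags) == 0L) {
    return(data.frame(neuron_id = character(0), fragment_id = integer(0),
                      length_nm = numeric(0), n_connectors = integer(0),
                      kept = logical(0), rule = character(0)))
  }
  len <- vapply(frags, `[[`, 0, "cable_length")
  ncon <- vapply(frags, `[[`, 0, "connector_count")
  largest <- max(len)
  cutoff <- if (params$relative_rule == "ratio") {
    largest / params$relative_length_factor
  } else {
    params$relative_length_factor * largest
  }
  selected <- select_fragments(frags, params)
  kept_sel <- vapply(frags, function(f) {
    any(vapply(selected, function(s) identical(s$node_ids, f$node_ids),
               logical(1)))
  }, logical(1))
  trimmed <- trim_distal_fragments(selected, pruned, params)
  kept_fin <- vapply(frags, function(f) {
    any(vapply(trimmed, function(s) identical(s$node_ids, f$node_ids),
               logical(1)))
  }, logical(1))
  rule <- ifelse(len > params$large_fragment_min_len, "large",
          ifelse(len <= params$small_fragment_min_len, "too_short",
          ifelse(ncon >= params$connector_density_max * len,
                 "connector_density",
          ifelse(len < cutoff, "relative_length", "small_retained"))))
  rule[kept_sel & !kept_fin] <- "distal_trim"
  data.frame(neuron_id = skel$neuron_id, fragment_id = seq_along(frags),
             length_nm = len, n_connectors = as.integer(ncon),
             kept = kept_fin, rule = rule)
}
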