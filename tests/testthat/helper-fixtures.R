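# Shared fixtures: tiny skeleton builders, random-tree generators, and an
# independent igraph-based oracle for the backbone rule set.

# straight path skeleton along +x with given node count and spacing (nm)
path_skeleton <- function(n, spacing = 8, id = "n1", origin = c(0, 0, 0)) {
  skeleton(id, data.frame(
    node_id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1L)),
    x = origin[1] + (seq_len(n) - 1L) * spacing,
    y = origin[2], z = origin[3], radius = 10))
}

# attach a straight twig of m nodes at node `at`, perpendicular (+y)
add_twig <- function(skel, at, m, spacing = 8) {
  nodes <- skel$nodes
  base <- nodes[match(at, nodes$node_id), ]
  start <- max(nodes$node_id)
  tw <- data.frame(node_id = start + seq_len(m),
                   parent_id = c(at, start + seq_len(m - 1L)),
                   x = base$x, y = base$y + seq_len(m) * spacing,
                   z = base$z, radius = 10)
  skeleton(skel$neuron_id, rbind(nodes, tw), soma_node = skel$soma_node)
}

# connector row(s) at given positions belonging to a neuron
connectors_at <- function(neuron_id, pos, kind = "TBAR", post = "partner") {
  pos <- matrix(pos, ncol = 3, byrow = is.null(dim(pos)))
  connector_table(data.frame(
    synapse_id = paste0("s", seq_len(nrow(pos))),
    pre = if (kind == "TBAR") neuron_id else post,
    post = if (kind == "TBAR") post else neuron_id,
    kind = kind, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    compartment = NA_character_, weight = 1L))
}

# random tree skeleton with <= n nodes; edge scale varied so every
# backbone rule (twig, 80 nm, 2500 nm, density, trim) gets exercised
random_skeleton <- function(n, id = "r1", scale = NULL) {
  if (is.null(scale)) scale <- sample(c(5, 40, 300, 1200), 1L)
  parent <- c(NA_integer_, vapply(2:n, function(i) {
    if (stats::runif(1) < 0.75) i - 1L else sample.int(i - 1L, 1L)
  }, 1L))
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    xyz[i, ] <- xyz[parent[i], ] + stats::rnorm(3, 0, scale)
  }
  skeleton(id, data.frame(node_id = seq_len(n), parent_id = parent,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          radius = 10))
}

# random connectors placed exactly on a subset of skeleton nodes
random_connectors <- function(skel, p = 0.15) {
  nodes <- skel$nodes
  hit <- which(stats::runif(nrow(nodes)) < p)
  if (length(hit) == 0L) return(NULL)
  connectors_at(skel$neuron_id,
                as.matrix(nodes[hit, c("x", "y", "z")]))
}

# ---- independent oracle for the backbone rule list (igraph-based) ---------

oracle_node_connectors <- function(skel, connectors, radius = 250) {
  nodes <- skel$nodes
  counts <- stats::setNames(integer(nrow(nodes)),
                            as.character(nodes$node_id))
  if (is.null(connectors) || nrow(connectors) == 0L) return(counts)
  mine <- connectors[connectors$pre == skel$neuron_id |
                       connectors$post == skel$neuron_id, , drop = FALSE]
  for (i in seq_len(nrow(mine))) {
    d <- sqrt((nodes$x - mine$x[i])^2 + (nodes$y - mine$y[i])^2 +
                (nodes$z - mine$z[i])^2)
    j <- which.min(d)
    if (d[j] <= radius) counts[j] <- counts[j] + mine$weight[i]
  }
  counts
}

oracle_graph <- function(nodes) {
  has <- !is.na(nodes$parent_id)
  igraph::graph_from_data_frame(
    data.frame(from = as.character(nodes$parent_id[has]),
               to = as.character(nodes$node_id[has])),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id)))
}

# simultaneous-round twig pruning to fixpoint, on igraph machinery
oracle_prune <- function(skel, node_conn, twig_max = 15) {
  nodes <- skel$nodes
  repeat {
    if (nrow(nodes) <= 1L) break
    g <- oracle_graph(nodes)
    deg <- igraph::degree(g)
    if (!any(deg >= 3)) break
    drop <- character(0)
    for (leaf in names(deg)[deg == 1]) {
      twig <- character(0)
      cur <- leaf
      prev <- NA_character_
      while (deg[cur] < 3) {
        twig <- c(twig, cur)
        nb <- setdiff(names(igraph::neighbors(g, cur)), c(prev, twig))
        if (length(nb) == 0L) { twig <- character(0); break }
        prev <- cur
        cur <- nb[1L]
      }
      if (length(twig) > 0L && length(twig) < twig_max &&
          sum(node_conn[twig]) == 0L) {
        drop <- union(drop, twig)
      }
    }
    if (length(drop) == 0L) break
    keep <- !(as.character(nodes$node_id) %in% drop)
    nodes <- nodes[keep, , drop = FALSE]
    nodes$parent_id[!(nodes$parent_id %in% nodes$node_id)] <- NA_integer_
  }
  nodes
}

# fragments via igraph: delete branch vertices, take components, rebuild
# each maximal degree-2 path with its terminal branch vertices re-attached
oracle_fragments <- function(nodes, node_conn) {
  if (nrow(nodes) <= 1L) return(list())
  g <- oracle_graph(nodes)
  deg <- igraph::degree(g)
  branch <- names(deg)[deg >= 3]
  g2 <- igraph::delete_vertices(g, branch)
  comps <- igraph::components(g2)
  frag_paths <- list()
  for (ci in seq_len(comps$no)) {
    members <- names(comps$membership)[comps$membership == ci]
    sub <- igraph::induced_subgraph(g2, members)
    dsub <- igraph::degree(sub)
    ends <- names(dsub)[dsub <= 1]
    ordered <- if (length(members) == 1L) members else {
      as_ids <- igraph::shortest_paths(sub, from = ends[1],
                                       to = ends[length(ends)])$vpath[[1]]
      names(as_ids)
    }
    # re-attach branch vertices adjacent to the chain ends
    for (side in c(1L, 2L)) {
      end <- if (side == 1L) ordered[1] else ordered[length(ordered)]
      nb <- intersect(names(igraph::neighbors(g, end)), branch)
      nb <- setdiff(nb, ordered)
      if (length(nb) > 0L) {
        ordered <- if (side == 1L) c(nb[1], ordered) else c(ordered, nb[1])
      }
    }
    frag_paths[[length(frag_paths) + 1L]] <- ordered
  }
  # branch-branch edges form their own 2-node fragments
  em <- igraph::as_edgelist(g)
  bb <- em[em[, 1] %in% branch & em[, 2] %in% branch, , drop = FALSE]
  for (i in seq_len(nrow(bb))) {
    frag_paths[[length(frag_paths) + 1L]] <- c(bb[i, 1], bb[i, 2])
  }
  lapply(frag_paths, function(p) {
    idx <- match(p, as.character(nodes$node_id))
    xyz <- as.matrix(nodes[idx, c("x", "y", "z")])
    list(node_ids = nodes$node_id[idx],
         cable_length = if (length(idx) < 2L) 0 else
           sum(sqrt(rowSums(diff(xyz)^2))),
         connector_count = sum(node_conn[p]))
  })
}

# literal transliteration of the published selection + trim rules
oracle_select_trim <- function(frags, nodes, p) {
  if (length(frags) == 0L) return(frags)
  len <- vapply(frags, `[[`, 0, "cable_length")
  ncon <- vapply(frags, `[[`, 0, "connector_count")
  largest_len <- max(len)
  keep <- len > p$large_fragment_min_len |
    (len <= p$large_fragment_min_len &
       len > p$small_fragment_min_len &
       ncon < p$connector_density_max * len &
       len >= largest_len / p$relative_length_factor)
  frags <- frags[keep]
  if (length(frags) <= 1L) return(frags)
  len <- vapply(frags, `[[`, 0, "cable_length")
  imax <- which.max(len)
  ids <- frags[[imax]]$node_ids
  endpts <- nodes[match(c(ids[1], ids[length(ids)]), nodes$node_id),
                  c("x", "y", "z")]
  near <- vapply(seq_along(frags), function(i) {
    if (i == imax) return(TRUE)
    fxyz <- nodes[match(frags[[i]]$node_ids, nodes$node_id),
                  c("x", "y", "z")]
    dmin <- Inf
    for (e in 1:2) {
      for (k in seq_len(nrow(fxyz))) {
        dmin <- min(dmin, sqrt(sum((fxyz[k, ] - endpts[e, ])^2)))
      }
    }
    dmin <= p$distal_trim_distance
  }, logical(1))
  frags[near]
}

oracle_backbone_nodes <- function(skel, connectors, p = backbone_params()) {
  nc <- oracle_node_connectors(skel, connectors, p$connector_map_radius)
  nodes <- oracle_prune(skel, nc, p$twig_node_max)
  frags <- oracle_fragments(nodes, nc)
  frags <- oracle_select_trim(frags, nodes, p)
  sort(unique(unlist(lapply(frags, `[[`, "node_ids"))))
}

# ---- brute-force CX filter reference (the "10-line" version) --------------

brute_filter <- function(catalog, connectors, p) {
  ok <- logical(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    n <- catalog$neuron_id[i]
    cx <- connectors[(connectors$pre == n | connectors$post == n) &
                       connectors$compartment %in% p$cx_regions, ]
    out <- connectors[connectors$pre == n, ]
    st <- if (nrow(out)) tapply(out$weight, out$post, sum) else 0
    ok[i] <- nrow(cx) > 0 && sum(cx$weight) > p$min_cx_synapses &&
      max(st) > p$min_single_connection
  }
  catalog[ok, , drop = FALSE]
}

# cached scenarios (built once per test run)
.fixture_env <- new.env()
cached_avp <- function(seed = 7) {
  key <- paste0("avp", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_avp_scenario(seed)
  }
  .fixture_env[[key]]
}
cached_fb <- function(seed = 3, noise = 300) {
  key <- paste0("fb", seed, "_", noise)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_fb_scenario(seed,
                                                dendrite_noise_sd = noise)
  }
  .fixture_env[[key]]
}
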