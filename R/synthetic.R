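#' Default synthetic compartment model
#'
#' A miniature bilateral brain model with the compartments the pipeline
#' analyses: an EB torus partitioned into the five annular domains
#' (EBa, EBoc, EBic, EBip, EBop), nine FB layer slabs, PB, the three noduli,
#' the asymmetrical body, the tripartite bulb (BUs/BUa/BUi, mirrored), and
#' the lateral input compartments (LAL, CRE, SMP, SIP, SLP, AOTU, mirrored).
#' Coordinates are nm; x is medio-lateral (midline x = 0), y
#' antero-posterior (+y anterior), z dorso-ventral (+z dorsal). Subregions
#' declare their parent compartment so counts can be rolled up.
#'
#' @return A [compartment_model()].
#' @export
default_compartment_model <- function() {
  eb <- function(name, u_range, v_range) {
    list(name = name, primitive = "torus_sector", parent = "EB",
         center = c(0, 0, 0), axis = c(0, 1, 0),
         ring_radius = 2000, tube_radius = 600,
         u_range = u_range, v_range = v_range)
  }
  fb_layer <- function(i) {
    zlo <- 1000 + (i - 1) * 800
    list(name = paste0("FB_l", i), primitive = "slab", parent = "FB",
         normal = c(0, 0, 1), range = c(zlo, zlo + 800),
         clip = list(center = c(0, -8000, zlo + 400),
                     half = c(4000, 2000, 401)))
  }
  box <- function(name, center, half, parent = name, mirror = FALSE) {
    list(name = name, primitive = "box", parent = parent, center = center,
         half = half, mirror = mirror)
  }
  sphere <- function(name, center, radius, parent = name, mirror = FALSE) {
    list(name = name, primitive = "sphere", parent = parent, center = center,
         radius = radius, mirror = mirror)
  }
  regions <- c(
    list(eb("EBa",  c(-600, 600), c(200, 600)),
         eb("EBoc", c(0, 600),    c(-200, 200)),
         eb("EBic", c(-600, 0),   c(-200, 200)),
         eb("EBip", c(-600, 0),   c(-600, -200)),
         eb("EBop", c(0, 600),    c(-600, -200))),
    lapply(1:9, fb_layer),
    list(box("PB", c(0, -12500, 6000), c(6000, 800, 800)),
         box("NO1", c(0, -5500, -1200), c(1200, 600, 350), parent = "NO"),
         box("NO2", c(0, -5500, -2000), c(1000, 500, 350), parent = "NO"),
         box("NO3", c(0, -5500, -2800), c(900, 450, 350), parent = "NO"),
         box("AB", c(600, -4500, 500), c(350, 350, 350)),
         sphere("BUs", c(4200, 1500, 900), 550, parent = "BU", mirror = TRUE),
         sphere("BUa", c(4200, 1500, 100), 450, parent = "BU", mirror = TRUE),
         sphere("BUi", c(4200, 1500, -2200), 550, parent = "BU",
                mirror = TRUE),
         box("LAL", c(4000, -1500, -3000), c(1500, 1800, 1200),
             mirror = TRUE),
         box("CRE", c(3200, -3500, 2500), c(1200, 1800, 1200),
             mirror = TRUE),
         box("SMP", c(2500, -3800, 6500), c(2500, 1800, 1500),
             mirror = TRUE),
         box("SIP", c(4800, -3000, 5500), c(1200, 1500, 1200),
             mirror = TRUE),
         box("SLP", c(6500, -4000, 5000), c(1500, 1800, 1500),
             mirror = TRUE),
         box("AOTU", c(7500, 500, 4500), c(900, 900, 1200), mirror = TRUE))
  )
  compartment_model(regions)
}

#' Describe one synthetic lineage
#'
#' A lineage is a cluster of somata in the cortical rind plus a tract
#' bundle: every neuron follows the lineage centerline (a waypoint
#' polyline from the soma cluster into the neuropil) with a constant
#' lateral offset drawn from a truncated Gaussian, emulating the tight
#' parallel fiber bundles of real tracts.
#'
#' @param lineage_id Lineage name.
#' @param n_neurons Fiber count; `NULL` draws uniformly from the config's
#'   `fibers_range` (the typical 50-150 fibers per tract).
#' @param soma_center Soma cluster centre (nm).
#' @param waypoints k x 3 matrix: tract centerline from the cluster into
#'   the neuropil.
#' @param types Optional named integer vector partitioning the neurons into
#'   type groups, in order (e.g. `c(TuBu_s = 10, TuBu_a = 4)`).
#' @param tract_noise_sd Lateral bundle spread sigma in nm (default 100);
#'   offsets are truncated at 3 sigma (fibers stay in the bundle).
#' @param n_twigs Connector-free terminal twigs per neuron (default 5),
#'   each below the twig pruning threshold by construction.
#' @param portal_index Waypoint at which the tract crosses its entry portal
#'   (default 2).
#' @param layers Optional integer vector (recycled over neurons) planting a
#'   per-neuron FB output layer.
#' @return A list describing the lineage.
#' @export
synth_lineage <- function(lineage_id, n_neurons, soma_center, waypoints,
                          types = NULL, tract_noise_sd = 100, n_twigs = 5,
                          portal_index = 2L, layers = NULL) {
  waypoints <- as_point_matrix(waypoints)
  stopifnot(nrow(waypoints) >= 2L, portal_index >= 1L,
            portal_index < nrow(waypoints))
  list(lineage_id = lineage_id, n_neurons = n_neurons,
       soma_center = as.numeric(soma_center), waypoints = waypoints,
       types = types, tract_noise_sd = tract_noise_sd, n_twigs = n_twigs,
       portal_index = as.integer(portal_index), layers = layers)
}

#' Configuration of the synthetic connectome generator
#'
#' The generator plants full ground truth: lineage membership, tract
#' backbones (node sets), bundle portals/seeds, and block-structured
#' connectivity with exact synapse budgets. Everything is deterministic
#' under `(config, seed)` from a single RNG stream.
#'
#' @param seed Integer seed.
#' @param lineages List of [synth_lineage()]s.
#' @param blocks List of connectivity blocks: each
#'   `list(src =, tgt =, region =, n =, kind = "TBAR", anchored = FALSE)`.
#'   `src`/`tgt` name a lineage, a type group, an extra group, or a single
#'   neuron id; `region` a compartment-model region; `n` the exact synapse
#'   budget (Poisson-drawn when `poisson = TRUE`).
#' @param compartments A [compartment_model()] (default
#'   [default_compartment_model()]).
#' @param node_spacing Skeleton node spacing in nm (default 8, so 15 nodes
#'   span about 120 nm).
#' @param twig_node_max Twigs get fewer nodes than this (default 15).
#' @param capture_radius Bundle capture radius in nm (default 400).
#' @param soma_cluster_sd Soma scatter sigma around the cluster centre
#'   (default 250 nm).
#' @param extra_groups Named integer vector of skeleton-less partner
#'   populations (e.g. `c(EPG = 12)`): they appear in the synapse table
#'   only, like truncated partners in a real volume.
#' @param dendrite_anchors Optional data.frame (`neuron_id`, `region`,
#'   `x`, `y`, `z`): per-neuron anchor points for `anchored` blocks.
#' @param anchor_sd Spatial sigma (nm) around dendrite anchors (default
#'   300).
#' @param poisson Draw block sizes as Poisson(n) instead of exactly n
#'   (default `FALSE`).
#' @param fibers_range Range for lineages with `n_neurons = NULL`
#'   (default `c(50, 150)`).
#' @param hemispheres `"right"` (default) or `"both"`; `"both"` mirrors
#'   every lineage across the midline (mirrored lineages get an `_L`
#'   suffix, as each hemisphere's bundle is annotated separately).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed, lineages, blocks = list(),
                         compartments = default_compartment_model(),
                         node_spacing = 8, twig_node_max = 15,
                         capture_radius = 400, soma_cluster_sd = 250,
                         extra_groups = NULL, dendrite_anchors = NULL,
                         anchor_sd = 300, poisson = FALSE,
                         fibers_range = c(50, 150),
                         hemispheres = c("right", "both")) {
  hemispheres <- match.arg(hemispheres)
  for (b in blocks) {
    if (is.null(b$src) || is.null(b$tgt) || is.null(b$region) ||
        is.null(b$n) || b$n < 0) {
      stop("each block needs src, tgt, region and a budget n >= 0")
    }
  }
  structure(list(seed = as.integer(seed), lineages = lineages,
                 blocks = blocks, compartments = compartments,
                 node_spacing = node_spacing, twig_node_max = twig_node_max,
                 capture_radius = capture_radius,
                 soma_cluster_sd = soma_cluster_sd,
                 extra_groups = extra_groups,
                 dendrite_anchors = dendrite_anchors, anchor_sd = anchor_sd,
                 poisson = poisson, fibers_range = fibers_range,
                 hemispheres = hemispheres),
            class = "synth_config")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# sample n points uniformly inside a named region (rejection against the
# full model so priority overlaps cannot mislabel a planted synapse);
# anchored sampling draws Gaussian around `anchor` instead
sample_in_region <- function(model, region_name, n, anchor = NULL,
                             anchor_sd = 300, what = region_name) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  names_all <- vapply(model$regions, `[[`, "", "name")
  ri <- match(region_name, names_all)
  if (is.na(ri)) stop("unknown region '", region_name, "' in ", what)
  region <- model$regions[[ri]]
  out <- matrix(numeric(0), ncol = 3)
  for (try in 1:300) {
    m <- max(2L * (n - nrow(out)), 16L)
    prop <- propose_points(region, m, model, anchor, anchor_sd)
    lab <- region_of(prop, model)
    out <- rbind(out, prop[lab == region_name, , drop = FALSE])
    if (nrow(out) >= n) break
  }
  if (nrow(out) < n) {
    stop("could not sample ", n, " points in region '", region_name,
         "' for ", what, " (region infeasible?)")
  }
  out[seq_len(n), , drop = FALSE]
}

propose_points <- function(region, m, model, anchor = NULL, anchor_sd = 300) {
  if (!is.null(anchor)) {
    return(cbind(stats::rnorm(m, anchor[1], anchor_sd),
                 stats::rnorm(m, anchor[2], anchor_sd),
                 stats::rnorm(m, anchor[3], anchor_sd)))
  }
  pts <- switch(region$primitive,
    box = {
      c0 <- region$center; h <- region$half
      cbind(stats::runif(m, c0[1] - h[1], c0[1] + h[1]),
            stats::runif(m, c0[2] - h[2], c0[2] + h[2]),
            stats::runif(m, c0[3] - h[3], c0[3] + h[3]))
    },
    sphere = {
      r <- region$radius * stats::runif(m)^(1 / 3)
      u <- stats::rnorm(m); v <- stats::rnorm(m); w <- stats::rnorm(m)
      nn <- sqrt(u^2 + v^2 + w^2)
      sweep(cbind(u, v, w) / nn * r, 2, region$center, `+`)
    },
    slab = {
      if (is.null(region$clip)) {
        stop("cannot sample an unbounded slab region '", region$name, "'")
      }
      cl <- region$clip
      cbind(stats::runif(m, cl$center[1] - cl$half[1], cl$center[1] + cl$half[1]),
            stats::runif(m, cl$center[2] - cl$half[2], cl$center[2] + cl$half[2]),
            stats::runif(m, cl$center[3] - cl$half[3], cl$center[3] + cl$half[3]))
    },
    torus_sector = {
      r <- region$tube_radius
      ur <- if (is.null(region$u_range)) c(-r, r) else region$u_range
      vr <- if (is.null(region$v_range)) c(-r, r) else region$v_range
      u <- stats::runif(m, max(ur[1], -r), min(ur[2], r))
      v <- stats::runif(m, max(vr[1], -r), min(vr[2], r))
      theta <- stats::runif(m, 0, 2 * pi)
      ax <- unit_vector(region$axis)
      e1 <- orthonormal_basis(ax)[, 1]
      e2 <- orthonormal_basis(ax)[, 2]
      d <- region$ring_radius + u
      ring <- outer(d * cos(theta), e1) + outer(d * sin(theta), e2)
      sweep(ring + outer(v, ax), 2, region$center, `+`)
    }
  )
  if (isTRUE(region$mirror)) {
    flip <- stats::runif(m) < 0.5
    if (any(flip)) {
      pts[flip, ] <- reflect_points(pts[flip, , drop = FALSE], model$midline)
    }
  }
  pts
}

orthonormal_basis <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vector(ref - sum(ref * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cbind(e1, e2)
}

# resample a waypoint polyline at fixed arc-length spacing
resample_polyline <- function(waypoints, spacing) {
  seg <- diff(waypoints)
  seglen <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  t <- seq(0, total, by = spacing)
  cbind(stats::approx(s, waypoints[, 1], xout = t)$y,
        stats::approx(s, waypoints[, 2], xout = t)$y,
        stats::approx(s, waypoints[, 3], xout = t)$y)
}

# mirrored copy of a lineage across the midline (x = 0)
mirror_lineage <- function(lin) {
  lin$lineage_id <- paste0(lin$lineage_id, "_L")
  lin$soma_center[1] <- -lin$soma_center[1]
  lin$waypoints[, 1] <- -lin$waypoints[, 1]
  lin
}

#' Generate a synthetic connectome with planted ground truth
#'
#' Builds the full miniature dataset: per-neuron SWC-style skeletons (soma,
#' noisy bundle tract, connector-free terminal twigs), a synapse table
#' realising the configured connectivity blocks with exact budgets and
#' in-region positions, the compartment model, true bundle annotations
#' (portal plane, seed fibers, capture radius), and ground-truth tables.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synthetic_connectome`: `skeletons` (named list),
#'   `connectors` ([connector_table()]), `compartments`, `bundles`,
#'   `groups` (named list group -> neuron ids), `truth` (list: `neurons`
#'   data.frame, `backbone_nodes` named list, `blocks` data.frame), `config`.
#' @export
generate_brain <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, function() generate_brain_impl(cfg))
}

generate_brain_impl <- function(cfg) {
  model <- cfg$compartments
  lineages <- cfg$lineages
  if (cfg$hemispheres == "both") {
    lineages <- c(lineages, lapply(lineages, mirror_lineage))
  }

  # --- neuron roster --------------------------------------------------------
  neuron_rows <- list()
  for (lin in lineages) {
    n <- lin$n_neurons
    if (is.null(n)) {
      n <- sample(cfg$fibers_range[1]:cfg$fibers_range[2], 1L)
    }
    ids <- sprintf("%s_%03d", lin$lineage_id, seq_len(n))
    type <- if (is.null(lin$types)) rep(lin$lineage_id, n) else {
      if (sum(lin$types) != n) {
        stop("lineage ", lin$lineage_id, ": types must sum to n_neurons")
      }
      rep(names(lin$types), lin$types)
    }
    layer <- if (is.null(lin$layers)) rep(NA_integer_, n) else {
      rep_len(as.integer(lin$layers), n)
    }
    hemi <- hemisphere_of(matrix(lin$soma_center, 1), model)
    neuron_rows[[length(neuron_rows) + 1L]] <- data.frame(
      neuron_id = ids, lineage = lin$lineage_id, type = type,
      hemisphere = hemi, layer = layer, stringsAsFactors = FALSE)
  }
  neurons <- do.call(rbind, neuron_rows)
  if (anyDuplicated(neurons$neuron_id)) stop("duplicate neuron ids generated")

  groups <- list()
  for (lid in unique(neurons$lineage)) {
    groups[[lid]] <- neurons$neuron_id[neurons$lineage == lid]
  }
  for (ty in unique(neurons$type)) {
    if (is.null(groups[[ty]])) {
      groups[[ty]] <- neurons$neuron_id[neurons$type == ty]
    }
  }
  if (!is.null(cfg$extra_groups)) {
    for (g in names(cfg$extra_groups)) {
      groups[[g]] <- sprintf("%s_%03d", g, seq_len(cfg$extra_groups[[g]]))
    }
  }
  resolve_group <- function(name, what) {
    if (!is.null(groups[[name]])) return(groups[[name]])
    if (name %in% neurons$neuron_id) return(name)
    stop("unknown group '", name, "' in ", what)
  }

  # --- synapse table from connectivity blocks ------------------------------
  anchors <- cfg$dendrite_anchors
  syn_chunks <- list()
  block_rows <- list()
  for (bi in seq_along(cfg$blocks)) {
    b <- cfg$blocks[[bi]]
    what <- sprintf("block %d (%s -> %s in %s)", bi, b$src, b$tgt, b$region)
    kind <- if (is.null(b$kind)) "TBAR" else b$kind
    src_ids <- resolve_group(b$src, what)
    tgt_ids <- resolve_group(b$tgt, what)
    n <- if (cfg$poisson) stats::rpois(1L, b$n) else as.integer(b$n)
    if (n > 0L) {
      pre <- sample(src_ids, n, replace = TRUE)
      post <- tgt_ids[((seq_len(n) - 1L) %% length(tgt_ids)) + 1L]
      if (isTRUE(b$anchored)) {
        pos <- matrix(NA_real_, n, 3)
        for (tn in unique(post)) {
          sel <- which(post == tn)
          a <- anchors[anchors$neuron_id == tn & anchors$region == b$region, ]
          if (nrow(a) != 1L) {
            stop("no dendrite anchor for neuron ", tn, " in region ",
                 b$region)
          }
          pos[sel, ] <- sample_in_region(model, b$region, length(sel),
                                         anchor = c(a$x, a$y, a$z),
                                         anchor_sd = cfg$anchor_sd,
                                         what = what)
        }
      } else {
        pos <- sample_in_region(model, b$region, n, what = what)
      }
      syn_chunks[[length(syn_chunks) + 1L]] <- data.frame(
        pre = pre, post = post, kind = kind,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        compartment = region_of(pos, model), stringsAsFactors = FALSE)
    }
    block_rows[[bi]] <- data.frame(src = b$src, tgt = b$tgt,
                                   region = b$region, kind = kind,
                                   n_planted = b$n, n_realized = n)
  }
  connectors <- if (length(syn_chunks) > 0L) {
    syn <- do.call(rbind, syn_chunks)
    syn$synapse_id <- sprintf("syn%07d", seq_len(nrow(syn)))
    syn$weight <- 1L
    connector_table(syn[, c("synapse_id", "pre", "post", "kind",
                            "x", "y", "z", "compartment", "weight")])
  } else {
    connector_table(data.frame(synapse_id = character(0),
                               pre = character(0), post = character(0),
                               kind = character(0), x = numeric(0),
                               y = numeric(0), z = numeric(0),
                               compartment = character(0),
                               weight = integer(0)))
  }

  # --- skeletons: soma + offset tract + connector-free twigs ----------------
  skeletons <- list()
  backbone_nodes <- list()
  bundle_crossings <- list()
  for (lin in lineages) {
    lid <- lin$lineage_id
    ids <- neurons$neuron_id[neurons$lineage == lid]
    pi_ <- lin$portal_index
    tangent <- unit_vector(lin$waypoints[pi_ + 1L, ] - lin$waypoints[pi_, ])
    basis <- orthonormal_basis(tangent)
    crossings <- matrix(NA_real_, length(ids), 3)
    for (k in seq_along(ids)) {
      # constant lateral offset perpendicular to the tract at the portal,
      # truncated at 3 sigma: fibers stay inside the glial bundle
      repeat {
        off2 <- stats::rnorm(2, 0, lin$tract_noise_sd)
        if (sum(off2^2) <= (3 * lin$tract_noise_sd)^2) break
      }
      offset <- as.vector(basis %*% off2)
      path <- resample_polyline(sweep(lin$waypoints, 2, offset, `+`),
                                cfg$node_spacing)
      soma <- lin$soma_center + stats::rnorm(3, 0, cfg$soma_cluster_sd)
      xyz <- rbind(soma, path)
      nid <- ids[k]
      n_tract <- nrow(xyz)
      nodes <- data.frame(node_id = seq_len(n_tract),
                          parent_id = c(NA_integer_, seq_len(n_tract - 1L)),
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          radius = 40)
      # twigs: attached away from this neuron's own synapses so twig nodes
      # can never capture a connector within the mapping radius
      own <- connectors[connectors$pre == nid | connectors$post == nid, ,
                        drop = FALSE]
      # keep both terminal runs of the tract at least twig_node_max nodes
      # long, so a twig can never turn a tract end into a prunable branch
      eligible <- (cfg$twig_node_max + 1L):(n_tract - cfg$twig_node_max)
      if (nrow(own) > 0L && length(eligible) > 0L) {
        op <- as.matrix(own[, c("x", "y", "z")])
        dmin <- vapply(eligible, function(i) {
          min((op[, 1] - xyz[i, 1])^2 + (op[, 2] - xyz[i, 2])^2 +
                (op[, 3] - xyz[i, 3])^2)
        }, 0)
        eligible <- eligible[dmin > 600^2]
      }
      next_id <- n_tract
      if (length(eligible) > 0L && lin$n_twigs > 0L) {
        at <- sample(eligible, min(lin$n_twigs, length(eligible)),
                     replace = FALSE)
        for (a in at) {
          m <- sample(3:(cfg$twig_node_max - 1L), 1L)
          dirv <- unit_vector(stats::rnorm(3))
          tw <- sweep(outer(seq_len(m) * cfg$node_spacing, dirv), 2,
                      xyz[a, ], `+`)
          tw_ids <- next_id + seq_len(m)
          nodes <- rbind(nodes, data.frame(
            node_id = tw_ids, parent_id = c(a, tw_ids[-m]),
            x = tw[, 1], y = tw[, 2], z = tw[, 3], radius = 20))
          next_id <- next_id + m
        }
      }
      skeletons[[nid]] <- skeleton(nid, nodes, soma_node = 1L)
      backbone_nodes[[nid]] <- seq_len(n_tract)
      crossings[k, ] <- lin$waypoints[pi_, ] + offset
    }
    bundle_crossings[[lid]] <- crossings
  }

  # --- true bundle annotations ---------------------------------------------
  bundles <- list()
  for (lin in lineages) {
    lid <- lin$lineage_id
    pi_ <- lin$portal_index
    portal_point <- lin$waypoints[pi_, ]
    tangent <- unit_vector(lin$waypoints[pi_ + 1L, ] - lin$waypoints[pi_, ])
    cr <- bundle_crossings[[lid]]
    seeds <- rbind(portal_point, cr[seq_len(min(8L, nrow(cr))), ,
                                    drop = FALSE])
    bundles[[lid]] <- bundle_annotation(
      lineage_id = lid, portal_point = portal_point,
      portal_normal = tangent, seed_fibers = seeds,
      capture_radius = cfg$capture_radius, soma_center = lin$soma_center)
  }

  structure(list(skeletons = skeletons, connectors = connectors,
                 compartments = model, bundles = bundles, groups = groups,
                 truth = list(neurons = neurons,
                              backbone_nodes = backbone_nodes,
                              blocks = do.call(rbind, block_rows)),
                 config = cfg),
            class = "synthetic_connectome")
}

#' @export
print.synthetic_connectome <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_connectome> %d neurons (%d lineages), ",
                     "%d synapses, %d regions\n"),
              length(x$skeletons), length(unique(x$truth$neurons$lineage)),
              nrow(x$connectors), length(x$compartments$regions)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `swc/<neuron>.swc`, `synapses.csv`, `compartments.json`,
#' `bundles.json` and `truth/{neurons,blocks,backbone_nodes}.csv` — the
#' file set the pipeline consumes.
#'
#' @param dataset A [generate_brain()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "swc"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (skel in dataset$skeletons) {
    write_swc(skel, file.path(dir, "swc", paste0(skel$neuron_id, ".swc")))
  }
  write_synapse_table(dataset$connectors, file.path(dir, "synapses.csv"))
  write_compartments(dataset$compartments,
                     file.path(dir, "compartments.json"))
  write_bundles(dataset$bundles, file.path(dir, "bundles.json"))
  utils::write.csv(dataset$truth$neurons,
                   file.path(dir, "truth", "neurons.csv"), row.names = FALSE)
  utils::write.csv(dataset$truth$blocks,
                   file.path(dir, "truth", "blocks.csv"), row.names = FALSE)
  bn <- do.call(rbind, lapply(names(dataset$truth$backbone_nodes), function(n) {
    data.frame(neuron_id = n, node_id = dataset$truth$backbone_nodes[[n]])
  }))
  utils::write.csv(bn, file.path(dir, "truth", "backbone_nodes.csv"),
                   row.names = FALSE)
  invisible(dir)
}
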