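#' Anterior-visual-pathway scenario with planted exclusivity
#'
#' A fixed-shape synthetic dataset emulating the developmentally segregated
#' visual input to the ellipsoid body: TuBu neurons of the DALcl1d
#' hemilineage (types TuBu_s, TuBu_a) synapse onto outer ER subclasses
#' (ER2, ER4d, ER4m) in the superior/anterior bulb, while DALcl2d TuBu
#' neurons (TuBu_i) target inner ER neurons (ER3) in the inferior bulb —
#' with 100% planted source exclusivity per ER subclass. ER output T-bars
#' land in the matching EB annular domains (EBa/EBoc for the DALcl1d
#' channel, EBic/EBip for DALcl2d).
#'
#' @param seed Integer seed.
#' @return A `synthetic_connectome` with a `scenario` element carrying the
#'   analysis groupings: `tubu_types`, `er_types` (named neuron -> group
#'   vectors), `hemilineage_partition` (TuBu type -> hemilineage), and
#'   `bu_regions`.
#' @export
generate_avp_scenario <- function(seed) {
  lineages <- list(
    synth_lineage("DALcl1d", 14,
                  soma_center = c(6500, 2800, 2600),
                  waypoints = rbind(c(6600, 2900, 2700),
                                    c(5800, 2200, 1800),
                                    c(5000, 1900, 1200),
                                    c(4300, 1700, 700)),
                  types = c(TuBu_s = 10, TuBu_a = 4)),
    synth_lineage("DALcl2d", 8,
                  soma_center = c(5600, 3200, 2400),
                  waypoints = rbind(c(5400, 3000, 2200),
                                    c(5000, 2200, 1200),
                                    c(4600, 1900, -300),
                                    c(4300, 1700, -1600)),
                  types = c(TuBu_i = 8)),
    synth_lineage("DALv2", 22,
                  soma_center = c(3000, 3400, -600),
                  waypoints = rbind(c(2900, 3200, -600),
                                    c(2700, 2400, -700),
                                    c(2500, 1200, -400),
                                    c(2350, 400, -100)),
                  types = c(ER2 = 6, ER4d = 5, ER4m = 4, ER3 = 7))
  )
  blocks <- list(
    list(src = "TuBu_s", tgt = "ER2", region = "BUs", n = 1200),
    list(src = "TuBu_s", tgt = "ER4d", region = "BUs", n = 1000),
    list(src = "TuBu_a", tgt = "ER4m", region = "BUa", n = 600),
    list(src = "TuBu_i", tgt = "ER3", region = "BUi", n = 1400),
    list(src = "ER2", tgt = "EPG", region = "EBoc", n = 700),
    list(src = "ER4d", tgt = "EPG", region = "EBa", n = 600),
    list(src = "ER4m", tgt = "EPG", region = "EBoc", n = 500),
    list(src = "ER3", tgt = "EPG", region = "EBic", n = 900),
    list(src = "ER3", tgt = "EPG", region = "EBip", n = 200)
  )
  cfg <- synth_config(seed, lineages, blocks, extra_groups = c(EPG = 12))
  ds <- generate_brain(cfg)
  nr <- ds$truth$neurons
  tubu <- nr$neuron_id[nr$lineage %in% c("DALcl1d", "DALcl2d")]
  ers <- nr$neuron_id[nr$lineage == "DALv2"]
  ds$scenario <- list(
    tubu_types = stats::setNames(nr$type[match(tubu, nr$neuron_id)], tubu),
    er_types = stats::setNames(nr$type[match(ers, nr$neuron_id)], ers),
    hemilineage_partition = c(TuBu_s = "DALcl1d", TuBu_a = "DALcl1d",
                              TuBu_i = "DALcl2d"),
    bu_regions = c("BUs", "BUa", "BUi"),
    eb_domains = c("EBa", "EBoc", "EBic", "EBip", "EBop")
  )
  ds
}

#' Tract-bundle scenario: planted backbones and well-separated bundles
#'
#' A minimal dataset for testing backbone recovery and lineage assignment
#' in isolation: parallel lineage bundles whose entry portals are spaced
#' 1200 nm apart (12 sigma of the default 100 nm tract noise), main tract
#' paths over 3000 nm of cable, the default connector-free twigs, and no
#' synapses. The planted backbone of every neuron is exactly its tract
#' node set.
#'
#' @param seed Integer seed.
#' @param n_per_lineage Neurons per bundle (default 10).
#' @param n_lineages Number of bundles (default 3).
#' @return A `synthetic_connectome`.
#' @export
generate_tract_scenario <- function(seed, n_per_lineage = 10,
                                    n_lineages = 3) {
  lineages <- lapply(seq_len(n_lineages), function(i) {
    x0 <- 2000 + 1200 * (i - 1)
    synth_lineage(sprintf("TR%02d", i), n_per_lineage,
                  soma_center = c(x0 + 200, 4000, 800),
                  waypoints = rbind(c(x0 + 180, 3900, 750),
                                    c(x0, 3000, 500),
                                    c(x0 - 100, 1800, 200),
                                    c(x0 - 150, 800, 0)))
  })
  generate_brain(synth_config(seed, lineages))
}

#' Fan-shaped-body scenario: planted input fractions and layer topography
#'
#' Emulates the lateral-input structure of the FB large-field network: five
#' lineages of FB tangential neurons (nine neurons each, one per output
#' layer), receiving 20,000 lateral input synapses in SMP/CRE/LAL with
#' planted per-lineage fractions 28.6% (DALcl2v), 23.2% (CP2d), 22.3%
#' (BAmv1) and the remainder split between DM6 and DPMpl2 — and a planted
#' dendrite-to-output-layer topography: neurons with dorsal output layers
#' have their dendrite anchors at more posterior (lower y) positions, in
#' steps of 280 nm per layer.
#'
#' @param seed Integer seed.
#' @param dendrite_noise_sd Spatial sigma (nm) of input-synapse positions
#'   around each neuron's dendrite anchor (default 300; 0 gives the
#'   noiseless gradient).
#' @return A `synthetic_connectome` with a `scenario` element:
#'   `target_lineage` (neuron -> lineage), `planted_fractions`,
#'   `layer_regions`, `posterior_axis`, `lateral_regions`.
#' @export
generate_fb_scenario <- function(seed, dendrite_noise_sd = 300) {
  geom <- list(
    DALcl2v = list(soma = c(5800, 3000, 2000),
                   wp = rbind(c(5700, 2900, 1900), c(5200, 2200, 1400),
                              c(4000, -1000, 2000), c(2500, -4500, 3000))),
    CP2d = list(soma = c(5500, -6500, 5500),
                wp = rbind(c(5400, -6400, 5400), c(5000, -5800, 5000),
                           c(4200, -5300, 4600), c(3400, -4800, 4300))),
    BAmv1 = list(soma = c(4500, 2500, -4500),
                 wp = rbind(c(4400, 2400, -4400), c(4000, 1800, -4000),
                            c(3500, -500, -3500), c(3000, -3500, -2000))),
    DM6 = list(soma = c(1500, -13500, 8000),
               wp = rbind(c(1450, -13400, 7900), c(1300, -12600, 7400),
                          c(1000, -11000, 7600), c(800, -10300, 7400))),
    DPMpl2 = list(soma = c(6000, -4800, 7800),
                  wp = rbind(c(5900, -4700, 7700), c(5500, -4300, 7300),
                             c(4500, -4800, 6500), c(4000, -5200, 6200)))
  )
  lineages <- lapply(names(geom), function(lid) {
    synth_lineage(lid, 9, soma_center = geom[[lid]]$soma,
                  waypoints = geom[[lid]]$wp, layers = 1:9)
  })

  # planted lateral-input budgets (fractions of 20,000 synapses), split
  # 60/30/10 across SMP, CRE and LAL
  lineage_syn <- c(DALcl2v = 5720, CP2d = 4640, BAmv1 = 4460,
                   DM6 = 3200, DPMpl2 = 1980)
  region_split <- c(SMP = 0.6, CRE = 0.3, LAL = 0.1)
  blocks <- list()
  for (lid in names(lineage_syn)) {
    for (r in names(region_split)) {
      blocks[[length(blocks) + 1L]] <- list(
        src = "lateral_inputs", tgt = lid, region = r,
        n = round(lineage_syn[[lid]] * region_split[[r]]),
        kind = "PSD", anchored = TRUE)
    }
  }
  # per-neuron output T-bars in the planted layer
  ids <- unlist(lapply(names(geom), function(lid) {
    sprintf("%s_%03d", lid, 1:9)
  }))
  layers <- rep(1:9, times = length(geom))
  for (i in seq_along(ids)) {
    blocks[[length(blocks) + 1L]] <- list(
      src = ids[i], tgt = "FB_columnar",
      region = paste0("FB_l", layers[i]), n = 40)
  }

  # dendrite anchors: region centre shifted posteriorly (lower y) by
  # 280 nm per output layer
  centers <- list(SMP = c(2500, -3800, 6500), CRE = c(3200, -3500, 2500),
                  LAL = c(4000, -1500, -3000))
  anchors <- do.call(rbind, lapply(seq_along(ids), function(i) {
    do.call(rbind, lapply(names(centers), function(r) {
      ctr <- centers[[r]]
      data.frame(neuron_id = ids[i], region = r, x = ctr[1],
                 y = ctr[2] - (layers[i] - 5) * 280, z = ctr[3])
    }))
  }))

  cfg <- synth_config(seed, lineages, blocks,
                      extra_groups = c(lateral_inputs = 40,
                                       FB_columnar = 20),
                      dendrite_anchors = anchors,
                      anchor_sd = dendrite_noise_sd)
  ds <- generate_brain(cfg)
  nr <- ds$truth$neurons
  tgt <- nr$neuron_id[nr$lineage %in% names(geom)]
  ds$scenario <- list(
    target_lineage = stats::setNames(nr$lineage[match(tgt, nr$neuron_id)],
                                     tgt),
    planted_fractions = lineage_syn / sum(lineage_syn),
    layer_regions = paste0("FB_l", 1:9),
    posterior_axis = c(0, -1, 0),
    lateral_regions = names(region_split),
    cx_parents = c("PB", "EB", "FB", "NO", "AB")
  )
  ds
}
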