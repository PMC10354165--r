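test_that("portal crossing interpolates the first plane intersection", {
  # straight segment through z = 0
  path <- rbind(c(0, 0, -10), c(0, 0, 10))
  expect_equal(portal_crossing(path, c(0, 0, 0), c(0, 0, 1)), c(0, 0, 0))

  # polyline parallel to the plane never crosses
  flat <- rbind(c(0, 0, 5), c(10, 0, 5), c(20, 3, 5))
  expect_null(portal_crossing(flat, c(0, 0, 0), c(0, 0, 1)))

  # zig-zag crossing three times returns the first crossing
  zig <- rbind(c(0, 0, -5), c(1, 0, 5), c(2, 0, -5), c(3, 0, 5))
  got <- portal_crossing(zig, c(0, 0, 0), c(0, 0, 1))
  expect_equal(got, c(0.5, 0, 0))
  # brute-force enumeration agrees there are 3 crossings after it
  s <- zig[, 3]
  expect_equal(sum(s[-length(s)] * s[-1] < 0), 3L)

  # a vertex exactly on the plane counts as the crossing
  onp <- rbind(c(0, 0, -5), c(1, 0, 0), c(2, 0, 5))
  expect_equal(portal_crossing(onp, c(0, 0, 0), c(0, 0, 1)), c(1, 0, 0))
})

test_that("lineage assignment picks the nearest captured bundle", {
  mk_bundle <- function(id, x0, soma) {
    bundle_annotation(id, portal_point = c(x0, 0, 0),
                      portal_normal = c(0, 0, 1),
                      seed_fibers = rbind(c(x0, 0, 0)),
                      capture_radius = 600, soma_center = soma)
  }
  bundles <- list(A = mk_bundle("A", -500, c(-500, 0, -3000)),
                  B = mk_bundle("B", 500, c(500, 0, -3000)))

  near_a <- rbind(c(-450, 0, -1000), c(-450, 0, 1000))
  row <- assign_lineage(near_a, c(-450, 0, -2000), bundles, "n1")
  expect_equal(row$lineage, "A")
  expect_equal(row$method, "PORTAL")
  expect_equal(row$score, exp(-50 / 600))

  # equidistant between A and B: the soma nearer A breaks the tie
  mid <- rbind(c(0, 0, -1000), c(0, 0, 1000))
  tie <- assign_lineage(mid, c(-400, 0, -3000), bundles, "n2")
  expect_equal(tie$lineage, "A")
  tie_b <- assign_lineage(mid, c(400, 0, -3000), bundles, "n3")
  expect_equal(tie_b$lineage, "B")
  # with equidistant somata the lexicographically first lineage wins
  tie_l <- assign_lineage(mid, c(0, 0, -3000), bundles, "n4")
  expect_equal(tie_l$lineage, "A")

  # far beyond every capture radius: unassigned
  far <- rbind(c(5000, 0, -1000), c(5000, 0, 1000))
  expect_equal(assign_lineage(far, c(5000, 0, -2000), bundles, "n5")$method,
               "UNASSIGNED")

  # no portal crossing at all: trajectory fallback
  parallel <- rbind(c(-450, 0, -300), c(-450, 0, -200), c(-450, 0, -100))
  tr <- assign_lineage(parallel, c(-450, 0, -2000), bundles, "n6")
  expect_equal(tr$method, "TRAJECTORY")
  expect_equal(tr$lineage, "A")
})

test_that("assignment is perfect on well-separated synthetic bundles", {
  ds <- cached_avp()
  catalog <- assign_lineages(ds$skeletons, ds$connectors, ds$bundles)
  truth <- ds$truth$neurons
  got <- catalog$lineage[match(truth$neuron_id, catalog$neuron_id)]
  expect_equal(mean(got == truth$lineage), 1.0)
  expect_true(all(catalog$method == "PORTAL"))
  expect_true(all(catalog$score >= 0 & catalog$score <= 1))
})

test_that("hemilineage split separates two crossing clusters", {
  # one lineage whose crossings form two clear sub-bundles
  bundles <- list(L = bundle_annotation(
    "L", portal_point = c(0, 0, 0), portal_normal = c(0, 0, 1),
    seed_fibers = rbind(c(-1000, 0, 0), c(1000, 0, 0)),
    capture_radius = 1500, soma_center = c(0, 0, -4000)))
  mk <- function(x, id) {
    nodes <- data.frame(node_id = 1:401, parent_id = c(NA, 1:400),
                        x = x, y = 0, z = seq(-1600, 1600, by = 8),
                        radius = 10)
    skeleton(id, nodes)
  }
  skels <- c(lapply(1:6, function(i) mk(-1000 + 10 * i, paste0("a", i))),
             lapply(1:6, function(i) mk(1000 + 10 * i, paste0("b", i))))
  names(skels) <- vapply(skels, function(s) s$neuron_id, "")
  cat2 <- assign_lineages(skels, NULL, bundles, split_hemilineages = TRUE)
  expect_true(all(cat2$lineage == "L"))
  hl <- cat2$hemilineage
  expect_equal(length(unique(hl)), 2L)
  # the split respects the spatial clusters
  expect_equal(length(unique(hl[1:6])), 1L)
  expect_equal(length(unique(hl[7:12])), 1L)
  expect_false(hl[1] == hl[7])
})

test_that("the CX catalog filter applies its three published rules", {
  mk_conn <- function(df) {
    df$synapse_id <- paste0("s", seq_len(nrow(df)))
    df$x <- 0; df$y <- 0; df$z <- 0
    connector_table(df)
  }
  catalog <- data.frame(neuron_id = c("lo", "hi", "weak"),
                        lineage = "L", stringsAsFactors = FALSE)
  rows <- rbind(
    # "lo": exactly 15 CX connectors -> excluded (strictly more required)
    data.frame(pre = "lo", post = sprintf("p%02d", 1:15), kind = "TBAR",
               compartment = "EB", weight = 1L),
    data.frame(pre = "lo", post = "q", kind = "TBAR",
               compartment = "EB", weight = 6L)[0, ],
    # "hi": 16 CX connectors and one 6-synapse connection -> included
    data.frame(pre = "hi", post = "q", kind = "TBAR",
               compartment = "EB", weight = 6L),
    data.frame(pre = "hi", post = sprintf("r%02d", 1:10), kind = "TBAR",
               compartment = "FB", weight = 1L),
    # "weak": 100 CX connectors, but every connection of strength 5
    data.frame(pre = "weak", post = sprintf("w%02d", 1:20), kind = "TBAR",
               compartment = "PB", weight = 5L)
  )
  conn <- mk_conn(rows)
  got <- filter_cx_largefield(catalog, conn)
  expect_equal(got$neuron_id, "hi")

  # "lo" with a 6-strength connection but still 15 total stays excluded
  lo_tot <- sum(conn$weight[conn$pre == "lo"])
  expect_equal(lo_tot, 15)
  # "weak" really had > 15 CX synapses and was excluded by rule (3)
  expect_equal(sum(conn$weight[conn$pre == "weak"]), 100)
})

test_that("the filter matches a brute-force reference on random catalogs", {
  set.seed(5)
  p <- cx_filter_params()
  for (trial in 1:250) {
    n_neu <- sample(3:8, 1)
    ids <- paste0("n", seq_len(n_neu))
    n_syn <- sample(5:60, 1)
    conn <- connector_table(data.frame(
      synapse_id = paste0("s", seq_len(n_syn)),
      pre = sample(ids, n_syn, replace = TRUE),
      post = sample(c(ids, "ext"), n_syn, replace = TRUE),
      kind = sample(c("TBAR", "PSD"), n_syn, replace = TRUE),
      x = 0, y = 0, z = 0,
      compartment = sample(c("PB", "EB", "FB", "NO", "AB", "LAL", "SMP"),
                           n_syn, replace = TRUE),
      weight = sample(1:8, n_syn, replace = TRUE)))
    catalog <- data.frame(neuron_id = ids, lineage = "L",
                          stringsAsFactors = FALSE)
    expect_identical(filter_cx_largefield(catalog, conn, p)$neuron_id,
                     brute_filter(catalog, conn, p)$neuron_id)
  }
})

test_that("the filter is idempotent on an already-filtered catalog", {
  ds <- cached_avp()
  catalog <- data.frame(neuron_id = names(ds$skeletons),
                        lineage = ds$truth$neurons$lineage[
                          match(names(ds$skeletons),
                                ds$truth$neurons$neuron_id)],
                        stringsAsFactors = FALSE)
  once <- filter_cx_largefield(catalog, ds$connectors,
                               model = ds$compartments)
  twice <- filter_cx_largefield(once, ds$connectors,
                                model = ds$compartments)
  expect_identical(once$neuron_id, twice$neuron_id)
})

test_that("lineage-by-compartment counts follow the innervation contract", {
  mk <- function(pre, comp) {
    data.frame(synapse_id = paste0("s", seq_along(pre)), pre = pre,
               post = "ext", kind = "TBAR", x = 0, y = 0, z = 0,
               compartment = comp, weight = 1L)
  }
  conn <- connector_table(rbind(
    mk(c("a1", "a2", "a3"), "EB"),
    mk("b1", "EB"), mk("b1", "FB")))
  catalog <- data.frame(neuron_id = c("a1", "a2", "a3", "b1"),
                        lineage = c("A", "A", "A", "B"))
  tab <- count_by_lineage_and_compartment(catalog, conn)
  expect_equal(unname(tab["A", "EB"]), 3L)
  # a neuron innervating two compartments counts once in each column
  expect_equal(unname(tab["B", "EB"]), 1L)
  expect_equal(unname(tab["B", "FB"]), 1L)
})

test_that("counts recover the planted lineage composition", {
  ds <- cached_avp()
  truth <- ds$truth$neurons
  catalog <- data.frame(neuron_id = truth$neuron_id,
                        lineage = truth$lineage, stringsAsFactors = FALSE)
  tab <- count_by_lineage_and_compartment(catalog, ds$connectors,
                                          model = ds$compartments)
  # every DALv2 neuron has EB output synapses; TuBu neurons have none
  expect_equal(unname(tab["DALv2", "EB"]), 22L)
  expect_false("DALcl1d" %in% rownames(tab) && tab["DALcl1d", "EB"] > 0)
  # all TuBu neurons appear in the BU column
  expect_equal(unname(tab["DALcl1d", "BU"]), 14L)
  expect_equal(unname(tab["DALcl2d", "BU"]), 8L)
  # DALv2 neurons also receive in the BU (PSD side counts)
  expect_equal(unname(tab["DALv2", "BU"]), 22L)
})
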