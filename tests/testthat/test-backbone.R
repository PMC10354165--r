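test_that("connector-free twigs below the node threshold are pruned", {
  skel <- add_twig(path_skeleton(200), at = 100L, m = 10)
  pruned <- prune_twigs(skel, NULL)
  expect_setequal(pruned$nodes$node_id, 1:200)

  # the same twig carrying one T-bar survives
  twig_tip <- skel$nodes[nrow(skel$nodes), c("x", "y", "z")]
  conn <- connectors_at("n1", as.numeric(twig_tip))
  expect_setequal(prune_twigs(skel, conn)$nodes$node_id, skel$nodes$node_id)

  # a twig at the node threshold is retained (strict "< 15 nodes")
  at20 <- add_twig(path_skeleton(200), at = 100L, m = 20)
  expect_setequal(prune_twigs(at20, NULL)$nodes$node_id,
                  at20$nodes$node_id)
  at15 <- add_twig(path_skeleton(200), at = 100L, m = 15)
  expect_setequal(prune_twigs(at15, NULL)$nodes$node_id,
                  at15$nodes$node_id)
  at14 <- add_twig(path_skeleton(200), at = 100L, m = 14)
  expect_setequal(prune_twigs(at14, NULL)$nodes$node_id, 1:200)

  # unbranched skeletons are never pruned
  plain <- path_skeleton(10)
  expect_identical(prune_twigs(plain, NULL)$nodes, plain$nodes)
})

test_that("twig pruning iterates to fixpoint through nested twigs", {
  # a 10-node twig carrying its own 5-node side twig: only iteration
  # removes both (the outer twig is not terminal until the inner one goes)
  skel <- add_twig(path_skeleton(100), at = 50L, m = 10)
  inner_at <- skel$nodes$node_id[105]
  skel <- add_twig(skel, at = inner_at, m = 5)
  pruned <- prune_twigs(skel, NULL)
  expect_setequal(pruned$nodes$node_id, 1:100)
})

test_that("cutting at branch points yields maximal unbranched fragments", {
  expect_length(fragment_at_branchpoints(path_skeleton(30)), 1L)

  y <- add_twig(path_skeleton(30), at = 15L, m = 20)
  expect_length(fragment_at_branchpoints(y), 3L)

  h <- add_twig(add_twig(path_skeleton(30), at = 10L, m = 20),
                at = 20L, m = 20)
  frags <- fragment_at_branchpoints(h)
  expect_length(frags, 5L)
  # fragments partition the edge set: edge count check
  n_edges <- sum(!is.na(h$nodes$parent_id))
  expect_equal(sum(vapply(frags, function(f) length(f$node_ids) - 1L, 0L)),
               n_edges)
  # branch points are duplicated into each incident fragment
  bp <- h$nodes$node_id[c(10L, 20L)]
  for (b in bp) {
    expect_equal(sum(vapply(frags, function(f) b %in% f$node_ids,
                            logical(1))), 3L)
  }
})

test_that("fragment selection applies the length and density rules", {
  frag <- function(len, ncon, n_nodes = 2) {
    list(node_ids = seq_len(n_nodes), cable_length = len,
         connector_count = ncon)
  }
  p <- backbone_params()
  # > 2500 nm fragments are kept regardless of connector load
  expect_length(select_fragments(list(frag(3000, 50)), p), 1L)
  # <= 80 nm fragments are always discarded
  expect_length(select_fragments(list(frag(3000, 0), frag(60, 0)), p), 1L)
  # connector density at or above 1% of cable length (nm) discards
  got <- select_fragments(list(frag(3000, 0), frag(1000, 12)), p)
  expect_length(got, 1L)
  got <- select_fragments(list(frag(3000, 0), frag(2000, 21)), p)
  expect_length(got, 1L)   # 21 >= 0.01 * 2000
  got <- select_fragments(list(frag(3000, 0), frag(2000, 19)), p)
  expect_length(got, 2L)   # 19 < 0.01 * 2000, and 2000 >= 3000 / 2.5
  # the relative-length rule: small fragments under largest/2.5 go
  got <- select_fragments(list(frag(10000, 0), frag(1000, 2)), p)
  expect_length(got, 1L)
  got <- select_fragments(list(frag(5000, 0), frag(2400, 2)), p)
  expect_length(got, 2L)  # 2400 >= 5000 / 2.5
  # literal reading of the rule text discards every small fragment
  plit <- backbone_params(relative_rule = "literal")
  got <- select_fragments(list(frag(5000, 0), frag(2400, 2)), plit)
  expect_length(got, 1L)
  expect_length(select_fragments(list(), p), 0L)
})

test_that("distal trimming keeps fragments near the main fragment's ends", {
  main <- path_skeleton(400)  # 399 * 8 = 3192 nm along +x
  nodes <- main$nodes
  sat <- function(start_id, origin, m = 30) {
    data.frame(node_id = start_id + seq_len(m),
               parent_id = c(NA, start_id + seq_len(m - 1L)),
               x = origin[1] + (seq_len(m) - 1) * 8, y = origin[2],
               z = origin[3], radius = 10)
  }
  # three disconnected satellites is not a tree; trim operates on
  # fragments, so build them directly
  mk <- function(origin, base_id) {
    xyz <- cbind(origin[1] + (0:29) * 8, origin[2], origin[3])
    list(node_ids = base_id + seq_len(30L), cable_length = 232,
         connector_count = 0, xyz = xyz)
  }
  # satellite 12000 nm from both endpoints is discarded
  far <- mk(c(1500, 12000, 0), 1000L)
  # satellite touching one end is kept
  touch <- mk(c(0, 0, 0), 2000L)
  # satellite 4000 nm from one end, ~20000 from the other, is kept
  near_one <- mk(c(-4000, 0, 0), 3000L)
  all_nodes <- rbind(nodes,
                     do.call(rbind, lapply(list(far, touch, near_one),
                                           function(f) {
      data.frame(node_id = f$node_ids, parent_id = NA,
                 x = f$xyz[, 1], y = f$xyz[, 2], z = f$xyz[, 3],
                 radius = 10)
    })))
  fake_skel <- list(neuron_id = "t", nodes = all_nodes, soma_node = 1L)
  class(fake_skel) <- "skeleton"
  main_frag <- list(node_ids = nodes$node_id, cable_length = 3192,
                    connector_count = 0)
  mkfrag <- function(f) list(node_ids = f$node_ids, cable_length = 232,
                             connector_count = 0)
  kept <- trim_distal_fragments(
    list(main_frag, mkfrag(far), mkfrag(touch), mkfrag(near_one)),
    fake_skel)
  kept_ids <- lapply(kept, `[[`, "node_ids")
  expect_length(kept, 3L)
  expect_true(any(vapply(kept_ids, function(k) k[1] == touch$node_ids[1],
                         logical(1))))
  expect_true(any(vapply(kept_ids, function(k) k[1] == near_one$node_ids[1],
                         logical(1))))
  expect_false(any(vapply(kept_ids, function(k) k[1] == far$node_ids[1],
                          logical(1))))
  # a single fragment passes through unchanged
  expect_length(trim_distal_fragments(list(main_frag), fake_skel), 1L)
})

test_that("backbone extraction recovers a planted main path exactly", {
  skel <- path_skeleton(400)              # 3192 nm main path
  for (at in c(50L, 150L, 250L, 350L)) {
    skel <- add_twig(skel, at = at, m = sample(3:14, 1))
  }
  bb <- extract_backbone(skel, NULL)
  expect_setequal(bb$node_ids, 1:400)
  expect_length(bb$fragments, 1L)

  # degenerate neuron: everything below 80 nm yields an empty backbone
  tiny <- path_skeleton(5)
  expect_warning(bbt <- extract_backbone(tiny, NULL), "empty")
  expect_length(bbt$node_ids, 0L)
})

test_that("re-extracting a backbone retains its largest fragment", {
  ds <- cached_avp()
  skel <- ds$skeletons[[3]]
  bb <- extract_backbone(skel, ds$connectors)
  keep <- skel$nodes$node_id %in% bb$node_ids
  bb_skel <- skeleton(skel$neuron_id, skel$nodes[keep, ], validate = FALSE)
  bb_skel$nodes$parent_id[!(bb_skel$nodes$parent_id %in%
                              bb_skel$nodes$node_id)] <- NA_integer_
  bb2 <- extract_backbone(bb_skel, ds$connectors)
  len <- vapply(bb$fragments, `[[`, 0, "cable_length")
  largest <- bb$fragments[[which.max(len)]]$node_ids
  expect_true(all(largest %in% bb2$node_ids))
})

test_that("backbone is a subset of the skeleton and monotone in thresholds", {
  set.seed(42)
  for (i in 1:25) {
    skel <- random_skeleton(sample(10:50, 1), id = paste0("m", i))
    conn <- random_connectors(skel)
    base <- suppressWarnings(extract_backbone(skel, conn))
    expect_true(all(base$node_ids %in% skel$nodes$node_id))
    # raising the large-fragment threshold never adds fragments
    for (thr in c(3500, 5000)) {
      p <- backbone_params(large_fragment_min_len = thr)
      harder <- suppressWarnings(extract_backbone(skel, conn, p))
      expect_true(length(harder$fragments) <= length(base$fragments) ||
                    all(unlist(lapply(harder$fragments, `[[`, "node_ids"))
                        %in% unlist(lapply(base$fragments, `[[`,
                                           "node_ids"))))
    }
  }
})

test_that("backbone extraction matches the independent rule oracle", {
  skip_if_not_installed("igraph")
  set.seed(99)
  agree <- 0L
  n_trials <- 150L
  for (i in seq_len(n_trials)) {
    skel <- random_skeleton(sample(5:50, 1), id = paste0("o", i))
    conn <- random_connectors(skel)
    impl <- suppressWarnings(extract_backbone(skel, conn))
    oracle <- oracle_backbone_nodes(skel, conn)
    agree <- agree + as.integer(setequal(impl$node_ids, oracle))
  }
  expect_equal(agree, n_trials)
})

test_that("the per-fragment report accounts for every fragment", {
  ds <- cached_avp()
  skel <- ds$skeletons[[1]]
  rep <- backbone_fragment_report(skel, ds$connectors)
  expect_true(all(c("neuron_id", "fragment_id", "length_nm", "n_connectors",
                    "kept", "rule") %in% names(rep)))
  expect_true(any(rep$kept))
  expect_true(all(rep$rule %in% c("large", "too_short", "connector_density",
                                  "relative_length", "small_retained",
                                  "distal_trim")))
  bb <- extract_backbone(skel, ds$connectors)
  expect_equal(sum(rep$kept), length(bb$fragments))
})
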