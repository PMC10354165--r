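# uniform sample on an ideal torus surface/volume
torus_sample <- function(n, R = 1000, r = 200, center = c(0, 0, 0),
                         axis = c(0, 0, 1)) {
  theta <- stats::runif(n, 0, 2 * pi)
  u <- stats::runif(n, -r, r)
  v <- stats::runif(n, -r, r)
  keep <- u^2 + v^2 <= r^2
  theta <- theta[keep]; u <- u[keep]; v <- v[keep]
  b <- if (all(axis == c(0, 0, 1))) cbind(c(1, 0, 0), c(0, 1, 0)) else {
    ref <- c(1, 0, 0)
    e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    cbind(e1, e2)
  }
  d <- R + u
  pts <- outer(d * cos(theta), b[, 1]) + outer(d * sin(theta), b[, 2]) +
    outer(v, axis)
  sweep(pts, 2, center, `+`)
}

test_that("torus axis fitting recovers a planted ring", {
  set.seed(8)
  pts <- torus_sample(4000, R = 1000, r = 200)
  fit <- fit_torus_axis(pts, orient = c(0, 0, 1))
  expect_gt(abs(sum(fit$axis * c(0, 0, 1))), 0.999)
  expect_lt(abs(fit$ring_radius - 1000) / 1000, 0.02)
  expect_lt(max(abs(fit$center)), 30)

  # equivariance: rotating the cloud rotates the fitted axis
  ang <- 0.7
  Q <- rbind(c(1, 0, 0),
             c(0, cos(ang), -sin(ang)),
             c(0, sin(ang), cos(ang)))
  fit_rot <- fit_torus_axis(pts %*% t(Q), orient = as.numeric(Q %*% c(0, 0, 1)))
  expect_gt(abs(sum(fit_rot$axis * (Q %*% fit$axis))), 0.999)
  expect_lt(abs(fit_rot$ring_radius - fit$ring_radius) / 1000, 0.005)

  # collinear clouds are rejected
  line <- cbind(seq_len(50), 0, 0)
  expect_error(fit_torus_axis(line), "degenerate")
  expect_error(fit_torus_axis(pts[1:5, ]), "at least 10")
})

test_that("circular projection collapses azimuth and conserves mass", {
  model <- torus_axis_model(c(0, 0, 0), c(0, 0, 1), 1000)
  # identical (distance-to-axis, height) at different azimuths project
  # to the same point
  two <- rbind(c(1100, 0, 50),
               1100 * c(cos(137 * pi / 180), sin(137 * pi / 180), 0) +
                 c(0, 0, 50))
  pr <- circular_project(two, model)
  expect_equal(pr$u[1], pr$u[2], tolerance = 1e-9)
  expect_equal(pr$v[1], pr$v[2], tolerance = 1e-9)
  expect_equal(pr$u[1], 100, tolerance = 1e-9)
  expect_equal(pr$v[1], 50, tolerance = 1e-9)

  # a point on the ring circle maps to the origin of the section
  ring_pt <- c(1000 * cos(0.3), 1000 * sin(0.3), 0)
  pr0 <- circular_project(rbind(ring_pt), model)
  expect_equal(c(pr0$u, pr0$v), c(0, 0), tolerance = 1e-9)

  # conservation of point count and total weight, and exact distances
  set.seed(12)
  pts <- torus_sample(1500, R = 1000, r = 200)
  w <- stats::runif(nrow(pts), 0, 3)
  pr2 <- circular_project(pts, model, weight = w)
  expect_equal(nrow(pr2), nrow(pts))
  expect_equal(sum(pr2$weight), sum(w))
  d_axis <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  expect_equal(pr2$u + 1000, d_axis, tolerance = 1e-9)

  # a uniform torus sample projects into the tube disc around (0, 0)
  expect_true(all(pr2$u^2 + pr2$v^2 <= 200^2 + 1e-6))
  expect_true(any(pr2$u > 0) && any(pr2$u < 0) &&
                any(pr2$v > 0) && any(pr2$v < 0))
})

test_that("density profiles are conservative weighted histograms", {
  proj <- data.frame(u = c(0.1, 0.2, 0.15, 0.12), v = 0, weight = 1)
  h <- density_profile(proj, "u", bins = c(0, 1))
  expect_equal(h$mass, 4)

  empty <- density_profile(data.frame(u = numeric(0), v = numeric(0),
                                      weight = numeric(0)), "u", bins = 5)
  expect_true(all(empty$mass == 0))

  set.seed(3)
  proj2 <- data.frame(u = stats::rnorm(500), v = stats::rnorm(500),
                      weight = stats::runif(500))
  breaks <- seq(-4, 4, length.out = 11)
  h2 <- density_profile(proj2, "u", bins = breaks)
  expect_equal(sum(h2$mass), sum(proj2$weight))
  # matches brute-force binning
  for (b in seq_len(10)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    inb <- if (b < 10) proj2$u >= lo & proj2$u < hi else
      proj2$u >= lo & proj2$u <= hi
    expect_equal(h2$mass[b], sum(proj2$weight[inb]))
  }
})

test_that("domain occupancy localises planted groups and conserves totals", {
  ds <- cached_avp()
  er_types <- ds$scenario$er_types
  occ <- domain_occupancy(ds$connectors, ds$compartments, er_types,
                          domains = ds$scenario$eb_domains)
  # ER4d output was planted exclusively in the EBa domain
  expect_equal(unname(occ["ER4d", "EBa"]), 600)
  expect_equal(sum(occ["ER4d", setdiff(colnames(occ), "EBa")]), 0)
  # ER3 splits between EBic and EBip at the planted 900/200 budget
  expect_equal(unname(occ["ER3", "EBic"]), 900)
  expect_equal(unname(occ["ER3", "EBip"]), 200)
  # conservation against the region-filtered connector weight
  in_dom <- ds$connectors$compartment %in% ds$scenario$eb_domains &
    ds$connectors$pre %in% names(er_types) &
    ds$connectors$kind == "TBAR"
  expect_equal(sum(occ), sum(ds$connectors$weight[in_dom]))

  # column sums are invariant to refining the grouping
  coarse <- stats::setNames(rep("ER", length(er_types)), names(er_types))
  occ_c <- domain_occupancy(ds$connectors, ds$compartments, coarse,
                            domains = ds$scenario$eb_domains)
  expect_equal(colSums(occ_c), colSums(occ))
})

test_that("modal output layer breaks ties toward the lower layer", {
  conn <- connector_table(data.frame(
    synapse_id = paste0("s", 1:4), pre = "n", post = "p", kind = "TBAR",
    x = 0, y = 0, z = 0,
    compartment = c("FB_l2", "FB_l2", "FB_l7", "FB_l7"), weight = 1L))
  got <- modal_output_layer(conn, "n", paste0("FB_l", 1:9))
  expect_equal(unname(got), 2L)
})

test_that("topography correlation detects planted gradients and nulls", {
  layers <- paste0("FB_l", 1:9)
  mk <- function(ys) {
    rows <- do.call(rbind, lapply(seq_along(ys), function(i) {
      rbind(
        data.frame(pre = paste0("n", i), post = "col", kind = "TBAR",
                   x = 0, y = 0, z = 0, compartment = paste0("FB_l", i),
                   weight = 1L),
        data.frame(pre = "src", post = paste0("n", i), kind = "PSD",
                   x = 0, y = ys[i], z = 0, compartment = "SMP",
                   weight = 1L))
    }))
    rows$synapse_id <- paste0("s", seq_len(nrow(rows)))
    connector_table(rows)
  }
  catalog <- data.frame(neuron_id = paste0("n", 1:9), lineage = "L")
  # dendrites march posteriorly (lower y) with the layer index
  conn <- mk(-(1:9) * 1000)
  tc <- topography_correlation(catalog, conn, layers, axis = c(0, -1, 0))
  expect_equal(tc$rho, 1.0)
  expect_equal(tc$by_lineage$rho, 1.0)
  # reversing the anatomical axis flips the sign
  tc_rev <- topography_correlation(catalog, conn, layers, axis = c(0, 1, 0))
  expect_equal(tc_rev$rho, -1.0)

  # layer-independent random centroids give near-zero correlation
  set.seed(77)
  n <- 100
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(
      data.frame(pre = paste0("r", i), post = "col", kind = "TBAR",
                 x = 0, y = 0, z = 0,
                 compartment = paste0("FB_l", sample(1:9, 1)), weight = 1L),
      data.frame(pre = "src", post = paste0("r", i), kind = "PSD",
                 x = 0, y = stats::runif(1, -5000, 5000), z = 0,
                 compartment = "SMP", weight = 1L))
  }))
  rows$synapse_id <- paste0("s", seq_len(nrow(rows)))
  null_cat <- data.frame(neuron_id = paste0("r", 1:n), lineage = "N")
  tc0 <- topography_correlation(null_cat, connector_table(rows), layers,
                                axis = c(0, -1, 0))
  expect_lt(abs(tc0$rho), 0.2)

  # lineages with fewer than three informative neurons report NA
  small <- topography_correlation(catalog[1:2, ], conn, layers,
                                  axis = c(0, -1, 0))
  expect_true(is.na(small$by_lineage$rho))
})
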