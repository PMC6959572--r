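test_that("Sholl counts crossings of straight and branched dendrites", {
  # one straight 55-um dendrite: radii 10..50 crossed once, 60 not
  straight <- neuron_tree(data.frame(
    id = 1:2, type = c(1, 3), x = c(0, 55), y = 0, z = 0, radius = 1,
    parent = c(-1, 1)))
  sh <- sholl(straight)
  expect_equal(sh$intersections[sh$radius_um <= 50], rep(1L, 5))
  expect_equal(sh$intersections[sh$radius_um == 60], 0L)
  # Y-branch at 25 um, both children to 45 um from the soma
  yb <- neuron_tree(data.frame(
    id = 1:4, type = c(1, 3, 3, 3),
    x = c(0, 25, 25 + 20 * cos(0.4), 25 + 20 * cos(-0.4)),
    y = c(0, 0, 20 * sin(0.4), 20 * sin(-0.4)),
    z = 0, radius = 1, parent = c(-1, 1, 2, 2)))
  shy <- sholl(yb, max_radius_um = 60)
  # trunk crosses r = 10 and 20; both children cross r = 30 and 40
  # (tips lie ~44 um from the soma); nothing reaches 50
  expect_equal(shy$intersections, c(1L, 1L, 2L, 2L, 0L, 0L))
  expect_equal(attr(shy, "sum"), 6L)
})

test_that("Sholl equals the dense-sampling oracle on 50 random trees", {
  for (s in 1:50) {
    tr <- random_tree(s)
    rmax <- max(sqrt(tr$nodes$x^2 + tr$nodes$y^2 + tr$nodes$z^2)) + 10
    got <- sholl(tr, max_radius_um = rmax)$intersections
    expect_equal(got, sholl_oracle(tr, max_radius_um = rmax),
                 info = paste("tree seed", s))
  }
})

test_that("tree metrics match hand-enumerated trees and are rotation invariant", {
  single <- neuron_tree(data.frame(
    id = 1:2, type = c(1, 3), x = c(0, 100), y = 0, z = 0, radius = 1,
    parent = c(-1, 1)))
  m1 <- tree_metrics(single)
  expect_equal(unlist(m1[c("total_length_um", "n_branches",
                           "n_branch_points", "n_end_tips",
                           "max_branch_order")]),
               c(100, 1, 0, 1, 1), ignore_attr = TRUE)
  # symmetric binary tree of depth 2 with 50-um segments:
  # 7 branches, 350 um, 3 branch points, 4 tips, max order 3
  ang <- c(0.5, -0.5)
  nodes <- data.frame(id = 1, type = 1, x = 0, y = 0, z = 0, radius = 1,
                      parent = -1)
  nodes <- rbind(nodes, data.frame(id = 2, type = 3, x = 50, y = 0, z = 0,
                                   radius = 1, parent = 1))
  nid <- 2
  lvl1 <- c()
  for (a in ang) {
    nid <- nid + 1
    nodes <- rbind(nodes, data.frame(id = nid, type = 3,
                                     x = 50 + 50 * cos(a),
                                     y = 50 * sin(a), z = 0, radius = 1,
                                     parent = 2))
    lvl1 <- c(lvl1, nid)
  }
  for (p in lvl1) {
    for (a in ang) {
      nid <- nid + 1
      nodes <- rbind(nodes, data.frame(id = nid, type = 3,
                                       x = nodes$x[nodes$id == p] +
                                         50 * cos(a),
                                       y = nodes$y[nodes$id == p] +
                                         50 * sin(a),
                                       z = 0, radius = 1, parent = p))
    }
  }
  bt <- neuron_tree(nodes)
  mb <- tree_metrics(bt)
  expect_equal(mb$total_length_um, 350)
  expect_equal(mb$n_branches, 7)
  expect_equal(mb$n_branch_points, 3)
  expect_equal(mb$n_end_tips, 4)
  expect_equal(mb$max_branch_order, 3)
  # rigid rotation leaves every metric unchanged
  th <- 0.7
  rot <- nodes
  rot$x <- nodes$x * cos(th) - nodes$y * sin(th)
  rot$y <- nodes$x * sin(th) + nodes$y * cos(th)
  mr <- tree_metrics(neuron_tree(rot))
  expect_equal(mr$total_length_um, mb$total_length_um)
  expect_equal(mr$n_branch_points, mb$n_branch_points)
  # cyclic input is rejected
  cyc <- data.frame(id = 1:3, type = 3, x = 0:2, y = 0, z = 0, radius = 1,
                    parent = c(3, 1, 2))
  expect_error(neuron_tree(cyc), "root|cyclic")
})

test_that("SWC files round-trip into trees", {
  path <- file.path(tempdir(), "n.swc")
  writeLines(c("# synthetic test neuron",
               "1 1 0 0 0 5 -1",
               "2 3 30 0 0 1 1",
               "3 3 60 10 0 1 2",
               "4 3 60 -10 0 1 2"), path)
  tr <- read_swc(path)
  m <- tree_metrics(tr)
  expect_equal(m$n_branches, 3)
  expect_equal(m$n_end_tips, 2)
  unlink(path)
})

test_that("soma metrics: circle, ellipse and joint rotation", {
  geom <- pixel_geometry(0.12)
  # circle of radius 5 um
  r_px <- 5 / 0.12
  circ <- synaptoglia:::.mask_ellipse(120, 120, 60, 60, r_px, r_px)
  sm <- soma_metrics(circ, geom, apical_angle_rad = 0)
  expect_equal(sm$area_um2, pi * 25, tolerance = 0.03)
  expect_equal(sm$diameter_um, 10, tolerance = 0.05)
  # 10 x 6 um ellipse with the apical axis along the major axis:
  # the perpendicular diameter is the 6-um minor axis
  ell <- synaptoglia:::.mask_ellipse(120, 120, 60, 60, 5 / 0.12,
                                     3 / 0.12)
  se <- soma_metrics(ell, geom, apical_angle_rad = 0)
  expect_equal(se$diameter_um, 6, tolerance = 0.06)
  # rotating mask and axis together changes nothing
  th <- pi / 5
  ellr <- synaptoglia:::.mask_ellipse(120, 120, 60, 60, 5 / 0.12,
                                      3 / 0.12, theta = th)
  ser <- soma_metrics(ellr, geom, apical_angle_rad = th)
  expect_equal(ser$diameter_um, se$diameter_um, tolerance = 0.05)
  expect_equal(ser$area_um2, se$area_um2, tolerance = 0.02)
  expect_error(soma_metrics(matrix(FALSE, 5, 5), geom, 0), "empty")
})

test_that("soma transcript coverage is the masked pixel fraction", {
  soma <- matrix(FALSE, 30, 30); soma[10:19, 10:19] <- TRUE
  full <- matrix(200, 30, 30)
  expect_equal(soma_transcript_coverage(soma, full, value = 50), 100)
  none <- matrix(0, 30, 30)
  expect_equal(soma_transcript_coverage(soma, none, value = 50), 0)
  # planted 5x5 supra-threshold patch inside the soma
  patch <- matrix(0, 30, 30); patch[12:16, 12:16] <- 120
  expect_equal(soma_transcript_coverage(soma, patch, value = 50),
               100 * 25 / 100)
  expect_error(soma_transcript_coverage(matrix(FALSE, 3, 3), none,
                                        value = 1), "empty")
})

test_that("relative expression: calibrator identity, per-cycle doubling, invariances", {
  mk <- function(sample, group, c4, refs = c(20, 21, 22)) {
    data.frame(sample = sample, group = group,
               gene = c("C4", "Gapdh", "Actb", "Hprt"),
               ct = c(c4, refs))
  }
  tab <- rbind(mk("a", "ctrl", 28), mk("b", "ctrl", 28),
               mk("c", "test", 27))
  re <- relative_expression(tab, "C4", calibrator = "ctrl")
  expect_equal(re$samples$fold[re$samples$group == "ctrl"], c(1, 1))
  # one cycle lower -> fold 2
  expect_equal(re$samples$fold[re$samples$sample == "c"], 2)
  # adding a constant to every Ct changes nothing
  tab2 <- tab; tab2$ct <- tab2$ct + 3.7
  re2 <- relative_expression(tab2, "C4", calibrator = "ctrl")
  expect_equal(re2$samples$fold, re$samples$fold)
  # incomplete reference set excludes the sample with a message
  tab3 <- rbind(tab, data.frame(sample = "d", group = "test",
                                gene = c("C4", "Gapdh"), ct = c(26, 20)))
  expect_message(re3 <- relative_expression(tab3, "C4",
                                            calibrator = "ctrl"),
                 "excluded")
  expect_false("d" %in% re3$samples$sample)
})

test_that("a synthetic 2.84-fold cohort is recovered with noisy triplicates", {
  set.seed(77)
  rows <- list()
  for (i in 1:12) {
    grp <- if (i <= 6) "control" else "overexpression"
    shift <- if (grp == "overexpression") -log2(2.84) else 0
    for (g in c("C4", "Gapdh", "Actb", "Hprt")) {
      mu <- if (g == "C4") 28 + shift else 20
      rows[[length(rows) + 1]] <- data.frame(
        sample = paste0("s", i), group = grp, gene = g,
        ct = stats::rnorm(3, mu, 0.2))
    }
  }
  re <- relative_expression(do.call(rbind, rows), "C4",
                            calibrator = "control")
  grp <- re$groups[re$groups$group == "overexpression", ]
  ci <- 1.96 * grp$sem_fold
  expect_gt(2.84, grp$mean_fold - 2 * ci)
  expect_lt(2.84, grp$mean_fold + 2 * ci)
  expect_equal(grp$mean_fold, 2.84, tolerance = 0.15)
})
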