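# PA = (C, L, PHY, S), classification, and panel summaries

test_that("the four structure indices follow their defining formulas", {
  expect_identical(convergence_index(1, 1), 10)
  expect_equal(convergence_index(80, 200), 4.0)
  expect_equal(convergence_index(0, 5), 0)
  expect_error(convergence_index(80, 0), "positive")
  expect_error(convergence_index(80, -2), "positive")

  expect_equal(leaf_structure_index(1.0, 45), 45)
  expect_equal(leaf_structure_index(0.5, 90), 45)
  expect_equal(leaf_structure_index(2 / pi, 90), 180 / pi, tolerance = 1e-12)

  expect_equal(phytomer_structure_index(300, 10), 30)
  expect_equal(phytomer_structure_index(540, 9), 60)
  expect_equal(phytomer_structure_index(0, 5), 0)
  expect_error(phytomer_structure_index(300, 0), "positive")

  expect_equal(stem_structure_index(c(0, 45, 90)), c(0, 45, 90))
  expect_error(stem_structure_index(200), "\\[0, 180\\]")
})

test_that("classification maps the published class anchors correctly", {
  expect_equal(classify_architecture(1.95), "loose")
  expect_equal(classify_architecture(4.12), "semi-compact")
  expect_equal(classify_architecture(9.56), "compact")
  expect_equal(classify_architecture(c(2.87, 5.72)), rep("semi-compact", 2))
  expect_equal(classify_architecture(6.36), "compact")
  # boundary behaviour at the midpoint thresholds
  expect_equal(classify_architecture(2.41 - 1e-9), "loose")
  expect_equal(classify_architecture(2.41), "semi-compact")
  expect_equal(classify_architecture(6.04), "compact")
  expect_error(classify_architecture(0), "positive")
  expect_error(classify_architecture(-1), "positive")
  # monotone and total on a grid
  grid <- seq(0.1, 12, by = 0.1)
  cls <- classify_architecture(grid)
  lev <- c(loose = 1, `semi-compact` = 2, compact = 3)
  expect_true(all(diff(lev[cls]) >= 0))
})

test_that("PA of a hand-built two-phytomer stem equals the hand-derived values", {
  oc <- phytomer3d:::organ_component
  mkcomp <- phytomer3d:::assembled_component
  # stem: internodes 10 and 8 on the z axis; straight horizontal leaves;
  # 5 cm ear; a 1 cm^2 square of spike vertices so S_area is non-degenerate.
  int1 <- oc(skeleton = skeleton_model(rbind(c(0, 0, 0), c(0, 0, 10))))
  int2 <- oc(skeleton = skeleton_model(rbind(c(0, 0, 10), c(0, 0, 18))))
  leaf1 <- oc(skeleton = skeleton_model(rbind(c(0, 0, 10), c(0, 8, 10))),
              widths = c(1.0, 1.5))
  leaf2 <- oc(skeleton = skeleton_model(rbind(c(0, 0, 18), c(12, 0, 18))),
              widths = c(2.0, 1.2))
  ear_mesh <- mesh_model(rbind(c(-0.5, -0.5, 23), c(0.5, -0.5, 23),
                               c(0.5, 0.5, 23), c(-0.5, 0.5, 23)),
                         rbind(c(1, 2, 3), c(1, 3, 4)))
  ear <- oc(mesh = ear_mesh,
            skeleton = skeleton_model(rbind(c(0, 0, 18), c(0, 0, 23))))
  stem <- structure(list(plant = 1, tiller = 1, n = 2, components = list(
    mkcomp(1, 1, 1, "internode", int1), mkcomp(1, 1, 1, "leaf", leaf1),
    mkcomp(1, 1, 2, "internode", int2), mkcomp(1, 1, 2, "leaf", leaf2),
    mkcomp(1, 1, 2, "appendage", ear))), class = "assembled_stem")
  shoot <- structure(list(plant = 1, stems = list(stem)), class = "assembled_shoot")

  pa <- plant_architecture_vector(shoot)
  # hand derivation:
  #   h = 23 (top of the ear); S_area = 1 (unit square) -> C = 230
  #   L_bend = 1 for both straight leaves, theta_l = 90 -> L = 90
  #   S_phy(1) = 10 * 8 * 1.5 = 120 ; S_phy(2) = (8 + 5) * 12 * 2 = 312
  #   N_length = 9 -> PHY = mean(120, 312)/9 = 24
  #   theta_s = 0 -> S = 0
  expect_equal(pa$C, 230, tolerance = 1e-9)
  expect_equal(pa$L, 90, tolerance = 1e-9)
  expect_equal(pa$PHY, 24, tolerance = 1e-9)
  expect_equal(pa$S, 0, tolerance = 1e-9)
  expect_equal(pa$class, "compact")

  # flag-leaf / top-phytomer aggregation keeps only rank 2
  pa_top <- plant_architecture_vector(shoot, aggregate = "flag_leaf")
  expect_equal(pa_top$PHY, 312 / 9, tolerance = 1e-9)
  expect_equal(pa_top$L, 90, tolerance = 1e-9)
})

test_that("PA is invariant under z-rotation and duplication changes only C", {
  set.seed(31)
  cfg <- synthetic_config(m = 2, n = 3, internode_lengths = c(9, 12, 16), stem_lean = 14)
  shoot <- shoot_from_digitized(generate_shoot(cfg)$plant)
  pa0 <- plant_architecture_vector(shoot)
  rot <- apply_transform(shoot, rotation_about_vertical(123.4))
  pa1 <- plant_architecture_vector(rot)
  for (v in c("C", "L", "PHY", "S")) expect_equal(pa1[[v]], pa0[[v]], tolerance = 1e-9)

  # duplicating a tiller (shifted in XY) leaves L, PHY, S unchanged; C moves
  # only through S_area
  dup <- shoot
  extra <- apply_transform(shoot$stems[[1]], rigid_transform(diag(3), c(6, 0, 0)))
  dup$stems <- c(dup$stems, list(extra))
  pa2 <- plant_architecture_vector(dup)
  expect_equal(pa2$L, pa0$L, tolerance = 1e-9)
  expect_equal(pa2$PHY, pa0$PHY, tolerance = 1e-9)
  expect_equal(pa2$S, pa0$S, tolerance = 1e-9)
  h <- plant_height(dup)
  expect_equal(pa2$C, h * 10 / spike_layer_projected_area(dup), tolerance = 1e-9)
})

test_that("C is monotone in h and S_area as the compactness story requires", {
  expect_gt(convergence_index(90, 150), convergence_index(80, 150))
  expect_lt(convergence_index(80, 200), convergence_index(80, 150))
})

test_that("panel_summary computes replicate spread and Pearson correlations", {
  rows <- data.frame(cultivar = rep("A", 3), replicate = 1:3,
                     C = 4, L = 50, PHY = 30, S = 10)
  ps <- panel_summary(rows)
  expect_equal(ps$summary$C_sd, 0)
  expect_equal(ps$summary$S_range, 0)
  expect_setequal(ps$degenerate, c("C", "L", "PHY", "S"))

  rows2 <- data.frame(cultivar = c("A", "B"), replicate = 1,
                      C = c(20, 10), L = c(1, 2), PHY = c(5, 6), S = c(10, 20))
  ps2 <- panel_summary(rows2)
  expect_equal(ps2$correlations["S", "C"], -1, tolerance = 1e-12)
  expect_true(isSymmetric(ps2$correlations))
  expect_equal(diag(ps2$correlations), c(C = 1, L = 1, PHY = 1, S = 1))

  set.seed(33)
  rows3 <- data.frame(cultivar = rep(1:10, each = 3), replicate = rep(1:3, 10),
                      C = runif(30, 1, 10), L = runif(30, 20, 70),
                      PHY = runif(30, 10, 60), S = runif(30, 0, 30))
  ps3 <- panel_summary(rows3)
  X <- as.matrix(rows3[, c("C", "L", "PHY", "S")])
  # brute-force Pearson from raw sums
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    xi <- X[, i] - mean(X[, i]); xj <- X[, j] - mean(X[, j])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(ps3$correlations), oracle, tolerance = 1e-12)
  expect_true(all(abs(ps3$correlations) <= 1))
  expect_error(panel_summary(data.frame()), "empty")
})
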