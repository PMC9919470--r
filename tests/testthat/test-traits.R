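# multi-scale trait extraction: curvature, angles, envelope, height, layer area

test_that("blade_curvature matches the analytic chord/arc oracles", {
  straight <- cbind(seq(0, 10, length.out = 30), 0, 0)
  expect_equal(blade_curvature(straight), 1.0, tolerance = 1e-12)
  th <- seq(0, pi, length.out = 200)                      # semicircle, r = 1
  semi <- cbind(cos(th), sin(th), 0)
  expect_equal(blade_curvature(semi), 2 / pi, tolerance = 1e-3)
  th <- seq(0, pi / 2, length.out = 200)                  # quarter circle
  expect_equal(blade_curvature(cbind(cos(th), sin(th), 0)), 2 * sqrt(2) / pi,
               tolerance = 1e-3)
  expect_error(blade_curvature(rbind(c(0, 0, 0), c(0, 0, 0))), ".")
  # scale invariance
  set.seed(2)
  poly <- cbind(cumsum(runif(10)), cumsum(runif(10)), cumsum(runif(10)))
  expect_equal(blade_curvature(poly * 7.3), blade_curvature(poly), tolerance = 1e-12)
})

test_that("stem_leaf_angle spans [0, 180]", {
  expect_equal(stem_leaf_angle(c(0, 0, 1), c(0, 0, 2)), 0)
  expect_equal(stem_leaf_angle(c(0, 0, 1), c(1, 0, 0)), 90)
  expect_equal(stem_leaf_angle(c(0, 0, 1), c(0, 0, -1)), 180)
  expect_error(stem_leaf_angle(c(0, 0, 0), c(1, 0, 0)), "zero vector")
})

test_that("phytomer_envelope is the three-length product of its definition", {
  oc <- phytomer3d:::organ_component
  internode <- oc(skeleton = skeleton_model(rbind(c(0, 0, 0), c(0, 0, 10))))
  leaf <- oc(skeleton = skeleton_model(rbind(c(0, 0, 10), c(7, 0, 12), c(15, 0, 10))),
             widths = c(1.0, 2.0, 1.4))
  # tip (15, 0, 10): perpendicular distance to the z axis = 15; max width 2
  expect_equal(phytomer_envelope(internode, leaf, spike_length = 0), 10 * 15 * 2)
  expect_equal(phytomer_envelope(internode, leaf, spike_length = 8), 18 * 15 * 2)
  onaxis <- oc(skeleton = skeleton_model(rbind(c(0, 0, 10), c(1, 0, 12), c(0, 0, 14))),
               widths = 1)
  expect_warning(v <- phytomer_envelope(internode, onaxis), "internode axis")
  expect_equal(v, 0, tolerance = 1e-12)
  expect_error(phytomer_envelope(internode, NULL), "without a leaf")
})

test_that("average_internode_length is the arithmetic mean", {
  expect_equal(average_internode_length(c(10, 8)), 9)
  expect_equal(average_internode_length(7), 7)
  set.seed(4)
  L <- runif(10, 3, 30)
  expect_equal(average_internode_length(L), sum(L) / 10, tolerance = 1e-12)
})

test_that("stem_vertical_angle measures inclination from +z", {
  expect_equal(stem_vertical_angle(stem_trace(rbind(c(0, 0, 0), c(0, 0, 50)))), 0)
  expect_equal(stem_vertical_angle(stem_trace(rbind(c(0, 0, 0), c(50, 0, 0)))), 90)
  expect_equal(stem_vertical_angle(stem_trace(rbind(c(0, 0, 0), c(10, 0, 10)))), 45,
               tolerance = 1e-9)
})

test_that("plant_height follows the spike top, including under lean", {
  # leaning stem of total length 100 at 30 degrees: h = 100 cos(30)
  cfg <- synthetic_config(m = 1, n = 3, internode_lengths = c(30, 30, 30),
                          ear_length = 10, stem_lean = 30)
  shoot <- shoot_from_digitized(generate_shoot(cfg)$plant)
  expect_equal(plant_height(shoot), 100 * cos(pi / 6), tolerance = 1e-6)
  # vertical: h = sum of internodes + ear
  cfg0 <- synthetic_config(m = 1, n = 3, internode_lengths = c(30, 30, 20),
                           ear_length = 0.5, stem_lean = 0)
  shoot0 <- shoot_from_digitized(generate_shoot(cfg0)$plant)
  expect_equal(plant_height(shoot0), 80.5, tolerance = 1e-9)
  # no spike: fallback with warning
  noear <- shoot0
  noear$stems[[1]]$components <-
    Filter(function(c) c$organ != "appendage", noear$stems[[1]]$components)
  expect_warning(h <- plant_height(noear), "no spike")
  expect_gt(h, 0)
})

test_that("spike_layer_projected_area is the XY hull of the spike layer", {
  oc <- phytomer3d:::organ_component
  mk_shoot <- function(pts) {
    comps <- lapply(seq_len(nrow(pts)), function(i)
      phytomer3d:::assembled_component(1, i, 1, "appendage",
        oc(skeleton = skeleton_model(rbind(pts[i, ], pts[i, ] + c(0, 0, 1e-3))))))
    structure(list(plant = 1,
                   stems = list(structure(list(plant = 1, tiller = 1, n = 1,
                                               components = comps),
                                          class = "assembled_stem"))),
              class = "assembled_shoot")
  }
  square <- rbind(c(0, 0, 50), c(1, 0, 50), c(1, 1, 50), c(0, 1, 50))
  expect_equal(spike_layer_projected_area(mk_shoot(square)), 1.0, tolerance = 1e-9)
  line <- cbind(seq(0, 1, length.out = 5), 0, 50)
  expect_warning(a <- spike_layer_projected_area(mk_shoot(line)), "degenerate")
  expect_equal(a, 0)
})

test_that("traits are invariant under vertical rotation + XY translation", {
  set.seed(21)
  cfg <- synthetic_config(m = 2, n = 3, internode_lengths = c(9, 13, 17), stem_lean = 12)
  shoot <- shoot_from_digitized(generate_shoot(cfg)$plant)
  t0 <- extract_traits(shoot)
  for (i in 1:5) {
    t1 <- extract_traits(apply_transform(shoot, random_vertical_motion()))
    expect_equal(t1$value, t0$value, tolerance = 1e-6)
  }
})

test_that("height and layer area follow the s / s^2 scaling laws", {
  cfg <- synthetic_config(m = 3, n = 3, internode_lengths = c(9, 13, 17), stem_lean = 15)
  shoot <- shoot_from_digitized(generate_shoot(cfg)$plant)
  s <- 2.5
  big <- scale_shoot(shoot, s)
  expect_equal(plant_height(big), s * plant_height(shoot), tolerance = 1e-9)
  expect_equal(spike_layer_projected_area(big),
               s^2 * spike_layer_projected_area(shoot), tolerance = 1e-9)
  # L_bend is dimensionless
  vein <- shoot$stems[[1]]$components[[2]]$skeleton$polyline
  expect_equal(blade_curvature(vein * s), blade_curvature(vein), tolerance = 1e-12)
})

test_that("extract_traits emits the full keyed table", {
  cfg <- synthetic_config(m = 2, n = 4)
  shoot <- shoot_from_digitized(generate_shoot(cfg)$plant)
  tr <- extract_traits(shoot)
  expect_setequal(unique(tr$trait),
                  c("L_bend", "theta_l", "S_phy", "N_length", "theta_s", "h", "S_area"))
  expect_equal(sum(tr$trait == "L_bend"), 2 * 4)
  expect_equal(sum(tr$trait == "theta_s"), 2)
  expect_equal(sum(tr$trait == "h"), 1)
  expect_true(all(tr$value[tr$trait == "L_bend"] <= 1 &
                    tr$value[tr$trait == "L_bend"] > 0))
  expect_true(all(tr$value >= 0))
})
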