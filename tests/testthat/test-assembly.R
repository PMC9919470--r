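# rigid-transform algebra, tiller/shoot assembly, template similarity

test_that("rotation_about_vertical behaves as the z-rotation group", {
  expect_points_equal(rotation_about_vertical(0)$rotation, diag(3), 1e-15)
  p <- apply_transform(matrix(c(1, 0, 0), 1), rotation_about_vertical(90))
  expect_points_equal(p, matrix(c(0, 1, 0), 1), 1e-12)
  expect_points_equal(rotation_about_vertical(360)$rotation, diag(3), 1e-12)
  expect_error(rigid_transform(matrix(1:9, 3, 3)), "orthonormal")
})

test_that("apply_transform preserves structure and pairwise distances", {
  set.seed(5)
  m <- random_mesh(15)
  expect_equal(apply_transform(m, rigid_transform())$vertices, m$vertices)
  up <- apply_transform(m, rigid_transform(diag(3), c(0, 0, 10)))
  expect_equal(up$vertices[, 3], m$vertices[, 3] + 10)
  expect_equal(up$faces, m$faces)
  for (i in 1:5) {
    tf <- random_transform()
    m2 <- apply_transform(m, tf)
    expect_lt(max(abs(dist(m2$vertices) - dist(m$vertices))), 1e-9)
  }
})

test_that("transform composition is associative and invertible", {
  set.seed(6)
  a <- random_transform(); b <- random_transform(); c_ <- random_transform()
  v <- matrix(rnorm(30), 10, 3)
  lhs <- apply_transform(v, compose_transforms(a, compose_transforms(b, c_)))
  rhs <- apply_transform(apply_transform(apply_transform(v, c_), b), a)
  expect_points_equal(lhs, rhs, 1e-9)
  ident <- compose_transforms(a, invert_transform(a))
  expect_points_equal(ident$rotation, diag(3), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)
})

test_that("single-phytomer stacked assembly reproduces the template", {
  tpl <- template_set(L = 12, ear_on_top = TRUE)
  stem <- assemble_tiller(tiller_spec(1, 1, "tpl1"), tpl)
  expect_length(stem$components, 3)  # internode + leaf + appendage
  int <- Filter(function(c) c$organ == "internode", stem$components)[[1]]
  expect_points_equal(int$skeleton$polyline, tpl$tpl1$internode$skeleton$polyline, 1e-12)
})

test_that("stacked heights follow the cumulative-sum oracle", {
  tpl <- template_set(L = c(10, 8))
  stem <- assemble_tiller(tiller_spec(1, 1, c("tpl1", "tpl2")), tpl)
  ints <- Filter(function(c) c$organ == "internode", stem$components)
  upper <- ints[[which(vapply(ints, `[[`, integer(1), "rank") == 2)]]
  expect_equal(upper$skeleton$polyline[1, 3], 10, tolerance = 1e-9)
  expect_equal(upper$skeleton$polyline[2, 3], 18, tolerance = 1e-9)
  # base of phytomer k+1 coincides with top node of phytomer k
  lower <- ints[[which(vapply(ints, `[[`, integer(1), "rank") == 1)]]
  expect_points_equal(upper$skeleton$polyline[1, ], lower$skeleton$polyline[2, ], 1e-6)
})

test_that("stacked assembly conserves total stem length (random tillers)", {
  set.seed(11)
  for (i in 1:8) {
    n <- sample(2:5, 1)
    L <- runif(n, 5, 25)
    tpl <- template_set(L = L)
    stem <- assemble_tiller(tiller_spec(1, 1, names(tpl), azimuths = runif(n, 0, 360)), tpl)
    top <- phytomer3d:::stem_endpoints(stem)$top
    expect_lt(abs(top[3] - sum(L)), 1e-6)
    expect_equal(internode_lengths(stem), L, tolerance = 1e-9)
  }
})

test_that("assembled leaf azimuths equal the spec azimuths", {
  tpl <- template_set(L = c(10, 9, 8))
  az <- c(0, 120, 240)
  stem <- assemble_tiller(tiller_spec(1, 1, names(tpl), azimuths = az), tpl)
  leaves <- Filter(function(c) c$organ == "leaf", stem$components)
  got <- sapply(leaves, function(c) polyline_azimuth(c$skeleton$polyline))
  ranks <- vapply(leaves, `[[`, integer(1), "rank")
  expect_equal(sort(abs(((got[order(ranks)] - az + 180) %% 360) - 180)),
               c(0, 0, 0), tolerance = 1e-6)
})

test_that("explicit heights override stacking and must be monotone", {
  tpl <- template_set(L = c(10, 8))
  stem <- assemble_tiller(tiller_spec(1, 1, c("tpl1", "tpl2"), heights = c(0, 14)), tpl)
  ints <- Filter(function(c) c$organ == "internode", stem$components)
  upper <- ints[[which(vapply(ints, `[[`, integer(1), "rank") == 2)]]
  expect_equal(upper$skeleton$polyline[1, 3], 14, tolerance = 1e-9)
  expect_error(tiller_spec(1, 1, c("a", "b"), heights = c(14, 0)), "non-decreasing")
  expect_error(tiller_spec(1, 1, character(0)), "at least one")
  expect_error(assemble_tiller(tiller_spec(1, 1, "nope"), tpl), "not found")
})

test_that("shoot assembly preserves tiller count, provenance and relative angles", {
  tpl <- template_set(L = c(10, 8))
  one <- assemble_tiller(tiller_spec(1, 1, names(tpl)), tpl)
  sh1 <- assemble_shoot(shoot_spec(1, list(tiller_spec(1, 1, names(tpl)))), tpl)
  expect_length(sh1$stems, 1)
  expect_points_equal(phytomer3d:::shoot_points(sh1), phytomer3d:::shoot_points(one), 1e-12)

  specs <- lapply(1:8, function(j) tiller_spec(1, j, names(tpl)))
  tfs <- lapply(1:8, function(j) rigid_transform(diag(3), c(cos(j), sin(j), 0)))
  sh8 <- assemble_shoot(shoot_spec(1, specs, tfs), tpl)
  expect_length(sh8$stems, 8)
  prov <- unique(t(sapply(unlist(lapply(sh8$stems, `[[`, "components"), recursive = FALSE),
                          function(c) c(c$tiller, c$rank, c$organ))))
  expect_equal(nrow(prov), 8 * 2 * 2 + 8)  # 8 tillers x 2 ranks x (internode+leaf) + 8 ears

  # whole-shoot z-rotation leaves every stem inclination unchanged
  th0 <- sapply(sh8$stems, stem_vertical_angle)
  rot <- apply_transform(sh8, rotation_about_vertical(37))
  expect_equal(sapply(rot$stems, stem_vertical_angle), th0, tolerance = 1e-9)
})

test_that("similarity selection agrees with a brute-force z-scored search", {
  set.seed(13)
  tdb <- lapply(1:20, function(i)
    list(params = list(L_internode = runif(1, 5, 25), L_leaf = runif(1, 10, 30),
                       theta_leaf = runif(1, 10, 80))))
  names(tdb) <- sprintf("t%02d", 1:20)
  X <- t(sapply(tdb, function(t) unlist(t$params)))
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  for (i in 1:10) {
    q <- c(L_internode = runif(1, 5, 25), L_leaf = runif(1, 10, 30),
           theta_leaf = runif(1, 10, 80))
    Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    zq <- (q - mu) / sdv
    oracle <- names(tdb)[which.min(rowSums(sweep(Z, 2, zq)^2))]
    expect_equal(select_template_by_similarity(q, tdb), oracle)
  }
  # exact parameter match wins with zero distance
  q0 <- unlist(tdb$t07$params)
  expect_equal(select_template_by_similarity(q0, tdb), "t07")
  # exact tie resolves to the earlier insertion index; constant parameters
  # are dropped from scoring with a warning
  tie <- list(a = list(params = list(p = 1, q = 5)), b = list(params = list(p = 3, q = 5)))
  expect_warning(got <- select_template_by_similarity(c(p = 2, q = 5), tie), "zero-variance")
  expect_equal(got, "a")
  expect_error(select_template_by_similarity(c(p = 1), list()), "empty")
})
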