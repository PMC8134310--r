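test_that("virtual grid geometry reproduces the physical 5-mm lattice", {
  g <- template_grid()
  expect_equal(g$n_rows, 13)
  expect_equal(g$n_cols, 13)
  # origin hole under an identity calibration is the stored origin
  expect_equal(hole_position(g, c("A", "1"))$xyz, g$origin_hole$xyz)
  # adjacent holes differ by exactly the pitch
  expect_identical(pt_distance(hole_position(g, c("A", "1")),
                               hole_position(g, c("A", "2"))), 5)
  expect_identical(pt_distance(hole_position(g, c("A", "1")),
                               hole_position(g, c("B", "1"))), 5)
  expect_error(hole_position(g, c("Z", "1")), "row label 'Z'")
  expect_error(hole_position(g, c("A", "99")), "column label '99'")
  expect_error(template_grid(axis_row = c(1, 0, 0), axis_col = c(1, 0, 0)),
               "orthogonal")

  # all pairwise hole distances match a brute-force lattice construction
  g4 <- template_grid(n_rows = 4, n_cols = 4)
  holes <- do.call(rbind, lapply(g4$row_labels, function(r)
    t(sapply(g4$col_labels, function(cl) hole_position(g4, c(r, cl))$xyz))))
  brute <- as.matrix(expand.grid(col = 0:3, row = 0:3))[, c("col", "row")] * 5
  brute <- cbind(brute, 0)
  brute <- sweep(brute, 2, -g4$origin_hole$xyz)
  expect_equal(as.numeric(dist(holes)), as.numeric(dist(brute)),
               tolerance = 1e-12)
})

test_that("calibration recovers known poses and flags degenerate fiducials", {
  fids <- default_fiducials()
  set.seed(21)
  truth <- rand_rigid("TEMPLATE", "LOWFIELD", max_deg = 15)
  picked <- lapply(fids$positions, function(p) rt_apply(truth, p))
  cal <- calibrate(fids, picked, observer = "C1")
  expect_equal(cal$fre, 0, tolerance = 1e-9)
  expect_equal(cal$transform$rotation, truth$rotation, tolerance = 1e-9)

  # label-based correspondence reorders picks
  cal2 <- calibrate(fids, picked[c(3, 1, 2)], observer = "C1",
                    labels = fids$labels[c(3, 1, 2)])
  expect_equal(cal2$transform$translation, truth$translation,
               tolerance = 1e-9)

  # with pick noise the FRE is positive and the pose stays near truth
  noisy <- lapply(picked, function(p)
    pt3(p$xyz + stats::rnorm(3, sd = 1), frame = "LOWFIELD"))
  cal3 <- calibrate(fids, noisy)
  expect_gt(cal3$fre, 0)
  expect_lt(sqrt(sum((cal3$transform$translation - truth$translation)^2)), 10)

  expect_error(fiducial_set(list(pt3(0, 0, 0, frame = "TEMPLATE"),
                                 pt3(5, 0, 0, frame = "TEMPLATE"),
                                 pt3(10, 0, 0, frame = "TEMPLATE"))),
               "collinear")
  expect_error(calibrate(fids, picked[1:2]), "count")
})

test_that("targets snap to the nearest needle trajectory with the label tie-break", {
  g <- template_grid()
  fids <- default_fiducials()
  set.seed(31)
  cal <- calibrate(fids, lapply(fids$positions, function(p)
    rt_apply(rand_rigid("TEMPLATE", "LOWFIELD", max_deg = 10), p)))
  # rebuild cal against one fixed transform for determinism of truth
  truth <- rand_rigid("TEMPLATE", "LOWFIELD", max_deg = 10)
  cal <- calibrate(fids, lapply(fids$positions, function(p) rt_apply(truth, p)))

  # a click exactly on a hole's needle line snaps to that hole
  h <- hole_position(g, c("D", "7"))
  click <- rt_apply(truth, pt3(h$xyz + 42 * g$needle_axis, frame = "TEMPLATE"))
  snap <- snap_target(click, g, cal)
  expect_identical(unname(snap$grid_coord), c("D", "7"))
  expect_lt(snap$distance_mm, 1e-9)
  # idempotence: snapping a point of the snapped trajectory returns the hole
  again <- snap_target(snap$trajectory$point, g, cal)
  expect_identical(again$grid_coord, snap$grid_coord)

  # equidistant between two adjacent hole lines: lower label wins
  mid_tpl <- (hole_position(g, c("A", "1"))$xyz +
              hole_position(g, c("A", "2"))$xyz) / 2 + 30 * g$needle_axis
  snap_mid <- snap_target(rt_apply(truth, pt3(mid_tpl, frame = "TEMPLATE")),
                          g, cal)
  expect_identical(unname(snap_mid$grid_coord), c("A", "1"))
  mid_rows <- (hole_position(g, c("A", "1"))$xyz +
               hole_position(g, c("B", "1"))$xyz) / 2
  snap_rows <- snap_target(rt_apply(truth, pt3(mid_rows, frame = "TEMPLATE")),
                           g, cal)
  expect_identical(unname(snap_rows$grid_coord), c("A", "1"))

  # random clicks agree with an exhaustive search over every hole's line
  set.seed(32)
  u_low <- rt_apply(truth, dir3(g$needle_axis))
  for (i in 1:40) {
    click <- rand_pt("LOWFIELD", scale = 50)
    snap <- snap_target(click, g, cal)
    best <- Inf; best_coord <- NULL
    for (r in g$row_labels) for (cl in g$col_labels) {
      d <- point_line_distance(click, hole_position(g, c(r, cl), cal), u_low)
      if (d < best - 1e-9) { best <- d; best_coord <- c(r, cl) }
    }
    expect_identical(unname(snap$grid_coord), best_coord)
    expect_equal(snap$distance_mm, best, tolerance = 1e-9)
  }
})

test_that("depth readout and projected core are mutually consistent", {
  g <- template_grid()
  kit0 <- biopsy_kit(tip_to_core_center_mm = 0)
  kit10 <- biopsy_kit(tip_to_core_center_mm = 10)
  id <- rt_identity("TEMPLATE", "LOWFIELD")
  h <- hole_position(g, c("G", "7"))
  target <- pt3(h$xyz + 30 * g$needle_axis, frame = "LOWFIELD")
  expect_equal(compute_depth(target, c("G", "7"), g, id, kit0), 30)
  expect_equal(compute_depth(target, c("G", "7"), g, id, kit10), 20)
  expect_error(compute_depth(pt3(h$xyz - 5 * g$needle_axis, frame = "LOWFIELD"),
                             c("G", "7"), g, id, kit10), "proximal")

  # explicit arithmetic: depth 40, offset 9, core 18 -> core spans z 40..58
  kit9 <- biopsy_kit(throw_mm = 20, core_length_mm = 18,
                     tip_to_core_center_mm = 9)
  core <- projected_core(c("A", "1"), 40, g, id, kit9)
  h11 <- hole_position(g, c("A", "1"))
  expect_equal(core$core$a$xyz, h11$xyz + c(0, 0, 40))
  expect_equal(core$core$b$xyz, h11$xyz + c(0, 0, 58))
  expect_equal(core$core_center$xyz, h11$xyz + c(0, 0, 49))
  expect_equal(seg_length(core$core), kit9$core_length_mm)
  expect_error(projected_core(c("A", "1"), -3, g, id, kit9), "positive")

  # round trip under random calibrations: the projected core center is the
  # on-axis projection of the target, and its direction the calibrated axis
  set.seed(41)
  for (i in 1:50) {
    truth <- rand_rigid("TEMPLATE", "LOWFIELD")
    cal <- calibrate(default_fiducials(),
                     lapply(default_fiducials()$positions,
                            function(p) rt_apply(truth, p)))
    coord <- c(sample(g$row_labels, 1), sample(g$col_labels, 1))
    h_tpl <- hole_position(g, coord)
    t_tpl <- h_tpl$xyz + runif(1, 15, 80) * g$needle_axis +
      runif(2, -2, 2) %*% rbind(g$axis_row, g$axis_col)
    target <- rt_apply(cal$transform, pt3(drop(t_tpl), frame = "TEMPLATE"))
    depth <- compute_depth(target, coord, g, cal, kit10)
    core <- projected_core(coord, depth, g, cal, kit10)
    proj_tpl <- h_tpl$xyz +
      sum((drop(t_tpl) - h_tpl$xyz) * g$needle_axis) * g$needle_axis
    expect_equal(core$core_center$xyz,
                 rt_apply(cal$transform, pt3(proj_tpl, frame = "TEMPLATE"))$xyz,
                 tolerance = 1e-9)
    expect_equal(unclass(core$direction),
                 unclass(rt_apply(cal$transform, dir3(g$needle_axis))),
                 tolerance = 1e-9)
    expect_equal(seg_length(core$core), kit10$core_length_mm, tolerance = 1e-9)
  }
})

test_that("plan_target records the snapped coordinate, depth and core center", {
  g <- template_grid()
  kit <- biopsy_kit()
  set.seed(51)
  truth <- rand_rigid("TEMPLATE", "LOWFIELD", max_deg = 10)
  cal <- calibrate(default_fiducials(),
                   lapply(default_fiducials()$positions,
                          function(p) rt_apply(truth, p)))
  click <- rt_apply(truth, pt3(3, -2, 47, frame = "TEMPLATE"))
  plan <- plan_target(click, g, cal, kit, needle_id = "N01")
  expect_s3_class(plan, "planned_target")
  expect_gt(plan$depth_mm, 0)
  # core center is the midpoint of the core
  expect_equal(seg_midpoint(plan$core)$xyz, plan$core_center$xyz,
               tolerance = 1e-9)
  # the core center lies on the planned hole's needle line
  expect_lt(point_line_distance(plan$core_center,
                                hole_position(g, plan$grid_coord, cal),
                                rt_apply(truth, dir3(g$needle_axis))), 1e-9)
})
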