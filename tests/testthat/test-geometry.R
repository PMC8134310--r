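test_that("point distance matches the closed form and its contract", {
  p <- pt3(0, 0, 0, frame = "LOWFIELD")
  q <- pt3(3, 4, 0, frame = "LOWFIELD")
  expect_equal(pt_distance(p, q), 5)
  expect_equal(pt_distance(p, p), 0)
  expect_error(pt_distance(p, pt3(1, 1, 1, frame = "TEMPLATE")),
               "LOWFIELD.*TEMPLATE")
  expect_error(pt3(1, Inf, 0, frame = "LOWFIELD"), "finite")
  expect_error(pt3(1, 2, 3, frame = "SCANNER"), "frame")

  set.seed(101)
  for (i in 1:100) {
    a <- rand_pt(); b <- rand_pt()
    expect_equal(pt_distance(a, b), oracle_distance(a$xyz, b$xyz),
                 tolerance = 1e-12)
    # symmetry and triangle inequality
    cpt <- rand_pt()
    expect_identical(pt_distance(a, b), pt_distance(b, a))
    expect_lte(pt_distance(a, b),
               pt_distance(a, cpt) + pt_distance(cpt, b) + 1e-12)
  }
})

test_that("point-to-line distance equals the cross-product formula and a 1-D minimizer", {
  p <- pt3(0, 1, 0, frame = "LOWFIELD")
  o <- pt3(0, 0, 0, frame = "LOWFIELD")
  ex <- dir3(1, 0, 0)
  expect_equal(point_line_distance(p, o, ex), 1)
  # any point on the line is at distance zero
  on_line <- pt3(c(17.3, 0, 0), frame = "LOWFIELD")
  expect_equal(point_line_distance(on_line, o, ex), 0)
  expect_error(dir3(0, 0, 0), "zero-norm")
  expect_error(point_line_distance(p, pt3(0, 0, 0, frame = "REFERENCE"), ex),
               "different frames")

  set.seed(202)
  for (i in 1:100) {
    q <- rand_pt(); lp <- rand_pt()
    d <- dir3(stats::rnorm(3))
    expect_equal(point_line_distance(q, lp, d),
                 oracle_point_line(q$xyz, lp$xyz, unclass(d)),
                 tolerance = 1e-6)
  }
})

test_that("point-to-segment distance clamps to the nearer endpoint", {
  a <- pt3(0, 0, 0, frame = "LOWFIELD")
  b <- pt3(5, 0, 0, frame = "LOWFIELD")
  s <- seg3(a, b)
  expect_equal(point_segment_distance(pt3(10, 1, 0, frame = "LOWFIELD"), s),
               sqrt(26))
  expect_equal(point_segment_distance(pt3(2, 1, 0, frame = "LOWFIELD"), s), 1)
  expect_error(seg3(a, pt3(0, 0, 0, frame = "LOWFIELD")), "degenerate")

  set.seed(303)
  for (i in 1:100) {
    p <- rand_pt(); u <- rand_pt(); v <- rand_pt()
    seg <- seg3(u, v)
    expect_equal(point_segment_distance(p, seg),
                 oracle_point_segment(p$xyz, u$xyz, v$xyz),
                 tolerance = 1e-6)
    # interior feet agree with the infinite-line distance
    dl <- point_line_distance(p, u, seg_direction(seg))
    expect_gte(point_segment_distance(p, seg), dl - 1e-12)
  }
})

test_that("rigid transforms apply, compose, invert and preserve distances", {
  id <- rt_identity("LOWFIELD")
  p <- pt3(4, -2, 7, frame = "LOWFIELD")
  expect_equal(rt_apply(id, p)$xyz, p$xyz)
  tr <- rigid_transform(diag(3), c(1, 2, 3), "TEMPLATE", "LOWFIELD")
  moved <- rt_apply(tr, pt3(0, 0, 0, frame = "TEMPLATE"))
  expect_equal(moved$xyz, c(1, 2, 3))
  expect_identical(moved$frame, "LOWFIELD")
  expect_error(rt_apply(tr, p), "expects frame TEMPLATE")

  inv <- rt_invert(tr)
  expect_equal(rt_apply(inv, moved)$xyz, c(0, 0, 0))
  expect_equal(inv$translation, c(-1, -2, -3))
  # improper or non-orthonormal rotations are rejected
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0),
                               "TEMPLATE", "LOWFIELD"), "not proper")
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0),
                               "TEMPLATE", "LOWFIELD"), "orthonormal")
  expect_error(rt_compose(tr, tr), "frame chain mismatch")

  set.seed(404)
  for (i in 1:50) {
    t1 <- rand_rigid("TEMPLATE", "LOWFIELD")
    t2 <- rand_rigid("LOWFIELD", "REFERENCE")
    a <- rand_pt("TEMPLATE"); b <- rand_pt("TEMPLATE")
    # isometry
    expect_equal(pt_distance(rt_apply(t1, a), rt_apply(t1, b)),
                 pt_distance(a, b), tolerance = 1e-9)
    # composition associativity with application
    expect_equal(rt_apply(rt_compose(t2, t1), a)$xyz,
                 rt_apply(t2, rt_apply(t1, a))$xyz, tolerance = 1e-9)
    # round trip to identity
    rt <- rt_compose(rt_invert(t1), t1)
    expect_equal(rt$rotation, diag(3), tolerance = 1e-9)
    expect_equal(rt$translation, c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("rigid transform JSON serialization round-trips", {
  set.seed(11)
  tr <- rand_rigid()
  js <- jsonlite::toJSON(rt_serialize(tr), auto_unbox = TRUE, digits = NA)
  back <- rt_deserialize(jsonlite::fromJSON(js))
  expect_equal(back$rotation, tr$rotation)
  expect_equal(back$translation, tr$translation)
  expect_identical(back$from_frame, tr$from_frame)
})

test_that("rigid fit recovers exact transforms and rejects degenerate input", {
  src <- list(pt3(0, 0, 0, frame = "TEMPLATE"),
              pt3(10, 0, 0, frame = "TEMPLATE"),
              pt3(0, 10, 0, frame = "TEMPLATE"),
              pt3(0, 0, 10, frame = "TEMPLATE"))
  # identity
  dst_same <- lapply(src, function(p) pt3(p$xyz, frame = "LOWFIELD"))
  fit <- fit_rigid(src, dst_same)
  expect_equal(fit$fre, 0, tolerance = 1e-12)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)

  # 90 degrees about z plus a shift
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  dst <- lapply(src, function(p)
    pt3(drop(Rz %*% p$xyz) + c(1, 2, 3), frame = "LOWFIELD"))
  fit <- fit_rigid(src, dst)
  expect_equal(fit$fre, 0, tolerance = 1e-9)
  expect_equal(fit$transform$rotation, Rz, tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(1, 2, 3), tolerance = 1e-9)

  expect_error(fit_rigid(src[1:2], dst_same[1:2]), "at least 3")
  coll <- list(pt3(0, 0, 0, frame = "TEMPLATE"),
               pt3(1, 1, 1, frame = "TEMPLATE"),
               pt3(2, 2, 2, frame = "TEMPLATE"))
  expect_error(fit_rigid(coll, coll), "collinear")
})

test_that("noise-free rigid fit recovers the generating transform; FRE ignores ordering", {
  set.seed(505)
  for (i in 1:25) {
    truth <- rand_rigid("TEMPLATE", "LOWFIELD")
    src <- lapply(1:5, function(j) rand_pt("TEMPLATE", scale = 60))
    dst <- lapply(src, function(p) rt_apply(truth, p))
    fit <- fit_rigid(src, dst)
    expect_lt(norm(fit$transform$rotation - truth$rotation, "F"), 1e-6)
    expect_equal(fit$transform$translation, truth$translation,
                 tolerance = 1e-6)

    # FRE is invariant under re-ordering of the point pairs
    noisy <- lapply(dst, function(p)
      pt3(p$xyz + stats::rnorm(3, sd = 0.5), frame = "LOWFIELD"))
    perm <- sample(length(src))
    f1 <- fit_rigid(src, noisy)
    f2 <- fit_rigid(src[perm], noisy[perm])
    expect_equal(f1$fre, f2$fre, tolerance = 1e-12)
  }
})

test_that("sphere radius from volume follows the closed form", {
  expect_equal(round(sphere_radius_from_volume(0.5)), 5)
  expect_equal(sphere_radius_from_volume(0.5), 4.9237, tolerance = 1e-4)
  expect_equal(sphere_radius_from_volume(4 / 3 * pi), 10)
  expect_error(sphere_radius_from_volume(0), "positive")
  expect_error(sphere_radius_from_volume(-1), "positive")
})
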