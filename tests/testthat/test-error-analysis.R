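.mk_gt <- function(center, dir = c(0, 0, 1), core_len = 18, needle = "N01") {
  u <- dir / sqrt(sum(dir^2))
  structure(list(needle_id = needle,
                 center = pt3(center, frame = "REFERENCE"),
                 segment = seg3(pt3(center - core_len / 2 * u, frame = "REFERENCE"),
                                pt3(center + core_len / 2 * u, frame = "REFERENCE")),
                 direction = dir3(u), source_observers = c("G1", "G2")),
            class = "ground_truth_core")
}

.mk_planned <- function(center, needle = "N01") {
  list(needle_id = needle, core_center = pt3(center, frame = "LOWFIELD"))
}

test_that("error metrics decouple lateral and axial displacement", {
  id <- rt_identity("REFERENCE", "LOWFIELD")
  # coincident cores: every metric is zero
  rec0 <- compute_errors(.mk_planned(c(0, 0, 50)), .mk_gt(c(0, 0, 50)), id)
  expect_equal(rec0$center_to_center_mm, 0)
  expect_equal(rec0$point_to_line_mm, 0)
  expect_equal(rec0$point_to_segment_mm, 0)

  # 2 mm purely lateral displacement, parallel cores: both metrics 2
  rec_lat <- compute_errors(.mk_planned(c(2, 0, 50)), .mk_gt(c(0, 0, 50)), id)
  expect_equal(rec_lat$center_to_center_mm, 2)
  expect_equal(rec_lat$point_to_line_mm, 2)
  expect_equal(rec_lat$point_to_segment_mm, 2)

  # purely axial displacement: line distance 0, center distance positive
  rec_ax <- compute_errors(.mk_planned(c(0, 0, 54)), .mk_gt(c(0, 0, 50)), id)
  expect_equal(rec_ax$point_to_line_mm, 0)
  expect_equal(rec_ax$center_to_center_mm, 4)
  # beyond the 9 mm half-core the segment metric clamps to the core end
  rec_far <- compute_errors(.mk_planned(c(0, 0, 70)), .mk_gt(c(0, 0, 50)), id)
  expect_equal(rec_far$point_to_segment_mm, 11)
  expect_equal(rec_far$point_to_line_mm, 0)
})

test_that("error metrics respect their geometric ordering on random records", {
  set.seed(71)
  for (i in 1:80) {
    reg <- rand_rigid("REFERENCE", "LOWFIELD")
    gt <- .mk_gt(runif(3, -40, 40), rnorm(3))
    rec <- compute_errors(.mk_planned(runif(3, -40, 40)), gt, reg)
    expect_gte(rec$point_to_segment_mm, rec$point_to_line_mm - 1e-12)
    expect_gte(rec$center_to_center_mm, rec$point_to_line_mm - 1e-12)
    expect_lte(rec$point_to_segment_mm,
               rec$center_to_center_mm + seg_length(gt$segment) / 2 + 1e-12)
  }
})

test_that("summary statistics follow the t-based convention", {
  s <- summarize_errors(c(1, 2, 3))
  expect_equal(s$n, 3)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)

  # CI matches a direct t-quantile derivation
  set.seed(72)
  x <- rexp(40, rate = 0.4)
  s2 <- summarize_errors(x)
  half <- qt(0.975, 39) * sd(x) / sqrt(40)
  expect_equal(s2$ci_low, mean(x) - half, tolerance = 1e-12)
  expect_equal(s2$ci_high, mean(x) + half, tolerance = 1e-12)
  expect_true(s2$min <= s2$mean && s2$mean <= s2$max)
  expect_true(s2$ci_low <= s2$mean && s2$mean <= s2$ci_high)

  # single observation: degenerate, flagged, zero-width
  expect_warning(s1 <- summarize_errors(5), "degenerate")
  expect_equal(s1$sd, 0)
  expect_equal(s1$ci_low, 5)
  expect_true(s1$degenerate)

  # permutation invariance and scale equivariance
  perm <- summarize_errors(sample(x))
  expect_equal(perm$mean, s2$mean)
  expect_equal(perm$sd, s2$sd)
  k <- 3.7
  sc <- summarize_errors(k * x)
  expect_equal(sc$mean, k * s2$mean)
  expect_equal(sc$sd, k * s2$sd)
  expect_equal(sc$min, k * s2$min)
  expect_equal(sc$ci_high, k * s2$ci_high)
})

test_that("interobserver variance acts on per-observer mean errors", {
  recs <- data.frame(needle_id = rep(c("N01", "N02"), 2),
                     observer_id = rep(c("C1", "C2"), each = 2),
                     center_to_center_mm = c(2, 2, 2, 2),
                     excluded = FALSE)
  expect_equal(interobserver_variance(recs), 0)

  # observer means 2.0 and 2.1 -> variance 0.005
  recs$center_to_center_mm <- c(1.9, 2.1, 2.0, 2.2)
  expect_equal(interobserver_variance(recs), 0.005)

  # shifting every record by a constant leaves the variance unchanged
  shifted <- recs
  shifted$center_to_center_mm <- recs$center_to_center_mm + 1.234
  expect_equal(interobserver_variance(shifted), interobserver_variance(recs))

  expect_error(interobserver_variance(recs[recs$observer_id == "C1", ]),
               "at least 2 observers")
})

test_that("needle exclusions propagate to every observer's record", {
  recs <- expand.grid(needle_id = sprintf("N%02d", 1:17),
                      observer_id = sprintf("C%d", 1:4),
                      stringsAsFactors = FALSE)
  recs$center_to_center_mm <- seq_len(nrow(recs)) / 10
  recs$excluded <- FALSE
  recs$reason <- ""

  out <- apply_exclusions(recs, data.frame(needle_id = "N17",
                                           reason = "entry not visible"))
  expect_equal(nrow(out$kept), 64)
  expect_equal(nrow(out$excluded), 4)
  expect_true(all(out$excluded$excluded))
  expect_true(all(out$excluded$reason == "entry not visible"))

  none <- apply_exclusions(recs, NULL)
  expect_equal(nrow(none$kept), 68)

  all_out <- apply_exclusions(recs, data.frame(
    needle_id = sprintf("N%02d", 1:17), reason = "x"))
  expect_equal(nrow(all_out$kept), 0)
  expect_error(summarize_errors(all_out$kept), "no non-excluded")
})

test_that("rendered tables carry the fixed clinical row labels", {
  set.seed(73)
  x <- abs(rnorm(64, 2.5, 1))
  s <- summarize_errors(x)
  tab <- render_error_table(list("Planned target to center of core" = s,
                                 "Planned target to core segment" = s),
                            c(a = 0.003, b = 0.04))
  txt <- paste(tab, collapse = "\n")
  for (lab in c("Number of samples", "Average error (mm)", "Min (mm)",
                "Max (mm)", "Standard deviation (mm)",
                "95% confidence interval", "Interobserver variance (mm^2)")) {
    expect_match(txt, lab, fixed = TRUE)
  }
  vt <- paste(render_variability_table(list(n_needles = 17, mean = 2.32,
                                            sd = 1.51, min = 0, max = 5.13)),
              collapse = "\n")
  expect_match(vt, "Number of needles", fixed = TRUE)
  expect_match(vt, "Average distance between selected points across the users (mm)",
               fixed = TRUE)
  expect_match(vt, "5.13", fixed = TRUE)
})
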