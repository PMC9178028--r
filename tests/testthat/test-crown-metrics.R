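test_that("occlusal frame recovers the construction plane", {
  arch <- small_arch()
  fr <- fit_occlusal_frame(arch$mesh, arch$truth$labels)
  tips <- arch$truth$teeth$tip
  resid <- (arch$mesh$vertices[tips, , drop = FALSE] -
              matrix(fr$plane_point, length(tips), 3, byrow = TRUE)) %*%
    fr$normal
  expect_lt(sqrt(mean(resid^2)), 0.01)
  # per-tooth frames are orthonormal triples
  for (i in seq_len(nrow(fr$axes))) {
    md <- fr$axes$md_axis[[i]]; bl <- fr$axes$bl_axis[[i]]
    expect_equal(sum(md^2), 1, tolerance = 1e-6)
    expect_equal(sum(bl^2), 1, tolerance = 1e-6)
    expect_lt(abs(sum(md * bl)), 1e-6)
    expect_lt(abs(sum(md * fr$normal)), 1e-6)
  }
  # too few teeth
  g3 <- generate_arch(arch_config(n_teeth = 2), seed = 1)
  expect_error(fit_occlusal_frame(g3$mesh, g3$truth$labels), "3 teeth")
})

test_that("MD width and CCH are exact on analytic shapes", {
  bx <- box_mesh(8, 6, 7)
  fr <- structure(list(plane_point = c(0, 0, 7), normal = c(0, 0, 1),
                       axes = tibble::tibble(position = 1L,
                                             md_axis = list(c(1, 0, 0)),
                                             bl_axis = list(c(0, 1, 0)))),
                  class = "occlusal_frame")
  expect_identical(measure_md_width(bx, fr, 1L), 8)
  # frustum-style: open cylinder of height h with its top on the plane
  cyl <- cylinder_surface(r = 2, h = 5, n_theta = 24, n_z = 6)
  fr2 <- structure(list(plane_point = c(0, 0, 5), normal = c(0, 0, 1),
                        axes = fr$axes), class = "occlusal_frame")
  expect_equal(measure_cch(cyl, fr2), 5)
  # translation parallel to the plane leaves CCH unchanged
  cyl2 <- rigid_transform(cyl, diag(3), c(13, -4, 0))
  expect_equal(measure_cch(cyl2, fr2), 5)
  expect_error(measure_cch(box_mesh(), fr), "rim")
})

test_that("generated teeth are recovered to high accuracy", {
  set.seed(31)
  errs <- vapply(1:100, function(i) {
    md <- runif(1, 6, 11); cch <- runif(1, 6, 10); bl <- runif(1, 6, 11)
    tw <- generate_tooth(sample(1:16, 1), c(md, cch, bl), seed = i)
    fr <- tooth_frame(tw)
    c(abs(measure_md_width(tw$mesh, fr, 1L) - md),
      abs(measure_cch(tw$mesh, fr, rim = tw$rim) - cch))
  }, numeric(2))
  expect_lt(mean(errs[1, ]), 0.05)
  expect_lt(mean(errs[2, ]), 0.05)
})

test_that("measurements are rigid-transform invariant", {
  tw <- generate_tooth(4, c(7.2, 7.9, 8.6), seed = 12)
  fr <- tooth_frame(tw)
  R <- rotation_matrix(); t <- c(11, -6, 3)
  mesh2 <- rigid_transform(tw$mesh, R, t)
  fr2 <- rigid_transform(fr, R, t)
  expect_lt(abs(measure_md_width(mesh2, fr2, 1L) -
                  measure_md_width(tw$mesh, fr, 1L)), 1e-6)
  expect_lt(abs(measure_cch(mesh2, fr2, rim = tw$rim) -
                  measure_cch(tw$mesh, fr, rim = tw$rim)), 1e-6)
})

test_that("ground truth is recoverable from the labelled arch", {
  arch <- small_arch()
  fr <- truth_frame(arch$truth)
  m <- measure_teeth(arch$mesh, arch$truth$labels, frame = fr)
  j <- match(m$position, arch$truth$teeth$position)
  expect_lt(max(abs(m$md_width - arch$truth$teeth$md[j])), 1e-9)
  expect_lt(max(abs(m$cch - arch$truth$teeth$cch[j])), 1e-9)
})

test_that("sheared molars overestimate MD width (parallelogram effect)", {
  gs <- generate_arch(arch_config(molar_shear = 0.35), seed = 7)
  fr <- truth_frame(gs$truth)
  m <- measure_teeth(gs$mesh, gs$truth$labels, frame = fr)
  sheared <- gs$truth$teeth$position[
    dentseg:::tooth_class_of_position(gs$truth$teeth$position) == 7L]
  for (p in sheared) {
    req <- gs$truth$teeth$md_requested[gs$truth$teeth$position == p]
    expect_gt(m$md_width[m$position == p], req)
  }
})

test_that("success judgement is reflexive and monotone in margin push", {
  tc <- tooth_column()
  ref <- column_region(tc$z_ref)
  # identity
  j <- judge_success(ref, ref, tc$mesh, tc$frame, 1L)
  expect_true(j$success)
  expect_length(j$reasons, 0)
  # margin pushed gingivally by delta * CCH: 0.20 ok, 0.25 boundary
  # (strict inequality: still success), 0.30 fails
  outcomes <- vapply(c(0.20, 0.25, 0.30), function(delta) {
    seg <- column_region(tc$z_ref - delta * tc$cch)
    judge_success(seg, ref, tc$mesh, tc$frame, 1L)$success
  }, logical(1))
  expect_identical(outcomes, c(TRUE, TRUE, FALSE))
  jf <- judge_success(column_region(tc$z_ref - 0.30 * tc$cch), ref,
                      tc$mesh, tc$frame, 1L)
  expect_identical(jf$reasons, "margin_deviation")
  # monotone deviation measurements
  devs <- vapply(c(0.1, 0.2, 0.3, 0.4), function(delta)
    judge_success(column_region(tc$z_ref - delta * tc$cch), ref,
                  tc$mesh, tc$frame, 1L)$margin_deviation_mm, numeric(1))
  expect_true(all(diff(devs) > 0))
})

test_that("occlusal defects and missing teeth are flagged", {
  tc <- tooth_column()
  ref <- column_region(tc$z_ref)
  # hole in the occlusal cap (top 20% of CCH)
  cap <- ref[tc$mesh$vertices[ref, 3] >= 12 - 0.2 * tc$cch]
  seg <- setdiff(ref, cap[seq_len(ceiling(length(cap) / 3))])
  j <- judge_success(seg, ref, tc$mesh, tc$frame, 1L)
  expect_false(j$success)
  expect_true("occlusal_defect" %in% j$reasons)
  # posterior molar: missing lingual wall sector
  side <- ref[tc$mesh$vertices[ref, 2] < -3.4 &
                tc$mesh$vertices[ref, 3] < 12 - 0.25 * tc$cch &
                tc$mesh$vertices[ref, 3] > 12 - 0.75 * tc$cch]
  seg2 <- setdiff(ref, side)
  j2 <- judge_success(seg2, ref, tc$mesh, tc$frame, 1L, posterior = TRUE)
  expect_false(j2$success)
  # missing tooth
  jm <- judge_success(integer(0), ref, tc$mesh, tc$frame, 1L)
  expect_false(jm$success)
  expect_identical(jm$reasons, "missing")
  expect_error(judge_success(ref, integer(0), tc$mesh, tc$frame, 1L),
               "empty reference")
})

test_that("measure_teeth produces a full per-tooth report", {
  arch <- small_arch()
  fr <- truth_frame(arch$truth)
  m <- measure_teeth(arch$mesh, arch$truth$labels,
                     reference = arch$truth$labels, frame = fr)
  expect_equal(nrow(m), 14L)
  expect_true(all(m$success))
  expect_s3_class(m, "tbl_df")
  expect_setequal(levels(m$group),
                  c("incisal", "canine", "premolar", "molar"))
})
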