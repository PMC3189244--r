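# Pseudo-slide simulator: template geometry, missing cores, rotation,
# stretching, suite structure, determinism.

test_that("default template is a 9x14 lattice of 126 separated cores", {
  sl <- make_pseudo_template()
  expect_equal(nrow(sl$truth), 126L)
  expect_equal(max(sl$truth$row), 9L)
  expect_equal(max(sl$truth$col), 14L)
  expect_equal(max(label_components(sl$image)), 126L)
  # lattice pitch 50 in both directions
  r1 <- sl$truth[sl$truth$row == 1, ]
  expect_equal(diff(sort(r1$cx)), rep(50, 13))
  expect_gte(min(dist(cbind(sl$truth$cx, sl$truth$cy))), 30)
  # 30 px nominal diameter: component areas near pi * 15^2
  st <- component_stats(label_components(sl$image))
  expect_true(all(st$area > 0.5 * pi * 15^2 & st$area < 2 * pi * 15^2))
})

test_that("1x1 spec yields a single core; equal seeds reproduce bytes", {
  one <- make_pseudo_template(pseudo_spec(n_rows = 1, n_cols = 1, seed = 3))
  expect_equal(nrow(one$truth), 1L)
  expect_equal(max(label_components(one$image)), 1L)
  a <- make_pseudo_template(pseudo_spec(seed = 9))
  b <- make_pseudo_template(pseudo_spec(seed = 9))
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("missing-core removal keeps survivor indices and is exact", {
  sl <- make_pseudo_template()
  expect_identical(apply_missing(sl, 0), sl)
  m31 <- apply_missing(sl, 31, seed = 5)
  expect_equal(nrow(m31$truth), 95L)
  expect_equal(max(label_components(m31$image)), 95L)
  expect_true(all(paste(m31$truth$row, m31$truth$col) %in%
                  paste(sl$truth$row, sl$truth$col)))
  empty <- apply_missing(sl, 126)
  expect_equal(nrow(empty$truth), 0L)
  expect_equal(sum(empty$image), 0L)
  expect_error(run_dearray(empty), "segmentation|gridding|degenerate")
})

test_that("rotation is rigid and invertible", {
  sl <- make_pseudo_template(pseudo_spec(seed = 4))
  r <- apply_rotation(sl, 15)
  expect_equal(as.matrix(dist(cbind(r$truth$cx, r$truth$cy))),
               as.matrix(dist(cbind(sl$truth$cx, sl$truth$cy))),
               tolerance = 0.5 / 50)
  back <- apply_rotation(r, -15)
  expect_lt(max(abs(back$truth$cx - sl$truth$cx)), 0.5)
  expect_lt(max(abs(back$truth$cy - sl$truth$cy)), 0.5)
  expect_identical(apply_rotation(sl, 0), sl)
})

test_that("stretch displacements follow the anchored monotone profile", {
  sl <- make_pseudo_template(pseudo_spec(seed = 7))
  expect_identical(apply_stretch(sl, 0, 0), sl)
  st <- apply_stretch(sl, 2, 0)
  # top row (pulled corner for a_h > 0): zero at left edge, monotone right
  for (rw in c(1, 9)) {
    d0 <- st$truth[st$truth$row == rw, ]
    s0 <- sl$truth[sl$truth$row == rw, ]
    dx <- d0$cx[order(d0$col)] - s0$cx[order(s0$col)]
    dx <- dx - dx[1]                     # canvas re-anchoring offset
    expect_equal(dx[1], 0)
    expect_true(all(diff(dx) >= -1e-9))
    if (rw == 1) expect_gt(max(dx), 15) else expect_lt(max(dx), 1e-6)
  }
  # +/- a_v fields mirror about the horizontal midline
  up <- apply_stretch(sl, 0, 1.5)
  dn <- apply_stretch(sl, 0, -1.5)
  dy_up <- up$truth$cy - sl$truth$cy
  dy_dn <- dn$truth$cy - sl$truth$cy
  mirror <- sl$truth
  mirror$row <- max(mirror$row) + 1L - mirror$row
  m_idx <- match(paste(mirror$row, mirror$col),
                 paste(sl$truth$row, sl$truth$col))
  expect_equal(dy_up - mean(dy_up), -(dy_dn[m_idx] - mean(dy_dn[m_idx])),
               tolerance = 1e-9)
  expect_error(apply_stretch(sl, 0, 80), "collapses")
})

test_that("suite has the published five-set structure and is deterministic", {
  s1 <- generate_suite(21)
  man <- attr(s1, "manifest")
  expect_equal(length(s1), 113L)
  expect_equal(as.vector(table(man$set)[c("missing", "rotation", "hstretch",
                                          "vstretch", "mixed")]),
               c(26L, 31L, 13L, 16L, 27L))
  expect_equal(range(man$missing[man$set == "missing"]), c(0L, 31L))
  expect_equal(range(man$theta[man$set == "rotation"]), c(-15, 15))
  expect_true(all(abs(man$theta[man$set == "mixed"]) <= 15))
  expect_true(all(man$missing[man$set == "mixed"] <= 31))
  # truth/image consistency on a sample of cases
  for (i in c(1, 30, 60, 80, 100)) {
    expect_equal(max(label_components(s1[[i]]$image)), nrow(s1[[i]]$truth))
  }
  s2 <- generate_suite(21)
  expect_identical(lapply(s1, `[[`, "truth"), lapply(s2, `[[`, "truth"))
  expect_false(identical(attr(generate_suite(22), "manifest")$seed, man$seed))
})

test_that("pseudo slides round-trip through disk as PGM + CSV", {
  sl <- make_pseudo_template(pseudo_spec(n_rows = 2, n_cols = 3, seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_pseudo_slide(sl, dir, "t")
  img <- read_thumbnail(paths[1])
  expect_equal(dim(img), c(sl$height, sl$width))
  expect_identical(img < 0.5, sl$image)    # cores are dark on white
  tr <- read.csv(paths[2])
  expect_equal(tr$row, sl$truth$row)
  expect_equal(tr$cx, sl$truth$cx, tolerance = 1e-6)
})
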