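# Gridding phase: edge filtering, traveling, column matching, post-processing.

lattice_pts <- function(nr, nc, pitch = 50, jitter = 0, seed = 1) {
  set.seed(seed)
  g <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  cbind(x = (g$col - 1) * pitch + 50 + runif(nrow(g), -jitter, jitter),
        y = (g$row - 1) * pitch + 50 + runif(nrow(g), -jitter, jitter))
}

test_that("length filter keeps lattice edges and drops diagonals", {
  g <- build_triangulation(lattice_pts(4, 4))
  keep <- filter_edges_by_length(g)
  expect_true(all(abs(g$edges$length[keep] - 50) < 0.5))
  expect_false(any(abs(g$edges$length[keep] - 50 * sqrt(2)) < 0.5))
  # one interior core deleted: retained edges never exceed the diagonal
  pts <- lattice_pts(4, 4)
  pts <- pts[-6, ]
  g2 <- build_triangulation(pts)
  keep2 <- filter_edges_by_length(g2)
  expect_true(all(g2$edges$length[keep2] <= 50 * sqrt(2) + 1e-6))
  # all-identical lengths: every edge in the smallest-2/3 tie group is kept
  tri <- build_triangulation(rbind(c(0, 0), c(50, 0), c(25, 25 * sqrt(3))))
  expect_equal(length(filter_edges_by_length(tri)), 3L)
})

test_that("angle filter finds the horizontal cluster and the rotation", {
  g <- build_triangulation(lattice_pts(5, 7, jitter = 0.4))
  af <- filter_edges_by_angle(g)
  expect_lt(abs(af$theta_hat), 1)
  expect_true(all(abs(g$edges$angle[af$edges]) < 5))
  # clockwise 15 degrees (y-down: positive angles)
  for (th in c(15, -10)) {
    pr <- rotate_points(lattice_pts(5, 7, jitter = 0.4), th, c(200, 150))
    gr <- build_triangulation(pr)
    afr <- filter_edges_by_angle(gr)
    expect_lt(abs(afr$theta_hat - th), 2)
    # cluster size ~ count of horizontal adjacencies
    expect_equal(length(intersect(afr$edges, filter_edges_by_length(gr))),
                 5 * 6)
  }
  # fewer than five edges: |angle| <= 22.5 fallback
  tri <- build_triangulation(rbind(c(0, 0), c(50, 5), c(25, 40)))
  aft <- filter_edges_by_angle(tri)
  expect_true(all(abs(tri$edges$angle[aft$edges]) <= 22.5))
})

test_that("template is the deduplicated left-to-right intersection", {
  g <- build_triangulation(lattice_pts(4, 6, jitter = 0.3))
  li <- filter_edges_by_length(g)
  af <- filter_edges_by_angle(g)
  tpl <- make_edge_template(g, li, af$edges)
  expect_equal(nrow(tpl), 4 * 5)               # n_rows * (n_cols - 1)
  expect_true(all(tpl$xe > tpl$xs))
  expect_false(any(duplicated(tpl[, c("s", "e")])))
  expect_error(make_edge_template(g, li[0], af$edges), "no horizontal structure")
})

test_that("traveling chains one complete row in ascending x", {
  pts <- cbind(x = seq(50, 250, by = 50), y = rep(40, 5))
  pts <- rbind(pts, cbind(x = seq(50, 250, by = 50), y = rep(90, 5)))
  g <- build_triangulation(pts)
  tpl <- make_edge_template(g, filter_edges_by_length(g),
                            filter_edges_by_angle(g)$edges)
  rows <- travel(tpl, W = 300, theta_hat = 0)
  expect_equal(length(rows), 2L)
  expect_true(all(vapply(rows, function(r) all(diff(r$x) > 0), logical(1))))
  expect_equal(sort(unlist(lapply(rows, function(r) r$vertex))), 1:10)
})

test_that("a deleted interior core becomes an imaginary vertex in place", {
  sl <- make_pseudo_template(pseudo_spec(n_rows = 3, n_cols = 5, seed = 2))
  gone <- sl$truth[sl$truth$row == 2 & sl$truth$col == 3, ]
  cent <- slide_centroids(sl)
  cent <- cent[-which.min((cent$cx - gone$cx)^2 + (cent$cy - gone$cy)^2), ]
  g <- build_triangulation(cent)
  tpl <- make_edge_template(g, filter_edges_by_length(g),
                            filter_edges_by_angle(g)$edges)
  rows <- travel(tpl, W = sl$width, theta_hat = 0)
  mid <- rows[[which.min(vapply(rows, function(r) abs(mean(r$y) - gone$cy),
                                numeric(1)))]]
  im <- mid[mid$imaginary, ]
  expect_gte(nrow(im), 1L)
  d <- sqrt((im$x - gone$cx)^2 + (im$y - gone$cy)^2)
  expect_lt(min(d), 5)
})

test_that("9x14 template with 31 missing cores yields 9 rows, each vertex once", {
  sl <- apply_missing(make_pseudo_template(), 31, seed = 8)
  cent <- slide_centroids(sl)
  g <- build_triangulation(cent)
  tpl <- make_edge_template(g, filter_edges_by_length(g),
                            filter_edges_by_angle(g)$edges)
  rows <- travel(tpl, W = sl$width, theta_hat = 0)
  expect_equal(length(rows), 9L)
  reals <- unlist(lapply(rows, function(r) r$vertex[!r$imaginary]))
  expect_equal(anyDuplicated(reals), 0L)
})

test_that("column matching recovers offsets for truncated rows", {
  sl <- make_pseudo_template()
  # delete the first two cores of the second row and re-render
  gone <- sl$truth$core_id[sl$truth$row == 2 & sl$truth$col <= 2]
  cores <- sl$cores[!sl$cores$core_id %in% gone, ]
  sl <- dearrayr:::as_pseudo_slide(
    dearrayr:::render_pseudo(cores, sl$spec$pitch), sl$spec, sl$provenance)
  g <- grid_pseudo(sl)
  expect_equal(grid_accuracy(g, sl$truth), 1)
  b_row <- g$cells[g$cells$row == 2, ]
  expect_equal(b_row$kind[1:2], c("imaginary", "imaginary"))
  first_real <- b_row[b_row$kind == "real", ][1, ]
  expect_equal(first_real$col, 3L)
})

test_that("two identical rows align at offset zero", {
  pts <- rbind(cbind(seq(50, 350, 50), 50), cbind(seq(50, 350, 50), 100))
  g <- grid_cores(pts, W = 400, H = 150)
  expect_equal(g$n_rows, 2L)
  expect_equal(g$cells$col[g$cells$row == 1], g$cells$col[g$cells$row == 2])
})

test_that("gridding is rotation-equivariant over the tested range", {
  sl <- make_pseudo_template(pseudo_spec(seed = 3))
  base <- grid_pseudo(sl)
  for (th in c(-15, -7, 7, 15)) {
    slr <- apply_rotation(sl, th)
    gr <- grid_pseudo(slr)
    expect_equal(abs(gr$theta_hat - th) < 2, TRUE, label = paste("theta", th))
    expect_equal(grid_accuracy(gr, slr$truth), 1, label = paste("rot", th))
    expect_equal(gr$n_rows, base$n_rows)
    expect_equal(gr$n_cols, base$n_cols)
  }
})

test_that("gridding is robust to stretching across the tested range", {
  sl <- make_pseudo_template(pseudo_spec(seed = 6))
  for (a in c(-2, -0.3, 0.3, 2)) {
    sh <- apply_stretch(sl, a, 0)
    expect_equal(grid_accuracy(grid_pseudo(sh), sh$truth), 1,
                 label = paste("a_h", a))
    sv <- apply_stretch(sl, 0, a)
    expect_equal(grid_accuracy(grid_pseudo(sv), sv$truth), 1,
                 label = paste("a_v", a))
  }
})

test_that("monotone index geometry after de-rotation", {
  sl <- apply_rotation(apply_missing(make_pseudo_template(), 20, seed = 4), 9)
  g <- grid_pseudo(sl)
  ctr <- colMeans(g$vertices)
  cells <- g$cells[g$cells$kind == "real", ]
  d <- rotate_points(cbind(cells$x, cells$y), -g$theta_hat, ctr)
  cells$dx <- d[, 1]; cells$dy <- d[, 2]
  for (r in unique(cells$row)) {
    rr <- cells[cells$row == r, ]
    rr <- rr[order(rr$col), ]
    expect_true(all(diff(rr$dx) > 0))
  }
  for (cc in unique(cells$col)) {
    cl <- cells[cells$col == cc, ]
    cl <- cl[order(cl$row), ]
    expect_true(all(diff(cl$dy) > 0))
  }
})

test_that("conservation: every vertex is gridded or an artefact", {
  sl <- apply_missing(make_pseudo_template(pseudo_spec(seed = 10)), 25, seed = 9)
  cent <- slide_centroids(sl)
  g <- grid_cores(cent, sl$width, sl$height)
  gridded <- g$cells$vertex[g$cells$kind == "real"]
  expect_equal(sort(c(gridded, g$artefacts)), seq_len(nrow(cent)))
})

test_that("post-processing merges near rows, trims imaginary boundaries, flags artefacts", {
  # two half-rows at nearly the same y merge into one full row
  pts <- rbind(cbind(seq(50, 200, 50), 50), cbind(seq(250, 400, 50), 53),
               cbind(seq(50, 400, 50), 100))
  g <- grid_cores(pts, W = 450, H = 150)
  expect_equal(g$n_rows, 2L)
  expect_equal(g$n_cols, 8L)
  expect_equal(grid_accuracy(g, data.frame(row = rep(1:2, c(8, 8)),
                                           col = c(1:8, 1:8),
                                           cx = c(seq(50, 400, 50), seq(50, 400, 50)),
                                           cy = rep(c(50, 53, 100), c(4, 4, 8)))), 1)

  # an off-grid blob two pitches away is marked as an artefact
  sl <- make_pseudo_template(pseudo_spec(n_rows = 4, n_cols = 6, seed = 11))
  cent <- rbind(as.matrix(slide_centroids(sl)),
                c(max(sl$truth$cx) + 100, max(sl$truth$cy) + 100))
  g2 <- grid_cores(cent, sl$width + 120, sl$height + 120)
  expect_equal(g2$artefacts, nrow(cent))
  expect_equal(grid_accuracy(g2, sl$truth), 1)
  expect_equal(g2$n_rows, 4L)   # artefact row trimmed away
})

test_that("grid accuracy scoring counts exact index matches", {
  sl <- make_pseudo_template()
  g <- grid_pseudo(sl)
  expect_equal(grid_accuracy(g, sl$truth), 1)
  wrong <- sl$truth
  wrong$col[1] <- wrong$col[1] + 1L
  expect_equal(grid_accuracy(g, wrong), 125 / 126)
})
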