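# Segmentation phase: thresholding, convex hulls, fragment joining, Fourier
# boundary smoothing and size filters.

test_that("uniform white image yields an empty mask with a degenerate flag", {
  img <- matrix(1, 100, 100)
  expect_warning(m <- enhance_and_threshold(img), "constant")
  expect_equal(sum(m), 0L)
  expect_true(isTRUE(attr(m, "degenerate")))
  expect_error(enhance_and_threshold(matrix(numeric(0), 0, 0)), "zero-sized")
})

test_that("dark discs on white are segmented as the right number of objects", {
  centers <- as.matrix(expand.grid(x = c(60, 140, 220), y = c(60, 140)))
  disc <- draw_discs(centers, 15, 200, 280)
  img <- matrix(0.95, 200, 280)
  img[disc] <- 0.1
  set.seed(4)
  # thumbnails are 100x-downsampled scans, so per-pixel noise is mild
  img <- pmin(pmax(img + 0.01 * rnorm(length(img)), 0), 1)
  mask <- enhance_and_threshold(img)
  cs <- finalize_candidates(extract_candidates(mask))
  expect_equal(nrow(cs$candidates), 6L)
  # centroid within 3 px of a unique disc center
  d <- as.matrix(dist(rbind(centers, cbind(cs$candidates$cx, cs$candidates$cy))))
  d <- d[1:6, 7:12]
  expect_true(all(apply(d, 1, min) < 3))
})

test_that("convex hulls: squares are fixed points, C-shapes become convex", {
  sq <- matrix(FALSE, 30, 30)
  sq[6:25, 6:25] <- TRUE
  cs <- extract_candidates(sq)
  expect_identical(cs$mask, sq)
  expect_equal(cs$candidates$area, 400L)

  cshape <- draw_discs(cbind(15, 15), 10, 31, 31)
  cshape[10:20, 15:31] <- FALSE          # carve out the mouth
  hull <- extract_candidates(cshape)$mask
  expect_true(all(hull[cshape]))          # superset of input
  expect_identical(hull, hull_closure_oracle(hull))   # convex (fixed point)
})

test_that("random blobs hull to the exhaustive convex-closure oracle", {
  for (s in 1:8) {
    blob <- random_blob(40, 24, 24, seed = s)
    got <- extract_candidates(blob, seg_params(min_speck_area = 1))$mask
    expect_identical(got, hull_closure_oracle(blob))
  }
})

test_that("hulling is idempotent and never shrinks objects", {
  for (s in 9:12) {
    blob <- random_blob(60, 28, 28, seed = s)
    once <- extract_candidates(blob, seg_params(min_speck_area = 1))
    twice <- extract_candidates(once$mask, seg_params(min_speck_area = 1))
    expect_identical(once$mask, twice$mask)
    expect_gte(once$candidates$area[1], sum(blob))
  }
})

test_that("speck filter removes area 9 and keeps area 10 after hulling", {
  m <- matrix(FALSE, 40, 40)
  m[3:5, 3:5] <- TRUE            # 3x3 = 9 px, convex
  m[20:21, 20:24] <- TRUE        # 2x5 = 10 px, convex
  cs <- extract_candidates(m)
  expect_equal(nrow(cs$candidates), 1L)
  expect_equal(cs$candidates$area, 10L)
})

test_that("fragment detection flags exactly the small close pair", {
  # 5x5 grid of equal discs; replace the centre core by two small fragments
  g <- as.matrix(expand.grid(x = seq(40, 240, by = 50), y = seq(40, 240, by = 50)))
  keep <- !(g[, 1] == 140 & g[, 2] == 140)
  m <- draw_discs(g[keep, , drop = FALSE], 14, 280, 280)
  m <- m | draw_discs(rbind(c(134, 140), c(146, 140)), 5, 280, 280)
  cs <- extract_candidates(m)
  pairs <- detect_fragments(cs$candidates)
  expect_equal(nrow(pairs), 1L)
  frag_areas <- cs$candidates$area[match(c(pairs$label_a, pairs$label_b),
                                         cs$candidates$label)]
  expect_true(all(frag_areas < 200))
  expect_lt(pairs$distance, 20)

  # an isolated equally-small speck a full pitch away is not flagged
  m2 <- draw_discs(g[keep, , drop = FALSE], 14, 280, 330)
  m2 <- m2 | draw_discs(cbind(300, 140), 5, 280, 330)
  pairs2 <- detect_fragments(extract_candidates(m2)$candidates)
  expect_equal(nrow(pairs2), 0L)

  # uniform grids produce no fragment pairs; tiny candidate sets bail out
  expect_equal(nrow(detect_fragments(extract_candidates(
    draw_discs(g, 14, 280, 280))$candidates)), 0L)
  expect_equal(nrow(detect_fragments(cs$candidates[1:3, ])), 0L)
})

test_that("joining fragments produces one convex component (incl. chains)", {
  m <- matrix(FALSE, 40, 60)
  m[15:24, 6:15] <- TRUE
  m[15:24, 28:37] <- TRUE
  cs <- extract_candidates(m)
  expect_equal(nrow(cs$candidates), 2L)
  pairs <- data.frame(label_a = 1L, label_b = 2L, distance = 22)
  joined <- join_fragments(cs, pairs)
  expect_equal(nrow(joined$candidates), 1L)
  expect_identical(joined$mask, hull_closure_oracle(m))  # hull of the union

  expect_identical(join_fragments(cs, pairs[0, ]), cs)   # empty pair list

  # chained pairs (a,b), (b,c) merge transitively
  m3 <- m; m3[15:24, 48:57] <- TRUE
  cs3 <- extract_candidates(m3)
  pr3 <- data.frame(label_a = c(1L, 2L), label_b = c(2L, 3L), distance = 22)
  expect_equal(nrow(join_fragments(cs3, pr3)$candidates), 1L)
  # a pair referencing a removed label is skipped with a warning
  expect_warning(join_fragments(cs, data.frame(label_a = 1L, label_b = 9L,
                                               distance = 1)), "removed label")
})

test_that("full-term Fourier reconstruction is the identity up to raster", {
  for (s in 1:4) {
    shape <- draw_discs(cbind(25, 25), 12 + s, 50, 50, noisy = TRUE, seed = s)
    N <- nrow(moore_boundary(shape))
    out <- smooth_boundaries(shape, P = N)
    expect_gte(jaccard(shape, out$mask), 0.98)
  }
})

test_that("low-order truncation recovers a near-circular shape", {
  circ <- draw_discs(cbind(30, 30), 15, 60, 60)
  out <- smooth_boundaries(circ, P = 8)$mask
  expect_lt(abs(sum(out) - pi * 15^2) / (pi * 15^2), 0.10)
  hull <- hull_closure_oracle(out)
  expect_lt((sum(hull) - sum(out)) / sum(hull), 0.05)   # convex deficiency
})

test_that("truncated descriptors remove a spur and match a direct oracle", {
  circ <- draw_discs(cbind(30, 30), 14, 60, 64)
  spur <- circ
  spur[31, 45:50] <- TRUE                  # 1x6 spur off the right rim
  sm <- smooth_boundaries(spur, P = 8)$mask
  expect_false(any(sm[31, 48:50]))         # outer spur pixels gone
  # oracle: direct DFT truncation of the same traced boundary
  b <- moore_boundary(spur)
  z <- complex(real = b[, 1], imaginary = b[, 2])
  N <- length(z)
  Z <- fft(z)
  f <- ifelse(seq_len(N) - 1 <= N / 2, seq_len(N) - 1, seq_len(N) - 1 - N)
  keep <- rank(abs(f) + 0.25 * (f < 0), ties.method = "first") <= 8
  zr <- fft(Z * keep, inverse = TRUE) / N
  oracle_poly <- cbind(Re(zr), Im(zr))
  # reconstructed boundary stays within 2 px of the package's smoothed rim
  bs <- moore_boundary(sm)
  d <- sqrt(outer(oracle_poly[, 1], bs[, 1], "-")^2 +
            outer(oracle_poly[, 2], bs[, 2], "-")^2)
  expect_lt(max(apply(d, 1, min)), 2)
})

test_that("boundaries shorter than P are left unchanged with a warning", {
  m <- matrix(FALSE, 20, 20)
  m[9:11, 9:11] <- TRUE
  expect_warning(out <- smooth_boundaries(m, P = 50), "shorter than P")
  expect_identical(out$mask, m)
})

test_that("final size filter: 199 px removed, 200 px kept; empty mask ok", {
  m <- matrix(FALSE, 60, 60)
  m[2:11, 2:21] <- TRUE               # 200 px
  m2 <- m; m2[2, 2] <- FALSE          # 199 px
  expect_equal(nrow(finalize_candidates(m)$candidates), 1L)
  expect_equal(nrow(finalize_candidates(m2)$candidates), 0L)
  expect_equal(nrow(finalize_candidates(matrix(FALSE, 10, 10))$candidates), 0L)
})

test_that("segment_cores recovers every simulated core once", {
  sl <- make_pseudo_template(pseudo_spec(n_rows = 4, n_cols = 6, seed = 5))
  cs <- segment_cores(sl$image)
  expect_equal(nrow(cs$candidates), nrow(sl$truth))
  d <- sqrt(outer(sl$truth$cx, cs$candidates$cx, "-")^2 +
            outer(sl$truth$cy, cs$candidates$cy, "-")^2)
  expect_true(all(apply(d, 1, min) < 3))
  expect_true(all(apply(d, 1, function(r) sum(r < 3)) == 1))
  expect_true(all(cs$candidates$area >= 200))
})
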