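# Independent oracles and fixture builders used across the suite. These are
# deliberately naive implementations (brute force / enumeration) kept free of
# the package's own algorithmic code paths.

# Brute-force Delaunay: every triple whose circumcircle strictly contains no
# other point. Valid for point sets in general position.
delaunay_oracle <- function(pts) {
  n <- nrow(pts)
  cmb <- t(utils::combn(n, 3L))
  ax <- pts[cmb[, 1L], 1L]; ay <- pts[cmb[, 1L], 2L]
  bx <- pts[cmb[, 2L], 1L]; by <- pts[cmb[, 2L], 2L]
  cx <- pts[cmb[, 3L], 1L]; cy <- pts[cmb[, 3L], 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ok <- abs(d) > 1e-12
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  inside <- outer(ux, pts[, 1L], "-")^2 + outer(uy, pts[, 2L], "-")^2 <
    r2 - 1e-9 * (1 + r2)
  empty <- rowSums(inside) == 0L
  tri <- cmb[ok & empty, , drop = FALSE]
  tri[order(tri[, 1L], tri[, 2L], tri[, 3L]), , drop = FALSE]
}

# Exhaustive convex closure (Caratheodory form): a lattice point belongs to
# the hull iff it lies in some triangle of foreground pixel centers.
hull_closure_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  x <- (idx - 1L) %/% nr   # 0-based
  y <- (idx - 1L) %% nr
  out <- matrix(FALSE, nr, nc)
  out[idx] <- TRUE
  if (length(idx) < 3L) return(out)
  # exact reduction: every pixel lies on the segment between its row's
  # extreme pixels, so the hull of the row-wise extremes is the same hull
  ext <- unlist(lapply(split(seq_along(y), y), function(i) {
    i[c(which.min(x[i]), which.max(x[i]))]
  }))
  x <- x[ext]; y <- y[ext]
  gx <- rep(min(x):max(x), each = max(y) - min(y) + 1L)
  gy <- rep(min(y):max(y), times = max(x) - min(x) + 1L)
  cmb <- utils::combn(length(x), 3L)
  eps <- 1e-9
  hit <- rep(FALSE, length(gx))
  for (t in seq_len(ncol(cmb))) {
    i <- cmb[, t]
    x1 <- x[i[1L]]; y1 <- y[i[1L]]
    x2 <- x[i[2L]]; y2 <- y[i[2L]]
    x3 <- x[i[3L]]; y3 <- y[i[3L]]
    d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(d) < eps) next
    l1 <- ((y2 - y3) * (gx - x3) + (x3 - x2) * (gy - y3)) / d
    l2 <- ((y3 - y1) * (gx - x3) + (x1 - x3) * (gy - y3)) / d
    l3 <- 1 - l1 - l2
    hit <- hit | (l1 >= -eps & l2 >= -eps & l3 >= -eps)
    if (all(hit)) break
  }
  out[cbind(gy[hit] + 1L, gx[hit] + 1L)] <- TRUE
  out
}

# Iterative BFS flood fill labeling (4/8-connectivity oracle for small masks).
label_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), 1L)
    lab[r0, c0] <- cur
    while (nrow(queue) > 0L) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# --- fixture builders ------------------------------------------------------

# Draw filled discs (optionally noisy) on a logical canvas; centers are
# 0-based (x, y).
draw_discs <- function(centers, radius, nr, nc, noisy = FALSE, seed = 1L) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(centers))) {
    r0 <- if (noisy) radius * runif(1, 0.9, 1.1) else radius
    a <- if (noisy) runif(1, 0, 0.05) else 0
    ph <- runif(1, 0, 2 * pi)
    xs <- pmax(0L, floor(centers[k, 1L] - r0 * 1.2)):pmin(nc - 1L, ceiling(centers[k, 1L] + r0 * 1.2))
    ys <- pmax(0L, floor(centers[k, 2L] - r0 * 1.2)):pmin(nr - 1L, ceiling(centers[k, 2L] + r0 * 1.2))
    gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
    dx <- gx - centers[k, 1L]; dy <- gy - centers[k, 2L]
    rphi <- r0 * (1 + a * cos(3 * atan2(dy, dx) + ph))
    inside <- sqrt(dx^2 + dy^2) <= rphi
    m[cbind(gy[inside] + 1L, gx[inside] + 1L)] <- TRUE
  }
  m
}

# Random 8-connected blob grown from a seed pixel (small, for hull oracles).
random_blob <- function(n_px, nr, nc, seed) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  r <- nr %/% 2L; c <- nc %/% 2L
  m[r, c] <- TRUE
  frontier <- matrix(c(r, c), 1L)
  while (sum(m) < n_px) {
    i <- sample.int(nrow(frontier), 1L)
    p <- frontier[i, ]
    dr <- sample(-1:1, 1L); dc <- sample(-1:1, 1L)
    rr <- min(max(p[1L] + dr, 1L), nr); cc <- min(max(p[2L] + dc, 1L), nc)
    if (!m[rr, cc]) {
      m[rr, cc] <- TRUE
      frontier <- rbind(frontier, c(rr, cc))
    }
  }
  m
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Centroids of a labeled pseudo slide, through the package's labeling.
slide_centroids <- function(slide) {
  st <- component_stats(label_components(slide$image))
  st[st$area >= 200, c("cx", "cy")]
}

grid_pseudo <- function(slide, params = grid_params()) {
  grid_cores(slide_centroids(slide), slide$width, slide$height, params)
}
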