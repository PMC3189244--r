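# Pixel-level primitives: shifting, morphology, CLAHE, Otsu, connected
# components, boundary tracing, polygon fill. Images are numeric matrices in
# [0, 1] (rows = y, columns = x); masks are logical matrices of the same
# orientation. Exported coordinates are 0-based with x rightward / y downward.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr
  cok <- cs >= 1L & cs <= nc
  if (any(rok) && any(cok)) out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

disk_offsets <- function(radius) {
  r <- max(0L, as.integer(round(radius)))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
}

binary_dilate <- function(mask, radius) {
  off <- disk_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mat(mask, off$dr[i], off$dc[i], fill = FALSE)
  }
  out
}

binary_erode <- function(mask, radius) {
  off <- disk_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mat(mask, off$dr[i], off$dc[i], fill = FALSE)
  }
  out
}

#' Morphological closing with a disk structuring element
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels.
#' @return logical matrix.
#' @keywords internal
binary_close <- function(mask, radius) {
  if (radius <= 0) return(mask)
  binary_erode(binary_dilate(mask, radius), radius)
}

#' Otsu's global threshold
#'
#' Maximizes the between-class variance on a fixed 256-bin histogram over
#' \code{[0, 1]}. Returns `NA` for a (near-)constant image, where the
#' criterion is undefined.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param nbins histogram bins.
#' @return scalar threshold in `(0, 1)`, or `NA_real_`.
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  v <- img[is.finite(img)]
  if (length(v) == 0L || diff(range(v)) < 1e-12) return(NA_real_)
  b <- pmin(pmax(floor(v * nbins) + 1L, 1L), nbins)
  h <- tabulate(b, nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- -Inf
  which.max(sigma2) / nbins
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with clipping and bilinear interpolation
#' between the tile mappings, after Zuiderveld's construction.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param tiles integer vector of length 1 or 2: tile grid (rows, cols).
#' @param clip clip limit as a fraction of the tile pixel count, in `(0, 1]`.
#' @param nbins histogram bins per tile.
#' @return numeric matrix in `[0, 1]`.
#' @export
clahe <- function(img, tiles = c(8L, 8L), clip = 0.01, nbins = 256L) {
  stopifnot(is.matrix(img), clip > 0, clip <= 1)
  if (length(tiles) == 1L) tiles <- c(tiles, tiles)
  nr <- nrow(img); nc <- ncol(img)
  tr <- max(1L, min(as.integer(tiles[1]), nr))
  tc <- max(1L, min(as.integer(tiles[2]), nc))
  bin <- matrix(pmin(pmax(floor(img * nbins) + 1L, 1L), nbins), nr, nc)
  # tile membership per row/column
  row_tile <- pmin(floor((seq_len(nr) - 1L) * tr / nr) + 1L, tr)
  col_tile <- pmin(floor((seq_len(nc) - 1L) * tc / nc) + 1L, tc)
  lut <- array(0, c(tr, tc, nbins))
  centers_r <- numeric(tr); centers_c <- numeric(tc)
  for (i in seq_len(tr)) centers_r[i] <- mean(which(row_tile == i)) - 1
  for (j in seq_len(tc)) centers_c[j] <- mean(which(col_tile == j)) - 1
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tb <- bin[row_tile == i, col_tile == j]
      h <- tabulate(tb, nbins)
      npx <- length(tb)
      limit <- max(1, clip * npx)
      excess <- sum(pmax(h - limit, 0))
      h <- pmin(h, limit) + excess / nbins
      lut[i, j, ] <- cumsum(h) / sum(h)
    }
  }
  # bilinear interpolation between the four surrounding tile mappings
  interp_axis <- function(pos, centers) {
    n <- length(pos)
    k <- length(centers)
    lo <- findInterval(pos, centers)
    lo <- pmin(pmax(lo, 1L), k)
    hi <- pmin(lo + 1L, k)
    below <- pos <= centers[1]
    lo[below] <- 1L; hi[below] <- 1L
    above <- pos >= centers[k]
    lo[above] <- k; hi[above] <- k
    span <- centers[hi] - centers[lo]
    w <- ifelse(span > 0, (pos - centers[lo]) / span, 0)
    list(lo = lo, hi = hi, w = w)
  }
  ay <- interp_axis(seq_len(nr) - 1, centers_r)
  ax <- interp_axis(seq_len(nc) - 1, centers_c)
  RLO <- matrix(ay$lo, nr, nc); RHI <- matrix(ay$hi, nr, nc)
  WR <- matrix(ay$w, nr, nc)
  CLO <- matrix(ax$lo, nr, nc, byrow = TRUE); CHI <- matrix(ax$hi, nr, nc, byrow = TRUE)
  WC <- matrix(ax$w, nr, nc, byrow = TRUE)
  gather <- function(ti, tj) {
    idx <- ti + (tj - 1L) * tr + (bin - 1L) * (tr * tc)
    matrix(lut[idx], nr, nc)
  }
  out <- (1 - WR) * (1 - WC) * gather(RLO, CLO) +
    (1 - WR) * WC * gather(RLO, CHI) +
    WR * (1 - WC) * gather(RHI, CLO) +
    WR * WC * gather(RHI, CHI)
  pmin(pmax(out, 0), 1)
}

# 3x3 convolution with replicate padding (used by the Laplacian sharpener).
conv3 <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- rbind(img[1, , drop = FALSE], img, img[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  out <- matrix(0, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      k <- kernel[dr + 2L, dc + 2L]
      if (k != 0) out <- out + k * pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
    }
  }
  out
}

# alpha-parameterised 3x3 Laplacian kernel (4-/8-neighbour blend).
laplacian_kernel <- function(alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  h1 <- alpha / (alpha + 1)
  h2 <- (1 - alpha) / (alpha + 1)
  matrix(c(h1, h2, h1, h2, -4 / (alpha + 1), h2, h1, h2, h1), 3, 3)
}

#' Label 8-connected components
#'
#' Run-based two-pass labeling with union-find; labels are compact integers
#' 1..K assigned in raster order of each component's first pixel.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape, 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  col <- (idx - 1L) %/% nr + 1L
  row <- (idx - 1L) %% nr + 1L
  # vertical runs within columns (matrix is column-major)
  new_run <- c(TRUE, !(diff(idx) == 1L & row[-1L] != 1L))
  run_id <- cumsum(new_run)
  n_run <- run_id[length(run_id)]
  starts <- which(new_run)
  ends <- c(starts[-1L] - 1L, length(idx))
  run_col <- col[starts]
  run_r0 <- row[starts]
  run_r1 <- row[ends]
  parent <- seq_len(n_run)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  runs_by_col <- split(seq_len(n_run), run_col)
  cols_present <- as.integer(names(runs_by_col))
  for (ci in seq_along(cols_present)[-1L]) {
    if (cols_present[ci] - cols_present[ci - 1L] != 1L) next
    a <- runs_by_col[[ci - 1L]]; b <- runs_by_col[[ci]]
    # 8-connectivity: row ranges within +/-1 of each other
    ov <- outer(run_r0[a], run_r1[b] + 1L, "<=") & outer(run_r1[a] + 1L, run_r0[b], ">=")
    w <- which(ov, arr.ind = TRUE)
    for (k in seq_len(nrow(w))) {
      ra <- find(a[w[k, 1L]]); rb <- find(b[w[k, 2L]])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(n_run), find, integer(1))
  # compact labels in raster order (first pixel: min col, then min row)
  ord <- order(run_col, run_r0)
  lab_of_root <- integer(n_run)
  nxt <- 0L
  for (r in ord) {
    rt <- root[r]
    if (lab_of_root[rt] == 0L) {
      nxt <- nxt + 1L
      lab_of_root[rt] <- nxt
    }
  }
  lab[idx] <- rep(lab_of_root[root], ends - starts + 1L)
  lab
}

#' Per-component geometry (area, centroid, bounding box)
#'
#' @param lab integer label matrix from [label_components()].
#' @return data.frame with columns `label`, `area`, `cx`, `cy`, `bbox_x`,
#'   `bbox_y`, `bbox_w`, `bbox_h`. Coordinates are 0-based pixel indices;
#'   bounding boxes are half-open `(x_min, y_min, width, height)`.
#' @export
component_stats <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(), area = integer(), cx = numeric(),
                      cy = numeric(), bbox_x = integer(), bbox_y = integer(),
                      bbox_w = integer(), bbox_h = integer()))
  }
  nr <- nrow(lab)
  l <- lab[idx]
  x <- (idx - 1L) %/% nr      # 0-based column
  y <- (idx - 1L) %% nr       # 0-based row
  K <- max(l)
  area <- tabulate(l, K)
  sx <- rowsum(x, l); sy <- rowsum(y, l)
  xmin <- vapply(split(x, l), min, numeric(1))
  xmax <- vapply(split(x, l), max, numeric(1))
  ymin <- vapply(split(y, l), min, numeric(1))
  ymax <- vapply(split(y, l), max, numeric(1))
  keep <- which(area > 0L)
  data.frame(
    label = keep,
    area = area[keep],
    cx = as.numeric(sx[, 1]) / area[keep],
    cy = as.numeric(sy[, 1]) / area[keep],
    bbox_x = as.integer(xmin),
    bbox_y = as.integer(ymin),
    bbox_w = as.integer(xmax - xmin + 1),
    bbox_h = as.integer(ymax - ymin + 1),
    row.names = NULL
  )
}

#' Trace the outer boundary of one component (Moore tracing)
#'
#' Clockwise (on screen, y down) Moore boundary tracing with Jacob's stopping
#' criterion. The start pixel is the component's topmost-then-leftmost pixel.
#'
#' @param mask logical matrix holding a single 8-connected component.
#' @return n x 2 matrix of 0-based `(x, y)` boundary pixel centers, closed
#'   implicitly (last connects to first).
#' @export
moore_boundary <- function(mask) {
  idx <- which(mask)
  stopifnot(length(idx) > 0L)
  nr <- nrow(mask); nc <- ncol(mask)
  col <- (idx - 1L) %/% nr + 1L
  row <- (idx - 1L) %% nr + 1L
  o <- order(row, col)
  r0 <- row[o[1L]]; c0 <- col[o[1L]]
  if (length(idx) == 1L) return(matrix(c(c0 - 1, r0 - 1), 1, 2))
  # neighbour offsets (dr, dc) in clockwise screen order starting at West
  nbr <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                  0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L), ncol = 2L, byrow = TRUE)
  at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  out_r <- integer(0); out_c <- integer(0)
  cr <- r0; cc <- c0
  dir <- 1L   # index into nbr of the backtrack direction (start: West)
  first_dir <- NA_integer_
  max_steps <- 8L * length(idx) + 16L
  for (step in seq_len(max_steps)) {
    found <- FALSE
    d <- dir
    for (k in seq_len(8L)) {
      d <- d %% 8L + 1L          # advance clockwise
      rr <- cr + nbr[d, 1L]; ccn <- cc + nbr[d, 2L]
      if (at(rr, ccn)) { found <- TRUE; break }
    }
    if (!found) break            # isolated pixel (handled above) - safety
    out_r <- c(out_r, cr); out_c <- c(out_c, cc)
    if (length(out_r) > 1L && cr == r0 && cc == c0 && d == first_dir) {
      out_r <- out_r[-length(out_r)]; out_c <- out_c[-length(out_c)]
      break
    }
    if (is.na(first_dir)) first_dir <- d
    cr <- rr; cc <- ccn
    # new backtrack: the neighbour checked just before the hit, i.e. opposite
    # side: position of previous pixel relative to the new one
    dir <- ((d + 3L) %% 8L) + 1L
  }
  cbind(x = out_c - 1L, y = out_r - 1L)
}

#' Fill a closed polygon into a logical mask (scanline)
#'
#' Non-convex polygons use the even-odd rule with a half-open edge
#' convention; `convex = TRUE` switches to an inclusive min/max intersection
#' rule, which is exact for convex polygons and keeps every pixel whose
#' center lies on the boundary (including horizontal extreme edges).
#'
#' @param px,py polygon vertex coordinates, 0-based pixel units.
#' @param nr,nc output mask dimensions (rows, cols).
#' @param convex whether the polygon is known to be convex.
#' @return logical matrix with pixels whose centers fall inside (or on the
#'   boundary of) the polygon set to `TRUE`.
#' @keywords internal
fill_polygon <- function(px, py, nr, nc, convex = FALSE) {
  out <- matrix(FALSE, nr, nc)
  n <- length(px)
  if (n == 0L) return(out)
  if (n <= 2L) {
    for (i in seq_len(n)) {
      r <- round(py[i]) + 1L; c <- round(px[i]) + 1L
      if (r >= 1L && r <= nr && c >= 1L && c <= nc) out[r, c] <- TRUE
    }
    return(out)
  }
  eps <- 1e-9
  x1 <- px; y1 <- py
  x2 <- c(px[-1L], px[1L]); y2 <- c(py[-1L], py[1L])
  ymin <- max(0L, floor(min(py)))
  ymax <- min(nr - 1L, ceiling(max(py)))
  for (yy in ymin:ymax) {
    if (convex) {
      # inclusive rule: every edge touching the scanline contributes
      touch <- pmin(y1, y2) <= yy + eps & pmax(y1, y2) >= yy - eps
      if (!any(touch)) next
      xs <- numeric(0)
      slant <- touch & abs(y2 - y1) > eps
      if (any(slant)) {
        xs <- x1[slant] + (yy - y1[slant]) * (x2[slant] - x1[slant]) /
          (y2[slant] - y1[slant])
      }
      flat <- touch & abs(y2 - y1) <= eps
      xs <- c(xs, x1[flat], x2[flat])
      a <- ceiling(min(xs) - eps); b <- floor(max(xs) + eps)
      a <- max(a, 0L); b <- min(b, nc - 1L)
      if (b >= a) out[yy + 1L, (a:b) + 1L] <- TRUE
      next
    }
    # even-odd with half-open rule: edge crosses if y in [min, max)
    cr <- (y1 <= yy & y2 > yy) | (y2 <= yy & y1 > yy)
    if (!any(cr)) next
    xs <- x1[cr] + (yy - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr])
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      a <- ceiling(xs[k] - eps); b <- floor(xs[k + 1L] + eps)
      if (b < a) next
      a <- max(a, 0L); b <- min(b, nc - 1L)
      if (b >= a) out[yy + 1L, (a:b) + 1L] <- TRUE
    }
  }
  # ensure vertex pixels at integer coordinates are included
  vi <- abs(px - round(px)) < eps & abs(py - round(py)) < eps
  rr <- round(py[vi]) + 1L; cc <- round(px[vi]) + 1L
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  out[cbind(rr[ok], cc[ok])] <- TRUE
  out
}

# Fill the convex hull of a set of 0-based pixel centers into a mask.
fill_convex_hull <- function(x, y, nr, nc) {
  if (length(x) == 1L) {
    out <- matrix(FALSE, nr, nc)
    out[y + 1L, x + 1L] <- TRUE
    return(out)
  }
  h <- grDevices::chull(x, y)
  m <- fill_polygon(x[h], y[h], nr, nc, convex = TRUE)
  m[cbind(y + 1L, x + 1L)] <- TRUE   # original pixels always kept
  m
}
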