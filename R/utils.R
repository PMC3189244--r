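# Small shared helpers: angles, quartile fences, 1-D k-means, labels, lines.

#' Normalize an angle to the undirected-edge range (-90, 90]
#'
#' Edge angles are measured in degrees from the +x axis with y pointing down
#' (image convention), and undirected edges are normalized into `(-90, 90]`.
#'
#' @param a numeric vector of angles in degrees.
#' @return numeric vector in `(-90, 90]`.
#' @keywords internal
normalize_angle <- function(a) {
  a <- ((a + 90) %% 180) - 90           # [-90, 90)
  a[a <= -90 + 1e-12 & a >= -90 - 1e-12] <- 90
  a
}

# Tukey-style lower/upper fences. `type = 7` quantiles (R default).
lower_fence <- function(x, k) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[1] - k * (q[2] - q[1])
}

upper_fence <- function(x, k) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + k * (q[2] - q[1])
}

#' Deterministic 1-D Lloyd k-means with fixed seed centers
#'
#' No restarts and no random initialisation: centers start at `centers` and a
#' cluster that loses all members keeps its previous center. Used for edge
#' angle clustering where the five seeds are part of the method.
#'
#' @param x numeric vector.
#' @param centers numeric vector of initial centers.
#' @param iter_max maximum Lloyd iterations.
#' @return list with `cluster` (assignment index per element) and `centers`.
#' @keywords internal
kmeans1d <- function(x, centers, iter_max = 100L) {
  k <- length(centers)
  cl <- rep(1L, length(x))
  for (it in seq_len(iter_max)) {
    d <- abs(outer(x, centers, "-"))
    cl <- max.col(-d, ties.method = "first")
    new <- vapply(seq_len(k), function(j) {
      if (any(cl == j)) mean(x[cl == j]) else centers[j]
    }, numeric(1))
    if (max(abs(new - centers)) < 1e-10) {
      centers <- new
      break
    }
    centers <- new
  }
  list(cluster = cl, centers = centers)
}

#' Spreadsheet-style row label (1 = A, 26 = Z, 27 = AA, ...)
#'
#' @param i positive integer vector.
#' @return character vector of labels.
#' @export
row_label <- function(i) {
  vapply(as.integer(i), function(n) {
    stopifnot(n >= 1L)
    s <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    s
  }, character(1))
}

# Bresenham digital line between two 0-based pixel centers; returns an
# n x 2 matrix of (x, y) lattice points, endpoints included.
bresenham <- function(x0, y0, x1, y1) {
  x0 <- round(x0); y0 <- round(y0); x1 <- round(x1); y1 <- round(y1)
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  pts <- matrix(0L, nrow = dx - dy + 1L, ncol = 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    pts[i, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(i), , drop = FALSE]
}

# Rotate points (n x 2, x/y columns) by `theta` degrees about `center`.
# theta > 0 rotates clockwise on screen (y-down image coordinates).
rotate_points <- function(pts, theta, center = c(0, 0)) {
  th <- theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, "+")
}
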