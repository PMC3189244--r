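# Delaunay triangulation over core centroids. Incremental Bowyer-Watson with
# a super-triangle; adequate and fast for the few hundred vertices of a TMA
# thumbnail. Verified in the test suite against a brute-force
# empty-circumcircle oracle.

# Circumcenter and squared circumradius of triangle (ax,ay)-(bx,by)-(cx,cy).
circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-300) return(c(NA_real_, NA_real_, Inf))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation of a 2-D point set
#'
#' Incremental Bowyer-Watson construction. Exactly co-circular point groups
#' (a perfect square lattice is the worst case) are resolved deterministically
#' by a minuscule internal perturbation used for topology only; all reported
#' geometry (edge lengths, angles) is computed from the original coordinates.
#'
#' @param pts n x 2 numeric matrix of `(x, y)` coordinates.
#' @return list with `triangles` (m x 3 integer matrix of vertex indices,
#'   each row sorted increasingly) in no guaranteed order.
#' @export
delaunay_triangulate <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) stop("degenerate point set: need at least 3 points")
  if (anyDuplicated(round(pts, 9L))) stop("degenerate point set: duplicate points")
  # collinearity check
  x <- pts[, 1]; y <- pts[, 2]
  cross <- abs((x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1]))
  span <- max(diff(range(x)), diff(range(y)))
  if (all(cross < 1e-9 * max(span, 1)^2)) stop("degenerate point set: collinear points")

  # normalize to the unit box; deterministic tie-breaking jitter for topology
  cx0 <- min(x); cy0 <- min(y)
  sc <- max(span, 1e-12)
  px <- (x - cx0) / sc
  py <- (y - cy0) / sc
  i <- seq_len(n)
  px <- px + (((i * 2654435761) %% 1013) / 1013 - 0.5) * 1e-9
  py <- py + (((i * 97003969) %% 1009) / 1009 - 0.5) * 1e-9

  # super-triangle; far enough that even thin hull slivers (enormous
  # circumcircles) do not reach it, else boundary triangles go missing
  px <- c(px, -1e5, 1e5, 0.5)
  py <- c(py, -8e4, -8e4, 1.3e5)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  cap <- 12L * n + 64L
  tri <- matrix(NA_integer_, cap, 3L)
  ccx <- numeric(cap); ccy <- numeric(cap); cr2 <- numeric(cap)
  alive <- logical(cap)
  tri[1L, ] <- c(s1, s2, s3)
  cc <- circumcircle(px[s1], py[s1], px[s2], py[s2], px[s3], py[s3])
  ccx[1L] <- cc[1]; ccy[1L] <- cc[2]; cr2[1L] <- cc[3]
  alive[1L] <- TRUE
  ntri <- 1L

  for (p in seq_len(n)) {
    ai <- which(alive[seq_len(ntri)])
    d2 <- (px[p] - ccx[ai])^2 + (py[p] - ccy[ai])^2
    bad <- ai[d2 < cr2[ai] * (1 - 1e-12) - 1e-13]
    if (length(bad) == 0L) {
      # numeric fallback: point exactly on circles; nudge comparison
      bad <- ai[d2 <= cr2[ai]]
      if (length(bad) == 0L) stop("triangulation failure: point outside all circumcircles")
    }
    # boundary of the cavity: edges appearing exactly once among bad triangles
    e <- rbind(tri[bad, c(1L, 2L), drop = FALSE],
               tri[bad, c(2L, 3L), drop = FALSE],
               tri[bad, c(1L, 3L), drop = FALSE])
    e <- t(apply(e, 1L, sort))
    key <- paste(e[, 1L], e[, 2L])
    once <- !(key %in% key[duplicated(key)])
    alive[bad] <- FALSE
    for (k in which(once)) {
      a <- e[k, 1L]; b <- e[k, 2L]
      ntri <- ntri + 1L
      if (ntri > cap) stop("triangulation overflow")
      tri[ntri, ] <- sort(c(a, b, p))
      cc <- circumcircle(px[a], py[a], px[b], py[b], px[p], py[p])
      ccx[ntri] <- cc[1]; ccy[ntri] <- cc[2]; cr2[ntri] <- cc[3]
      alive[ntri] <- TRUE
    }
  }

  keep <- which(alive[seq_len(ntri)])
  T <- tri[keep, , drop = FALSE]
  T <- T[rowSums(T > n) == 0L, , drop = FALSE]
  if (nrow(T) == 0L) stop("degenerate point set: no valid triangles")
  T <- T[order(T[, 1L], T[, 2L], T[, 3L]), , drop = FALSE]
  list(triangles = T)
}

#' Build the triangulated neighbourhood graph over core centroids
#'
#' Runs the Delaunay triangulation and derives the undirected edge set with
#' per-edge length (px) and angle (degrees in `(-90, 90]`, from the +x axis,
#' y pointing down).
#'
#' @param centroids n x 2 matrix or data.frame of `(x, y)` core centroids.
#' @return object of class `tri_graph`: list with `vertices` (n x 2 matrix),
#'   `triangles`, and `edges` (data.frame `i`, `j`, `length`, `angle`).
#' @export
build_triangulation <- function(centroids) {
  v <- as.matrix(centroids[, 1:2])
  colnames(v) <- c("x", "y")
  dt <- delaunay_triangulate(v)
  T <- dt$triangles
  e <- rbind(T[, c(1L, 2L), drop = FALSE],
             T[, c(2L, 3L), drop = FALSE],
             T[, c(1L, 3L), drop = FALSE])
  e <- unique(e)                       # rows already sorted i < j
  dx <- v[e[, 2L], 1L] - v[e[, 1L], 1L]
  dy <- v[e[, 2L], 2L] - v[e[, 1L], 2L]
  edges <- data.frame(
    i = e[, 1L], j = e[, 2L],
    length = sqrt(dx^2 + dy^2),
    angle = normalize_angle(atan2(dy, dx) * 180 / pi)
  )
  structure(list(vertices = v, triangles = T, edges = edges),
            class = "tri_graph")
}

#' @export
print.tri_graph <- function(x, ...) {
  cat("Delaunay triangulation:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles,", nrow(x$edges), "edges\n")
  invisible(x)
}
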