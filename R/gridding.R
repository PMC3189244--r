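# Gridding: assign logical (row, column) indices to core centroids.
# Pipeline: Delaunay triangulation -> edge length filter (smallest 2/3 +
# upper Tukey fence) -> edge angle filter (5-seed 1-D k-means, keep the
# near-horizontal cluster, estimate grid rotation theta_hat) -> template of
# directed left-to-right vectors -> traveling algorithm chaining vectors into
# rows, bridging gaps with sector searches and imaginary vertices -> row
# sorting + median-residual column matching -> post-processing (row merges,
# imaginary fill-in, artefact marking, boundary trimming).

#' Gridding parameters
#'
#' All distance factors are multiples of the mean core-to-core pitch `D`,
#' which the pipeline estimates as the median length of the length-filtered
#' edge set.
#'
#' @param neighbour_threshold_factor direct-neighbour distance threshold `T`
#'   as a multiple of `D` (used for adopting off-grid vertices).
#' @param stop_margin_factor traveling stop margin `eps` as a multiple of `D`:
#'   a chain ends once its terminal x reaches `W - eps`.
#' @param sector_radius_factor radius of the sector searched for the next
#'   vertex when no template vector continues a chain, as a multiple of `D`.
#' @param sector_half_angle half-angle (degrees) of that sector, centred on
#'   the estimated row direction.
#' @param row_merge_factor rows whose mean-y gap is below this multiple of
#'   `D` are merged.
#' @param length_outlier_k Tukey multiplier of the upper edge-length fence.
#' @param kmeans_seeds initial centers (degrees) for angle clustering.
#' @return object of class `grid_params`.
#' @export
grid_params <- function(neighbour_threshold_factor = 1.5,
                        stop_margin_factor = 0.75,
                        sector_radius_factor = 1.5,
                        sector_half_angle = 30,
                        row_merge_factor = 0.5,
                        length_outlier_k = 1.5,
                        kmeans_seeds = c(-90, -45, 0, 45, 90)) {
  stopifnot(neighbour_threshold_factor > 0, stop_margin_factor > 0,
            sector_radius_factor > 0, sector_half_angle > 0,
            row_merge_factor > 0, length_outlier_k > 0,
            length(kmeans_seeds) == 5L)
  structure(list(
    neighbour_threshold_factor = neighbour_threshold_factor,
    stop_margin_factor = stop_margin_factor,
    sector_radius_factor = sector_radius_factor,
    sector_half_angle = sector_half_angle,
    row_merge_factor = row_merge_factor,
    length_outlier_k = length_outlier_k,
    kmeans_seeds = kmeans_seeds
  ), class = "grid_params")
}

#' Keep the short (lattice) edges of the triangulation
#'
#' Sorts all edge lengths, keeps the smallest 2/3 (all ties at the cut length
#' are kept), and additionally removes any edge above the upper Tukey fence
#' `Q3 + k * IQR` of all edge lengths.
#'
#' @param graph `tri_graph` from [build_triangulation()].
#' @param params [grid_params()].
#' @return integer vector of retained edge row indices into `graph$edges`.
#' @export
filter_edges_by_length <- function(graph, params = grid_params()) {
  len <- graph$edges$length
  stopifnot(length(len) >= 3L)
  cut <- sort(len)[ceiling(2 / 3 * length(len))]
  keep <- which(len <= cut + 1e-9)
  fence <- upper_fence(len, params$length_outlier_k)
  keep[len[keep] <= fence]
}

#' Select the near-horizontal edge cluster and estimate grid rotation
#'
#' 1-D Lloyd k-means over edge angles with the five fixed seeds
#' `{-90, -45, 0, 45, 90}` degrees; the cluster whose converged center is
#' nearest 0 is the near-horizontal family and its center is the rotation
#' estimate `theta_hat`. With fewer than five edges the clustering is
#' meaningless and edges with `|angle| <= 22.5` degrees are selected instead.
#'
#' @param graph `tri_graph`.
#' @param params [grid_params()].
#' @param subset optional integer vector of edge indices to consider
#'   (default: all edges).
#' @return list with `edges` (retained edge indices) and `theta_hat`
#'   (degrees).
#' @export
filter_edges_by_angle <- function(graph, params = grid_params(), subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(graph$edges))
  ang <- graph$edges$angle[subset]
  if (length(ang) < 5L) {
    sel <- abs(ang) <= 22.5
    return(list(edges = subset[sel],
                theta_hat = if (any(sel)) mean(ang[sel]) else 0))
  }
  km <- kmeans1d(ang, params$kmeans_seeds)
  target <- which.min(abs(km$centers))
  list(edges = subset[km$cluster == target],
       theta_hat = km$centers[target])
}

#' Build the traveling template of directed horizontal vectors
#'
#' Intersects the length- and angle-filtered edge subsets and emits each
#' surviving undirected edge as a unique left-to-right directed vector.
#'
#' @param graph `tri_graph`.
#' @param length_idx edge indices from [filter_edges_by_length()].
#' @param angle_idx edge indices from [filter_edges_by_angle()] (`$edges`).
#' @return object of class `edge_template`: data.frame with vertex ids `s`,
#'   `e` and coordinates `xs`, `ys`, `xe`, `ye`; attributes `vertices` (the
#'   full centroid matrix) and `D` (median retained edge length, px).
#' @export
make_edge_template <- function(graph, length_idx, angle_idx) {
  idx <- intersect(length_idx, angle_idx)
  if (length(idx) == 0L) stop("no horizontal structure found")
  v <- graph$vertices
  i <- graph$edges$i[idx]
  j <- graph$edges$j[idx]
  # orient left -> right (ties broken by y so orientation is deterministic)
  flip <- v[j, 1L] < v[i, 1L] | (v[j, 1L] == v[i, 1L] & v[j, 2L] < v[i, 2L])
  s <- ifelse(flip, j, i)
  e <- ifelse(flip, i, j)
  tpl <- unique(data.frame(s = s, e = e))
  tpl$xs <- v[tpl$s, 1L]; tpl$ys <- v[tpl$s, 2L]
  tpl$xe <- v[tpl$e, 1L]; tpl$ye <- v[tpl$e, 2L]
  structure(tpl, class = c("edge_template", "data.frame"),
            vertices = v,
            D = stats::median(graph$edges$length[length_idx]))
}

#' Traveling algorithm: chain template vectors into grid rows
#'
#' Repeatedly takes the unused template vector with smallest start x and
#' chains vectors head-to-tail. When no template vector continues a chain and
#' the terminal x is still short of `W - eps`, a circular sector (radius
#' `sector_radius_factor * D`, half-angle `sector_half_angle`, centred on the
#' row direction `theta_hat`) is searched for the nearest unused vertex; if
#' none exists an imaginary vertex is appended one mean horizontal step
#' ahead. Every real vertex is used at most once across all rows.
#'
#' @param template `edge_template` from [make_edge_template()].
#' @param W image width (px).
#' @param params [grid_params()].
#' @param theta_hat grid rotation estimate (degrees) from
#'   [filter_edges_by_angle()].
#' @return list of row data.frames (`vertex`, `x`, `y`, `imaginary`), with
#'   attributes `vertices`, `D`, `theta_hat`, `W`.
#' @export
travel <- function(template, W, params = grid_params(), theta_hat = 0) {
  stopifnot(nrow(template) > 0L, W > 0)
  v <- attr(template, "vertices")
  D <- attr(template, "D")
  eps <- params$stop_margin_factor * D
  radius <- params$sector_radius_factor * D
  half_angle <- params$sector_half_angle
  step <- c(mean(template$xe - template$xs), mean(template$ye - template$ys))
  n <- nrow(v)
  used <- logical(n)
  vec_used <- logical(nrow(template))
  cap <- max(3L * ceiling(W / (0.5 * D)), 16L)
  rows <- list()

  sector_next <- function(px, py) {
    cand <- which(!used)
    if (length(cand) == 0L) return(NA_integer_)
    dx <- v[cand, 1L] - px
    dy <- v[cand, 2L] - py
    d <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx) * 180 / pi
    dang <- abs(((ang - theta_hat + 180) %% 360) - 180)
    ok <- d > 1e-9 & d <= radius & dang <= half_angle
    if (!any(ok)) return(NA_integer_)
    cand[ok][which.min(d[ok])]
  }

  repeat {
    avail <- which(!vec_used & !used[template$s] & !used[template$e])
    if (length(avail) == 0L) break
    b <- avail[which.min(template$xs[avail])]
    vec_used[b] <- TRUE
    s <- template$s[b]; e <- template$e[b]
    used[s] <- TRUE; used[e] <- TRUE
    chain <- data.frame(vertex = c(s, e),
                        x = c(v[s, 1L], v[e, 1L]),
                        y = c(v[s, 2L], v[e, 2L]),
                        imaginary = c(FALSE, FALSE))
    term_v <- e
    term_x <- v[e, 1L]; term_y <- v[e, 2L]
    while (term_x < W - eps) {
      if (nrow(chain) >= cap) {
        warning("runaway traveling chain aborted")
        break
      }
      nxt <- NA_integer_
      if (!is.na(term_v)) {
        cand <- which(!vec_used & template$s == term_v & !used[template$e])
        if (length(cand) > 0L) {
          # prefer the continuation closest to the row direction
          ca <- atan2(template$ye[cand] - template$ys[cand],
                      template$xe[cand] - template$xs[cand]) * 180 / pi
          bb <- cand[which.min(abs(ca - theta_hat))]
          vec_used[bb] <- TRUE
          nxt <- template$e[bb]
        }
      }
      if (is.na(nxt)) nxt <- sector_next(term_x, term_y)
      if (!is.na(nxt)) {
        used[nxt] <- TRUE
        chain <- rbind(chain, data.frame(vertex = nxt, x = v[nxt, 1L],
                                         y = v[nxt, 2L], imaginary = FALSE))
        term_v <- nxt
        term_x <- v[nxt, 1L]; term_y <- v[nxt, 2L]
      } else {
        term_x <- term_x + step[1L]
        term_y <- term_y + step[2L]
        term_v <- NA_integer_
        chain <- rbind(chain, data.frame(vertex = NA_integer_, x = term_x,
                                         y = term_y, imaginary = TRUE))
      }
    }
    rows[[length(rows) + 1L]] <- chain
  }
  structure(rows, vertices = v, D = D, theta_hat = theta_hat, W = W)
}

# Reference row positions extended linearly beyond both ends.
ref_position <- function(xr, idx) {
  nr <- length(xr)
  dstep <- if (nr >= 2L) mean(diff(xr)) else 1
  ifelse(idx < 1L, xr[1L] + (idx - 1L) * dstep,
         ifelse(idx > nr, xr[nr] + (idx - nr) * dstep,
                xr[pmin(pmax(idx, 1L), nr)]))
}

#' Sort rows and assign column indices by median-residual matching
#'
#' Rows are sorted by mean y in the de-rotated frame (rotation by
#' `-theta_hat`). The longest row is the reference; every other row is slid
#' over it by integer shifts and the shift minimizing the median absolute
#' positional residual (de-rotated x) is chosen; ties prefer the smaller
#' |shift|. Column indices are global: the smallest assigned index becomes
#' column 1.
#'
#' @param rows row lists from [travel()].
#' @param params [grid_params()].
#' @return object of class `tma_grid`: list with `cells` (data.frame `row`,
#'   `col`, `kind` in real/imaginary, `vertex`, `x`, `y`), `n_rows`,
#'   `n_cols`, `artefacts` (integer vertex ids), `vertices`, `D`,
#'   `theta_hat`.
#' @export
assign_rows_and_columns <- function(rows, params = grid_params()) {
  stopifnot(length(rows) >= 1L)
  v <- attr(rows, "vertices")
  D <- attr(rows, "D")
  theta <- attr(rows, "theta_hat")
  ctr <- colMeans(v)
  derot <- function(xy) rotate_points(xy, -theta, ctr)
  # de-rotated coordinates per row
  rows_d <- lapply(rows, function(r) {
    d <- derot(cbind(r$x, r$y))
    r$dx <- d[, 1L]; r$dy <- d[, 2L]
    r
  })
  ord <- order(vapply(rows_d, function(r) mean(r$dy), numeric(1)))
  rows_d <- rows_d[ord]
  ref <- rows_d[[which.max(vapply(rows_d, nrow, integer(1)))]]
  xr <- ref$dx
  cells <- NULL
  for (ri in seq_along(rows_d)) {
    r <- rows_d[[ri]]
    m <- nrow(r)
    if (length(xr) < 2L) {
      shift <- 0L          # single-column fallback
    } else {
      shifts <- (1L - m):(length(xr) - 1L)
      cost <- vapply(shifts, function(k) {
        stats::median(abs(r$dx - ref_position(xr, seq_len(m) + k)))
      }, numeric(1))
      best <- which(cost <= min(cost) + 1e-9)
      shift <- shifts[best[which.min(abs(shifts[best]))]]
    }
    cells <- rbind(cells, data.frame(
      row = ri, col = seq_len(m) + shift,
      kind = ifelse(r$imaginary, "imaginary", "real"),
      vertex = r$vertex, x = r$x, y = r$y, dy = r$dy
    ))
  }
  cells$col <- cells$col - min(cells$col) + 1L
  structure(list(cells = cells, n_rows = max(cells$row),
                 n_cols = max(cells$col), artefacts = integer(0),
                 vertices = v, D = D, theta_hat = theta),
            class = "tma_grid")
}

#' Post-process a grid assignment
#'
#' Merges adjacent rows closer than `row_merge_factor * D` (cells interleave
#' by column; collisions become artefacts), fills every empty cell with an
#' imaginary centroid by linear interpolation along its row (falling back to
#' its column, then to a global affine lattice fit), adopts unassigned
#' vertices into the nearest imaginary cell within
#' `neighbour_threshold_factor * D` (others become artefacts), and trims
#' boundary rows/columns that contain only imaginary cells.
#'
#' @param grid `tma_grid` from [assign_rows_and_columns()].
#' @param params [grid_params()].
#' @return `tma_grid` with complete cells, `row_labels` and `col_labels`.
#' @export
postprocess <- function(grid, params = grid_params()) {
  cells <- grid$cells
  D <- grid$D
  v <- grid$vertices
  artefacts <- grid$artefacts

  # --- merge rows whose mean-y gap is below the merge threshold
  row_y <- vapply(split(cells$dy, cells$row), mean, numeric(1))
  ord <- order(row_y)
  row_ids <- as.integer(names(row_y))[ord]
  row_y <- row_y[ord]
  group <- integer(length(row_ids))
  g <- 0L
  for (i in seq_along(row_ids)) {
    if (i == 1L || row_y[i] - row_y[i - 1L] >= params$row_merge_factor * D) g <- g + 1L
    group[i] <- g
  }
  new_row <- stats::setNames(group, row_ids)
  cells$row <- as.integer(new_row[as.character(cells$row)])
  # collisions after merging: keep the first real cell, drop imaginary dups,
  # real-real collisions mark the later vertex as artefact
  cells <- cells[order(cells$row, cells$col, cells$kind != "real"), ]
  dup <- duplicated(cells[, c("row", "col")])
  coll <- dup & cells$kind == "real"
  artefacts <- c(artefacts, cells$vertex[coll])
  cells <- cells[!dup, ]

  n_rows <- max(cells$row); n_cols <- max(cells$col)

  # --- fill empty cells with interpolated imaginary centroids
  real <- cells[cells$kind == "real", ]
  fit <- NULL
  if (nrow(real) >= 3L) {
    fit <- stats::lm.fit(cbind(1, real$row, real$col), cbind(real$x, real$y))
  }
  interp_cell <- function(r, c) {
    rr <- cells[cells$row == r & cells$kind == "real", ]
    if (nrow(rr) >= 2L) {
      return(c(stats::approx(rr$col, rr$x, xout = c, rule = 2)$y +
                 (c - stats::approx(rr$col, rr$col, xout = c, rule = 2)$y) *
                   mean(diff(rr$x) / diff(rr$col)),
               stats::approx(rr$col, rr$y, xout = c, rule = 2)$y +
                 (c - stats::approx(rr$col, rr$col, xout = c, rule = 2)$y) *
                   mean(diff(rr$y) / diff(rr$col))))
    }
    cc <- cells[cells$col == c & cells$kind == "real", ]
    if (nrow(cc) >= 2L) {
      return(c(stats::approx(cc$row, cc$x, xout = r, rule = 2)$y,
               stats::approx(cc$row, cc$y, xout = r, rule = 2)$y))
    }
    if (!is.null(fit)) return(drop(c(1, r, c) %*% fit$coefficients))
    c(NA_real_, NA_real_)
  }
  grid_full <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  have <- paste(cells$row, cells$col)
  missing_cells <- grid_full[!(paste(grid_full$row, grid_full$col) %in% have), ]
  if (nrow(missing_cells) > 0L) {
    add <- do.call(rbind, lapply(seq_len(nrow(missing_cells)), function(k) {
      xy <- interp_cell(missing_cells$row[k], missing_cells$col[k])
      data.frame(row = missing_cells$row[k], col = missing_cells$col[k],
                 kind = "imaginary", vertex = NA_integer_,
                 x = xy[1L], y = xy[2L], dy = NA_real_)
    }))
    cells <- rbind(cells, add)
  }

  # --- adopt unassigned vertices or mark them artefacts
  # A vertex with no horizontal adjacency at all (isolated by missing
  # neighbours) may sit in a row/column the traveling never visited, so the
  # imaginary field is first extended by boundary rings (positions from the
  # affine lattice fit) before nearest-imaginary adoption; untouched
  # all-imaginary boundaries are trimmed again below.
  assigned <- cells$vertex[!is.na(cells$vertex)]
  unassigned <- setdiff(seq_len(nrow(v)), c(assigned, artefacts))
  Tdist <- params$neighbour_threshold_factor * D
  cells$ring <- FALSE
  if (length(unassigned) > 0L && !is.null(fit)) {
    for (ring in 1:2) {
      rr <- range(cells$row); rc <- range(cells$col)
      border <- expand.grid(row = (rr[1L] - 1L):(rr[2L] + 1L),
                            col = (rc[1L] - 1L):(rc[2L] + 1L))
      border <- border[border$row < rr[1L] | border$row > rr[2L] |
                       border$col < rc[1L] | border$col > rc[2L], ]
      xy <- cbind(1, border$row, border$col) %*% fit$coefficients
      cells <- rbind(cells, data.frame(
        row = border$row, col = border$col, kind = "imaginary",
        vertex = NA_integer_, x = xy[, 1L], y = xy[, 2L], dy = NA_real_,
        ring = TRUE))
      adopted_outside <- FALSE
      still <- integer(0)
      for (u in unassigned) {
        im <- which(cells$kind == "imaginary" & !is.na(cells$x))
        d <- sqrt((cells$x[im] - v[u, 1L])^2 + (cells$y[im] - v[u, 2L])^2)
        # a vertex may only found a new boundary row/column if it sits on
        # the extrapolated lattice position; interior gaps are looser
        lim <- ifelse(cells$ring[im], 0.5 * D, Tdist)
        ok <- which(d <= lim)
        if (length(ok) > 0L) {
          hit <- im[ok[which.min(d[ok])]]
          if (cells$ring[hit]) adopted_outside <- TRUE
          cells$kind[hit] <- "real"
          cells$vertex[hit] <- u
          cells$x[hit] <- v[u, 1L]
          cells$y[hit] <- v[u, 2L]
        } else {
          still <- c(still, u)
        }
      }
      unassigned <- still
      if (!adopted_outside || length(unassigned) == 0L) break
    }
  }
  artefacts <- c(artefacts, unassigned)
  cells$ring <- NULL

  # --- trim all-imaginary boundary rows/columns
  repeat {
    real_rows <- sort(unique(cells$row[cells$kind == "real"]))
    real_cols <- sort(unique(cells$col[cells$kind == "real"]))
    if (length(real_rows) == 0L) break
    keep <- cells$row >= min(real_rows) & cells$row <= max(real_rows) &
            cells$col >= min(real_cols) & cells$col <= max(real_cols)
    if (all(keep)) break
    cells <- cells[keep, ]
  }
  cells$row <- cells$row - min(cells$row) + 1L
  cells$col <- cells$col - min(cells$col) + 1L
  cells$dy <- NULL
  cells <- cells[order(cells$row, cells$col), ]
  rownames(cells) <- NULL

  structure(list(cells = cells, n_rows = max(cells$row),
                 n_cols = max(cells$col),
                 artefacts = sort(unique(artefacts)),
                 vertices = v, D = D, theta_hat = grid$theta_hat,
                 row_labels = row_label(seq_len(max(cells$row))),
                 col_labels = seq_len(max(cells$col))),
            class = "tma_grid")
}

#' @export
print.tma_grid <- function(x, ...) {
  cat("TMA grid:", x$n_rows, "rows x", x$n_cols, "columns;",
      sum(x$cells$kind == "real"), "real,",
      sum(x$cells$kind == "imaginary"), "imaginary,",
      length(x$artefacts), "artefact(s); theta_hat =",
      round(x$theta_hat, 2), "deg, pitch D =", round(x$D, 1), "px\n")
  m <- matrix(".", x$n_rows, x$n_cols)
  m[cbind(x$cells$row, x$cells$col)] <-
    ifelse(x$cells$kind == "real", "o", "-")
  for (r in seq_len(x$n_rows)) {
    cat(sprintf("%3s ", row_label(r)), paste(m[r, ], collapse = " "), "\n")
  }
  invisible(x)
}

#' Run the whole gridding phase on a set of centroids
#'
#' @param centroids n x 2 matrix/data.frame of core centroids (px).
#' @param W,H image width and height (px).
#' @param params [grid_params()].
#' @return `tma_grid` (post-processed), with attribute `stages` giving
#'   per-stage edge counts.
#' @export
grid_cores <- function(centroids, W, H, params = grid_params()) {
  graph <- build_triangulation(centroids)
  li <- filter_edges_by_length(graph, params)
  af <- filter_edges_by_angle(graph, params)
  tpl <- make_edge_template(graph, li, af$edges)
  rows <- travel(tpl, W, params, af$theta_hat)
  grid <- assign_rows_and_columns(rows, params)
  grid <- postprocess(grid, params)
  attr(grid, "stages") <- list(edges = nrow(graph$edges),
                               length_filtered = length(li),
                               angle_filtered = length(af$edges),
                               template = nrow(tpl),
                               rows_found = length(rows))
  grid
}

#' Score a grid assignment against a ground-truth table
#'
#' Real cells are matched to true cores by nearest centroid within 5 px; the
#' accuracy is the fraction of true cores whose matched cell carries the true
#' `(row, col)` index. Unmatched or mis-indexed cores count as wrong.
#'
#' @param grid `tma_grid`.
#' @param truth data.frame with columns `row`, `col`, `cx`, `cy`.
#' @param tol matching tolerance in px.
#' @return fraction in `[0, 1]`.
#' @export
grid_accuracy <- function(grid, truth, tol = 5) {
  real <- grid$cells[grid$cells$kind == "real", ]
  if (nrow(truth) == 0L) return(NA_real_)
  correct <- 0L
  for (k in seq_len(nrow(truth))) {
    d <- sqrt((real$x - truth$cx[k])^2 + (real$y - truth$cy[k])^2)
    if (length(d) == 0L) break
    j <- which.min(d)
    if (d[j] <= tol && real$row[j] == truth$row[k] && real$col[j] == truth$col[k]) {
      correct <- correct + 1L
    }
  }
  correct / nrow(truth)
}
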