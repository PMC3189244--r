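# TMA core segmentation: contrast enhancement + thresholding, convex-hull
# regularization, fragment joining, Fourier-descriptor boundary smoothing and
# size filtering. The stage structure mirrors the de-arraying pipeline's
# first phase; each stage is exported on its own so intermediate results can
# be inspected.

#' Segmentation parameters
#'
#' @param clahe_clip CLAHE clip limit as a fraction of the tile pixel count,
#'   in `(0, 1]`.
#' @param clahe_tiles CLAHE tile grid count per axis.
#' @param laplacian_alpha shape parameter of the 3x3 Laplacian kernel used for
#'   sharpening, in `[0, 1]` (blend between 4- and 8-neighbour stencils).
#' @param close_radius disk radius (px) of the morphological close applied to
#'   the thresholded mask.
#' @param min_speck_area objects whose convex hull covers fewer pixels than
#'   this are discarded as specks (paper value: 10 px).
#' @param min_core_area objects smaller than this after boundary smoothing are
#'   discarded (paper value: 200 px).
#' @param fourier_terms number of low-frequency Fourier descriptor terms `P`
#'   kept when smoothing boundaries; `P >= 2`.
#' @param fragment_area_k IQR multiplier of the lower area fence used to flag
#'   fragment candidates (Tukey default 1.5).
#' @param fragment_dist_k IQR multiplier of the lower edge-length fence used
#'   to flag fragment pairs (Tukey default 1.5).
#' @return object of class `seg_params`.
#' @export
seg_params <- function(clahe_clip = 0.01, clahe_tiles = 8L,
                       laplacian_alpha = 0.2, close_radius = 2,
                       min_speck_area = 10, min_core_area = 200,
                       fourier_terms = 8L, fragment_area_k = 1.5,
                       fragment_dist_k = 1.5) {
  stopifnot(clahe_clip > 0, clahe_clip <= 1, clahe_tiles >= 1,
            laplacian_alpha >= 0, laplacian_alpha <= 1, close_radius >= 0,
            min_speck_area >= 0, min_core_area >= 0, fourier_terms >= 2,
            fragment_area_k > 0, fragment_dist_k > 0)
  structure(list(
    clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
    laplacian_alpha = laplacian_alpha, close_radius = close_radius,
    min_speck_area = min_speck_area, min_core_area = min_core_area,
    fourier_terms = as.integer(fourier_terms),
    fragment_area_k = fragment_area_k, fragment_dist_k = fragment_dist_k
  ), class = "seg_params")
}

#' Enhance a thumbnail and threshold it into a tissue mask
#'
#' CLAHE contrast enhancement, Laplacian sharpening (subtracting the filter
#' response, i.e. the negative of the Laplacian), Otsu global thresholding
#' (tissue is dark, so foreground is the *low* class) and a morphological
#' close with a disk of `close_radius`.
#'
#' A logical matrix input (an already-binary pseudo thumbnail) is passed
#' through unchanged apart from the close. A constant-intensity image yields
#' an empty mask carrying `attr(, "degenerate") = TRUE`, since Otsu's
#' criterion is undefined there.
#'
#' @param image numeric matrix in `[0, 1]`, RGB array, or logical matrix.
#' @param params [seg_params()].
#' @return logical mask; foreground = candidate tissue.
#' @export
enhance_and_threshold <- function(image, params = seg_params()) {
  if (is.logical(image)) {
    return(binary_close(image, params$close_radius))
  }
  image <- to_gray(image)
  if (length(image) == 0L || min(dim(image)) < 1L) stop("zero-sized image")
  if (min(dim(image)) < 32L) stop("image too small: need min(width, height) >= 32")
  if (diff(range(image)) < 1e-12) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
    attr(mask, "degenerate") <- TRUE
    warning("constant-intensity image: Otsu threshold undefined, returning empty mask")
    return(mask)
  }
  enh <- clahe(image, tiles = c(params$clahe_tiles, params$clahe_tiles),
               clip = params$clahe_clip)
  sharp <- enh - conv3(enh, laplacian_kernel(params$laplacian_alpha))
  sharp <- pmin(pmax(sharp, 0), 1)
  t <- otsu_threshold(sharp)
  if (is.na(t)) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
    attr(mask, "degenerate") <- TRUE
    warning("degenerate intensity histogram: returning empty mask")
    return(mask)
  }
  mask <- sharp <= t            # dark regions are tissue
  binary_close(mask, params$close_radius)
}

#' Convert binary objects to filled convex hulls and drop specks
#'
#' Every 8-connected component is replaced by its filled convex hull (the
#' smallest convex pixel set containing it); hulls with area below
#' `min_speck_area` are removed. Overlapping hulls merge.
#'
#' @param mask logical mask.
#' @param params [seg_params()].
#' @return object of class `core_set`: list with `mask` (logical), `labels`
#'   (integer matrix) and `candidates` (data.frame from [component_stats()]).
#' @export
extract_candidates <- function(mask, params = seg_params()) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- label_components(mask)
  out <- matrix(FALSE, nr, nc)
  K <- max(lab)
  for (k in seq_len(K)) {
    idx <- which(lab == k)
    x <- (idx - 1L) %/% nr
    y <- (idx - 1L) %% nr
    hull <- fill_convex_hull(x, y, nr, nc)
    if (sum(hull) >= params$min_speck_area) out <- out | hull
  }
  lab2 <- label_components(out)
  structure(list(mask = out, labels = lab2, candidates = component_stats(lab2)),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("core_set:", nrow(x$candidates), "candidates,",
      sum(x$mask), "foreground px\n")
  invisible(x)
}

#' Flag pairs of objects that look like fragments of one broken core
#'
#' An area-distance rule: a Delaunay-neighbouring pair is flagged when both
#' objects are lower area outliers (area below `Q1 - k_A * IQR` of all areas)
#' and their centroid distance is a lower edge-length outlier (below
#' `Q1 - k_d * IQR` of all triangulation edge lengths). With fewer than four
#' candidates the quartiles are meaningless and no pairs are returned.
#' Collinear centroid sets fall back to all pairwise distances in place of
#' Delaunay edges.
#'
#' @param candidates data.frame from [extract_candidates()] (`$candidates`).
#' @param params [seg_params()].
#' @return data.frame with columns `label_a`, `label_b`, `distance`.
#' @export
detect_fragments <- function(candidates, params = seg_params()) {
  empty <- data.frame(label_a = integer(), label_b = integer(),
                      distance = numeric())
  if (nrow(candidates) < 4L) return(empty)
  pts <- cbind(candidates$cx, candidates$cy)
  edges <- tryCatch({
    g <- build_triangulation(pts)
    g$edges
  }, error = function(e) {
    # degenerate geometry: use all pairwise distances
    cmb <- utils::combn(nrow(pts), 2L)
    data.frame(i = cmb[1L, ], j = cmb[2L, ],
               length = sqrt((pts[cmb[1L, ], 1] - pts[cmb[2L, ], 1])^2 +
                             (pts[cmb[1L, ], 2] - pts[cmb[2L, ], 2])^2))
  })
  area_fence <- lower_fence(candidates$area, params$fragment_area_k)
  dist_fence <- lower_fence(edges$length, params$fragment_dist_k)
  small <- candidates$area < area_fence
  hit <- small[edges$i] & small[edges$j] & edges$length < dist_fence
  if (!any(hit)) return(empty)
  data.frame(label_a = candidates$label[edges$i[hit]],
             label_b = candidates$label[edges$j[hit]],
             distance = edges$length[hit])
}

#' Join flagged fragment pairs
#'
#' Draws a 1-px digital line between the centroids of each flagged pair and
#' re-applies the convex hull stage, so chained pairs merge transitively into
#' one convex object.
#'
#' @param cores `core_set` from [extract_candidates()].
#' @param pairs data.frame from [detect_fragments()].
#' @param params [seg_params()].
#' @return updated `core_set`.
#' @export
join_fragments <- function(cores, pairs, params = seg_params()) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(cores)
  mask <- cores$mask
  cand <- cores$candidates
  for (k in seq_len(nrow(pairs))) {
    a <- match(pairs$label_a[k], cand$label)
    b <- match(pairs$label_b[k], cand$label)
    if (is.na(a) || is.na(b)) {
      warning("fragment pair references a removed label; skipped")
      next
    }
    ln <- bresenham(cand$cx[a], cand$cy[a], cand$cx[b], cand$cy[b])
    ok <- ln[, 1L] >= 0L & ln[, 1L] < ncol(mask) &
          ln[, 2L] >= 0L & ln[, 2L] < nrow(mask)
    mask[cbind(ln[ok, 2L] + 1L, ln[ok, 1L] + 1L)] <- TRUE
  }
  extract_candidates(mask, params)
}

# Keep the P lowest-frequency DFT terms of a complex boundary sequence and
# reconstruct. Frequencies are ranked by |f| with ties preferring positive f,
# i.e. retention is symmetric about zero frequency.
fourier_reconstruct <- function(z, P) {
  N <- length(z)
  Z <- stats::fft(z)
  k <- seq_len(N) - 1L
  f <- ifelse(k <= N / 2, k, k - N)
  ord <- order(abs(f), f < 0)
  keep <- logical(N)
  keep[ord[seq_len(min(P, N))]] <- TRUE
  stats::fft(Z * keep, inverse = TRUE) / N
}

#' Smooth object boundaries with truncated Fourier descriptors
#'
#' Each component's closed boundary is traced, expressed as a complex
#' sequence `x + iy`, transformed with the DFT, truncated to the `P` terms of
#' lowest absolute frequency (symmetric about zero), inverse-transformed and
#' re-filled as a polygon. Spurs and other high-frequency boundary detail are
#' removed; interior holes are filled. Components whose boundary is shorter
#' than `P` samples are left unchanged with a warning.
#'
#' @param cores `core_set` or logical mask.
#' @param P number of retained Fourier terms (default from [seg_params()]).
#' @return `core_set` with smoothed mask and recomputed candidates.
#' @export
smooth_boundaries <- function(cores, P = 8L) {
  mask <- if (inherits(cores, "core_set")) cores$mask else cores
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- label_components(mask)
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    b <- moore_boundary(comp)
    N <- nrow(b)
    if (N < max(P, 3L)) {
      if (N < P) warning("component ", k, " boundary shorter than P; left unchanged")
      out <- out | comp
      next
    }
    z <- complex(real = b[, 1L], imaginary = b[, 2L])
    zr <- fourier_reconstruct(z, P)
    poly <- fill_polygon(Re(zr), Im(zr), nr, nc)
    if (!any(poly)) poly <- comp    # degenerate reconstruction: keep original
    out <- out | poly
  }
  lab2 <- label_components(out)
  structure(list(mask = out, labels = lab2, candidates = component_stats(lab2)),
            class = "core_set")
}

#' Final size filter and candidate table
#'
#' Removes objects with area below `min_core_area` and returns the final
#' candidate set.
#'
#' @param cores `core_set` or logical mask.
#' @param params [seg_params()].
#' @return `core_set` whose `candidates` are the segmented TMA cores.
#' @export
finalize_candidates <- function(cores, params = seg_params()) {
  mask <- if (inherits(cores, "core_set")) cores$mask else cores
  lab <- label_components(mask)
  st <- component_stats(lab)
  drop <- st$label[st$area < params$min_core_area]
  if (length(drop)) {
    mask[lab %in% drop] <- FALSE
    lab <- label_components(mask)
    st <- component_stats(lab)
  }
  structure(list(mask = mask, labels = lab, candidates = st),
            class = "core_set")
}

#' Segment TMA cores from a slide thumbnail
#'
#' The full segmentation phase: enhancement + thresholding, convex hulls +
#' speck removal, fragment detection and joining, Fourier boundary smoothing,
#' and the final size filter.
#'
#' @param image grayscale matrix, RGB array or logical (binary) matrix.
#' @param params [seg_params()].
#' @return `core_set` with an extra `stages` list of per-stage counts
#'   (`thresholded_px`, `hulled`, `fragment_pairs`, `smoothed`, `final`).
#' @export
segment_cores <- function(image, params = seg_params()) {
  mask <- enhance_and_threshold(image, params)
  cs <- extract_candidates(mask, params)
  n_hulled <- nrow(cs$candidates)
  pairs <- detect_fragments(cs$candidates, params)
  cs <- join_fragments(cs, pairs, params)
  cs <- smooth_boundaries(cs, params$fourier_terms)
  n_smoothed <- nrow(cs$candidates)
  cs <- finalize_candidates(cs, params)
  cs$stages <- list(thresholded_px = sum(mask), hulled = n_hulled,
                    fragment_pairs = nrow(pairs), smoothed = n_smoothed,
                    final = nrow(cs$candidates))
  cs
}
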