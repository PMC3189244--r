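# Pseudo TMA slide simulator: binary thumbnails of near-circular cores on a
# regular lattice, with configurable missing cores, rigid rotation and
# cosine-model stretching, plus ground-truth (row, col, centroid) tables.
# This is the package's fixture generator for stress-testing the gridding
# phase, mirroring the five evaluation case sets.

#' Pseudo-slide specification
#'
#' Defaults describe the reference template: a 9 x 14 lattice (126 cores) at
#' 50 px pitch with ~30 px core diameter.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param pitch core centroid spacing (px) in both directions.
#' @param core_diameter mean core diameter (px); individual radii are
#'   jittered by +/-10% with low-order harmonic boundary noise.
#' @param seed integer RNG seed; every derived slide is deterministic in it.
#' @return object of class `pseudo_spec`.
#' @export
pseudo_spec <- function(n_rows = 9L, n_cols = 14L, pitch = 50,
                        core_diameter = 30, seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > core_diameter)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch = pitch, core_diameter = core_diameter,
                 seed = as.integer(seed)),
            class = "pseudo_spec")
}

# Rasterize cores (noisy discs) onto a canvas sized to hold all centroids
# with a one-pitch margin. `cores` carries per-core shape parameters so a
# slide can be re-rendered after centroid transforms.
render_pseudo <- function(cores, pitch) {
  margin <- pitch
  x0 <- min(cores$cx) - margin
  y0 <- min(cores$cy) - margin
  cores$cx <- cores$cx - x0
  cores$cy <- cores$cy - y0
  W <- ceiling(max(cores$cx) + margin)
  H <- ceiling(max(cores$cy) + margin)
  img <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(cores))) {
    r0 <- cores$r0[k]
    rmax <- r0 * 1.2
    xs <- max(0L, floor(cores$cx[k] - rmax)):min(W - 1L, ceiling(cores$cx[k] + rmax))
    ys <- max(0L, floor(cores$cy[k] - rmax)):min(H - 1L, ceiling(cores$cy[k] + rmax))
    gx <- rep(xs, times = length(ys))
    gy <- rep(ys, each = length(xs))
    dx <- gx - cores$cx[k]
    dy <- gy - cores$cy[k]
    d <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    rphi <- r0 * (1 + cores$a2[k] * cos(2 * phi + cores$p2[k]) +
                      cores$a3[k] * cos(3 * phi + cores$p3[k]))
    inside <- d <= rphi
    img[cbind(gy[inside] + 1L, gx[inside] + 1L)] <- TRUE
  }
  list(image = img, cores = cores, width = W, height = H)
}

as_pseudo_slide <- function(rend, spec, provenance) {
  truth <- data.frame(core_id = rend$cores$core_id,
                      row = rend$cores$row, col = rend$cores$col,
                      cx = rend$cores$cx, cy = rend$cores$cy)
  structure(list(image = rend$image, truth = truth, cores = rend$cores,
                 width = rend$width, height = rend$height, spec = spec,
                 provenance = provenance),
            class = "pseudo_slide")
}

#' @export
print.pseudo_slide <- function(x, ...) {
  cat("pseudo slide:", x$width, "x", x$height, "px,", nrow(x$truth),
      "cores;", paste(unlist(x$provenance), collapse = " "), "\n")
  invisible(x)
}

#' Generate the regular pseudo template slide
#'
#' Cores are near-circular discs (radius jitter +/-10%, low-order harmonic
#' boundary noise) at exact lattice positions; the ground-truth table maps
#' each core id to its true row, column and centroid.
#'
#' @param spec [pseudo_spec()].
#' @return object of class `pseudo_slide`: list with `image` (logical
#'   matrix), `truth` (data.frame `core_id`, `row`, `col`, `cx`, `cy`),
#'   `width`, `height`, per-core shape table `cores`, and `provenance`.
#' @export
make_pseudo_template <- function(spec = pseudo_spec()) {
  set.seed(spec$seed)
  n <- spec$n_rows * spec$n_cols
  g <- expand.grid(col = seq_len(spec$n_cols), row = seq_len(spec$n_rows))
  cores <- data.frame(
    core_id = seq_len(n),
    row = g$row, col = g$col,
    cx = (g$col - 1L) * spec$pitch,
    cy = (g$row - 1L) * spec$pitch,
    r0 = spec$core_diameter / 2 * stats::runif(n, 0.9, 1.1),
    a2 = stats::runif(n, 0, 0.04), p2 = stats::runif(n, 0, 2 * pi),
    a3 = stats::runif(n, 0, 0.03), p3 = stats::runif(n, 0, 2 * pi)
  )
  as_pseudo_slide(render_pseudo(cores, spec$pitch), spec,
                  list(case = "template"))
}

#' Remove k random cores from a pseudo slide
#'
#' Surviving cores keep their logical indices; the slide is re-rendered.
#'
#' @param slide `pseudo_slide`.
#' @param k number of cores to remove (`0 <= k <=` core count).
#' @param seed RNG seed for the removal draw.
#' @return `pseudo_slide`.
#' @export
apply_missing <- function(slide, k, seed = slide$spec$seed) {
  n <- nrow(slide$cores)
  stopifnot(k >= 0, k <= n)
  if (k == 0L) return(slide)
  set.seed(seed)
  drop <- sample.int(n, k)
  cores <- slide$cores[-drop, , drop = FALSE]
  prov <- c(slide$provenance, list(missing = k))
  if (nrow(cores) == 0L) {
    empty <- list(image = matrix(FALSE, slide$height, slide$width),
                  cores = cores, width = slide$width, height = slide$height)
    return(as_pseudo_slide(empty, slide$spec, prov))
  }
  as_pseudo_slide(render_pseudo(cores, slide$spec$pitch), slide$spec, prov)
}

#' Rotate a pseudo slide's grid layout rigidly
#'
#' Centroids rotate about the canvas center; `theta > 0` is clockwise on
#' screen (y-down coordinates). The canvas is re-padded so no core clips.
#'
#' @param slide `pseudo_slide`.
#' @param theta rotation in degrees, `|theta| <= 90`.
#' @return `pseudo_slide`.
#' @export
apply_rotation <- function(slide, theta) {
  stopifnot(abs(theta) <= 90)
  if (theta == 0) return(slide)
  cores <- slide$cores
  ctr <- c(slide$width / 2, slide$height / 2)
  xy <- rotate_points(cbind(cores$cx, cores$cy), theta, ctr)
  cores$cx <- xy[, 1L]; cores$cy <- xy[, 2L]
  as_pseudo_slide(render_pseudo(cores, slide$spec$pitch), slide$spec,
                  c(slide$provenance, list(rotation = theta)))
}

# Monotone difference-of-cosines stretch profile on [0, 1]:
# 0 at the fixed edge, 1 at the far (right) edge.
stretch_profile <- function(t) 1 - cos(pi * t / 2)

#' Stretch a pseudo slide's grid with the cosine deformation model
#'
#' Horizontal stretching adds `s * a_h * g(t_col) * w(row)` to x, where
#' `g(t) = 1 - cos(pi t / 2)` grows monotonically from the fixed left edge to
#' the right edge and the linear row weight `w` selects the pulled corner:
#' `a_h > 0` stretches the top-right corner, `a_h < 0` the bottom-right.
#' Vertical stretching is the analogue on y with amplitude `a_v` (`a_v > 0`
#' pulls the top-right corner downwards); the displacement fields for `+a`
#' and `-a` are mirror images about the horizontal midline.
#'
#' @param slide `pseudo_slide`.
#' @param a_h,a_v unitless stretch amplitudes (displacement is `s * a` px at
#'   the pulled corner).
#' @param s scaling factor (default 10).
#' @return `pseudo_slide`.
#' @export
apply_stretch <- function(slide, a_h = 0, a_v = 0, s = 10) {
  if (a_h == 0 && a_v == 0) return(slide)
  cores <- slide$cores
  R <- max(cores$row); C <- max(cores$col)
  tcol <- if (C > 1L) (cores$col - 1) / (C - 1) else rep(0, nrow(cores))
  trow <- if (R > 1L) (cores$row - 1) / (R - 1) else rep(0, nrow(cores))
  wtop <- 1 - trow          # 1 at top row, 0 at bottom
  wbot <- trow
  if (a_h != 0) {
    w <- if (a_h > 0) wtop else wbot
    cores$cx <- cores$cx + s * abs(a_h) * stretch_profile(tcol) * w
  }
  if (a_v != 0) {
    w <- if (a_v > 0) wtop else wbot
    dirn <- if (a_v > 0) 1 else -1
    cores$cy <- cores$cy + dirn * s * abs(a_v) * stretch_profile(tcol) * w
  }
  dmin <- min(stats::dist(cbind(cores$cx, cores$cy)))
  if (dmin < slide$spec$core_diameter) stop("stretch collapses lattice")
  as_pseudo_slide(render_pseudo(cores, slide$spec$pitch), slide$spec,
                  c(slide$provenance, list(a_h = a_h, a_v = a_v, s = s)))
}

#' Generate the five-set pseudo evaluation suite (113 slides)
#'
#' Mirrors the published suite structure: 26 missing-core cases (0-31 cores
#' removed, evenly spaced), 31 rotation cases spanning -15..+15 degrees, 13
#' horizontal-stretch and 16 vertical-stretch cases over `a_range`, and 27
#' mixed cases drawing all four degrees of freedom at random. Transform
#' order for mixed cases is missing -> stretch -> rotation (stretching is
#' defined on the lattice axes), recorded per-case in `provenance`.
#'
#' @param seed master seed; the whole suite is deterministic in it.
#' @param spec template [pseudo_spec()] (its `seed` field is overridden
#'   per case).
#' @param a_range stretch amplitude range for both axes.
#' @param max_missing largest missing-core count.
#' @param theta_range rotation range in degrees.
#' @return list of 113 `pseudo_slide` objects; attribute `manifest` is a
#'   data.frame of per-case parameters.
#' @export
generate_suite <- function(seed = 1L, spec = pseudo_spec(),
                           a_range = c(-2, 2), max_missing = 31L,
                           theta_range = c(-15, 15)) {
  set.seed(seed)
  n_cases <- 26L + 31L + 13L + 16L + 27L
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases + 27L * 4L)
  miss_k <- as.integer(round(seq(0L, max_missing, length.out = 26L)))
  rot_th <- seq(theta_range[1], theta_range[2], length.out = 31L)
  ah <- seq(a_range[1], a_range[2], length.out = 13L)
  av <- seq(a_range[1], a_range[2], length.out = 16L)
  slides <- vector("list", n_cases)
  manifest <- NULL
  ci <- 0L
  add <- function(set, k, th, a_h, a_v) {
    ci <<- ci + 1L
    sp <- spec
    sp$seed <- case_seeds[ci]
    sl <- make_pseudo_template(sp)
    sl$provenance <- list(case = sprintf("%s_%02d", set, ci), set = set,
                          order = "missing,stretch,rotation")
    if (k > 0L) sl <- apply_missing(sl, k, seed = case_seeds[ci] %% 1000003L + ci)
    if (a_h != 0 || a_v != 0) sl <- apply_stretch(sl, a_h, a_v)
    if (th != 0) sl <- apply_rotation(sl, th)
    slides[[ci]] <<- sl
    manifest <<- rbind(manifest, data.frame(
      case = ci, set = set, seed = case_seeds[ci], missing = k,
      theta = th, a_h = a_h, a_v = a_v, n_cores = nrow(sl$truth)))
  }
  for (k in miss_k) add("missing", k, 0, 0, 0)
  for (th in rot_th) add("rotation", 0L, th, 0, 0)
  for (a in ah) add("hstretch", 0L, 0, a, 0)
  for (a in av) add("vstretch", 0L, 0, 0, a)
  for (m in seq_len(27L)) {
    k <- sample.int(max_missing + 1L, 1L) - 1L
    th <- stats::runif(1, theta_range[1], theta_range[2])
    a_h <- stats::runif(1, a_range[1], a_range[2])
    a_v <- stats::runif(1, a_range[1], a_range[2])
    add("mixed", k, th, a_h, a_v)
  }
  attr(slides, "manifest") <- manifest
  slides
}

#' Write a pseudo slide to disk (mask + truth table)
#'
#' @param slide `pseudo_slide`.
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return invisibly, the two file paths.
#' @export
write_pseudo_slide <- function(slide, dir, name = "pseudo") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".pgm"))
  write_pgm(matrix(as.numeric(!slide$image), slide$height, slide$width), img_path)
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  utils::write.csv(slide$truth, truth_path, row.names = FALSE)
  invisible(c(img_path, truth_path))
}
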