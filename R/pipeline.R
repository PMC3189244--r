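# Pipeline plumbing: flat key=value configuration, the three-phase
# run_dearray() driver (segmentation -> gridding -> mapping), the pseudo
# suite evaluation harness, overlay rendering and a per-run report.

#' Default pipeline configuration
#'
#' A flat named list holding every segmentation and gridding parameter plus
#' `orientation` and the thumbnail-to-slide `downsample` factor. Serialized
#' as `key = value` lines; unknown keys are rejected on read.
#'
#' @return named list.
#' @export
pipeline_config <- function() {
  sp <- unclass(seg_params())
  gp <- unclass(grid_params())
  gp$kmeans_seeds <- paste(gp$kmeans_seeds, collapse = ";")
  c(sp, gp, list(orientation = "R0", downsample = 100))
}

#' Read a flat key=value configuration file
#'
#' @param path file of `key = value` lines; `#` starts a comment. Every key
#'   must be a known pipeline parameter; values keep the default's type.
#' @return named list as [pipeline_config()].
#' @export
read_config <- function(path) {
  cfg <- pipeline_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", l)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (is.numeric(cfg[[key]])) as.numeric(val) else val
  }
  cfg
}

#' Write a configuration to a flat key=value file
#'
#' @param cfg named list from [pipeline_config()]/[read_config()].
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) paste(format(v), collapse = ";"),
                            character(1))), path)
  invisible(path)
}

config_seg_params <- function(cfg) {
  seg_params(clahe_clip = cfg$clahe_clip, clahe_tiles = cfg$clahe_tiles,
             laplacian_alpha = cfg$laplacian_alpha,
             close_radius = cfg$close_radius,
             min_speck_area = cfg$min_speck_area,
             min_core_area = cfg$min_core_area,
             fourier_terms = cfg$fourier_terms,
             fragment_area_k = cfg$fragment_area_k,
             fragment_dist_k = cfg$fragment_dist_k)
}

config_grid_params <- function(cfg) {
  seeds <- cfg$kmeans_seeds
  if (is.character(seeds)) seeds <- as.numeric(strsplit(seeds, ";")[[1L]])
  grid_params(neighbour_threshold_factor = cfg$neighbour_threshold_factor,
              stop_margin_factor = cfg$stop_margin_factor,
              sector_radius_factor = cfg$sector_radius_factor,
              sector_half_angle = cfg$sector_half_angle,
              row_merge_factor = cfg$row_merge_factor,
              length_outlier_k = cfg$length_outlier_k,
              kmeans_seeds = seeds)
}

#' De-array a slide thumbnail end to end
#'
#' Runs segmentation, gridding, and (when a TMAMap is given) mapping, and
#' optionally writes the record table, grid table, labeled mask, overlay and
#' report to `out_dir`.
#'
#' @param image path to a thumbnail (PNG/JPEG/PGM/PPM/CSV), numeric matrix,
#'   RGB array or logical mask; a `pseudo_slide` is also accepted.
#' @param map optional TMAMap: path or `tmamap` matrix.
#' @param config [pipeline_config()] list (or path to a config file).
#' @param orientation orientation code applied to the map (overrides config).
#' @param out_dir optional output directory.
#' @return list with `records`, `grid`, `candidates`, `report`.
#' @export
run_dearray <- function(image, map = NULL, config = pipeline_config(),
                        orientation = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(orientation)) orientation <- config$orientation
  raw <- image
  if (inherits(image, "pseudo_slide")) raw <- image$image
  if (is.character(raw)) raw <- read_thumbnail(raw)

  cs <- tryCatch(segment_cores(raw, config_seg_params(config)),
                 error = function(e) stop("segmentation: ", conditionMessage(e)))
  cand <- cs$candidates
  W <- ncol(cs$mask); H <- nrow(cs$mask)
  if (nrow(cand) < 3L) stop("gridding: degenerate point set (fewer than 3 cores)")
  grid <- tryCatch(
    grid_cores(cand[, c("cx", "cy")], W, H, config_grid_params(config)),
    error = function(e) stop("gridding: ", conditionMessage(e)))

  if (!is.null(map)) {
    if (is.character(map) && !is.matrix(map)) map <- parse_tmamap(map)
    map <- orient_map(map, orientation)
    records <- tryCatch(
      map_names(grid, map, candidates = cand, scale = config$downsample),
      error = function(e) stop("mapping: ", conditionMessage(e)))
  } else {
    records <- grid_records(grid, candidates = cand, scale = config$downsample)
    records$name <- NA_character_
  }

  report <- make_report(cs, grid, config)
  out <- list(records = records, grid = grid, candidates = cand,
              mask = cs$mask, labels = cs$labels, report = report)
  if (!is.null(out_dir)) write_outputs(out, raw, out_dir)
  out
}

make_report <- function(cs, grid, config) {
  n_real <- sum(grid$cells$kind == "real")
  rep <- list(
    candidates = nrow(cs$candidates),
    fragment_pairs_joined = cs$stages$fragment_pairs,
    edges = attr(grid, "stages")$edges,
    edges_length_filtered = attr(grid, "stages")$length_filtered,
    edges_angle_filtered = attr(grid, "stages")$angle_filtered,
    template_vectors = attr(grid, "stages")$template,
    rows_found = attr(grid, "stages")$rows_found,
    n_rows = grid$n_rows, n_cols = grid$n_cols,
    gridded = n_real,
    imaginary = sum(grid$cells$kind == "imaginary"),
    artefacts = length(grid$artefacts),
    theta_hat = grid$theta_hat,
    pitch_D = grid$D
  )
  stopifnot(rep$gridded + rep$artefacts == rep$candidates)
  structure(rep, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    paste0("de-array report: %d candidates -> %d gridded + %d artefacts; ",
           "%dx%d grid, %d imaginary; theta=%.2f deg, D=%.1f px\n"),
    x$candidates, x$gridded, x$artefacts, x$n_rows, x$n_cols, x$imaginary,
    x$theta_hat, x$pitch_D))
  invisible(x)
}

write_outputs <- function(out, raw, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(out$grid$cells, file.path(out_dir, "grid.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(out$report),
                       file.path(out_dir, "report.json"), auto_unbox = TRUE)
  write_pgm(out$labels, file.path(out_dir, "labels.pgm"), maxval = 65535L)
  ov <- render_overlay(if (is.logical(raw)) matrix(as.numeric(!raw), nrow(raw), ncol(raw)) else raw,
                       out$grid, out$records)
  write_rgb(ov, file.path(out_dir, "overlay.ppm"))
  invisible(out_dir)
}

#' Evaluate gridding over the regenerated pseudo suite
#'
#' Generates the 113-case suite, grids every slide (gridding consumes the
#' centroids of the labeled binary mask) and scores each against its ground
#' truth.
#'
#' @param seed master suite seed.
#' @param config [pipeline_config()].
#' @param slides optional pre-generated suite (list of `pseudo_slide`).
#' @return data.frame per case (`case`, `set`, `n_cores`, `accuracy`), with
#'   attributes `overall` (core-weighted accuracy) and `per_set`.
#' @export
run_suite_eval <- function(seed = 1L, config = pipeline_config(),
                           slides = NULL) {
  if (is.null(slides)) slides <- generate_suite(seed)
  gp <- config_grid_params(config)
  sp <- config_seg_params(config)
  res <- lapply(seq_along(slides), function(i) {
    sl <- slides[[i]]
    acc <- tryCatch({
      lab <- label_components(sl$image)
      st <- component_stats(lab)
      st <- st[st$area >= sp$min_core_area, , drop = FALSE]
      g <- grid_cores(st[, c("cx", "cy")], sl$width, sl$height, gp)
      grid_accuracy(g, sl$truth)
    }, error = function(e) {
      warning("case ", i, " failed: ", conditionMessage(e))
      0
    })
    data.frame(case = i,
               set = if (!is.null(sl$provenance$set)) sl$provenance$set else "unknown",
               n_cores = nrow(sl$truth), accuracy = acc)
  })
  res <- do.call(rbind, res)
  w <- res$n_cores
  attr(res, "overall") <- sum(res$accuracy * w) / sum(w)
  attr(res, "per_set") <- vapply(split(res, res$set), function(d) {
    sum(d$accuracy * d$n_cores) / sum(d$n_cores)
  }, numeric(1))
  res
}

# --- overlay rendering -----------------------------------------------------

# Compact 3x5 bitmap font (rows top to bottom, '1' = ink) for grid labels.
glyphs3x5 <- function() {
  c("0" = "111101101101111", "1" = "010110010010111", "2" = "111001111100111",
    "3" = "111001111001111", "4" = "101101111001001", "5" = "111100111001111",
    "6" = "111100111101111", "7" = "111001010010010", "8" = "111101111101111",
    "9" = "111101111001111", "A" = "010101111101101", "B" = "110101110101110",
    "C" = "011100100100011", "D" = "110101101101110", "E" = "111100110100111",
    "F" = "111100110100100", "G" = "011100101101011", "H" = "101101111101101",
    "I" = "111010010010111", "J" = "001001001101010", "K" = "101110100110101",
    "L" = "100100100100111", "M" = "101111111101101", "N" = "101111111111101",
    "O" = "010101101101010", "P" = "110101110100100", "Q" = "010101101110011",
    "R" = "110101110110101", "S" = "011100010001110", "T" = "111010010010010",
    "U" = "101101101101111", "V" = "101101101101010", "W" = "101101111111101",
    "X" = "101101010101101", "Y" = "101101010010010", "Z" = "111001010100111",
    "," = "000000000010100", "?" = "111001010000010")
}

draw_text <- function(img, x, y, text, col = c(1, 0, 0)) {
  g <- glyphs3x5()
  h <- dim(img)[1]; w <- dim(img)[2]
  cx <- round(x)
  for (ch in strsplit(toupper(text), "")[[1L]]) {
    bits <- g[[ch]]
    if (!is.null(bits)) {
      m <- matrix(as.integer(strsplit(bits, "")[[1L]]) == 1L, 5, 3, byrow = TRUE)
      for (rr in 1:5) for (cc in 1:3) {
        if (m[rr, cc]) {
          py <- round(y) + rr; px <- cx + cc
          if (py >= 1 && py <= h && px >= 1 && px <= w) {
            img[py, px, ] <- col
          }
        }
      }
    }
    cx <- cx + 4L
  }
  img
}

#' Render a de-arraying overlay
#'
#' Draws grid labels on the thumbnail: real cells get their name (or
#' `row,col` index when no records/names are available), missing cells `M`,
#' unoccupied `U`, artefacts `A`. Mask boundaries are tinted when a labeled
#' mask is supplied.
#'
#' @param image grayscale matrix or RGB array.
#' @param grid `tma_grid`.
#' @param records optional record table from [map_names()].
#' @param labels optional label matrix whose object boundaries are tinted.
#' @return RGB array with attribute `annotations`: data.frame of drawn
#'   labels (`x`, `y`, `text`).
#' @export
render_overlay <- function(image, grid, records = NULL, labels = NULL) {
  img <- if (is.matrix(image)) {
    array(rep(pmin(pmax(image, 0), 1), 3L), c(nrow(image), ncol(image), 3L))
  } else image
  ann <- NULL
  add_ann <- function(x, y, text) {
    ann <<- rbind(ann, data.frame(x = x, y = y, text = text))
  }
  if (!is.null(labels)) {
    edge <- labels > 0 &
      (shift_mat(labels, 1, 0, 0L) != labels | shift_mat(labels, -1, 0, 0L) != labels |
       shift_mat(labels, 0, 1, 0L) != labels | shift_mat(labels, 0, -1, 0L) != labels)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[edge] <- c(0, 0.8, 0)[k]
      img[, , k] <- ch
    }
  }
  if (!is.null(records)) {
    for (i in seq_len(nrow(records))) {
      txt <- if (records$kind[i] == "artefact") "A"
             else if (!is.na(records$name[i])) records$name[i]
             else paste0(records$row_label[i], ",", records$col_index[i])
      add_ann(records$cx[i], records$cy[i], txt)
    }
  } else if (!is.null(grid) && nrow(grid$cells) > 0L) {
    for (i in seq_len(nrow(grid$cells))) {
      cell <- grid$cells[i, ]
      txt <- paste0(row_label(cell$row), ",", cell$col)
      add_ann(cell$x, cell$y, txt)
    }
    if (length(grid$artefacts)) {
      av <- grid$vertices[grid$artefacts, , drop = FALSE]
      for (i in seq_len(nrow(av))) add_ann(av[i, 1L], av[i, 2L], "A")
    }
  }
  if (!is.null(ann)) {
    for (i in seq_len(nrow(ann))) {
      img <- draw_text(img, ann$x[i] - 1.5 * nchar(ann$text[i]),
                       ann$y[i] - 2, ann$text[i])
    }
  }
  attr(img, "annotations") <- if (is.null(ann)) {
    data.frame(x = numeric(), y = numeric(), text = character())
  } else ann
  img
}
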