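# Mapping: correlate a grid assignment with a TMAMap (the spreadsheet grid
# of planned core names) to attach names and original-resolution coordinates.
# Slide orientation (8 possibilities: 4 rotations x optional left-right flip)
# is supplied by the user; the thumbnail-to-slide scale factor defaults to
# the 100x-per-axis downsampling used to produce thumbnails.

#' Parse a TMAMap file into a rectangular name grid
#'
#' CSV is read natively (no header; every row must have the same number of
#' fields); XLSX requires the optional \pkg{readxl} package. Blank cells are
#' preserved as empty strings; names are kept verbatim (including bracket
#' suffixes such as `A13T[4]`).
#'
#' @param path CSV or XLSX file.
#' @return object of class `tmamap`: a character matrix.
#' @export
parse_tmamap <- function(path) {
  if (!file.exists(path)) stop("TMAMap file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package; export the map as CSV")
    }
    df <- readxl::read_excel(path, col_names = FALSE, col_types = "text")
    m <- as.matrix(df)
    m[is.na(m)] <- ""
  } else if (ext == "csv") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0L || all(!nzchar(trimws(lines)))) stop("empty TMAMap file")
    lines <- lines[seq_len(max(which(nzchar(trimws(lines)))))]  # drop trailing blanks
    fields <- lapply(lines, function(l) {
      f <- scan(text = l, what = character(), sep = ",", quiet = TRUE,
                strip.white = TRUE, blank.lines.skip = FALSE)
      if (length(f) == 0L) "" else f
    })
    widths <- lengths(fields)
    if (length(unique(widths)) != 1L) {
      bad <- which(widths != widths[1L])[1L]
      stop("ragged TMAMap: row ", bad, " has ", widths[bad],
           " fields, expected ", widths[1L])
    }
    m <- do.call(rbind, fields)
  } else {
    stop("unsupported TMAMap format: .", ext)
  }
  m <- trimws(m)
  dimnames(m) <- NULL
  if (length(m) == 0L) stop("empty TMAMap file")
  structure(m, class = "tmamap")
}

rot90cw <- function(m) t(m[nrow(m):1L, , drop = FALSE])

#' The eight slide orientations
#'
#' Codes are `R0`, `R90`, `R180`, `R270` (clockwise rotation) with optional
#' suffix `F` for a preceding left-right flip, e.g. `"R90F"`.
#'
#' @return character vector of the eight codes.
#' @export
orientations <- function() {
  c("R0", "R90", "R180", "R270", "R0F", "R90F", "R180F", "R270F")
}

parse_orientation <- function(code) {
  code <- toupper(code)
  if (!code %in% orientations()) {
    stop("unknown orientation '", code, "'; use one of: ",
         paste(orientations(), collapse = ", "))
  }
  list(deg = as.integer(sub("^R(\\d+)F?$", "\\1", code)),
       flip = grepl("F$", code))
}

#' Re-orient a TMAMap
#'
#' Applies the optional left-right flip first, then the clockwise rotation.
#' Flipped codes are involutions; `R90`'s inverse is `R270` (see
#' [inverse_orientation()]).
#'
#' @param map `tmamap` (or plain matrix).
#' @param code orientation code, see [orientations()].
#' @return re-oriented `tmamap`.
#' @export
orient_map <- function(map, code = "R0") {
  o <- parse_orientation(code)
  m <- unclass(map)
  if (o$flip) m <- m[, ncol(m):1L, drop = FALSE]
  for (k in seq_len(o$deg / 90L)) m <- rot90cw(m)
  structure(m, class = "tmamap")
}

#' Inverse of an orientation code
#'
#' @param code orientation code.
#' @return the code whose application undoes `code`.
#' @export
inverse_orientation <- function(code) {
  o <- parse_orientation(code)
  if (o$flip) return(toupper(code))        # flip-then-rotate is an involution
  paste0("R", (360L - o$deg) %% 360L)
}

#' Correlate a grid assignment with a TMAMap
#'
#' Produces one de-array record per grid cell: real cells take the map name
#' at their (row, col); a real cell on a blank map position is unoccupied
#' (`"U"`); an imaginary cell with a nonblank name marks a missing core
#' (`"M"`); imaginary cells on blank positions are also `"U"`. Artefact
#' vertices are appended as records of kind `artefact` without a name.
#' Slide-scale bounding boxes are the thumbnail boxes multiplied by `scale`.
#'
#' @param grid `tma_grid` from [grid_cores()]/[postprocess()].
#' @param map `tmamap`; its shape must equal the grid's (orient it first).
#' @param candidates optional candidate table (from segmentation) supplying
#'   per-vertex bounding boxes; without it boxes are squares of side `D`
#'   centred on each centroid.
#' @param scale per-axis thumbnail-to-slide factor (default 100).
#' @return data.frame of de-array records: `name`, `row_label`, `col_index`,
#'   `kind`, `cx`, `cy`, `thumb_x`, `thumb_y`, `thumb_w`, `thumb_h`,
#'   `slide_x`, `slide_y`, `slide_w`, `slide_h`.
#' @export
map_names <- function(grid, map, candidates = NULL, scale = 100) {
  m <- unclass(map)
  if (nrow(m) != grid$n_rows || ncol(m) != grid$n_cols) {
    stop(sprintf("TMAMap shape %dx%d does not match grid shape %dx%d",
                 nrow(m), ncol(m), grid$n_rows, grid$n_cols))
  }
  rec <- grid_records(grid, candidates, scale)
  cellpos <- cbind(match(rec$row_label, row_label(seq_len(grid$n_rows))),
                   rec$col_index)
  on_grid <- rec$kind != "artefact"
  nm <- character(nrow(rec))
  nm[!on_grid] <- NA_character_
  mapped <- m[cellpos[on_grid, , drop = FALSE]]
  real <- rec$kind[on_grid] == "real"
  nm[on_grid] <- ifelse(nzchar(mapped),
                        ifelse(real, mapped, "M"),
                        "U")
  rec$name <- nm
  dup <- nm[on_grid & real][duplicated(nm[on_grid & real])]
  dup <- setdiff(dup, c("U", "M"))
  if (length(dup)) warning("duplicate TMAMap names: ", paste(dup, collapse = ", "))
  rec[, c("name", setdiff(names(rec), "name"))]
}

# Records table shared by map_names() and the no-map pipeline path.
grid_records <- function(grid, candidates = NULL, scale = 100) {
  cells <- grid$cells
  box <- function(vertex, x, y) {
    if (!is.null(candidates) && !is.na(vertex)) {
      k <- match(vertex, seq_len(nrow(grid$vertices)))
      if (!is.null(candidates$bbox_x) && !is.na(k) && k <= nrow(candidates)) {
        return(c(candidates$bbox_x[k], candidates$bbox_y[k],
                 candidates$bbox_w[k], candidates$bbox_h[k]))
      }
    }
    side <- round(grid$D)
    c(round(x - side / 2), round(y - side / 2), side, side)
  }
  bx <- t(vapply(seq_len(nrow(cells)),
                 function(i) box(cells$vertex[i], cells$x[i], cells$y[i]),
                 numeric(4)))
  rec <- data.frame(
    row_label = row_label(cells$row),
    col_index = cells$col,
    kind = cells$kind,
    cx = cells$x, cy = cells$y,
    thumb_x = bx[, 1L], thumb_y = bx[, 2L],
    thumb_w = bx[, 3L], thumb_h = bx[, 4L]
  )
  if (length(grid$artefacts)) {
    av <- grid$vertices[grid$artefacts, , drop = FALSE]
    side <- round(grid$D)
    rec <- rbind(rec, data.frame(
      row_label = NA_character_, col_index = NA_integer_, kind = "artefact",
      cx = av[, 1L], cy = av[, 2L],
      thumb_x = round(av[, 1L] - side / 2), thumb_y = round(av[, 2L] - side / 2),
      thumb_w = side, thumb_h = side
    ))
  }
  rec$slide_x <- rec$thumb_x * scale
  rec$slide_y <- rec$thumb_y * scale
  rec$slide_w <- rec$thumb_w * scale
  rec$slide_h <- rec$thumb_h * scale
  rownames(rec) <- NULL
  rec
}
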