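#' Read a TPS outline file
#'
#' Parses the TPS dialect written by outline-digitising software: records
#' begin with `LM=<n>` or `CURVES=<m>` followed by `POINTS=<n>` blocks, and
#' carry optional `ID=`, `IMAGE=` and `SCALE=` lines.  When both an `LM=`
#' block and a `CURVES=`/`POINTS=` block are present in one record the curve
#' points are taken as the outline (traced outlines are stored as curves);
#' the `LM=` points are ignored in that case.
#'
#' @param path Path to a TPS file.
#' @return A list of outline specimens, each a list with elements
#'   `points` (matrix, one row per point, columns x and y, already multiplied
#'   by the `SCALE=` factor when one is present), `specimen_id`,
#'   `species_code` (first six characters of the id, lowercased), `image` and
#'   `scale` (`NA` when absent).
#' @details Coordinates are planar with y increasing upward; no image-origin
#'   flipping is applied.  Malformed headers, point-count mismatches and
#'   non-numeric coordinates are errors that name the offending line.
#' @seealso [write_tps()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  specs <- list()
  i <- 1L
  n <- length(lines)
  parse_xy <- function(ln, lineno) {
    parts <- strsplit(trimws(ln), "[ \t,]+")[[1]]
    if (length(parts) != 2L)
      stop("line ", lineno, ": expected two coordinates, got '", ln, "'")
    xy <- suppressWarnings(as.numeric(parts))
    if (anyNA(xy) || any(!is.finite(xy)))
      stop("line ", lineno, ": non-numeric coordinate '", ln, "'")
    xy
  }
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^(LM|CURVES)=", ln, ignore.case = TRUE))
      stop("line ", i, ": expected LM= or CURVES= record header, got '", ln, "'")
    lm_pts <- NULL
    curve_pts <- NULL
    id <- NA_character_; image <- NA_character_; scale <- NA_real_
    read_block <- function(count, start) {
      pts <- matrix(NA_real_, count, 2L)
      if (count > 0) for (j in seq_len(count)) {
        if (start + j - 1L > n)
          stop("line ", n, ": file ends before ", count, " declared points")
        pts[j, ] <- parse_xy(lines[start + j - 1L], start + j - 1L)
      }
      pts
    }
    header_num <- function(ln, key, lineno) {
      v <- suppressWarnings(as.integer(sub(paste0("^", key, "="), "", ln,
                                           ignore.case = TRUE)))
      if (is.na(v) || v < 0) stop("line ", lineno, ": malformed ", key, "= header")
      v
    }
    read_curves <- function(ln, start) {
      ncurv <- header_num(ln, "CURVES", start)
      j <- start + 1L
      pts <- NULL
      for (ci in seq_len(ncurv)) {
        if (j > n || !grepl("^POINTS=", trimws(lines[j]), ignore.case = TRUE))
          stop("line ", j, ": expected POINTS= header inside CURVES block")
        cnt <- header_num(trimws(lines[j]), "POINTS", j)
        pts <- rbind(pts, read_block(cnt, j + 1L))
        j <- j + 1L + cnt
      }
      list(points = pts, next_line = j)
    }
    if (grepl("^LM=", ln, ignore.case = TRUE)) {
      cnt <- header_num(ln, "LM", i)
      lm_pts <- read_block(cnt, i + 1L)
      i <- i + 1L + cnt
    } else {
      res <- read_curves(ln, i)
      curve_pts <- res$points
      i <- res$next_line
    }
    # trailing lines of the record: an in-record CURVES block or keywords
    while (i <= n) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^LM=", ln, ignore.case = TRUE)) break
      if (grepl("^CURVES=", ln, ignore.case = TRUE)) {
        if (!is.null(curve_pts)) break  # next record
        res <- read_curves(ln, i)
        curve_pts <- res$points
        i <- res$next_line
      } else if (grepl("^POINTS=", ln, ignore.case = TRUE)) {
        stop("line ", i, ": POINTS= outside a CURVES block")
      } else if (grepl("^ID=", ln, ignore.case = TRUE)) {
        id <- sub("^ID=", "", ln, ignore.case = TRUE)
      } else if (grepl("^IMAGE=", ln, ignore.case = TRUE)) {
        image <- sub("^IMAGE=", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE=", ln, ignore.case = TRUE)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE=", "", ln,
                                                 ignore.case = TRUE)))
        if (is.na(scale) || scale <= 0)
          stop("line ", i, ": SCALE= must be a positive number")
      } else {
        stop("line ", i, ": unrecognised TPS keyword line '", ln, "'")
      }
      i <- i + 1L
    }
    pts <- if (!is.null(curve_pts)) curve_pts else lm_pts
    if (is.null(pts) || nrow(pts) < 1L)
      stop("record ending at line ", i - 1L, ": no points")
    if (!is.na(scale)) pts <- pts * scale
    specs[[length(specs) + 1L]] <- outline_spec(pts, specimen_id = id,
                                                scale = scale, image = image)
  }
  specs
}

#' Construct an outline specimen
#'
#' @param points Two-column numeric matrix of x,y coordinates tracing one
#'   closed curve; the first point must not be repeated at the end.
#' @param specimen_id,species_code,image Identifier strings.  When
#'   `species_code` is missing it is derived as the lowercased first six
#'   characters of `specimen_id` (the field's usual 6-letter species code).
#' @param scale Physical units per pixel, or `NA`.
#' @return An object of class `outline_spec`.
#' @export
outline_spec <- function(points, specimen_id = NA_character_,
                         species_code = NULL, scale = NA_real_,
                         image = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have two columns")
  storage.mode(points) <- "double"
  if (nrow(points) >= 2L &&
      isTRUE(all.equal(points[1L, ], points[nrow(points), ],
                       check.attributes = FALSE, tolerance = 0)))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 3L) stop("an outline needs at least 3 points")
  if (!all(is.finite(points))) stop("all coordinates must be finite")
  if (is.null(species_code))
    species_code <- tolower(substr(as.character(specimen_id), 1L, 6L))
  structure(list(points = unname(points),
                 specimen_id = as.character(specimen_id),
                 species_code = as.character(species_code),
                 scale = scale, image = image),
            class = "outline_spec")
}

#' @export
print.outline_spec <- function(x, ...) {
  cat("Outline specimen ", x$specimen_id, ": ", nrow(x$points), " points",
      if (!is.na(x$scale)) paste0(", scale ", x$scale), "\n", sep = "")
  invisible(x)
}

#' Write outlines to a TPS file
#'
#' Emits one record per specimen in the `CURVES=1`/`POINTS=` dialect read
#' back by [read_tps()].  Coordinates are written at full double precision so
#' a write/read round trip reproduces them to better than 1e-9.
#'
#' @param specs Non-empty list of outline specimens (see [outline_spec()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(specs, path) {
  if (length(specs) == 0L) stop("no outlines to write")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in specs) {
    pts <- s$points
    writeLines(c("CURVES=1", paste0("POINTS=", nrow(pts))), con)
    writeLines(sprintf("%.12g %.12g", pts[, 1L], pts[, 2L]), con)
    if (!is.na(s$specimen_id)) writeLines(paste0("ID=", s$specimen_id), con)
    if (!is.null(s$image) && !is.na(s$image))
      writeLines(paste0("IMAGE=", s$image), con)
    # SCALE is already applied to stored coordinates; never re-emitted
  }
  invisible(path)
}
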