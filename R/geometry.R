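#' Slide layer geometry
#'
#' Describes the tissue geometry of one whole slide as a rectangular strip
#' with three horizontal layer bands — intima at the bottom (luminal side),
#' media in the middle, adventitia on top — plus a list of excluded polygons
#' (blood, background) that are removed from all analyses. Coordinates are
#' in micrometers, origin at the bottom-left corner, continuous.
#'
#' @param width_um slide width (µm), > 0.
#' @param intima_um,media_um,adventitia_um layer thicknesses (µm), all > 0.
#' @param excluded list of excluded regions; each a list with `label`
#'   (`"blood"` or `"background"`) and `poly`, a two-column matrix of
#'   polygon vertices (µm, not closed). Polygons must lie within the slide
#'   bounds.
#'
#' @return An object of class `layer_geometry` with fields `width_um`,
#'   thicknesses, the cumulative boundaries `y_intima_media` and
#'   `y_media_adventitia`, total height `height_um`, and `excluded`.
#' @examples
#' g <- layer_geometry(1000, 100, 500, 400)
#' layer_areas(g)
#' @export
layer_geometry <- function(width_um, intima_um, media_um, adventitia_um,
                           excluded = list()) {
  if (!(width_um > 0)) stop("width_um must be > 0")
  if (!(intima_um > 0 && media_um > 0 && adventitia_um > 0))
    stop("layer thicknesses must be > 0")
  height <- intima_um + media_um + adventitia_um
  for (ex in excluded) {
    if (is.null(ex$label) || !ex$label %in% c("blood", "background"))
      stop("excluded region label must be 'blood' or 'background'")
    p <- ex$poly
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      stop("excluded polygon must be a matrix with >= 3 rows and 2 columns")
    if (any(p[, 1] < 0 | p[, 1] > width_um | p[, 2] < 0 | p[, 2] > height))
      stop("excluded polygon outside slide bounds")
  }
  structure(list(width_um = width_um, intima_um = intima_um,
                 media_um = media_um, adventitia_um = adventitia_um,
                 y_intima_media = intima_um,
                 y_media_adventitia = intima_um + media_um,
                 height_um = height, excluded = excluded),
            class = "layer_geometry")
}

#' @export
print.layer_geometry <- function(x, ...) {
  cat(sprintf("<layer_geometry> %.0f x %.0f um (I %.0f / M %.0f / A %.0f), %d excluded region(s)\n",
              x$width_um, x$height_um, x$intima_um, x$media_um,
              x$adventitia_um, length(x$excluded)))
  invisible(x)
}

# Ray-casting point-in-polygon; boundary points count as inside.
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y))
    xi <- px[j] + (y - py[j]) * (px[i] - px[j]) /
      ifelse(py[i] == py[j], Inf, py[i] - py[j])
    inside <- xor(inside, crosses & (x < xi))
    j <- i
  }
  # points exactly on an edge: treat as inside (excluded conservatively)
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    dx <- px[i] - px[j]; dy <- py[i] - py[j]
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((x - px[j]) * dx + (y - py[j]) * dy) / len2))
      d2 <- (px[j] + t * dx - x)^2 + (py[j] + t * dy - y)^2
      on_edge <- on_edge | d2 < 1e-12
    }
    j <- i
  }
  inside | on_edge
}

# Shoelace area of a simple polygon (absolute value).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman clip of a polygon to the horizontal band [y0, y1].
clip_polygon_band <- function(poly, y0, y1) {
  clip_half <- function(p, yb, keep_above) {
    if (is.null(p) || nrow(p) < 3L) return(NULL)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(p)
    inside <- if (keep_above) p[, 2] >= yb else p[, 2] <= yb
    for (i in seq_len(n)) {
      j <- if (i == 1L) n else i - 1L
      if (inside[i]) {
        if (!inside[j]) {
          t <- (yb - p[j, 2]) / (p[i, 2] - p[j, 2])
          out <- rbind(out, c(p[j, 1] + t * (p[i, 1] - p[j, 1]), yb))
        }
        out <- rbind(out, p[i, ])
      } else if (inside[j]) {
        t <- (yb - p[j, 2]) / (p[i, 2] - p[j, 2])
        out <- rbind(out, c(p[j, 1] + t * (p[i, 1] - p[j, 1]), yb))
      }
    }
    if (nrow(out) < 3L) NULL else out
  }
  p <- clip_half(poly, y0, TRUE)
  clip_half(p, y1, FALSE)
}

layer_bands <- function(geometry) {
  list(intima = c(0, geometry$y_intima_media),
       media = c(geometry$y_intima_media, geometry$y_media_adventitia),
       adventitia = c(geometry$y_media_adventitia, geometry$height_um))
}

#' Analyzed area of each tissue layer
#'
#' Band area minus the part of every excluded polygon that falls inside the
#' band. This is the denominator for all density computations.
#'
#' @param geometry a [layer_geometry()].
#' @return Named numeric vector (mm^2) for intima, media, adventitia.
#' @export
layer_areas <- function(geometry) {
  stopifnot(inherits(geometry, "layer_geometry"))
  bands <- layer_bands(geometry)
  out <- vapply(bands, function(b) {
    a <- geometry$width_um * (b[2] - b[1])
    for (ex in geometry$excluded) {
      cl <- clip_polygon_band(ex$poly, b[1], b[2])
      if (!is.null(cl)) a <- a - polygon_area(cl)
    }
    a
  }, numeric(1))
  if (any(out <= 0)) stop("analyzed layer area <= 0; check excluded regions")
  out / 1e6  # um^2 -> mm^2
}

#' Assign cells to tissue layers
#'
#' Point-in-region test against the layer bands and excluded polygons.
#' Cells inside an excluded polygon are labeled with the polygon's label
#' (`"blood"`/`"background"`) and are dropped from all downstream
#' summaries; cells outside the slide bounds are labeled `"background"`.
#' A cell exactly on a band boundary is assigned to the inner (more
#' luminal) layer.
#'
#' @param x_um,y_um numeric vectors of cell center positions (µm).
#' @param geometry a [layer_geometry()].
#' @return Character vector of labels among
#'   `"intima"`, `"media"`, `"adventitia"`, `"blood"`, `"background"`.
#' @examples
#' g <- layer_geometry(1000, 100, 500, 400)
#' assign_layer(c(10, 10, 10), c(50, 100, 700), g)
#' @export
assign_layer <- function(x_um, y_um, geometry) {
  stopifnot(inherits(geometry, "layer_geometry"), length(x_um) == length(y_um))
  out <- rep("background", length(x_um))
  inb <- x_um >= 0 & x_um <= geometry$width_um &
    y_um >= 0 & y_um <= geometry$height_um
  # boundary convention: y <= inner boundary -> inner layer
  out[inb & y_um <= geometry$y_intima_media] <- "intima"
  out[inb & y_um > geometry$y_intima_media &
        y_um <= geometry$y_media_adventitia] <- "media"
  out[inb & y_um > geometry$y_media_adventitia] <- "adventitia"
  for (ex in geometry$excluded) {
    hit <- inb & point_in_polygon(x_um, y_um, ex$poly)
    out[hit] <- ex$label
  }
  out
}

#' Read / write slide geometry as JSON
#'
#' @param geometry a [layer_geometry()].
#' @param path file path.
#' @return `write_geometry_json` returns `path` invisibly;
#'   `read_geometry_json` returns a [layer_geometry()].
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "layer_geometry"))
  doc <- list(width_um = geometry$width_um,
              intima_um = geometry$intima_um,
              media_um = geometry$media_um,
              adventitia_um = geometry$adventitia_um,
              excluded = lapply(geometry$excluded, function(ex)
                list(label = ex$label,
                     x = ex$poly[, 1], y = ex$poly[, 2])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  excluded <- list()
  if (length(doc$excluded)) {
    if (is.data.frame(doc$excluded)) {
      excluded <- lapply(seq_len(nrow(doc$excluded)), function(i)
        list(label = doc$excluded$label[i],
             poly = cbind(doc$excluded$x[[i]], doc$excluded$y[[i]])))
    } else {
      excluded <- lapply(doc$excluded, function(ex)
        list(label = ex$label, poly = cbind(ex$x, ex$y)))
    }
  }
  layer_geometry(doc$width_um, doc$intima_um, doc$media_um,
                 doc$adventitia_um, excluded = excluded)
}

#' Default slide geometry
#'
#' A 4 mm wide strip with 150 µm intima, 1200 µm media and 800 µm
#' adventitia — a desk-scale stand-in for a full-thickness ascending-aorta
#' section — with one luminal blood region (a 500 x 200 µm rectangle
#' straddling the intima/media boundary) excluded from analysis.
#'
#' @param with_blood include the default excluded blood region.
#' @return A [layer_geometry()].
#' @export
default_geometry <- function(with_blood = TRUE) {
  excluded <- if (with_blood) {
    list(list(label = "blood",
              poly = cbind(c(1000, 1500, 1500, 1000), c(0, 0, 200, 200))))
  } else list()
  layer_geometry(width_um = 4000, intima_um = 150, media_um = 1200,
                 adventitia_um = 800, excluded = excluded)
}
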