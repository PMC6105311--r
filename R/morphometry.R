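#' Circumferential landmarks of a 2D-map
#'
#' The classification of aortic cells hangs on three circumferential
#' landmarks: the ventral floor axis (placed by the user from the Z plane of
#' largest dorso-ventral diameter), the roof at half the unwrapped
#' circumference from it, and the two medio-lateral axes a quarter
#' circumference to either side of the floor.
#'
#' @param circumference map circumference `C` in um (width of the
#'   non-duplicated map times its pixel size).
#' @param floor_x circumferential coordinate of the ventral floor axis (um),
#'   reduced modulo `C`.
#' @return object of class `map_frame` with `roof_x` and
#'   `lateral_x` (`c(minus, plus)`), all in `[0, C)`.
#' @export
map_frame <- function(circumference, floor_x) {
  stopifnot(circumference > 0, is.finite(floor_x))
  floor_x <- floor_x %% circumference
  structure(
    list(
      circumference = circumference,
      floor_x = floor_x,
      roof_x = (floor_x + circumference / 2) %% circumference,
      lateral_x = c((floor_x - circumference / 4) %% circumference,
                    (floor_x + circumference / 4) %% circumference)
    ),
    class = "map_frame"
  )
}

.as_xy <- function(contour) {
  xy <- if (is.list(contour) && !is.null(contour$xy)) contour$xy else contour
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 3L) {
    stop("a contour needs an n x 2 matrix with at least 3 vertices")
  }
  storage.mode(xy) <- "double"
  xy
}

# do segments p1-p2 and p3-p4 properly intersect (shared endpoints excluded)?
.segs_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) -
    (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  idx <- rbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (.segs_cross(xy[idx[1L, i], ], xy[idx[2L, i], ],
                      xy[idx[1L, j], ], xy[idx[2L, j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Polygon area by the shoelace formula
#'
#' @param contour n x 2 matrix of vertices (um) or a contour list with an
#'   `xy` element; the polygon must be simple (seam-crossing contours are
#'   evaluated on the duplicated map, where they are simple).
#' @param pixel_size optional scale: when the contour is in map pixels,
#'   multiply coordinates by `pixel_size` to get um.
#' @return area in um^2, independent of vertex orientation.
#' @export
polygon_area <- function(contour, pixel_size = 1) {
  xy <- .as_xy(contour) * pixel_size
  if (!.is_simple_polygon(xy)) stop("self-intersecting polygon")
  x <- xy[, 1L]; y <- xy[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Best-fitting rectangle of a cell contour
#'
#' `length` is the extent parallel to the blood-flow (tube) axis — the map's
#' Y — and `width` the extent along the circumference (X). The default is the
#' axis-aligned bounding rectangle in map coordinates, which is what those
#' definitions pin down; `method = "rotated"` instead returns the dimensions
#' of the minimum-area rotated rectangle (rotating calipers over the convex
#' hull), assigning `length` to the side whose direction is closest to Y.
#'
#' @param contour n x 2 matrix (um) or contour list. Seam-crossing contours
#'   must be given in duplicated-map coordinates (continuous across the seam)
#'   so the width is the true circumferential extent.
#' @param method `"aligned"` (default) or `"rotated"`.
#' @return named numeric `c(length = , width = )` in um.
#' @export
bounding_rect <- function(contour, method = c("aligned", "rotated")) {
  xy <- .as_xy(contour)
  method <- match.arg(method)
  if (method == "aligned") {
    return(c(length = diff(range(xy[, 2L])), width = diff(range(xy[, 1L]))))
  }
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  n <- nrow(hull)
  best <- NULL; best_area <- Inf
  for (i in seq_len(n)) {
    e <- hull[(i %% n) + 1L, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[2L], u[1L])
    pu <- hull %*% u; pv <- hull %*% v
    du <- diff(range(pu)); dv <- diff(range(pv))
    if (du * dv < best_area) {
      best_area <- du * dv
      # which side is more axial (closer to Y)?
      best <- if (abs(u[2L]) >= abs(v[2L])) c(length = du, width = dv) else
        c(length = dv, width = du)
    }
  }
  best
}

#' Classify a cell as EHT, hemogenic or endothelial
#'
#' EHT identity is morphological/temporal and must be supplied by the user
#' (`eht_annotation`). Otherwise the positional rule applies: a cell is
#' (potentially) hemogenic when its circumferential span covers the ventral
#' floor axis while staying strictly within the two medio-lateral axes;
#' everything else is endothelial. The rule is invariant under cyclic shifts
#' of the theta origin.
#'
#' @param contour n x 2 matrix (um, duplicated-map coordinates allowed).
#' @param frame a [map_frame()].
#' @param eht_annotation logical; `TRUE` forces category `"EHT"`.
#' @return one of `"EHT"`, `"hemogenic"`, `"endothelial"`.
#' @export
classify_cell <- function(contour, frame, eht_annotation = FALSE) {
  stopifnot(inherits(frame, "map_frame"))
  if (isTRUE(eht_annotation)) return("EHT")
  xy <- .as_xy(contour)
  C <- frame$circumference
  xmin <- min(xy[, 1L]); xmax <- max(xy[, 1L])
  if (xmax - xmin > C + 1e-9) stop("contour wider than the circumference")
  # unwrap the floor axis next to the contour's interval (check the three
  # nearest periodic images; a contour wider than C/2 can cover more than one)
  k0 <- round(((xmin + xmax) / 2 - frame$floor_x) / C)
  for (k in (k0 - 1L):(k0 + 1L)) {
    fx <- frame$floor_x + k * C
    if (xmin <= fx && fx <= xmax &&
        xmin > fx - C / 4 && xmax < fx + C / 4) {
      return("hemogenic")
    }
  }
  "endothelial"
}

# squared distance from point p to segment a-b
.pt_seg_d2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  tt <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  q <- a + tt * ab
  sum((p - q)^2)
}

# minimum distance between segments a1-a2 and b1-b2
.seg_seg_dist <- function(a1, a2, b1, b2) {
  if (.segs_cross(a1, a2, b1, b2)) return(0)
  sqrt(min(.pt_seg_d2(a1, b1, b2), .pt_seg_d2(a2, b1, b2),
           .pt_seg_d2(b1, a1, a2), .pt_seg_d2(b2, a1, a2)))
}

.polygon_dist <- function(xy1, xy2) {
  n1 <- nrow(xy1); n2 <- nrow(xy2)
  i2 <- c(2:n1, 1L); j2 <- c(2:n2, 1L)
  best <- Inf
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      dd <- .seg_seg_dist(xy1[i, ], xy1[i2[i], ], xy2[j, ], xy2[j2[j], ])
      if (dd < best) best <- dd
      if (best == 0) return(0)
    }
  }
  best
}

#' Neighbour counts from cell contours
#'
#' Two cells are neighbours when at least part of their lateral junctions are
#' in direct contact, operationalised as: their `epsilon`-dilated polygons
#' intersect with positive measure, i.e. the minimum distance between the
#' polygon boundaries is strictly less than `2 * epsilon`. The test respects
#' the circumferential wrap (each pair is also compared with one polygon
#' shifted by the circumference).
#'
#' @param contours list of contours (n x 2 matrices or contour lists), um.
#' @param epsilon contact tolerance in um (default 0.5, about two map pixels;
#'   manual contours never share vertices exactly).
#' @param circumference map circumference in um, or `NULL` for a flat
#'   (non-wrapping) comparison.
#' @return list with `neighbor_ids` (list of integer vectors, indices into
#'   `contours`) and `n_neighbors` (integer vector). Symmetric by
#'   construction.
#' @export
count_neighbors <- function(contours, epsilon = 0.5, circumference = NULL) {
  stopifnot(epsilon >= 0)
  polys <- lapply(contours, .as_xy)
  n <- length(polys)
  adj <- matrix(FALSE, n, n)
  shifts <- if (is.null(circumference)) 0 else
    c(-circumference, 0, circumference)
  # strict "< 2 * epsilon" with a 1 nm guard so that polygons separated by
  # exactly 2 * epsilon never flip to neighbours through rounding
  thresh <- 2 * epsilon - 1e-9
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dmin <- Inf
      for (s in shifts) {
        shifted <- polys[[j]]
        shifted[, 1L] <- shifted[, 1L] + s
        dmin <- min(dmin, .polygon_dist(polys[[i]], shifted))
        if (dmin < thresh) break
      }
      adj[i, j] <- adj[j, i] <- dmin < thresh
    }
  }
  ids <- lapply(seq_len(n), function(i) which(adj[i, ]))
  names(ids) <- names(contours)
  list(neighbor_ids = ids, n_neighbors = vapply(ids, length, integer(1L)))
}

#' Measure and classify all cells of a map
#'
#' Runs [polygon_area()], [bounding_rect()], [classify_cell()] and
#' [count_neighbors()] over a contour set and returns the per-cell table the
#' CLI writes out.
#'
#' @param contours named list as produced by [read_contours()] (elements with
#'   `xy` and `eht`), coordinates in um.
#' @param frame a [map_frame()].
#' @param epsilon neighbour tolerance, um.
#' @param rect_method passed to [bounding_rect()].
#' @return data.frame `cell_id, category, length_um, width_um, area_um2,
#'   n_neighbors`.
#' @export
measure_cells <- function(contours, frame, epsilon = 0.5,
                          rect_method = "aligned") {
  stopifnot(length(contours) >= 1L)
  nb <- count_neighbors(lapply(contours, .as_xy), epsilon = epsilon,
                        circumference = frame$circumference)
  rows <- lapply(seq_along(contours), function(i) {
    cc <- contours[[i]]
    xy <- .as_xy(cc)
    rect <- bounding_rect(xy, method = rect_method)
    data.frame(
      cell_id = if (!is.null(names(contours))) names(contours)[i] else
        as.character(i),
      category = classify_cell(xy, frame,
                               eht_annotation = isTRUE(cc$eht)),
      length_um = unname(rect["length"]),
      width_um = unname(rect["width"]),
      area_um2 = polygon_area(xy),
      n_neighbors = nb$n_neighbors[i]
    )
  })
  do.call(rbind, rows)
}

#' Group means of cell morphometrics
#'
#' Summarises a per-cell table into per-category mean and SEM of length,
#' width and area. Pooling semantics are explicit: `by = "cell"` pools all
#' cells; `by = "map"` first averages within each map (requires a `map_id`
#' column) and then averages the per-map means, which is how figures quoting
#' "n = number of maps" are built.
#'
#' @param cells data.frame from [measure_cells()], optionally with `map_id`.
#' @param by `"cell"` or `"map"`.
#' @return data.frame with one row per category.
#' @export
summarize_morphometrics <- function(cells, by = c("cell", "map")) {
  by <- match.arg(by)
  vars <- c("length_um", "width_um", "area_um2")
  if (by == "map") {
    if (!("map_id" %in% names(cells))) {
      stop("`by = \"map\"` needs a map_id column")
    }
    cells <- stats::aggregate(
      cells[vars], by = cells[c("category", "map_id")], FUN = mean
    )
  }
  agg_mean <- stats::aggregate(cells[vars], by = cells["category"], FUN = mean)
  agg_sem <- stats::aggregate(
    cells[vars], by = cells["category"],
    FUN = function(x) stats::sd(x) / sqrt(length(x))
  )
  agg_n <- stats::aggregate(cells[vars[1L]], by = cells["category"],
                            FUN = length)
  out <- data.frame(
    category = agg_mean$category,
    n = agg_n[[2L]],
    mean_length_um = agg_mean$length_um,
    sem_length_um = agg_sem$length_um,
    mean_width_um = agg_mean$width_um,
    sem_width_um = agg_sem$width_um,
    mean_area_um2 = agg_mean$area_um2,
    sem_area_um2 = agg_sem$area_um2
  )
  out[order(out$category), , drop = FALSE]
}
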