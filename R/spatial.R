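#' Tract geometry
#'
#' Describes the location of the electrode tract in the same micrometre frame
#' as the spot coordinates. By default the tract is a point (its centroid);
#' an optional simple polygon outline can be supplied, in which case distances
#' are measured to the nearest polygon edge and are zero inside the outline.
#'
#' @param center_um Numeric length-2, planar tract centroid in micrometres.
#' @param polygon Optional two-column matrix (or data frame) of polygon
#'   vertices in micrometres, in order, not closed. Must be simple
#'   (non-self-intersecting) and contain `center_um`.
#' @return An object of class `tract_geometry`.
#' @export
tract_geometry <- function(center_um, polygon = NULL) {
  if (!is.numeric(center_um) || length(center_um) != 2L ||
      !all(is.finite(center_um))) {
    abort("`center_um` must be a finite numeric length-2 vector (x, y).")
  }
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L || !all(is.finite(polygon))) {
      abort("`polygon` must be a finite matrix with 2 columns and >= 3 rows.")
    }
    if (polygon_self_intersects(polygon)) {
      abort("`polygon` must be simple (non-self-intersecting).")
    }
    if (!point_in_polygon(center_um[1], center_um[2], polygon)) {
      abort("`polygon` must contain `center_um`.")
    }
  }
  structure(
    list(center_um = as.numeric(center_um), polygon = polygon),
    class = "tract_geometry"
  )
}

#' @export
print.tract_geometry <- function(x, ...) {
  cat(sprintf(
    "<tract_geometry> center (%.1f, %.1f) um%s\n",
    x$center_um[1], x$center_um[2],
    if (is.null(x$polygon)) "" else sprintf(", polygon with %d vertices",
                                            nrow(x$polygon))
  ))
  invisible(x)
}

# Segment intersection test used by the simple-polygon guard. Shared
# endpoints between adjacent edges are not counted as intersections.
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      # skip adjacent edges (they share a vertex)
      if (i == 1L && j == n) next
      if (segments_cross(poly[idx[i], ], poly[idx[i + 1L], ],
                         poly[idx[j], ], poly[idx[j + 1L], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Ray-casting point-in-polygon (boundary counts as inside).
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    hit <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  # points exactly on an edge: treat as inside (distance 0 either way)
  on_edge <- dist_to_polygon_edges(x, y, poly) < 1e-9
  inside | on_edge
}

# Minimum distance from points (x, y) to the polygon boundary (edges).
dist_to_polygon_edges <- function(x, y, poly) {
  n <- nrow(poly)
  dmin <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(x)) else ((x - ax) * vx + (y - ay) * vy) / len2
    t <- pmin(1, pmax(0, t))
    dx <- x - (ax + t * vx)
    dy <- y - (ay + t * vy)
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
    j <- i
  }
  dmin
}

#' Spot distances from the electrode tract
#'
#' Euclidean distance of each spot centroid from the tract. For a point tract
#' this is distance to the centroid; for a polygon tract it is distance to the
#' nearest polygon edge, with spots inside the outline assigned distance 0.
#'
#' @param spots A data frame with columns `barcode`, `x_um`, `y_um` (and
#'   optionally `in_tissue`, `artifact`).
#' @param tract A [tract_geometry()].
#' @return The input as a tibble with a `dist_um` column appended.
#' @export
spot_distances <- function(spots, tract) {
  spots <- validate_spot_table(spots)
  if (!inherits(tract, "tract_geometry")) {
    abort("`tract` must be a tract_geometry object.")
  }
  if (is.null(tract$polygon)) {
    d <- sqrt((spots$x_um - tract$center_um[1])^2 +
              (spots$y_um - tract$center_um[2])^2)
  } else {
    d <- dist_to_polygon_edges(spots$x_um, spots$y_um, tract$polygon)
    inside <- point_in_polygon(spots$x_um, spots$y_um, tract$polygon)
    d[inside] <- 0
  }
  dplyr::mutate(spots, dist_um = d)
}

validate_spot_table <- function(spots) {
  if (!is.data.frame(spots)) abort("`spots` must be a data frame.")
  need <- c("barcode", "x_um", "y_um")
  miss <- setdiff(need, names(spots))
  if (length(miss)) {
    abort(sprintf("`spots` is missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(spots$barcode)) abort("Spot barcodes must be unique.")
  if (!all(is.finite(spots$x_um)) || !all(is.finite(spots$y_um))) {
    abort("Spot coordinates must be finite.")
  }
  if (!"in_tissue" %in% names(spots)) spots$in_tissue <- TRUE
  if (!"artifact" %in% names(spots)) spots$artifact <- FALSE
  tibble::as_tibble(spots)
}

#' Assign distances to annular bins
#'
#' Half-open annuli `[k*w, (k+1)*w)`: a distance exactly on a bin edge falls
#' in the upper bin. Distances at or beyond `max_radius_um` are marked
#' "outside" (`NA` bin index).
#'
#' @param distances Numeric vector of distances (micrometres), or a data frame
#'   with a `dist_um` column as returned by [spot_distances()].
#' @param bin_width_um Bin width in micrometres (100 for expression and
#'   neuronal density, 10 for intensity profiles).
#' @param max_radius_um Distances at or beyond this are "outside" (default
#'   `Inf`: every distance gets a bin).
#' @return A tibble with columns `dist_um`, `bin` (integer index, 0-based, NA
#'   when outside), `bin_start_um`, `bin_end_um`; other input columns are
#'   retained when a data frame is supplied.
#' @export
assign_bins <- function(distances, bin_width_um = 100, max_radius_um = Inf) {
  assert_positive_scalar(bin_width_um, "bin_width_um")
  tbl <- if (is.data.frame(distances)) {
    if (!"dist_um" %in% names(distances)) {
      abort("`distances` data frame must have a `dist_um` column.")
    }
    tibble::as_tibble(distances)
  } else {
    tibble::tibble(dist_um = as.numeric(distances))
  }
  if (any(!is.finite(tbl$dist_um)) || any(tbl$dist_um < 0)) {
    abort("Distances must be finite and non-negative.")
  }
  idx <- floor(tbl$dist_um / bin_width_um)
  idx[tbl$dist_um >= max_radius_um] <- NA_integer_
  tbl$bin <- as.integer(idx)
  tbl$bin_start_um <- tbl$bin * bin_width_um
  tbl$bin_end_um <- (tbl$bin + 1L) * bin_width_um
  attr(tbl, "bin_width_um") <- bin_width_um
  attr(tbl, "max_radius_um") <- max_radius_um
  tbl
}

#' Select the electrode-site spot cluster
#'
#' Membership is strict: in-tissue, not artifact-flagged, and centroid
#' distance `< rmax_um` (matching the half-open 0-300 um bins 0-2 at the
#' default radius).
#'
#' @param spots Spot table (see [spot_distances()]).
#' @param tract A [tract_geometry()].
#' @param rmax_um Selection radius in micrometres (default 300).
#' @param name Label for the selection.
#' @return A `cluster_selection`: list with `name`, `barcodes`, `rmax_um`,
#'   `center_um`.
#' @export
select_cluster <- function(spots, tract, rmax_um = 300, name = "site") {
  assert_positive_scalar(rmax_um, "rmax_um")
  sp <- spot_distances(spots, tract)
  keep <- sp$in_tissue & !sp$artifact & sp$dist_um < rmax_um
  if (!any(keep)) {
    abort(sprintf(
      "Cluster '%s' is empty: no eligible spot within %g um of the tract.",
      name, rmax_um))
  }
  new_cluster_selection(name, sp$barcode[keep], rmax_um, tract$center_um)
}

new_cluster_selection <- function(name, barcodes, rmax_um, center_um = NULL) {
  structure(
    list(name = name, barcodes = as.character(barcodes),
         rmax_um = rmax_um, center_um = center_um),
    class = "cluster_selection"
  )
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection> '%s': %d spots, rmax %g um\n",
              x$name, length(x$barcodes), x$rmax_um))
  invisible(x)
}

#' Random non-overlapping naive-matched sites
#'
#' Draws `n_sites` disc-shaped regions from non-implanted tissue, matching the
#' electrode-site radius. Site centers are sampled uniformly from the
#' spot-occupied area (uniformly over eligible spot centroids) and accepted
#' only if every pairwise center distance exceeds `2 * radius_um`, so discs
#' never overlap. Rejection sampling is seeded and capped.
#'
#' @param spots Spot table.
#' @param n_sites Number of sites (default 3).
#' @param radius_um Disc radius (default 300).
#' @param seed RNG seed.
#' @param max_tries Rejection-sampling cap.
#' @return List of `cluster_selection` objects.
#' @export
select_naive_sites <- function(spots, n_sites = 3, radius_um = 300, seed = 1,
                               max_tries = 1000) {
  spots <- validate_spot_table(spots)
  assert_positive_scalar(radius_um, "radius_um")
  eligible <- spots[spots$in_tissue & !spots$artifact, , drop = FALSE]
  if (nrow(eligible) == 0L) abort("No eligible spots to place naive sites in.")
  with_seed(seed, {
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centers) < n_sites) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf(
          "Could not place %d non-overlapping sites of radius %g um in %d tries; tissue too small.",
          n_sites, radius_um, max_tries))
      }
      i <- sample.int(nrow(eligible), 1L)
      cand <- c(eligible$x_um[i], eligible$y_um[i])
      if (nrow(centers) > 0L) {
        dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
        if (any(dd <= 2 * radius_um)) next
      }
      centers <- rbind(centers, cand)
    }
    lapply(seq_len(n_sites), function(k) {
      tr <- tract_geometry(centers[k, ])
      select_cluster(spots, tr, rmax_um = radius_um,
                     name = sprintf("naive_site_%d", k))
    })
  })
}

annulus_area_um2 <- function(bin, bin_width_um) {
  pi * (((bin + 1)^2 - bin^2) * bin_width_um^2)
}

#' Radial neuronal density profile
#'
#' Counts neuron centroids per annulus around the tract and divides by the
#' annulus area, reported in neurons per square millimetre. For a point tract
#' the annulus area is analytic; for a polygon tract it is measured by dense
#' grid integration over the distance field.
#'
#' @param points Data frame with `x_um`, `y_um` neuron centroids.
#' @param tract A [tract_geometry()].
#' @param bin_width_um Bin width (default 100).
#' @param max_radius_um Outer radius of the profile.
#' @param grid_um Grid pitch for polygon-tract area integration (default 2).
#' @return A tibble `bin`, `bin_start_um`, `bin_end_um`, `n`, `area_mm2`,
#'   `value` (density, mm^-2) with class `radial_profile`.
#' @export
neuronal_density_profile <- function(points, tract, bin_width_um = 100,
                                     max_radius_um = 1000, grid_um = 2) {
  assert_positive_scalar(bin_width_um, "bin_width_um")
  assert_positive_scalar(max_radius_um, "max_radius_um")
  if (!is.data.frame(points) || !all(c("x_um", "y_um") %in% names(points))) {
    abort("`points` must be a data frame with `x_um` and `y_um`.")
  }
  d <- point_distances(points$x_um, points$y_um, tract)
  nb <- ceiling(max_radius_um / bin_width_um)
  bins <- 0:(nb - 1L)
  counts <- tabulate(floor(d[d < max_radius_um] / bin_width_um) + 1L, nbins = nb)
  if (is.null(tract$polygon)) {
    areas <- annulus_area_um2(bins, bin_width_um)
  } else {
    areas <- polygon_annulus_areas(tract, bins, bin_width_um, grid_um)
  }
  if (any(areas <= 0)) abort("Zero-area bin in density profile.")
  out <- tibble::tibble(
    bin = bins,
    bin_start_um = bins * bin_width_um,
    bin_end_um = (bins + 1L) * bin_width_um,
    n = counts,
    area_mm2 = areas / 1e6,
    value = counts / (areas / 1e6)
  )
  structure(out, class = c("radial_profile", class(out)),
            profile_type = "density", bin_width_um = bin_width_um)
}

point_distances <- function(x, y, tract) {
  if (!inherits(tract, "tract_geometry")) {
    abort("`tract` must be a tract_geometry object.")
  }
  if (is.null(tract$polygon)) {
    sqrt((x - tract$center_um[1])^2 + (y - tract$center_um[2])^2)
  } else {
    d <- dist_to_polygon_edges(x, y, tract$polygon)
    d[point_in_polygon(x, y, tract$polygon)] <- 0
    d
  }
}

# Measured annulus areas for a polygon tract, by grid integration of the
# distance-to-boundary field (cells inside the polygon are excluded from
# tissue area).
polygon_annulus_areas <- function(tract, bins, bin_width_um, grid_um) {
  rmax <- (max(bins) + 1L) * bin_width_um
  xr <- range(tract$polygon[, 1]) + c(-rmax, rmax)
  yr <- range(tract$polygon[, 2]) + c(-rmax, rmax)
  gx <- seq(xr[1] + grid_um / 2, xr[2], by = grid_um)
  gy <- seq(yr[1] + grid_um / 2, yr[2], by = grid_um)
  g <- expand.grid(x = gx, y = gy)
  d <- dist_to_polygon_edges(g$x, g$y, tract$polygon)
  inside <- point_in_polygon(g$x, g$y, tract$polygon)
  d <- d[!inside]
  cnt <- tabulate(floor(d[d < rmax] / bin_width_um) + 1L,
                  nbins = max(bins) + 1L)
  cnt * grid_um^2
}

#' Radial intensity profile
#'
#' Mean pixel intensity per annulus; pixels are assigned by their center.
#' Empty bins are recorded as missing (`NA`), not zero.
#'
#' @param field Data frame with `x_um`, `y_um`, `intensity` pixel samples on a
#'   micrometre-registered grid.
#' @param tract A [tract_geometry()].
#' @param bin_width_um Bin width (default 10, the convention for intensity).
#' @param max_radius_um Outer radius.
#' @return A `radial_profile` tibble with `value` = mean intensity per bin.
#' @export
intensity_profile <- function(field, tract, bin_width_um = 10,
                              max_radius_um = 300) {
  assert_positive_scalar(bin_width_um, "bin_width_um")
  assert_positive_scalar(max_radius_um, "max_radius_um")
  if (!is.data.frame(field) ||
      !all(c("x_um", "y_um", "intensity") %in% names(field))) {
    abort("`field` must be a data frame with `x_um`, `y_um`, `intensity`.")
  }
  d <- point_distances(field$x_um, field$y_um, tract)
  nb <- ceiling(max_radius_um / bin_width_um)
  bins <- 0:(nb - 1L)
  idx <- floor(d / bin_width_um)
  keep <- d < max_radius_um
  sums <- rep(0, nb); cnts <- rep(0L, nb)
  if (any(keep)) {
    agg <- tapply(field$intensity[keep], factor(idx[keep], levels = bins), sum)
    cnt <- tapply(rep(1L, sum(keep)), factor(idx[keep], levels = bins), sum)
    sums <- ifelse(is.na(agg), 0, agg)
    cnts <- ifelse(is.na(cnt), 0L, cnt)
  }
  value <- as.numeric(ifelse(cnts > 0, sums / cnts, NA_real_))
  out <- tibble::tibble(
    bin = bins,
    bin_start_um = bins * bin_width_um,
    bin_end_um = (bins + 1L) * bin_width_um,
    n = as.integer(cnts),
    area_mm2 = annulus_area_um2(bins, bin_width_um) / 1e6,
    value = value
  )
  structure(out, class = c("radial_profile", class(out)),
            profile_type = "intensity", bin_width_um = bin_width_um)
}

#' Summarize a radial profile within a radius
#'
#' Area-weighted mean of the per-bin values over all bins inside `rmax_um`.
#' For a density profile this equals total count / total area; for an
#' intensity profile it is the area-weighted mean intensity. This is the
#' within-300-um summary used to pair histology with recording metrics.
#'
#' @param profile A `radial_profile` from [neuronal_density_profile()] or
#'   [intensity_profile()].
#' @param rmax_um Summary radius (default 300). Profile bins must cover
#'   `[0, rmax_um)` completely.
#' @return A single numeric summary value.
#' @export
summarize_within <- function(profile, rmax_um = 300) {
  assert_positive_scalar(rmax_um, "rmax_um")
  if (!inherits(profile, "radial_profile")) {
    abort("`profile` must be a radial_profile.")
  }
  w <- attr(profile, "bin_width_um")
  covered <- profile$bin_start_um <= (rmax_um - w + 1e-9)
  sel <- profile[profile$bin_end_um <= rmax_um + 1e-9, , drop = FALSE]
  if (nrow(sel) == 0L || max(sel$bin_end_um) < rmax_um - 1e-9 ||
      any(diff(sel$bin) != 1L) || sel$bin[1] != 0L) {
    abort(sprintf("Profile bins do not cover [0, %g) completely.", rmax_um))
  }
  ok <- !is.na(sel$value)
  if (!any(ok)) abort("All bins within the summary radius are missing.")
  sum(sel$value[ok] * sel$area_mm2[ok]) / sum(sel$area_mm2[ok])
}
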