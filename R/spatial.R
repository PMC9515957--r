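#' Signed Euclidean distance from points to a tumor border
#'
#' Distance (in the units of the coordinates, conventionally micrometers)
#' from each point to the nearest segment of a border polyline, signed so
#' that points inside the tumor are negative. The tumor side is the side
#' of the polyline given by `tumor_side` relative to the vertex order
#' ("left" = the side a walker from vertex i to i+1 has on their left).
#'
#' @param points matrix or data.frame with columns `x`, `y`
#' @param border matrix or data.frame of ordered vertices (`x`, `y`);
#'   closed polygons are given by repeating the first vertex last.
#' @param tumor_side `"left"` or `"right"` of the vertex direction
#' @return numeric vector of signed distances (negative inside tumor)
#' @export
signedDistance <- function(points, border, tumor_side = c("left", "right")) {
  tumor_side <- match.arg(tumor_side)
  px <- points[["x"]]; py <- points[["y"]]
  stopifnot(all(is.finite(px)), all(is.finite(py)))
  bx <- border[["x"]]; by <- border[["y"]]
  n <- length(bx) - 1L
  stopifnot(n >= 1)
  best <- rep(Inf, length(px))
  side <- rep(0, length(px))
  for (i in seq_len(n)) {
    ax <- bx[i]; ay <- by[i]; dx <- bx[i + 1] - ax; dy <- by[i + 1] - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) next
    t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    qx <- ax + t * dx; qy <- ay + t * dy
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    upd <- d < best
    # side of the segment's infinite line: z of cross((b-a), (p-a))
    cr <- dx * (py - ay) - dy * (px - ax)
    side[upd] <- cr[upd]
    best[upd] <- d[upd]
  }
  inside <- if (tumor_side == "left") side > 0 else side < 0
  on_border <- best == 0
  out <- ifelse(inside, -best, best)
  out[on_border] <- 0
  out
}

#' Read border/mask polygons from GeoJSON or a vertex CSV
#'
#' GeoJSON: the first LineString or Polygon geometry found. CSV: columns
#' `x`, `y` in vertex order.
#'
#' @param path file path (`.geojson`/`.json` or `.csv`)
#' @return data.frame of vertices `x`, `y`
#' @export
readBorder <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path, simplifyVector = TRUE)
    geom <- if (!is.null(gj$features)) gj$features$geometry else gj
    coords <- geom$coordinates
    if (is.list(coords)) coords <- coords[[1]]
    if (is.list(coords)) coords <- coords[[1]]
    m <- matrix(unlist(coords), ncol = 2, byrow = !is.matrix(coords))
    if (is.matrix(coords)) m <- coords
    return(data.frame(x = m[, 1], y = m[, 2]))
  }
  utils::read.csv(path)[, c("x", "y")]
}

#' Density profile against signed border distance
#'
#' Bins cells of a marker class by signed distance to the tumor border
#' (negative = inside) over `[-range_um, +range_um]` and divides per-bin
#' counts by per-bin tissue area. Bin areas are computed by deterministic
#' grid sampling of the tissue mask at `grid_pitch` spacing (each grid
#' point inside the mask contributes pitch^2); for bins larger than about
#' 0.01 mm^2 this approximation is accurate to well under 1%.
#'
#' @param cells data.frame with `x`, `y` and logical marker columns
#' @param border vertex data.frame (see [signedDistance()])
#' @param mask tissue mask: either `c(xmin, xmax, ymin, ymax)` or a polygon
#'   data.frame (`x`, `y`)
#' @param class_filter optional logical vector (or marker column name)
#'   selecting the cell class profiled
#' @param bin_width bin width in um (default 50)
#' @param range_um profile half-range in um (default 500)
#' @param tumor_side passed to [signedDistance()]
#' @param grid_pitch area-sampling pitch in um (default 5)
#' @return data.frame `bin_left`, `bin_right`, `count`, `area_mm2`,
#'   `density` (cells/mm^2; NA for zero-area bins, which are flagged in
#'   `zero_area`)
#' @export
densityProfile <- function(cells, border, mask, class_filter = NULL,
                           bin_width = 50, range_um = 500,
                           tumor_side = "left", grid_pitch = 5) {
  if (is.character(class_filter)) class_filter <- as.logical(cells[[class_filter]])
  if (!is.null(class_filter)) cells <- cells[class_filter, , drop = FALSE]
  edges <- seq(-range_um, range_um, by = bin_width)
  d <- if (nrow(cells)) signedDistance(cells, border, tumor_side) else numeric()
  inr <- d >= -range_um & d <= range_um
  counts <- if (any(inr))
    table(cut(d[inr], edges, include.lowest = TRUE)) else
      table(cut(numeric(), edges, include.lowest = TRUE))
  # mask grid for bin areas
  if (is.numeric(mask) && length(mask) == 4) {
    gx <- seq(mask[1] + grid_pitch / 2, mask[2], by = grid_pitch)
    gy <- seq(mask[3] + grid_pitch / 2, mask[4], by = grid_pitch)
    grid <- expand.grid(x = gx, y = gy)
  } else {
    xr <- range(mask$x); yr <- range(mask$y)
    gx <- seq(xr[1] + grid_pitch / 2, xr[2], by = grid_pitch)
    gy <- seq(yr[1] + grid_pitch / 2, yr[2], by = grid_pitch)
    grid <- expand.grid(x = gx, y = gy)
    inp <- mgcv::in.out(as.matrix(rbind(mask[, c("x", "y")],
                                        mask[1, c("x", "y")])),
                        as.matrix(grid))
    grid <- grid[inp, , drop = FALSE]
  }
  gd <- signedDistance(grid, border, tumor_side)
  garea <- table(cut(gd[gd >= -range_um & gd <= range_um], edges,
                     include.lowest = TRUE))
  area_mm2 <- as.numeric(garea) * grid_pitch^2 * 1e-6
  out <- data.frame(bin_left = utils::head(edges, -1),
                    bin_right = edges[-1],
                    count = as.integer(counts),
                    area_mm2 = area_mm2)
  out$zero_area <- out$area_mm2 == 0
  out$density <- ifelse(out$zero_area, NA_real_, out$count / out$area_mm2)
  out
}

#' Classify the infiltration pattern of a density profile
#'
#' Compares mean density inside the tumor (negative bins) with outside:
#' ratio above `1 + epsilon` is infiltrated, below `1 - epsilon` excluded,
#' otherwise indeterminate.
#'
#' @param profile output of [densityProfile()]
#' @param epsilon tolerance band around 1 (default 0.1)
#' @return list `call` (one of infiltrated / excluded / indeterminate),
#'   `inside_mean`, `outside_mean`, `ratio`
#' @export
classifyInfiltration <- function(profile, epsilon = 0.1) {
  inside <- profile$density[profile$bin_right <= 0 & !profile$zero_area]
  outside <- profile$density[profile$bin_left >= 0 & !profile$zero_area]
  if (!length(inside) || !length(outside)) {
    warning("one-sided profile; infiltration indeterminate")
    return(list(call = "indeterminate", inside_mean = NA, outside_mean = NA,
                ratio = NA))
  }
  mi <- mean(inside); mo <- mean(outside)
  ratio <- if (mo == 0) Inf else mi / mo
  call <- if (ratio > 1 + epsilon) "infiltrated"
          else if (ratio < 1 - epsilon) "excluded"
          else "indeterminate"
  list(call = call, inside_mean = mi, outside_mean = mo, ratio = ratio)
}

#' Ki67-positive fraction of a T-cell lineage
#'
#' Fraction of Ki67+ cells among CD3+CD4+ (or CD3+CD8+) cells, with an
#' exact binomial confidence interval.
#'
#' @param cells data.frame with logical columns `CD3`, `CD4`, `CD8`, `Ki67`
#' @param lineage `"CD4"` or `"CD8"`
#' @param conf_level CI level (default 0.95)
#' @return data.frame `lineage`, `n`, `ki67_pos`, `fraction`, `ci_lo`,
#'   `ci_hi`
#' @export
ki67Fraction <- function(cells, lineage = c("CD4", "CD8"), conf_level = 0.95) {
  lineage <- match.arg(lineage)
  sel <- as.logical(cells$CD3) & as.logical(cells[[lineage]])
  n <- sum(sel)
  if (n == 0) stop("no CD3+", lineage, "+ cells: fraction undefined")
  k <- sum(as.logical(cells$Ki67)[sel])
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  data.frame(lineage = lineage, n = n, ki67_pos = k, fraction = k / n,
             ci_lo = ci[1], ci_hi = ci[2])
}

#' Per-region cell density and zone contrast
#'
#' Computes cell density (cells/mm^2) within labeled square or polygonal
#' regions and, when regions carry two zone labels, a two-sample t test on
#' the per-region densities between zones.
#'
#' @param cells data.frame with `x`, `y` (optionally pre-filtered to a
#'   marker class)
#' @param regions data.frame with `region_id`, `zone`, and either square
#'   specification (`cx`, `cy`, `edge` in um) or a `polygon` list-column of
#'   vertex data.frames
#' @return list `per_region` (region_id, zone, n, area_mm2, density) and
#'   `contrast` (zone_a, zone_b, t, p) when two zones are present
#' @export
regionalDensity <- function(cells, regions) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    if (!is.null(regions$polygon)) {
      poly <- regions$polygon[[i]]
      if (nrow(poly) < 3) return(NULL)  # degenerate
      inp <- mgcv::in.out(as.matrix(rbind(poly, poly[1, ])),
                          cbind(cells$x, cells$y))
      n <- sum(inp)
      area <- abs(sum(poly$x * c(poly$y[-1], poly$y[1]) -
                        c(poly$x[-1], poly$x[1]) * poly$y)) / 2
    } else {
      e <- regions$edge[i]
      if (is.na(e) || e <= 0) return(NULL)
      h <- e / 2
      n <- sum(cells$x >= regions$cx[i] - h & cells$x < regions$cx[i] + h &
                 cells$y >= regions$cy[i] - h & cells$y < regions$cy[i] + h)
      area <- e^2
    }
    data.frame(region_id = regions$region_id[i], zone = regions$zone[i],
               n = n, area_mm2 = area * 1e-6,
               density = n / (area * 1e-6), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  out <- list(per_region = per)
  zones <- unique(per$zone)
  if (length(zones) == 2) {
    a <- per$density[per$zone == zones[1]]
    b <- per$density[per$zone == zones[2]]
    if (length(a) > 1 && length(b) > 1) {
      tt <- stats::t.test(a, b)
      out$contrast <- data.frame(zone_a = zones[1], zone_b = zones[2],
                                 t = unname(tt$statistic), p = tt$p.value)
    }
  }
  out
}
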