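#' Classify ground vs canopy points in a field point cloud
#'
#' Transparent two-step ground filter: (1) seed the ground set with the
#' lowest point of each `cell_size` grid cell; (2) iteratively fit a plane
#' to the current ground set by least squares and re-classify — points
#' within `z_tolerance` of the plane are ground, points above it are
#' canopy. Suited to the gently varying terrain of a leveled field trial;
#' the contract downstream is only that the normalized heights (point
#' minus ground surface) are right.
#'
#' @param cloud data.frame with `x`, `y`, `z` (m).
#' @param cell_size grid cell size for minima seeding, m (default 1).
#' @param robust_iterations plane refits (default 3).
#' @param z_tolerance vertical band around the surface treated as ground,
#'   m (default 0.05).
#' @return The cloud with a `class` column (`"ground"` / `"canopy"`) and
#'   attribute `"plane"` = c(intercept, slope_x, slope_y).
#' @export
classify_ground <- function(cloud, cell_size = 1, robust_iterations = 3,
                            z_tolerance = 0.05) {
  stopifnot(all(c("x", "y", "z") %in% names(cloud)), nrow(cloud) > 0,
            all(is.finite(cloud$x)), all(is.finite(cloud$y)),
            all(is.finite(cloud$z)), cell_size > 0, z_tolerance > 0)
  cx <- floor(cloud$x / cell_size)
  cy <- floor(cloud$y / cell_size)
  cell <- paste(cx, cy)
  seed <- unlist(lapply(split(seq_len(nrow(cloud)), cell),
                        function(i) i[which.min(cloud$z[i])]),
                 use.names = FALSE)
  if (length(unique(cloud$x[seed])) < 2 && length(unique(cloud$y[seed])) < 2) {
    stop("degenerate geometry: ground candidates collinear in xy")
  }
  ground <- seed
  plane <- NULL
  for (it in seq_len(robust_iterations)) {
    X <- cbind(1, cloud$x[ground], cloud$y[ground])
    plane <- tryCatch(stats::lm.fit(X, cloud$z[ground])$coefficients,
                      error = function(e) NULL)
    if (is.null(plane) || anyNA(plane)) {
      # collinear seeds: fall back to a horizontal plane at the seed level
      plane <- c(stats::median(cloud$z[ground]), 0, 0)
    }
    surf <- plane[1] + plane[2] * cloud$x + plane[3] * cloud$y
    ground_new <- which(abs(cloud$z - surf) <= z_tolerance)
    if (length(ground_new) == 0) break
    if (setequal(ground_new, ground)) { ground <- ground_new; break }
    ground <- ground_new
  }
  cloud$class <- "canopy"
  cloud$class[ground] <- "ground"
  if (!any(cloud$class == "ground")) stop("no ground points identified")
  attr(cloud, "plane") <- plane
  cloud
}

#' Build a canopy height model from a classified cloud
#'
#' Interpolates the digital elevation model (DEM) over the cloud's
#' bounding box as a grid of node elevations evaluated from the fitted
#' ground plane, then normalizes every point by subtracting the
#' bilinearly interpolated DEM.
#'
#' @param cloud classified cloud from [classify_ground()].
#' @param cell_size DEM grid cell size, m (default 1).
#' @return List of class `chm`: `cloud` (with `height` column, m), `dem`
#'   (list: `x`, `y` node coordinates, `z` elevation matrix, `cell_size`).
#' @export
canopy_height_model <- function(cloud, cell_size = 1) {
  plane <- attr(cloud, "plane")
  if (is.null(plane) || !"class" %in% names(cloud)) {
    cloud <- classify_ground(cloud, cell_size = cell_size)
    plane <- attr(cloud, "plane")
  }
  xr <- range(cloud$x); yr <- range(cloud$y)
  gx <- seq(floor(xr[1]), ceiling(xr[2]) + cell_size, by = cell_size)
  gy <- seq(floor(yr[1]), ceiling(yr[2]) + cell_size, by = cell_size)
  dem_z <- outer(gx, gy, function(x, y) plane[1] + plane[2] * x +
                   plane[3] * y)
  # bilinear interpolation of the DEM at each point; a plane is exactly
  # reproduced, so normalized height = z - plane
  ix <- findInterval(cloud$x, gx, rightmost.closed = TRUE)
  iy <- findInterval(cloud$y, gy, rightmost.closed = TRUE)
  tx <- (cloud$x - gx[ix]) / cell_size
  ty <- (cloud$y - gy[iy]) / cell_size
  dem_at <- (1 - tx) * (1 - ty) * dem_z[cbind(ix, iy)] +
    tx * (1 - ty) * dem_z[cbind(ix + 1, iy)] +
    (1 - tx) * ty * dem_z[cbind(ix, iy + 1)] +
    tx * ty * dem_z[cbind(ix + 1, iy + 1)]
  cloud$height <- cloud$z - dem_at
  structure(list(cloud = cloud,
                 dem = list(x = gx, y = gy, z = dem_z,
                            cell_size = cell_size)),
            class = "chm")
}

#' Extract a percentile canopy height for one plot
#'
#' Percentile (default the 95th, "P95") of the normalized heights of all
#' points falling inside the plot rectangle; boundary-inclusive on the min
#' edges, exclusive on the max edges. The percentile uses linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param chm a [canopy_height_model()].
#' @param plot_rect named vector or one-row data.frame with `x_min`,
#'   `y_min`, `x_max`, `y_max` (m).
#' @param percentile in `(0, 100]` (default 95).
#' @param min_points plots with fewer points return `NA` (default 1).
#' @return Height in m, or `NA_real_` for an empty plot.
#' @export
extract_plot_percentile <- function(chm, plot_rect, percentile = 95,
                                    min_points = 1) {
  stopifnot(inherits(chm, "chm"), percentile > 0, percentile <= 100)
  r <- as.list(plot_rect)
  if (r$x_min >= r$x_max || r$y_min >= r$y_max) stop("degenerate rectangle")
  cl <- chm$cloud
  inside <- cl$x >= r$x_min & cl$x < r$x_max &
    cl$y >= r$y_min & cl$y < r$y_max
  h <- cl$height[inside]
  if (length(h) < min_points) return(NA_real_)
  unname(stats::quantile(h, percentile / 100, type = 7))
}

#' Per-plot canopy percentile table
#'
#' Applies [extract_plot_percentile()] over a table of plot rectangles for
#' one or more percentiles.
#'
#' @param chm a [canopy_height_model()].
#' @param plots data.frame: `plot_id`, `x_min`, `y_min`, `x_max`, `y_max`.
#' @param percentiles numeric vector (default `c(95, 99, 100)`).
#' @return data.frame: `plot_id`, one `p<q>_m` column per percentile,
#'   `n_points`.
#' @export
plot_canopy_metrics <- function(chm, plots, percentiles = c(95, 99, 100)) {
  cl <- chm$cloud
  out <- lapply(seq_len(nrow(plots)), function(i) {
    r <- plots[i, ]
    inside <- cl$x >= r$x_min & cl$x < r$x_max &
      cl$y >= r$y_min & cl$y < r$y_max
    vals <- vapply(percentiles, function(q) {
      if (sum(inside) == 0) NA_real_
      else unname(stats::quantile(cl$height[inside], q / 100, type = 7))
    }, numeric(1))
    row <- data.frame(plot_id = r$plot_id)
    row[paste0("p", percentiles, "_m")] <- as.list(vals)
    row$n_points <- sum(inside)
    row
  })
  do.call(rbind, out)
}
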