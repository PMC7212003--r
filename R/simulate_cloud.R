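#' Simulate a synthetic field point cloud with plot rectangles
#'
#' Generates a synthetic stand-in for a photogrammetric point cloud over a
#' plot grid: ground points on a (possibly tilted) ground plane plus
#' canopy points uniformly distributed between the ground and the plant
#' height within each plot footprint. Plot footprints follow the trial's
#' 0.76 m row spacing and 3.81 m plot lengths; rows advance along x,
#' ranges along y.
#'
#' @param plot_heights data.frame with `plot_id`, `range`, `row`,
#'   `height_m` (true canopy height per plot).
#' @param ground `c(intercept, slope_x, slope_y)` of the ground plane
#'   (default flat at z = 0).
#' @param density points per square meter, split evenly between ground and
#'   canopy (default 50; > 0).
#' @param row_spacing,plot_length footprint dimensions, m.
#' @param seed optional integer seed.
#' @return List: `cloud` (data.frame `x`, `y`, `z`), `plots` (data.frame
#'   `plot_id`, `x_min`, `y_min`, `x_max`, `y_max`), `empty_plots`
#'   (plot ids that received no canopy points).
#' @export
simulate_point_cloud_field <- function(plot_heights,
                                       ground = c(0, 0, 0),
                                       density = 50,
                                       row_spacing = 0.76,
                                       plot_length = 3.81,
                                       seed = NULL) {
  stopifnot(density > 0,
            all(c("plot_id", "range", "row", "height_m") %in%
                  names(plot_heights)))
  if (!is.null(seed)) set.seed(seed)
  plots <- data.frame(
    plot_id = plot_heights$plot_id,
    x_min = (plot_heights$row - 1) * row_spacing,
    y_min = (plot_heights$range - 1) * plot_length,
    stringsAsFactors = FALSE)
  plots$x_max <- plots$x_min + row_spacing
  plots$y_max <- plots$y_min + plot_length
  key <- paste(plots$x_min, plots$y_min)
  if (anyDuplicated(key)) stop("overlapping plot rectangles")

  area <- row_spacing * plot_length
  n_per <- max(1, round(density * area / 2))
  clouds <- list(); empty <- character(0)
  gz <- function(x, y) ground[1] + ground[2] * x + ground[3] * y
  for (i in seq_len(nrow(plots))) {
    gx <- stats::runif(n_per, plots$x_min[i], plots$x_max[i])
    gy <- stats::runif(n_per, plots$y_min[i], plots$y_max[i])
    g <- data.frame(x = gx, y = gy, z = gz(gx, gy))
    h <- plot_heights$height_m[i]
    if (h > 0) {
      cx <- stats::runif(n_per, plots$x_min[i], plots$x_max[i])
      cy <- stats::runif(n_per, plots$y_min[i], plots$y_max[i])
      cz <- gz(cx, cy) + stats::runif(n_per, 0, h)
      clouds[[i]] <- rbind(g, data.frame(x = cx, y = cy, z = cz))
    } else {
      clouds[[i]] <- g
      empty <- c(empty, plots$plot_id[i])
    }
  }
  list(cloud = do.call(rbind, c(clouds, make.row.names = FALSE)),
       plots = plots, empty_plots = empty)
}
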