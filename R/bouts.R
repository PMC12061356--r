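#' Segment labeled sessions into explore/exploit bouts
#'
#' A state episode is a maximal run of consecutive trials sharing one
#' explore/exploit label; every explore-to-exploit or exploit-to-explore
#' transition starts a new episode. For spatial metrics each episode is
#' further partitioned by choice aperture — an explore episode may contain
#' one left-side and one right-side bout, analysed separately.
#'
#' @param trials Labeled trial table with `state`, `side`, `x`, `y` and
#'   (multi-session) `mouse_id`, `session`, `trial`.
#' @param side_split Partition episodes by side (default `TRUE`). With
#'   `FALSE` one bout per episode is returned (`side = NA` when mixed).
#' @return A data frame with one row per bout: `mouse_id`, `session`,
#'   `episode`, `state`, `side`, `n_trials`, `trial_start`, `trial_end`,
#'   `centroid_x_px`, `centroid_y_px`.
#' @examples
#' b <- segment_bouts(make_fixture("side_switch_6"))
#' @export
segment_bouts <- function(trials, side_split = TRUE) {
  require_columns(trials, c("state", "side", "x", "y"))
  if (any(is.na(trials$state))) stop("state labels missing for some trials")
  out <- lapply(split_by_session(trials), function(g) {
    if ("trial" %in% names(g)) g <- g[order(g$trial), , drop = FALSE]
    n <- nrow(g)
    ep <- cumsum(c(TRUE, g$state[-1] != g$state[-n]))
    split_keys <- if (side_split) list(ep = ep, side = g$side) else list(ep = ep)
    grp <- interaction(split_keys, drop = TRUE)
    res <- do.call(rbind, lapply(split(seq_len(n), grp), function(idx) {
      data.frame(
        mouse_id = if ("mouse_id" %in% names(g)) g$mouse_id[idx[1]] else NA,
        session = if ("session" %in% names(g)) g$session[idx[1]] else 1L,
        episode = ep[idx[1]],
        state = g$state[idx[1]],
        side = if (side_split || length(unique(g$side[idx])) == 1) {
          g$side[idx[1]]
        } else NA_character_,
        n_trials = length(idx),
        trial_start = if ("trial" %in% names(g)) g$trial[idx[1]] else idx[1],
        trial_end = if ("trial" %in% names(g)) g$trial[idx[length(idx)]] else idx[length(idx)],
        centroid_x_px = mean(g$x[idx]),
        centroid_y_px = mean(g$y[idx]))
    }))
    res[order(res$episode, res$side), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-session bout counts
#'
#' Counts state episodes (not side-split bouts) per session: because
#' episodes strictly alternate between explore and exploit, the two counts
#' differ by at most one.
#'
#' @param trials Labeled trial table.
#' @return A data frame with `mouse_id`, `session`, `n_explore`,
#'   `n_exploit`, `n_total` (and `sex` when present).
#' @export
bout_counts <- function(trials) {
  require_columns(trials, "state")
  out <- lapply(split_by_session(trials), function(g) {
    if ("trial" %in% names(g)) g <- g[order(g$trial), , drop = FALSE]
    n <- nrow(g)
    ep_state <- g$state[c(TRUE, g$state[-1] != g$state[-n])]
    data.frame(
      mouse_id = if ("mouse_id" %in% names(g)) g$mouse_id[1] else NA,
      sex = if ("sex" %in% names(g)) g$sex[1] else NA,
      session = if ("session" %in% names(g)) g$session[1] else 1L,
      n_explore = sum(ep_state == "explore"),
      n_exploit = sum(ep_state == "exploit"),
      n_total = length(ep_state))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Distances between successive bout centroids
#'
#' Within each mouse, session, state and side, the Euclidean distance (mm)
#' between the centroids of successive bouts, in episode order. Groups
#' with fewer than two bouts yield no rows.
#'
#' @param bouts Output of [segment_bouts()].
#' @return A data frame with `mouse_id`, `session`, `state`, `side`,
#'   `from_episode`, `to_episode`, `shift_mm`.
#' @export
centroid_shift_distances <- function(bouts) {
  require_columns(bouts, c("state", "side", "episode",
                           "centroid_x_px", "centroid_y_px"), "bout table")
  keys <- interaction(bouts$mouse_id, bouts$session, bouts$state,
                      bouts$side, drop = TRUE)
  out <- do.call(rbind, lapply(split(bouts, keys), function(g) {
    g <- g[order(g$episode), , drop = FALSE]
    if (nrow(g) < 2) return(NULL)
    i <- seq_len(nrow(g) - 1)
    data.frame(
      mouse_id = g$mouse_id[i], session = g$session[i],
      state = g$state[i], side = g$side[i],
      from_episode = g$episode[i], to_episode = g$episode[i + 1],
      shift_mm = px_to_mm(sqrt(diff(g$centroid_x_px)^2 +
                                 diff(g$centroid_y_px)^2)))
  }))
  rownames(out) <- NULL
  out
}

#' Shoelace area and perimeter of a simple polygon
#'
#' @param polygon An n x 2 matrix/data frame of vertices (first vertex need
#'   not be repeated at the end), `n >= 3`.
#' @return A list with `area` (absolute shoelace area) and `perimeter`
#'   (summed edge lengths of the closed ring).
#' @examples
#' polygon_area_perimeter(cbind(c(0, 3, 0), c(0, 0, 4)))
#' @export
polygon_area_perimeter <- function(polygon) {
  p <- as.matrix(polygon)
  # drop a duplicated closing vertex
  if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3) stop("polygon needs at least 3 distinct vertices")
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  list(area = abs(sum(x * yn - xn * y)) / 2,
       perimeter = sum(sqrt((xn - x)^2 + (yn - y)^2)))
}

point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

choose_breaks <- function(v, coarsen) {
  nb <- tryCatch(grDevices::nclass.FD(v), error = function(e) 0L)
  if (!is.finite(nb) || nb < 1) nb <- grDevices::nclass.Sturges(v)
  nb <- max(2L, as.integer(ceiling(nb / coarsen)))
  seq(min(v), max(v), length.out = nb + 1L)
}

degenerate_contour <- function(n_points) {
  structure(list(polygons = list(), area_mm2 = NA_real_,
                 perimeter_mm = NA_real_, n_points = n_points,
                 n_components = 0L, degenerate = TRUE),
            class = "contour_result")
}

#' Density-contour boundary of a bout's touches
#'
#' Bins a bout's touch coordinates into a 2D histogram whose automatic bin
#' edges are coarsened by a factor of 2 (adjacent bins merged), normalises
#' the counts to `[0, 1]`, thresholds at `level`, and traces the iso-contour
#' boundaries of the occupied region on a zero-padded grid. The outermost
#' closed boundaries — those not nested inside any other — are identified by
#' a containment hierarchy; their shoelace areas and arc lengths are summed.
#'
#' @param x,y Touch coordinates of one bout.
#' @param units `"px"` (default; results converted to mm via the 0.29 mm/px
#'   calibration) or `"mm"`.
#' @param min_points Bouts with fewer points are flagged degenerate and get
#'   no area/perimeter (default 5).
#' @param level Normalised-density threshold in `[0, 1)`; the default 0
#'   keeps every occupied bin, i.e. the boundary of the least-dense
#'   outermost contour bin.
#' @param coarsen Bin-merging factor applied to the automatic
#'   (Freedman-Diaconis) edge count (default 2).
#' @return An object of class `contour_result`: `polygons` (list of vertex
#'   matrices in mm), `area_mm2`, `perimeter_mm`, `n_points`,
#'   `n_components` (number of top-level boundaries; > 1 flags disconnected
#'   regions whose measures were summed) and `degenerate`.
#' @examples
#' set.seed(1)
#' r <- bout_density_boundary(runif(2000, 0, 69), runif(2000, 0, 69))
#' r$area_mm2  # close to 20 mm x 20 mm = 400
#' @export
bout_density_boundary <- function(x, y, units = c("px", "mm"),
                                  min_points = 5, level = 0, coarsen = 2) {
  units <- match.arg(units)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < min_points) return(degenerate_contour(n))
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    return(degenerate_contour(n))
  }
  bx <- choose_breaks(x, coarsen)
  by <- choose_breaks(y, coarsen)
  cx <- cut(x, bx, include.lowest = TRUE, labels = FALSE)
  cy <- cut(y, by, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0, length(bx) - 1, length(by) - 1)
  for (k in seq_len(n)) counts[cx[k], cy[k]] <- counts[cx[k], cy[k]] + 1
  z <- counts / max(counts)
  mask <- ifelse(z > level & z > 0, 1, 0)

  # zero-pad one ring of cells so every boundary closes
  wx <- diff(bx[1:2]); wy <- diff(by[1:2])
  midx <- (bx[-1] + bx[-length(bx)]) / 2
  midy <- (by[-1] + by[-length(by)]) / 2
  midx <- c(midx[1] - wx, midx, midx[length(midx)] + wx)
  midy <- c(midy[1] - wy, midy, midy[length(midy)] + wy)
  zp <- matrix(0, length(midx), length(midy))
  zp[2:(length(midx) - 1), 2:(length(midy) - 1)] <- mask

  cl <- grDevices::contourLines(midx, midy, zp, levels = 0.5)
  if (!length(cl)) return(degenerate_contour(n))
  polys <- lapply(cl, function(p) cbind(p$x, p$y))
  depth <- vapply(seq_along(polys), function(i) {
    sum(vapply(seq_along(polys), function(j) {
      j != i && point_in_polygon(polys[[i]][1, 1], polys[[i]][1, 2],
                                 polys[[j]][, 1], polys[[j]][, 2])
    }, TRUE))
  }, 1L)
  outer_idx <- which(depth == 0L)
  scale <- if (units == "px") .MM_PER_PX else 1
  polys_mm <- lapply(polys, function(p) p * scale)
  geom <- lapply(polys_mm[outer_idx], polygon_area_perimeter)
  structure(
    list(polygons = polys_mm,
         area_mm2 = sum(vapply(geom, `[[`, 0, "area")),
         perimeter_mm = sum(vapply(geom, `[[`, 0, "perimeter")),
         n_points = n, n_components = length(outer_idx),
         degenerate = FALSE),
    class = "contour_result")
}

#' @export
print.contour_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Degenerate bout contour (%d point(s))\n", x$n_points))
  } else {
    cat(sprintf(
      "Bout contour: area %.1f mm^2, perimeter %.1f mm (%d point(s), %d component(s))\n",
      x$area_mm2, x$perimeter_mm, x$n_points, x$n_components))
  }
  invisible(x)
}

#' Full bout table with contour geometry
#'
#' Runs [segment_bouts()] and attaches each bout's density-contour area and
#' perimeter. Bouts below the minimum point count keep their counts and
#' centroids but carry `NA` geometry with `degenerate = TRUE`.
#'
#' @param trials Labeled trial table.
#' @param min_points Minimum touches for contour geometry (default 5).
#' @return The [segment_bouts()] table with `area_mm2`, `perimeter_mm`,
#'   `n_components`, `degenerate` columns appended.
#' @export
bout_table <- function(trials, min_points = 5) {
  bouts <- segment_bouts(trials)
  key_trials <- interaction(trials$mouse_id, trials$session, drop = TRUE)
  geoms <- lapply(seq_len(nrow(bouts)), function(i) {
    b <- bouts[i, ]
    idx <- which(as.character(key_trials) ==
                   paste(b$mouse_id, b$session, sep = ".") &
                 trials$trial >= b$trial_start & trials$trial <= b$trial_end &
                 trials$side == b$side)
    bout_density_boundary(trials$x[idx], trials$y[idx],
                          min_points = min_points)
  })
  bouts$area_mm2 <- vapply(geoms, `[[`, 0, "area_mm2")
  bouts$perimeter_mm <- vapply(geoms, `[[`, 0, "perimeter_mm")
  bouts$n_components <- vapply(geoms, `[[`, 0L, "n_components")
  bouts$degenerate <- vapply(geoms, `[[`, TRUE, "degenerate")
  bouts
}
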