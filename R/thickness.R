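#' Ray-traced thickness map between two interface surfaces
#'
#' At every valid grid node of the upper (more anterior) surface, a ray is
#' cast from the surface point along its local inward unit normal; the
#' thickness is the ray length to its intersection with the lower surface,
#' found by bracketed marching followed by bisection root refinement along
#' the ray. Nodes whose ray leaves the sampled aperture, or never intersects,
#' are masked invalid and counted.
#'
#' @param upper,lower congruent `surface_grid`s with the upper surface above
#'   (at smaller depth than) the lower surface on shared valid nodes.
#' @param layer label, `"EnDM"` or `"full_cornea"`.
#' @param step bracketing step along the ray, um (default: half the grid
#'   spacing).
#' @param tol bisection tolerance along the ray, um.
#' @param max_length maximum ray length before a node is declared
#'   non-intersecting, um.
#' @return An object of class `thickness_map`: grid coordinates, `thickness`
#'   matrix (um), valid-node `mask`, `layer` id and `n_failed` (rays masked
#'   during tracing).
#' @export
raytrace_thickness <- function(upper, lower, layer = c("EnDM", "full_cornea"),
                               step = upper$spacing / 2, tol = 1e-6,
                               max_length = 5000) {
  layer <- match.arg(layer)
  if (!isTRUE(all.equal(upper$x, lower$x)) || !isTRUE(all.equal(upper$y, lower$y)))
    abort("upper and lower surface grids are not congruent")
  nx <- length(upper$x); ny <- length(upper$y)
  valid <- upper$mask & lower$mask
  if (any(upper$z[valid] >= lower$z[valid]))
    abort("upper surface must lie above (at smaller depth than) the lower surface")

  # inward (posterior-directed) unit normals from central differences on the grid
  h <- upper$spacing
  z <- upper$z
  fx <- matrix(NA_real_, nx, ny); fy <- matrix(NA_real_, nx, ny)
  fx[2:(nx - 1), ] <- (z[3:nx, ] - z[1:(nx - 2), ]) / (2 * h)
  fx[1, ] <- (z[2, ] - z[1, ]) / h; fx[nx, ] <- (z[nx, ] - z[nx - 1, ]) / h
  fy[, 2:(ny - 1)] <- (z[, 3:ny] - z[, 1:(ny - 2)]) / (2 * h)
  fy[, 1] <- (z[, 2] - z[, 1]) / h; fy[, ny] <- (z[, ny] - z[, ny - 1]) / h

  idx <- which(valid)
  px <- upper$x[(idx - 1L) %% nx + 1L]
  py <- upper$y[(idx - 1L) %/% nx + 1L]
  pz <- z[idx]
  nrm <- sqrt(1 + fx[idx]^2 + fy[idx]^2)
  dx <- -fx[idx] / nrm; dy <- -fy[idx] / nrm; dz <- 1 / nrm

  n <- length(idx)
  rmax <- min(upper$rmax, lower$rmax)
  g_at <- function(t, sel) {
    (pz[sel] + t * dz[sel]) -
      eval_surface(lower, px[sel] + t * dx[sel], py[sel] + t * dy[sel])
  }
  in_aperture <- function(t, sel) {
    sqrt((px[sel] + t * dx[sel])^2 + (py[sel] + t * dy[sel])^2) <= rmax
  }

  lo <- numeric(n); hi <- rep(NA_real_, n)
  failed <- logical(n)
  active <- rep(TRUE, n)
  t_cur <- numeric(n)
  n_steps <- ceiling(max_length / step)
  for (k in seq_len(n_steps)) {
    if (!any(active)) break
    sel <- which(active)
    t_new <- t_cur[sel] + step
    out <- !in_aperture(t_new, sel)
    g <- g_at(t_new, sel)
    crossed <- !out & g >= 0
    hi[sel[crossed]] <- t_new[crossed]
    failed[sel[out]] <- TRUE
    active[sel[crossed | out]] <- FALSE
    still <- sel[!(crossed | out)]
    lo[still] <- t_new[!(crossed | out)]
    t_cur[still] <- t_new[!(crossed | out)]
  }
  failed[active] <- TRUE  # never crossed within max_length

  ok <- !failed
  if (any(ok)) {
    sel <- which(ok)
    a <- lo[sel]; b <- hi[sel]
    while (max(b - a) > tol) {
      mid <- (a + b) / 2
      g <- g_at(mid, sel)
      pos <- g >= 0
      b[pos] <- mid[pos]
      a[!pos] <- mid[!pos]
    }
    tt <- (a + b) / 2
  } else tt <- numeric(0)

  thick <- matrix(NA_real_, nx, ny)
  mask <- matrix(FALSE, nx, ny)
  thick[idx[ok]] <- tt
  mask[idx[ok]] <- TRUE
  structure(list(x = upper$x, y = upper$y, thickness = thick, mask = mask,
                 layer = layer, n_failed = sum(failed), spacing = upper$spacing),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> layer %s, %d valid nodes, central mean %.2f um\n",
              x$layer, sum(x$mask),
              tryCatch(central_mean(x)$mean_um, error = function(e) NA_real_)))
  invisible(x)
}

#' Mean thickness over a central circular zone
#'
#' Arithmetic mean of the map over valid nodes inside the disk of the given
#' diameter. The conventional central zone of corneal tomography is the
#' 2-mm-diameter disk centred on the vertex.
#'
#' @param map a `thickness_map`.
#' @param center zone centre `(x, y)`, um.
#' @param diameter zone diameter, um.
#' @return A one-row tibble: `mean_um`, `n_valid`, `center_x_um`,
#'   `center_y_um`, `diameter_um`, `layer`.
#' @export
central_mean <- function(map, center = c(0, 0), diameter = 2000) {
  nx <- length(map$x); ny <- length(map$y)
  X <- matrix(map$x, nx, ny)
  Y <- matrix(map$y, nx, ny, byrow = TRUE)
  inside <- (X - center[1])^2 + (Y - center[2])^2 <= (diameter / 2)^2
  sel <- inside & map$mask
  if (!any(sel)) abort("no valid nodes in ROI")
  tibble::tibble(mean_um = mean(map$thickness[sel]), n_valid = sum(sel),
                 center_x_um = center[1], center_y_um = center[2],
                 diameter_um = diameter, layer = map$layer)
}

#' Measure central En/DM and full corneal thickness for one visit
#'
#' Runs the full per-visit tomography chain on an OCT volume: segmentation of
#' every B-scan, 3-D point clouds for the three interfaces, bicubic surface
#' reconstruction, normal-ray thickness maps of the En/DM complex
#' (En/DM anterior interface to posterior surface) and the full cornea
#' (anterior to posterior surface), and their central-zone means. Errors from
#' any stage are re-raised tagged with the stage name.
#'
#' @param volume an `oct_volume`.
#' @param config a [segmentation_config()].
#' @param edits optional manual overrides (see [segment_volume()]).
#' @param spacing surface grid spacing, um.
#' @param zone_diameter central zone diameter, um.
#' @return A one-row tibble: `endmt_um`, `cct_um`, `n_valid_endmt`,
#'   `n_valid_cct`, `n_flagged_scans`, `zone_diameter_um`.
#' @export
measure_visit <- function(volume, config = segmentation_config(), edits = NULL,
                          spacing = 50, zone_diameter = 2000) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("[", name, "] ", conditionMessage(e))))
  }
  bset <- stage("segmentation", segment_volume(volume, config, edits))
  pts <- stage("reconstruction", lapply(
    c(anterior = "anterior", endm_anterior = "endm_anterior", posterior = "posterior"),
    function(i) boundaries_to_points(bset, i)))
  surf <- stage("reconstruction", lapply(pts, fit_surface_bicubic, spacing = spacing))
  endm_map <- stage("raytrace", raytrace_thickness(surf$endm_anterior, surf$posterior,
                                                   layer = "EnDM"))
  cct_map <- stage("raytrace", raytrace_thickness(surf$anterior, surf$posterior,
                                                  layer = "full_cornea"))
  endm <- stage("roi", central_mean(endm_map, diameter = zone_diameter))
  cct <- stage("roi", central_mean(cct_map, diameter = zone_diameter))
  n_flagged <- sum(vapply(bset$scans, function(s) length(s$flags) > 0, logical(1)))
  tibble::tibble(endmt_um = endm$mean_um, cct_um = cct$mean_um,
                 n_valid_endmt = endm$n_valid, n_valid_cct = cct$n_valid,
                 n_flagged_scans = n_flagged, zone_diameter_um = zone_diameter)
}
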