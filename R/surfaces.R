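#' Sample fitted boundaries into a 3-D point cloud
#'
#' Evaluates one interface's fitted curve on every usable (unflagged) B-scan
#' at a fixed column grid and maps radial-scan coordinates into the Cartesian
#' frame of the cornea: column `c` at cut angle `theta` maps to
#' `(r cos theta, r sin theta)` with signed radius
#' `r = (c - vertex_column) * lateral_um_per_px`, and rows convert to depth in
#' um via `axial_um_per_px`.
#'
#' @param bset a `boundary_set` from [segment_volume()].
#' @param interface `"anterior"`, `"endm_anterior"` or `"posterior"`.
#' @param column_step sampling stride along the column grid.
#' @return A tibble with columns `x_um`, `y_um`, `depth_um`, `angle_deg`,
#'   `r_um`, `scan`. Scans flagged `failed:*` are skipped; fewer than two
#'   usable scans is an error (`"no usable scans"`).
#' @export
boundaries_to_points <- function(bset, interface = c("anterior", "endm_anterior", "posterior"),
                                 column_step = 2L) {
  interface <- match.arg(interface)
  meta <- bset$meta
  usable <- which(vapply(bset$scans, function(s)
    !any(grepl("^failed:", s$flags)) && !is.null(s$fits[[interface]]), logical(1)))
  if (length(usable) < 2) abort("no usable scans")
  purrr::map_dfr(usable, function(s) {
    fit <- bset$scans[[s]]$fits[[interface]]
    cols <- seq(min(fit$columns), max(fit$columns), by = column_step)
    cols <- cols[cols != meta$vertex_column]
    r <- (cols - meta$vertex_column) * meta$lateral_um_per_px
    th <- meta$angles_deg[s] * pi / 180
    tibble::tibble(
      x_um = r * cos(th), y_um = r * sin(th),
      depth_um = predict_boundary(fit, cols) * meta$axial_um_per_px,
      angle_deg = meta$angles_deg[s], r_um = r, scan = s)
  })
}

#' Reconstruct a corneal interface surface by bicubic interpolation
#'
#' Two-stage bicubic reconstruction of an elevation surface from radial-scan
#' samples. A global bicubic trend (tensor products `x^i y^j`, `i, j <= 3`,
#' least squares) captures the corneal shape and makes the scheme exact for
#' planes and paraboloids; the lattice residuals are then interpolated on the
#' regular (meridian angle x radius) lattice with natural cubic splines
#' radially and periodic Catmull-Rom cubic convolution angularly, so the
#' reconstructed surface passes through every input sample. Points without
#' `angle_deg`/`r_um` columns fall back to the trend fit alone.
#'
#' @param points tibble from [boundaries_to_points()] (columns `x_um`, `y_um`,
#'   `depth_um`, and for full fidelity `angle_deg`, `r_um`).
#' @param spacing Cartesian grid spacing, um.
#' @param half_width half-extent of the square grid, um.
#' @return An object of class `surface_grid`: grid coordinates `x`, `y`
#'   (vectors, um), elevation matrix `z` (`z[i, j]` at `(x[i], y[j])`, depth
#'   um), logical `mask` of valid nodes (inside the sampled aperture) and the
#'   fitted-point RMSE.
#' @export
fit_surface_bicubic <- function(points, spacing = 50, half_width = 2900) {
  pts <- tibble::as_tibble(points)
  need <- c("x_um", "y_um", "depth_um")
  if (!all(need %in% names(pts)))
    abort("`points` needs columns x_um, y_um, depth_um")
  if (nrow(pts) < 16) abort("need at least 16 points to fit a bicubic surface")
  ang <- if ("angle_deg" %in% names(pts)) pts$angle_deg else
    (atan2(pts$y_um, pts$x_um) * 180 / pi) %% 180
  if (length(unique(round(ang %% 180, 6))) < 2)
    abort("degenerate point cloud: samples from fewer than 2 meridian angles")

  scale <- max(abs(c(pts$x_um, pts$y_um, 1)))
  B <- bicubic_basis(pts$x_um / scale, pts$y_um / scale)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    # radial sampling can be rank-deficient in the full tensor basis; drop
    # unsupported columns via the pivoted QR
    keep <- qrB$pivot[seq_len(qrB$rank)]
    beta <- rep(0, ncol(B))
    beta[keep] <- qr.coef(qr(B[, keep, drop = FALSE]), pts$depth_um)
  } else {
    beta <- qr.coef(qrB, pts$depth_um)
  }
  trend <- function(x, y) drop(bicubic_basis(x / scale, y / scale) %*% beta)

  has_lattice <- all(c("angle_deg", "r_um") %in% names(pts))
  resid_fun <- NULL
  rmax <- max(sqrt(pts$x_um^2 + pts$y_um^2))
  if (has_lattice) {
    resid <- pts$depth_um - trend(pts$x_um, pts$y_um)
    mer_angle <- ifelse(pts$r_um >= 0, pts$angle_deg, pts$angle_deg + 180) %% 360
    lat <- tibble::tibble(theta = mer_angle, rad = abs(pts$r_um), resid = resid)
    lat <- lat[lat$rad > 0, ]
    thetas <- sort(unique(lat$theta))
    if (length(thetas) >= 4 && max(abs(diff(diff(thetas)))) < 1e-6) {
      dth <- thetas[2] - thetas[1]
      splines <- lapply(thetas, function(t0) {
        m <- lat[lat$theta == t0, ]
        m <- m[order(m$rad), ]
        if (nrow(m) < 4) return(NULL)
        splinefun(m$rad, m$resid, method = "natural")
      })
      rmax <- min(vapply(seq_along(thetas), function(i)
        max(lat$rad[lat$theta == thetas[i]]), numeric(1)))
      if (!any(vapply(splines, is.null, logical(1)))) {
        resid_fun <- function(x, y) {
          rq <- sqrt(x^2 + y^2)
          tq <- (atan2(y, x) * 180 / pi) %% 360
          V <- vapply(splines, function(s) s(rq), numeric(length(rq)))
          if (is.null(dim(V))) V <- matrix(V, nrow = 1)
          j0 <- floor((tq - thetas[1]) / dth)
          s <- (tq - thetas[1]) / dth - j0
          wt <- cubic_conv_weights(s)
          nth <- length(thetas)
          out <- numeric(length(rq))
          for (k in 0:3) {
            jj <- ((j0 + (k - 1L)) %% nth) + 1L
            out <- out + wt[, k + 1L] * V[cbind(seq_along(rq), jj)]
          }
          out
        }
      }
    }
  }

  gx <- seq(-half_width, half_width, by = spacing)
  gy <- gx
  nodes <- expand.grid(x = gx, y = gy)
  z <- trend(nodes$x, nodes$y)
  if (!is.null(resid_fun)) z <- z + resid_fun(nodes$x, nodes$y)
  zmat <- matrix(z, nrow = length(gx))
  rad <- matrix(sqrt(nodes$x^2 + nodes$y^2), nrow = length(gx))
  mask <- rad <= rmax * 0.995

  eval_fun <- function(x, y) {
    out <- trend(x, y)
    if (!is.null(resid_fun)) out <- out + resid_fun(x, y)
    out
  }
  fitted <- eval_fun(pts$x_um, pts$y_um)
  structure(list(x = gx, y = gy, z = zmat, mask = mask, spacing = spacing,
                 rmax = rmax, eval = eval_fun,
                 fit_rmse = sqrt(mean((fitted - pts$depth_um)^2))),
            class = "surface_grid")
}

bicubic_basis <- function(xs, ys) {
  cols <- vector("list", 16L)
  k <- 1L
  for (i in 0:3) for (j in 0:3) {
    cols[[k]] <- xs^i * ys^j
    k <- k + 1L
  }
  do.call(cbind, cols)
}

#' Build a surface grid from an analytic elevation function
#'
#' Used to construct oracle surfaces (and ground-truth surfaces from a
#' phantom) on the same grid structure that [fit_surface_bicubic()] produces.
#'
#' @param f vectorised function `f(x, y)` returning depth in um.
#' @param spacing,half_width grid geometry, um.
#' @param mask_radius nodes farther than this from the origin are masked
#'   invalid (default: `half_width`).
#' @return A `surface_grid`.
#' @export
surface_from_function <- function(f, spacing = 50, half_width = 2900,
                                  mask_radius = half_width) {
  gx <- seq(-half_width, half_width, by = spacing)
  gy <- gx
  nodes <- expand.grid(x = gx, y = gy)
  zmat <- matrix(f(nodes$x, nodes$y), nrow = length(gx))
  rad <- matrix(sqrt(nodes$x^2 + nodes$y^2), nrow = length(gx))
  structure(list(x = gx, y = gy, z = zmat, mask = rad <= mask_radius,
                 spacing = spacing, rmax = mask_radius, eval = NULL,
                 fit_rmse = 0),
            class = "surface_grid")
}

#' Evaluate a surface grid at arbitrary points
#'
#' Uses the surface's own smooth interpolant when available (surfaces built by
#' [fit_surface_bicubic()]), otherwise bicubic convolution on the stored grid.
#'
#' @param surface a `surface_grid`.
#' @param x,y query coordinates, um.
#' @return depths in um.
#' @export
eval_surface <- function(surface, x, y) {
  if (!is.null(surface$eval)) return(surface$eval(x, y))
  interp_bicubic_grid(surface$x, surface$y, surface$z, x, y)
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %d x %d nodes, spacing %.3g um, %d valid, fit RMSE %.3g um\n",
              length(x$x), length(x$y), x$spacing, sum(x$mask), x$fit_rmse))
  invisible(x)
}
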