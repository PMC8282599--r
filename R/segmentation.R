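#' Segmentation configuration
#'
#' Free parameters of the boundary-estimation stage: per-A-scan band detection
#' followed by robust per-B-scan polynomial fitting of each interface with
#' RANSAC.
#'
#' @param poly_degree polynomial degree of the boundary model in the
#'   normalised lateral coordinate `u` in \[-1, 1\]. Default 4: the lowest even
#'   degree that represents a spherical-cap meridian over a 6-mm chord to
#'   sub-pixel accuracy.
#' @param ransac_iterations number of random minimal samples.
#' @param inlier_threshold_px absolute residual (axial px) below which a
#'   candidate supports a model.
#' @param min_peak_prominence minimum topographic prominence (relative
#'   intensity units) for an A-scan peak to count as a band candidate.
#' @param min_inlier_fraction consensus fraction under which a fit is flagged
#'   low-confidence (returned, not raised).
#' @param smooth_window_px boxcar width (axial px) applied to each A-scan
#'   before peak detection; sub-pixel refinement uses the raw profile.
#' @param seed integer seed driving the RANSAC sampler.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(poly_degree = 4L, ransac_iterations = 500L,
                                inlier_threshold_px = 2,
                                min_peak_prominence = 0.2,
                                min_inlier_fraction = 0.5,
                                smooth_window_px = 3L, seed = 1L) {
  if (poly_degree < 1) abort("`poly_degree` must be >= 1")
  if (ransac_iterations < 1) abort("`ransac_iterations` must be >= 1")
  if (inlier_threshold_px <= 0) abort("`inlier_threshold_px` must be positive")
  if (min_inlier_fraction <= 0 || min_inlier_fraction > 1)
    abort("`min_inlier_fraction` must lie in (0, 1]")
  structure(list(poly_degree = as.integer(poly_degree),
                 ransac_iterations = as.integer(ransac_iterations),
                 inlier_threshold_px = inlier_threshold_px,
                 min_peak_prominence = min_peak_prominence,
                 min_inlier_fraction = min_inlier_fraction,
                 smooth_window_px = as.integer(smooth_window_px),
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

#' Detect hyperreflective band candidates in a B-scan
#'
#' Works per A-scan column on a lightly smoothed depth profile: local maxima
#' with topographic prominence at or above `min_peak_prominence` are band
#' candidates. The shallowest peak is the anterior-surface candidate and the
#' two most posterior peaks are the En/DM anterior interface and posterior
#' surface, mirroring their appearance as the two most posterior
#' hyperreflective bands. Columns with fewer than three peaks, the saturation
#' (vertex) column, and columns whose refined rows violate the
#' anterior < En/DM < posterior ordering contribute no candidates. Peak rows
#' are refined to sub-pixel precision with a three-point log-quadratic fit on
#' the raw profile (exact for Gaussian band cross-sections).
#'
#' @param bscan `H x W` non-negative intensity matrix.
#' @param config a [segmentation_config()].
#' @param vertex_column saturation-artifact column to exclude.
#' @return A tibble with columns `interface` (`anterior`, `endm_anterior`,
#'   `posterior`), `column`, `row` (sub-pixel) and `intensity`. An all-zero
#'   image yields an empty candidate set carrying attribute
#'   `flag_empty_image = TRUE` plus a warning, never an error. The number of
#'   ordering-excluded columns is in attribute `n_order_excluded`.
#' @export
detect_bands <- function(bscan, config, vertex_column) {
  if (any(bscan < 0)) abort("B-scan intensities must be non-negative")
  empty <- tibble::tibble(interface = character(), column = integer(),
                          row = numeric(), intensity = numeric())
  if (all(bscan == 0)) {
    warn("all-zero B-scan: no band candidates")
    attr(empty, "flag_empty_image") <- TRUE
    attr(empty, "n_order_excluded") <- 0L
    return(empty)
  }
  h <- nrow(bscan); w <- ncol(bscan)
  sm <- boxcar_columns(bscan, config$smooth_window_px)
  up <- sm[2:(h - 1), , drop = FALSE] > sm[1:(h - 2), , drop = FALSE]
  dn <- sm[2:(h - 1), , drop = FALSE] >= sm[3:h, , drop = FALSE]
  tall <- sm[2:(h - 1), , drop = FALSE] >= config$min_peak_prominence
  hits <- which(up & dn & tall, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    attr(empty, "flag_empty_image") <- FALSE
    attr(empty, "n_order_excluded") <- 0L
    return(empty)
  }
  hits[, 1] <- hits[, 1] + 1L  # offset for the trimmed first row
  by_col <- split(hits[, 1], hits[, 2])

  out_col <- integer(0); out_row <- numeric(0)
  out_int <- numeric(0); out_if <- character(0)
  n_order_excluded <- 0L
  for (cc_chr in names(by_col)) {
    cc <- as.integer(cc_chr)
    if (cc == vertex_column) next
    prof <- sm[, cc]
    peaks <- by_col[[cc_chr]]
    # collapse plateau runs to a single representative
    if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
    prom <- vapply(peaks, function(p) peak_prominence(prof, p), numeric(1))
    peaks <- peaks[prom >= config$min_peak_prominence]
    if (length(peaks) < 3) next
    sel <- c(peaks[1], peaks[length(peaks) - 1L], peaks[length(peaks)])
    raw <- bscan[, cc]
    rows <- vapply(sel, function(p) refine_peak_subpixel(raw, p), numeric(1))
    if (!(rows[1] < rows[2] && rows[2] < rows[3])) {
      n_order_excluded <- n_order_excluded + 1L
      next
    }
    out_col <- c(out_col, rep(cc, 3L))
    out_row <- c(out_row, rows)
    out_int <- c(out_int, raw[sel])
    out_if <- c(out_if, c("anterior", "endm_anterior", "posterior"))
  }
  res <- tibble::tibble(interface = out_if, column = out_col,
                        row = out_row, intensity = out_int)
  attr(res, "flag_empty_image") <- FALSE
  attr(res, "n_order_excluded") <- n_order_excluded
  res
}

#' Robust polynomial boundary fit by random sample consensus
#'
#' Classical RANSAC: repeatedly draw `poly_degree + 1` candidates, fit the
#' interpolating polynomial in the normalised lateral coordinate, and count
#' candidates within `inlier_threshold_px` of it. The consensus-maximal model
#' wins; ties are broken by lower inlier RMSE, then by earlier iteration. The
#' final model is an ordinary least-squares refit on the consensus set.
#' Pinned points (manual expert edits) are always part of the refit and are
#' given dominating weight, so the returned curve honours them.
#'
#' @param points data frame with columns `column` and `row` (axial px).
#' @param config a [segmentation_config()].
#' @param u_center,u_halfwidth normalisation of the lateral coordinate,
#'   `u = (column - u_center) / u_halfwidth`; defaults map the data range to
#'   \[-1, 1\].
#' @param pinned optional logical vector marking rows of `points` that are
#'   manual overrides.
#' @param seed RANSAC seed (defaults to `config$seed`).
#' @return An object of class `boundary_fit`: `coefficients` (increasing
#'   degree, in `u`), `inlier_mask`, `rmse` (inlier RMSE, axial px),
#'   `inlier_fraction`, `low_confidence` flag and the `u` transform.
#' @export
ransac_fit <- function(points, config, u_center = NULL, u_halfwidth = NULL,
                       pinned = NULL, seed = config$seed) {
  pts <- as.data.frame(points)
  n <- nrow(pts)
  m <- config$poly_degree + 1L
  if (n < m) abort("insufficient candidates")
  if (is.null(pinned)) pinned <- rep(FALSE, n)
  if (is.null(u_center)) u_center <- (max(pts$column) + min(pts$column)) / 2
  if (is.null(u_halfwidth)) {
    u_halfwidth <- (max(pts$column) - min(pts$column)) / 2
    if (u_halfwidth <= 0) u_halfwidth <- 1
  }
  u <- (pts$column - u_center) / u_halfwidth
  y <- pts$row
  U <- outer(u, 0:config$poly_degree, `^`)
  thr <- config$inlier_threshold_px

  best <- list(score = -1L, rmse = Inf, inliers = NULL)
  withr::with_seed(seed, {
    for (it in seq_len(config$ransac_iterations)) {
      idx <- sample.int(n, m)
      beta <- tryCatch(solve(U[idx, , drop = FALSE], y[idx]),
                       error = function(e) NULL)
      if (is.null(beta)) next
      res <- abs(drop(U %*% beta) - y)
      inl <- res <= thr
      score <- sum(inl)
      if (score < m) next
      rmse <- sqrt(mean(res[inl]^2))
      if (score > best$score ||
          (score == best$score && rmse < best$rmse - 1e-12)) {
        best <- list(score = score, rmse = rmse, inliers = inl)
      }
    }
  })
  if (is.null(best$inliers)) abort("RANSAC failed: no valid minimal sample")

  keep <- best$inliers | pinned
  wts <- ifelse(pinned[keep], 1e8, 1)
  fit <- lm.wfit_poly(U[keep, , drop = FALSE], y[keep], wts)
  res_all <- abs(drop(U %*% fit) - y)
  inl_final <- (res_all <= thr) | pinned
  plain <- inl_final & !pinned
  rmse <- if (any(plain)) sqrt(mean(res_all[plain]^2)) else 0
  frac <- best$score / n

  structure(list(
    interface = NA_character_,
    coefficients = fit,
    u_center = u_center, u_halfwidth = u_halfwidth,
    inlier_mask = inl_final,
    columns = pts$column,
    rows = pts$row,
    rmse = rmse,
    inlier_fraction = frac,
    low_confidence = frac < config$min_inlier_fraction,
    n_candidates = n,
    pinned = pinned
  ), class = "boundary_fit")
}

lm.wfit_poly <- function(X, y, w) {
  sw <- sqrt(w)
  qr.coef(qr(X * sw), y * sw)
}

#' Evaluate a fitted boundary at given columns
#'
#' @param fit a `boundary_fit`.
#' @param columns column indices (may be fractional).
#' @return fitted rows (axial px).
#' @export
predict_boundary <- function(fit, columns) {
  u <- (columns - fit$u_center) / fit$u_halfwidth
  polyval_inc(fit$coefficients, u)
}

#' Segment every B-scan of a volume
#'
#' Applies [detect_bands()] then [ransac_fit()] per interface per B-scan.
#' Manual override points replace any detected candidate at the listed
#' columns and are pinned into the refit. Each scan carries quality flags:
#' `failed:<interface>` when an interface cannot be fit, `low_inlier:<interface>`
#' when the consensus is below `min_inlier_fraction`, and `ordering` when the
#' three fitted curves do not satisfy anterior < En/DM < posterior across the
#' candidate-supported aperture. The volume-level call errors only when more
#' than half of the scans fail.
#'
#' @param volume an `oct_volume`.
#' @param config a [segmentation_config()].
#' @param edits optional data frame of manual overrides with columns `scan`,
#'   `interface`, `column`, `row` (see [read_edits()]).
#' @return An object of class `boundary_set`: per-scan fits and flags plus the
#'   volume geometry needed for 3-D reconstruction.
#' @export
segment_volume <- function(volume, config = segmentation_config(), edits = NULL) {
  validate_volume(volume)
  if (!is.null(edits)) {
    edits <- tibble::as_tibble(edits)
    need <- c("scan", "interface", "column", "row")
    if (!all(need %in% names(edits)))
      abort("`edits` needs columns scan, interface, column, row")
  }
  n_scans <- length(volume$bscans)
  w <- ncol(volume$bscans[[1]])
  interfaces <- c("anterior", "endm_anterior", "posterior")
  scans <- vector("list", n_scans)
  n_failed <- 0L

  for (s in seq_len(n_scans)) {
    cand <- detect_bands(volume$bscans[[s]], config, volume$vertex_column)
    flags <- character(0)
    if (isTRUE(attr(cand, "flag_empty_image"))) flags <- c(flags, "empty_image")
    fits <- setNames(vector("list", 3L), interfaces)
    for (j in seq_along(interfaces)) {
      intf <- interfaces[j]
      pts <- cand[cand$interface == intf, c("column", "row")]
      pin <- rep(FALSE, nrow(pts))
      if (!is.null(edits)) {
        e <- edits[edits$scan == s & edits$interface == intf, ]
        if (nrow(e)) {
          keep <- !(pts$column %in% e$column)
          pts <- pts[keep, ]
          pts <- rbind(pts, data.frame(column = e$column, row = e$row))
          pin <- c(pin[keep], rep(TRUE, nrow(e)))
        }
      }
      if (nrow(pts) < config$poly_degree + 1L) {
        flags <- c(flags, paste0("failed:", intf))
        next
      }
      fit <- tryCatch(
        ransac_fit(pts, config, u_center = (w + 1) / 2, u_halfwidth = (w - 1) / 2,
                   pinned = pin, seed = config$seed + 1000L * s + j),
        error = function(e) NULL)
      if (is.null(fit)) {
        flags <- c(flags, paste0("failed:", intf))
        next
      }
      fit$interface <- intf
      if (fit$low_confidence) flags <- c(flags, paste0("low_inlier:", intf))
      fits[[intf]] <- fit
    }
    if (!any(grepl("^failed:", flags))) {
      cols_ok <- range(cand$column)
      grid <- seq(cols_ok[1], cols_ok[2], length.out = 201)
      za <- predict_boundary(fits$anterior, grid)
      ze <- predict_boundary(fits$endm_anterior, grid)
      zp <- predict_boundary(fits$posterior, grid)
      if (!all(za < ze & ze < zp)) flags <- c(flags, "ordering")
    } else {
      n_failed <- n_failed + 1L
    }
    scans[[s]] <- list(fits = fits, flags = flags,
                       n_candidates = nrow(cand) / 3,
                       inlier_fractions = vapply(
                         fits, function(f) if (is.null(f)) NA_real_ else f$inlier_fraction,
                         numeric(1)))
  }
  if (n_failed > n_scans / 2)
    abort(sprintf("segmentation failed on %d of %d scans (more than half)", n_failed, n_scans))

  structure(list(
    scans = scans,
    meta = list(n_scans = n_scans, angles_deg = volume$angles_deg,
                width = w, height = nrow(volume$bscans[[1]]),
                vertex_column = volume$vertex_column,
                axial_um_per_px = volume$axial_um_per_px,
                lateral_um_per_px = volume$lateral_um_per_px),
    config = config
  ), class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  nf <- sum(vapply(x$scans, function(s) any(grepl("^failed:", s$flags)), logical(1)))
  cat(sprintf("<boundary_set> %d scans (%d failed), poly degree %d\n",
              x$meta$n_scans, nf, x$config$poly_degree))
  invisible(x)
}

#' Serialise a boundary set to JSON
#'
#' Per scan and interface: polynomial coefficients, inlier count, RMSE and
#' flags, together with the volume geometry.
#'
#' @param bset a `boundary_set`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_boundary_set <- function(bset, path) {
  ser <- list(
    meta = bset$meta,
    config = unclass(bset$config),
    scans = lapply(bset$scans, function(s) list(
      flags = s$flags,
      fits = lapply(s$fits, function(f) {
        if (is.null(f)) return(NULL)
        list(interface = f$interface, coefficients = f$coefficients,
             u_center = f$u_center, u_halfwidth = f$u_halfwidth,
             n_inliers = sum(f$inlier_mask), rmse = f$rmse,
             inlier_fraction = f$inlier_fraction,
             low_confidence = f$low_confidence)
      })
    ))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read manual segmentation edits from CSV
#'
#' Expert overrides: one row per corrected candidate, columns
#' `scan, interface, column, row`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_edits <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan", "interface", "column", "row")
  missing <- setdiff(need, names(e))
  if (length(missing))
    abort(paste0("edits CSV is missing column(s): ", paste(missing, collapse = ", ")))
  tibble::as_tibble(e)
}
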