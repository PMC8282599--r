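#' Specification of a synthetic corneal OCT phantom
#'
#' Defines the geometry and appearance of a layered spherical-cap cornea used
#' to render synthetic anterior-segment OCT radial scans with known ground
#' truth. The three rendered interfaces are the anterior corneal surface, the
#' anterior interface of the endothelium/Descemet membrane complex (En/DM) and
#' the posterior corneal surface; the En/DM anterior interface is concentric
#' with the posterior surface so that the true normal-distance En/DM thickness
#' equals `endmt_true` everywhere (absent excrescences).
#'
#' @param anterior_radius radius of curvature of the anterior surface, um.
#' @param posterior_radius radius of curvature of the posterior surface, um;
#'   must be smaller than `anterior_radius` (nested shells).
#' @param apex_depth axial depth of the anterior apex in the scan, um.
#' @param cct_apex full corneal thickness at the apex, um.
#' @param endmt_true true En/DM thickness, um (normal separation of the En/DM
#'   anterior interface from the posterior surface).
#' @param band_width full width at half maximum of the hyperreflective bands,
#'   um (Gaussian cross-section in depth).
#' @param band_intensity peak band intensity, relative units in \[0, 1\].
#' @param background_intensity background (stromal) intensity in \[0, 1\].
#' @param speckle_sigma scale of the multiplicative log-normal speckle noise;
#'   0 renders a noiseless volume.
#' @param outlier_column_fraction fraction in \[0, 1) of non-vertex A-scan
#'   columns whose bands are rendered grossly displaced (>= 25 axial px).
#' @param excrescences optional data frame with columns `position_mm`,
#'   `height_um`, `width_um`: axisymmetric Gaussian nodular ridges on the
#'   En/DM anterior interface at the given radial distance from the vertex
#'   (height moves the interface anteriorly, thickening the En/DM).
#' @param seed integer seed; rendering is a pure function of the spec.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()], [render_volume()]
#' @export
phantom_spec <- function(anterior_radius = 7800, posterior_radius = 6500,
                         apex_depth = 200, cct_apex = 600, endmt_true = 15,
                         band_width = 4, band_intensity = 0.6,
                         background_intensity = 0.05, speckle_sigma = 0,
                         outlier_column_fraction = 0, excrescences = NULL,
                         seed = 1L) {
  spec <- list(
    anterior_radius = anterior_radius, posterior_radius = posterior_radius,
    apex_depth = apex_depth, cct_apex = cct_apex, endmt_true = endmt_true,
    band_width = band_width, band_intensity = band_intensity,
    background_intensity = background_intensity, speckle_sigma = speckle_sigma,
    outlier_column_fraction = outlier_column_fraction,
    excrescences = if (is.null(excrescences)) NULL else tibble::as_tibble(excrescences),
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (!(spec$posterior_radius < spec$anterior_radius))
    abort("`posterior_radius` must be smaller than `anterior_radius` (nested corneal shells)")
  if (!(spec$endmt_true > 0))
    abort("`endmt_true` must be positive")
  if (!(spec$endmt_true < spec$cct_apex))
    abort("`endmt_true` must be smaller than the total corneal thickness at the apex (`cct_apex`)")
  for (f in c("band_intensity", "background_intensity")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) abort(paste0("`", f, "` must lie in [0, 1]"))
  }
  if (spec$outlier_column_fraction < 0 || spec$outlier_column_fraction >= 1)
    abort("`outlier_column_fraction` must lie in [0, 1)")
  if (spec$speckle_sigma < 0) abort("`speckle_sigma` must be non-negative")
  if (!is.null(spec$excrescences)) {
    need <- c("position_mm", "height_um", "width_um")
    if (!all(need %in% names(spec$excrescences)))
      abort("`excrescences` needs columns position_mm, height_um, width_um")
  }
  invisible(spec)
}

#' Construct analytic ground-truth interfaces for a phantom
#'
#' Builds the three interface elevation functions (depth in um as a function of
#' lateral position) implied by a [phantom_spec()]: spherical caps for the
#' anterior and posterior surfaces, and a sphere concentric with the posterior
#' surface, optionally deformed by excrescence ridges, for the En/DM anterior
#' interface. The true central En/DM thickness and central corneal thickness
#' over the 2-mm zone are computed by closed-form normal-ray intersection with
#' the posterior sphere, integrated by quadrature over the central disk.
#'
#' @param spec a [phantom_spec()].
#' @param aperture_radius_um lateral half-extent over which interfaces are
#'   defined (default 3000 um for a 6-mm scan).
#' @return An object of class `ground_truth`: interface functions
#'   (`$interfaces$anterior` etc., vectorised over `(x, y)` um), the spec, and
#'   `$endmt_central` / `$cct_central` in um.
#' @export
make_phantom <- function(spec, aperture_radius_um = 3000) {
  validate_phantom_spec(spec)
  Ra <- spec$anterior_radius
  Rp <- spec$posterior_radius
  Re <- Rp + spec$endmt_true  # concentric, anterior to the posterior surface
  cz <- spec$apex_depth + spec$cct_apex + Rp   # common centre depth of posterior/En/DM spheres
  if (Re <= aperture_radius_um)
    abort("`endmt_true` too large: En/DM sphere radius must exceed the aperture radius")

  bump <- function(r) {
    if (is.null(spec$excrescences) || nrow(spec$excrescences) == 0) return(rep(0, length(r)))
    out <- rep(0, length(r))
    for (k in seq_len(nrow(spec$excrescences))) {
      e <- spec$excrescences[k, ]
      sig <- e$width_um / 2.355
      out <- out + e$height_um * exp(-(r - e$position_mm * 1000)^2 / (2 * sig^2))
    }
    out
  }

  z_anterior_r <- function(r) spec$apex_depth + Ra - sqrt(Ra^2 - pmin(r^2, Ra^2 - 1))
  z_posterior_r <- function(r) cz - sqrt(Rp^2 - pmin(r^2, Rp^2 - 1))
  z_endm_r <- function(r) cz - sqrt(Re^2 - pmin(r^2, Re^2 - 1)) - bump(r)

  as_xy <- function(fr) function(x, y) fr(sqrt(x^2 + y^2))

  # ordering check across the aperture
  rg <- seq(0, aperture_radius_um, length.out = 601)
  if (!all(z_anterior_r(rg) < z_endm_r(rg)))
    abort("interface ordering violated: `excrescences` push the En/DM interface above the anterior surface")
  if (!all(z_endm_r(rg) < z_posterior_r(rg)))
    abort("interface ordering violated: En/DM interface must stay anterior to the posterior surface")

  truth <- list(
    spec = spec,
    aperture_radius_um = aperture_radius_um,
    centre_depth_um = cz,
    interfaces = list(
      anterior = as_xy(z_anterior_r),
      endm_anterior = as_xy(z_endm_r),
      posterior = as_xy(z_posterior_r)
    ),
    profiles = list(anterior = z_anterior_r, endm_anterior = z_endm_r,
                    posterior = z_posterior_r)
  )
  class(truth) <- "ground_truth"
  truth$endmt_central <- true_layer_thickness(truth, "endm_anterior", diameter_um = 2000)
  truth$cct_central <- true_layer_thickness(truth, "anterior", diameter_um = 2000)
  truth
}

#' True central thickness of a phantom layer by analytic normal-ray quadrature
#'
#' Thickness is the distance from the named upper interface, along its local
#' (inward) surface normal, to the posterior sphere; rays intersect the sphere
#' in closed form. The central mean is the area average over the disk of the
#' given diameter centred on the vertex.
#'
#' @param truth a `ground_truth` object.
#' @param upper `"endm_anterior"` (En/DM thickness) or `"anterior"` (full
#'   corneal thickness).
#' @param diameter_um zone diameter, um.
#' @param n_r number of radial quadrature nodes.
#' @return mean thickness in um.
#' @export
true_layer_thickness <- function(truth, upper = c("endm_anterior", "anterior"),
                                 diameter_um = 2000, n_r = 2001) {
  upper <- match.arg(upper)
  f <- truth$profiles[[upper]]
  Rp <- truth$spec$posterior_radius
  cz <- truth$centre_depth_um
  a <- diameter_um / 2
  r <- seq(0, a, length.out = n_r)
  h <- 0.05
  fp <- (f(r + h) - f(pmax(r - h, 0))) / (h + pmin(r, h))  # one-sided at r = 0
  z <- f(r)
  # downward unit normal in the meridian plane: (-f'(r), 1)/sqrt(1 + f'^2)
  nrm <- sqrt(1 + fp^2)
  dr <- -fp / nrm
  dz <- 1 / nrm
  # intersect (r + t*dr, z + t*dz) with circle centre (0, cz) radius Rp
  pr <- r; pz <- z - cz
  b <- pr * dr + pz * dz
  cc <- pr^2 + pz^2 - Rp^2
  disc <- b^2 - cc
  if (any(disc < 0)) abort("normal ray fails to intersect the posterior sphere")
  t1 <- -b - sqrt(disc)
  t2 <- -b + sqrt(disc)
  tt <- ifelse(t1 > 1e-9, t1, t2)
  if (any(tt <= 0)) abort("normal ray fails to intersect the posterior sphere")
  # disk average: (2 / a^2) * integral t(r) r dr  (trapezoid)
  w <- r * tt
  integral <- sum((w[-1] + w[-n_r]) / 2) * (a / (n_r - 1))
  2 * integral / a^2
}

#' Render a synthetic OCT radial-scan volume from a phantom
#'
#' Each B-scan is a radial cut through the corneal vertex at evenly spaced
#' angles in \[0, 180). Every interface appears as a hyperreflective band with
#' a Gaussian depth cross-section centred on the (generally sub-pixel)
#' ground-truth interface row; depth of row `r` is `r * axial_um_per_px`.
#' Speckle is multiplicative log-normal with unit mean. A fixed bright
#' saturation column marks the vertex. A fraction of non-vertex columns can be
#' rendered as gross outliers whose bands are displaced by at least 25 axial
#' px. Rendering is a pure function of `(truth, spec, n_scans)` including the
#' seed, and intensities are pre-quantised to 16-bit so that a TIFF round trip
#' is lossless.
#'
#' @param truth a `ground_truth` from [make_phantom()].
#' @param spec the matching [phantom_spec()].
#' @param n_scans number of radial B-scans (>= 2).
#' @param height,width raster size in pixels (depth x lateral).
#' @param axial_um_per_px axial sampling, um per pixel.
#' @param angle_offset_deg common rotation of the set of cut angles (the
#'   angles remain within \[0, 180)).
#' @return An `oct_volume`: list of `height x width` intensity matrices in
#'   \[0, 1\], cut angles, pixel scales, vertex column and metadata (including
#'   the rendered outlier columns per scan, for validation studies).
#' @export
render_volume <- function(truth, spec, n_scans = 8L, height = 1024L,
                          width = 512L, axial_um_per_px = 2,
                          angle_offset_deg = 0) {
  if (n_scans < 2) abort("`n_scans` must be at least 2")
  lateral_um_per_px <- 6000 / width
  vertex_column <- as.integer(width / 2)
  angles <- angle_offset_deg + (seq_len(n_scans) - 1) * 180 / n_scans
  if (any(angles < 0) || any(angles >= 180))
    abort("`angle_offset_deg` must keep all cut angles within [0, 180)")
  sigma_px <- spec$band_width / 2.355 / axial_um_per_px
  rows_grid <- matrix(seq_len(height), nrow = height, ncol = width)
  r_cols <- (seq_len(width) - vertex_column) * lateral_um_per_px

  withr::with_seed(spec$seed, {
    bscans <- vector("list", n_scans)
    outlier_cols <- vector("list", n_scans)
    for (s in seq_len(n_scans)) {
      th <- angles[s] * pi / 180
      x <- r_cols * cos(th); y <- r_cols * sin(th)
      band_rows <- sapply(truth$interfaces, function(f) f(x, y) / axial_um_per_px)
      # gross outlier columns: displace every band by >= 25 axial px
      n_out <- floor(spec$outlier_column_fraction * (width - 1))
      oc <- integer(0)
      if (n_out > 0) {
        oc <- sample(setdiff(seq_len(width), vertex_column), n_out)
        for (j in seq_len(ncol(band_rows))) {
          disp <- runif(n_out, 25, 60) * sample(c(-1, 1), n_out, replace = TRUE)
          band_rows[oc, j] <- pmin(pmax(band_rows[oc, j] + disp, 3), height - 2)
        }
      }
      img <- matrix(spec$background_intensity, nrow = height, ncol = width)
      for (j in seq_len(ncol(band_rows))) {
        mu <- matrix(band_rows[, j], nrow = height, ncol = width, byrow = TRUE)
        img <- img + spec$band_intensity * exp(-(rows_grid - mu)^2 / (2 * sigma_px^2))
      }
      if (spec$speckle_sigma > 0) {
        z <- matrix(rnorm(height * width), nrow = height)
        img <- img * exp(spec$speckle_sigma * z - spec$speckle_sigma^2 / 2)
      }
      img[, vertex_column] <- 1
      img <- pmin(pmax(img, 0), 1)
      bscans[[s]] <- round(img * 65535) / 65535
      outlier_cols[[s]] <- sort(oc)
    }
  })

  oct_volume(bscans, angles_deg = angles, axial_um_per_px = axial_um_per_px,
             lateral_um_per_px = lateral_um_per_px, vertex_column = vertex_column,
             metadata = list(seed = spec$seed, outlier_columns = outlier_cols))
}

#' Ground-truth interface rows for each rendered B-scan
#'
#' Samples the analytic interfaces of a phantom at the column positions of a
#' rendered volume, in (fractional) row units. Used as the oracle when
#' validating band detection and boundary fitting.
#'
#' @param truth a `ground_truth`.
#' @param volume the `oct_volume` rendered from it.
#' @return list (one per scan) of `width x 3` matrices with columns
#'   `anterior`, `endm_anterior`, `posterior`.
#' @export
truth_interface_rows <- function(truth, volume) {
  r_cols <- (seq_len(ncol(volume$bscans[[1]])) - volume$vertex_column) *
    volume$lateral_um_per_px
  lapply(volume$angles_deg, function(a) {
    th <- a * pi / 180
    x <- r_cols * cos(th); y <- r_cols * sin(th)
    m <- sapply(truth$interfaces, function(f) f(x, y) / volume$axial_um_per_px)
    colnames(m) <- names(truth$interfaces)
    m
  })
}
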