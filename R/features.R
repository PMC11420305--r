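# Quantification of color-fundus-photograph parameters from an image plus
# landmark annotations.  All pixel coordinates are 0-based, origin at the
# top-left corner, x increasing rightward and y increasing DOWNWARD (the
# usual raster convention); "up" on the retina is therefore -y, and
# "inferior" is +y.

#' Canonical names of the 42 fundus parameters
#'
#' The fixed, documented ordering of the feature vector produced by
#' [extract_features()]: four vessel angles (degrees), the papillomacular
#' position (signed degrees), the optic-disc ovality ratio, then mean red,
#' green and blue intensity (0-255) and the tessellation fundus index
#' (TFI = R/(R+G+B)) at each of nine loci — eight peripapillary circles
#' `L1`..`L8` (L1 temporal, on the disc-to-fovea line, then proceeding
#' through superior, nasal and inferior) and the fovea `F`.
#'
#' @return Character vector of length 42.
#' @export
feature_names <- function() {
  loci <- c(paste0("L", 1:8), "F")
  c("st_ra", "it_ra", "st_va", "it_va", "pmp", "ovality_ratio",
    as.vector(t(outer(loci, c("_R", "_G", "_B", "_TFI"), paste0))))
}

#' Default measurement-circle diameters (pixels)
#'
#' The measurement scheme uses three circles, specified here by their
#' diameters in pixels: the vessel measurement circle centred on the optic
#' disc (208 px), the eight peripapillary sampling circles (96 px) and the
#' foveal sampling circle (32 px).  All three are configurable because the
#' original protocol does not state whether its pixel counts are diameters
#' or radii; diameters are this package's reading.
#'
#' @return Named list with elements `vessel`, `peripapillary`, `fovea`.
#' @export
circle_diameters <- function() {
  list(vessel = 208, peripapillary = 96, fovea = 32)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p)))
    stop(sprintf("'%s' must be a finite (x, y) pair", what), call. = FALSE)
  p
}

# Sign of the temporal direction along x: +1 if the fovea lies to the
# right of the disc centre, -1 if to the left.  Defining the temporal
# horizontal reference from the fovea's side makes the angle conventions
# independent of image left/right orientation.
temporal_sign <- function(disc_center, fovea) {
  dx <- fovea[1] - disc_center[1]
  if (dx == 0)
    stop("fovea lies directly above/below the disc center; temporal direction undefined",
         call. = FALSE)
  sign(dx)
}

#' Retinal vessel angle against the temporal horizontal line
#'
#' Unsigned angle, in degrees, between the ray from the optic-disc centre
#' to a vessel crossing point on the measurement circle and the temporal
#' horizontal reference (the horizontal ray from the disc centre pointing
#' toward the fovea's side).  Supratemporal and infratemporal vessel
#' angles are reported as magnitudes in `[0, 180)`.
#'
#' @param crossing (x, y) pixel coordinates of the vessel crossing point.
#' @param disc_center (x, y) pixel coordinates of the optic-disc centre.
#' @param fovea (x, y) pixel coordinates of the fovea.
#' @return Angle in degrees in `[0, 180]`.
#' @export
vessel_angle <- function(crossing, disc_center, fovea) {
  crossing <- as_point(crossing, "crossing")
  disc_center <- as_point(disc_center, "disc_center")
  fovea <- as_point(fovea, "fovea")
  v <- crossing - disc_center
  if (all(v == 0))
    stop("crossing coincides with disc center", call. = FALSE)
  ts <- temporal_sign(disc_center, fovea)
  along <- v[1] * ts             # component toward temporal
  up <- -v[2]                    # image y is down
  atan2(abs(up), along) * 180 / pi
}

#' Papillomacular position (PMP)
#'
#' Signed angle, in degrees, between the horizontal line through the
#' optic-disc centre and the line connecting the disc centre to the fovea.
#' Positive when the fovea is inferior to (below) the disc-centre
#' horizontal in an upright photograph; magnitude at most 90.
#'
#' @inheritParams vessel_angle
#' @return Signed angle in degrees.
#' @export
papillomacular_position <- function(disc_center, fovea) {
  disc_center <- as_point(disc_center, "disc_center")
  fovea <- as_point(fovea, "fovea")
  d <- fovea - disc_center
  if (all(d == 0))
    stop("fovea coincides with disc center", call. = FALSE)
  # inferior (image down, +y) is positive
  atan2(d[2], abs(d[1])) * 180 / pi
}

#' Optic-disc ovality ratio
#'
#' Minimum disc diameter divided by the maximum, computed from boundary
#' points as the ratio of the smallest to the largest directional width
#' (the extent of the point set projected on each direction), scanned over
#' `n_dir` uniformly spaced directions in half a turn.  A circle gives
#' 1.0; lower values indicate a more oval (tilted) disc.
#'
#' @param disc_boundary Numeric matrix, one (x, y) point per row, at least
#'   8 non-collinear points on the optic-disc margin.
#' @param n_dir Number of scan directions (default 3600, i.e. 0.05 degree
#'   resolution).
#' @return Ratio in (0, 1].
#' @export
ovality_ratio <- function(disc_boundary, n_dir = 3600L) {
  pts <- as.matrix(disc_boundary)
  if (ncol(pts) != 2L || nrow(pts) < 8L)
    stop("disc_boundary must be an n x 2 matrix with n >= 8", call. = FALSE)
  if (any(!is.finite(pts))) stop("non-finite boundary point", call. = FALSE)
  sv <- svd(sweep(pts, 2L, colMeans(pts)), nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * sv[1])
    stop("boundary points are collinear", call. = FALSE)
  theta <- seq(0, pi, length.out = n_dir + 1L)[-(n_dir + 1L)]
  proj <- pts %*% rbind(cos(theta), sin(theta))   # n_pts x n_dir
  widths <- apply(proj, 2L, max) - apply(proj, 2L, min)
  min(widths) / max(widths)
}

#' Mean RGB intensities over a sampling circle
#'
#' Per-channel arithmetic mean over the pixels whose centres lie strictly
#' inside the disk of the given diameter.  Pixel centres sit at integer
#' coordinates (0-based, origin top-left).
#'
#' @param image Numeric array `height x width x 3` with intensities on the
#'   0-255 scale.
#' @param center (x, y) centre of the sampling circle, pixels.
#' @param diameter Circle diameter in pixels.
#' @return List of class `rgb_sample` with elements `R`, `G`, `B`,
#'   `n_pixels`.
#' @export
sample_circle_mean <- function(image, center, diameter) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  center <- as_point(center, "center")
  r <- diameter / 2
  h <- dim(image)[1]; w <- dim(image)[2]
  if (center[1] - r < -0.5 || center[1] + r > w - 0.5 ||
      center[2] - r < -0.5 || center[2] + r > h - 0.5)
    stop("sampling circle extends outside the image", call. = FALSE)
  xs <- seq.int(max(0L, floor(center[1] - r)), min(w - 1L, ceiling(center[1] + r)))
  ys <- seq.int(max(0L, floor(center[2] - r)), min(h - 1L, ceiling(center[2] + r)))
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  inside <- outer(dy2, dx2, "+") < r^2       # rows = y, cols = x
  n <- sum(inside)
  if (n == 0L) stop("sampling circle covers no pixel center", call. = FALSE)
  sub <- image[ys + 1L, xs + 1L, , drop = FALSE]
  means <- vapply(1:3, function(ch) mean(sub[, , ch][inside]), numeric(1))
  structure(list(R = means[1], G = means[2], B = means[3], n_pixels = n),
            class = "rgb_sample")
}

#' Tessellation fundus index
#'
#' `TFI = R / (R + G + B)` of the mean channel intensities in a sampling
#' circle.  Quantifies the reddish, tessellated appearance produced by
#' visible choroidal vessels.
#'
#' @param sample An `rgb_sample` as returned by [sample_circle_mean()], or
#'   any list with numeric elements `R`, `G`, `B`.
#' @return Fraction in (0, 1).
#' @export
tessellation_index <- function(sample) {
  s <- sample$R + sample$G + sample$B
  if (!is.finite(s) || s <= 0)
    stop("TFI undefined: R + G + B is not positive", call. = FALSE)
  sample$R / s
}

#' Centres of the eight peripapillary sampling circles
#'
#' Eight circle centres equally spaced 45 degrees apart on a ring
#' concentric with the optic disc.  Locus L1 lies on the line from the
#' disc centre toward the fovea (the lateral/temporal circle); subsequent
#' loci proceed through the superior quadrant (L3 superior, L5 nasal,
#' L7 inferior).  The ring radius is the maximum disc semi-diameter (the
#' largest distance from the disc centre to a boundary point) plus the
#' sampling-circle radius, so the circles are tangent to the disc margin.
#'
#' @inheritParams vessel_angle
#' @param disc_boundary Matrix of boundary points, one (x, y) per row.
#' @param circle_radius Radius of the sampling circles, pixels.
#' @return List with `centers` (8 x 2 matrix) and `ring_radius`.
#' @export
peripapillary_loci <- function(disc_center, fovea, disc_boundary,
                               circle_radius = circle_diameters()$peripapillary / 2) {
  disc_center <- as_point(disc_center, "disc_center")
  fovea <- as_point(fovea, "fovea")
  pts <- as.matrix(disc_boundary)
  semi <- sqrt(max((pts[, 1] - disc_center[1])^2 + (pts[, 2] - disc_center[2])^2))
  ring_r <- semi + circle_radius
  u <- fovea - disc_center
  u <- u / sqrt(sum(u^2))
  up_first <- if (u[1] > 0) -1 else 1     # rotate toward image-up (superior)
  ang <- (0:7) * 45 * pi / 180 * up_first
  # rotation of u by ang in (x right, y down) coordinates; the sign above
  # makes L2 land in the superior half whatever the fovea's side
  rot <- cbind(cos(ang) * u[1] - sin(ang) * u[2],
               sin(ang) * u[1] + cos(ang) * u[2])
  # image y is down: visually this walks temporal -> superior -> nasal
  centers <- sweep(rot * ring_r, 2L, disc_center, "+")
  dimnames(centers) <- list(paste0("L", 1:8), c("x", "y"))
  list(centers = centers, ring_radius = ring_r)
}

check_landmarks <- function(landmarks) {
  need <- c("disc_center", "fovea", "disc_boundary", "crossings")
  for (nm in need)
    if (is.null(landmarks[[nm]]))
      stop(sprintf("missing landmark: %s", nm), call. = FALSE)
  for (v in c("ST_RA", "IT_RA", "ST_VA", "IT_VA"))
    if (is.null(landmarks$crossings[[v]]))
      stop(sprintf("missing landmark: crossings$%s", v), call. = FALSE)
  invisible(landmarks)
}

#' Extract the 42 fundus parameters from an image and its landmarks
#'
#' Computes the full feature vector in the fixed order of
#' [feature_names()]: the supratemporal/infratemporal retinal artery and
#' vein angles (ST-RA, IT-RA, ST-VA, IT-VA) from the crossing-point
#' landmarks, the papillomacular position, the disc ovality ratio, and
#' the mean R, G, B and TFI over the eight peripapillary circles and the
#' foveal circle.  Deterministic: repeated runs on the same inputs are
#' bit-identical.
#'
#' @param image Numeric `height x width x 3` array, intensities 0-255.
#' @param landmarks Landmark set: list with `disc_center`, `fovea`,
#'   `disc_boundary` (n x 2 matrix) and `crossings` (named list
#'   `ST_RA`, `IT_RA`, `ST_VA`, `IT_VA` of (x, y) points on the vessel
#'   measurement circle).
#' @param diameters Sampling-circle diameters, see [circle_diameters()].
#' @return Named numeric vector of length 42.
#' @export
extract_features <- function(image, landmarks, diameters = circle_diameters()) {
  check_landmarks(landmarks)
  dc <- as_point(landmarks$disc_center, "disc_center")
  fv <- as_point(landmarks$fovea, "fovea")
  cr <- landmarks$crossings
  out <- c(
    st_ra = vessel_angle(cr$ST_RA, dc, fv),
    it_ra = vessel_angle(cr$IT_RA, dc, fv),
    st_va = vessel_angle(cr$ST_VA, dc, fv),
    it_va = vessel_angle(cr$IT_VA, dc, fv),
    pmp = papillomacular_position(dc, fv),
    ovality_ratio = ovality_ratio(as.matrix(landmarks$disc_boundary))
  )
  loci <- peripapillary_loci(dc, fv, landmarks$disc_boundary,
                             circle_radius = diameters$peripapillary / 2)
  samples <- vector("list", 9L)
  for (k in 1:8)
    samples[[k]] <- sample_circle_mean(image, loci$centers[k, ],
                                       diameters$peripapillary)
  samples[[9]] <- sample_circle_mean(image, fv, diameters$fovea)
  names(samples) <- c(paste0("L", 1:8), "F")
  for (nm in names(samples)) {
    s <- samples[[nm]]
    tfi <- tryCatch(tessellation_index(s), error = function(e) NA_real_)
    out[paste0(nm, c("_R", "_G", "_B", "_TFI"))] <- c(s$R, s$G, s$B, tfi)
  }
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Read a landmark annotation file (JSON)
#'
#' Schema: `{disc_center:[x,y], fovea:[x,y], disc_boundary:[[x,y],...],
#' crossings:{ST_RA:[x,y], IT_RA:[x,y], ST_VA:[x,y], IT_VA:[x,y]}}`.
#'
#' @param path Path to the JSON file.
#' @return Landmark list suitable for [extract_features()].
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  lm$disc_center <- as.numeric(lm$disc_center)
  lm$fovea <- as.numeric(lm$fovea)
  lm$disc_boundary <- matrix(as.numeric(as.matrix(lm$disc_boundary)), ncol = 2L)
  lm$crossings <- lapply(lm$crossings, as.numeric)
  check_landmarks(lm)
}

#' Write a landmark annotation file (JSON)
#'
#' @param landmarks Landmark list (see [extract_features()]).
#' @param path Output path.
#' @export
write_landmarks <- function(landmarks, path) {
  check_landmarks(landmarks)
  out <- list(
    disc_center = landmarks$disc_center,
    fovea = landmarks$fovea,
    disc_boundary = apply(as.matrix(landmarks$disc_boundary), 1L, identity,
                          simplify = FALSE),
    crossings = landmarks$crossings
  )
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
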