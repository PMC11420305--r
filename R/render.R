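# Rasterization of a synthetic fundus scene into an 8-bit RGB image plus
# the matching landmark annotations.  The phantom is built for metrological
# fidelity, not photorealism: the color patches at the nine sampling loci
# are painted last, so the circle-sampled means equal the configured
# color truths exactly up to 8-bit quantization, even where a vessel
# polyline passes nearby.

paint_disk <- function(img, center, radius, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  xs <- seq.int(max(0L, floor(center[1] - radius)),
                min(w - 1L, ceiling(center[1] + radius)))
  ys <- seq.int(max(0L, floor(center[2] - radius)),
                min(h - 1L, ceiling(center[2] + radius)))
  # same pixel-center-inside rule as sample_circle_mean()
  inside <- outer((ys - center[2])^2, (xs - center[1])^2, "+") < radius^2
  for (ch in 1:3) {
    plane <- img[ys + 1L, xs + 1L, ch]
    plane[inside] <- rgb[ch]
    img[ys + 1L, xs + 1L, ch] <- plane
  }
  img
}

paint_ellipse <- function(img, center, semi_axes, tilt_deg, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  a <- semi_axes[1]; b <- semi_axes[2]
  r <- max(a, b)
  xs <- seq.int(max(0L, floor(center[1] - r)), min(w - 1L, ceiling(center[1] + r)))
  ys <- seq.int(max(0L, floor(center[2] - r)), min(h - 1L, ceiling(center[2] + r)))
  th <- tilt_deg * pi / 180
  dx <- outer(rep(1, length(ys)), xs - center[1])
  dy <- outer(ys - center[2], rep(1, length(xs)))
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  for (ch in 1:3) {
    plane <- img[ys + 1L, xs + 1L, ch]
    plane[inside] <- rgb[ch]
    img[ys + 1L, xs + 1L, ch] <- plane
  }
  img
}

paint_polyline <- function(img, from, to, width, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  L <- sqrt(sum((to - from)^2))
  t <- seq(0, 1, by = 0.5 / max(L, 1))
  px <- round(from[1] + t * (to[1] - from[1]))
  py <- round(from[2] + t * (to[2] - from[2]))
  half <- floor(width / 2)
  off <- expand.grid(ox = -half:half, oy = -half:half)
  for (k in seq_len(nrow(off))) {
    x <- px + off$ox[k]; y <- py + off$oy[k]
    ok <- x >= 0 & x < w & y >= 0 & y < h
    idx <- cbind(y[ok] + 1L, x[ok] + 1L)
    for (ch in 1:3) img[cbind(idx, ch)] <- rgb[ch]
  }
  img
}

# unit vectors of the scene's angular frame: temporal along x toward the
# fovea, "up" toward image top
scene_frame <- function(scene) {
  ts <- sign(scene$fovea[1] - scene$disc_center[1])
  list(temporal = c(ts, 0), up = c(0, -1))
}

crossing_point <- function(scene, vessel) {
  fr <- scene_frame(scene)
  r <- scene$diameters$vessel / 2
  ang <- scene$vessel_truth[[vessel]] * pi / 180
  vert <- if (grepl("^ST", vessel)) fr$up else -fr$up
  scene$disc_center + r * (cos(ang) * fr$temporal + sin(ang) * vert)
}

scene_boundary_points <- function(scene, n = 32L) {
  th <- scene$disc_tilt * pi / 180
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ex <- scene$disc_axes["major"] * cos(t)
  ey <- scene$disc_axes["minor"] * sin(t)
  cbind(scene$disc_center[1] + cos(th) * ex - sin(th) * ey,
        scene$disc_center[2] + sin(th) * ex + cos(th) * ey)
}

#' Render a fundus scene to a raster image and landmark set
#'
#' Paints, in order: a flat fundus-colored background, the optic disc as
#' a filled (tilted) ellipse, the four arcade-vessel polylines passing
#' through their measurement-circle crossing points at the configured
#' angles, and finally the nine sampling-locus color patches carrying the
#' configured per-locus mean colors.  Channel values are quantized to
#' 8-bit integers.  The emitted landmark set (disc centre, 32 boundary
#' points, fovea, four crossing points) is exactly consistent with the
#' rendering, so [extract_features()] on the output recovers the scene's
#' ground truth within quantization.
#'
#' @param scene A `fundus_scene` from [sample_scene()].
#' @return List with `image` (`size x size x 3` array, 0-255 integers)
#'   and `landmarks` (see [extract_features()]).
#' @export
render_image <- function(scene) {
  stopifnot(inherits(scene, "fundus_scene"))
  S <- scene$image_size
  r_peri <- scene$diameters$peripapillary / 2
  ring_ext <- scene$disc_axes["major"] + 2 * r_peri
  dc <- scene$disc_center
  if (dc[1] + ring_ext > S - 1 || dc[1] - ring_ext < 0 ||
      dc[2] + ring_ext > S - 1 || dc[2] - ring_ext < 0)
    stop("geometry error: sampling circles exceed image bounds", call. = FALSE)
  img <- array(0, dim = c(S, S, 3))
  img[, , 1] <- 185; img[, , 2] <- 105; img[, , 3] <- 62
  img <- paint_ellipse(img, dc, scene$disc_axes, scene$disc_tilt,
                       c(238, 210, 170))
  for (v in names(scene$vessel_truth)) {
    cp <- crossing_point(scene, v)
    dir <- (cp - dc) / sqrt(sum((cp - dc)^2))
    col <- if (grepl("RA$", v)) c(150, 40, 35) else c(110, 25, 30)
    img <- paint_polyline(img, dc, dc + dir * (scene$diameters$vessel * 0.95),
                          width = 3, rgb = col)
  }
  boundary <- scene_boundary_points(scene)
  landmarks <- list(
    disc_center = dc,
    fovea = scene$fovea,
    disc_boundary = boundary,
    crossings = lapply(stats::setNames(nm = names(scene$vessel_truth)),
                       function(v) crossing_point(scene, v))
  )
  loci <- peripapillary_loci(dc, scene$fovea, boundary,
                             circle_radius = r_peri)
  for (k in 1:8)
    img <- paint_disk(img, loci$centers[k, ], r_peri,
                      scene$color_truth[paste0("L", k), ])
  img <- paint_disk(img, scene$fovea, scene$diameters$fovea / 2,
                    scene$color_truth["F", ])
  img <- round(clamp(img, 0, 255))
  list(image = img, landmarks = landmarks)
}

#' Write a rendered image as PNG
#'
#' @param image `h x w x 3` array of 0-255 intensities.
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Read a PNG image back to a 0-255 array
#'
#' @param path PNG path.
#' @return `h x w x 3` numeric array on the 0-255 scale.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  img * 255
}
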