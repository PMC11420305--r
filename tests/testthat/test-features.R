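# Geometry and color quantification of the 42 fundus parameters.

test_that("vessel angle is measured against the temporal horizontal ray", {
  dc <- c(400, 384); fv <- c(100, 384)   # fovea temporal = image-left
  expect_equal(vessel_angle(c(300, 384), dc, fv), 0)          # on the ray
  expect_equal(vessel_angle(c(400, 284), dc, fv), 90)         # straight up
  expect_equal(vessel_angle(c(400, 484), dc, fv), 90)         # straight down
  expect_equal(vessel_angle(c(300, 284), dc, fv), 45)         # +100 along, +100 up
  # fovea on the other side flips the reference with it
  expect_equal(vessel_angle(c(500, 284), dc, c(700, 384)), 45)
  # nasal-side crossing: obtuse
  expect_equal(vessel_angle(c(500, 284), dc, fv), 135)
  expect_error(vessel_angle(dc, dc, fv), "coincides")
})

test_that("papillomacular position is signed, inferior positive", {
  dc <- c(400, 384)
  expect_equal(papillomacular_position(dc, c(100, 384)), 0)
  d <- 300
  below <- c(400 - d * cos(5 * pi / 180), 384 + d * sin(5 * pi / 180))
  above <- c(400 - d * cos(5 * pi / 180), 384 - d * sin(5 * pi / 180))
  expect_equal(papillomacular_position(dc, below), 5, tolerance = 1e-10)
  expect_equal(papillomacular_position(dc, above), -5, tolerance = 1e-10)
  expect_error(papillomacular_position(dc, dc), "coincides")
})

test_that("ovality ratio: circle, analytic ellipse, and width oracle", {
  # dense boundary sampling: the width of an m-point polygon underestimates
  # the smooth curve's by at most 1 - cos(pi/m)
  t <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- cbind(50 * cos(t), 50 * sin(t))
  expect_equal(ovality_ratio(circ), 1, tolerance = 1e-4)
  ell <- cbind(50 * cos(t), 40 * sin(t))
  expect_equal(ovality_ratio(ell), 0.8, tolerance = 1e-4)
  # random convex polygons against an independent fine-direction scan
  set.seed(11)
  for (k in 1:5) {
    pts <- matrix(rnorm(400, sd = 30), ncol = 2)
    hull <- pts[chull(pts), ]
    stopifnot(nrow(hull) >= 8)
    th <- seq(0, pi, length.out = 36001)[-36001]
    proj <- hull %*% rbind(cos(th), sin(th))
    w <- apply(proj, 2, max) - apply(proj, 2, min)
    expect_equal(ovality_ratio(hull), min(w) / max(w), tolerance = 1e-3)
  }
  expect_error(ovality_ratio(cbind(1:10, 2 * (1:10) + 3)), "collinear")
  expect_error(ovality_ratio(circ[1:5, ]), "n >= 8")
})

test_that("ovality ratio is invariant to scaling and to rotation", {
  set.seed(12)
  pts <- matrix(rnorm(400, sd = 30), ncol = 2)
  hull <- pts[chull(pts), ]
  stopifnot(nrow(hull) >= 8)
  expect_identical(ovality_ratio(hull), ovality_ratio(hull * 7.3))
  a <- 37 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  expect_equal(ovality_ratio(hull %*% R), ovality_ratio(hull),
               tolerance = 1e-6)
  # quarter-turn exactly
  Q <- matrix(c(0, 1, -1, 0), 2)
  expect_equal(ovality_ratio(hull %*% Q), ovality_ratio(hull),
               tolerance = 1e-9)
})

test_that("circle sampling: constant field, half-plane oracle, bounds", {
  img <- flat_image(128, c(10, 20, 30))
  s <- sample_circle_mean(img, c(64, 64), 40)
  expect_equal(c(s$R, s$G, s$B), c(10, 20, 30))
  expect_gt(s$n_pixels, 0)
  # vertical half-plane split 0/255 through the centre
  img2 <- flat_image(128, c(0, 0, 0))
  img2[, 65:128, 1] <- 255          # x >= 64 (0-based) is bright red
  s2 <- sample_circle_mean(img2, c(63.5, 64), 40)
  # independent pixel-count oracle over the same membership rule
  xs <- 0:127; ys <- 0:127
  inside <- outer((ys - 64)^2, (xs - 63.5)^2, "+") < 20^2
  bright <- outer(rep(TRUE, 128), xs >= 64)
  expect_equal(s2$R, 255 * sum(inside & bright) / sum(inside))
  expect_lt(abs(s2$R - 127.5), 1)
  expect_error(sample_circle_mean(img, c(5, 5), 40), "outside the image")
})

test_that("tessellation fundus index equals R/(R+G+B)", {
  expect_equal(tessellation_index(list(R = 128, G = 128, B = 128)), 1 / 3)
  expect_equal(tessellation_index(list(R = 120, G = 60, B = 60)), 0.5)
  expect_error(tessellation_index(list(R = 0, G = 0, B = 0)), "undefined")
})

test_that("peripapillary loci: placement, spacing and ring radius", {
  lm <- hand_landmarks()
  loci <- peripapillary_loci(lm$disc_center, lm$fovea, lm$disc_boundary)
  expect_equal(dim(loci$centers), c(8L, 2L))
  # L1 lies on the disc-to-fovea direction
  u <- (lm$fovea - lm$disc_center)
  u <- u / sqrt(sum(u^2))
  v1 <- (loci$centers[1, ] - lm$disc_center) / loci$ring_radius
  expect_equal(unname(v1), unname(u), tolerance = 1e-12)
  # ring radius = max boundary extent + sampling radius (tangent rule)
  ext <- max(sqrt(rowSums(sweep(lm$disc_boundary, 2, lm$disc_center)^2)))
  expect_equal(loci$ring_radius, ext + 48)
  # pairwise angular separations as seen from the disc centre are
  # multiples of 45 degrees, and consecutive loci are 45 degrees apart
  d <- sweep(loci$centers, 2, lm$disc_center)
  consec <- sapply(1:8, function(k) {
    a <- d[k, ]; b <- d[if (k == 8) 1 else k + 1, ]
    acos(sum(a * b) / loci$ring_radius^2) * 180 / pi
  })
  expect_equal(consec, rep(45, 8), tolerance = 1e-9)
  dots <- (d %*% t(d)) / loci$ring_radius^2
  expect_equal(sort(unique(round(acos(pmin(1, pmax(-1, dots))) * 180 / pi))),
               c(0, 45, 90, 135, 180))
})

test_that("extraction yields the 42 parameters in frozen order", {
  lm <- hand_landmarks()
  img <- flat_image(768, c(120, 60, 60))
  f <- extract_features(img, lm)
  expect_length(f, 42L)
  expect_identical(names(f), feature_names())
  expect_equal(unname(f["st_ra"]), 60)
  expect_equal(unname(f["pmp"]), 0)
  # the 32-point circular boundary supports a width deficit of at most
  # 1 - cos(pi/32) ~ 0.005
  expect_equal(unname(f["ovality_ratio"]), 1, tolerance = 0.005)
  expect_equal(unname(f["F_TFI"]), 0.5)
  # idempotent and bit-identical
  expect_identical(f, extract_features(img, lm))
})

test_that("channel fractions at every locus sum to one", {
  sim <- small_cohort(n = 6)
  sc <- sample_scene(sim$subjects[1, ], sim$config)
  rr <- render_image(sc)
  f <- extract_features(rr$image, rr$landmarks)
  for (L in c(paste0("L", 1:8), "F")) {
    s <- sum(f[paste0(L, c("_R", "_G", "_B"))])
    expect_lt(abs(f[paste0(L, "_R")] / s + f[paste0(L, "_G")] / s +
                    f[paste0(L, "_B")] / s - 1), 1e-12)
    expect_equal(unname(f[paste0(L, "_TFI")]),
                 unname(f[paste0(L, "_R")] / s), tolerance = 1e-12)
  }
})

test_that("angle magnitudes survive a half-turn of image and landmarks", {
  # a 180-degree rotation keeps the horizontal reference horizontal;
  # the temporal side flips with the fovea, so all angle magnitudes
  # (and PMP magnitude) must be unchanged
  lm <- hand_landmarks()
  S <- 768
  rot <- function(p) c(S - 1 - p[1], S - 1 - p[2])
  lm2 <- list(disc_center = rot(lm$disc_center), fovea = rot(lm$fovea),
              disc_boundary = t(apply(lm$disc_boundary, 1, rot)),
              crossings = lapply(lm$crossings, rot))
  img <- flat_image(S, c(120, 80, 50))
  f1 <- extract_features(img, lm)
  f2 <- extract_features(img, lm2)
  for (v in c("st_ra", "it_ra", "st_va", "it_va", "pmp", "ovality_ratio"))
    expect_equal(abs(f1[[v]]), abs(f2[[v]]), tolerance = 1e-6)
})

test_that("missing landmarks raise named errors", {
  lm <- hand_landmarks()
  img <- flat_image(768, c(120, 60, 60))
  lm_nofovea <- lm; lm_nofovea$fovea <- NULL
  expect_error(extract_features(img, lm_nofovea), "fovea")
  lm_nocross <- lm; lm_nocross$crossings$IT_VA <- NULL
  expect_error(extract_features(img, lm_nocross), "IT_VA")
})

test_that("landmark JSON round-trips through disk", {
  lm <- hand_landmarks()
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$disc_center, lm$disc_center)
  expect_equal(back$crossings$ST_RA, unname(lm$crossings$ST_RA))
  expect_equal(back$disc_boundary, unname(lm$disc_boundary))
})
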