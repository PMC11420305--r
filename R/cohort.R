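# Synthetic right-eye fundus cohort generator.  Subjects carry sex, age,
# body height, axial length and one latent "femininity" factor; fundus
# scenes carry ground-truth values for every quantity the feature
# extractor measures, so that the whole pipeline can be exercised against
# known truth.

norm01 <- function(n) stats::rnorm(n)

# truncated standard normal on [-4, 4] via inverse-CDF (exact, vectorised)
rtrunc4 <- function(n) {
  lo <- stats::pnorm(-4)
  stats::qnorm(stats::runif(n, lo, 1 - lo))
}

# Underlying normal parameters whose LEFT-truncated (at `lower`)
# distribution has the requested mean and SD, via the closed-form
# truncated-normal moments.  Keeps a >=40 screening cohort's observed
# age moments at their configured values.
truncnorm_params <- function(target_mean, target_sd, lower) {
  moments <- function(mu, sigma) {
    a <- (lower - mu) / sigma
    lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    c(m, sqrt(v))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' Default generative model for the primitive fundus quantities
#'
#' One row per primitive quantity drawn by the scene sampler: the six
#' geometric parameters (four vessel angles in degrees, papillomacular
#' position in degrees, ovality ratio) and the 27 mean channel
#' intensities (0-255) at the nine loci.  The TFI features are derived
#' from the channel truths and therefore have no row here.
#'
#' Columns: `name`; `mean` and `sd` (marginal, in the quantity's units);
#' `effect`, the standardized male-minus-female mean difference BEFORE
#' calibration (a direction pattern, scaled at configuration time to a
#' target oracle AROC); `loading`, the magnitude of the latent
#' femininity-factor loading (the factor enters each loaded feature in
#' its female direction, so the marginal SD stays `sd`).
#'
#' Effect directions follow the sex differences reported for this
#' measurement family: a rounder disc (higher ovality ratio), arcade
#' vessels farther from the fovea (larger angles) and stronger red
#' tessellation in men; higher peripapillary green/blue intensities and
#' lower foveal green in men reversed, i.e. higher in women.
#'
#' @return data.frame with 33 rows.
#' @export
default_feature_model <- function() {
  geo <- data.frame(
    name = c("st_ra", "it_ra", "st_va", "it_va", "pmp", "ovality_ratio"),
    mean = c(66, 64, 72, 70, 6.5, 0.87),
    sd = c(8, 8, 8, 8, 3.2, 0.055),
    effect = c(0.6, 0.6, 0.4, 0.4, 0, 1.0),
    loading = c(0.5, 0.5, 0.4, 0.4, 0, 0.5)
  )
  loci <- c(paste0("L", 1:8), "F")
  base <- data.frame(
    name = as.vector(t(outer(loci, c("_R", "_G", "_B"), paste0))),
    mean = c(rep(c(175, 95, 58), 8), c(150, 72, 45)),
    sd = rep(9, 27),
    effect = 0, loading = 0
  )
  # peripapillary: red slightly higher in men; green/blue higher in women,
  # strongest temporally and superiorly (L1-L3)
  for (L in paste0("L", 1:8)) {
    s <- if (L %in% c("L1", "L2", "L3")) 1 else 0.5
    base$effect[base$name == paste0(L, "_R")] <- 0.35 * s
    base$effect[base$name == paste0(L, "_G")] <- -0.8 * s
    base$effect[base$name == paste0(L, "_B")] <- -0.6 * s
  }
  base$effect[base$name == "F_G"] <- -0.3
  base$loading <- ifelse(base$effect != 0, 0.5, 0)
  rbind(geo, base)
}

#' Oracle AROC of a Gaussian two-class feature model
#'
#' For two classes whose standardized feature means differ by the vector
#' `effects` and that share covariance `diag(1 - loading^2) + v v'` with
#' `v` the (signed) latent loadings, the best attainable AROC is
#' `pnorm(Delta / sqrt(2))` with `Delta` the Mahalanobis distance between
#' the class means.  Computed in closed form (Sherman-Morrison).
#'
#' @param effects Standardized male-minus-female mean differences.
#' @param loadings Latent-factor loading magnitudes in `[0, 1)`; the
#'   factor loads on each feature in its female direction
#'   (`-sign(effect)`).
#' @return List with `auc` and `delta` (Mahalanobis distance).
#' @export
oracle_auc <- function(effects, loadings) {
  stopifnot(length(effects) == length(loadings), all(loadings >= 0),
            all(loadings < 1))
  v <- loadings * (-sign(effects))
  d_inv <- 1 / (1 - loadings^2)
  q <- sum(effects^2 * d_inv) -
    sum(effects * v * d_inv)^2 / (1 + sum(v^2 * d_inv))
  delta <- sqrt(q)
  list(auc = stats::pnorm(delta / sqrt(2)), delta = delta)
}

#' Scale an effect-size pattern to a target oracle AROC
#'
#' Multiplies the standardized effect pattern by the constant that makes
#' the closed-form oracle AROC of [oracle_auc()] equal `target_auc`,
#' holding the loadings fixed.
#'
#' @inheritParams oracle_auc
#' @param target_auc Desired oracle AROC in (0.5, 1).
#' @return Scaled effects vector.
#' @export
calibrate_effect_sizes <- function(effects, loadings, target_auc) {
  stopifnot(target_auc > 0.5, target_auc < 1)
  delta0 <- oracle_auc(effects, loadings)$delta
  if (delta0 == 0)
    stop("effect pattern is all zero; cannot calibrate", call. = FALSE)
  target_delta <- sqrt(2) * stats::qnorm(target_auc)
  effects * target_delta / delta0
}

#' Configuration of the synthetic fundus cohort
#'
#' Defaults describe the study conditions of a population screening of
#' adults aged 40+: 1,653 right eyes (838 men, 815 women), per-sex
#' Gaussian covariates (truncated at 4 SD) with male/female body height
#' 163.7 +/- 6.3 / 151.1 +/- 5.8 cm, axial length 23.71 +/- 0.83 /
#' 23.28 +/- 0.88 mm, age 52.8 +/- 9.4 / 54.0 +/- 10.8 years and
#' refraction -0.24 +/- 1.47 / -0.05 +/- 1.76 D.  Fundus-feature sex
#' effects default to [default_feature_model()] scaled to an oracle AROC
#' of 0.80, the accuracy regime reported for ridge-based sex
#' classification in this age group.  One latent femininity factor links
#' the informative features to axial length at within-sex correlation
#' `index_axial_rho` (default -0.13); body height is uncoupled from the
#' factor within sex.
#'
#' @param n_subjects Number of subjects (right eyes).
#' @param sex_ratio Fraction male in (0, 1).
#' @param seed Integer RNG seed recorded in the config.
#' @param height_params,axial_params,age_params,refraction_params Per-sex
#'   `list(male = c(mean, sd), female = c(mean, sd))`.
#' @param feature_model data.frame as [default_feature_model()].
#' @param feature_effect_sizes Optional replacement for the model's
#'   `effect` column (length must match; recycled errors are refused).
#' @param target_oracle_auc Oracle AROC the effect pattern is scaled to,
#'   or `NULL` to use the pattern as given.
#' @param index_axial_rho Target within-sex correlation between the
#'   latent factor and axial length, in (-1, 1).
#' @param image_size Side of the square image in pixels.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1653,
                          sex_ratio = 838 / 1653,
                          seed = 20050501,
                          height_params = list(male = c(163.7, 6.3),
                                               female = c(151.1, 5.8)),
                          axial_params = list(male = c(23.71, 0.83),
                                              female = c(23.28, 0.88)),
                          age_params = list(male = c(52.8, 9.4),
                                            female = c(54.0, 10.8)),
                          refraction_params = list(male = c(-0.24, 1.47),
                                                   female = c(-0.05, 1.76)),
                          feature_model = default_feature_model(),
                          feature_effect_sizes = NULL,
                          target_oracle_auc = 0.80,
                          index_axial_rho = -0.13,
                          image_size = 768) {
  if (!is.numeric(sex_ratio) || sex_ratio <= 0 || sex_ratio >= 1)
    stop("sex_ratio must lie strictly between 0 and 1", call. = FALSE)
  if (n_subjects < 4)
    stop("n_subjects must allow at least 2 subjects per sex", call. = FALSE)
  for (p in list(height_params, axial_params, age_params, refraction_params))
    for (sx in c("male", "female")) {
      v <- p[[sx]]
      if (length(v) != 2L || !all(is.finite(v)) || v[2] <= 0)
        stop("covariate params must be c(mean, sd) with sd > 0", call. = FALSE)
    }
  if (!is.null(feature_effect_sizes)) {
    if (length(feature_effect_sizes) != nrow(feature_model))
      stop(sprintf("feature_effect_sizes must have length %d (one per primitive quantity)",
                   nrow(feature_model)), call. = FALSE)
    feature_model$effect <- as.numeric(feature_effect_sizes)
  }
  if (any(feature_model$sd <= 0))
    stop("feature model SDs must be positive", call. = FALSE)
  if (abs(index_axial_rho) >= 1)
    stop("index_axial_rho must lie in (-1, 1)", call. = FALSE)
  if (!is.null(target_oracle_auc) && any(feature_model$effect != 0))
    feature_model$effect <- calibrate_effect_sizes(
      feature_model$effect, feature_model$loading, target_oracle_auc)
  cfg <- list(n_subjects = as.integer(n_subjects), sex_ratio = sex_ratio,
              seed = as.integer(seed),
              height_params = height_params, axial_params = axial_params,
              age_params = age_params, refraction_params = refraction_params,
              feature_model = feature_model,
              target_oracle_auc = target_oracle_auc,
              index_axial_rho = index_axial_rho,
              image_size = as.integer(image_size),
              diameters = circle_diameters())
  class(cfg) <- "cohort_config"
  check_scene_geometry(cfg)
  cfg
}

# fixed scene layout, in pixels, for a given image size; the disc sits
# nasally, the fovea temporally (image-left), as in a right-eye photograph
scene_layout <- function(config) {
  S <- config$image_size
  list(disc_center = c(round(0.625 * S), round(0.5 * S)),
       fovea_dist = 0.505 * S,
       disc_semi_major = c(mean = 86, sd = 4, lo = 78, hi = 94))
}

# the eight peripapillary circles must not overlap each other (adjacent
# ring centres at least one sampling diameter apart) and every sampling
# circle must stay inside the image
check_scene_geometry <- function(config) {
  lay <- scene_layout(config)
  S <- config$image_size
  r_peri <- config$diameters$peripapillary / 2
  a_max <- lay$disc_semi_major["hi"]
  ring_max <- a_max + r_peri
  ext <- ring_max + r_peri
  dc <- lay$disc_center
  if (dc[1] + ext > S - 1 || dc[1] - ext < 0 ||
      dc[2] + ext > S - 1 || dc[2] - ext < 0)
    stop("geometry error: image_size too small for the peripapillary ring",
         call. = FALSE)
  if (dc[1] - lay$fovea_dist - config$diameters$fovea / 2 < 0)
    stop("geometry error: image_size too small to place the fovea",
         call. = FALSE)
  a_min <- lay$disc_semi_major["lo"]
  if (2 * (a_min + r_peri) * sin(pi / 8) <= 2 * r_peri)
    stop("geometry error: peripapillary circles would overlap", call. = FALSE)
  invisible(config)
}

#' Sample subject covariates
#'
#' Draws `n_subjects` right-eye subject records with per-sex Gaussian
#' covariates truncated at 4 SD.  Axial length is coupled to the latent
#' femininity factor at the configured within-sex correlation; height,
#' age and refraction are conditionally independent of the factor given
#' sex.  Seeded from `config$seed`, so the same configuration always
#' yields the same cohort.
#'
#' @param config A [cohort_config()].
#' @return data.frame: `subject_id`, `sex` ("male"/"female"), `age`,
#'   `height_cm`, `axial_length_mm`, `refraction_d`, `eye` ("right"),
#'   `latent_factor` (generator ground truth, not a measured covariate).
#' @export
sample_covariates <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  n_male <- round(n * config$sex_ratio)
  if (n_male < 2 || n - n_male < 2)
    stop("need at least 2 subjects per sex", call. = FALSE)
  sex <- rep(c("male", "female"), c(n_male, n - n_male))
  z <- rtrunc4(n)
  rho <- config$index_axial_rho
  ax_res <- rtrunc4(n)
  draw <- function(params) {
    m <- ifelse(sex == "male", params$male[1], params$female[1])
    s <- ifelse(sex == "male", params$male[2], params$female[2])
    list(m = m, s = s)
  }
  ax <- draw(config$axial_params)
  axial <- ax$m + ax$s * (rho * z + sqrt(1 - rho^2) * ax_res)
  ht <- draw(config$height_params)
  height <- ht$m + ht$s * rtrunc4(n)
  # screening cohort of residents aged >= 40: draw from the normal whose
  # left truncation at 40 has the configured observed mean and SD
  agp <- lapply(config$age_params, function(p)
    truncnorm_params(p[1], p[2], lower = 40))
  mu_age <- ifelse(sex == "male", agp$male["mean"], agp$female["mean"])
  sd_age <- ifelse(sex == "male", agp$male["sd"], agp$female["sd"])
  lo_age <- stats::pnorm((40 - mu_age) / sd_age)
  age <- mu_age + sd_age * stats::qnorm(stats::runif(n) *
                                          (1 - lo_age) + lo_age)
  rf <- draw(config$refraction_params)
  refraction <- rf$m + rf$s * rtrunc4(n)
  data.frame(subject_id = sprintf("S%05d", seq_len(n)),
             sex = sex, age = age, height_cm = height,
             axial_length_mm = axial, refraction_d = refraction,
             eye = "right", latent_factor = z,
             stringsAsFactors = FALSE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# draws the primitive ground-truth quantities for one subject:
# value = mean + sd * (sex_shift + loading * z * female_direction + residual)
sample_primitives <- function(sex, z, model) {
  s <- if (sex == "male") 0.5 else -0.5
  u <- -sign(model$effect)               # female direction of each feature
  eps <- stats::rnorm(nrow(model))
  std <- s * model$effect + model$loading * u * z +
    sqrt(1 - model$loading^2) * eps
  val <- model$mean + model$sd * std
  names(val) <- model$name
  # physical ranges; symmetric clamps so the null model stays exchangeable
  ang <- c("st_ra", "it_ra", "st_va", "it_va")
  val[ang] <- clamp(val[ang], 1, 89)
  val["pmp"] <- clamp(val["pmp"], -45, 45)
  val["ovality_ratio"] <- clamp(val["ovality_ratio"], 0.40, 0.995)
  col <- setdiff(model$name, c(ang, "pmp", "ovality_ratio"))
  val[col] <- clamp(val[col], 5, 250)
  val
}

#' Sample the ground-truth fundus scene for one subject
#'
#' Draws the 33 primitive quantities from the configured per-sex model
#' (sharing the subject's latent factor), then lays out a right-eye
#' scene: elliptical disc with the drawn ovality, fovea placed temporally
#' at the drawn papillomacular angle, vessel crossing points on the
#' vessel measurement circle at the drawn angles, and per-locus color
#' truths.  Uses the current RNG stream (seed once per cohort).
#'
#' @param subject One row of [sample_covariates()] output.
#' @param config A [cohort_config()].
#' @return Object of class `fundus_scene`: `disc_center`, `disc_axes`
#'   (major, minor semi-axes px), `disc_tilt` (degrees), `fovea`,
#'   `vessel_truth` (named angles), `color_truth` (9 x 3 matrix),
#'   `primitives`, `image_size`.
#' @export
sample_scene <- function(subject, config) {
  stopifnot(inherits(config, "cohort_config"))
  lay <- scene_layout(config)
  prim <- sample_primitives(subject$sex, subject$latent_factor,
                            config$feature_model)
  a <- clamp(stats::rnorm(1, lay$disc_semi_major["mean"],
                          lay$disc_semi_major["sd"]),
             lay$disc_semi_major["lo"], lay$disc_semi_major["hi"])
  b <- a * prim["ovality_ratio"]
  tilt <- stats::rnorm(1, 90, 12)
  dc <- lay$disc_center
  pmp_rad <- prim["pmp"] * pi / 180
  # temporal is image-left; positive PMP puts the fovea inferior (+y)
  fovea <- dc + lay$fovea_dist * c(-cos(pmp_rad), sin(pmp_rad))
  loci <- c(paste0("L", 1:8), "F")
  color_truth <- matrix(prim[as.vector(t(outer(loci, c("_R", "_G", "_B"),
                                               paste0)))],
                        nrow = 9, byrow = TRUE,
                        dimnames = list(loci, c("R", "G", "B")))
  scene <- list(disc_center = dc,
                disc_axes = c(major = unname(a), minor = unname(b)),
                disc_tilt = tilt,
                fovea = fovea,
                vessel_truth = c(ST_RA = unname(prim["st_ra"]),
                                 IT_RA = unname(prim["it_ra"]),
                                 ST_VA = unname(prim["st_va"]),
                                 IT_VA = unname(prim["it_va"])),
                color_truth = color_truth,
                primitives = prim,
                image_size = config$image_size,
                diameters = config$diameters)
  class(scene) <- "fundus_scene"
  scene
}

#' Ground-truth feature vector of a scene
#'
#' The 42 parameters ([feature_names()] order) implied by a scene's
#' primitives, with the nine TFI values derived exactly from the channel
#' truths.  This is what a perfect extractor would recover (up to 8-bit
#' quantization of the rendered image).
#'
#' @param scene A `fundus_scene`.
#' @return Named numeric vector of length 42.
#' @export
scene_truth_features <- function(scene) {
  prim <- scene$primitives
  out <- prim[c("st_ra", "it_ra", "st_va", "it_va", "pmp", "ovality_ratio")]
  for (L in rownames(scene$color_truth)) {
    rgb <- scene$color_truth[L, ]
    out[paste0(L, c("_R", "_G", "_B", "_TFI"))] <-
      c(rgb, rgb["R"] / sum(rgb))
  }
  out <- out[feature_names()]
  stopifnot(!anyNA(out))
  out
}

#' Simulate a full cohort
#'
#' Seeds the RNG from the configuration, samples covariates and one scene
#' per subject, and assembles the ground-truth feature matrix.
#'
#' @param config A [cohort_config()].
#' @param scenes Keep the per-subject scene objects? (They are only
#'   needed when images will be rendered.)
#' @return List: `config`, `subjects` (covariate data.frame), `features`
#'   (n x 42 truth matrix, rownames = subject ids), and `scenes` (list or
#'   NULL).
#' @export
simulate_cohort <- function(config = cohort_config(), scenes = FALSE) {
  subjects <- sample_covariates(config)        # seeds the stream
  scn <- vector("list", nrow(subjects))
  feats <- matrix(NA_real_, nrow(subjects), 42L,
                  dimnames = list(subjects$subject_id, feature_names()))
  for (i in seq_len(nrow(subjects))) {
    sc <- sample_scene(subjects[i, ], config)
    feats[i, ] <- scene_truth_features(sc)
    if (scenes) scn[[i]] <- sc
  }
  list(config = config, subjects = subjects, features = feats,
       scenes = if (scenes) stats::setNames(scn, subjects$subject_id))
}
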