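# Association analyses downstream of the fundus sex index: correlations
# of the index with body height and axial length (overall and within
# sex), Mann-Whitney group comparisons, p-value-driven stepwise multiple
# regression for axial length, and the OLS regression of the index on
# height and sex.  Two-sided tests throughout; because the target cohort
# is large, significance is flagged at p < 0.001.

#' Correlation coefficient with p-value
#'
#' Pearson's product-moment correlation, or Spearman's rank correlation
#' computed as Pearson on midranks.  The p-value uses the t
#' approximation `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom (two-sided) for both methods.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param method "pearson" or "spearman".
#' @return List with `estimate`, `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(estimate = r, p_value = p, n = n, method = method)
}

#' Mann-Whitney U test
#'
#' U counts the pairs in which a value of `group_a` exceeds one of
#' `group_b`, plus one half per tied pair (computed via midranks).  The
#' two-sided p-value uses the normal approximation with the tie
#' correction.
#'
#' @param group_a,group_b Numeric vectors, both non-empty.
#' @return List with `U`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a == 0L || n_b == 0L)
    stop("data error: both groups must be non-empty", call. = FALSE)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  n <- n_a + n_b
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * (n + 1 - tie_term)
  p <- if (sigma2 <= 0) 1 else {
    z <- (U - n_a * n_b / 2) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }
  list(U = U, p_value = min(1, p), n_a = n_a, n_b = n_b)
}

std_coefs <- function(fit, y) {
  cf <- stats::coef(fit)[-1L]
  xsd <- vapply(names(cf), function(v) stats::sd(stats::model.matrix(fit)[, v]),
                numeric(1))
  cf * xsd / stats::sd(y)
}

#' Bidirectional p-value stepwise multiple regression
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' with the smallest partial-t p-value below `p_enter`, then removes any
#' included variable whose p-value is at or above `p_remove`, until the
#' selection stabilizes.  Deterministic given the data.  If no candidate
#' ever qualifies the intercept-only model is returned (not an error).
#'
#' @param response Numeric response vector.
#' @param candidates data.frame (or matrix) of candidate predictors.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @return List with `selected` (character), `coefficients`,
#'   `std_coefficients`, `p_values`, `fit` (the final `lm`).
#' @export
stepwise_regression <- function(response, candidates,
                                p_enter = 0.05, p_remove = 0.10) {
  candidates <- as.data.frame(candidates)
  ok <- stats::complete.cases(candidates) & is.finite(response)
  dat <- candidates[ok, , drop = FALSE]
  yv <- response[ok]
  if (nrow(dat) <= ncol(dat))
    stop("data error: need n > number of candidates after listwise deletion",
         call. = FALSE)
  dat <- dat[, vapply(dat, function(v) stats::sd(v) > 0, logical(1)),
             drop = FALSE]
  sel <- character(0)
  df_all <- cbind(.y = yv, dat)
  pvals_of <- function(vars) {
    fit <- stats::lm(stats::reformulate(vars, ".y"), data = df_all)
    summary(fit)$coefficients[vars, 4, drop = TRUE]
  }
  repeat {
    changed <- FALSE
    pool <- setdiff(names(dat), sel)
    if (length(pool)) {
      entry_p <- vapply(pool, function(v) {
        fit <- stats::lm(stats::reformulate(c(sel, v), ".y"), data = df_all)
        cf <- summary(fit)$coefficients
        if (v %in% rownames(cf)) cf[v, 4] else 1      # collinear: skip
      }, numeric(1))
      if (min(entry_p) < p_enter) {
        sel <- c(sel, pool[which.min(entry_p)])
        changed <- TRUE
      }
    }
    while (length(sel)) {
      pv <- pvals_of(sel)
      if (max(pv) >= p_remove) {
        sel <- setdiff(sel, names(pv)[which.max(pv)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (!length(sel)) {
    fit <- stats::lm(.y ~ 1, data = df_all)
    return(list(selected = character(0),
                coefficients = stats::coef(fit),
                std_coefficients = numeric(0), p_values = numeric(0),
                fit = fit))
  }
  fit <- stats::lm(stats::reformulate(sel, ".y"), data = df_all)
  list(selected = sel,
       coefficients = stats::coef(fit),
       std_coefficients = std_coefs(fit, yv),
       p_values = summary(fit)$coefficients[sel, 4],
       fit = fit)
}

#' Regress the fundus sex index on body height and sex
#'
#' Ordinary least squares of the index on height and sex (coded
#' female = 1), reporting standardized coefficients
#' (`b * SD(x) / SD(y)`) with their p-values.
#'
#' @param index Numeric fundus sex index values.
#' @param height Numeric body heights (cm).
#' @param sex Character ("male"/"female"), factor, or 0/1 with 1 =
#'   female.
#' @return List with `std_coefficients`, `coefficients`, `p_values`,
#'   `fit`.
#' @export
regress_index_on_height_sex <- function(index, height, sex) {
  female <- if (is.numeric(sex)) sex else as.integer(sex == "female")
  ok <- is.finite(index) & is.finite(height) & !is.na(female)
  if (sum(ok) < 10L) stop("need n >= 10 complete cases", call. = FALSE)
  d <- data.frame(index = index[ok], height = height[ok],
                  sex_female = female[ok])
  if (stats::sd(d$height) == 0 || stats::sd(d$sex_female) == 0)
    stop("collinearity error: constant predictor", call. = FALSE)
  fit <- stats::lm(index ~ height + sex_female, data = d)
  cf <- summary(fit)$coefficients
  list(std_coefficients = std_coefs(fit, d$index),
       coefficients = stats::coef(fit),
       p_values = cf[-1L, 4],
       fit = fit)
}

subgroup_rows <- function(ids, sex) {
  list(all = rep(TRUE, length(ids)),
       male = sex == "male",
       female = sex == "female")
}

#' Build the association report
#'
#' Assembles, from per-subject index values and the covariate table:
#' the correlation table (Pearson and Spearman, both reported) of the
#' index against body height and axial length in all subjects, men and
#' women; Mann-Whitney sex comparisons of age, refraction, axial length,
#' height and index; the OLS of index on height + sex; and, when a
#' feature matrix is supplied, the stepwise regression of axial length
#' on the index plus all fundus parameters (overall and per sex).
#' Significance is flagged at p < 0.001.  Deterministic: the same inputs
#' always produce the same report.
#'
#' @param index data.frame with `subject_id` and `fundus_sex_index`
#'   (e.g. the `index` element of [loocv_index()]).
#' @param covariates Covariate data.frame from [sample_covariates()] (or
#'   equivalent with `subject_id`, `sex`, `height_cm`,
#'   `axial_length_mm`).
#' @param features Optional n x 42 feature matrix with subject ids as
#'   rownames, enabling the stepwise analyses.
#' @param alpha Significance threshold (default 0.001).
#' @return Object of class `association_report`.
#' @export
build_report <- function(index, covariates, features = NULL, alpha = 0.001) {
  miss <- setdiff(index$subject_id, covariates$subject_id)
  if (length(miss))
    stop("join error: subject ids without covariates: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  d <- merge(index, covariates, by = "subject_id", sort = TRUE)
  grp <- subgroup_rows(d$subject_id, d$sex)
  pairs <- list(height = d$height_cm, axial_length = d$axial_length_mm)

  cor_tab <- do.call(rbind, lapply(names(pairs), function(v) {
    do.call(rbind, lapply(names(grp), function(g) {
      xi <- d$fundus_sex_index[grp[[g]]]; yi <- pairs[[v]][grp[[g]]]
      row <- data.frame(variable = v, subgroup = g, n = sum(grp[[g]]),
                        pearson_r = NA_real_, pearson_p = NA_real_,
                        spearman_rho = NA_real_, spearman_p = NA_real_)
      if (sum(is.finite(xi) & is.finite(yi)) >= 3) {
        pe <- correlate(xi, yi, "pearson")
        sp <- correlate(xi, yi, "spearman")
        row$pearson_r <- pe$estimate; row$pearson_p <- pe$p_value
        row$spearman_rho <- sp$estimate; row$spearman_p <- sp$p_value
      }
      row
    }))
  }))
  cor_tab$significant <- !is.na(cor_tab$pearson_p) & cor_tab$pearson_p < alpha

  test_vars <- c(age = "age", refraction = "refraction_d",
                 axial_length = "axial_length_mm", height = "height_cm",
                 fundus_sex_index = "fundus_sex_index")
  test_vars <- test_vars[unname(vapply(test_vars, function(v)
    v %in% names(d), logical(1)))]
  group_tab <- do.call(rbind, lapply(names(test_vars), function(v) {
    col <- test_vars[[v]]
    mw <- mann_whitney(d[[col]][d$sex == "male"],
                       d[[col]][d$sex == "female"])
    data.frame(variable = v,
               mean_male = mean(d[[col]][d$sex == "male"]),
               mean_female = mean(d[[col]][d$sex == "female"]),
               U = mw$U, p_value = mw$p_value,
               significant = mw$p_value < alpha)
  }))

  hs <- regress_index_on_height_sex(d$fundus_sex_index, d$height_cm, d$sex)

  stepwise <- NULL
  if (!is.null(features)) {
    f <- features[d$subject_id, , drop = FALSE]
    cand <- data.frame(fundus_sex_index = d$fundus_sex_index,
                       as.data.frame(f))
    stepwise <- lapply(grp, function(g) {
      if (sum(g) <= ncol(cand) + 1) return(NULL)
      sw <- stepwise_regression(d$axial_length_mm[g], cand[g, , drop = FALSE])
      sw$fit <- NULL   # keep the report serializable
      sw
    })
  }

  structure(list(correlations = cor_tab, group_tests = group_tab,
                 index_on_height_sex = list(
                   std_coefficients = hs$std_coefficients,
                   p_values = hs$p_values),
                 stepwise = stepwise,
                 alpha = alpha, n = nrow(d)),
            class = "association_report")
}

#' Write an association report to disk
#'
#' Emits `report.json` (machine-readable), plus `correlations.csv` and
#' `group_tests.csv`.
#'
#' @param report An `association_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "association_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$correlations,
                   file.path(dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(report$group_tests,
                   file.path(dir, "group_tests.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
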