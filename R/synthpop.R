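# Seeded synthetic cohort generator.
#
# One standard-normal latent risk z per person drives (i) shifts in the
# non-laboratory features (linear in z, noise SD = IQR/1.349) and (ii) the
# bivariate log-normal (FPG, 2hPG) pair, whose conditional means load on z
# and whose residuals are correlated. HbA1c is linear in the two glucose
# values plus noise. Diabetes status and glycemic subtype follow from the
# diagnostic thresholds, so prevalence and the discordance between fasting
# and post-load hyperglycemia are emergent properties of the glucose model,
# which calibrate_generator() tunes analytically.

# Non-DM medians/IQRs of a published Han-Chinese screening cohort; loadings
# are (DM median - non-DM median) / (E[z|DM] - E[z|non-DM]) with the
# denominator ~0.90 under the default glucose model. Pseudo-features
# (work status, education, sleep duration, cellphone years) are weakly or
# non-informative so that feature ranking has a real problem to solve.
default_feature_baselines <- function() {
  list(
    age            = list(median = 54.0,  iqr = c(47.0, 60.0),   loading = 3.3,  min = 20),
    sbp            = list(median = 134.0, iqr = c(122.0, 149.3), loading = 7.8,  min = 70),
    dbp            = list(median = 78.5,  iqr = c(71.0, 86.7),   loading = 3.6,  min = 40),
    rpr            = list(median = 79.0,  iqr = c(72.0, 87.0),   loading = 6.7,  min = 40),
    weight         = list(median = 56.5,  iqr = c(50.5, 63.0),   loading = 2.2,  min = 30),
    height         = list(median = 1.56,  iqr = c(1.52, 1.62),   loading = 0.0,  min = 1.3),
    wc             = list(median = 77.5,  iqr = c(71.0, 84.0),   loading = 3.1,  min = 50),
    hc             = list(median = 90.0,  iqr = c(86.0, 95.0),   loading = 1.1,  min = 60),
    sleep_duration = list(median = 7.0,   iqr = c(6.0, 8.0),     loading = -0.3, min = 3),
    cellphone_years= list(median = 8.0,   iqr = c(3.0, 14.0),    loading = 0.5,  min = 0)
  )
}

# Calibrated against prevalence 1047/8425 and diabetic-subtype split
# 41/28/31 (isolated post-load / isolated fasting / combined); see
# calibrate_generator() for the solver that produced these values.
default_glucose_model <- function() {
  list(
    mu_log_fpg = 1.734943, mu_log_2hpg = 1.980031,
    z_load_fpg = 0.065, z_load_2hpg = 0.15,
    sd_log_fpg = 0.13, sd_log_2hpg = 0.28,
    rho = 0.668354
  )
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_participants Number of rows to generate.
#' @param seed Integer seed; all sampling derives from it.
#' @param target_prevalence Intended diabetes prevalence (proportion).
#' @param target_subtype_fractions Named numeric of length 3
#'   (`isolated_postload`, `isolated_fasting`, `combined`), the intended
#'   split among diabetics; must sum to 1.
#' @param feature_baselines Named list; per feature `median`, `iqr`
#'   (c(lo, hi) in natural units), `loading` (feature units per SD of latent
#'   risk) and `min` (truncation floor).
#' @param glucose_model Bivariate log-scale glucose model: `mu_log_fpg`,
#'   `mu_log_2hpg` (log-mmol/L intercepts), `z_load_fpg`, `z_load_2hpg`
#'   (log-units per SD of latent risk), `sd_log_fpg`, `sd_log_2hpg`
#'   (residual SDs) and `rho` (residual correlation).
#' @param hba1c_model Linear model of HbA1c (%) on FPG and 2hPG:
#'   `intercept`, `slope_fpg`, `slope_2hpg`, `sd` (noise), `floor`
#'   (truncation, default 3.5).
#' @param missingness_rate MCAR masking rate for non-lab features, must be
#'   below 0.2 (features with 20%+ missingness would be excluded).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 8425,
                             seed = 20221128,
                             target_prevalence = 1047 / 8425,
                             target_subtype_fractions = c(
                               isolated_postload = 0.41,
                               isolated_fasting = 0.28,
                               combined = 0.31),
                             feature_baselines = default_feature_baselines(),
                             glucose_model = default_glucose_model(),
                             hba1c_model = list(intercept = 4.33,
                                                slope_fpg = 0.15,
                                                slope_2hpg = 0.05,
                                                sd = 0.30, floor = 3.5),
                             missingness_rate = 0) {
  config <- structure(
    list(n_participants = n_participants, seed = seed,
         target_prevalence = target_prevalence,
         target_subtype_fractions = target_subtype_fractions,
         feature_baselines = feature_baselines,
         glucose_model = glucose_model, hba1c_model = hba1c_model,
         missingness_rate = missingness_rate),
    class = "generator_config"
  )
  validate_generator_config(config)
  config
}

#' @rdname generator_config
#' @param config A `generator_config` to validate.
#' @export
validate_generator_config <- function(config) {
  fail <- function(field, why) {
    stop(sprintf("invalid generator config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(config$n_participants) || config$n_participants < 0 ||
      config$n_participants != round(config$n_participants)) {
    fail("n_participants", "must be a non-negative integer")
  }
  p <- config$target_prevalence
  if (!is.numeric(p) || p <= 0 || p >= 1) fail("target_prevalence", "must be in (0, 1)")
  fr <- config$target_subtype_fractions
  if (length(fr) != 3L || any(fr < 0)) {
    fail("target_subtype_fractions", "needs 3 non-negative proportions")
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    fail("target_subtype_fractions", sprintf("must sum to 1 (got %.12f)", sum(fr)))
  }
  g <- config$glucose_model
  if (g$sd_log_fpg <= 0 || g$sd_log_2hpg <= 0) {
    fail("glucose_model", "residual SDs must be positive")
  }
  if (g$rho <= -1 || g$rho >= 1) fail("glucose_model", "rho must be in (-1, 1)")
  if (config$hba1c_model$sd <= 0) fail("hba1c_model", "noise SD must be positive")
  m <- config$missingness_rate
  if (!is.numeric(m) || m < 0 || m >= 0.2) {
    fail("missingness_rate",
         "must be in [0, 0.2); features with 20%+ missing data are excluded")
  }
  for (nm in names(config$feature_baselines)) {
    b <- config$feature_baselines[[nm]]
    if (b$iqr[2] <= b$iqr[1]) fail("feature_baselines", paste0(nm, ": IQR hi <= lo"))
  }
  invisible(config)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  n_participants: %d, seed: %d\n", x$n_participants, x$seed))
  cat(sprintf("  target prevalence: %.4f; subtype split %s\n",
              x$target_prevalence,
              paste(sprintf("%.2f", x$target_subtype_fractions), collapse = "/")))
  cat(sprintf("  features: %s\n", paste(names(x$feature_baselines), collapse = ", ")))
  cat(sprintf("  missingness rate: %.3f\n", x$missingness_rate))
  invisible(x)
}

population_columns <- function(config = generator_config()) {
  c("id", names(config$feature_baselines),
    "sex", "smoke", "drink", "physical_activity", "work_status", "education",
    "bmi", "whr", "whtr", "fpg", "p2hpg", "hba1c", "dm_status", "subtype")
}

#' Sample a synthetic cohort
#'
#' Draws `n_participants` rows with the structure described in
#' [generator_config()]. Same config (including seed) gives a bit-identical
#' table. Anthropometric identities hold by construction: BMI =
#' weight/height^2, WHR = WC/HC, WHtR = WC/(100 height).
#'
#' @param config A [generator_config()].
#' @param thresholds [diagnostic_thresholds()] used to derive `dm_status`
#'   and `subtype` from the generated glucose values.
#' @return A tibble, one row per person.
#' @export
sample_population <- function(config = generator_config(),
                              thresholds = diagnostic_thresholds()) {
  validate_generator_config(config)
  n <- as.integer(config$n_participants)
  if (n == 0L) {
    cols <- population_columns(config)
    out <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cols)))
    names(out) <- cols
    out$subtype <- factor(character(0), levels = subtype_levels())
    out$dm_status <- logical(0)
    return(tibble::as_tibble(out))
  }
  withr::with_seed(config$seed, {
    z <- stats::rnorm(n)

    feats <- lapply(names(config$feature_baselines), function(nm) {
      b <- config$feature_baselines[[nm]]
      sd_noise <- (b$iqr[2] - b$iqr[1]) / 1.349
      x <- b$median + b$loading * z + stats::rnorm(n, 0, sd_noise)
      pmax(x, b$min)
    })
    names(feats) <- names(config$feature_baselines)

    # categorical features; only physical activity is (weakly) risk-linked
    sex <- stats::rbinom(n, 1, 0.355)                       # 1 = male
    smoke <- sample(0:2, n, replace = TRUE, prob = c(0.766, 0.192, 0.042))
    drink <- sample(0:2, n, replace = TRUE, prob = c(0.851, 0.125, 0.024))
    physical_activity <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.10) - 0.2 * z))
    work_status <- stats::rbinom(n, 1, 0.5)
    education <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))

    g <- config$glucose_model
    e1 <- stats::rnorm(n)
    e2 <- g$rho * e1 + sqrt(1 - g$rho^2) * stats::rnorm(n)
    fpg <- exp(g$mu_log_fpg + g$z_load_fpg * z + g$sd_log_fpg * e1)
    p2hpg <- exp(g$mu_log_2hpg + g$z_load_2hpg * z + g$sd_log_2hpg * e2)

    h <- config$hba1c_model
    floor_h <- if (is.null(h$floor)) 3.5 else h$floor
    hba1c <- pmax(h$intercept + h$slope_fpg * fpg + h$slope_2hpg * p2hpg +
                    stats::rnorm(n, 0, h$sd), floor_h)

    subtype <- dm_subtype(fpg, p2hpg, thresholds)

    tibble::tibble(
      id = seq_len(n),
      !!!feats,
      sex = sex, smoke = smoke, drink = drink,
      physical_activity = physical_activity,
      work_status = work_status, education = education,
      bmi = feats$weight / feats$height^2,
      whr = feats$wc / feats$hc,
      whtr = feats$wc / (feats$height * 100),
      fpg = fpg, p2hpg = p2hpg, hba1c = hba1c,
      dm_status = subtype != "NON_DM",
      subtype = subtype
    )
  })
}

# P(X >= za, Y >= zb) for standard bivariate normal with correlation r.
bivariate_upper_tail <- function(za, zb, r) {
  f <- function(x) {
    stats::dnorm(x) *
      stats::pnorm((zb - r * x) / sqrt(1 - r^2), lower.tail = FALSE)
  }
  stats::integrate(f, za, Inf, rel.tol = 1e-10)$value
}

#' Calibrate the generator to target prevalence and subtype split
#'
#' The marginal log-glucose distribution is bivariate normal with total SDs
#' `sqrt(z_load^2 + sd^2)` and total correlation induced by the shared
#' latent risk plus the residual correlation. The three targets (prevalence,
#' isolated post-load fraction, isolated fasting fraction; the combined
#' fraction is their complement) therefore determine the two log-scale
#' intercepts in closed form from the marginal exceedance probabilities, and
#' the total correlation by a 1-D root-find on the joint exceedance. The
#' solution is verified on a seeded Monte-Carlo sample.
#'
#' @param config Starting [generator_config()]; loadings and residual SDs
#'   are kept, intercepts and residual correlation are re-solved.
#' @param targets List with `prevalence` (proportion) and
#'   `subtype_fractions` (length-3, ordered isolated post-load / isolated
#'   fasting / combined, summing to 1).
#' @param n_calibration Size of the verification sample (>= 50000 advised).
#' @param seed Seed of the verification sample.
#' @param tol_prevalence,tol_subtype Absolute tolerances of the verification.
#' @param thresholds [diagnostic_thresholds()] defining the diagnosis.
#' @return The calibrated `generator_config`.
#' @export
calibrate_generator <- function(config = generator_config(),
                                targets = list(
                                  prevalence = config$target_prevalence,
                                  subtype_fractions = config$target_subtype_fractions),
                                n_calibration = 50000,
                                seed = config$seed,
                                tol_prevalence = 0.01,
                                tol_subtype = 0.03,
                                thresholds = diagnostic_thresholds()) {
  p <- targets$prevalence
  fr <- targets$subtype_fractions
  if (p <= 0 || p >= 1) stop("target prevalence must be in (0,1)", call. = FALSE)
  if (length(fr) != 3L || abs(sum(fr) - 1) > 1e-9) {
    stop("target subtype fractions must be 3 proportions summing to 1",
         call. = FALSE)
  }
  g <- config$glucose_model
  st_f <- sqrt(g$z_load_fpg^2 + g$sd_log_fpg^2)
  st_p <- sqrt(g$z_load_2hpg^2 + g$sd_log_2hpg^2)

  # marginal exceedances fix the intercepts in closed form
  p_f_hi <- p * (fr[[2]] + fr[[3]])   # P(FPG >= fpg_dm)
  p_p_hi <- p * (fr[[1]] + fr[[3]])   # P(2hPG >= p2hpg_dm)
  mu_f <- log(thresholds$fpg_dm) - st_f * stats::qnorm(1 - p_f_hi)
  mu_p <- log(thresholds$p2hpg_dm) - st_p * stats::qnorm(1 - p_p_hi)
  za <- (log(thresholds$fpg_dm) - mu_f) / st_f
  zb <- (log(thresholds$p2hpg_dm) - mu_p) / st_p

  # total correlation from the joint exceedance (combined fraction)
  target_joint <- p * fr[[3]]
  obj <- function(r) bivariate_upper_tail(za, zb, r) - target_joint
  lo <- -0.999; hi <- 0.999
  if (obj(lo) * obj(hi) > 0) {
    stop(sprintf(paste0(
      "calibration failure: combined-subtype target %.4f is outside the ",
      "attainable joint-exceedance range [%.4f, %.4f] for these marginals"),
      target_joint, bivariate_upper_tail(za, zb, lo) ,
      bivariate_upper_tail(za, zb, hi)), call. = FALSE)
  }
  r_tot <- stats::uniroot(obj, c(lo, hi), tol = 1e-10)$root
  rho_resid <- (r_tot * st_f * st_p - g$z_load_fpg * g$z_load_2hpg) /
    (g$sd_log_fpg * g$sd_log_2hpg)
  if (rho_resid <= -1 || rho_resid >= 1) {
    stop(sprintf(paste0(
      "calibration failure: required residual correlation %.4f is outside ",
      "(-1, 1); reduce the latent loadings or widen the residual SDs"),
      rho_resid), call. = FALSE)
  }

  out <- config
  out$glucose_model$mu_log_fpg <- mu_f
  out$glucose_model$mu_log_2hpg <- mu_p
  out$glucose_model$rho <- rho_resid
  out$target_prevalence <- p
  out$target_subtype_fractions <- fr

  # Monte-Carlo verification at n_calibration
  check <- out
  check$n_participants <- n_calibration
  check$seed <- seed
  check$missingness_rate <- 0
  pop <- sample_population(check, thresholds)
  ach_p <- mean(pop$dm_status)
  ach_fr <- as.numeric(prop.table(table(pop$subtype[pop$dm_status]))[
    c("ISOLATED_POSTLOAD", "ISOLATED_FASTING", "COMBINED")])
  if (abs(ach_p - p) > tol_prevalence || any(abs(ach_fr - unlist(fr)) > tol_subtype)) {
    stop(sprintf(paste0(
      "calibration verification failed: achieved prevalence %.4f ",
      "(target %.4f), subtype fractions %s (target %s)"),
      ach_p, p, paste(sprintf("%.3f", ach_fr), collapse = "/"),
      paste(sprintf("%.3f", unlist(fr)), collapse = "/")), call. = FALSE)
  }
  out
}

#' Mask non-laboratory feature cells completely at random
#'
#' Laboratory values (`fpg`, `p2hpg`, `hba1c`), identifiers and outcome
#' columns are never masked. Rates of 20% or more are rejected: such
#' features would be excluded rather than imputed.
#'
#' @param pop A population table.
#' @param rate Per-cell masking probability in `[0, 0.2)`.
#' @param seed Integer seed.
#' @return The table with `NA`s injected into feature columns.
#' @export
inject_missingness <- function(pop, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.2) {
    stop("missingness rate must be in [0, 0.2): features with 20% or more ",
         "missing data are excluded, not imputed", call. = FALSE)
  }
  if (rate == 0) return(pop)
  protected <- c("id", "fpg", "p2hpg", "hba1c", "dm_status", "subtype")
  cols <- setdiff(names(pop), protected)
  withr::with_seed(seed, {
    for (cl in cols) {
      mask <- stats::runif(nrow(pop)) < rate
      pop[[cl]][mask] <- NA
    }
  })
  pop
}

#' Split a cohort into development and testing sets
#'
#' Simple (unstratified) random split; the development set receives
#' `round(n * dev_fraction)` rows.
#'
#' @param pop Population table with at least 2 rows.
#' @param dev_fraction Proportion in (0, 1) assigned to development.
#' @param seed Integer seed.
#' @return List with `dev` and `test` tibbles (disjoint, exhaustive).
#' @export
split_dev_test <- function(pop, dev_fraction = 0.6, seed = 1L) {
  n <- nrow(pop)
  if (n < 2L) stop("need at least 2 rows to split", call. = FALSE)
  if (dev_fraction <= 0 || dev_fraction >= 1) {
    stop("dev_fraction must be in (0, 1)", call. = FALSE)
  }
  n_dev <- round(n * dev_fraction)
  n_dev <- min(max(n_dev, 1L), n - 1L)
  idx <- withr::with_seed(seed, sample.int(n, n_dev))
  list(dev = pop[sort(idx), , drop = FALSE],
       test = pop[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}
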