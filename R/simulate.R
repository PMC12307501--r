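# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: an
# older and a young group, log2-scale Gaussian measurement noise, a subset of
# proteins with linear or nonlinear chronological-age trajectories (seven
# archetype shapes), a subset of "clock" proteins loading on a latent
# biological age (chronological age plus a per-subject offset delta), sex and
# BMI covariate effects, and mixed left-censored + at-random missingness.
# Ground truth (planted slopes, loadings, archetype labels, delta, true ager
# class) is returned for recovery testing.

#' The seven trajectory archetype names
#' @export
ARCHETYPES <- c("linear_up", "linear_down", "plateau_up", "plateau_down",
                "late_rise", "late_fall", "nonmonotone")

#' Evaluate a trajectory archetype curve
#'
#' Curves are parameterized on the normalized age `t = (age - a0)/(a1 - a0)`
#' over the cohort age span `c(a0, a1)` and take values in `[0, 1]`:
#' `linear_up` maps span start to 0 and span end to 1, `linear_down` is its
#' mirror; plateau shapes are logistic with an early midpoint (t = 0.25),
#' late shapes logistic with a late midpoint (t = 0.75); `nonmonotone` is a
#' Gaussian bump centered at mid-span. Logistic transitions use scale 0.15
#' of the span (a transition spread over roughly a decade on a 19–91-year
#' cohort), matching the smooth trajectories the shapes emulate.
#'
#' @param shape one of [ARCHETYPES].
#' @param age numeric vector of ages (years) within `span`.
#' @param span length-2 numeric, the age interval.
#' @return numeric vector of curve values in `[0, 1]`.
#' @export
archetype_curve <- function(shape, age, span) {
  if (!shape %in% ARCHETYPES) stop("unknown archetype shape: ", shape)
  stopifnot(length(span) == 2, span[2] > span[1])
  if (any(age < span[1] - 1e-9 | age > span[2] + 1e-9))
    stop("age outside span")
  t <- (age - span[1]) / (span[2] - span[1])
  logis <- function(mid, scale = 0.15) 1 / (1 + exp(-(t - mid) / scale))
  switch(shape,
    linear_up = t,
    linear_down = 1 - t,
    plateau_up = logis(0.25),
    plateau_down = 1 - logis(0.25),
    late_rise = logis(0.75),
    late_fall = 1 - logis(0.75),
    nonmonotone = exp(-((t - 0.5) / 0.18)^2)
  )
}

#' Configuration of a synthetic cohort
#'
#' Defaults mirror the cohort the analysis is designed for: 19 young
#' (19–35 y) and 33 older (50–91 y) subjects, 634 quantified proteins, trend
#' effects of 1.5 log2 units across the full age span (the scale of typical
#' top aging-protein fold changes), measurement noise SD 0.5 log2 units, a
#' latent biological-age offset with SD 6 years, small sex and BMI effects,
#' and left-censored plus at-random missingness.
#'
#' @param n_young,n_old group sizes.
#' @param age_range_young,age_range_old sampling intervals (years).
#' @param n_proteins total protein count.
#' @param n_trend_proteins proteins with a planted chronological-age
#'   trajectory (assigned archetypes cycling through `archetypes`).
#' @param n_clock_proteins proteins loading linearly on latent biological age
#'   (chronological age + delta), with alternating signs.
#' @param trend_effect log2-unit change across the full age span for trend
#'   and clock proteins.
#' @param sigma_noise log2-unit Gaussian measurement noise SD.
#' @param sigma_delta SD (years) of the latent biological-age offset.
#' @param sex_effect,bmi_effect log2 units per unit covariate, applied to all
#'   proteins.
#' @param missing_rate_mcar missing-completely-at-random fraction in `[0,1)`.
#' @param censor_quantile left-censoring threshold quantile per protein in
#'   `[0,1)` (0 disables censoring).
#' @param archetypes subset of [ARCHETYPES] used for trend proteins.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_young = 19, n_old = 33,
                          age_range_young = c(19, 35),
                          age_range_old = c(50, 91),
                          n_proteins = 634, n_trend_proteins = 70,
                          n_clock_proteins = 15, trend_effect = 1.5,
                          sigma_noise = 0.5, sigma_delta = 6,
                          sex_effect = 0.2, bmi_effect = 0.02,
                          missing_rate_mcar = 0.02, censor_quantile = 0.05,
                          archetypes = ARCHETYPES, seed = 1) {
  cfg <- as.list(environment())
  if (n_young < 0 || n_old < 0 || n_proteins < 0 ||
      n_trend_proteins < 0 || n_clock_proteins < 0)
    stop("counts must be >= 0")
  if (n_trend_proteins + n_clock_proteins > n_proteins)
    stop("n_trend_proteins + n_clock_proteins must be <= n_proteins")
  if (sigma_noise < 0 || sigma_delta < 0) stop("sigma values must be >= 0")
  if (missing_rate_mcar < 0 || missing_rate_mcar >= 1 ||
      censor_quantile < 0 || censor_quantile >= 1)
    stop("rates must be in [0, 1)")
  if (!all(archetypes %in% ARCHETYPES)) stop("unknown archetype name")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws ages uniformly within each group's range, a latent offset
#' `delta ~ N(0, sigma_delta^2)` giving biological age `b = age + delta`,
#' sex ~ Bernoulli(0.5), BMI ~ N(24, 3^2) truncated to `[15, 40]`, and builds
#' each protein as
#' `baseline + f(age or b) + sex_effect * sex + bmi_effect * (bmi - mean)`
#' plus Gaussian noise, where `f` is the archetype curve scaled to
#' `trend_effect` (trend proteins track chronological age, clock proteins are
#' linear in biological age). Left-censoring below each protein's
#' `censor_quantile` quantile is applied first, then MCAR dropout.
#'
#' @param cfg a [cohort_config()].
#' @return list of class `cohort_sim` with elements `abundance` (matrix with
#'   `NA`s), `metadata` (data.frame), and `truth` (planted parameters: trend
#'   protein slopes and archetypes, clock loadings, per-sample `delta`,
#'   `true_ager_class`, missingness masks).
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_young + cfg$n_old
    sample_id <- sprintf("S%02d", seq_len(n))
    group <- factor(rep(c("young", "older"), c(cfg$n_young, cfg$n_old)),
                    levels = c("young", "older"))
    age <- c(stats::runif(cfg$n_young, cfg$age_range_young[1],
                          cfg$age_range_young[2]),
             stats::runif(cfg$n_old, cfg$age_range_old[1],
                          cfg$age_range_old[2]))
    sex <- stats::rbinom(n, 1, 0.5)
    bmi <- pmin(pmax(stats::rnorm(n, 24, 3), 15), 40)
    delta <- stats::rnorm(n, 0, cfg$sigma_delta)
    bio_age <- age + delta

    span <- c(min(cfg$age_range_young), max(cfg$age_range_old))
    span_years <- span[2] - span[1]
    mid <- mean(span)

    prot_id <- sprintf("P%04d", seq_len(cfg$n_proteins))
    n_tr <- cfg$n_trend_proteins; n_cl <- cfg$n_clock_proteins
    trend_ids <- prot_id[seq_len(n_tr)]
    clock_ids <- prot_id[n_tr + seq_len(n_cl)]
    arch <- if (n_tr) rep(cfg$archetypes, length.out = n_tr) else character()
    clock_sign <- if (n_cl) rep_len(c(1, -1), n_cl) else numeric()

    baseline <- stats::rnorm(cfg$n_proteins, 20, 2)
    x <- matrix(stats::rnorm(cfg$n_proteins * n, 0, cfg$sigma_noise),
                cfg$n_proteins, n, dimnames = list(prot_id, sample_id))
    x <- x + baseline +
      rep(cfg$sex_effect * sex, each = cfg$n_proteins) +
      rep(cfg$bmi_effect * (bmi - mean(bmi)), each = cfg$n_proteins)
    for (i in seq_len(n_tr))
      x[i, ] <- x[i, ] + cfg$trend_effect * archetype_curve(arch[i], age, span)
    b_clip <- pmin(pmax(bio_age, span[1]), span[2])
    for (i in seq_len(n_cl))
      x[n_tr + i, ] <- x[n_tr + i, ] +
        clock_sign[i] * cfg$trend_effect * (b_clip - mid) / span_years

    # left-censoring first, then MCAR, so the two mechanisms are separable
    censored <- matrix(FALSE, cfg$n_proteins, n)
    if (cfg$censor_quantile > 0) {
      thr <- apply(x, 1, stats::quantile, cfg$censor_quantile, names = FALSE)
      censored <- x < thr
    }
    mcar <- matrix(stats::runif(length(x)) < cfg$missing_rate_mcar,
                   cfg$n_proteins, n) & !censored
    x[censored | mcar] <- NA

    # planted per-year slope is exact for the linear archetypes only
    slope <- rep(NA_real_, n_tr)
    slope[arch == "linear_up"] <- cfg$trend_effect / span_years
    slope[arch == "linear_down"] <- -cfg$trend_effect / span_years
    dir_map <- c(linear_up = "up", linear_down = "down", plateau_up = "up",
                 plateau_down = "down", late_rise = "up", late_fall = "down",
                 nonmonotone = "none")

    truth <- list(
      trend_proteins = trend_ids,
      archetype_labels = stats::setNames(arch, trend_ids),
      trend_slopes = stats::setNames(slope, trend_ids),
      trend_directions = stats::setNames(unname(dir_map[arch]), trend_ids),
      clock_proteins = clock_ids,
      clock_loadings = stats::setNames(
        clock_sign * cfg$trend_effect / span_years, clock_ids),
      delta = stats::setNames(delta, sample_id),
      true_ager_class = stats::setNames(
        classify_agers(delta), sample_id),
      censored_mask = censored, mcar_mask = mcar,
      baseline = stats::setNames(baseline, prot_id),
      age_span = span
    )
    meta <- data.frame(sample_id = sample_id, age = age, sex = sex,
                       bmi = bmi, group = group,
                       stringsAsFactors = FALSE)
    # opacity grade: ordinal proxy rising with biological age in the older
    # group (graded 1-6), absent for young samples
    grade <- rep(NA_integer_, n)
    old <- group == "older"
    if (any(old)) {
      g <- cut(rank(bio_age[old], ties.method = "first"),
               breaks = 6, labels = FALSE)
      grade[old] <- g
    }
    meta$opacity_grade <- grade
    structure(list(abundance = x, metadata = meta, truth = truth,
                   config = cfg),
              class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$abundance), "proteins x",
      ncol(x$abundance), "samples\n")
  cat("  trend proteins:", length(x$truth$trend_proteins),
      "| clock proteins:", length(x$truth$clock_proteins), "\n")
  cat("  missing fraction:", round(mean(is.na(x$abundance)), 3), "\n")
  invisible(x)
}
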