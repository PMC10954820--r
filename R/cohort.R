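#' Classify glycemic status from the three laboratory markers
#'
#' Applies the clinical classification used for cohort labels: type 2
#' diabetes (T2DM) if any of fasting plasma glucose >= 126 mg/dL,
#' 2-h oral glucose tolerance test >= 200 mg/dL, or HbA1c >= 6.1 %;
#' otherwise normal glucose metabolism (NGM) only when all three of
#' FPG < 110, 2-h OGTT < 140 and HbA1c < 5.4 hold simultaneously;
#' everything else is prediabetes (Pre-DM).  Marker values that fall in
#' the narrow bands no printed class covers (FPG in (125, 126), OGTT in
#' (199, 200), HbA1c in [5.4, 5.6)) are assigned to Pre-DM with a
#' warning.
#'
#' @param fpg fasting plasma glucose, mg/dL.
#' @param ogtt2h 2-h OGTT glucose, mg/dL.
#' @param hba1c glycated hemoglobin, percent.
#' @return Factor with levels NGM, Pre-DM, T2DM (vectorised).
#' @examples
#' classify_glycemic_status(c(130, 92, 115), c(210, 105, 150), c(6.5, 5.2, 5.8))
#' @export
classify_glycemic_status <- function(fpg, ogtt2h, hba1c) {
  v <- c(fpg, ogtt2h, hba1c)
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("all three markers must be non-negative and finite.")
  }
  t2dm <- fpg >= 126 | ogtt2h >= 200 | hba1c >= 6.1
  ngm <- fpg < 110 & ogtt2h < 140 & hba1c < 5.4
  lab <- ifelse(t2dm, "T2DM", ifelse(ngm, "NGM", "Pre-DM"))
  gap <- !t2dm & !ngm &
    ((fpg > 125 & fpg < 126) | (ogtt2h > 199 & ogtt2h < 200) |
       (hba1c >= 5.4 & hba1c < 5.6))
  if (any(gap)) {
    warn(sprintf(
      "%d value(s) fall between the printed class bounds; assigned to Pre-DM.",
      sum(gap)
    ))
  }
  factor(lab, levels = alps_group_levels)
}

#' @rdname classify_glycemic_status
#' @format `alps_group_levels` gives the group factor levels in
#'   reference order (NGM first).
#' @export
alps_group_levels <- c("NGM", "Pre-DM", "T2DM")

#' Cohort simulation configuration
#'
#' Bundles the population parameters of a three-group glycemic cohort:
#' per-group sample sizes, ALPS index distributions, covariate
#' distributions, glycemic-marker distributions, the target partial
#' correlation between ALPS and HOMA-IR given the seven model
#' covariates, the Rician noise level of the simulated acquisition, and
#' the master seed.  Defaults reproduce the published cohort profile:
#' 30 NGM / 22 Pre-DM / 18 T2DM subjects, ALPS 1.58 +/- 0.20,
#' 1.43 +/- 0.08 and 1.36 +/- 0.14, and a partial correlation of -0.35.
#' Intracranial volume is not part of the published profile; its default
#' (1.45e6 +/- 1.4e5 mm^3) is a typical older-adult distribution.
#'
#' Any parameter can be overridden by passing a replacement: scalars are
#' recycled over the three groups (NGM, Pre-DM, T2DM order).
#'
#' @param group_sizes integer vector length 3 (NGM, Pre-DM, T2DM).
#' @param alps_mean,alps_sd per-group true ALPS distribution.
#' @param age_mean,age_sd years.
#' @param sex_male per-group proportion of male subjects.
#' @param education_mean,education_sd years.
#' @param icv_mean,icv_sd intracranial volume, mm^3.
#' @param hypertension,hyperlipidemia per-group prevalence.
#' @param fazekas_mean,fazekas_sd total Fazekas scale (realised as
#'   integers 0-6 from a discretised normal).
#' @param homair_mean,homair_sd HOMA-IR.
#' @param fpg_mean,fpg_sd fasting plasma glucose, mg/dL.
#' @param ogtt_mean,ogtt_sd 2-h OGTT glucose, mg/dL.
#' @param hba1c_mean,hba1c_sd HbA1c, percent.
#' @param alps_homair_partial_r target population partial correlation of
#'   ALPS with HOMA-IR given the seven covariates, in (-1, 1); `NULL`
#'   disables the coupling (HOMA-IR independent of ALPS within groups).
#' @param noise_sigma Rician noise SD relative to the b = 0 signal.
#' @param master_seed integer seed; every cohort draw is a pure function
#'   of (config, master_seed).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(30L, 22L, 18L),
                          alps_mean = c(1.58, 1.43, 1.36),
                          alps_sd = c(0.20, 0.08, 0.14),
                          age_mean = c(70.3, 72.1, 72.6),
                          age_sd = c(4.8, 4.0, 6.0),
                          sex_male = c(14 / 30, 10 / 22, 13 / 18),
                          education_mean = c(14.3, 14.1, 13.8),
                          education_sd = c(2.2, 1.9, 2.2),
                          icv_mean = 1.45e6,
                          icv_sd = 1.4e5,
                          hypertension = c(15 / 30, 15 / 22, 12 / 18),
                          hyperlipidemia = c(14 / 30, 18 / 22, 13 / 18),
                          fazekas_mean = c(2.1, 2.5, 2.78),
                          fazekas_sd = c(0.61, 0.8, 1.0),
                          homair_mean = c(0.8, 1.2, 1.7),
                          homair_sd = c(0.5, 0.4, 1.3),
                          fpg_mean = c(92.4, 99.0, 121.0),
                          fpg_sd = c(5.7, 7.8, 20.3),
                          ogtt_mean = c(105.0, 154.0, 254.4),
                          ogtt_sd = c(21.4, 21.0, 64.5),
                          hba1c_mean = c(5.5, 5.9, 6.6),
                          hba1c_sd = c(0.3, 0.2, 0.9),
                          alps_homair_partial_r = -0.35,
                          noise_sigma = 0.01,
                          master_seed = 1L) {
  rec <- function(x) {
    x <- rep_len(as.numeric(x), 3L)
    names(x) <- alps_group_levels
    x
  }
  group_sizes <- rep_len(as.integer(group_sizes), 3L)
  names(group_sizes) <- alps_group_levels
  cfg <- list(
    group_sizes = group_sizes,
    alps_mean = rec(alps_mean), alps_sd = rec(alps_sd),
    age_mean = rec(age_mean), age_sd = rec(age_sd),
    sex_male = rec(sex_male),
    education_mean = rec(education_mean), education_sd = rec(education_sd),
    icv_mean = rec(icv_mean), icv_sd = rec(icv_sd),
    hypertension = rec(hypertension), hyperlipidemia = rec(hyperlipidemia),
    fazekas_mean = rec(fazekas_mean), fazekas_sd = rec(fazekas_sd),
    homair_mean = rec(homair_mean), homair_sd = rec(homair_sd),
    fpg_mean = rec(fpg_mean), fpg_sd = rec(fpg_sd),
    ogtt_mean = rec(ogtt_mean), ogtt_sd = rec(ogtt_sd),
    hba1c_mean = rec(hba1c_mean), hba1c_sd = rec(hba1c_sd),
    alps_homair_partial_r = alps_homair_partial_r,
    noise_sigma = as.numeric(noise_sigma),
    master_seed = as.integer(master_seed)
  )
  validate_cohort_config(structure(cfg, class = "cohort_config"))
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$group_sizes < 0)) abort("group sizes must be >= 0.")
  if (sum(cfg$group_sizes) < 1) abort("at least one subject is required.")
  sds <- c(cfg$alps_sd, cfg$age_sd, cfg$education_sd, cfg$icv_sd,
           cfg$fazekas_sd, cfg$homair_sd, cfg$fpg_sd, cfg$ogtt_sd,
           cfg$hba1c_sd)
  if (any(sds < 0)) abort("standard deviations must be >= 0.")
  props <- c(cfg$sex_male, cfg$hypertension, cfg$hyperlipidemia)
  if (any(props < 0 | props > 1)) abort("proportions must lie in [0, 1].")
  r <- cfg$alps_homair_partial_r
  if (!is.null(r) && (!is.finite(r) || abs(r) >= 1)) {
    abort("`alps_homair_partial_r` must lie strictly inside (-1, 1).")
  }
  if (cfg$noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n = %s (NGM/Pre-DM/T2DM), ALPS %s, partial r target %s, noise %.3g, seed %d\n",
    paste(x$group_sizes, collapse = "/"),
    paste(sprintf("%.2f+/-%.2f", x$alps_mean, x$alps_sd), collapse = ", "),
    if (is.null(x$alps_homair_partial_r)) "none" else
      format(x$alps_homair_partial_r),
    x$noise_sigma, x$master_seed
  ))
  invisible(x)
}

# Exact pmf of the total Fazekas score: a normal discretised onto the
# integers 0..6 with the tails lumped into the end bins.
fazekas_pmf <- function(mean, sd) {
  k <- 0:6
  if (sd == 0) {
    p <- as.numeric(k == max(0, min(6, round(mean))))
  } else {
    up <- pnorm((k + 0.5 - mean) / sd)
    lo <- pnorm((k - 0.5 - mean) / sd)
    p <- up - lo
    p[1] <- up[1]
    p[7] <- 1 - lo[7]
  }
  p
}

# Per-group mean and variance of each of the seven model covariates
# (sex_male, age, icv, education, hypertension, hyperlipidemia,
# fazekas), exactly as the generator draws them.
covariate_moments <- function(cfg, g) {
  pf <- fazekas_pmf(cfg$fazekas_mean[g], cfg$fazekas_sd[g])
  fz_m <- sum((0:6) * pf)
  fz_v <- sum((0:6)^2 * pf) - fz_m^2
  bern_v <- function(p) p * (1 - p)
  list(
    mean = c(sex_male = cfg$sex_male[[g]], age = cfg$age_mean[[g]],
             icv = cfg$icv_mean[[g]], education = cfg$education_mean[[g]],
             hypertension = cfg$hypertension[[g]],
             hyperlipidemia = cfg$hyperlipidemia[[g]], fazekas = fz_m),
    var = c(sex_male = bern_v(cfg$sex_male[[g]]), age = cfg$age_sd[[g]]^2,
            icv = cfg$icv_sd[[g]]^2, education = cfg$education_sd[[g]]^2,
            hypertension = bern_v(cfg$hypertension[[g]]),
            hyperlipidemia = bern_v(cfg$hyperlipidemia[[g]]), fazekas = fz_v)
  )
}

#' Within-group coupling needed to hit a target partial correlation
#'
#' The generator draws HOMA-IR as `mu_H(g) + c * s_H(g) * z_A +
#' s_H(g) * sqrt(1 - c^2) * eps`, where `z_A` is the subject's
#' standardised within-group ALPS deviation.  Because the glycemic
#' groups differ in both their ALPS and their HOMA-IR means (and the
#' seven covariates only partly track group), the population partial
#' correlation of ALPS with HOMA-IR given the covariates is not simply
#' `c`: it picks up a between-group component.  This function computes
#' the population moment structure implied by the configuration
#' (mixture over groups; covariates independent of ALPS within group)
#' and solves the resulting linear equation for the `c` that makes the
#' population partial correlation equal the target.
#'
#' @param cfg a [cohort_config()].
#' @return List with `c` (within-group correlation), and the population
#'   quantities used (`residual_var_alps`, `residual_var_homair`,
#'   `between_cov`, `within_cov_unit`).
#' @export
calibrate_coupling <- function(cfg) {
  rho <- cfg$alps_homair_partial_r
  present <- names(cfg$group_sizes)[cfg$group_sizes > 0]
  w <- cfg$group_sizes[present] / sum(cfg$group_sizes[present])
  mom <- lapply(present, function(g) covariate_moments(cfg, g))
  names(mom) <- present
  k <- 7L
  mu_c <- sapply(mom, `[[`, "mean") # k x G
  var_c <- sapply(mom, `[[`, "var")
  mbar <- as.vector(mu_c %*% w)
  sigma_cc <- diag(as.vector(var_c %*% w), k) +
    mu_c %*% diag(w, length(w)) %*% t(mu_c) - tcrossprod(mbar)
  mu_a <- cfg$alps_mean[present]
  sd_a <- cfg$alps_sd[present]
  mu_h <- cfg$homair_mean[present]
  sd_h <- cfg$homair_sd[present]
  ea <- sum(w * mu_a)
  eh <- sum(w * mu_h)
  var_a <- sum(w * (sd_a^2 + mu_a^2)) - ea^2
  var_h <- sum(w * (sd_h^2 + mu_h^2)) - eh^2
  sigma_ac <- as.vector(mu_c %*% (w * mu_a)) - mbar * ea
  sigma_hc <- as.vector(mu_c %*% (w * mu_h)) - mbar * eh
  # drop zero-variance covariates (no adjustment information)
  keep <- diag(sigma_cc) > 1e-12 * max(1, diag(sigma_cc))
  adj <- function(u, v) {
    if (!any(keep)) return(0)
    scc <- sigma_cc[keep, keep, drop = FALSE]
    drop(crossprod(u[keep], solve(scc, v[keep])))
  }
  r_a2 <- var_a - adj(sigma_ac, sigma_ac)
  r_h2 <- var_h - adj(sigma_hc, sigma_hc)
  b <- (sum(w * mu_a * mu_h) - ea * eh) - adj(sigma_ac, sigma_hc)
  wcov <- sum(w * sd_a * sd_h)
  if (is.null(rho)) {
    return(list(c = 0, residual_var_alps = r_a2, residual_var_homair = r_h2,
                between_cov = b, within_cov_unit = wcov))
  }
  if (r_a2 <= 1e-15 || r_h2 <= 1e-15) {
    abort("coupling infeasible: ALPS (`alps_sd`/`alps_mean`) or HOMA-IR (`homair_sd`/`homair_mean`) has no residual variance after covariate adjustment.")
  }
  target_cov <- rho * sqrt(r_a2 * r_h2)
  if (wcov <= 0) {
    if (abs(target_cov - b) < 1e-12) {
      cc <- 0
    } else {
      abort("coupling infeasible: `alps_sd` and `homair_sd` give zero within-group covariance capacity; cannot reach `alps_homair_partial_r`.")
    }
  } else {
    cc <- (target_cov - b) / wcov
  }
  if (abs(cc) > 1) {
    abort(sprintf(
      "coupling infeasible: `alps_homair_partial_r` = %.3f needs within-group correlation %.3f (|c| > 1); shrink the target or increase `alps_sd`/`homair_sd`.",
      rho, cc
    ))
  }
  list(c = cc, residual_var_alps = r_a2, residual_var_homair = r_h2,
       between_cov = b, within_cov_unit = wcov)
}

# inverse-CDF truncated normal draw on (a, b)
rtruncnorm <- function(n, mean, sd, a = -Inf, b = Inf) {
  if (sd == 0) return(rep(min(max(mean, a), b), n))
  pa <- pnorm(a, mean, sd)
  pb <- pnorm(b, mean, sd)
  qnorm(runif(n, pa, pb), mean, sd)
}

# truncated normal on (a, b) that additionally avoids open gap
# intervals (list of c(lo, hi)), by redrawing
rtrunc_gaps <- function(n, mean, sd, a = -Inf, b = Inf, gaps = list()) {
  x <- rtruncnorm(n, mean, sd, a, b)
  if (length(gaps) == 0 || sd == 0) return(x)
  in_gap <- function(v) {
    Reduce(`|`, lapply(gaps, function(g) v > g[1] & v < g[2]),
           rep(FALSE, length(v)))
  }
  for (it in 1:100) {
    bad <- in_gap(x)
    if (!any(bad)) break
    x[bad] <- rtruncnorm(sum(bad), mean, sd, a, b)
  }
  x
}

#' Generate a synthetic glycemic cohort with ground-truth ALPS structure
#'
#' Draws one row per subject: group label, the three glycemic markers
#' (sampled from the group's distribution restricted to marker ranges
#' consistent with the group label, so [classify_glycemic_status()]
#' reproduces the intended group by construction), the seven model
#' covariates, HOMA-IR coupled to the subject's true ALPS index via the
#' calibrated latent model (see [calibrate_coupling()]), and the true
#' ALPS index drawn from the group's normal distribution truncated at
#' zero.  Ground truth additionally stores the four ROI diffusivities
#' realising the true index in the one-parameter family
#' `dyy_proj = dzz_assoc = 1e-3 mm^2/s`, `dxx_proj = dxx_assoc =
#' ALPS * 1e-3 mm^2/s`, and the per-subject DWI noise seed
#' (`master_seed + subject index`).
#'
#' @param config a [cohort_config()].
#' @return An object of class `alps_cohort`: list with `cohort` (tibble,
#'   one row per subject; the `alps` column is the subject's true index
#'   until an imaging pipeline overwrites it with a measured value),
#'   `truth` (tibble of ground-truth diffusivities and seeds), the
#'   `config`, and the calibrated `coupling`.
#' @examples
#' coh <- generate_cohort(cohort_config(group_sizes = c(5, 4, 3)))
#' dplyr::count(coh$cohort, group)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cal <- calibrate_coupling(config)
  set.seed(config$master_seed)
  rows <- list()
  truths <- list()
  idx0 <- 0L
  for (g in alps_group_levels) {
    n <- config$group_sizes[[g]]
    if (n == 0) next
    sex <- stats::rbinom(n, 1, config$sex_male[[g]])
    age <- rnorm(n, config$age_mean[[g]], config$age_sd[[g]])
    edu <- rnorm(n, config$education_mean[[g]], config$education_sd[[g]])
    icv <- rnorm(n, config$icv_mean[[g]], config$icv_sd[[g]])
    htn <- stats::rbinom(n, 1, config$hypertension[[g]])
    hld <- stats::rbinom(n, 1, config$hyperlipidemia[[g]])
    fz <- sample(0:6, n, replace = TRUE,
                 prob = fazekas_pmf(config$fazekas_mean[[g]],
                                    config$fazekas_sd[[g]]))
    mk <- draw_markers(n, g, config)
    alps_true <- rtruncnorm(n, config$alps_mean[[g]], config$alps_sd[[g]],
                            a = 0)
    z_a <- if (config$alps_sd[[g]] > 0) {
      (alps_true - config$alps_mean[[g]]) / config$alps_sd[[g]]
    } else {
      rep(0, n)
    }
    cc <- cal$c
    homa <- config$homair_mean[[g]] +
      config$homair_sd[[g]] * (cc * z_a + sqrt(1 - cc^2) * rnorm(n))
    idx <- idx0 + seq_len(n)
    rows[[g]] <- tibble(
      subject = sprintf("sub-%03d", idx),
      group = factor(g, levels = alps_group_levels),
      sex = factor(ifelse(sex == 1, "male", "female"),
                   levels = c("female", "male")),
      age = age, education = edu, icv = icv,
      hypertension = as.integer(htn), hyperlipidemia = as.integer(hld),
      fazekas = as.integer(fz),
      homa_ir = homa, fpg = mk$fpg, ogtt_2h = mk$ogtt, hba1c = mk$hba1c,
      alps = alps_true
    )
    truths[[g]] <- tibble(
      subject = sprintf("sub-%03d", idx),
      group = factor(g, levels = alps_group_levels),
      alps_true = alps_true,
      dxx_proj = alps_true * ALPS_DIFF_SCALE,
      dxx_assoc = alps_true * ALPS_DIFF_SCALE,
      dyy_proj = ALPS_DIFF_SCALE,
      dzz_assoc = ALPS_DIFF_SCALE,
      seed = config$master_seed + idx
    )
    idx0 <- idx0 + n
  }
  cohort <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truths)
  relab <- classify_glycemic_status(cohort$fpg, cohort$ogtt_2h, cohort$hba1c)
  stopifnot(identical(as.character(relab), as.character(cohort$group)))
  structure(list(cohort = cohort, truth = truth, config = config,
                 coupling = cal),
            class = "alps_cohort")
}

# group-consistent glycemic marker draws; ranges avoid the uncovered
# bands between printed classes so labels are exact by construction
draw_markers <- function(n, g, cfg) {
  m <- function(p) cfg[[paste0(p, "_mean")]][[g]]
  s <- function(p) cfg[[paste0(p, "_sd")]][[g]]
  if (g == "NGM") {
    list(fpg = rtruncnorm(n, m("fpg"), s("fpg"), 60, 110),
         ogtt = rtruncnorm(n, m("ogtt"), s("ogtt"), 60, 140),
         hba1c = rtruncnorm(n, m("hba1c"), s("hba1c"), 4.0, 5.4))
  } else if (g == "Pre-DM") {
    # HbA1c pinned to the Pre-DM band guarantees the label; FPG and
    # OGTT stay below the T2DM thresholds but may sit in their NGM
    # range (as in the published cohort, where mean Pre-DM FPG is 99)
    list(fpg = rtruncnorm(n, m("fpg"), s("fpg"), 60, 125),
         ogtt = rtruncnorm(n, m("ogtt"), s("ogtt"), 60, 199),
         hba1c = rtruncnorm(n, m("hba1c"), s("hba1c"), 5.6, 6.0))
  } else {
    # HbA1c >= 6.1 alone makes the subject T2DM; the other markers are
    # free (gaps between printed classes avoided by redraw)
    list(fpg = rtrunc_gaps(n, m("fpg"), s("fpg"), 60, Inf,
                           gaps = list(c(125, 126))),
         ogtt = rtrunc_gaps(n, m("ogtt"), s("ogtt"), 60, Inf,
                            gaps = list(c(199, 200))),
         hba1c = rtruncnorm(n, m("hba1c"), s("hba1c"), 6.1, Inf))
  }
}

#' @export
print.alps_cohort <- function(x, ...) {
  cat(sprintf("<alps_cohort> %d subjects (%s), coupling c = %.3f\n",
              nrow(x$cohort),
              paste(x$config$group_sizes, collapse = "/"), x$coupling$c))
  invisible(x)
}

#' @export
as_tibble.alps_cohort <- function(x, ...) x$cohort
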