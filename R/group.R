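## Group-level statistical layer: linear mixed models relating cross-validated
## TRF prediction accuracy to age, language condition and feature timing
## statistics. Mixed models are fit with lme4; t tests use the Satterthwaite
## degrees-of-freedom approximation via lmerTest. Age is mean-centered and
## condition is contrast-coded (native = -0.5, non-native = +0.5) throughout.

condition_code <- function(condition) {
  cond <- as.character(condition)
  if (!all(cond %in% c("native", "nonnative")))
    stop("condition must be 'native' or 'nonnative'")
  ifelse(cond == "native", -0.5, +0.5)
}

lmm_table <- function(fit) {
  sm <- stats::coef(summary(fit))
  out <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"], df = sm[, "df"],
                    t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

quiet_lmer <- function(formula, data, REML = TRUE) {
  withCallingHandlers(
    suppressMessages(lmerTest::lmer(formula, data = data, REML = REML)),
    warning = function(w) {
      if (grepl("singular|converge|different scales", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

check_records <- function(records, feature_level = FALSE) {
  need <- c("participant", "age_months", "condition", "r_observed")
  if (feature_level)
    need <- c(need, "feature", "r_baseline", "duration_rank",
              "occurrence_rank")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  invisible(records)
}

#' Condition-by-age model of prediction accuracy
#'
#' Linear mixed model `r_observed ~ age * condition + (1 | participant)` with
#' age mean-centered and condition contrast-coded (native -0.5, non-native
#' +0.5). The interaction tests whether the developmental trajectory of
#' prediction accuracy is specific to the native language; simple slopes per
#' condition are obtained by refitting with the condition of interest at
#' code 0.
#'
#' @param records data.frame with columns `participant`, `age_months`,
#'   `condition` (`"native"`/`"nonnative"`), `r_observed` (one row per
#'   participant x condition).
#' @return List of class `trf_lmm`: `table` (term, estimate, se, df
#'   (Satterthwaite), t, p), `slopes` (simple age slope per condition),
#'   `model` (the `lmerMod`).
#' @export
fit_condition_age_model <- function(records) {
  check_records(records)
  if (length(unique(records$participant)) < 2)
    stop("need at least 2 participants for a participant random intercept")
  d <- records
  d$age_c <- d$age_months - mean(d$age_months)
  d$cond <- condition_code(d$condition)
  fit <- quiet_lmer(r_observed ~ age_c * cond + (1 | participant), d)
  slopes <- lapply(c(native = -0.5, nonnative = +0.5), function(code) {
    d2 <- d
    d2$cond <- d2$cond - code    # puts the condition of interest at 0
    f2 <- quiet_lmer(r_observed ~ age_c * cond + (1 | participant), d2)
    tb <- lmm_table(f2)
    tb[tb$term == "age_c", c("estimate", "se", "df", "t", "p")]
  })
  slopes <- do.call(rbind, slopes)
  slopes <- cbind(condition = rownames(slopes), slopes)
  rownames(slopes) <- NULL
  structure(list(table = lmm_table(fit), slopes = slopes, model = fit),
            class = "trf_lmm")
}

#' @exportS3Method base::print
print.trf_lmm <- function(x, ...) {
  cat("Linear mixed model (Satterthwaite df)\n")
  tb <- x$table
  tb$estimate <- signif(tb$estimate, 4); tb$se <- signif(tb$se, 3)
  tb$df <- round(tb$df, 1); tb$t <- round(tb$t, 2); tb$p <- signif(tb$p, 3)
  print(tb, row.names = FALSE)
  if (!is.null(x$slopes)) {
    cat("\nSimple age slopes:\n")
    print(x$slopes, row.names = FALSE)
  }
  if (!is.null(x$lrt)) {
    cat("\nModel comparison (ML likelihood ratio): chisq =",
        round(x$lrt$chisq, 2), "df =", x$lrt$df, "p =",
        signif(x$lrt$p, 3), "\n")
  }
  invisible(x)
}

#' Age at which a prediction-accuracy difference diverges from zero
#'
#' Per participant, the difference in accuracy between the native and
#' non-native conditions (`pairing = "condition"`), or between observed and
#' permutation-baseline accuracy in the native condition
#' (`pairing = "baseline"`), is regressed on age. The pointwise 95%
#' confidence interval of the fitted line (the CI of the conditional mean,
#' not a prediction interval) is evaluated on a 1-month grid over the
#' observed age range; the divergence age is the smallest grid age from which
#' the lower CI bound exceeds zero.
#'
#' @inheritParams fit_condition_age_model
#' @param pairing which difference to test.
#' @param level confidence level.
#' @param grid_step grid resolution, months.
#' @return Divergence age in months, or `NA` (with attribute
#'   `"status" = "none"`) when the CI never excludes zero. Attributes carry
#'   the grid, fit and CI.
#' @export
divergence_age <- function(records, pairing = c("condition", "baseline"),
                           level = 0.95, grid_step = 1) {
  pairing <- match.arg(pairing)
  check_records(records)
  if (pairing == "condition") {
    nat <- records[records$condition == "native", ]
    non <- records[records$condition == "nonnative", ]
    m <- merge(nat[, c("participant", "age_months", "r_observed")],
               non[, c("participant", "r_observed")],
               by = "participant", suffixes = c("_nat", "_non"))
    d <- data.frame(age = m$age_months,
                    diff = m$r_observed_nat - m$r_observed_non)
  } else {
    if (!"r_baseline" %in% names(records))
      stop("records lack column(s): r_baseline")
    nat <- records[records$condition == "native", ]
    d <- data.frame(age = nat$age_months,
                    diff = nat$r_observed - nat$r_baseline)
  }
  fit <- stats::lm(diff ~ age, data = d)
  grid <- seq(ceiling(min(d$age)), floor(max(d$age)), by = grid_step)
  ci <- stats::predict(fit, newdata = data.frame(age = grid),
                       interval = "confidence", level = level)
  above <- ci[, "lwr"] > 0
  out <- if (any(above)) grid[which(above)[1]] else NA_real_
  attr(out, "status") <- if (is.na(out)) "none" else "diverged"
  attr(out, "grid") <- grid
  attr(out, "ci") <- ci
  attr(out, "fit") <- fit
  out
}

#' Feature-timing model of per-feature acquisition
#'
#' Mixed model for the baseline-corrected per-feature accuracy
#' `(r_observed - r_baseline) ~ age * duration_rank + occurrence_rank +
#' (1 | feature) + (1 | participant)`. The age x duration-rank interaction
#' tests whether longer (higher-rank) features show steeper developmental
#' trajectories; occurrence rank controls for mere exposure.
#'
#' @param records feature-level data.frame: columns `participant`,
#'   `age_months`, `condition`, `feature`, `r_observed`, `r_baseline`,
#'   `duration_rank`, `occurrence_rank` (one row per participant x feature,
#'   native condition).
#' @return A `trf_lmm` (see [fit_condition_age_model()]).
#' @export
fit_feature_timing_model <- function(records) {
  check_records(records, feature_level = TRUE)
  d <- records[records$condition == "native", ]
  if (stats::var(d$duration_rank) == 0)
    stop("duration_rank is constant; ranks are collinear/degenerate")
  d$age_c <- d$age_months - mean(d$age_months)
  d$dr <- d$duration_rank
  d$acc_diff <- d$r_observed - d$r_baseline
  fit <- quiet_lmer(
    acc_diff ~ age_c * dr + occurrence_rank + (1 | feature) +
      (1 | participant), d)
  structure(list(table = lmm_table(fit), model = fit), class = "trf_lmm")
}

# variance inflation factors of the fixed effects (intercept dropped)
fixed_effect_vif <- function(fit) {
  X <- lme4::getME(fit, "X")
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / max(1 - r2, 1e-12)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Pitch-similarity extension of the feature-timing model
#'
#' Adds `age x pitch_similarity_rank` to the feature-timing model and
#' compares the two by a likelihood-ratio test on maximum-likelihood fits
#' (the standard requirement for LR tests on fixed effects). Variance
#' inflation factors of the fixed effects are reported so that a
#' duration/pitch dissociation can be judged against collinearity.
#'
#' @inheritParams fit_feature_timing_model
#' @param compare run the ML likelihood-ratio comparison (default TRUE).
#' @return A `trf_lmm` with elements `table`, `model`, `lrt` (chisq, df, p)
#'   and `vif`.
#' @export
fit_pitch_similarity_model <- function(records, compare = TRUE) {
  check_records(records, feature_level = TRUE)
  if (!"pitch_similarity_rank" %in% names(records))
    stop("records lack column(s): pitch_similarity_rank")
  d <- records[records$condition == "native", ]
  if (stats::var(d$duration_rank) == 0 ||
      stats::var(d$pitch_similarity_rank) == 0)
    stop("rank columns are constant; collinear/degenerate design")
  d$age_c <- d$age_months - mean(d$age_months)
  d$dr <- d$duration_rank
  d$pr <- d$pitch_similarity_rank
  d$acc_diff <- d$r_observed - d$r_baseline
  full <- quiet_lmer(
    acc_diff ~ age_c * dr + age_c * pr + occurrence_rank + (1 | feature) +
      (1 | participant), d)
  lrt <- NULL
  if (compare) {
    m0 <- quiet_lmer(
      acc_diff ~ age_c * dr + occurrence_rank + (1 | feature) +
        (1 | participant), d, REML = FALSE)
    m1 <- quiet_lmer(
      acc_diff ~ age_c * dr + age_c * pr + occurrence_rank + (1 | feature) +
        (1 | participant), d, REML = FALSE)
    an <- suppressMessages(stats::anova(m0, m1))
    chisq <- an$Chisq[2]
    df <- an$Df[2]
    p <- an[["Pr(>Chisq)"]][2]
    if (!is.finite(p)) {  # rank-deficient extension adds no information
      chisq <- 0; p <- 1
    }
    lrt <- list(chisq = chisq, df = df, p = p)
  }
  structure(list(table = lmm_table(full), model = full, lrt = lrt,
                 vif = fixed_effect_vif(full)),
            class = "trf_lmm")
}

#' Sex-balanced bootstrap CIs for age interactions
#'
#' Draws `n_boot` resamples of participants, each balanced between the sexes
#' (equal numbers of each sex, with replacement, totalling the original
#' sample size), refits the requested model including sex as a factor, and
#' collects the t values of every interaction term involving age and sex.
#' Returns percentile 95% CIs of the t values and the fraction of resamples
#' in which each term is significant at alpha = 0.05.
#'
#' @param records participant-level records (see
#'   [fit_condition_age_model()]); must contain a `sex` column with two
#'   levels (`"f"`/`"m"`).
#' @param model `"condition_age"` (r ~ age * condition * sex) or `"timing"`
#'   (feature-level, acc_diff ~ age * duration_rank * sex).
#' @param n_boot number of resamples.
#' @param seed RNG seed (results are reproducible given the seed).
#' @return data.frame: term, ci_lower, ci_upper (t-value percentiles),
#'   prop_significant.
#' @export
balanced_bootstrap_ci <- function(records, model = c("condition_age", "timing"),
                                  n_boot = 1000, seed = 1) {
  model <- match.arg(model)
  check_records(records, feature_level = model == "timing")
  if (!"sex" %in% names(records)) stop("records lack column(s): sex")
  set.seed(seed)
  ids <- unique(records[, c("participant", "sex")])
  sexes <- sort(unique(as.character(ids$sex)))
  if (length(sexes) != 2) stop("both sexes must be present")
  n_total <- nrow(ids)
  n_half <- round(n_total / 2)
  by_sex <- split(ids$participant, as.character(ids$sex))
  fit_one <- function(d) {
    d$age_c <- d$age_months - mean(d$age_months)
    d$sex_code <- ifelse(as.character(d$sex) == sexes[1], -0.5, 0.5)
    if (model == "condition_age") {
      d$cond <- condition_code(d$condition)
      f <- quiet_lmer(r_observed ~ age_c * cond * sex_code +
                        (1 | participant), d)
    } else {
      d <- d[d$condition == "native", ]
      d$acc_diff <- d$r_observed - d$r_baseline
      d$dr <- d$duration_rank
      f <- quiet_lmer(acc_diff ~ age_c * dr * sex_code + occurrence_rank +
                        (1 | feature) + (1 | participant), d)
    }
    tb <- lmm_table(f)
    tb[grepl("age_c", tb$term) & grepl("sex_code", tb$term), ]
  }
  draws <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    take <- c(sample(by_sex[[1]], n_half, replace = TRUE),
              sample(by_sex[[2]], n_total - n_half, replace = TRUE))
    res <- lapply(seq_along(take), function(k) {
      rows <- records[records$participant == take[k], , drop = FALSE]
      rows$participant <- paste0("bs", k)
      rows
    })
    tb <- tryCatch(fit_one(do.call(rbind, res)), error = function(e) NULL)
    draws[[b]] <- tb
  }
  draws <- draws[!vapply(draws, is.null, TRUE)]
  terms <- draws[[1]]$term
  out <- do.call(rbind, lapply(terms, function(tm) {
    tv <- vapply(draws, function(d) d$t[d$term == tm], numeric(1))
    pv <- vapply(draws, function(d) d$p[d$term == tm], numeric(1))
    data.frame(term = tm,
               ci_lower = unname(stats::quantile(tv, 0.025)),
               ci_upper = unname(stats::quantile(tv, 0.975)),
               prop_significant = mean(pv < 0.05),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare developmental shapes of the age effect
#'
#' Adds logarithmic, quadratic and cubic age terms (one at a time) to the
#' linear condition-by-age model and reports a likelihood-ratio test for
#' each addition (maximum-likelihood fits).
#'
#' @inheritParams fit_condition_age_model
#' @return data.frame: term added, chisq, df, p.
#' @export
compare_age_shapes <- function(records) {
  check_records(records)
  d <- records
  if (length(unique(d$age_months)) <= 2)
    stop("age must span more than 2 distinct values")
  d$age_c <- d$age_months - mean(d$age_months)
  d$cond <- condition_code(d$condition)
  d$age_log <- log(d$age_months)
  d$age_q <- d$age_c^2
  d$age_cu <- d$age_c^3
  base <- quiet_lmer(r_observed ~ age_c * cond + (1 | participant), d,
                     REML = FALSE)
  adds <- c(log = "age_log", quadratic = "age_q", cubic = "age_cu")
  out <- do.call(rbind, lapply(names(adds), function(nm) {
    f <- stats::as.formula(paste("r_observed ~ age_c * cond +", adds[[nm]],
                                 "+ (1 | participant)"))
    m1 <- quiet_lmer(f, d, REML = FALSE)
    an <- suppressMessages(stats::anova(base, m1))
    data.frame(term = nm, chisq = an$Chisq[2], df = an$Df[2],
               p = an[["Pr(>Chisq)"]][2], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
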