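#' Relative tumor volume (% of day-1 baseline)
#'
#' Adds `rel_volume = 100 * volume / volume(day 1)` per mouse. Mice without a
#' day-1 record are excluded with a warning. Day 1 itself is 100% by
#' construction.
#'
#' @param panel data frame with columns `model_id`, `arm`, `mouse_id`, `day`,
#'   `volume_mm3` (positive; `(model, arm, mouse, day)` unique).
#' @param baseline_day day defining the 100% baseline (default 1).
#' @return the panel with column `rel_volume` appended.
#' @export
relative_volume <- function(panel, baseline_day = 1L) {
  stopifnot(all(c("model_id", "arm", "mouse_id", "day", "volume_mm3") %in% names(panel)))
  if (any(panel$volume_mm3 <= 0)) {
    stop_kamdecon("tumor volumes must be positive", class = "kamdecon_validation_error")
  }
  key <- interaction(panel$model_id, panel$arm, panel$mouse_id, drop = TRUE)
  base_idx <- panel$day == baseline_day
  v0 <- stats::setNames(panel$volume_mm3[base_idx], as.character(key[base_idx]))
  missing <- !(as.character(key) %in% names(v0))
  if (any(missing)) {
    warning(sprintf("%d mice have no day-%d record and were excluded",
                    length(unique(key[missing])), baseline_day), call. = FALSE)
    panel <- panel[!missing, , drop = FALSE]
    key <- key[!missing]
  }
  panel$rel_volume <- 100 * panel$volume_mm3 / v0[as.character(key)]
  rownames(panel) <- NULL
  panel
}

#' Zero-normalize relative volumes against the vehicle arm
#'
#' For each model and time point, subtracts the mean relative volume of the
#' baseline (vehicle) arm, so the vehicle arm's adjusted mean is exactly 0 at
#' every (model, day). Time points where a model has no baseline records are
#' dropped for that model (recorded in attribute `dropped`). Applying the
#' normalization twice is a no-op.
#'
#' @param panel_rel output of [relative_volume()].
#' @param baseline_arm arm label of the control (default `"vehicle"`).
#' @return the panel with column `adjusted` appended.
#' @export
zero_normalize <- function(panel_rel, baseline_arm = "vehicle") {
  stopifnot("rel_volume" %in% names(panel_rel))
  base <- panel_rel[panel_rel$arm == baseline_arm, , drop = FALSE]
  if (!nrow(base)) {
    stop_kamdecon("no records for baseline arm '%s'", baseline_arm,
                  class = "kamdecon_configuration_error")
  }
  ref <- stats::aggregate(list(base_mean = base$rel_volume),
                          by = base[c("model_id", "day")], FUN = mean)
  m <- merge(panel_rel, ref, by = c("model_id", "day"), all.x = TRUE)
  dropped <- unique(m[is.na(m$base_mean), c("model_id", "day")])
  out <- m[!is.na(m$base_mean), , drop = FALSE]
  out$adjusted <- out$rel_volume - out$base_mean
  out$base_mean <- NULL
  out <- out[order(out$model_id, out$arm, out$mouse_id, out$day), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Standardized GLM effect size for a treatment-versus-baseline contrast
#'
#' Fits a Gaussian identity-link linear model of the zero-normalized response
#' on a treatment indicator plus a day term (and model-identifier indicators
#' when `scope = "combined"`), across all time points and mice of the two
#' arms. The effect size is the standardized coefficient of the treatment
#' indicator: response and every predictor are scaled by their standard
#' deviations before fitting, and the response is negated so that growth
#' inhibition yields a positive effect size. The p-value is the Wald test of
#' the treatment coefficient. Contrasts whose design is unusable (an arm empty
#' after dropout, or a single time point) are returned as not testable.
#'
#' @param panel_adjusted output of [zero_normalize()].
#' @param arm treatment arm to test.
#' @param baseline comparison arm (default `"vehicle"`; any arm label works,
#'   e.g. a single-agent arm to test a combination against it).
#' @param scope a single `model_id`, or `"combined"` to pool all models with
#'   fixed model-identifier terms.
#' @param include_day include the day main effect (default TRUE).
#' @return one-row data frame of class `effect_estimate`: `model_scope`,
#'   `arm`, `baseline`, `std_coefficient`, `p_raw`, `n_arm`, `n_baseline`,
#'   `not_testable`.
#' @export
glm_effect <- function(panel_adjusted, arm, baseline = "vehicle",
                       scope = "combined", include_day = TRUE) {
  stopifnot("adjusted" %in% names(panel_adjusted))
  dat <- panel_adjusted[panel_adjusted$arm %in% c(arm, baseline), , drop = FALSE]
  if (!identical(scope, "combined")) {
    dat <- dat[dat$model_id %in% scope, , drop = FALSE]
  }
  nt <- function() {
    structure(data.frame(model_scope = paste(scope, collapse = "+"), arm = arm,
                         baseline = baseline, std_coefficient = NA_real_,
                         p_raw = NA_real_,
                         n_arm = length(unique(dat$mouse_id[dat$arm == arm])),
                         n_baseline = length(unique(dat$mouse_id[dat$arm == baseline])),
                         not_testable = TRUE, stringsAsFactors = FALSE),
              class = c("effect_estimate", "data.frame"))
  }
  n_arm <- length(unique(interaction(dat$model_id, dat$mouse_id)[dat$arm == arm]))
  n_base <- length(unique(interaction(dat$model_id, dat$mouse_id)[dat$arm == baseline]))
  if (n_arm < 2 || n_base < 2 || length(unique(dat$day)) < 2) return(nt())
  zscale <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  y <- zscale(-dat$adjusted)  # negate: inhibition (lower volume) => positive effect
  treat <- zscale(as.numeric(dat$arm == arm))
  X <- data.frame(treat = treat)
  if (include_day) X$day <- zscale(dat$day)
  if (identical(scope, "combined") && length(unique(dat$model_id)) > 1L) {
    mm <- stats::model.matrix(~ model_id, data = dat)[, -1, drop = FALSE]
    for (j in seq_len(ncol(mm))) X[[paste0("m", j)]] <- zscale(mm[, j])
  }
  keep <- vapply(X, function(col) stats::sd(col) > 0, logical(1))
  X <- X[keep]
  if (!"treat" %in% names(X)) return(nt())
  fit <- stats::lm(y ~ ., data = X)
  sm <- summary(fit)$coefficients
  if (!"treat" %in% rownames(sm)) return(nt())
  structure(data.frame(model_scope = paste(scope, collapse = "+"), arm = arm,
                       baseline = baseline,
                       std_coefficient = sm["treat", "Estimate"],
                       p_raw = sm["treat", "Pr(>|t|)"],
                       n_arm = n_arm, n_baseline = n_base,
                       not_testable = FALSE, stringsAsFactors = FALSE),
            class = c("effect_estimate", "data.frame"))
}

#' Benjamini-Hochberg FDR correction over a family of effect estimates
#'
#' Step-up BH adjustment of the raw GLM p-values across all contrasts of one
#' analysis run. Not-testable contrasts are left `NA` and do not count toward
#' the family size.
#'
#' @param estimates data frame of stacked [glm_effect()] rows (or any data
#'   frame with a `p_raw` column).
#' @return the input with column `p_fdr` appended.
#' @export
fdr_correct <- function(estimates) {
  stopifnot("p_raw" %in% names(estimates))
  estimates$p_fdr <- stats::p.adjust(estimates$p_raw, method = "BH")
  estimates
}

#' Per-time-point t-tests between treatment arms
#'
#' Two-sided equal-variance t-tests on relative volumes at each measurement
#' day for each requested arm pair. Days where either arm has fewer than 2
#' mice remaining (e.g. all mice of an arm culled for tumor size) are marked
#' not available (`NA`), mirroring the "X" convention of growth-curve p-value
#' tracks.
#'
#' @param panel_rel output of [relative_volume()] (single model, or pre-filter
#'   by model).
#' @param arm_pairs list of length-2 character vectors of arm labels.
#' @param days days to test; defaults to all days present in either arm.
#' @return numeric matrix of p-values, rows `armA vs armB`, columns days.
#' @export
timepoint_tests <- function(panel_rel, arm_pairs, days = NULL) {
  stopifnot("rel_volume" %in% names(panel_rel))
  if (!is.list(arm_pairs)) arm_pairs <- list(arm_pairs)
  days <- days %||% sort(unique(panel_rel$day))
  out <- matrix(NA_real_, length(arm_pairs), length(days),
                dimnames = list(vapply(arm_pairs, paste, "", collapse = " vs "),
                                as.character(days)))
  for (i in seq_along(arm_pairs)) {
    a <- arm_pairs[[i]][1]; b <- arm_pairs[[i]][2]
    for (j in seq_along(days)) {
      xa <- panel_rel$rel_volume[panel_rel$arm == a & panel_rel$day == days[j]]
      xb <- panel_rel$rel_volume[panel_rel$arm == b & panel_rel$day == days[j]]
      if (length(xa) >= 2 && length(xb) >= 2) out[i, j] <- ttest_p(xa, xb)
    }
  }
  out
}

#' Waterfall summary of per-tumor volume changes
#'
#' Compares each tumor's final volume (default day 21) to its starting volume
#' (day 1): the displayed relative change `100 * V(final) / V(1)` is capped at
#' 200% (twofold the starting volume). A tumor counts as regressing versus
#' day 1 when its final volume is below the day-1 volume, and versus
#' mid-treatment (default day 10) when below the mid-treatment volume.
#' Tumors without a final-day record are excluded (attribute `excluded`);
#' a missing mid-day gives an `NA` flag.
#'
#' @param panel a trajectory panel (raw volumes).
#' @param final_day,mid_day measurement days used for the comparison.
#' @param cap display cap in percent (default 200).
#' @return list of class `waterfall_summary`: `tumors` (per-tumor table with
#'   `rel_change` displayed value, `rel_change_uncapped`, `regressed_vs_d1`,
#'   `regressed_vs_mid`) and `arms` (per model/arm percent regressing vs
#'   day 1, vs mid-day, and vs either).
#' @export
waterfall <- function(panel, final_day = 21L, mid_day = 10L, cap = 200) {
  key <- c("model_id", "arm", "mouse_id")
  pick <- function(day) {
    sub <- panel[panel$day == day, c(key, "volume_mm3")]
    names(sub)[4] <- paste0("v", day)
    sub
  }
  d1 <- pick(1L)
  df <- merge(d1, pick(final_day), by = key)
  excluded <- merge(d1, pick(final_day), by = key, all.x = TRUE)
  excluded <- excluded[is.na(excluded[[paste0("v", final_day)]]), key]
  df <- merge(df, pick(mid_day), by = key, all.x = TRUE)
  vf <- df[[paste0("v", final_day)]]
  vm <- df[[paste0("v", mid_day)]]
  df$rel_change_uncapped <- 100 * vf / df$v1
  df$rel_change <- pmin(df$rel_change_uncapped, cap)
  df$regressed_vs_d1 <- vf < df$v1
  df$regressed_vs_mid <- ifelse(is.na(vm), NA, vf < vm)
  pct <- function(x) 100 * mean(x, na.rm = TRUE)
  arms <- do.call(rbind, lapply(split(df, df[c("model_id", "arm")], drop = TRUE),
    function(g) data.frame(model_id = g$model_id[1], arm = g$arm[1],
                           n_tumors = nrow(g),
                           pct_regressing_d1 = pct(g$regressed_vs_d1),
                           pct_regressing_mid = pct(g$regressed_vs_mid),
                           pct_regressing_any = pct(g$regressed_vs_d1 |
                                                      (!is.na(g$regressed_vs_mid) &
                                                         g$regressed_vs_mid)),
                           stringsAsFactors = FALSE)))
  rownames(arms) <- NULL
  structure(list(tumors = df, arms = arms, final_day = final_day,
                 mid_day = mid_day, cap = cap, excluded = excluded),
            class = "waterfall_summary")
}
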