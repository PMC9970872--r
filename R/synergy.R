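#' Estimate the GI50 of a single-agent dose-response curve
#'
#' GI50 is the drug concentration giving 50% growth inhibition in the 3-day
#' viability assay, i.e. the dose where surviving fraction crosses 0.5.
#' Curves come from 2-fold serial dilutions spanning at least 0.125x to 8x the
#' GI50. The default estimator interpolates linearly in log-concentration
#' between the two measured doses bracketing 0.5; `method = "hill"` instead
#' fits a 4-parameter logistic by least squares and solves it for 0.5.
#'
#' @param conc non-negative concentrations (any consistent unit).
#' @param viability surviving fractions relative to untreated (untreated = 1).
#'   Replicates are averaged per dose before estimation.
#' @param method `"log_linear_interpolation"` (default) or `"hill_fit"`
#'   (`"interpolation"` / `"hill"` accepted as shorthands).
#' @return list of class `gi50_fit`: `gi50`, `method`, `bracket` (the two doses
#'   used for interpolation) and, for the Hill fit, the fitted parameters.
#' @examples
#' d <- 2 ^ (-3:3)                 # 2-fold ladder around GI50 = 1
#' estimate_gi50(d, 1 / (1 + d))$gi50
#' @export
estimate_gi50 <- function(conc, viability,
                          method = c("log_linear_interpolation", "hill_fit",
                                     "interpolation", "hill")) {
  method <- match.arg(method)
  method <- unname(c(log_linear_interpolation = "log_linear_interpolation",
                     interpolation = "log_linear_interpolation",
                     hill_fit = "hill_fit", hill = "hill_fit")[method])
  stopifnot(length(conc) == length(viability), all(conc >= 0))
  curve <- stats::aggregate(list(viability = viability),
                            by = list(conc = conc), FUN = mean)
  curve <- curve[curve$conc > 0, , drop = FALSE]
  curve <- curve[order(curve$conc), ]
  if (nrow(curve) < 2L || min(curve$viability) > 0.5 || max(curve$viability) < 0.5) {
    stop_kamdecon("GI50 not bracketed: curve does not cross viability 0.5",
                  class = "kamdecon_gi50_error")
  }
  hit <- which(abs(curve$viability - 0.5) < 1e-12)
  if (length(hit)) {
    g <- curve$conc[hit[1L]]
    bracket <- rep(g, 2L)
  } else {
    cross <- which(diff(sign(curve$viability - 0.5)) != 0)
    if (!length(cross)) {
      stop_kamdecon("GI50 not bracketed: curve does not cross viability 0.5",
                    class = "kamdecon_gi50_error")
    }
    i <- cross[1L]
    x <- log10(curve$conc[i + 0:1])
    y <- curve$viability[i + 0:1]
    g <- 10 ^ (x[1] + (0.5 - y[1]) * diff(x) / diff(y))
    bracket <- curve$conc[i + 0:1]
  }
  fit <- list(gi50 = g, method = method, bracket = bracket)
  if (method == "hill_fit") {
    # 4-parameter logistic E = lower + (upper - lower) / (1 + (d / g)^h),
    # least squares over all (conc, viability) points with conc > 0
    sse <- function(par) {
      lower <- par[1]; upper <- par[2]; lg <- par[3]; h <- exp(par[4])
      pred <- lower + (upper - lower) / (1 + (curve$conc / exp(lg))^h)
      sum((pred - curve$viability)^2)
    }
    opt <- stats::optim(c(min(curve$viability), max(curve$viability), log(g), 0),
                        sse, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    lower <- opt$par[1]; upper <- opt$par[2]
    g_fit <- exp(opt$par[3]); h <- exp(opt$par[4])
    if (lower < 0.5 && upper > 0.5) {
      # solve lower + (upper-lower)/(1+(d/g)^h) = 0.5
      ratio <- (upper - lower) / (0.5 - lower) - 1
      fit$gi50 <- g_fit * ratio^(1 / h)
    }
    fit$hill <- list(lower = lower, upper = upper, inflection = g_fit, slope = h)
  }
  structure(fit, class = "gi50_fit")
}

floor_effects <- function(e, floor, what) {
  if (any(e < 0, na.rm = TRUE)) {
    stop_kamdecon("%s contains negative surviving fractions", what,
                  class = "kamdecon_domain_error")
  }
  n <- sum(e < floor, na.rm = TRUE)
  list(e = pmax(e, floor), n_floored = n)
}

#' Bliss combination index for a drug pair
#'
#' The Bliss independence null for two non-interacting drugs is that the
#' combined surviving fraction equals the product of the single-agent
#' surviving fractions. The combination index is
#' `CI = -log2(E_AB / (E_A * E_B))`: CI > 0 synergy, CI = 0 additivity,
#' CI < 0 antagonism. Surviving fractions below `floor` (default 1e-3) are
#' floored before the log to avoid infinities from fully killed wells; the
#' number floored is recorded in attribute `n_floored`. Negative fractions are
#' a domain error.
#'
#' @param e_a,e_b single-agent surviving fractions at the paired doses.
#' @param e_ab combined surviving fraction at those doses.
#' @param floor lower floor applied to all fractions before the log.
#' @return numeric CI (vectorized), attribute `n_floored`.
#' @examples
#' bliss_ci_pair(0.5, 0.5, 0.25)   # additive: CI = 0
#' bliss_ci_pair(0.5, 0.5, 0.125)  # synergy:  CI = 1
#' @export
bliss_ci_pair <- function(e_a, e_b, e_ab, floor = 1e-3) {
  fa <- floor_effects(e_a, floor, "e_a")
  fb <- floor_effects(e_b, floor, "e_b")
  fab <- floor_effects(e_ab, floor, "e_ab")
  ci <- -log2(fab$e / (fa$e * fb$e))
  ci <- ci + 0  # normalize IEEE -0 at exact independence
  attr(ci, "n_floored") <- fa$n_floored + fb$n_floored + fab$n_floored
  ci
}

#' Bliss combination index for a triple regimen against the two-drug null
#'
#' Scores the three-drug combination (A + B plus a third drug C held at its
#' cell-line-specific GI50) against the two-drug Bliss product:
#' `CI = -log2(E_ABC / (E_A * E_B))`. A Bliss-independent third drug that
#' halves survival on its own therefore contributes CI = 1 at every (A, B)
#' point.
#'
#' @param e_a,e_b single-agent surviving fractions of drugs A and B.
#' @param e_abc surviving fraction of the triple combination at the same A and
#'   B doses, with C fixed at its GI50.
#' @inheritParams bliss_ci_pair
#' @return numeric CI (vectorized), attribute `n_floored`.
#' @export
bliss_ci_triple <- function(e_a, e_b, e_abc, floor = 1e-3) {
  bliss_ci_pair(e_a, e_b, e_abc, floor = floor)
}

classify_ci <- function(ci, additive_tol = 0.1) {
  ifelse(abs(ci) <= additive_tol, "additive",
         ifelse(ci > 0, "synergistic", "antagonistic"))
}

match_dose <- function(nominal, measured, tol_factor = 1.25) {
  # nearest measured dose within a factor tol_factor of the nominal dose
  measured <- measured[measured > 0]
  if (!length(measured)) return(NA_real_)
  ratio <- exp(abs(log(measured / nominal)))
  i <- which.min(ratio)
  if (ratio[i] <= tol_factor) measured[i] else NA_real_
}

#' Grid combination-index scoring around the drugs' GI50s
#'
#' Computes per-point Bliss CIs over the 3 x 3 grid of doses at 0.5x, 1x and
#' 2x each drug's GI50 (9 points, the default design) or over the extended
#' GI25-GI75 window: every measured combination point whose single-agent
#' surviving fractions both lie in `[0.25, 0.75]` (12-20 points in the assay
#' designs this mirrors). Measured doses within a factor 1.25 of the nominal
#' grid dose are accepted as that grid cell. The summary CI is the unweighted
#' arithmetic mean of the per-point CIs, and the combination is classified
#' synergistic / additive / antagonistic with an additivity band of
#' `|CI| <= additive_tol`.
#'
#' @param surface data frame with columns `conc_a`, `conc_b`, `viability` and
#'   optionally `conc_c` (for triple designs) and `replicate`. Rows with one
#'   drug at dose 0 are the single-agent anchors; `conc_a = conc_b = 0` is the
#'   untreated control.
#' @param gi50_a,gi50_b GI50s of drugs A and B (e.g. from [estimate_gi50()]).
#' @param levels multiples of GI50 forming the default grid.
#' @param window `"default"` (GI50-anchored grid) or `"gi25_gi75"`.
#' @param design `"pair"` or `"triple"`; a triple design reads combination
#'   viabilities from rows with `conc_c > 0` but keeps the two-drug Bliss null.
#' @param additive_tol half-width of the additive classification band.
#' @param floor surviving-fraction floor, see [bliss_ci_pair()].
#' @return list of class `ci_result`: `points` (per-point table with doses and
#'   CI), `mean_ci`, `n_points`, `classification`, `window`.
#' @export
ci_grid <- function(surface, gi50_a, gi50_b, levels = c(0.5, 1, 2),
                    window = c("default", "gi25_gi75"),
                    design = c("pair", "triple"),
                    additive_tol = 0.1, floor = 1e-3) {
  window <- match.arg(window)
  design <- match.arg(design)
  stopifnot(all(c("conc_a", "conc_b", "viability") %in% names(surface)))
  if (!"conc_c" %in% names(surface)) surface$conc_c <- 0
  singles_a <- surface[surface$conc_a > 0 & surface$conc_b == 0 & surface$conc_c == 0, ]
  singles_b <- surface[surface$conc_b > 0 & surface$conc_a == 0 & surface$conc_c == 0, ]
  combos <- if (design == "pair") {
    surface[surface$conc_a > 0 & surface$conc_b > 0 & surface$conc_c == 0, ]
  } else {
    surface[surface$conc_a > 0 & surface$conc_b > 0 & surface$conc_c > 0, ]
  }
  e_single_a <- function(d) mean(singles_a$viability[singles_a$conc_a == d])
  e_single_b <- function(d) mean(singles_b$viability[singles_b$conc_b == d])

  if (window == "default") {
    cells <- expand.grid(level_a = levels, level_b = levels)
    cells$dose_a <- vapply(cells$level_a * gi50_a, match_dose,
                           numeric(1), measured = unique(singles_a$conc_a))
    cells$dose_b <- vapply(cells$level_b * gi50_b, match_dose,
                           numeric(1), measured = unique(singles_b$conc_b))
    has_combo <- function(da, db) {
      any(combos$conc_a == da & combos$conc_b == db)
    }
    cells$usable <- !is.na(cells$dose_a) & !is.na(cells$dose_b) &
      mapply(function(a, b) if (is.na(a) || is.na(b)) FALSE else has_combo(a, b),
             cells$dose_a, cells$dose_b)
    if (sum(cells$usable) < length(levels)^2) {
      miss <- cells[!cells$usable, ]
      stop_kamdecon(
        "default CI grid incomplete; missing cells at (levels of GI50): %s",
        paste(sprintf("(%gx, %gx)", miss$level_a, miss$level_b), collapse = " "),
        class = "kamdecon_grid_error")
    }
    cells <- cells[cells$usable, ]
  } else {
    cells <- unique(combos[c("conc_a", "conc_b")])
    names(cells) <- c("dose_a", "dose_b")
    ea <- vapply(cells$dose_a, e_single_a, numeric(1))
    eb <- vapply(cells$dose_b, e_single_b, numeric(1))
    keep <- is.finite(ea) & is.finite(eb) &
      ea >= 0.25 & ea <= 0.75 & eb >= 0.25 & eb <= 0.75
    cells <- cells[keep, , drop = FALSE]
    if (!nrow(cells)) {
      stop_kamdecon("no combination points with both single-agent effects in [GI25, GI75]",
                    class = "kamdecon_grid_error")
    }
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    da <- cells$dose_a[i]; db <- cells$dose_b[i]
    ea <- e_single_a(da); eb <- e_single_b(db)
    eab <- mean(combos$viability[combos$conc_a == da & combos$conc_b == db])
    data.frame(dose_a = da, dose_b = db, e_a = ea, e_b = eb, e_combo = eab,
               ci = as.numeric(bliss_ci_pair(ea, eb, eab, floor = floor)))
  }))
  mean_ci <- mean(pts$ci)
  structure(list(points = pts,
                 mean_ci = mean_ci,
                 n_points = nrow(pts),
                 classification = classify_ci(mean_ci, additive_tol),
                 window = window,
                 design = design),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("Bliss CI (%s design, %s window): mean CI = %.3f over %d points [%s]\n",
              x$design, x$window, x$mean_ci, x$n_points, x$classification))
  invisible(x)
}

#' Fold change in drug sensitivity from paired dose-response curves
#'
#' Log2 shift in GI50 when a modifier (second drug, ligand, knockdown...) is
#' present: `log2(GI50_alone / GI50_with_modifier)`. Positive values mean the
#' modifier sensitizes (left-shifts the curve); negative values mean induced
#' resistance. The alternative `"viability_ratio"` measure is
#' `log2(viability_alone / viability_with_modifier)` at the unmodified curve's
#' GI50 dose.
#'
#' @param conc_alone,viab_alone the single-agent dose-response curve.
#' @param conc_mod,viab_mod the curve in the presence of the modifier.
#' @param measure `"gi50_ratio"` (default) or `"viability_ratio"`.
#' @param method GI50 estimation method passed to [estimate_gi50()].
#' @return a single log2 fold change.
#' @export
fold_change_sensitivity <- function(conc_alone, viab_alone, conc_mod, viab_mod,
                                    measure = c("gi50_ratio", "viability_ratio"),
                                    method = "log_linear_interpolation") {
  measure <- match.arg(measure)
  g_alone <- estimate_gi50(conc_alone, viab_alone, method = method)$gi50
  if (measure == "gi50_ratio") {
    g_mod <- estimate_gi50(conc_mod, viab_mod, method = method)$gi50
    return(log2(g_alone / g_mod))
  }
  # viability at the unmodified GI50 dose, interpolated on each curve
  interp <- function(conc, viab, d) {
    o <- order(conc)
    stats::approx(log10(conc[o][conc[o] > 0]), viab[o][conc[o] > 0],
                  xout = log10(d), rule = 2)$y
  }
  log2(interp(conc_alone, viab_alone, g_alone) /
         interp(conc_mod, viab_mod, g_alone))
}
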