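#' Relative expression by the 2^(-ddCt) method with dual housekeeping controls
#'
#' For each (cell line, arm, target gene): `dCt = mean Ct(target) - mean of the
#' housekeeping genes' Cts` (arithmetic mean of the two reference genes,
#' equivalent to the geometric mean of their quantities); `ddCt = dCt(arm) -
#' dCt(calibrator arm)`; `rel_level = 2^(-ddCt)`. The calibrator arm's level is
#' 1 by construction. Targets whose mean Ct exceeds `na_cutoff` (default 35
#' cycles) are flagged unavailable. Per-replicate relative levels (replicate
#' Ct against the same replicate's housekeeping mean where present) are kept
#' in attribute `replicate_levels` for downstream t-tests.
#'
#' @param ct data frame with columns `cell_line`, `gene`, `gene_role`
#'   (`"target"` / `"housekeeping"`), `arm`, `replicate`, `ct`.
#' @param calibrator_arm arm whose dCt anchors ddCt (e.g. `"VEM"`).
#' @param housekeeping character vector of reference gene names (default
#'   `c("ACTB", "UBC")`); all must be present per (cell line, arm).
#' @param na_cutoff detection cutoff in cycles.
#' @return data frame of class `relative_expression` with columns `cell_line`,
#'   `gene`, `arm`, `delta_ct`, `ddct`, `rel_level`, `available`.
#' @examples
#' tbl <- simulate_ct_table(ct_sim_spec(seed = 1))
#' head(ddct(tbl, calibrator_arm = "VEM"))
#' @export
ddct <- function(ct, calibrator_arm, housekeeping = c("ACTB", "UBC"),
                 na_cutoff = 35) {
  stopifnot(all(c("cell_line", "gene", "gene_role", "arm", "replicate", "ct") %in%
                  names(ct)))
  hk <- ct[ct$gene %in% housekeeping, , drop = FALSE]
  targets <- ct[ct$gene_role == "target", , drop = FALSE]
  blocks <- unique(ct[c("cell_line", "arm")])
  for (i in seq_len(nrow(blocks))) {
    present <- unique(hk$gene[hk$cell_line == blocks$cell_line[i] &
                                hk$arm == blocks$arm[i]])
    if (!all(housekeeping %in% present)) {
      stop_kamdecon("missing housekeeping gene(s) %s for cell line %s, arm %s",
                    paste(setdiff(housekeeping, present), collapse = ", "),
                    blocks$cell_line[i], blocks$arm[i],
                    class = "kamdecon_configuration_error")
    }
  }
  # housekeeping reference per (cell_line, arm): mean of per-gene mean Cts
  hk_gene <- stats::aggregate(list(ct = hk$ct),
                              by = hk[c("cell_line", "arm", "gene")], FUN = mean)
  hk_ref <- stats::aggregate(list(hk_ct = hk_gene$ct),
                             by = hk_gene[c("cell_line", "arm")], FUN = mean)
  # per-replicate housekeeping mean, falling back to the block reference
  hk_rep <- stats::aggregate(list(hk_ct_rep = hk$ct),
                             by = hk[c("cell_line", "arm", "replicate")], FUN = mean)

  tmean <- stats::aggregate(list(ct = targets$ct),
                            by = targets[c("cell_line", "gene", "arm")], FUN = mean)
  tmean <- merge(tmean, hk_ref, by = c("cell_line", "arm"))
  tmean$delta_ct <- tmean$ct - tmean$hk_ct
  cal <- tmean[tmean$arm == calibrator_arm, c("cell_line", "gene", "delta_ct")]
  if (!nrow(cal)) {
    stop_kamdecon("calibrator arm '%s' not found", calibrator_arm,
                  class = "kamdecon_configuration_error")
  }
  names(cal)[3] <- "cal_delta_ct"
  tmean <- merge(tmean, cal, by = c("cell_line", "gene"), all.x = TRUE)
  tmean$ddct <- tmean$delta_ct - tmean$cal_delta_ct
  tmean$rel_level <- 2 ^ (-tmean$ddct)
  tmean$available <- tmean$ct <= na_cutoff
  tmean$rel_level[!tmean$available] <- NA_real_

  reps <- merge(targets, hk_rep, by = c("cell_line", "arm", "replicate"), all.x = TRUE)
  reps <- merge(reps, hk_ref, by = c("cell_line", "arm"))
  reps$hk_use <- ifelse(is.na(reps$hk_ct_rep), reps$hk_ct, reps$hk_ct_rep)
  reps <- merge(reps, cal, by = c("cell_line", "gene"), all.x = TRUE)
  reps$rel_level <- 2 ^ (-((reps$ct - reps$hk_use) - reps$cal_delta_ct))
  reps <- reps[order(reps$cell_line, reps$gene, reps$arm, reps$replicate),
               c("cell_line", "gene", "arm", "replicate", "rel_level")]
  rownames(reps) <- NULL

  out <- tmean[order(tmean$cell_line, tmean$gene, tmean$arm),
               c("cell_line", "gene", "arm", "delta_ct", "ddct", "rel_level",
                 "available")]
  rownames(out) <- NULL
  structure(out, class = c("relative_expression", "data.frame"),
            calibrator_arm = calibrator_arm, replicate_levels = reps)
}

#' Fold change against the mean expression across treatment arms
#'
#' For each (cell line, gene), divides each arm's relative level by the mean
#' relative level over the given arms. If any of the arms is unavailable, all
#' folds for that (cell line, gene) propagate to `NA`.
#'
#' @param rel a [ddct()] result.
#' @param arms the arms whose mean anchors the fold (default the three arms
#'   present, in the order of appearance).
#' @return data frame with columns `cell_line`, `gene`, `arm`,
#'   `fold_vs_arm_mean`.
#' @export
fold_vs_arm_mean <- function(rel, arms = NULL) {
  arms <- arms %||% unique(rel$arm)
  sub <- rel[rel$arm %in% arms, , drop = FALSE]
  parts <- split(sub, sub[c("cell_line", "gene")], drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(g) {
    lv <- g$rel_level[match(arms, g$arm)]
    fold <- if (length(lv) < length(arms) || anyNA(lv)) rep(NA_real_, nrow(g))
            else g$rel_level / mean(lv)
    data.frame(cell_line = g$cell_line, gene = g$gene, arm = g$arm,
               fold_vs_arm_mean = fold, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cell_line, out$gene, out$arm), ]
  rownames(out) <- NULL
  out
}

#' Proportion of measurements where a test arm expresses lower
#'
#' Percentage of available (cell line x comparator arm) measurements in which
#' the test arm's relative level is strictly lower than the comparator's
#' (ties count as not lower). Unavailable levels are excluded from both
#' numerator and denominator. Computed per gene by default; `per_gene = FALSE`
#' pools all genes into one percentage.
#'
#' @param rel a [ddct()] result spanning multiple cell lines.
#' @param test_arm arm being scored (e.g. `"VEM+DAS"`).
#' @param comparators arms compared against (e.g. `c("VEM", "VEM+GEF")`).
#' @param per_gene report one percentage per gene (default) or pooled.
#' @return data frame with columns `gene` (unless pooled), `percent_lower`,
#'   `n_lower`, `n_total`; zero available comparisons gives `NA`.
#' @export
proportion_lower <- function(rel, test_arm, comparators, per_gene = TRUE) {
  count_gene <- function(g) {
    n_lower <- 0L; n_total <- 0L
    for (cl in unique(g$cell_line)) {
      t_lv <- g$rel_level[g$cell_line == cl & g$arm == test_arm]
      if (!length(t_lv) || is.na(t_lv[1])) next
      for (cmp in comparators) {
        c_lv <- g$rel_level[g$cell_line == cl & g$arm == cmp]
        if (!length(c_lv) || is.na(c_lv[1])) next
        n_total <- n_total + 1L
        if (t_lv[1] < c_lv[1]) n_lower <- n_lower + 1L
      }
    }
    data.frame(percent_lower = if (n_total) 100 * n_lower / n_total else NA_real_,
               n_lower = n_lower, n_total = n_total)
  }
  if (per_gene) {
    genes <- sort(unique(rel$gene))
    out <- do.call(rbind, lapply(genes, function(gn) {
      cbind(gene = gn, count_gene(rel[rel$gene == gn, , drop = FALSE]),
            stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  } else {
    count_gene(rel)
  }
}

#' Equal-variance t-test on relative expression between two arms
#'
#' Two-sample two-tailed pooled-variance t-test on per-replicate relative
#' levels of one gene in one cell line (or on per-cell-line levels when
#' comparing across lines). Fewer than 2 observations per arm gives `NA` with
#' a warning; degenerate (zero-variance) data follow the package-wide
#' conventions.
#'
#' @param rel a [ddct()] result.
#' @param gene,cell_line the measurement to test; `cell_line = NULL` pools the
#'   arm-level summaries across cell lines.
#' @param arms length-2 character vector, test arm first.
#' @return a single p-value (or `NA`).
#' @export
expression_ttest <- function(rel, gene, arms, cell_line = NULL) {
  stopifnot(length(arms) == 2L)
  if (is.null(cell_line)) {
    x <- rel$rel_level[rel$gene == gene & rel$arm == arms[1]]
    y <- rel$rel_level[rel$gene == gene & rel$arm == arms[2]]
  } else {
    reps <- attr(rel, "replicate_levels")
    x <- reps$rel_level[reps$cell_line == cell_line & reps$gene == gene &
                          reps$arm == arms[1]]
    y <- reps$rel_level[reps$cell_line == cell_line & reps$gene == gene &
                          reps$arm == arms[2]]
  }
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    warning("fewer than 2 observations per arm; p-value not computable",
            call. = FALSE)
    return(NA_real_)
  }
  ttest_p(x, y)
}
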