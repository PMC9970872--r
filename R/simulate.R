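#' Random peptide-to-kinase incidence map
#'
#' Draws a many-to-many map in which each kinase targets a random subset of
#' the biological peptides. Y/S/T-free peptides (no phosphorylatable residue)
#' are never assigned to a kinase.
#'
#' @param layout a [plate_layout()].
#' @param n_kinases number of kinases/families to generate.
#' @param peptides_per_kinase integer range (length 2) of subset sizes.
#' @param seed RNG seed.
#' @return a [peptide_kinase_map()].
#' @export
simulate_kinase_map <- function(layout = plate_layout(), n_kinases = 40L,
                                peptides_per_kinase = c(3L, 12L), seed = 1L) {
  set.seed(seed)
  pool <- setdiff(layout$peptide_ids, layout$ystf_free_ids)
  entries <- lapply(seq_len(n_kinases), function(i) {
    n <- sample(seq(peptides_per_kinase[1], peptides_per_kinase[2]), 1L)
    data.frame(peptide_id = sample(pool, n),
               kinase_id = sprintf("KIN%02d", i), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, entries)
  peptide_kinase_map(df$peptide_id, df$kinase_id)
}

#' Specification for a simulated kinase-activity plate experiment
#'
#' Defines the ground truth of one simulated assay condition: each kinase in
#' `true_kinase_activity` adds its activity (nM ATP consumed) to every peptide
#' it maps to, on top of a flat baseline consumption, with Gaussian well noise.
#' The invariant `baseline + total activity + 3 * noise_sd <= atp0` keeps
#' consumption inside the assay's dynamic range with high probability.
#'
#' @param layout a [plate_layout()].
#' @param map a [peptide_kinase_map()].
#' @param true_kinase_activity named numeric vector, nM added per mapped
#'   peptide per kinase (empty = flat control condition).
#' @param baseline_consumption background ATP consumption in nM (default 20).
#' @param noise_sd Gaussian well noise in nM (default 1).
#' @param n_bio_reps,n_tech_reps replicate structure (one plate per replicate).
#' @param sample_id,treatment labels stamped on every well.
#' @param seed RNG seed; a fixed seed reproduces the output exactly.
#' @return list of class `plate_sim_spec`.
#' @export
plate_sim_spec <- function(layout = plate_layout(), map = simulate_kinase_map(layout),
                           true_kinase_activity = numeric(0),
                           baseline_consumption = 20, noise_sd = 1,
                           n_bio_reps = 1L, n_tech_reps = 1L,
                           sample_id = "sample1", treatment = "UNT", seed = 1L) {
  peak <- baseline_consumption + sum(abs(true_kinase_activity)) + 3 * noise_sd
  if (peak > layout$atp0_nM) {
    stop_kamdecon(
      "simulated consumption (baseline + activities + 3 sd = %.1f nM) exceeds atp0 = %g nM",
      peak, layout$atp0_nM, class = "kamdecon_sim_spec_error")
  }
  if (length(true_kinase_activity) && is.null(names(true_kinase_activity))) {
    stop_kamdecon("true_kinase_activity must be a named vector",
                  class = "kamdecon_sim_spec_error")
  }
  structure(list(layout = layout, map = map,
                 true_kinase_activity = true_kinase_activity,
                 baseline_consumption = baseline_consumption,
                 noise_sd = noise_sd, n_bio_reps = as.integer(n_bio_reps),
                 n_tech_reps = as.integer(n_tech_reps),
                 sample_id = sample_id, treatment = treatment,
                 seed = as.integer(seed)),
            class = "plate_sim_spec")
}

well_addresses <- function(n) {
  grid <- expand.grid(col = 1:24, row = LETTERS[1:16])
  paste0(grid$row, grid$col)[seq_len(n)]
}

#' Simulate kinase-activity assay plates with known ground truth
#'
#' Generates one plate per (biological, technical) replicate: the layout's
#' biological peptides (Y/S/T-free and reference peptides carried as tagged
#' well classes), peptide-free controls, plus 4 blank (0 nM ATP) and 4
#' full-ATP calibration wells. Well consumption is `baseline + sum of mapped
#' kinase activities + N(0, noise_sd)`, clipped to `[0, atp0]`; Y/S/T-free
#' peptides and peptide-free controls receive baseline only. RLU values are
#' produced by inverting a two-point affine calibration so that
#' [luminescence_to_atp()] recovers the consumption exactly. The true
#' per-peptide consumption (noiseless) is attached as attribute
#' `ground_truth`.
#'
#' @param spec a [plate_sim_spec()].
#' @return a `plate_table` covering all replicates of the condition.
#' @export
simulate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  set.seed(spec$seed)
  layout <- spec$layout
  atp0 <- layout$atp0_nM
  pep_ids <- layout$peptide_ids
  pep_class <- rep("biological_peptide", length(pep_ids))
  pep_class[pep_ids %in% layout$ystf_free_ids] <- "ystf_free_peptide"
  pep_class[pep_ids %in% layout$reference_ids] <- "reference_peptide"

  # noiseless expected consumption per peptide
  signal <- stats::setNames(rep(0, length(pep_ids)), pep_ids)
  for (k in names(spec$true_kinase_activity)) {
    targets <- unique(spec$map$peptide_id[spec$map$kinase_id == k])
    targets <- intersect(targets, pep_ids)
    signal[targets] <- signal[targets] + spec$true_kinase_activity[[k]]
  }
  signal[layout$ystf_free_ids] <- 0  # no phosphorylatable residue
  truth <- data.frame(peptide_id = pep_ids,
                      true_consumption = spec$baseline_consumption + unname(signal),
                      stringsAsFactors = FALSE)

  n_blank <- 4L; n_cal <- 4L
  n_wells <- length(pep_ids) + layout$n_peptide_free_controls + n_blank + n_cal
  addr <- well_addresses(n_wells)
  rlu_blank <- 1000; rlu_cal <- 41000
  to_rlu <- function(consumed) {
    rlu_blank + (atp0 - consumed) / atp0 * (rlu_cal - rlu_blank)
  }
  plates <- list()
  for (b in seq_len(spec$n_bio_reps)) {
    for (t in seq_len(spec$n_tech_reps)) {
      cons_pep <- truth$true_consumption +
        stats::rnorm(length(pep_ids), 0, spec$noise_sd)
      cons_pfc <- spec$baseline_consumption +
        stats::rnorm(layout$n_peptide_free_controls, 0, spec$noise_sd)
      cons <- pmin(pmax(c(cons_pep, cons_pfc), 0), atp0)
      df <- data.frame(
        plate_id = sprintf("%s_%s_b%dt%d", spec$sample_id, spec$treatment, b, t),
        well = addr,
        well_class = c(pep_class,
                       rep("peptide_free_control", layout$n_peptide_free_controls),
                       rep("blank", n_blank), rep("atp_calibration", n_cal)),
        peptide_id = c(pep_ids, rep(NA_character_,
                                    layout$n_peptide_free_controls + n_blank + n_cal)),
        sample_id = spec$sample_id,
        treatment = spec$treatment,
        bio_rep = b, tech_rep = t,
        rlu = c(to_rlu(cons), rep(rlu_blank, n_blank), rep(rlu_cal, n_cal)),
        stringsAsFactors = FALSE)
      plates[[length(plates) + 1L]] <- df
    }
  }
  out <- as_plate_table(do.call(rbind, plates), layout)
  attr(out, "ground_truth") <- truth
  out
}

#' Specification for a simulated drug-combination viability experiment
#'
#' Single-agent response follows a Hill curve `E(d) = 1 / (1 + (d/gi50)^hill)`
#' on a 2-fold dilution ladder spanning 0.125x to 8x each drug's GI50 (the
#' standard viability design). Combination wells deviate from Bliss
#' independence by a constant: `E_combo = E_a * E_b * 2^(-bliss_s)` (times
#' `E_c` at drug C's GI50 for triple designs), so the ground-truth pair CI is
#' exactly `bliss_s`. Viability noise is multiplicative lognormal with the
#' given coefficient of variation (mean 1).
#'
#' @param gi50_a,hill_a,gi50_b,hill_b per-drug Hill parameters.
#' @param bliss_s Bliss deviation in log2 units (0 = exact independence).
#' @param cv viability noise coefficient of variation (0 = noiseless).
#' @param n_reps replicates per well.
#' @param drug_c optional `list(gi50, hill)`; when present, combination wells
#'   carry drug C fixed at its GI50 (`conc_c = gi50`).
#' @param seed RNG seed.
#' @return list of class `combo_sim_spec`.
#' @export
combo_sim_spec <- function(gi50_a = 1, hill_a = 1, gi50_b = 2, hill_b = 1,
                           bliss_s = 0, cv = 0.05, n_reps = 3L,
                           drug_c = NULL, seed = 1L) {
  stopifnot(gi50_a > 0, gi50_b > 0, hill_a > 0, hill_b > 0, cv >= 0)
  if (!is.null(drug_c)) stopifnot(drug_c$gi50 > 0, drug_c$hill > 0)
  structure(list(gi50_a = gi50_a, hill_a = hill_a, gi50_b = gi50_b,
                 hill_b = hill_b, bliss_s = bliss_s, cv = cv,
                 n_reps = as.integer(n_reps), drug_c = drug_c,
                 seed = as.integer(seed)),
            class = "combo_sim_spec")
}

#' Simulate a dose-response surface with a controllable Bliss deviation
#'
#' @param spec a [combo_sim_spec()].
#' @return data frame with columns `drug_a`, `conc_a`, `drug_b`, `conc_b`,
#'   `drug_c`, `conc_c`, `replicate`, `viability`; attribute `ground_truth`
#'   records the generating parameters.
#' @export
simulate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "combo_sim_spec"))
  set.seed(spec$seed)
  hill <- function(d, g, h) 1 / (1 + (d / g)^h)
  ladder_a <- spec$gi50_a * 2 ^ (-3:3)
  ladder_b <- spec$gi50_b * 2 ^ (-3:3)
  conc_c <- if (is.null(spec$drug_c)) 0 else spec$drug_c$gi50
  e_c <- if (is.null(spec$drug_c)) 1 else
    hill(spec$drug_c$gi50, spec$drug_c$gi50, spec$drug_c$hill)
  grid <- rbind(
    data.frame(conc_a = 0, conc_b = 0, conc_c = 0),                 # untreated
    data.frame(conc_a = ladder_a, conc_b = 0, conc_c = 0),          # singles A
    data.frame(conc_a = 0, conc_b = ladder_b, conc_c = 0),          # singles B
    if (!is.null(spec$drug_c))
      data.frame(conc_a = 0, conc_b = 0, conc_c = conc_c),          # single C
    expand.grid(conc_a = ladder_a, conc_b = ladder_b, conc_c = conc_c))
  e_true <- rep(1, nrow(grid))  # untreated baseline
  combo <- grid$conc_a > 0 & grid$conc_b > 0
  single_a <- grid$conc_a > 0 & grid$conc_b == 0
  single_b <- grid$conc_b > 0 & grid$conc_a == 0
  single_c <- grid$conc_c > 0 & grid$conc_a == 0 & grid$conc_b == 0
  e_true[single_a] <- hill(grid$conc_a[single_a], spec$gi50_a, spec$hill_a)
  e_true[single_b] <- hill(grid$conc_b[single_b], spec$gi50_b, spec$hill_b)
  e_true[single_c] <- e_c
  e_true[combo] <- hill(grid$conc_a[combo], spec$gi50_a, spec$hill_a) *
    hill(grid$conc_b[combo], spec$gi50_b, spec$hill_b) * e_c * 2 ^ (-spec$bliss_s)
  out <- grid[rep(seq_len(nrow(grid)), each = spec$n_reps), , drop = FALSE]
  out$replicate <- rep(seq_len(spec$n_reps), nrow(grid))
  e_rep <- rep(e_true, each = spec$n_reps)
  if (spec$cv > 0) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    e_rep <- e_rep * stats::rlnorm(length(e_rep), -sdlog^2 / 2, sdlog)
  }
  out <- data.frame(drug_a = "A", conc_a = out$conc_a,
                    drug_b = "B", conc_b = out$conc_b,
                    drug_c = if (is.null(spec$drug_c)) NA_character_ else "C",
                    conc_c = out$conc_c,
                    replicate = out$replicate, viability = e_rep,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(bliss_s = spec$bliss_s,
                                    gi50_a = spec$gi50_a, gi50_b = spec$gi50_b,
                                    e_c = e_c)
  out
}

#' Specification for a simulated multi-arm xenograft study
#'
#' Per-mouse exponential growth `V(t) = V0 * exp((g - tau) * (t - 1))` with
#' multiplicative lognormal measurement noise after day 1. Mice enroll at
#' 100-150 mm3, are measured twice weekly through day 21, and are removed from
#' the study from the first day their volume would exceed the 2,000 mm3
#' welfare cap (dropout), so arms can empty at late time points.
#'
#' @param arms data frame with columns `arm`, `growth_rate` (g, per day) and
#'   `inhibition` (tau, per day); tau = 0 for vehicle. Defaults to a vehicle
#'   arm growing at 0.11/day plus doublet and triplet arms with increasing
#'   inhibition.
#' @param n_mice mice per arm (default 8).
#' @param days measurement days (default `c(1, 4, 8, 11, 15, 18, 21)`).
#' @param v0_range enrollment volume range in mm3.
#' @param noise_sd lognormal (log-scale) measurement noise sd.
#' @param cap maximum permitted tumor volume in mm3.
#' @param model_id model label.
#' @param seed RNG seed.
#' @return list of class `growth_sim_spec`.
#' @export
growth_sim_spec <- function(arms = data.frame(
                              arm = c("vehicle", "doublet", "triplet"),
                              growth_rate = 0.11,
                              inhibition = c(0, 0.08, 0.14)),
                            n_mice = 8L, days = c(1L, 4L, 8L, 11L, 15L, 18L, 21L),
                            v0_range = c(100, 150), noise_sd = 0.1,
                            cap = 2000, model_id = "model1", seed = 1L) {
  stopifnot(all(c("arm", "growth_rate", "inhibition") %in% names(arms)),
            days[1] == 1L, !is.unsorted(days))
  structure(list(arms = arms, n_mice = as.integer(n_mice), days = as.integer(days),
                 v0_range = v0_range, noise_sd = noise_sd, cap = cap,
                 model_id = model_id, seed = as.integer(seed)),
            class = "growth_sim_spec")
}

#' Simulate a tumor-volume trajectory panel
#'
#' @param spec a [growth_sim_spec()].
#' @return data frame with columns `model_id`, `arm`, `mouse_id`, `day`,
#'   `volume_mm3`; attribute `ground_truth` carries the arm parameters.
#' @export
simulate_tumor_study <- function(spec) {
  stopifnot(inherits(spec, "growth_sim_spec"))
  set.seed(spec$seed)
  rows <- list()
  for (i in seq_len(nrow(spec$arms))) {
    g <- spec$arms$growth_rate[i] - spec$arms$inhibition[i]
    for (m in seq_len(spec$n_mice)) {
      v0 <- stats::runif(1, spec$v0_range[1], spec$v0_range[2])
      noise <- c(0, stats::rnorm(length(spec$days) - 1L, 0, spec$noise_sd))
      v <- v0 * exp(g * (spec$days - 1L)) * exp(noise)
      keep <- cumsum(v > spec$cap) == 0  # dropout from first cap breach
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = spec$model_id, arm = spec$arms$arm[i],
        mouse_id = sprintf("%s_m%02d", spec$arms$arm[i], m),
        day = spec$days[keep], volume_mm3 = v[keep], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- spec$arms
  out
}

#' Specification for a simulated qPCR Ct table
#'
#' Target Ct values are built from the housekeeping mean plus a per-gene
#' baseline dCt minus `log2(fold)`, with Gaussian cycle noise, so that [ddct()]
#' recovers each arm's true fold against the calibrator exactly in the
#' noiseless case. Housekeeping genes (ACTB, UBC) get fixed nominal Cts plus
#' the same noise.
#'
#' @param cell_lines,genes,arms labels; `arms[1]` is the calibrator (fold 1).
#' @param folds numeric matrix `genes x arms` of true folds versus the
#'   calibrator; default 1 everywhere.
#' @param hk_ct named nominal housekeeping Cts.
#' @param baseline_dct per-gene baseline dCt (recycled).
#' @param n_reps replicates (default 4, mirroring quadruplicate assays).
#' @param noise_sd Gaussian Ct noise in cycles.
#' @param seed RNG seed.
#' @return list of class `ct_sim_spec`.
#' @export
ct_sim_spec <- function(cell_lines = "line1",
                        genes = c("MYC", "AXIN2", "ASCL2"),
                        arms = c("VEM", "VEM+GEF", "VEM+DAS"),
                        folds = NULL,
                        hk_ct = c(ACTB = 18, UBC = 20),
                        baseline_dct = 5, n_reps = 4L, noise_sd = 0.15,
                        seed = 1L) {
  if (is.null(folds)) {
    folds <- matrix(1, length(genes), length(arms),
                    dimnames = list(genes, arms))
  }
  stopifnot(all(folds > 0), nrow(folds) == length(genes),
            ncol(folds) == length(arms))
  structure(list(cell_lines = cell_lines, genes = genes, arms = arms,
                 folds = folds, hk_ct = hk_ct,
                 baseline_dct = rep_len(baseline_dct, length(genes)),
                 n_reps = as.integer(n_reps), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ct_sim_spec")
}

#' Simulate a qPCR Ct table
#'
#' @param spec a [ct_sim_spec()].
#' @return data frame with columns `cell_line`, `gene`, `gene_role`, `arm`,
#'   `replicate`, `ct`; attribute `ground_truth` carries the fold matrix.
#' @export
simulate_ct_table <- function(spec) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  set.seed(spec$seed)
  hk_mean <- mean(spec$hk_ct)
  rows <- list()
  for (cl in spec$cell_lines) {
    for (arm in spec$arms) {
      for (r in seq_len(spec$n_reps)) {
        for (h in names(spec$hk_ct)) {
          rows[[length(rows) + 1L]] <- data.frame(
            cell_line = cl, gene = h, gene_role = "housekeeping", arm = arm,
            replicate = r,
            ct = spec$hk_ct[[h]] + stats::rnorm(1, 0, spec$noise_sd),
            stringsAsFactors = FALSE)
        }
        for (gi in seq_along(spec$genes)) {
          rows[[length(rows) + 1L]] <- data.frame(
            cell_line = cl, gene = spec$genes[gi], gene_role = "target",
            arm = arm, replicate = r,
            ct = hk_mean + spec$baseline_dct[gi] -
              log2(spec$folds[gi, arm]) + stats::rnorm(1, 0, spec$noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- spec$folds
  out
}
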