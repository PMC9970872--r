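# Shared in-code fixtures: tiny layouts and hand-buildable plates.

mini_layout <- function(n_pep = 4L, n_pfc = 2L, atp0 = 250) {
  plate_layout(n_biological_peptides = n_pep, n_peptide_free_controls = n_pfc,
               n_ystf_free = 0L, n_reference_peptides = 0L, atp0_nM = atp0)
}

# Build a plate_table directly from per-well consumption values (bypasses the
# RLU conversion; rlu set to a dummy 0).
make_plate <- function(layout, pep_consumption, pfc_consumption,
                       plate_id = "p1", sample_id = "s1", treatment = "UNT",
                       bio_rep = 1L, tech_rep = 1L) {
  stopifnot(length(pep_consumption) == layout$n_biological_peptides,
            length(pfc_consumption) == layout$n_peptide_free_controls)
  n <- layout$n_biological_peptides + layout$n_peptide_free_controls
  cls <- rep("biological_peptide", layout$n_biological_peptides)
  cls[layout$peptide_ids %in% layout$ystf_free_ids] <- "ystf_free_peptide"
  cls[layout$peptide_ids %in% layout$reference_ids] <- "reference_peptide"
  df <- data.frame(
    plate_id = plate_id,
    well = paste0(rep(LETTERS[1:16], each = 24), rep(1:24, 16))[seq_len(n)],
    well_class = c(cls, rep("peptide_free_control", layout$n_peptide_free_controls)),
    peptide_id = c(layout$peptide_ids,
                   rep(NA_character_, layout$n_peptide_free_controls)),
    sample_id = sample_id, treatment = treatment,
    bio_rep = bio_rep, tech_rep = tech_rep, rlu = 0,
    stringsAsFactors = FALSE)
  plate <- as_plate_table(df, layout)
  plate$atp_consumed_nM <- c(pep_consumption, pfc_consumption)
  plate
}

# Replicate-level activity profile from a matrix (peptides x replicates).
profile_from_matrix <- function(m, treatment = "UNT", scheme = "internal_mean") {
  df <- data.frame(
    peptide_id = rep(rownames(m), ncol(m)),
    sample_id = "s1", treatment = treatment,
    bio_rep = rep(seq_len(ncol(m)), each = nrow(m)), tech_rep = 1L,
    plate_id = rep(paste0(treatment, "_r", seq_len(ncol(m))), each = nrow(m)),
    activity = as.vector(m), stringsAsFactors = FALSE)
  structure(df, class = c("activity_profile", "data.frame"), scheme = scheme)
}
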