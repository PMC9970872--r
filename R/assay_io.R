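#' Plate layout specification for the kinase activity mapping assay
#'
#' Describes the well composition of one 384-well phospho-catalytic profiling
#' run: biological peptide-sensor wells, peptide-free control wells (extract
#' plus ATP, no peptide), and two tagged subsets of the peptides used for
#' alternative normalization schemes -- Y/S/T-free peptides (no phosphorylatable
#' residue) and reference peptides. The default layout carries 228 peptides and
#' 14 peptide-free controls, so the internal-normalization well set has
#' 228 + 14 = 242 wells, with 16 Y/S/T-free and 63 reference peptides tagged
#' among the 228. Reactions start from 250 nM ATP.
#'
#' @param n_biological_peptides number of peptide-sensor wells (default 228).
#' @param n_peptide_free_controls number of peptide-free control wells (14).
#' @param n_ystf_free number of Y/S/T-free peptides, a tagged subset of the
#'   biological peptides (default 16).
#' @param n_reference_peptides number of reference peptides, a tagged subset of
#'   the biological peptides (default 63).
#' @param atp0_nM initial ATP per well in nM (default 250).
#' @param peptide_ids optional character vector of peptide identifiers; defaults
#'   to `pep001 ... pepNNN`.
#' @param ystf_free_ids,reference_ids optional explicit membership of the two
#'   tagged subsets; defaults take the first `n_ystf_free` peptides and the
#'   following `n_reference_peptides` (disjoint by construction).
#' @return an object of class `plate_layout`.
#' @examples
#' lay <- plate_layout()
#' lay$n_biological_peptides + lay$n_peptide_free_controls  # 242
#' @export
plate_layout <- function(n_biological_peptides = 228L,
                         n_peptide_free_controls = 14L,
                         n_ystf_free = 16L,
                         n_reference_peptides = 63L,
                         atp0_nM = 250,
                         peptide_ids = NULL,
                         ystf_free_ids = NULL,
                         reference_ids = NULL) {
  stopifnot(n_biological_peptides >= 1, n_peptide_free_controls >= 0,
            atp0_nM > 0)
  if (n_ystf_free + n_reference_peptides > n_biological_peptides) {
    stop_kamdecon(
      "tagged subsets (%d Y/S/T-free + %d reference) exceed the %d peptides",
      n_ystf_free, n_reference_peptides, n_biological_peptides,
      class = "kamdecon_layout_error")
  }
  if (is.null(peptide_ids)) {
    peptide_ids <- sprintf("pep%03d", seq_len(n_biological_peptides))
  }
  stopifnot(length(peptide_ids) == n_biological_peptides,
            !anyDuplicated(peptide_ids))
  if (is.null(ystf_free_ids)) {
    ystf_free_ids <- peptide_ids[seq_len(n_ystf_free)]
  }
  if (is.null(reference_ids)) {
    reference_ids <- setdiff(peptide_ids, ystf_free_ids)[seq_len(n_reference_peptides)]
  }
  if (!all(ystf_free_ids %in% peptide_ids) || !all(reference_ids %in% peptide_ids)) {
    stop_kamdecon("tagged subset ids must belong to the biological peptide set",
                  class = "kamdecon_layout_error")
  }
  structure(
    list(n_biological_peptides = as.integer(n_biological_peptides),
         n_peptide_free_controls = as.integer(n_peptide_free_controls),
         n_ystf_free = length(ystf_free_ids),
         n_reference_peptides = length(reference_ids),
         atp0_nM = atp0_nM,
         peptide_ids = peptide_ids,
         ystf_free_ids = ystf_free_ids,
         reference_ids = reference_ids),
    class = "plate_layout")
}

#' Read a plate layout from a YAML configuration file
#'
#' Recognized keys: `n_biological_peptides`, `n_peptide_free_controls`,
#' `n_ystf_free`, `n_reference_peptides`, `atp0_nM`.
#'
#' @param path path to a YAML file.
#' @return a [plate_layout()] object.
#' @export
read_plate_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(plate_layout, cfg[intersect(names(cfg),
    c("n_biological_peptides", "n_peptide_free_controls",
      "n_ystf_free", "n_reference_peptides", "atp0_nM"))])
}

plate_columns <- c("plate_id", "well", "well_class", "peptide_id", "sample_id",
                   "treatment", "bio_rep", "tech_rep", "rlu")

well_classes <- c("biological_peptide", "ystf_free_peptide", "reference_peptide",
                  "peptide_free_control", "atp_calibration", "blank", "unused")

#' Validate a data frame of well records as a plate table
#'
#' @param df data frame with at least the columns `well`, `well_class`,
#'   `peptide_id`, `sample_id`, `treatment`, `rlu` (plus `plate_id`, `bio_rep`,
#'   `tech_rep`, filled with defaults if absent).
#' @param layout a [plate_layout()] describing the expected composition.
#' @return the validated data frame with class `plate_table` and the layout
#'   attached as attribute `layout`.
#' @export
as_plate_table <- function(df, layout = plate_layout()) {
  required <- c("well", "well_class", "peptide_id", "sample_id", "treatment", "rlu")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_kamdecon("plate table is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", "),
                  class = "kamdecon_format_error")
  }
  if (!"plate_id" %in% names(df)) df$plate_id <- "plate1"
  if (!"bio_rep" %in% names(df)) df$bio_rep <- 1L
  if (!"tech_rep" %in% names(df)) df$tech_rep <- 1L
  df$peptide_id[!is.na(df$peptide_id) & df$peptide_id == ""] <- NA_character_
  bad <- setdiff(unique(df$well_class), well_classes)
  if (length(bad)) {
    stop_kamdecon("unknown well_class value(s): %s", paste(bad, collapse = ", "),
                  class = "kamdecon_validation_error")
  }
  dup <- stats::aggregate(seq_len(nrow(df)),
                          by = df[c("plate_id", "well")], FUN = length)
  if (any(dup$x > 1L)) {
    w <- dup[dup$x > 1L, , drop = FALSE]
    stop_kamdecon("duplicate well address(es): %s",
                  paste(paste0(w$plate_id, ":", w$well), collapse = ", "),
                  class = "kamdecon_validation_error")
  }
  if (any(df$well_class == "peptide_free_control" & !is.na(df$peptide_id))) {
    stop_kamdecon("peptide_free_control wells must have no peptide_id",
                  class = "kamdecon_validation_error")
  }
  if (any(!is.na(df$rlu) & df$rlu < 0)) {
    stop_kamdecon("rlu must be non-negative", class = "kamdecon_validation_error")
  }
  # composition check is advisory: deviation from the layout warns, not errors
  for (pid in unique(df$plate_id)) {
    sub <- df[df$plate_id == pid, ]
    n_pep <- sum(sub$well_class %in%
                   c("biological_peptide", "ystf_free_peptide", "reference_peptide"))
    n_pfc <- sum(sub$well_class == "peptide_free_control")
    if (n_pep != layout$n_biological_peptides ||
        n_pfc != layout$n_peptide_free_controls) {
      warning(sprintf(
        "plate %s: %d peptide wells and %d peptide-free controls (layout expects %d and %d)",
        pid, n_pep, n_pfc, layout$n_biological_peptides,
        layout$n_peptide_free_controls), call. = FALSE)
    }
  }
  if (!"atp_consumed_nM" %in% names(df)) df$atp_consumed_nM <- NA_real_
  df <- df[c(plate_columns, "atp_consumed_nM")]
  structure(df, class = c("plate_table", "data.frame"), layout = layout)
}

#' Read a plate measurement CSV
#'
#' Expects one row per well with header columns `well`, `well_class`,
#' `peptide_id`, `sample_id`, `treatment`, `rlu` (and optionally `plate_id`,
#' `bio_rep`, `tech_rep`, `atp_consumed_nM`). Counts per well class are checked
#' against the layout; deviations warn but do not fail.
#'
#' @param path CSV file path.
#' @inheritParams as_plate_table
#' @return a `plate_table`.
#' @export
read_plate <- function(path, layout = plate_layout()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(peptide_id = "character"))
  as_plate_table(df, layout)
}

#' Write a plate table to CSV
#'
#' @param plate a `plate_table`.
#' @param path output CSV path.
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(as.data.frame(plate), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert luminescence readings to ATP consumption (nM)
#'
#' The luminescent readout is proportional to the ATP remaining at the end of
#' the reaction, so a linear map takes RLU to nM ATP remaining and consumption
#' is `atp0 - remaining`. By default the map is a two-point calibration against
#' the plate's own control wells: `blank` wells (0 nM ATP) and
#' `atp_calibration` wells (the full `atp0`, default 250 nM). Alternatively an
#' explicit `list(slope, intercept)` gives `remaining = slope * rlu +
#' intercept`. Computed consumption is clipped to `[0, atp0]`; the number of
#' clipped wells is recorded in attribute `n_clipped`.
#'
#' @param plate a `plate_table` with `rlu` filled in.
#' @param calibration `"from_calibration_wells"` (default) or a list with
#'   elements `slope` and `intercept`.
#' @return the plate with `atp_consumed_nM` filled for all non-unused wells.
#' @examples
#' plate <- simulate_plate(plate_sim_spec(seed = 1))
#' plate <- luminescence_to_atp(plate)
#' range(plate$atp_consumed_nM, na.rm = TRUE)  # within [0, 250]
#' @export
luminescence_to_atp <- function(plate, calibration = "from_calibration_wells") {
  layout <- attr(plate, "layout")
  atp0 <- layout$atp0_nM
  if (identical(calibration, "from_calibration_wells")) {
    per_plate <- TRUE
  } else if (is.list(calibration) &&
             all(c("slope", "intercept") %in% names(calibration))) {
    if (calibration$slope <= 0) {
      stop_kamdecon("calibration slope must be positive",
                    class = "kamdecon_calibration_error")
    }
    per_plate <- FALSE
  } else {
    stop_kamdecon(
      "calibration must be \"from_calibration_wells\" or list(slope, intercept)",
      class = "kamdecon_configuration_error")
  }
  n_clipped <- 0L
  for (pid in unique(plate$plate_id)) {
    idx <- plate$plate_id == pid & plate$well_class != "unused"
    if (per_plate) {
      sub <- plate[plate$plate_id == pid, ]
      rlu_blank <- mean(sub$rlu[sub$well_class == "blank"])
      rlu_cal <- mean(sub$rlu[sub$well_class == "atp_calibration"])
      if (!is.finite(rlu_blank) || !is.finite(rlu_cal)) {
        stop_kamdecon(
          "plate %s: calibration from wells requires >=1 blank and >=1 atp_calibration well",
          pid, class = "kamdecon_configuration_error")
      }
      if (rlu_cal <= rlu_blank) {
        stop_kamdecon("plate %s: atp_calibration RLU must exceed blank RLU", pid,
                      class = "kamdecon_calibration_error")
      }
      slope <- atp0 / (rlu_cal - rlu_blank)
      intercept <- -slope * rlu_blank
    } else {
      slope <- calibration$slope
      intercept <- calibration$intercept
    }
    remaining <- slope * plate$rlu[idx] + intercept
    consumed <- atp0 - remaining
    n_clipped <- n_clipped + sum(consumed < 0 | consumed > atp0, na.rm = TRUE)
    plate$atp_consumed_nM[idx] <- pmin(pmax(consumed, 0), atp0)
  }
  attr(plate, "n_clipped") <- n_clipped
  plate
}
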