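#' Peptide-to-kinase incidence map
#'
#' A many-to-many map between peptide sensors and the kinases (or kinase
#' families) whose substrate motifs they carry. A kinase is deconvolutable only
#' when it maps to at least 3 distinct biological peptides; entries referencing
#' peptides absent from the layout are dropped with a warning at use time.
#'
#' @param peptide_id,kinase_id character vectors (recycled against each other).
#' @param kinase_kind `"single_kinase"` or `"kinase_family"` per entry.
#' @return a data frame of class `peptide_kinase_map`.
#' @export
peptide_kinase_map <- function(peptide_id, kinase_id,
                               kinase_kind = "single_kinase") {
  df <- unique(data.frame(peptide_id = as.character(peptide_id),
                          kinase_id = as.character(kinase_id),
                          kinase_kind = as.character(kinase_kind),
                          stringsAsFactors = FALSE))
  structure(df, class = c("peptide_kinase_map", "data.frame"))
}

#' Read a peptide-to-kinase map from TSV
#'
#' Columns: `peptide_id`, `kinase_id` and optionally `kinase_kind`.
#'
#' @param path TSV file path.
#' @return a `peptide_kinase_map`.
#' @export
read_kinase_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  peptide_kinase_map(df$peptide_id, df$kinase_id,
                     df$kinase_kind %||% "single_kinase")
}

scheme_levels <- c("internal_mean", "peptide_free", "ystf_free", "reference_peptides")

scheme_wells <- function(plate, scheme, layout) {
  pep_classes <- c("biological_peptide", "ystf_free_peptide", "reference_peptide")
  switch(scheme,
    internal_mean = plate$well_class %in% c(pep_classes, "peptide_free_control"),
    peptide_free = plate$well_class == "peptide_free_control",
    ystf_free = plate$well_class %in% pep_classes &
      plate$peptide_id %in% layout$ystf_free_ids,
    reference_peptides = plate$well_class %in% pep_classes &
      plate$peptide_id %in% layout$reference_ids,
    stop_kamdecon("unknown normalization scheme: %s", scheme,
                  class = "kamdecon_configuration_error"))
}

#' Normalization reference for one assay run
#'
#' The mean-centering value subtracted from every peptide's ATP consumption.
#' Under the default `internal_mean` scheme it is the average consumption over
#' the sample-containing wells -- all biological peptides plus the peptide-free
#' controls (242 wells in the default layout). Alternative schemes average the
#' 14 peptide-free control wells, the 16 Y/S/T-free peptides, or the 63
#' reference peptides.
#'
#' @param plate a `plate_table` with `atp_consumed_nM` computed, restricted to
#'   (or grouped by) `plate_id` -- one reference is returned per plate.
#' @param scheme one of `"internal_mean"`, `"peptide_free"`, `"ystf_free"`,
#'   `"reference_peptides"`.
#' @return named numeric vector, one reference (nM) per `plate_id`.
#' @export
normalization_reference <- function(plate, scheme = "internal_mean") {
  scheme <- match.arg(scheme, scheme_levels)
  layout <- attr(plate, "layout")
  ids <- unique(plate$plate_id)
  out <- vapply(ids, function(pid) {
    sub <- plate[plate$plate_id == pid, ]
    sel <- scheme_wells(sub, scheme, layout)
    if (!any(sel)) {
      stop_kamdecon("plate %s: no wells available for scheme %s", pid, scheme,
                    class = "kamdecon_configuration_error")
    }
    mean(sub$atp_consumed_nM[sel])
  }, numeric(1))
  names(out) <- ids
  out
}

#' Per-peptide phospho-catalytic activity
#'
#' Activity of each peptide sensor is its ATP consumption minus the
#' normalization reference of its plate, computed per replicate (one plate =
#' one biological/technical replicate run). Activities are in nM ATP and may be
#' negative; under `internal_mean` the activities of the 242 normalization
#' wells average to zero on each plate by construction.
#'
#' @inheritParams normalization_reference
#' @return a data frame of class `activity_profile` with columns `peptide_id`,
#'   `sample_id`, `treatment`, `bio_rep`, `tech_rep`, `plate_id`, `activity`;
#'   attribute `scheme` records the normalization scheme.
#' @export
peptide_activity <- function(plate, scheme = "internal_mean") {
  scheme <- match.arg(scheme, scheme_levels)
  if (anyNA(plate$atp_consumed_nM[plate$well_class != "unused"])) {
    stop_kamdecon("ATP consumption not computed; run luminescence_to_atp() first",
                  class = "kamdecon_configuration_error")
  }
  ref <- normalization_reference(plate, scheme)
  pep <- plate[plate$well_class %in%
                 c("biological_peptide", "ystf_free_peptide", "reference_peptide"), ]
  out <- data.frame(peptide_id = pep$peptide_id,
                    sample_id = pep$sample_id,
                    treatment = pep$treatment,
                    bio_rep = pep$bio_rep,
                    tech_rep = pep$tech_rep,
                    plate_id = pep$plate_id,
                    activity = pep$atp_consumed_nM - ref[pep$plate_id],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("activity_profile", "data.frame"), scheme = scheme)
}

#' Average an activity profile across replicates
#'
#' Arithmetic mean per peptide over all biological and technical replicates
#' (plates), keeping the replicate count.
#'
#' @param profile an `activity_profile`, or a list of them sharing one
#'   normalization scheme (they are stacked before averaging).
#' @return a data frame of class `activity_profile` with columns `peptide_id`,
#'   `activity`, `n_replicates`.
#' @export
aggregate_replicates <- function(profile) {
  profile <- bind_profiles(profile)
  agg <- stats::aggregate(activity ~ peptide_id, data = profile, FUN = mean)
  n <- stats::aggregate(activity ~ peptide_id, data = profile, FUN = length)
  agg$n_replicates <- n$activity[match(agg$peptide_id, n$peptide_id)]
  structure(agg, class = c("activity_profile", "data.frame"),
            scheme = attr(profile, "scheme"), aggregated = TRUE)
}

bind_profiles <- function(x) {
  if (is.data.frame(x)) return(x)
  schemes <- unique(vapply(x, function(p) attr(p, "scheme") %||% NA_character_,
                           character(1)))
  if (length(schemes) > 1L) {
    stop_kamdecon("profiles use mixed normalization schemes: %s",
                  paste(schemes, collapse = ", "),
                  class = "kamdecon_configuration_error")
  }
  out <- do.call(rbind, lapply(x, as.data.frame))
  structure(out, class = c("activity_profile", "data.frame"), scheme = schemes)
}

profile_matrix <- function(profile) {
  profile$rep_key <- interaction(profile$plate_id, profile$bio_rep,
                                 profile$tech_rep, drop = TRUE)
  peptides <- sort(unique(profile$peptide_id))
  reps <- levels(profile$rep_key)
  m <- matrix(NA_real_, length(peptides), length(reps),
              dimnames = list(peptides, reps))
  m[cbind(match(profile$peptide_id, peptides),
          match(profile$rep_key, reps))] <- profile$activity
  m
}

#' Differential activity between treated and control replicate profiles
#'
#' Per peptide, the difference of replicate-mean activities (treated minus
#' control, nM ATP) with a two-sample equal-variance two-sided t-test across
#' replicates. With fewer than 2 replicates in a group p is `NA`; two constant
#' groups give p = 1 when equal and p = 0 (flagged in column `degenerate`)
#' when not.
#'
#' @param treated,control replicate-level `activity_profile`s (or lists of
#'   them) from the same layout and scheme.
#' @return data frame of class `differential_table` with columns `unit`,
#'   `delta`, `p_two_sided`, `n_treated`, `n_control`, `degenerate`.
#' @export
differential_profile <- function(treated, control) {
  treated <- bind_profiles(treated)
  control <- bind_profiles(control)
  mt <- profile_matrix(treated)
  mc <- profile_matrix(control)
  peptides <- sort(union(rownames(mt), rownames(mc)))
  mt <- mt[match(peptides, rownames(mt)), , drop = FALSE]
  mc <- mc[match(peptides, rownames(mc)), , drop = FALSE]
  delta <- rowMeans(mt, na.rm = TRUE) - rowMeans(mc, na.rm = TRUE)
  p <- ttest_p_rows(mt, mc)
  vt <- apply(mt, 1L, stats::var, na.rm = TRUE)
  vc <- apply(mc, 1L, stats::var, na.rm = TRUE)
  out <- data.frame(unit = peptides,
                    delta = unname(delta),
                    p_two_sided = unname(p),
                    n_treated = as.integer(rowSums(is.finite(mt))),
                    n_control = as.integer(rowSums(is.finite(mc))),
                    degenerate = unname(is.finite(vt) & is.finite(vc) &
                                          vt == 0 & vc == 0),
                    stringsAsFactors = FALSE)
  structure(out, class = c("differential_table", "data.frame"), unit = "peptide")
}

#' Deconvolute peptide-level values into kinase activity signatures
#'
#' The activity of a kinase (or kinase family) is the arithmetic mean of the
#' activities of its mapped biological peptides. Only kinases detected with at
#' least `min_peptides` distinct peptides present in the input are reported
#' (default 3); the omitted kinases are listed in attribute `omitted`. The
#' standard error over the peptide subset accompanies each value.
#'
#' @param x an aggregated `activity_profile` (columns `peptide_id`, `activity`)
#'   or a `differential_table` (columns `unit`, `delta`).
#' @param map a [peptide_kinase_map()]. Entries whose peptide is absent from
#'   `x` are dropped with a warning.
#' @param min_peptides detection threshold on distinct mapped peptides.
#' @return data frame of class `kinase_signature` with columns `kinase_id`,
#'   `value`, `se`, `n_peptides`. For kinase-level p-values across replicate
#'   groups use [kinase_differential()].
#' @export
deconvolute <- function(x, map, min_peptides = 3L) {
  if (!nrow(map)) {
    stop_kamdecon("peptide-kinase map is empty", class = "kamdecon_configuration_error")
  }
  if (inherits(x, "differential_table")) {
    values <- stats::setNames(x$delta, x$unit)
  } else {
    if (any(duplicated(x$peptide_id))) {
      x <- aggregate_replicates(x)
    }
    values <- stats::setNames(x$activity, x$peptide_id)
  }
  known <- map$peptide_id %in% names(values)
  if (!all(known)) {
    warning(sprintf("%d map entries reference unknown peptides and were dropped",
                    sum(!known)), call. = FALSE)
    map <- map[known, , drop = FALSE]
  }
  splits <- split(map$peptide_id, map$kinase_id)
  n_pep <- vapply(splits, function(p) length(unique(p)), integer(1))
  keep <- n_pep >= min_peptides
  vals <- vapply(splits[keep], function(p) mean(values[unique(p)]), numeric(1))
  ses <- vapply(splits[keep], function(p) {
    v <- values[unique(p)]
    stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  out <- data.frame(kinase_id = names(vals),
                    value = unname(vals),
                    se = unname(ses),
                    n_peptides = unname(n_pep[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$kinase_id), ]
  rownames(out) <- NULL
  structure(out, class = c("kinase_signature", "data.frame"),
            omitted = names(splits)[!keep])
}

#' Differential kinase signature between treated and control profiles
#'
#' Deconvolutes each replicate's peptide profile into per-replicate kinase
#' means, then tests treated versus control per kinase with the two-sample
#' equal-variance two-sided t-test (`pvalue_on = "replicate_means"`, the
#' default). The alternative `"pooled_peptides"` tests the peptide-level deltas
#' of the kinase's subset against zero-centered pooling across replicates --
#' i.e. treated versus control observations pooled over (peptide, replicate).
#'
#' @inheritParams differential_profile
#' @inheritParams deconvolute
#' @param pvalue_on `"replicate_means"` or `"pooled_peptides"`.
#' @return data frame of class `differential_table` (unit kinase) with columns
#'   `unit`, `delta`, `p_two_sided`, `n_treated`, `n_control`, `n_peptides`.
#' @export
kinase_differential <- function(treated, control, map, min_peptides = 3L,
                                pvalue_on = c("replicate_means", "pooled_peptides")) {
  pvalue_on <- match.arg(pvalue_on)
  treated <- bind_profiles(treated)
  control <- bind_profiles(control)
  mt <- profile_matrix(treated)
  mc <- profile_matrix(control)
  peptides <- rownames(mt)
  map <- map[map$peptide_id %in% peptides & map$peptide_id %in% rownames(mc), ,
             drop = FALSE]
  splits <- split(map$peptide_id, map$kinase_id)
  splits <- lapply(splits, unique)
  keep <- vapply(splits, length, integer(1)) >= min_peptides
  splits <- splits[keep]
  rows <- lapply(names(splits), function(k) {
    p <- splits[[k]]
    kt <- colMeans(mt[p, , drop = FALSE], na.rm = TRUE)  # per-replicate kinase mean
    kc <- colMeans(mc[p, , drop = FALSE], na.rm = TRUE)
    if (pvalue_on == "replicate_means") {
      pv <- ttest_p(kt, kc)
    } else {
      pv <- ttest_p(as.vector(mt[p, , drop = FALSE]),
                    as.vector(mc[p, , drop = FALSE]))
    }
    data.frame(unit = k, delta = mean(kt, na.rm = TRUE) - mean(kc, na.rm = TRUE),
               p_two_sided = pv, n_treated = sum(is.finite(kt)),
               n_control = sum(is.finite(kc)), n_peptides = length(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$unit), ]
  rownames(out) <- NULL
  structure(out, class = c("differential_table", "data.frame"), unit = "kinase")
}

#' Volcano table: effect size versus significance
#'
#' One row per unit (peptide or kinase) with the activity change and
#' `-log10(p)`, sorted by ascending p, ties broken by decreasing `|delta|` and
#' then unit id.
#'
#' @param diff a `differential_table` with p-values.
#' @return data frame with columns `unit`, `delta`, `neg_log10_p`.
#' @export
volcano_table <- function(diff) {
  if (!"p_two_sided" %in% names(diff) || all(is.na(diff$p_two_sided))) {
    stop_kamdecon("differential table has no p-values",
                  class = "kamdecon_configuration_error")
  }
  out <- data.frame(unit = diff$unit, delta = diff$delta,
                    neg_log10_p = -log10(diff$p_two_sided),
                    stringsAsFactors = FALSE)
  out <- out[order(diff$p_two_sided, -abs(out$delta), out$unit), ]
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of an activity matrix
#'
#' Clusters rows and columns of a units-by-conditions matrix with the
#' conventional distance/linkage combinations for phospho-activity signatures:
#' Euclidean distance or (absolute) correlation, centered or uncentered, with
#' Ward, complete or average linkage. Ward linkage requires Euclidean distance.
#' Leaf order is deterministic for fixed input (ties resolved by input order,
#' as in [stats::hclust()]).
#'
#' @param mat numeric matrix, finite entries.
#' @param distance one of `"euclidean"`, `"correlation_centered"`,
#'   `"correlation_uncentered"`, `"abs_correlation"`.
#' @param linkage one of `"ward"`, `"complete"`, `"average"`.
#' @param cluster_columns also cluster the transposed matrix (default TRUE
#'   when the matrix has >= 3 columns).
#' @return list of class `kam_hclust`: `rows` and (optionally) `columns`
#'   [stats::hclust] trees plus `row_order` / `col_order` leaf orders.
#' @export
hier_cluster <- function(mat,
                         distance = c("euclidean", "correlation_centered",
                                      "correlation_uncentered", "abs_correlation"),
                         linkage = c("ward", "complete", "average"),
                         cluster_columns = ncol(mat) >= 3L) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (!all(is.finite(mat))) {
    stop_kamdecon("matrix must be finite", class = "kamdecon_validation_error")
  }
  if (linkage == "ward" && distance != "euclidean") {
    stop_kamdecon("Ward linkage requires Euclidean distance",
                  class = "kamdecon_configuration_error")
  }
  method <- c(ward = "ward.D2", complete = "complete", average = "average")[linkage]
  tree <- function(m) {
    d <- switch(distance,
      euclidean = stats::dist(m),
      correlation_centered = stats::as.dist(1 - stats::cor(t(m))),
      abs_correlation = stats::as.dist(1 - abs(stats::cor(t(m)))),
      correlation_uncentered = {
        num <- m %*% t(m)
        nrm <- sqrt(rowSums(m^2))
        stats::as.dist(1 - num / outer(nrm, nrm))
      })
    stats::hclust(d, method = method)
  }
  rows <- tree(mat)
  out <- list(rows = rows, row_order = rows$order)
  if (isTRUE(cluster_columns)) {
    cols <- tree(t(mat))
    out$columns <- cols
    out$col_order <- cols$order
  }
  structure(out, class = "kam_hclust")
}
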