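flat_plate <- function(value = 20, seed = 1) {
  plate <- simulate_plate(plate_sim_spec(baseline_consumption = value,
                                         noise_sd = 0, seed = seed))
  luminescence_to_atp(plate)
}

test_that("normalization reference matches a brute-force mean for every scheme", {
  plate <- luminescence_to_atp(
    simulate_plate(plate_sim_spec(noise_sd = 3, seed = 21)))
  lay <- attr(plate, "layout")
  pep_classes <- c("biological_peptide", "ystf_free_peptide", "reference_peptide")
  wells <- list(
    internal_mean = plate$well_class %in% c(pep_classes, "peptide_free_control"),
    peptide_free = plate$well_class == "peptide_free_control",
    ystf_free = !is.na(plate$peptide_id) & plate$peptide_id %in% lay$ystf_free_ids,
    reference_peptides = !is.na(plate$peptide_id) & plate$peptide_id %in% lay$reference_ids)
  expect_identical(sum(wells$internal_mean), 242L)
  for (scheme in names(wells)) {
    manual <- mean(plate$atp_consumed_nM[wells[[scheme]]])  # hand loop over wells
    expect_equal(unname(normalization_reference(plate, scheme)), manual,
                 info = scheme)
  }
})

test_that("a constant plate gives the same reference under every scheme and zero activities", {
  plate <- flat_plate(value = 30)
  for (scheme in c("internal_mean", "peptide_free", "ystf_free", "reference_peptides")) {
    expect_equal(unname(normalization_reference(plate, scheme)), 30, info = scheme)
  }
  act <- peptide_activity(plate)
  expect_equal(act$activity, rep(0, nrow(act)))
})

test_that("activities are mean-centering invariant and reproduce the spiked closed form", {
  plate <- flat_plate(value = 20)
  act0 <- peptide_activity(plate)
  shifted <- plate
  shifted$atp_consumed_nM <- plate$atp_consumed_nM + 7  # global plate offset
  expect_equal(peptide_activity(shifted)$activity, act0$activity)

  spiked <- plate
  i <- which(spiked$peptide_id == "pep100")
  spiked$atp_consumed_nM[i] <- spiked$atp_consumed_nM[i] + 10
  act <- peptide_activity(spiked)
  expect_equal(act$activity[act$peptide_id == "pep100"], 10 - 10 / 242)
  expect_equal(unique(round(act$activity[act$peptide_id != "pep100"], 12)),
               round(-10 / 242, 12))
})

test_that("replicate aggregation is an arithmetic mean with the averaging-order identity", {
  m <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("pep", 1:8), NULL))
  prof <- profile_from_matrix(m)
  agg <- aggregate_replicates(prof)
  expect_equal(agg$activity[match(rownames(m), agg$peptide_id)],
               unname(rowMeans(m)))
  expect_identical(unique(agg$n_replicates), 5L)

  one <- aggregate_replicates(profile_from_matrix(m[, 1, drop = FALSE]))
  expect_equal(one$activity, unname(m[order(rownames(m)), 1]))

  sym <- aggregate_replicates(profile_from_matrix(cbind(m[, 1], -m[, 1])))
  expect_equal(sym$activity, rep(0, 8))
})

test_that("mixed normalization schemes refuse to aggregate", {
  m <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("pep", 1:4), NULL))
  a <- profile_from_matrix(m, scheme = "internal_mean")
  b <- profile_from_matrix(m, scheme = "peptide_free")
  expect_error(aggregate_replicates(list(a, b)),
               class = "kamdecon_configuration_error")
})

test_that("differential profile handles identical groups, spikes and study-sized groups", {
  m <- matrix(rnorm(60, sd = 0.5), 6, 10,
              dimnames = list(paste0("pep", 1:6), NULL))
  same <- differential_profile(profile_from_matrix(m, "VEM"),
                               profile_from_matrix(m, "UNT"))
  expect_equal(same$delta, rep(0, 6))
  expect_equal(same$p_two_sided, rep(1, 6))

  set.seed(42)
  treated <- m
  treated["pep3", ] <- treated["pep3", ] + 5
  d <- differential_profile(profile_from_matrix(treated, "VEM"),
                            profile_from_matrix(m, "UNT"))
  expect_identical(d$unit[which.max(abs(d$delta))], "pep3")

  # the study's arm sizes (13 treated vs 23 control) are accepted
  big <- differential_profile(
    profile_from_matrix(matrix(rnorm(13 * 4), 4, 13,
                               dimnames = list(paste0("pep", 1:4), NULL)), "VEM"),
    profile_from_matrix(matrix(rnorm(23 * 4), 4, 23,
                               dimnames = list(paste0("pep", 1:4), NULL)), "UNT"))
  expect_identical(unique(big$n_treated), 13L)
  expect_identical(unique(big$n_control), 23L)
})

test_that("vectorized differential t-test agrees with stats::t.test", {
  set.seed(11)
  mt <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("pep", 1:10), NULL))
  mc <- matrix(rnorm(70, mean = 0.4), 10, 7,
               dimnames = list(paste0("pep", 1:10), NULL))
  d <- differential_profile(profile_from_matrix(mt, "VEM"),
                            profile_from_matrix(mc, "UNT"))
  for (p in d$unit) {
    expect_equal(d$p_two_sided[d$unit == p],
                 t.test(mt[p, ], mc[p, ], var.equal = TRUE)$p.value,
                 tolerance = 1e-12, info = p)
  }
})

test_that("deconvolution averages peptide subsets and applies the >=3 peptide rule", {
  prof <- structure(data.frame(peptide_id = paste0("pep", 1:5),
                               activity = c(1, 2, 3, 10, 20)),
                    class = c("activity_profile", "data.frame"),
                    scheme = "internal_mean")
  map <- peptide_kinase_map(c("pep1", "pep2", "pep3", "pep4", "pep5"),
                            c("K3", "K3", "K3", "K2", "K2"))
  sig <- deconvolute(prof, map)
  expect_identical(sig$kinase_id, "K3")
  expect_equal(sig$value, 2)
  expect_identical(sig$n_peptides, 3L)
  expect_identical(attr(sig, "omitted"), "K2")  # below the >=3 peptide threshold
})

test_that("deconvolution equals a brute-force incidence loop on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    n_pep <- sample(10:30, 1)
    peps <- sprintf("p%02d", seq_len(n_pep))
    act <- rnorm(n_pep)
    n_k <- sample(3:8, 1)
    map_df <- do.call(rbind, lapply(seq_len(n_k), function(k) {
      data.frame(peptide_id = sample(peps, sample(2:7, 1)),
                 kinase_id = paste0("K", k))
    }))
    map <- peptide_kinase_map(map_df$peptide_id, map_df$kinase_id)
    prof <- structure(data.frame(peptide_id = peps, activity = act),
                      class = c("activity_profile", "data.frame"),
                      scheme = "internal_mean")
    sig <- deconvolute(prof, map)
    # independent loop oracle
    for (k in unique(map$kinase_id)) {
      subset <- unique(map$peptide_id[map$kinase_id == k])
      if (length(subset) >= 3) {
        expected <- mean(act[match(subset, peps)])
        expect_equal(sig$value[sig$kinase_id == k], expected, info = k)
      } else {
        expect_false(k %in% sig$kinase_id)
      }
    }
  }
})

test_that("deconvolution is linear: a uniform shift of a kinase's subset moves its value by the shift", {
  prof <- structure(data.frame(peptide_id = paste0("pep", 1:6),
                               activity = rnorm(6)),
                    class = c("activity_profile", "data.frame"),
                    scheme = "internal_mean")
  map <- peptide_kinase_map(paste0("pep", 1:6), rep(c("KA", "KB"), each = 3))
  base <- deconvolute(prof, map)
  prof2 <- prof
  prof2$activity[1:3] <- prof2$activity[1:3] + 2.5
  shifted <- deconvolute(prof2, map)
  expect_equal(shifted$value[shifted$kinase_id == "KA"],
               base$value[base$kinase_id == "KA"] + 2.5)
  expect_equal(shifted$value[shifted$kinase_id == "KB"],
               base$value[base$kinase_id == "KB"])
})

test_that("internal-mean and peptide-free schemes agree when controls equal the peptide mean", {
  lay <- mini_layout(n_pep = 6L, n_pfc = 2L)
  pep <- c(1, 2, 3, 4, 5, 6) + 20
  plate <- make_plate(lay, pep, rep(mean(pep), 2))
  a <- peptide_activity(plate, "internal_mean")
  b <- peptide_activity(plate, "peptide_free")
  expect_equal(a$activity, b$activity)
})

test_that("volcano table ranks by significance with deterministic tie-breaks", {
  diff <- structure(data.frame(unit = c("a", "b", "c", "d"),
                               delta = c(1, -3, 2, 0.5),
                               p_two_sided = c(0.5, 0.01, 0.01, 1)),
                    class = c("differential_table", "data.frame"))
  v <- volcano_table(diff)
  expect_identical(v$unit, c("b", "c", "a", "d"))  # p asc, |delta| desc
  expect_equal(v$neg_log10_p, -log10(c(0.01, 0.01, 0.5, 1)))

  flat <- structure(data.frame(unit = c("x", "y"), delta = c(0, 0),
                               p_two_sided = c(1, 1)),
                    class = c("differential_table", "data.frame"))
  vf <- volcano_table(flat)
  expect_equal(vf$delta, c(0, 0))
  expect_equal(vf$neg_log10_p, c(0, 0))
})

test_that("an injected kinase shift tops the deconvoluted volcano", {
  lay <- plate_layout()
  map <- simulate_kinase_map(lay, seed = 5)
  trt <- luminescence_to_atp(simulate_plate(plate_sim_spec(
    lay, map, c(KIN07 = 5), n_bio_reps = 5, treatment = "VEM", seed = 31)))
  ctl <- luminescence_to_atp(simulate_plate(plate_sim_spec(
    lay, map, n_bio_reps = 5, treatment = "UNT", seed = 32)))
  kd <- kinase_differential(peptide_activity(trt), peptide_activity(ctl), map)
  expect_identical(volcano_table(kd)$unit[1], "KIN07")
  expect_identical(nrow(volcano_table(kd)), nrow(kd))  # one row per deconvolutable kinase
})

test_that("hierarchical clustering honors the distance/linkage contract", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(5, 5, 5))
  h <- hier_cluster(m, "euclidean", "average")
  expect_equal(h$rows$height[1], 0)  # identical rows merge first at height 0

  m2 <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("x", "y", "z"), NULL))
  h2 <- hier_cluster(m2, "euclidean", "average", cluster_columns = FALSE)
  # hand-computed: {0,1} merge at 1, then 10 joins at mean(10, 9) = 9.5
  expect_equal(h2$rows$height, c(1, 9.5))
  expect_identical(h2$rows$labels[h2$rows$merge[1, ] * -1], c("x", "y"))

  expect_error(hier_cluster(m, "correlation_centered", "ward"),
               class = "kamdecon_configuration_error")
  expect_error(hier_cluster(rbind(c(1, NA), c(0, 1)), "euclidean", "average"),
               class = "kamdecon_validation_error")
})

test_that("block-structured matrices cluster into their condition groups", {
  set.seed(8)
  base <- matrix(rnorm(40, sd = 0.2), 10, 4)
  mat <- cbind(base + 5, base)  # two condition groups of 4 columns
  colnames(mat) <- paste0("c", 1:8)
  rownames(mat) <- paste0("u", 1:10)
  h <- hier_cluster(mat, "euclidean", "complete")
  ord <- h$col_order
  grp <- rep(1:2, each = 4)[ord]
  expect_true(all(diff(grp) >= 0) || all(diff(grp) <= 0))  # groups contiguous
})
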