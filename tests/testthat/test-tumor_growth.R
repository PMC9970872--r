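make_panel <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df
}

test_that("relative volume is percent of day-1 baseline, matching a per-mouse loop", {
  panel <- simulate_tumor_study(growth_sim_spec(seed = 14))
  rel <- relative_volume(panel)
  expect_equal(rel$rel_volume[rel$day == 1], rep(100, sum(rel$day == 1)))
  for (i in sample(nrow(rel), 50)) {
    v1 <- panel$volume_mm3[panel$mouse_id == rel$mouse_id[i] &
                             panel$arm == rel$arm[i] & panel$day == 1]
    expect_equal(rel$rel_volume[i], 100 * rel$volume_mm3[i] / v1)
  }

  doubled <- make_panel(model_id = "m", arm = "a", mouse_id = "x",
                        day = c(1L, 8L), volume_mm3 = c(120, 240))
  expect_equal(relative_volume(doubled)$rel_volume, c(100, 200))

  no_base <- make_panel(model_id = "m", arm = "a", mouse_id = c("x", "x", "y"),
                        day = c(1L, 8L, 8L), volume_mm3 = c(100, 150, 200))
  expect_warning(out <- relative_volume(no_base), "excluded")
  expect_false("y" %in% out$mouse_id)
})

test_that("zero-normalization centers the vehicle arm at every (model, day) and is idempotent", {
  panel <- simulate_tumor_study(growth_sim_spec(seed = 15))
  adj <- zero_normalize(relative_volume(panel))
  veh <- adj[adj$arm == "vehicle", ]
  means <- tapply(veh$adjusted, veh$day, mean)
  expect_equal(as.vector(means), rep(0, length(means)))

  # idempotence: re-normalizing the adjusted response changes nothing
  again <- adj
  again$rel_volume <- again$adjusted
  adj2 <- zero_normalize(again)
  expect_equal(adj2$adjusted, adj2$rel_volume)
})

test_that("a constant treatment shift survives zero-normalization", {
  days <- c(1L, 5L, 10L)
  veh <- expand.grid(mouse_id = paste0("v", 1:4), day = days)
  trt <- expand.grid(mouse_id = paste0("t", 1:4), day = days)
  panel <- rbind(
    make_panel(model_id = "m", arm = "vehicle", mouse_id = veh$mouse_id,
               day = veh$day, volume_mm3 = 100 + 10 * veh$day),
    make_panel(model_id = "m", arm = "treated", mouse_id = trt$mouse_id,
               day = trt$day, volume_mm3 = 100 + 10 * trt$day))
  rel <- relative_volume(panel)
  rel$rel_volume[rel$arm == "treated"] <- rel$rel_volume[rel$arm == "treated"] - 50
  adj <- zero_normalize(rel)
  expect_equal(adj$adjusted[adj$arm == "treated" & adj$day > 1],
               rep(-50, sum(adj$arm == "treated" & adj$day > 1)))
})

test_that("GLM effect sizes are positive under inhibition and ordered by strength", {
  panel <- simulate_tumor_study(growth_sim_spec(seed = 16))
  adj <- zero_normalize(relative_volume(panel))
  eff <- rbind(glm_effect(adj, "doublet"), glm_effect(adj, "triplet"))
  expect_true(all(eff$std_coefficient > 0))
  expect_lt(eff$std_coefficient[1], eff$std_coefficient[2])  # stronger arm larger
  expect_true(all(!eff$not_testable))
})

test_that("contrasts with an unusable design are flagged not-testable, not errored", {
  panel <- simulate_tumor_study(growth_sim_spec(seed = 17))
  adj <- zero_normalize(relative_volume(panel))
  gone <- adj[adj$arm != "triplet" | adj$mouse_id == "triplet_m01", ]
  est <- glm_effect(gone, "triplet")
  expect_true(est$not_testable)
  expect_true(is.na(est$std_coefficient))
})

test_that("Benjamini-Hochberg correction matches the hand-computed step-up", {
  ests <- data.frame(p_raw = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(fdr_correct(ests)$p_fdr, rep(0.04, 4))
  expect_equal(fdr_correct(data.frame(p_raw = 0.2))$p_fdr, 0.2)
  expect_equal(fdr_correct(data.frame(p_raw = rep(1, 5)))$p_fdr, rep(1, 5))
})

test_that("per-day tests mark unavailable cells and detect separated arms", {
  days <- c(1L, 5L, 10L)
  grid <- expand.grid(mouse_id = 1:4, day = days)
  panel <- rbind(
    make_panel(model_id = "m", arm = "a", mouse_id = paste0("a", grid$mouse_id),
               day = grid$day, volume_mm3 = 100 + grid$day + grid$mouse_id),
    make_panel(model_id = "m", arm = "b", mouse_id = paste0("b", grid$mouse_id),
               day = grid$day, volume_mm3 = 100 + grid$day + grid$mouse_id))
  rel <- relative_volume(panel)
  same <- timepoint_tests(rel, list(c("a", "b")))
  expect_equal(unname(same[1, ]), c(1, 1, 1))  # identical arms: degenerate p = 1

  # all of arm b dropped at day 10 -> not-available cell
  dropped <- rel[!(rel$arm == "b" & rel$day == 10L), ]
  p <- timepoint_tests(dropped, list(c("a", "b")))
  expect_true(is.na(p[1, "10"]))

  sep <- rel
  sep$rel_volume[sep$arm == "b" & sep$day > 1] <-
    sep$rel_volume[sep$arm == "b" & sep$day > 1] + 200
  ps <- timepoint_tests(sep, list(c("a", "b")))
  expect_true(all(ps[1, c("5", "10")] < 0.05))
})

test_that("waterfall caps displayed change at 200% and counts regressions correctly", {
  panel <- make_panel(
    model_id = "m", arm = rep("quad", 3), mouse_id = c("t1", "t2", "t3"),
    day = rep(c(1L, 10L, 21L), each = 3),
    volume_mm3 = c(100, 100, 100,   # day 1
                   200, 120, 100,   # day 10
                   350, 150, 80))   # day 21: tripled, grew, regressed
  wf <- waterfall(panel)
  expect_equal(wf$tumors$rel_change[wf$tumors$mouse_id == "t1"], 200)  # capped
  expect_equal(wf$tumors$rel_change_uncapped[wf$tumors$mouse_id == "t1"], 350)
  expect_equal(wf$tumors$rel_change[wf$tumors$mouse_id == "t2"], 150)
  expect_false(wf$tumors$regressed_vs_d1[wf$tumors$mouse_id == "t2"])
  expect_true(wf$tumors$regressed_vs_d1[wf$tumors$mouse_id == "t3"])
  expect_true(wf$tumors$regressed_vs_mid[wf$tumors$mouse_id == "t3"])
  expect_equal(wf$arms$pct_regressing_d1, 100 / 3)

  flat <- make_panel(model_id = "m", arm = "a", mouse_id = "x",
                     day = c(1L, 21L), volume_mm3 = c(100, 100))
  wf2 <- waterfall(flat)
  expect_equal(wf2$tumors$rel_change, 100)
  expect_false(wf2$tumors$regressed_vs_d1)
  expect_true(is.na(wf2$tumors$regressed_vs_mid))  # no mid-treatment record
})

test_that("a constructed arm with 7 of 9 shrinking tumors reports 77.8% regressing", {
  v21 <- c(rep(80, 7), 120, 150)
  panel <- make_panel(model_id = "m", arm = "arm1", mouse_id = paste0("t", 1:9),
                      day = rep(c(1L, 21L), each = 9),
                      volume_mm3 = c(rep(100, 9), v21))
  wf <- waterfall(panel)
  expect_equal(wf$arms$pct_regressing_d1, 100 * 7 / 9, tolerance = 1e-12)
})

test_that("waterfall percent-regressing equals a brute-force count on random panels", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    v1 <- runif(n, 90, 160)
    v21 <- v1 * exp(rnorm(n, 0, 0.6))
    panel <- make_panel(model_id = "m", arm = "a", mouse_id = paste0("t", 1:n),
                        day = rep(c(1L, 21L), each = n), volume_mm3 = c(v1, v21))
    wf <- waterfall(panel)
    expect_equal(wf$arms$pct_regressing_d1, 100 * sum(v21 < v1) / n)
  }
})
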