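test_that("drought indices evaluate exactly", {
  expect_equal(yrr(30, 200), 0.85)
  expect_equal(yrr(200, 200), 0)
  expect_equal(yrr(0, 200), 1)
  expect_error(yrr(10, 0), "positive")
  expect_equal(dsi(60, 100, 50, 100), 0.8)
  expect_equal(dsi(100, 100, 50, 100), 0)
  expect_equal(dsi(50, 100, 50, 100), 1)   # variety tracks the population
  expect_error(dsi(50, 100, 100, 100), "DSI undefined")
  expect_equal(dri(50, 100, 50, 100), 1)
  expect_equal(dri(100, 100, 100, 100), 1)
  expect_equal(dri(0, 100, 50, 100), 0)
  expect_error(dri(50, 100, 0, 100), "Y_A")
})

test_that("indices are invariant to rescaling all yields", {
  set.seed(41)
  for (i in 1:10) {
    ya <- runif(1, 10, 100); ym <- runif(1, 100, 300)
    YA <- runif(1, 20, 90); YM <- runif(1, 100, 300)
    c1 <- runif(1, 0.1, 10)
    expect_equal(yrr(ya, ym), yrr(c1 * ya, c1 * ym), tolerance = 1e-12)
    expect_equal(dsi(ya, ym, YA, YM), dsi(c1 * ya, c1 * ym, c1 * YA, c1 * YM),
                 tolerance = 1e-12)
    expect_equal(dri(ya, ym, YA, YM), dri(c1 * ya, c1 * ym, c1 * YA, c1 * YM),
                 tolerance = 1e-12)
  }
})

test_that("tolerance classification recovers the generating groups", {
  grp <- rep(c("L1", "L2", "L3"), c(9, 5, 3))
  y <- generate_yields(17, grp, c(L1 = 0.85, L2 = 0.48, L3 = 0.27),
                       cv = 0.05, seed = 7)
  rec <- classify_tolerance(drought_indices(variety_yields(y)))
  expect_equal(adjusted_rand_index(rec$group,
                                   rec$group[match(rec$variety_id, rec$variety_id)]), 1)
  truth_grp <- y$group[match(rec$variety_id, y$variety_id)]
  expect_equal(adjusted_rand_index(rec$group, truth_grp), 1)
  # labels are ordered by descending mean YRR
  m <- tapply(rec$yrr, rec$group, mean)
  expect_true(m["L1"] > m["L2"] && m["L2"] > m["L3"])
})

test_that("classification is order-invariant and guards degeneracy", {
  grp <- rep(c("L1", "L2", "L3"), c(5, 4, 3))
  y <- generate_yields(12, grp, c(L1 = 0.8, L2 = 0.5, L3 = 0.2),
                       cv = 0.03, seed = 9)
  idx <- drought_indices(variety_yields(y))
  a <- classify_tolerance(idx)
  set.seed(10)
  b <- classify_tolerance(idx[sample(nrow(idx)), ])
  expect_equal(a$group[order(a$variety_id)], b$group[order(b$variety_id)])
  # identical indices: degenerate but deterministic
  same <- data.frame(variety_id = sprintf("V%02d", 1:5),
                     yrr = 0.5, dsi = 1, dri = 0.8)
  expect_warning(dg <- classify_tolerance(same), "degenerate")
  expect_true(attr(dg, "degenerate"))
  expect_equal(nrow(dg), 5L)
  # non-finite rows are excluded with a warning
  bad <- data.frame(variety_id = sprintf("V%02d", 1:6),
                    yrr = c(0.9, 0.8, 0.5, 0.4, 0.1, NA),
                    dsi = c(1.2, 1.1, 0.7, 0.6, 0.2, 0.4),
                    dri = c(0.1, 0.2, 0.6, 0.7, 1.2, 0.9))
  expect_warning(cl <- classify_tolerance(bad), "V06")
  expect_equal(nrow(cl), 5L)
  expect_error(classify_tolerance(bad[1:2, ]), "fewer")
})

test_that("two well-separated groups still split into k = 3 by YRR order", {
  toy <- data.frame(variety_id = sprintf("V%02d", 1:6),
                    yrr = c(0.90, 0.88, 0.89, 0.20, 0.21, 0.19),
                    dsi = c(1.5, 1.45, 1.48, 0.3, 0.32, 0.29),
                    dri = c(0.05, 0.06, 0.05, 1.2, 1.18, 1.21))
  cl <- classify_tolerance(toy, k = 3)
  expect_equal(length(unique(cl$group)), 3L)
  m <- tapply(cl$yrr, cl$group, mean)
  expect_true(all(diff(m[order(names(m))]) <= 0))  # L1 >= L2 >= L3
})

test_that("group dynamics report means, stds and change rates", {
  ph <- fab_phenos(list(D45 = c(1.7, 1.9), D60 = c(1.75, 1.85),
                        D70 = c(1.7, 1.82), D95 = c(1.6, 1.72)))
  ph$height[ph$stage == "D60"] <- c(1.75, 1.85)  # mean 1.80
  ph$height[ph$stage == "D95"] <- c(1.60, 1.72)  # mean 1.66
  groups <- data.frame(variety = 1L, group = "L1")
  dyn <- group_dynamics(ph, groups, "L1", "height")
  expect_equal(dyn$mean[dyn$stage == "D60"], 1.80)
  # 1.80 -> 1.66 is the -7.78% change the trial reported as -8%
  d95 <- dyn$change_rate[dyn$stage == "D95"]
  i70 <- dyn$mean[dyn$stage == "D70"]
  expect_equal(d95, (1.66 - i70) / i70, tolerance = 1e-12)
  direct <- (1.66 - 1.80) / 1.80
  expect_equal(round(100 * direct), -8)
  # first stage and stages after a gap have undefined change rates
  expect_true(is.na(dyn$change_rate[dyn$stage == "D45"]))
  expect_true(is.na(dyn$change_rate[dyn$stage == "D35"]))
  expect_true(is.na(dyn$change_rate[dyn$stage == "D20"]))
  # constant series: all defined change rates are zero
  ph2 <- fab_phenos(list(D20 = c(1, 1), D35 = c(1, 1), D45 = c(1, 1)))
  dyn2 <- group_dynamics(ph2, groups, "L1", "height")
  expect_equal(dyn2$change_rate[dyn2$stage %in% c("D35", "D45")], c(0, 0))
  # change rates reconstruct the mean series from the first value
  r <- dyn$change_rate[dyn$stage %in% c("D60", "D70", "D95")]
  rebuilt <- dyn$mean[dyn$stage == "D45"] * cumprod(1 + r)
  expect_equal(rebuilt, dyn$mean[dyn$stage %in% c("D60", "D70", "D95")],
               tolerance = 1e-12)
})

test_that("stage significance testing behaves at the extremes", {
  groups <- data.frame(variety = 1L, group = "L1")
  same <- fab_phenos(list(D45 = c(1, 1, 1), D60 = c(1, 1, 1)))
  res <- stage_significance(same, groups, "L1", "height", "D45", "D60")
  expect_equal(res$p_value, 1)
  expect_false(res$sig_05)
  set.seed(43)
  far <- fab_phenos(list(D45 = rnorm(10, 0, 1), D60 = rnorm(10, 10, 1)))
  res2 <- stage_significance(far, groups, "L1", "height", "D45", "D60")
  expect_lt(res2$p_value, 0.01)
  expect_true(res2$sig_01)
  small <- fab_phenos(list(D45 = 1, D60 = c(1, 2)))
  expect_error(stage_significance(small, groups, "L1", "height",
                                  "D45", "D60"), "at least 2")
})

test_that("PAD profiles average the group's plants per layer", {
  ph <- data.frame(plant_id = c("a", "b"), variety = 1L, row = 1:2,
                   stage = "D60",
                   pad_l1 = c(0.2, 0.4), pad_l2 = c(0.5, 0.7),
                   pad_l3 = c(0.9, 1.1), pad_l4 = c(0.6, 0.8),
                   pad_l5 = c(0.3, 0.5))
  groups <- data.frame(variety = 1L, group = "L3")
  pr <- pad_profile(ph, groups, "L3", "D60")
  expect_equal(unname(pr$mean), c(0.3, 0.6, 1.0, 0.7, 0.4))
  expect_equal(pr$n, 2L)
  # single-plant group: profile equals that plant, zero spread undefined-free
  pr1 <- pad_profile(ph[1, ], groups, "L3", "D60")
  expect_equal(unname(pr1$mean), unlist(ph[1, paste0("pad_l", 1:5)],
                                        use.names = FALSE))
  empty <- pad_profile(ph, groups, "L3", "D95")
  expect_true(all(is.na(empty$mean)))
})

test_that("a 20% smaller upper canopy shows up in the truth profiles", {
  base_area <- c(0.03, 0.07, 0.09, 0.08, 0.045)
  tol_area <- base_area * c(1, 1, 1, 0.8, 0.8)  # high tolerance: smaller top
  mk <- function(areas, seed) {
    g <- generate_plant(plant_spec(1.8, c(3, 4, 5, 4, 3), areas),
                        point_spacing = 0.01, seed = seed)
    unlist(g$truth[paste0("true_pad_l", 1:5)])
  }
  low <- colMeans(rbind(mk(base_area, 1), mk(base_area, 2)))
  high <- colMeans(rbind(mk(tol_area, 3), mk(tol_area, 4)))
  expect_lt(high[4], low[4])
  expect_lt(high[5], low[5])
  expect_equal(unname(high[4] / low[4]), 0.8, tolerance = 0.05)
})
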