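tg <- model_time_grid()

test_that("weight initialization is seeded and symmetric", {
  spec <- nn_spec(n_inputs = 6)
  expect_identical(nn_build(spec, 1)$W1, nn_build(spec, 1)$W1)
  expect_false(identical(nn_build(spec, 1)$W1, nn_build(spec, 2)$W1))
})

test_that("an untrained network stays near baseline in closed loop", {
  spec <- nn_spec(n_inputs = 6)
  panel <- default_agonist_panel()
  null_sched <- sched_from_dose(c(ADP = 0), panel)
  for (seed in 1:10) {
    nn <- nn_build(spec, seed)
    tr <- predict_closed_loop(nn, null_sched, tg)
    expect_true(all(tr$values >= 0.5 & tr$values <= 1.5))
  }
})

test_that("invalid lag sets are rejected", {
  expect_error(nn_spec(6, lags_s = c(2, 1)), "increasing")
  expect_error(nn_spec(6, lags_s = c(1, 2.5), dt_s = 1), "multiples")
})

test_that("training pairs carry baseline-padded lag features and counts", {
  panel <- default_agonist_panel()
  des <- enumerate_pairwise(panel, dose_grid(1))
  sch <- design_schedules(des, panel)
  d <- quiet_donor()
  ex <- average_experiment(simulate_experiment(d, sch, tg, replicates = 1,
                                               design = des))
  spec <- nn_spec(n_inputs = 6)
  pairs <- make_training_pairs(ex, spec)
  n_post <- sum(tg > 0)
  expect_equal(nrow(pairs$X), nrow(des) * n_post)
  expect_equal(unname(table(pairs$condition)), rep(n_post, nrow(des)),
               ignore_attr = TRUE)
  # null condition: all feedback slots 1, all targets 1, dose channels 0
  null_rows <- pairs$condition == which(des$label == "null")
  lag_cols <- 6 + seq_along(spec$lags_s)
  expect_true(all(pairs$X[null_rows, lag_cols] == 1))
  expect_true(all(pairs$X[null_rows, 1:6] == 0))
  expect_true(all(pairs$y[null_rows] == 1))
})

test_that("lag features match a hand-constructed table on a toy trace", {
  panel <- tiny_panel(1)
  tg_toy <- seq(-2, 7, by = 1)   # 10 grid points, 7 targets
  vals <- c(1, 1, 1, 1.1, 1.3, 1.6, 1.8, 1.9, 1.7, 1.5)
  sched <- sched_from_dose(c(A1 = 1), panel, horizon_s = 7)
  ex <- pas_experiment("T", "pairwise", NULL, list(sched), tg_toy,
                       matrix(vals, ncol = 1))
  spec <- nn_spec(n_inputs = 1, lags_s = c(1, 2), dt_s = 1)
  pairs <- make_training_pairs(ex, spec)
  targets <- which(tg_toy > 0)
  expect_equal(pairs$y, vals[targets])
  expect_equal(unname(pairs$X[, "lag1"]), vals[targets - 1])
  expect_equal(unname(pairs$X[, "lag2"]), vals[targets - 2])
  expect_equal(unname(pairs$X[, 1]), rep(log10(2) / log10(11), 7))
})

test_that("a constant-target problem is fit to machine-level MSE", {
  panel <- tiny_panel(1)
  tg_s <- model_time_grid(5, 60, 1)
  scheds <- lapply(c(0.1, 1, 10, 0.5, 2, 5, 8, 0.2, 3, 7), function(d)
    sched_from_dose(c(A1 = d), panel, horizon_s = 60))
  ex <- pas_experiment("C", "pairwise", NULL, scheds, tg_s,
                       matrix(1, length(tg_s), length(scheds)))
  spec <- nn_spec(n_inputs = 1, lags_s = c(1, 2, 4, 8, 16),
                  max_epochs = 200, patience = 200)
  nn <- nn_train(nn_build(spec, 3), make_training_pairs(ex, spec))
  expect_lt(nn$train_mse, 1e-6)
  pred <- predict_closed_loop(nn, scheds[[1]], tg_s)
  expect_true(all(abs(pred$values - 1) < 1e-3))
})

test_that("early stopping halts once validation error plateaus", {
  panel <- tiny_panel(1)
  tg_s <- model_time_grid(5, 60, 1)
  scheds <- lapply(c(0.1, 1, 10, 0.5, 2, 5, 8, 0.2, 3, 7), function(d)
    sched_from_dose(c(A1 = d), panel, horizon_s = 60))
  ex <- pas_experiment("C", "pairwise", NULL, scheds, tg_s,
                       matrix(1, length(tg_s), length(scheds)))
  spec <- nn_spec(n_inputs = 1, lags_s = c(1, 2, 4, 8, 16),
                  max_epochs = 1000, patience = 5)
  nn <- nn_train(nn_build(spec, 3), make_training_pairs(ex, spec))
  expect_lt(nn$epochs_run, 1000)
  expect_equal(nrow(nn$history), nn$epochs_run)
})

test_that("the network fits a noise-free synthetic donor teacher-forced", {
  d <- sub_panel_donor(c("ADP", "CVX", "Thrombin"))
  panel <- d$panel
  des <- enumerate_pairwise(panel, dose_grid())
  sch <- design_schedules(des, panel)
  ex <- average_experiment(simulate_experiment(d, sch, tg, replicates = 1,
                                               design = des))
  spec <- fast_spec(n_inputs = 3)
  pairs <- make_training_pairs(ex, spec)
  nn <- nn_train(nn_build(spec, 11), pairs, split_seed = 2)
  one_step_mse <- mean((nn_one_step(nn, pairs) - pairs$y)^2)
  expect_lt(one_step_mse, 1e-3)

  # closed loop on a training condition tracks the simulation
  idx <- which(des$label == "CVX:1|Thrombin:1")
  pred <- predict_closed_loop(nn, sch[[idx]], tg)
  expect_gt(pearson_r(pred$values, ex$traces[, idx]), 0.95)

  # teacher-forced one-step error lower-bounds closed-loop error
  pred_all <- nn_predict_closed_loop(
    nn, lapply(sch, condition_input_series, time_s = tg), tg)
  sel <- tg > 0
  closed_mse <- mean((pred_all[sel, ] - ex$traces[sel, ])^2)
  expect_lte(one_step_mse, closed_mse)
})

test_that("the one-step map is pure and long-horizon prediction stays bounded", {
  spec <- nn_spec(n_inputs = 6)
  nn <- nn_build(spec, 5)
  X <- matrix(runif(14 * 3), 3, 14)
  expect_identical(pascalc:::nn_forward_raw(nn, X),
                   pascalc:::nn_forward_raw(nn, X))
  # horizon far beyond the training window remains finite
  long_tg <- model_time_grid(20, 3000, 1)
  panel <- default_agonist_panel()
  sched <- sched_from_dose(c(CVX = 10, Thrombin = 10), panel,
                           horizon_s = 3000)
  tr <- predict_closed_loop(nn, sched, long_tg)
  expect_true(all(is.finite(tr$values)))
  # output is inherently bounded by the tanh layer
  bound <- (sum(abs(nn$w2)) + abs(nn$b2)) * nn$y_scale + nn$y_center
  expect_true(all(tr$values <= bound & tr$values >= spec$floor))
})

test_that("weights round-trip bit-exactly through JSON", {
  spec <- nn_spec(n_inputs = 6)
  nn <- nn_build(spec, 9)
  nn$x_center <- runif(14); nn$x_scale <- runif(14) + 0.5
  nn$y_center <- 1.234567891011; nn$y_scale <- 0.987654321
  f <- withr::local_tempfile(fileext = ".json")
  nn_save_json(nn, f)
  back <- nn_load_json(f)
  expect_identical(back$W1, nn$W1)
  expect_identical(back$b1, nn$b1)
  expect_identical(back$w2, nn$w2)
  expect_identical(back$b2, nn$b2)
  expect_identical(back$x_center, nn$x_center)
  expect_identical(back$y_scale, nn$y_scale)
  X <- matrix(runif(28), 2, 14)
  expect_identical(pascalc:::nn_forward_raw(back, X),
                   pascalc:::nn_forward_raw(nn, X))
})
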