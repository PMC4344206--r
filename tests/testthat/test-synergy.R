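tg <- model_time_grid()

test_that("raw synergy is the deviation from additivity", {
  expect_equal(raw_synergy(5, c(2, 3)), 0)
  expect_equal(raw_synergy(8, c(2, 3)), 3)
  expect_error(raw_synergy(5, 2), "at least 2")
})

test_that("raw synergy from simulated AUCs equals the ground-truth oracle", {
  d <- quiet_donor()
  panel <- d$panel
  des <- enumerate_pairwise(panel, dose_grid())
  for (lab in c("CVX:1|Thrombin:1", "ADP:0.1|Iloprost:10",
                "Thrombin:10|U46619:1", "U46619:0.1|GSNO:1")) {
    row <- des[des$label == lab, ]
    dose <- as.numeric(row[1, panel$name]); names(dose) <- panel$name
    a_comb <- trace_auc(simulate_trace(d, sched_from_dose(dose, panel), tg))
    singles <- vapply(names(dose)[dose > 0], function(a) {
      dd <- dose * 0; dd[a] <- dose[a]
      trace_auc(simulate_trace(d, sched_from_dose(dd, panel), tg))
    }, numeric(1))
    expect_equal(raw_synergy(a_comb, singles),
                 ground_truth_synergy(d, row, tg), tolerance = 1e-9)
  }
})

test_that("normalization scales to the maximum absolute deviation", {
  res <- normalize_synergy(c(2, -4))
  expect_equal(res$scores, c(0.5, -1))
  expect_equal(res$norm_const, 4)
  zero <- normalize_synergy(c(0, 0, 0))
  expect_equal(zero$scores, c(0, 0, 0))
  expect_equal(zero$norm_const, 0)
  set.seed(31)
  for (i in 1:20) {
    deltas <- rnorm(sample(3:40, 1)) * 10^runif(1, -3, 3)
    res <- normalize_synergy(deltas)
    expect_equal(max(abs(res$scores)), 1)
    expect_true(all(res$scores * deltas >= 0))        # signs preserved
    expect_equal(res$scores * res$norm_const, deltas) # invertible
  }
})

test_that("the pairwise design yields 135 scores and the trinary 160", {
  d <- quiet_donor()
  panel <- d$panel
  des <- enumerate_pairwise(panel, dose_grid())
  ex <- average_experiment(simulate_experiment(
    d, design_schedules(des, panel), tg, replicates = 1, design = des))
  syn <- synergy_vector(ex)
  expect_equal(nrow(syn), 135)
  expect_equal(max(abs(syn$score)), 1)
  expect_true(all(syn$order == 2))

  tri <- enumerate_trinary(panel, dose_grid(c(0.1, 1)))
  ext <- average_experiment(simulate_experiment(
    d, design_schedules(tri, panel), tg, replicates = 1, design = tri))
  synt <- synergy_vector(ext)
  expect_equal(nrow(synt), 160)
  expect_true(all(synt$order == 3))
})

test_that("a missing constituent single is reported by name", {
  d <- quiet_donor()
  panel <- d$panel
  des <- enumerate_pairwise(panel, dose_grid(1))
  drop_idx <- which(des$label == "ADP:1")
  des2 <- des[-drop_idx, ]
  class(des2) <- class(des)
  ex <- average_experiment(simulate_experiment(
    d, design_schedules(des2, panel), tg, replicates = 1, design = des2))
  expect_error(synergy_vector(ex), "ADP:1")
})

test_that("an additive donor gives near-zero scores after noise averaging", {
  pop <- default_donor_params()
  pop$crosstalk <- matrix(0, 6, 6)
  pop$saturation_K <- 1e9
  pop$fmax <- 1e9 / 4    # keep the response slope finite
  pop$donor_cv <- 0
  pop$kinetics$inhibitor_potency[] <- 0  # fully additive: no inhibition
  panel <- pop$panel
  des <- enumerate_pairwise(panel, dose_grid(c(0.1, 1)))
  ex <- average_experiment(simulate_experiment(
    d <- pop, design_schedules(des, panel), tg, replicates = 4, seed = 17,
    design = des))
  syn <- synergy_vector(ex)
  # deviations are pure noise; compare them to the scale of the responses
  aucs <- experiment_aucs(ex)
  rel <- syn$raw_delta / max(abs(aucs))
  expect_true(all(abs(rel) < 0.05))
})

test_that("percent inhibition recovers a multiplicative factor", {
  expect_equal(percent_inhibition(10, 10), 0)
  expect_equal(percent_inhibition(10, 2), 80)
  expect_error(percent_inhibition(0, 1), "positive")
  # donor with inhibitor potency 4 => drive factor 1/(1+4) = 0.2 at 1x
  pop <- quiet_donor(saturation_K = 1e9, fmax = 1e9 / 4)
  pop$kinetics$inhibitor_potency[pop$panel$name == "Iloprost"] <- 4
  panel <- pop$panel
  a_alone <- trace_auc(simulate_trace(pop, sched_from_dose(c(CVX = 1), panel), tg))
  a_inhib <- trace_auc(simulate_trace(
    pop, sched_from_dose(c(CVX = 1, Iloprost = 1), panel), tg))
  expect_equal(percent_inhibition(a_alone, a_inhib), 80, tolerance = 1e-6)
})

test_that("Hill fitting recovers exact and noisy parameters", {
  doses <- 10^seq(-2, 2, length.out = 9)
  hill <- function(d, bottom, top, ec50, h)
    bottom + (top - bottom) * d^h / (d^h + ec50^h)
  exact <- hill(doses, 0, 10, 1, 2)
  fit <- fit_hill_ec50(doses, exact)
  expect_equal(fit$ec50, 1, tolerance = 1e-6)
  expect_equal(fit$hill_slope, 2, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-5)
  expect_equal(fit$top, 10, tolerance = 1e-6)
  expect_error(fit_hill_ec50(doses, rep(3, 9)), "degenerate-fit")

  doses8 <- 10^seq(-2, 2, length.out = 8)
  truth <- hill(doses8, 0, 10, 1, 2)
  set.seed(77)
  ec50s <- replicate(100, {
    fit_hill_ec50(doses8, truth + rnorm(8, sd = 0.5))$ec50
  })
  expect_lt(abs(stats::median(ec50s) - 1), 0.1)
})

test_that("EC50 recovery from simulated dose-response AUCs is plausible", {
  d <- quiet_donor()
  panel <- d$panel
  doses <- 10^seq(-2, 2, length.out = 12)
  aucs <- vapply(doses, function(dd)
    trace_auc(simulate_trace(d, sched_from_dose(c(ADP = dd), panel), tg)),
    numeric(1))
  fit <- fit_hill_ec50(doses, aucs)
  # dose axis is in EC50 multiples, so the half-maximal point is near 1
  expect_gt(fit$ec50, 0.3)
  expect_lt(fit$ec50, 3)
})

test_that("pearson_r matches the covariance-ratio formula", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(50); y <- rnorm(50)
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y), num / den, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "undefined-correlation")
})

test_that("donor variation is the mean per-condition SD", {
  expect_equal(donor_variation(matrix(c(0, 1), 2, 1)), sqrt(0.5),
               tolerance = 1e-4)
  expect_equal(donor_variation(matrix(1, 4, 6)), 0)
  expect_error(donor_variation(matrix(1, 1, 3)), "2 donors")
  set.seed(13)
  m <- matrix(rnorm(5 * 8), 5, 8)
  manual <- mean(vapply(seq_len(8), function(j) {
    v <- m[, j]
    sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  }, numeric(1)))
  expect_equal(donor_variation(m), manual, tolerance = 1e-12)
})

test_that("long-format and TSV exports preserve the scores", {
  d <- quiet_donor()
  panel <- d$panel
  des <- enumerate_pairwise(panel, dose_grid(1))
  ex <- average_experiment(simulate_experiment(
    d, design_schedules(des, panel), tg, replicates = 1, design = des))
  syn <- synergy_vector(ex)
  long <- synergy_long(syn, des)
  expect_equal(nrow(long), sum(syn$order == 2))
  expect_setequal(long$score, syn$score[syn$order == 2])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_synergy(syn, f)
  back <- utils::read.delim(f)
  expect_equal(back$score, syn$score, tolerance = 1e-12)
})
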