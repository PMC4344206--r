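# Neural network ensemble ------------------------------------------------
#
# The calcium calculator proper: a bag of lagged-feedback networks, several
# per donor with distinct initial weights and train/validation splits,
# whose closed-loop predictions are averaged pointwise.

#' Train a multi-donor, multi-seed ensemble
#'
#' Trains `n_per_donor` networks on each donor's replicate-averaged
#' experiment with distinct derived seeds (distinct initializations and
#' condition splits). Member seeds are a deterministic hash of
#' `(base_seed, donor_id, index)`, so adding donors never perturbs existing
#' members. Members that fail to train are logged and dropped; the
#' ensemble is returned only if at least 80% of members trained.
#'
#' @param experiments list of averaged `pas_experiment` objects, one per
#'   donor.
#' @param n_per_donor networks per donor.
#' @param base_seed integer seed.
#' @param spec an [nn_spec()].
#' @return A list of class `pas_ensemble`: `members` (each with `nn`,
#'   `donor_id`, `seed`, `train_mse`, `val_mse`), `spec`, `failures`.
#' @export
train_ensemble <- function(experiments, n_per_donor, base_seed, spec) {
  stopifnot(n_per_donor >= 1, length(experiments) >= 1)
  members <- list(); failures <- list()
  for (exp_i in experiments) {
    pairs <- make_training_pairs(exp_i, spec)
    for (k in seq_len(n_per_donor)) {
      seed_k <- derive_seed(base_seed, exp_i$donor_id, k)
      res <- tryCatch({
        nn <- nn_build(spec, seed = seed_k)
        nn_train(nn, pairs, split_seed = derive_seed(seed_k, "split", k))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(donor_id = exp_i$donor_id, seed = seed_k,
               message = conditionMessage(res))
      } else {
        members[[length(members) + 1L]] <-
          list(nn = res, donor_id = exp_i$donor_id, seed = seed_k,
               train_mse = res$train_mse, val_mse = res$val_mse)
      }
    }
  }
  total <- length(experiments) * n_per_donor
  if (length(members) < 0.8 * total)
    stop("train_ensemble: only ", length(members), " of ", total,
         " members trained successfully")
  structure(list(members = members, spec = spec, failures = failures),
            class = "pas_ensemble")
}

# member closed-loop predictions for a list of schedules:
# array time x condition x member
member_predictions <- function(ensemble, schedules, time_s) {
  inputs <- lapply(schedules, condition_input_series, time_s = time_s)
  nm <- length(ensemble$members)
  out <- array(NA_real_, c(length(time_s), length(schedules), nm))
  ok <- rep(TRUE, nm)
  for (m in seq_len(nm)) {
    res <- tryCatch(
      nn_predict_closed_loop(ensemble$members[[m]]$nn, inputs, time_s),
      error = function(e) e)
    if (inherits(res, "error")) ok[m] <- FALSE else out[, , m] <- res
  }
  if (!any(ok)) stop("ensemble prediction: every member failed")
  list(array = out[, , ok, drop = FALSE], ok = ok)
}

#' Ensemble prediction for a set of schedules
#'
#' Pointwise arithmetic mean over the members' closed-loop predictions;
#' per-member traces are retained for range analysis. Members whose
#' prediction fails are excluded (with a note in `$excluded`) and the mean
#' is taken over survivors.
#'
#' @param ensemble a `pas_ensemble`.
#' @param schedules a [dispense_schedule()] or list of them.
#' @param time_s uniform time grid.
#' @return A list: `mean` (matrix time x condition), `members` (array
#'   time x condition x member), `excluded` (integer indices).
#' @export
predict_ensemble <- function(ensemble, schedules, time_s) {
  stopifnot(inherits(ensemble, "pas_ensemble"),
            length(ensemble$members) >= 1)
  if (inherits(schedules, "dispense_schedule")) schedules <- list(schedules)
  mp <- member_predictions(ensemble, schedules, time_s)
  list(mean = apply(mp$array, c(1, 2), mean), members = mp$array,
       excluded = which(!mp$ok))
}

#' Pointwise min/max envelope of member predictions
#'
#' The range of individual network predictions (intradonor variation); the
#' envelope always contains the ensemble mean.
#'
#' @inheritParams predict_ensemble
#' @return A list: `min`, `max` (matrices time x condition), `mean`.
#' @export
ensemble_range <- function(ensemble, schedules, time_s) {
  pred <- predict_ensemble(ensemble, schedules, time_s)
  list(min = apply(pred$members, c(1, 2), min),
       max = apply(pred$members, c(1, 2), max),
       mean = pred$mean)
}

# closed-loop MSE of one member over an experiment (post-dispense points)
member_mse <- function(nn, experiment) {
  inputs <- lapply(experiment$schedules, condition_input_series,
                   time_s = experiment$time_s)
  pred <- nn_predict_closed_loop(nn, inputs, experiment$time_s)
  sel <- experiment$time_s > 0
  mean((pred[sel, ] - experiment$traces[sel, ])^2)
}

#' Prune ensemble members by the IQR outlier rule
#'
#' Computes each member's closed-loop MSE on a validation experiment and
#' removes members above Tukey's upper fence, `Q3 + 1.5 IQR`. At least one
#' member is always retained.
#'
#' @param ensemble a `pas_ensemble`.
#' @param validation an averaged `pas_experiment`.
#' @param k fence multiplier (1.5 = Tukey's rule).
#' @return A list: `ensemble` (pruned), `report` (data frame of member,
#'   donor, MSE, removed flag), `fence`.
#' @export
prune_iqr <- function(ensemble, validation, k = 1.5) {
  stopifnot(inherits(ensemble, "pas_ensemble"))
  if (length(ensemble$members) == 0) stop("prune_iqr: empty ensemble")
  mses <- vapply(ensemble$members, function(m) member_mse(m$nn, validation),
                 numeric(1))
  q <- stats::quantile(mses, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + k * (q[2] - q[1])
  removed <- mses > fence
  if (all(removed)) removed[which.min(mses)] <- FALSE
  report <- data.frame(
    member = seq_along(mses),
    donor_id = vapply(ensemble$members, `[[`, character(1), "donor_id"),
    mse = mses, removed = removed)
  pruned <- ensemble
  pruned$members <- ensemble$members[!removed]
  list(ensemble = pruned, report = report, fence = fence)
}

#' Write / read an ensemble archive
#'
#' A directory of per-member JSON weight files plus a `manifest.tsv`
#' (donor, seed, training and validation MSE).
#'
#' @param ensemble a `pas_ensemble`.
#' @param dir directory path (created if needed).
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(file = character(0), donor_id = character(0),
                    seed = integer(0), train_mse = numeric(0),
                    val_mse = numeric(0))
  for (i in seq_along(ensemble$members)) {
    m <- ensemble$members[[i]]
    f <- sprintf("member_%03d.json", i)
    nn_save_json(m$nn, file.path(dir, f))
    man[i, ] <- list(f, m$donor_id, m$seed,
                     m$train_mse %||% NA_real_, m$val_mse %||% NA_real_)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  members <- lapply(seq_len(nrow(man)), function(i) {
    nn <- nn_load_json(file.path(dir, man$file[i]))
    list(nn = nn, donor_id = man$donor_id[i], seed = man$seed[i],
         train_mse = man$train_mse[i], val_mse = man$val_mse[i])
  })
  structure(list(members = members, spec = members[[1]]$nn$spec,
                 failures = list()),
            class = "pas_ensemble")
}
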