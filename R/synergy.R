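# Synergy scores and evaluation metrics ---------------------------------
#
# The synergy score S_n is the deviation of a combined response's AUC from
# the sum of its single-agonist AUCs, normalized by the maximum absolute
# deviation observed in the experiment: S_n in [-1, 1], positive =
# synergistic, 0 = additive, negative = antagonistic/saturating.

#' Raw deviation from additivity
#'
#' @param auc_combined AUC of the combined condition.
#' @param aucs_individual numeric vector (length >= 2) of the constituent
#'   single-agonist AUCs.
#' @return `auc_combined - sum(aucs_individual)`, in AUC units.
#' @export
raw_synergy <- function(auc_combined, aucs_individual) {
  if (length(aucs_individual) < 2)
    stop("raw_synergy: need at least 2 individual AUCs")
  auc_combined - sum(aucs_individual)
}

#' Normalize raw synergies to scores in [-1, 1]
#'
#' Each raw deviation is divided by the maximum absolute deviation in the
#' experiment; if all deviations are zero, all scores are zero.
#'
#' @param raw_deltas numeric vector of raw synergies.
#' @return A list: `scores`, `norm_const`.
#' @export
normalize_synergy <- function(raw_deltas) {
  stopifnot(length(raw_deltas) >= 1)
  nc <- max(abs(raw_deltas))
  if (nc == 0) return(list(scores = raw_deltas * 0, norm_const = 0))
  list(scores = raw_deltas / nc, norm_const = nc)
}

#' Synergy scores for every combined condition of an experiment
#'
#' Computes per-condition AUCs, then one score per order-2+ condition:
#' the AUC of the combined condition minus the AUCs of its constituent
#' single-agonist conditions *at the matching doses*, normalized within
#' the experiment. The full pairwise design yields 135 scores, the trinary
#' design 160.
#'
#' @param experiment an averaged `pas_experiment` whose design includes all
#'   constituent singles.
#' @param window AUC integration window in seconds.
#' @return A data frame of class `synergy_table`: `label`, `order`,
#'   `raw_delta`, `score`, `norm_const`.
#' @export
synergy_vector <- function(experiment, window = NULL) {
  design <- experiment$design
  if (is.null(design)) stop("synergy_vector: experiment carries no design")
  aucs <- experiment_aucs(experiment, window)
  agonists <- setdiff(names(design), c("label", "order"))
  combined <- which(design$order >= 2)
  if (length(combined) == 0) stop("synergy_vector: no combined conditions")
  deltas <- vapply(combined, function(i) {
    dose <- as.numeric(design[i, agonists])
    names(dose) <- agonists
    singles <- vapply(names(dose)[dose > 0], function(a) {
      d <- dose * 0; d[a] <- dose[a]
      lab <- condition_label(d)
      if (!lab %in% names(aucs))
        stop("synergy_vector: missing single-agonist condition '", lab, "'")
      aucs[[lab]]
    }, numeric(1))
    raw_synergy(aucs[[design$label[i]]], singles)
  }, numeric(1))
  norm <- normalize_synergy(deltas)
  out <- data.frame(label = design$label[combined],
                    order = design$order[combined],
                    raw_delta = deltas, score = norm$scores,
                    norm_const = norm$norm_const,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("synergy_table", "data.frame")
  out
}

#' Percent inhibition of an agonist response
#'
#' `100 * (1 - auc_with_inhibitor / auc_agonist)`. Negative values report
#' potentiation.
#'
#' @param auc_agonist AUC of the agonist alone (must be positive).
#' @param auc_with_inhibitor AUC of the agonist plus inhibitor.
#' @return Percentage inhibition.
#' @export
percent_inhibition <- function(auc_agonist, auc_with_inhibitor) {
  if (any(auc_agonist <= 0))
    stop("percent_inhibition: reference AUC must be positive")
  100 * (1 - auc_with_inhibitor / auc_agonist)
}

#' Fit a four-parameter Hill dose-response curve
#'
#' Least-squares fit of
#' `AUC(d) = bottom + (top - bottom) * d^h / (d^h + ec50^h)`
#' by Levenberg-Marquardt, multi-started over Hill slopes
#' `h in {0.5, 1, 2, 4}` with the best-RSS fit returned.
#'
#' @param doses positive numeric vector (>= 5 points spanning the
#'   transition).
#' @param aucs matching numeric vector of responses.
#' @return A list of class `hill_fit`: `bottom`, `top`, `ec50`,
#'   `hill_slope`, `rss`, `residuals`, `fitted`.
#' @export
fit_hill_ec50 <- function(doses, aucs) {
  stopifnot(length(doses) == length(aucs), length(doses) >= 5,
            all(doses > 0))
  if (stats::sd(aucs) < 1e-12 * max(1, abs(mean(aucs))))
    stop("degenerate-fit: flat dose-response data")
  df <- data.frame(d = doses, y = aucs)
  best <- NULL
  for (h0 in c(0.5, 1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) * d^h / (d^h + ec50^h), data = df,
        start = list(bottom = min(aucs), top = max(aucs),
                     ec50 = exp(mean(log(doses))), h = h0),
        lower = c(-Inf, -Inf, 1e-12, 0.05), upper = c(Inf, Inf, Inf, 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(stats::coef(fit)),
                list(rss = rss, residuals = as.numeric(stats::residuals(fit)),
                     fitted = as.numeric(stats::fitted(fit))))
  }
  if (is.null(best)) stop("degenerate-fit: Hill fit did not converge")
  structure(list(bottom = best$bottom, top = best$top, ec50 = best$ec50,
                 hill_slope = best$h, rss = best$rss,
                 residuals = best$residuals, fitted = best$fitted),
            class = "hill_fit")
}

#' Pooled Pearson correlation between predicted and measured traces
#'
#' The evaluation convention pools all conditions' time points into two
#' long vectors.
#'
#' @param predicted,measured numeric vectors or matrices of equal size.
#' @return Pearson R in [-1, 1].
#' @export
pearson_r <- function(predicted, measured) {
  x <- as.numeric(predicted); y <- as.numeric(measured)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation: zero variance input")
  stats::cor(x, y)
}

#' Mean between-donor standard deviation of synergy scores
#'
#' Sample standard deviation across donors for each condition's score,
#' averaged over conditions — the summary of donor-to-donor variation in a
#' given synergy score.
#'
#' @param per_donor_scores numeric matrix, donors x conditions.
#' @return Scalar mean SD.
#' @export
donor_variation <- function(per_donor_scores) {
  m <- as.matrix(per_donor_scores)
  if (nrow(m) < 2) stop("donor_variation: need at least 2 donors")
  mean(apply(m, 2, stats::sd))
}

#' Long-format synergy table for heat maps
#'
#' Expands a pairwise `synergy_table` into one row per (agonist_i, dose_i,
#' agonist_j, dose_j, score).
#'
#' @param synergy a `synergy_table` from [synergy_vector()].
#' @param design the matching `pas_design`.
#' @return A data frame with columns `agonist_i`, `dose_i`, `agonist_j`,
#'   `dose_j`, `score`.
#' @export
synergy_long <- function(synergy, design) {
  agonists <- setdiff(names(design), c("label", "order"))
  pairs <- synergy[synergy$order == 2, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- as.numeric(design[match(pairs$label[i], design$label), agonists])
    nz <- which(d > 0)
    data.frame(agonist_i = agonists[nz[1]], dose_i = d[nz[1]],
               agonist_j = agonists[nz[2]], dose_j = d[nz[2]],
               score = pairs$score[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a synergy table as TSV
#'
#' @param synergy a `synergy_table`.
#' @param path file path.
#' @export
write_synergy <- function(synergy, path) {
  utils::write.table(synergy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
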