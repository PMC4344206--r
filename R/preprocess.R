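# Calcium traces --------------------------------------------------------

#' Construct a calcium trace
#'
#' A uniformly sampled F/F0 time course. Time 0 is the first dispense;
#' negative times form the pre-dispense baseline.
#'
#' @param time_s numeric vector of sample times (seconds), uniform spacing.
#' @param values numeric vector of F/F0 values, same length.
#' @return A list of class `calcium_trace` with fields `time_s`, `values`,
#'   `dt_s`.
#' @export
calcium_trace <- function(time_s, values) {
  stopifnot(length(time_s) == length(values), length(time_s) >= 2)
  dt <- diff(time_s)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("calcium_trace: time grid must be uniform")
  if (any(!is.finite(values))) stop("calcium_trace: values must be finite")
  structure(list(time_s = as.numeric(time_s), values = as.numeric(values),
                 dt_s = dt[1]),
            class = "calcium_trace")
}

#' Default model time grid
#'
#' @param pre_s baseline window before the dispense, seconds.
#' @param post_s read window after the dispense, seconds.
#' @param dt_s sampling interval (2.5 s raw reads; 1 s model grid so the
#'   lag set maps to integer sample offsets).
#' @return Numeric vector of times from `-pre_s` to `post_s`.
#' @export
model_time_grid <- function(pre_s = 20, post_s = 210, dt_s = 1)
  seq(-pre_s, post_s, by = dt_s)

#' Normalize a raw fluorescence trace by its pre-dispense baseline
#'
#' @param raw numeric vector of raw fluorescence readings.
#' @param time_s matching time vector (dispense at t = 0).
#' @param baseline_window indices (or a logical mask) of the baseline
#'   samples; defaults to all samples with `time_s <= 0`.
#' @return A [calcium_trace()] whose baseline mean is exactly 1.
#' @export
normalize_trace <- function(raw, time_s, baseline_window = which(time_s <= 0)) {
  if (length(baseline_window) == 0) stop("degenerate-trace: empty baseline window")
  f0 <- mean(raw[baseline_window])
  if (!is.finite(f0) || f0 <= 0)
    stop("degenerate-trace: nonpositive baseline mean")
  calcium_trace(time_s, raw / f0)
}

#' Average replicate traces pointwise
#'
#' @param traces a list of [calcium_trace()] objects on identical grids.
#' @return A [calcium_trace()], the pointwise arithmetic mean.
#' @export
average_replicates <- function(traces) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]$time_s
  for (tr in traces)
    if (length(tr$time_s) != length(t0) || max(abs(tr$time_s - t0)) > 1e-9)
      stop("average_replicates: trace grids differ")
  vals <- rowMeans(vapply(traces, function(tr) tr$values,
                          numeric(length(t0))))
  calcium_trace(t0, vals)
}

#' Resample a trace onto a new uniform grid by linear interpolation
#'
#' @param trace a [calcium_trace()].
#' @param dt_new_s new sampling interval, seconds.
#' @return A [calcium_trace()] spanning the same interval; endpoints are
#'   preserved exactly.
#' @export
resample_trace <- function(trace, dt_new_s) {
  stopifnot(inherits(trace, "calcium_trace"), dt_new_s > 0)
  span <- range(trace$time_s)
  if (dt_new_s > diff(span)) stop("resample: dt_new larger than trace span")
  t_new <- seq(span[1], span[2], by = dt_new_s)
  if (t_new[length(t_new)] < span[2] - 1e-9)
    t_new <- c(t_new, span[2])  # preserve the right endpoint
  v <- stats::approx(trace$time_s, trace$values, xout = t_new)$y
  calcium_trace(t_new, v)
}

#' Area under the baseline-excess curve
#'
#' Trapezoidal integral of F/F0 - 1 over a time window. This is the
#' quantity A entering the synergy score: the null condition integrates to
#' exactly 0 and negative excursions are retained so the integral stays
#' linear.
#'
#' @param trace a [calcium_trace()].
#' @param window length-2 numeric, integration limits in seconds; default
#'   the full post-dispense window.
#' @return Scalar AUC in (F/F0-excess) x seconds.
#' @export
trace_auc <- function(trace, window = c(0, max(trace$time_s))) {
  stopifnot(inherits(trace, "calcium_trace"), length(window) == 2)
  sel <- trace$time_s >= window[1] - 1e-9 & trace$time_s <= window[2] + 1e-9
  if (sum(sel) < 2) stop("trace_auc: empty integration window")
  pracma::trapz(trace$time_s[sel], trace$values[sel] - 1)
}

# Experiment sets --------------------------------------------------------

#' Construct an experiment set
#'
#' Bundles one donor's traces for one design: a shared time grid, a
#' condition table (or schedule list) and a traces array.
#'
#' @param donor_id character donor identifier.
#' @param design_tag one of `"pairwise"`, `"trinary"`, `"higher"`,
#'   `"sequential"`.
#' @param design a `pas_design` condition table (may be `NULL` for
#'   schedule-only sets).
#' @param schedules list of [dispense_schedule()], one per condition.
#' @param time_s shared uniform time grid.
#' @param traces numeric array: time x condition (averaged) or
#'   time x condition x replicate.
#' @return A list of class `pas_experiment`.
#' @export
pas_experiment <- function(donor_id, design_tag, design, schedules, time_s,
                           traces) {
  nc <- length(schedules)
  dm <- dim(traces)
  if (is.null(dm)) stop("traces must be a matrix or 3-d array")
  stopifnot(dm[1] == length(time_s), dm[2] == nc)
  labels <- vapply(schedules, function(s) s$label, character(1))
  structure(list(donor_id = as.character(donor_id), design_tag = design_tag,
                 design = design, schedules = schedules, labels = labels,
                 time_s = as.numeric(time_s), traces = traces),
            class = "pas_experiment")
}

#' Average the replicate dimension of an experiment set
#'
#' @param experiment a `pas_experiment` with a time x condition x replicate
#'   traces array.
#' @return The experiment with `traces` collapsed to time x condition.
#' @export
average_experiment <- function(experiment) {
  tr <- experiment$traces
  if (length(dim(tr)) == 2) return(experiment)
  experiment$traces <- apply(tr, c(1, 2), mean)
  experiment
}

#' Per-condition AUCs of an experiment set
#'
#' @param experiment an averaged `pas_experiment`.
#' @param window integration window in seconds.
#' @return Named numeric vector of AUCs (names = condition labels).
#' @export
experiment_aucs <- function(experiment, window = NULL) {
  tr <- experiment$traces
  if (length(dim(tr)) == 3) tr <- apply(tr, c(1, 2), mean)
  if (is.null(window)) window <- c(0, max(experiment$time_s))
  aucs <- vapply(seq_len(ncol(tr)), function(j)
    trace_auc(calcium_trace(experiment$time_s, tr[, j]), window), numeric(1))
  names(aucs) <- experiment$labels
  aucs
}

# Trace matrix I/O -------------------------------------------------------

#' Write / read a trace matrix
#'
#' CSV with a `time_s` first column and one column per condition label.
#'
#' @param experiment an averaged `pas_experiment`.
#' @param path file path.
#' @export
write_traces <- function(experiment, path) {
  tr <- experiment$traces
  if (length(dim(tr)) == 3) stop("write_traces: average replicates first")
  df <- data.frame(time_s = experiment$time_s, tr, check.names = FALSE)
  names(df) <- c("time_s", experiment$labels)
  utils::write.csv(format(df, digits = 9, trim = TRUE), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @param donor_id,design_tag metadata for the reconstructed experiment.
#' @param design,schedules optional design objects to reattach.
#' @export
read_traces <- function(path, donor_id = "unknown", design_tag = "pairwise",
                        design = NULL, schedules = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  time_s <- as.numeric(df$time_s)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (is.null(schedules))
    schedules <- lapply(colnames(m), function(l)
      structure(list(events = NULL, horizon_s = max(time_s), label = l),
                class = "dispense_schedule"))
  pas_experiment(donor_id, design_tag, design, schedules, time_s, m)
}
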