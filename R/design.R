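# Condition tables ------------------------------------------------------
#
# A condition is a dose-multiplier assignment per agonist (0 = absent). A
# design is a data frame with columns: label, one numeric column per panel
# agonist, order (count of nonzero doses). Canonical ordering: the null
# condition first, then ascending order; within an order, agonist subsets in
# panel order and doses ascending.

fmt_dose <- function(d) formatC(d, format = "fg", width = 1)

#' Canonical condition label
#'
#' Agonists in panel order joined with their dose multipliers, e.g.
#' `"ADP:1|CVX:0.1"`; the null (buffer) condition is labelled `"null"`.
#'
#' @param dose named numeric vector of dose multipliers over the full panel.
#' @return A single string.
#' @keywords internal
condition_label <- function(dose) {
  nz <- which(dose > 0)
  if (length(nz) == 0) return("null")
  paste(paste(names(dose)[nz], fmt_dose(dose[nz]), sep = ":"), collapse = "|")
}

new_design <- function(rows, panel) {
  agonists <- panel$name
  mat <- do.call(rbind, rows)
  colnames(mat) <- agonists
  df <- data.frame(label = apply(mat, 1, function(d) {
    names(d) <- agonists
    condition_label(d)
  }), mat, check.names = FALSE, stringsAsFactors = FALSE)
  df$order <- as.integer(rowSums(mat > 0))
  if (anyDuplicated(df$label)) stop("internal error: duplicate condition labels")
  rownames(df) <- NULL
  class(df) <- c("pas_design", "data.frame")
  df
}

null_row <- function(n) numeric(n)

# all dose assignments for a fixed agonist subset, doses ascending within
# each slot, last slot varying fastest held to canonical expand.grid order
subset_rows <- function(idx, grid, n) {
  combos <- expand.grid(rep(list(as.numeric(grid)), length(idx)),
                        KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first factor fastest; reorder so the first
  # agonist in the subset is the slowest (lexicographic in panel order)
  ord <- do.call(order, as.list(combos))
  combos <- combos[ord, , drop = FALSE]
  lapply(seq_len(nrow(combos)), function(r) {
    row <- numeric(n)
    row[idx] <- as.numeric(combos[r, ])
    row
  })
}

enumerate_orders <- function(panel, grid, orders, include_null = TRUE) {
  assert_panel(panel)
  grid <- dose_grid(grid)
  n <- nrow(panel)
  rows <- if (include_null) list(null_row(n)) else list()
  for (k in sort(orders)) {
    subsets <- utils::combn(n, k, simplify = FALSE)
    for (idx in subsets) rows <- c(rows, subset_rows(idx, grid, n))
  }
  new_design(rows, panel)
}

#' Enumerate the pairwise agonist scanning design
#'
#' All single-agonist conditions, all unordered agonist-pair conditions at
#' every dose-pair, and one null (buffer) condition. For the default
#' six-agonist panel and three-dose grid this is the 154-condition PAS
#' plate.
#'
#' @param panel an [agonist_panel()].
#' @param grid a [dose_grid()] (or numeric vector of positive multipliers).
#' @return A `pas_design` data frame: `label`, one dose column per agonist,
#'   `order`.
#' @examples
#' nrow(enumerate_pairwise(default_agonist_panel(), dose_grid()))  # 154
#' @export
enumerate_pairwise <- function(panel, grid = dose_grid()) {
  assert_panel(panel)
  orders <- if (nrow(panel) >= 2) c(1L, 2L) else 1L
  enumerate_orders(panel, grid, orders)
}

#' Enumerate the trinary stimulation design
#'
#' All single and all three-agonist conditions over the dose grid, plus one
#' null condition (no pairs — matching the trinary plate layout). For six
#' agonists at two doses this is 173 conditions.
#'
#' @inheritParams enumerate_pairwise
#' @export
enumerate_trinary <- function(panel, grid = dose_grid(c(0.1, 1))) {
  assert_panel(panel)
  if (nrow(panel) < 3)
    stop("invalid-design: trinary design needs at least 3 agonists")
  enumerate_orders(panel, grid, c(1L, 3L))
}

#' Enumerate higher-order combination conditions
#'
#' Every condition whose order (number of agonists present) is in `orders`,
#' each present agonist at one grid multiplier. The count is
#' sum over k of choose(n, k) * g^k; for six agonists, three doses and
#' orders 4-6 this is the 3,402-condition space. No null condition is
#' included.
#'
#' @inheritParams enumerate_pairwise
#' @param orders integer vector of condition orders, each in `[2, n]`.
#' @export
enumerate_higher_order <- function(panel, grid = dose_grid(),
                                   orders = c(4L, 5L, 6L)) {
  assert_panel(panel)
  orders <- sort(unique(as.integer(orders)))
  if (any(orders < 2L) || any(orders > nrow(panel)))
    stop("invalid-design: orders must lie in [2, panel size]")
  enumerate_orders(panel, grid, orders, include_null = FALSE)
}

#' Stratified sample of a higher-order condition space
#'
#' Samples conditions without replacement, a fixed count per order
#' (default 16 four-agonist, 19 five-agonist and 10 six-agonist conditions
#' — about 1.3% of each stratum of the 3,402-condition space).
#'
#' @param space a `pas_design` (e.g. from [enumerate_higher_order()]).
#' @param counts_per_order named integer vector, names = orders.
#' @param seed integer seed; the sample is reproducible for a fixed seed.
#' @return A `pas_design` subset of `space`.
#' @export
sample_higher_order <- function(space,
                                counts_per_order = c("4" = 16, "5" = 19, "6" = 10),
                                seed = 1L) {
  stopifnot(inherits(space, "pas_design"))
  keep <- integer(0)
  local_seed(seed, {
    for (ord in names(counts_per_order)) {
      k <- as.integer(counts_per_order[[ord]])
      if (k == 0) next
      pool <- which(space$order == as.integer(ord))
      if (k > length(pool))
        stop("invalid-design: requested ", k, " conditions of order ", ord,
             " but only ", length(pool), " exist")
      keep <- c(keep, sort(sample(pool, k)))
    }
  })
  out <- space[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pas_design", "data.frame")
  out
}

# Dispense schedules -----------------------------------------------------

#' Construct a dispense schedule
#'
#' A schedule is an ordered list of agonist additions within one well's
#' read window. A simultaneous-addition condition is a schedule with one
#' event at t = 0.
#'
#' @param events a data frame with column `time_s` plus one dose column per
#'   panel agonist (the amounts *added* at that event).
#' @param horizon_s total read window after the first dispense, seconds.
#' @param label optional label; derived from the events if omitted.
#' @return A list of class `dispense_schedule`.
#' @export
dispense_schedule <- function(events, horizon_s, label = NULL) {
  stopifnot(is.data.frame(events), "time_s" %in% names(events))
  if (is.unsorted(events$time_s, strictly = TRUE))
    stop("invalid-design: event times must be strictly increasing")
  if (any(events$time_s < 0) || any(events$time_s >= horizon_s))
    stop("invalid-design: event times must lie in [0, horizon)")
  agonists <- setdiff(names(events), "time_s")
  if (is.null(label)) {
    parts <- vapply(seq_len(nrow(events)), function(i) {
      d <- as.numeric(events[i, agonists])
      names(d) <- agonists
      paste0("t", fmt_dose(events$time_s[i]), ">", condition_label(d))
    }, character(1))
    label <- paste(parts, collapse = ";")
    if (nrow(events) == 0) label <- "null"
  }
  structure(list(events = events, horizon_s = horizon_s, label = label),
            class = "dispense_schedule")
}

#' Convert a simultaneous-addition design to schedules
#'
#' @param design a `pas_design`.
#' @param panel the matching [agonist_panel()].
#' @param horizon_s read window after dispense, seconds.
#' @return A list of [dispense_schedule()] objects, one per condition.
#' @export
design_schedules <- function(design, panel, horizon_s = 210) {
  agonists <- panel$name
  lapply(seq_len(nrow(design)), function(i) {
    ev <- data.frame(time_s = 0)
    for (a in agonists) ev[[a]] <- design[[a]][i]
    dispense_schedule(ev, horizon_s = horizon_s, label = design$label[i])
  })
}

#' Enumerate sequential-addition schedules
#'
#' All ordered sequences of `n_dispenses` *distinct* agonists, each dispense
#' at one grid multiplier. For three agonists, three doses and two
#' dispenses this is the 54-schedule sequential experiment.
#'
#' @inheritParams enumerate_pairwise
#' @param n_dispenses number of dispenses per well.
#' @param dispense_times_s seconds of each dispense (first at 0).
#' @param horizon_s total read window, seconds.
#' @param include_null also append one null schedule.
#' @return A list of [dispense_schedule()] objects.
#' @export
enumerate_sequential <- function(panel, grid = dose_grid(), n_dispenses = 2,
                                 dispense_times_s = c(0, 300),
                                 horizon_s = 780, include_null = FALSE) {
  assert_panel(panel)
  grid <- dose_grid(grid)
  n <- nrow(panel)
  if (n_dispenses < 1) stop("invalid-design: n_dispenses must be >= 1")
  if (n_dispenses > n)
    stop("invalid-design: cannot dispense ", n_dispenses,
         " distinct agonists from a panel of ", n)
  stopifnot(length(dispense_times_s) >= n_dispenses)
  times <- dispense_times_s[seq_len(n_dispenses)]
  perms <- permutations_of(seq_len(n), n_dispenses)
  dosecombos <- expand.grid(rep(list(as.numeric(grid)), n_dispenses),
                            KEEP.OUT.ATTRS = FALSE)
  dosecombos <- dosecombos[do.call(order, as.list(dosecombos)), , drop = FALSE]
  out <- list()
  for (p in seq_len(nrow(perms))) {
    for (d in seq_len(nrow(dosecombos))) {
      ev <- data.frame(time_s = times)
      for (a in panel$name) ev[[a]] <- 0
      for (k in seq_len(n_dispenses))
        ev[k, panel$name[perms[p, k]]] <- as.numeric(dosecombos[d, k])
      out[[length(out) + 1L]] <- dispense_schedule(ev, horizon_s = horizon_s)
    }
  }
  if (include_null) {
    ev <- data.frame(time_s = 0)
    for (a in panel$name) ev[[a]] <- 0
    out[[length(out) + 1L]] <- dispense_schedule(ev, horizon_s = horizon_s,
                                                 label = "null")
  }
  out
}

# all ordered k-tuples of distinct elements of x (matrix, one row each)
permutations_of <- function(x, k) {
  if (k == 1) return(matrix(x, ncol = 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i], k - 1)
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Time-resolved agonist input series for a schedule
#'
#' Each agonist's column is a right-continuous step function: 0 before its
#' dispense, its cumulative multiplier afterwards (concentrations add
#' across dispenses; no dilution correction).
#'
#' @param schedule a [dispense_schedule()].
#' @param time_s uniform time grid in seconds covering `[0, horizon]`
#'   (negative times are the pre-dispense baseline).
#' @return A numeric matrix, `length(time_s)` rows x one column per agonist.
#' @export
condition_input_series <- function(schedule, time_s) {
  stopifnot(inherits(schedule, "dispense_schedule"))
  dt <- diff(time_s)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("invalid-design: time grid must be uniform")
  ev <- schedule$events
  agonists <- setdiff(names(ev), "time_s")
  if (nrow(ev) && (max(ev$time_s) > max(time_s)))
    stop("invalid-design: schedule event outside the time grid")
  m <- matrix(0, nrow = length(time_s), ncol = length(agonists),
              dimnames = list(NULL, agonists))
  for (i in seq_len(nrow(ev)))
    for (a in agonists)
      m[time_s >= ev$time_s[i], a] <- m[time_s >= ev$time_s[i], a] + ev[[a]][i]
  m
}

# Condition table I/O ----------------------------------------------------

#' Write / read a condition table
#'
#' Tab-separated with columns `label`, one dose column per agonist, `order`.
#' Doses are written with 9 significant digits so tables round-trip
#' bit-stably through [read_conditions()].
#'
#' @param design a `pas_design`.
#' @param path file path.
#' @export
write_conditions <- function(design, path) {
  out <- design
  for (nm in setdiff(names(out), c("label", "order")))
    out[[nm]] <- formatC(out[[nm]], format = "g", digits = 9)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conditions
#' @export
read_conditions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$order <- as.integer(df$order)
  class(df) <- c("pas_design", "data.frame")
  df
}
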