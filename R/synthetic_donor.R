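# Synthetic donor simulator ---------------------------------------------
#
# A phenomenological generator of baseline-normalized F/F0 calcium traces
# with the statistical structure the PAS analysis assumes: agonist-specific
# kinetics (fast-transient ADP/U46619, slow-sustained convulxin,
# fast-sustained thrombin), multiplicative inhibitor action (iloprost,
# GSNO), pairwise crosstalk of known sign, output saturation,
# donor-to-donor amplitude variation and additive measurement noise. It is
# not a mechanistic IP3/SOCE model; its role is to make training,
# prediction and synergy recovery testable with known ground truth.

#' Default synthetic donor population parameters
#'
#' Kinetic parameters per agonist (peak drive `a_max`, dose-response
#' steepness `hill_h`, rise/decay time constants, plateau fraction
#' `sustained_frac`, `inhibitor_potency`), a symmetric crosstalk matrix
#' `gamma` (positive = synergy; the default couples convulxin and
#' thrombin), output saturation scale `saturation_K`, maximum F/F0 excess
#' `fmax`, donor coefficient of variation `donor_cv` and additive noise SD
#' `noise_sd`.
#'
#' @param panel an [agonist_panel()]; defaults to the six-agonist panel.
#' @return A list of class `donor_params`.
#' @export
default_donor_params <- function(panel = default_agonist_panel()) {
  kin <- data.frame(
    name            = c("ADP", "CVX", "Thrombin", "U46619", "Iloprost", "GSNO"),
    a_max           = c(1.2, 2.6, 2.2, 1.0, 0, 0),
    hill_h          = c(1.3, 1.3, 1.3, 1.3, 1, 1),
    tau_rise_s      = c(4, 35, 7, 5, 5, 5),
    tau_decay_s     = c(30, 150, 110, 35, 100, 100),
    sustained_frac  = c(0.10, 0.85, 0.60, 0.10, 0, 0),
    inhibitor_potency = c(0, 0, 0, 0, 20, 0.3),
    stringsAsFactors = FALSE
  )
  kin <- kin[match(panel$name, kin$name), ]
  if (anyNA(kin$name)) {  # non-default panel: neutral activator kinetics
    miss <- is.na(kin$name)
    kin$name[miss] <- panel$name[miss]
    kin$a_max[miss] <- 1; kin$hill_h[miss] <- 1.3
    kin$tau_rise_s[miss] <- 5; kin$tau_decay_s[miss] <- 50
    kin$sustained_frac[miss] <- 0.2; kin$inhibitor_potency[miss] <- 0
    kin$a_max[miss & panel$role == "inhibitor"] <- 0
  }
  rownames(kin) <- kin$name
  gamma <- matrix(0, nrow(panel), nrow(panel),
                  dimnames = list(panel$name, panel$name))
  if (all(c("CVX", "Thrombin") %in% panel$name)) {
    gamma["CVX", "Thrombin"] <- 1.2
    gamma["Thrombin", "CVX"] <- 1.2
  }
  donor_params(panel = panel, kinetics = kin, crosstalk = gamma,
               saturation_K = 10, fmax = 4, donor_cv = 0.15, noise_sd = 0.02)
}

#' Construct (and validate) donor parameters
#'
#' @param panel an [agonist_panel()].
#' @param kinetics data frame of per-agonist kinetics (see
#'   [default_donor_params()]).
#' @param crosstalk symmetric numeric matrix with zero diagonal over the
#'   panel agonists.
#' @param saturation_K,fmax positive scalars: drive scale of the output
#'   saturation and maximum F/F0 excess.
#' @param donor_cv,noise_sd nonnegative scalars: lognormal CV applied to
#'   `a_max` per donor, and additive Gaussian noise SD on F/F0.
#' @return A list of class `donor_params`.
#' @export
donor_params <- function(panel, kinetics, crosstalk, saturation_K, fmax,
                         donor_cv = 0, noise_sd = 0) {
  assert_panel(panel)
  stopifnot(all(panel$name %in% kinetics$name))
  kinetics <- kinetics[match(panel$name, kinetics$name), ]
  if (any(kinetics$tau_rise_s <= 0) || any(kinetics$tau_decay_s <= 0))
    stop("donor_params: time constants must be positive")
  if (any(kinetics$sustained_frac < 0 | kinetics$sustained_frac > 1))
    stop("donor_params: sustained_frac must lie in [0, 1]")
  act <- panel$role == "activator"
  if (any(kinetics$inhibitor_potency[act] != 0))
    stop("donor_params: activators must have inhibitor_potency = 0")
  crosstalk <- as.matrix(crosstalk)
  stopifnot(nrow(crosstalk) == nrow(panel), ncol(crosstalk) == nrow(panel))
  if (max(abs(crosstalk - t(crosstalk))) > 1e-12)
    stop("donor_params: crosstalk matrix must be symmetric")
  if (any(diag(crosstalk) != 0))
    stop("donor_params: crosstalk diagonal must be zero")
  stopifnot(saturation_K > 0, fmax > 0, donor_cv >= 0, noise_sd >= 0)
  structure(list(panel = panel, kinetics = kinetics, crosstalk = crosstalk,
                 saturation_K = saturation_K, fmax = fmax,
                 donor_cv = donor_cv, noise_sd = noise_sd),
            class = "donor_params")
}

#' Draw a donor-specific realization from the population
#'
#' Each agonist's `a_max` is multiplied by an independent lognormal factor
#' with unit mean and coefficient of variation `donor_cv`.
#'
#' @param population a `donor_params` object.
#' @param seed integer; the draw is deterministic for a fixed seed.
#' @return A `donor_params` object for one donor.
#' @export
sample_donor <- function(population, seed) {
  stopifnot(inherits(population, "donor_params"))
  cv <- population$donor_cv
  if (cv == 0) return(population)
  sdlog <- sqrt(log(1 + cv^2))
  donor <- population
  local_seed(seed, {
    fac <- stats::rlnorm(nrow(donor$kinetics),
                         meanlog = -sdlog^2 / 2, sdlog = sdlog)
    donor$kinetics$a_max <- donor$kinetics$a_max * fac
  })
  donor
}

# drive of one activator: dose-saturated amplitude, exponential rise,
# partial decay to a sustained plateau
activator_drive <- function(t, t0, d, kin) {
  a <- kin$a_max * d^kin$hill_h / (d^kin$hill_h + 1)
  tt <- pmax(t - t0, 0)
  on <- as.numeric(t >= t0)
  a * on * (1 - exp(-tt / kin$tau_rise_s)) *
    (kin$sustained_frac + (1 - kin$sustained_frac) * exp(-tt / kin$tau_decay_s))
}

#' Simulate one calcium trace
#'
#' The noise-free response is
#' `F/F0(t) = 1 + fmax * D(t) / (D(t) + K)` where the total drive `D`
#' sums per-activator drives `r_i`, adds geometric-mean crosstalk terms
#' `gamma_ij * sqrt(r_i r_j)`, and is multiplied by
#' `prod_k 1 / (1 + potency_k * dose_k(t))` over dispensed inhibitors.
#' Negative drives are clipped at 0, so the pre-dispense baseline is
#' exactly 1 when `noise_sd = 0`.
#'
#' @param donor a `donor_params` object.
#' @param schedule a [dispense_schedule()].
#' @param time_s uniform time grid covering the baseline and horizon.
#' @param noise_seed integer seed for the additive noise, or `NULL` for a
#'   noise-free trace.
#' @return A [calcium_trace()].
#' @export
simulate_trace <- function(donor, schedule, time_s, noise_seed = NULL) {
  stopifnot(inherits(donor, "donor_params"),
            inherits(schedule, "dispense_schedule"))
  ev <- schedule$events
  if (!is.null(ev) && nrow(ev) && max(ev$time_s) > max(time_s))
    stop("simulate_trace: grid does not cover the schedule")
  panel <- donor$panel
  n <- nrow(panel)
  r <- matrix(0, length(time_s), n, dimnames = list(NULL, panel$name))
  inhib_dose <- matrix(0, length(time_s), n)
  if (!is.null(ev)) {
    for (i in seq_len(nrow(ev))) {
      for (j in seq_len(n)) {
        a <- panel$name[j]
        d <- ev[[a]][i]
        if (d <= 0) next
        if (panel$role[j] == "activator") {
          r[, j] <- r[, j] +
            activator_drive(time_s, ev$time_s[i], d, donor$kinetics[j, ])
        } else {
          inhib_dose[time_s >= ev$time_s[i], j] <-
            inhib_dose[time_s >= ev$time_s[i], j] + d
        }
      }
    }
  }
  # multiplicative inhibition on total drive (cAMP/cGMP-like global action)
  factor_t <- rep(1, length(time_s))
  for (j in seq_len(n))
    if (panel$role[j] == "inhibitor" && donor$kinetics$inhibitor_potency[j] > 0)
      factor_t <- factor_t /
        (1 + donor$kinetics$inhibitor_potency[j] * inhib_dose[, j])
  drive <- rowSums(r)
  gamma <- donor$crosstalk
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (gamma[i, j] != 0)
        drive <- drive + gamma[i, j] * sqrt(r[, i] * r[, j])
  drive <- pmax(drive * factor_t, 0)
  f <- 1 + donor$fmax * drive / (drive + donor$saturation_K)
  if (!is.null(noise_seed) && donor$noise_sd > 0)
    local_seed(noise_seed,
               f <- f + stats::rnorm(length(f), sd = donor$noise_sd))
  calcium_trace(time_s, f)
}

#' Simulate a full experiment set for one donor
#'
#' @param donor a `donor_params` object.
#' @param schedules list of [dispense_schedule()] (e.g. from
#'   [design_schedules()]).
#' @param time_s uniform time grid.
#' @param replicates number of replicate wells per condition.
#' @param seed integer; per-well noise seeds are derived from it.
#' @param donor_id,design_tag,design metadata passed to
#'   [pas_experiment()].
#' @return A `pas_experiment` with a time x condition x replicate array.
#' @export
simulate_experiment <- function(donor, schedules, time_s, replicates = 2,
                                seed = 1L, donor_id = "synthetic",
                                design_tag = "pairwise", design = NULL) {
  nc <- length(schedules)
  tr <- array(NA_real_, dim = c(length(time_s), nc, replicates))
  for (j in seq_len(nc))
    for (r in seq_len(replicates))
      tr[, j, r] <- simulate_trace(
        donor, schedules[[j]], time_s,
        noise_seed = if (donor$noise_sd > 0)
          derive_seed(seed, paste0(donor_id, ":", j), r) else NULL)$values
  pas_experiment(donor_id, design_tag, design, schedules, time_s, tr)
}

#' Ground-truth raw synergy of a condition
#'
#' Noise-free simulation of the combined condition and of each constituent
#' single-agonist condition, returning the raw deviation from additivity
#' `A_combined - sum(A_single)` in AUC units. Serves as the independent
#' oracle for synergy recovery.
#'
#' @param donor a `donor_params` object.
#' @param condition one row of a `pas_design` (data frame row).
#' @param time_s uniform time grid.
#' @param window AUC integration window, seconds.
#' @return Scalar raw synergy.
#' @export
ground_truth_synergy <- function(donor, condition, time_s,
                                 window = c(0, max(time_s))) {
  panel <- donor$panel
  dose <- as.numeric(condition[1, panel$name])
  names(dose) <- panel$name
  if (sum(dose > 0) < 2)
    stop("ground_truth_synergy: condition order must be >= 2")
  sched_of <- function(d) {
    ev <- data.frame(time_s = 0)
    for (a in panel$name) ev[[a]] <- unname(d[a])
    dispense_schedule(ev, horizon_s = max(time_s))
  }
  a_comb <- trace_auc(simulate_trace(donor, sched_of(dose), time_s), window)
  a_singles <- vapply(names(dose)[dose > 0], function(a) {
    d <- dose * 0; d[a] <- dose[a]
    trace_auc(simulate_trace(donor, sched_of(d), time_s), window)
  }, numeric(1))
  a_comb - sum(a_singles)
}
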