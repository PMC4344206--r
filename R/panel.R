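#' Construct an agonist panel
#'
#' An agonist panel defines the dose coordinate system of a PAS run: each
#' agonist carries an EC50 (the unit in which dose multipliers are
#' expressed), a role (activator or inhibitor) and a receptor label.
#'
#' @param name character vector of unique agonist names.
#' @param ec50 positive numeric vector of EC50 values.
#' @param ec50_unit character vector of concentration units (display only;
#'   all internal doses are EC50 multiples).
#' @param role character vector, each `"activator"` or `"inhibitor"`.
#' @param receptor character vector of receptor labels.
#' @return A data frame of class `agonist_panel` with one row per agonist.
#' @examples
#' default_agonist_panel()
#' @export
agonist_panel <- function(name, ec50, ec50_unit, role, receptor) {
  name <- as.character(name)
  if (length(name) == 0) stop("invalid-design: empty agonist panel")
  if (anyDuplicated(name)) stop("agonist names must be unique")
  ec50 <- as.numeric(ec50)
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) stop("ec50 values must be positive")
  role <- match.arg(as.character(role), c("activator", "inhibitor"),
                    several.ok = TRUE)
  n <- length(name)
  stopifnot(length(ec50) == n, length(role) == n,
            length(ec50_unit) == n, length(receptor) == n)
  panel <- data.frame(name = name, ec50 = ec50,
                      ec50_unit = as.character(ec50_unit),
                      role = role, receptor = as.character(receptor),
                      stringsAsFactors = FALSE)
  class(panel) <- c("agonist_panel", "data.frame")
  panel
}

#' The default six-agonist PAS panel
#'
#' ADP (P2Y1/P2Y12), convulxin (GPVI), thrombin (PAR1/PAR4) and U46619 (TP)
#' are activators; iloprost (IP, raises cAMP) and GSNO (NO donor, raises
#' cGMP) are inhibitors of calcium mobilization.
#'
#' @return An [agonist_panel()] with six rows.
#' @export
default_agonist_panel <- function() {
  agonist_panel(
    name      = c("ADP", "CVX", "Thrombin", "U46619", "Iloprost", "GSNO"),
    ec50      = c(1, 2, 20, 1, 0.5, 7),
    ec50_unit = c("uM", "nM", "nM", "uM", "uM", "uM"),
    role      = c("activator", "activator", "activator", "activator",
                  "inhibitor", "inhibitor"),
    receptor  = c("P2Y1/P2Y12", "GPVI", "PAR1/PAR4", "TP", "IP", "sGC")
  )
}

#' Validate a dose-multiplier grid
#'
#' Doses are expressed as multiples of each agonist's EC50. The zero dose is
#' implicit everywhere (an absent agonist), so the grid itself must be
#' strictly positive and strictly increasing.
#'
#' @param multipliers numeric vector of dose multipliers (xEC50).
#' @return The validated numeric vector, classed `dose_grid`.
#' @export
dose_grid <- function(multipliers = c(0.1, 1, 10)) {
  m <- as.numeric(multipliers)
  if (length(m) == 0) stop("invalid-design: dose grid is empty")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("invalid-design: dose multipliers must be positive")
  if (is.unsorted(m, strictly = TRUE))
    stop("invalid-design: dose multipliers must be strictly increasing")
  class(m) <- c("dose_grid", "numeric")
  m
}

# internal: stop unless x is a usable panel
assert_panel <- function(panel) {
  if (!inherits(panel, "agonist_panel") || nrow(panel) == 0)
    stop("invalid-design: need a nonempty agonist_panel")
  invisible(panel)
}
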