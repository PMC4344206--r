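# shared fixtures: tiny panels, quiet donors, fast network specs

tiny_panel <- function(n = 3) {
  agonist_panel(name = paste0("A", seq_len(n), recycle0 = TRUE),
                ec50 = rep(1, n), ec50_unit = rep("uM", n),
                role = rep("activator", n),
                receptor = paste0("R", seq_len(n)))
}

# noise-free population donor on the default panel
quiet_donor <- function(...) {
  pop <- default_donor_params()
  pop$noise_sd <- 0
  pop$donor_cv <- 0
  mods <- list(...)
  for (nm in names(mods)) pop[[nm]] <- mods[[nm]]
  pop
}

# independent brute-force condition enumeration: all dose assignments over
# {0, grid} filtered by order; returns count
brute_force_count <- function(n, grid, orders) {
  levels <- c(0, grid)
  all <- expand.grid(rep(list(levels), n))
  sum(rowSums(all > 0) %in% orders)
}

fast_spec <- function(n_inputs = 6, max_epochs = 150, patience = 150, ...) {
  nn_spec(n_inputs = n_inputs, max_epochs = max_epochs, patience = patience,
          ...)
}

# noise-free donor restricted to a subset of the default panel
sub_panel_donor <- function(names) {
  pop <- quiet_donor()
  sub <- pop$panel[pop$panel$name %in% names, ]
  class(sub) <- class(pop$panel)
  pop$panel <- sub
  pop$kinetics <- pop$kinetics[sub$name, ]
  pop$crosstalk <- pop$crosstalk[sub$name, sub$name]
  pop
}

# simultaneous schedule from a named dose vector over a panel
sched_from_dose <- function(dose, panel, horizon_s = 210) {
  ev <- data.frame(time_s = 0)
  for (a in panel$name) ev[[a]] <- if (a %in% names(dose)) unname(dose[[a]]) else 0
  dispense_schedule(ev, horizon_s = horizon_s)
}
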