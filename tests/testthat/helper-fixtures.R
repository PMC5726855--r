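# Shared fixtures. Heavy objects (the coarse intact sweep used by several
# acceptance checks) are computed once per test run and cached.

qg_cache <- new.env(parent = emptyenv())

qg_net <- function() {
  if (is.null(qg_cache$net)) qg_cache$net <- build_intact_network()
  qg_cache$net
}

# Coarse bidirectional sweep of the intact network (100 steps, 20 s per
# step: the package's coarse-screen convention).
qg_intact_sweep <- function() {
  if (is.null(qg_cache$sweep)) {
    qg_cache$sweep <- bifurcation_sweep(qg_net(), n_steps = 100,
                                        per_step = 20000, seed = 1,
                                        aux_runs = FALSE)
  }
  qg_cache$sweep
}

# Synthetic trajectory of square-wave flexor outputs. `offsets` gives each
# limb's flexion-onset phase within the cycle (cycle units); flexion lasts
# `duty` of the period. V is -40 mV (output 1/3) during flexion and -60 mV
# (output 0) otherwise.
square_wave_traj <- function(period = 200, duty = 0.3,
                             offsets = c(LF = 0, RF = 0, LH = 0, RH = 0),
                             duration = 2000, dt = 1) {
  t <- seq(0, duration, by = dt)
  flex <- limb_flexors(NULL)
  V <- sapply(names(flex), function(l) {
    ph_ms <- (t - offsets[[l]] * period) %% period   # integer-valued: exact
    ifelse(ph_ms < duty * period, -40, -60)
  })
  colnames(V) <- unname(flex[names(flex)])
  structure(list(t = t, V = V,
                 h = matrix(numeric(0), nrow = length(t), ncol = 0),
                 alpha = rep(0, length(t)), final_state = NULL,
                 config = list()),
            class = "cpg_trajectory")
}

# side-swap permutation of population ids
mirror_ids <- function(net) {
  p <- net$populations
  swapped <- ifelse(p$side == "left", "right", "left")
  paste(p$girdle, swapped, p$name, sep = "_")
}
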