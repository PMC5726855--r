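# Time integration of the network ODEs. The compiled core advances the
# system with an adaptive Dormand-Prince 5(4) stepper between the points of
# a fixed 1 ms grid; the Ornstein-Uhlenbeck noise current is updated exactly
# on that grid and held constant within each cell, so the adaptive solver
# only ever sees a smooth right-hand side. All durations are in ms.

#' Flexor-center ids of the four limbs
#'
#' @param net a `cpg_network`.
#' @return named character vector with elements `LF`, `RF`, `LH`, `RH`
#'   (left/right fore, left/right hind flexor centers).
#' @export
limb_flexors <- function(net) {
  c(LF = "fore_left_RG-F", RF = "fore_right_RG-F",
    LH = "hind_left_RG-F", RH = "hind_right_RG-F")
}

#' Randomized initial state
#'
#' Membrane potentials are drawn uniformly in \[-65, -55\] mV (spanning sub-
#' and suprathreshold values around the leak reversal), INaP inactivation
#' uniformly in \[0.2, 0.8\], and noise currents start at zero.
#'
#' @param net a `cpg_network`.
#' @param seed optional integer seed.
#' @return a state list with elements `V`, `h`, `I_noise`.
#' @export
randomize_initial_state <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(net$populations)
  list(V = stats::runif(n, -65, -55),
       h = stats::runif(length(rg_indices(net)), 0.2, 0.8),
       I_noise = rep(0, n))
}

default_initial_state <- function(net, constants = cell_constants()) {
  EL <- net$populations$EL
  list(V = EL, h = h_inf(EL[rg_indices(net)], constants),
       I_noise = rep(0, nrow(net$populations)))
}

#' Simulate the locomotor network
#'
#' Integrates the population ODEs for `duration` ms at a constant brainstem
#' drive `alpha` or along a piecewise-constant schedule. Reproducible: with
#' the same network, configuration and seed the trajectory is identical.
#'
#' @param net a `cpg_network`.
#' @param duration simulated time, ms.
#' @param alpha scalar brainstem drive, or a data frame with columns `t`
#'   (segment onset, ms, first must be 0) and `alpha` for a
#'   piecewise-constant schedule.
#' @param init initial state: `"default"` (rest at the leak reversal),
#'   `"random"` (see [randomize_initial_state()]), or a state list with
#'   `V`, `h` and optionally `I_noise` (e.g. `final_state(traj)` of a
#'   previous run).
#' @param seed optional integer seed (initial-state draw and noise).
#' @param noise_sd Ornstein-Uhlenbeck noise standard deviation, pA
#'   (default 0.005, several orders of magnitude below the other currents:
#'   enough to push the system off unstable trajectories without affecting
#'   behavior).
#' @param extra_drives optional additional drives, see [population_drives()].
#' @param constants see [cell_constants()].
#' @param rel_tol,abs_tol solver tolerances.
#' @param record_dt output sampling interval, ms (integer multiple of 1 ms).
#' @param record population ids to record (default: all).
#' @return A `cpg_trajectory`: list with `t` (ms), matrix `V` (time x
#'   recorded populations, mV), matrix `h` (time x RG centers), `alpha`
#'   (per sample) and the final full state for chaining.
#' @export
#' @examples
#' net <- build_intact_network()
#' traj <- simulate_network(net, duration = 2000, alpha = 0.3, seed = 1,
#'                          record = limb_flexors(net))
#' range(traj$V)
simulate_network <- function(net, duration, alpha, init = "random",
                             seed = NULL, noise_sd = 0.005,
                             extra_drives = NULL,
                             constants = cell_constants(),
                             rel_tol = 1e-8, abs_tol = 1e-8,
                             record_dt = 1, record = NULL) {
  stopifnot(duration > 0, record_dt >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- net$populations
  state <- if (identical(init, "random")) randomize_initial_state(net)
           else if (identical(init, "default")) default_initial_state(net, constants)
           else init
  if (is.null(state$I_noise)) state$I_noise <- rep(0, nrow(p))
  if (is.null(record)) record <- p$id
  rec_idx <- match(record, p$id)
  if (anyNA(rec_idx)) stop("unknown population(s) in `record`")

  sched <- if (is.data.frame(alpha)) alpha else data.frame(t = 0, alpha = alpha)
  stopifnot(sched$t[1] == 0, !is.unsorted(sched$t))
  seg_start <- sched$t
  seg_end <- c(sched$t[-1], duration)
  keep <- seg_end > seg_start
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  seg_alpha <- sched$alpha[keep]

  rg <- rg_indices(net)
  edges_src <- match(net$connections$src, p$id) - 1L
  edges_dst <- match(net$connections$dst, p$id) - 1L

  t_all <- V_all <- h_all <- NULL
  a_all <- numeric(0)
  for (s in seq_along(seg_alpha)) {
    drv <- population_drives(net, seg_alpha[s], extra_drives)
    res <- cpg_integrate_cpp(edges_src, edges_dst, net$connections$weight,
                             p$C, p$gL, p$EL, drv$DE, drv$DI, p$deleted,
                             rg - 1L, constants,
                             seg_end[s] - seg_start[s], record_dt,
                             state$V, state$h, state$I_noise, noise_sd,
                             rel_tol, abs_tol, rec_idx - 1L)
    state <- list(V = res$V_final, h = res$h_final, I_noise = res$noise_final)
    tt <- res$t + seg_start[s]
    if (is.null(t_all)) {
      t_all <- tt; V_all <- res$V; h_all <- res$h
      a_all <- rep(seg_alpha[s], length(tt))
    } else {
      t_all <- c(t_all, tt[-1])
      V_all <- rbind(V_all, res$V[-1, , drop = FALSE])
      h_all <- rbind(h_all, res$h[-1, , drop = FALSE])
      a_all <- c(a_all, rep(seg_alpha[s], length(tt) - 1L))
    }
  }
  colnames(V_all) <- record
  colnames(h_all) <- p$id[rg]
  names(state$V) <- names(state$I_noise) <- p$id
  names(state$h) <- p$id[rg]
  structure(list(t = t_all, V = V_all, h = h_all, alpha = a_all,
                 final_state = state,
                 config = list(duration = duration, alpha = sched,
                               noise_sd = noise_sd, seed = seed,
                               rel_tol = rel_tol, abs_tol = abs_tol,
                               record_dt = record_dt)),
            class = "cpg_trajectory")
}

#' Final state of a trajectory
#'
#' Returns the full system state at the end of a simulation, suitable as the
#' `init` argument of a subsequent [simulate_network()] call (protocols with
#' state hand-off between steps).
#'
#' @param traj a `cpg_trajectory`.
#' @return state list with `V`, `h`, `I_noise`.
#' @export
final_state <- function(traj) traj$final_state

#' Settle, then step the drive
#'
#' Composite protocol for abrupt drive changes: simulate a settling period at
#' `alpha_before`, then continue from the final state at `alpha_after`. Used
#' for the gait-transition experiments.
#'
#' @param net a `cpg_network`.
#' @param alpha_before,alpha_after drive before/after the abrupt change.
#' @param settle settling duration, ms (default 10000).
#' @param run duration after the change, ms.
#' @param init,seed initial state and seed for the settling run (see
#'   [simulate_network()]).
#' @param ... passed to both underlying [simulate_network()] calls.
#' @param extra_drives_after extra drives switched on at the change, see
#'   [population_drives()].
#' @return a `cpg_trajectory` covering settle + run, with time 0 at the
#'   start of the settling period.
#' @export
settle_then_step <- function(net, alpha_before, alpha_after, settle = 10000,
                             run = 10000, extra_drives_after = NULL,
                             init = "random", seed = NULL, ...) {
  pre <- simulate_network(net, duration = settle, alpha = alpha_before,
                          init = init, seed = seed, ...)
  post <- simulate_network(net, duration = run, alpha = alpha_after,
                           init = final_state(pre),
                           extra_drives = extra_drives_after, ...)
  splice_trajectories(pre, post)
}

splice_trajectories <- function(a, b) {
  offset <- a$t[length(a$t)]
  structure(list(t = c(a$t, b$t[-1] + offset),
                 V = rbind(a$V, b$V[-1, , drop = FALSE]),
                 h = rbind(a$h, b$h[-1, , drop = FALSE]),
                 alpha = c(a$alpha, b$alpha[-1]),
                 final_state = b$final_state,
                 config = list(spliced = list(a$config, b$config))),
            class = "cpg_trajectory")
}

#' @export
print.cpg_trajectory <- function(x, ...) {
  cat("<cpg_trajectory> ", length(x$t), " samples over ",
      round(x$t[length(x$t)] - x$t[1]), " ms, ",
      ncol(x$V), " recorded populations\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cpg_trajectory <- function(x, ...) {
  data.frame(t = rep(x$t, ncol(x$V)),
             population = rep(colnames(x$V), each = length(x$t)),
             V = as.vector(x$V))
}
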