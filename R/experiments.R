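# Experiment protocols: bifurcation sweeps of the brainstem drive with
# hysteresis detection, deletion phenotyping, noise-driven coordination
# variability, abrupt-transition dynamics, and connection-weight robustness
# screening. All protocols chain simulations by handing the final state of
# one step to the next.

#' Bifurcation sweep of the brainstem drive
#'
#' Steps the drive parameter alpha across an equally spaced grid, simulating
#' `per_step` ms at each value with the final state carried over to the next
#' step, first upward and then (continuing from the final state) downward.
#' At each step the last `n_last` cycles are summarized by circular
#' statistics; a step is accepted as a stable solution when every circular
#' standard deviation is below `sd_tol`. Disagreement between the up and
#' down branches at the same alpha marks bi- or multistability (hysteresis).
#'
#' When a discrete jump of any phase difference (> `jump_tol`) occurs
#' between adjacent steps, an auxiliary run in the opposite direction is
#' launched from the pre-jump state to uncover stable branches the main
#' sweeps may have missed; it stops when it merges with the existing branch
#' travelling the same way or reaches the end of the grid.
#'
#' @param net a `cpg_network`.
#' @param n_steps number of grid steps (canonical 1000; coarse grids are
#'   appropriate for routine use).
#' @param alpha_min,alpha_max grid range (default 0 to 1.05).
#' @param per_step simulated time per step, ms (default 10000).
#' @param noise_sd noise, pA (default 0.005).
#' @param seed integer seed (initial state + noise).
#' @param n_seeds independent repetitions with randomized initial
#'   conditions (seeds `seed`, `seed + 1`, ...); the stable-state sets are
#'   merged. Branch selection at symmetry-breaking bifurcations (e.g. left-
#'   vs right-leading gallop) depends on the initial state, so merged runs
#'   give a fuller picture of the stable repertoire.
#' @param directions subset of `c("up", "down")`.
#' @param aux_runs launch auxiliary opposite-direction runs at jumps.
#' @param jump_tol adjacent-step phase-difference change treated as a
#'   discrete jump (default 0.05).
#' @param n_last,sd_tol cycles summarized per step and the acceptance
#'   threshold on their circular standard deviations.
#' @param rel_tol,abs_tol solver tolerances.
#' @return A `cpg_bifurcation` object: list with `steps` (one row per grid
#'   point and branch: `direction`, `step`, `alpha`, frequency, durations,
#'   circular means/sds, `gait`, `accepted`) and the grid/configuration.
#' @export
bifurcation_sweep <- function(net, n_steps = 1000, alpha_min = 0,
                              alpha_max = 1.05, per_step = 10000,
                              noise_sd = 0.005, seed = NULL, n_seeds = 1,
                              directions = c("up", "down"), aux_runs = TRUE,
                              jump_tol = 0.05, n_last = 5, sd_tol = 0.001,
                              rel_tol = 1e-8, abs_tol = 1e-8) {
  if (n_seeds > 1) {
    if (is.null(seed)) seed <- sample.int(1e6, 1)
    runs <- lapply(seq_len(n_seeds) - 1L, function(k) {
      b <- bifurcation_sweep(net, n_steps = n_steps, alpha_min = alpha_min,
                             alpha_max = alpha_max, per_step = per_step,
                             noise_sd = noise_sd, seed = seed + k,
                             n_seeds = 1, directions = directions,
                             aux_runs = aux_runs, jump_tol = jump_tol,
                             n_last = n_last, sd_tol = sd_tol,
                             rel_tol = rel_tol, abs_tol = abs_tol)
      b$steps$seed <- seed + k
      b
    })
    out <- runs[[1]]
    out$steps <- do.call(rbind, lapply(runs, function(b) b$steps))
    out$config$seed <- seed
    out$config$n_seeds <- n_seeds
    return(out)
  }
  grid <- seq(alpha_min, alpha_max, length.out = n_steps + 1)
  flex <- limb_flexors(net)
  if (!is.null(seed)) set.seed(seed)
  state <- randomize_initial_state(net)

  run_branch <- function(idx_seq, state, direction) {
    rows <- vector("list", length(idx_seq))
    states <- vector("list", length(idx_seq))
    for (j in seq_along(idx_seq)) {
      a <- grid[idx_seq[j]]
      traj <- simulate_network(net, duration = per_step, alpha = a,
                               init = state, noise_sd = noise_sd,
                               rel_tol = rel_tol, abs_tol = abs_tol,
                               record = flex)
      state <- final_state(traj)
      sg <- steady_gait(phase_differences(detect_phases(traj)),
                        n_last = n_last, sd_tol = sd_tol)
      rows[[j]] <- cbind(data.frame(direction = direction,
                                    step = idx_seq[j], alpha = a), sg)
      states[[j]] <- state
    }
    list(steps = do.call(rbind, rows), states = states, final = state)
  }

  steps <- list(); branch_states <- list()
  up_idx <- seq_along(grid)
  down_idx <- rev(up_idx)
  if ("up" %in% directions) {
    br <- run_branch(up_idx, state, "up")
    steps$up <- br$steps; branch_states$up <- br$states; state <- br$final
  }
  if ("down" %in% directions) {
    br <- run_branch(down_idx, state, "down")
    steps$down <- br$steps; branch_states$down <- br$states
  }

  # auxiliary opposite-direction runs from pre-jump states
  if (aux_runs) {
    vars <- c("hind_lr", "fore_lr", "homolateral", "diagonal")
    for (dir in intersect(names(steps), c("up", "down"))) {
      st <- steps[[dir]]
      jumps <- integer(0)
      for (j in seq_len(nrow(st) - 1L)) {
        if (!st$accepted[j] || !st$accepted[j + 1L]) next
        d <- circular_distance(unlist(st[j, vars]), unlist(st[j + 1L, vars]))
        if (any(d > jump_tol)) jumps <- c(jumps, j)
      }
      opp_dir <- if (dir == "up") "down" else "up"
      main_opp <- steps[[opp_dir]]
      for (j in jumps) {
        pre_state <- branch_states[[dir]][[j]]
        start <- st$step[j]
        idx_seq <- if (dir == "up") rev(seq_len(start - 1L))
                   else seq(start + 1L, length(grid))
        if (length(idx_seq) == 0) next
        rows <- list(); state_a <- pre_state; merged <- 0L
        for (i in idx_seq) {
          a <- grid[i]
          traj <- simulate_network(net, duration = per_step, alpha = a,
                                   init = state_a, noise_sd = noise_sd,
                                   rel_tol = rel_tol, abs_tol = abs_tol,
                                   record = flex)
          state_a <- final_state(traj)
          sg <- steady_gait(phase_differences(detect_phases(traj)),
                            n_last = n_last, sd_tol = sd_tol)
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(direction = paste0("aux_", opp_dir),
                             step = i, alpha = a), sg)
          if (!is.null(main_opp) && sg$accepted) {
            ref <- main_opp[main_opp$step == i & main_opp$accepted, ]
            if (nrow(ref) &&
                all(circular_distance(unlist(sg[vars]),
                                      unlist(ref[1, vars])) < 0.02)) {
              merged <- merged + 1L
              if (merged >= 3L) break
            } else merged <- 0L
          }
        }
        steps[[paste0("aux_", dir, "_", j)]] <- do.call(rbind, rows)
      }
    }
  }

  out <- do.call(rbind, steps)
  rownames(out) <- NULL
  structure(list(steps = out, grid = grid,
                 config = list(n_steps = n_steps, per_step = per_step,
                               noise_sd = noise_sd, seed = seed,
                               directions = directions, sd_tol = sd_tol,
                               jump_tol = jump_tol)),
            class = "cpg_bifurcation")
}

#' @export
print.cpg_bifurcation <- function(x, ...) {
  cat("<cpg_bifurcation> ", length(x$grid), " grid points, branches: ",
      paste(unique(x$steps$direction), collapse = ", "), "\n", sep = "")
  cat("  gaits expressed:", paste(gait_inventory(x), collapse = ", "), "\n")
  invisible(x)
}

#' Gait inventory of a sweep
#'
#' The set of canonical gaits expressed at accepted (stable) steps of a
#' bifurcation sweep, across all branches.
#'
#' @param bif a `cpg_bifurcation`.
#' @return character vector, subset of walk, trot, gallop, bound.
#' @export
gait_inventory <- function(bif) {
  st <- bif$steps
  intersect(c("walk", "trot", "gallop", "bound"),
            unique(st$gait[st$accepted]))
}

#' Deletion phenotype
#'
#' Deletes the selected populations and runs a bifurcation sweep on the
#' lesioned network.
#'
#' @param net a `cpg_network`.
#' @param select selector of populations to delete (see
#'   [resolve_selector()]).
#' @param ... passed to [bifurcation_sweep()].
#' @return list with the lesioned `net`, the `sweep`, and the gait
#'   `inventory`.
#' @export
deletion_phenotype <- function(net, select, ...) {
  lesioned <- delete_populations(net, select)
  sweep <- bifurcation_sweep(lesioned, ...)
  list(net = lesioned, sweep = sweep, inventory = gait_inventory(sweep))
}

#' Step-to-step coordination variability under noise
#'
#' Long simulations at fixed drive values with strong noise; every locomotor
#' cycle's fore and hind left-right phase differences are assigned to one of
#' three equal circular bins by their appropriateness for trot (see
#' [bin_for_trot()]) and reported as percentages of all cycles.
#'
#' @param net a `cpg_network`.
#' @param alphas drive values (default `c(0.3, 0.6, 0.75)`).
#' @param noise_sd noise, pA (default 1.75).
#' @param duration simulated time per drive value, ms (default 1000000,
#'   i.e. 1000 s).
#' @param settle settling time before counting, ms.
#' @param seed integer seed.
#' @param ... passed to [simulate_network()].
#' @return data frame with columns `alpha`, `girdle` (fore/hind), `bin`
#'   (trot, quarter_off, sync), `pct`, `n_cycles`.
#' @export
noise_variability <- function(net, alphas = c(0.3, 0.6, 0.75),
                              noise_sd = 1.75, duration = 1e6,
                              settle = 10000, seed = NULL, ...) {
  flex <- limb_flexors(net)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (a in alphas) {
    pre <- simulate_network(net, duration = settle, alpha = a,
                            init = "random", noise_sd = noise_sd,
                            record = flex, ...)
    traj <- simulate_network(net, duration = duration, alpha = a,
                             init = final_state(pre), noise_sd = noise_sd,
                             record = flex, ...)
    pd <- phase_differences(detect_phases(traj))
    for (g in c("fore", "hind")) {
      x <- if (g == "fore") pd$fore_lr else pd$hind_lr
      x <- x[!is.na(x)]
      bins <- factor(bin_for_trot(x),
                     levels = c("trot", "quarter_off", "sync"))
      pct <- 100 * table(bins) / max(length(x), 1L)
      out[[length(out) + 1L]] <-
        data.frame(alpha = a, girdle = g, bin = names(pct),
                   pct = as.numeric(pct), n_cycles = length(x))
    }
  }
  do.call(rbind, out)
}

#' Dynamics of an abrupt gait transition
#'
#' Settles the model at `alpha_before`, abruptly switches to `alpha_after`
#' (optionally switching on additional drives to selected populations), and
#' measures how many cycles the system needs to restabilize: the first
#' post-change cycle after which the gait label stays constant and the
#' instantaneous frequency stays within `freq_tol` of its asymptotic value.
#'
#' @param net a `cpg_network`.
#' @param alpha_before,alpha_after drive before/after the change.
#' @param extra_drives_after additional drives applied from the change
#'   onward, see [population_drives()].
#' @param settle,run durations, ms.
#' @param seed integer seed.
#' @param freq_tol relative frequency tolerance for stationarity
#'   (default 0.05).
#' @param ... passed to [simulate_network()].
#' @return list: `cycles` (per-cycle observables with `gait` and `phase`
#'   pre/post), `gait_before`, `gait_after`, `freq_before`, `freq_after`,
#'   `cycles_to_stabilize` (number of post-change cycles before the gait and
#'   frequency are stationary), `transient_gaits`.
#' @export
transition_dynamics <- function(net, alpha_before, alpha_after,
                                extra_drives_after = NULL, settle = 10000,
                                run = 10000, seed = NULL, freq_tol = 0.05,
                                ...) {
  flex <- limb_flexors(net)
  traj <- settle_then_step(net, alpha_before, alpha_after, settle = settle,
                           run = run,
                           extra_drives_after = extra_drives_after,
                           seed = seed, record = flex, ...)
  pd <- gait_cycles(traj)
  # the cycle straddling the drive change belongs to neither regime
  pd$phase <- ifelse(pd$t_onset + pd$period <= settle + 1e-9, "pre",
                     ifelse(pd$t_onset >= settle - 1e-9, "post", "change"))
  post <- pd[pd$phase == "post" & !is.na(pd$gait), ]
  pre <- pd[pd$phase == "pre" & !is.na(pd$gait), ]
  gait_before <- if (nrow(pre)) pre$gait[nrow(pre)] else NA_character_
  freq_before <- if (nrow(pre)) pre$freq[nrow(pre)] else NA_real_
  if (nrow(post) < 3) {
    return(list(cycles = pd, gait_before = gait_before,
                gait_after = NA_character_, freq_before = freq_before,
                freq_after = NA_real_, cycles_to_stabilize = NA_integer_,
                transient_gaits = character(0)))
  }
  f_asym <- stats::median(utils::tail(post$freq, 3))
  g_asym <- post$gait[nrow(post)]
  stable <- post$gait == g_asym &
    abs(post$freq - f_asym) <= freq_tol * f_asym
  # last unstable cycle determines the transition length
  k <- if (all(stable)) 0L else max(which(!stable))
  list(cycles = pd, gait_before = gait_before, gait_after = g_asym,
       freq_before = freq_before, freq_after = f_asym,
       cycles_to_stabilize = k,
       transient_gaits = setdiff(unique(post$gait[seq_len(k)]), g_asym))
}

#' Robustness of the gait repertoire to weight perturbation
#'
#' Creates `n_models` randomly perturbed networks per perturbation level
#' (every weight multiplied by an independent N(1, sigma_p) draw), sweeps
#' each, and reports the fraction of models whose gait inventory lost at
#' least one of the gaits expressed by the intact network.
#'
#' @param net a `cpg_network` (intact reference).
#' @param sigma_p vector of perturbation standard deviations.
#' @param n_models models per level (canonical 100).
#' @param seed integer seed.
#' @param intact_inventory reference inventory; computed from an intact
#'   sweep with the same settings when `NULL`.
#' @param ... passed to [bifurcation_sweep()] (use a coarse `n_steps` for
#'   screening).
#' @return list with `summary` (one row per sigma_p: `frac_lost`) and
#'   `models` (per-model inventories).
#' @export
robustness_screen <- function(net, sigma_p = c(0.01, 0.02, 0.05, 0.10),
                              n_models = 100, seed = 1,
                              intact_inventory = NULL, ...) {
  if (is.null(intact_inventory)) {
    intact_inventory <- gait_inventory(
      bifurcation_sweep(net, seed = seed, ...))
  }
  models <- list(); summary <- list()
  for (sp in sigma_p) {
    lost <- logical(n_models)
    for (m in seq_len(n_models)) {
      sub_seed <- (seed * 1000L + round(sp * 1000) * 101L + m) %% .Machine$integer.max
      pert <- perturb_weights(net, sp, seed = sub_seed)
      inv <- gait_inventory(bifurcation_sweep(pert, seed = sub_seed, ...))
      lost[m] <- !all(intact_inventory %in% inv)
      models[[length(models) + 1L]] <-
        data.frame(sigma_p = sp, model = m,
                   inventory = paste(inv, collapse = "+"),
                   lost = lost[m])
    }
    summary[[length(summary) + 1L]] <-
      data.frame(sigma_p = sp, n_models = n_models,
                 frac_lost = mean(lost))
  }
  list(summary = do.call(rbind, summary),
       models = do.call(rbind, models),
       intact_inventory = intact_inventory)
}
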