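# Population dynamics: leak, persistent-sodium, synaptic, drive and noise
# currents of the activity-based model. These R functions define the model
# term by term and back the compiled integrator; `cpg_rhs()` is a plain-R
# evaluation of the full right-hand side usable with any ODE solver.

#' Population output function
#'
#' Translates the average membrane potential into the integrated population
#' activity: 0 below `Vthr`, rising linearly to 1 at `Vmax`, and saturated
#' above.
#'
#' @param V membrane potential(s), mV.
#' @param constants see [cell_constants()].
#' @return activity in \[0, 1\], vectorized over `V`.
#' @export
#' @examples
#' output_activity(c(-60, -25, 0))  # 0, 0.5, 1
output_activity <- function(V, constants = cell_constants()) {
  pmin(pmax((V - constants$Vthr) / (constants$Vmax - constants$Vthr), 0), 1)
}

#' Half-wave rectification of signed synaptic weights
#'
#' `rectify(x)` is `x` for nonnegative `x` and 0 otherwise; excitatory sums
#' use `rectify(w)` and inhibitory sums `rectify(-w)`, so each signed weight
#' feeds exactly one of the two synaptic conductances.
#'
#' @param x numeric vector.
#' @return elementwise rectified values.
#' @export
rectify <- function(x) pmax(x, 0)

#' Brainstem drive level
#'
#' Drives are linear in the dimensionless brainstem-drive parameter `alpha`:
#' `m * alpha + b`. Populations with zero slope and intercept receive no
#' drive.
#'
#' @param alpha brainstem drive parameter.
#' @param m slope.
#' @param b intercept.
#' @return drive level (dimensionless conductance factor).
#' @export
#' @examples
#' drive_level(0.5, m = 0.1, b = 0)   # flexor center at alpha = 0.5
#' drive_level(0.5, m = 0, b = 0.1)   # extensor center: constant 0.1
drive_level <- function(alpha, m, b) m * alpha + b

#' Persistent-sodium current kinetics
#'
#' Steady-state activation `m_inf`, steady-state inactivation `h_inf`, and
#' the voltage-dependent inactivation time constant `tau_h` of INaP, plus the
#' current itself. Activation is instantaneous; inactivation `h` relaxes
#' toward `h_inf(V)` with time constant `tau_h(V)`.
#'
#' @param V membrane potential, mV.
#' @param h inactivation variable in \[0, 1\].
#' @param constants see [cell_constants()].
#' @return `inap_current`: current in pA; the helpers return dimensionless
#'   gates or a time constant in ms.
#' @export
#' @examples
#' m_inf(-40)      # 0.5 at the half-activation voltage
#' tau_h(-35)      # maximal (160 ms) at the time-constant half-voltage
inap_current <- function(V, h, constants = cell_constants()) {
  constants$gNaP * m_inf(V, constants) * h * (V - constants$ENa)
}

#' @rdname inap_current
#' @export
m_inf <- function(V, constants = cell_constants()) {
  1 / (1 + exp((V - constants$V12m) / constants$km))
}

#' @rdname inap_current
#' @export
h_inf <- function(V, constants = cell_constants()) {
  1 / (1 + exp((V - constants$V12h) / constants$kh))
}

#' @rdname inap_current
#' @export
tau_h <- function(V, constants = cell_constants()) {
  constants$tau0 + (constants$taumax - constants$tau0) /
    cosh((V - constants$V12tau) / constants$ktau)
}

#' Evaluated drive levels for every population
#'
#' Computes the excitatory and inhibitory drive of each population at a given
#' `alpha`, optionally adding extra per-population drives (used for
#' drive-independent gait-switch protocols).
#'
#' @param net a `cpg_network`.
#' @param alpha brainstem drive parameter.
#' @param extra_drives optional data frame with columns `select` (a selector,
#'   see [resolve_selector()]) and any of `mE`, `bE`, `mI`, `bI`; the
#'   resulting drives are added to the canonical ones.
#' @return list with numeric vectors `DE` and `DI` (one entry per
#'   population, network order).
#' @export
population_drives <- function(net, alpha, extra_drives = NULL) {
  p <- net$populations
  DE <- drive_level(alpha, p$mE, p$bE)
  DI <- drive_level(alpha, p$mI, p$bI)
  if (!is.null(extra_drives)) {
    for (k in seq_len(nrow(extra_drives))) {
      row <- extra_drives[k, ]
      ids <- resolve_selector(net, row$select)
      sel <- p$id %in% ids
      gE <- function(col) if (col %in% names(row) && !is.na(row[[col]])) row[[col]] else 0
      DE[sel] <- DE[sel] + drive_level(alpha, gE("mE"), gE("bE"))
      DI[sel] <- DI[sel] + drive_level(alpha, gE("mI"), gE("bI"))
    }
  }
  list(DE = DE, DI = DI)
}

#' Synaptic currents of one population
#'
#' Excitatory and inhibitory synaptic currents: the rectified weighted sum of
#' presynaptic activities plus the drive term, times conductance and driving
#' force. Deleted populations must already be clamped to zero activity in
#' `activities`.
#'
#' @param i population index (into network order).
#' @param V_i membrane potential of population `i`, mV.
#' @param activities vector of presynaptic outputs `f(V_j)` for all
#'   populations.
#' @param net a `cpg_network`.
#' @param alpha brainstem drive parameter.
#' @param extra_drives see [population_drives()].
#' @param constants see [cell_constants()].
#' @return named vector `c(I_SynE, I_SynI)` in pA.
#' @export
synaptic_currents <- function(i, V_i, activities, net, alpha,
                              extra_drives = NULL,
                              constants = cell_constants()) {
  p <- net$populations
  cn <- net$connections
  drv <- population_drives(net, alpha, extra_drives)
  incoming <- cn[match(cn$dst, p$id) == i, , drop = FALSE]
  src_idx <- match(incoming$src, p$id)
  sumE <- sum(rectify(incoming$weight) * activities[src_idx]) + drv$DE[i]
  sumI <- sum(rectify(-incoming$weight) * activities[src_idx]) + drv$DI[i]
  c(I_SynE = constants$gSynE * sumE * (V_i - constants$ESynE),
    I_SynI = constants$gSynI * sumI * (V_i - constants$ESynI))
}

#' One Ornstein-Uhlenbeck noise update
#'
#' Advances the noisy current by one fixed grid step using the exact
#' discretization of the OU process, whose stationary standard deviation is
#' exactly `sigma` and whose autocorrelation decays as `exp(-dt/tauNoise)`.
#'
#' @param I current noise value(s), pA.
#' @param dt grid step, ms (the model uses 1 ms).
#' @param xi standard normal draw(s).
#' @param sigma noise standard deviation, pA.
#' @param constants see [cell_constants()].
#' @return updated noise current(s), pA.
#' @export
noise_step <- function(I, dt, xi, sigma, constants = cell_constants()) {
  k <- exp(-dt / constants$tauNoise)
  I * k + sigma * sqrt(1 - k^2) * xi
}

#' Right-hand side of the network ODEs (reference implementation)
#'
#' Plain-R evaluation of the full system: for rhythm-generator centers
#' `C dV/dt = -INaP - IL - ISynE - ISynI - INoise` together with the slow
#' INaP inactivation `tau_h(V) dh/dt = h_inf(V) - h`; all other populations
#' omit INaP. Intended for verification and small problems; the compiled
#' integrator used by [simulate_network()] evaluates the same equations.
#'
#' @param state list with `V` (all populations), `h` (rhythm-generator
#'   centers, in the order of `rg_indices(net)`), and optionally `I_noise`
#'   (per-population noise currents, default 0).
#' @param net a `cpg_network`.
#' @param alpha brainstem drive parameter.
#' @param extra_drives see [population_drives()].
#' @param constants see [cell_constants()].
#' @return list with `dV` (mV/ms) and `dh` (1/ms).
#' @export
cpg_rhs <- function(state, net, alpha, extra_drives = NULL,
                    constants = cell_constants()) {
  p <- net$populations
  cn <- net$connections
  V <- state$V
  h <- state$h
  I_noise <- if (is.null(state$I_noise)) rep(0, nrow(p)) else state$I_noise
  act <- output_activity(V, constants)
  act[p$deleted] <- 0
  drv <- population_drives(net, alpha, extra_drives)
  src_idx <- match(cn$src, p$id)
  dst_idx <- match(cn$dst, p$id)
  sumE <- drv$DE
  sumI <- drv$DI
  we <- rectify(cn$weight) * act[src_idx]
  wi <- rectify(-cn$weight) * act[src_idx]
  for (e in seq_along(src_idx)) {
    sumE[dst_idx[e]] <- sumE[dst_idx[e]] + we[e]
    sumI[dst_idx[e]] <- sumI[dst_idx[e]] + wi[e]
  }
  I <- p$gL * (V - p$EL) +
    constants$gSynE * sumE * (V - constants$ESynE) +
    constants$gSynI * sumI * (V - constants$ESynI) +
    I_noise
  rg <- rg_indices(net)
  I[rg] <- I[rg] + inap_current(V[rg], h, constants)
  dh <- (h_inf(V[rg], constants) - h) / tau_h(V[rg], constants)
  list(dV = -I / p$C, dh = dh)
}

#' Indices of the INaP-carrying rhythm-generator centers
#'
#' @param net a `cpg_network`.
#' @return integer positions (network order) of the RG-F and RG-E centers;
#'   the inactivation state `h` follows this order.
#' @export
rg_indices <- function(net) {
  which(net$populations$rhythmogenic)
}
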