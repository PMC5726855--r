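# Locomotor observables. A rhythm generator is "in flexion" while the output
# f(V) of its flexor center is >= 0.1, otherwise in extension. The locomotor
# period is the interval between consecutive left-hind flexion onsets;
# normalized phase differences are delays between extension onsets of RG
# pairs divided by the period, wrapped to [0, 1). Phase differences are
# circular quantities and are aggregated with circular statistics only.

#' Detect flexion/extension events of the four rhythm generators
#'
#' Finds threshold crossings of the flexor-center output at 0.1 with linear
#' interpolation between samples. Flexion onsets are upward crossings,
#' flexion offsets (= extension onsets) downward crossings.
#'
#' @param traj a `cpg_trajectory` whose recorded populations include the four
#'   flexor centers (see [limb_flexors()]).
#' @param constants see [cell_constants()].
#' @param threshold output threshold (default 0.1).
#' @return A `phase_events` object: per limb (`LF`, `RF`, `LH`, `RH`) a list
#'   with vectors `onsets` and `offsets` (ms). The attribute `rhythm` is
#'   `FALSE` when fewer than two left-hind onsets exist (no detectable
#'   rhythm).
#' @export
detect_phases <- function(traj, constants = cell_constants(),
                          threshold = 0.1) {
  flex <- limb_flexors(NULL)
  miss <- setdiff(flex, colnames(traj$V))
  if (length(miss))
    stop("trajectory does not record flexor center(s): ",
         paste(miss, collapse = ", "))
  ev <- lapply(flex, function(id) {
    a <- output_activity(traj$V[, id], constants)
    crossings(traj$t, a, threshold)
  })
  names(ev) <- names(flex)
  structure(ev, rhythm = length(ev$LH$onsets) >= 2, class = "phase_events")
}

# linearly interpolated threshold crossings of a sampled signal
crossings <- function(t, a, thr) {
  above <- a >= thr
  n <- length(a)
  up <- which(!above[-n] & above[-1])
  down <- which(above[-n] & !above[-1])
  interp <- function(i) t[i] + (thr - a[i]) / (a[i + 1] - a[i]) * (t[i + 1] - t[i])
  list(onsets = vapply(up, interp, numeric(1)),
       offsets = vapply(down, interp, numeric(1)))
}

#' Per-cycle phase differences and cycle descriptors
#'
#' For every complete left-hind cycle, computes the period (ms), frequency
#' (Hz), left-hind flexion and extension durations (ms), and the four
#' normalized phase differences: hind left-right (right hind - left hind),
#' fore left-right (right fore - left fore), homolateral (left fore - left
#' hind) and diagonal (right fore - left hind), each the delay between the
#' extension onsets of the pair divided by the period and wrapped to
#' \[0, 1). Cycles with a missing partner onset yield `NA` in that column.
#'
#' @param ev a `phase_events` object.
#' @return data frame with one row per cycle (zero rows when no rhythm):
#'   `cycle`, `t_onset`, `period`, `freq`, `flex_dur`, `ext_dur`,
#'   `hind_lr`, `fore_lr`, `homolateral`, `diagonal`, plus the side-swapped
#'   companion pairs `homolateral_r` (right fore - right hind) and
#'   `diagonal_r` (left fore - right hind) used for chirality-symmetric gait
#'   classification.
#' @export
phase_differences <- function(ev) {
  empty <- data.frame(cycle = integer(0), t_onset = numeric(0),
                      period = numeric(0), freq = numeric(0),
                      flex_dur = numeric(0), ext_dur = numeric(0),
                      hind_lr = numeric(0), fore_lr = numeric(0),
                      homolateral = numeric(0), diagonal = numeric(0),
                      homolateral_r = numeric(0), diagonal_r = numeric(0))
  if (!isTRUE(attr(ev, "rhythm"))) return(empty)
  on <- ev$LH$onsets
  n_cyc <- length(on) - 1L
  first_at_or_after <- function(times, t0) {
    i <- which(times >= t0 - 1e-9)
    if (length(i)) times[i[1]] else NA_real_
  }
  rows <- lapply(seq_len(n_cyc), function(k) {
    t0 <- on[k]; t1 <- on[k + 1L]
    period <- t1 - t0
    e_lh <- first_at_or_after(ev$LH$offsets, t0)
    flex <- if (!is.na(e_lh) && e_lh < t1) e_lh - t0 else NA_real_
    wrap <- function(partner_times, ref) {
      tp <- first_at_or_after(partner_times, ref)
      if (is.na(tp) || is.na(ref)) return(NA_real_)
      ((tp - ref) / period) %% 1
    }
    e_lf <- first_at_or_after(ev$LF$offsets, e_lh)
    e_rh <- first_at_or_after(ev$RH$offsets, e_lh)
    data.frame(cycle = k, t_onset = t0, period = period,
               freq = 1000 / period,
               flex_dur = flex, ext_dur = period - flex,
               hind_lr = wrap(ev$RH$offsets, e_lh),
               fore_lr = wrap(ev$RF$offsets, e_lf),
               homolateral = wrap(ev$LF$offsets, e_lh),
               diagonal = wrap(ev$RF$offsets, e_lh),
               homolateral_r = wrap(ev$RF$offsets, e_rh),
               diagonal_r = wrap(ev$LF$offsets, e_rh))
  })
  do.call(rbind, rows)
}

#' Per-cycle gait observables of a trajectory
#'
#' Convenience wrapper: [detect_phases()] followed by
#' [phase_differences()] and per-cycle gait labels.
#'
#' @param traj a `cpg_trajectory`.
#' @param ... passed to [detect_phases()].
#' @return the [phase_differences()] data frame with an extra `gait` column.
#' @export
gait_cycles <- function(traj, ...) {
  pd <- phase_differences(detect_phases(traj, ...))
  pd$gait <- classify_gait_sym(pd$hind_lr, pd$homolateral, pd$diagonal,
                               pd$homolateral_r, pd$diagonal_r,
                               pd$ext_dur > pd$flex_dur)
  pd
}

#' Circular mean and circular standard deviation on the unit cycle
#'
#' Phase differences live on the circle of circumference 1. Values are mapped
#' to angles, averaged as unit vectors, and mapped back: the circular mean is
#' `atan2` of the mean resultant, the circular standard deviation is
#' `sqrt(-2 log R)` of the mean resultant length R, both expressed in cycle
#' units.
#'
#' @param x numeric vector of normalized phases (cycle units).
#' @return `circular_mean`: mean in \[0, 1); `circular_sd`: standard
#'   deviation in cycle units (0 for perfectly concentrated samples).
#' @export
#' @examples
#' circular_mean(c(0.95, 0.05))  # 0, not 0.5
circular_mean <- function(x) {
  if (length(x) == 0 || all(is.na(x))) stop("no phase values")
  x <- x[!is.na(x)]
  th <- 2 * pi * x
  m <- (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi)) %% 1
  if (m > 1 - 1e-9) 0 else m    # 1 - eps is the same point as 0
}

#' @rdname circular_mean
#' @export
circular_sd <- function(x) {
  if (length(x) == 0 || all(is.na(x))) stop("no phase values")
  x <- x[!is.na(x)]
  th <- 2 * pi * x
  R <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  R <- min(R, 1)
  sqrt(-2 * log(R)) / (2 * pi)
}

# shortest distance between two points on the unit circle (cycle units)
circular_distance <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

#' Operational gait classification
#'
#' Assigns one of walk, trot, gallop, bound or unclassified from the hind
#' left-right, homolateral and diagonal normalized phase differences
#' (interval closures exactly as operationally defined):
#' \itemize{
#'   \item walk: hind L-R in \[0.25, 0.75\], homolateral in
#'     \[0.1, 0.4) or (0.6, 0.9\], diagonal in (0.1, 0.4\] or \[0.6, 0.9),
#'     and additionally longer extension than flexion;
#'   \item trot: hind L-R in \[0.25, 0.75\], homolateral in \[0.25, 0.75\],
#'     diagonal in \[0, 0.1\] or \[0.9, 1);
#'   \item gallop: hind L-R in (0.025, 0.25\] or \[0.75, 0.975),
#'     homolateral and diagonal in \[0.25, 0.75\];
#'   \item bound: hind L-R in \[0, 0.025\] or \[0.975, 1),
#'     homolateral and diagonal in \[0.25, 0.75\].
#' }
#' The regions are pairwise disjoint except on boundary points of measure
#' zero; candidates are tested in the order walk, trot, gallop, bound.
#'
#' @param hind_lr,homolateral,diagonal normalized phase differences in
#'   \[0, 1) (vectorized).
#' @param ext_gt_flex logical: extension longer than flexion (required for
#'   walk).
#' @return character vector of gait labels.
#' @export
#' @examples
#' classify_gait(0.5, 0.5, 0.0, TRUE)    # trot
#' classify_gait(0.5, 0.25, 0.75, TRUE)  # walk
classify_gait <- function(hind_lr, homolateral, diagonal,
                          ext_gt_flex = TRUE) {
  n <- max(length(hind_lr), length(homolateral), length(diagonal),
           length(ext_gt_flex))
  hind_lr <- rep_len(hind_lr, n); homolateral <- rep_len(homolateral, n)
  diagonal <- rep_len(diagonal, n); ext_gt_flex <- rep_len(ext_gt_flex, n)
  walk <- hind_lr >= 0.25 & hind_lr <= 0.75 &
    ((homolateral >= 0.1 & homolateral < 0.4) |
       (homolateral > 0.6 & homolateral <= 0.9)) &
    ((diagonal > 0.1 & diagonal <= 0.4) |
       (diagonal >= 0.6 & diagonal < 0.9)) &
    ext_gt_flex
  trot <- hind_lr >= 0.25 & hind_lr <= 0.75 &
    homolateral >= 0.25 & homolateral <= 0.75 &
    ((diagonal >= 0 & diagonal <= 0.1) | (diagonal >= 0.9 & diagonal < 1))
  sync_homo_diag <- homolateral >= 0.25 & homolateral <= 0.75 &
    diagonal >= 0.25 & diagonal <= 0.75
  gallop <- ((hind_lr > 0.025 & hind_lr <= 0.25) |
               (hind_lr >= 0.75 & hind_lr < 0.975)) & sync_homo_diag
  bound <- ((hind_lr >= 0 & hind_lr <= 0.025) |
              (hind_lr >= 0.975 & hind_lr < 1)) & sync_homo_diag
  out <- rep("unclassified", n)
  out[bound] <- "bound"
  out[gallop] <- "gallop"
  out[trot] <- "trot"
  out[walk] <- "walk"
  out[is.na(hind_lr) | is.na(homolateral) | is.na(diagonal)] <- NA_character_
  out
}

#' Chirality-symmetric gait classification
#'
#' The phase-difference intervals reference a specific side (homolateral =
#' left fore - left hind, diagonal = right fore - left hind), so a gait and
#' its left-right mirror image (e.g. left- vs right-leading gallop, both
#' expressed by the model) present different diagonal values. A cycle is
#' classified by [classify_gait()] on the observed tuple and, if that is
#' unclassified, on the side-swapped tuple (hind L-R reflected about 0.5,
#' homolateral/diagonal taken from the mirrored RG pairs).
#'
#' @param hind_lr,homolateral,diagonal canonical normalized phase
#'   differences.
#' @param homolateral_r,diagonal_r side-swapped companions (right fore -
#'   right hind, left fore - right hind), see [phase_differences()].
#' @param ext_gt_flex logical, extension longer than flexion.
#' @return character vector of gait labels.
#' @export
classify_gait_sym <- function(hind_lr, homolateral, diagonal,
                              homolateral_r, diagonal_r,
                              ext_gt_flex = TRUE) {
  g <- classify_gait(hind_lr, homolateral, diagonal, ext_gt_flex)
  unk <- !is.na(g) & g == "unclassified" &
    !is.na(homolateral_r) & !is.na(diagonal_r)
  if (any(unk)) {
    gm <- classify_gait((1 - hind_lr[unk]) %% 1, homolateral_r[unk],
                        diagonal_r[unk], rep_len(ext_gt_flex, length(g))[unk])
    g[unk][gm != "unclassified"] <- gm[gm != "unclassified"]
  }
  g
}

#' Three-bin partition of a left-right phase difference
#'
#' Partitions a normalized left-right phase difference into three equal
#' circular arcs of width 1/3, by appropriateness for trot: centered on 0.5
#' (`trot`: alternation), on 0.25/0.75 (`quarter_off`), and on 0
#' (`sync`: synchronized/antiphase).
#'
#' @param x normalized phase difference(s) in \[0, 1).
#' @return character vector with values `trot`, `quarter_off`, `sync`.
#' @export
#' @examples
#' bin_for_trot(c(0.5, 0.25, 0.0))
bin_for_trot <- function(x) {
  x <- x %% 1
  out <- rep("sync", length(x))
  out[x >= 1 / 6 & x < 1 / 3] <- "quarter_off"
  out[x >= 2 / 3 & x < 5 / 6] <- "quarter_off"
  out[x >= 1 / 3 & x < 2 / 3] <- "trot"
  out[is.na(x)] <- NA_character_
  out
}

#' Steady-state summary of the last cycles of a simulation
#'
#' Circular means and standard deviations of the four phase differences over
#' the last `n_last` complete cycles, with the mean frequency, mean phase
#' durations and the gait label of the circular-mean phase differences. A
#' point is `accepted` as a stable solution when every circular standard
#' deviation is below `sd_tol`.
#'
#' @param pd a [phase_differences()] data frame.
#' @param n_last number of final cycles to summarize (default 5).
#' @param sd_tol acceptance threshold on the circular standard deviations
#'   (default 0.001 cycle units).
#' @return one-row data frame with `freq`, `flex_dur`, `ext_dur`, the four
#'   circular means and sds, `gait`, `accepted`, and `n_cycles`; frequency
#'   `NA` and gait `"none"` when fewer than `n_last` complete cycles exist.
#' @export
steady_gait <- function(pd, n_last = 5, sd_tol = 0.001) {
  vars <- c("hind_lr", "fore_lr", "homolateral", "diagonal")
  pd <- pd[stats::complete.cases(pd[, c(vars, "flex_dur")]), , drop = FALSE]
  if (nrow(pd) < n_last) {
    out <- data.frame(freq = NA_real_, flex_dur = NA_real_,
                      ext_dur = NA_real_)
    for (v in vars) { out[[v]] <- NA_real_; out[[paste0(v, "_sd")]] <- NA_real_ }
    out$gait <- "none"; out$accepted <- FALSE
    out$n_cycles <- nrow(pd)
    return(out)
  }
  last <- pd[utils::tail(seq_len(nrow(pd)), n_last), ]
  out <- data.frame(freq = mean(last$freq),
                    flex_dur = mean(last$flex_dur),
                    ext_dur = mean(last$ext_dur))
  for (v in vars) {
    out[[v]] <- circular_mean(last[[v]])
    out[[paste0(v, "_sd")]] <- circular_sd(last[[v]])
  }
  mirror <- lapply(c("homolateral_r", "diagonal_r"), function(v)
    if (all(is.na(last[[v]]))) NA_real_ else circular_mean(last[[v]]))
  out$gait <- classify_gait_sym(out$hind_lr, out$homolateral, out$diagonal,
                                mirror[[1]], mirror[[2]],
                                out$ext_dur > out$flex_dur)
  out$accepted <- all(out[paste0(vars, "_sd")] < sd_tol)
  out$n_cycles <- nrow(pd)
  out
}
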