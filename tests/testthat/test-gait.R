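# Event detection, phase differences, circular statistics, gait regions.

test_that("square-wave fixtures give exact periods and onsets", {
  traj <- square_wave_traj(period = 200, duty = 0.3, duration = 2000)
  ev <- detect_phases(traj)
  expect_true(attr(ev, "rhythm"))
  expect_equal(diff(ev$LH$onsets), rep(200, length(ev$LH$onsets) - 1),
               tolerance = 1e-9)
  # flexion lasts duty * period (first offset after the first full onset)
  off1 <- ev$LH$offsets[ev$LH$offsets > ev$LH$onsets[1]][1]
  expect_equal(off1 - ev$LH$onsets[1], 60, tolerance = 1e-9)
  pd <- phase_differences(ev)
  expect_equal(unique(round(pd$freq, 9)), 5)     # 200 ms -> 5 Hz
  expect_equal(pd$freq, 1000 / pd$period, tolerance = 1e-9)
})

test_that("tonic activity yields a no-rhythm result, not an error", {
  t <- 0:1000
  V <- matrix(-30, length(t), 4,
              dimnames = list(NULL, unname(limb_flexors(NULL))))
  traj <- structure(list(t = t, V = V), class = "cpg_trajectory")
  ev <- detect_phases(traj)
  expect_false(attr(ev, "rhythm"))
  expect_equal(nrow(phase_differences(ev)), 0)
})

test_that("constructed gaits produce their defining phase differences", {
  # ideal trot: diagonal pairs synchronous, left-right antiphase
  trot <- square_wave_traj(offsets = c(LH = 0, RF = 0, RH = 0.5, LF = 0.5))
  pd <- phase_differences(detect_phases(trot))
  expect_equal(unique(round(pd$hind_lr, 6)), 0.5)
  expect_equal(unique(round(pd$homolateral, 6)), 0.5)
  expect_equal(unique(round(pd$diagonal, 6)), 0)
  # lateral-sequence walk: RH, RF, LH, LF at quarter-cycle intervals
  walk <- square_wave_traj(offsets = c(RH = 0, RF = 0.25, LH = 0.5,
                                       LF = 0.75))
  pdw <- phase_differences(detect_phases(walk))
  expect_equal(unique(round(pdw$hind_lr, 6)), 0.5)
  expect_equal(unique(round(pdw$homolateral, 6)), 0.25)
  expect_equal(unique(round(pdw$diagonal, 6)), 0.75)
  # synchrony: all differences zero
  syn <- square_wave_traj()
  pds <- phase_differences(detect_phases(syn))
  expect_true(all(round(unlist(pds[c("hind_lr", "homolateral",
                                     "diagonal")]), 6) == 0))
  # phase differences are invariant to a global time shift
  shift <- square_wave_traj(offsets = c(RH = 0.2, RF = 0.45, LH = 0.7,
                                        LF = 0.95))
  pdsh <- phase_differences(detect_phases(shift))
  expect_equal(unique(round(pdsh$homolateral, 6)), 0.25)
  expect_equal(unique(round(pdsh$diagonal, 6)), 0.75)
})

test_that("circular statistics wrap correctly", {
  expect_equal(circular_mean(c(0.1, 0.1, 0.1)), 0.1)
  expect_equal(circular_sd(c(0.1, 0.1, 0.1)), 0)
  expect_equal(circular_mean(c(0.95, 0.05)), 0)
  expect_equal(circular_mean(c(0.4, 0.6)), 0.5)
  expect_error(circular_mean(numeric(0)))
  # against the resultant-length formula evaluated directly
  x <- seq(0, 0.99, by = 0.01)
  R <- sqrt(mean(cos(2 * pi * x))^2 + mean(sin(2 * pi * x))^2)
  expect_equal(circular_sd(x), sqrt(-2 * log(R)) / (2 * pi))
  expect_gt(circular_sd(x), 0.2)                  # near-uniform: large sd
  # sd is rotation invariant (for concentrated samples; at resultant
  # length ~0 the statistic is ill-conditioned by construction)
  y <- c(0.05, 0.12, 0.2, 0.93)
  expect_equal(circular_sd((y + 0.37) %% 1), circular_sd(y))
})

test_that("gait regions classify the textbook cases", {
  expect_equal(classify_gait(0.5, 0.5, 0.0, TRUE), "trot")
  expect_equal(classify_gait(0.5, 0.5, 0.95, FALSE), "trot")
  expect_equal(classify_gait(0.0, 0.5, 0.5, FALSE), "bound")
  expect_equal(classify_gait(0.99, 0.5, 0.5, FALSE), "bound")
  expect_equal(classify_gait(0.5, 0.25, 0.75, TRUE), "walk")
  expect_equal(classify_gait(0.5, 0.25, 0.75, FALSE), "unclassified")
  expect_equal(classify_gait(0.85, 0.5, 0.4, FALSE), "gallop")
  expect_equal(classify_gait(0.15, 0.5, 0.4, FALSE), "gallop")
  expect_equal(classify_gait(0.5, 0.05, 0.5, TRUE), "unclassified")
})

test_that("gait regions are pairwise disjoint off their boundaries", {
  # independent region predicates, transliterated from the operational
  # definition; evaluated on a grid that avoids all interval endpoints
  g <- seq(0.00625, 0.99375, by = 0.0125)
  pts <- expand.grid(hind = g, homo = g, diag = g)
  in_walk <- with(pts, hind >= 0.25 & hind <= 0.75 &
    ((homo >= 0.1 & homo < 0.4) | (homo > 0.6 & homo <= 0.9)) &
    ((diag > 0.1 & diag <= 0.4) | (diag >= 0.6 & diag < 0.9)))
  in_trot <- with(pts, hind >= 0.25 & hind <= 0.75 &
    homo >= 0.25 & homo <= 0.75 &
    ((diag >= 0 & diag <= 0.1) | (diag >= 0.9 & diag < 1)))
  in_gal <- with(pts, ((hind > 0.025 & hind <= 0.25) |
                         (hind >= 0.75 & hind < 0.975)) &
    homo >= 0.25 & homo <= 0.75 & diag >= 0.25 & diag <= 0.75)
  in_bnd <- with(pts, ((hind >= 0 & hind <= 0.025) |
                         (hind >= 0.975 & hind < 1)) &
    homo >= 0.25 & homo <= 0.75 & diag >= 0.25 & diag <= 0.75)
  n_regions <- in_walk + in_trot + in_gal + in_bnd
  expect_true(all(n_regions <= 1))
  # the classifier agrees with the unique region (walk requires ext > flex,
  # supplied as TRUE here)
  lab <- classify_gait(pts$hind, pts$homo, pts$diag, TRUE)
  expect_equal(lab == "walk", in_walk)
  expect_equal(lab == "trot", in_trot)
  expect_equal(lab == "gallop", in_gal)
  expect_equal(lab == "bound", in_bnd)
  expect_true(all(lab[n_regions == 0] == "unclassified"))
})

test_that("hind left-right reflection leaves gait labels invariant", {
  set.seed(1)
  hind <- runif(500); homo <- runif(500); diag <- runif(500)
  a <- classify_gait(hind, homo, diag, TRUE)
  b <- classify_gait((1 - hind) %% 1, homo, diag, TRUE)
  off_boundary <- !(hind %in% c(0, 0.025, 0.25, 0.75, 0.975))
  expect_equal(a[off_boundary], b[off_boundary])
})

test_that("three trot-appropriateness bins tile the circle", {
  expect_equal(bin_for_trot(c(0.5, 0.25, 0.75, 0.0, 0.9)),
               c("trot", "quarter_off", "quarter_off", "sync", "sync"))
  x <- seq(0, 0.999, by = 0.001)
  b <- bin_for_trot(x)
  expect_true(all(!is.na(b)))
  tab <- table(b) / length(b)
  expect_equal(unname(tab[c("trot", "quarter_off", "sync")]),
               rep(1 / 3, 3), tolerance = 0.01, ignore_attr = TRUE)
})

test_that("chirality-symmetric classification recognizes the mirrored gallop", {
  # right-leading gallop satisfies the printed intervals directly
  expect_equal(classify_gait_sym(0.85, 0.55, 0.40, 0.55, 0.70, FALSE),
               "gallop")
  # left-leading gallop: canonical diagonal falls outside [0.25, 0.75],
  # the mirrored tuple brings it back
  expect_equal(classify_gait(0.15, 0.55, 0.80, FALSE), "unclassified")
  expect_equal(classify_gait_sym(0.15, 0.55, 0.80, 0.55, 0.40, FALSE),
               "gallop")
  # symmetric gaits are unaffected by the fallback
  expect_equal(classify_gait_sym(0.5, 0.5, 0.0, 0.5, 0.0, TRUE), "trot")
})

test_that("steady_gait accepts only converged cycles", {
  pd <- data.frame(cycle = 1:8, t_onset = (1:8) * 200, period = 200,
                   freq = 5, flex_dur = 60, ext_dur = 140,
                   hind_lr = 0.5, fore_lr = 0.5,
                   homolateral = 0.5, diagonal = 0.02,
                   homolateral_r = 0.5, diagonal_r = 0.02)
  sg <- steady_gait(pd)
  expect_true(sg$accepted)
  expect_equal(sg$gait, "trot")
  expect_equal(sg$freq, 5)
  pd$hind_lr <- seq(0.3, 0.7, length.out = 8)     # drifting: rejected
  expect_false(steady_gait(pd)$accepted)
  expect_equal(steady_gait(pd[1:3, ])$gait, "none")
})
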