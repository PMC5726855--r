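# Integration: determinism, state handling, cross-check against an
# independent solver, mirror symmetry, tolerance robustness.

test_that("simulation is reproducible and samples on the requested grid", {
  net <- qg_net()
  a <- simulate_network(net, 1000, alpha = 0.3, seed = 7)
  b <- simulate_network(net, 1000, alpha = 0.3, seed = 7)
  expect_identical(a$V, b$V)
  expect_identical(a$final_state, b$final_state)
  expect_equal(a$t, 0:1000)
  expect_true(all(diff(a$t) > 0))
  expect_true(all(is.finite(a$V)))
  c5 <- simulate_network(net, 1000, alpha = 0.3, seed = 7, record_dt = 5)
  expect_equal(c5$t, seq(0, 1000, by = 5))
})

test_that("randomized initial states respect their bounds and seed", {
  net <- qg_net()
  s1 <- randomize_initial_state(net, seed = 3)
  s2 <- randomize_initial_state(net, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(s1$V >= -65 & s1$V <= -55))
  expect_true(all(s1$h >= 0.2 & s1$h <= 0.8))
  expect_true(all(s1$I_noise == 0))
  s3 <- randomize_initial_state(net, seed = 4)
  expect_false(identical(s1$V, s3$V))
})

test_that("without any drive the network relaxes to a sub-threshold fixed point", {
  net <- qg_net()
  net$populations[c("mE", "bE", "mI", "bI")] <- 0
  traj <- simulate_network(net, 5000, alpha = 0.5, seed = 1, noise_sd = 0)
  last <- traj$V[nrow(traj$V), ]
  first <- traj$V[nrow(traj$V) - 500, ]
  expect_lt(max(abs(last - first)), 1e-6)        # settled
  expect_true(all(last < -50))                   # below output threshold
  expect_equal(nrow(gait_cycles(traj)), 0)       # no rhythm
})

test_that("compiled integrator agrees with an independent reference solver", {
  skip_if_not_installed("deSolve")
  net <- qg_net()
  cst <- cell_constants()
  rg <- rg_indices(net)
  init <- randomize_initial_state(net, seed = 5)
  alpha <- 0.3
  traj <- simulate_network(net, 1500, alpha = alpha, init = init,
                           noise_sd = 0, rel_tol = 1e-10, abs_tol = 1e-10)
  f <- function(t, y, parms) {
    st <- list(V = y[1:56], h = y[57:64])
    d <- cpg_rhs(st, net, alpha, constants = cst)
    list(c(d$dV, d$dh))
  }
  sol <- deSolve::ode(y = c(init$V, init$h), times = seq(0, 1500, by = 50),
                      func = f, parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-10)
  idx <- match(seq(0, 1500, by = 50), traj$t)
  expect_lt(max(abs(traj$V[idx, ] - sol[, 2:57])), 1e-4)
  expect_lt(max(abs(traj$h[idx, ] - sol[, 58:65])), 1e-6)
})

test_that("mirrored initial conditions give exact mirror trajectories", {
  net <- qg_net()
  ids <- net$populations$id
  init <- randomize_initial_state(net, seed = 11)
  names(init$V) <- ids
  mir <- mirror_ids(net)
  init_m <- init
  init_m$V <- unname(init$V[match(ids, mir)])
  rg_ids <- ids[rg_indices(net)]
  names(init$h) <- names(init_m$h) <- rg_ids
  init_m$h <- unname(init$h[match(rg_ids, mir[rg_indices(net)])])
  init$V <- unname(init$V); init$h <- unname(init$h)

  # the vector field itself is exactly mirror-equivariant
  d <- cpg_rhs(init, net, alpha = 0.4)
  dm <- cpg_rhs(init_m, net, alpha = 0.4)
  expect_lt(max(abs(d$dV[match(mir, ids)] - dm$dV)), 1e-12)

  # trajectories mirror each other; burst onsets amplify float-summation
  # noise, so the bound is loose compared to machine precision
  a <- simulate_network(net, 3000, alpha = 0.4, init = init, noise_sd = 0)
  b <- simulate_network(net, 3000, alpha = 0.4, init = init_m, noise_sd = 0)
  expect_lt(max(abs(a$V[, mir] - b$V[, ids])), 5e-3)
})

test_that("membrane potentials stay in the physical range", {
  net <- qg_net()
  for (alpha in c(0.02, 0.5, 1.0)) {
    traj <- simulate_network(net, 10000, alpha = alpha, seed = 2)
    expect_true(all(traj$V > -80 & traj$V < 10))
    expect_true(all(traj$h >= 0 & traj$h <= 1))
  }
})

test_that("analysis observables are solver-tolerance converged", {
  net <- qg_net()
  init <- randomize_initial_state(net, seed = 6)
  run <- function(rt) {
    traj <- simulate_network(net, 12000, alpha = 0.4, init = init,
                             noise_sd = 0, rel_tol = rt, abs_tol = rt)
    steady_gait(phase_differences(detect_phases(traj)))
  }
  a <- run(1e-8); b <- run(5e-9)
  vars <- c("hind_lr", "fore_lr", "homolateral", "diagonal")
  expect_lt(max(abs(unlist(a[vars]) - unlist(b[vars]))), 1e-3)
  expect_lt(abs(a$freq - b$freq) / a$freq, 1e-4)
})

test_that("settle_then_step hands the state over; equal drives leave the rhythm unchanged", {
  net <- qg_net()
  traj <- settle_then_step(net, 0.4, 0.4, settle = 8000, run = 8000, seed = 3)
  pd <- gait_cycles(traj)
  pre <- pd[pd$t_onset < 8000 & pd$t_onset > 4000, ]
  post <- pd[pd$t_onset > 12000, ]
  expect_equal(mean(post$freq), mean(pre$freq), tolerance = 0.01)
  expect_equal(unique(post$gait), unique(pre$gait))
  # piecewise alpha schedule equals chained runs
  sched <- simulate_network(net, 4000,
                            alpha = data.frame(t = c(0, 2000),
                                               alpha = c(0.3, 0.5)),
                            seed = 9, noise_sd = 0)
  expect_equal(sched$alpha[sched$t < 2000], rep(0.3, 2000))
  expect_true(all(is.finite(sched$V)))
})
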