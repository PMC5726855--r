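# Connectome construction, mutation and serialization.

test_that("intact network has the canonical population and connection counts", {
  net <- qg_net()
  p <- net$populations
  expect_equal(nrow(p), 56)
  expect_equal(sum(p$girdle == "fore"), 30)   # 15 per fore section
  expect_equal(sum(p$girdle == "hind"), 26)   # 13 per hind section
  expect_equal(nrow(net$connections), 84)
  expect_false(anyDuplicated(net$connections[c("src", "dst")]) > 0)

  # independent brute-force expansion oracle: count rows of the pathway
  # table times the number of sections in which the source exists and the
  # target exists in the mapped section
  rules <- list(  # src, dst, source-girdle restriction
    c("RG-F", 5, "both"), c("fRG-F", 2, "fore"), c("RG-E", 3, "both"),
    c("ipsi-rest", 5, "both"),                 # Ini-F, Ini-E, V2a, V2a-diag, IniV0V
    c("contra", 4, "both"),
    c("homo-fore", 2, "fore"), c("homo-hind", 1, "hind"),
    c("diag-fore", 2, "fore"), c("diag-hind", 1, "hind"))
  sections <- c(both = 4, fore = 2, hind = 2)
  n_expected <- sum(vapply(rules, function(r)
    as.numeric(r[2]) * sections[[r[3]]], numeric(1)))
  expect_equal(nrow(net$connections), n_expected)
})

test_that("specific pathway weights and drive coefficients match the design", {
  net <- qg_net()
  w <- function(src, dst) {
    hit <- net$connections[net$connections$src == src &
                             net$connections$dst == dst, "weight"]
    if (length(hit)) hit else NA_real_
  }
  expect_equal(w("hind_left_RG-E", "hind_left_Sh2-Hom"), 0.50)
  expect_equal(w("hind_left_Sh2-Hom", "fore_left_RG-F"), 0.125)
  expect_equal(w("fore_left_V0D-diag", "hind_right_RG-F"), -0.075)
  expect_equal(w("hind_right_V0V-diag", "fore_left_RG-F"), 0.065)
  expect_equal(w("fore_left_V0D", "fore_right_RG-F"), -0.07)
  # no hind V0D-diag or Ini-Hom populations, hence no such sources
  expect_false(any(grepl("^hind_.*_(V0D-diag|Ini-Hom)$",
                         c(net$populations$id, net$connections$src))))
  p <- net$populations
  expect_true(all(p[p$name == "RG-E", c("mE", "bE")] ==
                    rep(c(0, 0.1), each = 4)))
  expect_true(all(p[p$name == "RG-F", c("mE", "bE")] ==
                    rep(c(0.1, 0), each = 4)))
  expect_true(all(p$mI[p$name %in% c("V0D", "V0D-diag")] == 0.75))
  expect_true(all(p$mI[p$name == "V0V"] == 0.15))
  expect_true(all(p$mI[p$name %in% c("V0V-diag", "V2a", "V3", "CINi")] == 0))
})

test_that("side swap is an automorphism; girdle swap is not", {
  net <- qg_net()
  map <- stats::setNames(mirror_ids(net), net$populations$id)
  mirrored <- data.frame(src = unname(map[net$connections$src]),
                         dst = unname(map[net$connections$dst]),
                         weight = net$connections$weight)
  key <- function(d) sort(paste(d$src, d$dst, d$weight))
  expect_identical(key(mirrored), key(net$connections))

  p <- net$populations
  gswap <- stats::setNames(
    paste(ifelse(p$girdle == "fore", "hind", "fore"), p$side, p$name,
          sep = "_"), p$id)
  gsw <- data.frame(src = unname(gswap[net$connections$src]),
                    dst = unname(gswap[net$connections$dst]),
                    weight = net$connections$weight)
  expect_false(identical(key(gsw), key(net$connections)))
})

test_that("deletion clamps outputs, is idempotent and commutes", {
  net <- qg_net()
  expect_identical(delete_populations(net, character(0)), net)

  d1 <- delete_populations(net, "all V0V and V0D")
  del_names <- unique(net$populations$name[d1$populations$deleted])
  expect_setequal(del_names, c("V0V", "V0V-diag", "V0D", "V0D-diag"))

  # only the diagonal V0V LPNs, local CINs retained
  d2 <- delete_populations(net, "fore V0V-diag")
  expect_setequal(d2$populations$id[d2$populations$deleted],
                  c("fore_left_V0V-diag", "fore_right_V0V-diag"))

  expect_identical(delete_populations(d2, "fore V0V-diag"), d2)
  a <- delete_populations(delete_populations(net, "V3"), "CINi")
  b <- delete_populations(delete_populations(net, "CINi"), "V3")
  expect_identical(a, b)

  expect_error(delete_populations(net, "V0X"), "V0X")

  # descending-LPN selector: fore-section LPNs only
  d3 <- delete_populations(net, "cervical-to-lumbar LPNs")
  ids <- d3$populations$id[d3$populations$deleted]
  expect_true(all(grepl("^fore_", ids)))
  expect_setequal(unique(sub("^fore_(left|right)_", "", ids)),
                  c("Ini-Hom", "Sh2-Hom", "V0D-diag", "V0V-diag"))
})

test_that("deleted populations produce no output but keep their dynamics", {
  net <- delete_populations(qg_net(), "V3")
  st <- list(V = rep(-20, 56), h = rep(0.5, 8))
  rhs <- cpg_rhs(st, net, alpha = 0.5)
  # V3 still integrates (leak pulls it down from -20)
  i_v3 <- which(net$populations$id == "fore_left_V3")
  expect_lt(rhs$dV[i_v3], 0)
  # but a V3 target no longer receives its excitation: compare against the
  # intact network
  rhs0 <- cpg_rhs(st, qg_net(), alpha = 0.5)
  i_rgf <- which(net$populations$id == "fore_right_RG-F")
  expect_false(isTRUE(all.equal(rhs$dV[i_rgf], rhs0$dV[i_rgf])))
})

test_that("weight perturbation preserves structure and statistics", {
  net <- qg_net()
  expect_identical(perturb_weights(net, 0, seed = 1)$connections,
                   net$connections)
  p1 <- perturb_weights(net, 0.05, seed = 42)
  p2 <- perturb_weights(net, 0.05, seed = 42)
  expect_identical(p1$connections$weight, p2$connections$weight)
  expect_error(perturb_weights(net, -0.1), "sigma_p")

  # multipliers over many draws: mean ~ 1, sd ~ sigma_p
  mult <- unlist(lapply(1:200, function(s)
    perturb_weights(net, 0.05, seed = s)$connections$weight /
      net$connections$weight))
  expect_equal(mean(mult), 1, tolerance = 0.002)
  expect_equal(sd(mult), 0.05, tolerance = 0.02)
})

test_that("JSON round-trip and the bundled canonical file match the builder", {
  net <- qg_net()
  tmp <- tempfile(fileext = ".json")
  write_network(net, tmp)
  back <- read_network(tmp)
  expect_equal(back$populations, net$populations)
  expect_equal(back$connections, net$connections)

  canon <- read_network(system.file("extdata", "intact_network.json",
                                    package = "quadgait"))
  expect_equal(canon$populations, net$populations)
  expect_equal(canon$connections, net$connections)
})
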