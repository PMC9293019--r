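test_that("rate function implements elementary mass action", {
  # single irreversible decay
  net <- toy_network(c("A", "B"),
                     list(list(reactants = "A", products = "B", k_fwd = 1e-3)),
                     init = c(A = 1, B = 0),
                     roles = c(A = "intermediate", B = "product"))
  f <- assemble_rate_function(net)
  expect_equal(f(0, c(A = 2, B = 0), NULL)[[1]], c(-2e-3, 2e-3))

  # bimolecular rate k [A][B]
  net2 <- toy_network(c("A", "B", "C"),
                      list(list(reactants = c("A", "B"), products = "C",
                                k_fwd = 5)),
                      init = c(A = 1, B = 1, C = 0),
                      roles = c(A = "intermediate", B = "intermediate",
                                C = "product"))
  f2 <- assemble_rate_function(net2)
  expect_equal(f2(0, c(A = 0.3, B = 0.2, C = 0), NULL)[[1]],
               c(-0.3, -0.3, 0.3))

  # reversible step relaxes to detailed balance [B]/[A] = k_f/k_r
  net3 <- toy_network(c("A", "B"),
                      list(list(reactants = "A", products = "B",
                                k_fwd = 2, k_rev = 0.5)),
                      init = c(A = 1, B = 0))
  traj <- simulate_network(net3, t_end = 100)
  end <- traj$conc[nrow(traj$conc), ]
  expect_equal(unname(end["B"] / end["A"]), 4, tolerance = 1e-6)
})

test_that("integration matches the closed-form exponential", {
  net <- toy_network(c("A", "B"),
                     list(list(reactants = "A", products = "B", k_fwd = 1e-3)),
                     init = c(A = 1, B = 0),
                     roles = c(A = "intermediate", B = "product"),
                     catalyst = c(A = 1, B = 1))
  traj <- simulate_network(net, t_end = 3000)
  expect_equal(unname(traj$conc[nrow(traj$conc), "B"]), 0.950213,
               tolerance = 1e-6)
  expect_lt(max(traj$conservation), 1e-10)

  # zero-rate network stays constant
  net0 <- toy_network(c("A", "B"),
                      list(list(reactants = "A", products = "B", k_fwd = 0)),
                      init = c(A = 0.7, B = 0.1),
                      roles = c(A = "intermediate", B = "product"))
  traj0 <- simulate_network(net0, t_end = 1000)
  expect_equal(unname(traj0$conc[, "A"]), rep(0.7, length(traj0$time)))
})

test_that("stiff two-scale networks conserve mass", {
  # rates spanning 8 orders of magnitude
  net <- toy_network(c("A", "B", "C"),
                     list(list(reactants = "A", products = "B", k_fwd = 1e4,
                               k_rev = 1e4),
                          list(reactants = "B", products = "C",
                               k_fwd = 1e-4)),
                     init = c(A = 1, B = 0, C = 0),
                     roles = c(A = "intermediate", B = "intermediate",
                               C = "product"),
                     catalyst = c(A = 1, B = 1, C = 1))
  traj <- simulate_network(net, t_end = 1e4)
  expect_lt(max(traj$conservation), 1e-8)
  expect_true(all(traj$conc >= -1e-12))
})

test_that("selectivity arithmetic: designed channel yields give 92:8 and ee +84.8", {
  # landscape whose Curtin-Hammett yields are (RS, SR, RR, SS) =
  # (0.85, 0.07, 0.05, 0.03)
  RT <- gas_constant_kcal() * 298.15
  w <- c(RS = 0.85, SR = 0.07, RR = 0.05, SS = 0.03)
  pts <- dplyr::bind_rows(
    tibble::tibble(name = "EN", role = "intermediate", cycle = "A",
                   conformer = NA_character_, product_config = NA_character_,
                   g_rel = 0),
    tibble::tibble(name = "RC", role = "reactive_complex", cycle = "A",
                   conformer = NA_character_, product_config = NA_character_,
                   g_rel = 1),
    tibble::tibble(name = paste0("TS_", names(w)),
                   role = "transition_state", cycle = "A",
                   conformer = NA_character_, product_config = names(w),
                   g_rel = 19 + RT * log(max(w) / w)))
  net <- build_dual_cycle_network(landscape(pts, "aldol"))
  sel <- selectivity(simulate_network(net, t_end = 3e5))
  expect_equal(sel$dr$pct, c(92, 8), tolerance = 1e-3)
  expect_equal(sel$ee, 100 * (0.85 - 0.07) / 0.92, tolerance = 1e-3)
})

test_that("fast pre-equilibrium simulations match the Curtin-Hammett oracle", {
  for (ddg in c(0.5, 1.447)) {
    land <- generate_landscape(landscape_preset("two-channel", ddg = ddg))
    sel <- selectivity(simulate_network(build_dual_cycle_network(land),
                                        t_end = 3e5))
    ratio <- sel$dr$pct[1] / sel$dr$pct[2]
    expect_equal_rel(ratio, curtin_hammett_ratio(-ddg), 0.005)
  }
})

test_that("selectivity is invariant to catalyst loading and time rescaling", {
  land <- six_channel_landscape()
  ref <- NULL
  for (load in c(0.05, 0.3, 0.6)) {
    opts <- network_options(catalyst_equiv = load)
    net <- build_dual_cycle_network(land, opts)
    g <- glance(selectivity(simulate_network(net, t_end = 3e5)))
    if (is.null(ref)) ref <- g
    expect_equal(g$ee, ref$ee, tolerance = 1e-4)
    expect_equal(g$anti_pct, ref$anti_pct, tolerance = 1e-4)
    expect_equal(g$cycle_A_pct, ref$cycle_A_pct, tolerance = 1e-3)
  }
  # uniform rate scaling = time rescaling: selectivity unchanged
  net <- build_dual_cycle_network(land)
  scaled <- net
  scaled$reactions$k_fwd <- scaled$reactions$k_fwd * 10
  scaled$reactions$k_rev <- scaled$reactions$k_rev * 10
  scaled$channels$k_cc <- scaled$channels$k_cc * 10
  g1 <- glance(selectivity(simulate_network(net, t_end = 3e5)))
  g2 <- glance(selectivity(simulate_network(scaled, t_end = 3e4)))
  expect_equal(g2$ee, g1$ee, tolerance = 1e-4)
  expect_equal(g2$anti_pct, g1$anti_pct, tolerance = 1e-4)
})

test_that("mirror-swapped landscapes negate ee exactly and keep dr", {
  land <- six_channel_landscape()
  s1 <- selectivity(simulate_network(build_dual_cycle_network(land), 3e5))
  s2 <- selectivity(simulate_network(
    build_dual_cycle_network(mirror_landscape(land)), 3e5))
  expect_identical(s1$ee, -s2$ee)
  expect_identical(s1$dr$pct, s2$dr$pct)
})

test_that("degenerate selectivity inputs error cleanly", {
  net <- build_dual_cycle_network(minimal_landscape())
  # no catalyst, no turnover: selectivity undefined
  traj <- simulate_network(net, t_end = 100, init = c(cat = 0))
  expect_error(suppressWarnings(selectivity(traj)),
               class = "enaminekin_undefined_selectivity")
  expect_error(simulate_network(net, t_end = -1),
               class = "enaminekin_invalid_parameter")
})
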