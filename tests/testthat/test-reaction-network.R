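test_that("minimal single-cycle landscape gives a linear 4-step network", {
  net <- build_dual_cycle_network(minimal_landscape())
  expect_equal(nrow(net$reactions), 4)
  expect_equal(net$reactions$step,
               c("enamine_formation", "complex_formation", "cc_bond",
                 "hydrolysis"))
  expect_equal(nrow(net$channels), 1)
  expect_true(validate_network(net)$pass)
})

test_that("dual-cycle landscape yields one C-C reaction and product per TS", {
  net <- build_dual_cycle_network(six_channel_landscape())
  expect_equal(sum(net$reactions$step == "cc_bond"), 6)
  expect_equal(sum(net$species$role == "product"), 6)
  # stereo labels carried onto the product species rows
  expect_setequal(net$channels$product_config[net$channels$cycle == "A"],
                  c("RS", "SR", "RR", "SS"))
  # builder accounting: fixed overhead + 2 reactions per stereochannel
  overhead <- 2 + 4 + 2 + 2 # protonation, enamine formation, conformer
                            # exchange, complex formation
  expect_equal(nrow(net$reactions), overhead + 2 * 6)
  expect_true(validate_network(net)$pass)
})

test_that("michael landscapes get nitroalkene-cycle (INT3) naming", {
  spec <- landscape_preset("dual-cycle-michael")
  net <- build_dual_cycle_network(generate_landscape(spec))
  expect_true(any(grepl("^INT3_", net$species$name)))
  expect_false(any(grepl("^INT2_", net$species$name)))
  expect_equal(net$reaction_type, "michael")
  # michael default nucleophile excess is 8 equivalents
  expect_equal(unname(net$init["ketone"] / net$init["E"]), 8)
})

test_that("malformed landscapes are rejected with channel diagnostics", {
  pts <- tidy(minimal_landscape())
  no_rc <- pts[pts$role != "reactive_complex", ]
  expect_error(
    build_dual_cycle_network(landscape(no_rc, "aldol")),
    class = "enaminekin_malformed_landscape")
})

test_that("validate_network flags imbalance and unreachable species", {
  net <- build_dual_cycle_network(minimal_landscape())
  # corrupt one hydrolysis step so a catalyst tag disappears
  broken <- net
  hy <- which(broken$reactions$step == "hydrolysis")
  prods <- broken$reactions$products[[hy]]
  broken$reactions$products[[hy]] <- setdiff(prods, "cat")
  d <- validate_network(broken)
  expect_false(d$pass)
  expect_true("catalyst" %in% d$balance$tag)

  orphan <- net
  orphan$species <- dplyr::bind_rows(
    orphan$species,
    tibble::tibble(name = "ghost", role = "intermediate", catalyst = 0,
                   ketone = 0, electrophile = 0, acid_proton = 0,
                   product = 0))
  d2 <- validate_network(orphan)
  expect_false(d2$pass)
  expect_equal(d2$unreachable, "ghost")
})

test_that("catalyst tag total is conserved across every reaction", {
  for (land in list(minimal_landscape(), six_channel_landscape(),
                    generate_landscape(landscape_preset("dual-cycle-aldol")))) {
    net <- build_dual_cycle_network(land)
    expect_equal(nrow(validate_network(net)$balance), 0)
  }
})

test_that("C-C rate constants follow the Eyring relation on TS - RC gaps", {
  land <- six_channel_landscape()
  net <- build_dual_cycle_network(land)
  expect_equal(net$channels$k_cc,
               eyring_rate(net$channels$barrier, land$temperature))
  # barrier measured from the channel's own reactive complex
  a_rs <- net$channels[net$channels$ts_name == "TSa_RS", ]
  expect_equal(a_rs$barrier, 18 - 1)
})
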