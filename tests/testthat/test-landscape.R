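test_that("stereo table fixes the config/diastereomer mapping per reaction", {
  st_a <- stereo_table("aldol")
  expect_equal(st_a$diastereo_class[st_a$product_config %in% c("RS", "SR")],
               c("anti", "anti"))
  st_m <- stereo_table("michael")
  expect_equal(st_m$diastereo_class[st_m$product_config %in% c("RS", "SR")],
               c("syn", "syn"))
  # like topology iff both prochiral faces agree
  for (st in list(st_a, st_m)) {
    faces <- strsplit(st$face_pair, ",")
    expect_equal(st$topology,
                 ifelse(vapply(faces, function(f) f[1] == f[2], TRUE),
                        "lk", "ul"))
  }
})

test_that("landscape constructor validates points", {
  l <- minimal_landscape()
  expect_s3_class(l, "fe_landscape")
  expect_equal(tidy(l)$diastereo_class[tidy(l)$role == "transition_state"],
               "anti")

  bad_dup <- tidy(l)[c(1, 1, 2, 3), ]
  expect_error(landscape(bad_dup, "aldol"),
               class = "enaminekin_validation_error")

  bad_role <- tidy(l)
  bad_role$role[1] <- "saddle"
  expect_error(landscape(bad_role, "aldol"), class = "enaminekin_enum_error")

  no_ts <- tidy(l)[1:2, ]
  expect_error(landscape(no_ts, "aldol"),
               class = "enaminekin_validation_error")

  # TS without stereochemical label is rejected
  unlabelled <- tidy(l)
  unlabelled$product_config[unlabelled$role == "transition_state"] <- NA
  expect_error(landscape(unlabelled, "aldol"),
               class = "enaminekin_validation_error")

  # zero reference must be unique
  two_zero <- tidy(l)
  two_zero$g_rel[2] <- 0
  expect_error(landscape(two_zero, "aldol"),
               class = "enaminekin_validation_error")
})

test_that("landscape YAML round-trips and shipped presets parse", {
  l <- six_channel_landscape()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_landscape(l, path)
  l2 <- read_landscape(path)
  expect_equal(l2$reaction_type, l$reaction_type)
  expect_equal(tidy(l2), tidy(l))

  shipped <- system.file("extdata", "aldol_dual_cycle_synthetic.yaml",
                         package = "enaminekin")
  l3 <- read_landscape(shipped)
  expect_s3_class(l3, "fe_landscape")
  expect_equal(sum(tidy(l3)$role == "transition_state"), 8)
})

test_that("landscape file errors are specific", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("reaction_type: aldol",
               "points:",
               "- name: EN", "  role: intermediate", "  cycle: A",
               "  g_rel: 0.0",
               "- name: TS", "  role: transition_state", "  cycle: A",
               "  product_config: RS"), path)
  expect_error(read_landscape(path), "g_rel",
               class = "enaminekin_parse_error")

  writeLines(c("reaction_type: aldol",
               "points:",
               "- name: EN", "  role: minimum", "  cycle: A",
               "  g_rel: 0.0",
               "- name: TS", "  role: transition_state", "  cycle: A",
               "  product_config: RS", "  g_rel: 19.0"), path)
  expect_error(read_landscape(path), class = "enaminekin_enum_error")
})

test_that("mirror_landscape is an involution that swaps enantiomer labels", {
  l <- six_channel_landscape()
  m <- mirror_landscape(l)
  ts <- tidy(l)$role == "transition_state"
  expect_equal(tidy(m)$product_config[ts],
               unname(c(RS = "SR", SR = "RS", RR = "SS",
                        SS = "RR")[tidy(l)$product_config[ts]]))
  expect_equal(tidy(m)$g_rel, tidy(l)$g_rel)
  expect_equal(tidy(mirror_landscape(m)), tidy(l))
})
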