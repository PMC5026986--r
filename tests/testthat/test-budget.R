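test_that("profile validation accepts flagged-missing cells, rejects bad rows", {
  df <- make_profile_fixture()
  expect_equal(nrow(read_profiles(df)), 2)
  # not-determined ammonium mid-series is accepted, never imputed
  df3 <- tibble::tibble(sample_id = c("a", "b", "c"), source = "tree",
                        treatment = "unfiltered", week = c(0L, 1L, 4L),
                        nh4_uM = c(174, NA, 94), no2_uM = c(11, 8, 0),
                        no3_uM = c(219, 240, 332))
  got <- read_profiles(df3)
  expect_equal(nrow(got), 3)
  expect_true(is.na(got$nh4_uM[2]))
  bad <- df; bad$nh4_uM[1] <- -1
  expect_error(validate_profiles(bad), "negative nh4_uM in rows 1")
  bad <- df; bad$treatment[2] <- "f5um"
  expect_error(validate_profiles(bad), "unknown treatment")
  bad <- rbind(df, df[1, ])
  expect_error(validate_profiles(bad), "duplicate")
  bad <- df; bad$week[2] <- 9L
  expect_error(validate_profiles(bad), "week outside")
})

test_that("mineral nitrogen sums the three species", {
  expect_equal(mineral_nitrogen(174, 11, 219), 404)
  expect_equal(mineral_nitrogen(404, 5, 267), 676) # reported as 677 after rounding
  expect_equal(mineral_nitrogen(0, 0, 0), 0)
  # permutation-invariant and additive
  expect_equal(mineral_nitrogen(11, 219, 174), 404)
  expect_equal(mineral_nitrogen(10, 20, 30) + mineral_nitrogen(1, 2, 3),
               mineral_nitrogen(11, 22, 33))
  expect_error(mineral_nitrogen(174, NA, 219), "determined")
})

test_that("budget summary computes deltas, oxidized N, and excess", {
  # mirrors the active-throughfall pattern: dNO3 +113, dNO2 -11, dNH4 -80
  df <- make_profile_fixture(nh4 = c(174, 94), no2 = c(11, 0),
                             no3 = c(219, 332))
  b <- summarize_budget(df)
  expect_equal(b$delta_no3, 113)
  expect_equal(b$delta_no2, -11)
  expect_equal(b$delta_nh4, -80)
  expect_equal(b$oxidized_n_produced, 102)
  expect_equal(b$excess_over_nh4_consumption, 22)
  expect_equal(b$classification, "nitrifying")
  # all-zero deltas: inactive, zero excess
  df0 <- make_profile_fixture(nh4 = c(50, 50), no2 = c(2, 2), no3 = c(100, 100))
  b0 <- summarize_budget(df0)
  expect_equal(b0$excess_over_nh4_consumption, 0)
  expect_equal(b0$classification, "inactive")
  # nitrite builds up without nitrate gain: the coarse-filter fingerprint
  dfn <- make_profile_fixture(nh4 = c(100, 65), no2 = c(5, 35), no3 = c(150, 150))
  expect_equal(summarize_budget(dfn)$classification, "nitrite_accumulating")
})

test_that("missing ammonium never blocks nitrate/nitrite deltas", {
  df <- tibble::tibble(sample_id = c("a", "b", "c"), source = "tree",
                       treatment = "unfiltered", week = c(0L, 1L, 4L),
                       nh4_uM = c(174, 140, NA), no2_uM = c(11, 8, 0),
                       no3_uM = c(219, 240, 332))
  b <- summarize_budget(df)
  expect_equal(b$delta_no3, 113)
  expect_equal(b$delta_nh4, 140 - 174) # latest determined week (1)
  df_none <- df; df_none$nh4_uM <- NA_real_
  b2 <- summarize_budget(df_none)
  expect_true(is.na(b2$delta_nh4))
  expect_true(is.na(b2$excess_over_nh4_consumption))
  expect_equal(b2$delta_no3, 113)
})

test_that("classification is scale-invariant above absolute thresholds", {
  df <- make_profile_fixture(nh4 = c(174, 94), no2 = c(11, 0),
                             no3 = c(219, 332))
  for (scale in c(1, 2, 5, 10)) {
    scaled <- df
    for (col in c("nh4_uM", "no2_uM", "no3_uM")) {
      scaled[[col]] <- scaled[[col]] * scale
    }
    expect_equal(summarize_budget(scaled)$classification, "nitrifying")
  }
})

test_that("groups without post-incubation nitrate error unless strict=FALSE", {
  df <- make_profile_fixture(no3 = c(219, NA))
  expect_error(summarize_budget(df), "post-incubation")
  b <- summarize_budget(df, strict = FALSE)
  expect_true(is.na(b$classification))
  expect_match(b$note, "post-incubation")
})

test_that("budget conservation holds on noise-free simulator output", {
  sim <- simulate_incubation(scenario_templates(seed = 5)$cj1_like)
  pt <- sim$profiles_true[sim$profiles_true$treatment == "unfiltered", ]
  total <- pt$nh4_uM + pt$no2_uM + pt$no3_uM + pt$don_uM + pt$immobilized_uM
  expect_lt(max(abs(total - total[1])) / total[1], 1e-9)
  # endpoint identity: oxidized production == what left NH4+DON minus immobilized
  b <- summarize_budget(pt[, c("sample_id", "source", "treatment", "week",
                               "nh4_uM", "no2_uM", "no3_uM")])
  w0 <- pt[pt$week == 0, ]; w4 <- pt[pt$week == 4, ]
  expect_equal(b$oxidized_n_produced,
               (w0$nh4_uM + w0$don_uM) - (w4$nh4_uM + w4$don_uM) -
                 w4$immobilized_uM,
               tolerance = 1e-9)
})
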