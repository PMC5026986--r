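test_that("endmember prediction follows the 2/3-water, 1/3-O2 rule", {
  em <- nitrification_endmember(-10, -5, 23.5, 2 / 3)
  expect_equal(round(em$endmember_low, 1), 1.2)
  expect_equal(round(em$endmember_high, 1), 4.5)
  # degenerate water range
  em5 <- nitrification_endmember(-5, -5, 23.5, 2 / 3)
  expect_equal(em5$endmember_low, em5$endmember_high)
  expect_equal(em5$endmember_high, 4.5)
  # all sources identical -> that value, any fraction
  for (wf in c(0, 0.25, 2 / 3, 1)) {
    em1 <- nitrification_endmember(7, 7, 7, wf)
    expect_equal(em1$endmember_low, 7)
    expect_equal(em1$endmember_high, 7)
  }
  # interval width scales with the water fraction
  expect_equal(em$endmember_high - em$endmember_low, (2 / 3) * 5,
               tolerance = 1e-12)
  expect_error(nitrification_endmember(-5, -10), "inverted")
  expect_error(nitrification_endmember(-10, -5, water_fraction = 1.2), "0, 1")
})

test_that("mixing fraction reproduces the two-source mass balance", {
  expect_equal(mixing_fraction(74.1, 49.8, 1.2), 24.3 / 72.9,
               tolerance = 1e-12)
  expect_equal(mixing_fraction(10, 10, 2), 0)     # no change
  expect_equal(mixing_fraction(10, 2, 2), 1)      # fully replaced
  expect_error(mixing_fraction(5, 4, 5), "undefined")
  # clamping: within 2 SD of a bound warns and clamps
  expect_warning(f <- mixing_fraction(74.1, 74.5, 1.2, sd_permil = 0.59),
                 "clamped")
  expect_equal(f, 0)
  expect_error(mixing_fraction(74.1, 80, 1.2, sd_permil = 0.59), "envelope")
})

test_that("mixing fraction is monotone and bracketed by endmember bounds", {
  di <- 74.1; dn <- 2.85
  finals <- seq(70, 10, by = -5)
  fs <- vapply(finals, function(df) mixing_fraction(di, df, dn), numeric(1))
  expect_true(all(diff(fs) > 0))          # decreasing delta_final -> larger f
  expect_true(all(fs >= 0 & fs <= 1))
  # pointwise f for any water value lies inside the propagated interval
  em <- nitrification_endmember(-10, -5)
  for (water in seq(-10, -5, by = 0.5)) {
    dn_w <- (2 / 3) * water + (1 / 3) * 23.5
    f_pt <- mixing_fraction(di, 49.8, dn_w)
    f_lo <- mixing_fraction(di, 49.8, em$endmember_low)
    f_hi <- mixing_fraction(di, 49.8, em$endmember_high)
    expect_gte(f_pt, min(f_lo, f_hi) - 1e-12)
    expect_lte(f_pt, max(f_lo, f_hi) + 1e-12)
  }
})

test_that("forward mixing then inversion recovers the true new fraction", {
  # brute-force oracle over a grid of pools and signatures
  grid <- expand.grid(d_old = c(80, 74.1, 62), d_new = c(-3, 1.2, 4.5, 10),
                      ratio = c(0.1, 0.5, 1, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    c_old <- 219; c_new <- g$ratio * c_old
    d_mix <- mix_forward(c_old, g$d_old, c_new, g$d_new)
    f <- mixing_fraction(g$d_old, d_mix, g$d_new)
    expect_equal(f, c_new / (c_old + c_new), tolerance = 1e-9)
  }
})

test_that("new:original percentage and its inverse round-trip", {
  expect_equal(new_to_original_pct(0), 0)
  expect_equal(new_to_original_pct(0.5), 100)
  expect_equal(new_to_original_pct(1 / 3), 50, tolerance = 1e-9)
  expect_error(new_to_original_pct(1), "diverges")
  for (f in c(0, 0.1, 1 / 3, 0.75, 0.99)) {
    expect_equal(frac_from_pct(new_to_original_pct(f)), f, tolerance = 1e-12)
  }
})

test_that("concentration increase is a plain relative change", {
  expect_equal(concentration_increase_pct(219, 332), 51.598, tolerance = 1e-3)
  expect_equal(concentration_increase_pct(100, 150), 50)
  expect_equal(concentration_increase_pct(7, 7), 0)
  expect_error(concentration_increase_pct(0, 10), "positive")
})

test_that("implied delta-15N of new nitrate inverts the mass balance", {
  expect_equal(implied_new_delta15n(6.1, -1.7, 1 / 3), -17.3, tolerance = 1e-9)
  expect_lt(implied_new_delta15n(6.1, -1.7, 1 / 3), 0) # ammonium-like source
  expect_equal(implied_new_delta15n(4, 4, 0.3), 4)
  # forward-then-inverse recovers the endmember signature
  withr::local_seed(21)
  for (i in 1:25) {
    di <- runif(1, 0, 10); dn <- runif(1, -25, 0); f <- runif(1, 0.05, 0.95)
    dmix <- (1 - f) * di + f * dn
    expect_equal(implied_new_delta15n(di, dmix, f), dn, tolerance = 1e-9)
  }
  expect_error(implied_new_delta15n(6, 2, 0), "0, 1")
})

test_that("attribution assembles interval, cross-check, and consistency", {
  att <- attribute_nitrification(74.1, 49.8, nitrification_endmember(),
                                 c_initial = 219, c_final = 332)
  expect_equal(round(att$new_to_original_pct_low, 1), 50.0)
  expect_equal(round(att$new_to_original_pct_high, 1), 53.6)
  expect_equal(att$conc_based_pct, 51.6, tolerance = 0.05)
  expect_true(att$consistent)
  expect_lte(att$frac_new_of_final_low, att$frac_new_of_final_high)
  # no isotopic change and no concentration change -> all zero, consistent
  att0 <- attribute_nitrification(74.1, 74.1, nitrification_endmember(),
                                  c_initial = 219, c_final = 219)
  expect_equal(att0$new_to_original_pct_low, 0)
  expect_equal(att0$new_to_original_pct_high, 0)
  expect_equal(att0$conc_based_pct, 0)
  expect_true(att0$consistent)
  # disjoint interval vs concentration-based value at small tolerance
  att_bad <- attribute_nitrification(74.1, 66, c(1.2, 4.5),
                                     c_initial = 100, c_final = 140,
                                     tolerance_pp = 2)
  expect_lt(att_bad$new_to_original_pct_high, 15)
  expect_false(att_bad$consistent)
  # numeric endmember shorthand and missing concentrations
  att_na <- attribute_nitrification(74.1, 49.8, 2.85)
  expect_true(is.na(att_na$conc_based_pct))
  expect_true(is.na(att_na$consistent))
})

test_that("delta-method SD matches Monte-Carlo noise propagation", {
  di <- 74.1; df <- 49.8; dn <- 2.85; sd <- 0.59
  analytic <- mixing_pct_sd(di, df, dn, sd)
  withr::local_seed(88)
  pct <- replicate(20000, {
    di2 <- di + rnorm(1, 0, sd)
    df2 <- df + rnorm(1, 0, sd)
    f <- (di2 - df2) / (di2 - dn)
    100 * f / (1 - f)
  })
  expect_lt(abs(sd(pct) - analytic) / analytic, 0.1)
})
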