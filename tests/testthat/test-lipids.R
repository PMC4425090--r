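test_that("fatty-acid labels parse with typographic normalization", {
  fa <- parse_fatty_acid("C16")
  expect_equal(fa$carbons, 16L)
  expect_equal(fa$double_bonds, 0L)
  expect_equal(fa$class, "SFA")

  fa3 <- parse_fatty_acid("C18:3 n − 3")   # unicode minus, spaced
  expect_equal(fa3$carbons, 18L)
  expect_equal(fa3$double_bonds, 3L)
  expect_equal(fa3$omega, 3L)
  expect_equal(fa3$class, "PUFA")
  expect_equal(fa3$shorthand, "C18:3 n-3")

  expect_equal(parse_fatty_acid("C18:1 *n* - 9")$class, "MUFA")
  expect_error(parse_fatty_acid("C18:1x"), "cannot parse")
  expect_error(parse_fatty_acid("C17"), "even")
})

test_that("parse/render round-trips the table labels and random ones", {
  labels <- c("C16", "C16:1 n-7", "C18", "C18:1 n-9", "C18:2 n-6",
              "C18:3 n-3", "C20", "C20:1 n-9", "C20:5 n-3", "C22:1 n-9",
              "C22:2 n-6")
  for (l in labels) expect_equal(parse_fatty_acid(l)$shorthand, l)
  set.seed(5)
  for (i in 1:40) {
    carbons <- 2L * sample(2:13, 1)
    db <- sample(0:6, 1)
    om <- if (db > 0 && runif(1) < 0.5) sample(c(3L, 6L, 7L, 9L), 1) else NA
    l <- render_fatty_acid(carbons, db, om)
    fa <- parse_fatty_acid(l)
    expect_equal(fa$shorthand, l)
    expect_equal(fa$carbons, carbons)
    expect_equal(fa$double_bonds, db)
  }
})

test_that("class sums reproduce the packaged tables and are invariant", {
  cs_m <- class_sums(gx_fatty_acids("methf"))
  expect_equal(round(cs_m[["SFA"]], 2), 6.25)
  expect_equal(round(cs_m[["MUFA"]], 2), 61.83)
  expect_equal(round(cs_m[["PUFA"]], 2), 33.00)
  expect_equal(round(class_sums(gx_fatty_acids("hexane"))[["SFA"]], 2), 6.26)

  p <- fa_profile(c("C16", "C18:1 n-9", "C18:2 n-6"), c(5, 60, 30))
  base <- class_sums(p)
  # row order
  p2 <- fa_profile(c("C18:2 n-6", "C16", "C18:1 n-9"), c(30, 5, 60))
  expect_equal(class_sums(p2), base)
  # splitting an analyte into two rows with the same total
  p3 <- fa_profile(c("C16", "C18:1 n-9", "C18:1 n-9", "C18:2 n-6"),
                   c(5, 25, 35, 30))
  expect_equal(class_sums(p3), base)
  # empty profile
  expect_equal(unname(class_sums(fa_profile(character(), numeric()))),
               c(0, 0, 0))
})

test_that("profile invariants are enforced", {
  expect_error(fa_profile("C16", -1), "means")
  expect_error(fa_profile(c("C16", "C18:1 n-9"), c(60, 60)), "sums")
})

test_that("vitamin E equivalents weight the four tocopherols", {
  pm <- tocopherol_panel(c("alpha", "beta", "gamma", "delta"),
                         c(277, 3.5, 443, 13.3))
  expect_equal(as.numeric(vitamin_e_equivalents(pm)),
               (277 + 0.5 * 3.5 + 0.1 * 443 + 0.03 * 13.3) / 10)
  expect_equal(round_half_up(as.numeric(vitamin_e_equivalents(pm)), 1), 32.3)
  ph <- tocopherol_panel(c("alpha", "beta", "gamma", "delta"),
                         c(292, 3.3, 488, 14.3))
  # the hexane column computes to 34.3 against a reported 34.2 +- 1.0
  expect_equal(round_half_up(as.numeric(vitamin_e_equivalents(ph)), 1), 34.3)
  expect_equal(as.numeric(vitamin_e_equivalents(
    tocopherol_panel("alpha", 0))), 0)
  # censored entries contribute zero and are flagged
  pc <- tocopherol_panel(c("alpha", "gamma"), c(100, 5),
                         censored = c(FALSE, TRUE))
  v <- vitamin_e_equivalents(pc)
  expect_equal(as.numeric(v), 10)
  expect_equal(attr(v, "censored_dropped"), "gamma")
})

test_that("packaged tocopherol panels carry their censoring", {
  tp <- gx_tocopherols("methf")
  expect_true(all(tp$censored[grepl("tocotrienol|acetate", tp$compound)]))
  expect_equal(tp$mean[tp$compound == "alpha_tocotrienol"], 2)  # the limit
})

test_that("yield definition", {
  expect_equal(compute_yield(13.9, 30), 46.33, tolerance = 1e-3)
  expect_equal(compute_yield(0, 30), 0)
  expect_equal(compute_yield(30, 30), 100)
  expect_error(compute_yield(1, 0), "dry_seed_mass")
})

test_that("profile comparison uses Welch statistics from summaries", {
  hex <- gx_fatty_acids("hexane"); met <- gx_fatty_acids("methf")
  self <- compare_profiles(hex, hex)
  expect_equal(attr(self, "n_significant"), 0)

  cmp <- compare_profiles(hex, met)
  oleic <- cmp[cmp$analyte == "C18:1 n-9", ]
  expect_false(oleic$significant)
  expect_lt(abs(oleic$t), 0.05)
  expect_equal(oleic$p,
               oracle_welch_p(58.26, 0.88, 3, 58.28, 0.83, 3),
               tolerance = 1e-12)

  sep <- compare_profiles(fa_profile("C16", 10, 0.1, 3),
                          fa_profile("C16", 20, 0.1, 3))
  expect_true(sep$significant)

  # missing analyte reported as incomparable
  miss <- compare_profiles(fa_profile(c("C16", "C18"), c(5, 2), 0.1, 3),
                           fa_profile("C16", 5, 0.1, 3))
  expect_false(miss$comparable[miss$analyte == "C18"])
  expect_true(is.na(miss$p[miss$analyte == "C18"]))
  expect_error(compare_profiles(fa_profile("C16", 5, 0.1, 1),
                                fa_profile("C16", 5, 0.1, 3)), "n >= 2")
})

test_that("sterol fixtures: identified fractions sum to ~100%", {
  for (sv in c("hexane", "methf")) {
    d <- gx_sterols(sv)
    ident <- d[d$unit == "pct_identified_sterols" & !d$censored, ]
    expect_equal(sum(ident$mean), 100, tolerance = 0.6 / 100)
  }
})

test_that("censored composition values parse as limits", {
  d <- gx_sterols("methf")
  row <- d[d$analyte == "d7-stigmasterol", ]
  expect_true(row$censored)
  expect_equal(row$mean, 0.1)
})
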