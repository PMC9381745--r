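test_that("tie-line length matches the Euclidean definition", {
  tl <- tieline(c(17.58, 28.98), c(9.44, 61.42), c(22.43, 10.47))
  expect_equal(tl$tll, 52.58, tolerance = 0.01 / 52.58)
  # degenerate and axis-aligned cases (plain data frames, no labelling)
  expect_equal(tll(data.frame(top_ws = 5, top_wp = 30,
                              bot_ws = 5, bot_wp = 30)), 0)
  expect_equal(tll(data.frame(top_ws = 5, top_wp = 40,
                              bot_ws = 5, bot_wp = 30)), 10)
})

test_that("tie-line length is swap-symmetric and translation-invariant", {
  set.seed(41)
  for (i in 1:20) {
    d <- data.frame(top_ws = runif(1, 5, 15), top_wp = runif(1, 40, 70),
                    bot_ws = runif(1, 20, 35), bot_wp = runif(1, 5, 15))
    swapped <- data.frame(top_ws = d$bot_ws, top_wp = d$bot_wp,
                          bot_ws = d$top_ws, bot_wp = d$top_wp)
    expect_equal(tll(d), tll(swapped))
    shift <- rnorm(2)
    moved <- data.frame(top_ws = d$top_ws + shift[1],
                        top_wp = d$top_wp + shift[2],
                        bot_ws = d$bot_ws + shift[1],
                        bot_wp = d$bot_wp + shift[2])
    expect_equal(tll(d), tll(moved))
  }
})

test_that("packaged tie-lines reproduce reported lengths and monotone trend", {
  tl <- peg600_koh_tielines()
  expect_equal(tl$tll, reported_tll, tolerance = 0.01 / min(reported_tll))
  expect_true(all(abs(tl$tll - reported_tll) <= 0.01))
  expect_true(all(diff(tl$tll) > 0))            # deeper mixtures, longer lines
  expect_true(all(diff(tl$overall_ws) > 0))
})

test_that("tie-line tables validate closure and phase labels", {
  base <- data.frame(overall_ws = 16, overall_wp = 30, top_ws = 9,
                     top_wp = 60, bot_ws = 24, bot_wp = 10)
  expect_s3_class(as_tielines(base), "tielines")
  swapped <- base
  swapped[c("top_ws", "top_wp", "bot_ws", "bot_wp")] <-
    base[c("bot_ws", "bot_wp", "top_ws", "top_wp")]
  expect_warning(fixed <- as_tielines(swapped), "mislabelled")
  expect_equal(fixed$top_wp, 60)
  expect_error(as_tielines(swapped, fix_labels = FALSE), "convention")
  expect_error(as_tielines(base[, -1]), "needs columns")
  expect_error(as_tielines(base[0, ]), "empty")
  bad <- base; bad$top_wp <- 95   # polymer + salt exceed 100: water < 0
  expect_error(as_tielines(bad), "\\[0, 100\\]")
})

test_that("lever rule localises the overall composition on the segment", {
  tl <- tieline(c((9 + 24) / 2, (60 + 10) / 2), c(9, 60), c(24, 10))
  rep <- lever_rule_check(tl)
  expect_equal(rep$phase_fraction_top, 0.5)
  expect_equal(rep$max_deviation, 0)
  expect_true(rep$pass)
  # measured data: per-component fractions agree to ~0.01, passes at 0.8 wt%
  t2 <- peg600_koh_tielines()
  r2 <- lever_rule_check(t2, tolerance = 0.8)
  expect_equal(r2$fraction_salt[1], 0.3734, tolerance = 1e-3)
  expect_equal(r2$fraction_polymer[1], 0.3633, tolerance = 1e-3)
  expect_true(all(r2$pass))
  expect_lt(max(r2$max_deviation), 0.5)
  # overall displaced off the segment fails
  off <- as_tielines(data.frame(overall_ws = 16.5 + 4, overall_wp = 35,
                                top_ws = 9, top_wp = 60,
                                bot_ws = 24, bot_wp = 10))
  expect_false(lever_rule_check(off, tolerance = 0.8)$pass)
  degen <- data.frame(overall_ws = 9, overall_wp = 60, top_ws = 9,
                      top_wp = 60, bot_ws = 9, bot_wp = 60)
  expect_error(lever_rule_check(degen), "degenerate")
})

test_that("Othmer-Tobias fit recovers exact generating parameters", {
  tl <- exact_ot_tielines(k = 0.5, n = 1.2)
  fit <- fit_othmer_tobias(tl)
  expect_equal(coef(fit), c(k = 0.5, n = 1.2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$sd, 1e-12)
  # identical ratios on both sides force k = 1, n = 1
  bws <- c(25, 28, 31)
  same <- as_tielines(data.frame(overall_ws = (9 + bws) / 2,
                                 overall_wp = (bws + 8) / 2, top_ws = 9,
                                 top_wp = bws, bot_ws = bws, bot_wp = 8))
  expect_equal(coef(fit_othmer_tobias(same)), c(k = 1, n = 1),
               tolerance = 1e-12)
  # predict inverts the fitted relation
  expect_equal(predict(fit, tl$bot_ws), tl$top_wp, tolerance = 1e-10)
})

test_that("Othmer-Tobias fit signals singular or degenerate input", {
  tl <- exact_ot_tielines(0.5, 1.2)
  sing <- as.data.frame(tl); sing$top_wp[1] <- 100
  expect_error(fit_othmer_tobias(sing), "singular")
  one <- as.data.frame(tl)[c(1, 1), ]
  expect_error(fit_othmer_tobias(one), "degenerate")
  expect_error(fit_othmer_tobias(as.data.frame(tl)[1, , drop = FALSE]),
               "at least 2")
})

test_that("Bancroft fit recovers exact generating parameters", {
  tl <- exact_bancroft_tielines(k1 = 2.0, r = 0.8,
                                top_wp = seq(55, 70, length.out = 4))
  fit <- fit_bancroft(tl)
  expect_equal(coef(fit), c(k1 = 2.0, r = 0.8), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_bancroft(as.data.frame(tl)[c(2, 2), ]), "degenerate")
})

test_that("consistency fits verdict the packaged tie-lines as linear", {
  t2 <- peg600_koh_tielines()
  ot <- fit_othmer_tobias(t2)
  ba <- fit_bancroft(t2)
  expect_gte(ot$r_squared, 0.95)
  expect_gte(ba$r_squared, 0.95)
  expect_true(ot$consistent)
  expect_true(ba$consistent)
  # independent linearised-regression oracle via stats::lm
  y <- log10((1 - t2$top_wp / 100) / (t2$top_wp / 100))
  x <- log10((1 - t2$bot_ws / 100) / (t2$bot_ws / 100))
  m <- lm(y ~ x)
  expect_equal(unname(coef(ot)), unname(c(10^coef(m)[1], coef(m)[2])),
               tolerance = 1e-10)
  expect_equal(ot$r_squared, summary(m)$r.squared, tolerance = 1e-12)
})

test_that("Setschenow fit recovers exact generating parameters", {
  cfg <- sim_config(seed = 3, tieline_mode = "setschenow",
                    setschenow_truth = c(k_p = 0.2, k_s = 1.1))
  fit <- fit_setschenow(generate_tielines(cfg))
  expect_equal(coef(fit), c(k_p = 0.2, k_s = 1.1), tolerance = 1e-10)
  expect_lt(fit$sd, 1e-12)
  # zero salt-molality difference predicts ln-ratio = k_p
  expect_equal(unname(predict(fit, 0)), 0.2, tolerance = 1e-10)
})

test_that("Setschenow on the measured tie-lines is finite but anomalous", {
  # on the per-kg-water molality basis this water-poor top phase carries
  # more salt per kg water than the bottom in the last line, so the
  # salting-out slope comes out negative and the fitter must warn
  t2 <- peg600_koh_tielines()
  expect_warning(fit <- fit_setschenow(t2), "not positive")
  expect_true(all(is.finite(coef(fit))))
  expect_lt(coef(fit)[["k_s"]], 0)
  expect_gt(fit$sd, 0)
  expect_equal(fit$gof$n_points, 5L)
  zero_poly <- as.data.frame(t2); zero_poly$bot_wp <- 0
  expect_error(fit_setschenow(zero_poly), "zero polymer")
})

test_that("tie-line CSV reading validates input", {
  csv <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(peg600_koh_tielines())[, 1:6], csv,
            row.names = FALSE)
  tl <- read_tielines(csv)
  expect_s3_class(tl, "tielines")
  expect_equal(nrow(tl), 5L)
  empty <- tempfile(fileext = ".csv")
  writeLines("overall_ws,overall_wp,top_ws,top_wp,bot_ws,bot_wp", empty)
  expect_error(read_tielines(empty), "empty")
})
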