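test_that("generator configuration is validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_binodal_points = 0), ">= 1")
  expect_error(sim_config(binodal_noise_sd = -0.1), ">= 0")
  expect_error(sim_config(top_anchors = c(25, 26, 27, 28, 29),
                          bottom_anchors = c(21, 23, 25, 27, 29)),
               "below")
})

test_that("binodal generation is exact at zero noise and seed-stable", {
  cfg0 <- sim_config(seed = 9, binodal_noise_sd = 0)
  pts <- generate_binodal(cfg0)
  tr <- cfg0$binodal_truth
  expect_equal(pts$w_p, merchuk_wp(pts$w_s, tr["a"], tr["b"], tr["c"]))
  cfg <- sim_config(seed = 9)
  expect_identical(generate_binodal(cfg), generate_binodal(cfg))
  expect_false(identical(generate_binodal(cfg),
                         generate_binodal(sim_config(seed = 10))))
  # negative noiseless curve is refused
  neg <- sim_config(binodal_truth = c(a = -5, b = -0.95, c = 5e-6))
  expect_error(generate_binodal(neg), "negative")
})

test_that("binodal noise has the configured scale", {
  cfg <- sim_config(seed = 29, n_binodal_points = 200, binodal_noise_sd = 0.3)
  pts <- generate_binodal(cfg)
  tr <- cfg$binodal_truth
  res <- pts$w_p - merchuk_wp(pts$w_s, tr["a"], tr["b"], tr["c"])
  expect_gt(sd(res), 0.25)   # 99% chi-square band for n = 200
  expect_lt(sd(res), 0.35)
})

test_that("generated tie-lines satisfy the lever rule and conventions", {
  cfg <- sim_config(seed = 15)
  tl <- generate_tielines(cfg)
  expect_s3_class(tl, "tielines")
  expect_equal(nrow(tl), 5L)
  expect_true(all(tl$top_wp > tl$bot_wp))
  expect_true(all(tl$bot_ws > tl$top_ws))
  rep <- lever_rule_check(tl, tolerance = 1e-9)
  expect_true(all(rep$pass))
  expect_true(all(rep$phase_fraction_top >= 0.3 &
                    rep$phase_fraction_top <= 0.7))
  expect_identical(generate_tielines(cfg), generate_tielines(cfg))
  # endpoints lie exactly on the truth binodal in "binodal" mode
  tr <- cfg$binodal_truth
  expect_equal(tl$top_wp, merchuk_wp(tl$top_ws, tr["a"], tr["b"], tr["c"]))
  expect_equal(tl$bot_wp, merchuk_wp(tl$bot_ws, tr["a"], tr["b"], tr["c"]))
})

test_that("exact correlation modes reproduce their generating parameters", {
  ot <- sim_config(seed = 19, tieline_mode = "othmer_tobias",
                   othmer_tobias_truth = c(k = 0.3, n = 1.4))
  fit <- fit_othmer_tobias(generate_tielines(ot))
  expect_equal(coef(fit), c(k = 0.3, n = 1.4), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  se <- sim_config(seed = 19, tieline_mode = "setschenow",
                   setschenow_truth = c(k_p = 0.35, k_s = 0.9))
  sfit <- fit_setschenow(generate_tielines(se))
  expect_equal(coef(sfit), c(k_p = 0.35, k_s = 0.9), tolerance = 1e-10)
})

test_that("partition generation balances drug mass exactly", {
  cfg <- sim_config(seed = 33)
  tl <- generate_tielines(cfg)
  recs <- generate_partition(cfg, tl)
  expect_equal(nrow(recs), 10L)   # two drugs x five tie-lines
  phi <- lever_rule_check(tl, tolerance = Inf)$phase_fraction_top
  for (d in unique(recs$drug)) {
    sub <- recs[recs$drug == d, ]
    total <- phi * sub$w_top_drug + (1 - phi) * sub$w_bot_drug
    expect_equal(total, rep(0.002, 5), tolerance = 1e-14)
  }
  expect_identical(generate_partition(cfg, tl), generate_partition(cfg, tl))
  # zero noise: Diamond-Hsu truth recovered exactly
  cfg0 <- sim_config(seed = 33, partition_noise_sd = 0)
  recs0 <- generate_partition(cfg0, generate_tielines(cfg0))
  for (d in names(cfg0$partition_truth)) {
    fit <- fit_diamond_hsu(recs0[recs0$drug == d, ])
    expect_equal(coef(fit), cfg0$partition_truth[[d]], tolerance = 1e-9)
  }
})

test_that("refractometry generation inverts exactly at zero noise", {
  cfg0 <- sim_config(seed = 21, refractometry_noise_sd = 0)
  comps <- data.frame(w_p = c(61.42, 10.47), w_s = c(9.44, 22.43))
  r <- generate_refractometry(cfg0, comps)
  cal <- calibrate_refractometry(r$series_p, r$series_s)
  got <- invert_to_polymer_fraction(r$readings$n_d, r$readings$w_s_known, cal)
  expect_equal(got, r$readings$w_p_true, tolerance = 1e-12)
  cfg <- sim_config(seed = 21)
  r1 <- generate_refractometry(cfg, comps)
  r2 <- generate_refractometry(cfg, comps)
  expect_identical(r1, r2)
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(generate_binodal(sim_config(seed = 5)))
  expect_identical(.Random.seed, before)
  draws1 <- rnorm(3)
  set.seed(123); invisible(rnorm(0)); draws2 <- rnorm(3)
  expect_identical(draws1, draws2)
})

test_that("a full simulated bundle is written deterministically", {
  cfg <- sim_config(seed = 77)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_atps(cfg, d1)
  simulate_atps(cfg, d2)
  for (f in c("binodal.csv", "tielines.csv", "partition.csv",
              "refractometry.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # files parse back through the package readers
  expect_equal(nrow(read_binodal(file.path(d1, "binodal.csv"))), 20L)
  expect_s3_class(read_tielines(file.path(d1, "tielines.csv")), "tielines")
  expect_equal(nrow(read_partition(file.path(d1, "partition.csv"))), 10L)
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$binodal_truth$a, 1100)
  unlink(c(d1, d2), recursive = TRUE)
})
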