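test_that("partition coefficient and extraction efficiency basics", {
  expect_equal(partition_coefficient(0.004, 0.002), 2)
  expect_equal(partition_coefficient(0.003, 0.003), 1)
  expect_error(partition_coefficient(0.004, 0), "positive")
  expect_equal(extraction_efficiency(1), 50)
  expect_equal(extraction_efficiency(8.87), 89.87, tolerance = 1e-4)
  expect_equal(extraction_efficiency(6.66), 86.95, tolerance = 1e-4)
  expect_error(extraction_efficiency(0), "positive")
  expect_error(extraction_efficiency(-2), "positive")
  # K -> EE -> K round trip
  expect_equal(ee_to_k(extraction_efficiency(8.87)), 8.87)
  expect_error(ee_to_k(100), "strictly")
})

test_that("EE is a monotone bijection with the reflection identity", {
  set.seed(7)
  K <- exp(runif(50, -4, 4))
  EE <- extraction_efficiency(K)
  expect_true(all(EE > 0 & EE < 100))
  expect_equal(extraction_efficiency(K) + extraction_efficiency(1 / K),
               rep(100, 50))
  ord <- order(K)
  expect_true(all(diff(EE[ord]) > 0))
  expect_equal(ee_to_k(EE), K)
})

test_that("reported K and EE pairs satisfy the efficiency relation", {
  part <- peg600_koh_partition()
  expect_equal(nrow(part), 10L)
  dev <- abs(extraction_efficiency(part$K) - part$EE_reported)
  expect_true(all(dev <= 0.03))   # one row carries ~0.02 rounding slack
})

test_that("partition records match tie-lines by overall composition", {
  recs <- partition_records(peg600_koh_partition(), peg600_koh_tielines())
  expect_s3_class(recs, "partition_records")
  expect_true(all(recs$delta_w_peg > 0))
  expect_equal(recs$delta_w_peg[recs$drug == "ibuprofen"],
               recs$delta_w_peg[recs$drug == "acetaminophen"])
  expect_equal(recs$EE, extraction_efficiency(recs$K))
  # unmatched overall composition errors
  stray <- data.frame(drug = "x", overall_ws = 40, overall_wp = 40, K = 2)
  expect_error(partition_records(stray, peg600_koh_tielines()),
               "no tie-line matches")
  # concentrations route
  conc <- data.frame(drug = "x", overall_ws = 17.58, overall_wp = 28.98,
                     w_top_drug = 0.004, w_bot_drug = 0.002)
  expect_equal(partition_records(conc)$K, 2)
})

test_that("Diamond-Hsu fits recover exact generating parameters", {
  dw <- c(40, 50, 60, 70)
  tr <- c(A = 0.05, B = 0.0002)
  recs <- data.frame(K = exp(tr["A"] * dw + tr["B"] * dw^2),
                     delta_w_peg = dw)
  fit <- fit_diamond_hsu(recs)
  expect_equal(coef(fit), tr, tolerance = 1e-12)
  expect_lt(fit$sd, 1e-12)
  # no-intercept structure: dw = 0 predicts K = 1 exactly
  expect_equal(unname(predict(fit, 0)), 1)
  tr3 <- c(A1 = -1.0, B1 = 0.06, C1 = 0.0001)
  recs3 <- data.frame(K = exp(tr3["A1"] + tr3["B1"] * dw + tr3["C1"] * dw^2),
                      delta_w_peg = dw)
  fit3 <- fit_diamond_hsu(recs3, modified = TRUE)
  expect_equal(coef(fit3), tr3, tolerance = 1e-10)
  # data from the no-intercept model: modified fit finds A1 ~ 0 and nests
  fit_nested <- fit_diamond_hsu(recs, modified = TRUE)
  expect_lt(abs(coef(fit_nested)[["A1"]]), 1e-10)
  expect_lte(fit_nested$sd, fit$sd + 1e-15)
})

test_that("Diamond-Hsu fit rejects deficient designs", {
  expect_error(fit_diamond_hsu(data.frame(K = c(2, 3), delta_w_peg = c(50, 50))),
               "distinct")
  expect_error(fit_diamond_hsu(data.frame(K = c(2, 3, 4),
                                          delta_w_peg = c(40, 40, 50)),
                               modified = TRUE), ">= 3")
  two_drugs <- data.frame(drug = c("a", "b"), K = c(2, 3),
                          delta_w_peg = c(40, 50))
  expect_error(fit_diamond_hsu(two_drugs), "one drug")
})

test_that("modified form never fits worse than the original (nesting)", {
  recs <- partition_records(peg600_koh_partition(), peg600_koh_tielines())
  for (d in unique(recs$drug)) {
    sub <- recs[recs$drug == d, ]
    sd13 <- fit_diamond_hsu(sub)$sd
    sd14 <- fit_diamond_hsu(sub, modified = TRUE)$sd
    expect_lte(sd14, sd13)
    # and the two-parameter form nests a slope-only model (lm oracle)
    sd_a_only <- sqrt(mean(resid(lm(log(sub$K) ~ 0 + sub$delta_w_peg))^2))
    expect_lte(sd13, sd_a_only)
  }
  # synthetic noisy records, same ordering
  set.seed(13)
  dw <- seq(40, 65, length.out = 8)
  K <- exp(0.044 * dw - 3e-5 * dw^2 + rnorm(8, 0, 0.1))
  noisy <- data.frame(K = K, delta_w_peg = dw)
  expect_lte(fit_diamond_hsu(noisy, modified = TRUE)$sd,
             fit_diamond_hsu(noisy)$sd)
})

test_that("partitioning strengthens along the tie-line series", {
  recs <- partition_records(peg600_koh_partition(), peg600_koh_tielines())
  for (d in unique(recs$drug)) {
    sub <- recs[recs$drug == d, ]
    sub <- sub[order(sub$tll), ]
    expect_true(all(diff(sub$K) > 0))
  }
})

test_that("hydrophobicity ordering is checked per composition", {
  recs <- partition_records(peg600_koh_partition())
  rep <- rank_drugs_by_hydrophobicity(recs, peg600_koh_log_kow())
  expect_equal(rep$verdict, "consistent")
  expect_equal(rep$summary$drug[1], "ibuprofen")   # higher log Kow, higher EE
  # inverted synthetic data flips the verdict
  inv <- recs; inv$K <- ave(inv$K, inv$overall_ws, FUN = rev)
  inv$EE <- extraction_efficiency(inv$K)
  expect_equal(rank_drugs_by_hydrophobicity(inv, peg600_koh_log_kow())$verdict,
               "inconsistent")
  single <- recs[recs$drug == "ibuprofen", ]
  expect_equal(rank_drugs_by_hydrophobicity(single,
                                            peg600_koh_log_kow())$verdict,
               "consistent")
  expect_error(rank_drugs_by_hydrophobicity(recs, c(ibuprofen = 3.97)),
               "missing")
})
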