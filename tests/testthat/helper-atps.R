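# shared fixture builders (everything generated in code)

# tie-lines satisfying the Othmer-Tobias relation exactly, given (k, n)
exact_ot_tielines <- function(k, n, bot_ws = c(20, 23, 26, 29),
                              top_ws = 9, bot_wp = 10) {
  fsb <- bot_ws / 100
  fpt <- 1 / (1 + k * ((1 - fsb) / fsb)^n)
  as_tielines(data.frame(
    overall_ws = (top_ws + bot_ws) / 2,
    overall_wp = (fpt * 100 + bot_wp) / 2,
    top_ws = top_ws, top_wp = fpt * 100,
    bot_ws = bot_ws, bot_wp = bot_wp))
}

# tie-lines satisfying the Bancroft relation exactly, given (k1, r)
exact_bancroft_tielines <- function(k1, r,
                                    top_wp = seq(61, 71, length.out = 4),
                                    top_ws = 9.4,
                                    bot_ws = seq(22.4, 29.8, length.out = 4)) {
  x <- (100 - top_wp - top_ws) / top_wp
  ww_bot <- k1 * x^r * bot_ws
  bot_wp <- 100 - bot_ws - ww_bot
  as_tielines(data.frame(
    overall_ws = (top_ws + bot_ws) / 2, overall_wp = (top_wp + bot_wp) / 2,
    top_ws = top_ws, top_wp = top_wp, bot_ws = bot_ws, bot_wp = bot_wp))
}

# the five reported tie-line lengths and partition coefficients of the
# packaged PEG600 + KOH dataset, used across tests
reported_tll <- c(52.58, 55.86, 58.45, 61.96, 66.12)
reported_K <- list(
  ibuprofen = c(8.87, 9.51, 10.35, 11.93, 14.20),
  acetaminophen = c(6.66, 7.31, 8.14, 9.72, 11.99))
reported_EE <- list(
  ibuprofen = c(89.87, 90.49, 91.19, 92.27, 93.42),
  acetaminophen = c(86.95, 87.95, 89.06, 90.67, 92.30))
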