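test_that("two-way within-subject ANOVA matches hand-computed sums of squares", {
  # 4 subjects x 2 (roi) x 2 (soa), fixed values
  set.seed(61)
  d <- expand.grid(subject = paste0("s", 1:4), roi = c("L", "R"),
                   soa = c("0", "30"), stringsAsFactors = FALSE)
  d$y <- c(3.1, 2.5, 4.0, 3.3,  2.0, 1.7, 2.9, 2.2,
           4.2, 3.6, 5.1, 4.0,  3.0, 2.8, 3.5, 3.1)
  out <- rm_anova(d, "y", "subject", within = c("roi", "soa"))

  # independent oracle: direct mean/SS arithmetic
  g <- mean(d$y)
  m_s <- tapply(d$y, d$subject, mean)
  m_a <- tapply(d$y, d$roi, mean)
  m_b <- tapply(d$y, d$soa, mean)
  m_ab <- tapply(d$y, list(d$roi, d$soa), mean)
  m_sa <- tapply(d$y, list(d$subject, d$roi), mean)
  m_sb <- tapply(d$y, list(d$subject, d$soa), mean)
  ss_a <- 4 * 2 * sum((m_a - g)^2)
  ss_b <- 4 * 2 * sum((m_b - g)^2)
  ss_ab <- 4 * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + g)^2)
  ss_err_a <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) -
                         outer(rep(1, 4), m_a) + g)^2)
  ss_err_b <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) -
                         outer(rep(1, 4), m_b) + g)^2)
  # residual stratum: total within-cell deviation minus the other strata
  ss_total <- sum((d$y - g)^2)
  ss_subj <- 2 * 2 * sum((m_s - g)^2)
  ss_err_ab <- ss_total - ss_subj - ss_a - ss_b - ss_ab - ss_err_a - ss_err_b

  row <- function(e) out[out$effect == e, ]
  expect_equal(row("roi")$ss, ss_a, tolerance = 1e-8)
  expect_equal(row("roi")$error_ss, ss_err_a, tolerance = 1e-8)
  expect_equal(row("soa")$ss, ss_b, tolerance = 1e-8)
  expect_equal(row("soa")$error_ss, ss_err_b, tolerance = 1e-8)
  expect_equal(row("roi:soa")$ss, ss_ab, tolerance = 1e-8)
  expect_equal(row("roi:soa")$error_ss, ss_err_ab, tolerance = 1e-8)
  expect_equal(row("roi")$F, (ss_a / 1) / (ss_err_a / 3), tolerance = 1e-8)
  expect_equal(row("roi")$partial_eta_sq, ss_a / (ss_a + ss_err_a),
               tolerance = 1e-8)
  # 2-level factors: sphericity trivially holds
  expect_true(all(out$gg_epsilon == 1))
  expect_equal(out$p_gg, out$p_uncorrected)
})

test_that("ANOVA sums of squares decompose the total variance", {
  set.seed(62)
  d <- expand.grid(subject = paste0("s", 1:6), cond = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  d$grp <- ifelse(d$subject %in% paste0("s", 1:3), "young", "older")
  d$y <- rnorm(nrow(d))
  out <- rm_anova(d, "y", "subject", within = "cond", between = "grp")
  # between stratum: SS_grp + its error = between-subject SS;
  # within stratum: SS_cond + SS_cond:grp + error = within SS
  m_s <- tapply(d$y, d$subject, mean)
  g <- mean(d$y)
  ss_between <- 3 * sum((m_s - g)^2)
  ss_total <- sum((d$y - g)^2)
  btw <- out[out$effect == "grp", ]
  expect_equal(btw$ss + btw$error_ss, ss_between, tolerance = 1e-8)
  wth <- out[out$effect %in% c("cond", "grp:cond", "cond:grp"), ]
  expect_equal(sum(wth$ss) + wth$error_ss[1], ss_total - ss_between,
               tolerance = 1e-8)
  expect_true(all(wth$error_ss == wth$error_ss[1]))
})

test_that("constant data yield zero F and zero effect size", {
  d <- expand.grid(subject = paste0("s", 1:5), cond = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$y <- 2.5
  out <- rm_anova(d, "y", "subject", within = "cond")
  expect_equal(out$F, rep(0, nrow(out)))
  expect_equal(out$partial_eta_sq, rep(0, nrow(out)))
  expect_equal(out$p_uncorrected, rep(1, nrow(out)))
})

test_that("GG epsilon lies in [1/(k-1), 1] and corrects the p-value", {
  set.seed(63)
  k <- 4
  for (r in 1:20) {
    d <- expand.grid(subject = paste0("s", 1:8), cond = paste0("c", 1:k),
                     stringsAsFactors = FALSE)
    # heterogeneous correlation structure to stress sphericity
    base <- rnorm(8)
    d$y <- rnorm(nrow(d)) * rep(seq(0.5, 2, length.out = k), each = 8) +
      base * rep(seq(0, 1, length.out = k), each = 8)
    out <- rm_anova(d, "y", "subject", within = "cond")
    eps <- out$gg_epsilon[out$effect == "cond"]
    expect_gte(eps, 1 / (k - 1) - 1e-9)
    expect_lte(eps, 1 + 1e-9)
  }
})

test_that("partial eta squared is invariant to affine rescaling", {
  set.seed(64)
  d <- expand.grid(subject = paste0("s", 1:6), cond = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + as.numeric(factor(d$cond)) * 0.5
  out1 <- rm_anova(d, "y", "subject", within = "cond")
  d$y <- 3.7 * d$y + 11
  out2 <- rm_anova(d, "y", "subject", within = "cond")
  expect_equal(out1$partial_eta_sq, out2$partial_eta_sq, tolerance = 1e-9)
  expect_equal(out1$F, out2$F, tolerance = 1e-9)
})

test_that("unbalanced designs are refused", {
  d <- expand.grid(subject = paste0("s", 1:4), cond = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d))
  expect_error(rm_anova(d[-1, ], "y", "subject", within = "cond"),
               "unbalanced")
  expect_error(rm_anova(d, "z", "subject", within = "cond"), "not found")
})

test_that("null simulations reject at about the nominal rate", {
  set.seed(65)
  n_rep <- 500
  rejections <- 0
  d0 <- expand.grid(subject = paste0("s", 1:10), soa = c("0", "30", "50"),
                    stringsAsFactors = FALSE)
  d0$grp <- ifelse(d0$subject %in% paste0("s", 1:5), "young", "older")
  for (r in seq_len(n_rep)) {
    d0$y <- rnorm(nrow(d0))
    out <- rm_anova(d0, "y", "subject", within = "soa", between = "grp")
    if (out$p_uncorrected[out$effect == "soa"] < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_lt(abs(rejections / n_rep - 0.05), 0.03)
})

test_that("Tukey HSD q statistics match the studentized-range formula", {
  means <- c(a = 1.0, b = 1.2, c = 2.1)
  ms_error <- 0.4
  out <- tukey_hsd(means, ms_error, df_error = 12, n_per_cell = 5)
  q_expected <- abs(c(1.0 - 1.2, 1.0 - 2.1, 1.2 - 2.1)) / sqrt(0.4 / 5)
  expect_equal(out$q, q_expected)
  expect_equal(out$p,
               ptukey(q_expected, nmeans = 3, df = 12, lower.tail = FALSE))

  same <- tukey_hsd(c(x = 1, y = 1), 0.5, 10, 4)
  expect_gt(same$p, 0.999)
  far <- tukey_hsd(c(x = 0, y = 5), 1e-6, 10, 4)
  expect_lt(far$p, 0.001)
  expect_error(tukey_hsd(c(1, 2), 0.5, 10, c(4, 5)), "balanced")
})

test_that("hit scoring counts each event and response at most once", {
  events <- data.frame(onset = c(1000, 5000, 9000))
  expect_equal(score_hits(c(1400, 5300, 9900), events)$hit_rate, 100)
  expect_equal(score_hits(numeric(0), events)$hit_rate, 0)
  # one response cannot serve two events; repeats count once
  close_events <- data.frame(onset = c(1000, 1100))
  expect_equal(score_hits(1400, close_events)$n_hits, 1)
  expect_equal(score_hits(c(1390, 1400), close_events)$n_hits, 2)
  # outside the window
  expect_equal(score_hits(c(1100, 2200), data.frame(onset = 1000))$n_hits, 0)
})

test_that("a Bernoulli responder's empirical hit rate concentrates", {
  onsets <- seq(2000, by = 2000, length.out = 2000)
  sch <- list(task_events = data.frame(onset = onsets))
  resp <- generate_task_responses(sch, hit_prob = 0.8, seed = 66)
  sc <- score_hits(resp, sch$task_events)
  expect_equal(sc$n_events, 2000)
  expect_lt(abs(sc$hit_rate - 80), 2)
})
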