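test_that("the error metric satisfies the metric axioms", {
  expect_equal(euclidean_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_error(c(0, 0, 0), c(1, 2, 2)), 3)
  withr::with_seed(9, {
    for (i in 1:20) {
      a <- rnorm(3); b <- rnorm(3); cc <- rnorm(3)
      expect_equal(euclidean_error(a, b), euclidean_error(b, a))
      expect_lte(euclidean_error(a, cc),
                 euclidean_error(a, b) + euclidean_error(b, cc) + 1e-12)
    }
  })
})

test_that("error aggregation: subject means, grand mean, SD, SE = SD/sqrt(n)", {
  errs <- tibble::tibble(
    subject = rep(c("A", "B"), each = 3),
    error_cm = c(0.5, 1.0, 1.5, 2.5, 3.0, 3.5)
  )
  s <- error_summary(errs)
  expect_equal(s$mean_error_cm, 2)
  expect_equal(s$sd_cm, sqrt(2))
  expect_equal(s$se_cm, 1)

  s4 <- error_summary(tibble::tibble(subject = letters[1:4], error_cm = 1:4))
  expect_equal(s4$mean_error_cm, 2.5)
  expect_equal(s4$se_cm, sd(1:4) / 2, tolerance = 1e-4)
  expect_equal(round(s4$se_cm, 4), 0.6455)

  # permutation invariance in trial/subject order
  perm <- withr::with_seed(2, sample(nrow(errs)))
  expect_equal(error_summary(errs[perm, ]), s)

  # perfect predictor
  preds <- tibble::tibble(subject = "A", x = 1, y = 2, z = 3,
                          pred_x = 1, pred_y = 2, pred_z = 3)
  pe <- error_summary(prediction_errors(preds))
  expect_equal(pe$mean_error_cm, 0)
})

test_that("RM-ANOVA agrees with the brute-force SS decomposition", {
  withr::with_seed(14, {
    for (dims in list(c(4, 3), c(6, 6), c(5, 4))) {
      M <- matrix(rnorm(prod(dims), mean = 2), dims[1], dims[2])
      d <- tibble::tibble(
        subject = rep(seq_len(dims[1]), dims[2]),
        condition = rep(letters[seq_len(dims[2])], each = dims[1]),
        mean_error_cm = as.vector(M)
      )
      a <- rm_anova(d)
      expect_equal(a$F, brute_rm_anova_F(M), tolerance = 1e-8)
      expect_equal(a$df1, dims[2] - 1)
      expect_equal(a$df2, (dims[1] - 1) * (dims[2] - 1))
      # Bonferroni is exactly min(1, m * p)
      m <- choose(dims[2], 2)
      expect_equal(a$pairwise$p_adj, pmin(1, m * a$pairwise$p_raw))
    }
  })
})

test_that("RM-ANOVA flags clear effects and stays silent under the null", {
  null_d <- tibble::tibble(
    subject = rep(1:5, 3), condition = rep(c("a", "b", "c"), each = 5),
    mean_error_cm = rep(rep(2, 5), 3)
  )
  a0 <- rm_anova(null_d)
  expect_equal(a0$F, 0)
  expect_true(all(is.na(a0$pairwise$p_adj) | a0$pairwise$p_adj >= 0.05) ||
                all(a0$pairwise$t == 0))

  withr::with_seed(15, {
    A <- rnorm(12, 1, 0.1); B <- rnorm(12, 3, 0.1); C <- rnorm(12, 3, 0.1)
  })
  d <- tibble::tibble(
    subject = rep(1:12, 3),
    condition = rep(c("A", "B", "C"), each = 12),
    mean_error_cm = c(A, B, C)
  )
  a <- rm_anova(d)
  pAB <- a$pairwise[a$pairwise$a == "A" & a$pairwise$b == "B", ]
  expect_lt(pAB$p_adj, 0.05)
  # ordering statement groups B with C above A
  expect_match(a$ordering, "^(B = C|C = B) > A$")
  # sign-flip permutation oracle agrees the A-B contrast is extreme
  dAB <- A - B
  t_obs <- abs(mean(dAB) / (sd(dAB) / sqrt(12)))
  perm_t <- withr::with_seed(16, vapply(1:2000, function(i) {
    ds <- dAB * sample(c(-1, 1), 12, replace = TRUE)
    abs(mean(ds) / (sd(ds) / sqrt(12)))
  }, numeric(1)))
  expect_lt(mean(perm_t >= t_obs), 0.05 / 3)

  expect_error(rm_anova(d[-1, ]), "every subject")
})

test_that("paired t matches the closed-form statistic and handles degenerate input", {
  a <- c(1, 2, 3, 4, 5)
  t0 <- paired_ttest(a, a)
  expect_equal(t0$t, 0); expect_equal(t0$p, 1)

  t1 <- paired_ttest(a + 1, a)
  expect_true(t1$degenerate)
  expect_equal(t1$p, 0)

  withr::with_seed(17, { x <- rnorm(15); y <- rnorm(15) })
  tt <- paired_ttest(x, y)
  d <- x - y
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(15)), tolerance = 1e-10)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), 14), tolerance = 1e-10)
  expect_error(paired_ttest(1:4, 1:5), "equal length")
})

test_that("grand-average potentials are baseline-zero and average linearly", {
  fs <- 200
  n <- round(fs * 1.5)
  times <- -1 + (0:(n - 1)) / fs
  labels <- c("FC3", "C3", "C1", "CP3")
  flat <- eeg_epochs(array(0, c(5, 4, n)), fs, c(-1, 0.5), labels,
                     tibble::tibble(subject = "S", hand = "right", trial = 1:5))
  erp0 <- grand_average_erp(flat, list(contralateral = labels))
  expect_true(all(erp0$amplitude == 0))

  # -4 uV bump on one of the four group channels dilutes to -1 uV
  bump <- ifelse(abs(times + 0.3) <= 0.1, -4 * 0.5 * (1 + cos(2 * pi * (times + 0.3) / 0.2)) / 1, 0)
  dat <- array(0, c(3, 4, n))
  for (tr in 1:3) dat[tr, 2, ] <- bump
  ep <- eeg_epochs(dat + 7, fs, c(-1, 0.5), labels,   # +7 uV offset: baseline must absorb it
                   tibble::tibble(subject = "S", hand = "right", trial = 1:3))
  erp <- grand_average_erp(ep, list(contralateral = labels))
  bidx <- erp$time >= -1 & erp$time < -0.5
  expect_lt(max(abs(erp$amplitude[bidx])), 1e-9)
  expect_equal(min(erp$amplitude), -1, tolerance = 1e-6)

  expect_error(grand_average_erp(ep, list(contralateral = c("C3", "Nope"))), "Nope")
  short <- eeg_epochs(array(0, c(2, 4, fs)), fs, c(-0.5, 0.5), labels,
                      tibble::tibble(subject = "S", hand = "right", trial = 1:2))
  expect_error(grand_average_erp(short, list(contralateral = labels)), "baseline")
})

test_that("peak detection returns the most negative sample and flags flat input", {
  fs <- 200
  times <- seq(-1, 0.5 - 1 / fs, by = 1 / fs)
  flat <- detect_erp_peak(rep(0, length(times)), times)
  expect_equal(flat$amplitude_uv, 0)
  expect_true(flat$flat)

  w <- rep(0, length(times)); w[which.min(abs(times + 0.1))] <- -5
  pk <- detect_erp_peak(w, times)
  expect_equal(pk$amplitude_uv, -5)
  expect_equal(pk$latency_ms, -100)

  expect_error(detect_erp_peak(w, times, search_window = c(5, 6)), "outside")
})
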