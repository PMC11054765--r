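test_that("Mann-Whitney U, z, exact p and r behave as documented", {
  same <- mann_whitney_with_effect(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$r, 0)
  expect_equal(same$p, 1)

  sep <- mann_whitney_with_effect(c(1, 2, 3), c(4, 5, 6), method = "exact")
  expect_equal(sep$u, 0)
  expect_equal(sep$p, 0.1)      # 2/20 assignments as extreme, by enumeration

  swapped <- mann_whitney_with_effect(c(4, 5, 6), c(1, 2, 3), method = "exact")
  expect_equal(swapped$p, sep$p)
  expect_equal(swapped$r, sep$r)

  # identical constant data: z = 0, r = 0, p = 1
  flat <- mann_whitney_with_effect(rep(2, 4), rep(2, 5))
  expect_equal(flat$z, 0)
  expect_equal(flat$p, 1)
})

test_that("normal-approximation p tracks exact enumeration for n >= 3", {
  withr::with_seed(17, {
    for (na in 3:8) for (nb in 3:8) {
      x <- sample(seq_len(200), na + nb)   # untied by construction
      a <- x[seq_len(na)]; b <- x[-seq_len(na)]
      p_asy <- mann_whitney_with_effect(a, b, method = "asymptotic")$p
      p_ex <- mann_whitney_with_effect(a, b, method = "exact")$p
      expect_lt(abs(p_asy - p_ex), 0.03)
    }
  })
})

test_that("effect-size bands partition [0, Inf) with the printed mapping", {
  expect_equal(effect_size_label(c(0.51, 0.44, 0.26)),
               c("large", "moderate", "small"))
  expect_equal(effect_size_label(c(0, 0.0999, 0.1, 0.3, 0.5, 9)),
               c("none", "none", "small", "moderate", "large", "large"))
  # band edges: every non-negative r gets exactly one label
  rs <- seq(0, 1, by = 0.01)
  expect_false(anyNA(effect_size_label(rs)))
  expect_error(effect_size_label(-0.1))
})

test_that("Pearson chi-square without correction matches hand evaluation", {
  m <- rbind(c(2, 2), c(3, 6))
  # hand oracle: sum (O - E)^2 / E on the printed sex table
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2_hand <- sum((m - E)^2 / E)
  res <- pearson_chi_square(m)
  expect_equal(res$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(round(res$p, 3), 0.569)

  flat <- rbind(c(10, 10), c(10, 10))
  res0 <- pearson_chi_square(flat)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)

  # all-zero rows are dropped before df: 3x2 with a zero row -> df 2
  dev <- rbind(c(1, 1), c(0, 3), c(4, 4), c(0, 0))
  resd <- pearson_chi_square(dev)
  expect_equal(resd$df, 2)
  expect_equal(round(resd$p, 3), 0.296)

  expect_error(pearson_chi_square(rbind(c(3, 4), c(0, 0))),
               class = "cptstress_error_degenerate_table")
  expect_error(pearson_chi_square(rbind(c(1.5, 2), c(1, 1))),
               class = "cptstress_error_input")
})

test_that("pooled t-test matches the textbook formula", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  # direct formula oracle
  sp2 <- (var(a) * 2 + var(b) * 2) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  res <- two_sample_t(a, b)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)

  expect_equal(two_sample_t(c(5, 6), c(5, 6))$t, 0)
  jit <- two_sample_t(c(0, 1e-9), c(1, 1 + 1e-9))
  expect_lt(jit$p, 1e-6)
  zero_var <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(zero_var$p, 1)
})

test_that("median and quartiles follow the (n+1) interpolation convention", {
  m <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(m$median, 3)
  s <- median_iqr(7)
  expect_equal(c(s$median, s$p25, s$p75), c(7, 7, 7))
  q <- median_iqr(c(1, 2, 3, 4))
  expect_equal(q$p25, 1.25)
  expect_equal(q$p75, 3.75)
})

test_that("feasibility tallies count every enrolled participant once", {
  rec <- tibble::tibble(
    id = sprintf("A%02d", 1:13),
    stage = "baseline",
    status = rep(c("complete", "technical", "non_adherent", "combination"),
                 c(5, 4, 2, 2))
  )
  tal <- feasibility_tally(rec)
  got <- tal[tal$n > 0, ]
  expect_equal(sum(got$n), 13)                      # conservation
  pct <- setNames(round(got$pct), got$status)
  expect_equal(pct[["complete"]], 38)
  expect_equal(pct[["technical"]], 31)
  expect_equal(pct[["non_adherent"]], 15)
  expect_equal(pct[["combination"]], 15)

  all_done <- dplyr::mutate(rec, status = "complete")
  tal2 <- feasibility_tally(all_done)
  expect_equal(tal2$pct[tal2$status == "complete"], 100)
  expect_equal(sum(tal2$n[tal2$status != "complete"]), 0)

  expect_error(feasibility_tally(dplyr::mutate(rec, status = "lost_sensor")),
               class = "cptstress_error_input")
})
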