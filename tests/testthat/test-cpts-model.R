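test_that("daily model 1 is the stride-weighted PTI sum in MPa.s", {
  expect_equal(cpts_day_model1(66.2, 72.2, 3000, 1000), 270.8)
  expect_equal(cpts_day_model1(66.2, 72.2, 0, 0), 0)
  expect_equal(cpts_day_model1(100, NA, 1000, 0), 100)
  expect_error(cpts_day_model1(NA, 72.2, 10, 0),
               class = "cptstress_error_missing_factor")
})

test_that("daily model 2 weights each condition by its thermal response", {
  expect_equal(
    cpts_day_model2(66.2, 72.2, 3000, 1000, 0.66, 1.45),
    (66.2 * 3000 * 0.66 + 72.2 * 1000 * 1.45) / 1000
  )
  expect_equal(cpts_day_model2(66.2, 72.2, 3000, 1000, 0.66, 1.45), 235.766)
  expect_warning(
    neg <- cpts_day_model2(66.2, 72.2, 3000, 1000, -0.4, 0.1),
    class = "cptstress_warning_negative_tsr"
  )
  expect_lt(neg, 0)
  expect_error(cpts_day_model2(66.2, 72.2, 1, 1, NA, 1),
               class = "cptstress_error_missing_factor")
})

test_that("model 2 collapses to model 1 under unit thermal response", {
  withr::with_seed(21, {
    for (i in 1:25) {
      pti_in <- runif(1, 20, 120); pti_non <- runif(1, 20, 700)
      s_in <- rpois(1, 3000); s_non <- rpois(1, 1500)
      expect_identical(
        cpts_day_model2(pti_in, pti_non, s_in, s_non, 1, 1),
        cpts_day_model1(pti_in, pti_non, s_in, s_non)
      )
    }
  })
})

test_that("daily CPTS is linear in strides and in PTI", {
  base <- cpts_day_model1(66.2, 72.2, 3000, 1000)
  expect_equal(cpts_day_model1(66.2, 72.2, 6000, 2000), 2 * base)
  expect_equal(cpts_day_model1(2 * 66.2, 2 * 72.2, 3000, 1000), 2 * base)
})

test_that("summaries average over valid days only", {
  expect_equal(cpts_summary(c(100, 200, 300)), 200)
  expect_equal(cpts_summary(42), 42)
  expect_equal(cpts_summary(c(100, 200, 900), valid = c(TRUE, TRUE, FALSE)), 150)
  expect_error(cpts_summary(c(1, 2), valid = c(FALSE, FALSE)),
               class = "cptstress_error_non_adherent")
})

test_that("cpts_result fuses counts, PTI and TSR with provenance", {
  counts <- tibble::tibble(
    date = as.Date("2023-05-01") + 0:2,
    strides_in_device = c(3000, 3000, 3000),
    strides_non_device = c(1000, 1000, 1000)
  )
  res <- cpts_result(counts, pti_in = 66.2, pti_non = 72.2,
                     tsr_in = 0.66, tsr_non = 1.45)
  expect_s3_class(res, "cpts_result")
  expect_equal(res$summary_model1, 270.8)
  expect_equal(res$summary_model2, 235.766)
  expect_equal(res$n_valid_days, 3)

  td <- tidy(res)
  expect_equal(nrow(td), 3)
  expect_named(glance(res),
               c("summary_model1", "summary_model2", "n_valid_days",
                 "pti_in", "pti_non", "tsr_in", "tsr_non"))

  # without TSR the result still carries model 1
  res1 <- cpts_result(counts, pti_in = 66.2, pti_non = 72.2)
  expect_equal(res1$summary_model1, 270.8)
  expect_true(is.na(res1$summary_model2))

  # valid-day filter
  res_f <- cpts_result(dplyr::mutate(counts, strides_in_device = c(3000, 0, 0)),
                       66.2, 72.2, valid_dates = counts$date[1])
  expect_equal(res_f$n_valid_days, 1)
  expect_equal(res_f$summary_model1, 270.8)
  expect_error(cpts_result(counts, 66.2, 72.2, valid_dates = as.Date("1999-01-01")),
               class = "cptstress_error_non_adherent")
})
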