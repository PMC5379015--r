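test_that("SWAN factor scores are means over the fixed item partition", {
  all50 <- score_swan(rep(50, 18))
  expect_equal(all50$inattention, 50)
  expect_equal(all50$hyperactivity, 50)
  expect_equal(all50$impulsivity, 50)

  sep <- score_swan(c(rep(90, 9), rep(0, 9)))
  expect_equal(sep$inattention, 90)
  expect_equal(sep$hyperactivity, 0)
  expect_equal(sep$impulsivity, 0)

  fac <- swan_factors()
  expect_equal(lengths(fac), c(inattention = 9L, hyperactivity = 6L, impulsivity = 3L))
  expect_equal(sort(unlist(fac)), 1:18, ignore_attr = TRUE)
})

test_that("invalid SWAN inputs raise validation errors naming the problem", {
  expect_error(score_swan(rep(50, 17)), class = "cpt_swan_error")
  err <- expect_error(
    score_swan(c(rep(50, 10), 140, rep(50, 7))),
    class = "cpt_swan_error"
  )
  expect_match(conditionMessage(err), "item_11")

  df <- tibble::tibble(participant_id = "P1")
  expect_error(score_swan(df), class = "cpt_swan_error")
})

test_that("data-frame SWAN input carries id columns and scores rows", {
  df <- tibble::as_tibble(as.list(setNames(
    c(rep(20, 9), rep(40, 6), rep(80, 3)),
    sprintf("item_%02d", 1:18)
  )))
  df <- dplyr::bind_cols(tibble::tibble(participant_id = "P1"), df)
  out <- score_swan(df)
  expect_equal(out$participant_id, "P1")
  expect_equal(out$inattention, 20)
  expect_equal(out$hyperactivity, 40)
  expect_equal(out$impulsivity, 80)
})

test_that("perfectly aligned or opposed predictors give r of 1 and -1", {
  fac <- tibble::tibble(
    inattention = c(10, 30, 50, 70, 90),
    hyperactivity = c(20, 25, 30, 35, 40),
    impulsivity = c(5, 10, 40, 60, 95)
  )
  summ <- tibble::tibble(
    median_rt_s = fac$impulsivity,
    median_commission_index = -fac$impulsivity
  )
  rep <- correlate_traits(summ, fac)
  tt <- tidy(rep)
  expect_equal(tt$r[tt$predictor == "median_rt_s" & tt$factor == "impulsivity"], 1)
  expect_equal(
    tt$r[tt$predictor == "median_commission_index" & tt$factor == "impulsivity"],
    -1
  )
  expect_true(all(tt$n == 5))
})

test_that("Pearson cells match the closed-form hand calculation", {
  x <- c(0.62, 0.55, 0.48, 0.71, 0.52)
  y <- c(30, 55, 72, 18, 60)
  # closed form: r from centred sums, p from the two-sided t transform
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = 3)

  summ <- tibble::tibble(median_rt_s = x)
  fac <- tibble::tibble(inattention = y, hyperactivity = y, impulsivity = y)
  cell <- tidy(correlate_traits(summ, fac, predictors = "median_rt_s"))[1, ]
  expect_equal(cell$r, r_hand, tolerance = 1e-4)
  expect_equal(cell$p, p_hand, tolerance = 1e-4)
  # frozen values from the same hand calculation
  expect_equal(cell$r, -0.9851905062, tolerance = 1e-4)
  expect_equal(cell$p, 0.0021586244, tolerance = 1e-4)
})

test_that("missing predictors are handled pairwise-complete per cell", {
  withr::local_seed(10)
  summ <- tibble::tibble(
    median_rt_s = c(rnorm(8), rep(NA, 4)),
    median_commission_index = rnorm(12)
  )
  fac <- tibble::tibble(
    inattention = rnorm(12), hyperactivity = rnorm(12), impulsivity = rnorm(12)
  )
  tt <- tidy(correlate_traits(summ, fac))
  expect_true(all(tt$n[tt$predictor == "median_rt_s"] == 8))
  expect_true(all(tt$n[tt$predictor == "median_commission_index"] == 12))

  # fewer than 3 complete pairs: cell not computable
  summ$median_rt_s[3:12] <- NA
  tt2 <- tidy(correlate_traits(summ, fac))
  expect_true(all(is.na(tt2$r[tt2$predictor == "median_rt_s"])))
  expect_false(anyNA(tt2$r[tt2$predictor == "median_commission_index"]))
})

test_that("correlations are invariant to positive affine predictor rescaling", {
  withr::local_seed(11)
  summ <- tibble::tibble(median_rt_s = rnorm(20, 0.5, 0.1))
  fac <- tibble::tibble(
    inattention = rnorm(20, 50, 15),
    hyperactivity = rnorm(20, 50, 15),
    impulsivity = rnorm(20, 50, 15)
  )
  base <- tidy(correlate_traits(summ, fac, predictors = "median_rt_s"))
  summ2 <- tibble::tibble(median_rt_s = 1000 * summ$median_rt_s + 3)
  scaled <- tidy(correlate_traits(summ2, fac, predictors = "median_rt_s"))
  expect_equal(scaled$r, base$r, tolerance = 1e-12)
  expect_equal(scaled$p, base$p, tolerance = 1e-12)
})

test_that("Spearman agrees with Pearson on rank-linear data", {
  summ <- tibble::tibble(median_rt_s = seq(0.3, 0.8, length.out = 10))
  fac <- tibble::tibble(
    inattention = 2 * summ$median_rt_s + 1,
    hyperactivity = -3 * summ$median_rt_s,
    impulsivity = seq(10, 100, length.out = 10)
  )
  pe <- tidy(correlate_traits(summ, fac, predictors = "median_rt_s", method = "pearson"))
  sp <- tidy(correlate_traits(summ, fac, predictors = "median_rt_s", method = "spearman"))
  expect_equal(sp$r, pe$r, tolerance = 1e-9)
})

test_that("Holm adjustment never decreases a p-value", {
  withr::local_seed(12)
  summ <- tibble::tibble(
    median_rt_s = rnorm(15), median_commission_index = rnorm(15)
  )
  fac <- tibble::tibble(
    inattention = rnorm(15), hyperactivity = rnorm(15), impulsivity = rnorm(15)
  )
  raw <- tidy(correlate_traits(summ, fac))
  adj <- tidy(correlate_traits(summ, fac, adjust = "holm"))
  expect_true(all(adj$p >= raw$p - 1e-12))
})

test_that("reports render to markdown, CSV and JSON and round-trip", {
  summ <- tibble::tibble(
    median_rt_s = c(0.5, 0.6, 0.4, 0.7, 0.55),
    median_commission_index = c(0.1, NA, 0.3, 0.2, NA)
  )
  fac <- tibble::tibble(
    inattention = c(40, 50, 60, 20, 80),
    hyperactivity = c(45, 55, 35, 70, 50),
    impulsivity = c(30, 60, 80, 10, 55)
  )
  rep <- correlate_traits(summ, fac)

  md <- render_report(rep, "markdown")
  expect_length(md, 4) # header, rule, two predictor rows
  expect_match(md[1], "Inattention")

  csv_f <- withr::local_tempfile(fileext = ".csv")
  render_report(rep, "csv", csv_f)
  back <- read_report_csv(csv_f)
  expect_equal(tidy(back), tidy(rep), tolerance = 1e-9)

  js <- render_report(rep, "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$method, "pearson")
  expect_equal(nrow(parsed$cells), 6)

  # not-computable cells render as NA in markdown
  summ$median_commission_index <- NA_real_
  rep2 <- correlate_traits(summ, fac)
  md2 <- render_report(rep2, "markdown")
  expect_match(md2[4], "NA")

  g <- glance(rep)
  expect_equal(g$n_cells, 6L)
  expect_equal(g$method, "pearson")
})
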