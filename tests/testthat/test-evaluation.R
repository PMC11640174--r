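test_that("R2 and RMSE reproduce hand-computed cases", {
  y <- c(1, 2, 3)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 3)), 0)
  expect_equal(rSquared(y, c(1, 2, 4)), 0.5)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, c(2, 2, 2)), sqrt(2 / 3))
  # translation invariance
  expect_equal(rmse(y + 5, c(2, 2, 2) + 5), rmse(y, c(2, 2, 2)))
  expect_error(rSquared(c(1, 1), c(1, 2)), "constant")
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("RPD follows its algebraic identities", {
  withr::with_seed(8, {
    y <- rnorm(40, 4, 0.5)
    e <- rnorm(40, 0, 0.2)
  })
  yhat <- y + e - mean(e)             # zero-mean residuals
  n <- length(y)
  # constant-at-mean predictions: RPD = sqrt(n / (n - 1))
  expect_equal(rpd(y, rep(mean(y), n)), sqrt(n / (n - 1)), tolerance = 1e-12)
  # halving residuals doubles RPD
  expect_equal(rpd(y, y + (yhat - y) / 2), 2 * rpd(y, yhat), tolerance = 1e-12)
  # identity linking R2, RMSE and RPD for mean-unbiased predictions
  expect_equal(rpd(y, yhat)^2 * (1 - rSquared(y, yhat)) * (n - 1) / n, 1,
               tolerance = 1e-10)
  expect_equal(rpd(y, y), Inf)
  # printed variant is computable and positive
  expect_gt(rpd(y, yhat, method = "printed"), 0)
})

test_that("RPD credibility classes use inclusive 1.4-2.0 boundaries", {
  expect_equal(rpdClass(c(1.2, 1.4, 1.7, 2.0, 2.5)),
               c("unreliable", "credible", "credible", "credible",
                 "highly credible"))
  expect_error(rpdClass(-1), "non-negative")
})

test_that("report assembly flags the best model per process type", {
  row <- function(proc, pre, rp2, rpdv)
    evaluateModel(c(1, 2, 3), c(1, 2, 3.01), c(4, 4.4, 5, 4.1),
                  c(4, 4.4, 5, 4.1) + (5 - rpdv) / 100,
                  model = paste(pre, "none", "PLSR", sep = "-"),
                  process = proc, pretreatmentLabel = pre,
                  selector = "none", regressor = "PLSR", nBands = 10L)
  rows <- list()
  for (proc in c("CP", "FLS", "ST", "HD"))
    for (pre in c("MSC", "CT", "D1", "SG"))
      rows[[length(rows) + 1]] <- row(proc, pre, 0.9, 2)
  tab <- buildReport(rows)
  expect_equal(nrow(tab), 16L)
  expect_equal(sum(tab$best), 4L)
  expect_true(all(c("Rc2", "RMSEC", "Rp2", "RMSEP", "RPD", "credibility")
                  %in% names(tab)))
  # ST is normalised to SF
  expect_setequal(unique(tab$process), c("CP", "FLS", "SF", "HD"))
  # ranking: higher Rp2 wins regardless of RPD
  r1 <- evaluateModel(1:3, c(1, 2, 3.01), c(4, 5, 6, 7), c(4.05, 5.05, 6, 7),
                      process = "CP", pretreatmentLabel = "CT",
                      selector = "CARS", regressor = "PLSR")
  r2 <- evaluateModel(1:3, c(1, 2, 3.01), c(4, 5, 6, 7), c(4.3, 5.2, 6, 7),
                      process = "CP", pretreatmentLabel = "D1",
                      selector = "CARS", regressor = "PLSR")
  t2 <- buildReport(list(r1, r2))
  expect_true(t2$best[t2$pretreatment == "CT"])
  # duplicates rejected; empty input gives an empty table
  expect_error(buildReport(list(r1, r1)), "duplicate")
  expect_equal(nrow(buildReport(list())), 0L)
})

test_that("reports serialise byte-identically", {
  r <- evaluateModel(1:3, c(1.1, 2, 3), c(4, 5, 6, 7), c(4.2, 5, 6, 7.1),
                     model = "CT-none-PLSR", process = "CP",
                     pretreatmentLabel = "CT", selector = "none",
                     regressor = "PLSR", nBands = 943L)
  tab <- buildReport(list(r))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write.csv(tab, f1, row.names = FALSE)
  write.csv(buildReport(list(r)), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})
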