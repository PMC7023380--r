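test_that("calibration fitting recovers exact lines and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  f <- fitCalibration(x, 2 * x)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  f2 <- fitCalibration(c(1, 2), c(3, 5))
  expect_equal(f2$r_squared, 1)
  expect_true("under_determined" %in% f2$flags)
  expect_error(fitCalibration(rep(3, 5), 1:5), "degenerate")
})

test_that("DIN 32645 limits behave as the closed form dictates", {
  set.seed(31)
  x <- seq(7.5, 187.5, length.out = 9)
  y <- 2 * x + rnorm(9, 0, 4)
  lim <- din32645Limits(x, y)
  expect_true(lim$lod_mg_kg > 0 && lim$lod_mg_kg < lim$loq_mg_kg)
  # noiseless limit: LOD -> 0
  lim0 <- din32645Limits(x, 2 * x + 1e-9 * rnorm(9))
  expect_lt(lim0$lod_mg_kg, 1e-7)
  # doubling the residual sd (same design) exactly doubles the LOD
  fit <- lm(y ~ x)
  y2 <- fitted(fit) + 2 * residuals(fit)
  lim2 <- din32645Limits(x, y2)
  expect_equal(lim2$lod_mg_kg, 2 * lim$lod_mg_kg, tolerance = 1e-9)
  expect_error(din32645Limits(x[1:4], y[1:4]), "at least 5")
  expect_error(din32645Limits(x, rev(y)), "slope")
})

test_that("DIN 32645 matches an independently coded textbook calculation", {
  set.seed(123)
  x <- seq(10, 90, by = 10)
  y <- 0.5 * x + rnorm(9, 0, 1.5)
  lim <- din32645Limits(x, y, alpha = 0.01, k_loq = 3)
  # oracle: explicit sums, no lm()
  n <- length(x)
  xb <- sum(x) / n
  b <- sum((x - xb) * y) / sum((x - xb)^2)
  a <- sum(y) / n - b * xb
  sy <- sqrt(sum((y - a - b * x)^2) / (n - 2))
  qx <- sum((x - xb)^2)
  tv <- qt(0.99, n - 2)
  lod <- sy / b * tv * sqrt(1 + 1 / n + xb^2 / qx)
  loq <- 3 * lod
  for (i in 1:200)
    loq <- 3 * sy / b * tv * sqrt(1 + 1 / n + (loq - xb)^2 / qx)
  expect_equal(lim$lod_mg_kg, lod, tolerance = 1e-10)
  expect_equal(lim$loq_mg_kg, loq, tolerance = 1e-8)
})

test_that("recovery follows its definition and specification band", {
  x <- c(10, 20, 50, 100)
  r <- recovery(x, x)
  expect_equal(r$recovery_pct, 100)
  expect_true(r$in_spec)
  r74 <- recovery(x, 0.74 * x)
  expect_equal(r74$recovery_pct, 74)
  expect_false(r74$in_spec)
  # matrix blank is subtracted before the ratio
  rb <- recovery(x, x + 5, blank = 5)
  expect_equal(rb$recovery_pct, 100)
  # aggregation is the mean of per-level recoveries
  rm <- recovery(c(10, 100), c(5, 110))
  expect_equal(rm$recovery_pct, mean(c(50, 110)))
  expect_error(recovery(c(0, 10), c(1, 10)), "positive")
})

test_that("precision CV follows its definition and specification band", {
  expect_equal(precisionCV(rep(7, 4))$cv_pct, 0)
  v <- c(90, 100, 110)
  expect_equal(precisionCV(v)$cv_pct, 100 * sd(v) / mean(v))
  fake <- precisionCV(c(80, 124))  # CV 22.2-ish
  expect_false(fake$in_spec)
  expect_true(precisionCV(c(100, 108))$in_spec)
  expect_error(precisionCV(5), "2 replicates")
  expect_error(precisionCV(c(-1, 1)), "mean is zero")
})

test_that("one-factor balanced ANOVA reduces to the squared t statistic", {
  set.seed(9)
  d <- data.frame(device = rep(c("UltraShield", "Ascend"), each = 6),
                  coffee_type = "robusta", shaking_min = 20,
                  recovery_pct = rnorm(12, 100, 5))
  a <- factorialAnova(d)
  tt <- t.test(recovery_pct ~ device, data = d, var.equal = TRUE)
  expect_equal(a$F[a$factor == "device"], unname(tt$statistic)^2,
               tolerance = 1e-9)
})

test_that("three-factor ANOVA flags an injected coffee-type effect only", {
  design <- buildValidationDesign()
  set.seed(21)
  cells <- design$cells
  cells$recovery_pct <- 100 + ifelse(cells$coffee_type == "green", -25, 0) +
    rnorm(nrow(cells), 0, 3)
  a <- factorialAnova(cells)
  expect_true(a$significant[a$factor == "coffee_type"])
  expect_false(a$significant[a$factor == "device"])
  expect_false(a$significant[a$factor == "shaking_min"])
  expect_error(factorialAnova(cells[, -1][, -1]), "missing column")
})

test_that("ANOVA keeps its nominal type-I error under the null", {
  design <- buildValidationDesign()
  set.seed(77)
  hits <- 0L
  n_runs <- 200
  for (i in seq_len(n_runs)) {
    cells <- design$cells
    cells$recovery_pct <- rnorm(nrow(cells), 100, 3)
    a <- factorialAnova(cells)
    hits <- hits + sum(a$significant)
  }
  expect_lt(hits / (3 * n_runs), 0.09)
})

test_that("missing design cells raise the unbalanced warning", {
  design <- buildValidationDesign()
  cells <- design$cells[-1, ]
  set.seed(2)
  cells$recovery_pct <- rnorm(nrow(cells), 100, 3)
  expect_warning(factorialAnova(cells), "unbalanced")
})

test_that("recovery and CV estimators are unbiased on simulated data", {
  set.seed(55)
  x <- c(7.5, 37.5, 75, 187.5, 375)
  recs <- replicate(200, {
    recovery(x, x * (1 + rnorm(length(x), 0, 0.05)))$recovery_pct
  })
  expect_equal(mean(recs), 100, tolerance = 1)
})

test_that("the validation report assembles, flags and survives empty input", {
  empty <- buildValidationReport(data.frame())
  expect_s3_class(empty, "ValidationReport")
  expect_equal(nrow(empty$recovery_precision), 0)

  # constructed measurement table mirroring the design geometry
  design <- buildValidationDesign()
  plan <- design$plan
  set.seed(14)
  rows <- list()
  presets <- list(arabica_decaf = c(omc = 0.97, caffeine = 1.01),
                  robusta = c(omc = 1.01, caffeine = 1.02),
                  green = c(omc = 0.54, caffeine = 1.37))
  noise <- list(arabica_decaf = 0.05, robusta = 0.05, green = 0.8)
  for (ci in seq_len(nrow(design$cells))) {
    cell <- design$cells[ci, ]
    for (li in seq_len(nrow(plan))) {
      for (an in c("omc", "caffeine")) {
        spiked <- plan$target_mg_L[li] * 7.5
        bias <- presets[[cell$coffee_type]][[an]]
        meas <- if (plan$blank[li]) abs(rnorm(1, 0, 0.5)) else
          spiked * bias * max(0, 1 + rnorm(1, 0, noise[[cell$coffee_type]]))
        rows[[length(rows) + 1]] <- data.frame(
          array = cell$array, device = cell$device,
          coffee_type = cell$coffee_type, shaking_min = cell$shaking_min,
          analyte = an, blank = plan$blank[li], spiked_mg_kg = spiked,
          measured_mg_kg = meas)
      }
    }
  }
  m <- do.call(rbind, rows)
  rep <- buildValidationReport(m)
  rp <- rep$recovery_precision
  expect_setequal(unique(rp$matrix), c("arabica_decaf", "robusta", "green"))
  omc_green <- rp[rp$analyte == "omc" & rp$matrix == "green", ]
  expect_false(omc_green$recovery_in_spec)
  expect_false(omc_green$cv_in_spec)
  omc_decaf <- rp[rp$analyte == "omc" & rp$matrix == "arabica_decaf", ]
  expect_true(omc_decaf$recovery_in_spec)
  expect_true(omc_decaf$cv_in_spec)
  expect_gt(rep$linearity$r_squared[rep$linearity$analyte == "omc"], 0.99)
  expect_true(all(c("lod_mg_kg", "loq_mg_kg") %in% names(rep$limits)))
  expect_true(all(rep$limits$lod_mg_kg < rep$limits$loq_mg_kg))
  anova_omc <- rep$anova[rep$anova$analyte == "omc", ]
  expect_true(anova_omc$significant[anova_omc$factor == "coffee_type"])
  expect_output(print(rep), "Recovery / precision")
})
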