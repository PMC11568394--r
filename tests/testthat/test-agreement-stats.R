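pm_from_matrix <- function(x, col_role = "rater") {
  # subjects in rows, columns = raters/methods/replicates
  df <- expand.grid(subject_id = sprintf("s%02d", seq_len(nrow(x))),
                    col = seq_len(ncol(x)), stringsAsFactors = FALSE)
  df$angle <- as.vector(x)
  out <- data.frame(subject_id = df$subject_id,
                    method = "m", rater = "r1", replicate = 1L,
                    angle = df$angle)
  if (col_role == "rater") out$rater <- paste0("r", df$col)
  if (col_role == "method") out$method <- paste0("m", df$col)
  if (col_role == "replicate") out$replicate <- df$col
  paired_measurements(out)
}

test_that("identical columns give ICC 1 with an excellent band", {
  x <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40))
  res <- icc_absolute_agreement(pm_from_matrix(x), grouping = "raters")
  expect_equal(res$estimate, 1)
  expect_identical(res$band, "excellent")
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("ICC(2,1) reproduces the classic four-judge reliability example", {
  # Shrout & Fleiss six-target, four-judge table; published ICC(2,1) = 0.29
  x <- cbind(c(9, 6, 8, 7, 10, 6),
             c(2, 1, 4, 1, 5, 2),
             c(5, 3, 6, 2, 6, 4),
             c(8, 2, 8, 6, 9, 7))
  res <- icc_absolute_agreement(pm_from_matrix(x), grouping = "raters")
  expect_equal(res$estimate, 0.29, tolerance = 0.005)
  expect_identical(res$band, "poor")
  expect_lt(res$p_value, 0.001)
})

test_that("mean squares agree with an independent two-way ANOVA", {
  set.seed(3)
  for (rep in 1:5) {
    x <- matrix(sample(0:9, 9, replace = TRUE), 3, 3)
    # some draws have (near-)zero subject variance; the degeneracy warning is
    # expected and irrelevant to the mean-square arithmetic under test
    res <- suppressWarnings(
      icc_absolute_agreement(pm_from_matrix(x), grouping = "raters"))
    long <- data.frame(val = as.vector(x),
                       subj = factor(rep(1:3, 3)),
                       col = factor(rep(1:3, each = 3)))
    ms <- summary(stats::aov(val ~ subj + col, data = long))[[1]][["Mean Sq"]]
    expect_equal(unname(res$mean_squares["msr"]), ms[1], tolerance = 1e-10)
    expect_equal(unname(res$mean_squares["msc"]), ms[2], tolerance = 1e-10)
    expect_equal(unname(res$mean_squares["mse"]), ms[3], tolerance = 1e-10)
    # and the estimate equals the variance-components form assembled from them
    n <- 3; k <- 3
    icc <- (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
    expect_equal(res$estimate, icc, tolerance = 1e-10)
  }
})

test_that("ICC recovers variance-component ground truth in simulation", {
  pm <- simulate_paired_measurements(
    rep(50, 2000), methods = data.frame(name = c("r1", "r2"), bias = 0, sd = 1),
    subject_sd = 10, seed = 21)
  res <- icc_absolute_agreement(pm, grouping = "methods")
  expect_equal(res$estimate, 100 / 101, tolerance = 0.01)
  expect_identical(res$band, "excellent")
})

test_that("ICC rejects incomplete or ambiguous designs", {
  x <- cbind(c(10, 20, 30, 40), c(11, 21, 31, 41))
  pm <- pm_from_matrix(x)
  drop_one <- paired_measurements(as.data.frame(pm)[-2, ])
  expect_error(icc_absolute_agreement(drop_one, grouping = "raters"),
               "missing cell.*s02")
  two_reps <- paired_measurements(rbind(
    as.data.frame(pm),
    transform(as.data.frame(pm), replicate = 2L)))
  expect_error(icc_absolute_agreement(two_reps, grouping = "raters"),
               "multiple values")
  expect_equal(
    icc_absolute_agreement(two_reps, grouping = "raters", replicate = 1L)$estimate,
    icc_absolute_agreement(pm, grouping = "raters")$estimate)
})

test_that("zero between-subject variance is flagged", {
  x <- cbind(c(5, 5, 5, 5), c(6, 4, 6, 4))
  expect_warning(icc_absolute_agreement(pm_from_matrix(x), grouping = "raters"),
                 "between-subject")
})

test_that("Bland-Altman hand-computable cases and identities", {
  ba0 <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  ba <- bland_altman(c(9, 20, 31), c(10, 20, 30))  # d = -1, 0, 1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)

  set.seed(8)
  for (rep in 1:20) {
    a <- runif(50, 10, 70)
    b <- a + rnorm(50, 0.2, 2)
    ba <- bland_altman(a, b)
    expect_identical(ba$loa_low, ba$mean_diff - 1.96 * ba$sd_diff)
    expect_identical(ba$loa_high, ba$mean_diff + 1.96 * ba$sd_diff)
    expect_true(ba$loa_low <= ba$mean_diff && ba$mean_diff <= ba$loa_high)
    expect_equal(ba$means, (a + b) / 2)
  }
  expect_error(bland_altman(1:4, 1:3), "pairing")
  expect_error(bland_altman(1:2, 1:2), ">= 3")
})

test_that("accuracy rate uses a strict threshold and is monotone in it", {
  a <- c(10, 10, 10)
  b <- c(5.001, 5.0, 15)
  res <- accuracy_rate(a, b)
  expect_equal(res$rate, 1 / 3)     # |diff| = 4.999 in, 5.0 out, 5.0 out
  expect_identical(res$n_accurate, 1L)
  expect_equal(accuracy_rate(a, a)$rate, 1)

  set.seed(9)
  x <- runif(100, 10, 70)
  y <- x + rnorm(100, 0, 3)
  rates <- vapply(seq(0.5, 10, by = 0.5),
                  function(th) accuracy_rate(x, y, th)$rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_error(accuracy_rate(1:3, 1:2), "pairing")
})

test_that("stratified agreement: single-stratum data collapses to overall", {
  pm <- simulate_paired_measurements(
    runif(40, 12, 22),   # all mild under the reference
    methods = data.frame(name = c("app", "PACS"), bias = c(0.1, 0), sd = 1),
    seed = 33)
  rep <- stratified_agreement(pm, method = "app", reference = "PACS")
  expect_equal(rep$strata$moderate$n, 0L)
  expect_equal(rep$strata$severe$n, 0L)
  expect_null(rep$strata$moderate$bland_altman)
  expect_equal(rep$strata$mild$n, rep$overall$n)
  expect_equal(rep$strata$mild$bland_altman$mean_diff,
               rep$overall$bland_altman$mean_diff)
  expect_equal(rep$overall$n,
               rep$strata$mild$n + rep$strata$moderate$n + rep$strata$severe$n)
})

test_that("stratum-specific error SDs come back in the injected order", {
  set.seed(44)
  truths <- c(runif(150, 10, 24), runif(150, 26, 44), runif(150, 46, 70))
  noise_sd <- c(rep(1, 150), rep(2, 150), rep(4, 150))
  df <- data.frame(
    subject_id = sprintf("s%03d", 1:450),
    method = "app", rater = "r1", replicate = 1L,
    angle = truths + rnorm(450, 0, noise_sd))
  df_ref <- transform(df, method = "PACS", angle = truths)
  pm <- paired_measurements(rbind(df, df_ref))
  rep <- stratified_agreement(pm, method = "app", reference = "PACS")
  sds <- c(rep$strata$mild$bland_altman$sd_diff,
           rep$strata$moderate$bland_altman$sd_diff,
           rep$strata$severe$bland_altman$sd_diff)
  expect_true(all(diff(sds) > 0))
  expect_equal(rep$overall$n, 450L)
})

test_that("stratified agreement errors when the reference is incomplete", {
  pm <- simulate_paired_measurements(
    runif(10, 20, 40),
    methods = data.frame(name = c("app", "PACS"), bias = 0, sd = 1), seed = 2)
  df <- as.data.frame(pm)
  df <- df[!(df$method == "PACS" & df$subject_id == df$subject_id[1]), ]
  expect_error(
    stratified_agreement(paired_measurements(df), method = "app",
                         reference = "PACS"),
    "missing for subject.*s01")
  expect_error(stratified_agreement(pm, method = "nope"), "absent")
})

test_that("agreement statistics are invariant to subject order", {
  pm <- simulate_paired_measurements(
    runif(60, 10, 60),
    methods = data.frame(name = c("app", "PACS"), bias = c(0.3, 0), sd = 1.5),
    seed = 10)
  df <- as.data.frame(pm)
  shuffled <- paired_measurements(df[sample(nrow(df)), ])
  r1 <- stratified_agreement(pm, method = "app")
  r2 <- stratified_agreement(shuffled, method = "app")
  expect_equal(r1$overall$bland_altman$mean_diff, r2$overall$bland_altman$mean_diff)
  expect_equal(r1$overall$mae, r2$overall$mae)
  expect_equal(r1$icc$estimate, r2$icc$estimate)
})

test_that("agreement reports serialize to JSON and CSV", {
  pm <- simulate_paired_measurements(
    runif(30, 10, 60),
    methods = data.frame(name = c("app", "PACS"), bias = c(0.1, 0), sd = 1.5),
    seed = 3)
  rep <- stratified_agreement(pm, method = "app")
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_agreement_report(rep, jp, cp)
  parsed <- jsonlite::fromJSON(jp)
  expect_equal(parsed$icc$estimate, rep$icc$estimate)
  expect_equal(parsed$strata$overall$bland_altman$mean_diff,
               rep$overall$bland_altman$mean_diff)
  tab <- read.csv(cp)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$n[tab$stratum == "overall"], rep$overall$n)
})
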