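# Reliability battery for method-comparison studies: ICC(2,1) with
# consistency bands, Bland-Altman limits of agreement, mean absolute error,
# and the <5-degree accuracy rate, overall and per severity stratum.

ICC_BANDS <- data.frame(
  lower = c(-Inf, 0.250, 0.500, 0.700, 0.900),
  band = c("below-poor", "poor", "moderate", "good", "excellent"),
  stringsAsFactors = FALSE)

icc_band <- function(estimate) {
  ICC_BANDS$band[max(which(estimate >= ICC_BANDS$lower))]
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Computes the single-measurement absolute-agreement ICC — ICC(2,1) in the
#' Shrout-Fleiss nomenclature, "A,1" in McGraw-Wong — on a complete crossed
#' design extracted from a long measurement table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with the row, column and residual mean squares of the two-way ANOVA.
#' The 95% CI uses the standard F-based interval with Satterthwaite degrees
#' of freedom; the p-value is the F-test of zero subject variance
#' (`F = MSR / MSE`).  Estimates are banded as below-poor (<0.250), poor
#' (0.250-0.499), moderate (0.500-0.699), good (0.700-0.899) or excellent
#' (>= 0.900).
#'
#' @param data A [paired_measurements()] table.
#' @param grouping What forms the columns of the crossed design: `"raters"`
#'   (inter-observer), `"replicates"` (intra-observer repeatability) or
#'   `"methods"` (method comparison).
#' @param method,rater,replicate Optional filters fixing the non-grouping
#'   factors; after filtering, each (subject, column) cell must hold exactly
#'   one value.
#' @param conf_level Confidence level for the interval.
#' @return Object of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `band`, `model`, `p_value`, `n`, `k`.
#' @export
icc_absolute_agreement <- function(data,
                                   grouping = c("raters", "replicates", "methods"),
                                   method = NULL, rater = NULL, replicate = NULL,
                                   conf_level = 0.95) {
  stopifnot(inherits(data, "paired_measurements"))
  grouping <- match.arg(grouping)
  df <- as.data.frame(data)
  if (!is.null(method)) df <- df[df$method %in% method, ]
  if (!is.null(rater)) df <- df[df$rater %in% rater, ]
  if (!is.null(replicate)) df <- df[df$replicate %in% replicate, ]
  col_var <- switch(grouping, raters = "rater", replicates = "replicate",
                    methods = "method")
  df$column <- as.character(df[[col_var]])
  cell <- paste(df$subject_id, df$column, sep = "\r")
  if (anyDuplicated(cell)) {
    stop("multiple values per (subject, ", col_var,
         ") cell; fix the other factors with the method/rater/replicate filters",
         call. = FALSE)
  }
  wide <- stats::xtabs(angle ~ subject_id + column, data = df)
  present <- stats::xtabs(~ subject_id + column, data = df)
  if (any(present == 0)) {
    miss <- which(present == 0, arr.ind = TRUE)
    labels <- apply(miss, 1, function(ij) {
      paste0("(", rownames(present)[ij[1]], ", ", colnames(present)[ij[2]], ")")
    })
    stop("incomplete crossed design; missing cell(s): ",
         paste(utils::head(labels, 10), collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(unclass(wide))
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) {
    stop("need >= 2 subjects and >= 2 columns", call. = FALSE)
  }

  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  grand <- mean(x)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  resid <- x - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= mse) {
    warning("zero (or negative) between-subject variance; ICC degenerate",
            call. = FALSE)
  }
  est <- (msr - mse) / denom

  alpha <- 1 - conf_level
  # F-based CI (McGraw & Wong, case A,1) with Satterthwaite df; degenerates
  # to a point interval under perfect agreement (mse = 0)
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  if (!is.finite(ci_low)) ci_low <- est
  if (!is.finite(ci_high)) ci_high <- est
  p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  structure(list(estimate = est, ci_low = ci_low, ci_high = ci_high,
                 band = icc_band(est),
                 model = "ICC(2,1) two-way random effects, absolute agreement, single measures",
                 p_value = p, n = n, k = k,
                 mean_squares = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.3f (95%% CI %.3f-%.3f), %s consistency; n=%d, k=%d, p=%.3g\n",
              x$estimate, x$ci_low, x$ci_high, x$band, x$n, x$k, x$p_value))
  cat(" ", x$model, "\n")
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = a - b`; reports their mean, sample SD (n-1 denominator)
#' and the 95% limits of agreement `mean +/- 1.96 SD` (fixed z multiplier).
#' Per-pair means are returned for the conventional scatter plot.
#'
#' @param a,b Paired measurement vectors (same length, >= 3), degrees.
#' @return Object of class `bland_altman_result`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, `means`, `diffs`.
#' @examples
#' bland_altman(c(10, 20, 30), c(11, 20, 29))
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    stop("pairing error: vectors have lengths ", length(a), " and ", length(b),
         call. = FALSE)
  }
  if (length(a) < 3L) stop("need >= 3 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d), means = (a + b) / 2, diffs = d),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.2f deg, SD %.2f, 95%% LoA %.2f to %.2f (n=%d)\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Accuracy rate under an absolute-error threshold
#'
#' Fraction of pairs whose absolute difference from the reference is strictly
#' below the threshold (default 5 degrees, the clinical allowance for Cobb
#' angle measurement error).
#'
#' @param a Measurement vector, degrees.
#' @param b Reference vector, degrees, same length.
#' @param threshold Strict upper bound on `|a - b|`, degrees.
#' @return List: `rate` (fraction in [0, 1]), `n_accurate`, `n`.
#' @export
accuracy_rate <- function(a, b, threshold = 5) {
  if (length(a) != length(b)) {
    stop("pairing error: vectors have lengths ", length(a), " and ", length(b),
         call. = FALSE)
  }
  acc <- abs(a - b) < threshold
  list(rate = mean(acc), n_accurate = sum(acc), n = length(a))
}

#' Agreement report stratified by severity
#'
#' Pairs one measurement method against a reference method subject by
#' subject (values averaged over raters and replicates within each method),
#' assigns each subject a severity stratum from the *reference* angle, and
#' computes Bland-Altman statistics, mean absolute error and the accuracy
#' rate overall and within each stratum.  An overall method-vs-reference
#' ICC(2,1) is included.
#'
#' @param measurements A [paired_measurements()] table containing both
#'   methods.
#' @param method Name of the test method.
#' @param reference Name of the reference method (severity source).
#' @param threshold Accuracy threshold in degrees (strict).
#' @return Object of class `agreement_report`: `overall` and `strata` (named
#'   list mild/moderate/severe, each with `n`, `bland_altman`, `mae`,
#'   `accuracy`), plus `icc`, `method`, `reference`, `threshold`.
#' @export
stratified_agreement <- function(measurements, method, reference = "PACS",
                                 threshold = 5) {
  stopifnot(inherits(measurements, "paired_measurements"))
  df <- as.data.frame(measurements)
  for (m in c(method, reference)) {
    if (!m %in% df$method) stop("method '", m, "' absent from table", call. = FALSE)
  }
  agg <- stats::aggregate(angle ~ subject_id + method,
                          data = df[df$method %in% c(method, reference), ],
                          FUN = mean)
  test_v <- agg[agg$method == method, ]
  ref_v <- agg[agg$method == reference, ]
  missing_ref <- setdiff(test_v$subject_id, ref_v$subject_id)
  if (length(missing_ref)) {
    stop("reference method '", reference, "' missing for subject(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  ref_v <- ref_v[match(test_v$subject_id, ref_v$subject_id), ]
  a <- test_v$angle
  b <- ref_v$angle
  severity <- vapply(b, classify_severity, character(1))

  stat_block <- function(sel) {
    n <- sum(sel)
    if (n == 0L) {
      return(list(n = 0L, bland_altman = NULL, mae = NA_real_, accuracy = NULL))
    }
    list(n = n,
         bland_altman = if (n >= 3L) bland_altman(a[sel], b[sel]),
         mae = mean(abs(a[sel] - b[sel])),
         accuracy = accuracy_rate(a[sel], b[sel], threshold))
  }

  pm_sub <- paired_measurements(data.frame(
    subject_id = rep(test_v$subject_id, 2),
    method = rep(c(method, reference), each = length(a)),
    rater = "pooled", replicate = 1L, angle = c(a, b)))
  icc <- icc_absolute_agreement(pm_sub, grouping = "methods")

  structure(list(
    overall = stat_block(rep(TRUE, length(a))),
    strata = list(mild = stat_block(severity == "mild"),
                  moderate = stat_block(severity == "moderate"),
                  severe = stat_block(severity == "severe")),
    icc = icc, method = method, reference = reference, threshold = threshold,
    subjects = data.frame(subject_id = test_v$subject_id, test = a,
                          reference = b, severity = severity)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s vs %s (reference), n=%d\n",
              x$method, x$reference, x$overall$n))
  print(x$icc)
  print(x$overall$bland_altman)
  cat(sprintf("MAE %.2f deg; accuracy (<%g deg) %.1f%% (%d/%d)\n",
              x$overall$mae, x$threshold, 100 * x$overall$accuracy$rate,
              x$overall$accuracy$n_accurate, x$overall$accuracy$n))
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    if (st$n == 0) { cat(sprintf("  %s: n=0\n", s)); next }
    cat(sprintf("  %s: n=%d, MAE %.2f, accuracy %.1f%%%s\n", s, st$n, st$mae,
                100 * st$accuracy$rate,
                if (!is.null(st$bland_altman)) {
                  sprintf(", LoA %.2f to %.2f", st$bland_altman$loa_low,
                          st$bland_altman$loa_high)
                } else ""))
  }
  invisible(x)
}

#' Serialize an agreement report
#'
#' Writes the report as JSON (full structure) and, optionally, a flat CSV of
#' the per-stratum summary statistics.
#'
#' @param report An `agreement_report`.
#' @param json_path Output JSON path.
#' @param csv_path Optional output CSV path.
#' @return Invisibly, `json_path`.
#' @export
write_agreement_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  strip <- function(bl) {
    if (is.null(bl)) return(NULL)
    bl[c("mean_diff", "sd_diff", "loa_low", "loa_high", "n")]
  }
  blocks <- c(list(overall = report$overall), report$strata)
  payload <- list(
    method = report$method, reference = report$reference,
    threshold = report$threshold,
    icc = unclass(report$icc)[c("estimate", "ci_low", "ci_high", "band",
                                "model", "p_value", "n", "k")],
    strata = lapply(blocks, function(st) {
      list(n = st$n, bland_altman = strip(st$bland_altman), mae = st$mae,
           accuracy = st$accuracy)
    }))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(names(blocks), function(nm) {
      st <- blocks[[nm]]
      data.frame(stratum = nm, n = st$n,
                 mean_diff = if (is.null(st$bland_altman)) NA else st$bland_altman$mean_diff,
                 sd_diff = if (is.null(st$bland_altman)) NA else st$bland_altman$sd_diff,
                 loa_low = if (is.null(st$bland_altman)) NA else st$bland_altman$loa_low,
                 loa_high = if (is.null(st$bland_altman)) NA else st$bland_altman$loa_high,
                 mae = st$mae,
                 accuracy_rate = if (is.null(st$accuracy)) NA else st$accuracy$rate)
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
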