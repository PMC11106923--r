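#' Paired rater/model measurements
#'
#' Holds one measured quantity (cardiac axis in degrees or cardiothoracic
#' ratio) for the same cases measured twice: by a human rater and by the
#' automated pipeline. Pairs with a missing value in either column are dropped
#' (explicit pairwise deletion).
#'
#' @param rater,model Numeric vectors of equal length.
#' @param quantity Label for the quantity, e.g. `"cax_deg"` or `"ctr"`.
#' @return A `paired_measurements` object.
#' @export
paired_measurements <- function(rater, model, quantity = "value") {
  if (length(rater) != length(model)) stop("rater and model must have equal length")
  keep <- is.finite(rater) & is.finite(model)
  rater <- as.numeric(rater[keep]); model <- as.numeric(model[keep])
  if (length(rater) < 3L) stop("need at least 3 complete pairs, got ", length(rater))
  structure(list(rater = rater, model = model, quantity = quantity),
            class = "paired_measurements")
}

#' Normality-gated paired comparison
#'
#' Applies the Shapiro-Wilk test to the paired differences; if they are
#' compatible with normality (`p > alpha`) the means are compared with a
#' paired t-test, otherwise with the Wilcoxon signed-rank test. Both the
#' gating p-value and the comparison p-value are returned, so the routing is
#' auditable.
#'
#' @param pm A [paired_measurements()].
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return List with `normality_p`, `test_used` (`"paired_t"` or
#'   `"wilcoxon"`), `test_p`, and any `warnings`.
#' @export
paired_compare <- function(pm, alpha = 0.05) {
  stopifnot(inherits(pm, "paired_measurements"))
  d <- pm$rater - pm$model
  warnings <- character()
  if (all(d == d[1])) {
    # constant differences: Shapiro-Wilk and (for d == 0) Wilcoxon are undefined
    warnings <- c(warnings, "all paired differences are identical; comparison is degenerate")
    # zero spread: p = 1 for a zero offset, p -> 0 for any non-zero offset
    test_p <- if (d[1] == 0) 1 else 0
    return(list(normality_p = NA_real_, test_used = "paired_t",
                test_p = test_p, warnings = warnings))
  }
  normality_p <- stats::shapiro.test(d)$p.value
  if (normality_p > alpha) {
    test_used <- "paired_t"
    test_p <- stats::t.test(pm$rater, pm$model, paired = TRUE)$p.value
  } else {
    test_used <- "wilcoxon"
    test_p <- suppressWarnings(
      stats::wilcox.test(pm$rater, pm$model, paired = TRUE, exact = FALSE)$p.value)
  }
  list(normality_p = normality_p, test_used = test_used, test_p = test_p,
       warnings = warnings)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' The bias is the mean paired difference (rater minus model); the limits of
#' agreement are `bias +/- 1.96 sd(differences)`, and the bias confidence
#' interval uses the t distribution with `n - 1` degrees of freedom.
#'
#' @param pm A [paired_measurements()].
#' @param conf Confidence level for the bias CI (default 0.95).
#' @return List with `bias`, `sd_diff`, `bias_ci = c(low, high)`,
#'   `loa = c(low, high)`, `n`, and the per-pair `mean`/`diff` vectors used
#'   for plotting.
#' @export
bland_altman <- function(pm, conf = 0.95) {
  stopifnot(inherits(pm, "paired_measurements"))
  d <- pm$rater - pm$model
  n <- length(d)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * sd_diff / sqrt(n)
  list(bias = bias, sd_diff = sd_diff,
       bias_ci = c(bias - half, bias + half),
       loa = c(bias - 1.96 * sd_diff, bias + 1.96 * sd_diff),
       n = n, mean = (pm$rater + pm$model) / 2, diff = d)
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC: both
#' the cases and the two raters (human, model) are treated as random samples,
#' and systematic offsets between raters count against agreement. Computed
#' from the two-way ANOVA mean squares; the confidence interval follows the
#' standard F-distribution construction.
#'
#' @param pm A [paired_measurements()] with at least 5 pairs.
#' @param conf Confidence level (default 0.95).
#' @return List with `icc` and `icc_ci = c(low, high)`.
#' @export
icc <- function(pm, conf = 0.95) {
  stopifnot(inherits(pm, "paired_measurements"))
  Y <- cbind(pm$rater, pm$model)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 5L) stop("ICC needs at least 5 pairs, got ", n)
  if (stats::sd(Y) < .Machine$double.eps) stop("ICC undefined on constant data")
  row_m <- rowMeans(Y); col_m <- colMeans(Y); gm <- mean(Y)
  SSR <- k * sum((row_m - gm)^2)            # between subjects
  SSC <- n * sum((col_m - gm)^2)            # between raters
  SSE <- sum((Y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + gm)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (denom < .Machine$double.eps) stop("ICC undefined: no between-subject variance")
  icc_val <- (MSR - MSE) / denom

  if (MSE < .Machine$double.eps && MSC < .Machine$double.eps) {
    # perfect agreement: the F construction below is 0/0
    return(list(icc = icc_val, icc_ci = c(icc_val, icc_val)))
  }
  alpha <- 1 - conf
  a <- k * icc_val / (n * (1 - icc_val))
  b <- 1 + k * icc_val * (n - 1) / (n * (1 - icc_val))
  v <- (a * MSC + b * MSE)^2 /
       ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc_val, icc_ci = c(lower, upper))
}

#' Full agreement report between a rater and the automated model
#'
#' Composes the normality-gated paired comparison, the Bland-Altman analysis
#' and ICC(2,1) into one report, optionally rendering a Bland-Altman plot
#' (per-pair mean on x, difference on y, with the bias and limits of
#' agreement as horizontal lines).
#'
#' @param pm A [paired_measurements()].
#' @param alpha Significance level for the normality gate.
#' @param plot_file Optional path (`.svg`, `.pdf` or `.png`) for the
#'   Bland-Altman plot.
#' @return An `agreement_report` object with fields `quantity`, `n`,
#'   `normality_p`, `test_used`, `test_p`, `bias`, `sd_diff`, `bias_ci`,
#'   `loa`, `icc`, `icc_ci`, `warnings`.
#' @export
agreement_report <- function(pm, alpha = 0.05, plot_file = NULL) {
  stopifnot(inherits(pm, "paired_measurements"))
  cmp <- paired_compare(pm, alpha = alpha)
  ba <- bland_altman(pm)
  ic <- tryCatch(icc(pm), error = function(e) {
    list(icc = NA_real_, icc_ci = c(NA_real_, NA_real_), err = conditionMessage(e))
  })
  warnings <- cmp$warnings
  if (!is.null(ic$err)) warnings <- c(warnings, paste("ICC:", ic$err))
  rep <- structure(list(quantity = pm$quantity, n = ba$n,
                        normality_p = cmp$normality_p,
                        test_used = cmp$test_used, test_p = cmp$test_p,
                        bias = ba$bias, sd_diff = ba$sd_diff,
                        bias_ci = ba$bias_ci, loa = ba$loa,
                        icc = ic$icc, icc_ci = ic$icc_ci,
                        warnings = warnings),
                   class = "agreement_report")
  if (!is.null(plot_file)) plot_bland_altman(pm, ba, plot_file)
  rep
}

plot_bland_altman <- function(pm, ba, file) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    svg = grDevices::svg(file, width = 6, height = 5),
    pdf = grDevices::pdf(file, width = 6, height = 5),
    png = grDevices::png(file, width = 720, height = 600, res = 120),
    stop("unsupported plot format: .", ext))
  on.exit(grDevices::dev.off())
  graphics::plot(ba$mean, ba$diff, pch = 19, col = "grey30",
                 xlab = paste("Mean of rater and model", pm$quantity),
                 ylab = "Difference (rater - model)",
                 main = "Bland-Altman agreement")
  graphics::abline(h = ba$bias, col = "blue", lty = 2)
  graphics::abline(h = ba$loa, col = "red", lty = 2)
  invisible(file)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s, n = %d\n", x$quantity, x$n))
  cat(sprintf("  normality p = %s -> %s, p = %.4g\n",
              formatC(x$normality_p, digits = 4), x$test_used, x$test_p))
  cat(sprintf("  bias %.4f (95%% CI %.4f to %.4f), LoA %.4f to %.4f\n",
              x$bias, x$bias_ci[1], x$bias_ci[2], x$loa[1], x$loa[2]))
  cat(sprintf("  ICC(2,1) %.3f (95%% CI %.3f to %.3f)\n",
              x$icc, x$icc_ci[1], x$icc_ci[2]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
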