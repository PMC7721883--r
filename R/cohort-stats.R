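#' Aggregate per-image summaries into one per-mouse row
#'
#' Representative images from one animal are averaged with equal weights;
#' images where a metric is undefined (e.g. zero interior crypts, or no
#' nearest crypt within the search radius) are excluded from that metric's
#' mean, with the number of contributing images reported alongside.
#' Aggregation is permutation-invariant and the identity on a single
#' image.
#'
#' @param image_summaries tibble of [summarize_image()] rows (one per
#'   image) for one mouse.
#' @param mouse_id,genotype,timepoint,tumor_burden optional metadata
#'   carried into the output.
#' @return one-row tibble: metadata, `n_images`, and for every numeric
#'   metric its mean plus an `n_<metric>` count of images that defined it.
#' @export
aggregate_per_mouse <- function(image_summaries, mouse_id = NA,
                                genotype = NA, timepoint = NA,
                                tumor_burden = NA) {
  stopifnot(is.data.frame(image_summaries), nrow(image_summaries) >= 1L)
  num <- vapply(image_summaries, is.numeric, logical(1))
  out <- tibble::tibble(mouse_id = mouse_id, genotype = genotype,
                        timepoint = timepoint,
                        n_images = nrow(image_summaries))
  for (col in names(image_summaries)[num]) {
    v <- image_summaries[[col]]
    out[[col]] <- if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
    out[[paste0("n_", col)]] <- sum(!is.na(v))
  }
  out$tumor_burden <- tumor_burden
  out
}

#' Welch's unequal-variance t-test between two groups
#'
#' Two-sided Welch's t with the Welch-Satterthwaite degrees of freedom,
#' reported with group means and SEMs. When both groups have zero variance
#' the comparison is degenerate: equal means give t = 0, p = 1; unequal
#' means are flagged with an undefined p.
#'
#' @param group1,group2 numeric vectors, each of length >= 2.
#' @param labels character vector of two group names.
#' @param metric metric name carried into the output.
#' @return one-row tibble of class `group_comparison`: means, SEMs, `t`,
#'   `df`, two-sided `p`, `degenerate`.
#' @export
welch_t <- function(group1, group2, labels = c("group1", "group2"),
                    metric = "") {
  group1 <- group1[!is.na(group1)]
  group2 <- group2[!is.na(group2)]
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs at least two observations")
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  base <- tibble::tibble(metric = metric,
                         label1 = labels[1], label2 = labels[2],
                         n1 = length(group1), n2 = length(group2),
                         mean1 = mean(group1), mean2 = mean(group2),
                         sem1 = sem(group1), sem2 = sem(group2))
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0) {
    if (mean(group1) == mean(group2)) {
      res <- tibble::tibble(t = 0, df = NA_real_, p = 1, degenerate = TRUE)
    } else {
      res <- tibble::tibble(t = sign(mean(group1) - mean(group2)) * Inf,
                            df = NA_real_, p = NA_real_, degenerate = TRUE)
    }
  } else {
    ht <- stats::t.test(group1, group2, var.equal = FALSE)
    res <- tibble::tibble(t = unname(ht$statistic),
                          df = unname(ht$parameter),
                          p = ht$p.value, degenerate = FALSE)
  }
  out <- tibble::as_tibble(cbind(base, res))
  class(out) <- c("group_comparison", class(out))
  out
}

#' Pearson correlation of a crypt metric with tumor burden
#'
#' Sample Pearson r with the two-sided p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param metric_values,tumor_burden paired numeric vectors (pairs with
#'   missing values are dropped); need `n >= 3` and nonzero variance in
#'   both.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_burden <- function(metric_values, tumor_burden) {
  stopifnot(length(metric_values) == length(tumor_burden))
  keep <- stats::complete.cases(metric_values, tumor_burden)
  x <- metric_values[keep]
  y <- tumor_burden[keep]
  if (length(x) < 3L) {
    stop("need at least three complete pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the vectors")
  }
  r <- stats::cor(x, y)
  if (abs(r) == 1) {
    return(list(r = r, p = 0, n = length(x)))
  }
  ht <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Flag outliers by the iterative Grubbs test
#'
#' At each step the most extreme value is tested with the two-sided Grubbs
#' statistic `G = max |x - mean| / sd` against its critical value at level
#' `alpha`; if flagged it is removed and the test repeated while at least
#' three values remain. Values are only *flagged*, never silently removed:
#' exclusion is an explicit user action to be recorded in the report.
#'
#' @param values numeric vector, `n >= 3`.
#' @param alpha significance level (default 0.05).
#' @return integer vector of flagged indices into `values`, in flag order.
#' @export
flag_outliers <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values))
  if (length(values) < 3L) {
    stop("need at least three values")
  }
  active <- seq_along(values)
  flagged <- integer(0)
  repeat {
    x <- values[active]
    n <- length(x)
    if (n < 3L) break
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    tc <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    gcrit <- ((n - 1) / sqrt(n)) * sqrt(tc^2 / (n - 2 + tc^2))
    if (g <= gcrit) break
    worst <- active[which.max(dev)]
    flagged <- c(flagged, worst)
    active <- setdiff(active, worst)
  }
  flagged
}
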