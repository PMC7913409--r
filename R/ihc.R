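#' Sum the five counting areas of one slide
#'
#' The Ki67 protocol counts stained nuclei in five predefined areas per
#' slide (the four borders and the center) and sums them; the slide sum is
#' the per-cat value entering the group comparison.
#'
#' @param area_counts exactly five non-negative integer counts.
#' @return integer slide sum.
#' @examples
#' slideSum(c(2, 3, 1, 0, 4))  # 10
#' @export
slideSum <- function(area_counts) {
  if (length(area_counts) != 5)
    stop("expected 5 areas (4 borders, center), got ",
         length(area_counts), call. = FALSE)
  if (any(is.na(area_counts)) || any(area_counts < 0) ||
      any(area_counts != round(area_counts)))
    stop("area counts must be non-negative integers", call. = FALSE)
  as.integer(sum(area_counts))
}

#' Group means of Ki67 slide sums
#'
#' @param counts `data.frame` from [readKi67Counts()] (or with columns
#'   `group` and `slide_sum`).
#' @return named numeric vector `c(mean_hcm, mean_control)`.
#' @export
ki67GroupMeans <- function(counts) {
  for (g in c("hcm", "control"))
    if (!any(counts$group == g))
      stop("empty group: ", g, call. = FALSE)
  c(mean_hcm = mean(counts$slide_sum[counts$group == "hcm"]),
    mean_control = mean(counts$slide_sum[counts$group == "control"]))
}

#' Two-sample Student t test
#'
#' The classical pooled-variance two-sample t test (that is what the
#' name denotes), two-sided, with `df = n1 + n2 - 2`; the p-value is
#' evaluated through the regularized incomplete beta function,
#' `p = I_{df/(df + t^2)}(df/2, 1/2)`. A Welch (unequal-variance)
#' option is exposed but off by default. Zero pooled variance with equal
#' means gives `t = 0, p = 1`; with unequal means the comparison is
#' degenerate and flagged.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param welch use the Welch-Satterthwaite approximation instead of the
#'   pooled variance (default `FALSE`).
#' @param alpha significance level (default 0.05).
#' @return list of class `GroupComparison`: `mean_x`, `mean_y`,
#'   `t_statistic`, `degrees_of_freedom`, `p_two_sided`, `significant`,
#'   `flag`.
#' @examples
#' studentsTTest(c(1, 2, 3), c(4, 5, 6))  # t ~ -3.674, p ~ 0.021
#' @export
studentsTTest <- function(x, y, welch = FALSE, alpha = 0.05) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x); v2 <- var(y)
  flag <- ""
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 <= 0) {
    if (isTRUE(all.equal(m1, m2))) {
      t <- 0; p <- 1
    } else {
      t <- NA_real_; p <- NA_real_
      flag <- "degenerate: zero variance"
    }
  } else {
    t <- (m1 - m2) / sqrt(se2)
    ## two-sided tail of the t distribution via the regularized
    ## incomplete beta: P(|T| > |t|) = I_{df/(df+t^2)}(df/2, 1/2)
    p <- pbeta(df / (df + t^2), df / 2, 0.5)
    p <- min(1, max(0, p))
  }
  structure(list(mean_x = m1, mean_y = m2, t_statistic = t,
                 degrees_of_freedom = df, p_two_sided = p,
                 significant = !is.na(p) && p < alpha, flag = flag),
            class = "GroupComparison")
}

#' Compare Ki67 proliferative activity between groups
#'
#' Runs the pooled t test on per-cat slide sums, HCM versus control.
#'
#' @param counts `data.frame` from [readKi67Counts()].
#' @inheritParams studentsTTest
#' @return a `GroupComparison` (see [studentsTTest()]) with group means
#'   named `mean_hcm` / `mean_control`.
#' @export
compareKi67 <- function(counts, welch = FALSE, alpha = 0.05) {
  gm <- ki67GroupMeans(counts)  # validates both groups non-empty
  res <- studentsTTest(counts$slide_sum[counts$group == "hcm"],
                       counts$slide_sum[counts$group == "control"],
                       welch = welch, alpha = alpha)
  names(res)[1:2] <- c("mean_hcm", "mean_control")
  res
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("Two-sample t test (df = %.4g)\n", x$degrees_of_freedom))
  cat(sprintf("  means: %.3f vs %.3f\n", x[[1]], x[[2]]))
  cat(sprintf("  t = %.4f, p = %.4g%s\n", x$t_statistic, x$p_two_sided,
              if (isTRUE(x$significant)) "  (significant)" else ""))
  if (nzchar(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}
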