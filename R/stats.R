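#' Mean arterial pressure
#'
#' `MAP = (2 * diastolic + systolic) / 3`, all in mmHg.
#'
#' @param sbp,dbp systolic and diastolic pressure (mmHg), vectorized.
#' @return MAP in mmHg.
#' @export
meanArterialPressure <- function(sbp, dbp) {
  if (any(dbp <= 0)) stop("diastolic pressure must be positive")
  if (any(sbp <= dbp)) stop("systolic pressure must exceed diastolic")
  (2 * dbp + sbp) / 3
}

#' Paired t-test with 95% CI
#'
#' Classical paired Student t on the differences `after - before`
#' (t quantile CI, df = n - 1). Zero-variance differences make the
#' statistic undefined; that is reported as such rather than forced to
#' a p-value.
#'
#' @param before,after paired measurements; incomplete pairs are
#'   dropped.
#' @param conf confidence level.
#' @return list with `change` (mean difference), `ci`, `p`, `n`,
#'   `undefined`.
#' @export
pairedT <- function(before, after, conf = 0.95) {
  ok <- !is.na(before) & !is.na(after)
  b <- before[ok]; a <- after[ok]
  n <- length(b)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- a - b
  if (sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d))) || sd(d) == 0)
    return(list(change = mean(d), ci = c(NA_real_, NA_real_), p = NA_real_,
                n = n, undefined = TRUE))
  tt <- t.test(a, b, paired = TRUE, conf.level = conf)
  list(change = unname(tt$estimate), ci = unname(tt$conf.int),
       p = tt$p.value, n = n, undefined = FALSE)
}

#' Unpaired (pooled-variance Student) t-test with 95% CI
#'
#' The difference is `mean(b) - mean(a)`, with a pooled-variance CI at
#' df = n_a + n_b - 2 (classical Student, not Welch).
#'
#' @param a,b the two groups.
#' @param conf confidence level.
#' @return list with `difference`, `ci`, `p`, `n`.
#' @export
unpairedT <- function(a, b, conf = 0.95) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 observations")
  if (var(a) == 0 && var(b) == 0) stop("zero pooled variance")
  tt <- t.test(b, a, var.equal = TRUE, conf.level = conf)
  list(difference = unname(diff(rev(tt$estimate))),
       ci = unname(tt$conf.int), p = tt$p.value,
       n = c(length(a), length(b)))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sum of hypergeometric probabilities not exceeding the observed
#' table's probability (the usual two-sided convention).
#'
#' @param a,b,c,d the 2x2 cell counts (row-wise).
#' @return The two-sided p-value.
#' @export
fisherExact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (sum(counts) == 0L) stop("all margins are zero")
  fisher.test(matrix(counts, 2, byrow = TRUE))$p.value
}

#' Exact McNemar test on discordant pairs
#'
#' Exact binomial two-sided p on `min(b, c)` with `n = b + c` and null
#' probability 0.5. Without discordant pairs (`b + c = 0`) the
#' comparison is undefined and `NA` is returned.
#'
#' @param b,c the discordant-pair counts.
#' @return The exact p-value, or `NA` when `b + c = 0`.
#' @export
mcnemarExact <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("discordant counts must be non-negative integers")
  n <- b + c
  if (n == 0) return(NA_real_)
  binom.test(min(b, c), n, p = 0.5)$p.value
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; p via the t transform with df = n - 2.
#'
#' @param x,y numeric vectors (n >= 3, complete pairs used).
#' @return list with `r`, `p`, `n`.
#' @export
pearsonR <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' ICC(2,1): two-way random effects, absolute agreement, single rater
#'
#' From the two-way ANOVA decomposition (subjects x raters):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the F-based confidence interval of McGraw & Wong.
#'
#' @param ratings n x k matrix (subjects in rows, raters in columns,
#'   complete).
#' @param conf confidence level.
#' @return list with `icc`, `ci`, `n`, `k`.
#' @export
iccAbsoluteAgreement <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("ratings must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L || k < 2L) stop("need at least 5 subjects and 2 raters")
  G <- mean(ratings)
  Si <- rowMeans(ratings); Rj <- colMeans(ratings)
  MSR <- k * sum((Si - G)^2) / (n - 1)
  MSC <- n * sum((Rj - G)^2) / (k - 1)
  SSE <- sum((sweep(sweep(ratings, 1L, Si), 2L, Rj) + G)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= 0) stop("zero between-subject variance")
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  icc <- (MSR - MSE) / denom

  alpha <- 1 - conf
  if (MSE <= .Machine$double.eps * MSR) {
    ci <- c(icc, icc)  # degenerate: perfect agreement
  } else {
    aa <- k * icc / (n * (1 - icc))
    bb <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (aa * MSC + bb * MSE)^2 /
      ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci = ci, n = n, k = k)
}
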