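## Generalized extreme studentized deviate (GESD) outlier detection and the
## binary gene x patient outlier matrix built from it.

#' GESD test parameters
#'
#' @param alpha simultaneous significance level of the test (default 0.05).
#' @param maxOutliers upper bound `r` on the number of outliers per gene;
#'   `NULL` means `max(2, ceiling(n / 4))`, chosen so the outlier matrix
#'   stays sparse.
#' @param twoSided flag deviations in both directions (default `TRUE`).
#' @param logTransform apply `log2(x + 1)` before testing (default `TRUE`);
#'   GESD assumes approximate normality.
#' @return validated list of class `GesdParams`.
#' @export
gesdParams <- function(alpha = 0.05, maxOutliers = NULL, twoSided = TRUE,
                       logTransform = TRUE) {
  if (!(alpha > 0 && alpha < 1)) validationError("alpha must be in (0, 1)")
  if (!is.null(maxOutliers) && maxOutliers < 1)
    validationError("maxOutliers must be >= 1")
  out <- list(alpha = alpha, maxOutliers = maxOutliers,
              twoSided = twoSided, logTransform = logTransform)
  class(out) <- "GesdParams"
  out
}

#' Flag outliers in one vector with the GESD test
#'
#' Iteratively removes the most extreme studentized value. At step `i`
#' (testing on the remaining `n - i + 1` points) the statistic is
#' `R_i = max |x - mean| / sd`, and the critical value is
#' `lambda_i = (n - i) t / sqrt((n - i - 1 + t^2)(n - i + 1))` with
#' `t = qt(p, n - i - 1)` and `p = 1 - alpha / (2 (n - i + 1))` (two-sided).
#' The number of outliers is the largest `i` with `R_i > lambda_i`; the
#' first `i` removed points are flagged. A zero standard deviation stops the
#' iteration with the flags found so far.
#'
#' @param values numeric vector, length >= 4.
#' @param params a [gesdParams()] object.
#' @return integer vector of flagged indices (possibly empty) with an
#'   integer `direction` attribute (+1 above the running mean, -1 below).
#' @examples
#' gesdFlag(c(1, 2, 3, 4, 100))
#' @export
gesdFlag <- function(values, params = gesdParams()) {
  n <- length(values)
  if (n < 4) validationError("GESD needs at least 4 observations")
  if (any(!is.finite(values))) validationError("values must be finite")
  r <- params$maxOutliers
  if (is.null(r)) r <- max(2L, ceiling(n / 4))
  r <- as.integer(min(r, n - 3L))   # keep >= 3 points at the last step
  if (r < 1L) r <- 1L

  remaining <- seq_len(n)
  Rstat <- lambda <- numeric(r)
  removed <- dirs <- integer(r)
  steps <- 0L
  for (i in seq_len(r)) {
    x <- values[remaining]
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- if (params$twoSided) abs(x - m) else x - m
    j <- which.max(dev)
    Rstat[i] <- dev[j] / s
    removed[i] <- remaining[j]
    dirs[i] <- if (x[j] >= m) 1L else -1L
    ni <- n - i + 1
    p <- if (params$twoSided) 1 - params$alpha / (2 * ni)
         else 1 - params$alpha / ni
    tq <- stats::qt(p, df = n - i - 1)
    lambda[i] <- (n - i) * tq / sqrt((n - i - 1 + tq^2) * ni)
    remaining <- remaining[-j]
    steps <- i
  }
  k <- 0L
  if (steps > 0L) {
    exceed <- which(Rstat[seq_len(steps)] > lambda[seq_len(steps)])
    if (length(exceed)) k <- max(exceed)
  }
  out <- removed[seq_len(k)]
  attr(out, "direction") <- dirs[seq_len(k)]
  out
}

#' Build the expression-outlier matrix
#'
#' Applies [gesdFlag()] to every gene row of a normalized expression matrix
#' (after `log2(x + 1)` unless the matrix is already on the log2 scale or
#' `logTransform` is off). All-constant rows produce no flags.
#'
#' @param expr numeric matrix, genes x samples (>= 4 samples).
#' @param params a [gesdParams()] object.
#' @return an [OutlierMatrix-class].
#' @export
buildOutlierMatrix <- function(expr, params = gesdParams()) {
  if (ncol(expr) < 4)
    validationError("outlier detection needs at least 4 samples")
  n <- ncol(expr)
  r <- params$maxOutliers
  if (is.null(r)) r <- max(2L, ceiling(n / 4))
  r <- as.integer(min(r, n - 3L))
  doLog <- params$logTransform && !isTRUE(attr(expr, "log2"))

  mat <- matrix(0L, nrow(expr), n, dimnames = dimnames(expr))
  dir <- mat
  rowParams <- gesdParams(alpha = params$alpha, maxOutliers = r,
                          twoSided = params$twoSided, logTransform = FALSE)
  for (g in seq_len(nrow(expr))) {
    x <- expr[g, ]
    if (doLog) x <- log2(x + 1)
    if (all(x == x[1])) next
    fl <- gesdFlag(x, rowParams)
    if (length(fl)) {
      mat[g, fl] <- 1L
      dir[g, fl] <- attr(fl, "direction")
    }
  }
  methods::new("OutlierMatrix", mat = mat, direction = dir,
               maxOutliers = r)
}
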