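#' Confusion counts from continuous predictions
#'
#' Predictions at or above the threshold count as positive (ties go to the
#' positive class).
#'
#' @param preds Numeric predictions in (0, 1).
#' @param labels Class labels (`pos`/`neg`, 1/0 or logical).
#' @param threshold Decision threshold in (0, 1).
#' @return A list of class `ngn_confusion` with integer counts
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
ngn_confusion <- function(preds, labels, threshold = 0.5) {
  if (length(preds) != length(labels))
    stop("predictions and labels differ in length", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  y <- .as_posneg(labels)
  p <- ifelse(preds >= threshold, "pos", "neg")
  structure(list(tp = sum(p == "pos" & y == "pos"),
                 tn = sum(p == "neg" & y == "neg"),
                 fp = sum(p == "pos" & y == "neg"),
                 fn = sum(p == "neg" & y == "pos")),
            class = "ngn_confusion")
}

#' Classification statistics: concordance, sensitivity, specificity, MCC
#'
#' Concordance Q is the overall fraction of correct calls; sensitivity SE
#' the fraction of known positives called positive; specificity SP the
#' fraction of known negatives called negative; Matthews' correlation
#' coefficient balances all four counts in [-1, 1] and is defined as 0
#' whenever a factor of its denominator is 0.
#'
#' @param x An `ngn_confusion`, or a list/vector with `tp`, `tn`, `fp`, `fn`.
#' @return Named list with `Q`, `SE`, `SP`, `MCC` (proportions, not
#'   percentages).
#' @export
ngn_classification_metrics <- function(x) {
  tp <- x$tp; tn <- x$tn; fp <- x$fp; fn <- x$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(Q = (tp + tn) / total,
       SE = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       SP = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       MCC = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
}

#' Regression statistics: PRESS, SD and the q-squared score
#'
#' PRESS is the predictive residual sum of squares over the test set; SD
#' is the sum of squared deviations of the test *targets* from their own
#' mean (computed with respect to the test set only); the q-squared score
#' is PRESS normalized against SD, \eqn{q^2 = 1 - PRESS/SD}.  Unlike an
#' in-sample R-squared it can be arbitrarily negative.
#'
#' @param preds,targets Equal-length numeric vectors, length >= 2.
#' @return List with `press`, `sd`, `q2`.
#' @export
ngn_q2 <- function(preds, targets) {
  if (length(preds) != length(targets))
    stop("predictions and targets differ in length", call. = FALSE)
  if (length(targets) < 2L) stop("need at least 2 pairs", call. = FALSE)
  press <- sum((targets - preds)^2)
  sd <- sum((targets - mean(targets))^2)
  if (sd == 0)
    stop("q2 undefined: all targets identical (SD = 0)", call. = FALSE)
  list(press = press, sd = sd, q2 = 1 - press / sd)
}

#' Summed-residual Epsilon and its spread
#'
#' Epsilon is the per-trial sum of absolute residuals between normalized
#' targets and network outputs; smaller is better and Epsilon = 0 iff all
#' residuals vanish.  `epsilon_sd` is the sample standard deviation of the
#' absolute residuals (0 for a single pair).  `signed = TRUE` sums raw
#' residuals instead (so cancellation is possible).
#'
#' @param preds,targets Equal-length numeric vectors.
#' @param signed Use signed rather than absolute residuals.
#' @return List with `epsilon` and `epsilon_sd`.
#' @export
ngn_epsilon <- function(preds, targets, signed = FALSE) {
  if (length(preds) != length(targets))
    stop("predictions and targets differ in length", call. = FALSE)
  r <- targets - preds
  if (!signed) r <- abs(r)
  list(epsilon = sum(r),
       epsilon_sd = if (length(r) > 1L) stats::sd(r) else 0)
}

#' Pearson correlation between known values and estimates
#'
#' @param x,y Equal-length numeric vectors with nonzero variance.
#' @return The product-moment correlation coefficient in [-1, 1].
#' @export
ngn_cc <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Min-max normalization onto an output scale
#'
#' Maps values affinely so the dataset minimum lands on `lo` and the
#' maximum on `hi`:
#' \eqn{v \mapsto lo + (hi - lo)(v - \min) / (\max - \min)}.
#' This is the scaling applied to activities (e.g. LD50 values) before
#' they are used as network targets.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param lo,hi Target range, `lo < hi`.
#' @return Numeric vector of the same length.
#' @export
ngn_normalize <- function(values, lo = 0.2, hi = 0.8) {
  stopifnot(lo < hi)
  mn <- min(values); mx <- max(values)
  if (mx == mn)
    stop("cannot normalize: all values identical", call. = FALSE)
  lo + (hi - lo) * (values - mn) / (mx - mn)
}

#' Wilcoxon signed-rank test with exact small-sample enumeration
#'
#' Tests whether paired measurements differ systematically.  Zero
#' differences are dropped; tied absolute differences receive average
#' ranks.  For `n_used <= exact_limit` the null distribution of the
#' positive-rank sum W+ is obtained by exhaustive enumeration of all
#' 2^n sign patterns (valid under ties, unlike the classical exact
#' tables); above that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends to
#'   exceed b) or `"less"`.
#' @param exact_limit Largest `n_used` for exact enumeration.
#' @return List with `W` (positive-rank sum), `p`, `n_used`, `method`.
#' @export
ngn_wilcoxon <- function(a, b, alternative = c("two.sided", "greater", "less"),
                         exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("lengths differ", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("no information: all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    sums <- 0
    for (rk in r) sums <- c(sums, sums + rk)   # all 2^n sign patterns
    tol <- 1e-9
    p_ge <- mean(sums >= W - tol)
    p_le <- mean(sums <= W + tol)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- switch(alternative, two.sided = sign(W - mu) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (W - mu - cc) / sqrt(sig2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)))
    method <- "normal approximation"
  }
  list(W = W, p = p, n_used = n, method = method)
}

#' Label activities by a decision threshold
#'
#' Splits real-valued activities (e.g. pIC50) into positive and negative
#' classes at a threshold.  By convention activity at or above the
#' threshold is positive; `direction = "le"` inverts this for scales where
#' low values mean high activity.
#'
#' @param activities Finite numeric vector.
#' @param theta Threshold.
#' @param direction `"ge"` (default: activity >= theta is positive) or
#'   `"le"`.
#' @return Character vector of `"pos"`/`"neg"`.
#' @export
ngn_label_by_threshold <- function(activities, theta, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(activities)))
  pos <- if (direction == "ge") activities >= theta else activities <= theta
  ifelse(pos, "pos", "neg")
}
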