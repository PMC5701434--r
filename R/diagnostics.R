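#' Tabulate total scores into a histogram
#'
#' @param totals integer vector of total scores.
#' @param max_score largest attainable score; bins run 0..max_score.
#' @return an object of class \code{score_histogram}: list with
#'   \code{counts} (length max_score + 1, indexed by score 0..max_score) and
#'   \code{n} (total count).
#' @export
score_histogram <- function(totals, max_score) {
  max_score <- as.integer(max_score)
  if (is.na(max_score) || max_score < 0L)
    stop("`max_score` must be a nonnegative integer")
  if (length(totals)) {
    totals <- as.integer(totals)
    if (any(is.na(totals) | totals < 0L | totals > max_score))
      stop("totals must be integers in [0, max_score]")
  }
  counts <- tabulate(totals + 1L, nbins = max_score + 1L)
  structure(list(counts = counts, n = length(totals)),
            class = "score_histogram")
}

#' Turn counts (or an analytic pmf) into a score_histogram
#'
#' Accepts any nonnegative vector indexed from score 0 — observed counts,
#' expected counts, or raw probabilities — so the log-linearity fit can be
#' applied to noise-free oracle output as well as to simulated data.
#'
#' @param counts nonnegative numeric vector over scores 0..length-1.
#' @return a \code{score_histogram}.
#' @export
as_score_histogram <- function(counts) {
  if (inherits(counts, "score_histogram")) return(counts)
  if (inherits(counts, "total_pmf")) counts <- counts$probabilities
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be nonnegative and finite")
  structure(list(counts = as.numeric(counts), n = sum(counts)),
            class = "score_histogram")
}

#' @export
print.score_histogram <- function(x, ...) {
  cat(sprintf("<score_histogram> scores 0..%d, n = %g\n",
              length(x$counts) - 1L, x$n))
  invisible(x)
}

#' Write a score histogram as CSV (score,count)
#'
#' @param hist a \code{score_histogram}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_score_histogram <- function(hist, path) {
  hist <- as_score_histogram(hist)
  utils::write.csv(data.frame(score = seq_along(hist$counts) - 1L,
                              count = hist$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log-linear fit of a score histogram
#'
#' Quantifies the semi-log straight-line appearance of an exponential-like
#' score distribution: ordinary least squares of ln(count) on score. With
#' \code{range = "right_tail"} the fit starts at the modal score (the region
#' where the exponential pattern is expected to hold; low scores below the
#' mode are the part that departs from it); with \code{"full_range"} it
#' starts at score 0. Bins with count below \code{min_count} are excluded
#' (ln 0 is undefined and near-empty far-tail bins would dominate the fit
#' noise). Fewer than \code{min_bins} usable bins is an explicit error, not
#' a silent fit.
#'
#' By default the final bin — the instrument's maximum score — is also
#' excluded (\code{drop_ceiling}). On a bounded instrument that bin is
#' right-censored: it absorbs the entire latent tail beyond the highest
#' threshold, so when threshold spread pushes endorsement probabilities to 1
#' (most visibly under uniform thresholds, where all latent values above the
#' upper bound score the maximum) it carries an atom that belongs to the
#' censoring mechanism, not to the score distribution's log-linear law.
#' Under normal-family conditions the ceiling bin is essentially empty and
#' the default changes nothing.
#'
#' @param hist a \code{score_histogram}, a \code{total_pmf}, or a raw count
#'   vector indexed from score 0 (see [as_score_histogram()]).
#' @param range \code{"right_tail"} or \code{"full_range"}.
#' @param min_count smallest count a bin needs to enter the fit (default 5;
#'   use e.g. 1e-8 when fitting raw probabilities).
#' @param min_bins minimum number of usable bins (default 8).
#' @param drop_ceiling exclude the final (maximum-score, right-censored) bin
#'   from the fit (default TRUE).
#' @return an object of class \code{tail_fit}: list with \code{slope} (per
#'   score point, natural-log scale), \code{intercept}, \code{r_squared},
#'   \code{scores_used}, \code{n_bins_used}, \code{range}.
#' @export
#' @examples
#' counts <- round(5000 * exp(-0.3 * 0:30))
#' fit_log_linear(counts, "right_tail")$slope  # about -0.3
fit_log_linear <- function(hist, range = c("right_tail", "full_range"),
                           min_count = 5, min_bins = 8L,
                           drop_ceiling = TRUE) {
  range <- match.arg(range)
  hist <- as_score_histogram(hist)
  scores <- seq_along(hist$counts) - 1L
  start <- if (range == "right_tail") scores[which.max(hist$counts)] else 0L
  use <- scores >= start & hist$counts >= min_count
  if (drop_ceiling) use[length(use)] <- FALSE
  if (sum(use) < min_bins)
    stop(sprintf(
      "insufficient tail: only %d usable bins (count >= %g, score >= %d); need %d",
      sum(use), min_count, start, min_bins))
  x <- scores[use]
  y <- log(hist$counts[use])
  fit <- stats::lm(y ~ x)
  # R^2 computed directly: summary.lm warns on numerically perfect fits,
  # which exact geometric input legitimately produces
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else max(0, min(1, 1 - ssr / sst))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    scores_used = x,
    n_bins_used = length(x),
    range = range
  ), class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("<tail_fit> %s: slope %.4f, R^2 %.4f over %d bins (scores %d..%d)\n",
              x$range, x$slope, x$r_squared, x$n_bins_used,
              min(x$scores_used), max(x$scores_used)))
  invisible(x)
}

#' Serialize a tail fit to JSON
#'
#' @param fit a \code{tail_fit}.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
tail_fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "tail_fit"))
  js <- jsonlite::toJSON(unclass(fit), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Adjusted sample skewness
#'
#' Adjusted Fisher-Pearson standardized third moment:
#' g1 * sqrt(n (n - 1)) / (n - 2) with g1 = m3 / m2^(3/2). Positive values
#' indicate a long right tail; an Exp sample has population skewness 2.
#'
#' @param totals numeric vector, length >= 3, nonzero variance.
#' @return the adjusted skewness.
#' @export
#' @examples
#' sample_skewness(c(1, 2, 2, 3))  # 0
sample_skewness <- function(totals) {
  n <- length(totals)
  if (n < 3L) stop("need at least 3 observations")
  d <- totals - mean(totals)
  m2 <- mean(d^2)
  if (m2 == 0) stop("zero variance: skewness undefined")
  g1 <- mean(d^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
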