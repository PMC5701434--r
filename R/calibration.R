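#' Latent trait model: exponential severity
#'
#' The unobserved severity driving all question responses is modelled as
#' Exp(rate) on \code{[0, Inf)}: density rate * exp(-rate * x). Its standard
#' deviation is 1/rate, which is why the latent rate and the threshold
#' spread trade off against each other in the total-score shape.
#'
#' @param rate positive exponential rate (the parameter usually written
#'   lambda).
#' @return an object of class \code{latent_model}.
#' @export
latent_model <- function(rate) {
  if (!(is.numeric(rate) && length(rate) == 1L && is.finite(rate) && rate > 0))
    stop("`rate` must be a single positive number")
  structure(list(rate = as.numeric(rate)), class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> Exp(rate = %g), sd = %g\n", x$rate, 1 / x$rate))
  invisible(x)
}

#' Upper-tail quantile ("percentile point") of the exponential latent trait
#'
#' Returns the point t on the latent scale exceeded by a fraction p of the
#' population: P(X > t) = p for X ~ Exp(rate), i.e. t = -ln(p)/rate. This is
#' the percentile point that calibration assigns as a question's
#' threshold-distribution mean: a question endorsed by 5.49% of the
#' population gets mean -ln(0.0549) = 2.90 at rate 1.
#'
#' @param p prevalence, strictly in (0, 1); vectorized.
#' @param rate positive exponential rate.
#' @return nonnegative quantile(s) on the latent scale.
#' @export
#' @examples
#' round(exp_upper_quantile(0.0549, 1), 2)  # 2.90
exp_upper_quantile <- function(p, rate) {
  if (!(is.numeric(rate) && length(rate) == 1L && rate > 0))
    stop("`rate` must be a single positive number")
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0 | p >= 1))
    stop("`p` must lie strictly in (0, 1)")
  -log(p) / rate
}

#' Exponential survival function
#'
#' P(X > t) for X ~ Exp(rate); the inverse of [exp_upper_quantile()].
#'
#' @param t nonnegative quantile(s).
#' @param rate positive exponential rate.
#' @return survival probabilities.
#' @export
exp_survival <- function(t, rate) {
  if (!(is.numeric(rate) && length(rate) == 1L && rate > 0))
    stop("`rate` must be a single positive number")
  stats::pexp(t, rate = rate, lower.tail = FALSE)
}

#' Threshold distribution specification
#'
#' Thresholds are drawn independently per respondent and per question.
#' Two families are supported:
#' \describe{
#'   \item{normal}{each question q has its own mean (the calibrated
#'     percentile point) and a standard deviation \code{sd} shared across
#'     questions; \code{sd = 0} is the degenerate limit in which every
#'     respondent has the same threshold and calibration reproduces the
#'     prevalence exactly. Negative draws are kept: a threshold below 0 is
#'     always exceeded by the nonnegative latent trait.}
#'   \item{uniform}{a single Uniform(a, b) applied identically to every
#'     question; the regime in which endorsement probability grows linearly
#'     in the latent value and the total score mirrors the latent
#'     distribution over its whole range.}
#' }
#'
#' @param means numeric vector of per-question threshold means.
#' @param sd shared nonnegative standard deviation.
#' @param a,b uniform bounds, a < b.
#' @return an object of class \code{threshold_spec}.
#' @export
normal_thresholds <- function(means, sd) {
  if (!is.numeric(means) || length(means) < 1L || any(!is.finite(means)))
    stop("`means` must be a nonempty finite numeric vector")
  if (!(is.numeric(sd) && length(sd) == 1L && is.finite(sd) && sd >= 0))
    stop("`sd` must be a single nonnegative number")
  structure(list(family = "normal", means = as.numeric(means),
                 sd = as.numeric(sd)),
            class = "threshold_spec")
}

#' @rdname normal_thresholds
#' @export
uniform_thresholds <- function(a = 0, b = 5) {
  if (!(is.numeric(a) && is.numeric(b) && length(a) == 1L &&
        length(b) == 1L && is.finite(a) && is.finite(b) && a < b))
    stop("require finite bounds with a < b")
  structure(list(family = "uniform", a = as.numeric(a), b = as.numeric(b)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  if (x$family == "normal")
    cat(sprintf("<threshold_spec> normal, %d question means, sd = %g\n",
                length(x$means), x$sd))
  else
    cat(sprintf("<threshold_spec> uniform(%g, %g), all questions\n", x$a, x$b))
  invisible(x)
}

n_spec_questions <- function(spec, default = NULL) {
  if (spec$family == "normal") length(spec$means)
  else if (!is.null(default)) default
  else stop("uniform threshold_spec carries no question count; supply one")
}

#' Calibrate threshold means to a prevalence table
#'
#' Maps each question's prevalence p to the latent-scale percentile point
#' -ln(p)/rate and uses it as the mean of that question's normal threshold
#' distribution with shared standard deviation \code{sd}. With \code{sd = 0}
#' the simulated endorsement probability of each question equals its table
#' prevalence exactly.
#'
#' @param prevalence a \code{prevalence_table} (see
#'   [generate_prevalence_table()]).
#' @param latent a [latent_model()].
#' @param sd shared nonnegative threshold standard deviation.
#' @return a normal-family [normal_thresholds()] spec, with the calibration
#'   table attached as attribute \code{"calibration"} (columns item,
#'   question, prevalence, threshold_mean).
#' @export
#' @examples
#' pt <- generate_prevalence_table(cisr_instrument(), seed = 1)
#' spec <- calibrate_thresholds(pt, latent_model(1), sd = 2)
#' head(attr(spec, "calibration"))
calibrate_thresholds <- function(prevalence, latent, sd) {
  stopifnot(inherits(latent, "latent_model"))
  validate_prevalence(prevalence)
  means <- exp_upper_quantile(prevalence$prevalence, latent$rate)
  spec <- normal_thresholds(means, sd)
  attr(spec, "calibration") <- data.frame(
    item = prevalence$item,
    question = prevalence$question,
    prevalence = prevalence$prevalence,
    threshold_mean = means,
    stringsAsFactors = FALSE
  )
  spec
}

#' Write calibrated threshold means as CSV
#'
#' Columns \code{item,question,prevalence,threshold_mean}.
#'
#' @param spec a calibrated [normal_thresholds()] spec (from
#'   [calibrate_thresholds()]).
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_calibration <- function(spec, path) {
  cal <- attr(spec, "calibration")
  if (is.null(cal)) stop("spec carries no calibration table")
  out <- cal
  out$prevalence <- sprintf("%.6f", out$prevalence)
  out$threshold_mean <- sprintf("%.10g", out$threshold_mean)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Marginal endorsement probability of one question
#'
#' Closed form for P(X > T) where X ~ Exp(rate) is the latent trait and
#' T ~ Normal(mean, sd^2) is the question's threshold, independent of X.
#' Since X >= 0, a negative threshold is always exceeded, so
#' \deqn{P = \Phi(-\mu/\sigma) + e^{\lambda^2\sigma^2/2 - \lambda\mu}
#'       \Phi(\mu/\sigma - \lambda\sigma).}
#' At sd = 0 this degenerates to exp(-rate * max(mean, 0)) (probability 1
#' when the fixed threshold is negative), which is the calibration identity:
#' a mean set to the percentile point of p recovers prevalence p exactly.
#'
#' @param mean threshold mean (vectorized).
#' @param sd nonnegative threshold standard deviation.
#' @param rate positive exponential rate of the latent trait.
#' @return endorsement probability in \code{[0, 1]}.
#' @export
#' @examples
#' p <- 0.0549
#' marginal_item_prevalence(exp_upper_quantile(p, 1), sd = 0, rate = 1)  # p
marginal_item_prevalence <- function(mean, sd, rate) {
  if (!(is.numeric(sd) && length(sd) == 1L && is.finite(sd) && sd >= 0))
    stop("`sd` must be a single nonnegative number")
  if (!(is.numeric(rate) && length(rate) == 1L && is.finite(rate) && rate > 0))
    stop("`rate` must be a single positive number")
  if (!is.numeric(mean) || any(!is.finite(mean)))
    stop("`mean` must be finite numeric")
  if (sd == 0) return(exp(-rate * pmax(mean, 0)))
  # log-space second term avoids overflow of exp(rate^2 sd^2 / 2) at large
  # rate * sd, where the Gaussian tail factor is correspondingly tiny
  term1 <- stats::pnorm(-mean / sd)
  log_term2 <- rate^2 * sd^2 / 2 - rate * mean +
    stats::pnorm(mean / sd - rate * sd, log.p = TRUE)
  pmin(1, term1 + exp(log_term2))
}
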