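#' Simulation configuration
#'
#' Bundles everything one Monte-Carlo condition needs: the latent trait
#' model, the threshold family and its spread, the sample size and the seed.
#' For the normal family the per-question means are derived at run time by
#' [calibrate_thresholds()] from the prevalence table handed to
#' [simulate_condition()].
#'
#' @param rate positive exponential rate of the latent trait.
#' @param family \code{"normal"} or \code{"uniform"}.
#' @param sd shared threshold standard deviation (normal family).
#' @param a,b uniform threshold bounds (uniform family).
#' @param n number of simulated respondents (default 10000, the size of the
#'   population surveys the simulation emulates).
#' @param seed integer seed; every draw in [simulate_condition()] comes from
#'   one stream seeded with it.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(rate, family = c("normal", "uniform"),
                       sd = NULL, a = 0, b = 5, n = 10000L, seed = 1L) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (family == "normal") {
    if (!(is.numeric(sd) && length(sd) == 1L && sd >= 0))
      stop("normal family needs a single nonnegative `sd`")
  } else {
    if (!(a < b)) stop("uniform family needs a < b")
  }
  structure(list(latent = latent_model(rate), family = family,
                 sd = if (family == "normal") as.numeric(sd) else NULL,
                 a = if (family == "uniform") a else NULL,
                 b = if (family == "uniform") b else NULL,
                 n = n, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> rate = %g, %s thresholds (%s), n = %d, seed = %d\n",
              x$latent$rate, x$family,
              if (x$family == "normal") sprintf("sd = %g", x$sd)
              else sprintf("a = %g, b = %g", x$a, x$b),
              x$n, x$seed))
  invisible(x)
}

#' Draw latent severities
#'
#' i.i.d. Exp(rate) draws from the current RNG stream; nonnegative, mean
#' 1/rate, standard deviation 1/rate.
#'
#' @param n number of respondents.
#' @param latent a [latent_model()].
#' @return numeric vector of length n.
#' @export
draw_latent <- function(n, latent) {
  stopifnot(inherits(latent, "latent_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  stats::rexp(n, rate = latent$rate)
}

#' Draw per-respondent, per-question thresholds
#'
#' Normal family: entry (r, q) ~ Normal(means[q], sd^2), independent over
#' respondents and questions (local independence); negative draws are kept.
#' Uniform family: i.i.d. Uniform(a, b) for every entry.
#'
#' @param n number of respondents.
#' @param spec a [normal_thresholds()] or [uniform_thresholds()] spec.
#' @param n_questions question count; required for the uniform family,
#'   defaults to \code{length(spec$means)} for the normal family.
#' @return n x n_questions numeric matrix.
#' @export
draw_thresholds <- function(n, spec, n_questions = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  q <- n_spec_questions(spec, n_questions)
  if (spec$family == "normal") {
    # one rnorm call per question keeps draws column-contiguous and makes
    # the stream layout independent of n
    m <- matrix(stats::rnorm(n * q, mean = rep(spec$means, each = n),
                             sd = spec$sd), nrow = n, ncol = q)
  } else {
    m <- matrix(stats::runif(n * q, spec$a, spec$b), nrow = n, ncol = q)
  }
  m
}

#' Score questions by strict latent-versus-threshold comparison
#'
#' A question is endorsed (scored 1) when the respondent's latent value
#' strictly exceeds that question's threshold; ties score 0 (they have
#' probability zero under the continuous model).
#'
#' @param latent numeric vector of n latent values.
#' @param thresholds n x Q threshold matrix.
#' @return n x Q integer 0/1 matrix.
#' @export
score_binary <- function(latent, thresholds) {
  if (!is.matrix(thresholds) || length(latent) != nrow(thresholds))
    stop("`thresholds` must be a matrix with one row per latent value")
  m <- (latent > thresholds)
  storage.mode(m) <- "integer"
  m
}

#' Simulate one condition of the scoring process
#'
#' Runs the full process model: draw n latent severities from Exp(rate),
#' draw an independent threshold for every respondent-question pair
#' (normal means calibrated to the prevalence table, or uniform), endorse
#' each question whose threshold the latent value strictly exceeds, and sum
#' endorsements into a total score per respondent. All randomness comes from
#' a single stream seeded by \code{config$seed}, so results are fully
#' reproducible; the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @param inst an [instrument]; defaults to [cisr_instrument()].
#' @param prevalence a prevalence table matching the instrument's questions;
#'   required for the normal family (ignored by the uniform family).
#'   Defaults to [fixture_prevalence_table()] for the default instrument.
#' @return an object of class \code{sim_result} with elements
#'   \code{totals} (integer vector of length n), \code{scores} (n x Q binary
#'   matrix), \code{empirical_prevalence} (per-question endorsement
#'   proportions), \code{thresholds_spec}, and \code{config}.
#' @export
#' @examples
#' res <- simulate_condition(sim_config(1, "normal", sd = 2, n = 2000, seed = 7))
#' table(res$totals)[1:5]
simulate_condition <- function(config, inst = cisr_instrument(),
                               prevalence = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(inst, "instrument"))
  q <- sum(inst$n_questions)
  if (config$family == "normal") {
    if (is.null(prevalence)) prevalence <- fixture_prevalence_table(inst)
    validate_prevalence(prevalence, inst)
    spec <- calibrate_thresholds(prevalence, config$latent, config$sd)
  } else {
    spec <- uniform_thresholds(config$a, config$b)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  x <- draw_latent(config$n, config$latent)
  thr <- draw_thresholds(config$n, spec, n_questions = q)
  sc <- score_binary(x, thr)
  totals <- as.integer(rowSums(sc))
  structure(list(
    totals = totals,
    scores = sc,
    empirical_prevalence = colMeans(sc),
    thresholds_spec = spec,
    instrument = inst,
    config = config
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> n = %d respondents, %d questions, seed = %d\n",
              length(x$totals), ncol(x$scores), x$config$seed))
  cat(sprintf("  totals: mean %.3f, max %d (instrument max %d)\n",
              mean(x$totals), max(x$totals), max_total_score(x$instrument)))
  invisible(x)
}

#' Export a simulation result
#'
#' Writes respondent totals (\code{respondent,total}), the score histogram
#' (\code{score,count}) and a JSON echo of the configuration.
#'
#' @param result a \code{sim_result}.
#' @param totals_path,hist_path,config_path file paths; any may be NULL to
#'   skip that artifact.
#' @return invisibly, a list of the paths written.
#' @export
write_sim_result <- function(result, totals_path = NULL, hist_path = NULL,
                             config_path = NULL) {
  stopifnot(inherits(result, "sim_result"))
  written <- list()
  if (!is.null(totals_path)) {
    utils::write.csv(data.frame(respondent = seq_along(result$totals),
                                total = result$totals),
                     totals_path, row.names = FALSE, quote = FALSE)
    written$totals <- totals_path
  }
  if (!is.null(hist_path)) {
    h <- score_histogram(result$totals, max_total_score(result$instrument))
    write_score_histogram(h, hist_path)
    written$histogram <- hist_path
  }
  if (!is.null(config_path)) {
    cfg <- result$config
    echo <- list(rate = cfg$latent$rate, family = cfg$family, sd = cfg$sd,
                 a = cfg$a, b = cfg$b, n = cfg$n, seed = cfg$seed)
    jsonlite::write_json(echo[!vapply(echo, is.null, logical(1))],
                         config_path, auto_unbox = TRUE, digits = NA)
    written$config <- config_path
  }
  invisible(written)
}
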