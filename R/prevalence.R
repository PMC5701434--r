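#' Generate a synthetic per-question prevalence table
#'
#' Draws one endorsement probability per question, log-uniformly on
#' \code{[p_min, p_max]}. General-population endorsement rates of individual
#' depressive-symptom questions are right-skewed and span roughly 1--35%,
#' which the log-uniform draw emulates. Values are rounded to 6 decimal
#' places so CSV round trips are exact.
#'
#' @param inst an [instrument]; one prevalence row is produced per question.
#' @param seed integer seed; the table is deterministic given the seed.
#' @param p_min,p_max prevalence bounds, 0 < p_min < p_max < 1.
#' @return A \code{prevalence_table}: data frame with columns \code{item},
#'   \code{question} (1-based within item) and \code{prevalence}.
#' @export
#' @examples
#' pt <- generate_prevalence_table(cisr_instrument(), seed = 1)
#' range(pt$prevalence)
generate_prevalence_table <- function(inst, seed,
                                      p_min = 0.01, p_max = 0.35) {
  stopifnot(inherits(inst, "instrument"))
  if (!(is.numeric(p_min) && is.numeric(p_max) &&
        p_min > 0 && p_max < 1 && p_min < p_max))
    stop("require 0 < p_min < p_max < 1")
  qi <- question_index(inst)
  nq <- nrow(qi)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  p <- exp(stats::runif(nq, log(p_min), log(p_max)))
  qi$prevalence <- round(p, 6)
  class(qi) <- c("prevalence_table", "data.frame")
  qi
}

#' The committed synthetic prevalence fixture for the CIS-R-like instrument
#'
#' Returns the 57-row prevalence table shipped with the package. It is a
#' synthetic stand-in for general-population endorsement rates of the 57
#' CIS-R questions: the first question of "somatic symptoms" is pinned to
#' the published 5.49% rate, and the remaining 56 values were generated once
#' by [generate_prevalence_table()] (seed 20200817) and committed. No claim
#' is made that those 56 values match any survey.
#'
#' @param inst the CIS-R-like instrument (defaults to [cisr_instrument()]);
#'   supplied instruments must have the same question layout.
#' @return a \code{prevalence_table} with 57 rows; row 1 has prevalence
#'   exactly 0.0549.
#' @export
fixture_prevalence_table <- function(inst = cisr_instrument()) {
  path <- system.file("extdata", "prevalence_cisr_synthetic.csv",
                      package = "latentexp", mustWork = TRUE)
  pt <- read_prevalence_table(path)
  qi <- question_index(inst)
  if (nrow(qi) != nrow(pt) || !identical(qi$item, pt$item) ||
      !identical(qi$question, pt$question))
    stop("instrument does not match the 57-question fixture layout")
  pt
}

validate_prevalence <- function(pt, inst = NULL) {
  stopifnot(is.data.frame(pt),
            all(c("item", "question", "prevalence") %in% names(pt)))
  if (any(pt$prevalence <= 0 | pt$prevalence >= 1))
    stop("prevalence values must lie strictly in (0, 1)")
  if (!is.null(inst) && nrow(pt) != sum(inst$n_questions))
    stop("prevalence table must have one row per instrument question")
  invisible(pt)
}

#' Write / read a prevalence table as CSV
#'
#' Plain UTF-8 CSV with header \code{item,question,prevalence}, '.' decimal
#' separator, prevalence printed with six decimals so that a round trip
#' reproduces the stored values exactly.
#'
#' @param pt a \code{prevalence_table}.
#' @param path file path.
#' @return \code{write_prevalence_table} returns \code{path} invisibly;
#'   \code{read_prevalence_table} returns a \code{prevalence_table}.
#' @export
write_prevalence_table <- function(pt, path) {
  validate_prevalence(pt)
  out <- data.frame(
    item = pt$item,
    question = pt$question,
    prevalence = sprintf("%.6f", pt$prevalence),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_prevalence_table
#' @export
read_prevalence_table <- function(path) {
  pt <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(item = "character",
                                       question = "integer",
                                       prevalence = "numeric"))
  validate_prevalence(pt)
  class(pt) <- c("prevalence_table", "data.frame")
  pt
}
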