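#' Define a binary-question symptom instrument
#'
#' An instrument is an ordered set of items, each evaluated through one or
#' more binary (0/1) questions. Every endorsed question contributes a single
#' point to the total score, so the total ranges from 0 to the number of
#' questions.
#'
#' @param items character vector of item names.
#' @param n_questions integer vector, one entry per item, each >= 1: the
#'   number of binary questions probing that item.
#'
#' @return An object of class \code{instrument}: a data frame with columns
#'   \code{item} and \code{n_questions}.
#' @seealso [cisr_instrument()] for the 14-item, 57-question default.
#' @export
#' @examples
#' toy <- instrument(c("a", "b"), c(3, 3))
#' max_total_score(toy)  # 6
instrument <- function(items, n_questions) {
  if (length(items) != length(n_questions))
    stop("`items` and `n_questions` must have the same length")
  n_questions <- as.integer(n_questions)
  if (length(n_questions) && any(is.na(n_questions) | n_questions < 1L))
    stop("every item must have at least one question")
  if (anyDuplicated(items))
    stop("item names must be unique")
  out <- data.frame(
    item = as.character(items),
    n_questions = n_questions,
    stringsAsFactors = FALSE
  )
  class(out) <- c("instrument", "data.frame")
  out
}

#' The CIS-R-like instrument: 14 items, 57 binary questions
#'
#' The Revised Clinical Interview Schedule (CIS-R) measures depressive and
#' neurotic symptoms through 14 negative-symptom items. Each item is assessed
#' by four binary questions (depressive ideas by five), every endorsed
#' question adding one point, so the total score runs from 0 to 57.
#'
#' @return An [instrument] with 14 items and 57 questions in the standard
#'   item order (somatic symptoms through obsessions).
#' @export
#' @examples
#' inst <- cisr_instrument()
#' nrow(inst)               # 14
#' max_total_score(inst)    # 57
cisr_instrument <- function() {
  items <- c(
    "somatic symptoms", "fatigue", "concentration", "sleep",
    "irritability", "worry about physical health", "depression",
    "depressive ideas", "worry", "anxiety", "phobias", "panic",
    "compulsions", "obsessions"
  )
  nq <- rep(4L, 14L)
  nq[items == "depressive ideas"] <- 5L
  instrument(items, nq)
}

#' Total number of scoring thresholds in an instrument
#'
#' Each binary question has a single threshold on the latent scale; a k-point
#' Likert question would have k - 1. The count is the number of questions
#' times the per-question multiplier. For the CIS-R-like instrument with
#' binary questions this is 57; a 16-item scale with one four-point question
#' per item (CES-D-like) has 16 x 3 = 48.
#'
#' @param inst an [instrument].
#' @param thresholds_per_question positive integer multiplier (1 for binary
#'   questions, k - 1 for k-point questions).
#' @return integer threshold count.
#' @export
#' @examples
#' count_thresholds(cisr_instrument(), 1)                 # 57
#' count_thresholds(instrument(letters[1:16], rep(1, 16)), 3)  # 48
count_thresholds <- function(inst, thresholds_per_question = 1L) {
  stopifnot(inherits(inst, "instrument"))
  m <- as.integer(thresholds_per_question)
  if (length(m) != 1L || is.na(m) || m < 1L)
    stop("`thresholds_per_question` must be a single positive integer")
  sum(inst$n_questions) * m
}

#' Maximum attainable total score
#'
#' Equals the total question count: every question endorsed scores 1.
#'
#' @param inst an [instrument].
#' @return integer maximum total score.
#' @export
max_total_score <- function(inst) {
  stopifnot(inherits(inst, "instrument"))
  sum(inst$n_questions)
}

#' Question-level index of an instrument
#'
#' Expands an instrument to one row per question, with 1-based question
#' labels within each item. Used as the join key for prevalence tables and
#' calibrated threshold means.
#'
#' @param inst an [instrument].
#' @return data frame with columns \code{item} and \code{question}
#'   (integer, 1-based within item), one row per question.
#' @export
question_index <- function(inst) {
  stopifnot(inherits(inst, "instrument"))
  data.frame(
    item = rep(inst$item, inst$n_questions),
    question = unlist(lapply(inst$n_questions, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf("<instrument> %d items, %d binary questions (total score 0-%d)\n",
              nrow(x), sum(x$n_questions), sum(x$n_questions)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Serialize an instrument to JSON
#'
#' @param inst an [instrument].
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
instrument_to_json <- function(inst, path = NULL) {
  stopifnot(inherits(inst, "instrument"))
  js <- jsonlite::toJSON(
    lapply(seq_len(nrow(inst)), function(i)
      list(name = inst$item[i], n_questions = inst$n_questions[i])),
    auto_unbox = TRUE, pretty = TRUE
  )
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read an instrument from JSON
#'
#' @param path file path or JSON string as written by [instrument_to_json()].
#' @return an [instrument].
#' @export
instrument_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  instrument(x$name, x$n_questions)
}
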