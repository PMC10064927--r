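#' System Usability Scale score
#'
#' Standard SUS scoring of the 10-item alternating-tone questionnaire:
#' odd (positively worded) items contribute `item - 1`, even (negatively
#' worded) items contribute `5 - item`, and the sum of contributions is
#' scaled by 2.5 to a 0--100 score.
#'
#' @param items Integer vector of exactly 10 Likert responses in 1..5,
#'   ordered item 1..10.
#' @return Score in 0..100.
#' @export
sus_score <- function(items) {
  if (length(items) != 10L) stopf("SUS needs exactly 10 item responses")
  if (any(items != round(items)) || any(items < 1 | items > 5))
    stopf("SUS items must be integers in 1..5")
  odd <- items[c(1, 3, 5, 7, 9)]
  even <- items[c(2, 4, 6, 8, 10)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

# Sauro-Lewis curved grading scale: lower bound of each mark's score bin.
sus_grade_bins <- data.frame(
  mark = c("F", "D", "C-", "C", "C+", "B-", "B", "B+", "A-", "A", "A+"),
  lower = c(0, 51.7, 62.7, 65.0, 71.1, 72.6, 74.1, 77.2, 78.9, 80.8, 84.1),
  stringsAsFactors = FALSE)

#' Curved-grading mark for a SUS score
#'
#' Maps a 0--100 SUS score to a letter mark on the Sauro--Lewis curved
#' grading scale, whose bins are calibrated to the empirical distribution
#' of SUS scores across products (C centered near the global mean of 68):
#' A+ >= 84.1, A 80.8--84.0, A- 78.9--80.7, B+ 77.2--78.8, B 74.1--77.1,
#' B- 72.6--74.0, C+ 71.1--72.5, C 65.0--71.0, C- 62.7--64.9, D 51.7--62.6,
#' F < 51.7.
#'
#' @param score Numeric score(s) in 0..100.
#' @return Character mark(s).
#' @export
sus_grade <- function(score) {
  if (any(score < 0 | score > 100)) stopf("SUS score must be in 0..100")
  sus_grade_bins$mark[findInterval(score, sus_grade_bins$lower)]
}

#' Summarize SUS scores for a cohort of experts
#'
#' @param scores Data frame with columns `expert` and `score`, or a named
#'   numeric vector.
#' @return List with `per_expert` (data frame `expert`, `score`, `mark`),
#'   `mean_score` (arithmetic mean, rounded to 1 decimal) and
#'   `overall_mark` (grade of the mean).
#' @export
sus_cohort_summary <- function(scores) {
  if (is.numeric(scores))
    scores <- data.frame(expert = names(scores) %||% paste0("expert", seq_along(scores)),
                         score = as.numeric(scores), stringsAsFactors = FALSE)
  if (nrow(scores) == 0L) stopf("no scores given")
  per <- data.frame(expert = scores$expert, score = scores$score,
                    mark = sus_grade(scores$score), stringsAsFactors = FALSE)
  m <- round(mean(scores$score), 1)
  list(per_expert = per, mean_score = m, overall_mark = sus_grade(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read SUS questionnaire responses or scores from CSV
#'
#' Accepts either raw responses (`expert,i1..i10`, scored via
#' [sus_score()]) or pre-computed scores (`expert,score`).
#'
#' @param path CSV path.
#' @return Data frame with columns `expert` and `score`.
#' @export
read_sus_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("score" %in% names(df))
    return(data.frame(expert = as.character(df$expert), score = as.numeric(df$score),
                      stringsAsFactors = FALSE))
  item_cols <- paste0("i", 1:10)
  if (!all(item_cols %in% names(df)))
    stopf("SUS CSV needs either a 'score' column or item columns i1..i10")
  scores <- vapply(seq_len(nrow(df)), function(r) {
    tryCatch(sus_score(as.numeric(df[r, item_cols])),
             error = function(e) stopf("row %d: %s", r, conditionMessage(e)))
  }, numeric(1))
  data.frame(expert = as.character(df$expert), score = scores,
             stringsAsFactors = FALSE)
}
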