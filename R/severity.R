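# Lexicon-based severity grading of interaction sentences. Matched token
# polarities are averaged; negative polarity marks a dangerous (high-severity)
# interaction, positive polarity an advantageous (low-severity) one.

#' Load a polarity lexicon from TSV
#'
#' Expects two tab-separated columns, `token` and `score`, with scores in
#' `[-1, 1]`. Tokens are lower-cased on load and must be unique. An optional
#' header line `token<TAB>score` is skipped.
#'
#' @param path Path to the lexicon TSV.
#' @return Named numeric vector (class `polarity_lexicon`) mapping token to
#'   polarity score.
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  start <- 1L
  if (length(lines) > 0L && grepl("^token\t", lines[1L])) start <- 2L
  tokens <- character(0)
  scores <- numeric(0)
  for (ln in seq.int(start, length.out = max(0L, length(lines) - start + 1L))) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 2L) {
      stop_input("line ", ln, ": expected 'token<TAB>score', got ",
                 length(fields), " field(s)")
    }
    sc <- suppressWarnings(as.numeric(fields[2L]))
    if (is.na(sc)) stop_input("line ", ln, ": score '", fields[2L],
                              "' is not numeric")
    if (sc < -1 || sc > 1) {
      stop_input("line ", ln, ": score ", sc, " outside [-1, 1]")
    }
    tok <- tolower(trimws(fields[1L]))
    if (tok %in% tokens) stop_input("line ", ln, ": duplicate token '", tok, "'")
    tokens <- c(tokens, tok)
    scores <- c(scores, sc)
  }
  structure(stats::setNames(scores, tokens), class = "polarity_lexicon")
}

#' Bundled demonstration lexicon
#'
#' A small pharmacovigilance-flavoured polarity lexicon shipped with the
#' package, for examples and tests. It is a hand-written demonstration table,
#' not an import of SentiWordNet or any published lexicon.
#'
#' @return A `polarity_lexicon`.
#' @export
demo_lexicon <- function() {
  load_lexicon(system.file("extdata", "polarity_lexicon.tsv",
                           package = "ssoddi", mustWork = TRUE))
}

#' Polarity score of a token sequence
#'
#' Mean polarity of the tokens found in the lexicon; unmatched tokens are
#' ignored. A sentence with no lexicon hit scores 0 with `n_matched = 0`.
#'
#' @param tokens Character vector (lower-cased; [clean_tokens()] does this).
#' @param lexicon A [load_lexicon()] result.
#' @return List with `score` in `[-1, 1]` and `n_matched`.
#' @export
polarity_score <- function(tokens, lexicon) {
  stopifnot(is.character(tokens), inherits(lexicon, "polarity_lexicon"))
  hits <- unclass(lexicon)[tokens]
  hits <- hits[!is.na(hits)]
  if (length(hits) == 0L) return(list(score = 0, n_matched = 0L))
  list(score = mean(hits), n_matched = length(hits))
}

#' Map a polarity score to a severity grade
#'
#' Scores below `t_low` grade as a high-severity, dangerous interaction;
#' scores above `t_high` as low-severity, advantageous; scores between as
#' moderate, neutral. Defaults split `[-1, 1]` into symmetric thirds.
#'
#' @param score Polarity in `[-1, 1]`.
#' @param thresholds Numeric pair `(t_low, t_high)` with
#'   `-1 <= t_low < t_high <= 1`. Default `c(-1/3, 1/3)`.
#' @return List with `level` (`"low"`, `"moderate"`, `"high"`) and `direction`
#'   (`"advantageous"`, `"neutral"`, `"dangerous"`).
#' @export
#' @examples
#' severity_class(-0.5) # high / dangerous
severity_class <- function(score, thresholds = c(-1 / 3, 1 / 3)) {
  if (length(thresholds) != 2L || !(thresholds[1L] >= -1) ||
      !(thresholds[2L] <= 1) || !(thresholds[1L] < thresholds[2L])) {
    stop_input("thresholds must satisfy -1 <= t_low < t_high <= 1")
  }
  if (score < thresholds[1L]) {
    list(level = "high", direction = "dangerous")
  } else if (score > thresholds[2L]) {
    list(level = "low", direction = "advantageous")
  } else {
    list(level = "moderate", direction = "neutral")
  }
}

#' Grade the severity of an interaction sentence
#'
#' Convenience wrapper: cleans the tokens, scores polarity against the
#' lexicon, and maps the score to a severity grade.
#'
#' @param tokens Character token vector (raw; cleaned internally).
#' @param lexicon A `polarity_lexicon`. Default [demo_lexicon()].
#' @param thresholds Passed to [severity_class()].
#' @return List with `polarity`, `level`, `direction`, `n_matched`.
#' @export
grade_severity <- function(tokens, lexicon = demo_lexicon(),
                           thresholds = c(-1 / 3, 1 / 3)) {
  ps <- polarity_score(clean_tokens(tokens, lemmatize = FALSE), lexicon)
  cl <- severity_class(ps$score, thresholds)
  list(polarity = ps$score, level = cl$level, direction = cl$direction,
       n_matched = ps$n_matched)
}
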