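# Mention extraction: run compiled rules over raw text and emit typed
# mentions with character offsets (0-based, half-open, over the concatenated
# document text — surface == substr(text, start + 1, end)).

.mr_mention_cols <- c(
  "doc_id", "kind", "start", "end", "surface", "rule_id",
  "sex_category", "sex_qualifier",
  "age_min", "age_max", "age_unit", "age_qualifier"
)

mr_empty_mentions <- function() {
  tibble::tibble(
    doc_id = character(), kind = character(),
    start = integer(), end = integer(),
    surface = character(), rule_id = character(),
    sex_category = character(), sex_qualifier = character(),
    age_min = double(), age_max = double(),
    age_unit = character(), age_qualifier = character()
  )
}

# collect candidate matches for all rules of one kind, then resolve overlaps
# leftmost-longest (ties at the same span go to the rule listed first)
.mr_match_kind <- function(text, ruleset, kind, doc_id = NA_character_) {
  stopifnot(inherits(ruleset, "mr_ruleset"))
  if (length(text) != 1 || is.na(text) || !nzchar(text)) {
    return(mr_empty_mentions())
  }
  rules <- ruleset$rules[ruleset$rules$kind == kind, ]
  if (nrow(rules) == 0) return(mr_empty_mentions())

  cand <- purrr::map_dfr(seq_len(nrow(rules)), function(i) {
    loc <- stringr::str_locate_all(
      text, stringr::regex(rules$pattern[i], ignore_case = TRUE)
    )[[1]]
    if (nrow(loc) == 0) return(NULL)
    tibble::tibble(start1 = loc[, 1], end1 = loc[, 2], rule_idx = i)
  })
  if (is.null(cand) || nrow(cand) == 0) return(mr_empty_mentions())

  cand <- cand[order(cand$start1, -(cand$end1 - cand$start1), cand$rule_idx), ]
  keep <- integer(0)
  last_end <- 0L
  for (r in seq_len(nrow(cand))) {
    if (cand$start1[r] > last_end) {
      keep <- c(keep, r)
      last_end <- cand$end1[r]
    }
  }
  cand <- cand[keep, ]

  out <- tibble::tibble(
    doc_id = doc_id,
    kind = kind,
    start = as.integer(cand$start1 - 1L),          # 0-based half-open
    end = as.integer(cand$end1),
    surface = stringr::str_sub(text, cand$start1, cand$end1),
    rule_id = rules$rule_id[cand$rule_idx],
    sex_category = NA_character_, sex_qualifier = NA_character_,
    age_min = NA_real_, age_max = NA_real_,
    age_unit = NA_character_, age_qualifier = NA_character_
  )
  if (kind == "sex") {
    out$sex_category <- rules$category[cand$rule_idx]
    out$sex_qualifier <- rules$qualifier[cand$rule_idx]
  } else {
    parsed <- purrr::map_dfr(out$surface, parse_age_phrase)
    out$age_min <- parsed$age_min
    out$age_max <- parsed$age_max
    out$age_unit <- parsed$age_unit
    out$age_qualifier <- parsed$age_qualifier
  }
  out[, .mr_mention_cols]
}

#' Match sex mentions in text
#'
#' Dictionary matching of sex phrases, case-insensitive over the raw text.
#' No inference is performed beyond the dictionary: sex implied only by proxy
#' words such as "pregnant" is not matched, while bare "male"/"female" tokens
#' match wherever they occur (including breeding-scheme sentences such as
#' "crossing male carriers with ... females" — a documented false-positive
#' class that the matcher reproduces rather than fixes).
#'
#' @param text A single character string (the concatenated document text).
#' @param rules A compiled `mr_ruleset` (see [compile_rules()]).
#' @param doc_id Optional document id recorded in the mentions.
#' @return A mention tibble sorted by `start`: columns `doc_id`, `kind`,
#'   `start`, `end` (0-based, half-open), `surface`, `rule_id`,
#'   `sex_category` (`female`/`male`/`both`), `sex_qualifier`.
#' @examples
#' rs <- compile_rules(default_rules())
#' match_sex_mentions("mice of either sex were used", rs)$sex_category
#' @export
match_sex_mentions <- function(text, rules, doc_id = NA_character_) {
  .mr_match_kind(text, rules, "sex", doc_id)
}

#' Match age mentions in text
#'
#' Lexical age patterns: a numeral (or numeral range) adjacent to a
#' day/week/month unit plus an age clue ("aged", "old", "of age", attributive
#' "-old" forms).  Open-ended spans without a closed numeric range
#' ("postnatal day (P) 7 to several months") are not matched — the documented
#' false-negative class.
#'
#' @inheritParams match_sex_mentions
#' @return A mention tibble sorted by `start` with parsed `age_min`,
#'   `age_max`, `age_unit` (`day`/`week`/`month`), `age_qualifier`
#'   (`exact`/`range`).
#' @examples
#' rs <- compile_rules(default_rules())
#' match_age_mentions("mice aged 3 to 8 weeks old were used", rs)
#' @export
match_age_mentions <- function(text, rules, doc_id = NA_character_) {
  .mr_match_kind(text, rules, "age", doc_id)
}

#' Parse the surface form of an age mention
#'
#' Extracts the numeral(s) (digits, decimals, or the number words
#' one...twelve), the range connector ("to", "-", en/em dash, "and") and the
#' time unit, normalizing unit forms (d/day/days to `day`; wk/wks/week/weeks
#' to `week`; mo/mos/month/months to `month`).  A single value yields
#' `age_min == age_max` with qualifier `exact`.
#'
#' @param surface A string produced by an age rule (e.g. `"6-8-weeks old"`).
#' @return A one-row tibble: `age_min`, `age_max`, `age_unit`,
#'   `age_qualifier`.
#' @examples
#' parse_age_phrase("6-8-weeks old")
#' parse_age_phrase("six weeks of age")
#' @export
parse_age_phrase <- function(surface) {
  stopifnot(is.character(surface), length(surface) == 1)
  s <- stringr::str_to_lower(surface)
  num_rx <- paste0("\\b(", .rx_dec, "|", .rx_numword, ")\\b")
  toks <- stringr::str_match_all(s, num_rx)[[1]][, 2]
  vals <- vapply(toks, function(t) {
    if (t %in% names(.mr_numwords)) unname(.mr_numwords[t]) else as.numeric(t)
  }, numeric(1))
  unit_tok <- stringr::str_extract(s, paste0("\\b", .rx_unit, "\\b"))
  if (length(vals) < 1 || length(vals) > 2 || is.na(unit_tok)) {
    stop("unparseable age surface (rule/capture mismatch): '", surface, "'",
         call. = FALSE)
  }
  unit <- switch(substr(unit_tok, 1, 1), d = "day", w = "week", m = "month")
  lo <- min(vals)
  hi <- max(vals)
  tibble::tibble(
    age_min = lo, age_max = hi, age_unit = unit,
    age_qualifier = if (lo == hi) "exact" else "range"
  )
}

#' Normalize an age value to days
#'
#' Declared conversion convention: 1 day = 1, 1 week = 7, 1 month = 30 days.
#'
#' @param age_min,age_max Non-negative numbers with `age_min <= age_max`.
#' @param age_unit `"day"`, `"week"` or `"month"`.
#' @return A named numeric vector `c(min_days, max_days)` (vectorized inputs
#'   return a two-column matrix-like tibble via [normalize_age_table()]).
#' @examples
#' normalize_age_to_days(6, 8, "week")
#' @export
normalize_age_to_days <- function(age_min, age_max, age_unit) {
  f <- c(day = 1, week = 7, month = 30)
  if (any(!age_unit %in% names(f))) {
    stop("unknown age unit: ", paste(setdiff(age_unit, names(f)), collapse = ", "),
         call. = FALSE)
  }
  if (any(age_min > age_max)) stop("age_min > age_max", call. = FALSE)
  k <- f[age_unit]
  if (length(age_min) == 1) {
    c(min_days = unname(age_min * k), max_days = unname(age_max * k))
  } else {
    tibble::tibble(min_days = unname(age_min * k),
                   max_days = unname(age_max * k))
  }
}

#' @rdname normalize_age_to_days
#' @param x A tibble with columns `age_min`, `age_max`, `age_unit`.
#' @export
normalize_age_table <- function(x) {
  if (nrow(x) == 0) {
    return(tibble::tibble(min_days = double(), max_days = double()))
  }
  f <- c(day = 1, week = 7, month = 30)
  k <- f[x$age_unit]
  tibble::tibble(min_days = unname(x$age_min * k),
                 max_days = unname(x$age_max * k))
}
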