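# Rule definitions and compilation for the sex/age mention matcher.
#
# Rules are plain data (a tibble: rule_id, kind, pattern, category, qualifier)
# so the shipped defaults can be inspected, edited, written to a TSV config and
# substituted wholesale by a user-supplied set.

# number words accepted inside age expressions (one..twelve; larger counts are
# virtually always written as digits in Methods sections)
.mr_numwords <- c(
  one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
  seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11, twelve = 12
)

# regex building blocks (ICU flavour via stringr); matching is always
# case-insensitive so fragments are written in lower case
.rx_numword <- paste(names(.mr_numwords), collapse = "|")
.rx_int <- "(?<![.\\d])\\d+"              # not the fractional part of 6.5
.rx_dec <- "(?<![.\\d])\\d+(?:\\.\\d+)?"
# day/week/month plus the short forms seen in Methods prose (15-d, 8 wk, 3 mo)
.rx_unit <- "(?:days?|weeks?|wks?|months?|mos?|d)"
# dash dialects: hyphen, non-breaking hyphen, figure dash, en dash, em dash
.rx_dash <- "[-‐‑‒–—]"
# joiner between a numeral and its unit ("8 weeks", "6-8-weeks", "15-d")
.rx_join <- paste0("(?:\\s|", .rx_dash, ")")
# range connector ("3 to 8", "6-8", "8–12", "6 and 8")
.rx_conn <- paste0("(?:\\s+(?:to|and)\\s+|\\s*", .rx_dash, "\\s*)")

.mr_num_rx <- function(decimal = FALSE) {
  paste0("(?:", if (decimal) .rx_dec else .rx_int, "|", .rx_numword, ")")
}

#' Default extraction rules for mouse sex and age mentions
#'
#' Builds the shipped rule set: dictionary rules for sex (categories
#' `female`, `male`, `both`) and lexical patterns for age.  Age patterns
#' require a numeral (digits or a number word up to twelve) adjacent to a
#' `day`/`week`/`month` unit *and* an age clue (`aged`, `old`, `of age`,
#' attributive `-old` forms, `age:` ...); a bare `<number> <unit>` phrase is
#' deliberately not an age mention.  Open-ended spans ("postnatal day 7 to
#' several months") and embryonic-stage notation are not matched by the
#' default profile; `profile = "extended"` adds a postnatal-day rule.
#'
#' @param profile `"default"` or `"extended"` (adds postnatal-day ages).
#' @param decimal_ages if `TRUE`, numerals in age patterns may carry a decimal
#'   part ("6.5 weeks old"); off by default.
#' @return A tibble with columns `rule_id`, `kind`, `pattern`, `category`,
#'   `qualifier`, suitable for [compile_rules()].
#' @examples
#' rules <- default_rules()
#' table(rules$kind)
#' @export
default_rules <- function(profile = c("default", "extended"),
                          decimal_ages = FALSE) {
  profile <- match.arg(profile)
  num <- .mr_num_rx(decimal_ages)
  j <- .rx_join
  conn <- .rx_conn
  unit <- .rx_unit
  rng <- paste0(num, conn, num)          # "3 to 8", "6-8", "8–12"
  nu1 <- paste0(num, j, "?", unit)       # "8 weeks", "3-weeks", "15-d"
  nur <- paste0(rng, j, "?", unit)       # "6-8-weeks", "8–12 weeks"

  sex <- tibble::tribble(
    ~rule_id,                    ~pattern,                                         ~category, ~qualifier,
    "sex_mice_either_sex",       "\\b(?:mice|mouse)\\s+of\\s+either\\s+sex\\b",    "both",    "mixed",
    "sex_either_sex",            "\\beither\\s+sex\\b",                            "both",    "mixed",
    "sex_mice_both_sexes",       "\\b(?:mice|mouse)\\s+of\\s+both\\s+sexes\\b",    "both",    "unspecified",
    "sex_both_sexes",            "\\bboth\\s+sexes\\b",                            "both",    "unspecified",
    "sex_male_and_female",       "\\bmales?\\s+and\\s+females?\\b",                "both",    "unspecified",
    "sex_female_and_male",       "\\bfemales?\\s+and\\s+males?\\b",                "both",    "unspecified",
    "sex_male_or_female",        "\\bmales?\\s+or\\s+females?\\b",                 "both",    "unspecified",
    "sex_female_or_male",        "\\bfemales?\\s+or\\s+males?\\b",                 "both",    "unspecified",
    "sex_separated_by_sex",      "\\bseparated\\s+(?:by|according\\s+to)\\s+sex\\b", "both",  "separated",
    "sex_mixed_sex",             paste0("\\bmixed", .rx_join, "sex\\b"),           "both",    "mixed",
    "sex_female_mice",           "\\bfemales?\\s+(?:mice|mouse)\\b",               "female",  NA,
    "sex_male_mice",             "\\bmales?\\s+(?:mice|mouse)\\b",                 "male",    NA,
    "sex_female",                "\\bfemales?\\b",                                 "female",  NA,
    "sex_male",                  "\\bmales?\\b",                                   "male",    NA
  )
  sex$kind <- "sex"

  age_patterns <- c(
    # "aged 3 to 8 weeks old", "mice aged 8–12 weeks"
    age_aged_range          = paste0("\\baged\\s+", nur, "\\b(?:", j, "old\\b)?"),
    age_aged_single         = paste0("\\baged\\s+", nu1, "\\b(?:", j, "old\\b)?"),
    # "8–12 weeks old", "6-8-weeks old", "3-weeks old", "six weeks old"
    age_range_old           = paste0("\\b", nur, j, "old\\b"),
    age_single_old          = paste0("\\b", nu1, j, "old\\b"),
    # "6 to 8 weeks of age", "six weeks of age", "6-weeks-of-age"
    age_range_of_age        = paste0("\\b", nur, j, "of", j, "age\\b"),
    age_single_of_age       = paste0("\\b", nu1, j, "of", j, "age\\b"),
    # "at the age of 6(-8) weeks"
    age_at_age_of_range     = paste0("\\bat\\s+the\\s+age\\s+of\\s+", nur, "\\b"),
    age_at_age_of_single    = paste0("\\bat\\s+the\\s+age\\s+of\\s+", nu1, "\\b"),
    # "between 6 and 8 weeks of age/old"
    age_between             = paste0("\\bbetween\\s+", num, "\\s+and\\s+", num, j,
                                     "?", unit, "\\s+(?:of", j, "age|old)\\b"),
    age_aged_between        = paste0("\\baged\\s+between\\s+", num, "\\s+and\\s+",
                                     num, j, "?", unit, "\\b"),
    # "age: 8 weeks", "age, 6-8 weeks"
    age_colon_range         = paste0("\\bage\\s*[:,]\\s*", nur, "\\b"),
    age_colon_single        = paste0("\\bage\\s*[:,]\\s*", nu1, "\\b"),
    # "an age of 6(-8) weeks"
    age_age_of_range        = paste0("\\bage\\s+of\\s+", nur, "\\b"),
    age_age_of_single       = paste0("\\bage\\s+of\\s+", nu1, "\\b"),
    # "ages ranged from 6 to 8 weeks", "age range: 6-8 weeks"
    age_ranged_from         = paste0("\\bages?\\s+ranged?\\s+from\\s+", num,
                                     "\\s+to\\s+", num, j, "?", unit, "\\b"),
    age_range_label         = paste0("\\bage\\s+range\\s*[:,]?\\s*", nur, "\\b"),
    # "aged/ages from 6 to 8 weeks"
    age_aged_from           = paste0("\\bage[sd]\\s+from\\s+", num, "\\s+to\\s+",
                                     num, j, "?", unit, "\\b"),
    # "within the first 3 weeks of life"
    age_of_life             = paste0("\\b", nu1, j, "of", j, "life\\b")
  )
  age <- tibble::tibble(
    rule_id = names(age_patterns),
    pattern = unname(age_patterns),
    category = NA_character_,
    qualifier = NA_character_,
    kind = "age"
  )

  rules <- dplyr::bind_rows(sex, age)
  if (profile == "extended") {
    ext <- tibble::tibble(
      rule_id = "age_postnatal_day",
      pattern = paste0("\\bpostnatal\\s+day\\s+", num,
                       "(?:", conn, num, ")?\\b"),
      category = NA_character_, qualifier = NA_character_, kind = "age"
    )
    rules <- dplyr::bind_rows(rules, ext)
  }
  rules[, c("rule_id", "kind", "pattern", "category", "qualifier")]
}

#' Compile a rule table into a matcher
#'
#' Validates the rule table (unique ids, known kinds, patterns that compile;
#' sex rules must carry a category) and returns a `mr_ruleset` used by the
#' extraction functions.  Matching is deterministic; at a given start offset a
#' longer match shadows a shorter one.
#'
#' @param specs A rule tibble as produced by [default_rules()] or
#'   [read_rules()].
#' @return An object of class `mr_ruleset`.
#' @examples
#' rs <- compile_rules(default_rules())
#' @export
compile_rules <- function(specs) {
  specs <- tibble::as_tibble(specs)
  needed <- c("rule_id", "kind", "pattern")
  if (!all(needed %in% names(specs))) {
    stop("rule table must have columns rule_id, kind, pattern", call. = FALSE)
  }
  if (!"category" %in% names(specs)) specs$category <- NA_character_
  if (!"qualifier" %in% names(specs)) specs$qualifier <- NA_character_
  dup <- specs$rule_id[duplicated(specs$rule_id)]
  if (length(dup) > 0) {
    stop("duplicate rule_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(specs$kind), c("sex", "age"))
  if (length(bad_kind) > 0) {
    stop("unknown rule kind: ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  bad_cat <- specs$kind == "sex" &
    !(specs$category %in% c("female", "male", "both"))
  if (any(bad_cat)) {
    stop("sex rule without a valid category (female|male|both): ",
         paste(specs$rule_id[bad_cat], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(specs))) {
    ok <- tryCatch(
      {
        stringr::str_detect("", stringr::regex(specs$pattern[i],
                                               ignore_case = TRUE))
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      stop("pattern for rule '", specs$rule_id[i], "' does not compile",
           call. = FALSE)
    }
  }
  structure(list(rules = specs), class = "mr_ruleset")
}

#' @export
print.mr_ruleset <- function(x, ...) {
  n <- table(factor(x$rules$kind, levels = c("sex", "age")))
  cat(sprintf("<mr_ruleset> %d sex rules, %d age rules\n",
              n[["sex"]], n[["age"]]))
  invisible(x)
}

#' Read / write a rule table as a TSV config
#'
#' The on-disk form is a tab-separated file with columns
#' `rule_id`, `kind`, `pattern`, `category`, `qualifier`, so the shipped
#' default rules can be dumped, edited and substituted.
#'
#' @param file Path to a rules TSV.
#' @return `read_rules()` returns the rule tibble; `write_rules()` returns
#'   `file` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_rules(default_rules(), f)
#' identical(read_rules(f)$rule_id, default_rules()$rule_id)
#' @export
read_rules <- function(file) {
  if (!file.exists(file)) stop("rules file not found: ", file, call. = FALSE)
  readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' @rdname read_rules
#' @param rules A rule tibble.
#' @export
write_rules <- function(rules, file) {
  readr::write_tsv(rules, file)
  invisible(file)
}
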