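# Document-level unification: collapse all candidate mentions of one
# characteristic in a document to a single representative mention.

#' Unify candidate mentions of one characteristic
#'
#' Selects the mention with the maximal span length (`end - start`) —
#' usually the most informative one; ties are broken by the smallest start
#' offset.  The result does not depend on the input ordering.
#'
#' @param mentions A mention tibble (one document, one kind).
#' @param kind Optional `"sex"` or `"age"`; if given, mentions of any other
#'   kind are an error.  Mixed-kind input is always an error.
#' @return A one-row mention tibble, or `NULL` for empty input.
#' @examples
#' rs <- compile_rules(default_rules())
#' m <- match_sex_mentions("female mice and later some female controls", rs)
#' unify_mentions(m)$surface
#' @export
unify_mentions <- function(mentions, kind = NULL) {
  if (is.null(mentions) || nrow(mentions) == 0) return(NULL)
  kinds <- unique(mentions$kind)
  if (length(kinds) > 1) {
    stop("cannot unify mentions of mixed kinds: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  if (!is.null(kind) && kinds != kind) {
    stop("expected mentions of kind '", kind, "', got '", kinds, "'",
         call. = FALSE)
  }
  ids <- unique(mentions$doc_id)
  if (length(ids) > 1) {
    stop("cannot unify mentions from multiple documents", call. = FALSE)
  }
  ord <- order(-(mentions$end - mentions$start), mentions$start)
  mentions[ord[1], , drop = FALSE]
}

#' Map a unified sex mention to its document-level category
#'
#' @param m A one-row mention tibble of kind `"sex"`.
#' @return `"female"`, `"male"` or `"both"`.
#' @export
classify_sex_status <- function(m) {
  if (is.null(m) || nrow(m) != 1 || m$kind != "sex") {
    stop("classify_sex_status() expects a single sex mention", call. = FALSE)
  }
  m$sex_category
}

.mr_annotation_cols <- c(
  "doc_id",
  "sex_status", "sex_qualifier", "sex_surface", "sex_start", "sex_end",
  "sex_rule",
  "age_status", "age_min", "age_max", "age_unit", "age_surface",
  "age_start", "age_end", "age_rule"
)

mr_empty_annotations <- function() {
  tibble::tibble(
    doc_id = character(),
    sex_status = character(), sex_qualifier = character(),
    sex_surface = character(), sex_start = integer(), sex_end = integer(),
    sex_rule = character(),
    age_status = character(), age_min = double(), age_max = double(),
    age_unit = character(), age_surface = character(),
    age_start = integer(), age_end = integer(), age_rule = character()
  )
}

#' Annotate one document
#'
#' Runs the sex and age extractors over the full document text, unifies each
#' kind (longest mention, earliest on ties) and returns the document-level
#' annotation: one sex status and one age value per document.
#'
#' A document that contains separate `male` and `female` mentions but no
#' both-sexes phrase resolves to whichever single mention wins unification
#' (this may under-count both-sex studies; set
#' `options(micereport.verbose = TRUE)` to log such documents).
#'
#' @param doc A one-row tibble (or list) with at least `doc_id` and `text`.
#' @param rules A compiled `mr_ruleset`.
#' @return A one-row annotation tibble: `doc_id`; `sex_status`
#'   (`female`/`male`/`both`/`none`) with the chosen mention's surface, span
#'   and rule; `age_status` (`reported`/`none`) with `age_min`, `age_max`,
#'   `age_unit` and the chosen mention's surface, span and rule.
#' @examples
#' rs <- compile_rules(default_rules())
#' doc <- tibble::tibble(doc_id = "d1",
#'   text = "ten C57BL/6 female mice (6-8-weeks old) were injected")
#' annotate_document(doc, rs)
#' @export
annotate_document <- function(doc, rules) {
  doc_id <- doc$doc_id[[1]]
  text <- doc$text[[1]]
  sex_all <- match_sex_mentions(text, rules, doc_id)
  age_all <- match_age_mentions(text, rules, doc_id)
  sex_m <- unify_mentions(sex_all, "sex")
  age_m <- unify_mentions(age_all, "age")

  if (isTRUE(getOption("micereport.verbose", FALSE)) &&
      !is.null(sex_m) && sex_m$sex_category != "both" &&
      all(c("female", "male") %in% sex_all$sex_category)) {
    message("doc ", doc_id,
            ": separate male and female mentions unified to '",
            sex_m$sex_category, "'")
  }

  ann <- tibble::tibble(
    doc_id = doc_id,
    sex_status = "none", sex_qualifier = NA_character_,
    sex_surface = NA_character_, sex_start = NA_integer_,
    sex_end = NA_integer_, sex_rule = NA_character_,
    age_status = "none", age_min = NA_real_, age_max = NA_real_,
    age_unit = NA_character_, age_surface = NA_character_,
    age_start = NA_integer_, age_end = NA_integer_, age_rule = NA_character_
  )
  if (!is.null(sex_m)) {
    ann$sex_status <- classify_sex_status(sex_m)
    ann$sex_qualifier <- sex_m$sex_qualifier
    ann$sex_surface <- sex_m$surface
    ann$sex_start <- sex_m$start
    ann$sex_end <- sex_m$end
    ann$sex_rule <- sex_m$rule_id
  }
  if (!is.null(age_m)) {
    ann$age_status <- "reported"
    ann$age_min <- age_m$age_min
    ann$age_max <- age_m$age_max
    ann$age_unit <- age_m$age_unit
    ann$age_surface <- age_m$surface
    ann$age_start <- age_m$start
    ann$age_end <- age_m$end
    ann$age_rule <- age_m$rule_id
  }
  ann[, .mr_annotation_cols]
}

#' Annotate a corpus of documents
#'
#' @param corpus A tibble with columns `doc_id`, `text`.
#' @param rules A compiled `mr_ruleset` (defaults to the shipped rule set).
#' @return An annotation tibble, one row per document (see
#'   [annotate_document()]).
#' @export
annotate_corpus <- function(corpus, rules = compile_rules(default_rules())) {
  if (nrow(corpus) == 0) return(mr_empty_annotations())
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    annotate_document(corpus[i, ], rules)
  })
}
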