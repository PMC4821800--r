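# Corpus input/output: plain-text corpora, JATS (PMC OA flavour) XML,
# metadata / gold / journal-metric tables, and annotation files
# (TSV or JSON-lines).

.mr_sex_vocab <- c("female", "male", "both", "none")
.mr_subgroup_vocab <- c("genetics", "immunology", "physiopathology", "therapy")

#' Read a directory of plain-text articles
#'
#' One `ArticleDoc` per UTF-8 `.txt` file.  Unreadable or non-UTF-8 files are
#' skipped with a warning and listed in the rejects report, so that
#' `nrow(documents) + nrow(rejects)` always equals the number of input files.
#' Metadata fields (year, journal, groups) are absent until joined from a
#' metadata table.
#'
#' @param path Directory containing `.txt` files.
#' @param manifest Optional data frame (or TSV path) with columns `file`,
#'   `doc_id` mapping filenames to document ids; by default the id is the
#'   filename without extension.  Duplicate ids are a hard error.
#' @return A list with `documents` (tibble: `doc_id`, `text`, `file`) and
#'   `rejects` (tibble: `file`, `reason`).
#' @export
read_plain_text_corpus <- function(path, manifest = NULL) {
  if (!dir.exists(path)) stop("corpus directory not found: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  if (!is.null(manifest)) {
    if (is.character(manifest) && length(manifest) == 1) {
      manifest <- readr::read_tsv(manifest, col_types = "cc", progress = FALSE)
    }
    manifest <- tibble::as_tibble(manifest)
    stopifnot(all(c("file", "doc_id") %in% names(manifest)))
    files <- file.path(path, manifest$file)
    ids <- manifest$doc_id
  } else {
    ids <- sub("\\.txt$", "", basename(files))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate doc_id in corpus: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  docs <- list()
  rejects <- list()
  for (i in seq_along(files)) {
    f <- files[i]
    txt <- tryCatch(
      {
        raw <- readBin(f, "raw", n = file.size(f))
        out <- rawToChar(raw)
        if (!validUTF8(out)) stop("not valid UTF-8")
        out
      },
      error = function(e) structure(conditionMessage(e), class = "mr_reject")
    )
    if (inherits(txt, "mr_reject")) {
      warning("skipping unreadable file ", basename(f), ": ", txt,
              call. = FALSE)
      rejects[[length(rejects) + 1]] <-
        tibble::tibble(file = basename(f), reason = unclass(txt))
    } else {
      docs[[length(docs) + 1]] <-
        tibble::tibble(doc_id = ids[i], text = txt, file = basename(f))
    }
  }
  list(
    documents = if (length(docs)) dplyr::bind_rows(docs) else
      tibble::tibble(doc_id = character(), text = character(),
                     file = character()),
    rejects = if (length(rejects)) dplyr::bind_rows(rejects) else
      tibble::tibble(file = character(), reason = character())
  )
}

#' Read one JATS (PMC OA flavour) XML article
#'
#' The document text is the concatenation of body paragraphs in document
#' order; section titles are retained as labelled segments (tables and figure
#' captions inside the body are included).  Front-matter journal and
#' publication year are captured when present.  A missing `<body>` yields an
#' empty text with a warning; malformed XML is an error naming the file.
#'
#' @param file Path to a JATS XML file.
#' @return A one-row tibble: `doc_id`, `text`, `year`, `journal` and a
#'   `segments` list-column (tibble `section`, `text` per top-level section).
#' @export
read_jats_xml <- function(file) {
  x <- tryCatch(
    xml2::read_xml(file),
    error = function(e) {
      stop("malformed XML in '", file, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  id_node <- xml2::xml_find_first(
    x, ".//front//article-id[@pub-id-type='pmc' or @pub-id-type='pmcid']"
  )
  doc_id <- if (!inherits(id_node, "xml_missing")) {
    xml2::xml_text(id_node)
  } else {
    sub("\\.[^.]*$", "", basename(file))
  }
  j_node <- xml2::xml_find_first(x, ".//front//journal-title")
  journal <- if (inherits(j_node, "xml_missing")) NA_character_ else
    xml2::xml_text(j_node)
  y_node <- xml2::xml_find_first(x, ".//front//pub-date/year")
  year <- if (inherits(y_node, "xml_missing")) NA_integer_ else
    suppressWarnings(as.integer(xml2::xml_text(y_node)))

  body <- xml2::xml_find_first(x, ".//body")
  if (inherits(body, "xml_missing")) {
    warning("no <body> in '", file, "'; text is empty", call. = FALSE)
    segments <- tibble::tibble(section = character(), text = character())
    text <- ""
  } else {
    kids <- xml2::xml_children(body)
    seg_list <- purrr::map(kids, function(k) {
      nm <- xml2::xml_name(k)
      if (nm == "sec") {
        title <- xml2::xml_find_first(k, "./title")
        label <- if (inherits(title, "xml_missing")) NA_character_ else
          xml2::xml_text(title)
        ps <- xml2::xml_find_all(k, ".//p")
        tibble::tibble(section = label,
                       text = paste(xml2::xml_text(ps), collapse = "\n"))
      } else if (nm == "p") {
        tibble::tibble(section = NA_character_, text = xml2::xml_text(k))
      } else {
        NULL
      }
    })
    segments <- dplyr::bind_rows(seg_list)
    if (nrow(segments) == 0) {
      segments <- tibble::tibble(section = character(), text = character())
    }
    text <- paste(segments$text, collapse = "\n\n")
  }
  tibble::tibble(doc_id = doc_id, text = text, year = year,
                 journal = journal, segments = list(segments))
}

#' Read a per-document metadata table
#'
#' Tab-separated with columns `doc_id`, `year`, `journal`, `disease_groups`,
#' `subgroups`; the two group columns hold `;`-separated labels.  Subgroup
#' labels are validated against the declared vocabulary
#' (genetics, immunology, physiopathology, therapy).
#'
#' @param file Path to the metadata TSV.
#' @return A tibble, one row per document.
#' @export
read_metadata <- function(file) {
  md <- readr::read_tsv(
    file,
    col_types = readr::cols(
      doc_id = readr::col_character(),
      year = readr::col_integer(),
      journal = readr::col_character(),
      disease_groups = readr::col_character(),
      subgroups = readr::col_character()
    ),
    progress = FALSE
  )
  dup <- md$doc_id[duplicated(md$doc_id)]
  if (length(dup) > 0) {
    stop("duplicate doc_id in metadata: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  sg <- unlist(strsplit(md$subgroups[!is.na(md$subgroups)], ";\\s*"))
  bad <- setdiff(unique(sg), .mr_subgroup_vocab)
  if (length(bad) > 0) {
    stop("unknown subgroup label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  md
}

# normalize a gold sex token; "both (mixed)" / "both (separated)" map to both
.mr_norm_sex_token <- function(tok, row) {
  t <- stringr::str_to_lower(stringr::str_trim(tok))
  t <- stringr::str_replace_all(t, "\\s+", " ")
  if (t %in% c("female", "male", "both", "none")) return(t)
  if (stringr::str_detect(t, "^both\\s*\\((mixed|separated)\\)$")) return("both")
  stop("unknown sex status token '", tok, "' in gold row ", row, call. = FALSE)
}

#' Read a gold-annotation table
#'
#' Tab-separated with columns `doc_id`, `sex_status`, `sex_value`,
#' `age_status`, `age_value`.  `sex_status` is `reported`/`none` with the
#' category in `sex_value`; a category token (`female`, `male`, `both`,
#' `both (mixed)`, `both (separated)`) given directly as the status is also
#' accepted.  `age_value` is a phrase such as `"6-8 weeks"` or `"15 days"`.
#' Unknown status tokens are a hard error citing the row.
#'
#' @param file Path to the gold TSV.
#' @return A tibble with the same vocabulary as system annotations:
#'   `doc_id`, `sex_status` (`female`/`male`/`both`/`none`), `age_status`
#'   (`reported`/`none`), `age_min`, `age_max`, `age_unit`.
#' @export
read_gold_annotations <- function(file) {
  g <- readr::read_tsv(
    file,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c("doc_id", "sex_status", "age_status")
  if (!all(need %in% names(g))) {
    stop("gold table must have columns doc_id, sex_status, age_status",
         call. = FALSE)
  }
  if (!"sex_value" %in% names(g)) g$sex_value <- NA_character_
  if (!"age_value" %in% names(g)) g$age_value <- NA_character_
  n <- nrow(g)
  sex_status <- character(n)
  age_status <- character(n)
  age_min <- rep(NA_real_, n)
  age_max <- rep(NA_real_, n)
  age_unit <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    st <- stringr::str_to_lower(stringr::str_trim(g$sex_status[i]))
    if (identical(st, "none") || is.na(g$sex_status[i])) {
      sex_status[i] <- "none"
    } else if (identical(st, "reported")) {
      sex_status[i] <- .mr_norm_sex_token(g$sex_value[i], i)
      if (sex_status[i] == "none") {
        stop("gold row ", i, ": sex_status 'reported' with value 'none'",
             call. = FALSE)
      }
    } else {
      sex_status[i] <- .mr_norm_sex_token(g$sex_status[i], i)
    }
    ast <- stringr::str_to_lower(stringr::str_trim(g$age_status[i]))
    if (identical(ast, "none") || is.na(g$age_status[i])) {
      age_status[i] <- "none"
    } else if (ast %in% c("reported", "yes")) {
      if (is.na(g$age_value[i]) || !nzchar(g$age_value[i])) {
        stop("gold row ", i, ": age reported but age_value missing",
             call. = FALSE)
      }
      av <- parse_age_phrase(g$age_value[i])
      age_status[i] <- "reported"
      age_min[i] <- av$age_min
      age_max[i] <- av$age_max
      age_unit[i] <- av$age_unit
    } else {
      stop("unknown age status token '", g$age_status[i], "' in gold row ", i,
           call. = FALSE)
    }
  }
  tibble::tibble(
    doc_id = g$doc_id, sex_status = sex_status, age_status = age_status,
    age_min = age_min, age_max = age_max, age_unit = age_unit
  )
}

#' Write / read document-level annotations
#'
#' Tab-separated by default (missing fields are empty, never the string
#' `"NA"`), with a JSON-lines alternative; both round-trip through
#' [read_annotations()] without loss.
#'
#' @param annotations An annotation tibble (see [annotate_document()]).
#' @param file Output path; format is taken from the extension (`.jsonl` or
#'   `.ndjson` select JSON-lines) unless `format` is given.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `file`, invisibly.
#' @export
write_annotations <- function(annotations, file, format = NULL) {
  format <- format %||%
    (if (grepl("\\.(jsonl|ndjson)$", file)) "jsonl" else "tsv")
  if (format == "tsv") {
    readr::write_tsv(annotations, file, na = "")
  } else {
    con <- file(file, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(annotations, con, na = "null", verbose = FALSE)
  }
  invisible(file)
}

.mr_annotation_coltypes <- readr::cols(
  doc_id = readr::col_character(),
  sex_status = readr::col_character(),
  sex_qualifier = readr::col_character(),
  sex_surface = readr::col_character(),
  sex_start = readr::col_integer(),
  sex_end = readr::col_integer(),
  sex_rule = readr::col_character(),
  age_status = readr::col_character(),
  age_min = readr::col_double(),
  age_max = readr::col_double(),
  age_unit = readr::col_character(),
  age_surface = readr::col_character(),
  age_start = readr::col_integer(),
  age_end = readr::col_integer(),
  age_rule = readr::col_character()
)

#' @rdname write_annotations
#' @export
read_annotations <- function(file, format = NULL) {
  format <- format %||%
    (if (grepl("\\.(jsonl|ndjson)$", file)) "jsonl" else "tsv")
  if (format == "tsv") {
    ann <- readr::read_tsv(file, col_types = .mr_annotation_coltypes,
                           na = "", progress = FALSE)
  } else {
    con <- file(file, open = "r", encoding = "UTF-8")
    on.exit(close(con))
    ann <- tibble::as_tibble(jsonlite::stream_in(con, verbose = FALSE))
    if (nrow(ann) == 0) return(mr_empty_annotations())
    for (col in setdiff(.mr_annotation_cols, names(ann))) ann[[col]] <- NA
    ann$sex_start <- as.integer(ann$sex_start)
    ann$sex_end <- as.integer(ann$sex_end)
    ann$age_start <- as.integer(ann$age_start)
    ann$age_end <- as.integer(ann$age_end)
    ann$age_min <- as.double(ann$age_min)
    ann$age_max <- as.double(ann$age_max)
    for (col in c("doc_id", "sex_status", "sex_qualifier", "sex_surface",
                  "sex_rule", "age_status", "age_unit", "age_surface",
                  "age_rule")) {
      ann[[col]] <- as.character(ann[[col]])
    }
    ann <- ann[, .mr_annotation_cols]
  }
  ann
}

#' Read a journal-metric table
#'
#' Tab-separated with columns `journal`, `impact_factor`, `h_index`.
#'
#' @param file Path to the TSV.
#' @return A tibble.
#' @export
read_journal_metrics <- function(file) {
  readr::read_tsv(
    file,
    col_types = readr::cols(
      journal = readr::col_character(),
      impact_factor = readr::col_double(),
      h_index = readr::col_double()
    ),
    progress = FALSE
  )
}
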