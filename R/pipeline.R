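# Pipeline entry points behind the command-line interface:
# extract / evaluate / analyze / synth.  Each computes everything first and
# writes outputs through a temp-then-rename step, so no command leaves a
# partial output file on failure.

.mr_write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Extract annotations from a plain-text corpus
#'
#' Reads the corpus, runs extraction and unification over every document and
#' writes one annotation record per document.
#'
#' @param input Directory of `.txt` articles.
#' @param out Output annotations file (`.tsv` or `.jsonl`).
#' @param rules_file Optional rules TSV (default: the shipped rule set).
#' @param manifest Optional filename-to-doc_id manifest (see
#'   [read_plain_text_corpus()]).
#' @param quiet Suppress the summary message.
#' @return The annotation tibble, invisibly.
#' @export
run_extract <- function(input, out, rules_file = NULL, manifest = NULL,
                        quiet = FALSE) {
  rules <- if (is.null(rules_file)) {
    compile_rules(default_rules())
  } else {
    compile_rules(read_rules(rules_file))
  }
  corpus <- read_plain_text_corpus(input, manifest)
  ann <- annotate_corpus(corpus$documents, rules)
  .mr_write_atomic(function(p) write_annotations(ann, p,
    format = if (grepl("\\.(jsonl|ndjson)$", out)) "jsonl" else "tsv"), out)
  if (!quiet) {
    message(sprintf(
      "extracted %d documents (%d sex-reported, %d age-reported, %d rejected files)",
      nrow(ann), sum(ann$sex_status != "none"),
      sum(ann$age_status != "none"), nrow(corpus$rejects)
    ))
  }
  invisible(ann)
}

#' Evaluate an annotations file against gold
#'
#' @param system_file Annotations file written by [run_extract()].
#' @param gold_file Gold TSV (see [read_gold_annotations()]).
#' @param out Optional output TSV for the metric table.
#' @param age_tolerance_days Passed to [evaluate_annotations()].
#' @return The per-characteristic metric tibble (TP/TN/FP/FN, P, R, F),
#'   invisibly.
#' @export
run_evaluate <- function(system_file, gold_file, out = NULL,
                         age_tolerance_days = 0) {
  system <- read_annotations(system_file)
  gold <- read_gold_annotations(gold_file)
  if (nrow(gold) == 0) stop("empty gold table", call. = FALSE)
  extra <- setdiff(system$doc_id, gold$doc_id)
  if (length(extra) > 0) {
    stop("system doc_id(s) missing from gold: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  tbl <- evaluate_annotations(system, gold,
                              age_tolerance_days = age_tolerance_days)
  if (!is.null(out)) {
    .mr_write_atomic(function(p) readr::write_tsv(tbl, p), out)
  }
  invisible(tbl)
}

#' Corpus analytics report
#'
#' Computes reporting breakdowns (overall, by year, by disease group, by
#' subgroup), yearly trend fractions and the OLS trend slope, per-group sex
#' breakdowns and bias ratios, the binomial proportion test on female vs
#' male documents, a two-way ANOVA (without replication) of the per-group
#' reporting percentages, and — when a journal-metric table is supplied —
#' Spearman correlations of the per-journal reporting index with impact
#' factor and h-index.  All tables are written as TSV into `out_dir`.
#'
#' @param annotations_file Annotations file (or an annotation tibble).
#' @param metadata_file Metadata TSV (or a metadata tibble).
#' @param out_dir Report directory (created).
#' @param journal_metrics_file Optional journal-metric TSV (or tibble).
#' @return A named list of the computed tables, invisibly.
#' @export
run_analyze <- function(annotations_file, metadata_file, out_dir,
                        journal_metrics_file = NULL) {
  ann <- if (is.character(annotations_file)) {
    read_annotations(annotations_file)
  } else {
    annotations_file
  }
  md <- if (is.character(metadata_file)) read_metadata(metadata_file) else
    metadata_file
  missing <- setdiff(ann$doc_id, md$doc_id)
  if (length(missing) > 0) {
    stop("no metadata for doc_id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  tables <- list()
  notes <- character(0)
  tables$reporting_overall <- reporting_breakdown(ann)
  tables$reporting_by_year <- reporting_breakdown(ann, md, by = "year")
  tables$trend <- yearly_trend(tables$reporting_by_year)
  none_series <- tables$trend[tables$trend$category == "none", ]
  if (length(unique(none_series$year)) >= 2) {
    tables$trend_slope <- tibble::tibble(
      category = unique(tables$trend$category),
      slope = vapply(unique(tables$trend$category), function(cat) {
        trend_slope(tables$trend[tables$trend$category == cat, ])
      }, numeric(1))
    )
  } else {
    notes <- c(notes, "trend slope omitted: fewer than two distinct years")
  }
  tables$reporting_by_group <- reporting_breakdown(ann, md,
                                                   by = "disease_group")
  tables$reporting_by_subgroup <- reporting_breakdown(ann, md,
                                                      by = "subgroup")
  tables$sex_overall <- sex_breakdown(ann)
  tables$sex_by_group <- sex_breakdown(ann, md, by = "disease_group")

  sb <- tables$sex_by_group
  tables$bias_ratios <- purrr::map_dfr(unique(sb$stratum), function(s) {
    nf <- sb$n[sb$stratum == s & sb$sex_status == "female"]
    nm <- sb$n[sb$stratum == s & sb$sex_status == "male"]
    res <- suppressWarnings(sex_bias_ratio(nf, nm))
    tibble::tibble(stratum = s, direction = res$direction,
                   ratio = res$ratio, n_female = nf, n_male = nm)
  })

  so <- tables$sex_overall
  nf <- so$n[so$sex_status == "female"]
  nm <- so$n[so$sex_status == "male"]
  if (nf + nm > 0) {
    tables$binomial_test <- binomial_proportion_test(nf, nm)
  } else {
    notes <- c(notes, "binomial test omitted: no single-sex documents")
  }

  rbg <- tables$reporting_by_group
  if (length(unique(rbg$stratum)) >= 2) {
    wide <- tidyr::pivot_wider(rbg[, c("stratum", "category", "pct")],
                               names_from = "category",
                               values_from = "pct")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$stratum
    tables$anova_reporting <- two_way_anova_no_replication(m)
  } else {
    notes <- c(notes, "ANOVA omitted: fewer than two disease groups")
  }

  if (!is.null(journal_metrics_file)) {
    jm <- if (is.character(journal_metrics_file)) {
      read_journal_metrics(journal_metrics_file)
    } else {
      journal_metrics_file
    }
    res <- journal_metric_correlation(ann, md, jm)
    tables$journal_index <- res$index
    tables$journal_correlations <- res$correlations
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm2 in names(tables)) {
    tbl <- tables[[nm2]]
    .mr_write_atomic(
      function(p) readr::write_tsv(tbl, p),
      file.path(out_dir, paste0(nm2, ".tsv"))
    )
  }
  if (length(notes) > 0) {
    .mr_write_atomic(function(p) writeLines(notes, p),
                     file.path(out_dir, "notes.txt"))
  }
  invisible(tables)
}

#' Generate and write a synthetic corpus
#'
#' @param out_dir Output directory for the corpus (see
#'   [write_synth_corpus()]).
#' @param cfg A `synth_config` (default configuration if `NULL`).
#' @param ... Overrides passed to [synth_config()] when `cfg` is `NULL`.
#' @return The generated corpus list, invisibly.
#' @export
run_synth <- function(out_dir, cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- synth_config(...)
  syn <- generate_corpus(cfg)
  write_synth_corpus(syn, out_dir)
  invisible(syn)
}
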