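# Corpus-level reporting statistics: breakdowns and trends, sex-bias ratios,
# binomial proportion test with CI, two-way ANOVA without replication,
# Spearman rank correlations and the per-journal reporting index.
# Documents (not mice) are the unit of analysis throughout.

.mr_categories <- c("both", "sex_only", "age_only", "none")
.mr_strata <- c("year", "journal", "disease_group", "subgroup")

# exhaustive, mutually exclusive reporting category per document
.mr_category <- function(annotations) {
  s <- annotations$sex_status != "none"
  a <- annotations$age_status != "none"
  dplyr::case_when(
    s & a ~ "both",
    s ~ "sex_only",
    a ~ "age_only",
    TRUE ~ "none"
  )
}

# join annotations to metadata and explode the requested stratum column
.mr_stratify <- function(annotations, metadata, by) {
  df <- tibble::tibble(doc_id = annotations$doc_id)
  if (is.null(by)) {
    df$stratum <- "all"
    return(df)
  }
  if (!by %in% .mr_strata) {
    stop("unknown stratification field '", by, "' (expected one of: ",
         paste(.mr_strata, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(metadata)) stop("metadata required for stratification",
                              call. = FALSE)
  missing <- setdiff(df$doc_id, metadata$doc_id)
  if (length(missing) > 0) {
    stop("no metadata for doc_id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  md <- metadata[match(df$doc_id, metadata$doc_id), ]
  col <- switch(by, year = "year", journal = "journal",
                disease_group = "disease_groups", subgroup = "subgroups")
  df$stratum <- as.character(md[[col]])
  if (by %in% c("disease_group", "subgroup")) {
    df <- tidyr::separate_rows(df, "stratum", sep = ";\\s*")
  }
  df[!is.na(df$stratum) & nzchar(df$stratum), ]
}

#' Reporting breakdown by stratum
#'
#' Assigns every document to exactly one of the four reporting categories —
#' `both` (sex and age), `sex_only`, `age_only`, `none` — and tallies counts
#' and percentages per stratum.  Category counts sum to the stratum's
#' document count (a document belonging to several disease groups is counted
#' once in each group's stratum).
#'
#' @param annotations An annotation tibble.
#' @param metadata A metadata tibble (required when `by` is given).
#' @param by `NULL` (overall) or one of `"year"`, `"journal"`,
#'   `"disease_group"`, `"subgroup"`.
#' @return A tibble: `stratum`, `category`, `n`, `pct` (two decimals),
#'   `n_stratum`.
#' @export
reporting_breakdown <- function(annotations, metadata = NULL, by = NULL) {
  if (nrow(annotations) == 0) {
    return(tibble::tibble(stratum = character(), category = character(),
                          n = integer(), pct = double(),
                          n_stratum = integer()))
  }
  df <- .mr_stratify(annotations, metadata, by)
  df$category <- .mr_category(annotations)[match(df$doc_id,
                                                 annotations$doc_id)]
  out <- df |>
    dplyr::count(.data$stratum,
                 category = factor(.data$category, levels = .mr_categories),
                 .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(n_stratum = sum(.data$n),
                  pct = round(100 * .data$n / .data$n_stratum, 2)) |>
    dplyr::ungroup()
  out$category <- as.character(out$category)
  out[, c("stratum", "category", "n", "pct", "n_stratum")]
}

#' Sex-status breakdown by stratum
#'
#' Counts of documents reporting females only, males only, both sexes, or
#' not reporting sex, per stratum.
#'
#' @inheritParams reporting_breakdown
#' @return A tibble: `stratum`, `sex_status`
#'   (`female`/`male`/`both`/`not_reported`), `n`, `pct`, `n_stratum`.
#' @export
sex_breakdown <- function(annotations, metadata = NULL, by = NULL) {
  lv <- c("female", "male", "both", "not_reported")
  if (nrow(annotations) == 0) {
    return(tibble::tibble(stratum = character(), sex_status = character(),
                          n = integer(), pct = double(),
                          n_stratum = integer()))
  }
  df <- .mr_stratify(annotations, metadata, by)
  st <- annotations$sex_status[match(df$doc_id, annotations$doc_id)]
  df$sex_status <- ifelse(st == "none", "not_reported", st)
  out <- df |>
    dplyr::count(.data$stratum,
                 sex_status = factor(.data$sex_status, levels = lv),
                 .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(n_stratum = sum(.data$n),
                  pct = round(100 * .data$n / .data$n_stratum, 2)) |>
    dplyr::ungroup()
  out$sex_status <- as.character(out$sex_status)
  out[, c("stratum", "sex_status", "n", "pct", "n_stratum")]
}

#' Per-year normalized category fractions
#'
#' Divides each category count by that year's article count, so the four
#' category fractions sum to 1 within every year.
#'
#' @param breakdown_by_year Output of
#'   `reporting_breakdown(..., by = "year")`.
#' @return A tibble: `year` (integer), `category`, `fraction`.
#' @export
yearly_trend <- function(breakdown_by_year) {
  if (nrow(breakdown_by_year) == 0) {
    stop("need at least one year stratum", call. = FALSE)
  }
  tibble::tibble(
    year = as.integer(breakdown_by_year$stratum),
    category = breakdown_by_year$category,
    fraction = breakdown_by_year$n / breakdown_by_year$n_stratum
  )
}

#' Ordinary least-squares trend slope
#'
#' Slope of `fraction` on `year` (per-year change in the fraction).
#'
#' @param series A data frame with columns `year` and `fraction` (at least
#'   two distinct years).
#' @return The OLS slope (a single number).
#' @examples
#' trend_slope(data.frame(year = c(2000, 2010), fraction = c(1, 0.55)))
#' @export
trend_slope <- function(series) {
  if (length(unique(series$year)) < 2) {
    stop("need at least two distinct years for a trend slope", call. = FALSE)
  }
  unname(stats::coef(stats::lm(fraction ~ year, data = series))["year"])
}

#' Sex-bias ratio within a stratum
#'
#' Majority:minority ratio of female-only to male-only documents (or vice
#' versa); both-sex documents are excluded from both sides.  Equal counts
#' give ratio 1 with direction `"none"`.
#'
#' @param n_female,n_male Counts of female-only and male-only documents.
#' @return A one-row tibble: `direction` (`female`/`male`/`none`), `ratio`
#'   (`>= 1`; `Inf` when the minority count is zero).
#' @examples
#' sex_bias_ratio(45, 20)   # female-bias, 2.25
#' @export
sex_bias_ratio <- function(n_female, n_male) {
  if (n_female + n_male == 0) {
    warning("sex-bias ratio undefined: no single-sex documents",
            call. = FALSE)
    return(tibble::tibble(direction = NA_character_, ratio = NA_real_))
  }
  if (n_female == n_male) {
    return(tibble::tibble(direction = "none", ratio = 1))
  }
  if (n_female > n_male) {
    tibble::tibble(direction = "female", ratio = n_female / n_male)
  } else {
    tibble::tibble(direction = "male", ratio = n_male / n_female)
  }
}

#' Binomial proportion test for the female share
#'
#' Two-sided exact binomial test of p = 0.5 on `n_female` successes out of
#' `n_female + n_male`, with a 95% confidence interval for the female
#' proportion via the normal approximation
#' `p-hat +/- z * sqrt(p-hat (1 - p-hat) / n)`, reported on the percent
#' scale (Clopper-Pearson available via `ci_method = "exact"`).
#'
#' @param n_female,n_male Document counts.
#' @param ci_method `"normal"` (default) or `"exact"` (Clopper-Pearson).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `p_hat_pct`, `p_value`, `ci_low_pct`,
#'   `ci_high_pct`, `n`.
#' @examples
#' binomial_proportion_test(4875, 3580)
#' @export
binomial_proportion_test <- function(n_female, n_male,
                                     ci_method = c("normal", "exact"),
                                     conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  n <- n_female + n_male
  if (n == 0) stop("zero total count", call. = FALSE)
  bt <- stats::binom.test(n_female, n, p = 0.5, conf.level = conf_level)
  p_hat <- n_female / n
  if (ci_method == "normal") {
    # conventional two-decimal z multiplier at the default level (1.96)
    z <- if (conf_level == 0.95) 1.96 else
      stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(p_hat * (1 - p_hat) / n)
    ci <- c(p_hat - z * se, p_hat + z * se)
  } else {
    ci <- as.numeric(bt$conf.int)
  }
  tibble::tibble(
    p_hat_pct = 100 * p_hat, p_value = bt$p.value,
    ci_low_pct = 100 * ci[1], ci_high_pct = 100 * ci[2], n = n
  )
}

#' Two-way ANOVA without replication
#'
#' Classical partition of a two-factor table with one observation per cell:
#' `SS_total = SS_rows + SS_columns + SS_residual` with degrees of freedom
#' `(r - 1)`, `(c - 1)` and `(r - 1)(c - 1)`; the residual plays the role of
#' the interaction.  `F = MS_factor / MS_residual`, p-values from the F
#' distribution.  Fitted with [stats::aov()].
#'
#' @param tbl A numeric matrix or data frame (`>= 2` rows, `>= 2` columns,
#'   no missing cells); e.g. strata as rows and reporting categories as
#'   columns, on the percentage scale.
#' @return A tibble with rows `rows`, `columns`, `residuals`, `total`:
#'   `term`, `df`, `sumsq`, `meansq`, `statistic`, `p_value`.  A zero
#'   residual mean square makes the F statistics undefined (`NaN`, with a
#'   warning).
#' @export
two_way_anova_no_replication <- function(tbl) {
  m <- as.matrix(tbl)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (anyNA(m)) stop("missing cells are not allowed", call. = FALSE)
  long <- data.frame(
    value = as.vector(m),
    row = factor(rep(seq_len(nrow(m)), times = ncol(m))),
    col = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  fit <- stats::aov(value ~ row + col, data = long)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  get <- function(t) s[match(t, terms), ]
  rr <- get("row"); cc <- get("col"); re <- get("Residuals")
  # scale-relative zero test: a constant table leaves only rounding noise
  degenerate <- re$`Mean Sq` < 1e-12 * max(1, mean(m)^2)
  if (degenerate) {
    warning("zero residual mean square: F statistics undefined",
            call. = FALSE)
  }
  out <- tibble::tibble(
    term = c("rows", "columns", "residuals"),
    df = c(rr$Df, cc$Df, re$Df),
    sumsq = c(rr$`Sum Sq`, cc$`Sum Sq`, re$`Sum Sq`),
    meansq = c(rr$`Mean Sq`, cc$`Mean Sq`, re$`Mean Sq`),
    statistic = if (degenerate) c(NaN, NaN, NA_real_) else
      c(rr$`F value`, cc$`F value`, NA_real_),
    p_value = if (degenerate) c(NaN, NaN, NA_real_) else
      c(rr$`Pr(>F)`, cc$`Pr(>F)`, NA_real_)
  )
  dplyr::bind_rows(out, tibble::tibble(
    term = "total", df = sum(out$df), sumsq = sum(out$sumsq),
    meansq = NA_real_, statistic = NA_real_, p_value = NA_real_
  ))
}

#' Per-journal reporting index
#'
#' Number of articles reporting sex and/or age divided by the number
#' reporting neither.
#'
#' @param n_reporting_any,n_reporting_none Document counts.
#' @return The quotient; `NA` with a warning when the denominator is zero
#'   (such a journal is excluded from correlations).
#' @export
journal_reporting_index <- function(n_reporting_any, n_reporting_none) {
  if (n_reporting_none == 0) {
    warning("reporting index undefined: no non-reporting articles",
            call. = FALSE)
    return(NA_real_)
  }
  n_reporting_any / n_reporting_none
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged) with a two-sided p-value
#' from the t approximation, via
#' `stats::cor.test(method = "spearman", exact = FALSE)`.
#'
#' @param x,y Numeric vectors of equal length `>= 3`; constant vectors are
#'   an error.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
spearman_rank_corr <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Reporting index vs journal metrics, per journal
#'
#' Computes the per-journal reporting index and correlates it with the
#' supplied journal metrics (impact factor, h-index) by Spearman rank
#' correlation.  Journals with a zero denominator are excluded with a note.
#'
#' @param annotations,metadata Annotation and metadata tibbles.
#' @param journal_metrics A tibble with `journal`, `impact_factor`,
#'   `h_index` (see [read_journal_metrics()]).
#' @param min_articles Only journals with at least this many articles enter
#'   the correlation (default 1).
#' @return A list with `index` (per-journal tibble) and `correlations`
#'   (tibble: `metric`, `r`, `p_value`, `n`).
#' @export
journal_metric_correlation <- function(annotations, metadata,
                                       journal_metrics, min_articles = 1) {
  bd <- reporting_breakdown(annotations, metadata, by = "journal")
  idx <- bd |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_any = sum(.data$n[.data$category != "none"]),
      n_none = sum(.data$n[.data$category == "none"]),
      n_total = dplyr::first(.data$n_stratum)
    ) |>
    dplyr::rename(journal = "stratum") |>
    dplyr::filter(.data$n_total >= min_articles)
  idx$reporting_index <- purrr::map2_dbl(
    idx$n_any, idx$n_none,
    function(a, b) suppressWarnings(journal_reporting_index(a, b))
  )
  dropped <- idx$journal[is.na(idx$reporting_index)]
  if (length(dropped) > 0) {
    message("excluding journal(s) with undefined reporting index: ",
            paste(dropped, collapse = ", "))
  }
  joined <- dplyr::inner_join(
    idx[!is.na(idx$reporting_index), ], journal_metrics, by = "journal"
  )
  cors <- purrr::map_dfr(c("impact_factor", "h_index"), function(metric) {
    ok <- !is.na(joined[[metric]])
    if (sum(ok) < 3) {
      return(tibble::tibble(metric = metric, r = NA_real_,
                            p_value = NA_real_, n = sum(ok)))
    }
    res <- spearman_rank_corr(joined$reporting_index[ok], joined[[metric]][ok])
    tibble::tibble(metric = metric, r = res$r, p_value = res$p_value,
                   n = res$n)
  })
  list(index = joined, correlations = cors)
}
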