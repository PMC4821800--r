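# Independent oracles and small fixture builders used across the suite.

default_ruleset <- compile_rules(default_rules())

# brute-force per-document confusion tally (independent of confusion_matrix)
oracle_confusion <- function(system, gold, characteristic) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(system))) {
    g <- gold[gold$doc_id == system$doc_id[i], ]
    if (characteristic == "sex") {
      s_rep <- system$sex_status[i] != "none"
      g_rep <- g$sex_status != "none"
      ok <- s_rep && g_rep && system$sex_status[i] == g$sex_status
    } else {
      s_rep <- system$age_status[i] != "none"
      g_rep <- g$age_status != "none"
      ok <- s_rep && g_rep &&
        isTRUE(all.equal(
          unname(normalize_age_to_days(system$age_min[i], system$age_max[i],
                                       system$age_unit[i])),
          unname(normalize_age_to_days(g$age_min, g$age_max, g$age_unit))
        ))
    }
    if (ok) tp <- tp + 1
    else if (s_rep) fp <- fp + 1
    else if (g_rep) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# textbook sum-of-squares partition for a two-factor table, one obs per cell
oracle_anova_ss <- function(m) {
  m <- as.matrix(m)
  r <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- r * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  c(rows = ss_rows, cols = ss_cols,
    resid = ss_total - ss_rows - ss_cols, total = ss_total)
}

# rank-transform + Pearson covariance formula + t approximation
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# exact two-sided binomial p-value by tail enumeration under p = 0.5
oracle_binom_p <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  min(1, sum(probs[probs <= dbinom(k, n, 0.5) * (1 + 1e-7)]))
}

# closed-form OLS slope
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# quick annotation-row builder
ann_row <- function(doc_id, sex = "none", age = NULL) {
  tibble::tibble(
    doc_id = doc_id,
    sex_status = sex, sex_qualifier = NA_character_,
    sex_surface = NA_character_, sex_start = NA_integer_,
    sex_end = NA_integer_, sex_rule = NA_character_,
    age_status = if (is.null(age)) "none" else "reported",
    age_min = if (is.null(age)) NA_real_ else age[[1]],
    age_max = if (is.null(age)) NA_real_ else age[[2]],
    age_unit = if (is.null(age)) NA_character_ else age[[3]],
    age_surface = NA_character_, age_start = NA_integer_,
    age_end = NA_integer_, age_rule = NA_character_
  )
}

gold_row <- function(doc_id, sex = "none", age = NULL) {
  tibble::tibble(
    doc_id = doc_id, sex_status = sex,
    age_status = if (is.null(age)) "none" else "reported",
    age_min = if (is.null(age)) NA_real_ else age[[1]],
    age_max = if (is.null(age)) NA_real_ else age[[2]],
    age_unit = if (is.null(age)) NA_character_ else age[[3]]
  )
}

# random pair whose disagreements are presence/absence only (values always
# copied from gold when both report) — the domain where swapping system and
# gold exchanges FP and FN
random_presence_pair <- function(n, seed) {
  withr::with_seed(seed, {
    sexes <- c("female", "male", "both", "none")
    units <- c("day", "week", "month")
    g <- purrr::map_dfr(seq_len(n), function(i) {
      age <- if (runif(1) < 0.6) {
        a <- sample(1:9, 1); list(a, a + sample(0:3, 1), sample(units, 1))
      }
      gold_row(paste0("d", i), sample(sexes, 1), age)
    })
    s <- purrr::map_dfr(seq_len(n), function(i) {
      gi <- g[i, ]
      sex <- if (runif(1) < 0.7 && gi$sex_status != "none") {
        gi$sex_status
      } else if (runif(1) < 0.2 && gi$sex_status == "none") {
        "female"  # spurious report where gold is absent
      } else {
        "none"
      }
      age <- if (runif(1) < 0.7 && gi$age_status == "reported") {
        list(gi$age_min, gi$age_max, gi$age_unit)
      } else if (runif(1) < 0.2 && gi$age_status == "none") {
        list(2, 4, "week")
      }
      ann_row(gi$doc_id, sex, age)
    })
    list(system = s, gold = g)
  })
}

# random gold/system micro-corpus for oracle cross-checks
random_eval_pair <- function(n, seed) {
  withr::with_seed(seed, {
    sexes <- c("female", "male", "both", "none")
    units <- c("day", "week", "month")
    g <- purrr::map_dfr(seq_len(n), function(i) {
      age <- if (runif(1) < 0.6) {
        a <- sample(1:9, 1); list(a, a + sample(0:3, 1), sample(units, 1))
      }
      gold_row(paste0("d", i), sample(sexes, 1), age)
    })
    s <- purrr::map_dfr(seq_len(n), function(i) {
      if (runif(1) < 0.6) {  # copy gold
        gi <- g[i, ]
        age <- if (gi$age_status == "reported") {
          list(gi$age_min, gi$age_max, gi$age_unit)
        }
        ann_row(gi$doc_id, gi$sex_status, age)
      } else {               # random annotation
        age <- if (runif(1) < 0.5) {
          a <- sample(1:9, 1); list(a, a + sample(0:3, 1), sample(units, 1))
        }
        ann_row(paste0("d", i), sample(sexes, 1), age)
      }
    })
    list(system = s, gold = g)
  })
}
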