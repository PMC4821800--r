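mk_ann4 <- function() {
  dplyr::bind_rows(
    ann_row("d1", "female", list(6, 8, "week")),  # both
    ann_row("d2", "male"),                        # sex only
    ann_row("d3", age = list(3, 3, "day")),       # age only
    ann_row("d4")                                 # none
  )
}

test_that("reporting categories partition the corpus in every stratum", {
  ann <- mk_ann4()
  bd <- reporting_breakdown(ann)
  expect_equal(sort(bd$category), sort(c("both", "sex_only", "age_only",
                                         "none")))
  expect_equal(bd$n, rep(1L, 4))
  expect_equal(bd$pct, rep(25, 4))
  expect_equal(sum(bd$n), nrow(ann))

  expect_equal(nrow(reporting_breakdown(ann[0, ])), 0)

  md <- tibble::tibble(
    doc_id = paste0("d", 1:4), year = c(2001L, 2001L, 2002L, 2002L),
    journal = "J", disease_groups = c("cancer;lung", "cancer", "lung",
                                      "cancer"),
    subgroups = "genetics"
  )
  by_year <- reporting_breakdown(ann, md, by = "year")
  sums <- tapply(by_year$n, by_year$stratum, sum)
  expect_equal(as.vector(sums), c(2L, 2L))
  by_grp <- reporting_breakdown(ann, md, by = "disease_group")
  expect_equal(sum(by_grp$n[by_grp$stratum == "cancer"]), 3)  # d1,d2,d4
  expect_equal(sum(by_grp$n[by_grp$stratum == "lung"]), 2)    # d1,d3
  pct_sum <- tapply(by_grp$pct, by_grp$stratum, sum)
  expect_true(all(abs(pct_sum - 100) < 0.05))
  expect_error(reporting_breakdown(ann, md, by = "strain"),
               "unknown stratification field")
})

test_that("yearly fractions are normalized per article-year", {
  ann <- dplyr::bind_rows(purrr::map(1:10, function(i) {
    if (i <= 5) ann_row(paste0("d", i)) else
      ann_row(paste0("d", i), "female", list(6, 8, "week"))
  }))
  md <- tibble::tibble(doc_id = paste0("d", 1:10), year = 2005L,
                       journal = "J", disease_groups = "cancer",
                       subgroups = "therapy")
  tr <- yearly_trend(reporting_breakdown(ann, md, by = "year"))
  expect_equal(tr$fraction[tr$category == "none"], 0.5)
  expect_equal(sum(tr$fraction), 1)
})

test_that("trend slopes match the closed-form OLS oracle", {
  expect_equal(
    trend_slope(data.frame(year = c(2000, 2010), fraction = c(1, 0.55))),
    -0.045
  )
  expect_equal(
    trend_slope(data.frame(year = 2000:2010, fraction = rep(0.3, 11))), 0)
  withr::with_seed(13, {
    for (i in 1:5) {
      yr <- 1994:2014
      fr <- runif(length(yr))
      expect_equal(trend_slope(data.frame(year = yr, fraction = fr)),
                   oracle_ols_slope(yr, fr))
    }
  })
  expect_error(trend_slope(data.frame(year = 2000, fraction = 0.5)),
               "two distinct years")
})

test_that("sex-bias ratios report the majority direction", {
  expect_equal(as.list(sex_bias_ratio(45, 20)),
               list(direction = "female", ratio = 2.25))
  expect_equal(as.list(sex_bias_ratio(354, 100)),
               list(direction = "female", ratio = 3.54))
  expect_equal(as.list(sex_bias_ratio(100, 225)),
               list(direction = "male", ratio = 2.25))
  expect_equal(as.list(sex_bias_ratio(7, 7)),
               list(direction = "none", ratio = 1))
  expect_warning(res <- sex_bias_ratio(0, 0), "undefined")
  expect_true(is.na(res$ratio))
  # invariant under scaling both counts
  expect_equal(sex_bias_ratio(45, 20)$ratio, sex_bias_ratio(450, 200)$ratio)
})

test_that("binomial proportion test: exact p, normal CI", {
  res <- binomial_proportion_test(50, 50)
  expect_equal(res$p_hat_pct, 50)
  expect_equal(res$p_value, 1)

  res <- binomial_proportion_test(10, 0)
  expect_equal(res$p_value, oracle_binom_p(10, 10))
  expect_equal(res$p_value, 2 * 0.5^10)

  withr::with_seed(17, {
    for (i in 1:5) {
      n <- sample(20:60, 1); k <- sample(0:n, 1)
      expect_equal(binomial_proportion_test(k, n - k)$p_value,
                   oracle_binom_p(k, n))
    }
  })
  expect_error(binomial_proportion_test(0, 0), "zero total")
})

test_that("the normal CI shrinks as 1/sqrt(n)", {
  a <- binomial_proportion_test(300, 200)
  b <- binomial_proportion_test(1200, 800)
  w_a <- a$ci_high_pct - a$ci_low_pct
  w_b <- b$ci_high_pct - b$ci_low_pct
  expect_equal(w_a / w_b, 2, tolerance = 1e-10)
  # Clopper-Pearson variant is available and wider here
  cp <- binomial_proportion_test(300, 200, ci_method = "exact")
  expect_gt(cp$ci_high_pct - cp$ci_low_pct, 0)
})

test_that("two-way ANOVA partitions the sums of squares exactly", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6))
  res <- two_way_anova_no_replication(m)
  ss <- oracle_anova_ss(m)
  expect_equal(res$sumsq[res$term == "rows"], ss[["rows"]])
  expect_equal(res$sumsq[res$term == "columns"], ss[["cols"]])
  expect_equal(res$sumsq[res$term == "residuals"], ss[["resid"]])
  expect_equal(res$df[1:3], c(1, 2, 2))
  expect_equal(res$statistic[res$term == "rows"],
               (ss[["rows"]] / 1) / (ss[["resid"]] / 2))

  withr::with_seed(23, {
    for (i in 1:5) {
      r <- sample(3:6, 1); k <- sample(3:5, 1)
      mm <- matrix(runif(r * k, 0, 100), r, k)
      res <- two_way_anova_no_replication(mm)
      ss <- oracle_anova_ss(mm)
      expect_equal(res$sumsq[1:3],
                   unname(ss[c("rows", "cols", "resid")]),
                   tolerance = 1e-9)
      expect_equal(sum(res$sumsq[1:3]), ss[["total"]], tolerance = 1e-9)
      # permuting rows leaves the partition unchanged
      perm <- two_way_anova_no_replication(mm[sample(r), ])
      expect_equal(perm$sumsq, res$sumsq, tolerance = 1e-9)
    }
  })
})

test_that("degenerate ANOVA inputs are rejected or signalled", {
  expect_error(two_way_anova_no_replication(matrix(1, 1, 3)), "at least 2")
  expect_error(two_way_anova_no_replication(matrix(c(1, NA, 2, 3), 2, 2)),
               "missing cells")
  expect_warning(res <- two_way_anova_no_replication(matrix(5, 3, 3)),
                 "undefined")
  expect_equal(res$sumsq[1:3], c(0, 0, 0))
})

test_that("the journal reporting index guards its denominator", {
  expect_equal(journal_reporting_index(30, 10), 3)
  expect_equal(journal_reporting_index(0, 10), 0)
  expect_warning(idx <- journal_reporting_index(10, 0), "undefined")
  expect_true(is.na(idx))
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(spearman_rank_corr(1:10, (1:10)^2)$r, 1)
  expect_equal(spearman_rank_corr(1:10, -(1:10))$r, -1)
  withr::with_seed(29, {
    for (i in 1:5) {
      x <- rnorm(12); y <- rnorm(12) + 0.5 * x
      res <- spearman_rank_corr(x, y)
      orc <- oracle_spearman(x, y)
      expect_equal(res$r, orc[["r"]], tolerance = 1e-12)
      expect_equal(res$p_value, orc[["p"]], tolerance = 1e-9)
    }
  })
  expect_error(spearman_rank_corr(1:5, 1:4), "length mismatch")
  expect_error(spearman_rank_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rank_corr(1:2, 1:2), "at least 3")
})
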