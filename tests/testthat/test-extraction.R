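# Worked sentences: positives and documented misses of the rule engine.

rs <- default_ruleset

test_that("sex dictionary matching handles the worked sentences", {
  m <- match_sex_mentions("mice of either sex were used", rs)
  expect_equal(nrow(m), 1)
  expect_equal(m$sex_category, "both")

  m <- match_sex_mentions("ten C57BL/6 female mice (6-8-weeks old)", rs)
  expect_equal(nrow(m), 1)
  expect_match(m$surface, "female")
  expect_equal(m$sex_category, "female")

  # sex is never inferred from pregnancy
  m <- match_sex_mentions(paste(
    "Primary mouse mammary epithelial (PMME) cells were isolated from",
    "15-d timed-pregnant CD-1 mice"), rs)
  expect_equal(nrow(m), 0)

  # breeding-scheme false positives are reproduced, not fixed
  m <- match_sex_mentions(
    "maintained by crossing male carriers with FVB/NJ females", rs)
  expect_equal(m$sex_category, c("male", "female"))
  expect_equal(m$surface, c("male", "females"))
})

test_that("age patterns handle the worked sentences", {
  m <- match_age_mentions("aged 3 to 8 weeks old", rs)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$age_min, m$age_max), c(3, 8))
  expect_equal(m$age_unit, "week")

  m <- match_age_mentions("by peritoneal into 8–12 weeks old C56Bl/6 mice", rs)
  expect_equal(c(m$age_min, m$age_max), c(8, 12))

  # open-ended span: no closed numeric range, no mention
  m <- match_age_mentions(
    "of ages from postnatal day (P) 7 to several months", rs)
  expect_equal(nrow(m), 0)

  m <- match_age_mentions("tracheas of 3-weeks old Gprc5a mice", rs)
  expect_equal(c(m$age_min, m$age_max), c(3, 3))

  # numeral + unit without an age clue is not an age mention
  m <- match_age_mentions("isolated from 15-d timed-pregnant CD-1 mice", rs)
  expect_equal(nrow(m), 0)
})

test_that("every mention's surface equals the text slice at its offsets", {
  texts <- c(
    "ten C57BL/6 female mice (6-8-weeks old) were used",
    "Male and female mice aged 3 to 8 weeks old; later, females only.",
    "Mice of either sex (between 6 and 8 weeks of age) were examined."
  )
  for (txt in texts) {
    m <- dplyr::bind_rows(match_sex_mentions(txt, rs),
                          match_age_mentions(txt, rs))
    expect_gt(nrow(m), 0)
    expect_equal(m$surface, substr(rep(txt, nrow(m)), m$start + 1, m$end))
    expect_true(all(m$start >= 0 & m$start < m$end & m$end <= nchar(txt)))
  }
})

test_that("matching is deterministic and case-insensitive", {
  txt <- "FEMALE MICE AGED 3 TO 8 WEEKS OLD WERE USED"
  lo <- "female mice aged 3 to 8 weeks old were used"
  m_up <- dplyr::bind_rows(match_sex_mentions(txt, rs),
                           match_age_mentions(txt, rs))
  m_lo <- dplyr::bind_rows(match_sex_mentions(lo, rs),
                           match_age_mentions(lo, rs))
  expect_equal(m_up[, c("start", "end", "kind", "sex_category",
                        "age_min", "age_max", "age_unit")],
               m_lo[, c("start", "end", "kind", "sex_category",
                        "age_min", "age_max", "age_unit")])
  expect_identical(match_sex_mentions(lo, rs), match_sex_mentions(lo, rs))
})

test_that("injecting a template sentence adds exactly one expected mention", {
  filler <- paste(
    "Tissue samples were collected and processed.",
    "Statistical significance was assessed with nonparametric tests.",
    "Histological sections were stained with hematoxylin and eosin."
  )
  probes <- list(
    list(txt = "Adult female mice were obtained from the vendor.",
         kind = "sex", cat = "female"),
    list(txt = "Mice of either sex were used.", kind = "sex", cat = "both"),
    list(txt = "The animals were aged 2 to 5 months old.", kind = "age",
         val = c(2, 5), unit = "month"),
    list(txt = "Animals were 9 days old at the time of infection.",
         kind = "age", val = c(9, 9), unit = "day")
  )
  withr::with_seed(11, {
    for (p in probes) {
      for (rep in 1:3) {
        words <- strsplit(filler, "(?<=\\.) ", perl = TRUE)[[1]]
        pos <- sample(0:length(words), 1)
        doc <- paste(append(words, p$txt, after = pos), collapse = " ")
        m <- if (p$kind == "sex") match_sex_mentions(doc, rs) else
          match_age_mentions(doc, rs)
        expect_equal(nrow(m), 1)
        if (p$kind == "sex") {
          expect_equal(m$sex_category, p$cat)
        } else {
          expect_equal(c(m$age_min, m$age_max), p$val)
          expect_equal(m$age_unit, p$unit)
        }
      }
    }
  })
})

test_that("no age mention is emitted without a bound numeral", {
  misses <- c(
    "mice of several weeks of age",
    "aged mice were compared with young animals",
    "for many months the colony was monitored",
    "old mice were used throughout"
  )
  for (txt in misses) {
    expect_equal(nrow(match_age_mentions(txt, rs)), 0)
  }
})

test_that("age phrase parsing normalizes numerals, connectors and units", {
  expect_equal(
    as.list(parse_age_phrase("6-8-weeks old"))[c("age_min", "age_max", "age_unit")],
    list(age_min = 6, age_max = 8, age_unit = "week")
  )
  p <- parse_age_phrase("six weeks of age")
  expect_equal(c(p$age_min, p$age_max), c(6, 6))
  expect_equal(p$age_qualifier, "exact")
  p <- parse_age_phrase("15-d")
  expect_equal(c(p$age_min, p$age_max, p$age_unit), c("15", "15", "day"))
  p <- parse_age_phrase("aged 2 and 3 mos")
  expect_equal(p$age_unit, "month")
  expect_equal(p$age_qualifier, "range")
  expect_error(parse_age_phrase("weeks old"), "unparseable")
  expect_error(parse_age_phrase("3 to 8"), "unparseable")
})

test_that("day normalization follows the declared 1/7/30 convention", {
  expect_equal(normalize_age_to_days(6, 8, "week"),
               c(min_days = 42, max_days = 56))
  expect_equal(normalize_age_to_days(3, 3, "day"),
               c(min_days = 3, max_days = 3))
  expect_equal(normalize_age_to_days(1, 2, "month"),
               c(min_days = 30, max_days = 60))
  expect_error(normalize_age_to_days(2, 1, "week"), "age_min")
  expect_error(normalize_age_to_days(1, 2, "year"), "unknown age unit")
})
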