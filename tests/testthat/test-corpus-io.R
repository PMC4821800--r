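test_that("plain-text corpora load one document per readable file", {
  dir <- withr::local_tempdir()
  writeLines("Female mice were used.", file.path(dir, "a.txt"))
  writeLines("No animals here.", file.path(dir, "b.txt"))
  writeLines("aged 3 to 8 weeks old", file.path(dir, "c.txt"))
  res <- read_plain_text_corpus(dir)
  expect_equal(nrow(res$documents), 3)
  expect_equal(res$documents$doc_id, c("a", "b", "c"))
  expect_equal(nrow(res$rejects), 0)

  empty <- withr::local_tempdir()
  res0 <- read_plain_text_corpus(empty)
  expect_equal(nrow(res0$documents), 0)
})

test_that("non-UTF-8 files are rejected, not silently dropped", {
  dir <- withr::local_tempdir()
  writeLines("plain ascii", file.path(dir, "ok.txt"))
  # latin-1 bytes that are not valid UTF-8
  writeBin(c(charToRaw("caf"), as.raw(0xe9)), file.path(dir, "bad.txt"))
  expect_warning(res <- read_plain_text_corpus(dir), "bad.txt")
  expect_equal(res$documents$doc_id, "ok")
  expect_equal(res$rejects$file, "bad.txt")
  # nothing is silently dropped
  expect_equal(nrow(res$documents) + nrow(res$rejects), 2)
})

test_that("manifests map filenames to ids and duplicates are fatal", {
  dir <- withr::local_tempdir()
  writeLines("one", file.path(dir, "x.txt"))
  writeLines("two", file.path(dir, "y.txt"))
  man <- tibble::tibble(file = c("x.txt", "y.txt"), doc_id = c("d9", "d8"))
  res <- read_plain_text_corpus(dir, man)
  expect_equal(res$documents$doc_id, c("d9", "d8"))
  man$doc_id <- c("d9", "d9")
  expect_error(read_plain_text_corpus(dir, man), "duplicate doc_id")
})

jats <- function(body, front = "") {
  paste0(
    "<article><front><journal-meta><journal-title-group>",
    "<journal-title>Journal A</journal-title></journal-title-group>",
    "</journal-meta><article-meta>",
    "<article-id pub-id-type='pmc'>PMC123</article-id>",
    "<pub-date><year>2010</year></pub-date>", front,
    "</article-meta></front>", body, "</article>"
  )
}

test_that("JATS bodies are concatenated in document order with sections", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(jats("<body><p>mice of either sex were used</p></body>"), f)
  doc <- read_jats_xml(f)
  expect_equal(doc$doc_id, "PMC123")
  expect_equal(doc$journal, "Journal A")
  expect_equal(doc$year, 2010L)
  expect_match(doc$text, "mice of either sex were used")

  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(jats(paste0(
    "<body><sec><title>Methods</title><p>FIRST marker</p></sec>",
    "<sec><title>Results</title><p>SECOND marker</p></sec></body>"
  )), f2)
  doc2 <- read_jats_xml(f2)
  segs <- doc2$segments[[1]]
  expect_equal(segs$section, c("Methods", "Results"))
  expect_lt(regexpr("FIRST", doc2$text), regexpr("SECOND", doc2$text))
})

test_that("missing bodies warn and malformed XML names the file", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(jats(""), f)
  expect_warning(doc <- read_jats_xml(f), "no <body>")
  expect_equal(doc$text, "")

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<article><front>", bad)
  expect_error(read_jats_xml(bad), basename(bad))
})

test_that("gold tables parse statuses, categories and age phrases", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    doc_id = c("d1", "d2", "d3", "d4"),
    sex_status = c("reported", "none", "both (mixed)", "reported"),
    sex_value = c("female", "", "", "male"),
    age_status = c("reported", "none", "reported", "none"),
    age_value = c("6-8 weeks", "", "15 days", "")
  ), f)
  g <- read_gold_annotations(f)
  expect_equal(g$sex_status, c("female", "none", "both", "male"))
  expect_equal(g$age_status, c("reported", "none", "reported", "none"))
  expect_equal(g$age_min[1], 6)
  expect_equal(g$age_max[1], 8)
  expect_equal(g$age_unit[3], "day")

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    doc_id = "d1", sex_status = "hermaphrodite", sex_value = "",
    age_status = "none", age_value = ""
  ), bad)
  expect_error(read_gold_annotations(bad), "row 1")
})

test_that("annotations round-trip through TSV and JSON-lines", {
  syn <- generate_corpus(synth_config(n_docs = 10, seed = 3))
  ann <- annotate_corpus(syn$documents)
  for (fmt in c("tsv", "jsonl")) {
    f <- withr::local_tempfile(
      fileext = if (fmt == "tsv") ".tsv" else ".jsonl")
    write_annotations(ann, f)
    back <- read_annotations(f)
    expect_equal(as.data.frame(back), as.data.frame(ann))
  }
})

test_that("empty annotation sets and absent ages serialize cleanly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(annotate_corpus(
    tibble::tibble(doc_id = character(), text = character())), f)
  expect_equal(readLines(f)[1], paste(
    c("doc_id", "sex_status", "sex_qualifier", "sex_surface", "sex_start",
      "sex_end", "sex_rule", "age_status", "age_min", "age_max", "age_unit",
      "age_surface", "age_start", "age_end", "age_rule"),
    collapse = "\t"))
  expect_equal(length(readLines(f)), 1)  # header-only

  ann <- annotate_corpus(tibble::tibble(doc_id = "d1", text = "no info"))
  write_annotations(ann, f)
  lines <- readLines(f)
  expect_false(grepl("NA", lines[2]))    # empty fields, not the string "NA"
  expect_true(is.na(read_annotations(f)$age_min))
})
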