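test_that("FAERS-style join keeps only reports with both a drug and a reaction", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$quarter$age$wt$sex$indi_pt",
               "r1$2010Q1$55$80$F$Hypertension",
               "r2$2010Q1$abc$80$X$Hypertension",
               "r3$2010Q2$40$75$M$Hypertension"),
             file.path(dir, "demo.txt"))
  writeLines(c("primaryid$drug_seq$drugname",
               "r1$1$losartan", "r2$1$quinapril"),
             file.path(dir, "drug.txt"))
  writeLines(c("primaryid$pt",
               "r1$cough", "r2$dyspnea", "r3$cough"),
             file.path(dir, "reac.txt"))
  rs <- read_faers_quarter(file.path(dir, "demo.txt"),
                           file.path(dir, "drug.txt"),
                           file.path(dir, "reac.txt"))
  expect_equal(nrow(rs), 2)               # r3 has no drug mention
  expect_setequal(rs$report_id, c("r1", "r2"))
  expect_equal(attr(rs, "provenance")$records, c(3L, 2L, 3L))
  # unparseable age and out-of-vocabulary sex are coerced, not dropped
  r2 <- rs[rs$report_id == "r2", ]
  expect_true(is.na(r2$age))
  expect_equal(r2$sex, "U")
})

test_that("empty DRUG file with a valid header yields zero reports but full provenance", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$quarter$age$wt$sex$indi_pt",
               "r1$2010Q1$55$80$F$Hypertension",
               "r2$2010Q1$60$70$M$Hypertension",
               "r3$2010Q2$40$75$M$Hypertension"),
             file.path(dir, "demo.txt"))
  writeLines("primaryid$drug_seq$drugname", file.path(dir, "drug.txt"))
  writeLines(c("primaryid$pt", "r1$cough", "r2$cough", "r3$cough"),
             file.path(dir, "reac.txt"))
  rs <- read_faers_quarter(file.path(dir, "demo.txt"),
                           file.path(dir, "drug.txt"),
                           file.path(dir, "reac.txt"))
  expect_equal(nrow(rs), 0)
  expect_equal(attr(rs, "provenance")$records[1], 3L)
})

test_that("malformed headers and orphan rows are handled as contract says", {
  dir <- withr::local_tempdir()
  writeLines(c("id$quarter", "r1$2010Q1"), file.path(dir, "demo.txt"))
  writeLines("primaryid$drug_seq$drugname", file.path(dir, "drug.txt"))
  writeLines("primaryid$pt", file.path(dir, "reac.txt"))
  expect_error(read_faers_quarter(file.path(dir, "demo.txt"),
                                  file.path(dir, "drug.txt"),
                                  file.path(dir, "reac.txt")),
               "demo.txt")

  writeLines(c("primaryid$quarter$age$wt$sex$indi_pt",
               "r1$2010Q1$55$80$F$Hypertension"),
             file.path(dir, "demo.txt"))
  writeLines(c("primaryid$drug_seq$drugname",
               "r1$1$losartan", "zzz$1$ghost"), file.path(dir, "drug.txt"))
  writeLines(c("primaryid$pt", "r1$cough"), file.path(dir, "reac.txt"))
  expect_message(
    rs <- read_faers_quarter(file.path(dir, "demo.txt"),
                             file.path(dir, "drug.txt"),
                             file.path(dir, "reac.txt")),
    "no matching DEMO")
  expect_equal(nrow(rs), 1)
  expect_equal(attr(rs, "dropped")[["orphan_rows"]], 1L)
})

test_that("FAERS round-trip is the identity on report sets", {
  for (seed in 1:5) {
    rs <- random_report_set(20, seed)
    dir <- withr::local_tempdir()
    paths <- write_faers_quarter(rs, dir)
    back <- read_faers_quarter(paths["demo"], paths["drug"], paths["reac"])
    for (col in c("report_id", "quarter", "age", "weight", "sex",
                  "indication", "drug_mentions", "reactions")) {
      expect_equal(back[[col]], rs[[col]], info = paste("seed", seed, col))
    }
  }
})

test_that("write cardinality matches mention counts and dollar signs are sanitized", {
  rs <- make_reports(tibble::tibble(
    report_id = "a1",
    drug_mentions = list(c("losartan $50", "quinapril")),
    reactions = list(c("cough", "dyspnea", "pleurisy"))
  ))
  dir <- withr::local_tempdir()
  paths <- write_faers_quarter(rs, dir)
  expect_length(readLines(paths["drug"]), 3)   # header + 2
  expect_length(readLines(paths["reac"]), 4)   # header + 3
  back <- read_faers_quarter(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(back$drug_mentions[[1]][1], "losartan  50")

  empty <- rs[0, ]
  paths2 <- write_faers_quarter(empty, withr::local_tempdir())
  expect_true(all(vapply(paths2, function(p) length(readLines(p)) == 1,
                         logical(1))))
})

test_that("flat CSV groups rows by report and collapses duplicate triples", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "flat.csv")
  writeLines(c("report_id,quarter,age,weight,sex,drug,reaction",
               "r1,2010Q1,55,80,F,losartan,cough",
               "r1,2010Q1,55,80,F,losartan,dyspnea",
               "r1,2010Q1,55,80,F,quinapril,cough",
               "r1,2010Q1,55,80,F,quinapril,dyspnea",
               "r1,2010Q1,55,80,F,quinapril,dyspnea"), path)
  rs <- read_flat_csv(path)
  expect_equal(nrow(rs), 1)
  expect_setequal(rs$drug_mentions[[1]], c("losartan", "quinapril"))
  expect_setequal(rs$reactions[[1]], c("cough", "dyspnea"))

  writeLines("report_id,quarter", file.path(dir, "bad.csv"))
  expect_error(read_flat_csv(file.path(dir, "bad.csv")), "missing column")
})

test_that("flat CSV round-trips through write_flat_csv", {
  rs <- random_report_set(15, 42)
  path <- file.path(withr::local_tempdir(), "flat.csv")
  write_flat_csv(rs, path)
  back <- read_flat_csv(path)
  expect_equal(nrow(back), nrow(rs))
  # triple counts conserved (report sets store drug/reaction sets, so the
  # flat file is the full cross product per report)
  expect_equal(sum(lengths(back$drug_mentions) * lengths(back$reactions)),
               sum(lengths(rs$drug_mentions) * lengths(rs$reactions)))
})

test_that("gzip-compressed inputs are read transparently", {
  rs <- random_report_set(8, 3)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "flat.csv")
  write_flat_csv(rs, path)
  gzpath <- file.path(dir, "flat.csv.gz")
  con <- gzfile(gzpath, "w")
  writeLines(readLines(path), con)
  close(con)
  expect_equal(nrow(read_flat_csv(gzpath)), nrow(rs))
})

test_that("report_set validates its invariants", {
  base <- tibble::tibble(report_id = "x", quarter = "2010Q1", age = 50,
                         weight = 70, sex = "F", indication = NA_character_,
                         drug_mentions = list("a"), reactions = list("b"))
  expect_s3_class(report_set(base), "report_set")
  expect_error(report_set(dplyr::mutate(base, age = 200)), "age")
  expect_error(report_set(dplyr::mutate(base, weight = 0)), "weight")
  expect_error(report_set(dplyr::mutate(base, drug_mentions = list(character()))),
               "drug")
  expect_error(report_set(rbind(base, base)), "unique")
})
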