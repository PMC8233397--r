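# Report container and readers/writers for the simplified FAERS-style
# quarterly dialect (three $-delimited tables) and the flat CSV form.

#' Construct a report set
#'
#' A `report_set` is a tibble with one row per spontaneous safety report and
#' list-columns for the verbatim drug mentions and reaction terms, plus a
#' `provenance` attribute recording how many raw records each source file
#' contributed (before any report was dropped).
#'
#' @param reports A data frame with columns `report_id`, `quarter`, `age`,
#'   `weight`, `sex`, `indication` and list-columns `drug_mentions`,
#'   `reactions`.
#' @param provenance A tibble with columns `source` and `records`, or `NULL`.
#' @param dropped Named integer vector of reports dropped at read time
#'   (e.g. `no_drug`, `no_reaction`, `orphan_rows`).
#'
#' @return A tibble of class `report_set`.
#' @export
report_set <- function(reports, provenance = NULL, dropped = integer()) {
  reports <- as_tibble(reports)
  required <- c("report_id", "quarter", "age", "weight", "sex",
                "indication", "drug_mentions", "reactions")
  missing_cols <- setdiff(required, names(reports))
  if (length(missing_cols) > 0) {
    stop("report_set is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  reports <- reports[required]
  if (anyDuplicated(reports$report_id)) {
    stop("report_id values must be unique within a report_set")
  }
  if (any(!nzchar(reports$report_id))) stop("report_id must be non-empty")
  bad_drug <- vapply(reports$drug_mentions,
                     function(d) length(d) == 0 || all(!nzchar(d)), logical(1))
  bad_reac <- vapply(reports$reactions,
                     function(r) length(r) == 0 || all(!nzchar(r)), logical(1))
  if (any(bad_drug) || any(bad_reac)) {
    stop("every report needs at least one non-empty drug mention and reaction")
  }
  if (any(reports$age < 0 | reports$age > 130, na.rm = TRUE)) {
    stop("age must lie in [0, 130] or be missing")
  }
  if (any(reports$weight <= 0 | reports$weight > 700, na.rm = TRUE)) {
    stop("weight must lie in (0, 700] or be missing")
  }
  reports$sex <- ifelse(reports$sex %in% c("M", "F"), reports$sex, "U")
  if (is.null(provenance)) {
    provenance <- tibble(source = character(), records = integer())
  }
  structure(reports,
            provenance = as_tibble(provenance),
            dropped = dropped,
            class = c("report_set", class(reports)))
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", nrow(x), " reports\n", sep = "")
  prov <- attr(x, "provenance")
  if (nrow(prov) > 0) {
    cat("sources: ",
        paste0(prov$source, " (", prov$records, ")", collapse = ", "),
        "\n", sep = "")
  }
  dropped <- attr(x, "dropped")
  if (length(dropped) > 0 && sum(dropped) > 0) {
    cat("dropped: ",
        paste0(names(dropped), "=", dropped, collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

# FAERS legacy files are $-delimited with no quoting; all readers accept
# plain or gzip-compressed files (readr sniffs the compression).
.read_dollar <- function(path, required_cols) {
  tab <- tryCatch(
    readr::read_delim(path, delim = "$", quote = "",
                      col_types = readr::cols(.default = readr::col_character()),
                      na = c("", "NA"), progress = FALSE,
                      show_col_types = FALSE),
    error = function(e) stop("failed to read ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  missing_cols <- setdiff(required_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("malformed header in ", path, ": missing field(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab
}

.parse_num <- function(x, lo, hi, open_lo = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- !is.na(v) & (v > hi | if (open_lo) v <= lo else v < lo)
  v[bad] <- NA_real_
  v
}

#' Read a FAERS-style quarter (DEMO/DRUG/REAC)
#'
#' Reads the three `$`-delimited tables of the simplified FAERS quarterly
#' dialect and joins them on `primaryid` into one [report_set()]. Reports
#' with no drug mention or no reaction are dropped (the analysis unit is the
#' drug-event pair) and counted in the `dropped` attribute; DRUG/REAC rows
#' whose id is absent from DEMO are skipped and counted as orphans.
#' Unparseable or out-of-range ages and weights become missing; sex values
#' outside M/F become U.
#'
#' @param demo_path,drug_path,reac_path Paths to the DEMO, DRUG and REAC
#'   files (optionally gzip-compressed). DEMO needs fields `primaryid`,
#'   `quarter`, `age`, `wt`, `sex` (plus optional `indi_pt`); DRUG needs
#'   `primaryid`, `drugname`; REAC needs `primaryid`, `pt`.
#'
#' @return A [report_set()].
#' @export
read_faers_quarter <- function(demo_path, drug_path, reac_path) {
  demo <- .read_dollar(demo_path, c("primaryid", "quarter", "age", "wt", "sex"))
  drug <- .read_dollar(drug_path, c("primaryid", "drugname"))
  reac <- .read_dollar(reac_path, c("primaryid", "pt"))

  provenance <- tibble(
    source = c(demo_path, drug_path, reac_path),
    records = c(nrow(demo), nrow(drug), nrow(reac))
  )

  drug <- drug[!is.na(drug$drugname) & nzchar(drug$drugname), ]
  reac <- reac[!is.na(reac$pt) & nzchar(reac$pt), ]
  orphan <- sum(!(drug$primaryid %in% demo$primaryid)) +
    sum(!(reac$primaryid %in% demo$primaryid))
  if (orphan > 0) {
    message(orphan, " DRUG/REAC row(s) had no matching DEMO record; skipped")
  }

  drugs_by_id <- split(drug$drugname, factor(drug$primaryid, levels = demo$primaryid))
  reacs_by_id <- split(reac$pt, factor(reac$primaryid, levels = demo$primaryid))

  reports <- tibble(
    report_id = demo$primaryid,
    quarter = demo$quarter,
    age = .parse_num(demo$age, 0, 130),
    weight = .parse_num(demo$wt, 0, 700, open_lo = TRUE),
    sex = ifelse(demo$sex %in% c("M", "F") & !is.na(demo$sex), demo$sex, "U"),
    indication = if ("indi_pt" %in% names(demo)) demo$indi_pt else NA_character_,
    drug_mentions = unname(drugs_by_id),
    reactions = unname(reacs_by_id)
  )

  no_drug <- lengths(reports$drug_mentions) == 0
  no_reac <- lengths(reports$reactions) == 0
  dropped <- c(no_drug = sum(no_drug & !no_reac),
               no_reaction = sum(no_reac & !no_drug),
               no_drug_no_reaction = sum(no_drug & no_reac),
               orphan_rows = orphan)
  report_set(reports[!(no_drug | no_reac), ], provenance, dropped)
}

#' Read a flat CSV of (report, drug, reaction) rows
#'
#' One row per report x drug x reaction; rows sharing a `report_id` are
#' grouped into a single report and duplicate (report, drug, reaction)
#' triples collapse to one.
#'
#' @param path CSV path (optionally gzip-compressed) with columns
#'   `report_id`, `quarter`, `age`, `weight`, `sex`, `drug`, `reaction`
#'   and optionally `indication`.
#'
#' @return A [report_set()].
#' @export
read_flat_csv <- function(path) {
  tab <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE,
                         show_col_types = FALSE)
  required <- c("report_id", "quarter", "age", "weight", "sex", "drug", "reaction")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("flat CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  provenance <- tibble(source = path, records = nrow(tab))
  if (!"indication" %in% names(tab)) tab$indication <- NA_character_

  ids <- unique(tab$report_id)
  f <- factor(tab$report_id, levels = ids)
  first <- tab[!duplicated(tab$report_id), ]
  reports <- tibble(
    report_id = first$report_id,
    quarter = first$quarter,
    age = .parse_num(first$age, 0, 130),
    weight = .parse_num(first$weight, 0, 700, open_lo = TRUE),
    sex = ifelse(first$sex %in% c("M", "F") & !is.na(first$sex), first$sex, "U"),
    indication = first$indication,
    drug_mentions = lapply(split(tab$drug, f), unique),
    reactions = lapply(split(tab$reaction, f), unique)
  )
  reports$drug_mentions <- unname(reports$drug_mentions)
  reports$reactions <- unname(reports$reactions)
  keep <- lengths(reports$drug_mentions) > 0 & lengths(reports$reactions) > 0
  dropped <- c(no_drug_or_reaction = sum(!keep))
  report_set(reports[keep, ], provenance, dropped)
}

# "$" is the field delimiter and there is no quoting, so embedded dollars in
# free text are replaced by a space on write.
.sanitize_dollar <- function(x) gsub("\\$", " ", x)

.fmt_num <- function(x) {
  ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE, digits = 15))
}

#' Write a report set as FAERS-style DEMO/DRUG/REAC files
#'
#' Emits the three `$`-delimited tables that [read_faers_quarter()] inverts
#' exactly. Embedded `$` characters in free-text fields are replaced by a
#' space (the dialect has no quoting).
#'
#' @param reports A [report_set()].
#' @param out_dir Output directory (created if absent).
#'
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_faers_quarter <- function(reports, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  paths <- c(demo = file.path(out_dir, "demo.txt"),
             drug = file.path(out_dir, "drug.txt"),
             reac = file.path(out_dir, "reac.txt"))

  demo_lines <- c("primaryid$quarter$age$wt$sex$indi_pt",
                  if (nrow(reports) > 0)
                    paste(.sanitize_dollar(reports$report_id),
                          .sanitize_dollar(reports$quarter),
                          .fmt_num(reports$age),
                          .fmt_num(reports$weight),
                          reports$sex,
                          .sanitize_dollar(ifelse(is.na(reports$indication), "",
                                                  reports$indication)),
                          sep = "$"))
  drug_lines <- c("primaryid$drug_seq$drugname",
                  if (nrow(reports) > 0) {
                    ids <- rep(reports$report_id, lengths(reports$drug_mentions))
                    seqs <- unlist(lapply(lengths(reports$drug_mentions), seq_len),
                                   use.names = FALSE)
                    paste(.sanitize_dollar(ids), seqs,
                          .sanitize_dollar(unlist(reports$drug_mentions,
                                                  use.names = FALSE)),
                          sep = "$")
                  })
  reac_lines <- c("primaryid$pt",
                  if (nrow(reports) > 0) {
                    ids <- rep(reports$report_id, lengths(reports$reactions))
                    paste(.sanitize_dollar(ids),
                          .sanitize_dollar(unlist(reports$reactions,
                                                  use.names = FALSE)),
                          sep = "$")
                  })
  tryCatch({
    writeLines(demo_lines, paths["demo"], useBytes = TRUE)
    writeLines(drug_lines, paths["drug"], useBytes = TRUE)
    writeLines(reac_lines, paths["reac"], useBytes = TRUE)
  }, error = function(e) stop("cannot write to ", out_dir, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(paths)
}

#' Write a report set as a flat CSV
#'
#' One row per (report, drug, reaction) triple, the inverse of
#' [read_flat_csv()].
#'
#' @param reports A [report_set()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_flat_csv <- function(reports, path) {
  rows <- flat_triples(reports)
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Expand a report set into its (report, drug, reaction) triples
#'
#' @param reports A [report_set()].
#' @return A tibble with one row per report x drug x reaction combination,
#'   carrying the report-level demographics on every row.
#' @export
flat_triples <- function(reports) {
  if (nrow(reports) == 0) {
    return(tibble(report_id = character(), quarter = character(),
                  age = numeric(), weight = numeric(), sex = character(),
                  indication = character(), drug = character(),
                  reaction = character()))
  }
  per_report <- Map(function(id, q, a, w, s, ind, d, r) {
    grid <- expand.grid(drug = d, reaction = r,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tibble(report_id = id, quarter = q, age = a, weight = w, sex = s,
           indication = ind, drug = grid$drug, reaction = grid$reaction)
  }, reports$report_id, reports$quarter, reports$age, reports$weight,
     reports$sex, reports$indication, reports$drug_mentions, reports$reactions)
  dplyr::bind_rows(per_report)
}
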