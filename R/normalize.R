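# Verbatim drug-name canonicalization (regex cleanup + alias dictionary +
# Levenshtein clustering), reaction-term mapping, and cohort filtering.

#' Build a drug dictionary
#'
#' Maps canonical active ingredients to lowercase alias sets (brand names,
#' international names, salts) and to a drug-class label.
#'
#' @param entries A data frame with columns `ingredient`, `class`, `alias`
#'   (one row per alias; the canonical name itself should appear as an
#'   alias). Aliases are lowercased on construction.
#'
#' @return A tibble of class `drug_dictionary`.
#' @export
drug_dictionary <- function(entries) {
  entries <- as_tibble(entries)
  missing_cols <- setdiff(c("ingredient", "class", "alias"), names(entries))
  if (length(missing_cols) > 0) {
    stop("drug dictionary needs columns: ", paste(missing_cols, collapse = ", "))
  }
  entries$alias <- tolower(trimws(entries$alias))
  entries <- distinct(entries)
  dup <- entries$alias[duplicated(entries$alias)]
  if (length(dup) > 0) {
    stop("alias(es) assigned to more than one ingredient: ",
         paste(unique(dup), collapse = ", "))
  }
  cls <- unique(entries[c("ingredient", "class")])
  if (anyDuplicated(cls$ingredient)) {
    stop("every ingredient must carry exactly one class label")
  }
  if (any(is.na(cls$class) | !nzchar(cls$class))) {
    stop("every ingredient needs a class label")
  }
  structure(entries, class = c("drug_dictionary", class(entries)))
}

#' Read a drug dictionary from CSV
#'
#' @param path CSV with columns `ingredient`, `class`, `alias`.
#' @return A [drug_dictionary()].
#' @export
read_drug_dictionary <- function(path) {
  drug_dictionary(readr::read_csv(path, col_types = "ccc",
                                  progress = FALSE, show_col_types = FALSE))
}

#' Bundled ACEI/ARB drug dictionary
#'
#' Covers the ten ACE inhibitors (captopril, lisinopril, quinapril, ramipril,
#' enalapril, perindopril, fosinopril, cilazapril, benazepril, trandolapril)
#' and six angiotensin II receptor blockers (azilsartan, irbesartan,
#' losartan, olmesartan, telmisartan, valsartan) with common brand aliases.
#' Fully user-replaceable via [read_drug_dictionary()].
#'
#' @return A [drug_dictionary()].
#' @export
default_drug_dictionary <- function() {
  read_drug_dictionary(system.file("extdata", "drug_dictionary.csv",
                                   package = "pvprr", mustWork = TRUE))
}

#' Build an event vocabulary
#'
#' @param entries A data frame with columns `preferred_term` and `synonym`
#'   (one row per synonym; a preferred term is its own synonym).
#' @return A tibble of class `event_vocabulary`.
#' @export
event_vocabulary <- function(entries) {
  entries <- as_tibble(entries)
  missing_cols <- setdiff(c("preferred_term", "synonym"), names(entries))
  if (length(missing_cols) > 0) {
    stop("event vocabulary needs columns: ", paste(missing_cols, collapse = ", "))
  }
  entries$preferred_term <- tolower(trimws(entries$preferred_term))
  entries$synonym <- tolower(trimws(entries$synonym))
  entries <- distinct(entries)
  dup <- entries$synonym[duplicated(entries$synonym)]
  if (length(dup) > 0) {
    stop("synonym(s) mapping to more than one preferred term: ",
         paste(unique(dup), collapse = ", "))
  }
  structure(entries, class = c("event_vocabulary", class(entries)))
}

#' Read an event vocabulary from CSV
#' @param path CSV with columns `preferred_term`, `synonym`.
#' @return An [event_vocabulary()].
#' @export
read_event_vocabulary <- function(path) {
  event_vocabulary(readr::read_csv(path, col_types = "cc",
                                   progress = FALSE, show_col_types = FALSE))
}

#' Bundled pulmonary event vocabulary
#'
#' A small MedDRA-preferred-term-like vocabulary covering the thirteen
#' pulmonary adverse events of the analysis plus a handful of lay synonyms.
#' This is a stand-in vocabulary, not licensed MedDRA.
#'
#' @return An [event_vocabulary()].
#' @export
default_event_vocabulary <- function() {
  read_event_vocabulary(system.file("extdata", "event_vocabulary.csv",
                                    package = "pvprr", mustWork = TRUE))
}

#' The thirteen pulmonary adverse events
#'
#' The fixed pulmonary event list used as the default analysis whitelist:
#' pulmonary edema, pleural effusion, oropharyngeal pain, dyspnea, dysphonia,
#' cough, sinusitis, pneumonia, nasopharyngitis, bronchitis, pneumonia
#' aspiration, emphysema, and pleurisy.
#'
#' @return Character vector of 13 preferred terms (lowercase).
#' @export
pulmonary_events <- function() {
  c("pulmonary edema", "pleural effusion", "oropharyngeal pain", "dyspnea",
    "dysphonia", "cough", "sinusitis", "pneumonia", "nasopharyngitis",
    "bronchitis", "pneumonia aspiration", "emphysema", "pleurisy")
}

#' Clean a verbatim drug name
#'
#' Lowercases, strips parenthesized content, dosage tokens (numbers with or
#' without mg/ml/mcg/g units), formulation and salt tokens (tablet, capsule,
#' solution, hcl, hydrochloride, ...), punctuation, and collapses
#' whitespace. Idempotent; may return an empty string.
#'
#' @param raw Character vector of verbatim names.
#' @return Character vector of cleaned names.
#' @export
clean_name <- function(raw) {
  x <- tolower(raw)
  x <- gsub("\\([^)]*\\)", " ", x)            # parenthesized content
  x <- gsub("[(),;:/\\\\]", " ", x)           # stray punctuation
  x <- gsub("\\b[0-9]+(\\.[0-9]+)?\\s*(mg|mcg|ml|g|mgs)\\b", " ", x)
  x <- gsub("\\b[0-9]+(\\.[0-9]+)?\\b", " ", x)
  x <- gsub("\\b(tablet|tablets|tab|tabs|capsule|capsules|cap|caps|solution|oral|injection|hcl|hydrochloride|maleate|mesylate|sodium|potassium|medoxomil|cilexetil)\\b",
            " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Levenshtein edit distance
#'
#' Minimum number of unit-cost insertions, deletions and substitutions
#' turning `a` into `b`. Vectorized with the usual recycling.
#'
#' @param a,b Character vectors.
#' @return Non-negative integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  d <- adist(a, b, costs = 1)
  as.integer(d[cbind(seq_len(n), seq_len(n))])
}

# Resolve cleaned names against the alias table. Exact match first; then
# unique nearest alias within max_dist. Names of <= 4 characters must match
# exactly (short names collide too easily under fuzzy matching). Ties across
# different ingredients are refused (NA), never guessed.
.match_cleaned <- function(cleaned, dict, max_dist) {
  out <- dict$ingredient[match(cleaned, dict$alias)]
  todo <- which(is.na(out) & nzchar(cleaned) & nchar(cleaned) > 4 & max_dist > 0)
  if (length(todo) > 0) {
    dmat <- adist(cleaned[todo], dict$alias, costs = 1)
    for (k in seq_along(todo)) {
      dmin <- min(dmat[k, ])
      if (dmin <= max_dist) {
        cands <- unique(dict$ingredient[dmat[k, ] == dmin])
        if (length(cands) == 1) out[todo[k]] <- cands
      }
    }
  }
  out
}

#' Map a verbatim drug name to a canonical ingredient
#'
#' Cleans the name with [clean_name()], matches exactly against the alias
#' table, and otherwise assigns the unique nearest alias by Levenshtein
#' distance when that distance is at most `max_dist`. Ambiguous names (tied
#' between different ingredients) and names more distant than `max_dist`
#' return `NA` (unmapped is a value, not an error).
#'
#' @param raw Character vector of verbatim names.
#' @param dict A [drug_dictionary()].
#' @param max_dist Maximum edit distance for fuzzy matches (default 2).
#'   Cleaned names of four characters or fewer require an exact match.
#' @return Character vector of canonical ingredients, `NA` where unmapped.
#' @export
map_drug <- function(raw, dict, max_dist = 2) {
  stopifnot(max_dist >= 0)
  cleaned <- clean_name(raw)
  uniq <- unique(cleaned)
  res <- .match_cleaned(uniq, dict, max_dist)
  res[match(cleaned, uniq)]
}

.map_events <- function(raw, vocab) {
  x <- tolower(trimws(raw))
  vocab$preferred_term[match(x, vocab$synonym)]
}

#' Normalize a report set
#'
#' Maps every verbatim drug mention to a canonical ingredient (or records it
#' as unmapped) and every reaction string to a preferred term via the
#' vocabulary's synonyms, case-insensitively. Per-report sets are
#' deduplicated. No reports are dropped here; filtering belongs to
#' [filter_cohort()].
#'
#' @param reports A [report_set()].
#' @param dict A [drug_dictionary()].
#' @param vocab An [event_vocabulary()].
#' @param max_dist Fuzzy-match threshold passed to [map_drug()].
#'
#' @return A tibble of class `normalized_reports` with list-columns `drugs`,
#'   `events`, `unmapped_drugs`, `unmapped_events`.
#' @export
normalize_reports <- function(reports, dict, vocab, max_dist = 2) {
  mentions <- unlist(reports$drug_mentions, use.names = FALSE)
  mention_map <- map_drug(mentions, dict, max_dist)
  idx <- rep(seq_len(nrow(reports)), lengths(reports$drug_mentions))
  drugs <- lapply(split(mention_map, factor(idx, levels = seq_len(nrow(reports)))),
                  function(m) unique(m[!is.na(m)]))
  unmapped_d <- Map(function(m, raw) unique(raw[is.na(m)]),
                    split(mention_map, factor(idx, levels = seq_len(nrow(reports)))),
                    split(mentions, factor(idx, levels = seq_len(nrow(reports)))))

  reac <- unlist(reports$reactions, use.names = FALSE)
  reac_map <- .map_events(reac, vocab)
  ridx <- rep(seq_len(nrow(reports)), lengths(reports$reactions))
  events <- lapply(split(reac_map, factor(ridx, levels = seq_len(nrow(reports)))),
                   function(m) unique(m[!is.na(m)]))
  unmapped_e <- Map(function(m, raw) unique(raw[is.na(m)]),
                    split(reac_map, factor(ridx, levels = seq_len(nrow(reports)))),
                    split(reac, factor(ridx, levels = seq_len(nrow(reports)))))

  out <- tibble(
    report_id = reports$report_id,
    quarter = reports$quarter,
    age = reports$age,
    weight = reports$weight,
    sex = reports$sex,
    indication = reports$indication,
    drugs = unname(drugs),
    events = unname(events),
    unmapped_drugs = unname(unmapped_d),
    unmapped_events = unname(unmapped_e)
  )
  structure(out, class = c("normalized_reports", class(out)))
}

#' Filter normalized reports to the analysis cohort
#'
#' Keeps reports whose indication matches the include pattern and none of
#' the exclude patterns (case-insensitive regular expressions on the
#' free-text indication), restricts drugs to the whitelisted classes and
#' events to the event whitelist, and drops reports left without at least
#' one (drug, event) pair.
#'
#' @param reports A `normalized_reports` tibble.
#' @param indication_include Regex the indication must match
#'   (default `"hypertension"`).
#' @param indication_exclude Regexes that disqualify a report; the defaults
#'   exclude pulmonary arterial and intracranial hypertension.
#' @param event_whitelist Non-empty set of preferred terms to keep
#'   (default [pulmonary_events()]).
#' @param class_whitelist Drug classes to keep, or `NULL` for all classes in
#'   `dict`.
#' @param dict The [drug_dictionary()] supplying class labels.
#' @param keep_missing_indication Keep reports with a missing indication?
#'   Default `FALSE`.
#'
#' @return A filtered `normalized_reports` tibble.
#' @export
filter_cohort <- function(reports,
                          indication_include = "hypertension",
                          indication_exclude = c("pulmonary\\s+arterial\\s+hypertension",
                                                 "intracranial\\s+hypertension"),
                          event_whitelist = pulmonary_events(),
                          class_whitelist = NULL,
                          dict = default_drug_dictionary(),
                          keep_missing_indication = FALSE) {
  stopifnot(length(event_whitelist) > 0)
  ind <- reports$indication
  ok <- if (keep_missing_indication) is.na(ind) else rep(FALSE, length(ind))
  has <- !is.na(ind)
  ok[has] <- grepl(indication_include, ind[has], ignore.case = TRUE)
  for (pat in indication_exclude) {
    ok[has] <- ok[has] & !grepl(pat, ind[has], ignore.case = TRUE)
  }
  out <- reports[ok, ]

  cls <- unique(as_tibble(dict)[c("ingredient", "class")])
  keep_drugs <- if (is.null(class_whitelist)) cls$ingredient else
    cls$ingredient[cls$class %in% class_whitelist]
  out$drugs <- lapply(out$drugs, function(d) d[d %in% keep_drugs])
  out$events <- lapply(out$events, function(e) e[e %in% event_whitelist])

  keep <- lengths(out$drugs) > 0 & lengths(out$events) > 0
  out <- out[keep, ]
  if (nrow(out) == 0) warning("cohort filter left no reports")
  structure(out, class = unique(c("normalized_reports", class(out))))
}
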