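# Shared fixtures: tiny dictionaries, toy report sets, random report sets
# for round-trip fuzzing, and independent oracles used across test files.

toy_dict <- function() {
  drug_dictionary(tibble::tibble(
    ingredient = c("losartan", "losartan", "quinapril", "quinapril",
                   "trandolapril", "enalapril"),
    class = c("ARB", "ARB", "ACEI", "ACEI", "ACEI", "ACEI"),
    alias = c("losartan", "cozaar", "quinapril", "accupril",
              "trandolapril", "enalapril")
  ))
}

toy_vocab <- function() {
  event_vocabulary(tibble::tibble(
    preferred_term = c("cough", "cough", "dyspnea", "dyspnea", "pleurisy"),
    synonym = c("cough", "coughing", "dyspnea", "shortness of breath",
                "pleurisy")
  ))
}

make_reports <- function(rows) {
  report_set(tibble::tibble(
    report_id = rows$report_id,
    quarter = rows[["quarter"]] %||% rep("2019Q1", nrow(rows)),
    age = rows[["age"]] %||% rep(60, nrow(rows)),
    weight = rows[["weight"]] %||% rep(80, nrow(rows)),
    sex = rows[["sex"]] %||% rep("F", nrow(rows)),
    indication = rows[["indication"]] %||% rep("Hypertension", nrow(rows)),
    drug_mentions = rows$drug_mentions,
    reactions = rows$reactions
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random report set with messy-but-valid content, for round-trip fuzzing
random_report_set <- function(n, seed) {
  set.seed(seed)
  words <- c("lisinopril", "cozaar", "Accupril 10 MG", "enalapril maleate",
             "TRANDOLAPRIL", "losartan (Cozaar)", "telmisartan")
  evs <- c("Cough", "dyspnea", "PLEURISY", "shortness of breath",
           "pulmonary oedema")
  make_reports(tibble::tibble(
    report_id = sprintf("id%04d", sample.int(10 * n, n)),
    quarter = paste0(sample(2004:2019, n, TRUE), "Q", sample.int(4, n, TRUE)),
    age = ifelse(runif(n) < 0.2, NA_real_, round(runif(n, 18, 95), 1)),
    weight = ifelse(runif(n) < 0.2, NA_real_, round(runif(n, 45, 140), 1)),
    sex = sample(c("M", "F", "U"), n, TRUE),
    indication = sample(c("Hypertension", "Essential hypertension",
                          NA_character_), n, TRUE),
    drug_mentions = replicate(n, sample(words, sample.int(3, 1)),
                              simplify = FALSE),
    reactions = replicate(n, sample(evs, sample.int(3, 1)),
                          simplify = FALSE)
  ))
}

# brute-force recursive Levenshtein distance (exponential; strings <= 8)
lev_brute <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- as.integer(substring(a, 1, 1) != substring(b, 1, 1))
  min(lev_brute(substring(a, 2), b) + 1L,
      lev_brute(a, substring(b, 2)) + 1L,
      lev_brute(substring(a, 2), substring(b, 2)) + cost)
}

# independent 2x2 PRR oracle: a = r_ij, a + b = n_j, c = event_total - a,
# c + d = N - n_j
prr_oracle_2x2 <- function(a, b, c, d) {
  (a / (a + b)) / (c / (c + d))
}

# enumerate (report, drug, event) triples of a normalized tibble
triples_of <- function(norm) {
  out <- list()
  for (k in seq_len(nrow(norm))) {
    for (d in norm$drugs[[k]]) for (e in norm$events[[k]]) {
      out[[length(out) + 1]] <- c(norm$report_id[k], d, e)
    }
  }
  if (length(out) == 0) return(character())
  sort(vapply(out, paste, character(1), collapse = "|"))
}
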