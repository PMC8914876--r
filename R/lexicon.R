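#' Read a TBI term lexicon
#'
#' Loads a JSON lexicon of clinical search terms. Each entry carries a
#' canonical term, a category (`pathology`, `symptom`, `treatment` or
#' `indicator`), a pathology code (`SDH`, `SAH`, `EDH`, `focal`, `DAI`,
#' `skull_fracture` or `none`) and pattern variants: synonyms, acronyms and
#' a fixed misspelling-variant table. The same variant table drives both the
#' free-text search and the synthetic narrative generator, so extraction of
#' generated text is decidable rather than probabilistic.
#'
#' @param path path to a lexicon JSON file. Defaults to the lexicon shipped
#'   with the package.
#' @return An object of class `tbi_lexicon`: a list with `patterns` (one row
#'   per matcher string, with its canonical term, category, code and variant
#'   type) and `negation_cues`.
#' @examples
#' lex <- read_lexicon()
#' head(lex$patterns)
#' @export
read_lexicon <- function(path = system.file("extdata", "tbi_lexicon.json",
                                            package = "roadtbi")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- raw$entries
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    forms <- list(canonical = e$canonical_term,
                  synonym = unlist(e$synonyms),
                  acronym = unlist(e$acronyms),
                  misspelling = unlist(e$misspellings))
    do.call(rbind, lapply(names(forms), function(type) {
      pats <- forms[[type]]
      if (length(pats) == 0) return(NULL)
      data.frame(canonical_term = e$canonical_term,
                 category = e$category,
                 pathology_code = e$pathology_code,
                 pattern = pats,
                 pattern_type = type,
                 stringsAsFactors = FALSE)
    }))
  })
  patterns <- do.call(rbind, rows)
  lex <- structure(list(patterns = patterns,
                        negation_cues = tolower(unlist(raw$negation_cues))),
                   class = "tbi_lexicon")
  validate_lexicon(lex)
  lex
}

validate_lexicon <- function(lex) {
  p <- lex$patterns
  dup <- duplicated(p[, c("canonical_term", "pattern")])
  if (any(dup))
    stop("duplicate (canonical_term, pattern) pairs in lexicon: ",
         paste(p$pattern[dup], collapse = ", "))
  bad <- p$pathology_code != "none" & p$category != "pathology"
  if (any(bad))
    stop("lexicon entries with a pathology code must have category 'pathology': ",
         paste(unique(p$canonical_term[bad]), collapse = ", "))
  # every pattern must compile as a word-bounded regex
  for (pat in p$pattern) {
    ok <- tryCatch({ grepl(pattern_regex(pat), "x", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("lexicon pattern does not compile: ", pat)
  }
  invisible(lex)
}

# literal pattern -> case-insensitive word-bounded regex
pattern_regex <- function(pattern) {
  esc <- gsub("([][{}()+*^$|\\\\?.#-])", "\\\\\\1", pattern)
  paste0("(?i)\\b", esc, "\\b")
}

#' @export
print.tbi_lexicon <- function(x, ...) {
  cat("TBI term lexicon:", nrow(x$patterns), "patterns for",
      length(unique(x$patterns$canonical_term)), "terms;",
      length(x$negation_cues), "negation cues\n")
  cat("Categories:", paste(names(table(x$patterns$category)), collapse = ", "), "\n")
  invisible(x)
}
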