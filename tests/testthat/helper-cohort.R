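# shared fixtures built in code

the_lexicon <- read_lexicon()

# small cohort for pipeline-level tests
small_cohort <- function(seed = 1L, n_national = 2000, n_indepth = 300, ...) {
  generate_cohort(generator_config(n_national = n_national,
                                   n_indepth = n_indepth, seed = seed, ...))
}

# merge classified profiles against generator truth
roundtrip_agreement <- function(cohort, lexicon = the_lexicon) {
  cls <- classify_subjects(cohort$indepth, lexicon)
  m <- merge(cls$profiles, cohort$truth_indepth, by = "subject_id",
             suffixes = c("", ".t"))
  flags_ok <- m$SDH == m$SDH.t & m$SAH == m$SAH.t & m$EDH == m$EDH.t &
    m$focal == m$focal.t & m$DAI == m$DAI.t &
    m$skull_fracture == m$skull_fracture.t
  list(mayo = mean(m$mayo_severity == m$mayo_severity.t),
       flags = mean(flags_ok))
}

zero_noise <- c(misspelling = 0, acronym = 0, negation = 0)

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

empty_hits_for_test <- function() {
  filter_false_positives(extract_term_hits("", the_lexicon), the_lexicon)
}
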