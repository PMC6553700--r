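# Compact pedigree constructors used across test files.

# members("id fa mo sex aff", ...) with "." for missing parent;
# sex in {m,f,u}; aff in {a,u,p,?}
members <- function(...) {
  rows <- lapply(unlist(list(...)), function(s) {
    p <- strsplit(trimws(s), "\\s+")[[1L]]
    data.frame(individual_id = p[1L],
               father_id = if (p[2L] == ".") NA_character_ else p[2L],
               mother_id = if (p[3L] == ".") NA_character_ else p[3L],
               sex = c(m = "male", f = "female", u = "unknown")[p[4L]],
               affection = c(a = "affected", u = "unaffected",
                             p = "possible", "?" = "unknown")[p[5L]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# PLAU-like: unaffected carrier father, wildtype mother, five affected
# siblings (four carriers), one unaffected carrier sister
plau_family <- function() {
  ped <- pedigree("PLAU", members(
    "I-1 . . m u", "I-2 . . f u",
    "II-1 I-1 I-2 m a", "II-2 I-1 I-2 f a", "II-3 I-1 I-2 m a",
    "II-4 I-1 I-2 f a", "II-5 I-1 I-2 m a", "II-7 I-1 I-2 f u"))
  calls <- genotype_calls(
    c("I-1", "I-2", "II-1", "II-2", "II-3", "II-4", "II-5", "II-7"),
    c("carrier", "wildtype", "carrier", "carrier", "carrier", "carrier",
      "wildtype", "carrier"),
    "10:75673131:G:T")
  list(ped = ped, calls = calls, key = "10:75673131:G:T")
}

# sporadic proband with three unaffected carrier siblings, parents untyped
sporadic_family <- function() {
  ped <- pedigree("SPOR", members(
    "I-1 . . m u", "I-2 . . f u",
    "II-1 I-1 I-2 m a", "II-2 I-1 I-2 f u", "II-3 I-1 I-2 m u",
    "II-4 I-1 I-2 f u"))
  calls <- genotype_calls(c("II-1", "II-2", "II-3", "II-4"),
                          rep("carrier", 4L), "17:78319114:A:G")
  list(ped = ped, calls = calls, key = "17:78319114:A:G")
}

# cousin-pair carriers: untyped grandfather and both linking fathers
# connect the two observed carriers
cousin_family <- function() {
  ped <- pedigree("COUS", members(
    "I-1 . . m u", "I-2 . . f u",
    "II-1 I-1 I-2 m u", "II-2 . . f u",
    "II-3 I-1 I-2 m u", "II-4 . . f u",
    "III-1 II-1 II-2 m a", "III-2 II-3 II-4 f a"))
  calls <- genotype_calls(c("III-1", "III-2", "I-2", "II-2", "II-4"),
                          c("carrier", "carrier", "wildtype", "wildtype",
                            "wildtype"),
                          "1:1000:A:T")
  list(ped = ped, calls = calls, key = "1:1000:A:T")
}

random_masked_family <- function(seed, penetrance = 0.7, missingness = 0.4) {
  simulate_family(family_sim_config(
    family_id = paste0("R", seed), n_generations = 3L,
    sibship_size_mean = 2, penetrance = penetrance, phenocopy_rate = 0.05,
    genotype_missingness = missingness, min_affected_dna = 0L,
    n_background_variants = 0L, n_markers = 0L, seed = seed))
}
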