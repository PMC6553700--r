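test_that("worked family examples reproduce the published verdicts", {
  # 4 of 5 affected siblings carry; father is an unaffected transmitting
  # (obligate) carrier; one unaffected sister carries -> segregating
  f <- plau_family()
  r <- evaluate_segregation(f$ped, f$calls, f$key)
  expect_equal(r$n_affected_carriers, 4L)
  expect_equal(r$n_affected_informative, 5L)
  expect_equal(r$obligate_carriers, "I-1")
  expect_equal(r$n_unaffected_carriers_counted, 1L)
  expect_equal(r$verdict, "segregating")

  # sporadic proband with three unaffected carrier siblings: 1/1 affected
  # but too many unaffected carriers -> not segregating
  s <- sporadic_family()
  r2 <- evaluate_segregation(s$ped, s$calls, s$key)
  expect_equal(r2$affected_fraction, 1)
  expect_equal(r2$n_unaffected_carriers_counted, 3L)
  expect_equal(r2$verdict, "not_segregating")

  # 6 of 7 affected carriers, no unaffected carriers -> segregating
  k <- pedigree("KCNG4", members(
    "I-1 . . m u", "I-2 . . f u",
    paste0("II-", 1:7, " I-1 I-2 ", rep(c("m ", "f "), length.out = 7), "a")))
  kcalls <- genotype_calls(paste0("II-", 1:7),
                           c(rep("carrier", 6L), "wildtype"),
                           "16:84255962:C:T")
  r3 <- evaluate_segregation(k, kcalls, "16:84255962:C:T")
  expect_equal(r3$n_affected_carriers, 6L)
  expect_equal(r3$n_affected_informative, 7L)
  expect_equal(r3$n_unaffected_carriers_counted, 0L)
  expect_equal(r3$verdict, "segregating")
})

test_that("the 75% threshold is inclusive and untyped affected are excluded", {
  # 3 of 4 at exactly 75% passes
  ped <- pedigree("B", members(
    "I-1 . . m u", "I-2 . . f u",
    "II-1 I-1 I-2 m a", "II-2 I-1 I-2 f a", "II-3 I-1 I-2 m a",
    "II-4 I-1 I-2 f a"))
  calls <- genotype_calls(paste0("II-", 1:4),
                          c("carrier", "carrier", "carrier", "wildtype"), "k")
  r <- evaluate_segregation(ped, calls, "k")
  expect_equal(r$affected_fraction, 0.75)
  expect_equal(r$verdict, "segregating")

  # a 16-of-21 aggregate (76.2%) also clears the inclusive threshold
  big <- pedigree("AGG", members(
    "I-1 . . m u", "I-2 . . f u",
    paste0("II-", 1:21, " I-1 I-2 ", rep(c("m ", "f "), length.out = 21), "a")))
  bcalls <- genotype_calls(paste0("II-", 1:21),
                           c(rep("carrier", 16L), rep("wildtype", 5L)), "k")
  rb <- evaluate_segregation(big, bcalls, "k")
  expect_equal(round(100 * rb$affected_fraction, 2), 76.19)
  expect_equal(rb$verdict, "segregating")

  # a wholly untyped affected sibling drops out of the denominator
  # (not assumed wildtype); the untyped member stays uncounted
  ped5 <- pedigree("U", members(
    "I-1 . . m u", "I-2 . . f u",
    "II-1 I-1 I-2 m a", "II-2 I-1 I-2 f a", "II-3 I-1 I-2 m a",
    "II-4 I-1 I-2 f a", "II-5 I-1 I-2 m a"))
  calls5 <- genotype_calls(paste0("II-", 1:4),
                           c("carrier", "carrier", "carrier", "wildtype"), "k")
  r5 <- evaluate_segregation(ped5, calls5, "k")
  expect_equal(r5$n_affected_informative, 4L)
})

test_that("possible-affection members are excluded unless opted in", {
  ped <- pedigree("P", members(
    "I-1 . . m u", "I-2 . . f u",
    "II-1 I-1 I-2 m a", "II-2 I-1 I-2 f a", "II-3 I-1 I-2 m a",
    "II-4 I-1 I-2 f p"))
  calls <- genotype_calls(paste0("II-", 1:4),
                          c("carrier", "carrier", "carrier", "wildtype"), "k")
  r <- evaluate_segregation(ped, calls, "k")
  expect_equal(r$n_affected_informative, 3L)
  expect_equal(r$affected_fraction, 1)
  r2 <- evaluate_segregation(ped, calls, "k", include_possible = TRUE)
  expect_equal(r2$n_affected_informative, 4L)
  expect_equal(r2$affected_fraction, 0.75)
})

test_that("married-in members never enter the tallies", {
  ped <- pedigree("M", members(
    "I-1 . . m u", "I-2 . . f u",
    "II-1 I-1 I-2 m a", "II-2 . . f u",
    "II-3 I-1 I-2 f a",
    "III-1 II-1 II-2 m a"))
  calls <- genotype_calls(c("II-1", "II-2", "II-3", "III-1"),
                          c("carrier", "carrier", "carrier", "carrier"), "k")
  expect_warning(r <- evaluate_segregation(ped, calls, "k"), "single.founder")
  # II-2 (married-in, unaffected carrier) is not counted
  expect_equal(r$n_unaffected_carriers_counted, 0L)
  expect_equal(r$n_affected_informative, 3L)
})

test_that("verdict is invariant to member relabeling and order", {
  f <- plau_family()
  base <- evaluate_segregation(f$ped, f$calls, f$key)
  relabel <- stats::setNames(sprintf("Z%02d", seq_along(ped_ids(f$ped))),
                             ped_ids(f$ped))
  m <- f$ped$members
  m$individual_id <- unname(relabel[m$individual_id])
  m$father_id <- unname(relabel[m$father_id])
  m$mother_id <- unname(relabel[m$mother_id])
  m <- m[rev(seq_len(nrow(m))), ]
  ped2 <- pedigree("PLAU", m[c("individual_id", "father_id", "mother_id",
                               "sex", "affection")])
  calls2 <- f$calls
  calls2$individual_id <- unname(relabel[calls2$individual_id])
  r2 <- evaluate_segregation(ped2, calls2, f$key,
                             proband = relabel[["II-1"]])
  expect_equal(r2$verdict, base$verdict)
  expect_equal(r2$affected_fraction, base$affected_fraction)
  expect_equal(r2$n_unaffected_carriers_counted,
               base$n_unaffected_carriers_counted)
})

test_that("adding carriers moves the verdict monotonically", {
  set.seed(99)
  for (seed in 1:30) {
    fam <- random_masked_family(seed, missingness = 0.2)
    calls <- fam$calls
    if (!any(calls$call == "carrier") ||
        !any(fam$ped$members$affection == "affected")) next
    key <- fam$causal_key
    base <- suppressWarnings(evaluate_segregation(fam$ped, calls, key))
    m <- fam$ped$members
    truth <- stats::setNames(fam$truth$call, fam$truth$individual_id)

    # reveal a hidden affected carrier: never flips segregating -> not
    hidden_aff <- setdiff(
      m$individual_id[m$affection == "affected" & truth[m$individual_id] == "carrier"],
      calls$individual_id)
    if (length(hidden_aff) && base$verdict == "segregating") {
      more <- rbind(calls, genotype_calls(hidden_aff[1L], "carrier", key))
      r <- suppressWarnings(evaluate_segregation(fam$ped, more, key))
      expect_equal(r$verdict, "segregating", info = paste("seed", seed))
    }

    # reveal a hidden unaffected non-obligate carrier: never flips
    # not_segregating -> segregating
    hidden_un <- setdiff(
      m$individual_id[m$affection == "unaffected" &
                        truth[m$individual_id] == "carrier"],
      calls$individual_id)
    hidden_un <- setdiff(hidden_un, suppressWarnings(
      infer_obligate_carriers(fam$ped, calls, key)))
    if (length(hidden_un) && base$verdict == "not_segregating") {
      more <- rbind(calls, genotype_calls(hidden_un[1L], "carrier", key))
      r <- suppressWarnings(evaluate_segregation(fam$ped, more, key))
      expect_equal(r$verdict, "not_segregating", info = paste("seed", seed))
    }
  }
})

test_that("tallies agree with brute-force member enumeration", {
  for (seed in 1:25) {
    fam <- random_masked_family(seed, missingness = 0.3)
    if (!any(fam$calls$call == "carrier") ||
        !any(fam$ped$members$affection == "affected")) next
    key <- fam$causal_key
    r <- tryCatch(
      suppressWarnings(evaluate_segregation(fam$ped, fam$calls, key)),
      famcoseg_insufficient = function(e) NULL)
    if (is.null(r)) next
    aug <- suppressWarnings(infer_genotypes(fam$ped, fam$calls, key))
    geno <- famcoseg:::.obs_calls_with_inferred(fam$ped, aug, key)
    m <- fam$ped$members
    proband <- m$individual_id[m$affection == "affected"][1L]
    o <- oracle_tallies(fam$ped, geno, r$obligate_carriers, proband)
    expect_equal(r$n_affected_informative, o$n_inf, info = paste("seed", seed))
    expect_equal(r$n_affected_carriers, o$n_car, info = paste("seed", seed))
    expect_equal(r$n_unaffected_carriers_counted, o$n_unaff,
                 info = paste("seed", seed))
  }
})

test_that("nomination orders by fraction, CADD, then key, and reports unresolved", {
  fam <- simulate_family(family_sim_config(seed = 21, penetrance = 1,
                                           phenocopy_rate = 0,
                                           genotype_missingness = 0,
                                           n_background_variants = 0L))
  ped <- fam$ped
  aff <- ped$members$individual_id[ped$members$affection == "affected"]
  all_ids <- ped$members$individual_id
  truth <- stats::setNames(fam$truth$call, fam$truth$individual_id)

  # two tied shared variants differing only in CADD, one lower-fraction one
  keys <- c("2:10:A:G", "1:10:A:G", "3:10:A:G")
  vars <- data.frame(variant_key = keys, chrom = c("2", "1", "3"),
                     pos = 10L, ref = "A", alt = "G", gene = "G",
                     consequence = "missense", cadd_phred = c(12, 30, 25),
                     stringsAsFactors = FALSE)
  geno <- rbind(
    genotype_calls(all_ids, truth[all_ids], keys[1L]),
    genotype_calls(all_ids, truth[all_ids], keys[2L]),
    genotype_calls(all_ids, truth[all_ids], keys[3L]))
  vs <- famcoseg:::new_variant_set(vars, geno)
  shared <- shared_by_affected(vs, ped)
  nom <- nominate_candidates(ped, shared)
  expect_equal(nom$variant_key, c("1:10:A:G", "3:10:A:G", "2:10:A:G"))
  expect_true(all(nom$verdict == "segregating"))
  expect_equal(nom$mode, rep("full", 3L))

  # family where nothing is shared even all-but-one: empty result
  n <- length(aff)
  weak <- genotype_calls(aff, c(rep("wildtype", 2L), rep("carrier", n - 2L)),
                         "9:9:A:G")
  vs2 <- famcoseg:::new_variant_set(
    data.frame(variant_key = "9:9:A:G", chrom = "9", pos = 9L, ref = "A",
               alt = "G", gene = "G", consequence = "missense",
               cadd_phred = 1, stringsAsFactors = FALSE), weak)
  shared2 <- shared_by_affected(vs2, ped)
  expect_equal(nrow(nominate_candidates(ped, shared2)), 0L)
})

test_that("cohort mining keeps case-exclusive rare variants and records exclusions", {
  fam <- simulate_family(family_sim_config(seed = 31, penetrance = 1,
                                           phenocopy_rate = 0,
                                           genotype_missingness = 0,
                                           n_background_variants = 0L))
  ped <- fam$ped
  ids <- ped$members$individual_id
  truth <- stats::setNames(fam$truth$call, fam$truth$individual_id)
  carrier1 <- ids[truth[ids] == "carrier"][1L]

  keys <- c("5:100:A:G", "5:200:C:T", "5:300:G:A")
  vars <- data.frame(variant_key = keys, chrom = "5",
                     pos = c(100L, 200L, 300L), ref = c("A", "C", "G"),
                     alt = c("G", "T", "A"), gene = "GENE5",
                     consequence = "missense", cadd_phred = 20,
                     stringsAsFactors = FALSE)
  case_geno <- rbind(
    genotype_calls(carrier1, "carrier", keys[1L]),    # case-exclusive
    genotype_calls(carrier1, "carrier", keys[2L]),    # also in a control
    genotype_calls(carrier1, "wildtype", keys[3L]))   # not in any case
  ctrl_geno <- genotype_calls("ctrl_1", "carrier", keys[2L])
  case_vs <- famcoseg:::new_variant_set(vars, case_geno)
  ctrl_vs <- famcoseg:::new_variant_set(vars, ctrl_geno)
  freq <- data.frame(variant_key = keys, database = "popdb",
                     allele_fraction = 4e-5)
  family_calls <- genotype_calls(ids, truth[ids], keys[1L])

  out <- mine_cohort("GENE5", case_vs, ctrl_vs, freq,
                     stats::setNames(list(ped), ped$family_id), family_calls)
  expect_equal(out$results$variant_key, keys[1L])
  expect_equal(out$results$mode, "genotyped_followup")
  expect_equal(out$results$verdict, "segregating")
  expect_equal(out$excluded$variant_key, keys[2L])
  expect_equal(out$excluded$reason, "present_in_controls")
  expect_warning(mine_cohort("NOGENE", case_vs, ctrl_vs, freq, list(), NULL),
                 "absent")
})
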