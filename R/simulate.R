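# Mendelian simulator for multi-incident families and case/control
# cohorts: the ground-truth generator every other module is validated
# against.

#' Configuration for the family simulator
#'
#' Defaults describe the multi-incident families the analysis targets:
#' three generations, sibships around three children, a dominant variant
#' introduced by one founder, reduced penetrance and a small phenocopy
#' rate, with ascertainment on at least four affected members with DNA.
#'
#' @param family_id family identifier.
#' @param n_generations number of generations (default 3).
#' @param sibship_size_mean mean number of children per couple (>= 1;
#'   sampled as 1 + Poisson(mean - 1)).
#' @param penetrance probability that a carrier is affected, in (0, 1].
#' @param phenocopy_rate probability that a non-carrier is affected, in
#'   [0, 1).
#' @param genotype_missingness probability that an individual has no DNA
#'   (their genotype is masked in the observed call set).
#' @param founder_carrier introduce the variant through one founder
#'   (default `TRUE`).
#' @param min_affected_dna ascertainment: resample until at least this
#'   many affected members have DNA (default 4; set 0 to disable).
#' @param n_background_variants non-causal variants simulated alongside
#'   the causal one (default 25), with population frequencies spanning
#'   the 1% filter threshold.
#' @param n_markers microsatellite markers flanking the causal locus
#'   (default 4), transmitted in full linkage with it.
#' @param seed integer seed; identical seed and config give identical
#'   output.
#' @return An object of class `family_sim_config`.
#' @export
family_sim_config <- function(family_id = "FAM1", n_generations = 3L,
                              sibship_size_mean = 3, penetrance = 0.7,
                              phenocopy_rate = 0.05,
                              genotype_missingness = 0.1,
                              founder_carrier = TRUE,
                              min_affected_dna = 4L,
                              n_background_variants = 25L,
                              n_markers = 4L, seed = 1L) {
  stopifnot(n_generations >= 2L, sibship_size_mean >= 1,
            penetrance > 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate < 1,
            genotype_missingness >= 0, genotype_missingness < 1,
            min_affected_dna >= 0L, n_background_variants >= 0L,
            n_markers >= 0L)
  structure(as.list(environment()), class = "family_sim_config")
}

.rand_variant <- function(gene, consequence, chrom = NULL) {
  if (is.null(chrom)) chrom <- as.character(sample(1:22, 1L))
  pos <- sample(1e6:2e8, 1L)
  ra <- sample(c("A", "C", "G", "T"), 2L)
  data.frame(variant_key = paste(chrom, pos, ra[1L], ra[2L], sep = ":"),
             chrom = chrom, pos = pos, ref = ra[1L], alt = ra[2L],
             gene = gene, consequence = consequence,
             cadd_phred = round(runif(1L, 10, 40), 1L),
             stringsAsFactors = FALSE)
}

# transmit a dominant variant down an already-built pedigree from one
# introducing member; returns named logical carrier vector
.transmit <- function(members, introducer) {
  carrier <- stats::setNames(rep(FALSE, nrow(members)), members$individual_id)
  if (!is.na(introducer)) carrier[introducer] <- TRUE
  for (i in seq_len(nrow(members))) {  # members are in generation order
    fa <- members$father_id[i]; mo <- members$mother_id[i]
    if (is.na(fa)) next
    if (carrier[fa] || carrier[mo])
      carrier[i] <- runif(1L) < 0.5
  }
  carrier
}

#' Simulate one multi-incident family
#'
#' Builds a pedigree generation by generation (married-in partners are
#' always non-carriers: rare-variant assumption), introduces the causal
#' variant through one founder, transmits it as an independent fair coin
#' per meiosis, and samples affection as carrier -> affected with
#' probability `penetrance`, non-carrier -> affected with probability
#' `phenocopy_rate`.  The hidden truth is retained alongside an observed
#' call set masked at the configured missingness.  Microsatellite marker
#' haplotypes are transmitted in full linkage with the causal variant,
#' and background variants (each introduced by a random founder) are
#' simulated with the same Mendelian machinery.
#'
#' @param cfg a [family_sim_config()].
#' @return An object of class `sim_family`: list with `ped`
#'   ([pedigree()]), `truth` (complete genotype-call table), `calls`
#'   (observed calls for members with DNA), `variants` (a `variant_set`
#'   of causal plus background variants with observed genotypes and
#'   population frequencies), `causal_key`, `introducer`, `markers`
#'   (marker-genotype rows) and `config`.
#' @export
simulate_family <- function(cfg = family_sim_config()) {
  stopifnot(inherits(cfg, "family_sim_config"))
  set.seed(cfg$seed)
  for (attempt in seq_len(1000L)) {
    fam <- .sim_family_once(cfg)
    n_aff_dna <- sum(fam$members$affection == "affected" & fam$members$dna)
    if (n_aff_dna >= cfg$min_affected_dna) break
    if (attempt == 1000L)
      stop("ascertainment failed after 1000 attempts; relax min_affected_dna")
  }
  members <- fam$members
  ped <- pedigree(cfg$family_id,
                  members[c("individual_id", "father_id", "mother_id", "sex",
                            "affection", "age_at_onset", "age_at_exam")])

  causal <- .rand_variant("CAUSAL", "missense")
  truth <- genotype_calls(members$individual_id,
                          ifelse(fam$carrier, "carrier", "wildtype"),
                          causal$variant_key)
  calls <- truth[members$dna, , drop = FALSE]

  # background variants, genotyped for the same DNA set
  vars <- causal; geno <- calls
  freq <- data.frame(variant_key = character(0), database = character(0),
                     allele_fraction = numeric(0), stringsAsFactors = FALSE)
  founders <- members$individual_id[is.na(members$father_id)]
  for (j in seq_len(cfg$n_background_variants)) {
    chrom <- sample(c(as.character(1:22), "X"), 1L,
                    prob = c(rep(0.95 / 22, 22), 0.05))
    v <- .rand_variant(sprintf("BG%03d", j),
                       sample(c("missense", "nonsense", "other"), 1L,
                              prob = c(0.5, 0.15, 0.35)),
                       chrom = chrom)
    pop_freq <- 10^runif(1L, -4, log10(0.05))
    intro <- if (runif(1L) < 0.8) sample(founders, 1L) else NA_character_
    bg_car <- .transmit(members, intro)
    vars <- rbind(vars, v)
    geno <- rbind(geno, genotype_calls(
      members$individual_id[members$dna],
      ifelse(bg_car[members$dna], "carrier", "wildtype"), v$variant_key))
    freq <- rbind(freq, data.frame(variant_key = v$variant_key,
                                   database = "popdb",
                                   allele_fraction = pop_freq,
                                   stringsAsFactors = FALSE))
  }
  vs <- new_variant_set(vars, geno, freq)

  markers <- .sim_markers(members, fam$hap_from_carrier, causal, cfg)

  structure(list(ped = ped, truth = truth, calls = calls, variants = vs,
                 causal_key = causal$variant_key,
                 introducer = fam$introducer, markers = markers,
                 config = cfg),
            class = "sim_family")
}

# one structural draw: members df + carrier truth + linkage bookkeeping
.sim_family_once <- function(cfg) {
  mk_id <- function(g, k) paste0(as.character(utils::as.roman(g)), "-", k)
  rows <- list(); hap_src <- list()  # hap_src[[id]]: c(pat_hap, mat_hap) in 1:2
  add <- function(id, fa, mo, sex, carrier) {
    rows[[length(rows) + 1L]] <<- data.frame(
      individual_id = id, father_id = fa, mother_id = mo, sex = sex,
      carrier = carrier, stringsAsFactors = FALSE)
  }
  add("I-1", NA_character_, NA_character_, "male", isTRUE(cfg$founder_carrier))
  add("I-2", NA_character_, NA_character_, "female", FALSE)
  introducer <- if (isTRUE(cfg$founder_carrier)) "I-1" else NA_character_
  couples <- list(c("I-1", "I-2"))
  carrier_of <- c("I-1" = isTRUE(cfg$founder_carrier), "I-2" = FALSE)
  # which parental haplotype each member transmitted with the variant is
  # resolved later in .sim_markers; here record, per child, which of each
  # parent's two haplotypes was inherited (1 = variant-bearing for carriers)
  hap_from_carrier <- list()
  for (g in seq(2L, cfg$n_generations)) {
    k <- 0L; next_couples <- list()
    for (cp in couples) {
      fa <- cp[1L]; mo <- cp[2L]
      nk <- 1L + rpois(1L, max(cfg$sibship_size_mean - 1, 0))
      for (ch in seq_len(nk)) {
        k <- k + 1L
        id <- mk_id(g, k)
        sex <- sample(c("male", "female"), 1L)
        par_car <- carrier_of[fa] || carrier_of[mo]
        car <- if (par_car) runif(1L) < 0.5 else FALSE
        add(id, fa, mo, sex, car)
        carrier_of[id] <- car
        hap_from_carrier[[id]] <- c(father = if (carrier_of[fa])
          (if (car) 1L else 2L) else sample(1:2, 1L),
          mother = if (carrier_of[mo]) (if (car) 1L else 2L) else
            sample(1:2, 1L))
        if (g < cfg$n_generations) {
          k <- k + 1L
          sp <- mk_id(g, k)
          add(sp, NA_character_, NA_character_,
              if (sex == "male") "female" else "male", FALSE)
          carrier_of[sp] <- FALSE
          next_couples[[length(next_couples) + 1L]] <-
            if (sex == "male") c(id, sp) else c(sp, id)
        }
      }
    }
    couples <- next_couples
  }
  members <- do.call(rbind, rows)
  members$affection <- ifelse(
    runif(nrow(members)) < ifelse(members$carrier, cfg$penetrance,
                                  cfg$phenocopy_rate),
    "affected", "unaffected")
  onset <- pmin(pmax(round(rnorm(nrow(members), 32, 8)), 12), 60)
  members$age_at_onset <- ifelse(members$affection == "affected", onset,
                                 NA_real_)
  members$age_at_exam <- pmax(pmin(round(rnorm(nrow(members), 55, 15)), 90),
                              ifelse(is.na(members$age_at_onset), 20,
                                     members$age_at_onset))
  members$dna <- runif(nrow(members)) >= cfg$genotype_missingness
  list(members = members, carrier = stats::setNames(members$carrier,
                                                    members$individual_id),
       introducer = introducer, hap_from_carrier = hap_from_carrier)
}

# microsatellite haplotypes in full linkage with the causal variant
.sim_markers <- function(members, hap_from_carrier, causal, cfg) {
  if (cfg$n_markers == 0L)
    return(data.frame(family_id = character(0), individual_id = character(0),
                      marker_id = character(0), physical_pos = numeric(0),
                      allele1_bp = numeric(0), allele2_bp = numeric(0),
                      stringsAsFactors = FALSE))
  mk_pos <- sort(causal$pos + sample(c(-1, 1), cfg$n_markers, TRUE) *
                   sample(5e4:9e5, cfg$n_markers))
  mk_id <- sprintf("D%sS%03d", causal$chrom, seq_len(cfg$n_markers))
  base <- sample(seq(120L, 300L, by = 20L), cfg$n_markers, replace = TRUE)
  haps <- list()  # haps[[id]] = list(h1, h2); h1 of a carrier bears the variant
  for (i in seq_len(nrow(members))) {
    id <- members$individual_id[i]
    fa <- members$father_id[i]; mo <- members$mother_id[i]
    if (is.na(fa)) {
      haps[[id]] <- list(base + 2 * sample(0:7, cfg$n_markers, TRUE),
                         base + 2 * sample(0:7, cfg$n_markers, TRUE))
    } else {
      pick <- hap_from_carrier[[id]]
      h_pat <- haps[[fa]][[pick[["father"]]]]
      h_mat <- haps[[mo]][[pick[["mother"]]]]
      # keep the variant-bearing haplotype in slot 1 for carriers
      if (members$carrier[i] && members$carrier[match(mo, members$individual_id)])
        haps[[id]] <- list(h_mat, h_pat)
      else
        haps[[id]] <- list(h_pat, h_mat)
    }
  }
  do.call(rbind, lapply(members$individual_id[members$dna], function(id) {
    data.frame(family_id = cfg$family_id, individual_id = id,
               marker_id = mk_id, physical_pos = mk_pos,
               allele1_bp = haps[[id]][[1L]], allele2_bp = haps[[id]][[2L]],
               stringsAsFactors = FALSE)
  }))
}

#' Configuration for the cohort simulator
#'
#' Emulates the case/control carrier-count structure of a genotyped
#' cohort: a causal variant enriched in cases plus background variants at
#' equal frequency in both groups, spanning the 1% rarity threshold.
#'
#' @param n_cases,n_controls cohort sizes (diploid individuals).
#' @param causal_maf_cases,causal_maf_controls causal allele frequency
#'   per group, in [0, 0.5].
#' @param causal_reference_maf allele fraction recorded for the causal
#'   variant in the simulated population database.
#' @param n_background_variants number of null variants.
#' @param background_maf_range log-uniform range of background allele
#'   frequencies.
#' @param seed integer seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_cases = 500L, n_controls = 500L,
                              causal_maf_cases = 0.0026,
                              causal_maf_controls = 0,
                              causal_reference_maf = 0.001,
                              n_background_variants = 25L,
                              background_maf_range = c(1e-4, 0.05),
                              seed = 1L) {
  stopifnot(n_cases > 0L, n_controls > 0L,
            causal_maf_cases >= 0, causal_maf_cases <= 0.5,
            causal_maf_controls >= 0, causal_maf_controls <= 0.5,
            length(background_maf_range) == 2L,
            all(background_maf_range > 0 & background_maf_range <= 0.5))
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate a genotyped case/control cohort
#'
#' Carrier counts are binomial in allele number (2n) at the configured
#' frequency; carriers are heterozygous (rare-variant assumption).
#'
#' @param cfg a [cohort_sim_config()].
#' @return An object of class `sim_cohort`: list with `cases` and
#'   `controls` (`variant_set`s), `counts` (per-variant carrier-count
#'   table), `freq` (population-database rows) and `causal_key`.
#' @export
simulate_cohort <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  case_ids <- sprintf("case_%04d", seq_len(cfg$n_cases))
  ctrl_ids <- sprintf("ctrl_%04d", seq_len(cfg$n_controls))
  vars <- .rand_variant("CAUSAL", "missense")
  freqs <- data.frame(variant_key = vars$variant_key, database = "popdb",
                      allele_fraction = cfg$causal_reference_maf,
                      stringsAsFactors = FALSE)
  maf_cases <- cfg$causal_maf_cases; maf_ctrl <- cfg$causal_maf_controls
  for (j in seq_len(cfg$n_background_variants)) {
    v <- .rand_variant(sprintf("BG%03d", j),
                       sample(c("missense", "nonsense", "other"), 1L,
                              prob = c(0.5, 0.15, 0.35)))
    f <- 10^runif(1L, log10(cfg$background_maf_range[1L]),
                  log10(cfg$background_maf_range[2L]))
    vars <- rbind(vars, v)
    freqs <- rbind(freqs, data.frame(variant_key = v$variant_key,
                                     database = "popdb", allele_fraction = f,
                                     stringsAsFactors = FALSE))
    maf_cases <- c(maf_cases, f); maf_ctrl <- c(maf_ctrl, f)
  }
  draw_group <- function(ids, mafs) {
    rows <- lapply(seq_len(nrow(vars)), function(i) {
      k <- min(rbinom(1L, 2L * length(ids), mafs[i]), length(ids))
      call <- rep("wildtype", length(ids))
      if (k > 0L) call[sample(length(ids), k)] <- "carrier"
      genotype_calls(ids, call, vars$variant_key[i])
    })
    do.call(rbind, rows)
  }
  g_cases <- draw_group(case_ids, maf_cases)
  g_ctrl <- draw_group(ctrl_ids, maf_ctrl)
  count_car <- function(g) {
    car <- g[g$call == "carrier", , drop = FALSE]
    tab <- table(factor(car$variant_key, levels = vars$variant_key))
    as.integer(tab)
  }
  counts <- data.frame(variant_key = vars$variant_key, gene = vars$gene,
                       consequence = vars$consequence,
                       cases_carriers = count_car(g_cases),
                       cases_n = cfg$n_cases,
                       controls_carriers = count_car(g_ctrl),
                       controls_n = cfg$n_controls,
                       stringsAsFactors = FALSE)
  structure(list(cases = new_variant_set(vars, g_cases, freqs),
                 controls = new_variant_set(vars, g_ctrl, freqs),
                 counts = counts, freq = freqs,
                 causal_key = vars$variant_key[1L], config = cfg),
            class = "sim_cohort")
}

#' Write a self-contained fixture bundle
#'
#' Emits every input file the pipeline consumes -- PED, per-family VCFs,
#' cohort VCFs, frequency and carrier-count TSVs, marker TSV -- plus a
#' JSON manifest recording the generating configurations.  Bundles are
#' byte-identical for identical seeds and configurations.
#'
#' @param families list of [simulate_family()] results (may be empty).
#' @param cohort a [simulate_cohort()] result, or `NULL`.
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_bundle <- function(families = list(), cohort = NULL, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create bundle directory: ", dir)
  paths <- list()
  if (length(families)) {
    paths$ped <- file.path(dir, "families.ped")
    write_ped(lapply(families, `[[`, "ped"), paths$ped)
    paths$family_vcf <- vapply(families, function(f) {
      p <- file.path(dir, sprintf("family_%s.vcf", f$ped$family_id))
      write_variant_vcf(f$variants, p,
                        samples = unique(f$calls$individual_id))
      p
    }, character(1L))
    mk <- do.call(rbind, lapply(families, `[[`, "markers"))
    paths$markers <- file.path(dir, "markers.tsv")
    utils::write.table(mk, paths$markers, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  freq <- rbind(
    if (length(families))
      do.call(rbind, lapply(families, function(f) f$variants$frequencies)),
    if (!is.null(cohort)) cohort$freq)
  if (!is.null(freq)) {
    paths$frequencies <- file.path(dir, "frequencies.tsv")
    utils::write.table(unique(freq), paths$frequencies, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort)) {
    paths$cases_vcf <- file.path(dir, "cohort_cases.vcf")
    write_variant_vcf(cohort$cases, paths$cases_vcf)
    paths$controls_vcf <- file.path(dir, "cohort_controls.vcf")
    write_variant_vcf(cohort$controls, paths$controls_vcf)
    paths$counts <- file.path(dir, "cohort_counts.tsv")
    utils::write.table(cohort$counts, paths$counts, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    families = lapply(families, function(f)
      c(unclass(f$config), list(causal_key = f$causal_key))),
    cohort = if (!is.null(cohort))
      c(unclass(cohort$config), list(causal_key = cohort$causal_key)),
    files = lapply(paths, basename))
  paths$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}
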