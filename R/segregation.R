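# Per-family co-segregation rule and the discovery / cohort-mining
# orchestration around it.

#' Evaluate co-segregation of a variant in one family
#'
#' Applies the dominant reduced-penetrance criterion: a variant segregates
#' with disease when it is observed (or inferred) in at least 75% of the
#' affected blood relatives with an informative genotype, and in no more
#' than one unaffected family member, where obligate carriers -- unaffected
#' parents of affected carriers, plus forced carriers on the transmission
#' paths -- are excluded from the unaffected count.  Members with
#' "possible" or unknown affection are excluded from both tallies, as are
#' married-in members (no blood path to the proband).  Wholly untyped
#' affected members are excluded from the denominator rather than assumed
#' wildtype.
#'
#' @param ped a [pedigree()].
#' @param calls genotype-call table.
#' @param variant_key variant identifier.
#' @param proband individual whose blood relatives define the counted set;
#'   defaults to the first affected member in pedigree order.
#' @param include_possible count "possible" affection as affected
#'   (default `FALSE`).
#' @param extended_obligate forward to [infer_obligate_carriers()].
#' @param min_affected_fraction segregation threshold, inclusive
#'   (default 0.75, so 3 of 4 passes).
#' @param max_unaffected_carriers maximum counted unaffected carriers
#'   (default 1).
#' @param mode provenance label: `"full"`, `"all_but_one"` or
#'   `"genotyped_followup"`.
#' @return An object of class `segregation_result` with fields
#'   `family_id`, `variant_key`, `n_affected_informative`,
#'   `n_affected_carriers`, `affected_fraction`, `obligate_carriers`,
#'   `n_unaffected_carriers_counted`, `verdict`, `mode`.
#' @export
evaluate_segregation <- function(ped, calls, variant_key, proband = NULL,
                                 include_possible = FALSE,
                                 extended_obligate = TRUE,
                                 min_affected_fraction = 0.75,
                                 max_unaffected_carriers = 1L,
                                 mode = "full") {
  stopifnot(inherits(ped, "fam_pedigree"),
            mode %in% c("full", "all_but_one", "genotyped_followup"))
  m <- ped$members
  aff_levels <- if (include_possible) c("affected", "possible") else "affected"
  affected_ids <- m$individual_id[m$affection %in% aff_levels]
  if (!length(affected_ids))
    stop(errorCondition(
      paste0("no affected individual in family ", ped$family_id),
      class = "famcoseg_insufficient"))
  if (is.null(proband)) proband <- affected_ids[1L]
  core <- c(proband, blood_relatives(ped, proband))

  sol <- .solve_carriers(ped, calls, variant_key)
  if (sol$consistent) {
    calls2 <- .inferred_from_sol(ped, sol, calls, variant_key)
    obligate <- .obligate_from_sol(ped, sol, extended = extended_obligate)
  } else {
    if (!is.null(sol$trio))
      stop("Mendelian inconsistency in family ", ped$family_id, " at ",
           variant_key, ": carrier child ", sol$trio[["child"]],
           " with wildtype parents ", sol$trio[["father"]], "/",
           sol$trio[["mother"]])
    warning("family ", ped$family_id, ": single-founder model violated for ",
            variant_key, "; evaluating observed calls only")
    calls2 <- calls
    obligate <- character(0)
  }
  geno <- .obs_calls_with_inferred(ped, calls2, variant_key)

  aff_core <- intersect(affected_ids, core)
  informative <- aff_core[geno[aff_core] != "missing"]
  if (!length(informative))
    stop(errorCondition(
      paste0("no informative affected individual in family ", ped$family_id,
             " for ", variant_key),
      class = "famcoseg_insufficient"))
  n_car <- sum(geno[informative] == "carrier")
  frac <- n_car / length(informative)

  unaff_core <- intersect(m$individual_id[m$affection == "unaffected"], core)
  unaff_carriers <- unaff_core[geno[unaff_core] == "carrier"]
  counted <- setdiff(unaff_carriers, obligate)

  structure(list(
    family_id = ped$family_id,
    variant_key = variant_key,
    n_affected_informative = length(informative),
    n_affected_carriers = n_car,
    affected_fraction = frac,
    obligate_carriers = sort(obligate),
    n_unaffected_carriers_counted = length(counted),
    verdict = if (frac >= min_affected_fraction &&
                  length(counted) <= max_unaffected_carriers)
      "segregating" else "not_segregating",
    mode = mode), class = "segregation_result")
}

# calls (observed + inferred) folded to one call per member
.obs_calls_with_inferred <- function(ped, calls, variant_key) {
  ids <- ped_ids(ped)
  geno <- stats::setNames(rep("missing", length(ids)), ids)
  sub <- calls[calls$variant_key == variant_key & calls$call != "missing" &
                 calls$individual_id %in% ids, , drop = FALSE]
  # observed takes precedence over inferred (they never conflict by
  # construction, but be explicit)
  for (org in c("inferred", "observed")) {
    s <- sub[sub$origin == org, , drop = FALSE]
    geno[s$individual_id] <- s$call
  }
  geno
}

.empty_seg_df <- function(cadd = FALSE) {
  df <- data.frame(family_id = character(0), variant_key = character(0),
                   n_affected_informative = integer(0),
                   n_affected_carriers = integer(0),
                   affected_fraction = numeric(0),
                   n_unaffected_carriers_counted = integer(0),
                   obligate_carriers = character(0),
                   verdict = character(0), mode = character(0),
                   stringsAsFactors = FALSE)
  if (cadd) df$cadd_phred <- numeric(0)
  df
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "<segregation_result> family %s, %s: %d/%d affected carriers (%.1f%%), %d counted unaffected, %d obligate -> %s [%s]\n",
    x$family_id, x$variant_key, x$n_affected_carriers,
    x$n_affected_informative, 100 * x$affected_fraction,
    x$n_unaffected_carriers_counted, length(x$obligate_carriers),
    x$verdict, x$mode))
  invisible(x)
}

#' @export
as.data.frame.segregation_result <- function(x, ...) {
  data.frame(family_id = x$family_id, variant_key = x$variant_key,
             n_affected_informative = x$n_affected_informative,
             n_affected_carriers = x$n_affected_carriers,
             affected_fraction = x$affected_fraction,
             n_unaffected_carriers_counted = x$n_unaffected_carriers_counted,
             obligate_carriers = paste(x$obligate_carriers, collapse = ","),
             verdict = x$verdict, mode = x$mode, stringsAsFactors = FALSE)
}

#' Nominate segregating candidates in one family
#'
#' Runs genotype inference and [evaluate_segregation()] for every shared
#' candidate variant and returns the segregating ones, sorted by affected
#' fraction (descending), then CADD score (descending), then variant key.
#'
#' @param ped a [pedigree()].
#' @param shared a `variant_set` from [shared_by_affected()] (attribute
#'   `share_mode` is propagated into the result's `mode` column).
#' @param calls additional genotype calls (e.g. follow-up genotyping of
#'   family members not in the VCF); merged with the set's own genotypes.
#' @param ... forwarded to [evaluate_segregation()].
#' @return data frame of segregating results (zero rows when the family is
#'   unresolved), with a `cadd_phred` column appended.
#' @export
nominate_candidates <- function(ped, shared, calls = NULL, ...) {
  stopifnot(inherits(shared, "variant_set"))
  mode <- attr(shared, "share_mode")
  if (is.null(mode)) mode <- "full"
  all_calls <- rbind(shared$genotypes, calls)
  res <- list()
  for (i in seq_len(nrow(shared$variants))) {
    key <- shared$variants$variant_key[i]
    r <- tryCatch(
      evaluate_segregation(ped, all_calls, key, mode = mode, ...),
      famcoseg_insufficient = function(e) NULL)
    if (is.null(r) || r$verdict != "segregating") next
    df <- as.data.frame(r)
    df$cadd_phred <- shared$variants$cadd_phred[i]
    res[[length(res) + 1L]] <- df
  }
  if (!length(res)) return(.empty_seg_df(cadd = TRUE))
  out <- do.call(rbind, res)
  cadd <- ifelse(is.na(out$cadd_phred), -Inf, out$cadd_phred)
  out <- out[order(-out$affected_fraction, -cadd, out$variant_key), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine a cohort for rare case-exclusive variants in a gene
#'
#' Finds rare missense/nonsense variants in `gene` present in at least one
#' case and absent from every control record, then evaluates each within
#' the families of its carriers (`mode = "genotyped_followup"`).  Variants
#' found in controls are reported as excluded with the reason recorded.
#'
#' @param gene gene symbol of interest.
#' @param case_vs,control_vs `variant_set`s for cases and controls.
#' @param freq frequency data frame (see [read_frequency_table()]).
#' @param peds named list of [pedigree()]s, keyed by family id.
#' @param calls genotype-call table covering the family members
#'   (follow-up genotyping).
#' @param crit a [filter_criteria()].
#' @return list with `results` (data frame of segregation rows) and
#'   `excluded` (data frame `variant_key`, `reason`).
#' @export
mine_cohort <- function(gene, case_vs, control_vs, freq, peds, calls,
                        crit = filter_criteria()) {
  stopifnot(inherits(case_vs, "variant_set"), inherits(control_vs, "variant_set"))
  in_gene <- .vs_subset(case_vs,
                        case_vs$variants$variant_key[case_vs$variants$gene == gene])
  if (!nrow(in_gene$variants)) {
    warning("gene ", gene, " absent from the case annotation")
    return(list(results = .empty_seg_df(),
                excluded = data.frame(variant_key = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)))
  }
  rare <- apply_filter(attach_frequencies(in_gene, freq), crit)
  excluded <- data.frame(variant_key = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  results <- list()
  ctrl_carrier_keys <- unique(
    control_vs$genotypes$variant_key[control_vs$genotypes$call == "carrier"])
  for (i in seq_len(nrow(rare$variants))) {
    key <- rare$variants$variant_key[i]
    case_carriers <- rare$genotypes$individual_id[
      rare$genotypes$variant_key == key & rare$genotypes$call == "carrier"]
    if (!length(case_carriers)) next
    if (key %in% ctrl_carrier_keys) {
      excluded <- rbind(excluded, data.frame(
        variant_key = key, reason = "present_in_controls",
        stringsAsFactors = FALSE))
      next
    }
    fams <- Filter(function(p) any(case_carriers %in% ped_ids(p)), peds)
    for (ped in fams) {
      r <- evaluate_segregation(ped, calls, key, mode = "genotyped_followup")
      results[[length(results) + 1L]] <- as.data.frame(r)
    }
  }
  list(results = if (length(results)) do.call(rbind, results) else
    .empty_seg_df(), excluded = excluded)
}
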