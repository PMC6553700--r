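# Pipeline orchestration: configuration, the discovery run over a fixture
# or study bundle, and the association report.

#' Pipeline run configuration
#'
#' @param ped_path PED file with the families to analyse.
#' @param vcf_paths named character vector of per-family VCF paths (names
#'   are family ids); a single unnamed path is used for every family.
#' @param freq_path frequency-database TSV (optional).
#' @param counts_path carrier-count TSV for [run_assoc()] (optional).
#' @param out_dir output directory.
#' @param crit a [filter_criteria()].
#' @param min_affected_fraction,max_unaffected_carriers segregation
#'   thresholds (defaults 0.75 and 1).
#' @param consequence_tag INFO key for [load_variants()].
#' @param seed integer seed recorded with the outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(ped_path = NULL, vcf_paths = NULL, freq_path = NULL,
                       counts_path = NULL, out_dir = ".",
                       crit = filter_criteria(),
                       min_affected_fraction = 0.75,
                       max_unaffected_carriers = 1L,
                       consequence_tag = "ANN", seed = 1L) {
  for (p in c(ped_path, vcf_paths, freq_path, counts_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  stopifnot(min_affected_fraction > 0, min_affected_fraction <= 1,
            max_unaffected_carriers >= 0L)
  structure(as.list(environment()), class = "run_config")
}

#' Run the per-family discovery pipeline
#'
#' For every family: load the annotated VCF, apply the rare-candidate
#' filter, take the variants shared by the sequenced affected members
#' (with the all-but-one fallback), infer genotypes and evaluate
#' co-segregation.  Writes `candidates.tsv` (one row per family, an
#' explicit `unresolved` row when nothing segregates), `segregation.json`,
#' and `attrition.tsv` logging the per-family filter attrition (loaded ->
#' rare -> shared -> segregating).
#'
#' @param cfg a [run_config()] with `ped_path` and `vcf_paths` set.
#' @return Invisibly, a list with `candidates`, `attrition` and the
#'   output paths.
#' @export
run_discover <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$ped_path) || is.null(cfg$vcf_paths))
    stop("run_discover needs ped_path and vcf_paths")
  if (!dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  peds <- read_ped(cfg$ped_path)
  freq <- if (!is.null(cfg$freq_path)) read_frequency_table(cfg$freq_path)
  cand_rows <- list(); attr_rows <- list()
  for (fid in names(peds)) {
    ped <- peds[[fid]]
    vp <- if (is.null(names(cfg$vcf_paths))) cfg$vcf_paths[1L]
      else cfg$vcf_paths[[fid]]
    if (is.null(vp) || is.na(vp)) stop("no VCF configured for family ", fid)
    vs <- load_variants(vp, cfg$consequence_tag)
    if (!is.null(freq)) vs <- attach_frequencies(vs, freq)
    rare <- apply_filter(vs, cfg$crit)
    shared <- tryCatch(shared_by_affected(rare, ped),
                       famcoseg_insufficient = function(e) {
                         out <- .vs_subset(rare, character(0))
                         attr(out, "share_mode") <- "insufficient_data"
                         out
                       })
    nom <- nominate_candidates(
      ped, shared,
      min_affected_fraction = cfg$min_affected_fraction,
      max_unaffected_carriers = cfg$max_unaffected_carriers)
    attr_rows[[fid]] <- data.frame(
      family_id = fid, loaded = nrow(vs$variants),
      rare = nrow(rare$variants), shared = nrow(shared$variants),
      share_mode = attr(shared, "share_mode"),
      segregating = nrow(nom), stringsAsFactors = FALSE)
    cand_rows[[fid]] <- if (nrow(nom)) nom else data.frame(
      family_id = fid, variant_key = NA_character_,
      n_affected_informative = NA_integer_, n_affected_carriers = NA_integer_,
      affected_fraction = NA_real_, n_unaffected_carriers_counted = NA_integer_,
      obligate_carriers = NA_character_, verdict = "unresolved",
      mode = attr(shared, "share_mode"), cadd_phred = NA_real_,
      stringsAsFactors = FALSE)
  }
  candidates <- do.call(rbind, cand_rows)
  attrition <- do.call(rbind, attr_rows)
  rownames(candidates) <- rownames(attrition) <- NULL
  paths <- list(candidates = file.path(cfg$out_dir, "candidates.tsv"),
                attrition = file.path(cfg$out_dir, "attrition.tsv"),
                json = file.path(cfg$out_dir, "segregation.json"))
  utils::write.table(candidates, paths$candidates, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(attrition, paths$attrition, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(seed = cfg$seed, candidates = candidates,
                            attrition = attrition),
                       paths$json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(candidates = candidates, attrition = attrition,
                 paths = paths))
}

#' Run the case/control association report
#'
#' Reads a carrier-count TSV (columns `variant_key` or `gene`,
#' `cases_carriers`, `cases_n`, `controls_carriers`, `controls_n`) and
#' writes `association.tsv` with allele frequencies rendered as percent
#' strings (half-away-from-zero rounding) and `OR (CI)` formatted to two
#' decimals; rows where no carrier exists in either group are reported
#' with an error note rather than aborting the run.
#'
#' @param cfg a [run_config()] with `counts_path` set.
#' @return Invisibly, a list with the `association` data frame and the
#'   output path.
#' @export
run_assoc <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$counts_path)) stop("run_assoc needs counts_path")
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  df <- utils::read.table(cfg$counts_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("cases_carriers", "cases_n", "controls_carriers", "controls_n")
  bad <- setdiff(need, names(df))
  if (length(bad)) stop("counts table lacks columns: ",
                        paste(bad, collapse = ", "))
  out <- df
  out$maf_cases <- out$maf_controls <- out$or_ci <- rep(NA_character_,
                                                        nrow(df))
  out$correction_applied <- rep(NA, nrow(df))
  out$note <- rep("", nrow(df))
  for (i in seq_len(nrow(df))) {
    res <- tryCatch({
      cc <- carrier_counts(df$cases_carriers[i], df$cases_n[i],
                           df$controls_carriers[i], df$controls_n[i])
      odds_ratio(cc)
    }, error = function(e) e)
    if (inherits(res, "error")) { out$note[i] <- conditionMessage(res); next }
    out$maf_cases[i] <- percent_string(res$maf_cases)
    out$maf_controls[i] <- percent_string(res$maf_controls)
    out$or_ci[i] <- format_or(res)
    out$correction_applied[i] <- res$correction_applied
  }
  path <- file.path(cfg$out_dir, "association.tsv")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(association = out, path = path))
}
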