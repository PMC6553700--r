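# VCF loading, frequency-database handling and the rare-candidate filter:
# autosomal, heterozygous, missense/nonsense, MAF < 1% in every database.

#' Filter criteria for candidate variants
#'
#' @param maf_threshold retain a variant only when its allele fraction is
#'   strictly below this value in every configured frequency database
#'   (default 0.01; a variant at exactly 1% is removed).
#' @param consequences retained consequence classes.
#' @param autosomes_only restrict to chromosomes 1-22 (`"chr10"` and
#'   `"10"` are equivalent).
#' @param het_only heterozygous-carrier model flag; homozygous-alternate
#'   genotypes were already collapsed to carrier (with a warning) at load
#'   time, so this is descriptive of the dominant model rather than a
#'   second filter pass.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(maf_threshold = 0.01,
                            consequences = c("missense", "nonsense"),
                            autosomes_only = TRUE, het_only = TRUE) {
  stopifnot(is.numeric(maf_threshold), maf_threshold > 0, maf_threshold <= 1)
  structure(list(maf_threshold = maf_threshold,
                 consequences = consequences,
                 autosomes_only = isTRUE(autosomes_only),
                 het_only = isTRUE(het_only)),
            class = "filter_criteria")
}

.norm_chrom <- function(chrom) sub("^[Cc]hr", "", as.character(chrom))

.is_autosome <- function(chrom) .norm_chrom(chrom) %in% as.character(1:22)

.norm_consequence <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[grepl("missense", x)] <- "missense"
  out[grepl("nonsense|stop_gained|stopgain", x)] <- "nonsense"
  out
}

new_variant_set <- function(variants, genotypes = NULL, frequencies = NULL) {
  if (is.null(genotypes))
    genotypes <- genotype_calls(character(0), character(0), character(0))
  if (is.null(frequencies))
    frequencies <- data.frame(variant_key = character(0),
                              database = character(0),
                              allele_fraction = numeric(0),
                              stringsAsFactors = FALSE)
  structure(list(variants = variants, genotypes = genotypes,
                 frequencies = frequencies), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variants, %d genotype calls, %d frequency entries\n",
              nrow(x$variants), nrow(x$genotypes), nrow(x$frequencies)))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$variants)

# subset a variant_set to the given variant_keys, preserving order
.vs_subset <- function(vs, keys) {
  new_variant_set(
    vs$variants[vs$variants$variant_key %in% keys, , drop = FALSE],
    vs$genotypes[vs$genotypes$variant_key %in% keys, , drop = FALSE],
    vs$frequencies[vs$frequencies$variant_key %in% keys, , drop = FALSE])
}

#' Load annotated variants from a VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped) whose INFO field carries a
#' consequence annotation.  Two annotation dialects are accepted for the
#' tag named by `consequence_tag`: a minimal `alt|consequence|gene` triple,
#' or a full ANN-style entry (`Allele|Annotation|Impact|Gene_Name|...`);
#' for multi-entry annotations the first transcript consequence wins.  A
#' numeric `CADD` INFO tag is read when present.  Multiallelic records are
#' split into biallelic records sharing `chrom:pos`.  Genotypes are mapped
#' to the dominant-model calls: `0/1` or `1/0` to carrier, `0/0` to
#' wildtype, `./.` to missing, and `1/1` to carrier with a warning
#' (heterozygote collapse).
#'
#' @param vcf_path path to the VCF.
#' @param consequence_tag INFO key holding the consequence annotation
#'   (default `"ANN"`).
#' @return A `variant_set`: list with data frames `variants`
#'   (`variant_key`, `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#'   `cadd_phred`), `genotypes` (long form, one row per sample per
#'   variant) and `frequencies` (empty; see [attach_frequencies()]).
#' @export
load_variants <- function(vcf_path, consequence_tag = "ANN") {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) return(new_variant_set(data.frame(
    variant_key = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), gene = character(0),
    consequence = character(0), cadd_phred = numeric(0),
    stringsAsFactors = FALSE)))
  ann <- vcfR::extract.info(vcf, element = consequence_tag)
  if (all(is.na(ann)))
    stop("INFO tag '", consequence_tag, "' absent from every record of ",
         vcf_path)
  cadd <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "CADD")))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)

  var_rows <- list(); geno_rows <- list(); homozygote_seen <- FALSE
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    if (is.na(ann[i]))
      stop("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " lacks INFO tag '", consequence_tag, "'")
    entries <- strsplit(ann[i], ",", fixed = TRUE)[[1L]]
    efields <- strsplit(entries, "|", fixed = TRUE)
    gt_i <- if (length(samples)) gt[i, , drop = TRUE] else character(0)
    gt_split <- strsplit(ifelse(is.na(gt_i), ".", gt_i), "[/|]")
    for (k in seq_along(alts)) {
      # pick the first annotation entry matching this allele, else entry k,
      # else the first
      sel <- which(vapply(efields, `[`, "", 1L) == alts[k])
      e <- if (length(sel)) efields[[sel[1L]]]
        else if (length(efields) >= k) efields[[k]] else efields[[1L]]
      if (length(e) >= 4L) { cons <- e[2L]; gene <- e[4L] }
      else if (length(e) == 3L) { cons <- e[2L]; gene <- e[3L] }
      else if (length(e) == 2L) { cons <- e[1L]; gene <- e[2L] }
      else stop("unparseable ", consequence_tag, " annotation at ",
                fix[i, "CHROM"], ":", fix[i, "POS"])
      key <- paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts[k],
                   sep = ":")
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        variant_key = key, chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]), ref = fix[i, "REF"], alt = alts[k],
        gene = gene, consequence = .norm_consequence(cons),
        cadd_phred = cadd[i], stringsAsFactors = FALSE)
      if (length(samples)) {
        nalt <- vapply(gt_split, function(g) sum(g == as.character(k)),
                       integer(1L))
        has_missing <- vapply(gt_split, function(g) any(g == "."), logical(1L))
        call <- ifelse(has_missing & nalt == 0L, "missing",
                       ifelse(nalt >= 1L, "carrier", "wildtype"))
        if (any(nalt >= 2L)) homozygote_seen <- TRUE
        geno_rows[[length(geno_rows) + 1L]] <- genotype_calls(
          samples, call, key)
      }
    }
  }
  if (homozygote_seen)
    warning("homozygous-alternate genotypes collapsed to carrier ",
            "(dominant heterozygote model)")
  vars <- do.call(rbind, var_rows)
  if (anyDuplicated(vars$variant_key))
    stop("duplicate variant_key in ", vcf_path)
  new_variant_set(vars, if (length(geno_rows)) do.call(rbind, geno_rows))
}

#' Read a frequency-database table
#'
#' Tab-separated with header columns `variant_key`, `database`,
#' `allele_fraction`.
#'
#' @param path path to the TSV.
#' @return data frame with those three columns.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("variant_key", "database", "allele_fraction")
  if (!all(need %in% names(df)))
    stop("frequency table must have columns ", paste(need, collapse = ", "))
  df[need]
}

#' Attach database frequencies to a variant set
#'
#' A variant absent from a database is treated as frequency 0 there
#' ("not present"), so only positive observations need rows.
#'
#' @param vs a `variant_set`.
#' @param freq frequency data frame (see [read_frequency_table()]); rows
#'   for variants outside `vs` are dropped.
#' @return The updated `variant_set`.
#' @export
attach_frequencies <- function(vs, freq) {
  stopifnot(inherits(vs, "variant_set"))
  vs$frequencies <- freq[freq$variant_key %in% vs$variants$variant_key, ,
                         drop = FALSE]
  vs
}

#' Apply the rare-candidate filter
#'
#' Retains variants that are autosomal, of an allowed consequence class,
#' and strictly below the MAF threshold in every configured database (a
#' variant with no entry in a database counts as absent, frequency 0).
#' Input order is preserved and the input is not modified.
#'
#' @param vs a `variant_set` with frequencies attached.
#' @param crit a [filter_criteria()].
#' @return The filtered `variant_set`.
#' @export
apply_filter <- function(vs, crit = filter_criteria()) {
  stopifnot(inherits(vs, "variant_set"), inherits(crit, "filter_criteria"))
  v <- vs$variants
  keep <- v$consequence %in% crit$consequences
  if (crit$autosomes_only) keep <- keep & .is_autosome(v$chrom)
  if (nrow(vs$frequencies)) {
    max_freq <- tapply(vs$frequencies$allele_fraction,
                       vs$frequencies$variant_key, max)
    f <- max_freq[v$variant_key]
    f[is.na(f)] <- 0
    keep <- keep & (f < crit$maf_threshold)
  }
  .vs_subset(vs, v$variant_key[keep])
}

#' Variants shared by the sequenced affected members
#'
#' Discovery pass: returns variants carried by every sequenced affected
#' family member.  When that set is empty, a fallback pass returns
#' variants carried by all but one of them (n-1 of n); the result carries
#' attribute `share_mode` (`"full"` or `"all_but_one"`).
#'
#' @param vs a `variant_set` holding the family's genotypes.
#' @param ped the family [pedigree()].
#' @return The shared `variant_set` with attribute `share_mode`.
#' @export
shared_by_affected <- function(vs, ped) {
  stopifnot(inherits(vs, "variant_set"), inherits(ped, "fam_pedigree"))
  m <- ped$members
  affected <- m$individual_id[m$affection == "affected"]
  sequenced <- intersect(affected,
                         vs$genotypes$individual_id[vs$genotypes$call != "missing"])
  if (length(sequenced) < 2L)
    stop(errorCondition(
      paste0("fewer than 2 sequenced affected individuals in family ",
             ped$family_id),
      class = "famcoseg_insufficient"))
  g <- vs$genotypes[vs$genotypes$individual_id %in% sequenced &
                      vs$genotypes$call == "carrier", , drop = FALSE]
  n_car <- table(factor(g$variant_key, levels = vs$variants$variant_key))
  full <- names(n_car)[n_car == length(sequenced)]
  if (length(full)) {
    out <- .vs_subset(vs, full); attr(out, "share_mode") <- "full"
  } else {
    abo <- names(n_car)[n_car >= length(sequenced) - 1L]
    out <- .vs_subset(vs, abo); attr(out, "share_mode") <- "all_but_one"
  }
  out
}

#' Write a variant set as a plain-text VCF
#'
#' Minimal VCF 4.2 emitter using the same annotation dialect
#' [load_variants()] reads (`ANN=alt|consequence|gene`, numeric `CADD`,
#' per-sample `GT`).  Biallelic records are written one per row;
#' round-tripping through [load_variants()] reproduces the set.
#'
#' @param vs a `variant_set`.
#' @param path output path.
#' @param samples sample ids to emit as columns; defaults to the
#'   individuals present in the genotype table.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vs, path, samples = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  if (is.null(samples)) samples <- unique(vs$genotypes$individual_id)
  v <- vs$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=ANN,Number=.,Type=String,Description=\"alt|consequence|gene\">",
           "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD phred score\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(samples)) c("FORMAT", samples)),
                 collapse = "\t"))
  gmap <- c(carrier = "0/1", wildtype = "0/0", missing = "./.")
  lines <- vapply(seq_len(nrow(v)), function(i) {
    info <- paste0("ANN=", v$alt[i], "|", v$consequence[i], "|", v$gene[i])
    if (!is.na(v$cadd_phred[i]))
      info <- paste0(info, ";CADD=", format(v$cadd_phred[i]))
    cells <- c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS", info)
    if (length(samples)) {
      g <- vs$genotypes[vs$genotypes$variant_key == v$variant_key[i], ,
                        drop = FALSE]
      call <- stats::setNames(rep("missing", length(samples)), samples)
      call[g$individual_id[g$individual_id %in% samples]] <-
        g$call[g$individual_id %in% samples]
      cells <- c(cells, "GT", gmap[call])
    }
    paste(cells, collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
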