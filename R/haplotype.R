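# Microsatellite haplotype sharing across families carrying the same
# variant: shared founder vs independent mutational origin.

#' Construct a marker haplotype
#'
#' The ordered allele sizes carried on the variant-bearing chromosome of a
#' family, at microsatellite markers flanking the locus.  Allele sizes are
#' assumed CEPH-normalized so integer base-pair sizes are directly
#' comparable across families.
#'
#' @param family_id family identifier.
#' @param locus locus label (e.g. the gene or variant key).
#' @param markers data frame with columns `marker_id`, `physical_pos`
#'   (bp) and `allele_size` (bp, `NA` when not phased/genotyped).
#' @return An object of class `marker_haplotype`, markers sorted by
#'   physical position.
#' @export
marker_haplotype <- function(family_id, locus, markers) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("marker_id", "physical_pos", "allele_size")
  if (!all(need %in% names(markers)))
    stop("markers needs columns ", paste(need, collapse = ", "))
  markers <- markers[order(markers$physical_pos), need, drop = FALSE]
  structure(list(family_id = family_id, locus = locus, markers = markers),
            class = "marker_haplotype")
}

#' @export
print.marker_haplotype <- function(x, ...) {
  cat(sprintf("<marker_haplotype> family %s, locus %s: %d markers (%d typed)\n",
              x$family_id, x$locus, nrow(x$markers),
              sum(!is.na(x$markers$allele_size))))
  invisible(x)
}

#' Compare two disease haplotypes
#'
#' Families share a founder when their variant-bearing haplotypes carry
#' identical allele sizes at every co-genotyped marker; any mismatch
#' indicates independent mutational origin (a recurrent mutation at a
#' hotspot).  Fewer than `min_shared` co-genotyped markers is
#' inconclusive and raises a condition of class `famcoseg_inconclusive`,
#' distinct from either verdict.
#'
#' @param h1,h2 [marker_haplotype()]s at the same locus.
#' @param min_shared minimum co-genotyped markers required (default 3).
#' @return `"shared_founder"` or `"independent_origin"`.
#' @export
compare_haplotypes <- function(h1, h2, min_shared = 3L) {
  stopifnot(inherits(h1, "marker_haplotype"), inherits(h2, "marker_haplotype"))
  if (h1$locus != h2$locus)
    stop("haplotypes are from different loci: ", h1$locus, " vs ", h2$locus)
  m1 <- h1$markers[!is.na(h1$markers$allele_size), ]
  m2 <- h2$markers[!is.na(h2$markers$allele_size), ]
  common <- intersect(m1$marker_id, m2$marker_id)
  if (length(common) < min_shared)
    stop(errorCondition(
      sprintf("only %d co-genotyped markers between families %s and %s (need %d): inconclusive",
              length(common), h1$family_id, h2$family_id, min_shared),
      class = "famcoseg_inconclusive"))
  a1 <- m1$allele_size[match(common, m1$marker_id)]
  a2 <- m2$allele_size[match(common, m2$marker_id)]
  if (all(a1 == a2)) "shared_founder" else "independent_origin"
}

#' Read a marker-genotype table
#'
#' Tab-separated with header columns `family_id`, `individual_id`,
#' `marker_id`, `physical_pos`, `allele1_bp`, `allele2_bp`.
#'
#' @param path path to the TSV.
#' @return data frame with those columns.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("family_id", "individual_id", "marker_id", "physical_pos",
            "allele1_bp", "allele2_bp")
  if (!all(need %in% names(df)))
    stop("marker table must have columns ", paste(need, collapse = ", "))
  df[need]
}

#' Phase the variant-bearing haplotype of a family
#'
#' Simple transmission rule: for each marker, the allele co-transmitted
#' with the variant is the single allele size compatible with every
#' informative meiosis (carrier parent to carrier child); at least
#' `min_meioses` informative meioses are required, otherwise the marker is
#' left unphased (`NA`).
#'
#' @param ped a [pedigree()].
#' @param calls genotype-call table for `variant_key`.
#' @param variant_key the variant defining carrier status.
#' @param markers marker-genotype rows for this family (see
#'   [read_marker_table()]).
#' @param locus locus label for the resulting haplotype.
#' @param min_meioses minimum informative meioses per marker (default 2).
#' @return A [marker_haplotype()].
#' @export
phase_variant_haplotype <- function(ped, calls, variant_key, markers,
                                    locus = variant_key, min_meioses = 2L) {
  stopifnot(inherits(ped, "fam_pedigree"))
  obs <- .obs_calls(ped, calls, variant_key)
  m <- ped$members
  carriers <- names(obs)[obs == "carrier"]
  # informative meioses: carrier parent -> carrier child
  kid <- m$individual_id[m$individual_id %in% carriers]
  meioses <- list()
  for (id in kid) {
    i <- match(id, m$individual_id)
    for (p in c(m$father_id[i], m$mother_id[i]))
      if (!is.na(p) && p %in% carriers)
        meioses[[length(meioses) + 1L]] <- c(parent = p, child = id)
  }
  out <- lapply(unique(markers$marker_id), function(mk) {
    sub <- markers[markers$marker_id == mk, , drop = FALSE]
    alleles_of <- function(id) {
      r <- sub[sub$individual_id == id, , drop = FALSE]
      if (!nrow(r)) return(NULL)
      c(r$allele1_bp[1L], r$allele2_bp[1L])
    }
    cons <- NULL; n_inf <- 0L
    for (me in meioses) {
      pa <- alleles_of(me[["parent"]]); ch <- alleles_of(me[["child"]])
      if (is.null(pa) || is.null(ch)) next
      cand <- intersect(pa, ch)
      if (!length(cand)) next
      n_inf <- n_inf + 1L
      cons <- if (is.null(cons)) cand else intersect(cons, cand)
    }
    size <- if (n_inf >= min_meioses && length(cons) == 1L) cons else NA_real_
    data.frame(marker_id = mk, physical_pos = sub$physical_pos[1L],
               allele_size = size, stringsAsFactors = FALSE)
  })
  marker_haplotype(ped$family_id, locus, do.call(rbind, out))
}
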