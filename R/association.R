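# Carrier-based allele frequencies and 2x2 odds ratios with Woolf
# confidence intervals.

#' Minor allele frequency from carrier counts
#'
#' Under the heterozygous-carrier assumption each carrier contributes one
#' minor allele, so MAF = carriers / (2 * individuals).
#'
#' @param carriers number of carrier individuals.
#' @param n_individuals number of diploid individuals genotyped.
#' @return Allele fraction in `[0, 0.5]`.
#' @export
allele_frequency <- function(carriers, n_individuals) {
  if (n_individuals == 0) stop("n_individuals must be positive")
  stopifnot(carriers >= 0, carriers <= n_individuals)
  carriers / (2 * n_individuals)
}

#' Render a fraction as a percent string
#'
#' Rounds half away from zero (so 0.0465% renders "0.05%", 0.2598%
#' renders "0.26%"), the convention used throughout the cohort tables.
#'
#' @param frac allele fraction (not yet in percent).
#' @param digits decimal places (default 2).
#' @return e.g. `"0.26%"`.
#' @export
percent_string <- function(frac, digits = 2L) {
  p <- frac * 100
  r <- sign(p) * floor(abs(p) * 10^digits + 0.5 + 1e-9) / 10^digits
  sprintf("%.*f%%", digits, r)
}

#' Case/control carrier counts
#'
#' @param cases_carriers,cases_n carrier and total individual counts in
#'   cases; likewise `controls_carriers`, `controls_n` for controls.
#' @return An object of class `carrier_counts`.
#' @export
carrier_counts <- function(cases_carriers, cases_n, controls_carriers,
                           controls_n) {
  x <- list(cases_carriers = cases_carriers, cases_n = cases_n,
            controls_carriers = controls_carriers, controls_n = controls_n)
  if (any(unlist(x) < 0)) stop("counts must be non-negative")
  if (cases_carriers > cases_n || controls_carriers > controls_n)
    stop("carriers cannot exceed group size")
  structure(x, class = "carrier_counts")
}

.or_from_cells <- function(a, b, c, d, z = 1.96) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(odds_ratio = or,
       ci95_low = exp(log(or) - z * se),
       ci95_high = exp(log(or) + z * se),
       correction_applied = corrected)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' Builds the case/control 2x2 table and computes OR = (a d)/(b c) with
#' the Woolf log-normal interval exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c +
#' 1/d)).  When any cell is zero the Haldane-Anscombe correction (+0.5 to
#' all cells) is applied and flagged.  With `unit = "carrier"` (default)
#' the table counts carrier vs non-carrier individuals, the arithmetic
#' behind the published cohort comparisons; `unit = "allele"` counts minor
#' vs major alleles under the heterozygote assumption (b = 2n - carriers).
#' MAFs are always reported on the allele scale.
#'
#' @param counts a [carrier_counts()].
#' @param unit `"carrier"` or `"allele"` (table construction; see above).
#' @return An object of class `association_result`: `maf_cases`,
#'   `maf_controls`, `odds_ratio`, `ci95_low`, `ci95_high`,
#'   `correction_applied`.
#' @export
odds_ratio <- function(counts, unit = c("carrier", "allele")) {
  stopifnot(inherits(counts, "carrier_counts"))
  unit <- match.arg(unit)
  a <- counts$cases_carriers; c <- counts$controls_carriers
  if (a == 0 && c == 0)
    stop("odds ratio undefined: no carriers in either group")
  b <- switch(unit, carrier = counts$cases_n - a, allele = 2 * counts$cases_n - a)
  d <- switch(unit, carrier = counts$controls_n - c,
              allele = 2 * counts$controls_n - c)
  out <- .or_from_cells(a, b, c, d)
  structure(c(list(
    maf_cases = allele_frequency(a, counts$cases_n),
    maf_controls = allele_frequency(c, counts$controls_n)), out),
    class = "association_result")
}

#' Odds ratio against a reference-population allele frequency
#'
#' When no genotyped control carries the variant, reference databases
#' (e.g. exome aggregation cohorts) supply the comparison frequency.  The
#' reference side of the 2x2 table is reconstructed on the allele scale as
#' c = round(maf * alleles), d = alleles - c; the case side uses allele
#' counts (carriers heterozygous).
#'
#' @param carriers,n_individuals case carrier count and cohort size.
#' @param reference_maf reference allele fraction (must be < 1).
#' @param reference_alleles total allele count behind the reference MAF.
#' @return An `association_result` (with `maf_controls` the reconstructed
#'   reference fraction).
#' @export
frequency_vs_reference <- function(carriers, n_individuals, reference_maf,
                                   reference_alleles) {
  if (reference_alleles <= 0) stop("reference_alleles must be positive")
  if (reference_maf >= 1) stop("reference_maf must be below 1")
  a <- carriers; b <- 2 * n_individuals - carriers
  c <- round(reference_maf * reference_alleles)
  d <- reference_alleles - c
  if (a == 0 && c == 0)
    stop("odds ratio undefined: no carriers on either side")
  out <- .or_from_cells(a, b, c, d)
  structure(c(list(maf_cases = allele_frequency(carriers, n_individuals),
                   maf_controls = c / reference_alleles), out),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> MAF %s vs %s; OR %s%s\n",
              percent_string(x$maf_cases), percent_string(x$maf_controls),
              format_or(x),
              if (x$correction_applied) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Format an odds ratio with its confidence interval
#'
#' @param x an `association_result`.
#' @param digits decimal places (default 2).
#' @return e.g. `"3.10 (0.36-26.56)"`.
#' @export
format_or <- function(x, digits = 2L) {
  sprintf("%.*f (%.*f-%.*f)", digits, x$odds_ratio, digits, x$ci95_low,
          digits, x$ci95_high)
}
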