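# Independent brute-force oracle: enumerate every Mendelian-consistent
# carrier assignment (single founder introduction, no de novo, dominant)
# and derive forced/possible carriers by set intersection/union.  Kept
# deliberately separate from the package's dominator-based solver.

oracle_solve <- function(ped, calls, variant_key) {
  m <- ped$members
  ids <- m$individual_id
  obs <- stats::setNames(rep("missing", length(ids)), ids)
  sub <- calls[calls$variant_key == variant_key & calls$call != "missing", ,
               drop = FALSE]
  obs[sub$individual_id] <- sub$call
  unknown <- ids[obs == "missing"]
  fixed <- ids[obs == "carrier"]
  founders <- ids[is.na(m$father_id)]
  stopifnot(length(unknown) <= 18L)
  fa <- m$father_id; mo <- m$mother_id
  consistent <- list()
  for (mask in 0:(2^length(unknown) - 1L)) {
    sel <- bitwAnd(bitwShiftR(mask, seq_along(unknown) - 1L), 1L) == 1L
    S <- c(fixed, unknown[sel])
    if (sum(founders %in% S) != 1L) next
    ok <- TRUE
    for (id in S) {
      i <- match(id, ids)
      if (is.na(fa[i])) next
      if (!(fa[i] %in% S) && !(mo[i] %in% S)) { ok <- FALSE; break }
    }
    if (ok) consistent[[length(consistent) + 1L]] <- S
  }
  list(consistent = consistent,
       forced = if (length(consistent)) Reduce(intersect, consistent)
         else character(0),
       possible = unique(unlist(consistent)),
       obs = obs)
}

oracle_obligate <- function(ped, calls, variant_key) {
  sol <- oracle_solve(ped, calls, variant_key)
  if (!length(sol$consistent)) return(character(0))
  m <- ped$members
  untyped <- names(sol$obs)[sol$obs == "missing"]
  aff_car <- intersect(sol$forced,
                       m$individual_id[m$affection == "affected"])
  parents <- unique(stats::na.omit(unlist(
    m[match(aff_car, m$individual_id), c("father_id", "mother_id")])))
  unaff_par <- parents[m$affection[match(parents, m$individual_id)] ==
                         "unaffected"]
  sort(union(intersect(unaff_par, sol$forced),
             intersect(sol$forced, untyped)))
}

oracle_inferred <- function(ped, calls, variant_key) {
  sol <- oracle_solve(ped, calls, variant_key)
  untyped <- names(sol$obs)[sol$obs == "missing"]
  list(carrier = sort(intersect(sol$forced, untyped)),
       wildtype = sort(setdiff(untyped, sol$possible)),
       n_consistent = length(sol$consistent))
}

# brute-force segregation tallies by direct member enumeration
oracle_tallies <- function(ped, geno, obligate, proband) {
  m <- ped$members
  core <- c(proband, blood_relatives(ped, proband))
  aff <- m$individual_id[m$affection == "affected"]
  aff <- intersect(aff, core)
  informative <- aff[geno[aff] != "missing"]
  unaff <- intersect(m$individual_id[m$affection == "unaffected"], core)
  counted <- setdiff(unaff[geno[unaff] == "carrier"], obligate)
  list(n_inf = length(informative),
       n_car = sum(geno[informative] == "carrier"),
       n_unaff = length(counted))
}
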