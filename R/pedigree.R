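# Pedigree structures, PED I/O, relationship queries and genotype inference
# under a dominant single-founder-introduction model.

SEX_LEVELS <- c("male", "female", "unknown")
AFFECTION_LEVELS <- c("affected", "unaffected", "possible", "unknown")
CALL_LEVELS <- c("carrier", "wildtype", "missing")

#' Construct a pedigree object
#'
#' A pedigree is a directed, acyclic family graph.  Every non-founder has
#' two recorded parents; records listing only one parent are padded with a
#' placeholder founder so that path logic can assume a uniform two-parent
#' graph.
#'
#' @param family_id single family identifier.
#' @param members data frame with columns `individual_id`, `father_id`,
#'   `mother_id` (`NA` for founders), `sex` (`"male"`, `"female"`,
#'   `"unknown"`), `affection` (`"affected"`, `"unaffected"`, `"possible"`,
#'   `"unknown"`), and optionally `age_at_onset`, `age_at_exam` (years,
#'   `NA` if unknown).
#' @return An object of class `fam_pedigree`.
#' @export
pedigree <- function(family_id, members) {
  stopifnot(is.character(family_id), length(family_id) == 1L)
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  need <- c("individual_id", "father_id", "mother_id", "sex", "affection")
  miss <- setdiff(need, names(members))
  if (length(miss)) stop("members lacks columns: ", paste(miss, collapse = ", "))
  for (col in c("age_at_onset", "age_at_exam"))
    if (is.null(members[[col]])) members[[col]] <- NA_real_
  if (is.null(members$placeholder)) members$placeholder <- FALSE
  members$individual_id <- as.character(members$individual_id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  if (anyDuplicated(members$individual_id))
    stop("duplicate individual_id within family ", family_id, ": ",
         paste(unique(members$individual_id[duplicated(members$individual_id)]),
               collapse = ", "))
  if (!all(members$sex %in% SEX_LEVELS)) stop("invalid sex code")
  if (!all(members$affection %in% AFFECTION_LEVELS)) stop("invalid affection code")

  members <- .pad_single_parents(members)
  members <- .add_unlisted_parents(members, family_id)
  .check_parent_sex(members)
  members$founder <- is.na(members$father_id) & is.na(members$mother_id)
  one_parent <- xor(is.na(members$father_id), is.na(members$mother_id))
  if (any(one_parent)) stop("internal: padding failed")
  ped <- structure(list(family_id = family_id, members = members),
                   class = "fam_pedigree")
  .check_acyclic(ped)
  ped
}

.pad_single_parents <- function(members) {
  extra <- list()
  for (i in seq_len(nrow(members))) {
    fa <- members$father_id[i]; mo <- members$mother_id[i]
    if (is.na(fa) != is.na(mo)) {
      role <- if (is.na(fa)) "pat" else "mat"
      pid <- paste0("ph:", members$individual_id[i], ":", role)
      extra[[length(extra) + 1L]] <- data.frame(
        individual_id = pid, father_id = NA_character_,
        mother_id = NA_character_,
        sex = if (role == "pat") "male" else "female",
        affection = "unknown", age_at_onset = NA_real_,
        age_at_exam = NA_real_, placeholder = TRUE,
        stringsAsFactors = FALSE)
      if (role == "pat") members$father_id[i] <- pid else members$mother_id[i] <- pid
    }
  }
  if (length(extra))
    members <- rbind(members, do.call(rbind, extra)[names(members)])
  members
}

.add_unlisted_parents <- function(members, family_id) {
  refd <- setdiff(stats::na.omit(c(members$father_id, members$mother_id)),
                  members$individual_id)
  if (length(refd)) {
    sex <- ifelse(refd %in% members$father_id, "male", "female")
    members <- rbind(members, data.frame(
      individual_id = refd, father_id = NA_character_,
      mother_id = NA_character_, sex = sex, affection = "unknown",
      age_at_onset = NA_real_, age_at_exam = NA_real_,
      placeholder = FALSE, stringsAsFactors = FALSE)[names(members)])
  }
  members
}

.check_parent_sex <- function(members) {
  sex <- members$sex[match(members$father_id, members$individual_id)]
  if (any(sex %in% "female"))
    stop("father with female sex: ",
         members$father_id[which(sex %in% "female")[1L]])
  sex <- members$sex[match(members$mother_id, members$individual_id)]
  if (any(sex %in% "male"))
    stop("mother with male sex: ",
         members$mother_id[which(sex %in% "male")[1L]])
}

.check_acyclic <- function(ped) {
  m <- ped$members
  state <- stats::setNames(integer(nrow(m)), m$individual_id)  # 0 new 1 open 2 done
  visit <- function(id) {
    if (state[id] == 1L)
      stop("pedigree cycle detected involving individual ", id)
    if (state[id] == 2L) return(invisible())
    state[id] <<- 1L
    i <- match(id, m$individual_id)
    for (p in c(m$father_id[i], m$mother_id[i]))
      if (!is.na(p)) visit(p)
    state[id] <<- 2L
    invisible()
  }
  for (id in m$individual_id) visit(id)
  invisible(ped)
}

#' @export
print.fam_pedigree <- function(x, ...) {
  m <- x$members
  cat(sprintf("<fam_pedigree> family %s: %d members (%d founders, %d affected)\n",
              x$family_id, nrow(m), sum(m$founder),
              sum(m$affection == "affected")))
  invisible(x)
}

#' @export
as.data.frame.fam_pedigree <- function(x, ...) {
  cbind(family_id = x$family_id, x$members)
}

ped_ids <- function(ped) ped$members$individual_id

.ped_row <- function(ped, id) {
  i <- match(id, ped$members$individual_id)
  if (is.na(i)) stop("unknown individual '", id, "' in family ", ped$family_id)
  i
}

#' Read a PED pedigree file
#'
#' Standard whitespace-delimited 6-column PED (FID IID PAT MAT SEX PHENO)
#' with optional extension columns 7 (age at onset) and 8 (age at exam);
#' `0` marks a missing value.  Affection codes: 1 = unaffected,
#' 2 = affected, 3 = possible (extension), 0 or -9 = unknown.
#'
#' @param path path to a PED file.
#' @return A named list of [pedigree()] objects, one per family.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#",
                           fill = TRUE)
  if (ncol(raw) < 6L) stop("PED file must have >= 6 columns: ", path)
  raw[raw == ""] <- "0"  # ragged optional columns
  num_or_na <- function(x) {
    v <- suppressWarnings(as.numeric(x)); v[x %in% c("0", "-9", "")] <- NA; v
  }
  df <- data.frame(
    family_id = raw[[1L]],
    individual_id = raw[[2L]],
    father_id = ifelse(raw[[3L]] == "0", NA_character_, raw[[3L]]),
    mother_id = ifelse(raw[[4L]] == "0", NA_character_, raw[[4L]]),
    sex = c("1" = "male", "2" = "female")[raw[[5L]]],
    affection = c("1" = "unaffected", "2" = "affected", "3" = "possible")[raw[[6L]]],
    stringsAsFactors = FALSE)
  df$sex[is.na(df$sex)] <- "unknown"
  df$affection[is.na(df$affection)] <- "unknown"
  df$age_at_onset <- if (ncol(raw) >= 7L) num_or_na(raw[[7L]]) else NA_real_
  df$age_at_exam <- if (ncol(raw) >= 8L) num_or_na(raw[[8L]]) else NA_real_
  df$placeholder <- startsWith(df$individual_id, "ph:")
  peds <- lapply(split(df, df$family_id), function(fam)
    pedigree(fam$family_id[1L], fam[-1L]))
  peds[unique(df$family_id)]
}

#' Write pedigrees to a PED file
#'
#' Emits the same dialect [read_ped()] consumes, so a read/write cycle is
#' lossless (placeholder founders are written as ordinary rows with a
#' reserved `ph:` id prefix).
#'
#' @param peds a `fam_pedigree` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(peds, path) {
  if (inherits(peds, "fam_pedigree")) peds <- list(peds)
  rows <- lapply(peds, function(ped) {
    m <- ped$members
    data.frame(
      ped$family_id, m$individual_id,
      ifelse(is.na(m$father_id), "0", m$father_id),
      ifelse(is.na(m$mother_id), "0", m$mother_id),
      c(male = "1", female = "2", unknown = "0")[m$sex],
      c(unaffected = "1", affected = "2", possible = "3", unknown = "0")[m$affection],
      ifelse(is.na(m$age_at_onset), "0", format(m$age_at_onset)),
      ifelse(is.na(m$age_at_exam), "0", format(m$age_at_exam)),
      stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ancestors of id including id itself
.ancestors_self <- function(ped, id) {
  m <- ped$members
  out <- character(0); queue <- id
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (cur %in% out) next
    out <- c(out, cur)
    i <- match(cur, m$individual_id)
    queue <- c(queue, stats::na.omit(c(m$father_id[i], m$mother_id[i])))
  }
  out
}

#' Blood relatives of an individual
#'
#' Two members are blood relatives when they share at least one common
#' ancestor (an individual is the trivial common ancestor of itself and of
#' its descendants).  Married-in members -- connected to the family only
#' through a partner -- are therefore excluded.
#'
#' @param ped a [pedigree()].
#' @param id individual identifier.
#' @return Character vector of individual ids (excluding `id` itself).
#' @export
blood_relatives <- function(ped, id) {
  .ped_row(ped, id)
  anc_id <- .ancestors_self(ped, id)
  others <- setdiff(ped_ids(ped), id)
  others[vapply(others, function(j)
    length(intersect(anc_id, .ancestors_self(ped, j))) > 0L, logical(1L))]
}

# ---- genotype calls ------------------------------------------------------

#' Build a genotype-call table
#'
#' @param individual_id,call,variant_key vectors recycled to equal length;
#'   `call` is `"carrier"`, `"wildtype"` or `"missing"`.
#' @param origin `"observed"` or `"inferred"`.
#' @return data frame with columns `individual_id`, `variant_key`, `call`,
#'   `origin`.
#' @export
genotype_calls <- function(individual_id, call, variant_key, origin = "observed") {
  if (!length(individual_id)) origin <- character(0)
  df <- data.frame(individual_id = as.character(individual_id),
                   variant_key = as.character(variant_key),
                   call = as.character(call),
                   origin = as.character(origin),
                   stringsAsFactors = FALSE)
  if (!all(df$call %in% CALL_LEVELS)) stop("invalid genotype call")
  if (!all(df$origin %in% c("observed", "inferred"))) stop("invalid origin")
  df
}

# observed call per member for one variant ("missing" when absent)
.obs_calls <- function(ped, calls, variant_key) {
  ids <- ped_ids(ped)
  obs <- stats::setNames(rep("missing", length(ids)), ids)
  sub <- calls[calls$variant_key == variant_key & calls$call != "missing", ,
               drop = FALSE]
  sub <- sub[sub$individual_id %in% ids, , drop = FALSE]
  if (nrow(sub)) {
    agg <- tapply(sub$call, sub$individual_id, function(x) unique(x))
    if (any(lengths(agg) > 1L))
      stop("contradictory genotype calls for ",
           paste(names(agg)[lengths(agg) > 1L], collapse = ", "))
    obs[names(agg)] <- unlist(agg)
  }
  obs
}

# Individuals reachable from founder f by parent->child descent through the
# vertex set A (f assumed in A).
.descent_reach <- function(ped, f, A) {
  m <- ped$members
  in_A <- stats::setNames(m$individual_id %in% A, m$individual_id)
  reached <- stats::setNames(rep(FALSE, nrow(m)), m$individual_id)
  reached[f] <- TRUE
  repeat {
    fa_r <- reached[m$father_id]; mo_r <- reached[m$mother_id]
    fa_r[is.na(fa_r)] <- FALSE; mo_r[is.na(mo_r)] <- FALSE
    new <- in_A[m$individual_id] & !reached & (fa_r | mo_r)
    if (!any(new)) break
    reached[m$individual_id[new]] <- TRUE
  }
  names(reached)[reached]
}

# Core constraint solver for one variant under the dominant
# single-founder-introduction, zero-de-novo model.
#
# A carrier assignment is consistent when (i) it contains every observed
# carrier and no observed wildtype, (ii) exactly one founder carries, and
# (iii) every non-founder carrier has a carrier parent.  Equivalently, the
# carrier set is a union of descent paths from one introducing founder f
# avoiding observed wildtypes and other founders.  An untyped individual is
# *forced* to carry iff for every consistent f it lies on all f->c descent
# paths for some observed carrier c (a dominator), and *forced wildtype*
# iff it is descent-reachable from no consistent f.
.solve_carriers <- function(ped, calls, variant_key) {
  m <- ped$members
  ids <- m$individual_id
  obs <- .obs_calls(ped, calls, variant_key)
  carriers <- ids[obs[ids] == "carrier"]
  if (!length(carriers))
    stop(errorCondition(
      paste0("no observed carrier of ", variant_key, " in family ",
             ped$family_id),
      class = "famcoseg_insufficient"))
  founders <- ids[m$founder]
  allowed_base <- ids[!m$founder & obs[ids] != "wildtype"]

  cand <- character(0)
  for (f in founders[obs[founders] != "wildtype"]) {
    r <- .descent_reach(ped, f, c(f, allowed_base))
    if (all(carriers %in% r)) cand <- c(cand, f)
  }
  if (!length(cand)) {
    # report a directly offending trio when one exists
    trio <- NULL
    for (c_id in carriers) {
      i <- match(c_id, ids)
      fa <- m$father_id[i]; mo <- m$mother_id[i]
      if (!is.na(fa) && obs[fa] == "wildtype" && obs[mo] == "wildtype") {
        trio <- c(child = c_id, father = fa, mother = mo); break
      }
    }
    return(list(consistent = FALSE, trio = trio, obs = obs,
                candidates = character(0),
                forced = character(0), possible = character(0)))
  }

  untyped <- ids[obs[ids] == "missing"]
  forced <- character(0); possible <- character(0)
  for (v in untyped) {
    forced_v <- TRUE; possible_v <- FALSE
    for (f in cand) {
      A <- c(f, allowed_base)
      r <- .descent_reach(ped, f, A)
      if (v %in% r) possible_v <- TRUE
      if (v != f) {
        r2 <- .descent_reach(ped, f, setdiff(A, v))
        if (all(carriers %in% r2)) forced_v <- FALSE
      } # v == f: every assignment under f contains f
    }
    if (forced_v) forced <- c(forced, v)
    if (possible_v) possible <- c(possible, v)
  }
  list(consistent = TRUE, trio = NULL, obs = obs, candidates = cand,
       forced = forced, possible = possible)
}

.obligate_from_sol <- function(ped, sol, extended = TRUE) {
  m <- ped$members
  ids <- m$individual_id
  carrier_all <- union(ids[sol$obs[ids] == "carrier"], sol$forced)
  affected_carriers <- intersect(carrier_all,
                                 ids[m$affection == "affected"])
  par_ids <- unique(stats::na.omit(unlist(
    m[match(affected_carriers, ids), c("father_id", "mother_id")])))
  # a parent counts as obligate only when it is a carrier in every
  # consistent assignment; parent rule restricted to unaffected parents
  oblig_parents <- intersect(
    par_ids[m$affection[match(par_ids, ids)] == "unaffected"], carrier_all)
  out <- oblig_parents
  if (extended) out <- union(out, sol$forced)  # untyped connecting-path carriers
  sort(out)
}

#' Infer obligate carriers for one variant
#'
#' Under a dominant model with a single founder introduction and no de novo
#' events, returns the union of (a) unaffected parents of affected carriers
#' that must carry the variant, and (b) ungenotyped individuals lying on
#' every transmission path connecting the observed carriers (forced
#' carriers).  Observed-wildtype individuals are never returned.  When the
#' observed carriers cannot be connected through any single founder the
#' model is violated: a warning is raised and the empty set returned.
#'
#' @param ped a [pedigree()].
#' @param calls genotype-call table (see [genotype_calls()]).
#' @param variant_key variant identifier (`chrom:pos:ref:alt`).
#' @param extended when `TRUE` (default) include forced carriers anywhere on
#'   the connecting paths, not only unaffected parents of patients.
#' @return Sorted character vector of individual ids.
#' @export
infer_obligate_carriers <- function(ped, calls, variant_key, extended = TRUE) {
  sol <- .solve_carriers(ped, calls, variant_key)
  if (!sol$consistent) {
    warning("family ", ped$family_id, ": observed carriers of ", variant_key,
            " are not connectable through a single founder introduction")
    return(character(0))
  }
  .obligate_from_sol(ped, sol, extended = extended)
}

.inferred_from_sol <- function(ped, sol, calls, variant_key) {
  have <- calls$individual_id[calls$variant_key == variant_key &
                                calls$call != "missing"]
  new_car <- setdiff(sol$forced, have)
  new_wt <- setdiff(setdiff(names(sol$obs)[sol$obs == "missing"], sol$possible),
                    have)
  add <- NULL
  if (length(new_car) || length(new_wt))
    add <- genotype_calls(c(new_car, new_wt),
                          rep(c("carrier", "wildtype"),
                              c(length(new_car), length(new_wt))),
                          variant_key, origin = "inferred")
  rbind(calls, add)
}

#' Infer unobserved genotypes for one variant
#'
#' Adds `origin = "inferred"` carrier calls for untyped individuals that
#' carry the variant in every Mendelian-consistent assignment (single
#' founder introduction, no de novo events), and inferred wildtype calls
#' only when forced (e.g. both parents wildtype).  All other untyped
#' individuals remain missing.  The operation is idempotent and inferred
#' calls never contradict observed ones.
#'
#' @inheritParams infer_obligate_carriers
#' @return The input call table with inferred rows appended.
#' @export
infer_genotypes <- function(ped, calls, variant_key) {
  sol <- .solve_carriers(ped, calls, variant_key)
  if (!sol$consistent) {
    if (!is.null(sol$trio))
      stop("Mendelian inconsistency in family ", ped$family_id, " at ",
           variant_key, ": carrier child ", sol$trio[["child"]],
           " with wildtype parents ", sol$trio[["father"]], "/",
           sol$trio[["mother"]])
    warning("family ", ped$family_id, ": observed carriers of ", variant_key,
            " are not connectable through a single founder introduction; ",
            "no genotypes inferred")
    return(calls)
  }
  .inferred_from_sol(ped, sol, calls, variant_key)
}
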