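#' Construct a pedigree
#'
#' A pedigree is an ordered table of individuals with parent links, sex,
#' affection status and a flag for DNA availability. Founders have both
#' parent ids missing (`NA`); non-founders must have both parents present
#' in the same pedigree, and the parent graph must be acyclic.
#'
#' @param id character vector of unique individual ids.
#' @param father_id,mother_id character vectors of parent ids; `NA` (or
#'   `"0"`) for founders. Both must be set or both missing per individual.
#' @param sex one of `"male"`, `"female"`, `"unknown"` per individual.
#' @param affection one of `"affected"`, `"unaffected"`, `"unknown"`.
#' @param sampled logical; whether DNA is available for the individual.
#' @param family_id single family label used when writing PED.
#'
#' @return An object of class `pedigree`: a data.frame with columns
#'   `id`, `father_id`, `mother_id`, `sex`, `affection`, `sampled`, in
#'   input order, with attribute `family_id`.
#' @export
pedigree <- function(id, father_id, mother_id,
                     sex = "unknown", affection = "unknown",
                     sampled = TRUE, family_id = "F1") {
  id <- as.character(id)
  n <- length(id)
  father_id <- .norm_parent(rep_len(as.character(father_id), n))
  mother_id <- .norm_parent(rep_len(as.character(mother_id), n))
  sex <- .check_levels(rep_len(sex, n), c("male", "female", "unknown"), "sex")
  affection <- .check_levels(rep_len(affection, n),
                             c("affected", "unaffected", "unknown"),
                             "affection")
  ped <- data.frame(id = id, father_id = father_id, mother_id = mother_id,
                    sex = sex, affection = affection,
                    sampled = rep_len(as.logical(sampled), n),
                    stringsAsFactors = FALSE)
  attr(ped, "family_id") <- family_id
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

.check_levels <- function(x, levels, what) {
  bad <- !(x %in% levels)
  if (any(bad))
    stop("invalid ", what, " value(s): ", paste(unique(x[bad]), collapse = ", "))
  x
}

.norm_parent <- function(x) {
  x[!is.na(x) & x == "0"] <- NA_character_
  x
}

#' Validate pedigree structure
#'
#' Checks id uniqueness, the both-parents-or-neither rule, that parent
#' references resolve, and that the parent graph is acyclic (a topological
#' order with ancestors before descendants exists).
#'
#' @param ped a [pedigree()].
#' @return `ped`, invisibly, or an error describing the defect.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id))
    stop("duplicate individual ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  one_parent <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(one_parent))
    stop("individuals with exactly one parent recorded: ",
         paste(ped$id[one_parent], collapse = ", "))
  parents <- c(ped$father_id, ped$mother_id)
  unknown <- setdiff(parents[!is.na(parents)], ped$id)
  if (length(unknown))
    stop("parent ids not present in pedigree: ",
         paste(unknown, collapse = ", "))
  ped_topological_order(ped)  # errors on cycles
  invisible(ped)
}

#' Topological order of a pedigree (ancestors first)
#'
#' @param ped a [pedigree()].
#' @return character vector of ids, every individual after both parents.
#' @export
ped_topological_order <- function(ped) {
  placed <- character(0)
  remaining <- ped$id
  repeat {
    if (!length(remaining)) return(placed)
    idx <- match(remaining, ped$id)
    ready <- (is.na(ped$father_id[idx]) |
                ped$father_id[idx] %in% placed) &
             (is.na(ped$mother_id[idx]) |
                ped$mother_id[idx] %in% placed)
    if (!any(ready))
      stop("pedigree contains a parent-link cycle involving: ",
           paste(remaining, collapse = ", "))
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
}

#' Read a PED/FAM file
#'
#' Six whitespace-separated columns: family, individual, father, mother,
#' sex, affection. `0` denotes a missing parent; sex is coded 1 = male,
#' 2 = female, 0 = unknown; affection 2 = affected, 1 = unaffected,
#' 0 = unknown (PLINK-style convention).
#'
#' @param path path to the PED text file.
#' @return a [pedigree()] preserving input order.
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6)
    stop("PED file must have six columns (family, id, father, mother, sex, affection)")
  self_parent <- tab[[2]] == tab[[3]] | tab[[2]] == tab[[4]]
  if (any(self_parent))
    stop("individual listed as own parent: ",
         paste(tab[[2]][self_parent], collapse = ", "))
  pedigree(id = tab[[2]], father_id = tab[[3]], mother_id = tab[[4]],
           sex = c("0" = "unknown", "1" = "male", "2" = "female")[tab[[5]]],
           affection = c("0" = "unknown", "1" = "unaffected",
                         "2" = "affected")[tab[[6]]],
           family_id = tab[[1]][1])
}

#' Write a pedigree in PED format
#'
#' Emits the same 6-column dialect that [read_ped()] consumes.
#'
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  aff <- c(affected = "2", unaffected = "1", unknown = "0")[ped$affection]
  fam <- attr(ped, "family_id")
  if (is.null(fam)) fam <- "F1"
  lines <- paste(fam, ped$id,
                 ifelse(is.na(ped$father_id), "0", ped$father_id),
                 ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                 sex, aff)
  writeLines(lines, path)
  invisible(path)
}

#' Kinship matrix by the recursive tabular method
#'
#' Computes the kinship coefficient phi for every pair of individuals by
#' the standard recursion over a topological order: for a founder i,
#' phi(i,i) = 1/2 and phi(i,j) = 0 for any non-descendant j; for a
#' non-founder i with parents f and m, phi(i,i) = (1 + phi(f,m)) / 2 and
#' phi(i,j) = (phi(f,j) + phi(m,j)) / 2 for any j that is not a
#' descendant of i. Founders are assumed mutually unrelated and
#' non-inbred.
#'
#' @param ped a [pedigree()].
#' @return symmetric numeric matrix with dimnames = ids.
#' @export
kinship_matrix <- function(ped) {
  ord <- ped_topological_order(ped)
  n <- length(ord)
  phi <- matrix(0, n, n, dimnames = list(ord, ord))
  father <- stats::setNames(ped$father_id, ped$id)
  mother <- stats::setNames(ped$mother_id, ped$id)
  for (k in seq_len(n)) {
    i <- ord[k]
    f <- father[[i]]; m <- mother[[i]]
    if (is.na(f)) {
      phi[i, i] <- 0.5
      # phi[i, j] stays 0 for previously placed j: founders unrelated
    } else {
      phi[i, i] <- 0.5 * (1 + phi[f, m])
      if (k > 1) {
        j <- ord[seq_len(k - 1)]
        phi[i, j] <- 0.5 * (phi[f, j] + phi[m, j])
        phi[j, i] <- phi[i, j]
      }
    }
  }
  phi
}

#' Kinship and relatedness for one pair
#'
#' @param ped a [pedigree()].
#' @param a,b individual ids (may be equal: the self pair has phi = 1/2,
#'   r = 1 for a non-inbred individual).
#' @return list with `pair`, `kinship_phi`, `relatedness_r` (= 2 phi for
#'   outbred pairs), and `expected_shared_percent` (= 100 r).
#' @export
kinship <- function(ped, a, b) {
  missing_ids <- setdiff(c(a, b), ped$id)
  if (length(missing_ids))
    stop("unknown individual id(s): ", paste(missing_ids, collapse = ", "))
  phi <- kinship_matrix(ped)
  p <- phi[a, b]
  list(pair = c(a, b), kinship_phi = p, relatedness_r = 2 * p,
       expected_shared_percent = 100 * 2 * p)
}

#' Expected identity-by-descent sharing report
#'
#' One row per requested pair with the kinship coefficient, relatedness
#' and expected shared-genome percent (rounded to one decimal in the
#' `percent_1dp` column; full precision kept alongside).
#'
#' @param ped a [pedigree()].
#' @param pairs list of length-2 character vectors of ids.
#' @return data.frame with columns `id_a`, `id_b`, `kinship_phi`,
#'   `relatedness_r`, `expected_shared_percent`, `percent_1dp`.
#' @export
expected_sharing_report <- function(ped, pairs) {
  phi <- kinship_matrix(ped)
  rows <- lapply(pairs, function(p) {
    missing_ids <- setdiff(p, ped$id)
    if (length(missing_ids))
      stop("unknown individual id(s): ", paste(missing_ids, collapse = ", "))
    k <- phi[p[1], p[2]]
    data.frame(id_a = p[1], id_b = p[2], kinship_phi = k,
               relatedness_r = 2 * k,
               expected_shared_percent = 200 * k,
               percent_1dp = round(200 * k, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Carrier penetrance
#'
#' Fraction of variant carriers that are affected, the quantity by which
#' incomplete penetrance is usually quoted (e.g. 5 affected among 16
#' carriers gives f = 0.3125, reported as 31%).
#'
#' @param carriers_total number of carriers observed.
#' @param carriers_affected number of those carriers that are affected.
#' @return list with `carriers_total`, `carriers_affected`,
#'   `penetrance_f`, and `percent` (nearest integer).
#' @export
penetrance <- function(carriers_total, carriers_affected) {
  if (carriers_total <= 0)
    stop("penetrance undefined: no carriers")
  if (carriers_affected < 0 || carriers_affected > carriers_total)
    stop("affected carriers must lie in [0, carriers_total]")
  f <- carriers_affected / carriers_total
  list(carriers_total = carriers_total,
       carriers_affected = carriers_affected,
       penetrance_f = f,
       percent = round(100 * f))
}

#' The packaged 22-member neuroblastoma family
#'
#' A synthetic stand-in for the study family: four generations descending
#' from one founder couple, five affected members in total, of which two
#' (E5 and E10) are second cousins — they share only the founding
#' great-grandparental couple, so their expected genome sharing is
#' 1/32 (~3%). Two unaffected distant relatives (E6, E8) sit in a third
#' branch. All 22 members are flagged as sampled.
#'
#' @return a [pedigree()].
#' @export
family_pedigree <- function() {
  # col order: id, father, mother, sex, affection
  def <- matrix(c(
    "E1",  NA,    NA,    "male",   "unaffected",
    "E2",  NA,    NA,    "female", "unaffected",
    "E3",  "E1",  "E2",  "male",   "unaffected",
    "E4",  "E1",  "E2",  "female", "unaffected",
    "E20", "E1",  "E2",  "female", "unaffected",
    "E21", NA,    NA,    "female", "unaffected",
    "E22", NA,    NA,    "male",   "unaffected",
    "E19", NA,    NA,    "male",   "unaffected",
    "E7",  "E3",  "E21", "male",   "unaffected",
    "E9",  "E3",  "E21", "female", "affected",
    "E11", "E22", "E4",  "female", "unaffected",
    "E12", "E22", "E4",  "male",   "unaffected",
    "E13", "E19", "E20", "female", "unaffected",
    "E14", NA,    NA,    "female", "unaffected",
    "E15", NA,    NA,    "male",   "unaffected",
    "E16", NA,    NA,    "male",   "unaffected",
    "E5",  "E7",  "E14", "male",   "affected",
    "E17", "E7",  "E14", "female", "affected",
    "E10", "E15", "E11", "female", "affected",
    "E18", "E15", "E11", "male",   "affected",
    "E6",  "E16", "E13", "female", "unaffected",
    "E8",  "E16", "E13", "male",   "unaffected"
  ), ncol = 5, byrow = TRUE)
  pedigree(id = def[, 1], father_id = def[, 2], mother_id = def[, 3],
           sex = def[, 4], affection = def[, 5], family_id = "NBFAM")
}
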