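#' Validate and order a pedigree
#'
#' Builds a `ped` object from raw parentage records. The pedigree is checked
#' for cycles (no individual may be its own ancestor), parent sexes are checked
#' for consistency (sires male, dams female, where sex is known), parents that
#' are referenced but have no record of their own are added as founders, and
#' individuals are re-ordered topologically so that every parent precedes its
#' offspring.
#'
#' @param records data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`"F"`/`"M"`, `NA` allowed) and `cohort` (birth year). Missing
#'   parents are `NA` or the empty string.
#' @return an object of class `ped`: a data frame with columns `id`, `sire`,
#'   `dam`, `sex`, `cohort`, topologically sorted, with integer parent indices
#'   in columns `si` and `di` (`NA` = unknown) and a validation `report`
#'   attribute listing added founders and flagged records.
#' @examples
#' validate_pedigree(data.frame(id = c("s", "d", "x"),
#'                              sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
#'                              sex = c("M", "F", "F")))
#' @export
validate_pedigree <- function(records) {
  records <- as.data.frame(records)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(records)))
    stop("pedigree records need columns id, sire, dam")
  blank2na <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
    x
  }
  id <- blank2na(records$id)
  sire <- blank2na(records$sire)
  dam <- blank2na(records$dam)
  if (anyNA(id)) stop("missing individual id in pedigree records")
  if (anyDuplicated(id))
    stop("duplicated pedigree ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sex <- if ("sex" %in% names(records)) blank2na(records$sex) else
    rep(NA_character_, length(id))
  if (!all(is.na(sex) | sex %in% c("F", "M")))
    stop("sex must be 'F', 'M' or missing")
  cohort <- if ("cohort" %in% names(records))
    suppressWarnings(as.numeric(records$cohort)) else rep(NA_real_, length(id))

  report <- list(added_founders = character(), flagged = character())

  # referenced parents with no record become founders
  refs <- setdiff(stats::na.omit(unique(c(sire, dam))), id)
  if (length(refs)) {
    ref_sex <- ifelse(refs %in% sire, "M", "F")
    both <- refs %in% sire & refs %in% dam
    if (any(both))
      stop("individual(s) appear as both sire and dam: ",
           paste(refs[both], collapse = ", "))
    id <- c(id, refs)
    sire <- c(sire, rep(NA_character_, length(refs)))
    dam <- c(dam, rep(NA_character_, length(refs)))
    sex <- c(sex, ref_sex)
    cohort <- c(cohort, rep(NA_real_, length(refs)))
    report$added_founders <- refs
  }

  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)

  # sex consistency
  bad_s <- which(!is.na(si) & !is.na(sex[si]) & sex[si] != "M")
  bad_d <- which(!is.na(di) & !is.na(sex[di]) & sex[di] != "F")
  if (length(bad_s) || length(bad_d))
    stop("sex-inconsistent parent assignment for: ",
         paste(unique(id[c(bad_s, bad_d)]), collapse = ", "))

  # Kahn topological sort; leftovers are on a cycle
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        if (p == i) stop("individual is its own parent: ", id[i])
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n)
    stop("pedigree cycle detected involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))

  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    sex = sex[ord], cohort = cohort[ord],
                    stringsAsFactors = FALSE)
  out$si <- match(out$sire, out$id)
  out$di <- match(out$dam, out$id)
  class(out) <- c("ped", "data.frame")
  attr(out, "report") <- report
  out
}

#' @export
print.ped <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals (",
      sum(is.na(x$si) & is.na(x$di)), "founders ),",
      sum(x$sex == "F", na.rm = TRUE), "females\n")
  invisible(x)
}

is_ped <- function(x) inherits(x, "ped")

stopifnot_ped <- function(x) {
  if (!is_ped(x)) stop("expected a validated pedigree; see validate_pedigree()")
  invisible(x)
}

#' Read / write pedigree CSV
#'
#' Column layout: `id, sire, dam, sex, cohort`; empty field = unknown parent.
#'
#' @param file path to a CSV file.
#' @return `read_pedigree` returns a validated `ped`.
#' @export
read_pedigree <- function(file) {
  validate_pedigree(utils::read.csv(file, stringsAsFactors = FALSE,
                                    colClasses = "character"))
}

#' @param ped a validated `ped`.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, file) {
  stopifnot_ped(ped)
  out <- ped[, c("id", "sire", "dam", "sex", "cohort")]
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Individuals that are neither phenotyped nor ancestors of phenotyped
#' individuals contribute nothing to the likelihood of an animal model; they
#' are removed. The result keeps topological order.
#'
#' @param ped a validated `ped`.
#' @param keep ids of phenotyped individuals.
#' @return a validated `ped` restricted to `keep` and its ancestor closure.
#' @export
prune_pedigree <- function(ped, keep) {
  stopifnot_ped(ped)
  miss <- setdiff(keep, ped$id)
  if (length(miss))
    stop("not in the pedigree: ", paste(utils::head(miss, 5), collapse = ", "))
  want <- ped$id %in% keep
  repeat {
    idx <- which(want)
    parents <- c(ped$si[idx], ped$di[idx])
    parents <- parents[!is.na(parents)]
    grew <- !want[parents]
    if (!any(grew)) break
    want[parents] <- TRUE
  }
  validate_pedigree(ped[want, c("id", "sire", "dam", "sex", "cohort")])
}
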