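#' Read a PLINK PED/FAM pedigree file
#'
#' Whitespace-delimited, first six columns `family id father mother sex
#' phenotype`; parent id `0` means founder; sex coded 1 = male,
#' 2 = female, other = unknown; affection coded 1 = unaffected,
#' 2 = affected, 0/-9 = unknown.  Construction is two-pass, so rows may
#' appear in any order.  Roles (which members are the exome-sequenced
#' cases/controls, which are validation relatives, which belong to the
#' case-control panel) are assigned from a companion configuration since
#' PED carries no such notion.
#'
#' @param path PED/FAM file path
#' @param roles optional named list with character-vector elements
#'   `exome_case`, `exome_control`, `relative`, `panel_case`,
#'   `panel_control`; ids not listed get role `NA`.
#' @return a `pedigree`: data.frame with columns `family`, `id`,
#'   `father`, `mother` (NA for founders), `sex`, `affected`, `role`.
#' @export
read_pedigree <- function(path, roles = NULL) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 6) stop("PED file needs at least 6 columns: ", path)
  ped <- data.frame(
    family = as.character(raw[[1]]), id = as.character(raw[[2]]),
    father = as.character(raw[[3]]), mother = as.character(raw[[4]]),
    sex = c("male", "female")[match(raw[[5]], c(1, 2))],
    affected = c("unaffected", "affected")[match(raw[[6]], c(1, 2))],
    stringsAsFactors = FALSE)
  ped$sex[is.na(ped$sex)] <- "unknown"
  ped$affected[is.na(ped$affected)] <- "unknown"
  ped$father[ped$father == "0"] <- NA
  ped$mother[ped$mother == "0"] <- NA
  pedigree(ped, roles)
}

#' Construct and validate a pedigree
#'
#' Checks id uniqueness, that linked parents exist, parent sex
#' consistency where sex is known, and that parent links are acyclic.
#' @param ped data.frame with columns `id`, `father`, `mother`,
#'   `sex`, `affected` (and optionally `family`)
#' @param roles see [read_pedigree()]
#' @return the validated data.frame with class `pedigree`
#' @export
pedigree <- function(ped, roles = NULL) {
  if (anyDuplicated(ped$id))
    stop("duplicate sample id(s) in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (is.null(ped$family)) ped$family <- "FAM1"
  for (p in c("father", "mother")) {
    linked <- !is.na(ped[[p]])
    missing_parent <- setdiff(ped[[p]][linked], ped$id)
    if (length(missing_parent))
      stop("linked ", p, "(s) not present in pedigree: ",
           paste(missing_parent, collapse = ", "))
  }
  sex_of <- setNames(ped$sex, ped$id)
  bad_f <- !is.na(ped$father) & sex_of[ped$father] == "female"
  bad_m <- !is.na(ped$mother) & sex_of[ped$mother] == "male"
  if (any(bad_f, na.rm = TRUE) || any(bad_m, na.rm = TRUE))
    stop("parent sex inconsistent with father/mother links")

  # cycle check: repeatedly peel individuals all of whose parents are peeled
  depth <- setNames(rep(NA_real_, nrow(ped)), ped$id)
  repeat {
    ready <- is.na(depth) &
      (is.na(ped$father) | !is.na(depth[ped$father])) &
      (is.na(ped$mother) | !is.na(depth[ped$mother]))
    if (!any(ready)) break
    pd <- pmax(ifelse(is.na(ped$father), 0, depth[ped$father] + 1),
               ifelse(is.na(ped$mother), 0, depth[ped$mother] + 1))
    depth[ped$id[ready]] <- pd[ready]
  }
  if (anyNA(depth))
    stop("cyclic parentage involving: ",
         paste(names(depth)[is.na(depth)], collapse = ", "))
  ped$role <- NA_character_
  if (!is.null(roles)) {
    for (r in names(roles)) {
      unknown <- setdiff(roles[[r]], ped$id)
      if (length(unknown))
        stop("role '", r, "' lists unknown id(s): ",
             paste(unknown, collapse = ", "))
      ped$role[ped$id %in% roles[[r]]] <- r
    }
  }
  ped <- ped[order(depth[ped$id], ped$id), , drop = FALSE]  # parents first
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Write a pedigree to PLINK PED format
#' @param ped a `pedigree`
#' @param path output path
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    ped$family, ped$id,
    ifelse(is.na(ped$father), "0", ped$father),
    ifelse(is.na(ped$mother), "0", ped$mother),
    match(ped$sex, c("male", "female"), nomatch = 0),
    match(ped$affected, c("unaffected", "affected"), nomatch = 0))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Resolvable parent-child trios of a pedigree
#' @param ped a `pedigree`
#' @return data.frame with columns `child`, `father`, `mother`
#'   (only children with both parents present)
#' @export
pedigree_trios <- function(ped) {
  full <- !is.na(ped$father) & !is.na(ped$mother)
  data.frame(child = ped$id[full], father = ped$father[full],
             mother = ped$mother[full], stringsAsFactors = FALSE)
}

#' Ids with a given role
#' @param ped a `pedigree`
#' @param role role label, e.g. `"exome_case"`
#' @export
role_ids <- function(ped, role) ped$id[!is.na(ped$role) & ped$role == role]
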