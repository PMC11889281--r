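#' Validate a pedigree / design table
#'
#' A pedigree table describes the crossing design: one row per individual
#' with columns `id`, `mother`, `father` (`NA` for founders), `sex`
#' ("F"/"M"), `species`, `cross_id`, `cross_type` ("AAxAA", "AAxME" or
#' "founder") and, when produced by [build_design()], `factorial` and
#' `balanced_subset`. Validation checks id uniqueness, that parents
#' appear as rows before their offspring (acyclicity), that parents of
#' offspring are female mothers and male fathers, and that `cross_type`
#' is consistent with the parental species labels (intra-specific when
#' both parents are "AA", inter-specific otherwise).
#'
#' @param ped A data.frame pedigree table.
#' @return `ped` invisibly, after validation.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "mother", "father", "sex", "species", "cross_id", "cross_type")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop2("pedigree lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ped$id))
    stop2("duplicate pedigree ids: ",
          paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (!all(ped$sex %in% c("F", "M")))
    stop2("sex must be 'F' or 'M'")
  pos <- seq_len(nrow(ped)); names(pos) <- ped$id
  for (col in c("mother", "father")) {
    par <- ped[[col]]
    known <- !is.na(par)
    bad <- known & !(par %in% ped$id)
    if (any(bad)) stop2(col, " '", par[bad][1], "' of individual '",
                        ped$id[bad][1], "' is not a pedigree row")
    later <- known & pos[par] >= pos
    if (any(later, na.rm = TRUE))
      stop2(col, " '", par[which(later)[1]], "' listed after its offspring '",
            ped$id[which(later)[1]], "' (pedigree must be ancestor-ordered)")
  }
  off <- !is.na(ped$mother) & !is.na(ped$father)
  if (any(off)) {
    msex <- ped$sex[pos[ped$mother[off]]]
    fsex <- ped$sex[pos[ped$father[off]]]
    if (any(msex != "F")) stop2("mother of '", ped$id[off][msex != "F"][1], "' is not female")
    if (any(fsex != "M")) stop2("father of '", ped$id[off][fsex != "M"][1], "' is not male")
    msp <- ped$species[pos[ped$mother[off]]]
    fsp <- ped$species[pos[ped$father[off]]]
    expect_ct <- ifelse(msp == "AA" & fsp == "AA", "AAxAA", "AAxME")
    bad <- ped$cross_type[off] != expect_ct
    if (any(bad))
      stop2("cross_type '", ped$cross_type[off][bad][1], "' of '",
            ped$id[off][bad][1], "' inconsistent with parental species (",
            msp[bad][1], " x ", fsp[bad][1], ")")
  }
  invisible(ped)
}

#' Validate long-format phenotype records
#'
#' Records are one row per (individual, trait, year) observation with
#' columns `id`, `trait`, `year`, `value`. Every id must be present in
#' the pedigree, values must be finite, and (id, trait, year) must be
#' unique.
#'
#' @param records Phenotype data.frame.
#' @param ped Pedigree table the ids must belong to.
#' @return `records` invisibly.
#' @export
validate_phenotypes <- function(records, ped) {
  need <- c("id", "trait", "year", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop2("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(records$id, ped$id)
  if (length(unknown))
    stop2("phenotyped id(s) absent from pedigree: ",
          paste(utils::head(unknown, 5), collapse = ", "))
  if (any(!is.finite(records$value)))
    stop2("non-finite phenotype value for id '",
          records$id[!is.finite(records$value)][1], "'")
  key <- paste(records$id, records$trait, records$year, sep = "\r")
  if (anyDuplicated(key))
    stop2("duplicate (id, trait, year) record: ",
          gsub("\r", "/", key[duplicated(key)][1]))
  invisible(records)
}

#' Read / write pedigree and phenotype CSV files
#'
#' Thin CSV wrappers that validate on read and write deterministic,
#' unquoted CSV.
#'
#' @param path File path.
#' @return The validated data.frame (readers) or `path` invisibly
#'   (writers).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  for (col in c("mother", "father"))
    if (col %in% names(ped)) ped[[col]] <- as.character(ped[[col]])
  validate_pedigree(ped)
  ped
}

#' @rdname read_pedigree
#' @param ped Pedigree data.frame.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_pedigree
#' @param ped2 Pedigree used to validate record ids.
#' @export
read_phenotypes <- function(path, ped2 = NULL) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  rec$year <- as.character(rec$year)
  if (!is.null(ped2)) validate_phenotypes(rec, ped2)
  rec
}

#' @rdname read_pedigree
#' @param records Phenotype data.frame.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
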