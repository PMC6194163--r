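# Cohort manifest: the planted-truth description of every family.

VALID_CATEGORIES <- c(
  "mt_point", "mt_single_deletion", "mt_multiple_deletions", "mt_depletion",
  "nuclear_AR_hom", "nuclear_AR_comphet", "nuclear_XLR",
  "nuclear_XLD_denovo", "nuclear_AD_denovo", "nuclear_AD_inherited", "none"
)

split_field <- function(x) {
  if (is.na(x) || x == "." || x == "") character(0) else strsplit(x, ";")[[1]]
}

#' Load a planted-truth cohort manifest
#'
#' Reads a tab-separated cohort manifest in which one row describes one
#' family (the cohort counting unit): family structure (consanguinity,
#' number of affected patients), patient group (1 = probable/definite
#' mitochondrial disease, 2 = possible), MDC score, and the planted
#' genetic defect, if any, as one or more category/gene pairs. Lines
#' starting with `#expect` declare category totals that are validated
#' after parsing. The packaged 117-family manifest transcribing the study
#' cohort is the default.
#'
#' The filtering *strategy* is derived from family structure: strategy A
#' (recessive/X-linked models) for consanguineous families and/or
#' families with more than one patient, strategy B (recessive plus
#' panel-restricted dominant models) for single patients from
#' non-consanguineous families.
#'
#' @param path path to a manifest TSV; defaults to the packaged cohort
#' @return a `cohort_manifest`: a tibble of families with parsed
#'   list-columns (`categories`, `genes`, `mitocarta`) and a derived
#'   `strategy` column
#' @export
load_manifest <- function(path = mitotriage_example("paper_cohort_manifest.tsv")) {
  lines <- readLines(path)
  expects <- grep("^#expect\t", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  m <- utils::read.delim(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  required <- c("family_id", "consanguineous", "n_affected", "group",
                "mdc_score", "categories", "genes", "mitocarta",
                "variant_info", "mt_signature", "affected_sex",
                "parents_available", "subclinical_parent")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0)
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  m <- tibble::as_tibble(m)
  m$consanguineous <- m$consanguineous == "yes"
  m$parents_available <- m$parents_available != "no"
  m$categories <- lapply(m$categories, split_field)
  m$genes <- lapply(m$genes, split_field)
  m$mitocarta <- lapply(m$mitocarta, function(x) split_field(x) == "yes")
  m$affected_sex <- lapply(m$affected_sex, split_field)
  m$strategy <- ifelse(m$consanguineous | m$n_affected > 1, "A", "B")

  for (i in seq_len(nrow(m))) {
    cats <- m$categories[[i]]
    bad <- setdiff(cats, VALID_CATEGORIES)
    if (length(bad) > 0)
      stop("row ", m$family_id[i], ": unknown category ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (length(cats) == 0)
      stop("row ", m$family_id[i], ": empty category field", call. = FALSE)
    nuclear <- grepl("^nuclear_", cats)
    if (any(nuclear) && length(m$genes[[i]]) != sum(nuclear))
      stop("row ", m$family_id[i],
           ": gene list does not match nuclear categories", call. = FALSE)
    if (any(nuclear) && length(m$mitocarta[[i]]) != sum(nuclear))
      stop("row ", m$family_id[i], ": mitocarta flags do not match genes",
           call. = FALSE)
    if (grepl("XLR|XLD", paste(cats, collapse = ",")) &&
        length(m$affected_sex[[i]]) == 0)
      stop("row ", m$family_id[i],
           ": X-linked defect requires explicit affected sex", call. = FALSE)
  }

  validate_manifest(m, parse_expects(expects))
  class(m) <- c("cohort_manifest", class(m))
  m
}

parse_expects <- function(lines) {
  if (length(lines) == 0) return(NULL)
  kv <- sub("^#expect\t", "", lines)
  parts <- strsplit(kv, "=")
  stats::setNames(as.integer(vapply(parts, `[`, "", 2)),
                  vapply(parts, `[`, "", 1))
}

#' Validate manifest invariants
#'
#' Checks structural invariants (strategy-A families must be
#' consanguineous or have more than one patient) and, when declared
#' totals are supplied, that category marginals match them.
#'
#' @param manifest a parsed manifest tibble
#' @param expects optional named integer vector of declared totals
#'   (`total`, `mtdna`, `nuclear`, `none`, `strategyA`, `strategyB`)
#' @return the manifest, invisibly; errors on violation
#' @export
validate_manifest <- function(manifest, expects = NULL) {
  bad <- manifest$strategy == "A" &
    !(manifest$consanguineous | manifest$n_affected > 1)
  if (any(bad))
    stop("strategy-A families must be consanguineous or have >1 patient: ",
         paste(manifest$family_id[bad], collapse = ", "), call. = FALSE)
  if (!is.null(expects)) {
    cats <- vapply(manifest$categories, paste, "", collapse = ",")
    got <- c(total = nrow(manifest),
             mtdna = sum(grepl("^mt_", cats)),
             nuclear = sum(grepl("nuclear", cats)),
             none = sum(cats == "none"),
             strategyA = sum(manifest$strategy == "A"),
             strategyB = sum(manifest$strategy == "B"))
    for (k in names(expects)) {
      if (!k %in% names(got)) next
      if (got[[k]] != expects[[k]])
        stop("manifest declares ", k, "=", expects[[k]], " but contains ",
             got[[k]], call. = FALSE)
    }
  }
  invisible(manifest)
}

#' Build the pedigree members of a family
#'
#' Expands a manifest row into its members: two parents plus the affected
#' patients, with parent links, sex (explicit for X-linked defects,
#' deterministic otherwise), affected status, and the subclinical-parent
#' flag used by dominant segregation checks. When the manifest marks
#' parents unavailable they are still listed (so genotype tables have a
#' consistent shape) but flagged absent.
#'
#' @param family one manifest row (as a list or single-row tibble)
#' @return tibble with columns `member_id`, `father`, `mother`, `sex`,
#'   `affected`, `subclinical`, `available`
#' @export
family_members <- function(family) {
  fid <- family$family_id
  n <- family$n_affected
  sexes <- family$affected_sex[[1]]
  if (length(sexes) == 0) {
    sexes <- rep(c("F", "M"), length.out = n)
  } else {
    sexes <- rep(sexes, length.out = n)
  }
  kids <- sprintf("%s_P%d", fid, seq_len(n))
  subclin <- family$subclinical_parent %||% "."
  tibble::tibble(
    member_id = c(sprintf("%s_FTH", fid), sprintf("%s_MTH", fid), kids),
    father = c(NA, NA, rep(sprintf("%s_FTH", fid), n)),
    mother = c(NA, NA, rep(sprintf("%s_MTH", fid), n)),
    sex = c("M", "F", sexes),
    affected = c(FALSE, FALSE, rep(TRUE, n)),
    subclinical = c(identical(subclin, "father"), identical(subclin, "mother"),
                    rep(FALSE, n)),
    available = c(rep(family$parents_available %||% TRUE, 2), rep(TRUE, n))
  )
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cats <- vapply(x$categories, paste, "", collapse = ",")
  cat("Cohort manifest: ", nrow(x), " families (",
      sum(grepl("^mt_", cats)), " mtDNA, ",
      sum(grepl("nuclear", cats)), " nuclear, ",
      sum(cats == "none"), " defect-free)\n", sep = "")
  cat("  strategy A: ", sum(x$strategy == "A"),
      "  strategy B: ", sum(x$strategy == "B"),
      "  group 1: ", sum(x$group == 1),
      "  group 2: ", sum(x$group == 2), "\n", sep = "")
  NextMethod()
}
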