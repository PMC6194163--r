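# WES stage: frequency/effect filter cascade, inheritance-model candidate
# selection, segregation checking and per-family diagnosis.

#' Frequency filter for exome variants
#'
#' Annotated variants (a population allele frequency is present) are
#' kept when that frequency is strictly below `popmax` (default 1%).
#' Non-annotated variants are maintained unless their frequency in the
#' in-house patient database exceeds `inhouse_max` (default 5%).
#'
#' @param variants variant annotation tibble (see
#'   [generate_wes_variants()] for the columns)
#' @param popmax strict upper bound on the population allele frequency
#' @param inhouse_max inclusive upper bound on the in-house frequency of
#'   non-annotated variants
#' @return the filtered tibble
#' @export
frequency_filter <- function(variants, popmax = 0.01, inhouse_max = 0.05) {
  stopifnot(popmax > 0, popmax <= 1, inhouse_max > 0, inhouse_max <= 1)
  if (nrow(variants) == 0) return(variants)
  keep <- ifelse(is.na(variants$pop_af),
                 variants$inhouse_af <= inhouse_max,
                 variants$pop_af < popmax)
  variants[keep, , drop = FALSE]
}

#' Effect filter for exome variants
#'
#' Nonsense, frameshift and splice-site variants are always maintained,
#' whatever their predictor calls. Missense variants are kept when at
#' least `min_damaging` of the four pathogenicity predictors
#' (PolyPhen-2, SIFT, PROVEAN, MutationTaster - consumed as upstream
#' annotation flags) call them damaging. Synonymous and other effects
#' are removed.
#'
#' @inheritParams frequency_filter
#' @param min_damaging minimum damaging predictor calls for missense
#'   retention (0-4)
#' @return the filtered tibble
#' @export
effect_filter <- function(variants, min_damaging = 1L) {
  stopifnot(min_damaging >= 0, min_damaging <= 4)
  if (nrow(variants) == 0) return(variants)
  n_damaging <- rowSums(cbind(variants$dmg_polyphen, variants$dmg_sift,
                              variants$dmg_provean, variants$dmg_mtaster))
  keep <- variants$effect %in% c("nonsense", "frameshift", "splice") |
    (variants$effect == "missense" & n_damaging >= min_damaging)
  variants[keep, , drop = FALSE]
}

# genotype lookup matrix: rows = variant_id, cols = member_id
genotype_matrix <- function(genotypes, variant_ids, member_ids) {
  g <- matrix("missing", nrow = length(variant_ids),
              ncol = length(member_ids),
              dimnames = list(variant_ids, member_ids))
  idx <- cbind(match(genotypes$variant_id, variant_ids),
               match(genotypes$member_id, member_ids))
  ok <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  g[idx[ok, , drop = FALSE]] <- genotypes$genotype[ok]
  g
}

carries_alt <- function(gt) gt %in% c("het", "hom_alt", "hemi_alt")

empty_candidates <- function() {
  tibble::tibble(mode = character(), gene = character(),
                 variant_ids = list(), in_roh = logical(),
                 de_novo = logical(), phased = logical(),
                 inherited_parent = character())
}

candidate_row <- function(mode, gene, vids, in_roh = FALSE, de_novo = NA,
                          phased = NA, inherited_parent = NA_character_) {
  tibble::tibble(mode = mode, gene = gene, variant_ids = list(vids),
                 in_roh = in_roh, de_novo = de_novo, phased = phased,
                 inherited_parent = inherited_parent)
}

in_roh_region <- function(chrom, pos, roh) {
  if (is.null(roh) || nrow(roh) == 0) return(rep(FALSE, length(chrom)))
  vapply(seq_along(chrom), function(i) {
    any(roh$chrom == chrom[i] & roh$start <= pos[i] & roh$end >= pos[i])
  }, TRUE)
}

# parental origin of a heterozygous variant in the affecteds:
# "paternal", "maternal", "unknown" (parent data missing or ambiguous),
# or "neither" (carried by no parent, i.e. apparently de novo)
phase_origin <- function(gt_row, father, mother) {
  fgt <- if (length(father) == 1) gt_row[father] else "missing"
  mgt <- if (length(mother) == 1) gt_row[mother] else "missing"
  if (fgt == "missing" || mgt == "missing") return("unknown")
  fa <- carries_alt(fgt); mo <- carries_alt(mgt)
  if (fa && !mo) "paternal"
  else if (mo && !fa) "maternal"
  else if (fa && mo) "unknown"
  else "neither"
}

#' Recessive and X-linked candidate selection
#'
#' Applies the recessive inheritance models to frequency- and
#' effect-filtered variants:
#' * `AR_hom`: autosomal variants homozygous in every affected and not
#'   homozygous in any unaffected member; candidates falling inside a
#'   detected ROH of an affected are flagged `in_roh` and ranked first
#'   (ROH is a ranking signal to prioritise the most promising variants,
#'   not a hard filter, so compound heterozygotes of consanguineous
#'   families are not lost).
#' * `AR_comphet`: at least two retained heterozygous variants in one
#'   gene carried by every affected, in trans by parental genotypes;
#'   pairs proven in cis are rejected, pairs that cannot be phased
#'   (missing parents, both parents carriers) are retained and flagged
#'   `phased = FALSE`.
#' * `XLR`: X-chromosomal variants hemizygous in affected males, with
#'   unaffected members at most carriers.
#'
#' @param members pedigree tibble from [family_members()]
#' @param variants filtered variant tibble
#' @param genotypes long genotype tibble (`variant_id`, `member_id`,
#'   `genotype`)
#' @param roh optional ROH regions from [detect_roh()]
#' @return candidate tibble (one row per candidate; `variant_ids` is a
#'   list-column), ROH hits first
#' @export
recessive_candidates <- function(members, variants, genotypes, roh = NULL) {
  if (nrow(variants) == 0) return(empty_candidates())
  g <- genotype_matrix(genotypes, variants$variant_id, members$member_id)
  aff <- members$member_id[members$affected]
  unaff <- members$member_id[!members$affected]
  father <- members$member_id[is.na(members$father) & members$sex == "M"]
  mother <- members$member_id[is.na(members$father) & members$sex == "F"]
  is_x <- variants$chrom %in% c("chrX", "X")
  out <- list()

  # AR homozygous
  for (i in which(!is_x)) {
    ga <- g[i, aff]
    if (!all(ga == "hom_alt")) next
    gu <- g[i, unaff]
    if (any(gu == "hom_alt")) next
    hit <- in_roh_region(variants$chrom[i], variants$pos[i], roh)
    out[[length(out) + 1]] <- candidate_row(
      "AR_hom", variants$gene[i], variants$variant_id[i], in_roh = hit)
  }

  # AR compound heterozygous
  for (gene in unique(variants$gene[!is_x])) {
    vi <- which(variants$gene == gene & !is_x)
    het_all <- vi[vapply(vi, function(i) all(g[i, aff] == "het"), TRUE)]
    if (length(het_all) < 2) next
    origins <- vapply(het_all, function(i) phase_origin(g[i, ], father,
                                                        mother), "")
    vids <- variants$variant_id[het_all]
    if (any(origins == "paternal") && any(origins == "maternal")) {
      keep <- origins %in% c("paternal", "maternal")
      out[[length(out) + 1]] <- candidate_row(
        "AR_comphet", gene, vids[keep], phased = TRUE)
    } else if (any(origins == "unknown")) {
      out[[length(out) + 1]] <- candidate_row(
        "AR_comphet", gene, vids, phased = FALSE)
    }
    # all variants on one parental haplotype: cis, rejected
  }

  # X-linked recessive: requires an affected male
  aff_male <- members$member_id[members$affected & members$sex == "M"]
  if (length(aff_male) > 0) {
    for (i in which(is_x)) {
      ga_m <- g[i, aff_male]
      if (!all(ga_m == "hemi_alt")) next
      aff_f <- setdiff(aff, aff_male)
      if (length(aff_f) > 0 && !all(g[i, aff_f] == "hom_alt")) next
      gu <- g[i, unaff]
      if (any(gu %in% c("hemi_alt", "hom_alt"))) next
      out[[length(out) + 1]] <- candidate_row(
        "XLR", variants$gene[i], variants$variant_id[i])
    }
  }

  if (length(out) == 0) return(empty_candidates())
  res <- dplyr::bind_rows(out)
  res[order(-res$in_roh), , drop = FALSE]
}

#' Dominant candidate selection for single non-consanguineous patients
#'
#' Heterozygous retained variants are considered dominant candidates
#' only in genes from the supplied OMIM dominant-disease panel (the
#' panel restriction keeps the heterozygous search space tractable; the
#' cost is that de novo variants in novel genes are missed). A candidate
#' is flagged de novo when both parental genotypes are available and
#' neither parent carries the allele; a variant present in a parent is
#' retained but flagged inherited (a parent may show subclinical
#' symptoms); with missing parental genotypes the de novo status is
#' unknown (`NA`). X-chromosomal candidates are labelled `XLD`.
#'
#' @inheritParams recessive_candidates
#' @param omim_ad character vector of dominant-disease gene symbols
#' @return candidate tibble
#' @export
dominant_candidates <- function(members, variants, genotypes,
                                omim_ad = omim_ad_panel()) {
  if (nrow(variants) == 0) return(empty_candidates())
  g <- genotype_matrix(genotypes, variants$variant_id, members$member_id)
  aff <- members$member_id[members$affected]
  father <- members$member_id[is.na(members$father) & members$sex == "M"]
  mother <- members$member_id[is.na(members$father) & members$sex == "F"]
  out <- list()
  for (i in which(variants$gene %in% omim_ad)) {
    ga <- g[i, aff]
    if (!all(ga %in% c("het", "hemi_alt"))) next
    origin <- phase_origin(g[i, ], father, mother)
    de_novo <- switch(origin, neither = TRUE, unknown = NA, FALSE)
    inherited <- switch(origin, paternal = "father", maternal = "mother",
                        NA_character_)
    mode <- if (variants$chrom[i] %in% c("chrX", "X")) "XLD" else "AD"
    out[[length(out) + 1]] <- candidate_row(
      mode, variants$gene[i], variants$variant_id[i], de_novo = de_novo,
      inherited_parent = inherited)
  }
  if (length(out) == 0) return(empty_candidates())
  dplyr::bind_rows(out)
}

#' Check that a candidate segregates with disease in the family
#'
#' A candidate passes when every affected member carries the
#' disease-consistent genotype under the candidate's inheritance mode
#' and no unaffected member does: homozygous (or, for compound
#' heterozygotes, carrying the full trans pair) for recessive modes,
#' hemizygous for XLR males, any carrier genotype for dominant modes.
#' Unaffected carriers fail a dominant candidate unless that parent is
#' flagged subclinical. Members with missing genotypes are skipped.
#'
#' @param candidate one row of a candidate tibble
#' @param members pedigree tibble
#' @param genotypes long genotype tibble
#' @return `TRUE` or `FALSE`
#' @export
segregation_check <- function(candidate, members, genotypes) {
  vids <- candidate$variant_ids[[1]]
  g <- genotype_matrix(genotypes, vids, members$member_id)
  aff <- members$member_id[members$affected]
  unaff <- members$member_id[!members$affected]
  mode <- candidate$mode

  ok_affected <- function(m) {
    gm <- g[, m]
    if (all(gm == "missing")) return(TRUE)
    switch(mode,
           AR_hom = all(gm == "hom_alt"),
           AR_comphet = all(gm == "het"),
           XLR = all(gm %in% c("hemi_alt", "hom_alt")),
           AD = , XLD = all(carries_alt(gm)))
  }
  ok_unaffected <- function(m) {
    gm <- g[, m]
    if (all(gm == "missing")) return(TRUE)
    subclin <- members$subclinical[members$member_id == m]
    switch(mode,
           AR_hom = !any(gm == "hom_alt"),
           AR_comphet = !all(carries_alt(gm)),
           XLR = {
             sex <- members$sex[members$member_id == m]
             if (sex == "M") !any(gm %in% c("hemi_alt", "hom_alt"))
             else !any(gm == "hom_alt")
           },
           AD = , XLD = !any(carries_alt(gm)) || isTRUE(subclin))
  }
  all(vapply(aff, ok_affected, TRUE)) &&
    all(vapply(unaff, ok_unaffected, TRUE))
}

#' Diagnose a family from its segregation-checked candidates
#'
#' A family is solved when at least one candidate passes segregation and
#' all of its variants carry ACMG class 4 ("most probably disease
#' causing") or 5 ("disease causing") annotations; class-3 candidates
#' remain variants of unknown significance and do not solve. All passing
#' genes are reported - multi-genic diagnoses list every causal gene,
#' each with its MitoCarta membership flag.
#'
#' @param family_id family identifier
#' @param candidates candidate tibble (rows that passed
#'   [segregation_check()])
#' @param variants variant annotation tibble (for ACMG classes)
#' @param mitocarta MitoCarta gene panel
#' @return one-row tibble: `family_id`, `solved`, `genes`, `modes`,
#'   `mitocarta` (list-columns), `de_novo`, `multi_genic`, `stage`
#' @export
diagnose_family <- function(family_id, candidates, variants,
                            mitocarta = mitocarta_panel()) {
  unsolved <- tibble::tibble(
    family_id = family_id, solved = FALSE, genes = list(character(0)),
    modes = list(character(0)), mitocarta = list(logical(0)),
    de_novo = FALSE, multi_genic = FALSE, stage = "WES")
  if (nrow(candidates) == 0) return(unsolved)
  cls_ok <- vapply(candidates$variant_ids, function(v) {
    all(variants$acmg_class[match(v, variants$variant_id)] >= 4)
  }, TRUE)
  passing <- candidates[cls_ok, , drop = FALSE]
  if (nrow(passing) == 0) return(unsolved)
  # one reported gene per passing candidate (deduplicated by gene+mode)
  passing <- passing[!duplicated(paste(passing$gene, passing$mode)), ,
                     drop = FALSE]
  gene_vec <- passing$gene
  flag_vec <- gene_vec %in% mitocarta
  tibble::tibble(
    family_id = family_id, solved = TRUE, genes = list(gene_vec),
    modes = list(passing$mode),
    mitocarta = list(flag_vec),
    de_novo = any(vapply(passing$de_novo, isTRUE, TRUE)),
    multi_genic = length(gene_vec) > 1, stage = "WES")
}
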