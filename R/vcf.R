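# Plain-text VCF v4.2 writers for the generated/derived variant tables.

GT_CODE <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
             hemi_ref = "0", hemi_alt = "1", missing = "./.")

vcf_header <- function(extra = character(0)) {
  c("##fileformat=VCFv4.2",
    "##source=mitotriage",
    extra)
}

#' Write a per-family nuclear variant table as VCF
#'
#' Emits one genotyped record per variant with the annotation fields the
#' filter cascade consumes carried in INFO (GENE, population and
#' in-house allele frequencies, effect class, damaging-predictor count,
#' ACMG class, MitoCarta membership).
#'
#' @param variants variant annotation tibble
#' @param genotypes long genotype tibble
#' @param members pedigree tibble
#' @param path output file
#' @return `path`, invisibly
#' @export
write_family_vcf <- function(variants, genotypes, members, path) {
  samples <- members$member_id
  g <- genotype_matrix(genotypes, variants$variant_id, samples)
  info <- sprintf(
    "GENE=%s;POPAF=%s;IHAF=%.4g;EFFECT=%s;NDMG=%d;ACMG=%d;MITOCARTA=%d",
    variants$gene,
    ifelse(is.na(variants$pop_af), ".",
           formatC(variants$pop_af, format = "g")),
    variants$inhouse_af, variants$effect,
    rowSums(cbind(variants$dmg_polyphen, variants$dmg_sift,
                  variants$dmg_provean, variants$dmg_mtaster)),
    variants$acmg_class, as.integer(variants$mitocarta))
  gts <- apply(g, 2, function(col) GT_CODE[col])
  if (is.null(dim(gts))) gts <- matrix(gts, nrow = 1)
  body <- cbind(variants$chrom,
                format(variants$pos, scientific = FALSE, trim = TRUE),
                variants$variant_id, variants$ref, variants$alt, ".",
                "PASS", info, "GT", gts)
  lines <- c(
    vcf_header(c(
      '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
      '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population allele frequency">',
      '##INFO=<ID=IHAF,Number=1,Type=Float,Description="In-house allele frequency">',
      '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Effect class">',
      '##INFO=<ID=NDMG,Number=1,Type=Integer,Description="Damaging predictor calls (of 4)">',
      '##INFO=<ID=ACMG,Number=1,Type=Integer,Description="ACMG variant class">',
      '##INFO=<ID=MITOCARTA,Number=0,Type=Flag,Description="Gene in MitoCarta panel">',
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write mtDNA calls as VCF
#'
#' Point variants carry their heteroplasmy as the allele fraction
#' (FORMAT AF); large deletions are emitted as symbolic `<DEL>` records
#' with END and SVLEN.
#'
#' @param calls output of [call_point_variants()]
#' @param deletions output of [detect_deletions()]
#' @param path output file
#' @param sample sample name
#' @param reference mtDNA reference (for the deletion REF base)
#' @return `path`, invisibly
#' @export
write_mt_vcf <- function(calls, deletions, path, sample = "patient",
                         reference = synthetic_mt_reference()) {
  rows <- character(0)
  if (nrow(calls) > 0) {
    rows <- c(rows, sprintf(
      "chrM\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:AF\t0/1:%.4f",
      calls$pos, calls$ref, calls$alt,
      ifelse(calls$passed_cutoff, "PASS", "LowHet"),
      calls$heteroplasmy))
  }
  if (nrow(deletions) > 0) {
    rows <- c(rows, sprintf(
      "chrM\t%d\t.\t%s\t<DEL>\t.\tPASS\tEND=%d;SVLEN=-%d;SUPPORT=%d\tGT:AF\t./.:.",
      deletions$b5, substr(reference, deletions$b5, deletions$b5),
      deletions$b3 - 1L, deletions$size, deletions$supporting_reads))
  }
  lines <- c(
    vcf_header(c(
      '##ALT=<ID=DEL,Description="Large mtDNA deletion">',
      '##INFO=<ID=END,Number=1,Type=Integer,Description="Last deleted base">',
      '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Deletion length">',
      '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Junction reads">',
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Heteroplasmy (alt allele fraction)">')),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"),
    rows)
  writeLines(lines, path)
  invisible(path)
}
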