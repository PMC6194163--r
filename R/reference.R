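# mtDNA coordinate system, synthetic reference genome, gene panels.

#' Length of the human mitochondrial reference (rCRS numbering)
#' @export
MT_GENOME_LENGTH <- 16569L

.mitotriage_env <- new.env(parent = emptyenv())

#' D-loop (control region) positions excluded from mtDNA variant calling
#'
#' The hypervariable control region is excluded from pathogenic-variant
#' calling. The standard definition spans the origin: positions
#' 16024-16569 and 1-576 (1-based rCRS numbering). The bounds are
#' configurable in [call_point_variants()].
#'
#' @return integer vector of excluded positions
#' @export
dloop_positions <- function() {
  c(16024:16569, 1:576)
}

#' Synthetic rCRS-like mitochondrial reference sequence
#'
#' A deterministic 16,569 nt synthetic stand-in for the revised Cambridge
#' Reference Sequence used as the coordinate system for all simulated
#' mtDNA data (the real rCRS is not redistributed with the package). Two
#' fix-ups make it behave like the coordinate conventions expect:
#' reference alleles at the packaged known-pathogenic sites match the
#' canonical rCRS alleles, and the bases flanking the three recurrent
#' deletion junctions (8482:13460, 7462:15747, 9514:15792) are forced
#' unequal so those junctions are their own leftmost representation.
#'
#' @return a single character string of length 16,569
#' @export
synthetic_mt_reference <- function() {
  if (!is.null(.mitotriage_env$mt_ref)) return(.mitotriage_env$mt_ref)
  bases <- c("A", "C", "G", "T")
  s <- with_seed(20181012L, sample(bases, MT_GENOME_LENGTH, replace = TRUE))
  # canonical reference alleles at known-pathogenic positions
  s[3243]  <- "A"
  s[8344]  <- "A"
  s[8993]  <- "T"
  s[11778] <- "G"
  s[13513] <- "G"
  s[14484] <- "T"
  # make the recurrent junctions leftmost-unique: base retained 5' of the
  # junction must differ from the last deleted base
  for (bp in list(c(8482L, 13460L), c(7462L, 15747L), c(9514L, 15792L))) {
    if (s[bp[1]] == s[bp[2] - 1L]) {
      s[bp[2] - 1L] <- setdiff(bases, c(s[bp[1]], s[bp[2] - 2L]))[1]
    }
  }
  ref <- paste(s, collapse = "")
  .mitotriage_env$mt_ref <- ref
  ref
}

#' Table of known pathogenic mtDNA point variants
#'
#' Packaged lookup of recurrent pathogenic mtDNA alleles with their
#' syndrome labels (LHON, MELAS/MIDD, Leigh, ...). Membership in this
#' table drives the lower 2% heteroplasmy cut-off in
#' [call_point_variants()]; all other positions and small indels use 5%.
#'
#' @return a tibble with columns `position`, `ref`, `alt`, `label`,
#'   `syndrome`
#' @export
known_pathogenic_table <- function() {
  utils::read.delim(mitotriage_example("mt_known_pathogenic.tsv"),
                    stringsAsFactors = FALSE) %>%
    tibble::as_tibble()
}

#' Gene panels: MitoCarta membership and OMIM dominant-disease genes
#'
#' Newline-delimited gene lists packaged with the cohort fixture. The
#' MitoCarta panel models the inventory of genes encoding
#' mitochondria-localised proteins at the time of diagnosis; causal genes
#' absent from it quantify what a panel-based approach would have missed.
#' The OMIM-dominant panel restricts the dominant/de-novo filter applied
#' to single patients from non-consanguineous families.
#'
#' @return character vector of gene symbols
#' @export
mitocarta_panel <- function() {
  readLines(mitotriage_example("mitocarta_panel.txt"))
}

#' @rdname mitocarta_panel
#' @export
omim_ad_panel <- function() {
  readLines(mitotriage_example("omim_dominant_panel.txt"))
}

# Synthetic nuclear gene coordinates. Causal genes from the cohort plus
# panel padding get deterministic positions on a simplified genome
# (22 autosomes + X, 120 Mb each); X-linked disease genes are pinned to X.
nuclear_gene_map <- function() {
  if (!is.null(.mitotriage_env$gene_map)) return(.mitotriage_env$gene_map)
  x_genes <- c("SLC16A2", "TAZ", "WDR45", "CASK")
  auto_genes <- c(
    "AARS2", "SERAC1", "ACY1", "ANTXR2", "SPG7", "FBXL4", "MTFMT",
    "NDUFAF4", "QRSL1", "SLC25A46", "RRM2B", "COQ7", "NDUFAF5",
    "TMEM126A", "PYCR2", "SLC19A3", "IER3IP1", "POLG1", "NDUFS7", "MTO1",
    "NDUFA12", "KARS", "NDUFV2", "C19orf12", "TMEM126B", "TRMU",
    "ATPAF2", "AMACR", "C12ORF65", "MFN2", "C10orf2", "BICD2", "HPS1",
    "IARS", "CHRNE", "CLPP", "SLC25A32", "CAPN3", "AP4M1", "ADD3",
    "LMOD3", "LPIN1", "NBAS", "SCN4A", "RELN", "ACAD8", "DNA2",
    "CWF19L1", "ACTA1", "PURA", "DYNC1H1", "CTNNB1"
  )
  n <- length(auto_genes)
  map <- tibble::tibble(
    gene  = c(auto_genes, x_genes),
    chrom = c(paste0("chr", 1 + (seq_len(n) - 1L) %% 22L),
              rep("chrX", length(x_genes))),
    tss   = c(10e6 + ((seq_len(n) - 1L) %/% 22L) * 30e6 +
                ((seq_len(n) - 1L) %% 22L) * 1e6,
              10e6 + seq_along(x_genes) * 15e6)
  )
  .mitotriage_env$gene_map <- map
  map
}

# Background "exome universe": anonymous filler genes used for
# non-causal variants, disjoint from the causal gene map and panels.
background_gene_universe <- function(n = 500L) {
  tibble::tibble(
    gene  = sprintf("BGG%04d", seq_len(n)),
    chrom = paste0("chr", 1 + (seq_len(n) - 1L) %% 22L),
    tss   = 5e6 + ((seq_len(n) - 1L) %/% 22L) * 2.5e6 +
      ((seq_len(n) - 1L) %% 22L) * 1e5
  )
}
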