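# Shared fixtures and independent brute-force oracles.

# A manifest-shaped single-row family for driving the generators directly.
make_family <- function(family_id = "FAM1", consanguineous = FALSE,
                        n_affected = 1L, group = 1L, mdc_score = 6L,
                        categories = "none", genes = character(0),
                        mitocarta = logical(0), variant_info = ".",
                        mt_signature = ".", affected_sex = character(0),
                        parents_available = TRUE,
                        subclinical_parent = ".") {
  fam <- tibble::tibble(
    family_id = family_id, consanguineous = consanguineous,
    n_affected = n_affected, group = group, mdc_score = mdc_score,
    categories = list(categories), genes = list(genes),
    mitocarta = list(mitocarta), variant_info = variant_info,
    mt_signature = mt_signature, affected_sex = list(affected_sex),
    parents_available = parents_available,
    subclinical_parent = subclinical_parent)
  fam$strategy <- ifelse(fam$consanguineous | fam$n_affected > 1, "A", "B")
  fam
}

# A deterministic toy reference (<= 200 nt) for junction oracles.
toy_reference <- function(n = 120, seed = 42) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Independent left-shift (the leftmost-junction convention, re-derived).
bf_leftmost <- function(s, b5, b3) {
  while (b5 >= 1 && substr(s, b5, b5) == substr(s, b3 - 1, b3 - 1)) {
    b5 <- b5 - 1
    b3 <- b3 - 1
  }
  c(b5, b3)
}

# Brute-force junction oracle: enumerate every (b5, b3) pair on a toy
# reference and keep those whose deleted molecule contains the read
# spanning the junction; report unique leftmost representations.
bf_junctions <- function(read, ref) {
  n <- nchar(ref)
  L <- nchar(read)
  found <- list()
  for (b5 in 1:(n - 2)) {
    for (b3 in (b5 + 2):n) {
      molecule <- paste0(substr(ref, 1, b5), substr(ref, b3, n))
      hits <- gregexpr(read, molecule, fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      for (o in hits) {
        if (o <= b5 && o + L - 1 >= b5 + 1) {   # read spans the junction
          found[[length(found) + 1]] <- bf_leftmost(ref, b5, b3)
        }
      }
    }
  }
  if (length(found) == 0) return(NULL)
  unique(do.call(rbind, found))
}

# Brute-force ROH oracle: enumerate all maximal windows with at most
# `het_tolerance` heterozygous calls and span >= cutoff.
bf_roh <- function(pos, geno, cutoff, het_tolerance = 0L) {
  usable <- geno != "missing"
  pos <- pos[usable]
  geno <- geno[usable]
  n <- length(pos)
  is_het <- geno == "het"
  qualifies <- function(i, j) sum(is_het[i:j]) <= het_tolerance
  out <- list()
  for (i in 1:n) {
    for (j in i:n) {
      if (!qualifies(i, j)) next
      if (i > 1 && qualifies(i - 1, j)) next
      if (j < n && qualifies(i, j + 1)) next
      if (pos[j] - pos[i] + 1 >= cutoff) {
        out[[length(out) + 1]] <- c(start = pos[i], end = pos[j])
      }
    }
  }
  if (length(out) == 0) return(NULL)
  unique(do.call(rbind, out))
}

# Small genotype-track builder: genotype string vector at fixed spacing.
make_track <- function(genotypes, spacing = 1e5, chrom = "chr1",
                       member_id = "P1") {
  tibble::tibble(member_id = member_id, chrom = chrom,
                 pos = seq_along(genotypes) * spacing,
                 genotype = genotypes)
}

# Minimal pileup: one variant site plus optional reference-only sites.
make_pileup <- function(pos, ref, alt, alt_count, depth) {
  alleles <- c(ref, alt)
  counts <- c(depth - alt_count, alt_count)
  tibble::tibble(pos = rep(pos, 2), ref = rep(ref, 2),
                 allele = alleles, count = counts)
}

# Hand-built nuclear variant row for filter tests.
make_variant <- function(variant_id = "v1", gene = "GENE1",
                         chrom = "chr1", pos = 1e6, effect = "missense",
                         pop_af = 0.001, inhouse_af = 0.001,
                         n_damaging = 2L, acmg_class = 5L,
                         mitocarta = FALSE, omim_ad = FALSE) {
  dmg <- seq_len(4) <= n_damaging
  tibble::tibble(variant_id = variant_id, gene = gene, chrom = chrom,
                 pos = pos, ref = "C", alt = "T", effect = effect,
                 pop_af = pop_af, inhouse_af = inhouse_af,
                 dmg_polyphen = dmg[1], dmg_sift = dmg[2],
                 dmg_provean = dmg[3], dmg_mtaster = dmg[4],
                 acmg_class = acmg_class, mitocarta = mitocarta,
                 omim_ad = omim_ad, planted = TRUE)
}

# Long genotype tibble from member_id -> genotype pairs.
make_genotypes <- function(variant_id, ...) {
  g <- c(...)
  tibble::tibble(variant_id = variant_id, member_id = names(g),
                 genotype = unname(g))
}

# A simple trio pedigree.
trio_members <- function(child_sex = "F", affected_child = TRUE,
                         subclinical_father = FALSE) {
  tibble::tibble(
    member_id = c("FTH", "MTH", "P1"),
    father = c(NA, NA, "FTH"), mother = c(NA, NA, "MTH"),
    sex = c("M", "F", child_sex),
    affected = c(FALSE, FALSE, affected_child),
    subclinical = c(subclinical_father, FALSE, FALSE),
    available = TRUE)
}
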