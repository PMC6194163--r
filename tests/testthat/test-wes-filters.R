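test_that("frequency filter keeps rare annotated and trusted non-annotated variants", {
  v <- dplyr::bind_rows(
    make_variant("v1", pop_af = 0.005),
    make_variant("v2", pop_af = 0.02),
    make_variant("v3", pop_af = NA, inhouse_af = 0.03),
    make_variant("v4", pop_af = NA, inhouse_af = 0.07),
    make_variant("v5", pop_af = 0.01))          # boundary: < is strict
  kept <- frequency_filter(v)
  expect_equal(kept$variant_id, c("v1", "v3"))
  # in-house boundary is inclusive (rule removes only above 5%)
  expect_equal(nrow(frequency_filter(
    make_variant("v6", pop_af = NA, inhouse_af = 0.05))), 1)
  expect_equal(nrow(frequency_filter(v[0, ])), 0)
})

test_that("effect filter always keeps truncating variants and triages missense", {
  v <- dplyr::bind_rows(
    make_variant("v1", effect = "frameshift", n_damaging = 0L),
    make_variant("v2", effect = "nonsense", n_damaging = 0L),
    make_variant("v3", effect = "splice", n_damaging = 0L),
    make_variant("v4", effect = "missense", n_damaging = 0L),
    make_variant("v5", effect = "missense", n_damaging = 1L),
    make_variant("v6", effect = "synonymous", n_damaging = 4L),
    make_variant("v7", effect = "other", n_damaging = 4L))
  kept <- effect_filter(v)
  expect_equal(kept$variant_id, c("v1", "v2", "v3", "v5"))
  strict <- effect_filter(v, min_damaging = 2L)
  expect_false("v5" %in% strict$variant_id)
  expect_true("v1" %in% strict$variant_id)
})

test_that("the filter cascade is order-stable", {
  fams <- list(
    make_family(categories = "nuclear_AR_hom", genes = "SPG7",
                mitocarta = TRUE, consanguineous = TRUE),
    make_family(categories = "nuclear_AD_denovo", genes = "MFN2",
                mitocarta = TRUE))
  for (fam in fams) {
    for (s in c(2, 17)) {
      w <- generate_wes_variants(fam, sim_config(seed = s))
      a <- effect_filter(frequency_filter(w$variants))
      b <- frequency_filter(effect_filter(w$variants))
      expect_equal(a[order(a$variant_id), ], b[order(b$variant_id), ])
    }
  }
})

test_that("recessive candidates: homozygous model with ROH ranking", {
  mem <- trio_members()
  v <- dplyr::bind_rows(
    make_variant("v1", gene = "G1", chrom = "chr1", pos = 2e6),
    make_variant("v2", gene = "G2", chrom = "chr2", pos = 9e6))
  g <- dplyr::bind_rows(
    make_genotypes("v1", FTH = "het", MTH = "het", P1 = "hom_alt"),
    make_genotypes("v2", FTH = "het", MTH = "het", P1 = "hom_alt"))
  roh <- tibble::tibble(member_id = "P1", chrom = "chr1", start = 1e6,
                        end = 7e6, length = 6e6 + 1, n_markers = 60L)
  cands <- recessive_candidates(mem, v, g, roh)
  expect_equal(nrow(cands), 2)
  expect_equal(cands$mode, c("AR_hom", "AR_hom"))
  # the in-ROH candidate ranks first; ROH is not a hard filter
  expect_equal(cands$gene[1], "G1")
  expect_true(cands$in_roh[1])
  expect_false(cands$in_roh[2])

  # an unaffected homozygous sib kills the candidate
  mem2 <- dplyr::bind_rows(mem, tibble::tibble(
    member_id = "S1", father = "FTH", mother = "MTH", sex = "M",
    affected = FALSE, subclinical = FALSE, available = TRUE))
  g2 <- dplyr::bind_rows(g, make_genotypes("v1", S1 = "hom_alt"),
                         make_genotypes("v2", S1 = "het"))
  cands2 <- recessive_candidates(mem2, v, g2, roh)
  expect_equal(cands2$gene, "G2")
})

test_that("compound heterozygotes require trans configuration", {
  mem <- trio_members()
  v <- dplyr::bind_rows(
    make_variant("v1", gene = "G1", pos = 2e6),
    make_variant("v2", gene = "G1", pos = 2.1e6))
  trans <- dplyr::bind_rows(
    make_genotypes("v1", FTH = "het", MTH = "hom_ref", P1 = "het"),
    make_genotypes("v2", FTH = "hom_ref", MTH = "het", P1 = "het"))
  ct <- recessive_candidates(mem, v, trans)
  expect_equal(ct$mode, "AR_comphet")
  expect_true(ct$phased)
  expect_setequal(ct$variant_ids[[1]], c("v1", "v2"))

  cis <- dplyr::bind_rows(
    make_genotypes("v1", FTH = "hom_ref", MTH = "het", P1 = "het"),
    make_genotypes("v2", FTH = "hom_ref", MTH = "het", P1 = "het"))
  expect_equal(nrow(recessive_candidates(mem, v, cis)), 0)

  # missing parents: retained but flagged unphasable
  nop <- dplyr::bind_rows(
    make_genotypes("v1", FTH = "missing", MTH = "missing", P1 = "het"),
    make_genotypes("v2", FTH = "missing", MTH = "missing", P1 = "het"))
  cu <- recessive_candidates(mem, v, nop)
  expect_equal(cu$mode, "AR_comphet")
  expect_false(cu$phased)
})

test_that("X-linked recessive candidates need hemizygous affected males", {
  mem <- trio_members(child_sex = "M")
  v <- make_variant("v1", gene = "GX", chrom = "chrX", pos = 3e6)
  g <- make_genotypes("v1", FTH = "hemi_ref", MTH = "het", P1 = "hemi_alt")
  cx <- recessive_candidates(mem, v, g)
  expect_equal(cx$mode, "XLR")
  # carrier mother is fine; a hemizygous unaffected father is not
  g2 <- make_genotypes("v1", FTH = "hemi_alt", MTH = "het", P1 = "hemi_alt")
  expect_equal(nrow(recessive_candidates(mem, v, g2)), 0)
  # no affected male, no XLR candidate
  memf <- trio_members(child_sex = "F")
  gf <- make_genotypes("v1", FTH = "hemi_ref", MTH = "het", P1 = "het")
  expect_equal(nrow(recessive_candidates(memf, v, gf)), 0)
})

test_that("dominant candidates are panel-restricted and de novo aware", {
  mem <- trio_members()
  v <- dplyr::bind_rows(
    make_variant("v1", gene = "MFN2", pos = 2e6),
    make_variant("v2", gene = "NOTINPANEL", pos = 3e6),
    make_variant("v3", gene = "WDR45", chrom = "chrX", pos = 4e6))
  g <- dplyr::bind_rows(
    make_genotypes("v1", FTH = "hom_ref", MTH = "hom_ref", P1 = "het"),
    make_genotypes("v2", FTH = "hom_ref", MTH = "hom_ref", P1 = "het"),
    make_genotypes("v3", FTH = "hemi_ref", MTH = "hom_ref", P1 = "het"))
  cands <- dominant_candidates(mem, v, g)
  expect_setequal(cands$gene, c("MFN2", "WDR45"))   # panel restriction
  expect_true(all(cands$de_novo))
  expect_equal(cands$mode[cands$gene == "WDR45"], "XLD")

  # inherited from a parent: retained, flagged, not de novo
  gi <- make_genotypes("v1", FTH = "het", MTH = "hom_ref", P1 = "het")
  ci <- dominant_candidates(mem, v[1, ], gi)
  expect_false(ci$de_novo)
  expect_equal(ci$inherited_parent, "father")

  # unknown parental genotypes: de novo status is NA, not dropped
  gu <- make_genotypes("v1", FTH = "missing", MTH = "missing", P1 = "het")
  expect_true(is.na(dominant_candidates(mem, v[1, ], gu)$de_novo))
})

test_that("segregation checks enforce mode-consistent genotypes", {
  mem <- dplyr::bind_rows(trio_members(), tibble::tibble(
    member_id = "S1", father = "FTH", mother = "MTH", sex = "F",
    affected = FALSE, subclinical = FALSE, available = TRUE))
  v <- make_variant("v1", gene = "G1")
  cand <- mitotriage:::candidate_row("AR_hom", "G1", "v1")

  carrier_parents <- dplyr::bind_rows(
    make_genotypes("v1", FTH = "het", MTH = "het", P1 = "hom_alt",
                   S1 = "het"))
  expect_true(segregation_check(cand, mem, carrier_parents))
  hom_sib <- make_genotypes("v1", FTH = "het", MTH = "het",
                            P1 = "hom_alt", S1 = "hom_alt")
  expect_false(segregation_check(cand, mem, hom_sib))

  # dominant: an unaffected carrier parent fails unless subclinical
  ad <- mitotriage:::candidate_row("AD", "MFN2", "v1", de_novo = FALSE,
                                   inherited_parent = "father")
  gi <- make_genotypes("v1", FTH = "het", MTH = "hom_ref", P1 = "het",
                       S1 = "hom_ref")
  expect_false(segregation_check(ad, mem, gi))
  mem_sub <- mem
  mem_sub$subclinical[mem_sub$member_id == "FTH"] <- TRUE
  expect_true(segregation_check(ad, mem_sub, gi))
})

test_that("diagnosis requires ACMG class 4/5 and reports multi-genic results", {
  v <- dplyr::bind_rows(
    make_variant("v1", gene = "SERAC1", acmg_class = 5L),
    make_variant("v2", gene = "ACY1", acmg_class = 4L),
    make_variant("v3", gene = "VUSGENE", acmg_class = 3L))
  cands <- dplyr::bind_rows(
    mitotriage:::candidate_row("AR_hom", "SERAC1", "v1"),
    mitotriage:::candidate_row("AR_hom", "ACY1", "v2"),
    mitotriage:::candidate_row("AR_hom", "VUSGENE", "v3"))
  dx <- diagnose_family("F1", cands, v)
  expect_true(dx$solved)
  expect_setequal(dx$genes[[1]], c("SERAC1", "ACY1"))
  expect_true(dx$multi_genic)
  expect_equal(dx$mitocarta[[1]],
               c(TRUE, FALSE)[match(dx$genes[[1]], c("SERAC1", "ACY1"))])

  # a lone class-3 candidate stays a VUS: unsolved
  dx3 <- diagnose_family("F2", cands[3, ], v)
  expect_false(dx3$solved)
  expect_false(diagnose_family("F3", cands[0, ], v)$solved)
})
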