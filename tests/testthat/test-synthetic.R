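test_that("generation is byte-identical under the same seed", {
  fam <- make_family(consanguineous = TRUE, categories = "nuclear_AR_hom",
                     genes = "FBXL4", mitocarta = TRUE,
                     mt_signature = "depletion")
  cfg <- sim_config(seed = 4)
  expect_identical(simulate_family_inputs(fam, cfg),
                   simulate_family_inputs(fam, cfg))
  # a different seed changes stochastic fields but not the planted truth
  other <- simulate_family_inputs(fam, sim_config(seed = 5))
  base <- simulate_family_inputs(fam, cfg)
  expect_false(identical(base$qpcr$patient$mt_nd1,
                         other$qpcr$patient$mt_nd1))
  expect_identical(base$wes$truth, other$wes$truth)
  planted <- function(w) w$variants[w$variants$planted, c(1:7, 14)]
  expect_identical(planted(base$wes), planted(other$wes))
})

test_that("homoplasmic variants appear in every covering read", {
  fam <- make_family(categories = "mt_point",
                     variant_info = "11778:G:A:1.0", group = 1L)
  mt <- generate_mt_reads(fam, sim_config(seed = 6))
  site <- mt$pileup[mt$pileup$pos == 11778, ]
  expect_equal(site$count[site$allele == "A"], 1000)
  expect_equal(site$count[site$allele == "G"], 0)
})

test_that("qPCR records hit the depletion window or the null level", {
  depl <- make_family(mt_signature = "depletion")
  for (s in 1:5) {
    q <- generate_qpcr(depl, sim_config(seed = s))
    cn <- assess_copy_number(q$patient, q$controls)
    expect_gte(cn$percent_of_controls, 10)
    expect_lte(cn$percent_of_controls, 30)
    qn <- generate_qpcr(make_family(), sim_config(seed = s))
    cnn <- assess_copy_number(qn$patient, qn$controls)
    expect_gt(cnn$percent_of_controls, 70)
    expect_false(cnn$depleted)
  }
})

test_that("planted defects survive the cascade alone; backgrounds never do", {
  cases <- list(
    make_family(consanguineous = TRUE, categories = "nuclear_AR_hom",
                genes = "SPG7", mitocarta = TRUE),
    make_family(categories = "nuclear_AR_comphet", genes = "KARS",
                mitocarta = TRUE),
    make_family(categories = "nuclear_XLR", genes = "TAZ",
                mitocarta = FALSE, affected_sex = "M"),
    make_family(categories = "nuclear_AD_denovo", genes = "MFN2",
                mitocarta = TRUE),
    make_family(categories = "nuclear_AD_inherited", genes = "DNA2",
                mitocarta = TRUE, subclinical_parent = "father"),
    make_family(categories = "nuclear_XLD_denovo", genes = "WDR45",
                mitocarta = FALSE, affected_sex = "F"))
  for (fam in cases) {
    w <- generate_wes_variants(fam, sim_config(seed = 3))
    kept <- effect_filter(frequency_filter(w$variants))
    # every planted causal variant survives the cascade
    expect_true(all(w$variants$variant_id[w$variants$planted] %in%
                      kept$variant_id),
                label = paste("planted survives:", fam$categories[[1]]))
    # no background variant survives it
    expect_false(any(kept$variant_id %in%
                       w$variants$variant_id[!w$variants$planted]),
                 label = paste("background removed:", fam$categories[[1]]))
    # and the family is solved with exactly the planted gene set
    cands <- recessive_candidates(w$members, kept, w$genotypes)
    if (fam$strategy == "B") {
      cands <- dplyr::bind_rows(
        cands, dominant_candidates(w$members, kept, w$genotypes))
    }
    seg <- vapply(seq_len(nrow(cands)), function(k)
      segregation_check(cands[k, ], w$members, w$genotypes), TRUE)
    dx <- diagnose_family(fam$family_id, cands[seg, , drop = FALSE], kept)
    expect_true(dx$solved)
    expect_setequal(dx$genes[[1]], fam$genes[[1]])
  }
})

test_that("defect-free families yield zero candidates", {
  for (fam in list(make_family(), make_family(consanguineous = TRUE))) {
    w <- generate_wes_variants(fam, sim_config(seed = 10))
    kept <- effect_filter(frequency_filter(w$variants))
    expect_equal(nrow(kept), 0)
  }
})

test_that("X-linked recessive truth cannot be planted without an affected male", {
  fam <- make_family(categories = "nuclear_XLR", genes = "TAZ",
                     mitocarta = FALSE, affected_sex = "F")
  expect_error(generate_wes_variants(fam, sim_config(seed = 1)),
               "male")
})

test_that("family VCF output round-trips through a standard parser", {
  skip_if_not_installed("vcfR")
  fam <- make_family(categories = "nuclear_AR_comphet", genes = "KARS",
                     mitocarta = TRUE)
  w <- generate_wes_variants(fam, sim_config(seed = 2))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_family_vcf(w$variants, w$genotypes, w$members, p)
  vcf <- vcfR::read.vcfR(p, verbose = FALSE)
  expect_equal(nrow(vcf@fix), nrow(w$variants))
  expect_equal(colnames(vcf@gt)[-1], w$members$member_id)
  # genotypes survive the round trip for the planted pair
  gt <- vcfR::extract.gt(vcf)
  child <- w$members$member_id[w$members$affected]
  planted <- w$variants$variant_id[w$variants$planted]
  expect_true(all(gt[planted, child] == "0/1"))
})

test_that("mtDNA VCF carries heteroplasmy as AF and deletions as <DEL>", {
  skip_if_not_installed("vcfR")
  calls <- call_point_variants(make_pileup(3243, "A", "G", 240, 1000))
  dels <- tibble::tibble(b5 = 8482L, b3 = 13460L, size = 4977L,
                         supporting_reads = 12L,
                         single_or_multiple = "single")
  p <- withr::local_tempfile(fileext = ".vcf")
  write_mt_vcf(calls, dels, p)
  vcf <- vcfR::read.vcfR(p, verbose = FALSE)
  expect_equal(nrow(vcf@fix), 2)
  expect_true(any(vcf@fix[, "ALT"] == "<DEL>"))
  expect_match(vcf@fix[vcf@fix[, "ALT"] == "<DEL>", "INFO"],
               "SVLEN=-4977")
  af <- vcfR::extract.gt(vcf, element = "AF")
  expect_equal(as.numeric(af[1, 1]), 0.24)
})
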