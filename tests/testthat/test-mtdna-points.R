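test_that("heteroplasmy is the mutant read fraction and cut-offs are tiered", {
  # 720/1000 at the Leigh-syndrome ND5 site: known pathogenic, passes
  calls <- call_point_variants(make_pileup(13513, "G", "A", 720, 1000))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$heteroplasmy, 0.72)
  expect_true(calls$known_pathogenic)
  expect_true(calls$passed_cutoff)
  expect_equal(calls$label, "m.13513G>A")

  # 3% at a known site passes the 2% cut-off ...
  low_known <- call_point_variants(make_pileup(3243, "A", "G", 30, 1000))
  expect_true(low_known$passed_cutoff)
  # ... but 3% at an unlisted site is below the general 5% cut-off
  low_other <- call_point_variants(make_pileup(5000, "A", "G", 30, 1000))
  expect_false(low_other$passed_cutoff)
  expect_false(low_other$known_pathogenic)
  # inclusive boundaries: exactly 2% (known) and exactly 5% (other) pass
  expect_true(call_point_variants(
    make_pileup(3243, "A", "G", 20, 1000))$passed_cutoff)
  expect_true(call_point_variants(
    make_pileup(5000, "A", "G", 50, 1000))$passed_cutoff)
})

test_that("reference-only pileups, zero depth and D-loop sites are excluded", {
  ref_only <- tibble::tibble(pos = 4000, ref = "A", allele = "A",
                             count = 1000)
  expect_equal(nrow(call_point_variants(ref_only)), 0)

  zero <- make_pileup(4000, "A", "G", 0, 0)
  expect_warning(out <- call_point_variants(zero), "zero depth")
  expect_equal(nrow(out), 0)

  dloop <- make_pileup(16100, "A", "G", 900, 1000)
  expect_message(out <- call_point_variants(dloop), "D-loop")
  expect_equal(nrow(out), 0)
  # the same variant outside the D-loop is called
  expect_equal(nrow(suppressMessages(
    call_point_variants(make_pileup(15000, "A", "G", 900, 1000)))), 1)
})

test_that("small indel alleles use the 5% cut-off", {
  pile <- tibble::tibble(pos = c(7000, 7000), ref = "A",
                         allele = c("A", "+CT"), count = c(940, 60))
  calls <- call_point_variants(pile)
  expect_equal(calls$alt, "+CT")
  expect_true(calls$passed_cutoff)
  pile$count <- c(970, 30)
  expect_false(call_point_variants(pile)$passed_cutoff)
})

test_that("calling is invariant to pileup row order", {
  pile <- dplyr::bind_rows(
    make_pileup(13513, "G", "A", 700, 1000),
    make_pileup(3243, "A", "G", 300, 1000),
    make_pileup(9000, "C", "T", 80, 1000))
  shuffled <- pile[withr::with_seed(7, sample(nrow(pile))), ]
  expect_equal(call_point_variants(pile), call_point_variants(shuffled))
})

test_that("heteroplasmy estimates from binomial pileups are unbiased", {
  fam <- make_family(categories = "mt_point", variant_info = "9000:C:T:0.5",
                     group = 1L)
  # 9000 C ref in the synthetic reference is arbitrary; override via pileup
  h <- vapply(1:100, function(s) {
    mt <- generate_mt_reads(fam, sim_config(seed = s))
    calls <- call_point_variants(mt$pileup)
    calls$heteroplasmy[calls$pos == 9000]
  }, 1.0)
  se <- sqrt(0.5 * 0.5 / 1000) / sqrt(100)
  expect_lt(abs(mean(h) - 0.5), 3 * se)
})

test_that("copy-number assessment normalises to the control mean", {
  controls <- tibble::tibble(sample = c("c1", "c2"), nuc_b2m = c(100, 100),
                             mt_nd1 = c(10000, 30000))  # ratios r and 3r
  patient <- tibble::tibble(sample = "p", nuc_b2m = 100, mt_nd1 = 20000)
  r <- assess_copy_number(patient, controls)          # patient at 2r
  expect_equal(r$percent_of_controls, 100)
  expect_false(r$depleted)

  depl <- assess_copy_number(
    tibble::tibble(sample = "p", nuc_b2m = 100, mt_nd1 = 4000), controls)
  expect_equal(depl$percent_of_controls, 20)
  expect_true(depl$depleted)

  expect_error(assess_copy_number(patient, controls[0, ]), "control")
  patient$mt_nd1 <- -1
  expect_error(assess_copy_number(patient, controls), "positive")
})

test_that("mtDNA stage classification follows the escalation rules", {
  no_calls <- call_point_variants(
    tibble::tibble(pos = integer(), ref = character(),
                   allele = character(), count = integer()))
  no_dels <- detect_deletions(character(0))
  one_del <- tibble::tibble(b5 = 8482L, b3 = 13460L, size = 4977L,
                            supporting_reads = 10L,
                            single_or_multiple = "single")
  two_dels <- tibble::tibble(b5 = c(6465L, 7816L), b3 = c(13999L, 14561L),
                             size = c(7533L, 6744L),
                             supporting_reads = c(8L, 9L),
                             single_or_multiple = "multiple")
  normal_cn <- list(ratio = 1, percent_of_controls = 98, depleted = FALSE)
  low_cn <- list(ratio = 0.2, percent_of_controls = 20, depleted = TRUE)

  point <- call_point_variants(make_pileup(11778, "G", "A", 1000, 1000))
  expect_equal(classify_mt_findings(point, no_dels, normal_cn)$outcome,
               "solved_point")
  expect_equal(classify_mt_findings(no_calls, one_del, normal_cn)$outcome,
               "solved_single_deletion")
  expect_equal(classify_mt_findings(no_calls, two_dels, normal_cn)$outcome,
               "escalate_to_wes")
  expect_equal(classify_mt_findings(no_calls, no_dels, low_cn)$outcome,
               "escalate_to_wes")
  expect_equal(classify_mt_findings(no_calls, no_dels, normal_cn)$outcome,
               "negative")
})
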