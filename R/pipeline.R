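# Cohort orchestration: mtDNA stage first, WES second, then the yield
# tables that constitute the study-level result.

run_family <- function(family, cfg, reference, known, mitocarta, omim,
                       min_support, depletion_threshold, roh_cutoff) {
  mt <- generate_mt_reads(family, cfg, reference)
  qpcr <- generate_qpcr(family, cfg)
  calls <- call_point_variants(mt$pileup, known)
  dels <- detect_deletions(mt$reads, reference, min_support)
  cn <- assess_copy_number(qpcr$patient, qpcr$controls, depletion_threshold)
  mtdx <- classify_mt_findings(calls, dels, cn)

  base <- tibble::tibble(
    family_id = family$family_id, group = family$group,
    strategy = family$strategy, mt_outcome = mtdx$outcome,
    mt_label = NA_character_, mt_b5 = NA_integer_, mt_b3 = NA_integer_,
    stage = NA_character_, solved = FALSE, genes = list(character(0)),
    modes = list(character(0)), mitocarta = list(logical(0)),
    de_novo = FALSE, multi_genic = FALSE, errored = FALSE)

  if (mtdx$outcome == "solved_point") {
    base$stage <- "mtDNA"
    base$solved <- TRUE
    base$mt_label <- mtdx$point_call$label
    return(base)
  }
  if (mtdx$outcome == "solved_single_deletion") {
    base$stage <- "mtDNA"
    base$solved <- TRUE
    base$mt_b5 <- dels$b5[1]
    base$mt_b3 <- dels$b3[1]
    base$mt_label <- sprintf("del_%d:%d_%dbp", dels$b5[1], dels$b3[1],
                             dels$size[1])
    return(base)
  }

  # negative or escalated families proceed to WES
  wes <- generate_wes_variants(family, cfg)
  roh <- if (family$consanguineous) {
    detect_roh(generate_genotype_track(family, cfg), cutoff = roh_cutoff)
  } else NULL
  filtered <- effect_filter(frequency_filter(wes$variants))
  cands <- recessive_candidates(wes$members, filtered, wes$genotypes, roh)
  if (family$strategy == "B") {
    cands <- dplyr::bind_rows(
      cands, dominant_candidates(wes$members, filtered, wes$genotypes, omim))
  }
  if (nrow(cands) > 0) {
    seg <- vapply(seq_len(nrow(cands)), function(k) {
      segregation_check(cands[k, ], wes$members, wes$genotypes)
    }, TRUE)
    cands <- cands[seg, , drop = FALSE]
  }
  dx <- diagnose_family(family$family_id, cands, filtered, mitocarta)
  base$stage <- "WES"
  base$solved <- dx$solved
  base$genes <- dx$genes
  base$modes <- dx$modes
  base$mitocarta <- dx$mitocarta
  base$de_novo <- dx$de_novo
  base$multi_genic <- dx$multi_genic
  base
}

frac <- function(num, den) {
  list(n = num, d = den, pct = pct_round(num, den))
}

compute_yields <- function(fam) {
  fam <- fam[!fam$errored, , drop = FALSE]
  n <- nrow(fam)
  mt_solved <- fam$stage == "mtDNA" & fam$solved
  wes_solved <- fam$stage == "WES" & fam$solved
  wes_entered <- fam$stage == "WES"
  a <- fam$strategy == "A"
  b <- fam$strategy == "B"
  g2 <- fam$group == 2
  list(
    overall = frac(sum(fam$solved), n),
    mtdna = frac(sum(mt_solved), n),
    wes = frac(sum(wes_solved), n),
    mtdna_strategy_A = frac(sum(mt_solved & a), sum(a)),
    mtdna_strategy_B = frac(sum(mt_solved & b), sum(b)),
    wes_strategy_A = frac(sum(wes_solved & a), sum(wes_entered & a)),
    wes_strategy_B = frac(sum(wes_solved & b), sum(wes_entered & b)),
    wes_B_de_novo = frac(sum(wes_solved & b & fam$de_novo),
                         sum(wes_entered & b)),
    wes_strategy_A_group1 = frac(sum(wes_solved & a & !g2),
                                 sum(wes_entered & a & !g2)),
    wes_strategy_A_group2 = frac(sum(wes_solved & a & g2),
                                 sum(wes_entered & a & g2)),
    wes_strategy_B_group1 = frac(sum(wes_solved & b & !g2),
                                 sum(wes_entered & b & !g2)),
    wes_strategy_B_group2 = frac(sum(wes_solved & b & g2),
                                 sum(wes_entered & b & g2))
  )
}

#' Run the two-step diagnostic pipeline over a cohort
#'
#' For every family: simulate/collect the mtDNA inputs, run the mtDNA
#' stage (point variants, deletions, copy number), stop when it solves
#' the family, and otherwise proceed to the WES stage with the filtering
#' strategy dictated by family structure (strategy A: recessive and
#' X-linked models, with ROH ranking in consanguineous families;
#' strategy B: additionally the panel-restricted dominant model).
#' Families on which a stage fails are flagged errored and excluded from
#' all denominators with a warning (or abort the run in strict mode).
#'
#' @param manifest a [load_manifest()] cohort
#' @param cfg a [sim_config()]
#' @param reference mtDNA reference sequence
#' @param known known-pathogenic mtDNA table
#' @param mitocarta MitoCarta gene panel
#' @param omim OMIM dominant-disease gene panel
#' @param min_support minimum junction reads per deletion call
#' @param depletion_threshold depletion cut-off, percent of control mean
#' @param roh_cutoff minimum ROH length in bp
#' @param strict abort on per-family errors instead of flagging
#' @return a `cohort_report`: list with `families` (per-family results),
#'   `yields` (each a list `n`, `d`, `pct`), `mt_breakdown` and
#'   `mitocarta_summary`
#' @export
run_pipeline <- function(manifest, cfg = sim_config(),
                         reference = synthetic_mt_reference(),
                         known = known_pathogenic_table(),
                         mitocarta = mitocarta_panel(),
                         omim = omim_ad_panel(),
                         min_support = 3L, depletion_threshold = 35,
                         roh_cutoff = 5e6, strict = FALSE) {
  rows <- list(tibble::tibble(
    family_id = character(), group = integer(), strategy = character(),
    mt_outcome = character(), mt_label = character(), mt_b5 = integer(),
    mt_b3 = integer(), stage = character(), solved = logical(),
    genes = list(), modes = list(), mitocarta = list(),
    de_novo = logical(), multi_genic = logical(), errored = logical()))
  for (i in seq_len(nrow(manifest))) {
    fam <- manifest[i, ]
    rows[[i + 1L]] <- tryCatch(
      run_family(fam, cfg, reference, known, mitocarta, omim,
                 min_support, depletion_threshold, roh_cutoff),
      error = function(e) {
        if (strict) stop(e)
        warning("family ", fam$family_id, " errored and was excluded: ",
                conditionMessage(e), call. = FALSE)
        tibble::tibble(
          family_id = fam$family_id, group = fam$group,
          strategy = fam$strategy, mt_outcome = NA_character_,
          mt_label = NA_character_, mt_b5 = NA_integer_,
          mt_b3 = NA_integer_, stage = NA_character_, solved = FALSE,
          genes = list(character(0)), modes = list(character(0)),
          mitocarta = list(logical(0)), de_novo = FALSE,
          multi_genic = FALSE, errored = TRUE)
      })
  }
  families <- dplyr::bind_rows(rows)
  report <- structure(
    list(families = families, yields = compute_yields(families)),
    class = "cohort_report")
  report$mt_breakdown <- mtdna_breakdown(report, known)
  report$mitocarta_summary <- mitocarta_summary(report, mitocarta)
  report
}

#' Break down the mtDNA-stage diagnoses by defect
#'
#' Tallies the solved mtDNA families by mutation identity (with the
#' syndrome labels of the known-pathogenic table, e.g. LHON alleles) and
#' by event type, including a per-breakpoint tally of the single large
#' deletions.
#'
#' @param report a `cohort_report`
#' @param known known-pathogenic mtDNA table
#' @return list with `n_mt_solved`, `by_label` (tibble label/syndrome/n),
#'   `lhon`, `m3243`, `single_deletions` (each a `n`/`d`/`pct` list) and
#'   `deletion_breakpoints`
#' @export
mtdna_breakdown <- function(report, known = known_pathogenic_table()) {
  fam <- report$families
  mt <- fam[!fam$errored & fam$stage == "mtDNA" & fam$solved, , drop = FALSE]
  n <- nrow(mt)
  if (n == 0) {
    return(list(n_mt_solved = 0L,
                by_label = tibble::tibble(label = character(),
                                          syndrome = character(),
                                          n = integer()),
                lhon = frac(0L, 0L), m3243 = frac(0L, 0L),
                single_deletions = frac(0L, 0L),
                deletion_breakpoints = table(character(0))))
  }
  syndrome <- known$syndrome[match(mt$mt_label, known$label)]
  is_del <- !is.na(mt$mt_b5)
  by_label <- dplyr::count(
    tibble::tibble(label = mt$mt_label,
                   syndrome = ifelse(is_del, "single deletion", syndrome)),
    .data$label, .data$syndrome, name = "n")
  list(
    n_mt_solved = n,
    by_label = by_label,
    lhon = frac(sum(!is.na(syndrome) & syndrome == "LHON"), n),
    m3243 = frac(sum(mt$mt_label == "m.3243A>G", na.rm = TRUE), n),
    single_deletions = frac(sum(is_del), n),
    deletion_breakpoints = table(sprintf("%d:%d", mt$mt_b5[is_del],
                                         mt$mt_b3[is_del]))
  )
}

#' MitoCarta coverage of the group-1 WES diagnoses
#'
#' Over the WES-solved families of group 1 (probable/definite
#' mitochondrial disease), counts the causal genes absent from the
#' MitoCarta panel. Multi-genic families contribute every causal gene,
#' so the denominator counts gene instances across families.
#'
#' @param report a `cohort_report`
#' @param mitocarta MitoCarta gene panel
#' @return list with `genes` (tibble gene/in_mitocarta), and
#'   `absent` (a `n`/`d`/`pct` list)
#' @export
mitocarta_summary <- function(report, mitocarta = mitocarta_panel()) {
  fam <- report$families
  g1 <- fam[!fam$errored & fam$stage == "WES" & fam$solved &
              fam$group == 1, , drop = FALSE]
  genes <- as.character(unlist(g1$genes))
  flags <- as.logical(unlist(g1$mitocarta))
  list(genes = tibble::tibble(gene = genes, in_mitocarta = flags),
       absent = frac(sum(!flags), length(genes)))
}

fmt_frac <- function(f) sprintf("%d%% (%d/%d)", f$pct, f$n, f$d)

#' @export
print.cohort_report <- function(x, ...) {
  y <- x$yields
  cat("Two-step diagnostic pipeline report\n")
  cat("  families analysed:     ", y$overall$d,
      if (any(x$families$errored)) sprintf("  (%d errored, excluded)",
                                           sum(x$families$errored)) else "",
      "\n", sep = "")
  cat("  overall yield:         ", fmt_frac(y$overall), "\n", sep = "")
  cat("  mtDNA stage:           ", fmt_frac(y$mtdna), "\n", sep = "")
  cat("  WES stage:             ", fmt_frac(y$wes), "\n", sep = "")
  cat("  WES strategy A:        ", fmt_frac(y$wes_strategy_A),
      "  [group 1: ", fmt_frac(y$wes_strategy_A_group1),
      ", group 2: ", fmt_frac(y$wes_strategy_A_group2), "]\n", sep = "")
  cat("  WES strategy B:        ", fmt_frac(y$wes_strategy_B),
      "  [group 1: ", fmt_frac(y$wes_strategy_B_group1),
      ", group 2: ", fmt_frac(y$wes_strategy_B_group2), "]\n", sep = "")
  cat("  de novo (strategy B):  ", fmt_frac(y$wes_B_de_novo), "\n", sep = "")
  bd <- x$mt_breakdown
  if (bd$n_mt_solved > 0) {
    cat("  mtDNA breakdown:        LHON ", fmt_frac(bd$lhon),
        ", m.3243A>G ", fmt_frac(bd$m3243),
        ", single deletions ", fmt_frac(bd$single_deletions), "\n", sep = "")
  }
  ms <- x$mitocarta_summary
  cat("  MitoCarta-absent genes (group-1 WES): ", fmt_frac(ms$absent),
      "\n", sep = "")
  invisible(x)
}
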