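# mtDNA stage: point-variant calling with heteroplasmy, large-deletion
# breakpoint detection from junction reads, copy-number depletion, and
# classification of the stage outcome.

#' Call mtDNA point variants with heteroplasmy levels
#'
#' Heteroplasmy at a position is the read depth of the mutant allele over
#' the total depth. A call passes the cut-off when its heteroplasmy is at
#' least `cutoff_known` (default 2%) for alleles present in the
#' known-pathogenic table and at least `cutoff_other` (default 5%) for
#' all remaining positions and small indels; both cut-offs are inclusive.
#' Positions inside the hypervariable D-loop are excluded from calling.
#' Sites with zero total depth are skipped with a warning.
#'
#' @param pileup tibble with columns `pos`, `ref`, `allele`, `count`; one
#'   row per observed allele per position (the reference allele included),
#'   rCRS 1-based coordinates
#' @param known known-pathogenic lookup, see [known_pathogenic_table()]
#' @param cutoff_known inclusive heteroplasmy cut-off for known
#'   pathogenic alleles
#' @param cutoff_other inclusive cut-off for all other alleles
#' @param dloop integer positions excluded from calling
#' @return tibble of calls: `pos`, `ref`, `alt`, `depth`, `heteroplasmy`,
#'   `known_pathogenic`, `label`, `passed_cutoff`
#' @export
call_point_variants <- function(pileup, known = known_pathogenic_table(),
                                cutoff_known = 0.02, cutoff_other = 0.05,
                                dloop = dloop_positions()) {
  empty <- tibble::tibble(pos = integer(), ref = character(),
                          alt = character(), depth = integer(),
                          heteroplasmy = double(),
                          known_pathogenic = logical(), label = character(),
                          passed_cutoff = logical())
  if (nrow(pileup) == 0) return(empty)
  stopifnot(all(pileup$pos >= 1), all(pileup$pos <= MT_GENOME_LENGTH))

  in_dloop <- pileup$pos %in% dloop
  if (any(in_dloop)) {
    message("excluded ", length(unique(pileup$pos[in_dloop])),
            " D-loop position(s) from calling")
    pileup <- pileup[!in_dloop, , drop = FALSE]
  }
  if (nrow(pileup) == 0) return(empty)

  totals <- stats::aggregate(count ~ pos, data = pileup, FUN = sum)
  zero <- totals$pos[totals$count == 0]
  if (length(zero) > 0) {
    warning("skipping ", length(zero), " site(s) with zero depth")
    pileup <- pileup[!pileup$pos %in% zero, , drop = FALSE]
    totals <- totals[!totals$pos %in% zero, , drop = FALSE]
  }

  alt <- pileup[pileup$allele != pileup$ref & pileup$count > 0, , drop = FALSE]
  if (nrow(alt) == 0) return(empty)
  depth <- totals$count[match(alt$pos, totals$pos)]
  key <- paste(alt$pos, alt$ref, alt$allele)
  kidx <- match(key, paste(known$position, known$ref, known$alt))
  h <- alt$count / depth
  calls <- tibble::tibble(
    pos = alt$pos, ref = alt$ref, alt = alt$allele,
    depth = as.integer(depth), heteroplasmy = h,
    known_pathogenic = !is.na(kidx),
    label = ifelse(is.na(kidx), NA_character_, known$label[kidx]),
    passed_cutoff = ifelse(!is.na(kidx), h >= cutoff_known,
                           h >= cutoff_other)
  )
  calls[order(calls$pos, calls$alt), , drop = FALSE]
}

# Longest common prefix length between a read (from offset `from`) and the
# reference string starting at `at` (both 1-based).
match_extent <- function(read_raw, ref_raw, from, at, forward = TRUE) {
  n <- 0L
  if (forward) {
    lim <- min(length(read_raw) - from, length(ref_raw) - at) + 1L
    while (n < lim && read_raw[from + n] == ref_raw[at + n]) n <- n + 1L
  } else {
    lim <- min(from, at)
    while (n < lim && read_raw[from - n] == ref_raw[at - n]) n <- n + 1L
  }
  n
}

# Left-align a junction on the reference: shifting the junction one base
# left is valid while the retained 5' base equals the last deleted base.
leftmost_junction <- function(ref_raw, b5, b3) {
  while (b5 >= 1 && ref_raw[b5] == ref_raw[b3 - 1L]) {
    b5 <- b5 - 1L
    b3 <- b3 - 1L
  }
  c(b5, b3)
}

place_junction <- function(read, reference, ref2_str, ref2_raw, min_anchor) {
  L <- nchar(read)
  if (L < 2L * min_anchor) return(NULL)
  if (length(Biostrings::matchPattern(read, ref2_str)) > 0) return(NULL)
  read_raw <- charToRaw(read)

  pre <- substr(read, 1, min_anchor)
  suf <- substr(read, L - min_anchor + 1, L)
  pre_hits <- Biostrings::start(Biostrings::matchPattern(pre, ref2_str))
  suf_hits <- Biostrings::start(Biostrings::matchPattern(suf, ref2_str))
  if (length(pre_hits) == 0 || length(suf_hits) == 0) return(NULL)

  best <- NULL
  for (a in pre_hits) {
    pl <- min_anchor +
      match_extent(read_raw, ref2_raw, min_anchor + 1L, a + min_anchor)
    for (s0 in suf_hits) {
      e <- s0 + min_anchor - 1L   # end of the suffix anchor on the reference
      sl <- min_anchor +
        match_extent(read_raw, ref2_raw, L - min_anchor, s0 - 1L,
                     forward = FALSE)
      if (pl + sl < L) next
      j <- max(1L, L - sl)            # leftmost admissible split in the read
      if (j > pl) next
      b5 <- a + j - 1L
      b3 <- e + j + 1L - L
      if (b3 <= b5 + 1L) next         # no deleted bases
      cand <- list(b5 = b5, b3 = b3, score = pl + sl)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  bp <- leftmost_junction(ref2_raw, best$b5, best$b3)
  n <- nchar(reference)
  # reduce doubled-reference coordinates back to 1..n
  if (bp[1] > n) bp <- bp - n
  c(b5 = bp[1], b3 = bp[2])
}

#' Detect large mtDNA deletions from junction-spanning reads
#'
#' Places each read that does not align contiguously to the reference by
#' locally matching its 5' and 3' ends (anchors of at least `min_anchor`
#' nt, maximally extended), yielding the last retained base before the
#' deleted segment (`b5`) and the first retained base after it (`b3`).
#' Junctions flanked by direct repeats are ambiguous; they are reported
#' in their leftmost representation, and reads differing only by a
#' repeat shift merge into one event. Deletion size is `b3 - b5 - 1`.
#' Events supported by fewer than `min_support` reads are dropped.
#' The circular genome is handled by aligning against a doubled linear
#' reference; origin-spanning fragments are outside the contract.
#'
#' @param reads character vector of read sequences
#' @param reference mtDNA reference sequence (character string)
#' @param min_support minimum junction reads per reported event
#' @param min_anchor minimum exact anchor length on each side of the
#'   junction
#' @return tibble of events: `b5`, `b3`, `size`, `supporting_reads`,
#'   `single_or_multiple`
#' @export
detect_deletions <- function(reads, reference = synthetic_mt_reference(),
                             min_support = 3L, min_anchor = 20L) {
  empty <- tibble::tibble(b5 = integer(), b3 = integer(), size = integer(),
                          supporting_reads = integer(),
                          single_or_multiple = character())
  if (length(reads) == 0) return(empty)
  ref2_str <- paste0(reference, reference)
  ref2_raw <- charToRaw(ref2_str)
  hits <- lapply(sort(reads), place_junction, reference = reference,
                 ref2_str = ref2_str, ref2_raw = ref2_raw,
                 min_anchor = min_anchor)
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(hits) || nrow(hits) == 0) return(empty)

  key <- paste(hits[, "b5"], hits[, "b3"])
  tab <- table(key)
  keep <- names(tab)[tab >= min_support]
  if (length(keep) == 0) return(empty)
  bp <- do.call(rbind, strsplit(keep, " "))
  out <- tibble::tibble(
    b5 = as.integer(bp[, 1]), b3 = as.integer(bp[, 2]),
    supporting_reads = as.integer(tab[keep])
  )
  out$size <- out$b3 - out$b5 - 1L
  out <- out[order(out$b5, out$b3), c("b5", "b3", "size",
                                      "supporting_reads")]
  out$single_or_multiple <- if (nrow(out) > 1) "multiple" else "single"
  out
}

#' Assess mtDNA copy number against healthy controls
#'
#' Normalises the mitochondrial target quantity (ND1) to the nuclear
#' target (B2M) and expresses the patient's mt/nuclear ratio as a
#' percentage of the control mean ratio. Depletion is called when that
#' percentage falls below `threshold` (default 35%, chosen to capture
#' patients at 10-30% of controls).
#'
#' @param record patient tibble with columns `mt_nd1`, `nuc_b2m`
#' @param controls control tibble with the same columns (at least one row)
#' @param threshold depletion threshold as percent of control mean
#' @return list with `ratio`, `percent_of_controls`, `depleted`
#' @export
assess_copy_number <- function(record, controls, threshold = 35) {
  if (nrow(controls) == 0) stop("empty control set", call. = FALSE)
  qty <- c(record$mt_nd1, record$nuc_b2m, controls$mt_nd1, controls$nuc_b2m)
  if (any(qty <= 0)) stop("non-positive qPCR quantity", call. = FALSE)
  ratio <- record$mt_nd1 / record$nuc_b2m
  ctrl_mean <- mean(controls$mt_nd1 / controls$nuc_b2m)
  percent <- ratio / ctrl_mean * 100
  list(ratio = ratio, percent_of_controls = percent,
       depleted = percent < threshold)
}

#' Classify the outcome of the mtDNA sequencing stage
#'
#' A passing known-pathogenic point variant solves the family at the
#' mtDNA stage. Otherwise, multiple distinct deletions or copy-number
#' depletion escalate the family to WES (suggestive of a nuclear mtDNA
#' maintenance defect), a single large deletion solves the family, and
#' anything else is negative (negative families also proceed to WES in
#' the cohort pipeline).
#'
#' @param calls output of [call_point_variants()]
#' @param deletions output of [detect_deletions()]
#' @param copy_number output of [assess_copy_number()], or NULL
#' @return list of class `mt_diagnosis` with `outcome` in
#'   `solved_point`, `solved_single_deletion`, `escalate_to_wes`,
#'   `negative`, plus the supporting calls
#' @export
classify_mt_findings <- function(calls, deletions, copy_number = NULL) {
  passing <- calls[calls$passed_cutoff & calls$known_pathogenic, ,
                   drop = FALSE]
  depleted <- !is.null(copy_number) && isTRUE(copy_number$depleted)
  outcome <-
    if (nrow(passing) > 0) "solved_point"
    else if (nrow(deletions) > 1 || depleted) "escalate_to_wes"
    else if (nrow(deletions) == 1) "solved_single_deletion"
    else "negative"
  primary <- if (nrow(passing) > 0) {
    passing[which.max(passing$heteroplasmy), , drop = FALSE]
  } else NULL
  structure(list(outcome = outcome, point_call = primary,
                 deletions = deletions, copy_number = copy_number),
            class = "mt_diagnosis")
}
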