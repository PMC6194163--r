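# Runs of homozygosity / hemizygosity from biallelic genotype tracks.

roh_empty <- function() {
  tibble::tibble(member_id = character(), chrom = character(),
                 start = double(), end = double(), length = double(),
                 n_markers = integer())
}

detect_roh_chrom <- function(pos, geno, cutoff, het_tolerance) {
  usable <- geno != "missing"        # missing calls do not break runs
  pos <- pos[usable]
  geno <- geno[usable]
  n <- length(pos)
  if (n == 0) return(NULL)
  is_het <- geno == "het"
  # maximal windows containing at most `het_tolerance` het calls:
  # two-pointer sweep; a window is maximal when it can be extended on
  # neither side without exceeding the tolerance.
  out <- list()
  lo <- 1L
  hets <- 0L
  for (hi in seq_len(n)) {
    hets <- hets + is_het[hi]
    while (hets > het_tolerance) {
      hets <- hets - is_het[lo]
      lo <- lo + 1L
    }
    maximal <- hi == n || (hets + is_het[hi + 1L]) > het_tolerance
    if (maximal && lo <= hi) {
      len <- pos[hi] - pos[lo] + 1
      if (len >= cutoff) {
        out[[length(out) + 1]] <- c(start = pos[lo], end = pos[hi],
                                    n_markers = hi - lo + 1L)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Detect runs of homozygosity (and hemizygosity) in a genotype track
#'
#' Scans each member/chromosome track, sorted by position, for maximal
#' runs of non-heterozygous calls (allowing at most `het_tolerance`
#' heterozygous calls per run; missing calls neither break nor extend a
#' run) whose physical span between the first and last marker reaches
#' `cutoff` (default 5 Mb). Hemizygous calls count as homozygous, so X
#' tracks of males are handled transparently.
#'
#' @param track tibble with columns `chrom`, `pos`, `genotype` (values
#'   `hom_ref`, `hom_alt`, `het`, `hemi_ref`, `hemi_alt`, `missing`) and
#'   optionally `member_id`
#' @param cutoff minimum run length in bp
#' @param het_tolerance maximum heterozygous calls tolerated inside a run
#' @return tibble of regions: `member_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `length`, `n_markers`
#' @export
detect_roh <- function(track, cutoff = 5e6, het_tolerance = 0L) {
  if (is.null(track) || nrow(track) == 0) return(roh_empty())
  if (!"member_id" %in% names(track)) track$member_id <- "sample"
  out <- list()
  for (m in unique(track$member_id)) {
    tm <- track[track$member_id == m, , drop = FALSE]
    for (ch in unique(tm$chrom)) {
      tc <- tm[tm$chrom == ch, , drop = FALSE]
      if (is.unsorted(tc$pos, strictly = FALSE))
        stop("track not sorted by position on ", ch, " (", m, ")",
             call. = FALSE)
      runs <- detect_roh_chrom(tc$pos, tc$genotype, cutoff, het_tolerance)
      if (!is.null(runs)) {
        st <- unname(as.numeric(runs[, "start"]))
        en <- unname(as.numeric(runs[, "end"]))
        out[[length(out) + 1]] <- tibble::tibble(
          member_id = m, chrom = ch, start = st, end = en,
          length = en - st + 1,
          n_markers = as.integer(unname(runs[, "n_markers"])))
      }
    }
  }
  if (length(out) == 0) return(roh_empty())
  dplyr::bind_rows(out)
}

#' Write ROH regions as a BED file
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param regions output of [detect_roh()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_roh_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE,
                                 trim = TRUE),
                    name = regions$member_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
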