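# Mitochondrial disease criteria (MDC) scoring.

#' Compute the mitochondrial disease criteria score
#'
#' Sums the three MDC sections - clinical signs and symptoms, metabolic
#' abnormalities and neuroimaging, histologic anomalies - each capped at
#' 4 points, into a 0-12 total, and assigns the disease-likelihood bin:
#' total 1 = unlikely, 2-4 = possible, 5-7 = probable, 8-12 = definite
#' (a total of 0 also maps to unlikely, an extension for empty input).
#' Patients with a probable or definite mitochondrial disorder form
#' group 1; by default the group boundary is a total of at least
#' `group1_min` (5). The itemised symptom-to-point checklist is upstream
#' of this function; sections arrive as points.
#'
#' @param clinical clinical section points (0-4)
#' @param metabolic_imaging metabolic/neuroimaging section points (0-4)
#' @param histology histology section points (0-4)
#' @param group1_min minimum total score assigned to group 1
#' @return tibble with `clinical`, `metabolic_imaging`, `histology`,
#'   `total`, `bin`, `group` (vectorised over the inputs)
#' @export
score_mdc <- function(clinical, metabolic_imaging, histology,
                      group1_min = 5L) {
  sections <- cbind(clinical, metabolic_imaging, histology)
  if (any(is.na(sections)) || any(sections < 0))
    stop("MDC section scores must be non-negative", call. = FALSE)
  if (any(sections > 4)) {
    warning("MDC section scores above 4 capped at 4")
    sections <- pmin(sections, 4)
  }
  total <- as.integer(rowSums(sections))
  bin <- cut(total, breaks = c(-1, 1, 4, 7, 12),
             labels = c("unlikely", "possible", "probable", "definite"))
  tibble::tibble(clinical = sections[, 1],
                 metabolic_imaging = sections[, 2],
                 histology = sections[, 3],
                 total = total, bin = as.character(bin),
                 group = ifelse(total >= group1_min, 1L, 2L))
}
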