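# Synthetic cohort generator: per-family mtDNA read sets/pileups, qPCR
# copy-number records, SNP genotype tracks and exome variant tables, all
# driven by the planted truth in the cohort manifest.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. Defaults match the
#' study conditions the pipeline is validated against: 1000x mean mtDNA
#' depth, 300 nt reads (paired-end chemistry is not modelled beyond read
#' length), and a zero base-error rate so that cut-off decisions on the
#' packaged cohort are noise-free; the error rate can be raised for
#' robustness experiments.
#'
#' @param seed integer seed; together with the manifest it fully
#'   determines every generated byte
#' @param mt_depth mean mtDNA read depth at a site
#' @param read_length mtDNA read length in nt
#' @param base_error_rate per-base substitution error probability
#' @param background_variants_per_exome count of non-causal variants
#'   planted per family exome
#' @param n_junction_reads reads spanning each planted deletion junction
#' @param n_reference_reads ordinary (non-junction) mtDNA reads
#' @param marker_spacing SNP-track marker spacing in bp
#' @param chrom_length simulated chromosome length in bp
#' @param roh_length length of the embedded homozygous run in
#'   consanguineous families (bp)
#' @param n_controls qPCR control samples
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       mt_depth = 1000L,
                       read_length = 300L,
                       base_error_rate = 0,
                       background_variants_per_exome = 40L,
                       n_junction_reads = 50L,
                       n_reference_reads = 20L,
                       marker_spacing = 1e5,
                       chrom_length = 120e6,
                       roh_length = 8e6,
                       n_controls = 8L) {
  stopifnot(mt_depth > 0, read_length > 0, base_error_rate >= 0,
            base_error_rate < 1, background_variants_per_exome >= 0,
            n_junction_reads > 0, n_controls > 0)
  structure(list(seed = as.integer(seed), mt_depth = as.integer(mt_depth),
                 read_length = as.integer(read_length),
                 base_error_rate = base_error_rate,
                 background_variants_per_exome =
                   as.integer(background_variants_per_exome),
                 n_junction_reads = as.integer(n_junction_reads),
                 n_reference_reads = as.integer(n_reference_reads),
                 marker_spacing = marker_spacing,
                 chrom_length = chrom_length, roh_length = roh_length,
                 n_controls = as.integer(n_controls)),
            class = "sim_config")
}

parse_mt_variant <- function(vinfo) {
  parts <- strsplit(vinfo, ":")[[1]]
  if (parts[1] == "del") {
    list(type = "del", b5 = as.integer(parts[2]), b3 = as.integer(parts[3]))
  } else {
    list(type = "point", pos = as.integer(parts[1]), ref = parts[2],
         alt = parts[3], h = as.numeric(parts[4]))
  }
}

mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  vapply(reads, function(r) {
    s <- strsplit(r, "")[[1]]
    hit <- stats::runif(length(s)) < error_rate
    if (any(hit)) {
      s[hit] <- vapply(s[hit],
                       function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                       "")
    }
    paste(s, collapse = "")
  }, "", USE.NAMES = FALSE)
}

junction_reads <- function(ref, b5, b3, n, read_length, error_rate = 0) {
  if (b5 < 1 || b3 > MT_GENOME_LENGTH || b5 >= b3)
    stop("invalid breakpoints (", b5, ", ", b3, ")", call. = FALSE)
  ref2 <- paste0(ref, ref)  # circular contract: doubled linear sequence
  anchor <- 25L
  j <- sample(seq(anchor, read_length - anchor), n, replace = TRUE)
  reads <- vapply(j, function(jj) {
    paste0(substr(ref2, b5 - jj + 1, b5),
           substr(ref2, b3, b3 + (read_length - jj) - 1))
  }, "")
  mutate_reads(reads, error_rate)
}

reference_reads <- function(ref, n, read_length, error_rate = 0) {
  ref2 <- paste0(ref, ref)
  starts <- sample.int(MT_GENOME_LENGTH, n, replace = TRUE)
  reads <- vapply(starts, function(s) substr(ref2, s, s + read_length - 1), "")
  mutate_reads(reads, error_rate)
}

#' Simulate the mtDNA sequencing data of one family
#'
#' Emulates the aligned output of deep mtDNA sequencing according to the
#' family's planted defect. Point variants are emitted as a pileup in
#' which each read covering the site carries the alternate allele with
#' probability equal to the planted heteroplasmy (binomial sampling at
#' the configured depth). Deletions are emitted as unaligned
#' junction-spanning reads that concatenate the reference up to the 5'
#' breakpoint with the reference from the 3' breakpoint, so the deletion
#' caller must place the breakpoints itself; families flagged with a
#' multiple-deletion signature receive reads from two distinct junctions.
#' Depletion families produce normal reads (copy-number loss is carried
#' by the qPCR record, not the read set).
#'
#' @param family one manifest row
#' @param cfg a [sim_config()]
#' @param reference mtDNA reference sequence (character string)
#' @return list with `pileup` (tibble: pos, ref, allele, count), `reads`
#'   (character vector), and `truth` (the planted description)
#' @export
generate_mt_reads <- function(family, cfg = sim_config(),
                              reference = synthetic_mt_reference()) {
  seed <- string_seed(cfg$seed, paste0(family$family_id, ":mt"))
  cats <- family$categories[[1]]
  mtsig <- family$mt_signature
  with_seed(seed, {
    pileup <- tibble::tibble(pos = integer(), ref = character(),
                             allele = character(), count = integer())
    reads <- character(0)
    truth <- list(points = list(), deletions = list())

    planted_pos <- if ("mt_point" %in% cats)
      parse_mt_variant(family$variant_info)$pos else integer(0)
    # a few reference-only decoy positions so empty calls are exercised
    decoy <- sort(sample(setdiff(600:16000, planted_pos), 5))
    for (p in decoy) {
      pileup <- tibble::add_row(pileup, pos = p,
                                ref = substr(reference, p, p),
                                allele = substr(reference, p, p),
                                count = cfg$mt_depth)
    }

    if ("mt_point" %in% cats) {
      v <- parse_mt_variant(family$variant_info)
      if (v$h < 0 || v$h > 1)
        stop("heteroplasmy outside [0,1]: ", v$h, call. = FALSE)
      depth <- cfg$mt_depth
      alt_n <- stats::rbinom(1, depth, v$h)
      pileup <- tibble::add_row(pileup, pos = v$pos, ref = v$ref,
                                allele = v$ref, count = depth - alt_n)
      pileup <- tibble::add_row(pileup, pos = v$pos, ref = v$ref,
                                allele = v$alt, count = alt_n)
      truth$points <- list(v)
    }
    dels <- list()
    if ("mt_single_deletion" %in% cats) {
      v <- parse_mt_variant(family$variant_info)
      dels <- list(c(v$b5, v$b3))
    }
    if (identical(mtsig, "multiple_deletions") ||
        "mt_multiple_deletions" %in% cats) {
      dels <- list(c(6465L, 13999L), c(7816L, 14561L))
    }
    if (length(dels) > 0) {
      for (bp in dels) {
        reads <- c(reads, junction_reads(reference, bp[1], bp[2],
                                         cfg$n_junction_reads,
                                         cfg$read_length,
                                         cfg$base_error_rate))
      }
      reads <- c(reads, reference_reads(reference, cfg$n_reference_reads,
                                        cfg$read_length,
                                        cfg$base_error_rate))
      truth$deletions <- dels
    }
    list(pileup = pileup, reads = reads, truth = truth)
  })
}

#' Simulate a qPCR mtDNA copy-number record
#'
#' Produces mitochondrial-target (ND1) and nuclear-target (B2M)
#' quantities for the patient and a set of healthy controls. Families
#' with a depletion signature are drawn at 10-30% of the control mean
#' mt/nuclear ratio; all other families sit near 100%.
#'
#' @inheritParams generate_mt_reads
#' @return list with tibbles `patient` and `controls`
#'   (columns: sample, mt_nd1, nuc_b2m)
#' @export
generate_qpcr <- function(family, cfg = sim_config()) {
  seed <- string_seed(cfg$seed, paste0(family$family_id, ":qpcr"))
  depleted <- identical(family$mt_signature, "depletion") ||
    "mt_depletion" %in% family$categories[[1]]
  with_seed(seed, {
    ctrl_ratio <- pmax(0.5, stats::rnorm(cfg$n_controls, 1, 0.05))
    controls <- tibble::tibble(sample = sprintf("CTRL%02d",
                                                seq_len(cfg$n_controls)),
                               nuc_b2m = 100,
                               mt_nd1 = 100 * 100 * ctrl_ratio)
    factor <- if (depleted) stats::runif(1, 0.10, 0.30)
              else pmax(0.5, stats::rnorm(1, 1, 0.05))
    patient <- tibble::tibble(sample = family$family_id, nuc_b2m = 100,
                              mt_nd1 = 100 * 100 * mean(ctrl_ratio) * factor)
    list(patient = patient, controls = controls)
  })
}

# Baseline per-chromosome genotype vector: homozygous background with
# heterozygous markers every 20-45 markers (2-4.5 Mb), guaranteeing that
# no background run reaches the 5 Mb cutoff.
baseline_chrom_track <- function(n_markers) {
  g <- sample(c("hom_ref", "hom_alt"), n_markers, replace = TRUE,
              prob = c(0.7, 0.3))
  i <- sample(20:45, 1)
  while (i <= n_markers) {
    g[i] <- "het"
    i <- i + sample(20:45, 1)
  }
  g
}

#' Simulate SNP genotype tracks for homozygosity mapping
#'
#' Builds per-member biallelic genotype tracks over a simplified genome
#' (two surveyed autosomes per family, markers every 100 kb by default).
#' Affected members of consanguineous families receive one embedded
#' homozygous run of at least the configured length; when the family
#' carries a homozygous causal variant the run is centred on that locus,
#' otherwise it is placed on a locus-free chromosome (compound
#' heterozygotes in consanguineous families legitimately fall outside
#' ROH). Every family additionally gets a decoy homozygous run just
#' under 5 Mb, and non-consanguineous families carry only sub-cutoff
#' runs.
#'
#' @inheritParams generate_mt_reads
#' @return tibble with columns `member_id`, `chrom`, `pos`, `genotype`
#' @export
generate_genotype_track <- function(family, cfg = sim_config()) {
  seed <- string_seed(cfg$seed, paste0(family$family_id, ":track"))
  members <- family_members(family)
  affected <- members$member_id[members$affected]
  gm <- nuclear_gene_map()
  cats <- family$categories[[1]]
  genes <- family$genes[[1]]
  hom_idx <- which(cats == "nuclear_AR_hom")
  causal <- if (length(hom_idx) > 0) {
    gm[gm$gene == genes[hom_idx[1]], ]
  } else NULL

  run_chrom <- if (!is.null(causal)) causal$chrom else "chr2"
  run_center <- if (!is.null(causal)) causal$tss else 54e6
  other_chrom <- if (run_chrom == "chr5") "chr6" else "chr5"
  positions <- seq(cfg$marker_spacing, cfg$chrom_length,
                   by = cfg$marker_spacing)

  with_seed(seed, {
    out <- list()
    for (m in affected) {
      for (chrom in c(run_chrom, other_chrom)) {
        g <- baseline_chrom_track(length(positions))
        if (chrom == run_chrom && family$consanguineous) {
          inside <- positions >= run_center - cfg$roh_length / 2 &
            positions <= run_center + cfg$roh_length / 2
          g[inside] <- sample(c("hom_ref", "hom_alt"), sum(inside),
                              replace = TRUE)
          if (!is.null(causal)) {
            # the causal homozygous locus sits inside the run
            g[inside & abs(positions - run_center) < cfg$marker_spacing] <-
              "hom_alt"
          }
        }
        if (chrom == other_chrom) {
          # decoy run just below the cutoff: 48 markers = 4.7 Mb span
          st <- 300L
          g[st - 1L] <- "het"
          g[st + 48L] <- "het"
          g[st:(st + 47L)] <- sample(c("hom_ref", "hom_alt"), 48,
                                     replace = TRUE)
        }
        out[[length(out) + 1]] <- tibble::tibble(member_id = m, chrom = chrom,
                                                 pos = positions, genotype = g)
      }
    }
    dplyr::bind_rows(out)
  })
}

plant_genotypes <- function(vid, category, members, x_linked,
                            origin = "father") {
  father <- members$member_id[is.na(members$father) & members$sex == "M"]
  mother <- members$member_id[is.na(members$father) & members$sex == "F"]
  kids <- members[members$affected, ]
  g <- stats::setNames(rep("hom_ref", nrow(members)), members$member_id)
  if (x_linked) {
    g[members$member_id[members$sex == "M"]] <- "hemi_ref"
  }
  gt_carrier <- function(sex) if (x_linked && sex == "M") "hemi_alt" else "het"
  switch(category,
    nuclear_AR_hom = {
      g[kids$member_id] <- "hom_alt"
      g[father] <- "het"; g[mother] <- "het"
    },
    nuclear_XLR = {
      if (!any(kids$sex == "M"))
        stop("X-linked recessive defect requires a male affected",
             call. = FALSE)
      g[kids$member_id] <- ifelse(kids$sex == "M", "hemi_alt", "hom_alt")
      g[mother] <- "het"
    },
    nuclear_AD_denovo = ,
    nuclear_XLD_denovo = {
      g[kids$member_id] <- mapply(gt_carrier, kids$sex)
    },
    nuclear_AD_inherited = {
      g[kids$member_id] <- mapply(gt_carrier, kids$sex)
      parent <- if (origin == "father") father else mother
      g[parent] <- gt_carrier(members$sex[members$member_id == parent])
    },
    comphet_paternal = {
      g[kids$member_id] <- "het"
      g[father] <- "het"
    },
    comphet_maternal = {
      g[kids$member_id] <- "het"
      g[mother] <- "het"
    },
    stop("unhandled genotype category ", category, call. = FALSE)
  )
  g[!members$available] <- "missing"
  tibble::tibble(variant_id = vid, member_id = names(g),
                 genotype = unname(g))
}

planted_variant_row <- function(vid, gene, gm_row, offset, effect, pop_af,
                                inhouse_af, acmg_class, mitocarta, omim) {
  damaging <- if (effect == "missense") c(TRUE, TRUE, TRUE, FALSE)
              else c(FALSE, FALSE, FALSE, FALSE)
  tibble::tibble(
    variant_id = vid, gene = gene, chrom = gm_row$chrom,
    pos = gm_row$tss + offset, ref = "C", alt = "T", effect = effect,
    pop_af = pop_af, inhouse_af = inhouse_af,
    dmg_polyphen = damaging[1], dmg_sift = damaging[2],
    dmg_provean = damaging[3], dmg_mtaster = damaging[4],
    acmg_class = acmg_class, mitocarta = mitocarta, omim_ad = omim,
    planted = TRUE
  )
}

#' Simulate the annotated exome variant table of one family
#'
#' Plants the family's causal variants with annotations that survive the
#' filter cascade (population allele frequency below 1% or absent,
#' in-house frequency at most 5%, a retained effect class or damaging
#' missense predictions, ACMG class 4/5) and genotypes that segregate
#' with disease under the planted inheritance model: homozygous
#' recessive variants are homozygous in all affecteds with carrier
#' parents, compound-heterozygous pairs place one variant on each
#' parental haplotype, X-linked recessive variants are hemizygous in
#' affected males, and de novo dominant variants are absent from both
#' parents. Background variants are generated so the cascade removes
#' them: common alleles, benign-predicted missense, synonymous changes,
#' or non-annotated variants over the in-house 5% rule, all with ACMG
#' class below 4.
#'
#' @inheritParams generate_mt_reads
#' @return list with `variants` (annotation tibble), `genotypes` (long
#'   tibble: variant_id, member_id, genotype), `members` (pedigree
#'   tibble) and `truth`
#' @export
generate_wes_variants <- function(family, cfg = sim_config()) {
  seed <- string_seed(cfg$seed, paste0(family$family_id, ":wes"))
  members <- family_members(family)
  cats <- family$categories[[1]]
  genes <- family$genes[[1]]
  gm <- nuclear_gene_map()
  mito <- mitocarta_panel()
  omim <- omim_ad_panel()
  nuclear_cats <- cats[grepl("^nuclear_", cats)]
  if (length(nuclear_cats) > 0 && length(genes) != length(nuclear_cats))
    stop("family ", family$family_id, ": genes/categories mismatch",
         call. = FALSE)

  with_seed(seed, {
    variants <- list()
    genotypes <- list()
    vno <- 0L
    new_vid <- function() {
      vno <<- vno + 1L
      sprintf("%s_v%02d", family$family_id, vno)
    }
    effects <- c("missense", "nonsense", "frameshift", "splice")

    for (k in seq_along(nuclear_cats)) {
      cat_k <- nuclear_cats[k]
      gene <- genes[k]
      gm_row <- gm[gm$gene == gene, ]
      if (nrow(gm_row) == 0)
        stop("gene ", gene, " missing from the synthetic gene map",
             call. = FALSE)
      x_linked <- gm_row$chrom == "chrX"
      if (cat_k %in% c("nuclear_XLR", "nuclear_XLD_denovo") && !x_linked)
        stop("category ", cat_k, " planted in autosomal gene ", gene,
             call. = FALSE)
      cls <- if (k %% 2 == 0) 4L else 5L
      if (cat_k == "nuclear_AR_comphet") {
        v1 <- new_vid(); v2 <- new_vid()
        variants[[length(variants) + 1]] <- planted_variant_row(
          v1, gene, gm_row, 101, effects[(k - 1) %% 4 + 1],
          pop_af = 5e-4, inhouse_af = 0.001, cls, gene %in% mito,
          gene %in% omim)
        variants[[length(variants) + 1]] <- planted_variant_row(
          v2, gene, gm_row, 501, effects[k %% 4 + 1],
          pop_af = NA_real_, inhouse_af = 0.01, cls, gene %in% mito,
          gene %in% omim)
        genotypes[[length(genotypes) + 1]] <-
          plant_genotypes(v1, "comphet_paternal", members, x_linked)
        genotypes[[length(genotypes) + 1]] <-
          plant_genotypes(v2, "comphet_maternal", members, x_linked)
      } else {
        vid <- new_vid()
        variants[[length(variants) + 1]] <- planted_variant_row(
          vid, gene, gm_row, 101, effects[(k - 1) %% 4 + 1],
          pop_af = 5e-4, inhouse_af = 0.001, cls, gene %in% mito,
          gene %in% omim)
        genotypes[[length(genotypes) + 1]] <-
          plant_genotypes(vid, cat_k, members, x_linked,
                          origin = if (family$subclinical_parent == "mother")
                            "mother" else "father")
      }
    }

    # background variants, all removable by the frequency/effect filters
    universe <- background_gene_universe()
    n_bg <- cfg$background_variants_per_exome
    if (n_bg > 0) {
      bg_genes <- universe[sample.int(nrow(universe), n_bg), ]
      for (b in seq_len(n_bg)) {
        vid <- new_vid()
        type <- (b - 1) %% 5
        row <- switch(as.character(type),
          "0" = planted_variant_row(vid, bg_genes$gene[b], list(
            chrom = bg_genes$chrom[b], tss = bg_genes$tss[b]), 200 + b,
            "missense", pop_af = stats::runif(1, 0.02, 0.4),
            inhouse_af = 0.1, 2L, FALSE, FALSE),
          "1" = planted_variant_row(vid, bg_genes$gene[b], list(
            chrom = bg_genes$chrom[b], tss = bg_genes$tss[b]), 200 + b,
            "missense", pop_af = 0.003, inhouse_af = 0.002, 2L, FALSE,
            FALSE),
          "2" = planted_variant_row(vid, bg_genes$gene[b], list(
            chrom = bg_genes$chrom[b], tss = bg_genes$tss[b]), 200 + b,
            "synonymous", pop_af = 0.004, inhouse_af = 0.002, 2L, FALSE,
            FALSE),
          "3" = planted_variant_row(vid, bg_genes$gene[b], list(
            chrom = bg_genes$chrom[b], tss = bg_genes$tss[b]), 200 + b,
            "missense", pop_af = NA_real_, inhouse_af = 0.07, 2L, FALSE,
            FALSE),
          "4" = planted_variant_row(vid, bg_genes$gene[b], list(
            chrom = bg_genes$chrom[b], tss = bg_genes$tss[b]), 200 + b,
            "frameshift", pop_af = 0.15, inhouse_af = 0.12, 2L, FALSE,
            FALSE))
        row$planted <- FALSE
        # benign missense backgrounds: clear the damaging flags
        if (type == 1 || type == 3) {
          row$dmg_polyphen <- row$dmg_sift <- row$dmg_provean <-
            row$dmg_mtaster <- FALSE
        }
        variants[[length(variants) + 1]] <- row
        origin <- if (b %% 2 == 0) "comphet_paternal" else "comphet_maternal"
        genotypes[[length(genotypes) + 1]] <-
          plant_genotypes(vid, origin, members, FALSE)
      }
    }

    variants <- dplyr::bind_rows(variants)
    genotypes <- dplyr::bind_rows(genotypes)
    list(variants = variants, genotypes = genotypes, members = members,
         truth = list(categories = nuclear_cats, genes = genes))
  })
}

#' Generate every synthetic input of one family
#'
#' Convenience bundle of the four per-family generators.
#'
#' @inheritParams generate_mt_reads
#' @return list with elements `mt`, `qpcr`, `track` (NULL for
#'   non-consanguineous families) and `wes`
#' @export
simulate_family_inputs <- function(family, cfg = sim_config(),
                                   reference = synthetic_mt_reference()) {
  list(mt = generate_mt_reads(family, cfg, reference),
       qpcr = generate_qpcr(family, cfg),
       track = if (family$consanguineous)
         generate_genotype_track(family, cfg) else NULL,
       wes = generate_wes_variants(family, cfg))
}
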