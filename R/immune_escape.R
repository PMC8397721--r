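#' Call HLA loss of heterozygosity from binned allele coverage
#'
#' For each sample x HLA gene, estimates allele-specific copy number from the
#' mean linear copy ratio corrected for purity
#' (\code{cn = (ratio - (1 - purity)) / purity}) and tests the per-bin log2
#' copy-ratio difference between the two alleles with a paired two-sided
#' t test. LOH is called when the minor allele copy number falls below
#' \code{cn_cut} (default 0.5) AND the allele difference is significant at
#' \code{p_cut} (default 0.01); the lost allele is the one with the smaller
#' estimated copy number.
#'
#' @param hla_coverage Bin-level table (see [simulate_hla_coverage()] /
#'   [read_hla_coverage()]) with columns \code{sample}, \code{hla_gene},
#'   \code{allele1}, \code{allele2}, \code{logr_allele1},
#'   \code{logr_allele2}; >= 5 bins per gene.
#' @param metadata Sample metadata with \code{sample} and \code{purity}.
#' @param cn_cut Minor-allele copy-number threshold.
#' @param p_cut Significance threshold for the paired t test.
#' @return \code{data.frame} per sample x gene: \code{cn_allele1},
#'   \code{cn_allele2}, \code{minor_cn}, \code{p_value}, \code{is_loh},
#'   \code{lost_allele}.
#' @export
call_hla_loh <- function(hla_coverage, metadata, cn_cut = 0.5, p_cut = 0.01) {
  req <- c("sample", "hla_gene", "logr_allele1", "logr_allele2")
  miss <- setdiff(req, names(hla_coverage))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  groups <- split(hla_coverage,
                  list(hla_coverage$sample, hla_coverage$hla_gene), drop = TRUE)
  out <- lapply(groups, function(g) {
    if (nrow(g) < 5) stop("need >= 5 coverage bins per HLA gene (sample ",
                          g$sample[1], ", gene ", g$hla_gene[1], ")")
    purity <- metadata$purity[match(g$sample[1], metadata$sample)]
    if (is.na(purity)) stop("no purity for sample ", g$sample[1])
    cn_hat <- function(logr) {
      ratio <- mean(2^logr)
      max((ratio - (1 - purity)) / purity, 0)
    }
    cn1 <- cn_hat(g$logr_allele1)
    cn2 <- cn_hat(g$logr_allele2)
    p <- stats::t.test(g$logr_allele1, g$logr_allele2, paired = TRUE)$p.value
    minor <- min(cn1, cn2)
    is_loh <- minor < cn_cut && p < p_cut
    lost <- NA_character_
    if (is_loh) {
      lost <- if (cn1 <= cn2) g$allele1[1] else g$allele2[1]
    }
    data.frame(sample = g$sample[1], hla_gene = g$hla_gene[1],
               cn_allele1 = cn1, cn_allele2 = cn2, minor_cn = minor,
               p_value = p, is_loh = is_loh, lost_allele = lost,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' HLA-LOH incidence across a cohort
#'
#' A patient is positive when any of their considered samples carries an LOH
#' call in any HLA gene.
#'
#' @param loh_calls Output of [call_hla_loh()].
#' @param metadata Sample metadata with \code{sample}, \code{patient} and
#'   \code{lesion}.
#' @param lesion Restrict to one lesion ("primary"/"metastasis") or
#'   \code{NULL} for any sample.
#' @return List: \code{percent} (0-100), \code{positive}, \code{total}.
#' @export
loh_incidence <- function(loh_calls, metadata, lesion = NULL) {
  md <- metadata[metadata$lesion != "normal", , drop = FALSE]
  if (!is.null(lesion)) md <- md[md$lesion == lesion, , drop = FALSE]
  patients <- unique(md$patient)
  if (length(patients) == 0) stop("no patients in metadata")
  calls <- loh_calls[loh_calls$sample %in% md$sample, , drop = FALSE]
  pos_samples <- unique(calls$sample[calls$is_loh])
  pos <- unique(md$patient[md$sample %in% pos_samples])
  list(percent = 100 * length(pos) / length(patients),
       positive = length(pos), total = length(patients))
}

#' Depth-based neoantigen variant filter
#'
#' Two rules: (1) discard records whose matched-normal coverage is at or
#' below \code{normal_cov_cutoff} while the normal VAF reaches
#' \code{normal_vaf_cutoff} (likely germline leakage; the coverage cutoff can
#' be raised to 20x for stricter germline exclusion); (2) retain only records
#' with tumor depth >= \code{tumor_cov_cutoff} and tumor VAF >=
#' \code{tumor_vaf_cutoff}. Idempotent.
#'
#' @param records Neoantigen candidate table with columns
#'   \code{dna_normal_depth}, \code{dna_normal_vaf}, \code{dna_tumor_depth},
#'   \code{dna_tumor_vaf}.
#' @param normal_cov_cutoff Normal-coverage rule threshold (default 5; may
#'   be raised up to \code{strict_normal_cov}).
#' @param normal_vaf_cutoff Normal VAF threshold (default 0.02).
#' @param tumor_cov_cutoff Minimum tumor depth (default 10).
#' @param tumor_vaf_cutoff Minimum tumor VAF (default 0.40).
#' @param strict_normal_cov Upper bound documented for the normal-coverage
#'   rule (20x).
#' @return The retained rows.
#' @export
depth_filter_variants <- function(records, normal_cov_cutoff = 5,
                                  normal_vaf_cutoff = 0.02,
                                  tumor_cov_cutoff = 10,
                                  tumor_vaf_cutoff = 0.40,
                                  strict_normal_cov = 20) {
  if (normal_cov_cutoff > strict_normal_cov) {
    stop("normal_cov_cutoff may be raised at most to ", strict_normal_cov, "x")
  }
  germline_leak <- records$dna_normal_depth <= normal_cov_cutoff &
    records$dna_normal_vaf >= normal_vaf_cutoff
  tumor_ok <- records$dna_tumor_depth >= tumor_cov_cutoff &
    records$dna_tumor_vaf >= tumor_vaf_cutoff
  records[!germline_leak & tumor_ok, , drop = FALSE]
}

#' Neoantigen expression call from RNA read support
#'
#' A neoantigen is expressed when at least \code{min_depth} RNA-seq reads map
#' to the mutation site and at least \code{min_alt} of them carry the mutant
#' base. Missing RNA data gives \code{NA} (unknown).
#'
#' @param rna_site_depth RNA reads mapped at the mutation site.
#' @param rna_alt_reads RNA reads carrying the mutated base.
#' @param min_depth,min_alt Read-support thresholds (defaults 5 and 3).
#' @return Logical vector (NA where RNA data are missing).
#' @export
call_expressed <- function(rna_site_depth, rna_alt_reads,
                           min_depth = 5, min_alt = 3) {
  ifelse(is.na(rna_site_depth) | is.na(rna_alt_reads), NA,
         rna_site_depth >= min_depth & rna_alt_reads >= min_alt)
}

#' Per-sample neoantigen summary and expression-depletion correlation
#'
#' Tabulates clonal/subclonal x expressed/non-expressed neoantigen counts per
#' sample and computes the Pearson correlation, across samples, between the
#' total number of neoantigens and the number of non-expressed ones.
#' Records with unknown expression status are excluded from the expression
#' denominators.
#'
#' @param records Neoantigen table with columns \code{sample},
#'   \code{clonality} and \code{expressed} (logical, NA = unknown).
#' @return List: \code{counts} (per-sample \code{data.frame}) and
#'   \code{correlation} (list with \code{r}, \code{p_value}; \code{r} is
#'   \code{NA} with fewer than 3 samples or zero variance).
#' @export
neoantigen_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    return(list(counts = data.frame(sample = character(0), total = integer(0),
                                    clonal = integer(0), subclonal = integer(0),
                                    expressed = integer(0), non_expressed = integer(0),
                                    clonal_expressed = integer(0),
                                    subclonal_expressed = integer(0)),
                correlation = list(r = NA_real_, p_value = NA_real_)))
  }
  by_sample <- split(records, records$sample)
  counts <- do.call(rbind, lapply(by_sample, function(g) {
    known <- g[!is.na(g$expressed), , drop = FALSE]
    data.frame(
      sample = g$sample[1],
      total = nrow(g),
      clonal = sum(g$clonality == "clonal"),
      subclonal = sum(g$clonality == "subclonal"),
      expressed = sum(known$expressed),
      non_expressed = sum(!known$expressed),
      clonal_expressed = sum(known$expressed & known$clonality == "clonal"),
      subclonal_expressed = sum(known$expressed & known$clonality == "subclonal"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(counts) <- NULL
  corr <- list(r = NA_real_, p_value = NA_real_)
  if (nrow(counts) >= 3 && stats::sd(counts$total) > 0 &&
      stats::sd(counts$non_expressed) > 0) {
    ct <- stats::cor.test(counts$total, counts$non_expressed)
    corr <- list(r = unname(ct$estimate), p_value = ct$p.value)
  }
  list(counts = counts, correlation = corr)
}

#' Tumor mutational burden with HLA-LOH correction
#'
#' Reports, per sample, the raw mutation count, its clonal/subclonal split,
#' and an HLA-corrected count that discounts mutations whose entire set of
#' predicted presenting alleles (neoantigen binders at
#' \code{binding_rank <= binder_rank_cutoff}) is lost to HLA-LOH in that
#' sample — such mutations can no longer yield presentable neoantigens.
#' Mutations without any binder are unaffected by the correction.
#'
#' @param mutations CCF-annotated mutation table (needs \code{sample} and
#'   \code{clonality}).
#' @param neoantigens Neoantigen table with \code{sample},
#'   \code{variant_key}, \code{hla_allele}, \code{binding_rank}.
#' @param loh_calls Output of [call_hla_loh()].
#' @param binder_rank_cutoff Percentile rank defining a binder (default 2,
#'   the standard weak-binder convention).
#' @param capture_mb Optional capture size in megabases; when given, per-Mb
#'   TMB columns are added (53 Mb matches a whole-exome capture).
#' @return \code{data.frame} per sample: \code{tmb_total}, \code{tmb_clonal},
#'   \code{tmb_subclonal}, \code{tmb_hla_corrected} (+ per-Mb columns when
#'   \code{capture_mb} is given).
#' @export
hla_corrected_tmb <- function(mutations, neoantigens = NULL, loh_calls = NULL,
                              binder_rank_cutoff = 2, capture_mb = NULL) {
  lost_by_sample <- list()
  if (!is.null(loh_calls) && nrow(loh_calls)) {
    lost <- loh_calls[loh_calls$is_loh, , drop = FALSE]
    lost_by_sample <- split(lost$lost_allele, lost$sample)
  }
  out <- do.call(rbind, lapply(split(mutations, mutations$sample), function(m) {
    sample_id <- m$sample[1]
    key <- paste(m$chrom, m$pos, m$ref, m$alt, sep = ":")
    n_removed <- 0L
    if (!is.null(neoantigens) && nrow(neoantigens)) {
      neo <- neoantigens[neoantigens$sample == sample_id &
                           neoantigens$binding_rank <= binder_rank_cutoff, ,
                         drop = FALSE]
      if (nrow(neo)) {
        lost_alleles <- lost_by_sample[[sample_id]]
        if (!is.null(lost_alleles)) {
          all_lost <- tapply(neo$hla_allele %in% lost_alleles, neo$variant_key, all)
          removed_keys <- names(all_lost)[all_lost]
          n_removed <- sum(key %in% removed_keys)
        }
      }
    }
    res <- data.frame(
      sample = sample_id,
      tmb_total = nrow(m),
      tmb_clonal = sum(m$clonality == "clonal"),
      tmb_subclonal = sum(m$clonality == "subclonal"),
      tmb_hla_corrected = nrow(m) - n_removed,
      stringsAsFactors = FALSE
    )
    res
  }))
  rownames(out) <- NULL
  if (!is.null(capture_mb)) {
    for (col in c("tmb_total", "tmb_clonal", "tmb_subclonal", "tmb_hla_corrected")) {
      out[[paste0(col, "_per_mb")]] <- out[[col]] / capture_mb
    }
  }
  out
}
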