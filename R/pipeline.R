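#' Pipeline configuration
#'
#' Thresholds used across the stages, each documented at its operation:
#' see [classify_clonality()], [estimate_ccf()], [arm_level_call()],
#' [call_hla_loh()], [hla_corrected_tmb()], [call_expressed()] and
#' [filter_low_purity()].
#'
#' @param min_purity Sample exclusion floor (default 0.20).
#' @param ci_cut Clonal CI-bound threshold (default 0.95).
#' @param clonal_mass_min \code{NULL} for the two-component clonal
#'   probability, or a tail-mass threshold in (0, 1).
#' @param amp_cut,del_cut Arm-level log2 thresholds (+/- 0.2).
#' @param scna_clonal_cut Arm-event CCF threshold for clonality (0.9).
#' @param loh_cn_cut,loh_p_cut HLA-LOH thresholds (0.5, 0.01).
#' @param binder_rank_cutoff Neoantigen binder rank cutoff (2).
#' @param neo_normal_cov_cutoff,neo_normal_vaf_cutoff,neo_tumor_cov_cutoff,neo_tumor_vaf_cutoff
#'   Neoantigen depth-screen thresholds (5x / 2\% / 10x / 40\%); note the
#'   40\% tumor-VAF screen presumes near-clonal VAFs at high purity — at
#'   purity 0.6 a clonal heterozygous diploid mutation peaks at VAF 0.3, so
#'   moderate-purity cohorts should lower it deliberately.
#' @param expr_min_depth,expr_min_alt Expression read cutoffs (5, 3).
#' @param min_recurrent_samples Recurrence floor for pattern genes (2).
#' @param seed Seed recorded in the run manifest.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(min_purity = 0.20, ci_cut = 0.95,
                            clonal_mass_min = NULL,
                            amp_cut = 0.2, del_cut = -0.2,
                            scna_clonal_cut = 0.9,
                            loh_cn_cut = 0.5, loh_p_cut = 0.01,
                            binder_rank_cutoff = 2,
                            neo_normal_cov_cutoff = 5,
                            neo_normal_vaf_cutoff = 0.02,
                            neo_tumor_cov_cutoff = 10,
                            neo_tumor_vaf_cutoff = 0.40,
                            expr_min_depth = 5, expr_min_alt = 3,
                            min_recurrent_samples = 2, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full paired-cohort analysis
#'
#' Chains the stages on a cohort (simulated or read from disk):
#' low-purity sample exclusion, CCF estimation and clonality, SNV and
#' arm-level evolution patterns, per-patient maximum-parsimony trees,
#' HLA-LOH calls, neoantigen expression and HLA-corrected TMB, and cohort
#' summaries. When \code{out_dir} is given, all result tables, Newick trees
#' and a JSON run manifest (config and seed) are written there.
#'
#' @param cohort A \code{paired_cohort} (see [simulate_cohort()],
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with \code{mutations} (CCF-annotated), \code{patterns},
#'   \code{pattern_proportions}, \code{arm_patterns}, \code{trees},
#'   \code{loh_calls}, \code{loh_incidence}, \code{neoantigens},
#'   \code{neoantigen_summary}, \code{tmb}, \code{excluded_samples}.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (is.null(cohort$mutations) || nrow(cohort$mutations) == 0) {
    stop("empty cohort: no mutation calls")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. purity filter
  md <- stage("filter_low_purity",
              filter_low_purity(cohort$metadata, config$min_purity, quiet = TRUE))
  excluded <- attr(md, "excluded")
  keep <- cohort$mutations$sample %in% md$sample
  mutations <- cohort$mutations[keep, , drop = FALSE]

  # 2. CCF + clonality
  mutations <- stage("ccf_clonality",
                     annotate_ccf(mutations,
                                  clonal_mass_min = config$clonal_mass_min))

  # 3. SNV patterns (patients with both lesions retained)
  both <- names(which(tapply(md$lesion[md$lesion != "normal"], md$patient[md$lesion != "normal"],
                             function(l) all(c("primary", "metastasis") %in% l))))
  pat_mut <- mutations[mutations$patient %in% both, , drop = FALSE]
  patterns <- stage("evolution_patterns", cohort_pattern_table(pat_mut))
  props <- do.call(rbind, lapply(split(patterns, patterns$patient), function(p)
    data.frame(patient = p$patient[1], t(pattern_proportions(p)),
               stringsAsFactors = FALSE)))
  rownames(props) <- NULL

  # 4. arm-level patterns
  arm_patterns <- stage("arm_patterns", do.call(rbind, lapply(both, function(pt) {
    sp <- md$sample[md$patient == pt & md$lesion == "primary"]
    sm <- md$sample[md$patient == pt & md$lesion == "metastasis"]
    ap <- arm_pattern_table(
      cohort$segments[cohort$segments$sample == sp, , drop = FALSE],
      cohort$segments[cohort$segments$sample == sm, , drop = FALSE],
      md$purity[md$sample == sp], md$purity[md$sample == sm],
      amp_cut = config$amp_cut, del_cut = config$del_cut,
      clonal_cut = config$scna_clonal_cut)
    if (nrow(ap)) cbind(patient = pt, ap) else NULL
  })))

  # 5. phylogenies
  trees <- stage("phylogeny", lapply(stats::setNames(both, both), function(pt) {
    infer_parsimony_tree(build_matrix(
      mutations[mutations$patient == pt, , drop = FALSE]))
  }))

  # 6. immune escape
  loh_calls <- NULL; loh_inc <- NULL; neo <- NULL; neo_sum <- NULL
  if (!is.null(cohort$hla_coverage) && nrow(cohort$hla_coverage)) {
    hla <- cohort$hla_coverage[cohort$hla_coverage$sample %in% md$sample, ,
                               drop = FALSE]
    loh_calls <- stage("call_hla_loh",
                       call_hla_loh(hla, md, config$loh_cn_cut, config$loh_p_cut))
    loh_inc <- list(
      all = loh_incidence(loh_calls, md),
      primary = loh_incidence(loh_calls, md, "primary"),
      metastasis = loh_incidence(loh_calls, md, "metastasis"))
  }
  if (!is.null(cohort$neoantigens) && nrow(cohort$neoantigens)) {
    neo <- cohort$neoantigens[cohort$neoantigens$sample %in% md$sample, ,
                              drop = FALSE]
    neo <- stage("depth_filter", depth_filter_variants(
      neo, config$neo_normal_cov_cutoff, config$neo_normal_vaf_cutoff,
      config$neo_tumor_cov_cutoff, config$neo_tumor_vaf_cutoff))
    key <- paste(mutations$chrom, mutations$pos, mutations$ref, mutations$alt,
                 sep = ":")
    idx <- match(paste(neo$sample, neo$variant_key),
                 paste(mutations$sample, key))
    neo$clonality <- mutations$clonality[idx]
    neo$expressed <- call_expressed(neo$rna_site_depth, neo$rna_alt_reads,
                                    config$expr_min_depth, config$expr_min_alt)
    neo <- neo[!is.na(neo$clonality), , drop = FALSE]
    neo_sum <- stage("neoantigen_summary", neoantigen_summary(neo))
  }
  tmb <- stage("hla_corrected_tmb",
               hla_corrected_tmb(mutations, neo, loh_calls,
                                 config$binder_rank_cutoff))

  results <- list(mutations = mutations, patterns = patterns,
                  pattern_proportions = props, arm_patterns = arm_patterns,
                  trees = trees, loh_calls = loh_calls,
                  loh_incidence = loh_inc, neoantigens = neo,
                  neoantigen_summary = neo_sum, tmb = tmb,
                  excluded_samples = excluded)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(mutations, file.path(out_dir, "mutations_ccf.tsv"))
    .write_tsv(patterns, file.path(out_dir, "patterns.tsv"))
    .write_tsv(props, file.path(out_dir, "pattern_proportions.tsv"))
    if (!is.null(arm_patterns)) .write_tsv(arm_patterns, file.path(out_dir, "arm_patterns.tsv"))
    if (!is.null(loh_calls)) .write_tsv(loh_calls, file.path(out_dir, "hla_loh_calls.tsv"))
    if (!is.null(neo)) .write_tsv(neo, file.path(out_dir, "neoantigens_filtered.tsv"))
    .write_tsv(tmb, file.path(out_dir, "tmb_report.tsv"))
    for (pt in names(trees)) {
      writeLines(trees[[pt]]$newick, file.path(out_dir, paste0("tree_", pt, ".nwk")))
    }
    cfg <- config
    cfg$clonal_mass_min <- if (is.null(cfg$clonal_mass_min)) "two-component" else
      cfg$clonal_mass_min
    manifest <- list(
      package = "clonemet",
      version = as.character(utils::packageVersion("clonemet")),
      config = unclass(cfg),
      config_hash = substr(.manifest_hash(cfg), 1, 12),
      n_samples = nrow(md), excluded_samples = as.list(excluded))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}

.manifest_hash <- function(x) {
  f <- tempfile(); on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = ""), f)
  unname(tools::md5sum(f))
}
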