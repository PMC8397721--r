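#' Simulation configuration for a paired primary/metastasis cohort
#'
#' Bundles the knobs of the synthetic cohort generator. Defaults emulate the
#' study conditions downstream stages are validated against: 15 patients,
#' whole-exome read counts at a mean depth of 150x, tumor purity 0.6 in both
#' lesions, 20 coverage bins per HLA gene and RNA coverage at mutation sites.
#'
#' @param n_patients Number of patients (each contributes a primary and a
#'   metastasis sample plus a matched normal).
#' @param mean_depth Mean sequencing depth for DNA read counts (Poisson).
#' @param purity_primary,purity_metastasis Tumor purity per lesion, in (0, 1].
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical.
#' @param hla_bins Coverage bins per HLA gene (>= 5).
#' @param rna_mean_depth Mean RNA depth at expressed mutation sites.
#' @param rna_offtarget_depth Mean RNA depth at non-expressed sites.
#' @param p_cn3 Fraction of mutations placed on a 3-copy (2+1) locus.
#' @param p_neoantigen Probability a mutation yields a neoantigen candidate.
#' @param p_binder Probability a candidate is a binder (rank <= 2).
#' @param p_expressed Probability a mutation site is expressed in RNA
#'   (default 0.35: most neoantigen sites lack RNA support, reflecting the
#'   transcriptional depletion of neoantigens in these tumors).
#' @param p_hla_loh_primary,p_hla_loh_metastasis Per-patient probability of a
#'   true HLA-LOH event in the lesion (defaults follow the cohort incidences
#'   the pipeline is benchmarked on: 2/15 and 4/15).
#' @param burden_dispersion SD of the log-normal per-patient mutation-burden
#'   multiplier (default 0.5): tumor cohorts show wide inter-patient TMB
#'   variation, and clone mutation counts are scaled patient-wise by
#'   \code{exp(N(0, burden_dispersion))}. Set to 0 for identical burdens.
#' @param seg_log2_sd Gaussian noise SD on per-segment log2 ratios.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_patients = 15, mean_depth = 150,
                       purity_primary = 0.6, purity_metastasis = 0.6,
                       seed = 1L, hla_bins = 20, rna_mean_depth = 50,
                       rna_offtarget_depth = 2,
                       p_cn3 = 0.1, p_neoantigen = 0.35, p_binder = 0.5,
                       p_expressed = 0.35,
                       p_hla_loh_primary = 2 / 15,
                       p_hla_loh_metastasis = 4 / 15,
                       burden_dispersion = 0.5,
                       seg_log2_sd = 0.02) {
  stopifnot(n_patients >= 1, mean_depth > 0, hla_bins >= 5,
            purity_primary > 0, purity_primary <= 1,
            purity_metastasis > 0, purity_metastasis <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Default clone template
#'
#' One truncal clone (CCF 1 in both lesions) plus seven lesion-variable
#' clones chosen so that every primary-to-metastasis pattern label
#' (C-C, C-S, S-C, S-S, 0-C, 0-S, C-0, S-0) is represented — each downstream
#' classifier branch is exercised by every simulated patient.
#'
#' @return \code{data.frame} with columns \code{clone_id},
#'   \code{ccf_primary}, \code{ccf_metastasis}, \code{n_mutations}.
#' @export
default_clone_template <- function() {
  data.frame(
    clone_id = c("truncal", "cs", "sc", "ss", "zc", "zs", "cz", "sz"),
    ccf_primary    = c(1.0, 1.0, 0.30, 0.30, 0.0, 0.00, 1.0, 0.30),
    ccf_metastasis = c(1.0, 0.30, 1.0, 0.30, 1.0, 0.30, 0.0, 0.00),
    n_mutations = c(40L, 10L, 12L, 10L, 10L, 8L, 8L, 8L),
    stringsAsFactors = FALSE
  )
}

# clonality code used in ground truth and pattern labels: C / S / 0
.status_code <- function(status) c(clonal = "C", subclonal = "S", absent = "0")[status]

.true_status <- function(ccf) {
  ifelse(ccf == 0, "absent", ifelse(ccf >= 0.95, "clonal", "subclonal"))
}

#' Simulate read counts for one mutation in one sample
#'
#' Total depth is Poisson around the mean; alt reads are binomial at the
#' expected VAF implied by the CCF, purity, copy state and multiplicity
#' (see [expected_vaf()]). Uses the current RNG state.
#'
#' @inheritParams expected_vaf
#' @param depth Mean sequencing depth (Poisson parameter).
#' @return \code{list(alt =, total =)} integer read counts.
#' @export
simulate_reads <- function(ccf, purity, cn_tumor, cn_normal = 2,
                           multiplicity = 1, depth = 150) {
  stopifnot(ccf >= 0, ccf <= 1)
  if (multiplicity > cn_tumor || multiplicity < 1) {
    stop("multiplicity must lie in [1, cn_tumor]")
  }
  total <- stats::rpois(1, depth)
  vaf <- expected_vaf(ccf, purity, cn_tumor, cn_normal, multiplicity)
  list(alt = stats::rbinom(1, total, vaf), total = total)
}

#' Simulate binned allele-specific HLA coverage
#'
#' Per bin and per allele, tumor coverage is Poisson with mean proportional to
#' \code{purity * true_cn + (1 - purity)} (one copy per allele in
#' contaminating normal cells) and matched-normal coverage is Poisson at the
#' neutral one-copy level. Per-bin log2 copy ratios are computed against the
#' normal with a 0.5 pseudocount.
#'
#' @param true_cn_allele1,true_cn_allele2 True tumor copy number of each allele.
#' @param purity Tumor purity.
#' @param n_bins Number of coverage bins (>= 5).
#' @param depth Mean total depth over both alleles.
#' @return \code{data.frame} with one row per bin: coverage and log2 ratio
#'   per allele.
#' @export
simulate_hla_coverage <- function(true_cn_allele1, true_cn_allele2, purity,
                                  n_bins = 20, depth = 150) {
  stopifnot(n_bins >= 5)
  per_allele <- depth / 2
  lam1 <- per_allele * (purity * true_cn_allele1 + (1 - purity))
  lam2 <- per_allele * (purity * true_cn_allele2 + (1 - purity))
  t1 <- stats::rpois(n_bins, lam1)
  t2 <- stats::rpois(n_bins, lam2)
  n1 <- stats::rpois(n_bins, per_allele)
  n2 <- stats::rpois(n_bins, per_allele)
  data.frame(
    bin = seq_len(n_bins),
    tumor_cov_allele1 = t1, tumor_cov_allele2 = t2,
    normal_cov_allele1 = n1, normal_cov_allele2 = n2,
    logr_allele1 = log2((t1 + 0.5) / (n1 + 0.5)),
    logr_allele2 = log2((t2 + 0.5) / (n2 + 0.5)),
    stringsAsFactors = FALSE
  )
}

# built-in gene pool: recurrently reported CRC/metastasis genes + filler
.gene_pool <- function(n_extra = 60) {
  core <- c("APC", "TP53", "KRAS", "SYNE1", "CACNA1H", "PCLO", "FBXL2",
            "DNAH11", "AXIN1", "AMER1", "TCF7L2", "KMT2D", "COL5A1", "HGF",
            "PIK3CA", "SMAD4", "FBXW7", "BRAF", "SOX9", "ARID1A")
  c(core, sprintf("GENE%03d", seq_len(n_extra)))
}

.random_base <- function(n, exclude = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(exclude)) return(sample(bases, n, replace = TRUE))
  vapply(exclude, function(b) sample(setdiff(bases, b), 1), character(1))
}

# default arm-event truth: recurrent colorectal arm aberrations spanning
# C-C, S-C and 0-C transitions
.default_arm_truth <- function() {
  data.frame(
    arm = c("8q", "17p", "20q"),
    direction = c("amp", "del", "amp"),
    delta_cn = c(1, -1, 1),
    ccf_primary = c(1.0, 0.30, 0.0),
    ccf_metastasis = c(1.0, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Simulate one patient's paired-lesion data
#'
#' Draws mutation read counts for both lesions from the clone specification,
#' arm-level copy-number segments, binned HLA allele coverage, RNA counts at
#' mutation sites and neoantigen candidates, together with the ground truth
#' that generated them. Uses the current RNG state; see [simulate_cohort()]
#' for seeded cohort-level generation.
#'
#' @param config A [sim_config()] object.
#' @param clones Clone specification \code{data.frame} (see
#'   [default_clone_template()]); must contain a truncal clone with CCF 1 in
#'   both lesions.
#' @param patient_id Patient identifier string.
#' @return A list with elements \code{mutations}, \code{segments},
#'   \code{hla_coverage}, \code{rna_counts}, \code{neoantigens},
#'   \code{metadata} and \code{truth}.
#' @export
simulate_patient <- function(config, clones = default_clone_template(),
                             patient_id = "P1") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(clones) || nrow(clones) == 0) stop("empty clone list")
  stopifnot(all(clones$ccf_primary >= 0 & clones$ccf_primary <= 1),
            all(clones$ccf_metastasis >= 0 & clones$ccf_metastasis <= 1),
            all(clones$n_mutations >= 0))
  if (!any(clones$ccf_primary == 1 & clones$ccf_metastasis == 1)) {
    stop("clone specification must include a truncal clone (CCF 1 in both lesions)")
  }

  # inter-patient mutation-burden variation (log-normal multiplier)
  if (config$burden_dispersion > 0) {
    scale <- exp(stats::rnorm(1, 0, config$burden_dispersion))
    clones$n_mutations <- pmax(1L, as.integer(round(clones$n_mutations * scale)))
  }
  n_mut <- sum(clones$n_mutations)
  pool <- .gene_pool()
  genes <- sample(pool, n_mut, replace = TRUE)
  chroms <- as.character(sample(1:22, n_mut, replace = TRUE))
  pos <- sample.int(5e7, n_mut, replace = FALSE)
  ref <- .random_base(n_mut)
  alt <- .random_base(n_mut, exclude = ref)
  key <- paste(chroms, pos, ref, alt, sep = ":")
  clone_of <- rep(seq_len(nrow(clones)), clones$n_mutations)
  cn3 <- stats::runif(n_mut) < config$p_cn3
  cn_major <- ifelse(cn3, 2L, 1L)
  cn_minor <- rep(1L, n_mut)
  cn_tumor <- cn_major + cn_minor

  lesions <- c(primary = config$purity_primary,
               metastasis = config$purity_metastasis)
  samples <- stats::setNames(paste(patient_id, names(lesions), sep = "_"),
                             names(lesions))

  mut_rows <- list()
  for (lesion in names(lesions)) {
    purity <- lesions[[lesion]]
    ccf <- if (lesion == "primary") clones$ccf_primary[clone_of] else
      clones$ccf_metastasis[clone_of]
    present <- ccf > 0
    if (!any(present)) next
    idx <- which(present)
    total <- stats::rpois(length(idx), config$mean_depth)
    vaf <- expected_vaf(ccf[idx], purity, cn_tumor[idx], 2, 1)
    alt_n <- stats::rbinom(length(idx), total, vaf)
    called <- alt_n >= 1          # a caller cannot report a 0-alt site
    idx <- idx[called]
    mut_rows[[lesion]] <- data.frame(
      patient = patient_id, sample = samples[[lesion]], lesion = lesion,
      gene = genes[idx], chrom = chroms[idx], pos = pos[idx],
      ref = ref[idx], alt = alt[idx],
      t_alt = alt_n[called], t_depth = total[called],
      n_alt = 0L, n_depth = stats::rpois(sum(called), config$mean_depth),
      cn_major = cn_major[idx], cn_minor = cn_minor[idx],
      purity = purity, stringsAsFactors = FALSE
    )
  }
  mutations <- do.call(rbind, mut_rows)
  rownames(mutations) <- NULL

  # ground truth per mutation
  st_p <- .true_status(clones$ccf_primary[clone_of])
  st_m <- .true_status(clones$ccf_metastasis[clone_of])
  truth_mut <- data.frame(
    patient = patient_id, variant_key = key, gene = genes,
    clone_id = clones$clone_id[clone_of],
    ccf_primary = clones$ccf_primary[clone_of],
    ccf_metastasis = clones$ccf_metastasis[clone_of],
    status_primary = st_p, status_metastasis = st_m,
    pattern = paste(.status_code(st_p), .status_code(st_m), sep = "-"),
    stringsAsFactors = FALSE
  )

  # arm-level segments
  arms <- hg19_arms()
  arm_truth <- .default_arm_truth()
  seg_rows <- list()
  for (lesion in names(lesions)) {
    purity <- lesions[[lesion]]
    for (i in seq_len(nrow(arms))) {
      a <- arms[i, ]
      hit <- arm_truth[arm_truth$arm == a$arm, ]
      f <- 0; delta <- 0
      if (nrow(hit) == 1) {
        f <- if (lesion == "primary") hit$ccf_primary else hit$ccf_metastasis
        delta <- hit$delta_cn
      }
      ratio <- (purity * (2 + f * delta) + (1 - purity) * 2) / 2
      n_seg <- sample(2:4, 1)
      inner <- sort(a$start + sample.int(a$end - a$start - 1, n_seg - 1))
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        sample = samples[[lesion]], chrom = a$chrom,
        start = c(a$start, inner + 1), end = c(inner, a$end),
        log2_ratio = log2(ratio) + stats::rnorm(n_seg, 0, config$seg_log2_sd),
        cn_major = NA_integer_, cn_minor = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL

  # HLA coverage + LOH truth
  hla_genes <- c("A", "B", "C")
  loh_lesion <- c(primary = stats::runif(1) < config$p_hla_loh_primary,
                  metastasis = stats::runif(1) < config$p_hla_loh_metastasis)
  loh_gene <- sample(hla_genes, 1) # the affected gene, if any lesion has LOH
  hla_rows <- list(); hla_truth <- list()
  for (lesion in names(lesions)) {
    purity <- lesions[[lesion]]
    for (g in hla_genes) {
      is_loh <- loh_lesion[[lesion]] && g == loh_gene
      cn1 <- 1; cn2 <- if (is_loh) 0 else 1
      bins <- simulate_hla_coverage(cn1, cn2, purity, config$hla_bins,
                                    config$mean_depth)
      bins <- cbind(
        data.frame(patient = patient_id, sample = samples[[lesion]],
                   lesion = lesion, hla_gene = g,
                   allele1 = sprintf("HLA-%s*01", g),
                   allele2 = sprintf("HLA-%s*02", g),
                   stringsAsFactors = FALSE),
        bins)
      hla_rows[[length(hla_rows) + 1]] <- bins
      hla_truth[[length(hla_truth) + 1]] <- data.frame(
        patient = patient_id, sample = samples[[lesion]], lesion = lesion,
        hla_gene = g, is_loh = is_loh,
        lost_allele = if (is_loh) sprintf("HLA-%s*02", g) else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  hla_coverage <- do.call(rbind, hla_rows)
  rownames(hla_coverage) <- NULL

  # RNA counts at mutation sites, per tumor sample
  expressed <- stats::runif(n_mut) < config$p_expressed
  rna_rows <- list()
  for (lesion in names(lesions)) {
    ml <- mutations[mutations$lesion == lesion, ]
    if (nrow(ml) == 0) next
    k <- match(paste(ml$chrom, ml$pos, ml$ref, ml$alt, sep = ":"), key)
    expr <- expressed[k]
    depth <- stats::rpois(nrow(ml), ifelse(expr, config$rna_mean_depth,
                                           config$rna_offtarget_depth))
    vaf <- ifelse(expr, ml$t_alt / pmax(ml$t_depth, 1), 0)
    rna_rows[[lesion]] <- data.frame(
      patient = patient_id, sample = ml$sample,
      variant_key = key[k],
      rna_depth = depth, rna_alt = stats::rbinom(nrow(ml), depth, vaf),
      true_expressed = expr, stringsAsFactors = FALSE
    )
  }
  rna_counts <- do.call(rbind, rna_rows)
  rownames(rna_counts) <- NULL

  # neoantigen candidates: subset of mutations, one peptide/allele each
  neo_idx <- which(stats::runif(n_mut) < config$p_neoantigen)
  neo_rows <- list()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (length(neo_idx)) {
    peptide <- vapply(neo_idx, function(i)
      paste(sample(aa, 9, replace = TRUE), collapse = ""), character(1))
    allele <- paste0("HLA-", sample(hla_genes, length(neo_idx), replace = TRUE),
                     "*0", sample(1:2, length(neo_idx), replace = TRUE))
    binder <- stats::runif(length(neo_idx)) < config$p_binder
    rank <- ifelse(binder, stats::runif(length(neo_idx), 0.01, 2),
                   stats::runif(length(neo_idx), 2.01, 50))
    for (lesion in names(lesions)) {
      ml <- mutations[mutations$lesion == lesion, ]
      mk <- paste(ml$chrom, ml$pos, ml$ref, ml$alt, sep = ":")
      j <- match(key[neo_idx], mk)
      keep <- !is.na(j)
      if (!any(keep)) next
      rl <- rna_counts[rna_counts$sample == samples[[lesion]], ]
      rj <- match(key[neo_idx][keep], rl$variant_key)
      neo_rows[[lesion]] <- data.frame(
        patient = patient_id, sample = samples[[lesion]],
        variant_key = key[neo_idx][keep],
        peptide = peptide[keep], hla_allele = allele[keep],
        binding_rank = rank[keep],
        dna_normal_depth = ml$n_depth[j[keep]],
        dna_normal_vaf = ml$n_alt[j[keep]] / pmax(ml$n_depth[j[keep]], 1),
        dna_tumor_depth = ml$t_depth[j[keep]],
        dna_tumor_vaf = ml$t_alt[j[keep]] / pmax(ml$t_depth[j[keep]], 1),
        rna_site_depth = rl$rna_depth[rj],
        rna_alt_reads = rl$rna_alt[rj],
        stringsAsFactors = FALSE
      )
    }
  }
  neoantigens <- do.call(rbind, neo_rows)
  if (!is.null(neoantigens)) rownames(neoantigens) <- NULL

  metadata <- data.frame(
    patient = patient_id, sample = samples, lesion = names(lesions),
    purity = unname(lesions), stringsAsFactors = FALSE
  )
  rownames(metadata) <- NULL

  list(mutations = mutations, segments = segments,
       hla_coverage = hla_coverage, rna_counts = rna_counts,
       neoantigens = neoantigens, metadata = metadata,
       truth = list(mutations = truth_mut,
                    hla = do.call(rbind, hla_truth),
                    arms = cbind(patient = patient_id, arm_truth),
                    rna = rna_counts[, c("sample", "variant_key", "true_expressed")]))
}

#' Simulate a full paired cohort with ground truth
#'
#' Generates \code{config$n_patients} patients from the clone template under
#' a fixed seed. Identical config and seed give byte-identical tables.
#'
#' @param config A [sim_config()] object.
#' @param clones Clone template applied to every patient.
#' @return A list of class \code{"paired_cohort"} with combined
#'   \code{mutations}, \code{segments}, \code{hla_coverage},
#'   \code{rna_counts}, \code{neoantigens}, \code{metadata} and \code{truth}
#'   tables.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 2, seed = 7))
#' head(cohort$mutations)
#' @export
simulate_cohort <- function(config = sim_config(),
                            clones = default_clone_template()) {
  set.seed(config$seed)
  patients <- lapply(seq_len(config$n_patients), function(i)
    simulate_patient(config, clones, patient_id = sprintf("P%d", i)))
  bind <- function(extract) {
    parts <- Filter(Negate(is.null), lapply(patients, extract))
    out <- do.call(rbind, parts); rownames(out) <- NULL; out
  }
  structure(list(
    mutations = bind(function(p) p$mutations),
    segments = bind(function(p) p$segments),
    hla_coverage = bind(function(p) p$hla_coverage),
    rna_counts = bind(function(p) p$rna_counts),
    neoantigens = bind(function(p) p$neoantigens),
    metadata = bind(function(p) p$metadata),
    truth = list(
      mutations = bind(function(p) p$truth$mutations),
      hla = bind(function(p) p$truth$hla),
      arms = bind(function(p) p$truth$arms),
      rna = bind(function(p) p$truth$rna)
    ),
    config = config
  ), class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("paired_cohort:", length(unique(x$metadata$patient)), "patients,",
      nrow(x$mutations), "mutation rows,",
      nrow(x$segments), "segments,",
      if (is.null(x$neoantigens)) 0 else nrow(x$neoantigens),
      "neoantigen candidates\n")
  invisible(x)
}
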