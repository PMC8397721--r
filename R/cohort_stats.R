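#' Half-up rounding to integer percent
#'
#' Display convention for cohort percentages: 36.7 prints as 37. The raw
#' fraction should always be retained alongside.
#'
#' @param x Percentage value(s).
#' @return Integer percent.
#' @export
percent_display <- function(x) floor(x + 0.5)

#' Mutational frequency of a gene across samples or patients
#'
#' @param mutations Mutation table (or any table with \code{gene} plus the
#'   chosen unit column).
#' @param gene Gene symbol.
#' @param unit Counting unit: each tumor sample once, or each patient once.
#' @param metadata Optional metadata giving the full denominator (units with
#'   zero mutations); defaults to the units present in \code{mutations}.
#' @return List: \code{percent} (0-100), \code{numerator},
#'   \code{denominator}.
#' @export
mutational_frequency <- function(mutations, gene, unit = c("sample", "patient"),
                                 metadata = NULL) {
  unit <- match.arg(unit)
  units_all <- if (!is.null(metadata)) {
    md <- metadata[metadata$lesion != "normal", , drop = FALSE]
    unique(md[[unit]])
  } else unique(mutations[[unit]])
  if (!gene %in% mutations$gene) {
    warning("gene '", gene, "' not present in any sample")
  }
  hit <- unique(mutations[[unit]][mutations$gene == gene])
  list(percent = 100 * length(hit) / length(units_all),
       numerator = length(hit), denominator = length(units_all))
}

#' Fraction of patients with at least one mutated gene in a set
#'
#' A patient counts once no matter how many genes of the set (or lesions)
#' are hit.
#'
#' @param mutations Mutation table with \code{patient} and \code{gene}.
#' @param gene_set Non-empty character vector of gene symbols.
#' @param metadata Optional metadata giving the full patient denominator.
#' @return List: \code{percent}, \code{numerator}, \code{denominator}.
#' @export
pathway_patient_frequency <- function(mutations, gene_set, metadata = NULL) {
  if (length(gene_set) == 0) stop("empty gene set")
  patients_all <- if (!is.null(metadata)) unique(metadata$patient) else
    unique(mutations$patient)
  hit <- unique(mutations$patient[mutations$gene %in% gene_set])
  list(percent = 100 * length(hit) / length(patients_all),
       numerator = length(hit), denominator = length(patients_all))
}

#' Two-group comparison with the cohort's standard tests
#'
#' Wilcoxon-Mann-Whitney for continuous values, Fisher's exact or chi-square
#' for categorical counts. All tests are two-sided.
#'
#' @param x For "wilcoxon": numeric values; for "fisher"/"chisq": a 2xK
#'   contingency matrix (then \code{group} is ignored).
#' @param group Group labels for the Wilcoxon test (exactly 2 non-empty
#'   groups).
#' @param test Which test to run.
#' @return List: \code{test}, \code{statistic}, \code{p_value}.
#' @export
group_compare <- function(x, group = NULL,
                          test = c("wilcoxon", "fisher", "chisq")) {
  test <- match.arg(test)
  if (test == "wilcoxon") {
    g <- factor(group)
    if (nlevels(g) != 2 || any(table(g) == 0)) {
      stop("wilcoxon needs exactly 2 non-empty groups")
    }
    res <- suppressWarnings(
      stats::wilcox.test(x[g == levels(g)[1]], x[g == levels(g)[2]]))
    list(test = "wilcoxon", statistic = unname(res$statistic),
         p_value = res$p.value)
  } else {
    if (!is.matrix(x)) stop(test, " needs a contingency matrix")
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
      stop("degenerate contingency table (empty margin)")
    }
    if (test == "fisher") {
      res <- stats::fisher.test(x)
      list(test = "fisher", statistic = NA_real_, p_value = res$p.value)
    } else {
      res <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
      list(test = "chisq", statistic = unname(res$statistic),
           p_value = res$p.value)
    }
  }
}

#' Worked-example cohort tally
#'
#' A small deterministic 15-patient, 30-tumor-sample cohort summary used in
#' the documentation examples and the reproduction script: per-sample gene
#' hits arranged so that the WNT pathway genes (APC, AXIN1, AMER1, TCF7L2,
#' KMT2D) are mutated in 12/15 patients, the HGF/MET pathway genes (KRAS,
#' COL5A1, HGF) in 9/15 patients, SYNE1 in 11/30 samples (metastasis-only in
#' P5, P11 and P15), and per-patient HLA-LOH flags giving incidences of 2/15
#' in primaries, 4/15 in metastases and 4/15 overall.
#'
#' @return List: \code{mutations} (patient, sample, lesion, gene),
#'   \code{metadata}, \code{loh} (sample-level \code{is_loh} flags).
#' @export
example_cohort_tally <- function() {
  patients <- sprintf("P%d", 1:15)
  metadata <- do.call(rbind, lapply(patients, function(p) data.frame(
    patient = p, sample = paste(p, c("primary", "metastasis"), sep = "_"),
    lesion = c("primary", "metastasis"), purity = 0.6,
    stringsAsFactors = FALSE)))

  rows <- list()
  add <- function(p, lesion, gene) {
    rows[[length(rows) + 1]] <<- data.frame(
      patient = p, sample = paste(p, lesion, sep = "_"), lesion = lesion,
      gene = gene, stringsAsFactors = FALSE)
  }
  wnt <- c("APC", "AXIN1", "AMER1", "TCF7L2", "KMT2D")
  hgf_met <- c("KRAS", "COL5A1", "HGF")
  # WNT genes hit in patients P1..P12 (12/15)
  for (i in 1:12) add(patients[i], "primary", wnt[(i - 1) %% 5 + 1])
  # HGF/MET genes hit in P1..P9 (9/15)
  for (i in 1:9) add(patients[i], "primary", hgf_met[(i - 1) %% 3 + 1])
  # SYNE1 in 11/30 samples: both lesions of P1..P4, metastasis-only P5, P11, P15
  for (i in 1:4) { add(patients[i], "primary", "SYNE1"); add(patients[i], "metastasis", "SYNE1") }
  for (i in c(5, 11, 15)) add(patients[i], "metastasis", "SYNE1")
  mutations <- do.call(rbind, rows)

  # HLA-LOH flags: primaries of P1, P2; metastases of P1, P2, P3, P4
  loh <- data.frame(sample = metadata$sample, stringsAsFactors = FALSE)
  loh$is_loh <- loh$sample %in% c("P1_primary", "P2_primary",
                                  "P1_metastasis", "P2_metastasis",
                                  "P3_metastasis", "P4_metastasis")
  list(mutations = mutations, metadata = metadata, loh = loh)
}
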