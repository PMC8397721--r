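#' Match somatic mutations across paired lesions
#'
#' Joins one patient's primary and metastasis mutation tables on the variant
#' key \code{chrom:pos:ref:alt} (position-based, robust to annotation
#' differences in gene symbols). Each distinct variant appears exactly once;
#' a variant present in both lesions is shared, otherwise private to the
#' lesion carrying it.
#'
#' @param primary,metastasis Mutation tables for the two lesions of one
#'   patient (see [read_mutation_table()] for the layout); CCF/clonality
#'   columns from [annotate_ccf()] are carried over when present.
#' @return \code{data.frame} of paired variants: \code{variant_key},
#'   \code{gene}, \code{status_primary}, \code{status_metastasis} in
#'   \{absent, subclonal, clonal\} (or \code{"present"} when clonality has
#'   not been annotated), \code{ccf_primary}, \code{ccf_metastasis} and
#'   \code{shared}.
#' @export
match_mutations <- function(primary, metastasis) {
  key_of <- function(x) if (nrow(x)) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":") else character(0)
  kp <- key_of(primary); km <- key_of(metastasis)
  if (anyDuplicated(kp)) stop("duplicate variant keys in primary sample: ",
                              paste(unique(kp[duplicated(kp)]), collapse = ", "))
  if (anyDuplicated(km)) stop("duplicate variant keys in metastasis sample: ",
                              paste(unique(km[duplicated(km)]), collapse = ", "))
  status_of <- function(x) if ("clonality" %in% names(x)) x$clonality else
    rep("present", nrow(x))
  ccf_of <- function(x) if ("ccf_hat" %in% names(x)) x$ccf_hat else
    rep(NA_real_, nrow(x))

  keys <- union(kp, km)
  ip <- match(keys, kp); im <- match(keys, km)
  gene <- ifelse(!is.na(ip), primary$gene[ip], metastasis$gene[im])
  out <- data.frame(
    variant_key = keys, gene = gene,
    status_primary = ifelse(is.na(ip), "absent", status_of(primary)[ip]),
    status_metastasis = ifelse(is.na(im), "absent", status_of(metastasis)[im]),
    ccf_primary = ifelse(is.na(ip), NA_real_, ccf_of(primary)[ip]),
    ccf_metastasis = ifelse(is.na(im), NA_real_, ccf_of(metastasis)[im]),
    stringsAsFactors = FALSE
  )
  out$shared <- out$status_primary != "absent" & out$status_metastasis != "absent"
  out
}

#' Primary-to-metastasis clonal evolution pattern label
#'
#' Encodes the per-lesion clonality statuses as C (clonal), S (subclonal) and
#' 0 (absent) and concatenates them: e.g. subclonal in the primary and clonal
#' in the metastasis is "S-C"; absent in the primary and clonal in the
#' metastasis is "0-C".
#'
#' @param status_primary,status_metastasis Per-lesion statuses in
#'   \{clonal, subclonal, absent\}. Vectorized.
#' @return Character vector of labels among C-C, C-S, S-C, S-S, 0-C, 0-S,
#'   C-0, S-0.
#' @export
classify_pattern <- function(status_primary, status_metastasis) {
  ok <- c("clonal", "subclonal", "absent")
  if (!all(status_primary %in% ok) || !all(status_metastasis %in% ok)) {
    stop("statuses must be one of: ", paste(ok, collapse = ", "))
  }
  if (any(status_primary == "absent" & status_metastasis == "absent")) {
    stop("a variant cannot be absent in both lesions")
  }
  paste(.status_code(status_primary), .status_code(status_metastasis), sep = "-")
}

#' Shared / private mutation proportions for one patient
#'
#' @param pairs Paired-variant table from [match_mutations()].
#' @return Named numeric vector of fractions \code{shared},
#'   \code{primary_private}, \code{metastasis_private}; sums to 1.
#' @export
pattern_proportions <- function(pairs) {
  if (nrow(pairs) == 0) stop("empty paired-variant table")
  n <- nrow(pairs)
  c(shared = sum(pairs$shared) / n,
    primary_private = sum(pairs$status_metastasis == "absent") / n,
    metastasis_private = sum(pairs$status_primary == "absent") / n)
}

#' Rank genes by median CCF within a lesion
#'
#' A high median CCF marks an early (ancestral) event, a low one a late
#' event. Ties are broken lexicographically by gene symbol so the ranking is
#' stable.
#'
#' @param mutations CCF-annotated mutation table ([annotate_ccf()]).
#' @param lesion Lesion to rank within ("primary" or "metastasis").
#' @return \code{data.frame} with \code{gene}, \code{median_ccf},
#'   \code{n_mutations}, \code{rank}, sorted by descending median CCF.
#' @export
median_ccf_ranking <- function(mutations, lesion = c("primary", "metastasis")) {
  lesion <- match.arg(lesion)
  m <- mutations[mutations$lesion == lesion, , drop = FALSE]
  if (nrow(m) == 0) {
    return(data.frame(gene = character(0), median_ccf = numeric(0),
                      n_mutations = integer(0), rank = integer(0)))
  }
  med <- tapply(m$ccf_hat, m$gene, stats::median)
  out <- data.frame(gene = names(med), median_ccf = as.numeric(med),
                    n_mutations = as.integer(table(m$gene)[names(med)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$median_ccf, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Genes recurrently following a given evolution pattern
#'
#' @param cohort_patterns \code{data.frame} with columns \code{patient},
#'   \code{gene}, \code{pattern} — one row per paired variant (see
#'   [classify_pattern()]).
#' @param pattern Pattern label to query, e.g. "S-C".
#' @param min_samples Minimum number of patients in which the gene shows the
#'   pattern (default 2).
#' @return \code{data.frame} of genes with their patient counts, most
#'   recurrent first.
#' @export
recurrent_pattern_genes <- function(cohort_patterns, pattern, min_samples = 2) {
  hits <- cohort_patterns[cohort_patterns$pattern == pattern, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(gene = character(0), n_patients = integer(0)))
  }
  cnt <- tapply(hits$patient, hits$gene, function(p) length(unique(p)))
  out <- data.frame(gene = names(cnt), n_patients = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[out$n_patients >= min_samples, , drop = FALSE]
  out <- out[order(-out$n_patients, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Cohort pattern table across all patients
#'
#' Runs [match_mutations()] and [classify_pattern()] for each patient of a
#' CCF-annotated cohort mutation table.
#'
#' @param mutations CCF-annotated mutation table covering both lesions of
#'   every patient.
#' @return \code{data.frame}: one row per patient x variant with gene, per-
#'   lesion status/CCF and \code{pattern} — the data behind a CCF-CCF
#'   scatter of the two lesions.
#' @export
cohort_pattern_table <- function(mutations) {
  out <- lapply(split(mutations, mutations$patient), function(pm) {
    pairs <- match_mutations(pm[pm$lesion == "primary", , drop = FALSE],
                             pm[pm$lesion == "metastasis", , drop = FALSE])
    pairs$pattern <- classify_pattern(pairs$status_primary, pairs$status_metastasis)
    cbind(patient = pm$patient[1], pairs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail probability of observing at least the seen
#' overlap between a gene list and each gene set, within a fixed universe.
#' Genes outside the universe are dropped with a warning.
#'
#' @param genes Character vector, the query gene list.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of background genes (must contain the
#'   query list).
#' @return \code{data.frame} per set: overlap size, set size and P value.
#' @export
gene_set_enrichment <- function(genes, gene_sets, universe) {
  genes <- unique(genes)
  if (!all(genes %in% universe)) stop("gene list must be a subset of the universe")
  out <- lapply(names(gene_sets), function(nm) {
    set <- unique(gene_sets[[nm]])
    if (!all(set %in% universe)) {
      warning("gene set '", nm, "' not fully inside the universe; intersecting")
      set <- intersect(set, universe)
    }
    q <- length(intersect(genes, set))
    # P(X >= q) for X ~ Hypergeom(|set| in universe, draws = |genes|)
    p <- stats::phyper(q - 1, length(set), length(universe) - length(set),
                       length(genes), lower.tail = FALSE)
    data.frame(set = nm, overlap = q, set_size = length(set),
               n_query = length(genes), p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
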