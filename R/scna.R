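#' hg19 chromosome arm boundaries
#'
#' Autosome arm intervals (1-based inclusive) derived from the standard hg19
#' centromere coordinates; used to aggregate copy-number segments to arm
#' level.
#'
#' @return \code{data.frame} with columns \code{chrom}, \code{arm},
#'   \code{start}, \code{end}.
#' @export
hg19_arms <- function() {
  path <- system.file("extdata", "hg19_arms.tsv", package = "clonemet")
  utils::read.delim(path, colClasses = c(chrom = "character"))
}

#' Call arm-level copy-number events from a segment table
#'
#' For each chromosome arm, computes the segment-length-weighted mean log2
#' copy ratio over segments overlapping the arm and calls an amplification
#' when it reaches \code{amp_cut} (default +0.2), a deletion at
#' \code{del_cut} (default -0.2), neutral otherwise. Arms with no covered
#' bases are omitted.
#'
#' @param segments Segment \code{data.frame} for one sample with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{log2_ratio} (1-based
#'   inclusive intervals).
#' @param arms Arm definition table (default [hg19_arms()]).
#' @param amp_cut,del_cut Log2-ratio thresholds for amp/del calls.
#' @return \code{data.frame} with one row per covered arm: \code{arm},
#'   \code{mean_log2}, \code{direction} in \{amp, del, neutral\}.
#' @export
arm_level_call <- function(segments, arms = hg19_arms(),
                           amp_cut = 0.2, del_cut = -0.2) {
  stopifnot(all(c("chrom", "start", "end", "log2_ratio") %in% names(segments)))
  out <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    s <- segments[segments$chrom == a$chrom, , drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    ov_start <- pmax(s$start, a$start)
    ov_end <- pmin(s$end, a$end)
    w <- pmax(ov_end - ov_start + 1, 0)
    if (sum(w) == 0) return(NULL)
    m <- sum(w * s$log2_ratio) / sum(w)
    data.frame(arm = a$arm, mean_log2 = m,
               direction = if (m >= amp_cut) "amp" else
                 if (m <= del_cut) "del" else "neutral",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cancer cell fraction of an arm-level copy-number event
#'
#' Inverts the total-copy-ratio model for a single event of signed copy
#' change \code{delta_cn} on a diploid background:
#' \deqn{f = \frac{2^{log2ratio + 1} - 2}{purity \cdot \Delta cn}}
#' clamped to \[0, 1\]. Assumes one event per arm; exact at zero noise.
#'
#' @param mean_log2_ratio Arm-level mean log2 copy ratio.
#' @param purity Tumor purity in (0, 1].
#' @param delta_cn Signed copy change of the event (+1 single gain, -1 single
#'   loss, ...); must be non-zero.
#' @return Event CCF in \[0, 1\]. Vectorized.
#' @examples
#' scna_ccf(log2(3 / 2), purity = 1, delta_cn = 1)    # 1: fully clonal gain
#' scna_ccf(log2(2.5 / 2), purity = 1, delta_cn = 1)  # 0.5
#' @export
scna_ccf <- function(mean_log2_ratio, purity, delta_cn) {
  if (any(delta_cn == 0)) stop("delta_cn must be non-zero")
  if (any(purity <= 0)) stop("purity must be > 0")
  f <- (2^(mean_log2_ratio + 1) - 2) / (purity * delta_cn)
  pmin(pmax(f, 0), 1)
}

#' Arm-event clonality and paired-lesion pattern labels
#'
#' Calls arm events in both lesions of one patient, assigns each event a CCF
#' via [scna_ccf()] (single-event ratio inversion, +1 for amps, -1 for dels)
#' and a clonality status (clonal when CCF >= \code{clonal_cut}), then labels
#' the primary-to-metastasis transition with the same C/S/0 taxonomy used for
#' SNVs.
#'
#' @param segments_primary,segments_metastasis Per-lesion segment tables.
#' @param purity_primary,purity_metastasis Per-lesion tumor purity.
#' @param arms Arm definition table.
#' @param amp_cut,del_cut Arm-call thresholds, see [arm_level_call()].
#' @param clonal_cut CCF threshold for calling an arm event clonal.
#' @return \code{data.frame} with one row per arm aberrant in either lesion:
#'   direction, per-lesion CCF and status, and \code{pattern}.
#' @export
arm_pattern_table <- function(segments_primary, segments_metastasis,
                              purity_primary, purity_metastasis,
                              arms = hg19_arms(), amp_cut = 0.2,
                              del_cut = -0.2, clonal_cut = 0.9) {
  call_one <- function(segments, purity) {
    calls <- arm_level_call(segments, arms, amp_cut, del_cut)
    calls$scna_ccf <- ifelse(
      calls$direction == "neutral", 0,
      scna_ccf(calls$mean_log2, purity, ifelse(calls$direction == "amp", 1, -1)))
    calls$status <- ifelse(calls$direction == "neutral", "absent",
                           ifelse(calls$scna_ccf >= clonal_cut, "clonal", "subclonal"))
    calls
  }
  p <- call_one(segments_primary, purity_primary)
  m <- call_one(segments_metastasis, purity_metastasis)
  merged <- merge(p, m, by = "arm", suffixes = c("_primary", "_metastasis"))
  merged <- merged[merged$status_primary != "absent" |
                     merged$status_metastasis != "absent", , drop = FALSE]
  if (nrow(merged) == 0) return(cbind(merged, pattern = character(0)))
  # direction of the event: from whichever lesion carries it
  merged$direction <- ifelse(merged$direction_primary != "neutral",
                             merged$direction_primary, merged$direction_metastasis)
  merged$pattern <- classify_pattern(merged$status_primary, merged$status_metastasis)
  rownames(merged) <- NULL
  merged
}
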