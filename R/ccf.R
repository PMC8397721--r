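#' Expected variant allele fraction for a given cancer cell fraction
#'
#' Maps a cancer cell fraction (CCF) to the variant allele fraction (VAF)
#' expected in sequencing reads, given tumor purity, local tumor copy number,
#' normal copy number and mutation multiplicity:
#' \deqn{VAF = \frac{ccf \cdot purity \cdot m}{purity \cdot cn_{tumor} +
#'   (1 - purity) \cdot cn_{normal}}}
#'
#' @param ccf Cancer cell fraction in \[0, 1\].
#' @param purity Tumor purity (fraction of tumor cells in the specimen), in (0, 1\].
#' @param cn_tumor Total tumor copy number at the locus.
#' @param cn_normal Copy number in contaminating normal cells (2 for autosomes).
#' @param multiplicity Number of mutated copies per tumor cell (1..cn_tumor).
#' @return Expected VAF, a fraction in \[0, 1\]. Vectorized over all arguments.
#' @examples
#' expected_vaf(1, 1, 2, 2, 1)     # 0.5: pure diploid heterozygous clonal
#' expected_vaf(1, 0.5, 3, 2, 1)   # 0.2
#' @export
expected_vaf <- function(ccf, purity, cn_tumor, cn_normal = 2, multiplicity = 1) {
  denom <- purity * cn_tumor + (1 - purity) * cn_normal
  if (any(denom == 0)) stop("zero denominator: purity*cn_tumor + (1-purity)*cn_normal must be > 0")
  ccf * purity * multiplicity / denom
}

#' Estimate mutation multiplicity from observed read counts
#'
#' Inverts the VAF relation at CCF = 1 and rounds to the nearest integer copy,
#' clamped to \[1, cn_tumor\]. Assumes diploid contaminating normal cells.
#'
#' @param t_alt Tumor alt read count.
#' @param t_depth Tumor total depth at the site (> 0).
#' @param purity Tumor purity in (0, 1].
#' @param cn_tumor Total tumor copy number (>= 1).
#' @return Integer multiplicity in \[1, cn_tumor\]. Vectorized.
#' @export
estimate_multiplicity <- function(t_alt, t_depth, purity, cn_tumor) {
  if (any(t_depth <= 0)) stop("t_depth must be > 0")
  if (any(cn_tumor < 1)) stop("cn_tumor must be >= 1")
  vaf <- t_alt / t_depth
  m <- round(vaf * (purity * cn_tumor + (1 - purity) * 2) / purity)
  as.integer(pmin(pmax(m, 1), cn_tumor))
}

#' Posterior CCF estimate for one somatic mutation
#'
#' Computes a posterior over a uniform CCF grid \{0, 0.01, ..., 1\} with
#' binomial read-count likelihood
#' \code{Binom(t_alt | t_depth, expected_vaf(ccf, ...))} and a flat prior.
#' The point estimate is the posterior mode and the interval is the 95\%
#' highest-posterior-density (HPD) credible interval on the grid. An HPD
#' interval is used rather than an equal-tailed one because the CCF scale is
#' truncated at 1: for truly clonal mutations the posterior piles up at the
#' boundary and an equal-tailed interval sheds its upper tail there,
#' under-covering CCF = 1.
#'
#' The clonal probability \code{pr_clonal} is a two-component assignment
#' probability in the style of ABSOLUTE's \code{Pr_somatic_clonal}: the
#' mutation is either clonal (CCF exactly 1) or subclonal (CCF uniform on the
#' grid), with equal prior odds, and \code{pr_clonal} is the posterior
#' probability of the clonal component. Set \code{clonal_mass_min} to a value
#' in (0, 1) to use the simpler tail-mass convention
#' \code{Pr(ccf >= clonal_mass_min)} under the flat grid posterior instead.
#'
#' @param t_alt,t_depth Tumor alt and total read counts (t_depth > 0).
#' @param purity Tumor purity in (0, 1].
#' @param cn_tumor Total tumor copy number at the site.
#' @param cn_normal Normal-cell copy number (default 2, autosomes).
#' @param multiplicity Mutated copies per tumor cell; if \code{NULL} it is
#'   estimated with [estimate_multiplicity()].
#' @param grid_step CCF grid resolution (default 0.01).
#' @param clonal_mass_min \code{NULL} (default) for the two-component
#'   \code{pr_clonal}; otherwise the tail-mass threshold.
#' @return A one-row \code{data.frame} with columns \code{ccf_hat},
#'   \code{ccf_ci95_low}, \code{ccf_ci95_high}, \code{pr_clonal},
#'   \code{pr_subclonal}, \code{multiplicity}, \code{clonality}.
#' @examples
#' estimate_ccf(50, 100, purity = 1, cn_tumor = 2, multiplicity = 1)
#' @export
estimate_ccf <- function(t_alt, t_depth, purity, cn_tumor, cn_normal = 2,
                         multiplicity = NULL, grid_step = 0.01,
                         clonal_mass_min = NULL) {
  if (t_depth <= 0) stop("t_depth must be > 0")
  if (t_alt < 0 || t_alt > t_depth) stop("t_alt must lie in [0, t_depth]")
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (is.null(multiplicity)) {
    multiplicity <- estimate_multiplicity(t_alt, t_depth, purity, cn_tumor)
  }
  if (multiplicity < 1 || multiplicity > cn_tumor) {
    stop("multiplicity must lie in [1, cn_tumor]")
  }

  grid <- seq(0, 1, by = grid_step)
  vaf_grid <- pmin(expected_vaf(grid, purity, cn_tumor, cn_normal, multiplicity), 1)
  lik <- stats::dbinom(t_alt, t_depth, vaf_grid)
  if (sum(lik) == 0) { # deep underflow; fall back to log-likelihood shift
    ll <- stats::dbinom(t_alt, t_depth, vaf_grid, log = TRUE)
    lik <- exp(ll - max(ll))
  }
  post <- lik / sum(lik)

  ccf_hat <- grid[which.max(post)]
  # 95% HPD on the grid: highest-density points until 0.95 mass is reached
  ord <- order(post, decreasing = TRUE)
  k <- which(cumsum(post[ord]) >= 0.95)[1]
  ci_low <- grid[min(ord[1:k])]
  ci_high <- grid[max(ord[1:k])]

  if (is.null(clonal_mass_min)) {
    # two-component posterior: point mass at ccf = 1 vs uniform subclonal grid
    lik_clonal <- stats::dbinom(t_alt, t_depth,
                                min(expected_vaf(1, purity, cn_tumor, cn_normal, multiplicity), 1))
    lik_subclonal <- mean(lik)
    denom <- lik_clonal + lik_subclonal
    pr_clonal <- if (denom > 0) lik_clonal / denom else 0
  } else {
    pr_clonal <- sum(post[grid >= clonal_mass_min])
  }
  pr_subclonal <- 1 - pr_clonal

  out <- data.frame(
    ccf_hat = ccf_hat, ccf_ci95_low = ci_low, ccf_ci95_high = ci_high,
    pr_clonal = pr_clonal, pr_subclonal = pr_subclonal,
    multiplicity = as.integer(multiplicity),
    stringsAsFactors = FALSE
  )
  out$clonality <- classify_clonality(out$ccf_ci95_high, out$pr_clonal, out$pr_subclonal)
  out
}

#' Clonal/subclonal decision rule
#'
#' A mutation is clonal when the upper bound of its 95\% credible interval
#' reaches the clonal region (\code{ccf_ci95_high >= 0.95}, equivalently
#' >= 1 on the capped CCF scale) AND the clonal assignment probability
#' exceeds the subclonal one (\code{pr_clonal > pr_subclonal}); otherwise
#' subclonal.
#'
#' @param ccf_ci95_high Upper 95\% credible bound(s) of the CCF.
#' @param pr_clonal,pr_subclonal Clonal/subclonal assignment probabilities.
#' @param ci_cut CI-bound threshold (default 0.95).
#' @return Character vector, \code{"clonal"} or \code{"subclonal"}.
#' @export
classify_clonality <- function(ccf_ci95_high, pr_clonal,
                               pr_subclonal = 1 - pr_clonal, ci_cut = 0.95) {
  ifelse(ccf_ci95_high >= ci_cut & pr_clonal > pr_subclonal, "clonal", "subclonal")
}

#' Exclude low-purity samples
#'
#' Samples whose tumor cell purity is below the floor (default 20\%) are
#' removed from clonality analysis; the boundary value itself is retained.
#'
#' @param metadata \code{data.frame} with columns \code{sample} and
#'   \code{purity}.
#' @param min_purity Exclusion floor (default 0.20); strict "below".
#' @param quiet Suppress the exclusion message.
#' @return The retained rows; excluded sample names in attribute
#'   \code{"excluded"}.
#' @export
filter_low_purity <- function(metadata, min_purity = 0.20, quiet = FALSE) {
  stopifnot(is.data.frame(metadata), "purity" %in% names(metadata))
  if (anyNA(metadata$purity)) stop("missing purity for sample(s): ",
                                   paste(metadata$sample[is.na(metadata$purity)], collapse = ", "))
  drop <- metadata$purity < min_purity
  if (any(drop) && !quiet) {
    message("excluding ", sum(drop), " sample(s) with purity < ", min_purity, ": ",
            paste(metadata$sample[drop], collapse = ", "))
  }
  out <- metadata[!drop, , drop = FALSE]
  attr(out, "excluded") <- metadata$sample[drop]
  out
}

#' Append CCF and clonality columns to a mutation table
#'
#' Runs [estimate_ccf()] row-wise on a mutation table (MAF-like layout, see
#' [read_mutation_table()]) and appends \code{ccf_hat}, \code{ccf_ci95_low},
#' \code{ccf_ci95_high}, \code{pr_clonal}, \code{multiplicity} and
#' \code{clonality}.
#'
#' @param mutations Mutation \code{data.frame} with columns \code{t_alt},
#'   \code{t_depth}, \code{purity}, \code{cn_major}, \code{cn_minor}.
#' @param ... Passed on to [estimate_ccf()].
#' @return The input with CCF columns appended.
#' @export
annotate_ccf <- function(mutations, ...) {
  req <- c("t_alt", "t_depth", "purity", "cn_major", "cn_minor")
  miss <- setdiff(req, names(mutations))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(mutations) == 0) {
    for (col in c("ccf_hat", "ccf_ci95_low", "ccf_ci95_high", "pr_clonal", "pr_subclonal"))
      mutations[[col]] <- numeric(0)
    mutations$multiplicity <- integer(0)
    mutations$clonality <- character(0)
    return(mutations)
  }
  est <- do.call(rbind, lapply(seq_len(nrow(mutations)), function(i) {
    row <- mutations[i, ]
    estimate_ccf(row$t_alt, row$t_depth, row$purity,
                 cn_tumor = row$cn_major + row$cn_minor, ...)
  }))
  cbind(mutations, est)
}
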