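# Readers/writers for the headered TSV formats used throughout. All
# positions and intervals are 1-based inclusive (MAF/SEG convention).

.read_tsv <- function(path, required, label, validators = list()) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop(label, " '", path, "': missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (nm in names(validators)) {
    bad <- which(!validators[[nm]](x))
    if (length(bad)) {
      stop(label, " '", path, "': ", nm, " at line(s) ",
           paste(utils::head(bad + 1, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
    }
  }
  x
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a MAF-like mutation table
#'
#' Required columns: patient, sample, lesion, gene, chrom, pos (1-based),
#' ref, alt, t_alt, t_depth, n_alt, n_depth, cn_major, cn_minor, purity.
#' Rows failing basic invariants (pos >= 1, 0 <= t_alt <= t_depth) are
#' reported with their line numbers.
#'
#' @param path File path.
#' @return \code{data.frame}; \code{write_mutation_table} returns the path
#'   invisibly.
#' @export
read_mutation_table <- function(path) {
  req <- c("patient", "sample", "lesion", "gene", "chrom", "pos", "ref", "alt",
           "t_alt", "t_depth", "n_alt", "n_depth", "cn_major", "cn_minor",
           "purity")
  x <- .read_tsv(path, req, "mutation table", validators = list(
    "position must be 1-based (pos >= 1)" = function(x) x$pos >= 1,
    "alt reads must lie in [0, depth]" = function(x)
      x$t_alt >= 0 & x$t_alt <= x$t_depth
  ))
  x$chrom <- as.character(x$chrom)
  x
}

#' @rdname read_mutation_table
#' @param x Table to write.
#' @export
write_mutation_table <- function(x, path) .write_tsv(x, path)

#' Read / write a SEG-like segment table
#'
#' Required columns: sample, chrom, start, end, log2_ratio (1-based
#' inclusive intervals); optional cn_major/cn_minor.
#'
#' @param path File path.
#' @export
read_segments <- function(path) {
  x <- .read_tsv(path, c("sample", "chrom", "start", "end", "log2_ratio"),
                 "segment table", validators = list(
                   "intervals must be 1-based with start <= end" = function(x)
                     x$start >= 1 & x$end >= x$start))
  x$chrom <- as.character(x$chrom)
  x
}

#' @rdname read_segments
#' @param x Table to write.
#' @export
write_segments <- function(x, path) .write_tsv(x, path)

#' Read / write the bin-level HLA coverage table
#' @param path File path.
#' @export
read_hla_coverage <- function(path) {
  .read_tsv(path, c("sample", "hla_gene", "allele1", "allele2", "bin",
                    "logr_allele1", "logr_allele2"), "HLA coverage table")
}

#' @rdname read_hla_coverage
#' @param x Table to write.
#' @export
write_hla_coverage <- function(x, path) .write_tsv(x, path)

#' Read / write the neoantigen candidate table
#' @param path File path.
#' @export
read_neoantigens <- function(path) {
  .read_tsv(path, c("sample", "variant_key", "peptide", "hla_allele",
                    "binding_rank"), "neoantigen table")
}

#' @rdname read_neoantigens
#' @param x Table to write.
#' @export
write_neoantigens <- function(x, path) .write_tsv(x, path)

#' Read / write sample metadata (patient, sample, lesion, purity)
#' @param path File path.
#' @export
read_metadata <- function(path) {
  x <- .read_tsv(path, c("patient", "sample", "lesion", "purity"),
                 "metadata table")
  bad <- setdiff(unique(x$lesion), c("normal", "primary", "metastasis"))
  if (length(bad)) stop("unknown lesion type(s): ", paste(bad, collapse = ", "))
  x
}

#' @rdname read_metadata
#' @param x Table to write.
#' @export
write_metadata <- function(x, path) .write_tsv(x, path)

#' Write all tables of a simulated cohort to a directory
#'
#' Emits mutations.tsv, segments.tsv, hla_coverage.tsv, rna_counts.tsv,
#' neoantigens.tsv, metadata.tsv and the ground-truth tables under
#' \code{truth_*.tsv}.
#'
#' @param cohort A \code{paired_cohort} from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  .write_tsv(cohort$segments, file.path(dir, "segments.tsv"))
  .write_tsv(cohort$hla_coverage, file.path(dir, "hla_coverage.tsv"))
  .write_tsv(cohort$rna_counts, file.path(dir, "rna_counts.tsv"))
  if (!is.null(cohort$neoantigens)) {
    .write_tsv(cohort$neoantigens, file.path(dir, "neoantigens.tsv"))
  }
  .write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  .write_tsv(cohort$truth$mutations, file.path(dir, "truth_mutations.tsv"))
  .write_tsv(cohort$truth$hla, file.path(dir, "truth_hla.tsv"))
  .write_tsv(cohort$truth$arms, file.path(dir, "truth_arms.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory path.
#' @return A list of class \code{paired_cohort} (without ground truth unless
#'   present on disk).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  truth <- NULL
  if (file.exists(p("truth_mutations.tsv"))) {
    truth <- list(
      mutations = utils::read.delim(p("truth_mutations.tsv"), stringsAsFactors = FALSE),
      hla = utils::read.delim(p("truth_hla.tsv"), stringsAsFactors = FALSE),
      arms = utils::read.delim(p("truth_arms.tsv"), stringsAsFactors = FALSE)
    )
  }
  structure(list(
    mutations = read_mutation_table(p("mutations.tsv")),
    segments = read_segments(p("segments.tsv")),
    hla_coverage = read_hla_coverage(p("hla_coverage.tsv")),
    rna_counts = if (file.exists(p("rna_counts.tsv")))
      utils::read.delim(p("rna_counts.tsv"), stringsAsFactors = FALSE) else NULL,
    neoantigens = if (file.exists(p("neoantigens.tsv")))
      read_neoantigens(p("neoantigens.tsv")) else NULL,
    metadata = read_metadata(p("metadata.tsv")),
    truth = truth
  ), class = "paired_cohort")
}
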