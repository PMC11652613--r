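# Multiregion cohort container, validation, and delimited-file IO.

#' Construct a multiregion expression cohort
#'
#' The universal input of the pipeline: a gene x sample expression
#' matrix (assumed log scale), a sample sheet mapping every sample to a
#' patient, a tumor region, and a tissue label, and (optionally) one
#' survival record per patient.
#'
#' @param expression Numeric gene x sample matrix with gene ids as row
#'   names and sample ids as column names.  Values are log-scale
#'   expression (unitless).
#' @param samples `data.frame` with columns `sample_id`, `patient_id`,
#'   `region_id`, `tissue` (`"tumor"` or `"normal"`).  Sample order in
#'   this sheet defines the column order of the stored matrix.
#' @param survival Optional `data.frame` with columns `patient_id`,
#'   `time` (days, > 0), `event` (0 censored / 1 event), one row per
#'   patient; every survival patient must appear in `samples`.
#' @return An object of class `multiregion_cohort`: a list with
#'   elements `expression`, `samples`, `survival`.
#' @seealso [read_cohort()], [subset_tumor()]
#' @export
multiregion_cohort <- function(expression, samples, survival = NULL) {
  expression <- as.matrix(expression)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "region_id", "tissue")
  if (!all(need %in% names(samples)))
    stop("samples sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  samples <- samples[, need]
  for (cl in need) samples[[cl]] <- as.character(samples[[cl]])

  in_meta <- setdiff(colnames(expression), samples$sample_id)
  if (length(in_meta))
    stop("sample(s) in expression matrix but not in metadata: ",
         paste(in_meta, collapse = ", "), call. = FALSE)
  missing_cols <- setdiff(samples$sample_id, colnames(expression))
  if (length(missing_cols))
    stop("sample(s) in metadata but absent from expression matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  # metadata order wins
  expression <- expression[, samples$sample_id, drop = FALSE]

  if (!is.null(survival)) {
    survival <- as.data.frame(survival, stringsAsFactors = FALSE)
    sneed <- c("patient_id", "time", "event")
    if (!all(sneed %in% names(survival)))
      stop("survival table needs columns: ", paste(sneed, collapse = ", "),
           call. = FALSE)
    survival <- survival[, sneed]
    survival$patient_id <- as.character(survival$patient_id)
    survival$time <- as.numeric(survival$time)
    survival$event <- as.integer(survival$event)
  }

  out <- structure(list(expression = expression, samples = samples,
                        survival = survival),
                   class = "multiregion_cohort")
  validate_cohort(out)
}

#' Validate a multiregion cohort
#'
#' Enforces the container invariants: unique sample ids, unique
#' (patient, region) pairs, complete and unique gene ids, numeric
#' expression, tissue labels in {tumor, normal}, positive survival
#' times, events coded 0/1, and survival patients present in the
#' sample sheet.  Called by [multiregion_cohort()]; exported so that
#' externally manipulated objects can be re-checked.
#'
#' @param x A `multiregion_cohort`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "multiregion_cohort"))
  expr <- x$expression
  smp <- x$samples
  if (!is.numeric(expr)) stop("expression matrix must be numeric", call. = FALSE)
  if (is.null(rownames(expr)) || any(is.na(rownames(expr))) ||
      any(rownames(expr) == ""))
    stop("expression matrix has missing gene ids", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))])[1:3],
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(smp$sample_id))
    stop("duplicated sample ids: ",
         paste(unique(smp$sample_id[duplicated(smp$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (!identical(colnames(expr), smp$sample_id))
    stop("expression columns do not match sample sheet order", call. = FALSE)
  if (!all(smp$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'", call. = FALSE)
  pr <- paste(smp$patient_id, smp$region_id, sep = "\r")
  if (anyDuplicated(pr))
    stop("duplicated (patient_id, region_id) pair(s)", call. = FALSE)
  sv <- x$survival
  if (!is.null(sv)) {
    if (anyDuplicated(sv$patient_id))
      stop("duplicated patient_id in survival table", call. = FALSE)
    if (any(!is.finite(sv$time)) || any(sv$time <= 0))
      stop("survival times must be finite and > 0", call. = FALSE)
    if (!all(sv$event %in% c(0L, 1L)))
      stop("survival event must be 0 or 1", call. = FALSE)
    unknown <- setdiff(sv$patient_id, smp$patient_id)
    if (length(unknown))
      stop("survival patient(s) not present among samples: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.multiregion_cohort <- function(x, ...) {
  smp <- x$samples
  cat("multiregion_cohort: ", nrow(x$expression), " genes x ",
      nrow(smp), " samples\n", sep = "")
  cat("  patients: ", length(unique(smp$patient_id)),
      " | tumor samples: ", sum(smp$tissue == "tumor"),
      " | normal samples: ", sum(smp$tissue == "normal"), "\n", sep = "")
  cat("  survival: ",
      if (is.null(x$survival)) "none"
      else paste0(nrow(x$survival), " patients, ",
                  sum(x$survival$event), " events"), "\n", sep = "")
  invisible(x)
}

#' Number of genes / samples in a cohort
#' @param cohort A `multiregion_cohort`.
#' @return Integer count.
#' @export
n_genes <- function(cohort) nrow(cohort$expression)

#' @rdname n_genes
#' @export
n_samples <- function(cohort) ncol(cohort$expression)

#' Restrict a cohort to tumor samples
#'
#' Heterogeneity scoring and the sampling-bias audit operate on tumor
#' regions only; normal tissue samples are removed here.  The
#' operation is idempotent and leaves the gene universe unchanged.
#'
#' @param cohort A `multiregion_cohort`.
#' @return A `multiregion_cohort` containing only `tissue == "tumor"`
#'   samples.  Errors if no tumor sample remains.
#' @export
subset_tumor <- function(cohort) {
  stopifnot(inherits(cohort, "multiregion_cohort"))
  keep <- cohort$samples$tissue == "tumor"
  if (!any(keep)) stop("cohort contains no tumor samples", call. = FALSE)
  if (all(keep)) return(cohort)
  multiregion_cohort(cohort$expression[, keep, drop = FALSE],
                     cohort$samples[keep, , drop = FALSE],
                     cohort$survival)
}

# Internal guard used by analysis functions whose contracts assume
# tumor-only input; forces the caller to make the exclusion explicit.
assert_tumor_only <- function(cohort, fn) {
  if (any(cohort$samples$tissue != "tumor"))
    stop(fn, "() expects a tumor-only cohort; call subset_tumor() first",
         call. = FALSE)
  invisible(cohort)
}

#' Read a cohort from delimited files
#'
#' @param expr_path Gene x sample matrix: first column gene id, header
#'   row of sample ids.  `.csv` is comma-separated, anything else is
#'   read as tab-separated.
#' @param meta_path Sample sheet with columns `sample_id`,
#'   `patient_id`, `region_id`, `tissue`.
#' @param survival_path Optional patient table with columns
#'   `patient_id`, `time`, `event`.
#' @param log1p If `TRUE`, apply `log2(x + 1)` on load.  Use for
#'   linear-scale inputs such as TPM; the pipeline assumes log-scale
#'   expression throughout, and the transform applied is recorded in
#'   the returned object's `"log1p"` attribute so downstream output
#'   provenance is explicit.
#' @return A validated [multiregion_cohort()] with samples in the
#'   metadata file's order.  Non-numeric expression cells, samples
#'   present in only one of the two files, and duplicate ids are hard
#'   errors naming the offending entry.
#' @export
read_cohort <- function(expr_path, meta_path, survival_path = NULL,
                        log1p = FALSE) {
  expr <- read_expression(expr_path)
  meta <- utils::read.table(meta_path, sep = delim_for(meta_path),
                            header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE)
  sv <- NULL
  if (!is.null(survival_path))
    sv <- utils::read.table(survival_path, sep = delim_for(survival_path),
                            header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE)
  if (log1p) expr <- log2(expr + 1)
  out <- multiregion_cohort(expr, meta, sv)
  attr(out, "log1p") <- log1p
  out
}

# Parse a delimited gene x sample matrix, reporting the coordinates of
# any non-numeric cell instead of silently coercing to NA.
read_expression <- function(path) {
  raw <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("expression file has no sample columns", call. = FALSE)
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("non-numeric expression value ", dQuote(vals[i, j]),
         " at gene ", dQuote(genes[i]), ", sample ",
         dQuote(colnames(vals)[j]), call. = FALSE)
  }
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Write a cohort to delimited files
#'
#' Inverse of [read_cohort()].  Expression values are written with 17
#' significant digits so that a write/read round trip reproduces every
#' double exactly.
#'
#' @param cohort A `multiregion_cohort`.
#' @param expr_path,meta_path Output paths (extension selects the
#'   delimiter as in [read_cohort()]).
#' @param survival_path Optional output path for the survival table;
#'   required when the cohort carries survival data.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, expr_path, meta_path,
                         survival_path = NULL) {
  stopifnot(inherits(cohort, "multiregion_cohort"))
  sep <- delim_for(expr_path)
  m <- cohort$expression
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  df <- data.frame(gene = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(m))
  utils::write.table(df, expr_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$samples, meta_path, sep = delim_for(meta_path),
                     quote = FALSE, row.names = FALSE)
  written <- c(expr_path, meta_path)
  if (!is.null(cohort$survival)) {
    if (is.null(survival_path))
      stop("cohort has survival data; supply survival_path", call. = FALSE)
    utils::write.table(cohort$survival, survival_path,
                       sep = delim_for(survival_path), quote = FALSE,
                       row.names = FALSE)
    written <- c(written, survival_path)
  }
  invisible(written)
}

#' Collapse probe-level rows to gene level
#'
#' Microarray platforms measure several probes per gene.  When a
#' two-column probe-to-gene annotation is available, this keeps, for
#' each gene, the probe with the highest mean expression across
#' samples (the common "max mean" convention) and discards unannotated
#' probes.
#'
#' @param expression Probe x sample numeric matrix (probe ids as row
#'   names).
#' @param annotation `data.frame` whose first two columns are probe id
#'   and gene id.
#' @return Gene x sample matrix with one row per gene.
#' @export
collapse_probes <- function(expression, annotation) {
  expression <- as.matrix(expression)
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  probe <- as.character(annotation[[1]])
  gene <- as.character(annotation[[2]])
  keep <- !is.na(gene) & gene != "" & probe %in% rownames(expression)
  probe <- probe[keep]; gene <- gene[keep]
  if (!length(probe)) stop("no annotated probe matches the matrix", call. = FALSE)
  mu <- rowMeans(expression)[probe]
  best <- tapply(seq_along(probe), gene, function(ii) ii[which.max(mu[ii])])
  out <- expression[probe[unlist(best)], , drop = FALSE]
  rownames(out) <- names(best)
  out
}
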