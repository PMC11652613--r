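# Gene signatures: the linear risk-score formula's carrier object.

#' Construct a gene signature
#'
#' A named, ordered list of (gene, coefficient) pairs.  The signature
#' risk score of a sample is `sum_i coefficient_i * expression_i`; see
#' [risk_score()].
#'
#' @param genes Character vector of unique gene ids (>= 1).
#' @param coefficients Numeric vector, one finite coefficient per gene.
#' @param name Signature label used in printed output.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(genes, coefficients, name = "signature") {
  genes <- as.character(genes)
  coefficients <- as.numeric(coefficients)
  if (length(genes) < 1) stop("signature needs at least one gene", call. = FALSE)
  if (length(genes) != length(coefficients))
    stop("genes and coefficients differ in length", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicated gene in signature: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(coefficients)))
    stop("signature coefficients must be finite", call. = FALSE)
  structure(list(name = as.character(name)[1], genes = genes,
                 coefficients = stats::setNames(coefficients, genes)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature ", dQuote(x$name), ": ", length(x$genes),
      " genes (", sum(x$coefficients > 0), " risk / ",
      sum(x$coefficients < 0), " protective)\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Read a gene signature from a two-column delimited file
#'
#' The file holds one `gene, coefficient` pair per row; a header row is
#' detected automatically (present when the second field of the first
#' line does not parse as a number).  Row order is preserved.
#'
#' @param path File path; `.csv` comma-separated, otherwise tab.
#' @param name Signature label; defaults to the file name.
#' @return A [gene_signature()].  Duplicate genes and non-numeric
#'   coefficients are hard errors.
#' @export
read_signature <- function(path, name = NULL) {
  sep <- delim_for(path)
  first <- utils::read.table(path, sep = sep, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  if (ncol(first) < 2)
    stop("signature file must have two columns (gene, coefficient)",
         call. = FALSE)
  has_header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  genes <- tab[[1]]
  coefs <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(coefs)) {
    bad <- which(is.na(coefs))[1]
    stop("non-numeric coefficient ", dQuote(tab[[2]][bad]),
         " for gene ", dQuote(genes[bad]), call. = FALSE)
  }
  gene_signature(genes, coefs,
                 name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a gene signature to a two-column delimited file
#'
#' @param signature A [gene_signature()].
#' @param path Output path (extension selects the delimiter).
#' @return Invisibly, `path`.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  df <- data.frame(gene = signature$genes,
                   coefficient = sprintf("%.17g", signature$coefficients))
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
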