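#' Construct a single gene model
#'
#' A gene model is the reference frame for junction classification: an ordered
#' set of (union-merged) exons on one scaffold, with introns derived as the
#' gaps between consecutive exons. All coordinates are 0-based half-open
#' (BED-style), so the length of any interval is `end - start`.
#'
#' @param gene_id Gene identifier.
#' @param scaffold Scaffold/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of 0-based half-open exon
#'   intervals; they must be non-overlapping once sorted by start.
#' @return A list of class `gene_model` with elements `gene_id`, `scaffold`,
#'   `strand`, `exons` and `introns` (both two-column matrices).
#' @export
gene_model <- function(gene_id, scaffold, strand, exons) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop("gene ", gene_id, ": exon with end <= start")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("gene ", gene_id, ": overlapping exons after sorting")
  if (!strand %in% c("+", "-"))
    stop("gene ", gene_id, ": strand must be '+' or '-'")
  n <- nrow(exons)
  introns <- if (n > 1) {
    cbind(start = exons[-n, 2], end = exons[-1, 1])
  } else {
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  }
  structure(list(gene_id = as.character(gene_id),
                 scaffold = as.character(scaffold),
                 strand = strand, exons = exons, introns = introns),
            class = "gene_model")
}

#' Bundle gene models into an indexed collection
#'
#' @param genes List of `gene_model` objects.
#' @return An object of class `gene_models`: a named list of models plus a
#'   scaffold index used by the classifier.
#' @export
gene_models <- function(genes) {
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate gene ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genes) <- ids
  scaf <- vapply(genes, function(g) g$scaffold, character(1))
  structure(list(genes = genes, by_scaffold = split(ids, scaf)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  n_ex <- vapply(x$genes, function(g) nrow(g$exons), integer(1))
  cat("gene_models:", length(x$genes), "genes on",
      length(x$by_scaffold), "scaffolds;",
      "exons/gene:", min(n_ex), "-", max(n_ex), "\n")
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, sprintf("(%s%s)", x$scaffold, x$strand),
      nrow(x$exons), "exons,", nrow(x$introns), "introns\n")
  invisible(x)
}

#' Length of each interval in a two-column (start, end) matrix
#' @noRd
interval_lengths <- function(m) {
  if (nrow(m) == 0) return(numeric(0))
  m[, 2] - m[, 1]
}
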