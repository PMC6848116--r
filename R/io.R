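# File readers/writers. Internal convention everywhere: 0-based half-open
# intervals (BED-style). GFF3/GTF and RepeatMasker coordinates (1-based
# inclusive) are converted on read; BED inputs pass through unchanged.

#' Read a gene annotation (GFF3 or GTF) into gene models
#'
#' Exon features are grouped by their gene identifier and union-merged per
#' gene (overlapping exons of alternative transcripts collapse into one
#' interval), so all downstream classification is done at gene level.
#' 1-based inclusive GFF coordinates are converted to 0-based half-open.
#'
#' @param path Path to a GFF3 or GTF file (format inferred by
#'   [rtracklayer::import()] from the extension).
#' @param feature_type Feature type(s) treated as exons (default `"exon"`).
#' @param gene_attribute Attribute holding the gene id; the first of these
#'   present in the file is used.
#' @return A [gene_models] collection.
#' @export
read_gene_annotation <- function(path, feature_type = "exon",
                                 gene_attribute = c("gene_id", "Parent", "gene")) {
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  exon <- gr[tolower(as.character(meta$type)) %in% tolower(feature_type)]
  if (length(exon) == 0) stop("no '", paste(feature_type, collapse = "/"),
                              "' features in ", path)
  attr_name <- gene_attribute[gene_attribute %in% names(S4Vectors::mcols(exon))][1]
  if (is.na(attr_name)) stop("no gene identifier attribute (tried: ",
                             paste(gene_attribute, collapse = ", "), ")")
  gid <- S4Vectors::mcols(exon)[[attr_name]]
  if (methods::is(gid, "List") || is.list(gid))
    gid <- vapply(gid, function(v) as.character(v)[1], character(1))
  gid <- as.character(gid)
  if (anyNA(gid)) stop("exon feature without a '", attr_name, "' attribute")

  keys <- split(seq_along(exon), gid)
  genes <- lapply(names(keys), function(id) {
    sub <- exon[keys[[id]]]
    merged <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(sub),
                                               GenomicRanges::end(sub)))
    gene_model(id,
               scaffold = as.character(GenomicRanges::seqnames(sub))[1],
               strand = as.character(GenomicRanges::strand(sub))[1],
               exons = cbind(IRanges::start(merged) - 1L, IRanges::end(merged)))
  })

  # genes declared in the file but carrying no exon features are skipped
  gene_feat <- gr[tolower(as.character(meta$type)) == "gene"]
  if (length(gene_feat) > 0) {
    declared <- S4Vectors::mcols(gene_feat)$ID
    if (!is.null(declared)) {
      missing <- setdiff(as.character(declared), names(keys))
      if (length(missing) > 0)
        warning(length(missing), " gene(s) with zero exons skipped: ",
                paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  gene_models(genes)
}

#' Read a per-sample back-spliced junction table
#'
#' Supported dialects:
#' \describe{
#'   \item{`plain-tsv`}{columns `scaffold, start, end, strand, count`, with a
#'     header row; this is also the package's own output dialect.}
#'   \item{`bed6`}{BED6 with the back-spliced read count in the score column.}
#'   \item{`circexplorer2`}{CIRCexplorer2-style annotation output: BED12-like,
#'     read count parsed from column 13 (`readNumber`).}
#' }
#' BED-family inputs are already 0-based half-open. Duplicate junctions within
#' one file have their counts summed. Each junction gets the deterministic id
#' `"{scaffold}_{start}_{end}"`.
#'
#' @param path Input file.
#' @param sample_id Sample label attached to every row.
#' @param dialect One of `"plain-tsv"`, `"bed6"`, `"circexplorer2"`.
#' @return data.frame with columns `scaffold, start, end, strand, count,
#'   sample_id, circ_id` (zero rows for an empty file).
#' @export
read_junctions <- function(path, sample_id,
                           dialect = c("plain-tsv", "bed6", "circexplorer2")) {
  dialect <- match.arg(dialect)
  empty <- data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      count = numeric(0), sample_id = character(0),
                      circ_id = character(0), stringsAsFactors = FALSE)
  header <- dialect == "plain-tsv"
  raw <- tryCatch(utils::read.table(path, header = header, sep = "\t",
                                    stringsAsFactors = FALSE,
                                    comment.char = "#"),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) return(empty)
  j <- switch(dialect,
    "plain-tsv" = data.frame(scaffold = as.character(raw[[1]]),
                             start = raw[[2]], end = raw[[3]],
                             strand = as.character(raw[[4]]), count = raw[[5]],
                             stringsAsFactors = FALSE),
    "bed6" = data.frame(scaffold = as.character(raw[[1]]),
                        start = raw[[2]], end = raw[[3]],
                        strand = as.character(raw[[6]]), count = raw[[5]],
                        stringsAsFactors = FALSE),
    "circexplorer2" = data.frame(scaffold = as.character(raw[[1]]),
                                 start = raw[[2]], end = raw[[3]],
                                 strand = as.character(raw[[6]]),
                                 count = raw[[13]], stringsAsFactors = FALSE))
  j$count <- suppressWarnings(as.integer(j$count))
  bad <- which(!is.finite(j$start) | !is.finite(j$end) | j$end <= j$start)
  if (length(bad) > 0)
    stop(path, ": row ", bad[1], " has end <= start (start=", j$start[bad[1]],
         ", end=", j$end[bad[1]], ")")
  bad <- which(is.na(j$count) | j$count < 0)
  if (length(bad) > 0)
    stop(path, ": row ", bad[1], " has a negative or non-integer count")
  j$strand[!j$strand %in% c("+", "-")] <- "."
  key <- paste(j$scaffold, j$start, j$end, sep = "_")
  agg <- rowsum(j$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- j[first, , drop = FALSE]
  out$count <- as.vector(agg[match(key[first], rownames(agg)), 1])
  out$sample_id <- sample_id
  out$circ_id <- key[first]
  rownames(out) <- NULL
  out
}

#' Write a junction table
#'
#' `plain-tsv` (headered, the package's native dialect) or `bed6` (count in
#' the score column). Round-trips through [read_junctions()] reproduce
#' identical `circ_id`s and counts.
#'
#' @param junctions data.frame as produced by [read_junctions()].
#' @param path Output path.
#' @param dialect `"plain-tsv"` or `"bed6"`.
#' @export
write_junctions <- function(junctions, path, dialect = c("plain-tsv", "bed6")) {
  dialect <- match.arg(dialect)
  if (dialect == "plain-tsv") {
    out <- junctions[, c("scaffold", "start", "end", "strand", "count")]
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(junctions$scaffold, junctions$start, junctions$end,
                      ".", junctions$count, junctions$strand)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read repeat annotations (RepeatMasker ".out" or BED)
#'
#' RepeatMasker files: three header lines, whitespace-separated body,
#' 1-based inclusive begin/end (converted to 0-based half-open); malformed
#' body rows are skipped with a warning. BED files: columns
#' `scaffold, start, end, repeat_class[, repeat_name]`, passed through.
#'
#' @param path Input file.
#' @param dialect `"auto"` (by extension: `.out` is RepeatMasker),
#'   `"repeatmasker"` or `"bed"`.
#' @return data.frame with columns `scaffold, start, end, repeat_class,
#'   repeat_name`.
#' @export
read_repeats <- function(path, dialect = c("auto", "repeatmasker", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.out$", path)) "repeatmasker" else "bed"
  empty <- data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), repeat_class = character(0),
                      repeat_name = character(0), stringsAsFactors = FALSE)
  if (dialect == "bed") {
    raw <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                      stringsAsFactors = FALSE),
                    error = function(e) NULL)
    if (is.null(raw) || nrow(raw) == 0) return(empty)
    out <- data.frame(scaffold = as.character(raw[[1]]), start = raw[[2]],
                      end = raw[[3]],
                      repeat_class = as.character(raw[[4]]),
                      repeat_name = if (ncol(raw) >= 5) as.character(raw[[5]])
                                    else as.character(raw[[4]]),
                      stringsAsFactors = FALSE)
    if (any(out$end <= out$start)) stop(path, ": repeat with end <= start")
    return(out)
  }
  lines <- readLines(path)
  if (length(lines) <= 3) return(empty)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(body, function(l) strsplit(trimws(l), "\\s+")[[1]])
  keep <- vapply(rows, function(f) {
    length(f) >= 11 && !is.na(suppressWarnings(as.numeric(f[6]))) &&
      !is.na(suppressWarnings(as.numeric(f[7])))
  }, logical(1))
  if (any(!keep))
    warning(path, ": skipped ", sum(!keep), " malformed RepeatMasker row(s)")
  rows <- rows[keep]
  if (length(rows) == 0) return(empty)
  data.frame(scaffold = vapply(rows, `[`, character(1), 5),
             start = vapply(rows, function(f) as.numeric(f[6]), numeric(1)) - 1,
             end = vapply(rows, function(f) as.numeric(f[7]), numeric(1)),
             repeat_class = vapply(rows, `[`, character(1), 11),
             repeat_name = vapply(rows, `[`, character(1), 10),
             stringsAsFactors = FALSE)
}

#' Construct an expression table
#'
#' @param values Numeric matrix, rows = features (gene or circRNA ids),
#'   columns = samples.
#' @param sample_stage Named character vector mapping each sample (name) to
#'   its stage (value); must cover every column of `values`.
#' @return Object of class `expr_table`: list with `values` and
#'   `sample_stage`.
#' @export
expr_table <- function(values, sample_stage) {
  values <- as.matrix(values)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  missing <- setdiff(colnames(values), names(sample_stage))
  if (length(missing) > 0)
    stop("sample(s) missing from the stage map: ",
         paste(missing, collapse = ", "))
  sample_stage <- sample_stage[colnames(values)]
  structure(list(values = values, sample_stage = sample_stage),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat("expr_table:", nrow(x$values), "features x", ncol(x$values),
      "samples; stages:",
      paste(sprintf("%s(%d)", unique(x$sample_stage),
                    table(x$sample_stage)[unique(x$sample_stage)]),
            collapse = " "), "\n")
  invisible(x)
}

#' Read a TSV expression table
#'
#' First column = feature id, remaining columns = samples; every sample must
#' appear in `sample_stage`, duplicate feature ids are an error.
#'
#' @param path TSV with a header row.
#' @inheritParams expr_table
#' @return An [expr_table].
#' @export
read_expression <- function(path, sample_stage) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(raw[[1]]))
    stop(path, ": duplicate feature id(s): ",
         paste(unique(raw[[1]][duplicated(raw[[1]])]), collapse = ", "))
  values <- as.matrix(raw[, -1, drop = FALSE])
  rownames(values) <- raw[[1]]
  expr_table(values, sample_stage)
}

#' Read a gene-to-term map
#'
#' @param path TSV with two columns (`gene_id`, `term_id`); a header row is
#'   detected and skipped.
#' @return data.frame with unique `(gene_id, term_id)` pairs.
#' @export
read_term_map <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (identical(tolower(as.character(raw[1, 1])), "gene_id"))
    raw <- raw[-1, , drop = FALSE]
  out <- data.frame(gene_id = as.character(raw[[1]]),
                    term_id = as.character(raw[[2]]), stringsAsFactors = FALSE)
  unique(out)
}

#' Read a sample-to-stage map
#' @param path TSV with columns `sample`, `stage` (header optional).
#' @return Named character vector (names = samples, values = stages).
#' @export
read_sample_map <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (identical(tolower(as.character(raw[1, 1])), "sample"))
    raw <- raw[-1, , drop = FALSE]
  stats::setNames(as.character(raw[[2]]), as.character(raw[[1]]))
}
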