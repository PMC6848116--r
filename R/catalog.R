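# Consolidated circRNA catalog: junction classification against gene models,
# replicate/stage set comparisons, CPM normalization, read-count filters.

#' Classify one back-spliced junction against the gene models
#'
#' A junction is *exonic* when its start coincides with some merged-exon
#' start and its end with some merged-exon end of one gene (the two
#' boundaries may belong to different exons, giving multi-exon circRNAs);
#' *intronic* when the interval lies entirely within a single intron of a
#' gene; otherwise *other*, with the parent set to the gene whose span
#' contains the junction midpoint (or none). Classification ignores junction
#' strand by default because upstream callers disagree on strand
#' conventions; `strict_strand = TRUE` restricts matches to genes on the
#' junction's strand.
#'
#' @param scaffold,start,end Junction coordinates (0-based half-open).
#' @param genes A [gene_models] collection.
#' @param strand Junction strand (`"+"`, `"-"` or `"."`); only used when
#'   `strict_strand = TRUE`.
#' @param strict_strand Require the parent gene to lie on `strand`.
#' @param tol Boundary-matching tolerance in bp (default 0 = exact).
#' @return List with `circ_class` (`"exonic"`, `"intronic"` or `"other"`)
#'   and `parent_gene` (gene id or `NA`).
#' @export
classify_junction <- function(scaffold, start, end, genes, strand = ".",
                              strict_strand = FALSE, tol = 0) {
  cand_ids <- genes$by_scaffold[[scaffold]]
  if (strict_strand && strand %in% c("+", "-"))
    cand_ids <- cand_ids[vapply(genes$genes[cand_ids],
                                function(g) g$strand == strand, logical(1))]
  mid <- (start + end) / 2
  other_parent <- NA_character_
  for (id in cand_ids) {
    g <- genes$genes[[id]]
    ex <- g$exons
    if (any(abs(ex[, 1] - start) <= tol) && any(abs(ex[, 2] - end) <= tol))
      return(list(circ_class = "exonic", parent_gene = id))
  }
  for (id in cand_ids) {
    g <- genes$genes[[id]]
    intr <- g$introns
    if (nrow(intr) > 0 &&
        any(intr[, 1] <= start & end <= intr[, 2]))
      return(list(circ_class = "intronic", parent_gene = id))
  }
  for (id in cand_ids) {
    g <- genes$genes[[id]]
    span <- range(g$exons)
    if (mid >= span[1] && mid < span[2]) { other_parent <- id; break }
  }
  list(circ_class = "other", parent_gene = other_parent)
}

#' Build the consolidated circRNA catalog
#'
#' Junction calls from all samples are merged by exact junction coordinates
#' (`circ_id = "{scaffold}_{start}_{end}"`), classified against the gene
#' models, and laid out as a per-sample count matrix with CPM normalization.
#'
#' @param junctions data.frame of junction calls from all samples (rows as
#'   produced by [read_junctions()]), or a list of such data.frames.
#' @param genes A [gene_models] collection.
#' @param sample_stage Named character vector mapping samples to stages.
#' @param denominators Optional per-sample CPM denominators (named); default
#'   is the total back-spliced junction read count per sample.
#' @param strict_strand,tol Passed to [classify_junction()].
#' @return Object of class `circ_catalog`: list with `table` (circ_id,
#'   coordinates, class, parent gene), `counts` and `cpm` matrices
#'   (circRNAs x samples), and `sample_stage`.
#' @export
build_catalog <- function(junctions, genes, sample_stage,
                          denominators = NULL, strict_strand = FALSE,
                          tol = 0) {
  if (is.list(junctions) && !is.data.frame(junctions))
    junctions <- do.call(rbind, junctions)
  samples <- names(sample_stage)
  bad <- setdiff(unique(junctions$sample_id), samples)
  if (length(bad) > 0)
    stop("sample(s) missing from the stage map: ", paste(bad, collapse = ", "))

  first <- !duplicated(junctions$circ_id)
  tab <- junctions[first, c("circ_id", "scaffold", "start", "end", "strand"),
                   drop = FALSE]
  rownames(tab) <- NULL
  counts <- matrix(0L, nrow(tab), length(samples),
                   dimnames = list(tab$circ_id, samples))
  if (nrow(junctions) > 0) {
    ri <- match(junctions$circ_id, tab$circ_id)
    ci <- match(junctions$sample_id, samples)
    for (k in seq_len(nrow(junctions)))
      counts[ri[k], ci[k]] <- counts[ri[k], ci[k]] + junctions$count[k]
  }
  cls <- character(nrow(tab)); par <- character(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    res <- classify_junction(tab$scaffold[k], tab$start[k], tab$end[k],
                             genes, tab$strand[k], strict_strand, tol)
    cls[k] <- res$circ_class
    par[k] <- res$parent_gene
  }
  tab$circ_class <- cls
  tab$parent_gene <- par
  # samples without any back-spliced read get an all-zero CPM column
  if (is.null(denominators)) {
    denominators <- colSums(counts)
    denominators[denominators == 0] <- 1
  }
  cpm <- if (nrow(tab) > 0) normalize_cpm(counts, denominators)
         else counts + 0
  structure(list(table = tab, counts = counts, cpm = cpm,
                 sample_stage = sample_stage),
            class = "circ_catalog")
}

#' @export
print.circ_catalog <- function(x, ...) {
  cls <- table(factor(x$table$circ_class,
                      levels = c("exonic", "intronic", "other")))
  cat("circ_catalog:", nrow(x$table), "circRNAs x",
      ncol(x$counts), "samples\n")
  cat("  classes: exonic", cls[["exonic"]], "| intronic", cls[["intronic"]],
      "| other", cls[["other"]], "\n")
  invisible(x)
}

#' @export
summary.circ_catalog <- function(object, min_count = 1, ...) {
  pres <- stage_presence(object$counts, object$sample_stage, min_count)
  stages <- unique(object$sample_stage)
  per_stage <- vapply(stages, function(s)
    sum(vapply(pres, function(p) s %in% p, logical(1))), integer(1))
  out <- list(n = nrow(object$table),
              by_class = table(object$table$circ_class),
              expressed_per_stage = per_stage,
              total_counts = colSums(object$counts))
  class(out) <- "summary.circ_catalog"
  out
}

#' @export
print.summary.circ_catalog <- function(x, ...) {
  cat("circRNAs:", x$n, "\n")
  print(x$by_class)
  cat("expressed per stage (any sample above threshold):\n")
  print(x$expressed_per_stage)
  invisible(x)
}

#' Subset a catalog to a set of circ_ids
#' @noRd
subset_catalog <- function(catalog, ids) {
  keep <- catalog$table$circ_id %in% ids
  structure(list(table = catalog$table[keep, , drop = FALSE],
                 counts = catalog$counts[keep, , drop = FALSE],
                 cpm = catalog$cpm[keep, , drop = FALSE],
                 sample_stage = catalog$sample_stage),
            class = "circ_catalog")
}

#' Replicate consensus: circRNAs shared by two replicates
#'
#' Identity is the exact junction position (`circ_id`), so the consensus is
#' a plain set intersection.
#'
#' @param repA,repB Character vectors of circ_ids.
#' @return Character vector of shared circ_ids.
#' @export
consensus_replicates <- function(repA, repB) {
  intersect(unique(repA), unique(repB))
}

#' Three-way stage comparison (Venn regions)
#'
#' @param stage_sets Named list of 3 character vectors of circ_ids (one per
#'   stage).
#' @return Object of class `stage_comparison`: named integer vector of the 7
#'   exclusive Venn regions (`only_<s>`, `<s1>_<s2>`, `all`) plus the union
#'   size as attribute `union`.
#' @export
compare_stages <- function(stage_sets) {
  if (length(stage_sets) != 3) stop("exactly 3 stage sets required")
  if (is.null(names(stage_sets))) names(stage_sets) <- paste0("S", 1:3)
  s <- lapply(stage_sets, unique)
  nm <- names(s)
  u <- unique(unlist(s))
  member <- vapply(s, function(x) u %in% x, logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1)
  code <- member %*% c(1, 2, 4)
  cnt <- function(x) sum(code == x)
  regions <- c(cnt(1), cnt(2), cnt(4), cnt(3), cnt(5), cnt(6), cnt(7))
  names(regions) <- c(paste0("only_", nm),
                      paste(nm[1], nm[2], sep = "_"),
                      paste(nm[1], nm[3], sep = "_"),
                      paste(nm[2], nm[3], sep = "_"),
                      "all")
  structure(regions, union = length(u), class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat("stage comparison (union =", attr(x, "union"), "):\n")
  print(unclass(x)[seq_along(x)])
  invisible(x)
}

#' Counts-per-million normalization
#'
#' `cpm = count / denominator * 1e6`. The default denominator is the total
#' back-spliced junction read count of each sample (column sums); a named
#' vector of user-supplied totals (e.g. clean reads) may be given instead.
#'
#' @param counts Count matrix (circRNAs x samples).
#' @param denominators Optional named per-sample totals; must be > 0.
#' @return CPM matrix with the same dimensions.
#' @export
normalize_cpm <- function(counts, denominators = NULL) {
  if (is.null(denominators)) denominators <- colSums(counts)
  if (!is.null(names(denominators)) && !is.null(colnames(counts)))
    denominators <- denominators[colnames(counts)]
  if (any(!is.finite(denominators)) || any(denominators <= 0))
    stop("zero or invalid CPM denominator for sample(s): ",
         paste(colnames(counts)[!is.finite(denominators) | denominators <= 0],
               collapse = ", "))
  sweep(counts, 2, denominators, "/") * 1e6
}

#' Filter a catalog on the total back-spliced read count
#'
#' Retains circRNAs whose count summed over all samples reaches the cutoff
#' (default 5, the study's characterization filter). `mode = "any"` instead
#' requires the cutoff in at least one sample. Monotone and idempotent.
#'
#' @param catalog A `circ_catalog`.
#' @param cutoff Minimum read count (default 5).
#' @param mode `"sum"` (default: sum over samples) or `"any"`.
#' @return Filtered `circ_catalog` (CPM values are kept as computed on the
#'   unfiltered catalog).
#' @export
filter_by_total_count <- function(catalog, cutoff = 5,
                                  mode = c("sum", "any")) {
  mode <- match.arg(mode)
  keep <- if (mode == "sum") rowSums(catalog$counts) >= cutoff
          else apply(catalog$counts, 1, function(x) any(x >= cutoff))
  subset_catalog(catalog, catalog$table$circ_id[keep])
}

#' Stages in which each circRNA is expressed
#'
#' A stage is present when any of its samples has a count at or above
#' `min_count` (default 1, i.e. detected in either replicate).
#'
#' @param counts Count matrix (circRNAs x samples) or a single named row.
#' @param sample_stage Named character vector mapping samples to stages.
#' @param min_count Detection threshold.
#' @return List (one element per circRNA) of character vectors of stages.
#' @export
stage_presence <- function(counts, sample_stage, min_count = 1) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  stages <- unique(sample_stage)
  lapply(seq_len(nrow(counts)), function(r) {
    pres <- vapply(stages, function(s) {
      any(counts[r, names(sample_stage)[sample_stage == s]] >= min_count)
    }, logical(1))
    stages[pres]
  })
}
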