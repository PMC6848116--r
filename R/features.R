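# Genomic features of exonic circRNAs: exon position within the parent gene,
# spanned exons, flanking/control introns, repeat coverage, inverted repeats,
# and the alternative-circularization summary.

#' Spanned merged-exon indices (genomic order) for an exonic circRNA
#' @noRd
spanned_idx <- function(start, end, gene) {
  ex <- gene$exons
  which(ex[, 2] > start & ex[, 1] < end)
}

check_exonic <- function(start, end, gene) {
  ex <- gene$exons
  if (!any(ex[, 1] == start) || !any(ex[, 2] == end))
    stop("circRNA [", start, ",", end, ") is not exonic on gene ",
         gene$gene_id)
}

#' Position of a circRNA's back-spliced exons within its parent gene
#'
#' Exon indices are transcriptional: for minus-strand genes the genomically
#' last exon is the gene's first. The class is `"first"` when the circRNA
#' includes the first exon but not the last, `"last"` symmetrically,
#' `"ambiguous"` when it includes both, and `"middle"` otherwise.
#'
#' @param start,end circRNA junction coordinates (0-based half-open); they
#'   must coincide with merged-exon boundaries of `gene`.
#' @param gene The parent [gene_model].
#' @return `"first"`, `"middle"`, `"last"` or `"ambiguous"`.
#' @export
position_class <- function(start, end, gene) {
  check_exonic(start, end, gene)
  idx <- spanned_idx(start, end, gene)
  n <- nrow(gene$exons)
  if (gene$strand == "-") idx <- n + 1 - idx
  has_first <- 1 %in% idx
  has_last <- n %in% idx
  if (has_first && has_last) return("ambiguous")
  if (has_first) return("first")
  if (has_last) return("last")
  "middle"
}

#' Number and summed length of back-spliced exons
#'
#' Counts the merged exons intersecting the circRNA interval and sums their
#' lengths clipped to the interval (the exonic sequence between the two
#' junction positions).
#'
#' @inheritParams position_class
#' @return List with `n_backspliced_exons` and `exonic_length`.
#' @export
spanned_exons <- function(start, end, gene) {
  idx <- spanned_idx(start, end, gene)
  if (length(idx) == 0)
    stop("circRNA [", start, ",", end, ") spans no exon of gene ",
         gene$gene_id)
  ex <- gene$exons[idx, , drop = FALSE]
  len <- sum(pmin(ex[, 2], end) - pmax(ex[, 1], start))
  list(n_backspliced_exons = length(idx), exonic_length = len)
}

#' Flanking and control introns of an exonic circRNA
#'
#' The left (genomically upstream) flank is the intron immediately before
#' the first spanned exon (`NULL` when that exon is the gene's genomically
#' first); the right flank symmetrically. Control introns are, by default,
#' the introns internal to the circRNA span — the introns of the "linear
#' gene" region bracketed by the back-splice. `controls = "noncirc"`
#' instead uses all remaining (non-flank, non-internal) introns of the gene.
#'
#' @inheritParams position_class
#' @param controls `"internal"` (default) or `"noncirc"`.
#' @return List with `left` and `right` (length-2 vectors `(start, end)` or
#'   `NULL`) and `controls` (two-column matrix, possibly zero rows).
#' @export
flanking_and_control_introns <- function(start, end, gene,
                                         controls = c("internal", "noncirc")) {
  controls <- match.arg(controls)
  empty <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(gene$exons) <= 1)
    return(list(left = NULL, right = NULL, controls = empty))
  idx <- spanned_idx(start, end, gene)
  i1 <- min(idx); i2 <- max(idx)
  n <- nrow(gene$exons)
  # intron k sits between exon k and exon k+1
  left <- if (i1 > 1) gene$introns[i1 - 1, ] else NULL
  right <- if (i2 < n) gene$introns[i2, ] else NULL
  ctrl_idx <- if (controls == "internal") {
    if (i2 > i1) i1:(i2 - 1) else integer(0)
  } else {
    setdiff(seq_len(n - 1), c(i1 - 1, i2, if (i2 > i1) i1:(i2 - 1)))
  }
  list(left = left, right = right,
       controls = gene$introns[ctrl_idx, , drop = FALSE])
}

#' Compare flanking and control intron lengths (one-sided Wilcoxon)
#'
#' Tests H1: flanking introns are longer, by the Wilcoxon rank-sum test —
#' exact enumeration when `min(n1, n2) <= 10` and there are no ties, and the
#' tie-corrected normal approximation (with continuity correction)
#' otherwise.
#'
#' @param flank_lens,control_lens Numeric vectors of intron lengths (nt),
#'   both non-empty.
#' @return List with `mean_flank`, `mean_control`, `p` (one-sided) and
#'   `exact` (logical).
#' @export
compare_intron_lengths <- function(flank_lens, control_lens) {
  if (length(flank_lens) == 0 || length(control_lens) == 0)
    stop("both intron length lists must be non-empty")
  ties <- anyDuplicated(c(flank_lens, control_lens)) > 0
  exact <- min(length(flank_lens), length(control_lens)) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(flank_lens, control_lens, alternative = "greater",
                       exact = exact, correct = TRUE))
  list(mean_flank = mean(flank_lens), mean_control = mean(control_lens),
       p = wt$p.value, exact = exact)
}

#' Fraction of an intron covered by repeats
#'
#' Overlapping repeat intervals are merged before summing, so nested or
#' overlapping annotations never count twice.
#'
#' @param intron Length-2 numeric `(start, end)`, 0-based half-open.
#' @param repeats Two-column matrix/data.frame of repeat intervals on the
#'   same scaffold (columns start, end), or a data.frame with `start`/`end`
#'   columns.
#' @return Covered fraction in \[0, 1\].
#' @export
repeat_coverage <- function(intron, repeats) {
  len <- intron[2] - intron[1]
  if (len <= 0) stop("intron length must be > 0")
  if (is.null(repeats) || NROW(repeats) == 0) return(0)
  rs <- if (is.data.frame(repeats)) repeats$start else repeats[, 1]
  re <- if (is.data.frame(repeats)) repeats$end else repeats[, 2]
  cs <- pmax(rs, intron[1]); ce <- pmin(re, intron[2])
  keep <- ce > cs
  if (!any(keep)) return(0)
  merged <- IRanges::reduce(IRanges::IRanges(cs[keep] + 1, ce[keep]))
  sum(IRanges::width(merged)) / len
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Find inverted repeats between two flanking-intron sequences
#'
#' Reports all maximal exact matches of length `>= min_len` between
#' `left_seq` and the reverse complement of `right_seq` — the configuration
#' that can base-pair across the flanks and drive circularization. Matching
#' is seed-and-extend: shared k-mers (`k = min(min_len, 12)`) are extended
#' bidirectionally and deduplicated to maximal intervals. `N` never
#' matches.
#'
#' @param left_seq,right_seq DNA strings over `A,C,G,T,N`.
#' @param min_len Minimum reported match length (default 20, >= 8).
#' @return data.frame with columns `left_pos`, `right_pos` (0-based offsets
#'   of the match in `left_seq` and in `right_seq`'s own orientation) and
#'   `length`, sorted by position.
#' @export
find_inverted_repeats <- function(left_seq, right_seq, min_len = 20) {
  if (min_len < 8) stop("min_len must be >= 8")
  left_seq <- toupper(left_seq); right_seq <- toupper(right_seq)
  for (s in c(left_seq, right_seq))
    if (grepl("[^ACGTN]", s)) stop("non-DNA character in sequence")
  empty <- data.frame(left_pos = integer(0), right_pos = integer(0),
                      length = integer(0))
  nl <- nchar(left_seq); nr <- nchar(right_seq)
  if (nl < min_len || nr < min_len) return(empty)
  rc <- revcomp_chr(right_seq)  # match in rc coords, report in right coords
  k <- min(min_len, 12L)

  kmers_at <- function(s, n) substring(s, 1:(n - k + 1), k:n)
  lk <- kmers_at(left_seq, nl)
  rk <- kmers_at(rc, nr)
  lk[grepl("N", lk, fixed = TRUE)] <- NA
  rk[grepl("N", rk, fixed = TRUE)] <- NA
  idx <- split(seq_along(rk), rk)

  lc <- strsplit(left_seq, "")[[1]]
  rcc <- strsplit(rc, "")[[1]]
  match_at <- function(i, j) lc[i] == rcc[j] & lc[i] != "N"

  seen <- new.env(hash = TRUE)
  hits <- list()
  for (i in seq_along(lk)) {
    if (is.na(lk[i])) next
    js <- idx[[lk[i]]]
    if (is.null(js)) next
    for (j in js) {
      # extend left
      a <- i; b <- j
      while (a > 1 && b > 1 && match_at(a - 1, b - 1)) { a <- a - 1; b <- b - 1 }
      # extend right
      ae <- i + k - 1; be <- j + k - 1
      while (ae < nl && be < nr && match_at(ae + 1, be + 1)) {
        ae <- ae + 1; be <- be + 1
      }
      len <- ae - a + 1
      if (len < min_len) next
      key <- paste(a, b, len, sep = ":")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      hits[[length(hits) + 1]] <- c(a - 1L, b - 1L, len)
    }
  }
  if (length(hits) == 0) return(empty)
  m <- do.call(rbind, hits)
  # convert rc offset to right_seq's own orientation
  out <- data.frame(left_pos = as.integer(m[, 1]),
                    right_pos = as.integer(nr - m[, 2] - m[, 3]),
                    length = as.integer(m[, 3]))
  out <- unique(out)
  out[order(out$left_pos, out$right_pos), , drop = FALSE]
}

#' Per-circRNA genomic feature profiles
#'
#' For every exonic circRNA in the catalog: position class, spanned exon
#' count and summed exonic length, flanking/control intron lengths, repeat
#' coverage of each intron class, and (when the genome is supplied)
#' inverted-repeat hits between the two flanking introns.
#'
#' @param catalog A `circ_catalog`.
#' @param genes A [gene_models] collection.
#' @param repeats Optional repeat data.frame (see [read_repeats()]).
#' @param genome Optional [Biostrings::DNAStringSet] of the scaffolds.
#' @param min_ir_len Minimum inverted-repeat length (default 20).
#' @param controls Control-intron definition, see
#'   [flanking_and_control_introns()].
#' @return data.frame, one row per exonic circRNA: `circ_id, parent_gene,
#'   position_class, n_backspliced_exons, exonic_length, left_flank_len,
#'   right_flank_len, n_control_introns, mean_control_len, left_repeat_frac,
#'   right_repeat_frac, control_repeat_frac, n_inverted_repeats,
#'   max_inverted_len`. Flank-length columns are `NA` where the flank does
#'   not exist; repeat/IR columns are `NA` when the corresponding input was
#'   not supplied.
#' @export
feature_profiles <- function(catalog, genes, repeats = NULL, genome = NULL,
                             min_ir_len = 20,
                             controls = c("internal", "noncirc")) {
  controls <- match.arg(controls)
  tab <- catalog$table
  ex <- tab[tab$circ_class == "exonic", , drop = FALSE]
  nr <- nrow(ex)
  out <- data.frame(circ_id = ex$circ_id, parent_gene = ex$parent_gene,
                    position_class = rep(NA_character_, nr),
                    n_backspliced_exons = rep(NA_integer_, nr),
                    exonic_length = rep(NA_real_, nr),
                    left_flank_len = rep(NA_real_, nr),
                    right_flank_len = rep(NA_real_, nr),
                    n_control_introns = rep(0L, nr),
                    mean_control_len = rep(NA_real_, nr),
                    left_repeat_frac = rep(NA_real_, nr),
                    right_repeat_frac = rep(NA_real_, nr),
                    control_repeat_frac = rep(NA_real_, nr),
                    n_inverted_repeats = rep(NA_integer_, nr),
                    max_inverted_len = rep(NA_integer_, nr),
                    stringsAsFactors = FALSE)
  if (nr == 0) return(out)
  for (r in seq_len(nrow(ex))) {
    g <- genes$genes[[ex$parent_gene[r]]]
    s <- ex$start[r]; e <- ex$end[r]
    out$position_class[r] <- position_class(s, e, g)
    sp <- spanned_exons(s, e, g)
    out$n_backspliced_exons[r] <- sp$n_backspliced_exons
    out$exonic_length[r] <- sp$exonic_length
    fl <- flanking_and_control_introns(s, e, g, controls)
    if (!is.null(fl$left)) out$left_flank_len[r] <- fl$left[2] - fl$left[1]
    if (!is.null(fl$right)) out$right_flank_len[r] <- fl$right[2] - fl$right[1]
    out$n_control_introns[r] <- nrow(fl$controls)
    if (nrow(fl$controls) > 0)
      out$mean_control_len[r] <- mean(interval_lengths(fl$controls))
    if (!is.null(repeats)) {
      rs <- repeats[repeats$scaffold == g$scaffold, , drop = FALSE]
      if (!is.null(fl$left))
        out$left_repeat_frac[r] <- repeat_coverage(fl$left, rs)
      if (!is.null(fl$right))
        out$right_repeat_frac[r] <- repeat_coverage(fl$right, rs)
      if (nrow(fl$controls) > 0) {
        covs <- apply(fl$controls, 1, repeat_coverage, repeats = rs)
        out$control_repeat_frac[r] <- mean(covs)
      }
    }
    if (!is.null(genome) && !is.null(fl$left) && !is.null(fl$right)) {
      seq_of <- function(iv) as.character(
        Biostrings::subseq(genome[[g$scaffold]], iv[1] + 1, iv[2]))
      lf <- seq_of(fl$left); rf <- seq_of(fl$right)
      if (nchar(lf) >= min_ir_len && nchar(rf) >= min_ir_len) {
        ir <- find_inverted_repeats(lf, rf, min_ir_len)
        out$n_inverted_repeats[r] <- nrow(ir)
        out$max_inverted_len[r] <- if (nrow(ir) > 0) max(ir$length) else 0L
      } else {
        out$n_inverted_repeats[r] <- 0L
        out$max_inverted_len[r] <- 0L
      }
    }
  }
  out
}

#' Alternative-circularization summary
#'
#' Groups exonic circRNAs by parent gene. Genes producing two or more
#' distinct circRNA isoforms are alternative-circularization loci; the event
#' count is the total number of isoforms arising from those loci, and the
#' histogram bins loci by isoform count (2, 3, >= 4).
#'
#' @param catalog A `circ_catalog`.
#' @return List of class `altcirc_summary`: `n_loci`, `n_events`,
#'   `histogram` (named vector `2`, `3`, `>=4`), `isoforms_per_gene`
#'   (named integer vector over all parent genes).
#' @export
alt_circularization <- function(catalog) {
  tab <- catalog$table
  ex <- tab[tab$circ_class == "exonic" & !is.na(tab$parent_gene), , drop = FALSE]
  iso <- table(ex$parent_gene)
  multi <- iso[iso >= 2]
  hist <- c(`2` = sum(multi == 2), `3` = sum(multi == 3),
            `>=4` = sum(multi >= 4))
  structure(list(n_loci = length(multi), n_events = as.integer(sum(multi)),
                 histogram = hist,
                 isoforms_per_gene = stats::setNames(as.integer(iso),
                                                     names(iso))),
            class = "altcirc_summary")
}

#' @export
print.altcirc_summary <- function(x, ...) {
  cat("alternative circularization:", x$n_events, "events from", x$n_loci,
      "parent gene loci\n")
  cat("  loci by isoform count: 2:", x$histogram[["2"]],
      " 3:", x$histogram[["3"]], " >=4:", x$histogram[[">=4"]], "\n")
  invisible(x)
}
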