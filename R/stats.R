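# Statistical machinery: correlation t-test, hypergeometric enrichment,
# BH q-values, stage-wise differential expression.

#' Pearson correlation between two expression profiles
#'
#' Returns `NA` (with a warning) when either profile has zero variance —
#' such pairs are excluded from correlation classification downstream.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Sample Pearson correlation coefficient, or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance profile; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Significance of a Pearson correlation via the t-distribution
#'
#' The statistic is `t = r / sqrt((1 - r^2) / (N - 2))`, referred to a
#' t-distribution with `N - 2` degrees of freedom (two-sided). `|r| = 1`
#' gives `p = 0` by convention.
#'
#' @param r Pearson correlation coefficient in \[-1, 1\].
#' @param N Number of paired samples (>= 3).
#' @return List with elements `t` and `p`.
#' @export
corr_t_test <- function(r, N) {
  if (N < 3) stop("N must be >= 3")
  if (is.na(r)) return(list(t = NA_real_, p = NA_real_))
  if (abs(r) > 1 + 1e-12) stop("|r| > 1")
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(t = sign(r) * Inf, p = 0))
  tval <- r / sqrt((1 - r^2) / (N - 2))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = N - 2))
}

#' Classify a correlation result against the r/q thresholds
#'
#' Defaults follow the study design: positive if `r >= 0.9` and `q < 0.01`,
#' negative if `r <= -0.9` and `q < 0.01`, otherwise `"none"`.
#'
#' @param r Correlation coefficient (NA allowed, gives `"none"`).
#' @param q FDR-adjusted p-value.
#' @param pos_r,neg_r,q_max Classification thresholds.
#' @return `"positive"`, `"negative"` or `"none"`.
#' @export
classify_correlation <- function(r, q, pos_r = 0.9, neg_r = -0.9,
                                 q_max = 0.01) {
  if (is.na(r) || is.na(q)) return("none")
  if (r >= pos_r && q < q_max) return("positive")
  if (r <= neg_r && q < q_max) return("negative")
  "none"
}

#' Hypergeometric point probability (log-space)
#'
#' P(X = k) where X counts annotated genes in a draw of `N` from a universe
#' of `n` annotated + `m` unannotated genes. Computed via log binomial
#' coefficients for stability at large counts.
#'
#' @param n Annotated genes in the universe.
#' @param m Unannotated genes in the universe.
#' @param N Draw (query set) size.
#' @param k Annotated genes observed in the draw.
#' @return Probability mass at `k`.
#' @export
hypergeom_pmf <- function(n, m, N, k) {
  if (k < max(0, N - m) || k > min(n, N)) return(0)
  exp(lchoose(n, k) + lchoose(m, N - k) - lchoose(n + m, N))
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= i): the enrichment p-value for observing `i` or more annotated
#' genes among `N` drawn from a universe of `n` annotated and `m`
#' unannotated genes. Summed in log space over the upper support.
#'
#' @inheritParams hypergeom_pmf
#' @param i Observed number of annotated genes in the query set.
#' @return Upper-tail probability in (0, 1\].
#' @export
hypergeom_tail <- function(n, m, N, i) {
  if (n < 0 || m < 0) stop("n and m must be non-negative")
  if (N < 0 || N > n + m) stop("N must satisfy 0 <= N <= n + m")
  if (i < 0 || i > min(n, N)) stop("i must satisfy 0 <= i <= min(n, N)")
  if (i <= max(0, N - m)) return(1)  # whole support
  ks <- i:min(n, N)
  logs <- lchoose(n, ks) + lchoose(m, N - ks) - lchoose(n + m, N)
  mx <- max(logs)
  min(1, exp(mx + log(sum(exp(logs - mx)))))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) p_(j) * M / j`, capped at 1;
#' the input order is preserved in the output.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric term enrichment for a query gene set
#'
#' One test per term carried by at least one query gene: `n` = universe genes
#' with the term, `m` = universe genes without it, `N` = query size, `i` =
#' query genes with the term; p = upper-tail hypergeometric probability,
#' q = BH adjustment across all tested terms. Results are sorted by q then p.
#'
#' @param query_genes Character vector (the query set, e.g. circRNA parent
#'   genes); must be a subset of `universe`.
#' @param term_map data.frame with columns `gene_id`, `term_id`.
#' @param universe Character vector of all genes in the annotation.
#' @return data.frame with columns `term_id, n, m, N, i, p, q`.
#' @export
enrich_terms <- function(query_genes, term_map, universe) {
  query_genes <- unique(as.character(query_genes))
  universe <- unique(as.character(universe))
  off <- setdiff(query_genes, universe)
  if (length(off) > 0)
    stop("query gene(s) absent from universe: ",
         paste(utils::head(off, 10), collapse = ", "))
  empty <- data.frame(term_id = character(0), n = integer(0), m = integer(0),
                      N = integer(0), i = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE)
  if (length(query_genes) == 0) return(empty)
  tm <- unique(term_map[term_map$gene_id %in% universe, , drop = FALSE])
  genes_by_term <- split(tm$gene_id, tm$term_id)
  hit <- vapply(genes_by_term, function(g) sum(query_genes %in% g), integer(1))
  genes_by_term <- genes_by_term[hit > 0]
  if (length(genes_by_term) == 0) return(empty)
  U <- length(universe)
  Nq <- length(query_genes)
  n <- vapply(genes_by_term, length, integer(1))
  i <- hit[hit > 0]
  p <- mapply(function(nn, ii) hypergeom_tail(nn, U - nn, Nq, ii), n, i)
  out <- data.frame(term_id = names(genes_by_term), n = n, m = U - n,
                    N = Nq, i = i, p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation testing and classification for feature pairs
#'
#' For each (circRNA, partner) pair: Pearson r over the shared samples, the
#' t-statistic `r / sqrt((1 - r^2) / (N - 2))`, a two-sided p from the
#' t-distribution with N - 2 df, BH q-values over all testable pairs in one
#' family, and the positive/negative/none call. Pairs with a zero-variance
#' profile are flagged (`undefined = TRUE`) and excluded from the family.
#'
#' @param circ_expr,partner_expr [expr_table]s holding the circRNA and
#'   partner (parent gene / NAT) profiles.
#' @param pairs data.frame with columns `circ_id`, `partner_id`.
#' @param pos_r,neg_r,q_max Classification thresholds (see
#'   [classify_correlation()]).
#' @return data.frame with columns `circ_id, partner_id, r, N, t, p, q,
#'   corr_class, undefined`.
#' @export
correlate_pairs <- function(circ_expr, partner_expr, pairs,
                            pos_r = 0.9, neg_r = -0.9, q_max = 0.01) {
  samples <- intersect(colnames(circ_expr$values), colnames(partner_expr$values))
  if (length(samples) < 3) stop("fewer than 3 shared samples")
  out <- data.frame(circ_id = as.character(pairs$circ_id),
                    partner_id = as.character(pairs$partner_id),
                    r = NA_real_, N = length(samples), t = NA_real_,
                    p = NA_real_, q = NA_real_, corr_class = "none",
                    undefined = FALSE, stringsAsFactors = FALSE)
  if (nrow(out) == 0) return(out)
  for (k in seq_len(nrow(out))) {
    ci <- out$circ_id[k]; gi <- out$partner_id[k]
    if (!ci %in% rownames(circ_expr$values) ||
        !gi %in% rownames(partner_expr$values)) {
      out$undefined[k] <- TRUE
      next
    }
    x <- circ_expr$values[ci, samples]
    y <- partner_expr$values[gi, samples]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      out$undefined[k] <- TRUE
      next
    }
    out$r[k] <- stats::cor(x, y)
    tt <- corr_t_test(out$r[k], length(samples))
    out$t[k] <- tt$t
    out$p[k] <- tt$p
  }
  ok <- !out$undefined
  out$q[ok] <- bh_adjust(out$p[ok])
  for (k in which(ok))
    out$corr_class[k] <- classify_correlation(out$r[k], out$q[k],
                                              pos_r, neg_r, q_max)
  out
}

#' Stage-wise differential expression of circRNAs
#'
#' For each circRNA, two-sided equal-variance two-sample t-tests are run for
#' every pair of stages on the per-sample abundances (CPM); the reported p is
#' the smallest pairwise p with a Bonferroni correction for the number of
#' pairs tested (3 for the standard three-stage design), and q-values are BH
#' over all non-degenerate circRNAs. `highest_stage` is the stage with the
#' largest mean abundance (ties resolved to the lexicographically first
#' stage and flagged).
#'
#' @param circ_expr [expr_table] of circRNA abundances (rows = circRNAs).
#' @param correct_pairs Multiply the minimum pairwise p by the number of
#'   stage pairs (default TRUE). Setting FALSE reports the raw minimum.
#' @param var_equal Use the pooled-variance t-test (default TRUE; with two
#'   replicates per stage the Welch degrees of freedom are degenerate).
#' @return data.frame: `circ_id`, one `mean_<stage>` column per stage,
#'   `p, q, highest_stage, tie, degenerate`.
#' @export
de_test <- function(circ_expr, correct_pairs = TRUE, var_equal = TRUE) {
  stages <- unique(circ_expr$sample_stage)
  per_stage <- table(circ_expr$sample_stage)
  if (any(per_stage < 2))
    stop("stage(s) with fewer than 2 samples: ",
         paste(names(per_stage)[per_stage < 2], collapse = ", "))
  vals <- circ_expr$values
  stage_cols <- lapply(stages, function(s)
    which(circ_expr$sample_stage == s))
  names(stage_cols) <- stages
  pair_idx <- utils::combn(stages, 2, simplify = FALSE)

  n <- nrow(vals)
  means <- matrix(NA_real_, n, length(stages),
                  dimnames = list(rownames(vals), stages))
  p <- rep(NA_real_, n)
  degenerate <- logical(n)
  for (r in seq_len(n)) {
    x <- vals[r, ]
    for (s in stages) means[r, s] <- mean(x[stage_cols[[s]]])
    pw <- vapply(pair_idx, function(pr) {
      a <- x[stage_cols[[pr[1]]]]; b <- x[stage_cols[[pr[2]]]]
      if (stats::sd(c(a, b)) == 0) return(NA_real_)
      tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(pw))) {
      degenerate[r] <- TRUE
    } else {
      pmin_raw <- min(pw, na.rm = TRUE)
      p[r] <- if (correct_pairs) min(1, length(pair_idx) * pmin_raw)
              else pmin_raw
    }
  }
  q <- rep(NA_real_, n)
  q[!degenerate] <- bh_adjust(p[!degenerate])
  hi <- apply(means, 1, function(m) {
    stages[order(-m, stages)][1]
  })
  tie <- apply(means, 1, function(m) sum(m == max(m)) > 1)
  out <- data.frame(circ_id = rownames(vals), means, p = p, q = q,
                    highest_stage = hi, tie = tie, degenerate = degenerate,
                    stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out)[1 + seq_along(stages)] <- paste0("mean_", stages)
  rownames(out) <- NULL
  out
}
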