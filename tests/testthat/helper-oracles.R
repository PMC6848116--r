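# Brute-force / first-principles oracles, kept independent of the package's
# computation paths: integer Pascal-triangle binomials instead of log-space
# lchoose, literal draw enumeration, per-nucleotide scans, all-substring
# comparison. Used to freeze expected values and in property tests.

# Binomial coefficients via Pascal's triangle (exact integer arithmetic in
# doubles; valid far beyond n = 20).
pascal_choose <- local({
  rows <- list(c(1))
  function(n, k) {
    if (k < 0 || k > n) return(0)
    while (length(rows) < n + 1) {
      prev <- rows[[length(rows)]]
      rows[[length(rows) + 1]] <<- c(1, prev[-1] + prev[-length(prev)], 1)
    }
    rows[[n + 1]][k + 1]
  }
})

# Upper-tail hypergeometric by exact integer arithmetic.
oracle_hyper_tail_pascal <- function(n, m, N, i) {
  ks <- max(i, max(0, N - m)):min(n, N)
  if (i > min(n, N)) return(0)
  num <- sum(vapply(ks, function(k)
    pascal_choose(n, k) * pascal_choose(m, N - k), numeric(1)))
  num / pascal_choose(n + m, N)
}

# Upper-tail hypergeometric by literal enumeration of every draw of N items
# from a universe of n annotated + m unannotated.
oracle_hyper_tail_enum <- function(n, m, N, i) {
  if (N == 0) return(if (i <= 0) 1 else 0)
  draws <- utils::combn(n + m, N)
  hits <- colSums(draws <= n)  # first n items are the annotated ones
  mean(hits >= i)
}

# One-sided (greater) Wilcoxon rank-sum p by full enumeration of all
# C(n1+n2, n1) assignments of the pooled ranks to group 1.
oracle_wilcoxon_greater <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  n1 <- length(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(length(pooled), n1)
  u_all <- apply(subsets, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mean(u_all >= u_obs)
}

# BH step-up applied literally from its definition.
oracle_bh <- function(p) {
  M <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(M)
  for (i in seq_len(M)) {
    js <- i:M
    q[i] <- min(1, min(ps[js] * M / js))
  }
  out <- numeric(M)
  out[o] <- q
  out
}

# Spanned exons by per-nucleotide membership scan.
oracle_spanned <- function(start, end, gene) {
  bases <- start:(end - 1)
  in_exon <- vapply(bases, function(b)
    any(gene$exons[, 1] <= b & b < gene$exons[, 2]), logical(1))
  touched <- vapply(seq_len(nrow(gene$exons)), function(j)
    any(bases >= gene$exons[j, 1] & bases < gene$exons[j, 2]), logical(1))
  list(n = sum(touched), len = sum(in_exon))
}

# Repeat coverage by per-nucleotide boolean scan.
oracle_repeat_coverage <- function(intron, reps) {
  if (NROW(reps) == 0) return(0)
  bases <- intron[1]:(intron[2] - 1)
  covered <- vapply(bases, function(b)
    any(reps[, 1] <= b & b < reps[, 2]), logical(1))
  mean(covered)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# All maximal exact matches >= min_len between L and revcomp(R), by direct
# comparison of every (i, j) start pair (O(n^2 L)).
oracle_inverted_repeats <- function(L, R, min_len) {
  rc <- oracle_revcomp(R)
  lc <- strsplit(L, "")[[1]]
  rcc <- strsplit(rc, "")[[1]]
  nl <- length(lc); nr <- length(rcc)
  eq <- function(i, j) lc[i] == rcc[j] && lc[i] != "N"
  hits <- list()
  for (i in seq_len(nl)) {
    for (j in seq_len(nr)) {
      if (!eq(i, j)) next
      if (i > 1 && j > 1 && eq(i - 1, j - 1)) next  # not left-maximal
      len <- 0
      while (i + len <= nl && j + len <= nr && eq(i + len, j + len))
        len <- len + 1
      if (len >= min_len)
        hits[[length(hits) + 1]] <-
          c(left_pos = i - 1L, right_pos = nr - (j - 1L) - len,
            length = as.integer(len))
    }
  }
  if (length(hits) == 0)
    return(data.frame(left_pos = integer(0), right_pos = integer(0),
                      length = integer(0)))
  out <- unique(as.data.frame(do.call(rbind, hits)))
  out[order(out$left_pos, out$right_pos), , drop = FALSE]
}

# Random DNA string (test fixtures)
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Small gene-model fixture with given exon intervals
mk_gene <- function(exons, strand = "+", id = "g1", scaffold = "scf1") {
  gene_model(id, scaffold, strand, do.call(rbind, exons))
}

expect_df_equal <- function(a, b) {
  rownames(a) <- NULL; rownames(b) <- NULL
  testthat::expect_equal(a, b)
}
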