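# Genomic features: exon position, spanned exons, flanking introns,
# Wilcoxon comparison, repeat coverage, inverted repeats, alt-circ.

five_exon_gene <- function(strand = "+")
  mk_gene(list(c(100, 200), c(300, 400), c(500, 600), c(700, 800),
               c(900, 1000)), strand = strand)

test_that("position class uses transcriptional exon order", {
  g <- five_exon_gene()
  expect_equal(position_class(300, 600, g), "middle")   # exons 2-3
  expect_equal(position_class(100, 200, g), "first")    # exon 1 alone
  expect_equal(position_class(900, 1000, g), "last")
  expect_equal(position_class(100, 1000, g), "ambiguous")
  # minus strand: genomically last exon is the transcriptional first
  gm <- five_exon_gene("-")
  expect_equal(position_class(900, 1000, gm), "first")
  expect_equal(position_class(100, 200, gm), "last")
  expect_equal(position_class(300, 600, gm), "middle")
  expect_error(position_class(150, 600, g), "not exonic")
})

test_that("spanned exons: count and clipped length match the base scan", {
  g <- mk_gene(list(c(100, 200), c(300, 400)))
  expect_equal(spanned_exons(100, 400, g),
               list(n_backspliced_exons = 2L, exonic_length = 200))
  expect_equal(spanned_exons(300, 400, g),
               list(n_backspliced_exons = 1L, exonic_length = 100))
  set.seed(23)
  for (rep in 1:30) {
    k <- sample(2:5, 1)
    starts <- cumsum(sample(20:60, 2 * k))
    ex <- lapply(seq_len(k), function(j) c(starts[2 * j - 1], starts[2 * j]))
    g <- mk_gene(ex)
    i1 <- sample(seq_len(k), 1); i2 <- (i1:k)[sample.int(k - i1 + 1, 1)]
    s <- g$exons[i1, 1]; e <- g$exons[i2, 2]
    got <- spanned_exons(s, e, g)
    want <- oracle_spanned(s, e, g)
    expect_equal(got$n_backspliced_exons, want$n)
    expect_equal(got$exonic_length, want$len)
  }
})

test_that("exonic length is invariant under splitting an exon in two", {
  g <- mk_gene(list(c(100, 200), c(300, 400), c(500, 600)))
  # split exon 2 at 350 into two abutting exons; merged model re-fuses them,
  # so build the split model directly and compare the clipped sum
  g_split <- mk_gene(list(c(100, 200), c(300, 350), c(350, 400),
                          c(500, 600)))
  a <- spanned_exons(100, 600, g)$exonic_length
  b <- spanned_exons(100, 600, g_split)$exonic_length
  expect_equal(a, b)
})

test_that("flanking and control introns follow the bracketing definition", {
  g <- mk_gene(list(c(100, 200), c(300, 400), c(500, 600), c(700, 800)))
  fl <- flanking_and_control_introns(300, 600, g)
  expect_equal(unname(fl$left), c(200, 300))
  expect_equal(unname(fl$right), c(600, 700))
  expect_equal(nrow(fl$controls), 1)
  expect_equal(unname(fl$controls[1, ]), c(400, 500))
  # circRNA at the gene's first exon: no left flank
  fl <- flanking_and_control_introns(100, 200, g)
  expect_null(fl$left)
  expect_equal(unname(fl$right), c(200, 300))
  expect_equal(nrow(fl$controls), 0)
  # single-exon gene: nothing to report
  g1 <- mk_gene(list(c(100, 200)))
  fl <- flanking_and_control_introns(100, 200, g1)
  expect_null(fl$left); expect_null(fl$right)
  expect_equal(nrow(fl$controls), 0)
  # alternative control definition: remaining introns of the gene
  fl <- flanking_and_control_introns(300, 600, g, controls = "noncirc")
  expect_equal(nrow(fl$controls), 0)  # both non-internal introns are flanks
})

test_that("intron length comparison: exact Wilcoxon for tiny samples", {
  res <- compare_intron_lengths(c(3, 4), c(1, 2))
  expect_true(res$exact)
  expect_equal(res$p, 1 / 6, tolerance = 1e-12)
  expect_equal(res$mean_flank, 3.5)
  # identical distributions: one-sided p >= 0.5
  res <- compare_intron_lengths(c(1.5, 2.5, 3.5), c(1.5, 2.5, 3.5) + 1e-9)
  expect_gte(res$p, 0.5)
  expect_error(compare_intron_lengths(numeric(0), c(1)), "non-empty")
})

test_that("repeat coverage merges overlapping repeats before summing", {
  reps <- rbind(c(10, 40), c(30, 60))
  expect_equal(repeat_coverage(c(0, 100), reps), 0.5)
  expect_equal(repeat_coverage(c(0, 100), NULL), 0)
  expect_equal(repeat_coverage(c(0, 100), rbind(c(0, 100))), 1)
  # clipping to the intron
  expect_equal(repeat_coverage(c(50, 100), rbind(c(0, 75))), 0.5)
  set.seed(29)
  for (rep in 1:25) {
    iv <- c(0, sample(50:150, 1))
    nr <- sample(0:6, 1)
    rp <- if (nr > 0) {
      st <- sample(seq(-20, iv[2] + 20), nr, replace = TRUE)
      cbind(st, st + sample(5:40, nr, replace = TRUE))
    } else matrix(numeric(0), ncol = 2)
    expect_equal(repeat_coverage(iv, rp), oracle_repeat_coverage(iv, rp),
                 tolerance = 1e-12)
  }
})

test_that("inverted repeats: planted matches found, random pairs clean", {
  set.seed(31)
  s <- rand_seq(30)
  left <- paste0(rand_seq(40), s, rand_seq(40))
  right <- paste0(rand_seq(25), oracle_revcomp(s), rand_seq(35))
  hits <- find_inverted_repeats(left, right, min_len = 20)
  expect_gte(nrow(hits), 1)
  expect_gte(max(hits$length), 30)
  best <- hits[which.max(hits$length), ]
  # the reported left substring must equal the revcomp of the right one
  lsub <- substr(left, best$left_pos + 1, best$left_pos + best$length)
  rsub <- substr(right, best$right_pos + 1, best$right_pos + best$length)
  expect_equal(lsub, oracle_revcomp(rsub))
  # same sequence on both sides is not an inverted repeat
  expect_equal(nrow(find_inverted_repeats(left, left, 20)), 0)
  expect_error(find_inverted_repeats("ACGTX", "ACGT", 8), "non-DNA")
  expect_error(find_inverted_repeats("ACGT", "ACGT", 4), "min_len")
})

test_that("inverted repeats: N never matches", {
  s <- strrep("ACGT", 10)
  left <- s
  right <- oracle_revcomp(s)
  expect_gte(nrow(find_inverted_repeats(left, right, 20)), 1)
  # poisoning the middle of the left copy with N splits the match
  left_n <- paste0(substr(s, 1, 19), "N", substr(s, 21, 40))
  hits <- find_inverted_repeats(left_n, right, 8)
  expect_true(all(hits$length < 40))
})

test_that("inverted repeats match the all-substring oracle and are
           symmetric", {
  set.seed(37)
  for (rep in 1:15) {
    L <- rand_seq(sample(40:70, 1))
    R <- rand_seq(sample(40:70, 1))
    if (rep %% 3 == 0) {  # plant one
      s <- rand_seq(sample(12:20, 1))
      substr(L, 5, 4 + nchar(s)) <- s
      substr(R, 8, 7 + nchar(s)) <- oracle_revcomp(s)
    }
    got <- find_inverted_repeats(L, R, 10)
    want <- oracle_inverted_repeats(L, R, 10)
    expect_df_equal(got, want)
    # symmetry: swapping the sequences mirrors the coordinates
    swapped <- find_inverted_repeats(R, L, 10)
    expect_df_equal(swapped[order(swapped$right_pos, swapped$left_pos),
                            c("right_pos", "left_pos", "length")] |>
                      stats::setNames(c("left_pos", "right_pos", "length")),
                    got[order(got$left_pos, got$right_pos), ])
  }
})

test_that("alternative circularization tallies loci, events, histogram", {
  tab <- data.frame(circ_id = paste0("c", 1:6),
                    circ_class = "exonic",
                    parent_gene = c("g1", "g1", "g2", "g2", "g2", "g3"),
                    stringsAsFactors = FALSE)
  cat <- structure(list(table = tab), class = "circ_catalog")
  ac <- alt_circularization(cat)
  expect_equal(ac$n_loci, 2)
  expect_equal(ac$n_events, 5)
  expect_equal(unname(ac$histogram), c(1, 1, 0))
  # all singletons
  tab$parent_gene <- paste0("g", 1:6)
  ac <- alt_circularization(structure(list(table = tab),
                                      class = "circ_catalog"))
  expect_equal(ac$n_loci, 0)
  expect_equal(ac$n_events, 0)
  # random catalogs vs group-by tally
  set.seed(41)
  for (rep in 1:15) {
    tab <- data.frame(circ_id = paste0("c", 1:30),
                      circ_class = sample(c("exonic", "intronic"), 30,
                                          replace = TRUE, prob = c(.8, .2)),
                      parent_gene = sample(paste0("g", 1:12), 30,
                                           replace = TRUE),
                      stringsAsFactors = FALSE)
    ac <- alt_circularization(structure(list(table = tab),
                                        class = "circ_catalog"))
    cnt <- table(tab$parent_gene[tab$circ_class == "exonic"])
    expect_equal(ac$n_events, as.integer(sum(cnt[cnt >= 2])))
    expect_equal(ac$n_loci, sum(cnt >= 2))
  }
})

test_that("position classes partition the exonic circRNAs of a catalog", {
  sim <- simulate_dataset(sim_config(n_genes = 40, n_circ = 60,
                                     n_pos_pairs = 5, n_neg_pairs = 5,
                                     n_null_pairs = 5, n_de = 5, seed = 43))
  cat <- build_catalog(do.call(rbind, sim$junctions), sim$genes,
                       sim$config$sample_stage)
  f <- feature_profiles(cat, sim$genes)
  expect_equal(nrow(f), sum(cat$table$circ_class == "exonic"))
  expect_true(all(f$position_class %in%
                    c("first", "middle", "last", "ambiguous")))
  expect_true(all(f$n_backspliced_exons >= 1))
  expect_true(all(f$exonic_length >= f$n_backspliced_exons))
})
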