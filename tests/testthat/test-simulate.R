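# Synthetic-data generator: determinism, structural validity, limit cases,
# plant placement, concordance calibration.

small_cfg <- function(...) {
  args <- list(n_genes = 40, n_circ = 60, n_pos_pairs = 5, n_neg_pairs = 5,
               n_null_pairs = 5, n_de = 5, n_repeat_flanks = 6,
               n_inverted_pairs = 4, seed = 42)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("the generator is deterministic: identical datasets and files", {
  cfg <- small_cfg()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$circs, b$circs)
  expect_identical(a$junctions, b$junctions)
  expect_identical(a$circ_expr$values, b$circ_expr$values)
  expect_identical(as.character(a$genome), as.character(b$genome))
  d1 <- file.path(tempdir(), "simdet1"); d2 <- file.path(tempdir(), "simdet2")
  write_sim_dataset(a, d1)
  write_sim_dataset(b, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  md5 <- function(d, f) unname(tools::md5sum(file.path(d, f)))
  for (f in f1) expect_equal(md5(d1, f), md5(d2, f))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("emitted files are structurally valid pipeline inputs", {
  sim <- simulate_dataset(small_cfg())
  d <- file.path(tempdir(), "simvalid")
  p <- write_sim_dataset(sim, d)
  gm <- read_gene_annotation(p$annotation)
  expect_equal(length(gm$genes), 40)
  # gene models survive the GFF3 round trip exactly
  for (id in names(gm$genes))
    expect_equal(gm$genes[[id]]$exons, sim$genes$genes[[id]]$exons)
  for (s in names(p$junctions)) {
    j <- read_junctions(p$junctions[s], s)
    expect_identical(j$circ_id, sim$junctions[[s]]$circ_id)
    expect_identical(j$count, as.integer(sim$junctions[[s]]$count))
  }
  # every planted exonic circRNA sits on merged-exon boundaries
  ex <- sim$circs[sim$circs$circ_class == "exonic", ]
  for (r in seq_len(nrow(ex))) {
    g <- gm$genes[[ex$gene_id[r]]]
    expect_true(ex$start[r] %in% g$exons[, 1])
    expect_true(ex$end[r] %in% g$exons[, 2])
  }
  # every planted intronic circRNA lies inside one intron of its gene
  int <- sim$circs[sim$circs$circ_class == "intronic", ]
  for (r in seq_len(nrow(int))) {
    g <- gm$genes[[int$gene_id[r]]]
    expect_true(any(g$introns[, 1] <= int$start[r] &
                      int$end[r] <= g$introns[, 2]))
  }
  unlink(d, recursive = TRUE)
})

test_that("limit cases: forced concordance and strict middle bias", {
  sim <- simulate_dataset(small_cfg(replicate_concordance = 1))
  ids <- lapply(sim$junctions, function(j) sort(j$circ_id))
  expect_identical(ids$M1, ids$M2)
  expect_identical(ids$P1, ids$FB2)  # detection probability 1 everywhere

  sim <- simulate_dataset(small_cfg(middle_exon_bias = 1))
  ex <- sim$truth[sim$truth$circ_class == "exonic", ]
  expect_true(all(ex$position_class == "middle"))
})

test_that("flank inflation 1 leaves flanks and controls exchangeable", {
  sim <- simulate_dataset(small_cfg(flank_inflation = 1, n_circ = 80,
                                    n_genes = 60))
  cat <- build_catalog(do.call(rbind, sim$junctions), sim$genes,
                       sim$config$sample_stage)
  f <- feature_profiles(cat, sim$genes)
  flanks <- c(f$left_flank_len, f$right_flank_len)
  flanks <- flanks[!is.na(flanks)]
  ctrl <- rep(f$mean_control_len[f$n_control_introns > 0],
              f$n_control_introns[f$n_control_introns > 0])
  expect_lt(abs(mean(flanks) / mean(ctrl) - 1), 0.25)
})

test_that("planted inverted repeats are present as reverse complements", {
  sim <- simulate_dataset(small_cfg())
  ircirc <- sim$circs[sim$circs$planted_ir, ]
  expect_gt(nrow(ircirc), 0)
  for (r in seq_len(nrow(ircirc))) {
    g <- sim$genes$genes[[ircirc$gene_id[r]]]
    fl <- flanking_and_control_introns(ircirc$start[r], ircirc$end[r], g)
    seq_of <- function(iv) as.character(
      Biostrings::subseq(sim$genome[[g$scaffold]], iv[1] + 1, iv[2]))
    hits <- find_inverted_repeats(seq_of(fl$left), seq_of(fl$right),
                                  min_len = 20)
    expect_gte(max(hits$length), sim$config$inverted_len)
  }
})

test_that("planted simple repeats land in the recorded flank intervals", {
  sim <- simulate_dataset(small_cfg())
  expect_gt(nrow(sim$repeats), 0)
  unit <- sim$config$repeat_unit
  for (r in seq_len(nrow(sim$repeats))) {
    sq <- as.character(Biostrings::subseq(
      sim$genome[[sim$repeats$scaffold[r]]],
      sim$repeats$start[r] + 1, sim$repeats$end[r]))
    expect_equal(sq, substr(strrep(unit, nchar(sq)), 1, nchar(sq)))
  }
})

test_that("plant bookkeeping: truth manifest ids exist in the emitted data", {
  sim <- simulate_dataset(small_cfg())
  tr <- sim$truth
  expect_setequal(tr$circ_id, sim$circs$circ_id)
  expect_true(all(tr$parent_gene %in% names(sim$genes$genes)))
  expect_true(all(stats::na.omit(tr$de_stage) %in%
                    unique(sim$config$sample_stage)))
  expect_true(all(rownames(sim$circ_expr$values) == tr$circ_id))
  # planted enrichment terms appear in the term map
  expect_true(all(attr(tr, "enriched_terms") %in% sim$term_map$term_id))
  # no DE plants among correlation plants
  expect_false(any(tr$de & tr$pair_class %in% c("positive", "negative",
                                                "null")))
  # disabling DE plants empties the manifest column
  sim0 <- simulate_dataset(small_cfg(n_de = 0))
  expect_false(any(sim0$truth$de))
})

test_that("replicate concordance is calibrated to the configured target", {
  # mean realized shared fraction (intersection over union, per stage)
  # across seeds should sit within +/-0.05 of the target
  fr <- c()
  for (seed in 1:12) {
    cfg <- small_cfg(seed = seed)
    ann <- simulate_annotation(cfg)
    junc <- simulate_junctions(cfg, ann)
    for (st in unique(cfg$sample_stage)) {
      reps <- names(cfg$sample_stage)[cfg$sample_stage == st]
      a <- junc[[reps[1]]]$circ_id; b <- junc[[reps[2]]]$circ_id
      fr <- c(fr, length(intersect(a, b)) / length(union(a, b)))
    }
  }
  expect_lt(abs(mean(fr) - 0.25), 0.05)
})

test_that("plant-count overflow and invalid configs are rejected", {
  expect_error(sim_config(fraction_exonic = 1.4), "probabilities")
  expect_error(sim_config(n_circ = -1), "non-negative")
  expect_error(sim_config(nb_dispersion = -0.1), "nb_dispersion")
  cfg <- small_cfg(n_pos_pairs = 100, n_neg_pairs = 100)
  expect_error(simulate_dataset(cfg), "exceeds|not enough")
})
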