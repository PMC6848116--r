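# Synthetic dataset with planted ground truth: a compact fungal-style
# genome annotation, back-spliced junction tables for 3 stages x 2
# replicates, repeat annotations, expression tables, and a term map. Every
# plant (circRNA class and position, flank inflation, correlated pairs,
# enriched terms, differentially expressed circRNAs, replicate concordance)
# is recorded in a truth manifest so recovery can be scored.

#' Simulation configuration
#'
#' Defaults emulate a fungal circRNA survey design: 3 developmental
#' stages (M = mycelia, P = primordia, FB = fruiting bodies) x 2 replicates,
#' ~25% replicate concordance, a strong middle-exon origin preference,
#' flanking introns twice as long as controls, negative-binomial
#' back-spliced counts, and planted positive/negative circRNA-gene
#' correlations, enriched terms and stage-specific differential expression.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Length-2 integer range of exons per gene.
#' @param exon_len_meanlog,exon_len_sdlog,exon_len_min Log-normal exon
#'   length parameters (nt).
#' @param intron_len_meanlog,intron_len_sdlog,intron_len_min Log-normal
#'   intron length parameters (nt).
#' @param flank_inflation Multiplicative length factor applied to the
#'   flanking introns of circRNA-producing spans (default 2).
#' @param n_circ Number of planted circRNAs.
#' @param fraction_exonic Fraction of planted circRNAs that are exonic.
#' @param middle_exon_bias Probability an exonic circRNA avoids the gene's
#'   first/last exons.
#' @param replicate_concordance Target shared fraction (intersection over
#'   union) between two replicates of one stage.
#' @param nb_mean,nb_dispersion Negative-binomial count parameters
#'   (`size = 1/nb_dispersion`; dispersion 0 gives the Poisson limit).
#' @param n_pos_pairs,n_neg_pairs,n_null_pairs Planted
#'   positively/negatively/un-correlated circRNA-parent-gene pairs.
#' @param corr_noise_sd Log-scale noise s.d. on planted expression profiles.
#' @param enriched_terms List of `list(term_id=, fold=)` enrichment plants.
#' @param n_background_terms,term_base_prob Background term map density.
#' @param n_de,de_fold Planted differentially expressed circRNAs and their
#'   stage fold-change.
#' @param n_repeat_flanks Flanking introns receiving a planted simple
#'   repeat.
#' @param repeat_unit,repeat_len Simple-repeat unit and planted length (nt).
#' @param n_inverted_pairs circRNAs receiving an inverted-repeat pair
#'   across their two flanking introns.
#' @param inverted_len Planted inverted-repeat length (nt; default 44,
#'   comfortably above the 30-40 nt pairing length sufficient to drive
#'   circularization).
#' @param n_scaffolds,intergenic_len,scaffold_len Genome layout; genes are
#'   placed round-robin without overlap. `scaffold_len = NULL` sizes each
#'   scaffold to its content; a fixed length errors if too short.
#' @param sample_stage Named character vector mapping the 6 samples to the
#'   3 stages.
#' @param seed Integer seed fixing every random draw.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 100,
                       exons_per_gene = c(5, 9),
                       exon_len_meanlog = log(200), exon_len_sdlog = 0.4,
                       exon_len_min = 60,
                       intron_len_meanlog = log(80), intron_len_sdlog = 0.3,
                       intron_len_min = 40,
                       flank_inflation = 2.0,
                       n_circ = 150,
                       fraction_exonic = 0.85,
                       middle_exon_bias = 0.98,
                       replicate_concordance = 0.25,
                       nb_mean = 8, nb_dispersion = 0.5,
                       n_pos_pairs = 20, n_neg_pairs = 20, n_null_pairs = 40,
                       corr_noise_sd = 0.03,
                       enriched_terms = list(list(term_id = "T_planted",
                                                  fold = 10)),
                       n_background_terms = 30, term_base_prob = 0.05,
                       n_de = 20, de_fold = 8,
                       n_repeat_flanks = 20,
                       repeat_unit = "AT", repeat_len = 50,
                       n_inverted_pairs = 10, inverted_len = 44,
                       n_scaffolds = 5, intergenic_len = 300,
                       scaffold_len = NULL,
                       sample_stage = c(M1 = "M", M2 = "M", P1 = "P",
                                        P2 = "P", FB1 = "FB", FB2 = "FB"),
                       seed = 42) {
  cfg <- as.list(environment())
  probs <- c(fraction_exonic, middle_exon_bias, replicate_concordance,
             term_base_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_genes, n_circ, n_pos_pairs, n_neg_pairs, n_null_pairs,
              n_de, n_repeat_flanks, n_inverted_pairs, n_background_terms)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (flank_inflation <= 0) stop("flank_inflation must be > 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_circ, "circRNAs,",
      length(x$sample_stage), "samples; seed", x$seed, "\n")
  invisible(x)
}

# sample() treats a length-1 numeric vector as 1:n; always index explicitly
sample_vec <- function(v, n = 1) v[sample.int(length(v), n)]

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tile_repeat <- function(unit, len) {
  substr(strrep(unit, ceiling(len / nchar(unit))), 1, len)
}

#' Simulate the genome annotation, sequence and repeat features
#'
#' Genes are placed without overlap on round-robin scaffolds. circRNA spans
#' are chosen first (exonic at merged-exon boundaries with the configured
#' middle-exon bias, intronic within single introns); the flanking introns
#' of exonic spans are then scaled by `flank_inflation`; a subset of flanks
#' receives a planted simple repeat, and a subset of circRNAs receives an
#' exact inverted-repeat pair (a random sequence in the left flank and its
#' reverse complement in the right flank) written into the genome sequence.
#'
#' @param cfg A [sim_config].
#' @return List with `genes` ([gene_models]), `genome`
#'   ([Biostrings::DNAStringSet]), `repeats` (data.frame) and `circs`
#'   (data.frame of planted circRNAs with coordinates, parent gene, type,
#'   position flags and plant flags).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], cfg$n_genes,
                 replace = TRUE)
  exon_lens <- lapply(n_ex, function(k)
    pmax(round(stats::rlnorm(k, cfg$exon_len_meanlog, cfg$exon_len_sdlog)),
         cfg$exon_len_min))
  intron_lens <- lapply(n_ex, function(k)
    pmax(round(stats::rlnorm(k - 1, cfg$intron_len_meanlog,
                             cfg$intron_len_sdlog)),
         cfg$intron_len_min))
  strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)

  # --- choose circRNA spans (gene-local, before layout) ---
  ne_circ <- round(cfg$n_circ * cfg$fraction_exonic)
  ni_circ <- cfg$n_circ - ne_circ
  eligible <- which(n_ex >= 4)
  if (length(eligible) == 0) stop("no gene has enough exons for circRNAs")
  span_probs <- c(0.45, 0.35, 0.20)

  # spans are placed so that a flanking intron of one circRNA is never
  # internal to another circRNA's span on the same gene: flank inflation
  # and control introns then stay disjoint, so the planted inflation factor
  # is recoverable from the emitted annotation
  seen_span <- character(0)
  gene_spans <- vector("list", cfg$n_genes)
  span_conflicts <- function(g, i1, i2) {
    cand_int <- if (i2 > i1) i1:(i2 - 1) else integer(0)
    cand_fl <- c(i1 - 1, i2)
    for (sp in gene_spans[[g]]) {
      ex_int <- if (sp[2] > sp[1]) sp[1]:(sp[2] - 1) else integer(0)
      ex_fl <- c(sp[1] - 1, sp[2])
      if (any(cand_fl %in% ex_int) || any(ex_fl %in% cand_int)) return(TRUE)
    }
    FALSE
  }
  exonic <- vector("list", ne_circ)
  for (c_i in seq_len(ne_circ)) {
    placed <- FALSE
    for (try in 1:400) {
      g <- sample_vec(eligible)
      k <- n_ex[g]
      middle <- stats::runif(1) < cfg$middle_exon_bias
      if (middle) {
        w <- sample(1:3, 1, prob = span_probs)
        w <- min(w, k - 2)
        i1 <- sample_vec(seq.int(2, k - w))
        i2 <- i1 + w - 1
      } else {
        w <- min(sample(1:3, 1, prob = span_probs), k - 1)
        if (stats::runif(1) < 0.5) { i1 <- 1; i2 <- w }
        else { i2 <- k; i1 <- k - w + 1 }
      }
      key <- paste(g, i1, i2)
      if (!key %in% seen_span && !span_conflicts(g, i1, i2)) {
        seen_span <- c(seen_span, key)
        gene_spans[[g]] <- c(gene_spans[[g]], list(c(i1, i2)))
        exonic[[c_i]] <- list(gene = g, i1 = i1, i2 = i2, middle = middle)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("n_circ exceeds the available exon-boundary slots; ",
           "increase n_genes or exons_per_gene")
  }

  intronic <- vector("list", ni_circ)
  seen_int <- character(0)
  for (c_i in seq_len(ni_circ)) {
    for (try in 1:200) {
      g <- sample_vec(which(n_ex >= 2))
      k <- sample_vec(seq_len(n_ex[g] - 1))
      ilen <- intron_lens[[g]][k]
      a <- sample.int(max(1, floor(ilen * 0.2)), 1)
      b <- a + max(10, floor(ilen * 0.5))
      if (b >= ilen) next
      key <- paste(g, k, a)
      if (!key %in% seen_int) {
        seen_int <- c(seen_int, key)
        intronic[[c_i]] <- list(gene = g, intron = k, off1 = a, off2 = b)
        break
      }
    }
    if (is.null(intronic[[c_i]]))
      stop("could not place intronic circRNA; introns too short")
  }

  # --- inflate flanking introns of exonic spans (each intron once, even
  # when shared by several circRNAs of the same gene) ---
  inflate <- unique(do.call(rbind, lapply(exonic, function(e)
    rbind(c(e$gene, e$i1 - 1), c(e$gene, e$i2)))))
  for (r in seq_len(NROW(inflate))) {
    g <- inflate[r, 1]; ii <- inflate[r, 2]
    if (ii >= 1 && ii <= n_ex[g] - 1)
      intron_lens[[g]][ii] <- round(intron_lens[[g]][ii] *
                                      cfg$flank_inflation)
  }

  # --- genome layout ---
  scaf_names <- sprintf("scf%02d", seq_len(cfg$n_scaffolds))
  scaf_of_gene <- scaf_names[(seq_len(cfg$n_genes) - 1) %% cfg$n_scaffolds + 1]
  cursor <- stats::setNames(rep(cfg$intergenic_len, cfg$n_scaffolds),
                            scaf_names)
  genes <- vector("list", cfg$n_genes)
  exon_abs <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    sc <- scaf_of_gene[g]
    pos <- cursor[sc]
    k <- n_ex[g]
    ex <- matrix(0, k, 2)
    for (j in seq_len(k)) {
      ex[j, 1] <- pos
      pos <- pos + exon_lens[[g]][j]
      ex[j, 2] <- pos
      if (j < k) pos <- pos + intron_lens[[g]][j]
    }
    cursor[sc] <- pos + cfg$intergenic_len
    exon_abs[[g]] <- ex
    genes[[g]] <- gene_model(sprintf("G%04d", g), sc, strands[g], ex)
  }
  scaf_len <- cursor
  if (!is.null(cfg$scaffold_len)) {
    if (any(scaf_len > cfg$scaffold_len))
      stop("scaffold too short to place genes; increase scaffold_len to at ",
           "least ", max(scaf_len))
    scaf_len[] <- cfg$scaffold_len
  }
  gm <- gene_models(genes)

  # --- circRNA absolute coordinates ---
  circ_rows <- list()
  for (e in exonic) {
    ex <- exon_abs[[e$gene]]
    st <- ex[e$i1, 1]; en <- ex[e$i2, 2]
    circ_rows[[length(circ_rows) + 1]] <-
      data.frame(gene_id = sprintf("G%04d", e$gene),
                 scaffold = scaf_of_gene[e$gene],
                 start = st, end = en, strand = strands[e$gene],
                 circ_class = "exonic", i1 = e$i1, i2 = e$i2,
                 middle = e$middle, stringsAsFactors = FALSE)
  }
  for (e in intronic) {
    g <- genes[[e$gene]]
    iv <- g$introns[e$intron, ]
    circ_rows[[length(circ_rows) + 1]] <-
      data.frame(gene_id = g$gene_id, scaffold = g$scaffold,
                 start = iv[1] + e$off1,
                 end = min(iv[1] + e$off2, iv[2] - 1),
                 strand = g$strand, circ_class = "intronic",
                 i1 = NA_integer_, i2 = NA_integer_, middle = NA,
                 stringsAsFactors = FALSE)
  }
  circs <- do.call(rbind, circ_rows)
  circs$circ_id <- paste(circs$scaffold, circs$start, circs$end, sep = "_")
  circs <- circs[!duplicated(circs$circ_id), , drop = FALSE]
  rownames(circs) <- NULL

  # --- planted repeats in flanking introns ---
  ex_idx <- which(circs$circ_class == "exonic")
  flank_of <- function(r, side) {
    g <- gm$genes[[circs$gene_id[r]]]
    fl <- flanking_and_control_introns(circs$start[r], circs$end[r], g)
    fl[[side]]
  }
  rep_rows <- list()
  circs$planted_repeat <- FALSE
  rep_seq <- tile_repeat(cfg$repeat_unit, cfg$repeat_len)
  both_flanks <- ex_idx[vapply(ex_idx, function(r)
    !is.null(flank_of(r, "left")) && !is.null(flank_of(r, "right")),
    logical(1))]
  n_rep <- min(cfg$n_repeat_flanks, length(both_flanks))
  rep_circ <- if (n_rep > 0) sample_vec(both_flanks, n_rep) else integer(0)
  for (r in rep_circ) {
    side <- sample(c("left", "right"), 1)
    fl <- flank_of(r, side)
    if (fl[2] - fl[1] < cfg$repeat_len + 10) next
    st <- fl[1] + 5
    rep_rows[[length(rep_rows) + 1]] <-
      data.frame(scaffold = circs$scaffold[r], start = st,
                 end = st + cfg$repeat_len, repeat_class = "Simple_repeat",
                 repeat_name = paste0("(", cfg$repeat_unit, ")n"),
                 stringsAsFactors = FALSE)
    circs$planted_repeat[r] <- TRUE
  }
  repeats <- if (length(rep_rows) > 0) do.call(rbind, rep_rows)
             else data.frame(scaffold = character(0), start = numeric(0),
                             end = numeric(0), repeat_class = character(0),
                             repeat_name = character(0))

  # --- planted inverted repeats across flanks ---
  circs$planted_ir <- FALSE
  plant_seq <- list()  # (scaffold, start, seq)
  ir_cand <- setdiff(both_flanks, rep_circ)
  n_ir <- min(cfg$n_inverted_pairs, length(ir_cand))
  ir_circ <- if (n_ir > 0) sample_vec(ir_cand, n_ir) else integer(0)
  for (r in ir_circ) {
    lf <- flank_of(r, "left"); rf <- flank_of(r, "right")
    if (lf[2] - lf[1] < cfg$inverted_len + 10 ||
        rf[2] - rf[1] < cfg$inverted_len + 10) next
    s <- rand_dna(cfg$inverted_len)
    plant_seq[[length(plant_seq) + 1]] <-
      list(scaffold = circs$scaffold[r], start = lf[1] + 5, seq = s)
    plant_seq[[length(plant_seq) + 1]] <-
      list(scaffold = circs$scaffold[r], start = rf[1] + 5,
           seq = revcomp_chr(s))
    circs$planted_ir[r] <- TRUE
  }

  # --- genome sequence with plants written in place ---
  seqs <- lapply(scaf_names, function(sc) rand_dna(scaf_len[sc]))
  names(seqs) <- scaf_names
  for (p in c(lapply(seq_len(nrow(repeats)), function(k)
                list(scaffold = repeats$scaffold[k],
                     start = repeats$start[k], seq = rep_seq)),
              plant_seq)) {
    s <- seqs[[p$scaffold]]
    substr(s, p$start + 1, p$start + nchar(p$seq)) <- p$seq
    seqs[[p$scaffold]] <- s
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- scaf_names

  list(genes = gm, genome = genome, repeats = repeats, circs = circs)
}

#' Simulate per-sample back-spliced junction tables
#'
#' Each planted circRNA is detected independently in each sample with
#' probability `p = 2c / (1 + c)` where `c` is the target replicate
#' concordance, so the expected replicate-shared fraction (intersection over
#' union) equals `c`. Detected counts are negative binomial
#' (`mu = nb_mean`, `size = 1/nb_dispersion`; Poisson when dispersion is 0),
#' floored at 1.
#'
#' @param cfg A [sim_config].
#' @param ann Output of [simulate_annotation()].
#' @return Named list (one element per sample) of junction data.frames with
#'   columns `scaffold, start, end, strand, count, sample_id, circ_id`.
#' @export
simulate_junctions <- function(cfg, ann) {
  set.seed(cfg$seed + 1L)
  p <- 2 * cfg$replicate_concordance / (1 + cfg$replicate_concordance)
  samples <- names(cfg$sample_stage)
  circs <- ann$circs
  out <- list()
  for (s in samples) {
    det <- stats::runif(nrow(circs)) < p
    n <- sum(det)
    counts <- if (cfg$nb_dispersion > 0)
      stats::rnbinom(n, mu = cfg$nb_mean, size = 1 / cfg$nb_dispersion)
    else stats::rpois(n, cfg$nb_mean)
    counts <- pmax(1L, counts)
    out[[s]] <- data.frame(scaffold = circs$scaffold[det],
                           start = circs$start[det], end = circs$end[det],
                           strand = circs$strand[det], count = counts,
                           sample_id = s, circ_id = circs$circ_id[det],
                           stringsAsFactors = FALSE)
  }
  out
}

#' Simulate expression tables, the term map and the truth manifest
#'
#' Gene profiles are drawn on a log-normal scale over the 6 samples. Planted
#' positive pairs set the circRNA profile to `b * gene + noise` with
#' `b > 0`; negative pairs use `b < 0` plus an offset keeping abundances
#' positive; null pairs and all remaining circRNAs get flat independent
#' profiles. Planted DE circRNAs have one stage's samples scaled by
#' `de_fold`. Planted enriched terms over-assign the term to circRNA parent
#' genes by the configured fold over the background probability.
#'
#' @param cfg A [sim_config].
#' @param ann Output of [simulate_annotation()].
#' @return List with `circ_expr` and `gene_expr` ([expr_table]s),
#'   `term_map` (data.frame) and `truth` (data.frame, one row per planted
#'   circRNA, with attributes `enriched_terms`, `flank_inflation`,
#'   `replicate_concordance`).
#' @export
simulate_expression <- function(cfg, ann) {
  set.seed(cfg$seed + 2L)
  samples <- names(cfg$sample_stage)
  stages <- unique(cfg$sample_stage)
  ns <- length(samples)
  circs <- ann$circs
  gene_ids <- names(ann$genes$genes)

  gene_vals <- t(vapply(gene_ids, function(g) {
    exp(stats::rnorm(ns, stats::rnorm(1, log(50), 0.5), 0.8))
  }, numeric(ns)))
  colnames(gene_vals) <- samples

  ex_idx <- which(circs$circ_class == "exonic" & !is.na(circs$gene_id))
  need <- cfg$n_pos_pairs + cfg$n_neg_pairs + cfg$n_null_pairs + cfg$n_de
  if (need > nrow(circs))
    stop("n_pos_pairs + n_neg_pairs + n_null_pairs + n_de (", need,
         ") exceeds the number of planted circRNAs (", nrow(circs), ")")
  if (need > length(ex_idx))
    stop("not enough exonic circRNAs (", length(ex_idx),
         ") for the requested plants (", need, ")")
  pick <- sample_vec(ex_idx, need)
  pos_set <- pick[seq_len(cfg$n_pos_pairs)]
  neg_set <- pick[cfg$n_pos_pairs + seq_len(cfg$n_neg_pairs)]
  null_set <- pick[cfg$n_pos_pairs + cfg$n_neg_pairs +
                     seq_len(cfg$n_null_pairs)]
  de_set <- pick[cfg$n_pos_pairs + cfg$n_neg_pairs + cfg$n_null_pairs +
                   seq_len(cfg$n_de)]

  circ_vals <- matrix(NA_real_, nrow(circs), ns,
                      dimnames = list(circs$circ_id, samples))
  pair_class <- rep(NA_character_, nrow(circs))
  de_flag <- logical(nrow(circs))
  de_stage <- rep(NA_character_, nrow(circs))
  for (r in seq_len(nrow(circs))) {
    g <- gene_vals[circs$gene_id[r], ]
    if (r %in% pos_set) {
      b <- stats::runif(1, 0.5, 2)
      prof <- b * g + stats::rnorm(ns, 0, cfg$corr_noise_sd * stats::sd(b * g))
      pair_class[r] <- "positive"
    } else if (r %in% neg_set) {
      b <- -stats::runif(1, 0.5, 2)
      a <- -b * max(g) * 1.1 + 1
      prof <- a + b * g + stats::rnorm(ns, 0, cfg$corr_noise_sd * stats::sd(b * g))
      pair_class[r] <- "negative"
    } else {
      base <- exp(stats::rnorm(1, log(30), 0.5))
      prof <- base * exp(stats::rnorm(ns, 0, cfg$corr_noise_sd))
      if (r %in% null_set) pair_class[r] <- "null"
      if (r %in% de_set) {
        st <- sample_vec(stages)
        prof[cfg$sample_stage == st] <- prof[cfg$sample_stage == st] *
          cfg$de_fold
        de_flag[r] <- TRUE
        de_stage[r] <- st
      }
    }
    circ_vals[r, ] <- pmax(prof, 0.01)
  }

  # term map: background density everywhere, planted fold on parent genes
  parents <- unique(circs$gene_id[circs$circ_class == "exonic"])
  tm_rows <- list()
  for (t_i in seq_len(cfg$n_background_terms)) {
    tid <- sprintf("T%03d", t_i)
    g <- gene_ids[stats::runif(length(gene_ids)) < cfg$term_base_prob]
    if (length(g) > 0)
      tm_rows[[length(tm_rows) + 1]] <-
        data.frame(gene_id = g, term_id = tid, stringsAsFactors = FALSE)
  }
  enriched_ids <- character(0)
  for (pl in cfg$enriched_terms) {
    p_parent <- min(1, cfg$term_base_prob * pl$fold)
    hit <- c(parents[stats::runif(length(parents)) < p_parent],
             setdiff(gene_ids, parents)[
               stats::runif(length(gene_ids) - length(parents)) <
                 cfg$term_base_prob])
    if (length(hit) == 0) hit <- parents[1]
    tm_rows[[length(tm_rows) + 1]] <-
      data.frame(gene_id = hit, term_id = pl$term_id,
                 stringsAsFactors = FALSE)
    enriched_ids <- c(enriched_ids, pl$term_id)
  }
  term_map <- unique(do.call(rbind, tm_rows))
  rownames(term_map) <- NULL

  pos_cls <- rep(NA_character_, nrow(circs))
  for (r in which(circs$circ_class == "exonic")) {
    g <- ann$genes$genes[[circs$gene_id[r]]]
    pos_cls[r] <- position_class(circs$start[r], circs$end[r], g)
  }
  truth <- data.frame(circ_id = circs$circ_id,
                      circ_class = circs$circ_class,
                      parent_gene = circs$gene_id,
                      position_class = pos_cls,
                      pair_class = pair_class,
                      de = de_flag, de_stage = de_stage,
                      planted_repeat = circs$planted_repeat,
                      planted_ir = circs$planted_ir,
                      stringsAsFactors = FALSE)
  attr(truth, "enriched_terms") <- enriched_ids
  attr(truth, "flank_inflation") <- cfg$flank_inflation
  attr(truth, "replicate_concordance") <- cfg$replicate_concordance

  list(circ_expr = expr_table(circ_vals, cfg$sample_stage),
       gene_expr = expr_table(gene_vals, cfg$sample_stage),
       term_map = term_map, truth = truth)
}

#' Simulate the complete dataset
#'
#' Runs [simulate_annotation()], [simulate_junctions()] and
#' [simulate_expression()] under the configuration's seed. The same
#' configuration always yields an identical dataset.
#'
#' @param cfg A [sim_config].
#' @return List of class `sim_dataset`: `config`, `genes`, `genome`,
#'   `repeats`, `circs`, `junctions` (per-sample list), `circ_expr`,
#'   `gene_expr`, `term_map`, `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ann <- simulate_annotation(cfg)
  junc <- simulate_junctions(cfg, ann)
  expr <- simulate_expression(cfg, ann)
  structure(c(list(config = cfg), ann,
              list(junctions = junc), expr),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", length(x$genes$genes), "genes,", nrow(x$circs),
      "planted circRNAs,", length(x$junctions), "samples\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits all pipeline input files: `annotation.gff3`, `genome.fa`,
#' `repeats.bed`, one `<sample>.junc.tsv` per sample (plain-tsv dialect),
#' `circ_expr.tsv`, `gene_expr.tsv`, `sample_map.tsv`, `term_map.tsv` and
#' `truth_manifest.tsv`. Writing is deterministic: the same dataset always
#' produces byte-identical files.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  gr_rows <- list()
  for (g in sim$genes$genes) {
    n <- nrow(g$exons)
    gr_rows[[length(gr_rows) + 1]] <- data.frame(
      scaffold = g$scaffold, start = g$exons[, 1] + 1, end = g$exons[, 2],
      strand = g$strand, type = "exon", gene_id = g$gene_id,
      stringsAsFactors = FALSE)
  }
  gdf <- do.call(rbind, gr_rows)
  gr <- GenomicRanges::GRanges(gdf$scaffold,
                               IRanges::IRanges(gdf$start, gdf$end),
                               strand = gdf$strand)
  S4Vectors::mcols(gr)$type <- gdf$type
  S4Vectors::mcols(gr)$source <- "circchar_sim"
  S4Vectors::mcols(gr)$gene_id <- gdf$gene_id
  paths$annotation <- file.path(dir, "annotation.gff3")
  rtracklayer::export(gr, paths$annotation, format = "gff3")

  paths$genome <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, paths$genome)

  paths$repeats <- file.path(dir, "repeats.bed")
  utils::write.table(sim$repeats, paths$repeats, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  paths$junctions <- character(0)
  for (s in names(sim$junctions)) {
    p <- file.path(dir, paste0(s, ".junc.tsv"))
    write_junctions(sim$junctions[[s]], p, "plain-tsv")
    paths$junctions[s] <- p
  }

  write_expr <- function(et, p) {
    df <- data.frame(feature_id = rownames(et$values), et$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths$circ_expr <- file.path(dir, "circ_expr.tsv")
  write_expr(sim$circ_expr, paths$circ_expr)
  paths$gene_expr <- file.path(dir, "gene_expr.tsv")
  write_expr(sim$gene_expr, paths$gene_expr)

  paths$sample_map <- file.path(dir, "sample_map.tsv")
  utils::write.table(data.frame(sample = names(sim$config$sample_stage),
                                stage = sim$config$sample_stage),
                     paths$sample_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  paths$term_map <- file.path(dir, "term_map.tsv")
  utils::write.table(sim$term_map, paths$term_map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  paths$truth <- file.path(dir, "truth_manifest.tsv")
  tr <- sim$truth
  utils::write.table(tr, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
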