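# End-to-end orchestration: read inputs, build and filter the catalog,
# replicate/stage comparisons, features, enrichment, differential
# expression, correlation, alternative circularization; write all
# intermediate TSVs and a machine-readable report.

default_pipeline_config <- function() {
  list(junction_dialect = "plain-tsv",
       min_count = 1, total_cutoff = 5, cutoff_mode = "sum",
       pos_r = 0.9, neg_r = -0.9, corr_q = 0.01, de_q = 0.05,
       ir_min_len = 20, controls = "internal",
       strict_strand = FALSE, tol = 0, seed = NULL)
}

#' Assemble a pipeline configuration
#'
#' Paths plus every threshold of the analysis, with the study's values as
#' defaults: per-sample junction read cutoff 1, total back-spliced count
#' cutoff 5, correlation thresholds r >= 0.9 / r <= -0.9 at q < 0.01,
#' differential expression at q < 0.05, inverted-repeat minimum length 20.
#'
#' @param annotation Path to the GFF3/GTF annotation (required).
#' @param junctions Named character vector of junction-table paths, one per
#'   sample (required; names are the sample ids).
#' @param sample_stage Named character vector mapping samples to stages, or
#'   the path of a two-column TSV (required).
#' @param out_dir Output directory (required).
#' @param genome Optional genome FASTA (enables the inverted-repeat scan).
#' @param repeats Optional repeat annotation (RepeatMasker `.out` or BED).
#' @param term_map Optional gene-to-term TSV (enables enrichment).
#' @param gene_expr Optional gene expression TSV (enables the
#'   circRNA-parent-gene correlation stage).
#' @param circ_expr Optional circRNA abundance TSV (e.g. externally computed
#'   CPM); when supplied it is used for the differential-expression and
#'   correlation stages instead of the catalog's own junction-count CPM.
#' @param ... Threshold overrides (see Details in [run_pipeline()]).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, junctions, sample_stage, out_dir,
                            genome = NULL, repeats = NULL, term_map = NULL,
                            gene_expr = NULL, circ_expr = NULL, ...) {
  cfg <- utils::modifyList(default_pipeline_config(), list(...))
  cfg$annotation <- annotation
  cfg$junctions <- junctions
  cfg$sample_stage <- sample_stage
  cfg$out_dir <- out_dir
  cfg$genome <- genome
  cfg$repeats <- repeats
  cfg$term_map <- term_map
  cfg$gene_expr <- gene_expr
  cfg$circ_expr <- circ_expr
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

catalog_frame <- function(catalog, min_count = 1) {
  tab <- catalog$table
  if (nrow(tab) == 0) {
    return(cbind(tab, stages_present = character(0)))
  }
  pres <- stage_presence(catalog$counts, catalog$sample_stage, min_count)
  cnt <- catalog$counts
  colnames(cnt) <- paste0("count_", colnames(cnt))
  cpm <- round(catalog$cpm, 4)
  colnames(cpm) <- paste0("cpm_", colnames(cpm))
  data.frame(tab, cnt, cpm,
             stages_present = vapply(pres, paste, character(1),
                                     collapse = ","),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full circRNA characterization pipeline
#'
#' Stages, in order: read inputs; build the consolidated catalog (junction
#' read cutoff `min_count`); replicate consensus per stage; three-way stage
#' comparison (exonic and intronic); total-count filter (`total_cutoff`,
#' default 5 summed over samples); genomic features with flank/control
#' intron comparison, repeat coverage and inverted-repeat scan; term
#' enrichment of the filtered parent genes; stage-wise differential
#' expression on CPM; circRNA-parent-gene correlation; alternative
#' circularization. Every stage writes a TSV under `out_dir`; tallies land
#' in `report.json`. The pipeline itself draws no random numbers, so
#' identical inputs give byte-identical outputs. A failing stage aborts
#' with the stage name. Optional inputs may be omitted: without a genome
#' the inverted-repeat fields are `NA`; without a term map or gene
#' expression table those stages are skipped.
#'
#' @param config A [pipeline_config] (or plain named list with the same
#'   fields).
#' @return Object of class `circ_run_report` (invisible): all stage results
#'   plus `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_pipeline_config(), unclass(config))
  for (f in c("annotation", "junctions", "sample_stage", "out_dir"))
    if (is.null(cfg[[f]])) stop("pipeline config lacks '", f, "'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()

  inputs <- stage("read_inputs", {
    sm <- cfg$sample_stage
    if (is.character(sm) && length(sm) == 1 && file.exists(sm))
      sm <- read_sample_map(sm)
    genes <- read_gene_annotation(cfg$annotation)
    junc <- lapply(names(cfg$junctions), function(s)
      read_junctions(cfg$junctions[[s]], s, cfg$junction_dialect))
    names(junc) <- names(cfg$junctions)
    genome <- if (!is.null(cfg$genome))
      Biostrings::readDNAStringSet(cfg$genome) else NULL
    if (!is.null(genome)) names(genome) <- sub("\\s.*", "", names(genome))
    repeats <- if (!is.null(cfg$repeats)) read_repeats(cfg$repeats) else NULL
    term_map <- if (!is.null(cfg$term_map)) read_term_map(cfg$term_map)
                else NULL
    gene_expr <- if (!is.null(cfg$gene_expr))
      read_expression(cfg$gene_expr, sm) else NULL
    circ_expr <- if (!is.null(cfg$circ_expr))
      read_expression(cfg$circ_expr, sm) else NULL
    list(genes = genes, junc = junc, genome = genome, repeats = repeats,
         term_map = term_map, gene_expr = gene_expr, circ_expr = circ_expr,
         sample_stage = sm)
  })
  sm <- inputs$sample_stage
  stages <- unique(sm)

  catalog <- stage("catalog", {
    junc <- do.call(rbind, inputs$junc)
    junc <- junc[junc$count >= cfg$min_count, , drop = FALSE]
    build_catalog(junc, inputs$genes, sm,
                  strict_strand = cfg$strict_strand, tol = cfg$tol)
  })
  paths$catalog <- write_tsv(catalog_frame(catalog, cfg$min_count),
                             file.path(cfg$out_dir, "catalog.tsv"))

  consensus <- stage("replicate_consensus", {
    out <- list()
    for (s in stages) {
      reps <- names(sm)[sm == s]
      if (length(reps) != 2) next
      ids <- lapply(reps, function(r)
        catalog$table$circ_id[catalog$counts[, r] >= cfg$min_count])
      shared <- consensus_replicates(ids[[1]], ids[[2]])
      un <- union(ids[[1]], ids[[2]])
      out[[s]] <- list(stage = s, n_rep1 = length(ids[[1]]),
                       n_rep2 = length(ids[[2]]), n_shared = length(shared),
                       n_union = length(un),
                       shared_fraction = if (length(un) > 0)
                         length(shared) / length(un) else NA_real_,
                       shared_ids = shared)
    }
    out
  })
  paths$consensus <- write_tsv(
    do.call(rbind, lapply(consensus, function(x)
      data.frame(x[c("stage", "n_rep1", "n_rep2", "n_shared", "n_union",
                     "shared_fraction")]))),
    file.path(cfg$out_dir, "replicate_consensus.tsv"))

  stage_cmp <- stage("stage_comparison", {
    if (length(stages) != 3) NULL else {
      sets_for <- function(cls) {
        lapply(stats::setNames(stages, stages), function(s) {
          reps <- names(sm)[sm == s]
          keep <- catalog$table$circ_class == cls &
            apply(catalog$counts[, reps, drop = FALSE] >= cfg$min_count,
                  1, any)
          catalog$table$circ_id[keep]
        })
      }
      list(exonic = compare_stages(sets_for("exonic")),
           intronic = compare_stages(sets_for("intronic")))
    }
  })
  if (!is.null(stage_cmp)) {
    cmp_df <- do.call(rbind, lapply(names(stage_cmp), function(cls) {
      x <- stage_cmp[[cls]]
      data.frame(circ_class = cls, region = names(x),
                 count = as.integer(x), stringsAsFactors = FALSE)
    }))
    paths$stage_comparison <- write_tsv(
      cmp_df, file.path(cfg$out_dir, "stage_comparison.tsv"))
  }

  filtered <- stage("filter", {
    filter_by_total_count(catalog, cfg$total_cutoff, cfg$cutoff_mode)
  })
  paths$filtered <- write_tsv(catalog_frame(filtered, cfg$min_count),
                              file.path(cfg$out_dir, "catalog_filtered.tsv"))

  features <- stage("features", {
    feature_profiles(filtered, inputs$genes, inputs$repeats, inputs$genome,
                     cfg$ir_min_len, cfg$controls)
  })
  paths$features <- write_tsv(features,
                              file.path(cfg$out_dir, "features.tsv"))

  feature_summary <- stage("feature_summary", {
    pos_tab <- table(factor(features$position_class,
                            levels = c("first", "middle", "last",
                                       "ambiguous")))
    flanks <- c(features$left_flank_len, features$right_flank_len)
    flanks <- flanks[!is.na(flanks)]
    ctrl_rows <- features[features$n_control_introns > 0, , drop = FALSE]
    ctrls <- rep(ctrl_rows$mean_control_len, ctrl_rows$n_control_introns)
    intron_cmp <- if (length(flanks) > 0 && length(ctrls) > 0)
      compare_intron_lengths(flanks, ctrls) else NULL
    has_rep <- function(x) !is.na(x) & x > 0
    list(n_exonic = nrow(features), position_classes = pos_tab,
         n_flank_introns = length(flanks), n_control_introns = length(ctrls),
         intron_comparison = intron_cmp,
         repeats_left = sum(has_rep(features$left_repeat_frac)),
         repeats_right = sum(has_rep(features$right_repeat_frac)),
         repeats_control = sum(has_rep(features$control_repeat_frac)),
         circ_with_inverted = sum(features$n_inverted_repeats > 0,
                                  na.rm = TRUE))
  })

  enrichment <- stage("enrichment", {
    if (is.null(inputs$term_map)) NULL else {
      query <- unique(features$parent_gene)
      if (length(query) == 0) NULL else
        enrich_terms(query, inputs$term_map, names(inputs$genes$genes))
    }
  })
  if (!is.null(enrichment))
    paths$enrichment <- write_tsv(enrichment,
                                  file.path(cfg$out_dir, "enrichment.tsv"))

  # abundance profiles for DE/correlation: the supplied circRNA expression
  # table when given (restricted to catalog members), else junction CPM
  circ_profiles <- stage("circ_profiles", {
    if (!is.null(inputs$circ_expr)) {
      keep <- rownames(inputs$circ_expr$values) %in% filtered$table$circ_id
      expr_table(inputs$circ_expr$values[keep, , drop = FALSE], sm)
    } else {
      expr_table(filtered$cpm, sm)
    }
  })

  de <- stage("differential_expression", {
    if (nrow(circ_profiles$values) == 0) NULL else de_test(circ_profiles)
  })
  if (!is.null(de))
    paths$de <- write_tsv(de, file.path(cfg$out_dir, "de.tsv"))

  correlation <- stage("correlation", {
    if (is.null(inputs$gene_expr)) NULL else {
      ex <- filtered$table[filtered$table$circ_class == "exonic" &
                             !is.na(filtered$table$parent_gene) &
                             filtered$table$circ_id %in%
                               rownames(circ_profiles$values), ,
                           drop = FALSE]
      pairs <- data.frame(circ_id = ex$circ_id, partner_id = ex$parent_gene,
                          stringsAsFactors = FALSE)
      if (nrow(pairs) == 0) NULL else
        correlate_pairs(circ_profiles, inputs$gene_expr, pairs,
                        cfg$pos_r, cfg$neg_r, cfg$corr_q)
    }
  })
  if (!is.null(correlation))
    paths$correlation <- write_tsv(correlation,
                                   file.path(cfg$out_dir, "correlation.tsv"))

  altcirc <- stage("alt_circularization", alt_circularization(filtered))
  paths$altcirc <- write_tsv(
    data.frame(metric = c("n_loci", "n_events", "loci_2", "loci_3",
                          "loci_ge4"),
               value = c(altcirc$n_loci, altcirc$n_events,
                         altcirc$histogram)),
    file.path(cfg$out_dir, "altcirc.tsv"))

  report <- structure(list(
    n_junctions = nrow(catalog$table),
    by_class = as.list(table(catalog$table$circ_class)),
    consensus = lapply(consensus, function(x)
      x[c("stage", "n_shared", "n_union", "shared_fraction")]),
    stage_comparison = if (!is.null(stage_cmp))
      lapply(stage_cmp, function(x) as.list(unclass(x))) else NULL,
    n_filtered = nrow(filtered$table),
    feature_summary = list(
      n_exonic = feature_summary$n_exonic,
      position_classes = as.list(feature_summary$position_classes),
      mean_flank = feature_summary$intron_comparison$mean_flank,
      mean_control = feature_summary$intron_comparison$mean_control,
      wilcoxon_p = feature_summary$intron_comparison$p,
      repeats_left = feature_summary$repeats_left,
      repeats_right = feature_summary$repeats_right,
      repeats_control = feature_summary$repeats_control,
      circ_with_inverted = feature_summary$circ_with_inverted),
    n_enriched_q01 = if (!is.null(enrichment)) sum(enrichment$q < 0.01)
                     else NULL,
    n_de_q05 = if (!is.null(de)) sum(de$q < cfg$de_q, na.rm = TRUE)
               else NULL,
    n_corr_positive = if (!is.null(correlation))
      sum(correlation$corr_class == "positive") else NULL,
    n_corr_negative = if (!is.null(correlation))
      sum(correlation$corr_class == "negative") else NULL,
    altcirc = list(n_loci = altcirc$n_loci, n_events = altcirc$n_events,
                   histogram = as.list(altcirc$histogram)),
    provenance = list(
      package_version = as.character(utils::packageVersion("circchar")),
      seed = cfg$seed,
      config_md5 = {
        par_only <- cfg[setdiff(names(cfg),
                                c("annotation", "junctions", "sample_stage",
                                  "out_dir", "genome", "repeats", "term_map",
                                  "gene_expr", "circ_expr"))]
        tf <- tempfile()
        writeLines(deparse(par_only[order(names(par_only))]), tf)
        h <- unname(tools::md5sum(tf)); unlink(tf); h
      })),
    class = "circ_run_report")
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  paths$report <- file.path(cfg$out_dir, "report.json")

  out <- structure(list(report = report, catalog = catalog,
                        filtered = filtered, consensus = consensus,
                        stage_comparison = stage_cmp, features = features,
                        feature_summary = feature_summary,
                        enrichment = enrichment, de = de,
                        correlation = correlation, altcirc = altcirc,
                        paths = paths),
                   class = "circ_run")
  invisible(out)
}

#' @export
print.circ_run <- function(x, ...) {
  r <- x$report
  cat("circRNA characterization run\n")
  cat("  junctions:", r$n_junctions,
      sprintf("(exonic %s, intronic %s, other %s)",
              r$by_class$exonic %||% 0, r$by_class$intronic %||% 0,
              r$by_class$other %||% 0), "\n")
  cat("  filtered (total count):", r$n_filtered, "\n")
  fs <- r$feature_summary
  if (!is.null(fs$wilcoxon_p))
    cat(sprintf("  flank vs control introns: %.1f vs %.1f nt, p = %.3g\n",
                fs$mean_flank, fs$mean_control, fs$wilcoxon_p))
  if (!is.null(r$n_de_q05)) cat("  DE circRNAs (q<0.05):", r$n_de_q05, "\n")
  if (!is.null(r$n_corr_positive))
    cat("  correlations: ", r$n_corr_positive, " positive, ",
        r$n_corr_negative, " negative\n", sep = "")
  cat("  alt-circ:", r$altcirc$n_events, "events from", r$altcirc$n_loci,
      "loci\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
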