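# End-to-end orchestration: simulate -> call peaks -> quantify -> classify ->
# enrichment tests -> co-occurrence -> expression -> report. One seed fixes
# the whole run; the summary JSON plus the run log reproduce it.

#' Default pipeline configuration
#'
#' All analysis thresholds default to the study's stated values: positivity
#' 5 reads/Kb, 1.5-fold change classification, CpG proximity 1 Kb, profile
#' window 3 Kb, heat-map window 1 Kb, co-occurrence window 2,500 bp scanned
#' across +/- 20 Kb, expression filter 2-fold at p < 0.05.
#'
#' @param seed integer seed for the whole run.
#' @param ... overrides of any top-level element (overrides are echoed to the
#'   run log with a warning-level note).
#' @return a nested configuration list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulation = list(),           # sim_config() overrides
    thresholds = list(positivity = 5, fold = 1.5, cpg_max_gap = 1000,
                      profile_flank = 3000, heatmap_flank = 1000, bin = 50,
                      pseudocount = 1, profile_pseudocount = 0.5,
                      cooccur_window = 2500, cooccur_span = 20000,
                      cooccur_step = 500, de_fold = 2, de_alpha = 0.05),
    peak_calling = list(window = 200, step = 50, min_fold = 4, p_max = 1e-5,
                        merge_gap = 200),
    stages = list(simulate = TRUE, callpeaks = TRUE, quantify = TRUE,
                  classify = TRUE, cooccur = TRUE, expression = TRUE),
    factors = c("rnf2", "suz12", "jarid2"))
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  attr(cfg, "overridden") <- names(over)
  cfg
}

#' Validate and normalize a pipeline configuration
#'
#' Checks every threshold and reports all problems at once rather than
#' stopping at the first. A missing seed is defaulted to 1 and noted.
#'
#' @param config a configuration list (e.g. from [default_config()] or
#'   [yaml::read_yaml()]).
#' @return the normalized configuration; attribute `"notes"` carries
#'   non-fatal normalization messages.
#' @export
validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  errs <- character(); notes <- character()
  if (is.null(config$seed)) {
    cfg$seed <- 1L
    notes <- c(notes, "seed missing; defaulted to 1")
  }
  th <- cfg$thresholds
  num_pos <- c("positivity", "cpg_max_gap", "profile_flank", "heatmap_flank",
               "bin", "cooccur_window", "cooccur_span", "cooccur_step",
               "de_alpha")
  for (nm in num_pos)
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0)
      errs <- c(errs, paste0("thresholds$", nm, " must be positive"))
  if (is.numeric(th$fold) && th$fold <= 1)
    errs <- c(errs, "thresholds$fold must exceed 1 (classification degenerate at 1)")
  if (is.numeric(th$de_fold) && th$de_fold <= 1)
    errs <- c(errs, "thresholds$de_fold must exceed 1")
  if (is.numeric(th$bin) && th$bin > 0) {
    for (nm in c("profile_flank", "heatmap_flank"))
      if (is.numeric(th[[nm]]) && (2 * th[[nm]]) %% th$bin != 0)
        errs <- c(errs, paste0("2 * thresholds$", nm,
                               " must be a multiple of thresholds$bin"))
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  attr(cfg, "notes") <- notes
  cfg
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full synthetic-study pipeline
#'
#' Simulates the study, calls binding-site peaks for the anchor factor
#' against IgG, builds the per-peak signal table, classifies 1.5-fold
#' gains/losses and tests their enrichment against TSS-distance-matched
#' controls, computes the co-occurrence matrix of the anchor and PRC1 peaks,
#' runs the expression filter, and writes tables, BED exports, a run log and
#' a JSON summary to `outdir`. Identical config + seed gives a byte-identical
#' summary.
#'
#' @param config configuration list (validated via [validate_config()]).
#' @param outdir output directory.
#' @return the summary list, invisibly; side effect: files under `outdir`.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  cfg <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logf))
  for (nt in attr(cfg, "notes")) .log_line(logf, "NOTE ", nt)
  for (ov in attr(config, "overridden") %||% character())
    .log_line(logf, "WARN threshold override: ", ov)
  th <- cfg$thresholds
  summary <- list(seed = cfg$seed)

  .log_line(logf, "simulate: toy genome + planted sites + tag tracks")
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulation))
  genome <- make_genome(scfg)
  sites <- plant_sites(genome, scfg)
  tracks <- simulate_tags(genome, sites, scfg)
  if (isTRUE(cfg$stages$simulate))
    write_simulation(file.path(outdir, "simulated"), scfg, genome, sites)
  summary$n_genes <- nrow(genome$genes)
  summary$n_cpg_islands <- nrow(genome$cpg_islands)
  summary$planted_sites <- as.list(table(sites$sites$site_class))

  peaks <- NULL
  if (isTRUE(cfg$stages$callpeaks)) {
    .log_line(logf, "callpeaks: rest_wt vs igg_wt (Poisson window test)")
    pc <- cfg$peak_calling
    peaks <- call_peaks(tracks$rest_wt, tracks$igg_wt, window = pc$window,
                        step = pc$step, min_fold = pc$min_fold,
                        p_max = pc$p_max, merge_gap = pc$merge_gap,
                        chrom_lengths = genome$chrom_lengths)
    write_bed(peaks[, c("chrom", "start", "end", "id")],
              file.path(outdir, "rest_peaks.bed"))
    summary$n_peaks <- nrow(peaks)
  }

  tab <- NULL
  if (isTRUE(cfg$stages$quantify) && !is.null(peaks) && nrow(peaks)) {
    .log_line(logf, "quantify: per-peak signal table")
    qt <- tracks[paste(rep(cfg$factors, each = 2), c("wt", "ko"), sep = "_")]
    tab <- peak_signal_table(peaks, qt, genes = genome$genes,
                             islands = genome$cpg_islands,
                             flank = th$heatmap_flank,
                             positivity_threshold = th$positivity,
                             pseudocount = th$pseudocount, fold = th$fold)
    write_tsv(as.data.frame(tab), file.path(outdir, "peak_signal_table.tsv"))
    summary$positivity <- lapply(stats::setNames(cfg$factors, cfg$factors),
                                 function(f) sum(tab[[paste0(f, "_positive")]]))
  }

  if (isTRUE(cfg$stages$classify) && !is.null(tab)) {
    .log_line(logf, "classify: 1.5-fold classes + chi2 vs matched controls")
    ctl <- matched_controls(peaks, genome$genes, genome$chrom_lengths,
                            seed = cfg$seed + 10L)
    qt <- tracks[paste(rep(cfg$factors, each = 2), c("wt", "ko"), sep = "_")]
    ctab <- peak_signal_table(ctl$controls, qt, flank = th$heatmap_flank,
                              positivity_threshold = th$positivity,
                              pseudocount = th$pseudocount, fold = th$fold)
    summary$classes <- list(); summary$chi2 <- list()
    for (f in cfg$factors) {
      sub <- positivity_filter(tab, f, th$positivity)
      csub <- positivity_filter(ctab, f, th$positivity)
      cls <- table(factor(sub[[paste0(f, "_class")]],
                          levels = c("decreased", "unchanged", "increased")))
      summary$classes[[f]] <- as.list(cls)
      bed <- sub[, c("chrom", "start", "end")]
      bed$id <- paste(sub$peak_id, sub[[paste0(f, "_class")]], sep = "|")
      write_bed(bed, file.path(outdir, paste0("classified_", f, ".bed")))
      for (dirn in c("decreased", "increased")) {
        et <- chi2_enrichment(sub[[paste0(f, "_class")]],
                              csub[[paste0(f, "_class")]], direction = dirn)
        summary$chi2[[paste(f, dirn, sep = "_")]] <-
          list(statistic = et$statistic, p_value = et$p_value)
      }
    }
  }

  if (isTRUE(cfg$stages$cooccur) && !is.null(peaks) && nrow(peaks)) {
    .log_line(logf, "cooccur: observed/expected matrix around TSS and TE")
    rnf2_peaks <- call_peaks(tracks$rnf2_wt, tracks$igg_wt,
                             chrom_lengths = genome$chrom_lengths)
    offs <- seq(-th$cooccur_span, th$cooccur_span, by = th$cooccur_step)
    summary$cooccurrence <- list()
    for (anch in c("tss", "te")) {
      ia <- gene_offset_indicators(peaks, genome$genes, anchor = anch,
                                   offsets = offs, window = th$cooccur_window)
      ib <- gene_offset_indicators(rnf2_peaks, genome$genes, anchor = anch,
                                   offsets = offs, window = th$cooccur_window)
      cm <- cooccurrence_matrix(ia, ib, anchor = anch)
      write_tsv(cooccurrence_table(cm),
                file.path(outdir, paste0("cooccurrence_", anch, ".tsv")))
      summary$cooccurrence[[anch]] <-
        list(cells = cm$bonferroni_cells,
             significant = sum(cm$significant, na.rm = TRUE))
    }
  }

  if (isTRUE(cfg$stages$expression)) {
    .log_line(logf, "expression: DE filter + Venn")
    expr <- simulate_expression(scfg)
    tgs <- setdiff(names(expr$groups), "control")
    de <- lapply(stats::setNames(tgs, tgs), function(g)
      de_filter(expr$matrix, expr$groups, control = "control", test = g,
                fold = th$de_fold, alpha = th$de_alpha, direction = "up"))
    for (g in tgs)
      write_tsv(de[[g]], file.path(outdir, paste0("de_", g, ".tsv")))
    summary$de_counts <- lapply(de, function(d) sum(d$pass))
    if (length(tgs) >= 2) {
      vc <- venn_counts(de[[1]]$probe_id[de[[1]]$pass],
                        de[[2]]$probe_id[de[[2]]$pass])
      summary$venn <- as.list(vc)
    }
  }

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, file.path(outdir, "summary.json"))
  .log_line(logf, "done: ", file.path(outdir, "summary.json"))
  invisible(summary)
}
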