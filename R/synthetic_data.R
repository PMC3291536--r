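# Synthetic study generator. The defaults define the simulated study: a toy
# genome of 2 chromosomes x 10 Mb carrying 1,000 genes, 600 planted binding
# sites in three occupancy classes (Rest-dependent loss of PcG distal from CpG
# islands, CpG-proximal PcG gain in the knockout, unchanged), uniform Poisson
# background tags, Gaussian focal tags at planted sites, and an IgG control
# with background only. Every draw is fixed by the seed.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic study; every field
#' has a default, so `sim_config(seed = 1)` is a complete configuration.
#'
#' @param seed integer; fixes every random draw.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_genes number of genes to place.
#' @param gene_length_range min/max gene body length in bp.
#' @param cpg_fraction_of_promoters probability that a gene's promoter carries
#'   a CpG island overlapping its TSS.
#' @param cpg_width_range min/max CpG island width in bp.
#' @param n_sites named vector of planted site counts per class
#'   (`rest_dependent_loss`, `cpg_gain`, `unchanged`, `background_control`).
#'   The `background_control` class models Rest-independent PcG binding: no
#'   Rest signal, PcG factors at base intensity in both genotypes; these sites
#'   give randomly placed control regions realistic, stable PcG signal to
#'   score positive on.
#' @param site_width planted binding site width in bp.
#' @param min_site_spacing minimum center-to-center distance between planted
#'   sites in bp.
#' @param background_rate background tag rate in tags per bp per sample; at
#'   the default 0.001 the chance of a random region passing the 5 reads/Kb
#'   positivity filter on background alone is negligible, so control-region
#'   positivity reflects the planted Rest-independent PcG sites.
#' @param focal_sd Gaussian spread (bp) of focal tags around a site center.
#' @param intensity named vector of mean focal tag counts per site in the
#'   wild type, per factor; `igg` always receives 0.
#' @param true_fold planted fold change at loss (wt/ko) and gain (ko/wt)
#'   sites.
#' @param gain_wt_attenuation multiplier on the wild-type PcG intensity at
#'   `cpg_gain` sites (the knockout gain builds on this attenuated base), so
#'   gained signal is signal the wild type largely lacked and total focal tags
#'   stay comparable between genotypes.
#' @param depth named vector of per-sample relative depths (multiplies both
#'   background and focal rates); defaults to 1 for every sample.
#' @param edge_margin keep planted sites this far from chromosome ends.
#' @param expression parameters for [simulate_expression()]: a list with
#'   `n_probes`, `groups` (named replicate counts), `n_de_up` (named per test
#'   group), `de_overlap`, `de_fold`, `noise_sd`, `base_mean`.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                       n_genes = 1000,
                       gene_length_range = c(2000, 20000),
                       cpg_fraction_of_promoters = 0.6,
                       cpg_width_range = c(500, 2000),
                       n_sites = c(rest_dependent_loss = 200, cpg_gain = 200,
                                   unchanged = 200, background_control = 1500),
                       site_width = 200,
                       min_site_spacing = 4000,
                       background_rate = 0.001,
                       focal_sd = 100,
                       intensity = c(rest = 80, rnf2 = 60, suz12 = 60,
                                     jarid2 = 60, h3k27me3 = 60),
                       true_fold = 4,
                       gain_wt_attenuation = 1 / 3,
                       depth = NULL,
                       edge_margin = 5000,
                       expression = list()) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_genes = n_genes, gene_length_range = gene_length_range,
              cpg_fraction_of_promoters = cpg_fraction_of_promoters,
              cpg_width_range = cpg_width_range, n_sites = n_sites,
              site_width = site_width, min_site_spacing = min_site_spacing,
              background_rate = background_rate, focal_sd = focal_sd,
              intensity = intensity, true_fold = true_fold,
              gain_wt_attenuation = gain_wt_attenuation, depth = depth,
              edge_margin = edge_margin,
              expression = utils::modifyList(
                list(n_probes = 1000,
                     groups = c(control = 3, rest_kd = 3, rnf2_kd = 3),
                     n_de_up = c(rest_kd = 100, rnf2_kd = 60),
                     de_overlap = 30, de_fold = 4, noise_sd = 0.25,
                     base_mean = 100),
                expression))
  errs <- character()
  if (is.null(names(cfg$chrom_lengths)) || anyDuplicated(names(cfg$chrom_lengths)))
    errs <- c(errs, "chrom_lengths must have unique names")
  if (any(cfg$chrom_lengths <= 0)) errs <- c(errs, "chrom_lengths must be > 0")
  if (cfg$background_rate < 0) errs <- c(errs, "background_rate must be >= 0")
  if (any(cfg$intensity < 0)) errs <- c(errs, "intensities must be >= 0")
  if (cfg$cpg_fraction_of_promoters < 0 || cfg$cpg_fraction_of_promoters > 1)
    errs <- c(errs, "cpg_fraction_of_promoters must be in [0, 1]")
  if (cfg$true_fold <= 1.5) errs <- c(errs, "true_fold must exceed 1.5")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  structure(cfg, class = "sim_config")
}

#' Generate the toy genome: layout, gene models and CpG islands
#'
#' Genes are placed without overlap (uniform random gaps between consecutive
#' gene bodies), strands drawn 50/50, and a Bernoulli
#' (`cpg_fraction_of_promoters`) subset of promoters receives a CpG island
#' overlapping the TSS. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_genome` with `chrom_lengths`, `genes` (gene
#'   model table), `cpg_islands` (interval data frame).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- names(config$chrom_lengths)
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = length(chroms) + 1)))
  genes <- list(); islands <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]; len <- config$chrom_lengths[[ci]]
    ng <- per_chrom[ci]
    if (!ng) next
    glen <- round(stats::runif(ng, config$gene_length_range[1],
                               config$gene_length_range[2]))
    slack <- len - sum(glen)
    if (slack < ng + 1)
      stop("cannot place ", ng, " non-overlapping genes on ", ch,
           " at the requested density")
    # random partition of the slack into ng+1 intergenic gaps
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, ng + 1)))
    starts <- cumsum(gaps[-length(gaps)]) + c(0, cumsum(glen[-ng]))
    ends <- starts + glen
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    tss <- ifelse(strand == "+", starts, ends)
    te <- ifelse(strand == "+", ends, starts)
    gid <- sprintf("gene_%s_%04d", ch, seq_len(ng))
    genes[[ci]] <- data.frame(gene_id = gid, chrom = ch, strand = strand,
                              tss = tss, te = te, stringsAsFactors = FALSE)
    has_cpg <- stats::runif(ng) < config$cpg_fraction_of_promoters
    if (any(has_cpg)) {
      w <- round(stats::runif(sum(has_cpg), config$cpg_width_range[1],
                              config$cpg_width_range[2]))
      u <- stats::runif(sum(has_cpg), 0.2, 0.8)   # TSS sits inside the island
      is_start <- pmax(0, round(tss[has_cpg] - w * u))
      is_end <- pmin(len, is_start + w)
      islands[[ci]] <- data.frame(chrom = ch, start = is_start, end = is_end,
                                  id = paste0("cpg_", gid[has_cpg]),
                                  stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  islands <- if (length(islands)) do.call(rbind, islands) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               id = character())
  structure(list(chrom_lengths = config$chrom_lengths, genes = genes,
                 cpg_islands = islands),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>", length(x$chrom_lengths), "chromosomes,",
      sum(x$chrom_lengths) / 1e6, "Mb,", nrow(x$genes), "genes,",
      nrow(x$cpg_islands), "CpG islands\n")
  invisible(x)
}

# Border gap from a candidate site [s, e) to the nearest island; Inf with no
# islands on the chromosome.
.island_gap <- function(ch, s, e, islands) {
  ii <- which(islands$chrom == ch)
  if (!length(ii)) return(Inf)
  g <- pmax(islands$start[ii] - e, s - islands$end[ii])
  max(min(g), 0)
}

#' Plant binding sites with known occupancy classes
#'
#' Places `n_sites` sites per class at random, subject to: loss sites more
#' than 1 Kb from any CpG island (border gap), gain sites within 1 Kb of an
#' island, all site centers at least `min_site_spacing` apart and
#' `edge_margin` from chromosome ends. Each site gets a per-factor,
#' per-genotype true focal intensity: the wild-type level from
#' `config$intensity`, the knockout level divided (loss) or multiplied (gain)
#' by `true_fold` for the PcG factors, unchanged otherwise. Rest signal is
#' absent in the knockout everywhere (the gene is deleted) and IgG has no
#' focal signal. `background_control` sites carry no Rest signal but stable
#' PcG signal in both genotypes.
#'
#' @param genome a [make_genome()] result.
#' @param config a [sim_config()].
#' @param max_tries placement retries per site before failing.
#' @return list of class `planted_sites`: `sites` (interval data frame with
#'   `site_class`, `cpg_gap`, `cpg_linked`) and `intensities` (long table
#'   site_id x factor x genotype -> intensity).
#' @export
plant_sites <- function(genome, config, max_tries = 10000) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(config$seed + 1L)
  chroms <- names(genome$chrom_lengths)
  probs <- genome$chrom_lengths / sum(genome$chrom_lengths)
  w <- config$site_width
  isl <- genome$cpg_islands
  centers <- list()   # accepted centers per chromosome
  rows <- list()
  classes <- rep(names(config$n_sites), config$n_sites)
  k <- 0
  for (cls in classes) {
    k <- k + 1
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      if (cls == "cpg_gain") {
        if (!nrow(isl)) stop("cpg_gain sites need CpG islands in the genome")
        j <- sample(nrow(isl), 1)
        ch <- isl$chrom[j]
        ctr <- round(stats::runif(1, isl$start[j] - 1000 - w / 2,
                                  isl$end[j] + 1000 + w / 2))
      } else {
        ch <- sample(chroms, 1, prob = probs)
        ctr <- round(stats::runif(1, config$edge_margin,
                                  genome$chrom_lengths[[ch]] - config$edge_margin))
      }
      if (ctr < config$edge_margin ||
          ctr > genome$chrom_lengths[[ch]] - config$edge_margin) next
      s <- ctr - w %/% 2; e <- s + w
      gap <- .island_gap(ch, s, e, isl)
      if (cls == "rest_dependent_loss" && gap <= 1000) next
      if (cls == "cpg_gain" && gap > 1000) next
      prev <- centers[[ch]]
      if (!is.null(prev) && length(prev) &&
          min(abs(prev - ctr)) < config$min_site_spacing) next
      centers[[ch]] <- c(prev, ctr)
      rows[[k]] <- data.frame(chrom = ch, start = s, end = e,
                              id = sprintf("site_%04d", k),
                              site_class = cls, cpg_gap = gap,
                              cpg_linked = gap <= 1000,
                              stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("failed to place a '", cls, "' site after ", max_tries, " tries")
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               id = character(), site_class = character(),
               cpg_gap = numeric(), cpg_linked = logical())
  pcg <- setdiff(names(config$intensity), "rest")
  grid <- expand.grid(site_id = sites$id,
                      factor = c(names(config$intensity), "igg"),
                      genotype = c("wt", "ko"), stringsAsFactors = FALSE)
  if (!nrow(grid))
    return(structure(list(sites = sites,
                          intensities = cbind(grid, intensity = numeric(0))),
                     class = "planted_sites"))
  grid$intensity <- 0
  cls_of <- sites$site_class[match(grid$site_id, sites$id)]
  base <- ifelse(grid$factor == "igg", 0,
                 config$intensity[grid$factor])
  focal <- grid$factor != "igg"
  wtlev <- ifelse(focal, base, 0)
  # background_control sites carry Rest-independent, genotype-stable PcG
  # signal: no Rest binding, PcG factors at base intensity in both genotypes
  wtlev[grid$factor == "rest" & cls_of == "background_control"] <- 0
  gainrows <- focal & cls_of == "cpg_gain" & grid$factor %in% pcg
  wtlev[gainrows] <- wtlev[gainrows] * config$gain_wt_attenuation
  kolev <- wtlev
  lossrows <- focal & cls_of == "rest_dependent_loss" & grid$factor %in% pcg
  kolev[lossrows] <- wtlev[lossrows] / config$true_fold
  kolev[gainrows] <- wtlev[gainrows] * config$true_fold
  kolev[grid$factor == "rest"] <- 0      # the factor itself is knocked out
  grid$intensity <- ifelse(grid$genotype == "wt", wtlev, kolev)
  structure(list(sites = sites, intensities = grid),
            class = "planted_sites")
}

#' @export
print.planted_sites <- function(x, ...) {
  cat("<planted_sites>\n")
  print(table(x$sites$site_class))
  invisible(x)
}

#' Default sample sheet for the simulated ChIP-seq study
#'
#' @param factors antibody labels (IgG is appended automatically).
#' @param genotypes genotype labels.
#' @return data frame with `sample_id`, `factor`, `genotype`, `depth`.
#' @export
sample_sheet <- function(factors = c("rest", "rnf2", "suz12", "jarid2",
                                     "h3k27me3"),
                         genotypes = c("wt", "ko")) {
  grid <- expand.grid(factor = c(factors, "igg"), genotype = genotypes,
                      stringsAsFactors = FALSE)
  data.frame(sample_id = paste(grid$factor, grid$genotype, sep = "_"),
             factor = grid$factor, genotype = grid$genotype, depth = 1,
             stringsAsFactors = FALSE)
}

#' Simulate ChIP-seq tag tracks
#'
#' Per sample: a uniform Poisson background (`background_rate x length x
#' depth` expected tags per chromosome) plus, for each planted site, a
#' Poisson(`intensity x depth`) number of focal tags at Gaussian offsets
#' (`focal_sd`) around the site center, truncated to the chromosome. IgG
#' samples receive background only; strands are drawn 50/50. Deterministic
#' given the config seed; samples are generated in sheet order.
#'
#' @param genome a [make_genome()] result.
#' @param sites a [plant_sites()] result.
#' @param config a [sim_config()].
#' @param samples a sample sheet (default [sample_sheet()]); a `depth` column
#'   scales each sample's rates.
#' @return named list of [tag_track()] objects keyed by sample id.
#' @export
simulate_tags <- function(genome, sites, config, samples = sample_sheet()) {
  stopifnot(inherits(genome, "sim_genome"), inherits(sites, "planted_sites"))
  set.seed(config$seed + 2L)
  if (!is.null(config$depth)) {
    idx <- match(samples$sample_id, names(config$depth))
    samples$depth <- ifelse(is.na(idx), 1, config$depth[idx])
  }
  tracks <- list()
  for (si in seq_len(nrow(samples))) {
    fac <- samples$factor[si]; gt <- samples$genotype[si]
    depth <- samples$depth[si]
    pos <- lapply(names(genome$chrom_lengths), function(ch) {
      len <- genome$chrom_lengths[[ch]]
      nbg <- stats::rpois(1, config$background_rate * len * depth)
      p <- floor(stats::runif(nbg, 0, len))
      sit <- sites$sites[sites$sites$chrom == ch, , drop = FALSE]
      if (nrow(sit)) {
        lam_map <- stats::setNames(
          sites$intensities$intensity,
          paste(sites$intensities$site_id, sites$intensities$factor,
                sites$intensities$genotype))
        lam <- unname(lam_map[paste(sit$id, fac, gt)])
        lam[is.na(lam)] <- 0
        ctr <- interval_center(sit)
        for (j in seq_len(nrow(sit))) {
          nf <- stats::rpois(1, lam[j] * depth)
          if (nf)
            p <- c(p, pmin(pmax(round(stats::rnorm(nf, ctr[j],
                                                   config$focal_sd)), 0),
                           len - 1))
        }
      }
      sort(p)
    })
    names(pos) <- names(genome$chrom_lengths)
    str <- lapply(pos, function(p) sample(c("+", "-"), length(p),
                                          replace = TRUE))
    tracks[[samples$sample_id[si]]] <-
      tag_track(pos, sample_id = samples$sample_id[si], factor = fac,
                genotype = gt, strand = str,
                chrom_lengths = genome$chrom_lengths)
  }
  tracks
}

#' Simulate a probe-level expression matrix with planted DE genes
#'
#' Probes get a common base mean; each test group's planted up-regulated
#' probes are multiplied by `de_fold` (true fold > 2 on the mean scale),
#' `de_overlap` of them shared between the first two test groups. Replicate
#' noise is log-normal: `value = mean * 2^rnorm(0, noise_sd)`. Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()]; see the `expression` element.
#' @return list of class `sim_expression`: `matrix` (probe x sample),
#'   `groups` (named list of sample names), `truth` (probe_id, per-test-group
#'   logical DE flags).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  set.seed(config$seed + 3L)
  ngrp <- ex$groups
  samples <- unlist(lapply(names(ngrp), function(g)
    paste(g, seq_len(ngrp[[g]]), sep = "_")))
  groups <- lapply(names(ngrp), function(g)
    paste(g, seq_len(ngrp[[g]]), sep = "_"))
  names(groups) <- names(ngrp)
  np <- ex$n_probes
  probe_ids <- sprintf("probe_%05d", seq_len(np))
  test_groups <- setdiff(names(ngrp), "control")
  truth <- data.frame(probe_id = probe_ids, stringsAsFactors = FALSE)
  de_sets <- list()
  shared <- seq_len(min(ex$de_overlap, np))
  nxt <- length(shared) + 1
  for (g in test_groups) {
    nde <- if (g %in% names(ex$n_de_up)) ex$n_de_up[[g]] else 0
    own <- max(0, nde - length(shared))
    idx <- c(shared[seq_len(min(length(shared), nde))],
             if (own > 0) seq(nxt, length.out = own))
    nxt <- nxt + own
    de_sets[[g]] <- idx
    truth[[paste0("de_", g)]] <- seq_len(np) %in% idx
  }
  m <- matrix(NA_real_, np, length(samples),
              dimnames = list(probe_ids, samples))
  for (g in names(ngrp)) {
    mu <- rep(ex$base_mean, np)
    if (g %in% names(de_sets)) mu[de_sets[[g]]] <- mu[de_sets[[g]]] * ex$de_fold
    for (s in groups[[g]])
      m[, s] <- mu * 2^stats::rnorm(np, 0, ex$noise_sd)
  }
  structure(list(matrix = m, groups = groups, truth = truth),
            class = "sim_expression")
}

#' Write the full synthetic bundle to a directory
#'
#' Emits tag tracks as BED6, planted sites and CpG islands as BED, gene
#' models and the ground-truth manifest as TSV, the expression matrix as TSV,
#' and a YAML echo of the configuration.
#'
#' @param genome,sites,tracks,expr outputs of the generator stages (any may
#'   be NULL to skip).
#' @param config the [sim_config()] used.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(dir, config, genome, sites = NULL, tracks = NULL,
                             expr = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(seed = config$seed,
                        chrom_lengths = as.list(config$chrom_lengths),
                        n_genes = config$n_genes,
                        background_rate = config$background_rate,
                        focal_sd = config$focal_sd,
                        true_fold = config$true_fold),
                   file.path(dir, "config.yaml"))
  write_genes(genome$genes, file.path(dir, "genes.tsv"))
  if (nrow(genome$cpg_islands))
    write_bed(genome$cpg_islands, file.path(dir, "cpg_islands.bed"))
  if (!is.null(sites)) {
    write_bed(sites$sites[, c("chrom", "start", "end", "id")],
              file.path(dir, "planted_sites.bed"))
    write_tsv(sites$sites, file.path(dir, "ground_truth_sites.tsv"))
    write_tsv(sites$intensities, file.path(dir, "ground_truth_intensities.tsv"))
  }
  if (!is.null(tracks))
    for (nm in names(tracks))
      write_tags(tracks[[nm]], file.path(dir, paste0("tags_", nm, ".bed")))
  if (!is.null(expr)) {
    df <- data.frame(probe_id = rownames(expr$matrix), expr$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, file.path(dir, "expression.tsv"))
    write_tsv(expr$truth, file.path(dir, "ground_truth_expression.tsv"))
  }
  invisible(dir)
}
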