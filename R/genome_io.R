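# Coordinate convention: every interval in this package is 0-based, half-open
# [start, end). BED files on disk use the same convention, so I/O is a straight
# column mapping and round-trips are bit-exact. The center of an interval is
# floor((start + end) / 2).

#' Construct a validated interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optionally `id`, `score`, `strand`. Coordinates are 0-based, half-open.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors; `0 <= start < end` required.
#' @param id optional character ids (unique labels recommended).
#' @param score optional numeric scores.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return a `data.frame` with the interval columns present.
#' @export
intervals <- function(chrom, start, end, id = NULL, score = NULL, strand = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    stop("chrom, start and end must have equal length")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at index ", bad[1])
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(id)) df$id <- as.character(id)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'")
    df$strand <- strand
  }
  df
}

#' Interval centers
#'
#' @param x an interval data frame.
#' @return integer-valued centers, `floor((start + end) / 2)`.
#' @export
interval_center <- function(x) floor((x$start + x$end) / 2)

.check_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " must be a data.frame with chrom, start, end columns")
  if (nrow(x) && any(x$start >= x$end))
    stop(what, " contain start >= end")
  invisible(x)
}

#' Read a BED file of intervals
#'
#' Accepts 3- to 6-column BED (chrom, start, end, name, score, strand),
#' whitespace- or tab-delimited. Malformed lines are reported with their line
#' number. Coordinates are kept 0-based half-open.
#'
#' @param path file path.
#' @return an interval data frame; `id`/`score`/`strand` columns are present
#'   when the file carries 4+/5+/6 columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3 | nf > 6))
    stop("malformed BED at line ", which(nf < 3 | nf > 6)[1],
         ": expected 3-6 columns, got ", nf[which(nf < 3 | nf > 6)[1]])
  ncol <- min(nf)
  m <- matrix(unlist(lapply(fields, `[`, seq_len(ncol))), ncol = ncol, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED at line ", bad[1], ": non-numeric coordinates")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("malformed BED at line ", bad[1], ": need 0 <= start < end (got ",
         start[bad[1]], ", ", end[bad[1]], ")")
  out <- data.frame(chrom = m[, 1], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (ncol >= 4) out$id <- m[, 4]
  if (ncol >= 5) out$score <- suppressWarnings(as.numeric(m[, 5]))
  if (ncol >= 6) {
    if (!all(m[, 6] %in% c("+", "-", ".")))
      stop("malformed BED at line ", which(!(m[, 6] %in% c("+", "-", ".")))[1],
           ": bad strand field")
    out$strand <- m[, 6]
  }
  out
}

#' Write intervals as BED
#'
#' Intervals are sorted by (chrom, start) on write; columns beyond the first
#' three are emitted only as far as they are present (BED3/4/5/6).
#'
#' @param x interval data frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  .check_intervals(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$id)) {
    cols <- c(cols, list(x$id))
    if (!is.null(x$score)) {
      cols <- c(cols, list(format(x$score, scientific = FALSE, trim = TRUE)))
      if (!is.null(x$strand)) cols <- c(cols, list(x$strand))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Construct a tag track
#'
#' A tag track holds the 5' positions of aligned sequencing reads for one
#' sample (one antibody in one genotype), sorted per chromosome, together with
#' the library size used for depth normalization. Strand is carried but ignored
#' by all counting operations.
#'
#' @param positions named list: one sorted numeric vector of 0-based tag
#'   positions per chromosome (sorting is enforced here).
#' @param sample_id,factor,genotype sample annotation labels.
#' @param strand optional named list of strand vectors parallel to `positions`.
#' @param chrom_lengths optional named vector of chromosome lengths used for
#'   bounds checks.
#' @return an object of class `tag_track`.
#' @export
tag_track <- function(positions, sample_id = "sample", factor = NA_character_,
                      genotype = NA_character_, strand = NULL,
                      chrom_lengths = NULL) {
  stopifnot(is.list(positions))
  ord <- lapply(positions, order)
  positions <- Map(function(p, o) as.numeric(p)[o], positions, ord)
  if (!is.null(strand)) strand <- Map(function(s, o) s[o], strand, ord)
  if (!is.null(chrom_lengths)) {
    for (ch in names(positions)) {
      if (!ch %in% names(chrom_lengths))
        stop("tags on unknown chromosome: ", ch)
      p <- positions[[ch]]
      if (length(p) && (min(p) < 0 || max(p) >= chrom_lengths[[ch]]))
        stop("tag position out of bounds on ", ch)
    }
  }
  structure(list(sample_id = sample_id, factor = factor, genotype = genotype,
                 tags = positions, strand = strand,
                 library_size = sum(lengths(positions)),
                 chrom_lengths = chrom_lengths),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat("<tag_track>", x$sample_id,
      sprintf("(factor=%s, genotype=%s)\n", x$factor, x$genotype))
  cat("  ", x$library_size, "tags on", length(x$tags), "chromosome(s)\n")
  invisible(x)
}

#' Read aligned tags from a BED file
#'
#' Tags are single-base records; the 5' position is taken from the BED start
#' column as given (no read extension). Positions are sorted per chromosome on
#' load and the library size is set to the total tag count.
#'
#' @param path BED file of tags.
#' @param sample_id,factor,genotype sample annotation.
#' @param chrom_lengths optional named vector; tags on chromosomes absent from
#'   it raise an error naming the chromosome.
#' @return a [tag_track()].
#' @export
read_tags <- function(path, sample_id = basename(path), factor = NA_character_,
                      genotype = NA_character_, chrom_lengths = NULL) {
  bed <- read_bed(path)
  pos <- split(bed$start, bed$chrom)
  str <- if (!is.null(bed$strand)) split(bed$strand, bed$chrom) else NULL
  tag_track(pos, sample_id = sample_id, factor = factor, genotype = genotype,
            strand = str, chrom_lengths = chrom_lengths)
}

#' Write a tag track as BED6
#'
#' @param track a [tag_track()].
#' @param path output path.
#' @export
write_tags <- function(track, path) {
  chroms <- names(track$tags)
  dfs <- lapply(chroms, function(ch) {
    p <- track$tags[[ch]]
    if (!length(p)) return(NULL)
    s <- if (!is.null(track$strand)) track$strand[[ch]] else rep(".", length(p))
    data.frame(chrom = ch, start = p, end = p + 1,
               id = paste0("tag_", ch, "_", seq_along(p)), score = 0,
               strand = s, stringsAsFactors = FALSE)
  })
  write_bed(do.call(rbind, dfs), path)
}

#' Write binned signal as bedGraph
#'
#' Adjacent bins with equal value are merged into one record; a track
#' definition line is emitted first.
#'
#' @param binned data frame with columns `chrom`, `start`, `end`, `value`
#'   (fixed bin width, non-overlapping, sorted within chromosome).
#' @param path output path.
#' @param name track name for the header line.
#' @export
write_bedgraph <- function(binned, path, name = "signal") {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(binned)))
  out <- c(sprintf("track type=bedGraph name=\"%s\"", name))
  for (ch in unique(binned$chrom)) {
    b <- binned[binned$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    # run-length merge of equal-value adjacent bins
    brk <- c(TRUE, b$value[-1] != b$value[-nrow(b)] |
               b$start[-1] != b$end[-nrow(b)])
    grp <- cumsum(brk)
    st <- tapply(b$start, grp, min)
    en <- tapply(b$end, grp, max)
    va <- tapply(b$value, grp, `[`, 1)
    out <- c(out, sprintf("%s\t%s\t%s\t%s", ch,
                          format(st, scientific = FALSE, trim = TRUE),
                          format(en, scientific = FALSE, trim = TRUE),
                          format(va, scientific = FALSE, trim = TRUE)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a gene model table
#'
#' Tab-separated with header `gene_id, chrom, strand, tss, te`. On the `+`
#' strand `tss < te`; on the `-` strand `tss > te`.
#'
#' @param path TSV path.
#' @return a gene model data frame.
#' @export
read_genes <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "te")
  if (!all(need %in% names(g)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  .check_genes(g)
  g
}

.check_genes <- function(g) {
  if (!all(g$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  bad <- (g$strand == "+" & g$tss >= g$te) | (g$strand == "-" & g$tss <= g$te)
  if (any(bad)) stop("gene orientation inconsistent with strand for: ",
                     paste(utils::head(g$gene_id[bad], 3), collapse = ", "))
  invisible(g)
}

#' @rdname read_genes
#' @param genes gene model data frame.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-by-sample expression matrix
#'
#' Tab-separated, header row names the samples, first column carries probe
#' ids. All cells must be numeric and probe ids unique; `groups` assigns each
#' sample to a replicate group and every group must have at least two
#' replicates (group comparisons are t-tests).
#'
#' @param path TSV path.
#' @param groups named list: group name -> character vector of sample (column)
#'   names.
#' @return a list with `matrix` (numeric, probes x samples) and `groups`.
#' @export
read_expression <- function(path, groups) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  probe_ids <- as.character(tab[[1]])
  if (anyDuplicated(probe_ids))
    stop("duplicated probe id: ", probe_ids[duplicated(probe_ids)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("non-numeric or missing value for probe ", probe_ids[bad])
  }
  rownames(m) <- probe_ids
  .check_groups(groups, colnames(m))
  list(matrix = m, groups = groups)
}

.check_groups <- function(groups, samples) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  for (g in names(groups)) {
    miss <- setdiff(groups[[g]], samples)
    if (length(miss))
      stop("group '", g, "' names unknown sample(s): ",
           paste(miss, collapse = ", "))
    if (length(groups[[g]]) < 2)
      stop("group '", g, "' has fewer than 2 replicates; t-tests undefined")
  }
  invisible(groups)
}

#' Write a result table as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
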