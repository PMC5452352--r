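# Chromatin integration: mark-region-to-gene association, marked-gene
# fractions, metagene occupancy profiles, event-to-region distances,
# region-width comparison and replicate track correlation.

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = vapply(genes, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(genes, `[[`, integer(1), "start") + 1L,
      end = vapply(genes, `[[`, integer(1), "end")),
    strand = vapply(genes, `[[`, character(1), "strand"),
    gene_id = vapply(genes, `[[`, character(1), "gene_id")
  )
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

#' Associate mark regions with genes
#'
#' A region is associated with every gene whose span contains it (default),
#' or, with the alternative overlap modes, whose span overlaps it at all or
#' contains its midpoint.
#'
#' @param genes List of [gene_model()] objects.
#' @param regions Mark-region `data.frame` (as from [read_bed()]).
#' @param overlap_mode `"containment"` (region fully inside the gene span,
#'   the literal reading of association within gene start and end), `"any"`,
#'   or `"midpoint"`.
#' @return A `data.frame` with one row per gene: `gene_id`, `marked`,
#'   `n_regions`, and a `regions` list-column of row indices into `regions`.
#' @export
associate_regions <- function(genes, regions,
                              overlap_mode = c("containment", "any",
                                               "midpoint")) {
  overlap_mode <- match.arg(overlap_mode)
  gene_gr <- genes_to_granges(genes)
  check_chrom_namespace(as.character(GenomicRanges::seqnames(gene_gr)),
                        regions$chrom)
  reg_gr <- switch(overlap_mode,
    midpoint = {
      mid <- floor((regions$start + regions$end) / 2)
      GenomicRanges::GRanges(regions$chrom,
                             IRanges::IRanges(mid + 1L, mid + 1L))
    },
    regions_to_granges(regions)
  )
  type <- if (overlap_mode == "any") "any" else "within"
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    reg_gr, gene_gr, type = type, ignore.strand = TRUE))
  by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  reg_idx <- lapply(seq_along(genes), function(i) {
    v <- by_gene[[as.character(i)]]
    if (is.null(v)) integer(0) else as.integer(v)
  })
  out <- data.frame(
    gene_id = gene_gr$gene_id,
    marked = lengths(reg_idx) > 0,
    n_regions = lengths(reg_idx),
    stringsAsFactors = FALSE
  )
  out$regions <- reg_idx
  out
}

#' Fraction of a gene set carrying the mark
#'
#' @param gene_set Character vector of gene ids (must all be annotated).
#' @param annotations Output of [associate_regions()].
#' @return The fraction of genes in `gene_set` with at least one associated
#'   region.
#' @export
fraction_marked <- function(gene_set, annotations) {
  if (length(gene_set) == 0) stop("empty gene set")
  idx <- match(gene_set, annotations$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) not annotated: ",
         paste(gene_set[is.na(idx)][1:min(3, sum(is.na(idx)))],
               collapse = ", "))
  }
  mean(annotations$marked[idx])
}

#' Metagene occupancy profile around TSS or TTS
#'
#' Extracts strand-oriented signal in a fixed window around each gene's
#' anchor (positive offsets point downstream of transcription), averages it
#' per bin within each gene class, and returns one profile per class. Genes
#' whose window exceeds the track's chromosome bounds are skipped and
#' counted.
#'
#' @param track bedGraph `data.frame` (from [read_bedgraph()]).
#' @param genes List of [gene_model()] objects.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param window Length-2 window in bp around the anchor (default
#'   `c(-2000, 2000)`).
#' @param bin Bin width in bp (default 50).
#' @param classes Optional named character vector mapping gene id to class
#'   label; unlisted genes form class `"all"`.
#' @return A list with `profiles` (a `data.frame` with `class`, `offset`
#'   (bin left edge relative to the anchor), `mean_signal`, `n_genes`) and
#'   `n_skipped`.
#' @export
metagene_profile <- function(track, genes, anchor = c("TSS", "TTS"),
                             window = c(-2000, 2000), bin = 50,
                             classes = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(length(window) == 2, window[1] < window[2],
            (window[2] - window[1]) %% bin == 0)
  cov <- track_coverage(track)
  n_bins <- (window[2] - window[1]) %/% bin
  offsets <- window[1] + bin * (seq_len(n_bins) - 1L)

  per_gene <- list()
  gene_class <- character(0)
  n_skipped <- 0L
  for (g in genes) {
    cv <- cov[[g$chrom]]
    if (is.null(cv)) { n_skipped <- n_skipped + 1L; next }
    minus <- identical(g$strand, "-")
    anchor_pos <- if (anchor == "TSS") {
      if (minus) g$end - 1L else g$start
    } else {
      if (minus) g$start else g$end - 1L
    }
    lo <- if (minus) anchor_pos - window[2] + 1L else anchor_pos + window[1]
    hi <- lo + (window[2] - window[1])  # half-open genomic window
    if (lo < 0 || hi > length(cv)) { n_skipped <- n_skipped + 1L; next }
    vals <- as.numeric(cv[(lo + 1L):hi])
    if (minus) vals <- rev(vals)
    per_gene[[length(per_gene) + 1L]] <-
      colMeans(matrix(vals, nrow = bin))
    cls <- if (!is.null(classes) && g$gene_id %in% names(classes)) {
      classes[[g$gene_id]]
    } else "all"
    gene_class <- c(gene_class, cls)
  }
  if (length(per_gene) == 0) stop("no gene window covered by the track")
  mat <- do.call(rbind, per_gene)
  profs <- lapply(sort(unique(gene_class)), function(cl) {
    rows <- gene_class == cl
    data.frame(class = cl, offset = offsets,
               mean_signal = colMeans(mat[rows, , drop = FALSE]),
               n_genes = sum(rows), stringsAsFactors = FALSE)
  })
  list(profiles = do.call(rbind, profs), n_skipped = n_skipped)
}

#' Distance from an event's alternative region to the nearest mark region
#'
#' @param event One event row (from [enumerate_events()]).
#' @param annotation The gene's row from [associate_regions()] output.
#' @param regions The region `data.frame` the annotation indexes into.
#' @return Minimum gap in bp (0 when overlapping), or `NA` for an unmarked
#'   gene.
#' @export
event_region_distance <- function(event, annotation, regions) {
  if (!identical(event$gene_id, annotation$gene_id)) {
    stop("event gene ", event$gene_id, " does not match annotation gene ",
         annotation$gene_id)
  }
  idx <- annotation$regions[[1]]
  if (length(idx) == 0) return(NA_real_)
  gaps <- pmax(0, pmax(event$alt_start, regions$start[idx]) -
                  pmin(event$alt_end, regions$end[idx]))
  min(gaps)
}

#' Compare event-to-region distances between dependence classes
#'
#' One-sided Mann-Whitney U test of the hypothesis that mark-dependent
#' events lie closer to a mark region than mark-independent events. The
#' exact null distribution is used for small untied samples, otherwise the
#' continuity-corrected normal approximation.
#'
#' @param dep_dists,indep_dists Numeric distance vectors (`NA`s dropped;
#'   dropped counts reported).
#' @param exact Passed to [stats::wilcox.test()]; `NULL` lets it decide.
#' @return A list with `statistic` (U for dependent < independent),
#'   `p_value`, `n_dep`, `n_indep`, `n_dropped`.
#' @export
compare_distance_distributions <- function(dep_dists, indep_dists,
                                           exact = NULL) {
  n_dropped <- sum(is.na(dep_dists)) + sum(is.na(indep_dists))
  dep <- dep_dists[!is.na(dep_dists)]
  ind <- indep_dists[!is.na(indep_dists)]
  if (length(dep) == 0 || length(ind) == 0) {
    stop("empty distance sample after dropping unmarked genes")
  }
  wt <- suppressWarnings(stats::wilcox.test(dep, ind, alternative = "less",
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = unname(wt$p.value),
       n_dep = length(dep), n_indep = length(ind), n_dropped = n_dropped)
}

#' Compare mark-region widths between two conditions
#'
#' @param regions_a,regions_b Region `data.frame`s for the two conditions.
#' @return A list with per-condition `median_width`s, the `median_ratio`
#'   (b over a), and the two-sided Mann-Whitney `p_value`.
#' @export
compare_region_widths <- function(regions_a, regions_b) {
  wa <- regions_a$end - regions_a$start
  wb <- regions_b$end - regions_b$start
  stopifnot(length(wa) > 0, length(wb) > 0)
  wt <- suppressWarnings(stats::wilcox.test(wa, wb, exact = FALSE))
  list(median_width_a = stats::median(wa), median_width_b = stats::median(wb),
       median_ratio = stats::median(wb) / stats::median(wa),
       p_value = unname(wt$p.value))
}

#' Pearson correlation of two tracks in genomic bins
#'
#' The genome is partitioned into fixed-size windows, per-window signal sums
#' are computed for both tracks, windows where either track exceeds its
#' `trim_quantile` are removed (guarding against a few extreme-count regions
#' dominating the correlation), and the Pearson correlation of the remaining
#' windows is returned.
#'
#' @param track1,track2 bedGraph `data.frame`s.
#' @param bin Window size in bp (default 1000).
#' @param trim_quantile Upper quantile above which windows are dropped
#'   (default 0.999).
#' @return Pearson correlation coefficient.
#' @export
binned_track_correlation <- function(track1, track2, bin = 1000,
                                     trim_quantile = 0.999) {
  check_chrom_namespace(track1$chrom, track2$chrom)
  chroms <- intersect(unique(track1$chrom), unique(track2$chrom))
  lens <- vapply(chroms, function(ch) {
    max(track1$end[track1$chrom == ch], track2$end[track2$chrom == ch])
  }, numeric(1))
  cov1 <- track_coverage(track1, as.list(lens))
  cov2 <- track_coverage(track2, as.list(lens))
  bin_sums <- function(cv, len) {
    n <- ceiling(len / bin)
    starts <- (seq_len(n) - 1L) * bin + 1L
    ends <- pmin(seq_len(n) * bin, len)
    as.numeric(IRanges::viewSums(IRanges::Views(
      cv, IRanges::IRanges(starts, ends))))
  }
  s1 <- unlist(lapply(chroms, function(ch) bin_sums(cov1[[ch]], lens[[ch]])))
  s2 <- unlist(lapply(chroms, function(ch) bin_sums(cov2[[ch]], lens[[ch]])))
  keep <- s1 <= stats::quantile(s1, trim_quantile) &
    s2 <= stats::quantile(s2, trim_quantile)
  if (sum(keep) < 3) stop("fewer than 3 windows remain after trimming")
  stats::cor(s1[keep], s2[keep], method = "pearson")
}
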