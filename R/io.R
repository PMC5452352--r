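# Readers/writers for the standard formats the pipeline touches.
#
# Internal coordinate convention: 0-based half-open everywhere. GTF (1-based
# closed) converts at the boundary; BED and bedGraph pass through verbatim.
# Chromosome names are taken verbatim (no "chr" normalisation).

#' Construct a transcript model
#'
#' @param transcript_id Transcript identifier.
#' @param exons Two-column integer matrix of exon `(start, end)` intervals,
#'   0-based half-open. Rows are sorted ascending by start; exons must be
#'   non-overlapping and non-empty.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) < 1) stop("transcript needs >= 1 exon")
  if (any(exons[, 1] >= exons[, 2])) stop("empty exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, exons = exons),
            class = "transcript_model")
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name (verbatim).
#' @param strand `"+"` or `"-"` (`"*"` tolerated with a warning; genes on
#'   unknown strand cannot carry alternative 5'/3' splice-site events).
#' @param transcripts List of [transcript_model()] objects.
#' @return A list of class `gene_model`; `start`/`end` is the 0-based
#'   half-open span over all transcripts.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  if (!strand %in% c("+", "-")) {
    warning("gene ", gene_id, " has strand '", strand,
            "'; treated as unstranded")
    strand <- "*"
  }
  if (length(transcripts) < 1) stop("gene needs >= 1 transcript")
  starts <- vapply(transcripts, function(t) min(t$exons[, 1]), integer(1))
  ends <- vapply(transcripts, function(t) max(t$exons[, 2]), integer(1))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = min(starts), end = max(ends),
                 transcripts = transcripts),
            class = "gene_model")
}

#' Read gene models from a GTF file
#'
#' Exon features are grouped by `transcript_id` within `gene_id`; the
#' 1-based closed GTF coordinates are converted to the internal 0-based
#' half-open convention. Non-exon features are ignored.
#'
#' @param path Path to a GTF file.
#' @return A named list of [gene_model()] objects, sorted by gene id.
#' @export
read_gtf <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    stop("exon feature without transcript_id in ", path)
  }
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes <- lapply(split(df, df$gene_id), function(g) {
    chrom <- unique(g$chrom)
    if (length(chrom) != 1) {
      stop("gene ", g$gene_id[1], " has exons on multiple chromosomes")
    }
    strand <- unique(g$strand)
    if (length(strand) != 1) {
      stop("gene ", g$gene_id[1], " has mixed strands")
    }
    txs <- lapply(split(g, g$transcript_id), function(t) {
      transcript_model(t$transcript_id[1], cbind(t$start, t$end))
    })
    gene_model(g$gene_id[1], chrom, strand, unname(txs[order(names(txs))]))
  })
  genes[order(names(genes))]
}

#' Write gene models to a GTF file
#'
#' Emits one `exon` feature per exon with `gene_id` then `transcript_id`
#' attributes, converting back to 1-based closed coordinates. Output is
#' deterministic (no timestamp headers), so identical inputs give
#' byte-identical files.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- unlist(lapply(genes, function(g) {
    unlist(lapply(g$transcripts, function(t) {
      sprintf("%s\tthermosplice\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
              g$chrom, t$exons[, 1] + 1L, t$exons[, 2], g$strand,
              g$gene_id, t$transcript_id)
    }))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read mark regions from a BED file
#'
#' BED3 or BED5 (name and score optional). Coordinates are 0-based
#' half-open and preserved verbatim. The score column is interpreted as
#' mean occupancy; when absent it defaults to 1.0.
#'
#' @param path Path to a BED file.
#' @param condition Condition label attached to every region (e.g. `"16C"`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`,
#'   `occupancy`, `condition`.
#' @export
read_bed <- function(path, condition = NA_character_) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs >= 3 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    occupancy = if (ncol(df) >= 5) as.numeric(df[[5]]) else 1.0,
                    condition = condition,
                    stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    stop("BED record with start >= end at line(s) ",
         paste(bad, collapse = ", "), " in ", path)
  }
  if (any(out$occupancy < 0)) stop("negative occupancy in ", path)
  out
}

#' Write mark regions to a BED5 file
#'
#' @param regions `data.frame` as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- sprintf("region%d", seq_len(nrow(regions)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%g", regions$chrom, regions$start,
                   regions$end, name, regions$occupancy)
  writeLines(lines, path)
  invisible(path)
}

#' Read an occupancy track from a bedGraph file
#'
#' @param path Path to a bedGraph file (`chrom start end value`, 0-based
#'   half-open).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("bedGraph needs 4 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    value = as.numeric(df[[4]]),
                    stringsAsFactors = FALSE)
  if (any(out$value < 0)) stop("negative track value in ", path)
  out
}

#' Write an occupancy track to a bedGraph file
#'
#' @param track `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", track$chrom, track$start,
                     track$end, track$value), path)
  invisible(path)
}

# Per-chromosome run-length coverage of a bedGraph track; values are mean
# signal per bp. Returns a named list of Rle vectors, each covering
# [0, chrom_len) where chrom_len is the largest end seen (or `chrom_lens`).
# Track intervals on a chromosome must not overlap.
track_coverage <- function(track, chrom_lens = NULL) {
  lapply(split(track, track$chrom), function(t) {
    t <- t[order(t$start), , drop = FALSE]
    len <- if (!is.null(chrom_lens)) chrom_lens[[t$chrom[1]]] else max(t$end)
    n <- nrow(t)
    gap <- t$start - c(0L, t$end[-n])
    if (any(gap < 0)) stop("overlapping bedGraph intervals on ", t$chrom[1])
    lens <- as.vector(rbind(gap, t$end - t$start))
    vals <- as.vector(rbind(0, t$value))
    if (len > t$end[n]) {
      lens <- c(lens, len - t$end[n])
      vals <- c(vals, 0)
    }
    keep <- lens > 0
    S4Vectors::Rle(vals[keep], lens[keep])
  })
}

# Warn (once) when two interval sets share no chromosome names.
check_chrom_namespace <- function(chroms_a, chroms_b) {
  if (length(intersect(unique(chroms_a), unique(chroms_b))) == 0) {
    warning("no shared chromosome names between the two inputs; ",
            "check chromosome naming conventions")
  }
  invisible(NULL)
}
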