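# Enumeration of the five classical alternative-splicing event types
# (IR, ES, A5, A3, MXE) from pairwise comparison of transcript exon chains.
#
# Each event is a local structural difference between two chains that share
# anchor exon sequence on both sides. The inclusion form is always the form
# containing more transcribed sequence in the alternative region (retained
# intron, included exon, longer splice-site variant; for MXE the form with
# the upstream-in-transcript exon), and PSI is the inclusion fraction.

# introns of an exon chain: (end_i, start_{i+1}) half-open gaps
chain_introns <- function(exons) {
  n <- nrow(exons)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cbind(exons[-n, 2], exons[-1, 1])
}

event_row <- function(type, chrom, strand, alt, flank_left, flank_right,
                      incl, excl, detail, gene_id = NA_character_) {
  data.frame(
    event_id = NA_character_, gene_id = gene_id, type = type,
    chrom = chrom, strand = strand,
    alt_start = alt[1], alt_end = alt[2],
    flank_left_start = flank_left[1], flank_left_end = flank_left[2],
    flank_right_start = flank_right[1], flank_right_end = flank_right[2],
    inclusion_form = encode_form(incl), exclusion_form = encode_form(excl),
    event_key = paste(type, chrom, strand, alt[1], alt[2], detail, sep = "|"),
    stringsAsFactors = FALSE
  )
}

empty_events <- function() {
  event_row("IR", "x", "+", c(0L, 1L), c(0L, 1L), c(0L, 1L),
            matrix(c(0L, 1L), ncol = 2), matrix(c(0L, 1L), ncol = 2), "")[0, ]
}

# IR: chain x has an intron strictly inside a single exon of chain y.
detect_ir <- function(ex_x, ex_y, chrom, strand, gene_id) {
  out <- list()
  introns <- chain_introns(ex_x)
  nx <- nrow(ex_x)
  for (i in seq_len(nrow(introns))) {
    a <- introns[i, 1]; b <- introns[i, 2]
    hit <- which(ex_y[, 1] < a & ex_y[, 2] > b)
    for (j in hit) {
      fl <- c(max(ex_x[i, 1], ex_y[j, 1]), a)
      fr <- c(b, min(ex_x[i + 1, 2], ex_y[j, 2]))
      if (fl[1] >= fl[2] || fr[1] >= fr[2]) next  # degenerate anchor
      incl <- matrix(c(fl[1], fr[2]), ncol = 2)        # retained intron
      excl <- rbind(c(fl[1], a), c(b, fr[2]))          # spliced junction
      out[[length(out) + 1]] <- event_row(
        "IR", chrom, strand, c(a, b), fl, fr, incl, excl, "", gene_id)
    }
  }
  out
}

# ES: chain x has an internal exon; chain y joins the two flanking exons
# with a junction at exactly the facing boundaries.
detect_es <- function(ex_x, ex_y, chrom, strand, gene_id) {
  out <- list()
  nx <- nrow(ex_x); ny <- nrow(ex_y)
  if (nx < 3 || ny < 2) return(out)
  introns_y <- chain_introns(ex_y)
  for (i in 2:(nx - 1)) {
    pe <- ex_x[i - 1, 2]; ns <- ex_x[i + 1, 1]
    j <- which(introns_y[, 1] == pe & introns_y[, 2] == ns)
    for (jj in j) {
      fl <- c(max(ex_x[i - 1, 1], ex_y[jj, 1]), pe)
      fr <- c(ns, min(ex_x[i + 1, 2], ex_y[jj + 1, 2]))
      if (fl[1] >= fl[2] || fr[1] >= fr[2]) next
      alt <- ex_x[i, , drop = TRUE]
      incl <- rbind(c(fl[1], pe), alt, c(ns, fr[2]))
      excl <- rbind(c(fl[1], pe), c(ns, fr[2]))
      out[[length(out) + 1]] <- event_row(
        "ES", chrom, strand, alt, fl, fr, incl, excl,
        paste(pe, ns, sep = ";"), gene_id)
    }
  }
  out
}

# A5/A3: the two chains share one intron boundary and differ at the other.
# Donor (5') side is the intron boundary nearer the transcript's 5' end:
# the left intron edge on "+", the right edge on "-". The inclusion form is
# the longer exon variant (the one extending into the alternative segment).
detect_alt_ss <- function(ex_x, ex_y, chrom, strand, gene_id) {
  out <- list()
  in_x <- chain_introns(ex_x); in_y <- chain_introns(ex_y)
  if (nrow(in_x) == 0 || nrow(in_y) == 0) return(out)
  for (i in seq_len(nrow(in_x))) {
    for (j in seq_len(nrow(in_y))) {
      ax <- in_x[i, 1]; bx <- in_x[i, 2]
      ay <- in_y[j, 1]; by <- in_y[j, 2]
      if (bx == by && ax != ay) {
        # shared right (downstream-in-genome) boundary, differing left edge
        if (strand == "*") {
          stop("alternative 5'/3' splice-site candidate in unstranded gene ",
               gene_id, "; strand is required to assign donor/acceptor side")
        }
        lo <- min(ax, ay); hi <- max(ax, ay)
        fl <- c(max(ex_x[i, 1], ex_y[j, 1]), lo)
        fr <- c(bx, min(ex_x[i + 1, 2], ex_y[j + 1, 2]))
        if (fl[1] >= fl[2] || fr[1] >= fr[2]) next
        type <- if (strand == "+") "A5" else "A3"
        incl <- rbind(c(fl[1], hi), c(bx, fr[2]))
        excl <- rbind(c(fl[1], lo), c(bx, fr[2]))
        out[[length(out) + 1]] <- event_row(
          type, chrom, strand, c(lo, hi), fl, fr, incl, excl,
          paste("R", bx, sep = ";"), gene_id)
      } else if (ax == ay && bx != by) {
        # shared left boundary, differing right edge
        if (strand == "*") {
          stop("alternative 5'/3' splice-site candidate in unstranded gene ",
               gene_id, "; strand is required to assign donor/acceptor side")
        }
        lo <- min(bx, by); hi <- max(bx, by)
        fl <- c(max(ex_x[i, 1], ex_y[j, 1]), ax)
        fr <- c(hi, min(ex_x[i + 1, 2], ex_y[j + 1, 2]))
        if (fl[1] >= fl[2] || fr[1] >= fr[2]) next
        type <- if (strand == "+") "A3" else "A5"
        incl <- rbind(c(fl[1], ax), c(lo, fr[2]))
        excl <- rbind(c(fl[1], ax), c(hi, fr[2]))
        out[[length(out) + 1]] <- event_row(
          type, chrom, strand, c(lo, hi), fl, fr, incl, excl,
          paste("L", ax, sep = ";"), gene_id)
      }
    }
  }
  out
}

# MXE: chain x carries internal exon A, chain y internal exon B, A and B do
# not overlap, neither chain carries the other's exon, and both chains share
# the flanking exons at the facing boundaries.
detect_mxe <- function(ex_x, ex_y, chrom, strand, gene_id) {
  out <- list()
  nx <- nrow(ex_x); ny <- nrow(ex_y)
  if (nx < 3 || ny < 3) return(out)
  has_exon <- function(ex, e) any(ex[, 1] == e[1] & ex[, 2] == e[2])
  for (i in 2:(nx - 1)) {
    for (j in 2:(ny - 1)) {
      A <- ex_x[i, ]; B <- ex_y[j, ]
      if (A[2] <= B[1] || B[2] <= A[1]) {          # non-overlapping
        pe_x <- ex_x[i - 1, 2]; ns_x <- ex_x[i + 1, 1]
        pe_y <- ex_y[j - 1, 2]; ns_y <- ex_y[j + 1, 1]
        if (pe_x != pe_y || ns_x != ns_y) next
        if (has_exon(ex_y, A) || has_exon(ex_x, B)) next
        fl <- c(max(ex_x[i - 1, 1], ex_y[j - 1, 1]), pe_x)
        fr <- c(ns_x, min(ex_x[i + 1, 2], ex_y[j + 1, 2]))
        if (fl[1] >= fl[2] || fr[1] >= fr[2]) next
        lo_exon <- if (A[1] < B[1]) A else B
        hi_exon <- if (A[1] < B[1]) B else A
        # upstream-in-transcript exon defines the inclusion form
        up <- if (strand == "-") hi_exon else lo_exon
        dn <- if (strand == "-") lo_exon else hi_exon
        alt <- c(lo_exon[1], hi_exon[2])
        incl <- rbind(c(fl[1], pe_x), up, c(ns_x, fr[2]))
        excl <- rbind(c(fl[1], pe_x), dn, c(ns_x, fr[2]))
        out[[length(out) + 1]] <- event_row(
          "MXE", chrom, strand, alt, fl, fr, incl, excl,
          paste(pe_x, ns_x, lo_exon[1], lo_exon[2], hi_exon[1], hi_exon[2],
                sep = ";"), gene_id)
      }
    }
  }
  out
}

#' Classify the alternative-splicing events between two transcripts
#'
#' Compares two exon chains from the same gene and returns every local
#' structural difference matching one of the five event patterns (IR, ES,
#' A5, A3, MXE). Differences matching none of the patterns (alternative
#' first/last exons, complex regions) yield no event. Events with a
#' degenerate shared anchor (< 1 bp of flanking exon overlap) are discarded.
#'
#' @param t1,t2 [transcript_model()] objects.
#' @param strand `"+"` or `"-"` (`"*"` only for genes without alternative
#'   splice-site candidates).
#' @param chrom Chromosome name.
#' @param gene_id Optional gene id recorded in the output.
#' @return A `data.frame` with one row per event (possibly zero rows):
#'   event coordinates (`alt_start`/`alt_end`, 0-based half-open), shared
#'   flank segments, and the minimal inclusion/exclusion exon-chain forms.
#' @export
classify_pair <- function(t1, t2, strand, chrom = "chr1",
                          gene_id = NA_character_) {
  e1 <- t1$exons; e2 <- t2$exons
  rows <- c(
    detect_ir(e1, e2, chrom, strand, gene_id),
    detect_ir(e2, e1, chrom, strand, gene_id),
    detect_es(e1, e2, chrom, strand, gene_id),
    detect_es(e2, e1, chrom, strand, gene_id),
    detect_alt_ss(e1, e2, chrom, strand, gene_id),
    detect_mxe(e1, e2, chrom, strand, gene_id)
  )
  if (length(rows) == 0) return(empty_events())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$event_key), , drop = FALSE]
  out$event_id <- content_id(out$event_key)
  rownames(out) <- NULL
  out
}

#' Enumerate the alternative-splicing events of a gene
#'
#' Applies [classify_pair()] to every unordered pair of the gene's
#' transcripts and de-duplicates by event key (type, chromosome, strand,
#' alternative region and inner anchor boundaries). Event ids are stable
#' content-derived hashes, identical across runs and machines.
#'
#' @param gene A [gene_model()] object.
#' @return A `data.frame` of unique events (zero rows for single-transcript
#'   genes).
#' @export
enumerate_events <- function(gene) {
  txs <- gene$transcripts
  n <- length(txs)
  if (n < 2) return(empty_events())
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rows[[length(rows) + 1]] <-
        classify_pair(txs[[i]], txs[[j]], gene$strand, gene$chrom,
                      gene$gene_id)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$event_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate events for a list of genes
#'
#' @param genes List of [gene_model()] objects (as from [read_gtf()]).
#' @return A `data.frame` of all unique events across genes.
#' @export
enumerate_all_events <- function(genes) {
  out <- do.call(rbind, lapply(genes, enumerate_events))
  rownames(out) <- NULL
  out
}

#' Write an event catalog and optional BED of alternative regions
#'
#' @param events Event `data.frame` from [enumerate_events()].
#' @param path Output TSV path.
#' @param bed_path Optional BED6 path for the alternative regions.
#' @return `path`, invisibly.
#' @export
write_event_catalog <- function(events, path, bed_path = NULL) {
  write_tsv(events, path)
  if (!is.null(bed_path)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", events$chrom,
                       events$alt_start, events$alt_end, events$event_id,
                       events$strand), bed_path)
  }
  invisible(path)
}
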