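# Seeded synthetic-data generators for every pipeline input, with ground
# truth for recovery tests.
#
# The generators emulate the study design the analysis assumes: multi-isoform
# genes carrying exactly one event of each type, temperature-dependent PSI
# shifts concentrated in a subset of events, genotype-dependent attenuation
# of those shifts in mark-depleted mutants, mark regions peaking ~0.5 kb
# downstream of the TSS with condition-dependent width, negative-binomial
# expression counts, and flowering phenotypes scored on a 2-day screening
# grid.

#' Simulation configuration with study-design defaults
#'
#' Defaults mirror the experimental design: three biological replicates per
#' condition, two temperatures (16C, 25C), a wild type plus two
#' methyltransferase mutants with fully attenuated temperature response for
#' mark-dependent events, a mark-region peak 500 bp downstream of the TSS
#' that broadens at the higher temperature, and flowering trays of 15 plants
#' scored every two days.
#'
#' @param seed Base seed; each generator derives a fixed child seed from it.
#' @param n_genes Number of simulated genes.
#' @param event_mix Proportions of the five event types (must sum to 1).
#' @param dis_fraction Fraction of events with a true temperature PSI shift.
#' @param true_delta_psi Absolute true PSI shift of differential events.
#' @param baseline_psi_range Range the baseline (16C) PSI is drawn from.
#' @param depth_per_replicate Mean isoform-specific reads per replicate.
#' @param n_replicates Replicates per condition.
#' @param genotypes Named list of attenuation factors in \[0, 1\] (fraction
#'   of the PSI shift lost at mark-dependent events; the wild type is 0).
#' @param dependent_fraction Fraction of differential events that are
#'   mark-dependent.
#' @param marked_fraction_by_class Named fractions of marked genes per gene
#'   class.
#' @param mark_peak_offset Mark-region centre, bp downstream of the TSS.
#' @param mark_width_by_condition Named region widths (bp) per condition.
#' @param mark_dependent_overlap When `TRUE`, genes with a mark-dependent
#'   event get their region centred on the event's alternative region and
#'   genes with a mark-independent event get a distal region, for
#'   distance-analysis recovery.
#' @param deg_fraction Fraction of non-differentially-spliced genes that are
#'   differentially expressed.
#' @param true_lfc Absolute log2 fold change of differentially expressed
#'   genes.
#' @param nb_dispersion Negative-binomial dispersion of expression counts.
#' @param phenotype_effects Named list of per-genotype mean days-to-bolting,
#'   one value per condition.
#' @param plants_per_tray,n_trays Flowering-assay design.
#' @param conditions The two condition labels, low temperature first.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1337,
                       n_genes = 300,
                       event_mix = c(IR = 0.3, ES = 0.3, A5 = 0.15,
                                     A3 = 0.15, MXE = 0.1),
                       dis_fraction = 0.5,
                       true_delta_psi = 0.3,
                       baseline_psi_range = c(0.35, 0.6),
                       depth_per_replicate = 100,
                       n_replicates = 3,
                       genotypes = list(WT = 0, sdg8 = 1, sdg26 = 1),
                       dependent_fraction = 0.5,
                       marked_fraction_by_class = c(DiS = 0.96, DEG = 0.65,
                                                    neither = 0.4),
                       mark_peak_offset = 500,
                       mark_width_by_condition = c("16C" = 300, "25C" = 450),
                       mark_dependent_overlap = FALSE,
                       deg_fraction = 0.1,
                       true_lfc = 2,
                       nb_dispersion = 0.1,
                       phenotype_effects = list(
                         WT = c("16C" = 70, "25C" = 50),
                         sdg8 = c("16C" = 70, "25C" = 69),
                         sdg26 = c("16C" = 70, "25C" = 69)),
                       plants_per_tray = 15,
                       n_trays = 3,
                       conditions = c("16C", "25C")) {
  stopifnot(abs(sum(event_mix) - 1) < 1e-9, depth_per_replicate >= 0,
            dis_fraction >= 0, dis_fraction <= 1,
            length(conditions) == 2)
  structure(as.list(environment()), class = "sim_config")
}

# Build one two-transcript gene carrying exactly one event of `type`,
# anchored at genomic offset `at` (gene-local coordinates are shifted by
# `at`). Returns list(gene=gene_model, alt=c(start,end) absolute).
build_event_gene <- function(gene_id, chrom, strand, type, at) {
  len <- function() sample(100:300, 1)
  ivl <- function() sample(80:1000, 1)
  ext <- function() sample(30:80, 1)
  sh <- function(m) m + at
  if (type == "IR") {
    l1 <- len(); i1 <- ivl(); l2 <- len()
    e1 <- c(0L, l1); e2 <- c(l1 + i1, l1 + i1 + l2)
    t1 <- rbind(e1, e2)                      # spliced (exclusion)
    t2 <- rbind(c(0L, l1 + i1 + l2))         # retained intron (inclusion)
    alt <- c(l1, l1 + i1)
  } else if (type == "ES") {
    l1 <- len(); i1 <- ivl(); l2 <- len(); i2 <- ivl(); l3 <- len()
    e1 <- c(0L, l1)
    e2 <- c(l1 + i1, l1 + i1 + l2)
    e3 <- c(e2[2] + i2, e2[2] + i2 + l3)
    t1 <- rbind(e1, e2, e3)
    t2 <- rbind(e1, e3)
    alt <- e2
  } else if (type %in% c("A5", "A3")) {
    # left-extension structure is A5 on "+", A3 on "-"; the right-extension
    # mirror is used when the requested type and strand demand it
    left_ext <- (type == "A5") == (strand == "+")
    l1 <- len(); d <- ext(); i1 <- ivl(); l2 <- len()
    if (left_ext) {
      e2 <- c(l1 + d + i1, l1 + d + i1 + l2)
      t1 <- rbind(c(0L, l1 + d), e2)   # longer variant (inclusion)
      t2 <- rbind(c(0L, l1), e2)
      alt <- c(l1, l1 + d)
    } else {
      s <- l1 + i1
      e1 <- c(0L, l1)
      t1 <- rbind(e1, c(s, s + d + l2))      # longer variant
      t2 <- rbind(e1, c(s + d, s + d + l2))
      alt <- c(s, s + d)
    }
  } else if (type == "MXE") {
    l1 <- len(); i1 <- ivl(); l2 <- len(); i2 <- ivl(); l3 <- len()
    i3 <- ivl(); l4 <- len()
    e1 <- c(0L, l1)
    x1 <- c(l1 + i1, l1 + i1 + l2)
    x2 <- c(x1[2] + i2, x1[2] + i2 + l3)
    e4 <- c(x2[2] + i3, x2[2] + i3 + l4)
    t1 <- rbind(e1, x1, e4)
    t2 <- rbind(e1, x2, e4)
    alt <- c(x1[1], x2[2])
  } else {
    stop("unknown event type ", type)
  }
  txs <- list(transcript_model(paste0(gene_id, ".1"), sh(t1)),
              transcript_model(paste0(gene_id, ".2"), sh(t2)))
  # a third transcript (duplicate structure) for some genes exercises
  # de-duplication without adding events
  if (stats::runif(1) < 1 / 3) {
    txs <- c(txs, list(transcript_model(paste0(gene_id, ".3"), sh(t1))))
  }
  list(gene = gene_model(gene_id, chrom, strand, txs), alt = alt + at)
}

#' Generate gene models carrying one event each, with ground truth
#'
#' Genes are tiled 50 per chromosome with 2-kb gaps (and a 3-kb margin at
#' the chromosome start so metagene windows fit), alternating strand. Each
#' gene carries exactly one event of a type drawn from `event_mix`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genes` (list of [gene_model()]) and `truth` (a
#'   `data.frame` with per-event type, coordinates, differential-splicing
#'   and dependence labels, PSI parameters, and per-gene class labels).
#' @export
gen_gene_models <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$n_genes
    types <- sample(names(cfg$event_mix), n, replace = TRUE,
                    prob = cfg$event_mix)
    is_dis <- seq_len(n) %in% sample.int(n, round(n * cfg$dis_fraction))
    dep <- rep(NA_character_, n)
    dis_idx <- which(is_dis)
    n_dep <- round(length(dis_idx) * cfg$dependent_fraction)
    dep_idx <- if (n_dep > 0) sample(dis_idx, n_dep) else integer(0)
    dep[dep_idx] <- "dependent"
    dep[setdiff(dis_idx, dep_idx)] <- "independent"
    non_dis <- which(!is_dis)
    n_deg <- round(n * cfg$deg_fraction)
    deg_idx <- if (n_deg > 0) sample(non_dis, min(n_deg, length(non_dis)))
               else integer(0)
    gene_class <- ifelse(is_dis, "DiS", "neither")
    gene_class[deg_idx] <- "DEG"
    baseline <- stats::runif(n, cfg$baseline_psi_range[1],
                             cfg$baseline_psi_range[2])
    delta <- ifelse(is_dis,
                    cfg$true_delta_psi * sample(c(-1, 1), n, replace = TRUE),
                    0)

    genes <- vector("list", n)
    rows <- vector("list", n)
    cursor <- 3000L
    for (i in seq_len(n)) {
      chrom <- paste0("chr", (i - 1) %/% 50 + 1)
      if ((i - 1) %% 50 == 0) cursor <- 3000L
      strand <- if (i %% 2 == 0) "-" else "+"
      gid <- sprintf("g%04d", i)
      built <- build_event_gene(gid, chrom, strand, types[i], cursor)
      genes[[i]] <- built$gene
      ev <- enumerate_events(built$gene)
      if (nrow(ev) != 1) stop("gene construction yielded ", nrow(ev),
                              " events for ", gid)
      rows[[i]] <- data.frame(
        gene_id = gid, event_id = ev$event_id, type = types[i],
        chrom = chrom, strand = strand,
        gene_start = built$gene$start, gene_end = built$gene$end,
        alt_start = built$alt[1], alt_end = built$alt[2],
        is_dis = is_dis[i], dependence = dep[i],
        baseline_psi = baseline[i], delta_psi = delta[i],
        gene_class = gene_class[i], is_deg = gene_class[i] == "DEG",
        stringsAsFactors = FALSE
      )
      cursor <- built$gene$end + 2000L
    }
    list(genes = genes, truth = do.call(rbind, rows))
  })
}

#' Generate per-replicate isoform-specific event counts
#'
#' Per genotype, condition and replicate the total isoform-specific depth is
#' Poisson and the inclusion count Binomial with the event's true PSI: the
#' baseline at the low temperature, baseline plus the true shift at the high
#' temperature for differential events, with the shift multiplied by
#' `1 - attenuation` in mutant genotypes at mark-dependent events.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [gen_gene_models()].
#' @return Long `data.frame`: `event_id`, `sample_id`, `genotype`,
#'   `condition`, `replicate`, `n_incl`, `n_excl`.
#' @export
gen_event_counts <- function(cfg, truth) {
  with_seed(derive_seed(cfg$seed, 2L), {
    rows <- list()
    for (g in names(cfg$genotypes)) {
      att <- cfg$genotypes[[g]]
      for (ci in 1:2) {
        cond <- cfg$conditions[ci]
        shift_scale <- ifelse(
          !is.na(truth$dependence) & truth$dependence == "dependent",
          1 - att, 1)
        psi <- if (ci == 1) truth$baseline_psi else {
          truth$baseline_psi + truth$delta_psi * shift_scale
        }
        if (any(psi < 0 | psi > 1)) {
          warning("true PSI outside [0, 1]; clipped")
          psi <- pmin(pmax(psi, 0), 1)
        }
        for (r in seq_len(cfg$n_replicates)) {
          total <- stats::rpois(nrow(truth), cfg$depth_per_replicate)
          n_incl <- stats::rbinom(nrow(truth), total, psi)
          rows[[length(rows) + 1]] <- data.frame(
            event_id = truth$event_id,
            sample_id = paste(g, cond, r, sep = "_"),
            genotype = g, condition = cond, replicate = r,
            n_incl = n_incl, n_excl = total - n_incl,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate mark regions and occupancy tracks
#'
#' Genes are marked with the per-class probability; each marked gene gets
#' one region per condition centred `mark_peak_offset` bp downstream of its
#' TSS (strand-aware) with the condition-specific width. Tracks are Gaussian
#' bumps over the regions plus a small constant background and seeded noise,
#' sampled in 10-bp bins. With `mark_dependent_overlap = TRUE`, regions of
#' genes carrying a mark-dependent event are centred on the event's
#' alternative region instead, and genes with a mark-independent event get a
#' short region at the gene start, away from the event.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [gen_gene_models()].
#' @return A list with `regions` (a `data.frame` with `condition` column)
#'   and `tracks` (named list of bedGraph `data.frame`s per condition).
#' @export
gen_mark_data <- function(cfg, truth) {
  with_seed(derive_seed(cfg$seed, 3L), {
    n <- nrow(truth)
    frac <- cfg$marked_fraction_by_class[truth$gene_class]
    marked <- stats::runif(n) < frac
    center <- ifelse(truth$strand == "+",
                     truth$gene_start + cfg$mark_peak_offset,
                     truth$gene_end - 1 - cfg$mark_peak_offset)
    width_override <- rep(NA_real_, n)
    if (isTRUE(cfg$mark_dependent_overlap)) {
      dep <- !is.na(truth$dependence) & truth$dependence == "dependent"
      ind <- !is.na(truth$dependence) & truth$dependence == "independent"
      marked[dep | ind] <- TRUE
      center[dep] <- floor((truth$alt_start[dep] + truth$alt_end[dep]) / 2)
      center[ind] <- truth$gene_start[ind] + 40
      width_override[ind] <- 80
    }
    occupancy <- round(stats::runif(n, 2, 10), 3)

    regions <- do.call(rbind, lapply(cfg$conditions, function(cond) {
      w <- ifelse(is.na(width_override),
                  cfg$mark_width_by_condition[[cond]], width_override)
      # keep each region inside its gene span (regions are associated to
      # genes by containment); genes shorter than the width get a
      # span-wide region
      ctr <- pmin(pmax(center, truth$gene_start + w %/% 2),
                  truth$gene_end - (w - w %/% 2))
      start <- pmax(truth$gene_start, as.integer(ctr - w %/% 2))
      end <- pmin(truth$gene_end, as.integer(ctr + (w - w %/% 2)))
      data.frame(chrom = truth$chrom,
                 start = start,
                 end = end,
                 occupancy = occupancy,
                 condition = cond,
                 gene_id = truth$gene_id,
                 stringsAsFactors = FALSE)[marked, , drop = FALSE]
    }))
    rownames(regions) <- NULL

    chrom_len <- tapply(truth$gene_end, truth$chrom, max) + 2500
    tracks <- lapply(cfg$conditions, function(cond) {
      reg <- regions[regions$condition == cond, , drop = FALSE]
      do.call(rbind, lapply(names(chrom_len), function(ch) {
        len <- ceiling(chrom_len[[ch]] / 10) * 10
        starts <- seq(0L, len - 10L, by = 10L)
        x <- starts + 5
        val <- rep(0.1, length(x)) +
          abs(stats::rnorm(length(x), 0, 0.02))
        rr <- reg[reg$chrom == ch, , drop = FALSE]
        for (k in seq_len(nrow(rr))) {
          mid <- (rr$start[k] + rr$end[k]) / 2
          sdv <- (rr$end[k] - rr$start[k]) / 4
          win <- which(abs(x - mid) < 4 * sdv)
          val[win] <- val[win] +
            rr$occupancy[k] * exp(-((x[win] - mid)^2) / (2 * sdv^2))
        }
        data.frame(chrom = ch, start = starts, end = starts + 10L,
                   value = round(val, 4), stringsAsFactors = FALSE)
      }))
    })
    names(tracks) <- cfg$conditions
    list(regions = regions, tracks = tracks)
  })
}

#' Generate a negative-binomial expression count matrix
#'
#' Gene baseline means are log-normal; differentially expressed genes are
#' shifted by `true_lfc` (random sign) at the high temperature. Samples are
#' `n_replicates` per condition for the wild type.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [gen_gene_models()].
#' @return A list with `counts` (integer matrix, genes x samples) and
#'   `groups` (condition label per sample).
#' @export
gen_expression_counts <- function(cfg, truth) {
  with_seed(derive_seed(cfg$seed, 4L), {
    n <- nrow(truth)
    base <- exp(stats::rnorm(n, log(200), 1))
    lfc <- ifelse(truth$is_deg,
                  cfg$true_lfc * sample(c(-1, 1), n, replace = TRUE), 0)
    groups <- rep(cfg$conditions, each = cfg$n_replicates)
    mu <- outer(base, ifelse(groups == cfg$conditions[2], 1, 0),
                function(b, hi) b) *
      2^outer(lfc, ifelse(groups == cfg$conditions[2], 1, 0))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$nb_dispersion),
                     nrow = n)
    rownames(counts) <- truth$gene_id
    colnames(counts) <- paste(groups, rep(seq_len(cfg$n_replicates), 2),
                              sep = "_")
    list(counts = counts, groups = groups)
  })
}

#' Generate a flowering-time phenotype table
#'
#' Per genotype, condition and tray, plant days-to-bolting are Normal around
#' the configured mean (sd 3) rounded to the 2-day screening grid; rosette
#' leaf number is correlated with days to bolting.
#'
#' @param cfg A [sim_config()].
#' @return `data.frame` with columns `genotype`, `condition`,
#'   `replicate_tray`, `plant_id`, `dtb`, `rln`.
#' @export
gen_phenotype <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 5L), {
    rows <- list()
    for (g in names(cfg$phenotype_effects)) {
      for (cond in cfg$conditions) {
        mu <- cfg$phenotype_effects[[g]][[cond]]
        for (tr in seq_len(cfg$n_trays)) {
          dtb_raw <- stats::rnorm(cfg$plants_per_tray, mu, 3)
          dtb <- pmax(2, 2 * round(dtb_raw / 2))  # 2-day screening grid
          rln <- pmax(0, round(0.85 * dtb + stats::rnorm(cfg$plants_per_tray,
                                                         0, 2)))
          rows[[length(rows) + 1]] <- data.frame(
            genotype = g, condition = cond, replicate_tray = tr,
            plant_id = sprintf("%s_%s_t%d_p%02d", g, cond, tr,
                               seq_len(cfg$plants_per_tray)),
            dtb = dtb, rln = rln, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a gene-to-term annotation map
#'
#' One term is enriched in the differentially spliced genes; the remaining
#' terms draw members uniformly from all genes.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [gen_gene_models()].
#' @param n_terms Total number of terms (>= 2).
#' @return `data.frame` with columns `term_id`, `gene_id`, `description`.
#' @export
gen_term_map <- function(cfg, truth, n_terms = 5) {
  with_seed(derive_seed(cfg$seed, 6L), {
    dis_genes <- truth$gene_id[truth$is_dis]
    enriched <- unique(c(
      sample(dis_genes, max(5, round(0.6 * length(dis_genes)))),
      sample(truth$gene_id, round(0.05 * nrow(truth)))))
    rows <- list(data.frame(term_id = "T0001", gene_id = enriched,
                            description = "splicing response",
                            stringsAsFactors = FALSE))
    for (k in seq_len(n_terms - 1)) {
      members <- sample(truth$gene_id,
                        min(sample(10:40, 1), nrow(truth)))
      rows[[k + 1]] <- data.frame(
        term_id = sprintf("T%04d", k + 1), gene_id = members,
        description = sprintf("background process %d", k),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Emit simulated read alignments for one event
#'
#' Draws reads from the inclusion form with probability `psi` and the
#' exclusion form otherwise, placing read starts uniformly along the chosen
#' form and mapping them back to genomic blocks. Used to exercise
#' isoform-specific read counting.
#'
#' @param event One event row (from [enumerate_events()]).
#' @param n_reads Number of reads.
#' @param psi True inclusion fraction.
#' @param read_length Read length in transcript bp.
#' @param seed Integer seed.
#' @return A list of two-column block matrices (0-based half-open).
#' @export
gen_read_alignments <- function(event, n_reads, psi, read_length = 80,
                                seed = 1337) {
  incl <- decode_form(event$inclusion_form)
  excl <- decode_form(event$exclusion_form)
  tx_to_blocks <- function(form, s, e) {
    # transcript-coordinate interval [s, e) -> genomic blocks
    lens <- form[, 2] - form[, 1]
    offs <- cumsum(c(0, lens[-length(lens)]))
    blocks <- list()
    for (k in seq_len(nrow(form))) {
      lo <- max(s, offs[k]); hi <- min(e, offs[k] + lens[k])
      if (lo < hi) {
        blocks[[length(blocks) + 1]] <-
          c(form[k, 1] + lo - offs[k], form[k, 1] + hi - offs[k])
      }
    }
    do.call(rbind, blocks)
  }
  with_seed(seed, {
    lapply(seq_len(n_reads), function(i) {
      form <- if (stats::runif(1) < psi) incl else excl
      L <- sum(form[, 2] - form[, 1])
      rl <- min(read_length, L)
      s <- sample.int(L - rl + 1L, 1) - 1L
      tx_to_blocks(form, s, s + rl)
    })
  })
}

#' Write every simulated input to a directory
#'
#' Emits `genes.gtf`, `truth.tsv`, `counts_<genotype>.tsv`,
#' `marks_<condition>.bed`, `track_<condition>.bedgraph`, `expression.tsv`,
#' `expression_groups.tsv`, `phenotype.tsv`, `term_map.tsv` and the resolved
#' configuration (`sim_config.yaml`). Fully deterministic given the
#' configuration seed.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
simulate_all <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gm <- gen_gene_models(cfg)
  write_gtf(gm$genes, file.path(out_dir, "genes.gtf"))
  write_tsv(gm$truth, file.path(out_dir, "truth.tsv"))

  counts <- gen_event_counts(cfg, gm$truth)
  for (g in names(cfg$genotypes)) {
    write_tsv(counts[counts$genotype == g, , drop = FALSE],
              file.path(out_dir, paste0("counts_", g, ".tsv")))
  }

  marks <- gen_mark_data(cfg, gm$truth)
  for (cond in cfg$conditions) {
    reg <- marks$regions[marks$regions$condition == cond, , drop = FALSE]
    write_bed(reg, file.path(out_dir, paste0("marks_", cond, ".bed")))
    write_bedgraph(marks$tracks[[cond]],
                   file.path(out_dir, paste0("track_", cond, ".bedgraph")))
  }

  expr <- gen_expression_counts(cfg, gm$truth)
  expr_df <- data.frame(gene_id = rownames(expr$counts), expr$counts,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr_df, file.path(out_dir, "expression.tsv"))
  write_tsv(data.frame(sample_id = colnames(expr$counts),
                       group = expr$groups, stringsAsFactors = FALSE),
            file.path(out_dir, "expression_groups.tsv"))

  write_tsv(gen_phenotype(cfg), file.path(out_dir, "phenotype.tsv"))
  write_tsv(gen_term_map(cfg, gm$truth), file.path(out_dir, "term_map.tsv"))

  cfg_out <- cfg
  class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, file.path(out_dir, "sim_config.yaml"))
  invisible(out_dir)
}
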