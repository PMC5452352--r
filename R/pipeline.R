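# Pipeline orchestration: simulate -> events -> dis -> dependence ->
# chromatin -> expression -> phenotype, with a run manifest.

default_config <- function() {
  list(
    seed = 1337,
    sim = list(),
    dis = list(bf_threshold = 5, min_reads = 20, min_reps = 2,
               n_draws = 100000),
    chromatin = list(overlap_mode = "containment", window = c(-2000, 2000),
                     bin = 50),
    deg = list(lfc_threshold = 1, alpha = 0.05),
    enrichment = list(alpha = 0.05, min_genes = 5)
  )
}

validate_config <- function(config) {
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  merged <- default_config()
  for (k in names(config)) {
    if (is.list(merged[[k]]) && is.list(config[[k]])) {
      merged[[k]][names(config[[k]])] <- config[[k]]
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  stopifnot(is.numeric(merged$seed), length(merged$seed) == 1)
  merged
}

stage_input <- function(stage, path) {
  if (!file.exists(path)) {
    stop("stage '", stage, "': missing input file ", path)
  }
  path
}

#' Run the full pipeline on simulated inputs
#'
#' Executes the stages in dependency order: simulate (emit all inputs),
#' events (enumerate the event catalog from the GTF), dis (per-genotype
#' differential-splicing calls), dependence (mark-dependence classification
#' and |delta PSI| ecdf comparisons), chromatin (region association,
#' marked-gene fractions per gene class, metagene profiles, region widths,
#' event-to-region distances), expression (differential expression, overlap
#' with differentially spliced genes, term enrichment) and phenotype
#' (temperature-response ratios). Outputs are deterministic given the
#' configuration seed; a run manifest with seeds, input digests and row
#' counts is written last.
#'
#' @param config Path to a YAML configuration file, or a configuration list.
#'   Keys: `seed`, `sim` (overrides for [sim_config()]), `dis`, `chromatin`,
#'   `deg`, `enrichment`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    config <- yaml::read_yaml(stage_input("config", config))
  }
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts_rows <- list()

  # --- simulate ---------------------------------------------------------
  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  sim_dir <- file.path(out_dir, "sim")
  simulate_all(cfg, sim_dir)

  # --- events -----------------------------------------------------------
  genes <- read_gtf(stage_input("events", file.path(sim_dir, "genes.gtf")))
  events <- enumerate_all_events(genes)
  write_event_catalog(events, file.path(out_dir, "events.tsv"),
                      file.path(out_dir, "events_alt_regions.bed"))
  counts_rows$events <- nrow(events)

  # --- dis --------------------------------------------------------------
  genotypes <- names(cfg$genotypes)
  dis <- list()
  for (g in genotypes) {
    path <- stage_input("dis", file.path(sim_dir,
                                         paste0("counts_", g, ".tsv")))
    cts <- read_table_schema(path, c("event_id", "condition", "replicate",
                                     "n_incl", "n_excl"))
    res <- call_dis_table(cts, cfg$conditions[1], cfg$conditions[2],
                          bf_threshold = config$dis$bf_threshold,
                          min_reads = config$dis$min_reads,
                          min_reps = config$dis$min_reps,
                          n_draws = config$dis$n_draws,
                          seed = derive_seed(config$seed, 10L))
    res$genotype <- g
    res$gene_id <- events$gene_id[match(res$event_id, events$event_id)]
    write_tsv(res, file.path(out_dir, paste0("dis_", g, ".tsv")))
    dis[[g]] <- res
  }
  counts_rows$dis_significant_wt <- sum(dis[[1]]$significant)

  # --- dependence -------------------------------------------------------
  wt <- dis[[1]]
  mutants <- dis[-1]
  dep_calls <- do.call(rbind, lapply(seq_len(nrow(wt)), function(i) {
    classify_dependence(
      wt[i, , drop = FALSE],
      lapply(mutants, function(m) m[m$event_id == wt$event_id[i], ,
                                    drop = FALSE]))
  }))
  dep_calls$gene_id <- wt$gene_id
  write_tsv(dep_calls, file.path(out_dir, "dependence.tsv"))
  counts_rows$dependent <- sum(dep_calls$class == "dependent")
  counts_rows$independent <- sum(dep_calls$class == "independent")

  sig_ids <- wt$event_id[wt$significant]
  ks_rows <- lapply(names(mutants), function(g) {
    if (length(sig_ids) < 1) {
      return(data.frame(genotype = g, ks_statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    m <- mutants[[g]]
    cmp <- delta_psi_ecdf_compare(
      abs(wt$delta_psi[wt$event_id %in% sig_ids]),
      abs(m$delta_psi[m$event_id %in% sig_ids]))
    data.frame(genotype = g, ks_statistic = cmp$ks_statistic,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, ks_rows), file.path(out_dir, "ks_summary.tsv"))

  # --- expression (before chromatin: gene classes need the DEG calls) ---
  expr_df <- read_table_schema(
    stage_input("expression", file.path(sim_dir, "expression.tsv")),
    "gene_id")
  groups <- read_table_schema(
    stage_input("expression", file.path(sim_dir, "expression_groups.tsv")),
    c("sample_id", "group"))
  mat <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(mat) <- expr_df$gene_id
  deg <- call_deg(mat, groups$group[match(colnames(mat), groups$sample_id)],
                  lfc_threshold = config$deg$lfc_threshold,
                  alpha = config$deg$alpha)
  write_tsv(deg, file.path(out_dir, "deg.tsv"))
  counts_rows$deg <- sum(deg$is_deg)

  dis_genes <- sort(unique(wt$gene_id[wt$significant]))
  deg_genes <- sort(deg$gene_id[deg$is_deg])
  ov <- overlap_sets(dis_genes, deg_genes)
  jsonlite::write_json(ov, file.path(out_dir, "overlap.json"),
                       auto_unbox = TRUE)

  term_map <- read_table_schema(
    stage_input("expression", file.path(sim_dir, "term_map.tsv")),
    c("term_id", "gene_id"))
  if (length(dis_genes) > 0) {
    enr <- hypergeom_enrichment(dis_genes, deg$gene_id, term_map,
                                alpha = config$enrichment$alpha,
                                min_genes = config$enrichment$min_genes)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  }

  # --- chromatin --------------------------------------------------------
  regions <- lapply(cfg$conditions, function(cond) {
    read_bed(stage_input("chromatin",
                         file.path(sim_dir, paste0("marks_", cond, ".bed"))),
             condition = cond)
  })
  names(regions) <- cfg$conditions
  ann <- associate_regions(genes, regions[[1]],
                           overlap_mode = config$chromatin$overlap_mode)
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  classes <- ifelse(gene_ids %in% dis_genes, "DiS",
                    ifelse(gene_ids %in% deg_genes, "DEG", "neither"))
  names(classes) <- gene_ids
  frac_rows <- do.call(rbind, lapply(unique(classes), function(cl) {
    set <- gene_ids[classes == cl]
    data.frame(class = cl, n_genes = length(set),
               fraction_marked = fraction_marked(set, ann),
               stringsAsFactors = FALSE)
  }))
  write_tsv(frac_rows, file.path(out_dir, "fractions.tsv"))

  track <- read_bedgraph(stage_input(
    "chromatin", file.path(sim_dir, paste0("track_", cfg$conditions[1],
                                           ".bedgraph"))))
  prof <- metagene_profile(track, genes, anchor = "TSS",
                           window = config$chromatin$window,
                           bin = config$chromatin$bin, classes = classes)
  write_tsv(prof$profiles, file.path(out_dir, "profiles.tsv"))

  widths <- compare_region_widths(regions[[1]], regions[[2]])
  write_tsv(data.frame(condition = cfg$conditions,
                       median_width = c(widths$median_width_a,
                                        widths$median_width_b),
                       median_ratio = widths$median_ratio,
                       p_value = widths$p_value),
            file.path(out_dir, "width_summary.tsv"))

  dist_of <- function(ids) {
    vapply(ids, function(id) {
      ev <- events[events$event_id == id, , drop = FALSE]
      arow <- ann[ann$gene_id == ev$gene_id, , drop = FALSE]
      event_region_distance(ev, arow, regions[[1]])
    }, numeric(1))
  }
  dep_ids <- dep_calls$event_id[dep_calls$class == "dependent"]
  ind_ids <- dep_calls$event_id[dep_calls$class == "independent"]
  dist_df <- data.frame(
    event_id = c(dep_ids, ind_ids),
    class = rep(c("dependent", "independent"),
                c(length(dep_ids), length(ind_ids))),
    distance = c(dist_of(dep_ids), dist_of(ind_ids)),
    stringsAsFactors = FALSE)
  write_tsv(dist_df, file.path(out_dir, "distances.tsv"))
  dist_test <- tryCatch(
    compare_distance_distributions(
      dist_df$distance[dist_df$class == "dependent"],
      dist_df$distance[dist_df$class == "independent"]),
    error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                             n_dep = 0, n_indep = 0, n_dropped = 0))
  write_tsv(data.frame(statistic = dist_test$statistic,
                       p_value = dist_test$p_value,
                       n_dependent = dist_test$n_dep,
                       n_independent = dist_test$n_indep,
                       n_unmarked_dropped = dist_test$n_dropped),
            file.path(out_dir, "distance_summary.tsv"))

  # --- phenotype --------------------------------------------------------
  pheno <- read_table_schema(
    stage_input("phenotype", file.path(sim_dir, "phenotype.tsv")),
    c("genotype", "condition", "replicate_tray", "dtb", "rln"))
  pheno_rows <- list()
  summaries <- list()
  for (g in unique(pheno$genotype)) {
    for (trait in c("DTB", "RLN")) {
      rs <- response_ratio(pheno, g, trait, cond_low = cfg$conditions[1],
                           cond_high = cfg$conditions[2])
      summaries[[paste(g, trait)]] <- rs
      pheno_rows[[paste(g, trait)]] <- data.frame(
        genotype = g, trait = trait, mean_ratio = rs$mean_ratio,
        ratios = paste(signif(rs$per_replicate_ratios, 6), collapse = ","),
        p_vs_first = NA_real_, stringsAsFactors = FALSE)
    }
  }
  first <- unique(pheno$genotype)[1]
  for (nm in names(pheno_rows)) {
    g <- pheno_rows[[nm]]$genotype
    trait <- pheno_rows[[nm]]$trait
    if (g != first) {
      pheno_rows[[nm]]$p_vs_first <- compare_response(
        summaries[[paste(first, trait)]], summaries[[nm]])$p_value
    }
  }
  pheno_sum <- do.call(rbind, pheno_rows)
  rownames(pheno_sum) <- NULL
  write_tsv(pheno_sum, file.path(out_dir, "phenotype_summary.tsv"))

  # --- manifest ---------------------------------------------------------
  inputs <- list.files(sim_dir, full.names = TRUE)
  manifest <- list(
    tool = "thermosplice",
    version = as.character(utils::packageVersion("thermosplice")),
    seed = config$seed,
    config = config,
    input_digests = as.list(tools::md5sum(inputs)),
    row_counts = counts_rows,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
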