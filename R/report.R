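# Summary tables and figures from a pipeline output directory.

# Save a ggplot headlessly; falls back to PDF when no PNG device is
# available. Returns the path written.
save_plot <- function(p, path_base, width = 7, height = 5) {
  path <- paste0(path_base, ".png")
  ok <- tryCatch({
    grDevices::png(path, width = width * 100, height = height * 100,
                   res = 100)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    path <- paste0(path_base, ".pdf")
    grDevices::pdf(path, width = width, height = height)
    print(p)
    grDevices::dev.off()
  }
  path
}

#' Build summary tables and plots from a pipeline run
#'
#' Emits a PSI matrix (significant events x samples, per-replicate posterior
#' means) with a heatmap, the metagene profile plot, the |delta PSI| ecdf
#' plot with the Kolmogorov-Smirnov annotation, and the response-ratio
#' table. Runs headless. When no event is significant, the report states so
#' explicitly instead of failing.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return Invisibly, the list of files written.
#' @export
report <- function(out_dir) {
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  sim_dir <- file.path(out_dir, "sim")
  wt_path <- list.files(out_dir, "^dis_.*\\.tsv$", full.names = TRUE)[1]
  wt <- read_table_schema(wt_path, c("event_id", "delta_psi", "significant"))
  genotype_wt <- wt$genotype[1]

  # PSI heatmap matrix: per-replicate posterior-mean PSI of significant
  # events in the first (wild-type) genotype
  sig <- wt$event_id[wt$significant]
  cts <- read_table_schema(
    file.path(sim_dir, paste0("counts_", genotype_wt, ".tsv")),
    c("event_id", "sample_id", "n_incl", "n_excl"))
  cts <- cts[cts$event_id %in% sig, , drop = FALSE]
  if (nrow(cts) > 0) {
    cts$psi <- mapply(function(i, e) estimate_psi(i, e)$psi_mean,
                      cts$n_incl, cts$n_excl)
    mat <- stats::reshape(
      cts[, c("event_id", "sample_id", "psi")],
      idvar = "event_id", timevar = "sample_id", direction = "wide")
    names(mat) <- sub("^psi\\.", "", names(mat))
    write_tsv(mat, file.path(out_dir, "psi_matrix.tsv"))
    emit(file.path(out_dir, "psi_matrix.tsv"))
    p <- ggplot2::ggplot(cts, ggplot2::aes(
      x = sample_id, y = event_id, fill = psi)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                   limits = c(0, 1)) +
      ggplot2::labs(x = NULL, y = NULL, fill = "PSI") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                     axis.text.x = ggplot2::element_text(angle = 90))
    emit(save_plot(p, file.path(out_dir, "psi_heatmap")))
  } else {
    writeLines("no significant events",
               file.path(out_dir, "psi_matrix.tsv"))
    emit(file.path(out_dir, "psi_matrix.tsv"))
  }

  # metagene profile plot
  prof <- read_table_schema(file.path(out_dir, "profiles.tsv"),
                            c("class", "offset", "mean_signal"))
  p <- ggplot2::ggplot(prof, ggplot2::aes(
    x = offset, y = mean_signal, colour = class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from TSS (bp)", y = "mean occupancy") +
    ggplot2::theme_minimal()
  emit(save_plot(p, file.path(out_dir, "metagene_profile")))

  # |delta PSI| ecdf across genotypes for wild-type-significant events
  dis_files <- list.files(out_dir, "^dis_.*\\.tsv$", full.names = TRUE)
  ecdf_df <- do.call(rbind, lapply(dis_files, function(f) {
    d <- read_table_schema(f, c("event_id", "delta_psi", "genotype"))
    d <- d[d$event_id %in% sig, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(genotype = d$genotype, abs_dpsi = abs(d$delta_psi),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ecdf_df) && nrow(ecdf_df) > 0) {
    ks <- read_table_schema(file.path(out_dir, "ks_summary.tsv"),
                            c("genotype", "ks_statistic", "p_value"))
    lab <- paste(sprintf("%s: D=%.2f, p=%.2g", ks$genotype,
                         ks$ks_statistic, ks$p_value), collapse = "\n")
    p <- ggplot2::ggplot(ecdf_df, ggplot2::aes(
      x = abs_dpsi, colour = genotype)) +
      ggplot2::stat_ecdf() +
      ggplot2::coord_cartesian(xlim = c(0, 1)) +
      ggplot2::annotate("text", x = 0.7, y = 0.2, label = lab, size = 3) +
      ggplot2::labs(x = "|delta PSI|", y = "ecdf") +
      ggplot2::theme_minimal()
    emit(save_plot(p, file.path(out_dir, "dpsi_ecdf")))
  } else {
    writeLines("no significant events", file.path(out_dir, "dpsi_ecdf.txt"))
    emit(file.path(out_dir, "dpsi_ecdf.txt"))
  }

  # response-ratio table is already written by the pipeline; re-emit as the
  # report's ratio bar table
  ph <- read_table_schema(file.path(out_dir, "phenotype_summary.tsv"),
                          c("genotype", "trait", "mean_ratio"))
  write_tsv(ph, file.path(out_dir, "response_ratio_table.tsv"))
  emit(file.path(out_dir, "response_ratio_table.tsv"))

  invisible(written)
}
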