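# Flowering-time temperature response: per-tray trait ratios between the
# low and the high ambient temperature, and genotype comparisons.

#' Temperature-response ratio for one genotype and trait
#'
#' Per replicate tray, the ratio of the tray's mean trait value at the low
#' temperature over its mean at the high temperature; the summary is the
#' arithmetic mean of the per-tray ratios. A genotype that accelerates
#' flowering at the high temperature has a ratio above 1; a non-responder
#' sits at 1. Plants are never pooled across trays.
#'
#' @param records Phenotype `data.frame` with columns `genotype`,
#'   `condition`, `replicate_tray`, `plant_id`, `dtb`, `rln`.
#' @param genotype Genotype to summarise.
#' @param trait `"DTB"` (days to bolting) or `"RLN"` (rosette leaf number).
#' @param cond_low,cond_high Condition labels for the ratio numerator and
#'   denominator (defaults `"16C"` / `"25C"`).
#' @return A list (`ResponseSummary`) with `genotype`, `trait`,
#'   `per_replicate_ratios`, `mean_ratio`.
#' @export
response_ratio <- function(records, genotype, trait = c("DTB", "RLN"),
                           cond_low = "16C", cond_high = "25C") {
  trait <- match.arg(trait)
  col <- if (trait == "DTB") "dtb" else "rln"
  rec <- records[records$genotype == genotype, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for genotype ", genotype)
  trays <- sort(unique(rec$replicate_tray))
  ratios <- vapply(trays, function(tr) {
    lo <- rec[[col]][rec$replicate_tray == tr & rec$condition == cond_low]
    hi <- rec[[col]][rec$replicate_tray == tr & rec$condition == cond_high]
    if (length(lo) == 0 || length(hi) == 0) {
      stop("tray ", tr, " of genotype ", genotype,
           " is missing a condition")
    }
    mean(lo) / mean(hi)
  }, numeric(1))
  list(genotype = genotype, trait = trait,
       per_replicate_ratios = unname(ratios),
       mean_ratio = mean(ratios))
}

#' Compare temperature responses of two genotypes
#'
#' Two-sided two-sample Student's t-test (pooled variance) on the per-tray
#' response ratios.
#'
#' @param summary_a,summary_b `ResponseSummary` objects from
#'   [response_ratio()] with at least two replicate ratios each.
#' @return A list with `t_statistic` and `p_value`.
#' @export
compare_response <- function(summary_a, summary_b) {
  ra <- summary_a$per_replicate_ratios
  rb <- summary_b$per_replicate_ratios
  if (length(ra) < 2 || length(rb) < 2) {
    stop("need >= 2 replicate ratios per genotype")
  }
  if (stats::sd(ra) == 0 && stats::sd(rb) == 0) {
    # degenerate case: constant ratios in both groups
    if (mean(ra) == mean(rb)) return(list(t_statistic = 0, p_value = 1))
    return(list(t_statistic = sign(mean(ra) - mean(rb)) * Inf, p_value = 0))
  }
  tt <- stats::t.test(ra, rb, var.equal = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = unname(tt$p.value))
}
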