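# Differential-splicing calls, H3K36me3-dependence classification, and
# genotype-level effect-size comparison.

#' Call differential splicing for one event between two conditions
#'
#' Computes per-replicate PSIs, pooled per-condition PSIs, the pooled
#' delta PSI (condition b minus condition a) and the Savage-Dickey Bayes
#' factor on the pooled counts. The event is significant when it passes the
#' read-support filter, the replicate-consistency filter, and the Bayes
#' factor reaches `bf_threshold`.
#'
#' @param replicates_a,replicates_b Count `data.frame`s (one row per
#'   replicate; columns `event_id`, `condition`, `n_incl`, `n_excl`).
#' @param bf_threshold Bayes-factor significance threshold (default 5).
#' @param min_reads,min_reps Read-support filter parameters (defaults 20
#'   reads in at least 2 replicates of each condition).
#' @param n_draws Posterior draws for the Bayes factor.
#' @param seed Integer seed for the Bayes-factor computation.
#' @return A one-row `data.frame` (`DiSResult`): pooled PSI estimates and
#'   intervals per condition, `delta_psi`, `bayes_factor`, filter flags and
#'   `significant`.
#' @export
call_dis <- function(replicates_a, replicates_b, bf_threshold = 5,
                     min_reads = 20, min_reps = 2, n_draws = 100000,
                     seed = 1337) {
  stopifnot(nrow(replicates_a) >= 1, nrow(replicates_b) >= 1)
  event_id <- unique(c(replicates_a$event_id, replicates_b$event_id))
  if (length(event_id) != 1) stop("call_dis: mixed event ids")

  rep_psi <- function(reps) {
    tot <- reps$n_incl + reps$n_excl
    keep <- tot > 0  # zero-read replicates carry no PSI information
    mapply(function(i, e) estimate_psi(i, e)$psi_mean,
           reps$n_incl[keep], reps$n_excl[keep])
  }
  psis_a <- rep_psi(replicates_a)
  psis_b <- rep_psi(replicates_b)

  pa <- pool_counts(replicates_a)
  pb <- pool_counts(replicates_b)
  est_a <- estimate_psi(pa$n_incl, pa$n_excl)
  est_b <- estimate_psi(pb$n_incl, pb$n_excl)
  bf <- bayes_factor_delta(pa, pb, n_draws = n_draws, seed = seed)

  passed_support <- support_filter(replicates_a, replicates_b,
                                   min_reads = min_reads,
                                   min_reps = min_reps)
  passed_consistency <- consistency_filter(psis_a, psis_b)

  data.frame(
    event_id = event_id,
    psi_a = est_a$psi_mean, ci_low_a = est_a$ci_low, ci_high_a = est_a$ci_high,
    psi_b = est_b$psi_mean, ci_low_b = est_b$ci_low, ci_high_b = est_b$ci_high,
    delta_psi = est_b$psi_mean - est_a$psi_mean,
    bayes_factor = bf,
    passed_support = passed_support,
    passed_consistency = passed_consistency,
    significant = passed_support && passed_consistency && bf >= bf_threshold,
    stringsAsFactors = FALSE
  )
}

#' Call differential splicing for every event in a counts table
#'
#' @param counts Long-format counts `data.frame` (columns `event_id`,
#'   `condition`, `replicate`, `n_incl`, `n_excl`).
#' @param cond_a,cond_b Condition labels (delta PSI is `cond_b` minus
#'   `cond_a`).
#' @param ... Passed on to [call_dis()].
#' @param seed Base seed; each event gets a deterministic child seed.
#' @return A `data.frame` with one `DiSResult` row per event.
#' @export
call_dis_table <- function(counts, cond_a, cond_b, ..., seed = 1337) {
  ids <- sort(unique(counts$event_id))
  rows <- lapply(seq_along(ids), function(i) {
    ev <- counts[counts$event_id == ids[i], , drop = FALSE]
    call_dis(ev[ev$condition == cond_a, , drop = FALSE],
             ev[ev$condition == cond_b, , drop = FALSE],
             ..., seed = derive_seed(seed, i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify an event's dependence on the histone mark
#'
#' An event is mark-dependent when it is significantly differentially
#' spliced in the wild type but in none of the mutants (losing the mark
#' abolishes the temperature response), mark-independent when it is
#' significant in the wild type and in every mutant, and unclassified
#' otherwise.
#'
#' @param wt One-row `DiSResult` for the wild type.
#' @param mutants List of one-row `DiSResult`s for the mutant genotypes.
#' @return A one-row `data.frame` with `event_id` and `class` in
#'   `dependent`, `independent`, `unclassified`.
#' @export
classify_dependence <- function(wt, mutants) {
  ids <- c(wt$event_id, vapply(mutants, function(m) m$event_id, character(1)))
  if (length(unique(ids)) != 1) {
    stop("classify_dependence: mismatched event ids: ",
         paste(unique(ids), collapse = ", "))
  }
  mut_sig <- vapply(mutants, function(m) isTRUE(m$significant), logical(1))
  class <- if (isTRUE(wt$significant) && !any(mut_sig)) {
    "dependent"
  } else if (isTRUE(wt$significant) && all(mut_sig)) {
    "independent"
  } else {
    "unclassified"
  }
  data.frame(event_id = wt$event_id, class = class, stringsAsFactors = FALSE)
}

#' Compare |delta PSI| distributions between genotypes
#'
#' Two-sample Kolmogorov-Smirnov test on absolute delta-PSI values, as used
#' to compare the wild-type splicing response with attenuated responses in
#' mark-depleted mutants. Returns the asymptotic two-sided p value plus the
#' two empirical cumulative distribution functions for plotting.
#'
#' @param abs_dpsi_wt,abs_dpsi_mut Nonempty numeric vectors of |delta PSI|.
#' @return A list with `ks_statistic`, `p_value`, `ecdf_wt`, `ecdf_mut`.
#' @export
delta_psi_ecdf_compare <- function(abs_dpsi_wt, abs_dpsi_mut) {
  if (length(abs_dpsi_wt) < 1 || length(abs_dpsi_mut) < 1) {
    stop("both samples must be nonempty")
  }
  kt <- suppressWarnings(
    stats::ks.test(abs_dpsi_wt, abs_dpsi_mut, exact = FALSE))
  list(ks_statistic = unname(kt$statistic),
       p_value = unname(kt$p.value),
       ecdf_wt = stats::ecdf(abs_dpsi_wt),
       ecdf_mut = stats::ecdf(abs_dpsi_mut))
}
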