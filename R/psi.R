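# Bayesian PSI quantification on isoform-specific read counts.
#
# The statistical core is a two-form Beta-Binomial model: with a Uniform(0,1)
# prior on PSI, n_incl inclusion-specific and n_excl exclusion-specific reads
# give a Beta(n_incl + 1, n_excl + 1) posterior. Differential splicing
# between two conditions is tested with a Savage-Dickey density ratio at
# delta PSI = 0.

#' Count isoform-specific reads for an event
#'
#' A read (a sorted list of exonic blocks) is compatible with a form when
#' every block nests inside the form's exon segments and every junction the
#' read spans matches a form junction exactly. Reads compatible with exactly
#' one of the inclusion/exclusion forms are isoform-specific; reads
#' compatible with both or neither are ignored.
#'
#' @param event One event (single-row `data.frame` from
#'   [enumerate_events()]).
#' @param alignments List of two-column matrices of read blocks
#'   `(start, end)`, 0-based half-open, on the event's chromosome.
#' @return A one-row `data.frame` with `event_id`, `n_incl`, `n_excl`.
#' @export
count_event_reads <- function(event, alignments) {
  incl <- decode_form(event$inclusion_form)
  excl <- decode_form(event$exclusion_form)
  compatible <- function(blocks, form) {
    blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
    for (k in seq_len(nrow(blocks))) {
      if (!any(form[, 1] <= blocks[k, 1] & form[, 2] >= blocks[k, 2])) {
        return(FALSE)
      }
    }
    if (nrow(blocks) > 1) {
      jx <- chain_introns(blocks)
      fj <- chain_introns(form)
      for (k in seq_len(nrow(jx))) {
        if (nrow(fj) == 0 ||
            !any(fj[, 1] == jx[k, 1] & fj[, 2] == jx[k, 2])) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  n_incl <- 0L; n_excl <- 0L
  for (blocks in alignments) {
    ci <- compatible(blocks, incl)
    ce <- compatible(blocks, excl)
    if (ci && !ce) n_incl <- n_incl + 1L
    if (ce && !ci) n_excl <- n_excl + 1L
  }
  data.frame(event_id = event$event_id, n_incl = n_incl, n_excl = n_excl,
             stringsAsFactors = FALSE)
}

#' Posterior PSI estimate from isoform-specific counts
#'
#' Beta-Binomial model: posterior is
#' `Beta(n_incl + prior_a, n_excl + prior_b)`; the point estimate is the
#' posterior mean and the interval is the central 95% credible interval.
#'
#' @param n_incl,n_excl Nonnegative isoform-specific read counts.
#' @param prior_a,prior_b Beta prior parameters (default Uniform(0,1)).
#' @return A list with `psi_mean`, `ci_low`, `ci_high`, `n_total`.
#' @export
estimate_psi <- function(n_incl, n_excl, prior_a = 1, prior_b = 1) {
  if (n_incl < 0 || n_excl < 0) stop("counts must be nonnegative")
  a <- n_incl + prior_a
  b <- n_excl + prior_b
  list(psi_mean = a / (a + b),
       ci_low = stats::qbeta(0.025, a, b),
       ci_high = stats::qbeta(0.975, a, b),
       n_total = as.integer(n_incl + n_excl))
}

#' Pool replicate counts within a condition
#'
#' Sums isoform-specific counts across the replicates of one condition,
#' mirroring a differential test run on merged replicates.
#'
#' @param replicates `data.frame` of counts (columns `event_id`,
#'   `condition`, `n_incl`, `n_excl`) for a single event and condition.
#' @return A one-row `data.frame` with summed counts and
#'   `replicate = "pooled"`.
#' @export
pool_counts <- function(replicates) {
  if (length(unique(replicates$event_id)) != 1) {
    stop("pool_counts: mixed event ids")
  }
  if (length(unique(replicates$condition)) != 1) {
    stop("pool_counts: mixed conditions")
  }
  data.frame(event_id = replicates$event_id[1],
             condition = replicates$condition[1],
             replicate = "pooled",
             n_incl = sum(replicates$n_incl),
             n_excl = sum(replicates$n_excl),
             stringsAsFactors = FALSE)
}

#' Savage-Dickey Bayes factor for a PSI difference
#'
#' Tests delta = psi_b - psi_a != 0. Under independent Uniform(0,1) priors
#' on the two PSIs, the prior density of delta at 0 is exactly 1 (triangular
#' density on \[-1, 1\]). The posterior density at 0 is estimated from
#' `n_draws` paired Beta-posterior samples with a Gaussian kernel
#' (Silverman's rule bandwidth, floored at 0.01). BF10 = prior(0) /
#' posterior(0): values above 1 favour a splicing difference.
#'
#' @param pooled_a,pooled_b One-row count `data.frame`s (columns `n_incl`,
#'   `n_excl`) for the two conditions.
#' @param n_draws Number of posterior draws (>= 1000).
#' @param seed Integer seed; the computation is deterministic given the seed.
#' @return The Bayes factor (nonnegative; capped at 1e12).
#' @export
bayes_factor_delta <- function(pooled_a, pooled_b, n_draws = 100000,
                               seed = 1337) {
  stopifnot(n_draws >= 1000)
  with_seed(seed, {
    psi_a <- stats::rbeta(n_draws, pooled_a$n_incl + 1, pooled_a$n_excl + 1)
    psi_b <- stats::rbeta(n_draws, pooled_b$n_incl + 1, pooled_b$n_excl + 1)
  })
  delta <- psi_b - psi_a
  bw <- max(stats::bw.nrd0(delta), 0.01)
  dens0 <- mean(stats::dnorm(0, mean = delta, sd = bw))
  min(1 / max(dens0, 1e-12), 1e12)
}

#' Read-support filter
#'
#' An event is considered quantifiable when, in each condition, at least
#' `min_reps` replicates carry at least `min_reads` isoform-specific reads.
#'
#' @param replicates_a,replicates_b Count `data.frame`s (columns `n_incl`,
#'   `n_excl`), one row per replicate.
#' @param min_reads Minimum isoform-specific reads per qualifying replicate.
#' @param min_reps Minimum number of qualifying replicates per condition.
#' @return `TRUE` or `FALSE`.
#' @export
support_filter <- function(replicates_a, replicates_b, min_reads = 20,
                           min_reps = 2) {
  qual <- function(reps) {
    sum(reps$n_incl + reps$n_excl >= min_reads) >= min_reps
  }
  qual(replicates_a) && qual(replicates_b)
}

#' Replicate-consistency filter
#'
#' Requires the within-condition spread of replicate PSIs to be strictly
#' smaller than the between-condition difference: the maximum pairwise
#' |PSI_i - PSI_j| within either condition must be below
#' |mean_a - mean_b| of the per-replicate posterior-mean PSIs. Ties fail.
#'
#' @param replicate_psis_a,replicate_psis_b Numeric vectors of per-replicate
#'   posterior-mean PSIs (replicates with zero reads should be excluded by
#'   the caller).
#' @return `TRUE` or `FALSE`.
#' @export
consistency_filter <- function(replicate_psis_a, replicate_psis_b) {
  if (length(replicate_psis_a) < 1 || length(replicate_psis_b) < 1) {
    return(FALSE)
  }
  max_spread <- function(x) {
    if (length(x) < 2) return(0)
    max(x) - min(x)
  }
  within <- max(max_spread(replicate_psis_a), max_spread(replicate_psis_b))
  between <- abs(mean(replicate_psis_a) - mean(replicate_psis_b))
  within < between
}
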