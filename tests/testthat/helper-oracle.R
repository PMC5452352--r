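# Independent oracles used to validate the package implementations.

# --- brute-force event oracle -------------------------------------------
# Works from per-base exon membership and junction sets, a different
# computation route than the package's containing-exon search. Returns
# tuples (type, alt_start, alt_end, flank_left_end, flank_right_start).

oracle_junctions <- function(ex) {
  n <- nrow(ex)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cbind(ex[-n, 2], ex[-1, 1])
}

oracle_exonic <- function(ex, pos) {
  any(ex[, 1] <= pos & pos < ex[, 2])
}

oracle_has_junction <- function(J, a, b) {
  nrow(J) > 0 && any(J[, 1] == a & J[, 2] == b)
}

oracle_pair_events <- function(ex1, ex2, strand) {
  tuples <- character(0)
  add <- function(type, a1, a2, fle, frs) {
    tuples <<- c(tuples, paste(type, a1, a2, fle, frs, sep = "|"))
  }
  chains <- list(ex1, ex2)
  Js <- lapply(chains, oracle_junctions)

  for (o in 1:2) {
    x <- chains[[o]]; y <- chains[[3 - o]]
    Jx <- Js[[o]]; Jy <- Js[[3 - o]]
    # IR: x junction (a,b) inside one y exon: y exonic at a-1 and b and no
    # y junction begins in [a-1, b)
    for (k in seq_len(nrow(Jx))) {
      a <- Jx[k, 1]; b <- Jx[k, 2]
      if (oracle_exonic(y, a - 1) && oracle_exonic(y, b) &&
          !(nrow(Jy) > 0 && any(Jy[, 1] >= a - 1 & Jy[, 1] < b))) {
        add("IR", a, b, a, b)
      }
    }
    # ES: x junction (pe, ns); y has junctions (pe, s) and (e, ns) around
    # one exon (s, e)
    for (k in seq_len(nrow(Jx))) {
      pe <- Jx[k, 1]; ns <- Jx[k, 2]
      for (m in seq_len(nrow(y))) {
        s <- y[m, 1]; e <- y[m, 2]
        if (oracle_has_junction(Jy, pe, s) && oracle_has_junction(Jy, e, ns)) {
          add("ES", s, e, pe, ns)
        }
      }
    }
  }
  # A5/A3 over all junction pairs; the anchor requirement is on the exons
  # adjacent to the two junctions (junction k sits between exons k and k+1)
  for (i in seq_len(nrow(Js[[1]]))) {
    for (j in seq_len(nrow(Js[[2]]))) {
      a <- Js[[1]][i, 1]; c1 <- Js[[1]][i, 2]
      b <- Js[[2]][j, 1]; c2 <- Js[[2]][j, 2]
      if (c1 == c2 && a != b) {
        m <- min(a, b)
        if (ex1[i, 1] <= m - 1 && ex2[j, 1] <= m - 1) {
          add(if (strand == "+") "A5" else "A3", m, max(a, b), m, c1)
        }
      }
      if (a == b && c1 != c2) {
        M <- max(c1, c2)
        if (ex1[i + 1, 2] > M && ex2[j + 1, 2] > M) {
          add(if (strand == "+") "A3" else "A5", min(c1, c2), M, a, M)
        }
      }
    }
  }
  # MXE: junction-surrounded exons with equal outer boundaries
  surrounded <- function(ex, J) {
    out <- list()
    for (m in seq_len(nrow(ex))) {
      s <- ex[m, 1]; e <- ex[m, 2]
      pj <- which(J[, 2] == s); nj <- which(J[, 1] == e)
      if (length(pj) == 1 && length(nj) == 1) {
        out[[length(out) + 1]] <- c(J[pj, 1], s, e, J[nj, 2])
      }
    }
    out
  }
  sx <- surrounded(ex1, Js[[1]]); sy <- surrounded(ex2, Js[[2]])
  for (u in sx) {
    for (v in sy) {
      if (u[1] == v[1] && u[4] == v[4] &&
          (u[3] <= v[2] || v[3] <= u[2])) {
        add("MXE", min(u[2], v[2]), max(u[3], v[3]), u[1], u[4])
      }
    }
  }
  unique(tuples)
}

oracle_gene_events <- function(gene) {
  txs <- gene$transcripts
  n <- length(txs)
  if (n < 2) return(character(0))
  tuples <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tuples <- c(tuples, oracle_pair_events(txs[[i]]$exons, txs[[j]]$exons,
                                             gene$strand))
    }
  }
  unique(tuples)
}

impl_event_tuples <- function(events) {
  if (nrow(events) == 0) return(character(0))
  unique(paste(events$type, events$alt_start, events$alt_end,
               events$flank_left_end, events$flank_right_start, sep = "|"))
}

# Random multi-isoform gene: a master exon chain plus transcripts derived
# by random structural edits (intron retention, exon drop, boundary shift,
# exon replacement, duplication). Produces matches for every pattern as
# well as complex regions that must yield no event.
random_test_gene <- function(gene_id = "g", n_tx = NULL) {
  n_ex <- sample(3:6, 1)
  lens <- sample(30:120, n_ex, replace = TRUE)
  gaps <- sample(20:100, n_ex - 1, replace = TRUE)
  starts <- cumsum(c(0, lens[-n_ex] + gaps))
  master <- cbind(starts, starts + lens)
  pick <- function(v) v[sample.int(length(v), 1)]
  edit <- function(ex) {
    n <- nrow(ex)
    op <- pick(1:5)
    if (op == 1 && n >= 2) {              # retain an intron
      k <- pick(seq_len(n - 1))
      ex[k, 2] <- ex[k + 1, 2]
      ex <- ex[-(k + 1), , drop = FALSE]
    } else if (op == 2 && n >= 3) {       # skip an internal exon
      ex <- ex[-pick(2:(n - 1)), , drop = FALSE]
    } else if (op == 3 && n >= 2) {       # shift a donor-side boundary
      k <- pick(seq_len(n - 1))
      gap <- ex[k + 1, 1] - ex[k, 2]
      if (gap > 12) ex[k, 2] <- ex[k, 2] + pick(5:(gap - 6))
    } else if (op == 4 && n >= 2) {       # shift an acceptor-side boundary
      k <- pick(2:n)
      gap <- ex[k, 1] - ex[k - 1, 2]
      if (gap > 12) ex[k, 1] <- ex[k, 1] - pick(5:(gap - 6))
    } else if (op == 5 && n >= 3) {       # replace an internal exon
      k <- pick(2:(n - 1))
      lo <- ex[k - 1, 2] + 5; hi <- ex[k + 1, 1] - 5
      if (hi - lo > 20) {
        len <- pick(10:min(60, hi - lo - 5))
        s <- pick(lo:(hi - len))
        ex[k, ] <- c(s, s + len)
      }
    }
    ex[order(ex[, 1]), , drop = FALSE]
  }
  valid <- function(ex) {
    nrow(ex) >= 1 && all(ex[, 1] < ex[, 2]) &&
      (nrow(ex) < 2 || all(ex[-1, 1] > ex[-nrow(ex), 2]))
  }
  if (is.null(n_tx)) n_tx <- sample(2:4, 1)
  txs <- lapply(seq_len(n_tx), function(t) {
    ex <- master
    for (r in seq_len(sample(0:2, 1))) {
      cand <- edit(ex)
      if (valid(cand)) ex <- cand
    }
    transcript_model(paste0(gene_id, ".", t), ex)
  })
  gene_model(gene_id, "chr1", sample(c("+", "-"), 1), txs)
}

# --- Bayes-factor quadrature oracle -------------------------------------
# The posterior density of delta = psi_b - psi_a at 0 is the overlap
# integral of the two Beta posteriors; BF10 = 1 / that density.
bf_quadrature <- function(n_incl_a, n_excl_a, n_incl_b, n_excl_b) {
  dens0 <- stats::integrate(function(t) {
    stats::dbeta(t, n_incl_a + 1, n_excl_a + 1) *
      stats::dbeta(t, n_incl_b + 1, n_excl_b + 1)
  }, 0, 1, rel.tol = 1e-10)$value
  1 / dens0
}

# --- exact two-sample statistics ----------------------------------------

# Exact one-sided Mann-Whitney p (x tends smaller) by enumerating all
# assignments of the pooled sample (no ties assumed). The test statistic is
# the number of (x, y) pairs with x > y; small values support "x < y".
exact_mw_less_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">")) +
    0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(us <= u_obs + 1e-12)
}

# Brute-force two-sample KS statistic: sup over the pooled support.
brute_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# --- canonical event fixtures -------------------------------------------

canonical_event_gene <- function(type, strand = "+") {
  txs <- switch(type,
    IR = list(transcript_model("t1", rbind(c(0, 100), c(200, 300))),
              transcript_model("t2", rbind(c(0, 300)))),
    ES = list(transcript_model("t1", rbind(c(0, 100), c(200, 300),
                                           c(400, 500))),
              transcript_model("t2", rbind(c(0, 100), c(400, 500)))),
    A5 = list(transcript_model("t1", rbind(c(0, 150), c(200, 300))),
              transcript_model("t2", rbind(c(0, 100), c(200, 300)))),
    A3 = list(transcript_model("t1", rbind(c(0, 100), c(150, 300))),
              transcript_model("t2", rbind(c(0, 100), c(200, 300)))),
    MXE = list(transcript_model("t1", rbind(c(0, 100), c(200, 300),
                                            c(600, 700))),
               transcript_model("t2", rbind(c(0, 100), c(400, 500),
                                            c(600, 700)))),
    stop("unknown type"))
  gene_model(paste0("gene_", type), "chr1", strand, txs)
}
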