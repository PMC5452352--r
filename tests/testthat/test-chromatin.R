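two_exon_gene <- function(gene_id, chrom, start, end, strand = "+") {
  mid <- (start + end) %/% 2
  gene_model(gene_id, chrom, strand, list(transcript_model(
    paste0(gene_id, ".1"), rbind(c(start, mid - 10), c(mid + 10, end)))))
}

test_that("region-gene association honours the overlap mode", {
  g <- two_exon_gene("g1", "chr1", 1000L, 5000L)
  inside <- data.frame(chrom = "chr1", start = 1500L, end = 2000L,
                       occupancy = 1, condition = "16C")
  straddle <- data.frame(chrom = "chr1", start = 900L, end = 1100L,
                         occupancy = 1, condition = "16C")
  expect_true(associate_regions(list(g), inside)$marked)
  expect_false(associate_regions(list(g), straddle)$marked)
  expect_true(associate_regions(list(g), straddle,
                                overlap_mode = "any")$marked)
  expect_true(associate_regions(list(g), straddle,
                                overlap_mode = "midpoint")$marked)
  mid_out <- data.frame(chrom = "chr1", start = 400L, end = 1200L,
                        occupancy = 1, condition = "16C")
  expect_false(associate_regions(list(g), mid_out,
                                 overlap_mode = "midpoint")$marked)
})

test_that("association equals a brute-force containment scan", {
  set.seed(41)
  genes <- lapply(1:50, function(i) {
    chrom <- paste0("chr", sample(1:3, 1))
    start <- sample(0:50000, 1)
    two_exon_gene(sprintf("g%02d", i), chrom, start,
                  start + sample(500:5000, 1))
  })
  s <- sample(0:55000, 200, replace = TRUE)
  regions <- data.frame(chrom = paste0("chr", sample(1:3, 200, TRUE)),
                        start = s, end = s + sample(50:800, 200, TRUE),
                        occupancy = 1, condition = "16C")
  ann <- associate_regions(genes, regions)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    brute <- which(regions$chrom == g$chrom & regions$start >= g$start &
                     regions$end <= g$end)
    expect_setequal(ann$regions[[i]], brute)
    expect_equal(ann$marked[i], length(brute) > 0)
  }
  # monotonicity: adding a region never unmarks a gene
  extra <- rbind(regions,
                 data.frame(chrom = genes[[1]]$chrom,
                            start = genes[[1]]$start + 10,
                            end = genes[[1]]$start + 60,
                            occupancy = 1, condition = "16C"))
  ann2 <- associate_regions(genes, extra)
  expect_true(all(ann2$marked >= ann$marked))
})

test_that("marked fractions are exact set arithmetic", {
  g <- lapply(1:4, function(i) two_exon_gene(paste0("g", i), "chr1",
                                             i * 10000L, i * 10000L + 2000L))
  regions <- data.frame(chrom = "chr1", start = c(10100L, 20100L),
                        end = c(10500L, 20500L), occupancy = 1,
                        condition = "16C")
  ann <- associate_regions(g, regions)
  expect_equal(fraction_marked(c("g1", "g2"), ann), 1.0)
  expect_equal(fraction_marked(c("g3", "g4"), ann), 0.0)
  expect_equal(fraction_marked(paste0("g", 1:4), ann), 0.5)
  expect_error(fraction_marked(character(0), ann), "empty")
  expect_error(fraction_marked("nope", ann), "not annotated")
})

flat_track <- function(chrom, len, value, bin = 10L) {
  starts <- seq(0L, len - bin, by = bin)
  data.frame(chrom = chrom, start = starts, end = starts + bin,
             value = value, stringsAsFactors = FALSE)
}

test_that("metagene profiles are strand-oriented and linear", {
  gp <- two_exon_gene("gp", "chr1", 5000L, 8000L, "+")
  gm <- two_exon_gene("gm", "chr1", 5000L, 8000L, "-")
  const <- flat_track("chr1", 12000L, 3)
  prof <- metagene_profile(const, list(gp, gm), anchor = "TSS")$profiles
  expect_true(all(abs(prof$mean_signal - 3) < 1e-12))
  expect_equal(prof$n_genes, rep(2L, nrow(prof)))

  # mirror-symmetric bump around the window: the minus-strand gene sees the
  # same profile as the plus-strand gene
  bump <- flat_track("chr1", 12000L, 0)
  centre_p <- 5000 + 700   # 700 bp downstream of the + TSS
  bump$value <- exp(-((bump$start + 5 - centre_p)^2) / (2 * 150^2))
  prof_p <- metagene_profile(bump, list(gp), anchor = "TSS")$profiles
  bump_m <- flat_track("chr1", 12000L, 0)
  centre_m <- 7999 - 700
  bump_m$value <- exp(-((bump_m$start + 5 - centre_m)^2) / (2 * 150^2))
  prof_m <- metagene_profile(bump_m, list(gm), anchor = "TSS")$profiles
  # 10-bp track bins cannot mirror exactly around the anchor, hence the
  # small discretisation tolerance (bump amplitude is 1)
  expect_lt(max(abs(prof_m$mean_signal - prof_p$mean_signal)), 0.01)
  expect_lte(abs(prof_p$offset[which.max(prof_p$mean_signal)] - 700), 50)

  # linearity: the profile of a sum of tracks is the sum of profiles
  sum_track <- const
  sum_track$value <- const$value + bump$value
  prof_sum <- metagene_profile(sum_track, list(gp, gm))$profiles
  prof_a <- metagene_profile(const, list(gp, gm))$profiles
  prof_b <- metagene_profile(bump, list(gp, gm))$profiles
  expect_equal(prof_sum$mean_signal, prof_a$mean_signal + prof_b$mean_signal,
               tolerance = 1e-9)

  # genes whose window leaves the track are skipped and counted
  edge <- two_exon_gene("edge", "chr1", 500L, 3000L)
  res <- metagene_profile(const, list(gp, edge))
  expect_equal(res$n_skipped, 1L)
})

test_that("event-to-region distance is a gap with overlap giving zero", {
  g <- canonical_event_gene("IR")
  ev <- enumerate_events(g)   # alt region (100, 200)
  regions <- data.frame(chrom = "chr1", start = c(150L, 500L),
                        end = c(400L, 900L), occupancy = 1,
                        condition = "16C")
  make_ann <- function(idx) {
    ann <- data.frame(gene_id = "gene_IR", marked = length(idx) > 0,
                      n_regions = length(idx), stringsAsFactors = FALSE)
    ann$regions <- list(as.integer(idx))
    ann
  }
  # overlapping region wins with distance 0; nearest gap otherwise
  expect_equal(event_region_distance(ev, make_ann(1:2), regions), 0)
  expect_equal(event_region_distance(ev, make_ann(2), regions), 300)
  expect_true(is.na(event_region_distance(ev, make_ann(integer(0)),
                                          regions)))
  ann_bad <- make_ann(1); ann_bad$gene_id <- "other"
  expect_error(event_region_distance(ev, ann_bad, regions),
               "does not match")
})

test_that("distance distributions compare one-sidedly as expected", {
  res <- compare_distance_distributions(c(0, 0, 10), c(500, 600, 700))
  expect_lt(res$p_value, 0.05)
  same <- compare_distance_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4),
                                         exact = FALSE)
  expect_gt(same$p_value, 0.3)
  expect_lt(same$p_value, 0.7)
  # one-sided p values of the two orderings are complementary (the
  # continuity correction leaves a small gap that shrinks with n)
  set.seed(44)
  a <- runif(25, 0, 100); b <- runif(25, 20, 120)
  p1 <- compare_distance_distributions(a, b, exact = FALSE)$p_value
  p2 <- compare_distance_distributions(b, a, exact = FALSE)$p_value
  expect_lt(abs(p1 - (1 - p2)), 0.05)
  expect_equal(compare_distance_distributions(c(0, NA), c(1, NA))$n_dropped,
               2)
  expect_error(compare_distance_distributions(NA_real_, c(1, 2)), "empty")
})

test_that("region-width comparison recovers medians and their ratio", {
  set.seed(42)
  w <- sample(200:400, 60, TRUE)
  s <- sample(0:100000, 60)
  a <- data.frame(chrom = "chr1", start = s, end = s + w, occupancy = 1,
                  condition = "16C")
  same <- compare_region_widths(a, a)
  expect_equal(same$median_ratio, 1)
  expect_gt(same$p_value, 0.9)
  b <- a; b$end <- b$start + 2L * w
  doubled <- compare_region_widths(a, b)
  expect_equal(doubled$median_ratio, 2)
  expect_lt(doubled$p_value, 1e-6)
})

test_that("binned track correlation is scale-invariant and trims outliers", {
  set.seed(43)
  t1 <- flat_track("chr1", 1000000L, 0, bin = 100L)
  t1$value <- rgamma(nrow(t1), 2, 1)
  t2 <- t1; t2$value <- 2 * t1$value
  expect_equal(binned_track_correlation(t1, t2), 1, tolerance = 1e-12)

  noise <- t1; noise$value <- rgamma(nrow(noise), 2, 1)
  expect_lt(abs(binned_track_correlation(t1, noise)), 0.1)

  r_base <- binned_track_correlation(t1, noise)
  spike1 <- t1; spike2 <- noise
  spike1$value[5000] <- 1e6; spike2$value[5000] <- 1e6
  r_untrimmed <- binned_track_correlation(spike1, spike2, trim_quantile = 1)
  r_trimmed <- binned_track_correlation(spike1, spike2)
  expect_gt(r_untrimmed, 0.9)
  expect_lt(abs(r_trimmed - r_base), 0.02)

  tiny <- flat_track("chr1", 2000L, 1)
  expect_error(binned_track_correlation(tiny, tiny), "3 windows")
})
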