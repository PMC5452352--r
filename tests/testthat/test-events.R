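canonical_expectations <- list(
  IR = c(100, 200), ES = c(200, 300), A5 = c(100, 150),
  A3 = c(150, 200), MXE = c(200, 500))

test_that("the five canonical event fixtures are classified exactly", {
  for (type in names(canonical_expectations)) {
    g <- canonical_event_gene(type)
    ev <- enumerate_events(g)
    expect_equal(nrow(ev), 1L, info = type)
    expect_equal(ev$type, type)
    expect_equal(c(ev$alt_start, ev$alt_end),
                 canonical_expectations[[type]], info = type)
    expect_false(identical(ev$inclusion_form, ev$exclusion_form))
  }
})

test_that("IR exclusion form carries a junction spanning the alt region", {
  ev <- enumerate_events(canonical_event_gene("IR"))
  excl <- thermosplice:::decode_form(ev$exclusion_form)
  j <- thermosplice:::chain_introns(excl)
  expect_equal(unname(j[1, ]), c(ev$alt_start, ev$alt_end))
})

test_that("classify_pair is symmetric in transcript order", {
  set.seed(11)
  for (i in 1:25) {
    g <- random_test_gene()
    if (length(g$transcripts) < 2) next
    e12 <- classify_pair(g$transcripts[[1]], g$transcripts[[2]], g$strand)
    e21 <- classify_pair(g$transcripts[[2]], g$transcripts[[1]], g$strand)
    expect_setequal(e12$event_key, e21$event_key)
  }
})

test_that("strand geometry: flipping swaps A5/A3, reflection preserves it", {
  reflect <- function(t, M) {
    transcript_model(t$transcript_id,
                     cbind(M - t$exons[, 2], M - t$exons[, 1]))
  }
  swap <- c(IR = "IR", ES = "ES", MXE = "MXE", A5 = "A3", A3 = "A5")
  set.seed(12)
  for (i in 1:25) {
    g <- random_test_gene()
    if (length(g$transcripts) < 2) next
    M <- g$end + 10L
    flipped <- if (g$strand == "+") "-" else "+"
    fwd <- classify_pair(g$transcripts[[1]], g$transcripts[[2]], g$strand)

    # flipping the strand at fixed coordinates swaps donor and acceptor
    # sides, so A5 <-> A3 while IR/ES/MXE are unchanged
    flip <- classify_pair(g$transcripts[[1]], g$transcripts[[2]], flipped)
    expect_setequal(paste(swap[fwd$type], fwd$alt_start, fwd$alt_end),
                    paste(flip$type, flip$alt_start, flip$alt_end))

    # reflecting coordinates AND flipping strand preserves the transcripts'
    # 5'->3' geometry, so every event keeps its type
    rev <- classify_pair(reflect(g$transcripts[[1]], M),
                         reflect(g$transcripts[[2]], M), flipped)
    expect_setequal(paste(fwd$type, M - fwd$alt_end, M - fwd$alt_start),
                    paste(rev$type, rev$alt_start, rev$alt_end))
  }
})

test_that("enumeration de-duplicates shared events and is idempotent", {
  # three transcripts where two pairs reveal the same skipped exon
  t1 <- transcript_model("t1", rbind(c(0, 100), c(200, 300), c(400, 500)))
  t2 <- transcript_model("t2", rbind(c(0, 100), c(400, 500)))
  t3 <- transcript_model("t3", rbind(c(0, 100), c(400, 520)))
  g <- gene_model("g1", "chr1", "+", list(t1, t2, t3))
  ev <- enumerate_events(g)
  expect_equal(sum(ev$type == "ES"), 1L)

  # duplicating every transcript changes nothing
  dup <- gene_model("g1", "chr1", "+", c(g$transcripts, lapply(
    g$transcripts, function(t) transcript_model(paste0(t$transcript_id, "b"),
                                                t$exons))))
  expect_setequal(enumerate_events(dup)$event_key, ev$event_key)
})

test_that("event ids are distinct per locus and stable across runs", {
  t1 <- transcript_model("t1", rbind(c(0, 100), c(200, 300), c(400, 500),
                                     c(700, 800)))
  t2 <- transcript_model("t2", rbind(c(0, 300), c(400, 500), c(700, 800)))
  t3 <- transcript_model("t3", rbind(c(0, 100), c(200, 300), c(700, 800)))
  g <- gene_model("g1", "chr1", "+", list(t1, t2, t3))
  ev1 <- enumerate_events(g)
  ev2 <- enumerate_events(g)
  expect_setequal(ev1$type, c("IR", "ES"))
  expect_equal(anyDuplicated(ev1$event_id), 0L)
  expect_identical(ev1$event_id, ev2$event_id)
  expect_match(ev1$event_id, "^[0-9a-f]{12}$")
})

test_that("degenerate inputs are handled per contract", {
  s1 <- transcript_model("s1", rbind(c(0, 100)))
  s2 <- transcript_model("s2", rbind(c(50, 200)))
  expect_equal(nrow(classify_pair(s1, s2, "+")), 0L)
  expect_equal(nrow(enumerate_events(
    gene_model("g", "chr1", "+", list(s1)))), 0L)

  # alternative splice-site candidates need a strand
  g <- suppressWarnings(gene_model("g", "chr1", ".", list(
    transcript_model("t1", rbind(c(0, 150), c(200, 300))),
    transcript_model("t2", rbind(c(0, 100), c(200, 300))))))
  expect_error(enumerate_events(g), "strand")
})

test_that("alternative first/last exons and complex regions yield no event", {
  # alternative first exon: different TSS, shared downstream structure
  t1 <- transcript_model("t1", rbind(c(0, 100), c(300, 400)))
  t2 <- transcript_model("t2", rbind(c(150, 250), c(300, 400)))
  expect_equal(nrow(classify_pair(t1, t2, "+")), 0L)
  # complex region: two exons skipped at once is not a simple ES
  t3 <- transcript_model("t3", rbind(c(0, 100), c(200, 250), c(300, 350),
                                     c(500, 600)))
  t4 <- transcript_model("t4", rbind(c(0, 100), c(500, 600)))
  ev <- classify_pair(t3, t4, "+")
  expect_false("ES" %in% ev$type)
})
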