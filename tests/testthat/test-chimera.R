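test_that("duplicate reads collapse to the first record with preserved
           multiplicity", {
    r <- data.frame(read_id = c("a", "b", "c"),
                    sequence = c("AAA", "AAA", "AAC"))
    d <- dedupReads(r)
    expect_equal(d$unique$read_id, c("a", "c"))
    expect_equal(unname(d$multiplicity), c(2L, 1L))
    expect_equal(names(d$multiplicity), c("a", "c"))

    e <- dedupReads(r[0, ])
    expect_equal(nrow(e$unique), 0)
    expect_length(e$multiplicity, 0)

    set.seed(3)
    big <- data.frame(read_id = sprintf("r%d", 1:1000),
                      sequence = vapply(1:1000, function(i)
                          rand_seq(40, seed = i), character(1)))
    stopifnot(!anyDuplicated(big$sequence))
    expect_equal(nrow(dedupReads(big)$unique), 1000)
})

test_that("outfmt-6 parsing converts coordinates and flags malformed rows", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("r1\tmirX\t100.0\t22\t0\t0\t1\t22\t1\t22\t1e-5\t44",
                 "r1\ttx1\t95.0\t30\t1\t0\t25\t54\t200\t171\t1e-4\t50"),
               f)
    h <- readAlignmentHits(f)
    expect_equal(h$q_start, c(0L, 24L))
    expect_equal(h$q_end, c(22L, 54L))
    expect_equal(h$strand, c("+", "-"))
    expect_equal(h$s_start[2], 170L)
    expect_equal(h$s_end[2], 200L)

    writeLines(c("r1\tmirX\t100.0\t22\t0\t0\t1\t22\t1\t22\t1e-5\t44",
                 "r2\tmirX\tok\t22\t0\t0\t1\t22\t1\t22\t1e-5\t44"), f)
    expect_error(readAlignmentHits(f), "line 2")
})

test_that("hit filtering enforces e-value, strand and loop rules", {
    base <- data.frame(read_id = "r", subject_id = "s", q_start = 0L,
                       q_end = 20L, s_start = 0L, s_end = 20L,
                       strand = "+", mismatch = 0L, gapopen = 0L,
                       evalue = 0.1, bitscore = 40)
    expect_equal(nrow(filterHits(base)), 1)              # e-value == 0.1 kept
    worse <- base; worse$evalue <- 0.11
    expect_equal(nrow(filterHits(worse)), 0)
    anti <- base; anti$strand <- "-"
    expect_equal(nrow(filterHits(anti)), 0)
    looped <- base; looped$gapopen <- 1L
    expect_equal(nrow(filterHits(looped)), 0)
})

make_hit <- function(read_id, subject_id, q0, q1, s0 = 0L, s1 = NULL,
                     evalue = 1e-6, bitscore = 40) {
    if (is.null(s1)) s1 <- s0 + (q1 - q0)
    data.frame(read_id = read_id, subject_id = subject_id,
               q_start = as.integer(q0), q_end = as.integer(q1),
               s_start = as.integer(s0), s_end = as.integer(s1),
               strand = "+", mismatch = 0L, gapopen = 0L,
               evalue = evalue, bitscore = bitscore,
               stringsAsFactors = FALSE)
}

test_that("chimera calling respects gap, overlap and orientation rules", {
    read <- list(read_id = "r1", sequence = rand_seq(60, 1))
    mh <- make_hit("r1", "mirX", 0, 22)
    th <- make_hit("r1", "tx1", 24, 60, s0 = 100)
    cc <- callChimeras(read, mh, th)
    expect_equal(nrow(cc), 1)
    expect_equal(cc$gap_nt, 2)
    expect_equal(cc$mirna_portion, substr(read$sequence, 1, 22))
    expect_equal(cc$site_start, 100)

    th5 <- make_hit("r1", "tx1", 27, 60)       # gap 5
    expect_equal(nrow(callChimeras(read, mh, th5)), 0)
    th_ov <- make_hit("r1", "tx1", 20, 60)     # overlap 2
    expect_equal(nrow(callChimeras(read, mh, th_ov)), 0)
    ## mRNA-first order rejected by default, allowed when relaxed
    mh2 <- make_hit("r1", "mirX", 40, 60)
    th2 <- make_hit("r1", "tx1", 0, 38)
    expect_equal(nrow(callChimeras(read, mh2, th2)), 0)
    relaxed <- PipelineConfig(require_mirna_first = FALSE)
    expect_equal(nrow(callChimeras(read, mh2, th2, relaxed)), 1)
})

test_that("best-pair selection is a deterministic total order", {
    read <- list(read_id = "r1", sequence = rand_seq(60, 2))
    mk <- function(mid, tid, e, b) {
        cc <- callChimeras(read, make_hit("r1", mid, 0, 22, evalue = e,
                                          bitscore = b / 2),
                           make_hit("r1", tid, 24, 60, evalue = e,
                                    bitscore = b / 2))
        cc
    }
    calls <- rbind(mk("mirA", "tx1", 0.01, 40), mk("mirB", "tx2", 0.02, 90))
    expect_equal(selectBestPairs(calls)$mirna_id, "mirA")
    calls <- rbind(mk("mirA", "tx1", 0.01, 40), mk("mirB", "tx2", 0.01, 90))
    expect_equal(selectBestPairs(calls)$mirna_id, "mirB")
    calls <- rbind(mk("mirB", "tx1", 0.01, 40), mk("mirA", "tx1", 0.01, 40))
    expect_equal(selectBestPairs(calls)$mirna_id, "mirA")

    ## permutation invariance
    set.seed(5)
    pool <- do.call(rbind, lapply(1:6, function(i)
        mk(paste0("mir", i), paste0("tx", i),
           sample(c(0.01, 0.02), 1), sample(c(40, 60, 90), 1))))
    ref_order <- selectBestPairs(pool, PipelineConfig(top_k_pairs = 6))
    for (i in 1:5) {
        perm <- pool[sample(nrow(pool)), ]
        expect_equal(selectBestPairs(perm,
                                     PipelineConfig(top_k_pairs = 6)),
                     ref_order)
    }
})

test_that("read support counts multiplicity-weighted distinct reads", {
    read_call <- function(rid, portion) {
        data.frame(read_id = rid, mirna_id = "m", transcript_id = "t",
                   mirna_q_start = 0L, mirna_q_end = 3L,
                   mrna_q_start = 5L, mrna_q_end = 10L,
                   site_start = 0L, site_end = 5L, gap_nt = 2L,
                   evalue = 1e-6, bitscore = 40, mirna_portion = portion,
                   mrna_portion = "CCCCC", stringsAsFactors = FALSE)
    }
    calls <- rbind(read_call("r1", "AAAA"), read_call("r2", "AAAA"),
                   read_call("r3", "CCCC"))
    mult <- c(r1 = 8L, r2 = 2L, r3 = 3L)
    out <- filterSupport(calls, PipelineConfig(min_support_reads = 10),
                         mult)
    expect_equal(unique(out$mirna_portion), "AAAA")
    expect_equal(unique(out$read_support), 10L)
    out9 <- filterSupport(calls, PipelineConfig(min_support_reads = 11),
                          mult)
    expect_equal(nrow(out9), 0)
    ## min_support_reads = 1 is the identity filter
    all_kept <- filterSupport(calls, PipelineConfig(min_support_reads = 1))
    expect_equal(nrow(all_kept), 3)
    ## brute-force recount on a mixed pool
    mixed <- do.call(rbind, c(
        lapply(sprintf("a%d", 1:12), read_call, portion = "AAAA"),
        lapply(sprintf("b%d", 1:3), read_call, portion = "GGGG")))
    kept <- filterSupport(mixed, PipelineConfig(min_support_reads = 10))
    expect_setequal(unique(kept$mirna_portion), "AAAA")
    expect_equal(nrow(kept), 12)
})

test_that("variant calling applies the strict quality-over-30 rule", {
    ref <- rand_seq(22, seed = 6)
    q <- rep(40L, 22)
    expect_equal(callVariant(ref, q, ref)$status, "exact_mirna")

    iso <- ref
    old <- substr(iso, 11, 11)
    substr(iso, 11, 11) <- setdiff(c("A", "C", "G", "T"), old)[1]
    q31 <- q; q31[11] <- 31L
    v <- callVariant(iso, q31, ref)
    expect_equal(v$status, "isomir")
    expect_equal(v$variant_positions, 10L)
    q30 <- q; q30[11] <- 30L
    expect_equal(callVariant(iso, q30, ref)$status, "rejected")
    expect_error(callVariant(iso, q[1:10], ref), "data error")
    ## added 3' nucleotides count as variation positions
    iso3 <- paste0(ref, "A")
    q23 <- c(q, 25L)
    expect_equal(callVariant(iso3, q23, ref)$status, "rejected")
    q23[23] <- 35L
    expect_equal(callVariant(iso3, q23, ref)$status, "isomir")
})

test_that("the full pipeline recovers planted pairs when support allows and
           none otherwise", {
    ## one transcript per miRNA keeps every small RNA sequence unique, so
    ## read support cannot pool across planted pairs
    cfg12 <- SimulationConfig(n_mirnas = 6, n_transcripts = 6,
                              reads_per_pair = 12, base_error_rate = 0,
                              seed = 31)
    sim <- simulateInteractionDataset(cfg12)
    res <- runChimeraPipeline(sim$reads, sim$hits_mirna,
                              sim$hits_transcript, sim$references$mirnas,
                              PipelineConfig())
    ints <- res$interactions
    planted <- unique(sim$manifest[, c("mirna_id", "transcript_id",
                                       "site_start", "site_end")])
    recovered <- vapply(seq_len(nrow(planted)), function(i) {
        p <- planted[i, ]
        any(ints$mirna_id == p$mirna_id &
            ints$transcript_id == p$transcript_id &
            ints$site_start < p$site_end & p$site_start < ints$site_end)
    }, logical(1))
    expect_true(all(recovered))
    ## no surviving call violates the filters
    expect_true(all(ints$gap_nt >= 0 & ints$gap_nt <= 4))
    expect_true(all(ints$evalue <= 0.1))
    expect_true(all(ints$read_support >= 10))

    cfg9 <- SimulationConfig(n_mirnas = 6, n_transcripts = 6,
                             reads_per_pair = 9, base_error_rate = 0,
                             seed = 31)
    sim9 <- simulateInteractionDataset(cfg9)
    res9 <- runChimeraPipeline(sim9$reads, sim9$hits_mirna,
                               sim9$hits_transcript,
                               sim9$references$mirnas, PipelineConfig())
    expect_equal(nrow(res9$interactions), 0)
})
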