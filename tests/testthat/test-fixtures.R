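test_that("reference generation is deterministic under a fixed seed and
           seed-sensitive", {
    cfg <- SimulationConfig(n_mirnas = 2, mirna_len_range = c(22, 22),
                            n_transcripts = 2, seed = 1)
    a <- simulateReferences(cfg)
    b <- simulateReferences(cfg)
    expect_identical(a, b)
    expect_length(a$mirnas, 2)
    expect_false(a$mirnas[[1]] == a$mirnas[[2]])
    expect_true(all(nchar(a$mirnas) == 22))
    cfg2 <- SimulationConfig(n_mirnas = 2, mirna_len_range = c(22, 22),
                             n_transcripts = 2, seed = 2)
    expect_false(identical(simulateReferences(cfg2)$mirnas, a$mirnas))
    ## 3'UTR occupies the final fraction of each transcript
    expect_equal(a$utr$utr_end, unname(nchar(a$transcripts)))
    expect_true(all(a$utr$utr_start < a$utr$utr_end))
})

test_that("degenerate simulation parameters are rejected", {
    expect_error(SimulationConfig(n_mirnas = 0), "n_mirnas")
    expect_error(SimulationConfig(mirna_len_range = c(24, 20)),
                 "min <= max")
    expect_error(SimulationConfig(base_error_rate = 1), "error_rate")
})

test_that("isomiR constructions match their definitions", {
    ref <- "ACGTACGTACGTACGTACGTAC"
    add3 <- simulateIsomir(ref, "3p_add", size = 2, seed = 5)
    expect_identical(substr(add3$seq, 1, nchar(ref)), ref)
    expect_equal(nchar(add3$seq), nchar(ref) + 2)
    expect_identical(add3$types, "3p_add")

    del5 <- simulateIsomir(ref, "5p_del", size = 2, seed = 5)
    expect_identical(del5$seq, substr(ref, 3, nchar(ref)))

    snp <- simulateIsomir(ref, "SNP", seed = 5)
    expect_equal(nchar(snp$seq), nchar(ref))
    diffs <- which(isomiRTarget:::seq_chars(snp$seq) !=
                   isomiRTarget:::seq_chars(ref))
    expect_length(diffs, 1)
    expect_true(diffs > 1 && diffs < nchar(ref))

    expect_error(simulateIsomir(ref, "5p_del", size = 22), "deletion size")
    expect_error(simulateIsomir("ACGTACGTACGT", "SNP"), "17 nt")
})

test_that("planted sites contain the seed match exactly once and respect
           bounds", {
    tx <- rand_seq(200, seed = 3)
    m <- rand_seq(22, seed = 4)
    p <- plantTargetSite(tx, m, "seed_complement_only", 100)
    site <- substr(p$transcript, p$site_start + 1, p$site_end)
    seed_match <- isomiRTarget:::revcomp(substr(m, 2, 7))
    occ <- gregexpr(seed_match, site, fixed = TRUE)[[1]]
    expect_equal(sum(occ > 0), 1)
    expect_equal(occ[1] - 1, p$seed_offset)
    expect_equal(nchar(p$transcript), nchar(tx))

    expect_error(plantTargetSite(tx, m, "seed_complement_only", 190),
                 "placement error")
    expect_error(plantTargetSite(tx, m, "seed_complement_only", 100,
                                 existing = list(c(100, 130))),
                 "placement error")
    p2 <- plantTargetSite(tx, m, "seed_plus_3prime", 50)
    site2 <- substr(p2$transcript, 51, 80)
    expect_true(grepl(isomiRTarget:::revcomp(substr(m, 10, 16)), site2,
                      fixed = TRUE))
})

test_that("error-free chimeric reads are exact duplicates that embed the
           small RNA", {
    cfg <- SimulationConfig(n_mirnas = 2, n_transcripts = 2,
                            reads_per_pair = 12, base_error_rate = 0,
                            seed = 7)
    sim <- simulateInteractionDataset(cfg, align = FALSE)
    for (pid in unique(sim$pairs$pair_id)) {
        rr <- sim$reads[startsWith(sim$reads$read_id, paste0(pid, "_")), ]
        expect_equal(nrow(rr), 12)
        expect_length(unique(rr$sequence), 1)
    }
    expect_true(all(mapply(startsWith, sim$reads$sequence,
                           sim$manifest$isomir_sequence[
                               match(sim$reads$read_id,
                                     sim$manifest$read_id)])))
    ## qualities uniformly high without errors
    expect_true(all(unlist(lapply(sim$reads$quality, function(q)
        isomiRTarget:::char_to_phred(q))) == 40))
})

test_that("spacer gaps only take values 0 to 4", {
    pairs <- data.frame(pair_id = sprintf("p%04d", 1:2000),
                        mirna_id = "m", small_rna_seq = rand_seq(20),
                        isomir_types = "", transcript_id = "t",
                        site_start = 0, site_end = 30,
                        site_seq = rand_seq(30, 2))
    cfg <- SimulationConfig(reads_per_pair = 1, base_error_rate = 0,
                            seed = 9)
    sim <- simulateChimericReads(pairs, cfg)
    expect_true(all(sim$manifest$gap_nt %in% 0:4))
    expect_setequal(unique(sim$manifest$gap_nt), 0:4)
    expect_equal(nchar(sim$reads$sequence), 50 + sim$manifest$gap_nt)
})

test_that("the surrogate aligner reports exact matches, misses unrelated
           sequences, and orders e-values by quality", {
    ref <- c(mirX = rand_seq(22, seed = 21))
    reads <- data.frame(read_id = "r1", sequence = ref[[1]])
    hits <- simulateAlignmentHits(reads, ref)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$mismatch, 0)
    expect_equal(hits$qend - hits$qstart + 1, 22)
    expect_equal(hits$gapopen, 0)

    unrelated <- data.frame(read_id = "r2",
                            sequence = strrep("A", 40))
    expect_equal(nrow(simulateAlignmentHits(unrelated,
                                            c(x = strrep("GC", 20)))), 0)

    mm2 <- ref[[1]]
    substr(mm2, 5, 5) <- "A"; substr(mm2, 12, 12) <- "A"
    if (identical(mm2, ref[[1]])) {
        substr(mm2, 5, 5) <- "C"; substr(mm2, 12, 12) <- "C"
    }
    h2 <- simulateAlignmentHits(data.frame(read_id = "r3", sequence = mm2),
                                ref)
    expect_equal(nrow(h2), 1)
    expect_gt(h2$evalue, hits$evalue)
    expect_lt(h2$bitscore, hits$bitscore)
})

test_that("byte-identical outputs are written for identical configs", {
    cfg <- SimulationConfig(n_mirnas = 2, n_transcripts = 3,
                            reads_per_pair = 3, seed = 5)
    d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
    simulateInteractionDataset(cfg, outdir = d1)
    simulateInteractionDataset(cfg, outdir = d2)
    for (f in list.files(d1)) {
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
    }
})

test_that("directly simulated training pairs are balanced, long enough and
           UTR-confined", {
    cfg <- SimulationConfig(n_mirnas = 4, n_transcripts = 30, seed = 13)
    pairs <- simulateTrainingPairs(cfg)
    expect_equal(sum(pairs$label == 1), 30)
    expect_gte(sum(pairs$label == 0), 25)   # few rejections tolerated
    expect_true(all(nchar(pairs$site_seq) >= 30))
    refs <- simulateReferences(cfg)
    utr <- refs$utr
    neg <- pairs[pairs$label == 0, ]
    u <- utr[match(neg$transcript_id, utr$transcript_id), ]
    expect_true(all(neg$site_start >= u$utr_start &
                    neg$site_end <= u$utr_end))
})
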