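## Brute-force anchoring oracle: exhaustive offset search with the same
## tie-break, written independently of the implementation.
oracle_anchor <- function(iso, ref, max_shift = 6) {
    iso <- strsplit(iso, "")[[1]]; ref <- strsplit(ref, "")[[1]]
    best <- NULL
    for (o in -max_shift:max_shift) {
        r <- intersect(seq_along(ref), o + seq_along(iso))
        if (!length(r)) next
        nm <- sum(ref[r] == iso[r - o])
        cand <- list(o = o, matches = nm)
        if (is.null(best) || nm > best$matches ||
            (nm == best$matches &&
             (abs(o) < abs(best$o) ||
              (abs(o) == abs(best$o) && o < best$o))))
            best <- cand
    }
    best
}

test_that("anchored comparison matches an exhaustive offset search", {
    expect_identical(anchorAlign(rand_seq(22, 1), rand_seq(22, 1))[
        c("offset_5p", "offset_3p")], list(offset_5p = 0L, offset_3p = 0L))
    ref <- rand_seq(22, seed = 2)
    a <- anchorAlign(paste0(ref, "AA"), ref)
    expect_equal(a$offset_3p, 2)
    expect_equal(a$offset_5p, 0)

    set.seed(42)
    for (i in 1:100) {
        ref <- rand_seq(22, seed = 1000 + i)
        type <- sample(ISOMIR_TYPES, 1)
        iso <- simulateIsomir(ref, type, seed = 2000 + i)$seq
        got <- anchorAlign(iso, ref)
        exp <- oracle_anchor(iso, ref)
        expect_equal(got$offset_5p, exp$o, label = paste(type, i))
    }
    ## SNP at a fixed internal position
    ref <- rand_seq(22, seed = 77)
    iso <- ref
    old <- substr(iso, 11, 11)
    substr(iso, 11, 11) <- setdiff(c("A", "C", "G", "T"), old)[1]
    a <- anchorAlign(iso, ref)
    expect_equal(a$offset_5p, 0)
    expect_equal(a$internal_mismatch_positions, 10)   # 0-based
    expect_error(anchorAlign(strrep("A", 20), strrep("C", 20)),
                 "unclassifiable")
})

test_that("the eight isomiR types classify by definition", {
    ref <- "ACGTACGTACGTACGTACGTAC"
    expect_identical(classifyIsomir(substr(ref, 3, 22), ref), "5p_del")
    mnp <- ref
    substr(mnp, 10, 10) <- "A"; substr(mnp, 15, 15) <- "T"
    expect_identical(classifyIsomir(mnp, ref), "MNP")
    rep3 <- paste0(substr(ref, 1, 21), "G")   # last base C -> G
    expect_identical(classifyIsomir(rep3, ref), "3p_rep")
    expect_identical(classifyIsomir(ref, ref), character(0))
})

test_that("classification is a left inverse of the generator across all
           eight types", {
    set.seed(1)
    n_per_type <- 30
    for (type in ISOMIR_TYPES) {
        for (i in seq_len(n_per_type)) {
            ref <- rand_seq(sample(20:24, 1), seed = i * 31 +
                                match(type, ISOMIR_TYPES))
            iso <- simulateIsomir(ref, type, seed = i)
            expect_identical(classifyIsomir(iso$seq, ref), type,
                             label = paste(type, i))
        }
    }
})

## exhaustive enumeration over all 2^n outcome vectors
oracle_binom_tail <- function(obs, n, p) {
    total <- 0
    for (bits in 0:(2^n - 1)) {
        v <- as.integer(intToBits(bits))[1:n]
        k <- sum(v)
        if (k >= obs) total <- total + p^k * (1 - p)^(n - k)
    }
    total
}

test_that("enrichment p-values equal exhaustive enumeration and handle
           edge cases", {
    counts <- data.frame(mirna_id = "m1", type = "3p_add",
                         observed = 10, total = 10)
    r <- typeEnrichment(counts, background = c("3p_add" = 0.5))
    expect_equal(r$p_raw, 0.5^10, tolerance = 1e-12)

    for (case in list(c(3, 8, 0.2), c(5, 12, 0.4), c(0, 6, 0.3),
                      c(7, 7, 0.9))) {
        counts <- data.frame(mirna_id = "m", type = "SNP",
                             observed = case[1], total = case[2])
        r <- typeEnrichment(counts, background = c(SNP = case[3]))
        expect_equal(r$p_raw,
                     oracle_binom_tail(case[1], case[2], case[3]),
                     tolerance = 1e-10, label = paste(case, collapse = "/"))
    }
    ## observed = 0: the one-sided upper tail holds all the mass
    r0 <- typeEnrichment(data.frame(mirna_id = "m", type = "SNP",
                                    observed = 0, total = 5),
                         background = c(SNP = 0.3))
    expect_equal(r0$p_raw, 1)
    r1 <- typeEnrichment(data.frame(mirna_id = "m", type = "SNP",
                                    observed = 3, total = 5),
                         background = c(SNP = 1))
    expect_equal(r1$p_raw, 1)
    expect_error(typeEnrichment(data.frame(mirna_id = "m", type = "SNP",
                                           observed = 6, total = 5),
                                background = c(SNP = 0.5)), "data error")
})

test_that("Bonferroni correction spans all tests and caps at 1", {
    counts <- data.frame(mirna_id = rep(c("m1", "m2"), each = 2),
                         type = rep(c("3p_add", "SNP"), 2),
                         observed = c(9, 1, 2, 8), total = 10)
    r <- typeEnrichment(counts, background = c("3p_add" = 0.25,
                                               SNP = 0.25))
    expect_equal(r$p_corrected, pmin(r$p_raw * 4, 1))
    expect_true(all(r$p_raw <= r$p_corrected))
})

test_that("pooled background frequencies are used by default", {
    counts <- data.frame(mirna_id = c("m1", "m1", "m2"),
                         type = c("3p_add", "SNP", "3p_add"),
                         observed = c(6, 2, 4), total = c(8, 8, 4))
    r <- typeEnrichment(counts)
    expect_equal(unique(r$expected_prob[r$type == "3p_add"]), 10 / 12)
    expect_equal(unique(r$expected_prob[r$type == "SNP"]), 2 / 12)
})

## independent log-space summation of the binomial upper tail
oracle_support_tail <- function(n, p, thr) {
    if (thr > n) return(0)
    k <- thr:n
    logs <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
    m <- max(logs)
    exp(m) * sum(exp(logs - m))
}

test_that("the read-support probability model is exact and monotone", {
    p22 <- supportProbability(1000, 22, 0.001, 10)
    expect_equal(p22, 8.87e-8, tolerance = 0.01)
    p_read <- 0.001 * (1 - 0.001)^21
    expect_equal(p22, oracle_support_tail(1000, p_read, 10),
                 tolerance = 1e-12)

    expect_equal(supportProbability(100, 22, 0, 1), 0)
    expect_equal(supportProbability(20, 22, 0.001, 1),
                 1 - (1 - p_read)^20, tolerance = 1e-12)
    expect_equal(supportProbability(50, 22, 0.001, 60), 0)

    for (n in c(50, 500, 2000)) {
        thr <- c(1, 3, 10)
        vals <- vapply(thr, function(t)
            supportProbability(n, 22, 0.001, t), numeric(1))
        expect_true(all(diff(vals) <= 0))     # non-increasing in threshold
        for (t in thr)
            expect_equal(supportProbability(n, 22, 0.001, t),
                         oracle_support_tail(n, p_read, t),
                         tolerance = 1e-12)
    }
    ns <- c(100, 400, 1000, 2000)
    vals_n <- vapply(ns, function(n)
        supportProbability(n, 22, 0.001, 5), numeric(1))
    expect_true(all(diff(vals_n) >= 0))       # non-decreasing in n
})
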