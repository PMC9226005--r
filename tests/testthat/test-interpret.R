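## build a tiny trained-ish model whose kernels we can overwrite
make_probe_net <- function() {
    net <- buildModel(tiny_model_config(seed = 12))
    net@trained <- TRUE
    net
}

test_that("kernel fractions sit at the 0.25 baseline for flat kernels and
           flag one-hot-like kernels informative", {
    net <- make_probe_net()
    kl <- net@config@kernel_len
    ## kernel 1: constant; kernel 2: one dominant base per column
    net@weights$conv_m_W[1, ] <- 0.3
    onehot <- matrix(-1, 4, kl); onehot[1, ] <- 2
    net@weights$conv_m_W[2, ] <- as.vector(onehot)
    motifs <- extractKernelMotifs(net)
    m1 <- motifs[[1]]; m2 <- motifs[[2]]
    expect_true(all(abs(m1$column_fractions - 0.25) < 1e-12))
    expect_false(m1$informative)
    expect_true(m2$informative)
    expect_true(all(abs(colSums(m2$column_fractions) - 1) < 1e-9))
    expect_equal(length(motifs), 2 * net@config@n_kernels)
    expect_warning(extractKernelMotifs(buildModel(tiny_model_config())),
                   "untrained")
})

write_jaspar <- function(motifs, path) {
    lines <- character(0)
    for (id in names(motifs)) {
        lines <- c(lines, paste0(">", id, " ", id))
        m <- motifs[[id]]
        for (b in c("A", "C", "G", "T"))
            lines <- c(lines, paste0(b, "  [ ",
                                     paste(m[b, ], collapse = " "), " ]"))
    }
    writeLines(lines, path)
}

test_that("JASPAR parsing and motif matching behave as specified", {
    set.seed(20)
    mk <- function(w) {
        m <- matrix(rpois(4 * w, 10), 4, w,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
        m
    }
    db <- list(MA0001 = mk(8), MA0002 = mk(12), SHORTY = mk(3))
    f <- tempfile(fileext = ".pfm")
    write_jaspar(db, f)
    parsed <- expect_silent(readJasparMotifs(f))
    expect_equal(names(parsed), names(db))
    expect_equal(parsed$MA0002, db$MA0002, ignore_attr = FALSE)

    probe <- isomiRTarget:::.normalize_pfm(db$MA0001)
    expect_warning(res <- matchMotifs(probe, parsed), "SHORTY")
    expect_equal(res$db_motif_id[1], "MA0001")
    expect_equal(res$similarity[1], 1, tolerance = 1e-12)

    permuted <- db$MA0001[, c(3, 1, 4, 2, 6, 8, 5, 7)]
    res2 <- matchMotifs(probe, list(P = permuted))
    expect_lt(res2$similarity[1], 1)

    uniform <- matrix(1, 4, 8, dimnames = list(c("A", "C", "G", "T"),
                                               NULL))
    res3 <- matchMotifs(uniform, list(M = db$MA0001))
    expect_equal(res3$similarity, 0)
    ## scaling invariance: similarity unchanged when db motif is scaled
    res4 <- matchMotifs(probe, list(M = db$MA0002))
    res5 <- matchMotifs(probe, list(M = db$MA0002 * 7))
    expect_equal(res4$similarity, res5$similarity, tolerance = 1e-12)
    ## symmetry: which matrix is 'motif' and which is 'db' cannot matter
    res6 <- matchMotifs(isomiRTarget:::.normalize_pfm(db$MA0002),
                        list(M = db$MA0001))
    expect_equal(res4$similarity, res6$similarity, tolerance = 1e-12)
})

test_that("perturbation profiles have window-arithmetic lengths and exact
           zeros on padding", {
    net <- make_probe_net()
    pairs <- toy_pairs(4, seed = 21)
    ## shorten one small RNA so its 3' tail is N padding
    pairs$small_rna_seq[1] <- substr(pairs$small_rna_seq[1], 1, 6)
    scan <- perturbationScan(net, pairs)
    expect_equal(nrow(scan$mirna), 12 - 4 + 1)
    expect_equal(nrow(scan$site), 16 - 4 + 1)
    expect_equal(unique(scan$mirna$n), nrow(pairs))
    ## windows wholly inside the padded region change nothing
    expect_equal(scan$deltas_mirna[1, 7:9], rep(0, 3))
    expect_true(all(scan$mirna$var_delta >= 0))
    expect_error(perturbationScan(net, pairs, mask_len = 20), "mask_len")
})

test_that("profile aggregation matches a streaming oracle", {
    net <- make_probe_net()
    pairs <- toy_pairs(6, seed = 22)
    scan <- perturbationScan(net, pairs)
    ## Welford streaming mean/variance, one pass over pairs
    d <- scan$deltas_mirna
    for (j in seq_len(ncol(d))) {
        mean_s <- 0; m2 <- 0
        for (i in seq_len(nrow(d))) {
            delta <- d[i, j] - mean_s
            mean_s <- mean_s + delta / i
            m2 <- m2 + delta * (d[i, j] - mean_s)
        }
        expect_equal(scan$mirna$mean_delta[j], mean_s, tolerance = 1e-12)
        expect_equal(scan$mirna$var_delta[j], m2 / (nrow(d) - 1),
                     tolerance = 1e-12)
    }
})

test_that("sensitivity clustering follows 1 - correlation with average
           linkage", {
    base <- sin(seq(0, 3, length.out = 20))
    prof <- rbind(a = base, b = base * 2 + 0.1,   # r = 1 with a
                  c = -base)                      # r = -1
    cl <- clusterSensitivity(prof, h = 0.99)
    expect_equal(cl$assignments[["a"]], cl$assignments[["b"]])
    expect_false(cl$assignments[["a"]] == cl$assignments[["c"]])

    ## three profiles: verify the linkage against the pairwise oracle
    set.seed(23)
    p3 <- matrix(rnorm(60), 3, 20,
                 dimnames = list(c("x", "y", "z"), NULL))
    cm <- cor(t(p3))
    d <- 1 - cm
    first_pair <- sort(rownames(p3)[
        which(d == min(d[upper.tri(d)]), arr.ind = TRUE)[1, ]])
    k2 <- clusterSensitivity(p3, k = 2)$assignments
    expect_equal(k2[[first_pair[1]]], k2[[first_pair[2]]])

    flat <- rbind(f = rep(1, 20), g = base)
    expect_warning(clusterSensitivity(flat, k = 2), "constant")
    expect_error(clusterSensitivity(prof[1, , drop = FALSE], k = 1),
                 "at least 2")
})
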