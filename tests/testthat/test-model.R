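test_that("one-hot encoding follows the fixed A/T/C/G row order with N
           padding and 3' trimming", {
    expect_equal(unname(encodeSequence("A", 1)[, 1]), c(1, 0, 0, 0))
    expect_equal(unname(encodeSequence("T", 1)[, 1]), c(0, 1, 0, 0))
    expect_equal(unname(encodeSequence("C", 1)[, 1]), c(0, 0, 1, 0))
    expect_equal(unname(encodeSequence("G", 1)[, 1]), c(0, 0, 0, 1))
    expect_equal(unname(encodeSequence("N", 1)[, 1]), rep(0.25, 4))
    expect_equal(encodeSequence("U", 1), encodeSequence("T", 1))

    s32 <- rand_seq(32, seed = 1)
    m <- encodeSequence(s32, 30)
    expect_equal(dim(m), c(4, 30))
    expect_equal(decodeMatrix(m), substr(s32, 1, 30))   # 3' trim
    mp <- encodeSequence("ACGT", 6)
    expect_equal(decodeMatrix(mp), "ACGTNN")            # 3' N padding
    expect_true(all(abs(colSums(mp) - 1) < 1e-12))
    expect_error(encodeSequence("ACXT", 4), "position 3")
})

test_that("the default architecture reproduces the printed shape chain", {
    sh <- modelShapes(ModelConfig())
    expect_equal(sh$conv_mirna, c(10, 23))
    expect_equal(sh$conv_site, c(10, 53))
    expect_equal(sh$pool_mirna, c(10, 20))
    expect_equal(sh$pool_site, c(10, 50))
    expect_equal(sh$merged, c(10, 70))
    expect_equal(sh$blstm, c(20, 70))
    expect_equal(sh$flatten, 1400)
})

test_that("shape propagation matches the closed form across configs", {
    ## valid-padding arithmetic at the edge
    sh <- modelShapes(ModelConfig(mirna_len = 8, site_len = 11,
                                  kernel_len = 8, pool_size = 1))
    expect_equal(sh$conv_mirna[2], 1)
    for (Lm in c(16, 30)) for (Ls in c(24, 60)) for (ps in c(2, 4)) {
        cfg <- ModelConfig(mirna_len = Lm, site_len = Ls, pool_size = ps,
                           lstm_units = 7)
        sh <- modelShapes(cfg)
        expect_equal(sh$flatten,
                     2 * 7 * (Lm + Ls - 2 * 8 - 2 * ps + 4))
        ## cross-check with a real forward pass
        net <- buildModel(cfg)
        fw <- isomiRTarget:::nn_forward(net@weights, cfg,
            isomiRTarget:::encode_batch(rand_seq(Lm, 1), Lm),
            isomiRTarget:::encode_batch(rand_seq(Ls, 2), Ls))
        expect_length(fw$p, 1)
    }
})

test_that("analytic gradients agree with finite differences", {
    for (bn in c(FALSE, TRUE)) {
        cfg <- tiny_model_config(batchnorm_after_conv = bn, seed = 3)
        net <- buildModel(cfg)
        set.seed(9)
        n <- 4
        Xm <- isomiRTarget:::encode_batch(
            vapply(1:n, function(i) rand_seq(12, i), character(1)), 12)
        Xs <- isomiRTarget:::encode_batch(
            vapply(1:n, function(i) rand_seq(16, 10 + i), character(1)), 16)
        y <- c(1, 0, 1, 0)
        params <- net@weights
        fw <- isomiRTarget:::nn_forward(params, cfg, Xm, Xs,
                                        training = TRUE)
        g <- isomiRTarget:::nn_backward(params, cfg, fw, y)
        lossfun <- function(p) {
            f <- isomiRTarget:::nn_forward(p, cfg, Xm, Xs, training = TRUE)
            isomiRTarget:::nn_loss(p, cfg, f$z, y)
        }
        eps <- 1e-6
        set.seed(5)
        for (nm in names(g)) {
            w <- params[[nm]]
            for (i in sample(length(w), min(4, length(w)))) {
                p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
                p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
                num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
                ana <- g[[nm]][i]
                expect_lt(abs(num - ana) /
                          max(1e-6, abs(num) + abs(ana)), 1e-4,
                          label = paste(nm, i, "bn", bn))
            }
        }
    }
})

test_that("training produces a finite per-epoch history and reduces loss on
           a memorizable set", {
    cfg <- tiny_model_config(seed = 2, l1_penalty = 0.001,
                             learning_rate = 0.01)
    pairs <- toy_pairs(20, seed = 3)
    net <- buildModel(cfg)
    net1 <- trainModel(net, pairs, epochs = 1)
    expect_length(lossHistory(net1), 1)
    expect_true(is.finite(lossHistory(net1)))

    net30 <- trainModel(net, pairs, epochs = 30)
    h <- lossHistory(net30)
    expect_lt(tail(h, 1), h[1])
    expect_true(isTrained(net30))

    ## single-class training set warns but proceeds
    expect_warning(trainModel(net, pairs[pairs$label == 1, ][1:8, ],
                              epochs = 1), "single class")
})

test_that("training is reproducible under a fixed seed", {
    cfg <- tiny_model_config(seed = 6)
    pairs <- toy_pairs(10, seed = 4)
    a <- trainModel(buildModel(cfg), pairs, epochs = 3)
    b <- trainModel(buildModel(cfg), pairs, epochs = 3)
    expect_identical(a@weights, b@weights)
    expect_identical(lossHistory(a), lossHistory(b))
})

test_that("prediction is deterministic, bounded and thresholded half-open", {
    cfg <- tiny_model_config(seed = 8)
    net <- buildModel(cfg)
    pairs <- toy_pairs(5, seed = 9)
    p1 <- predictPairs(net, pairs)
    p2 <- predictPairs(net, pairs)
    expect_identical(p1, p2)
    expect_true(all(p1$probability >= 0 & p1$probability <= 1))
    ## binary label: probability >= threshold
    fake <- p1
    expect_equal(predictPairs(net, pairs, threshold = 1.1)$prediction,
                 rep(0L, nrow(pairs)))
    expect_equal(predictPairs(net, pairs, threshold = 0)$prediction,
                 rep(1L, nrow(pairs)))
})

test_that("model serialisation round-trips bit-identically and rejects
           tampered headers", {
    cfg <- tiny_model_config(seed = 10)
    pairs <- toy_pairs(8, seed = 11)
    net <- trainModel(buildModel(cfg), pairs, epochs = 2)
    path <- tempfile(fileext = ".json")
    saveModel(net, path)
    back <- loadModel(path)
    expect_identical(predictPairs(back, pairs), predictPairs(net, pairs))
    expect_identical(back@weights, net@weights)

    expect_error(loadModel(tempfile()), "not found")
    txt <- readLines(path)
    writeLines(gsub("\"format_version\":\"1\"",
                    "\"format_version\":\"99\"", txt), path)
    expect_error(loadModel(path), "version mismatch")
    writeLines("{\"something\": 1}", path)
    expect_error(loadModel(path), "format")
})
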