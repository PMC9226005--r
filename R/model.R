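## User-facing model layer: one-hot encoding, construction, training,
## prediction and a portable serialisation format.

MODEL_FORMAT <- "isomiRTarget-model"
MODEL_FORMAT_VERSION <- "1"

#' One-hot encode a nucleotide sequence
#'
#' `A`, `T`, `C`, `G` map to the four unit columns (in that fixed row
#' order) and `N` to a uniform 0.25 column; `U` is treated as `T`.
#' Sequences longer than `target_len` are trimmed at the 3' end and
#' shorter ones padded with `N` at the 3' end, preserving the 5' seed
#' region.
#'
#' @param seq nucleotide string over A/C/G/T/U/N (case-insensitive)
#' @param target_len fixed output length
#' @return a 4 x `target_len` matrix with rownames A, T, C, G; every
#'   column sums to 1
#' @examples
#' encodeSequence("AN", 3)
#' @export
encodeSequence <- function(seq, target_len) {
    s <- normalize_seq(seq)
    chars <- seq_chars(s)
    bad <- which(!chars %in% c("A", "T", "C", "G", "N"))
    if (length(bad))
        stop("encoding error: unsupported symbol '", chars[bad[1]],
             "' at position ", bad[1])
    chars <- head(chars, target_len)
    m <- matrix(0, 4L, target_len,
                dimnames = list(c("A", "T", "C", "G"), NULL))
    n_real <- length(chars)
    if (n_real > 0) {
        row_idx <- match(chars, c("A", "T", "C", "G"))
        for (t in seq_len(n_real)) {
            if (is.na(row_idx[t])) m[, t] <- 0.25 else m[row_idx[t], t] <- 1
        }
    }
    if (n_real < target_len) m[, (n_real + 1L):target_len] <- 0.25
    m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Unit columns map back to their base; uniform columns decode to `N`.
#' @param m a 4 x L matrix as produced by [encodeSequence()]
#' @return nucleotide string
#' @export
decodeMatrix <- function(m) {
    paste0(apply(m, 2, function(col) {
        if (max(col) == 1) c("A", "T", "C", "G")[which.max(col)] else "N"
    }), collapse = "")
}

## Batch encoding: n x (4 target_len), position-major blocks of (A,T,C,G).
encode_batch <- function(seqs, target_len) {
    out <- matrix(0, length(seqs), 4L * target_len)
    for (i in seq_along(seqs))
        out[i, ] <- as.vector(encodeSequence(seqs[[i]], target_len))
    out
}

#' Layer output shapes of an architecture
#'
#' @param x a [ModelConfig-class] or [TargetNet-class]
#' @return list of (channels, positions) dimensions: `conv_mirna`,
#'   `conv_site`, `pool_mirna`, `pool_site`, `merged`, `blstm`, and the
#'   `flatten` length
#' @examples
#' modelShapes(ModelConfig())$flatten   # 1400
#' @export
modelShapes <- function(x) {
    cfg <- if (is(x, "TargetNet")) x@config else x
    stopifnot(is(cfg, "ModelConfig"))
    nn_shapes(cfg)
}

#' Build an untrained interaction classifier
#'
#' Initialises the two-branch CNN + BLSTM network (Glorot-uniform
#' weights, forget-gate biases 1) for the given configuration.
#'
#' @param config a [ModelConfig-class]
#' @return an untrained [TargetNet-class]
#' @examples
#' net <- buildModel(ModelConfig())
#' @export
buildModel <- function(config = ModelConfig()) {
    stopifnot(is(config, "ModelConfig"))
    validObject(config)
    params <- with_seed(derive_seed(config@seed, "model"),
                        nn_init_params(config))
    if (config@batchnorm_after_conv) {
        K <- config@n_kernels
        params$bn_m_rmu <- numeric(K); params$bn_m_rvar <- rep(1, K)
        params$bn_s_rmu <- numeric(K); params$bn_s_rvar <- rep(1, K)
    }
    new("TargetNet", config = config, weights = params, trained = FALSE,
        history = numeric(0), version = MODEL_FORMAT_VERSION)
}

#' Train the classifier
#'
#' Mini-batch training with binary cross-entropy loss, the Adam
#' optimiser, inverted dropout (active only here) and an L1 penalty on
#' convolution kernels and the dense weight matrix.  Reproducible under a
#' fixed `config@seed`.
#'
#' @param model a [TargetNet-class]
#' @param pairs data.frame with `small_rna_seq`, `site_seq` and `label`
#'   (0/1) columns
#' @param epochs overrides `config@epochs` when given
#' @param verbose print the mean loss each epoch
#' @return the trained model; per-epoch mean losses in [lossHistory()]
#' @export
trainModel <- function(model, pairs, epochs = NULL, verbose = FALSE) {
    stopifnot(is(model, "TargetNet"))
    cfg <- model@config
    if (is.null(epochs)) epochs <- cfg@epochs
    y <- as.numeric(pairs$label)
    if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
    if (length(unique(y)) < 2L)
        warning("training set contains a single class; ",
                "ranking metrics will be undefined downstream")
    Xm <- encode_batch(pairs$small_rna_seq, cfg@mirna_len)
    Xs <- encode_batch(pairs$site_seq, cfg@site_len)
    n <- length(y)
    params <- model@weights
    state <- nn_adam_init(params[setdiff(names(params),
        c("bn_m_rmu", "bn_m_rvar", "bn_s_rmu", "bn_s_rvar"))])
    history <- numeric(epochs)
    bn_momentum <- 0.9
    with_seed(derive_seed(cfg@seed, "model") + 1L, {
        for (ep in seq_len(epochs)) {
            ord <- sample.int(n)
            losses <- c()
            for (start in seq(1L, n, by = cfg@batch_size)) {
                idx <- ord[start:min(start + cfg@batch_size - 1L, n)]
                fw <- nn_forward(params, cfg, Xm[idx, , drop = FALSE],
                                 Xs[idx, , drop = FALSE], training = TRUE)
                losses <- c(losses, nn_loss(params, cfg, fw$z, y[idx]))
                grads <- nn_backward(params, cfg, fw, y[idx])
                upd <- nn_adam_step(params, grads, state,
                                    cfg@learning_rate)
                ## carry over non-optimised entries (BN running stats)
                for (nm in names(grads)) params[[nm]] <- upd$params[[nm]]
                state <- upd$state
                if (cfg@batchnorm_after_conv) {
                    params$bn_m_rmu <- bn_momentum * params$bn_m_rmu +
                        (1 - bn_momentum) * fw$cache$bn_m$mu
                    params$bn_m_rvar <- bn_momentum * params$bn_m_rvar +
                        (1 - bn_momentum) * fw$cache$bn_m$sd^2
                    params$bn_s_rmu <- bn_momentum * params$bn_s_rmu +
                        (1 - bn_momentum) * fw$cache$bn_s$mu
                    params$bn_s_rvar <- bn_momentum * params$bn_s_rvar +
                        (1 - bn_momentum) * fw$cache$bn_s$sd^2
                }
            }
            history[ep] <- mean(losses)
            if (!all(is.finite(history[ep])))
                stop("training diverged (non-finite loss) at epoch ", ep)
            if (verbose)
                message("epoch ", ep, ": loss ", signif(history[ep], 5))
        }
    })
    model@weights <- params
    model@trained <- TRUE
    model@history <- c(model@history, history)
    model
}

#' Predict interaction probabilities for sequence pairs
#'
#' Inference is deterministic (dropout disabled).
#'
#' @param model a [TargetNet-class]
#' @param pairs data.frame with `small_rna_seq` and `site_seq` columns
#' @param threshold probability cut-off for the binary label (defaults to
#'   the configuration's `decision_threshold`)
#' @return data.frame with `probability` in [0, 1] and binary
#'   `prediction` (1 iff probability >= threshold)
#' @export
predictPairs <- function(model, pairs, threshold = NULL) {
    stopifnot(is(model, "TargetNet"))
    cfg <- model@config
    if (is.null(threshold)) threshold <- cfg@decision_threshold
    n <- nrow(pairs)
    prob <- numeric(n)
    chunk <- 512L
    for (start in if (n) seq(1L, n, by = chunk) else integer(0)) {
        idx <- start:min(start + chunk - 1L, n)
        Xm <- encode_batch(pairs$small_rna_seq[idx], cfg@mirna_len)
        Xs <- encode_batch(pairs$site_seq[idx], cfg@site_len)
        prob[idx] <- nn_forward(model@weights, cfg, Xm, Xs,
                                training = FALSE)$p
    }
    data.frame(probability = prob,
               prediction = as.integer(prob >= threshold))
}

## numeric payload <-> lossless base64 (exact round trip of doubles)
.num_encode <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                  size = 8, endian = "little"))
}
.num_decode <- function(s, dims) {
    x <- readBin(jsonlite::base64_dec(s), "numeric",
                 n = prod(dims), size = 8, endian = "little")
    if (length(dims) > 1L) dim(x) <- dims
    x
}

#' Save a model to a portable single-file artifact
#'
#' JSON with a version-stamped header, the full configuration, and
#' losslessly encoded weights; [loadModel()] reproduces predictions
#' bit-identically.
#'
#' @param model a [TargetNet-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "TargetNet"))
    cfg <- model@config
    cfg_list <- lapply(setNames(slotNames(cfg), slotNames(cfg)),
                       function(s) slot(cfg, s))
    payload <- list(
        format = MODEL_FORMAT,
        format_version = MODEL_FORMAT_VERSION,
        config = cfg_list,
        trained = model@trained,
        history = model@history,
        weights = lapply(model@weights, function(w)
            list(dims = if (is.matrix(w)) dim(w) else length(w),
                 data = .num_encode(w))))
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
               path)
    invisible(path)
}

#' Load a model saved by [saveModel()]
#'
#' @param path model file
#' @return a [TargetNet-class]
#' @export
loadModel <- function(path) {
    if (!file.exists(path)) stop("model file not found: ", path)
    payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                        error = function(e)
                            stop("corrupt model file: ",
                                 conditionMessage(e)))
    if (!identical(payload$format, MODEL_FORMAT))
        stop("not a recognised model file (missing format header)")
    if (!identical(as.character(payload$format_version),
                   MODEL_FORMAT_VERSION))
        stop("model format version mismatch: file has '",
             payload$format_version, "', this build reads '",
             MODEL_FORMAT_VERSION, "'")
    cfg <- do.call(ModelConfig, payload$config)
    weights <- lapply(payload$weights, function(w)
        .num_decode(w$data, as.integer(w$dims)))
    new("TargetNet", config = cfg, weights = weights,
        trained = isTRUE(payload$trained),
        history = as.numeric(payload$history),
        version = as.character(payload$format_version))
}
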