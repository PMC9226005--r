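## Feature interpretation for a trained classifier: convolutional-kernel
## motif analysis with motif-database matching, and the sliding N-mask
## input-perturbation scan with per-position sensitivity profiles and
## miRNA clustering by sensitivity.

#' Export the convolutional kernels as candidate motifs
#'
#' Each 4 x kernel_len kernel of both branches is exported with its raw
#' weights and a per-column fraction matrix (weights min-shifted and
#' normalised to sum 1, so an uninformative column sits exactly at the
#' 0.25 uniform baseline).  A kernel is flagged informative when at least
#' half of its columns assign some base a fraction above `0.25 + delta`;
#' kernels whose weights are too similar across the four bases are not.
#'
#' @param model a [TargetNet-class] (a warning is issued when untrained:
#'   informativeness of random kernels is meaningless)
#' @param delta margin above the uniform 0.25 baseline (default 0.05)
#' @return list of kernel motifs, each a list with `branch`
#'   (`"mirna"`/`"site"`), `kernel_index`, `weights` (4 x kernel_len,
#'   rows A/T/C/G), `column_fractions` (columns sum to 1) and
#'   `informative`
#' @export
extractKernelMotifs <- function(model, delta = 0.05) {
    stopifnot(is(model, "TargetNet"))
    if (!model@trained)
        warning("model is untrained: kernel informativeness reflects ",
                "random initialisation only")
    kl <- model@config@kernel_len
    out <- list()
    for (branch in c("mirna", "site")) {
        W <- model@weights[[if (branch == "mirna") "conv_m_W" else
                            "conv_s_W"]]
        for (k in seq_len(nrow(W))) {
            w <- matrix(W[k, ], 4L, kl,
                        dimnames = list(c("A", "T", "C", "G"), NULL))
            fr <- apply(w, 2, function(col) {
                shifted <- col - min(col)
                if (sum(shifted) == 0) rep(0.25, 4) else
                    shifted / sum(shifted)
            })
            informative <- sum(apply(fr, 2, max) > 0.25 + delta) >= kl / 2
            out[[length(out) + 1L]] <- list(
                branch = branch, kernel_index = k, weights = w,
                column_fractions = fr, informative = informative)
        }
    }
    out
}

#' Parse a JASPAR-style PFM text file
#'
#' Accepts the JASPAR 2020 flavour: a `>ID NAME` header followed by four
#' base rows, either `A [ 1 2 3 ]` bracketed or bare counts.
#'
#' @param path PFM text file
#' @return named list of 4 x width count matrices (rows A, C, G, T as in
#'   the format)
#' @export
readJasparMotifs <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    headers <- grep("^>", lines)
    if (!length(headers)) stop("no motif headers ('>') found in ", path)
    motifs <- list()
    for (h in seq_along(headers)) {
        i <- headers[h]
        lim <- if (h < length(headers)) headers[h + 1] - 1L else
            length(lines)
        body <- lines[(i + 1L):lim]
        if (length(body) < 4L)
            stop("motif at line ", i, " has fewer than 4 base rows")
        id <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]][1]
        rows <- lapply(body[1:4], function(ln) {
            nums <- regmatches(ln, gregexpr("-?[0-9.]+", ln))[[1]]
            as.numeric(nums)
        })
        if (length(unique(lengths(rows))) != 1L)
            stop("ragged motif matrix for ", id)
        m <- do.call(rbind, rows)
        rownames(m) <- c("A", "C", "G", "T")
        motifs[[id]] <- m
    }
    motifs
}

## Column-normalise a count/weight matrix to frequencies.
.normalize_pfm <- function(m) {
    cs <- colSums(m)
    cs[cs == 0] <- 1
    sweep(m, 2, cs, "/")
}

## Pearson correlation with the zero-variance convention (similarity 0).
.safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    cor(a, b)
}

#' Match a kernel motif against a motif database
#'
#' Similarity between a kernel's column-fraction matrix and each
#' database motif (column-normalised to frequencies) is the maximum
#' Pearson correlation over all full-overlap offsets, the shorter matrix
#' slid along the longer; rows are aligned by base letter.  Zero-variance
#' comparisons score 0 by convention.  No reverse-complement scan is done
#' by default (single-stranded RNA inputs); set `revcomp = TRUE` to add
#' one.
#'
#' @param motif a kernel motif from [extractKernelMotifs()] or a 4 x w
#'   numeric matrix with base rownames
#' @param db named list of motif matrices ([readJasparMotifs()])
#' @param revcomp also scan the reverse complement of each db motif
#' @return data.frame (db_motif_id, similarity) sorted by similarity
#'   descending, ties broken by id
#' @export
matchMotifs <- function(motif, db, revcomp = FALSE) {
    m <- if (is.list(motif) && !is.null(motif$column_fractions))
        motif$column_fractions else motif
    if (is.null(rownames(m)))
        stop("motif matrix needs base rownames")
    base_order <- c("A", "C", "G", "T")
    m <- .normalize_pfm(m[base_order, , drop = FALSE])
    score_pair <- function(a, b) {
        ## slide the shorter fully inside the longer
        if (ncol(a) > ncol(b)) { tmp <- a; a <- b; b <- tmp }
        wa <- ncol(a); wb <- ncol(b)
        best <- -Inf
        for (off in 0:(wb - wa)) {
            s <- .safe_cor(as.vector(a),
                           as.vector(b[, (off + 1):(off + wa),
                                       drop = FALSE]))
            if (s > best) best <- s
        }
        best
    }
    ids <- names(db)
    sims <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
        dm <- db[[i]]
        if (ncol(dm) < 4L) {
            warning("skipping motif ", ids[i], ": fewer than 4 columns")
            next
        }
        dm <- .normalize_pfm(dm[base_order, , drop = FALSE])
        s <- score_pair(m, dm)
        if (revcomp) {
            rc <- dm[rev(base_order), rev(seq_len(ncol(dm))), drop = FALSE]
            rownames(rc) <- base_order
            s <- max(s, score_pair(m, rc))
        }
        sims[i] <- s
    }
    ok <- !is.na(sims)
    out <- data.frame(db_motif_id = ids[ok], similarity = sims[ok],
                      stringsAsFactors = FALSE)
    out <- out[order(-out$similarity, out$db_motif_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## Pad/trim a raw sequence to the model input length (3' end).
.pad_to <- function(seq, L) {
    s <- substr(normalize_seq(seq), 1L, L)
    if (nchar(s) < L) s <- paste0(s, strrep("N", L - nchar(s)))
    s
}

#' Sliding N-mask perturbation scan
#'
#' Every contiguous window of `mask_len` nt in each input sequence
#' (after 3' padding/trimming to the model's fixed lengths) is replaced
#' by `N` and the change in prediction probability recorded:
#' `delta = p(original) - p(masked)`, so positive deltas mark regions
#' supporting the interaction call.  Per-position means and variances
#' are aggregated over all pairs.
#'
#' @param model a trained [TargetNet-class]
#' @param pairs data.frame with `small_rna_seq` and `site_seq`
#' @param mask_len mask width in nt (default 4)
#' @return list with `mirna` and `site` profile data.frames (position
#'   0-based window start, mean_delta, var_delta, n), the per-pair delta
#'   matrices `deltas_mirna` and `deltas_site`, and `prob_original`
#' @export
perturbationScan <- function(model, pairs, mask_len = 4L) {
    stopifnot(is(model, "TargetNet"))
    cfg <- model@config
    if (mask_len > min(cfg@mirna_len, cfg@site_len))
        stop("mask_len exceeds an input sequence length")
    n <- nrow(pairs)
    mir <- vapply(pairs$small_rna_seq, .pad_to, character(1),
                  L = cfg@mirna_len, USE.NAMES = FALSE)
    sit <- vapply(pairs$site_seq, .pad_to, character(1),
                  L = cfg@site_len, USE.NAMES = FALSE)
    p0 <- predictPairs(model, data.frame(small_rna_seq = mir,
                                         site_seq = sit))$probability
    scan_branch <- function(seqs, other, L, mirna_branch) {
        n_win <- L - mask_len + 1L
        deltas <- matrix(0, n, n_win)
        mask <- strrep("N", mask_len)
        for (s in seq_len(n_win)) {
            masked <- seqs
            substr(masked, s, s + mask_len - 1L) <- mask
            df <- if (mirna_branch)
                data.frame(small_rna_seq = masked, site_seq = other)
            else data.frame(small_rna_seq = other, site_seq = masked)
            deltas[, s] <- p0 - predictPairs(model, df)$probability
        }
        deltas
    }
    dm <- scan_branch(mir, sit, cfg@mirna_len, TRUE)
    ds <- scan_branch(sit, mir, cfg@site_len, FALSE)
    profile <- function(d) {
        v <- apply(d, 2, var)
        v[is.na(v)] <- 0
        data.frame(position = seq_len(ncol(d)) - 1L,
                   mean_delta = colMeans(d), var_delta = v,
                   n = nrow(d))
    }
    list(mirna = profile(dm), site = profile(ds),
         deltas_mirna = dm, deltas_site = ds, prob_original = p0)
}

#' Cluster miRNAs by their perturbation-sensitivity profiles
#'
#' Agglomerative clustering (average linkage) under the distance
#' `1 - Pearson correlation` between per-miRNA mean-delta vectors.
#' Constant profiles have undefined correlation and are assigned
#' distance 1 to all others, with a warning.
#'
#' @param profiles numeric matrix: one row per miRNA (rownames used as
#'   ids), one column per position
#' @param k number of clusters, or
#' @param h distance cut-off (one of `k`/`h` required)
#' @return list with `assignments` (named integer vector) and `tree`
#'   (the [stats::hclust] object)
#' @export
clusterSensitivity <- function(profiles, k = NULL, h = NULL) {
    if (nrow(profiles) < 2L) stop("need at least 2 profiles to cluster")
    if (is.null(k) && is.null(h)) stop("supply k or h")
    sds <- apply(profiles, 1, stats::sd)
    if (any(sds == 0))
        warning("constant profile(s) ",
                paste(rownames(profiles)[sds == 0], collapse = ", "),
                ": assigned distance 1 to all others")
    cm <- suppressWarnings(cor(t(profiles)))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 1
    d <- as.dist(1 - cm)
    tree <- hclust(d, method = "average")
    assignments <- if (!is.null(k)) cutree(tree, k = k) else
        cutree(tree, h = h)
    list(assignments = assignments, tree = tree)
}
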