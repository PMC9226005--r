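## Labelled training-pair construction: 3' site extension, the >= 30 nt
## length filter, energy-screened negative-site sampling inside the 3'UTR,
## and train/test splitting (stratified by pair or disjoint by miRNA).

#' Extend a target site at its 3' end
#'
#' Advances the 3' end of the site interval by up to `extension` nt
#' (clipped at the transcript end) to capture more complete target sites;
#' extended sites shorter than `min_len` are rejected.
#'
#' @param transcript_seq transcript sequence
#' @param site_start,site_end 0-based half-open site interval
#' @param extension nt added at the 3' end (default 25)
#' @param min_len minimum accepted extended length (default 30)
#' @return list with `site_start`, `site_end`, `site_seq`, or `NULL` when
#'   the extended site is shorter than `min_len`
#' @examples
#' tx <- strrep("ACGT", 125)                       # 500 nt
#' extendSite(tx, 100, 130)$site_end               # 155
#' @export
extendSite <- function(transcript_seq, site_start, site_end,
                       extension = 25L, min_len = 30L) {
    L <- nchar(transcript_seq)
    site_start <- as.integer(site_start); site_end <- as.integer(site_end)
    if (site_start < 0L || site_end > L || site_start >= site_end)
        stop("data error: site interval [", site_start, ", ", site_end,
             ") outside transcript bounds [0, ", L, ")")
    new_end <- min(L, site_end + as.integer(extension))
    if (new_end - site_start < min_len) return(NULL)
    list(site_start = site_start, site_end = new_end,
         site_seq = substr(transcript_seq, site_start + 1L, new_end))
}

## Complementarity scores for the built-in pairing-strength proxy.
.pair_score <- function(a, b) {
    key <- paste0(a, b)
    score <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
    s <- score[key]
    s[is.na(s)] <- 0
    unname(s)
}

#' Duplex energy of a small RNA bound to a target site
#'
#' `backend = "builtin_proxy"` scores the best ungapped complementary
#' alignment of the small RNA against the site read 3' to 5', as
#' `-(3 GC + 2 AU + 1 GU)` summed over paired positions: a fast,
#' deterministic proxy that is monotone in pairing strength and serves as
#' the default screen for negative-site sampling.
#' `backend = "external_cofold"` shells out to an RNAcofold-compatible
#' executable (ViennaRNA) and parses the predicted hybrid minimum free
#' energy in kcal/mol.
#'
#' @param small_rna_seq miRNA or isomiR sequence
#' @param site_seq candidate target-site sequence
#' @param backend `"builtin_proxy"` or `"external_cofold"`
#' @param cofold executable name or path for the external backend
#' @return energy in kcal/mol (more negative = stronger pairing)
#' @examples
#' duplexEnergy("GGGG", "CCCC")    # -12: four G:C pairs
#' @export
duplexEnergy <- function(small_rna_seq, site_seq,
                         backend = c("builtin_proxy", "external_cofold"),
                         cofold = "RNAcofold") {
    backend <- match.arg(backend)
    if (!nchar(small_rna_seq) || !nchar(site_seq))
        stop("sequences must be non-empty")
    if (backend == "external_cofold")
        return(.cofold_energy(small_rna_seq, site_seq, cofold))
    a <- seq_chars(normalize_seq(small_rna_seq))
    b <- rev(seq_chars(normalize_seq(site_seq)))   # 3'->5' orientation
    La <- length(a); Lb <- length(b)
    best <- 0
    for (o in (-La + 1L):(Lb - 1L)) {
        i <- seq_len(La)
        j <- i + o
        ok <- j >= 1L & j <= Lb
        if (!any(ok)) next
        s <- sum(.pair_score(a[ok], b[j[ok]]))
        if (s > best) best <- s
    }
    -best
}

.cofold_energy <- function(small_rna_seq, site_seq, cofold) {
    exe <- Sys.which(cofold)
    if (!nzchar(exe))
        stop("configuration error: external energy backend '", cofold,
             "' not found on PATH")
    input <- paste0(chartr("T", "U", normalize_seq(small_rna_seq)), "&",
                    chartr("T", "U", normalize_seq(site_seq)))
    out <- system2(exe, c("--noPS"), input = input, stdout = TRUE)
    ## last line ends in "( -dG )" or "(-dG)"
    m <- regmatches(out, regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out))
    m <- m[lengths(regmatches(m, gregexpr("[0-9]", m))) > 0]
    if (!length(m))
        stop("could not parse an energy from ", cofold, " output")
    as.numeric(gsub("[()\\s]", "", m[length(m)], perl = TRUE))
}

#' Sample a negative target site in a transcript's 3'UTR
#'
#' Uniformly samples candidate start positions (without replacement
#' across attempts) within the annotated 3'UTR and accepts the first
#' candidate of length `site_len` lying at least `min_distance` nt from
#' every positive site and satisfying the configured duplex-energy
#' predicate with the small RNA.
#'
#' @param transcript_seq transcript sequence
#' @param utr_interval 0-based half-open (start, end) of the 3'UTR
#' @param positive_sites list/matrix of 0-based half-open positive-site
#'   intervals on this transcript
#' @param site_len negative site length (use the paired positive extended
#'   site length to keep length distributions matched between classes)
#' @param small_rna_seq the small RNA of the paired positive interaction
#' @param config a [NegativeConfig-class]
#' @param seed integer seed
#' @return list with `site_start`, `site_end`, `site_seq`, `energy`, or
#'   `NULL` when no acceptable candidate exists within `max_attempts`
#' @export
sampleNegativeSite <- function(transcript_seq, utr_interval, positive_sites,
                               site_len, small_rna_seq,
                               config = NegativeConfig(), seed = 1L) {
    stopifnot(is(config, "NegativeConfig"))
    u0 <- as.integer(utr_interval[1]); u1 <- as.integer(utr_interval[2])
    site_len <- as.integer(site_len)
    if (u1 - u0 < site_len) return(NULL)          # UTR too short
    starts <- u0:(u1 - site_len)
    far_enough <- function(s) {
        for (iv in positive_sites) {
            if (s < iv[2] + config@min_distance &&
                iv[1] - config@min_distance < s + site_len) return(FALSE)
        }
        TRUE
    }
    with_seed(seed, {
        cand <- resample(starts)
        cand <- head(cand, config@max_attempts)
        for (s in cand) {
            if (!far_enough(s)) next
            site_seq <- substr(transcript_seq, s + 1L, s + site_len)
            e <- duplexEnergy(small_rna_seq, site_seq,
                              backend = config@energy_backend)
            ok <- if (config@energy_mode == "less_than")
                e < config@energy_threshold else e > config@energy_threshold
            if (ok)
                return(list(site_start = s, site_end = s + site_len,
                            site_seq = site_seq, energy = e))
        }
        NULL
    })
}

#' Build labelled interaction pairs from pipeline calls
#'
#' Positive pairs are the interaction calls with their target sites
#' extended by 25 nt at the 3' end (sites shorter than 30 nt after
#' extension are dropped).  For every positive pair one negative pair is
#' generated with the same small RNA and an energy-screened site sampled
#' from the 3'UTR of the same transcript.
#'
#' @param interactions data.frame from [runChimeraPipeline()] (columns
#'   small_rna_seq, transcript_id, site_start, site_end; duplicate
#'   (small RNA, transcript, site) combinations are collapsed)
#' @param transcripts named character vector of transcript sequences
#' @param utr data.frame: transcript_id, utr_start, utr_end (0-based
#'   half-open)
#' @param neg_config a [NegativeConfig-class]
#' @param extension,min_len site-extension parameters (see [extendSite()])
#' @param seed integer seed for negative sampling
#' @return data.frame of pairs: small_rna_seq, site_seq, label (1/0),
#'   transcript_id, site_start, site_end, provenance
#' @export
buildTrainingPairs <- function(interactions, transcripts, utr,
                               neg_config = NegativeConfig(),
                               extension = 25L, min_len = 30L, seed = 1L) {
    key <- paste(interactions$small_rna_seq, interactions$transcript_id,
                 interactions$site_start, interactions$site_end)
    interactions <- interactions[!duplicated(key), , drop = FALSE]
    utr_map <- split(utr[, c("utr_start", "utr_end")], utr$transcript_id)
    ## all positive (extended) intervals per transcript, for the distance rule
    pos_by_tx <- list()
    ext <- vector("list", nrow(interactions))
    for (i in seq_len(nrow(interactions))) {
        r <- interactions[i, ]
        tx <- transcripts[[r$transcript_id]]
        if (is.null(tx)) next
        e <- extendSite(tx, r$site_start, r$site_end, extension, min_len)
        ext[[i]] <- e
        if (!is.null(e))
            pos_by_tx[[r$transcript_id]] <-
                c(pos_by_tx[[r$transcript_id]],
                  list(c(e$site_start, e$site_end)))
    }
    rows <- list()
    seeds <- with_seed(derive_seed(seed, "dataset"),
                       sample.int(.Machine$integer.max - 1L,
                                  nrow(interactions)))
    for (i in seq_len(nrow(interactions))) {
        e <- ext[[i]]
        if (is.null(e)) next
        r <- interactions[i, ]
        rows[[length(rows) + 1L]] <- data.frame(
            small_rna_seq = r$small_rna_seq, site_seq = e$site_seq,
            label = 1L, transcript_id = r$transcript_id,
            site_start = e$site_start, site_end = e$site_end,
            provenance = "clash-like", stringsAsFactors = FALSE)
        uiv <- utr_map[[r$transcript_id]]
        if (is.null(uiv)) next
        neg <- sampleNegativeSite(transcripts[[r$transcript_id]],
                                  c(uiv$utr_start[1], uiv$utr_end[1]),
                                  pos_by_tx[[r$transcript_id]],
                                  nchar(e$site_seq), r$small_rna_seq,
                                  neg_config, seed = seeds[i])
        if (is.null(neg)) next
        rows[[length(rows) + 1L]] <- data.frame(
            small_rna_seq = r$small_rna_seq, site_seq = neg$site_seq,
            label = 0L, transcript_id = r$transcript_id,
            site_start = neg$site_start, site_end = neg$site_end,
            provenance = "negative-sampled", stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Split labelled pairs into training and test sets
#'
#' `mode = "by_pair"` samples `round(train_fraction * n)` pairs per label
#' class (stratified).  `mode = "by_mirna"` partitions the reference
#' miRNA identities so that no small RNA's reference miRNA appears on
#' both sides (requires a `mirna_id` column), probing generalisation to
#' unseen miRNAs.
#'
#' @param pairs data.frame of labelled pairs
#' @param train_fraction fraction assigned to training (default 0.8)
#' @param mode `"by_pair"` or `"by_mirna"`
#' @param seed integer seed
#' @return list with `train` and `test` data.frames
#' @export
splitPairs <- function(pairs, train_fraction = 0.8,
                       mode = c("by_pair", "by_mirna"), seed = 1L) {
    mode <- match.arg(mode)
    if (train_fraction <= 0 || train_fraction >= 1)
        stop("train_fraction must lie strictly between 0 and 1")
    with_seed(derive_seed(seed, "split"), {
        if (mode == "by_pair") {
            idx_train <- integer(0)
            for (lab in unique(pairs$label)) {
                idx <- which(pairs$label == lab)
                n_train <- round(train_fraction * length(idx))
                idx_train <- c(idx_train, resample(idx, n_train))
            }
            train <- pairs[sort(idx_train), , drop = FALSE]
            test <- pairs[-sort(idx_train), , drop = FALSE]
        } else {
            if (!"mirna_id" %in% names(pairs))
                stop("by_mirna split requires a mirna_id column")
            ids <- unique(pairs$mirna_id)
            n_train <- round(train_fraction * length(ids))
            train_ids <- resample(ids, n_train)
            train <- pairs[pairs$mirna_id %in% train_ids, , drop = FALSE]
            test <- pairs[!pairs$mirna_id %in% train_ids, , drop = FALSE]
        }
        rownames(train) <- NULL; rownames(test) <- NULL
        list(train = train, test = test)
    })
}
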