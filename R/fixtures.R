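## Synthetic-data generator: references with annotated 3'UTRs, isomiR
## variants of known type, planted target sites, chimeric FASTQ reads and a
## surrogate alignment-hit table, all deterministic under a fixed seed.

#' The eight isomiR type labels
#'
#' 5'/3' end addition, deletion and replacement, plus single- (SNP) and
#' multi-nucleotide (MNP) internal polymorphisms.
#' @export
ISOMIR_TYPES <- c("5p_add", "5p_del", "5p_rep",
                  "3p_add", "3p_del", "3p_rep", "SNP", "MNP")

#' Generate synthetic miRNA and transcript references
#'
#' Transcripts carry an annotated 3'UTR occupying their final
#' `utr_fraction` (0-based half-open coordinates).  All randomness is fixed
#' by `config@seed`; no two miRNAs are identical.
#'
#' @param config a [SimulationConfig-class]
#' @return list with `mirnas` (named character), `transcripts` (named
#'   character) and `utr` (data.frame: transcript_id, utr_start, utr_end)
#' @examples
#' refs <- simulateReferences(SimulationConfig(n_mirnas = 2, seed = 1))
#' names(refs$mirnas)
#' @export
simulateReferences <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    with_seed(derive_seed(config@seed, "simulate"), {
        mirnas <- character(0)
        while (length(mirnas) < config@n_mirnas) {
            need <- config@n_mirnas - length(mirnas)
            lens <- resample(seq(config@mirna_len_range[1],
                                 config@mirna_len_range[2]),
                             need, replace = TRUE)
            mirnas <- unique(c(mirnas, random_dna(need, lens)))
        }
        names(mirnas) <- sprintf("mir-%03d", seq_along(mirnas))
        tx_lens <- resample(seq(config@transcript_len_range[1],
                                config@transcript_len_range[2]),
                            config@n_transcripts, replace = TRUE)
        transcripts <- random_dna(config@n_transcripts, tx_lens)
        names(transcripts) <- sprintf("tx-%04d", seq_len(config@n_transcripts))
        utr_start <- as.integer(floor(tx_lens * (1 - config@utr_fraction)))
        utr <- data.frame(transcript_id = names(transcripts),
                          utr_start = utr_start,
                          utr_end = tx_lens,
                          stringsAsFactors = FALSE)
        list(mirnas = mirnas, transcripts = transcripts, utr = utr)
    })
}

#' Construct an isomiR of a prescribed type
#'
#' Builds a sequence variant of `mirna_seq` belonging to exactly one of the
#' eight canonical isomiR types, together with its truth label.  The
#' construction is checked to be unambiguous: re-anchoring the variant
#' against the reference recovers exactly the intended offsets and
#' mismatches (the generator retries with fresh random letters otherwise).
#'
#' @param mirna_seq reference mature miRNA sequence (>= 17 nt)
#' @param type one of [ISOMIR_TYPES]
#' @param size edit size in nt (additions/deletions 1-3, replacement runs
#'   1-2, MNP 2-3 substitutions); drawn at random when `NULL`
#' @param seed integer seed
#' @return list with `seq` (the isomiR) and `types` (character truth label)
#' @examples
#' simulateIsomir("ACGTACGTACGTACGTACGTAC", "3p_add", size = 2, seed = 1)
#' @export
simulateIsomir <- function(mirna_seq, type = sample(ISOMIR_TYPES, 1),
                           size = NULL, seed = 1L) {
    mirna_seq <- normalize_seq(mirna_seq)
    L <- nchar(mirna_seq)
    if (L < 17L)
        stop("reference miRNA must be at least 17 nt long")
    type <- match.arg(type, ISOMIR_TYPES)
    with_seed(seed, {
        if (is.null(size)) {
            size <- switch(type,
                "5p_add" = , "3p_add" = , "5p_del" = , "3p_del" =
                    sample(1:3, 1),
                "5p_rep" = , "3p_rep" = sample(1:2, 1),
                "SNP" = 1L,
                "MNP" = sample(2:3, 1))
        }
        size <- as.integer(size)
        if (type %in% c("5p_del", "3p_del") && size >= L)
            stop("deletion size must be smaller than the sequence length")
        if (type == "SNP" && size != 1L)
            stop("a SNP isomiR has exactly one substitution")
        if (type == "MNP" && size < 2L)
            stop("an MNP isomiR has at least two substitutions")
        ref <- seq_chars(mirna_seq)
        other <- function(b) sample(setdiff(BASES, b), 1)
        for (attempt in 1:100) {
            iso <- switch(type,
                "5p_add" = {
                    added <- vapply(seq_len(size),
                                    function(i) other(ref[i]), character(1))
                    c(added, ref)
                },
                "5p_del" = ref[-seq_len(size)],
                "5p_rep" = {
                    x <- ref
                    for (i in seq_len(size)) x[i] <- other(ref[i])
                    x
                },
                "3p_add" = {
                    added <- vapply(seq_len(size),
                                    function(i) other(ref[L - size + i]),
                                    character(1))
                    c(ref, added)
                },
                "3p_del" = ref[seq_len(L - size)],
                "3p_rep" = {
                    x <- ref
                    for (i in (L - size + 1L):L) x[i] <- other(ref[i])
                    x
                },
                "SNP" = {
                    pos <- sample(4:(L - 3L), 1)
                    x <- ref
                    x[pos] <- other(ref[pos])
                    x
                },
                "MNP" = {
                    pos <- sort(sample(seq(4L, L - 3L, by = 2L), size))
                    x <- ref
                    for (p in pos) x[p] <- other(ref[p])
                    x
                })
            iso_seq <- paste0(iso, collapse = "")
            if (.isomir_is_unambiguous(iso_seq, mirna_seq, type, size))
                return(list(seq = iso_seq, types = type))
        }
        stop("failed to build an unambiguous ", type, " isomiR; ",
             "the reference sequence may be too repetitive")
    })
}

## Check that anchored re-comparison recovers exactly the intended edit.
.isomir_is_unambiguous <- function(iso_seq, ref_seq, type, size) {
    anc <- tryCatch(anchorAlign(iso_seq, ref_seq), error = function(e) NULL)
    if (is.null(anc)) return(FALSE)
    expected <- switch(type,
        "5p_add" = c(-size, 0L), "5p_del" = c(size, 0L),
        "3p_add" = c(0L, size), "3p_del" = c(0L, -size),
        c(0L, 0L))
    if (anc$offset_5p != expected[1] || anc$offset_3p != expected[2])
        return(FALSE)
    n_int <- length(anc$internal_mismatch_positions)
    identical(classifyIsomir(iso_seq, ref_seq), type) &&
        switch(type,
               "SNP" = n_int == 1L,
               "MNP" = n_int == size,
               n_int == 0L)
}

#' Plant a miRNA target site into a transcript
#'
#' Overwrites `site_len` nt of the transcript starting at `position`
#' (0-based) so that the region contains the reverse complement of small
#' RNA positions 2-7 (the seed match, placed towards the site's 3' end) and,
#' under the `"seed_plus_3prime"` model, additionally the reverse complement
#' of positions 10-16 towards the site's 5' end.  The seed match is made to
#' occur exactly once within the planted region.
#'
#' @param transcript_seq transcript sequence (character)
#' @param mirna_seq the interacting small RNA sequence
#' @param site_model `"seed_complement_only"` or `"seed_plus_3prime"`
#' @param position 0-based start of the site on the transcript
#' @param existing list/matrix of previously planted `(start, end)`
#'   0-based half-open intervals; overlap raises an error
#' @param site_len planted site length in nt (default 30)
#' @return list with `transcript` (modified sequence), `site_start`,
#'   `site_end` (0-based half-open) and `seed_offset` (0-based offset of the
#'   seed match within the site)
#' @export
plantTargetSite <- function(transcript_seq, mirna_seq,
                            site_model = c("seed_complement_only",
                                           "seed_plus_3prime"),
                            position, existing = NULL, site_len = 30L) {
    site_model <- match.arg(site_model)
    transcript_seq <- normalize_seq(transcript_seq)
    mirna_seq <- normalize_seq(mirna_seq)
    position <- as.integer(position)
    site_len <- as.integer(site_len)
    Lt <- nchar(transcript_seq)
    if (position < 0L || position + site_len > Lt)
        stop("placement error: site [", position, ", ", position + site_len,
             ") outside transcript bounds [0, ", Lt, ")")
    if (!is.null(existing)) {
        for (iv in existing) {
            if (position < iv[2] && iv[1] < position + site_len)
                stop("placement error: site overlaps a previously planted ",
                     "site at [", iv[1], ", ", iv[2], ")")
        }
    }
    site <- seq_chars(substr(transcript_seq, position + 1L,
                             position + site_len))
    seed_match <- seq_chars(revcomp(substr(mirna_seq, 2L, 7L)))
    seed_off <- site_len - 10L            # 0-based within site
    site[(seed_off + 1L):(seed_off + 6L)] <- seed_match
    if (site_model == "seed_plus_3prime") {
        suppl <- seq_chars(revcomp(substr(mirna_seq, 10L, 16L)))
        site[5:11] <- suppl
    }
    ## knock out spurious copies of the seed match elsewhere in the site
    seed_str <- paste0(seed_match, collapse = "")
    repeat {
        site_str <- paste0(site, collapse = "")
        occ <- gregexpr(seed_str, site_str, fixed = TRUE)[[1]]
        occ <- occ[occ > 0]
        spurious <- setdiff(occ, seed_off + 1L)
        spurious <- spurious[spurious + 5L < seed_off + 1L |
                             spurious > seed_off + 6L]
        if (!length(spurious)) break
        p <- spurious[1]
        site[p] <- BASES[(match(site[p], BASES) %% 4L) + 1L]
    }
    out <- transcript_seq
    substr(out, position + 1L, position + site_len) <-
        paste0(site, collapse = "")
    ## make the junction alignment-unambiguous: the transcript bases
    ## flanking the site must mismatch the read bases that will abut the
    ## site portion (the small RNA's terminal base when the spacer is
    ## empty), so a local alignment cannot creep across the junction
    in_existing <- function(pos0) {
        if (is.null(existing)) return(FALSE)
        any(vapply(existing, function(iv) pos0 >= iv[1] && pos0 < iv[2],
                   logical(1)))
    }
    avoid_at <- function(pos1, avoid) {
        b <- substr(out, pos1, pos1)
        if (b %in% avoid) {
            repl <- setdiff(BASES, avoid)[1]
            substr(out, pos1, pos1) <<- repl
        }
    }
    m_first <- substr(mirna_seq, 1L, 1L)
    m_last <- substr(mirna_seq, nchar(mirna_seq), nchar(mirna_seq))
    if (position > 0L && !in_existing(position - 1L))
        avoid_at(position, m_last)
    if (position + site_len < Lt && !in_existing(position + site_len))
        avoid_at(position + site_len + 1L, m_first)
    list(transcript = out,
         site_start = position, site_end = position + site_len,
         seed_offset = seed_off)
}

#' Simulate chimeric reads for a set of interaction pairs
#'
#' Each read is the small RNA portion, a spacer of 0-4 random nt (drawn
#' once per pair, so error-free copies are exact duplicates), and the
#' target-site portion; the order follows `config@mirna_first`.  Per-base
#' substitution errors are applied at `config@base_error_rate`; erroneous
#' bases receive `low_q`, all others `high_q` (Phred+33 on output).
#'
#' @param pairs data.frame with columns `pair_id`, `mirna_id`,
#'   `small_rna_seq`, `isomir_types` (`""` for exact miRNAs),
#'   `transcript_id`, `site_start`, `site_end`, `site_seq`
#' @param config a [SimulationConfig-class]
#' @return list with `reads` (data.frame: read_id, sequence, quality) and
#'   `manifest` (the truth manifest, one row per read)
#' @export
simulateChimericReads <- function(pairs, config) {
    stopifnot(is(config, "SimulationConfig"))
    with_seed(derive_seed(config@seed, "simulate") + 7L, {
        rows <- vector("list", nrow(pairs))
        for (i in seq_len(nrow(pairs))) {
            p <- pairs[i, ]
            ## non-templated terminal additions sit at the ligation
            ## junction, so they consume part of the 0-4 nt budget the
            ## pipeline tolerates there; cap the spacer accordingly
            spacer_max <- if (!is.null(p$spacer_max)) p$spacer_max else 4L
            gap <- if (!is.null(p$gap)) p$gap else resample(0:spacer_max, 1)
            ## spacer bases are drawn to mismatch the transcript bases at
            ## the corresponding junction offsets, so alignments cannot
            ## creep across the ligation junction by chance
            spacer <- if (gap > 0) {
                flank <- if (config@mirna_first) p$flank5 else p$flank3
                chars <- vapply(seq_len(gap), function(k) {
                    avoid <- if (is.null(flank) || is.na(flank)) "" else {
                        nf <- nchar(flank)
                        if (config@mirna_first && nf >= gap)
                            substr(flank, nf - gap + k, nf - gap + k)
                        else if (!config@mirna_first && nf >= k)
                            substr(flank, k, k)
                        else ""
                    }
                    resample(setdiff(BASES, avoid), 1)
                }, character(1))
                paste0(chars, collapse = "")
            } else ""
            core <- if (config@mirna_first)
                paste0(p$small_rna_seq, spacer, p$site_seq)
            else
                paste0(p$site_seq, spacer, p$small_rna_seq)
            Lr <- nchar(core)
            core_chars <- seq_chars(core)
            copies <- lapply(seq_len(config@reads_per_pair), function(k) {
                x <- core_chars
                q <- rep(config@high_q, Lr)
                err <- which(runif(Lr) < config@base_error_rate)
                for (e in err) {
                    x[e] <- sample(setdiff(BASES, x[e]), 1)
                    q[e] <- config@low_q
                }
                data.frame(read_id = paste0(p$pair_id, "_r", k),
                           sequence = paste0(x, collapse = ""),
                           quality = phred_string(q),
                           stringsAsFactors = FALSE)
            })
            reads_i <- do.call(rbind, copies)
            manifest_i <- data.frame(
                read_id = reads_i$read_id,
                mirna_id = p$mirna_id,
                isomir_sequence = p$small_rna_seq,
                isomir_true_types = p$isomir_types,
                transcript_id = p$transcript_id,
                site_start = p$site_start,
                site_end = p$site_end,
                gap_nt = gap,
                stringsAsFactors = FALSE)
            rows[[i]] <- list(reads = reads_i, manifest = manifest_i)
        }
        list(reads = do.call(rbind, lapply(rows, `[[`, "reads")),
             manifest = do.call(rbind, lapply(rows, `[[`, "manifest")))
    })
}

## Best ungapped segment on one alignment diagonal: the window of the
## logical match vector maximising score = length - 3 * mismatches (i.e.
## match +1, mismatch -2, mirroring aligners whose mismatch penalty
## exceeds the match reward, so segments never absorb marginal mismatched
## flanks) under the mismatch cap.  Optimal segments start and end on a
## match, so it suffices to enumerate runs of 0..max_mm consecutive
## mismatch positions and span match blocks around them.  Returns
## c(start, end, mismatches) or NULL when nothing reaches min_len.
.best_segment <- function(m, max_mm, min_len) {
    n <- length(m)
    if (n < min_len) return(NULL)
    mis <- which(!m)
    nmis <- length(mis)
    bounds <- c(0L, mis, n + 1L)
    best <- NULL; best_score <- -Inf
    for (i in 0:nmis) {
        jmax <- min(i + max_mm, nmis)
        for (j in i:jmax) {
            start <- bounds[i + 1L] + 1L       # after mismatch i (or 1)
            end <- bounds[j + 2L] - 1L         # before mismatch j+1 (or n)
            if (end - start + 1L < min_len) next
            mm <- j - i
            score <- (end - start + 1L) - 3L * mm
            if (score > best_score) {
                best_score <- score
                best <- c(start, end, mm)
            }
        }
    }
    best
}

## Surrogate e-value and bit score (documented test-only stand-ins for
## BLAST statistics): e = L_ref * 4^-(len - 2 mm), monotone increasing in
## mismatches and decreasing in matched length; bitscore = 2 (len - 2 mm).
.surrogate_evalue <- function(ref_len, len, mm) ref_len * 4^(-(len - 2 * mm))
.surrogate_bitscore <- function(len, mm) 2 * (len - 2 * mm)

#' Generate a surrogate alignment-hit table (BLAST outfmt-6 dialect)
#'
#' A deliberately simple ungapped test aligner standing in for an external
#' aligner: every read is scanned against every reference (both strands)
#' along alignment diagonals; the best segment per diagonal with at most
#' `max_mismatches` substitutions and length at least `min_anchor` is
#' emitted with 1-based inclusive coordinates, a surrogate e-value
#' monotone increasing in mismatches and decreasing in match length, and a
#' surrogate bit score monotone in matches.  Antisense hits carry
#' `sstart > send`, as in BLAST tabular output.
#'
#' @param reads data.frame with `read_id` and `sequence` columns (or a
#'   named character vector)
#' @param refs named character vector of reference sequences
#' @param max_mismatches maximum substitutions per segment (default 3)
#' @param min_anchor minimum matched segment length in nt (default 16)
#' @param seed_k k-mer length used to select candidate diagonals for
#'   references longer than 80 nt (shorter references are scanned
#'   exhaustively)
#' @return data.frame in outfmt-6 column order: qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore
#' @export
simulateAlignmentHits <- function(reads, refs, max_mismatches = 3L,
                                  min_anchor = 16L, seed_k = 12L) {
    if (is.data.frame(reads)) {
        reads <- setNames(reads$sequence, reads$read_id)
    }
    reads <- vapply(reads, normalize_seq, character(1))
    refs <- vapply(refs, normalize_seq, character(1))
    out <- list()
    ref_bytes <- lapply(refs, utf8ToInt)
    ref_rc <- revcomp(refs)
    ref_rc_bytes <- lapply(ref_rc, utf8ToInt)
    ## k-mer position index per (long) reference and strand
    kmer_index <- function(b) {
        L <- length(b)
        if (L < seed_k) return(NULL)
        s <- intToUtf8(b, multiple = FALSE)
        kms <- substring(s, 1:(L - seed_k + 1), seq_k_end <- seed_k:L)
        split(seq_along(kms), kms)
    }
    idx_fwd <- lapply(ref_bytes, kmer_index)
    idx_rev <- lapply(ref_rc_bytes, kmer_index)
    for (ri in seq_along(reads)) {
        qid <- names(reads)[ri]
        qb <- utf8ToInt(reads[[ri]])
        Lq <- length(qb)
        if (Lq < min_anchor) next
        qs <- reads[[ri]]
        qkms <- if (Lq >= seed_k)
            substring(qs, 1:(Lq - seed_k + 1), seed_k:Lq) else character(0)
        for (si in seq_along(refs)) {
            sid <- names(refs)[si]
            for (strand in c("+", "-")) {
                sb <- if (strand == "+") ref_bytes[[si]] else
                    ref_rc_bytes[[si]]
                Ls <- length(sb)
                if (Ls < min_anchor) next
                if (Ls > 80L) {
                    idx <- if (strand == "+") idx_fwd[[si]] else idx_rev[[si]]
                    hitpos <- idx[qkms]
                    diags <- unique(unlist(lapply(seq_along(hitpos),
                        function(i) if (!is.null(hitpos[[i]]))
                            i - hitpos[[i]] else integer(0))))
                } else {
                    diags <- seq(min_anchor - Ls, Lq - min_anchor)
                }
                for (d in diags) {
                    q1 <- max(1L, 1L + d); s1 <- q1 - d
                    len_ov <- min(Lq - q1, Ls - s1) + 1L
                    if (len_ov < min_anchor) next
                    m <- qb[q1:(q1 + len_ov - 1L)] ==
                        sb[s1:(s1 + len_ov - 1L)]
                    seg <- .best_segment(m, max_mismatches, min_anchor)
                    if (is.null(seg)) next
                    qstart <- q1 + seg[1] - 1L
                    qend <- q1 + seg[2] - 1L
                    sstart <- s1 + seg[1] - 1L
                    send <- s1 + seg[2] - 1L
                    len <- qend - qstart + 1L
                    mm <- seg[3]
                    if (strand == "-") {
                        tmp_start <- Ls - send + 1L
                        tmp_end <- Ls - sstart + 1L
                        sstart <- tmp_end; send <- tmp_start
                    }
                    out[[length(out) + 1L]] <- data.frame(
                        qseqid = qid, sseqid = sid,
                        pident = round(100 * (len - mm) / len, 2),
                        length = len, mismatch = mm, gapopen = 0L,
                        qstart = qstart, qend = qend,
                        sstart = sstart, send = send,
                        evalue = .surrogate_evalue(Ls, len, mm),
                        bitscore = .surrogate_bitscore(len, mm),
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    if (!length(out)) {
        return(data.frame(qseqid = character(0), sseqid = character(0),
                          pident = numeric(0), length = integer(0),
                          mismatch = integer(0), gapopen = integer(0),
                          qstart = integer(0), qend = integer(0),
                          sstart = integer(0), send = integer(0),
                          evalue = numeric(0), bitscore = numeric(0),
                          stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
}

#' Simulate a complete interaction study
#'
#' Generates references, plants one target site per transcript (round-robin
#' over the miRNA panel; a configurable fraction of pairs use an isomiR of
#' a random type instead of the exact miRNA), simulates chimeric reads and
#' surrogate alignment-hit tables, and optionally writes everything to
#' `outdir` (mirnas.fa, transcripts.fa, utr.tsv, reads.fastq, manifest.tsv,
#' hits_mirna.tsv, hits_transcript.tsv).
#'
#' @param config a [SimulationConfig-class]
#' @param outdir optional output directory
#' @param align whether to run the built-in test aligner (the slowest step)
#' @param reads whether to simulate chimeric reads (implied by `align`)
#' @return list: `references`, `pairs`, `reads`, `manifest`, and (when
#'   `align = TRUE`) `hits_mirna`, `hits_transcript`
#' @examples
#' sim <- simulateInteractionDataset(
#'     SimulationConfig(n_mirnas = 2, n_transcripts = 2, seed = 1),
#'     align = FALSE)
#' head(sim$manifest)
#' @export
simulateInteractionDataset <- function(config, outdir = NULL, align = TRUE,
                                       reads = TRUE) {
    stopifnot(is(config, "SimulationConfig"))
    refs <- simulateReferences(config)
    with_seed(derive_seed(config@seed, "simulate") + 13L, {
        n <- config@n_transcripts
        mirna_idx <- ((seq_len(n) - 1L) %% config@n_mirnas) + 1L
        use_isomir <- runif(n) < config@isomir_fraction
        iso_seeds <- sample.int(1e6, n)
        site_seeds <- sample.int(1e6, n)
        pair_rows <- vector("list", n)
        for (j in seq_len(n)) {
            mid <- names(refs$mirnas)[mirna_idx[j]]
            mseq <- refs$mirnas[[mirna_idx[j]]]
            if (use_isomir[j]) {
                iso <- simulateIsomir(mseq, sample(ISOMIR_TYPES, 1),
                                      seed = iso_seeds[j])
                small <- iso$seq; types <- iso$types
                anc <- anchorAlign(small, mseq)
                overhang <- if (config@mirna_first)
                    max(0L, anc$offset_3p) else max(0L, -anc$offset_5p)
            } else {
                small <- mseq; types <- ""
                overhang <- 0L
            }
            tid <- refs$utr$transcript_id[j]
            u0 <- refs$utr$utr_start[j]; u1 <- refs$utr$utr_end[j]
            site_len <- 30L
            spacer_max <- max(0L, 4L - overhang)
            gap <- resample(0:spacer_max, 1)
            pos <- with_seed(site_seeds[j],
                             resample(u0:(u1 - site_len), 1))
            planted <- plantTargetSite(refs$transcripts[[j]], small,
                                       config@site_model, pos,
                                       site_len = site_len)
            ## guarantee the transcript bases the small RNA tail will
            ## abut (just beyond the spacer) mismatch it, so local
            ## alignments can never creep across the ligation junction
            tx <- planted$transcript
            Lsm <- nchar(small); Lt <- nchar(tx)
            for (d in 1:4) {
                if (config@mirna_first) {
                    p1 <- planted$site_start - gap - d + 1L  # 1-based
                    if (p1 < 1L || d > Lsm) next
                    read_b <- substr(small, Lsm - d + 1L, Lsm - d + 1L)
                } else {
                    p1 <- planted$site_end + gap + d
                    if (p1 > Lt || d > Lsm) next
                    read_b <- substr(small, d, d)
                }
                if (substr(tx, p1, p1) == read_b)
                    substr(tx, p1, p1) <- setdiff(BASES, read_b)[1]
            }
            planted$transcript <- tx
            refs$transcripts[[j]] <- planted$transcript
            pair_rows[[j]] <- data.frame(
                pair_id = sprintf("pair-%04d", j),
                mirna_id = mid,
                small_rna_seq = small,
                isomir_types = types,
                transcript_id = tid,
                site_start = planted$site_start,
                site_end = planted$site_end,
                site_seq = substr(planted$transcript,
                                  planted$site_start + 1L,
                                  planted$site_end),
                spacer_max = spacer_max,
                gap = gap,
                flank5 = substr(planted$transcript,
                                max(1L, planted$site_start - 3L),
                                planted$site_start),
                flank3 = substr(planted$transcript,
                                planted$site_end + 1L,
                                planted$site_end + 4L),
                stringsAsFactors = FALSE)
        }
        pairs <- do.call(rbind, pair_rows)
        out <- list(references = refs, pairs = pairs,
                    reads = NULL, manifest = NULL)
        if (reads || align) {
            sim_reads <- simulateChimericReads(pairs, config)
            out$reads <- sim_reads$reads
            out$manifest <- sim_reads$manifest
        }
        if (align) {
            out$hits_mirna <- simulateAlignmentHits(sim_reads$reads,
                                                    refs$mirnas)
            out$hits_transcript <- simulateAlignmentHits(sim_reads$reads,
                                                         refs$transcripts)
        }
        if (!is.null(outdir)) writeSimulatedDataset(out, outdir)
        out
    })
}

#' Simulate labelled training pairs directly
#'
#' Convenience wrapper for model studies: generates references and
#' planted target sites (one positive interaction per transcript, so
#' `config@n_transcripts` positives) and pairs every positive with an
#' energy-screened negative site from the same transcript's 3'UTR,
#' skipping read simulation and alignment.
#'
#' @param config a [SimulationConfig-class]
#' @param neg_config a [NegativeConfig-class]
#' @return data.frame of labelled pairs (see [buildTrainingPairs()]),
#'   with a `mirna_id` column for miRNA-disjoint splits
#' @examples
#' pairs <- simulateTrainingPairs(
#'     SimulationConfig(n_mirnas = 2, n_transcripts = 4, seed = 1))
#' table(pairs$label)
#' @export
simulateTrainingPairs <- function(config, neg_config = NegativeConfig()) {
    sim <- simulateInteractionDataset(config, align = FALSE, reads = FALSE)
    interactions <- data.frame(
        small_rna_seq = sim$pairs$small_rna_seq,
        transcript_id = sim$pairs$transcript_id,
        site_start = sim$pairs$site_start,
        site_end = sim$pairs$site_end,
        stringsAsFactors = FALSE)
    pairs <- buildTrainingPairs(interactions, sim$references$transcripts,
                                sim$references$utr, neg_config,
                                seed = config@seed)
    mid <- setNames(sim$pairs$mirna_id,
                    paste(sim$pairs$small_rna_seq, sim$pairs$transcript_id))
    pairs$mirna_id <- mid[paste(pairs$small_rna_seq, pairs$transcript_id)]
    pairs
}

#' Write a simulated dataset to disk
#'
#' @param sim result of [simulateInteractionDataset()]
#' @param outdir output directory (created if absent)
#' @return `outdir`, invisibly
#' @export
writeSimulatedDataset <- function(sim, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeFasta(sim$references$mirnas, file.path(outdir, "mirnas.fa"))
    writeFasta(sim$references$transcripts,
               file.path(outdir, "transcripts.fa"))
    write.table(sim$references$utr, file.path(outdir, "utr.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeFastq(sim$reads, file.path(outdir, "reads.fastq"))
    write.table(sim$manifest, file.path(outdir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sim$hits_mirna))
        write.table(sim$hits_mirna, file.path(outdir, "hits_mirna.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    if (!is.null(sim$hits_transcript))
        write.table(sim$hits_transcript,
                    file.path(outdir, "hits_transcript.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    invisible(outdir)
}

#' Write named sequences as FASTA
#' @param seqs named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFasta <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Write reads as Phred+33 FASTQ
#' @param reads data.frame with `read_id`, `sequence`, `quality`
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFastq <- function(reads, path) {
    x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
    q <- Biostrings::BStringSet(reads$quality)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    invisible(path)
}
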