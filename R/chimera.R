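## The chimeric-read deconvolution pipeline: FASTQ + alignment-hit tables
## in, supported miRNA/isomiR-mRNA interaction calls out.  All transcript
## and read intervals are handled as 0-based half-open internally; BLAST
## tabular 1-based inclusive coordinates are converted on ingestion and
## minus-strand hits are detected by sstart > send.

#' Read chimeric reads from a Phred+33 FASTQ file
#'
#' Reads are assumed adapter-free (adapter trimming is upstream of this
#' tool).
#'
#' @param path FASTQ file
#' @return data.frame with `read_id`, `sequence` (DNA letters, U
#'   normalised to T) and `quality` (Phred+33 string)
#' @export
readChimericReads <- function(path) {
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    data.frame(read_id = sub("\\s.*$", "", names(x)),
               sequence = as.character(x),
               quality = as.character(Biostrings::quality(x)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse exact-duplicate reads
#'
#' Exact-sequence duplicates are collapsed to the first record
#' encountered; the number of original reads behind each retained record
#' is preserved so that read-support filters can weight calls by
#' duplicate multiplicity.
#'
#' @param reads data.frame with `read_id` and `sequence` (and optionally
#'   `quality`) columns
#' @return list with `unique` (the retained records) and `multiplicity`
#'   (named integer vector keyed by retained read_id)
#' @examples
#' r <- data.frame(read_id = c("a", "b", "c"),
#'                 sequence = c("AAA", "AAA", "AAC"))
#' dedupReads(r)$multiplicity
#' @export
dedupReads <- function(reads) {
    if (!nrow(reads))
        return(list(unique = reads,
                    multiplicity = setNames(integer(0), character(0))))
    first <- !duplicated(reads$sequence)
    uniq <- reads[first, , drop = FALSE]
    rownames(uniq) <- NULL
    counts <- table(reads$sequence)
    mult <- as.integer(counts[uniq$sequence])
    list(unique = uniq, multiplicity = setNames(mult, uniq$read_id))
}

#' Parse a BLAST tabular (outfmt-6) hit table
#'
#' Expects the default 12-column order (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) with no
#' header.  Query and subject intervals are converted to 0-based half-open
#' coordinates; antisense hits (sstart > send) get strand `"-"`.
#'
#' @param path TSV file of hits
#' @return data.frame with read_id, subject_id, q_start, q_end, s_start,
#'   s_end, strand, mismatch, gapopen, evalue, bitscore
#' @export
readAlignmentHits <- function(path) {
    raw <- read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "")
    if (ncol(raw) != 12L)
        stop("parse error: expected 12 tab-separated columns, found ",
             ncol(raw))
    num <- c(3:12)
    vals <- suppressWarnings(lapply(raw[num], as.numeric))
    bad <- which(Reduce(`|`, lapply(vals, is.na)))
    if (length(bad))
        stop("parse error: malformed numeric field at line ", bad[1])
    hitsFromTable(data.frame(qseqid = raw[[1]], sseqid = raw[[2]],
                             pident = vals[[1]], length = vals[[2]],
                             mismatch = vals[[3]], gapopen = vals[[4]],
                             qstart = vals[[5]], qend = vals[[6]],
                             sstart = vals[[7]], send = vals[[8]],
                             evalue = vals[[9]], bitscore = vals[[10]],
                             stringsAsFactors = FALSE))
}

#' Convert an in-memory outfmt-6 data.frame to internal hit records
#'
#' @param tab data.frame with the 12 outfmt-6 columns (as produced by
#'   [simulateAlignmentHits()])
#' @return the internal hit data.frame used by [filterHits()]
#' @export
hitsFromTable <- function(tab) {
    minus <- tab$sstart > tab$send
    s_start <- ifelse(minus, tab$send, tab$sstart) - 1
    s_end <- ifelse(minus, tab$sstart, tab$send)
    data.frame(read_id = tab$qseqid, subject_id = tab$sseqid,
               q_start = as.integer(tab$qstart - 1),
               q_end = as.integer(tab$qend),
               s_start = as.integer(s_start), s_end = as.integer(s_end),
               strand = ifelse(minus, "-", "+"),
               mismatch = as.integer(tab$mismatch),
               gapopen = as.integer(tab$gapopen),
               evalue = tab$evalue, bitscore = tab$bitscore,
               stringsAsFactors = FALSE)
}

#' Filter alignment hits
#'
#' Retains hits with e-value at most `config@max_evalue`, on the sense
#' strand, and without gap openings (gapped alignments are read as
#' alignment loops and discarded, keeping variant calling
#' substitution/end-edit only).
#'
#' @param hits internal hit data.frame ([readAlignmentHits()])
#' @param config a [PipelineConfig-class]
#' @return the retained rows
#' @export
filterHits <- function(hits, config = PipelineConfig()) {
    keep <- hits$evalue <= config@max_evalue &
        hits$strand == "+" & hits$gapopen == 0L
    out <- hits[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Enumerate candidate chimera calls for one read
#'
#' Every (miRNA hit, mRNA hit) combination whose query intervals are
#' separated by a spacer of 0 to `max_gap` nt (overlaps up to
#' `max_overlap` tolerated, default none) yields a call; when
#' `require_mirna_first` is set the miRNA portion must lie 5' of the mRNA
#' portion.
#'
#' @param read one-row data.frame (or list) with `read_id`, `sequence`
#' @param mirna_hits,mrna_hits filtered hits for this read against the
#'   miRNA and transcript databases
#' @param config a [PipelineConfig-class]
#' @return data.frame of calls (possibly empty): identifiers, query
#'   intervals, site interval on the transcript, gap, combined e-value
#'   (max of the two hits) and combined bit score (sum)
#' @export
callChimeras <- function(read, mirna_hits, mrna_hits,
                         config = PipelineConfig()) {
    empty <- data.frame(read_id = character(0), mirna_id = character(0),
                        transcript_id = character(0),
                        mirna_q_start = integer(0), mirna_q_end = integer(0),
                        mrna_q_start = integer(0), mrna_q_end = integer(0),
                        site_start = integer(0), site_end = integer(0),
                        gap_nt = integer(0), evalue = numeric(0),
                        bitscore = numeric(0),
                        mirna_portion = character(0),
                        mrna_portion = character(0),
                        stringsAsFactors = FALSE)
    if (!nrow(mirna_hits) || !nrow(mrna_hits)) return(empty)
    out <- list()
    for (i in seq_len(nrow(mirna_hits))) {
        mh <- mirna_hits[i, ]
        for (j in seq_len(nrow(mrna_hits))) {
            th <- mrna_hits[j, ]
            mirna_first <- mh$q_start <= th$q_start
            gap <- if (mirna_first) th$q_start - mh$q_end
                   else mh$q_start - th$q_end
            if (gap > config@max_gap || gap < -config@max_overlap) next
            if (config@require_mirna_first && !mirna_first) next
            out[[length(out) + 1L]] <- data.frame(
                read_id = read$read_id,
                mirna_id = mh$subject_id,
                transcript_id = th$subject_id,
                mirna_q_start = mh$q_start, mirna_q_end = mh$q_end,
                mrna_q_start = th$q_start, mrna_q_end = th$q_end,
                site_start = th$s_start, site_end = th$s_end,
                gap_nt = as.integer(gap),
                evalue = max(mh$evalue, th$evalue),
                bitscore = mh$bitscore + th$bitscore,
                mirna_portion = substr(read$sequence, mh$q_start + 1L,
                                       mh$q_end),
                mrna_portion = substr(read$sequence, th$q_start + 1L,
                                      th$q_end),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out)) return(empty)
    do.call(rbind, out)
}

#' Keep the best-ranked chimera calls of one read
#'
#' Calls are ordered by combined e-value ascending, then combined bit
#' score descending, then lexicographically on (miRNA id, transcript id)
#' for reproducibility; the first `top_k_pairs` are returned.
#'
#' @param calls calls of a single read ([callChimeras()])
#' @param config a [PipelineConfig-class]
#' @return the retained rows, in rank order
#' @export
selectBestPairs <- function(calls, config = PipelineConfig()) {
    if (!nrow(calls)) return(calls)
    ord <- order(calls$evalue, -calls$bitscore, calls$mirna_id,
                 calls$transcript_id, method = "radix")
    out <- head(calls[ord, , drop = FALSE], config@top_k_pairs)
    rownames(out) <- NULL
    out
}

#' Apply the read-support filter
#'
#' A call survives iff its exact miRNA-portion sequence is supported by at
#' least `min_support_reads` chimeric reads; each distinct read counts
#' with its duplicate multiplicity (from [dedupReads()]), so twelve
#' identical raw reads collapsed to one record still contribute twelve.
#'
#' @param calls pooled calls across reads
#' @param config a [PipelineConfig-class]
#' @param multiplicity named integer vector keyed by read_id (defaults to
#'   1 per read)
#' @return the surviving rows with a `read_support` column prepended
#' @export
filterSupport <- function(calls, config = PipelineConfig(),
                          multiplicity = NULL) {
    if (!nrow(calls)) {
        calls$read_support <- integer(0)
        return(calls)
    }
    w <- if (is.null(multiplicity)) setNames(rep(1L, nrow(calls)),
                                             calls$read_id)[
                                       unique(calls$read_id)]
         else multiplicity
    per_read <- unique(calls[, c("read_id", "mirna_portion")])
    wt <- w[per_read$read_id]
    wt[is.na(wt)] <- 1L
    support <- tapply(wt, per_read$mirna_portion, sum)
    calls$read_support <- as.integer(support[calls$mirna_portion])
    out <- calls[calls$read_support >= config@min_support_reads, ,
                 drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Compare a read's miRNA portion with its reference miRNA
#'
#' A perfect match is an exact miRNA call.  Otherwise the portion is
#' anchored against the reference and the call is accepted as an isomiR
#' iff the sequencing quality at every variation position (anchored
#' mismatches plus 5'/3' added nucleotides) is strictly greater than
#' `min_variant_quality`; it is rejected otherwise.
#'
#' @param portion_seq the miRNA portion extracted from the read
#' @param portion_qual integer Phred scores for the portion (same length)
#' @param ref_seq the reference mature miRNA the portion aligned to
#' @param config a [PipelineConfig-class]
#' @return list with `status` (`"exact_mirna"`, `"isomir"` or
#'   `"rejected"`) and `variant_positions` (0-based portion coordinates)
#' @export
callVariant <- function(portion_seq, portion_qual, ref_seq,
                        config = PipelineConfig()) {
    portion_seq <- normalize_seq(portion_seq)
    ref_seq <- normalize_seq(ref_seq)
    if (length(portion_qual) < nchar(portion_seq))
        stop("data error: quality vector shorter than the miRNA portion")
    if (identical(portion_seq, ref_seq))
        return(list(status = "exact_mirna", variant_positions = integer(0)))
    a <- tryCatch(anchorAlign(portion_seq, ref_seq),
                  error = function(e) NULL)
    if (is.null(a))
        return(list(status = "rejected", variant_positions = integer(0)))
    Li <- nchar(portion_seq)
    var_pos <- a$mismatch_positions_iso
    if (a$offset_5p < 0L) var_pos <- c(0:(-a$offset_5p - 1L), var_pos)
    if (a$offset_3p > 0L) var_pos <- c(var_pos, (Li - a$offset_3p):(Li - 1L))
    var_pos <- sort(unique(as.integer(var_pos)))
    ok <- all(portion_qual[var_pos + 1L] > config@min_variant_quality)
    list(status = if (ok) "isomir" else "rejected",
         variant_positions = var_pos)
}

#' Run the full chimera pipeline
#'
#' Deduplicates reads, filters hits (e-value, strand, gap openings),
#' enumerates chimera calls per unique read, keeps the best-ranked
#' `top_k_pairs` per read, applies the multiplicity-weighted read-support
#' filter, and classifies each surviving call as an exact miRNA or a
#' quality-checked isomiR.
#'
#' @param reads data.frame from [readChimericReads()] (or the simulator)
#' @param hits_mirna,hits_transcript outfmt-6 data.frames (12 columns) or
#'   internal hit tables
#' @param mirna_refs named character vector of mature miRNA sequences
#' @param config a [PipelineConfig-class]
#' @return list with `interactions` (read_support, mirna_id, isomir_seq
#'   (`"="` for exact miRNA calls), transcript_id, site_start, site_end
#'   0-based half-open, gap_nt, evalue, bitscore, plus read_id and
#'   small_rna_seq convenience columns) and `stats` (counts at each
#'   filter stage)
#' @export
runChimeraPipeline <- function(reads, hits_mirna, hits_transcript,
                               mirna_refs, config = PipelineConfig()) {
    as_hits <- function(h) {
        if ("qseqid" %in% names(h)) hitsFromTable(h) else h
    }
    dd <- dedupReads(reads)
    uniq <- dd$unique
    stats <- c(reads_in = nrow(reads), reads_after_dedup = nrow(uniq))
    hm <- filterHits(as_hits(hits_mirna), config)
    ht <- filterHits(as_hits(hits_transcript), config)
    hm <- hm[hm$read_id %in% uniq$read_id, , drop = FALSE]
    ht <- ht[ht$read_id %in% uniq$read_id, , drop = FALSE]
    stats["hits_after_filter"] <- nrow(hm) + nrow(ht)
    hm_split <- split(hm, hm$read_id)
    ht_split <- split(ht, ht$read_id)
    calls <- list()
    for (k in seq_len(nrow(uniq))) {
        rid <- uniq$read_id[k]
        mh <- hm_split[[rid]]
        th <- ht_split[[rid]]
        if (is.null(mh) || is.null(th)) next
        cc <- callChimeras(uniq[k, ], mh, th, config)
        if (nrow(cc)) calls[[length(calls) + 1L]] <-
            selectBestPairs(cc, config)
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
        callChimeras(list(read_id = "x", sequence = ""),
                     data.frame(), data.frame(), config)
    stats["calls_before_support"] <- nrow(calls)
    calls <- filterSupport(calls, config, dd$multiplicity)
    stats["calls_after_support"] <- nrow(calls)
    ## variant check against the reference each portion aligned to
    qual_by_read <- setNames(uniq$quality, uniq$read_id)
    keep <- logical(nrow(calls))
    isomir_seq <- character(nrow(calls))
    for (k in seq_len(nrow(calls))) {
        cl <- calls[k, ]
        ref <- mirna_refs[[cl$mirna_id]]
        if (is.null(ref)) next
        q <- char_to_phred(qual_by_read[[cl$read_id]])
        pq <- q[(cl$mirna_q_start + 1L):cl$mirna_q_end]
        v <- callVariant(cl$mirna_portion, pq, ref, config)
        if (v$status == "rejected") next
        keep[k] <- TRUE
        isomir_seq[k] <- if (v$status == "exact_mirna") "=" else
            cl$mirna_portion
    }
    calls <- calls[keep, , drop = FALSE]
    isomir_seq <- isomir_seq[keep]
    ## re-apply the support rule to accepted isomiR sequences
    if (nrow(calls)) {
        iso_rows <- isomir_seq != "="
        if (any(iso_rows)) {
            ok <- calls$read_support[iso_rows] >= config@min_support_reads
            drop_idx <- which(iso_rows)[!ok]
            if (length(drop_idx)) {
                calls <- calls[-drop_idx, , drop = FALSE]
                isomir_seq <- isomir_seq[-drop_idx]
            }
        }
    }
    stats["interactions_out"] <- nrow(calls)
    interactions <- data.frame(
        read_id = calls$read_id,
        read_support = calls$read_support,
        mirna_id = calls$mirna_id,
        isomir_seq = isomir_seq,
        small_rna_seq = calls$mirna_portion,
        transcript_id = calls$transcript_id,
        site_start = calls$site_start,
        site_end = calls$site_end,
        gap_nt = calls$gap_nt,
        evalue = calls$evalue,
        bitscore = calls$bitscore,
        stringsAsFactors = FALSE)
    rownames(interactions) <- NULL
    list(interactions = interactions, stats = stats)
}
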