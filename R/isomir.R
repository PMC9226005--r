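## Anchored isomiR-vs-miRNA comparison, the eight-type classification,
## per-miRNA type-enrichment statistics and the read-support probability
## model behind the >= 10-read filter.

#' Anchor an isomiR against its reference miRNA
#'
#' Ungapped anchored comparison: the relative offset in
#' `[-max_shift, +max_shift]` maximising the number of matching positions
#' in the overlap is chosen (ties broken towards the smallest absolute
#' offset, then the negative one).  End edits are modelled as offsets, not
#' gaps, because gapped alignments are discarded upstream.
#'
#' @param isomir_seq candidate isomiR sequence
#' @param ref_seq reference mature miRNA sequence
#' @param max_shift maximum |offset| searched (default 6)
#' @return list with `offset_5p` (isomiR start minus reference start, in
#'   nt: negative means 5' addition), `offset_3p` (isomiR end minus
#'   reference end: positive means 3' addition),
#'   `internal_mismatch_positions` (0-based reference coordinates of
#'   mismatches not contiguous with either end of the overlap),
#'   `five_run`/`three_run` (lengths of terminal mismatch runs at the two
#'   overlap ends) and `mismatch_positions_iso` (0-based isomiR
#'   coordinates of all overlap mismatches)
#' @examples
#' anchorAlign("GTACGTACGTACGTACGTAC", "ACGTACGTACGTACGTACGTAC")
#' @export
anchorAlign <- function(isomir_seq, ref_seq, max_shift = 6L) {
    isomir_seq <- normalize_seq(isomir_seq)
    ref_seq <- normalize_seq(ref_seq)
    if (nchar(isomir_seq) < 10L || nchar(ref_seq) < 10L)
        stop("sequences must be at least 10 nt long for anchoring")
    iso <- utf8ToInt(isomir_seq)
    ref <- utf8ToInt(ref_seq)
    Li <- length(iso); Lr <- length(ref)
    offsets <- seq(-max_shift, max_shift)
    ## order encodes the tie-break: more matches first, then smaller |o|,
    ## then the negative of the pair
    offsets <- offsets[order(abs(offsets), offsets)]
    best_o <- NA_integer_; best_matches <- -1L; best_ov <- 0L
    for (o in offsets) {
        r0 <- max(0L, o); r1 <- min(Lr, o + Li)   # ref coords, half-open
        if (r1 - r0 < 1L) next
        ri <- (r0 + 1L):r1
        ii <- ri - o
        nm <- sum(iso[ii] == ref[ri])
        if (nm > best_matches) {
            best_matches <- nm; best_o <- o; best_ov <- r1 - r0
        }
    }
    if (is.na(best_o) || best_matches < 0.5 * best_ov)
        stop("unclassifiable: no anchoring offset reaches 50% identity ",
             "in the overlap")
    o <- best_o
    r0 <- max(0L, o); r1 <- min(Lr, o + Li)
    ri <- (r0 + 1L):r1
    mism <- which(iso[ri - o] != ref[ri])          # 1-based within overlap
    ov_len <- r1 - r0
    five_run <- 0L
    while (five_run < length(mism) && (five_run + 1L) %in% mism &&
           mism[five_run + 1L] == five_run + 1L)
        five_run <- five_run + 1L
    three_run <- 0L
    while (three_run < length(mism) &&
           (ov_len - three_run) %in% mism)
        three_run <- three_run + 1L
    if (five_run + three_run > length(mism)) {     # fully mismatched overlap
        five_run <- length(mism); three_run <- 0L
    }
    internal <- mism[mism > five_run & mism <= ov_len - three_run]
    list(offset_5p = o,
         offset_3p = (o + Li) - Lr,
         internal_mismatch_positions = r0 + internal - 1L,
         five_run = five_run,
         three_run = three_run,
         mismatch_positions_iso = (r0 + mism - 1L) - o)
}

#' Classify an isomiR into the eight canonical types
#'
#' Types: `5p_add`/`5p_del`/`5p_rep` (5' addition, deletion, terminal
#' replacement), the symmetric `3p_*` types, `SNP` (exactly one internal
#' mismatch) and `MNP` (two or more).  An isomiR may belong to several
#' types; an exact copy of the reference belongs to none.
#'
#' @inheritParams anchorAlign
#' @return character vector of type labels (subset of [ISOMIR_TYPES]),
#'   empty for an exact match
#' @examples
#' classifyIsomir("GTACGTACGTACGTACGTAC", "ACGTACGTACGTACGTACGTAC") # 5p_del
#' @export
classifyIsomir <- function(isomir_seq, ref_seq, max_shift = 6L) {
    isomir_seq <- normalize_seq(isomir_seq)
    ref_seq <- normalize_seq(ref_seq)
    if (identical(isomir_seq, ref_seq)) return(character(0))
    a <- anchorAlign(isomir_seq, ref_seq, max_shift)
    types <- character(0)
    if (a$offset_5p < 0L) types <- c(types, "5p_add")
    if (a$offset_5p > 0L) types <- c(types, "5p_del")
    if (a$offset_5p == 0L && a$five_run > 0L) types <- c(types, "5p_rep")
    if (a$offset_3p > 0L) types <- c(types, "3p_add")
    if (a$offset_3p < 0L) types <- c(types, "3p_del")
    if (a$offset_3p == 0L && a$three_run > 0L) types <- c(types, "3p_rep")
    n_int <- length(a$internal_mismatch_positions)
    if (n_int == 1L) types <- c(types, "SNP")
    if (n_int >= 2L) types <- c(types, "MNP")
    ISOMIR_TYPES[ISOMIR_TYPES %in% types]
}

#' Per-miRNA isomiR type-enrichment test
#'
#' One-sided binomial test of whether a type occurs more often among a
#' miRNA's isomiR interactions than expected: for each (miRNA, type) with
#' observed count `k` out of `n` interactions and expected probability
#' `p`, `p_raw = P(X >= k)` for `X ~ Binomial(n, p)`.  P-values are
#' corrected over all tests performed (Bonferroni by default) and a type
#' is called enriched when the corrected p-value is below `alpha`.
#'
#' The expected probability of each type defaults to its pooled frequency
#' across all miRNAs in the input; `background = "uniform"` uses 1/8, or a
#' named numeric vector supplies explicit per-type probabilities.
#'
#' @param counts data.frame with columns `mirna_id`, `type`, `observed`
#'   and `total` (the miRNA's total isomiR interactions)
#' @param background `NULL` (pooled), `"uniform"`, or a named numeric
#'   vector of expected probabilities per type
#' @param alpha significance level on the corrected p-value (default 0.01)
#' @param correction multiple-testing method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`)
#' @return data.frame: mirna_id, type, observed, total, expected_prob,
#'   p_raw, p_corrected, significant
#' @export
typeEnrichment <- function(counts, background = NULL, alpha = 0.01,
                           correction = "bonferroni") {
    needed <- c("mirna_id", "type", "observed", "total")
    if (!all(needed %in% names(counts)))
        stop("counts must have columns ", paste(needed, collapse = ", "))
    if (any(counts$observed > counts$total))
        stop("data error: observed count exceeds the miRNA's total")
    if (any(counts$total < 1L))
        stop("each miRNA must have at least one interaction")
    if (is.null(background)) {
        per_mirna_total <- tapply(counts$total, counts$mirna_id,
                                  function(x) x[1])
        grand_total <- sum(per_mirna_total)
        background <- tapply(counts$observed, counts$type, sum) / grand_total
        background <- setNames(as.numeric(background), names(background))
    } else if (identical(background, "uniform")) {
        background <- setNames(rep(1 / 8, length(ISOMIR_TYPES)),
                               ISOMIR_TYPES)
    }
    p <- background[counts$type]
    if (anyNA(p))
        stop("no background probability for type(s): ",
             paste(unique(counts$type[is.na(p)]), collapse = ", "))
    p <- pmin(pmax(as.numeric(p), 0), 1)
    p_raw <- pbinom(counts$observed - 1L, counts$total, p,
                    lower.tail = FALSE)
    p_corrected <- pmin(p.adjust(p_raw, method = correction), 1)
    data.frame(mirna_id = counts$mirna_id, type = counts$type,
               observed = counts$observed, total = counts$total,
               expected_prob = p, p_raw = p_raw,
               p_corrected = p_corrected,
               significant = p_corrected < alpha,
               stringsAsFactors = FALSE)
}

#' Tabulate isomiR type counts for enrichment testing
#'
#' @param calls data.frame with `mirna_id` and `types` (semicolon-joined
#'   type labels per interaction; empty string for exact miRNAs, which are
#'   excluded)
#' @return data.frame in the shape [typeEnrichment()] expects
#' @export
isomirTypeCounts <- function(calls) {
    calls <- calls[nzchar(calls$types), , drop = FALSE]
    if (!nrow(calls))
        return(data.frame(mirna_id = character(0), type = character(0),
                          observed = integer(0), total = integer(0)))
    totals <- table(calls$mirna_id)
    rows <- list()
    for (mid in names(totals)) {
        tys <- unlist(strsplit(calls$types[calls$mirna_id == mid], ";",
                               fixed = TRUE))
        tab <- table(tys)
        rows[[mid]] <- data.frame(mirna_id = mid, type = names(tab),
                                  observed = as.integer(tab),
                                  total = as.integer(totals[[mid]]),
                                  stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Probability of recurrent sequencing-error support
#'
#' Chance that one specific single-error variant of a miRNA read is
#' observed at least `threshold` times among `n_reads` reads, used to
#' justify the read-support cut-off: a specific erroneous sequence arises
#' from a read with probability
#' `p = error_rate * (1 - error_rate)^(read_len - 1)` (an error at one
#' given position, no errors elsewhere), and the tail
#' `P(X >= threshold)` for `X ~ Binomial(n_reads, p)` is evaluated
#' exactly.  At the historical defaults (1000 reads, 22 nt, error rate
#' 0.001, threshold 10) this is about 8.9e-08.
#'
#' @param n_reads number of reads mapped to the miRNA
#' @param read_len miRNA length in nt
#' @param error_rate per-base sequencing error probability, in [0, 1)
#' @param threshold minimum number of identical erroneous reads
#' @return the tail probability (0 when `threshold > n_reads`)
#' @examples
#' supportProbability(1000, 22, 0.001, 10)
#' @export
supportProbability <- function(n_reads, read_len, error_rate, threshold) {
    if (error_rate < 0 || error_rate >= 1)
        stop("error_rate must lie in [0, 1)")
    if (n_reads < 0 || read_len < 1)
        stop("n_reads and read_len must be positive")
    if (threshold > n_reads) return(0)
    if (threshold <= 0) return(1)
    p_read <- error_rate * (1 - error_rate)^(read_len - 1)
    pbinom(threshold - 1, n_reads, p_read, lower.tail = FALSE)
}
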