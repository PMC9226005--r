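## Shared test helpers: tiny deterministic sequences and configs.

rand_seq <- function(n, seed = 1) {
    set.seed(seed)
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## a small but non-degenerate network config for fast tests
tiny_model_config <- function(...) {
    ModelConfig(mirna_len = 12L, site_len = 16L, n_kernels = 3L,
                kernel_len = 4L, pool_size = 2L, lstm_units = 2L,
                dense_units = 5L, dropout_merge = 0, dropout_lstm = 0,
                dropout_dense = 0, batch_size = 8L, ...)
}

## deterministic separable toy pairs: positives carry the reverse
## complement of smallRNA[2:7] inside the site, negatives are random
toy_pairs <- function(n_per_class, mirna_len = 12, site_len = 16,
                      seed = 1) {
    set.seed(seed)
    rows <- list()
    for (i in seq_len(n_per_class)) {
        m <- paste0(sample(c("A", "C", "G", "T"), mirna_len, TRUE),
                    collapse = "")
        planted <- isomiRTarget:::revcomp(substr(m, 2, 7))
        flank1 <- paste0(sample(c("A", "C", "G", "T"), 5, TRUE),
                         collapse = "")
        flank2 <- paste0(sample(c("A", "C", "G", "T"),
                                site_len - 5 - 6, TRUE), collapse = "")
        rows[[2 * i - 1]] <- data.frame(
            small_rna_seq = m, site_seq = paste0(flank1, planted, flank2),
            label = 1L, stringsAsFactors = FALSE)
        rows[[2 * i]] <- data.frame(
            small_rna_seq = m,
            site_seq = paste0(sample(c("A", "C", "G", "T"), site_len,
                                     TRUE), collapse = ""),
            label = 0L, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}
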