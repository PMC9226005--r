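## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

## Run `expr` under a fixed RNG state without clobbering the caller's.
with_seed <- function(seed, expr) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a stream-specific child seed from a global one; stays below 2^31.
derive_seed <- function(seed, stream) {
    offsets <- c(simulate = 101L, pipeline = 211L, dataset = 307L,
                 model = 401L, interpret = 503L, evaluate = 601L,
                 split = 701L)
    off <- offsets[[stream]]
    (as.integer(seed) * 1103L + off) %% 2147483647L
}

## Normalise an RNA/DNA string to upper-case DNA letters (U -> T).
normalize_seq <- function(x) {
    chartr("acgtun", "ACGTTN", chartr("U", "T", toupper(x)))
}

## Vectorised reverse complement on plain character strings.
revcomp <- function(x) {
    comp <- chartr("ACGTN", "TGCAN", normalize_seq(x))
    vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
           USE.NAMES = FALSE)
}

## Random DNA string(s) of the given length(s).
random_dna <- function(n, len) {
    len <- rep_len(len, n)
    vapply(len, function(L) paste0(sample(BASES, L, replace = TRUE),
                                   collapse = ""), character(1))
}

## sample() without the scalar-x surprise.
resample <- function(x, size = length(x), replace = FALSE) {
    x[sample.int(length(x), size, replace = replace)]
}

## Split a string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Phred+33 encoding helpers.
phred_to_char <- function(q) {
    vapply(q, function(qq) intToUtf8(qq + 33L), character(1), USE.NAMES = FALSE)
}
phred_string <- function(q) intToUtf8(q + 33L, multiple = FALSE)
char_to_phred <- function(s) utf8ToInt(s) - 33L
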