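#' @import methods
#' @importFrom stats pbinom p.adjust rbinom runif rnorm setNames var cor
#'   hclust as.dist cutree
#' @importFrom utils head tail read.table write.table
NULL

## ---------------------------------------------------------------------------
## Configuration classes
## ---------------------------------------------------------------------------

#' Simulation settings for the synthetic-data generator
#'
#' Controls the synthetic references (miRNAs and transcripts with annotated
#' 3'UTRs), the planted target sites, and the chimeric read simulator.
#'
#' @slot n_mirnas number of distinct mature miRNA reference sequences.
#' @slot mirna_len_range integer (min, max) miRNA length in nt.
#' @slot n_transcripts number of transcripts; each transcript receives one
#'   planted target site inside its 3'UTR.
#' @slot transcript_len_range integer (min, max) transcript length in nt.
#' @slot reads_per_pair chimeric read copies emitted per interaction pair,
#'   so read-support filters can be exercised.
#' @slot base_error_rate per-base substitution error probability
#'   (Illumina-like default 0.001).
#' @slot high_q,low_q Phred scores assigned to error-free and erroneous
#'   bases respectively (defaults 40 / 20, bracketing the quality-30 filter).
#' @slot utr_fraction fraction of each transcript annotated as 3'UTR
#'   (occupying the transcript's 3' end).
#' @slot site_model `"seed_complement_only"` plants the reverse complement
#'   of miRNA positions 2-7; `"seed_plus_3prime"` additionally plants the
#'   reverse complement of positions 10-16.
#' @slot isomir_fraction fraction of interaction pairs whose small RNA is an
#'   isomiR variant rather than the exact miRNA.
#' @slot mirna_first if `TRUE` (the chimera convention) reads are laid out
#'   miRNA portion, spacer, target portion; `FALSE` reverses the order.
#' @slot seed integer seed fixing all randomness.
#' @export
setClass("SimulationConfig", representation(
    n_mirnas = "integer",
    mirna_len_range = "integer",
    n_transcripts = "integer",
    transcript_len_range = "integer",
    reads_per_pair = "integer",
    base_error_rate = "numeric",
    high_q = "integer",
    low_q = "integer",
    utr_fraction = "numeric",
    site_model = "character",
    isomir_fraction = "numeric",
    mirna_first = "logical",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (object@n_mirnas < 1L) msg <- c(msg, "n_mirnas must be >= 1")
    if (object@n_transcripts < 1L) msg <- c(msg, "n_transcripts must be >= 1")
    if (object@reads_per_pair < 1L) msg <- c(msg, "reads_per_pair must be >= 1")
    if (length(object@mirna_len_range) != 2L ||
        diff(object@mirna_len_range) < 0L)
        msg <- c(msg, "mirna_len_range must be (min, max) with min <= max")
    if (length(object@transcript_len_range) != 2L ||
        diff(object@transcript_len_range) < 0L)
        msg <- c(msg, "transcript_len_range must be (min, max) with min <= max")
    if (object@base_error_rate < 0 || object@base_error_rate >= 1)
        msg <- c(msg, "base_error_rate must lie in [0, 1)")
    if (object@utr_fraction <= 0 || object@utr_fraction > 1)
        msg <- c(msg, "utr_fraction must lie in (0, 1]")
    if (!object@site_model %in% c("seed_complement_only", "seed_plus_3prime"))
        msg <- c(msg, "unknown site_model")
    if (object@isomir_fraction < 0 || object@isomir_fraction > 1)
        msg <- c(msg, "isomir_fraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a [SimulationConfig-class]
#'
#' @param n_mirnas,mirna_len_range,n_transcripts,transcript_len_range
#'   reference-set dimensions; see the class documentation.
#' @param reads_per_pair,base_error_rate,high_q,low_q read simulator settings.
#' @param utr_fraction,site_model,isomir_fraction,mirna_first layout settings.
#' @param seed integer seed fixing all randomness.
#' @return a validated `SimulationConfig` object.
#' @examples
#' cfg <- SimulationConfig(n_mirnas = 2, seed = 1)
#' @export
SimulationConfig <- function(n_mirnas = 12L,
                             mirna_len_range = c(20L, 24L),
                             n_transcripts = 24L,
                             transcript_len_range = c(400L, 600L),
                             reads_per_pair = 12L,
                             base_error_rate = 0.001,
                             high_q = 40L,
                             low_q = 20L,
                             utr_fraction = 0.4,
                             site_model = "seed_complement_only",
                             isomir_fraction = 0.5,
                             mirna_first = TRUE,
                             seed = 1L) {
    new("SimulationConfig",
        n_mirnas = as.integer(n_mirnas),
        mirna_len_range = as.integer(mirna_len_range),
        n_transcripts = as.integer(n_transcripts),
        transcript_len_range = as.integer(transcript_len_range),
        reads_per_pair = as.integer(reads_per_pair),
        base_error_rate = as.numeric(base_error_rate),
        high_q = as.integer(high_q),
        low_q = as.integer(low_q),
        utr_fraction = as.numeric(utr_fraction),
        site_model = site_model,
        isomir_fraction = as.numeric(isomir_fraction),
        mirna_first = isTRUE(mirna_first),
        seed = as.integer(seed))
}

#' Chimera-pipeline thresholds
#'
#' Filtering thresholds for turning alignment hits on chimeric reads into
#' supported interaction calls.
#'
#' @slot max_evalue retain alignment hits with e-value at or below this
#'   bound (default 0.1).
#' @slot min_support_reads a small-RNA portion sequence must be seen in at
#'   least this many chimeric reads (duplicate-multiplicity weighted) for
#'   its calls to survive (default 10).
#' @slot max_gap maximum spacer, in nt, between the miRNA portion and the
#'   mRNA portion of a chimeric read (default 4).
#' @slot max_overlap maximum tolerated overlap between the two portions
#'   (default 0: portions must be disjoint).
#' @slot min_variant_quality Phred threshold for isomiR variant positions;
#'   the call requires quality strictly greater than this (default 30).
#' @slot top_k_pairs how many best-ranked (miRNA, transcript) pairs to keep
#'   per read (default 1; 5 mirrors a top-five sensitivity variant).
#' @slot require_mirna_first only accept chimeras whose miRNA portion lies
#'   5' of the mRNA portion in the read.
#' @export
setClass("PipelineConfig", representation(
    max_evalue = "numeric",
    min_support_reads = "integer",
    max_gap = "integer",
    max_overlap = "integer",
    min_variant_quality = "numeric",
    top_k_pairs = "integer",
    require_mirna_first = "logical"
))

setValidity("PipelineConfig", function(object) {
    msg <- character(0)
    if (object@max_evalue <= 0) msg <- c(msg, "max_evalue must be positive")
    if (object@min_support_reads < 1L)
        msg <- c(msg, "min_support_reads must be >= 1")
    if (object@max_gap < 0L) msg <- c(msg, "max_gap must be >= 0")
    if (object@max_overlap < 0L) msg <- c(msg, "max_overlap must be >= 0")
    if (object@min_variant_quality <= 0)
        msg <- c(msg, "min_variant_quality must be positive")
    if (object@top_k_pairs < 1L) msg <- c(msg, "top_k_pairs must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a [PipelineConfig-class]
#'
#' @param max_evalue,min_support_reads,max_gap,max_overlap threshold values;
#'   see the class documentation.
#' @param min_variant_quality,top_k_pairs,require_mirna_first see the class
#'   documentation.
#' @return a validated `PipelineConfig` object.
#' @examples
#' PipelineConfig(min_support_reads = 5)
#' @export
PipelineConfig <- function(max_evalue = 0.1,
                           min_support_reads = 10L,
                           max_gap = 4L,
                           max_overlap = 0L,
                           min_variant_quality = 30,
                           top_k_pairs = 1L,
                           require_mirna_first = TRUE) {
    new("PipelineConfig",
        max_evalue = as.numeric(max_evalue),
        min_support_reads = as.integer(min_support_reads),
        max_gap = as.integer(max_gap),
        max_overlap = as.integer(max_overlap),
        min_variant_quality = as.numeric(min_variant_quality),
        top_k_pairs = as.integer(top_k_pairs),
        require_mirna_first = isTRUE(require_mirna_first))
}

#' Negative-site sampling settings
#'
#' @slot min_distance minimum distance, in nt, between a sampled negative
#'   site and every positive site on the transcript (default 10).
#' @slot energy_threshold duplex energy threshold in kcal/mol (default 10).
#' @slot energy_mode `"less_than"` accepts candidates with energy strictly
#'   below `energy_threshold` (the permissive reading of the printed
#'   criterion); `"greater_than"` accepts energies above it, for users who
#'   read the criterion as excluding stably pairing sites.
#' @slot energy_backend `"builtin_proxy"` (documented pairing-strength
#'   proxy) or `"external_cofold"` (shells out to an RNAcofold-compatible
#'   executable).
#' @slot max_attempts candidate starts examined before giving up.
#' @export
setClass("NegativeConfig", representation(
    min_distance = "integer",
    energy_threshold = "numeric",
    energy_mode = "character",
    energy_backend = "character",
    max_attempts = "integer"
))

setValidity("NegativeConfig", function(object) {
    msg <- character(0)
    if (object@min_distance < 0L) msg <- c(msg, "min_distance must be >= 0")
    if (object@max_attempts < 1L) msg <- c(msg, "max_attempts must be >= 1")
    if (!object@energy_mode %in% c("less_than", "greater_than"))
        msg <- c(msg, "energy_mode must be 'less_than' or 'greater_than'")
    if (!object@energy_backend %in% c("builtin_proxy", "external_cofold"))
        msg <- c(msg, "unknown energy_backend")
    if (length(msg)) msg else TRUE
})

#' Construct a [NegativeConfig-class]
#'
#' @param min_distance,energy_threshold,energy_mode,energy_backend,max_attempts
#'   see the class documentation.
#' @return a validated `NegativeConfig` object.
#' @examples
#' NegativeConfig()
#' @export
NegativeConfig <- function(min_distance = 10L,
                           energy_threshold = 10,
                           energy_mode = "less_than",
                           energy_backend = "builtin_proxy",
                           max_attempts = 200L) {
    new("NegativeConfig",
        min_distance = as.integer(min_distance),
        energy_threshold = as.numeric(energy_threshold),
        energy_mode = energy_mode,
        energy_backend = energy_backend,
        max_attempts = as.integer(max_attempts))
}

#' Network architecture and training hyperparameters
#'
#' Defaults reproduce the reference two-branch architecture: 4 x 30 and
#' 4 x 60 one-hot inputs, 10 convolutional kernels of size 4 x 8 per branch
#' (valid padding, stride 1), max pooling of size 4 with stride 1, merge
#' along the position axis, a bidirectional LSTM with 10 units per
#' direction returning per-position states, a 100-unit rectified dense
#' layer and one sigmoid output.
#'
#' @slot mirna_len,site_len fixed one-hot input lengths (nt).
#' @slot n_kernels,kernel_len convolution kernels per branch and their width.
#' @slot pool_size,conv_stride,pool_stride pooling window and strides.
#' @slot lstm_units LSTM units per direction.
#' @slot dense_units width of the fully connected layer.
#' @slot dropout_merge,dropout_lstm,dropout_dense dropout rates after the
#'   branch merge, the BLSTM, and the dense layer.
#' @slot l1_penalty L1 regularisation weight on convolutional kernels and
#'   the dense weight matrix (not biases).
#' @slot learning_rate,batch_size,epochs Adam step size, mini-batch size and
#'   training epochs.
#' @slot decision_threshold probability cut-off for the binary label.
#' @slot batchnorm_after_conv optional batch normalisation after each
#'   convolution (off by default).
#' @slot seed integer seed for weight initialisation, shuffling and dropout.
#' @export
setClass("ModelConfig", representation(
    mirna_len = "integer",
    site_len = "integer",
    n_kernels = "integer",
    kernel_len = "integer",
    pool_size = "integer",
    conv_stride = "integer",
    pool_stride = "integer",
    lstm_units = "integer",
    dense_units = "integer",
    dropout_merge = "numeric",
    dropout_lstm = "numeric",
    dropout_dense = "numeric",
    l1_penalty = "numeric",
    learning_rate = "numeric",
    batch_size = "integer",
    epochs = "integer",
    decision_threshold = "numeric",
    batchnorm_after_conv = "logical",
    seed = "integer"
))

setValidity("ModelConfig", function(object) {
    msg <- character(0)
    if (object@mirna_len < object@kernel_len ||
        object@site_len < object@kernel_len)
        msg <- c(msg, "input lengths must be >= kernel_len")
    rates <- c(object@dropout_merge, object@dropout_lstm, object@dropout_dense)
    if (any(rates < 0 | rates >= 1))
        msg <- c(msg, "dropout rates must lie in [0, 1)")
    if (object@conv_stride != 1L || object@pool_stride != 1L)
        msg <- c(msg, "only stride 1 is supported (as in the reference design)")
    conv_m <- object@mirna_len - object@kernel_len + 1L
    conv_s <- object@site_len - object@kernel_len + 1L
    if (object@pool_size > min(conv_m, conv_s))
        msg <- c(msg, "pool_size exceeds post-convolution width")
    if (object@n_kernels < 1L || object@lstm_units < 1L ||
        object@dense_units < 1L)
        msg <- c(msg, "layer sizes must be >= 1")
    if (object@learning_rate <= 0) msg <- c(msg, "learning_rate must be > 0")
    if (object@batch_size < 1L) msg <- c(msg, "batch_size must be >= 1")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a [ModelConfig-class]
#'
#' @param mirna_len,site_len,n_kernels,kernel_len,pool_size architecture
#'   dimensions; see the class documentation.
#' @param conv_stride,pool_stride,lstm_units,dense_units architecture
#'   dimensions continued.
#' @param dropout_merge,dropout_lstm,dropout_dense,l1_penalty regularisation.
#' @param learning_rate,batch_size,epochs,decision_threshold training.
#' @param batchnorm_after_conv,seed options.
#' @return a validated `ModelConfig` object.
#' @examples
#' ModelConfig(epochs = 20)
#' @export
ModelConfig <- function(mirna_len = 30L, site_len = 60L,
                        n_kernels = 10L, kernel_len = 8L,
                        pool_size = 4L, conv_stride = 1L, pool_stride = 1L,
                        lstm_units = 10L, dense_units = 100L,
                        dropout_merge = 0.25, dropout_lstm = 0.50,
                        dropout_dense = 0.50, l1_penalty = 0.01,
                        learning_rate = 0.001, batch_size = 100L,
                        epochs = 500L, decision_threshold = 0.5,
                        batchnorm_after_conv = FALSE, seed = 1L) {
    new("ModelConfig",
        mirna_len = as.integer(mirna_len), site_len = as.integer(site_len),
        n_kernels = as.integer(n_kernels),
        kernel_len = as.integer(kernel_len),
        pool_size = as.integer(pool_size),
        conv_stride = as.integer(conv_stride),
        pool_stride = as.integer(pool_stride),
        lstm_units = as.integer(lstm_units),
        dense_units = as.integer(dense_units),
        dropout_merge = as.numeric(dropout_merge),
        dropout_lstm = as.numeric(dropout_lstm),
        dropout_dense = as.numeric(dropout_dense),
        l1_penalty = as.numeric(l1_penalty),
        learning_rate = as.numeric(learning_rate),
        batch_size = as.integer(batch_size),
        epochs = as.integer(epochs),
        decision_threshold = as.numeric(decision_threshold),
        batchnorm_after_conv = isTRUE(batchnorm_after_conv),
        seed = as.integer(seed))
}

#' Trained (or initialised) interaction classifier
#'
#' Holds the architecture configuration, the parameter list, the per-epoch
#' training-loss history and a format version stamp used by
#' [saveModel()]/[loadModel()].
#'
#' @slot config the [ModelConfig-class] the network was built with.
#' @slot weights named list of parameter matrices/vectors.
#' @slot trained `TRUE` once [trainModel()] has run.
#' @slot history numeric vector of per-epoch mean training losses.
#' @slot version serialisation format stamp.
#' @export
setClass("TargetNet", representation(
    config = "ModelConfig",
    weights = "list",
    trained = "logical",
    history = "numeric",
    version = "character"
))

#' @describeIn SimulationConfig-class compact display
#' @param object a configuration object
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@n_mirnas, "miRNAs,",
        object@n_transcripts, "transcripts,",
        object@reads_per_pair, "reads/pair, error rate",
        object@base_error_rate, "\n")
})

#' @describeIn PipelineConfig-class compact display
#' @param object a configuration object
#' @export
setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig: e-value <=", object@max_evalue,
        "| support >=", object@min_support_reads,
        "| gap <=", object@max_gap,
        "| variant quality >", object@min_variant_quality, "\n")
})

#' @describeIn TargetNet-class compact display
#' @param object a `TargetNet`
#' @export
setMethod("show", "TargetNet", function(object) {
    cfg <- object@config
    cat("TargetNet (two-branch CNN + BLSTM classifier)\n",
        " inputs: 4 x ", cfg@mirna_len, " (small RNA), 4 x ", cfg@site_len,
        " (target site)\n",
        " kernels: ", cfg@n_kernels, " x (4 x ", cfg@kernel_len,
        ") per branch; BLSTM ", cfg@lstm_units,
        " units/direction; dense ", cfg@dense_units, "\n",
        " trained: ", object@trained,
        if (length(object@history))
            paste0(" (", length(object@history), " epochs, final loss ",
                   signif(tail(object@history, 1L), 4), ")") else "",
        "\n", sep = "")
})

#' Architecture configuration of a model
#' @param object a [TargetNet-class]
#' @return the embedded [ModelConfig-class]
#' @export
modelConfig <- function(object) {
    stopifnot(is(object, "TargetNet"))
    object@config
}

#' Per-epoch training loss history
#' @param object a [TargetNet-class]
#' @return numeric vector, one mean training loss per epoch
#' @export
lossHistory <- function(object) {
    stopifnot(is(object, "TargetNet"))
    object@history
}

#' Has the model been trained?
#' @param object a [TargetNet-class]
#' @return logical
#' @export
isTrained <- function(object) {
    stopifnot(is(object, "TargetNet"))
    object@trained
}
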