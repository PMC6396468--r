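#' The six scoring-module kinds
#'
#' The framework composes five scored regions (donor, acceptor, exon, 5'
#' intron, 3' intron) from six trained modules: the exon and intron networks
#' are each trained with two output heads (one per MPRA-style library) and
#' split afterwards, giving `exon5p`/`exon3p` and `intron5p`/`intron3p`.
#'
#' @return Character vector of the six module kinds.
#' @export
module_kinds <- function() {
  c("donor", "acceptor", "exon5p", "exon3p", "intron5p", "intron3p")
}

# input-length contracts; NA = variable length
module_input_length <- function(kind, windows = window_spec()) {
  switch(kind,
    donor = windows$donor_exonic + windows$donor_intronic,
    acceptor = windows$acceptor_intronic + windows$acceptor_exonic,
    exon5p = , exon3p = , intron5p = , intron3p = ,
    exon_pair = , intron_pair = NA_integer_,
    stop("unknown module kind: ", kind)
  )
}

#' Build an untrained scoring module
#'
#' Architectures:
#' * `donor` — multilayer perceptron on the flattened one-hot 18-nt window:
#'   two ReLU hidden layers, each with batch normalization and dropout 0.2,
#'   and a single sigmoid output (applied in the loss; the module's score is
#'   the pre-activation).
#' * `acceptor` — convolutional network on the 53-nt window: 32 filters of
#'   width 15 (valid padding), then 32 width-1 filters with batch
#'   normalization and dropout 0.2, flatten, dense output.
#' * `exon_pair` / `intron_pair` — one shared convolution layer (128 or 256
#'   filters of width 15, same padding) with ReLU, global average pooling,
#'   and a dense layer with two heads; trained jointly, then split with
#'   [split_heads()] into `exon5p`/`exon3p` (`intron5p`/`intron3p`). Global
#'   pooling makes these modules accept sequences of any length.
#' * `exon5p`, `exon3p`, `intron5p`, `intron3p` — the single-head version of
#'   the above (mostly useful for direct experimentation).
#'
#' @param kind One of [module_kinds()], `"exon_pair"`, or `"intron_pair"`.
#' @param hyperparams Named list; recognised entries `hidden` (donor, two
#'   hidden sizes, default `c(64, 32)`), `filters` (conv kinds; defaults 32
#'   for acceptor, 128 for exon, 256 for intron), `kernel` (default 15),
#'   `dropout` (default 0.2).
#' @param seed Integer seed for weight initialization.
#' @param windows A [window_spec()] fixing the splice-site input lengths.
#' @return An `ss_module` (untrained).
#' @export
build_module <- function(kind, hyperparams = list(), seed = 1L,
                         windows = window_spec()) {
  hp <- utils::modifyList(list(hidden = c(64L, 32L), kernel = 15L,
                               dropout = 0.2), hyperparams)
  if (any(unlist(hp[c("hidden", "kernel")]) <= 0)) {
    stop("layer sizes must be positive")
  }
  set.seed(seed)
  layers <- switch(kind,
    donor = {
      din <- 4L * module_input_length("donor", windows)
      h <- hp$hidden
      list(layer_dense(din, h[1]), layer_batchnorm(h[1]), layer_relu(),
           layer_dropout(hp$dropout),
           layer_dense(h[1], h[2]), layer_batchnorm(h[2]), layer_relu(),
           layer_dropout(hp$dropout),
           layer_dense(h[2], 1L))
    },
    acceptor = {
      len <- module_input_length("acceptor", windows)
      f <- hp$filters %||% 32L
      lo <- len - hp$kernel + 1L
      list(layer_conv1d(4L, f, hp$kernel, "valid"), layer_relu(),
           layer_conv1d(f, f, 1L, "valid"), layer_batchnorm(f),
           layer_relu(), layer_dropout(hp$dropout),
           layer_flatten(), layer_dense(lo * f, 1L))
    },
    exon_pair = , exon5p = , exon3p = {
      f <- hp$filters %||% 128L
      heads <- if (kind == "exon_pair") 2L else 1L
      list(layer_conv1d(4L, f, hp$kernel, "same"), layer_relu(),
           layer_gap(), layer_dense(f, heads))
    },
    intron_pair = , intron5p = , intron3p = {
      f <- hp$filters %||% 256L
      heads <- if (kind == "intron_pair") 2L else 1L
      list(layer_conv1d(4L, f, hp$kernel, "same"), layer_relu(),
           layer_gap(), layer_dense(f, heads))
    },
    stop("unknown module kind: ", kind)
  )
  net <- list(layers = layers)
  structure(list(kind = kind, net = net, windows = windows,
                 hyperparams = hp, trained = FALSE,
                 n_params = nn_count_params(net)),
            class = "ss_module")
}

#' @export
print.ss_module <- function(x, ...) {
  cat(sprintf("<ss_module> kind=%s, %d parameter(s), %s\n", x$kind,
              x$n_params, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# One-hot encode a batch of equal-length sequences into the module's input
# format: 2-D (n, 4*len) for the donor MLP, 3-D (n, len, 4) otherwise.
encode_batch <- function(kind, seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences in a batch must have equal length")
  L <- lens[1]
  X <- array(0, c(length(seqs), L, 4L))
  for (i in seq_along(seqs)) X[i, , ] <- one_hot(seqs[i])
  if (kind == "donor") {
    dim(X) <- c(length(seqs), L * 4L)
  }
  X
}

check_input_length <- function(module, len) {
  want <- module_input_length(module$kind, module$windows)
  if (!is.na(want) && len != want) {
    stop(sprintf("%s module expects %d-nt input, got %d", module$kind, want, len))
  }
}

#' Score a sequence with a module
#'
#' Returns the module's pre-activation score `S`; `sigmoid(S)` is the
#' module's probability / PSI prediction. Inference is deterministic
#' (dropout disabled, batch-norm running statistics). Fixed-length modules
#' (donor 18 nt, acceptor 53 nt) reject other lengths — upstream
#' [split_region()] pads short exons/flanks with `N`. Variable-length
#' modules accept any length of at least 1; the empty string (an absent
#' intronic flank) scores 0 by convention so that its delta is 0.
#'
#' @param module An `ss_module`.
#' @param sequence Nucleotide string, or character vector of equal-length
#'   strings for batched scoring.
#' @return Numeric vector of scores.
#' @export
score_sequence <- function(module, sequence) {
  stopifnot(inherits(module, "ss_module"))
  if (length(sequence) == 0L) return(numeric(0))
  if (length(sequence) == 1L && nchar(sequence) == 0L) return(0)
  check_input_length(module, nchar(sequence[1]))
  X <- encode_batch(module$kind, sequence)
  out <- nn_forward(module$net, X)$out
  if (ncol(out) != 1L) stop("module has multiple heads; split with split_heads() first")
  as.vector(out)
}

#' Split a two-headed exon/intron network into two scoring modules
#'
#' The exon (intron) network is trained with two output heads sharing one
#' convolution layer; after training each head becomes its own module. The
#' shared convolution weights are identical between the two resulting
#' modules.
#'
#' @param module A trained `exon_pair` or `intron_pair` module.
#' @return Named list of two `ss_module`s (`exon5p`/`exon3p` or
#'   `intron5p`/`intron3p`).
#' @export
split_heads <- function(module) {
  stopifnot(inherits(module, "ss_module"),
            module$kind %in% c("exon_pair", "intron_pair"))
  kinds <- if (module$kind == "exon_pair") c("exon5p", "exon3p")
           else c("intron5p", "intron3p")
  out <- lapply(1:2, function(h) {
    m <- module
    m$kind <- kinds[h]
    last <- length(m$net$layers)
    W <- m$net$layers[[last]]$params$W
    b <- m$net$layers[[last]]$params$b
    m$net$layers[[last]]$params$W <- W[, h, drop = FALSE]
    m$net$layers[[last]]$params$b <- b[h]
    m$n_params <- nn_count_params(m$net)
    m
  })
  names(out) <- kinds
  out
}

#' Train a scoring module
#'
#' Minimises the binary cross-entropy `-(psi log psihat + (1-psi)
#' log(1-psihat))` — labels may be fractional PSI values in \[0, 1\] — with
#' the Adam optimizer on mini-batches, keeping the weights of the epoch with
#' the smallest validation loss. The dataset's `split` column defines the
#' 80/20 train/validation partition.
#'
#' @param module An `ss_module` (`exon_pair`/`intron_pair` train both heads
#'   jointly; their label matrix must then have two columns).
#' @param dataset Data frame with columns `sequence`, `label` (or `label1`,
#'   `label2` for two-headed training) and `split` (`"train"`/`"val"`), as
#'   produced by [make_splice_site_training_set()] or [generate_mpra_like()].
#' @param lr,batch_size,epochs,patience Optimizer settings (Adam lr `1e-3`,
#'   batch 64, at most 100 epochs, early stopping patience 5 on the
#'   validation loss).
#' @param seed Integer seed controlling shuffling and dropout.
#' @return The trained `ss_module`, with the per-epoch `training_log`
#'   (train/validation loss) attached.
#' @export
train_module <- function(module, dataset, lr = 1e-3, batch_size = 64L,
                         epochs = 100L, patience = 5L, seed = 1L) {
  stopifnot(inherits(module, "ss_module"), nrow(dataset) > 0L)
  heads <- ncol(module$net$layers[[length(module$net$layers)]]$params$W)
  lab_cols <- if (heads == 2L) c("label1", "label2") else "label"
  if (!all(lab_cols %in% names(dataset))) {
    stop(sprintf("module has %d head(s); dataset must provide column(s) %s",
                 heads, paste(lab_cols, collapse = ", ")))
  }
  Y <- as.matrix(dataset[, lab_cols, drop = FALSE])
  if (any(!is.finite(Y)) || any(Y < 0) || any(Y > 1)) {
    stop("labels must lie in [0, 1]")
  }
  is_val <- dataset$split == "val"
  if (!any(!is_val)) stop("empty training split")
  Xall <- encode_batch(module$kind, dataset$sequence)
  if (!any(is_val)) {                     # degenerate: validate on train
    Xtr <- Xall; Ytr <- Y; Xva <- Xall; Yva <- Y
  } else {
    Xtr <- slice_rows(Xall, which(!is_val)); Ytr <- Y[!is_val, , drop = FALSE]
    Xva <- slice_rows(Xall, which(is_val)); Yva <- Y[is_val, , drop = FALSE]
  }
  set.seed(seed)
  res <- train_network(module$net, Xtr, Ytr, Xva, Yva, lr = lr,
                       batch_size = batch_size, epochs = epochs,
                       patience = patience)
  module$net <- res$net
  module$trained <- TRUE
  module$training_log <- res$log
  module$best_val_loss <- res$best_val
  module
}

#' Build splice-site classification training data from an annotation
#'
#' Positives are the unique annotated splice-site windows of the requested
#' kind (donor: last 5 exonic + first 13 intronic nt; acceptor: last 50
#' intronic + first 3 exonic nt), in transcript orientation; non-canonical
#' sites are kept. Negatives are windows sampled at random positions within
#' the genes contributing positives, never centred on an annotated site, and
#' a fraction `canonical_frac` of them is constrained to carry the canonical
#' dinucleotide (GT for donors, AG for acceptors) at the junction.
#'
#' @param annotation An `ss_annotation`.
#' @param genome An `ss_genome`.
#' @param kind `"donor"` or `"acceptor"`.
#' @param neg_ratio Negatives per positive (default 1.5).
#' @param canonical_frac Fraction of negatives with the canonical
#'   dinucleotide (default 0.5).
#' @param seed Integer seed.
#' @param windows A [window_spec()].
#' @return Data frame with columns `sequence`, `label` (1 positive / 0
#'   negative), `split` (80/20 train/val).
#' @export
make_splice_site_training_set <- function(annotation, genome,
                                          kind = c("donor", "acceptor"),
                                          neg_ratio = 1.5,
                                          canonical_frac = 0.5, seed = 1L,
                                          windows = window_spec()) {
  kind <- match.arg(kind)
  stopifnot(canonical_frac >= 0, canonical_frac <= 1, neg_ratio >= 0)
  ex <- annotation$exons
  if (nrow(ex) == 0L) stop("annotation has no exons")
  set.seed(seed)
  # junction = genomic coordinate of the splice site, with strand. Only real
  # exon-intron junctions qualify: the transcript-last exon of a gene has no
  # donor and the transcript-first exon no acceptor.
  jx <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    plus <- d$strand[1] == "+"
    if (kind == "donor") {
      drop <- if (plus) which.max(d$end) else which.min(d$start)
      pos <- if (plus) d$end else d$start
    } else {
      drop <- if (plus) which.min(d$start) else which.max(d$end)
      pos <- if (plus) d$start else d$end
    }
    if (nrow(d) == 1L) return(NULL)
    data.frame(contig = d$contig[-drop], strand = d$strand[-drop],
               pos = pos[-drop], gene_id = d$gene_id[-drop],
               stringsAsFactors = FALSE)
  }))
  if (is.null(jx) || nrow(jx) == 0L) stop("no internal splice junctions in annotation")
  jx <- jx[!duplicated(paste(jx$contig, jx$strand, jx$pos)), , drop = FALSE]
  win <- if (kind == "donor") c(windows$donor_exonic, windows$donor_intronic)
         else c(windows$acceptor_intronic, windows$acceptor_exonic)
  canon <- if (kind == "donor") "GT" else "AG"

  # window in transcript orientation around a junction
  site_seq <- function(contig, strand, pos) {
    if (kind == "donor") {
      g <- if (strand == "+") c(pos - win[1], pos + win[2])
           else c(pos - win[2], pos + win[1])
    } else {
      g <- if (strand == "+") c(pos - win[1], pos + win[2])
           else c(pos - win[2], pos + win[1])
    }
    if (g[1] < 0 || g[2] > contig_length(genome, contig)) return(NA_character_)
    s <- get_seq(genome, contig, g[1], g[2])
    if (strand == "-") s <- revcomp(s)
    s
  }
  # the canonical dinucleotide of a window: donors GT at intron start,
  # acceptors AG at intron end
  dinuc <- function(s) {
    if (kind == "donor") substr(s, win[1] + 1L, win[1] + 2L)
    else substr(s, win[1] - 1L, win[1])
  }

  pos_seqs <- mapply(site_seq, jx$contig, jx$strand, jx$pos)
  keep <- !is.na(pos_seqs)
  pos_seqs <- unname(pos_seqs[keep])
  n_neg <- round(neg_ratio * length(pos_seqs))
  pos_key <- paste(jx$contig, jx$strand, jx$pos)[keep]

  genes <- annotation$genes[annotation$genes$gene_id %in% jx$gene_id, , drop = FALSE]
  neg_seqs <- character(0)
  want_canon <- stats::rbinom(n_neg, 1L, canonical_frac) == 1L
  guard <- 0L
  while (length(neg_seqs) < n_neg) {
    guard <- guard + 1L
    if (guard > 200L * max(n_neg, 1L)) {
      stop("could not sample enough negative sites within the genes")
    }
    g <- genes[sample.int(nrow(genes), 1L), ]
    pos <- sample(seq.int(g$start + win[1] + 2L, g$end - win[2] - 2L), 1L)
    key <- paste(g$contig, g$strand, pos)
    if (key %in% pos_key) next
    s <- site_seq(g$contig, g$strand, pos)
    if (is.na(s)) next
    need_canon <- want_canon[length(neg_seqs) + 1L]
    if ((dinuc(s) == canon) != need_canon) next
    neg_seqs <- c(neg_seqs, s)
  }
  d <- data.frame(sequence = c(pos_seqs, neg_seqs),
                  label = c(rep(1, length(pos_seqs)), rep(0, length(neg_seqs))),
                  stringsAsFactors = FALSE)
  d$split <- ifelse(stats::runif(nrow(d)) < 0.8, "train", "val")
  d[sample.int(nrow(d)), , drop = FALSE]
}

#' Seeded random hyperparameter search
#'
#' Samples `trials` configurations uniformly from a discrete search space
#' and returns the one minimising a validation loss, mirroring the selection
#' criterion of validation-loss-based tuning.
#'
#' @param space Named list; each element a vector (or list) of candidate
#'   values for that hyperparameter.
#' @param trials Number of seeded random draws (>= 1).
#' @param seed Integer seed.
#' @param eval_fn Function taking a named configuration list and returning a
#'   scalar validation loss.
#' @return List with `best` (configuration), `loss`, and the full `trace`.
#' @export
random_search <- function(space, trials, seed, eval_fn) {
  stopifnot(is.list(space), length(space) > 0L, trials >= 1L)
  if (any(vapply(space, length, integer(1)) == 0L)) stop("empty search space")
  set.seed(seed)
  configs <- lapply(seq_len(trials), function(i) {
    lapply(space, function(v) v[[sample.int(length(v), 1L)]])
  })
  losses <- vapply(configs, eval_fn, numeric(1))
  best <- which.min(losses)
  list(best = configs[[best]], loss = losses[best],
       trace = list(configs = configs, losses = losses))
}

#' Build the full set of six scoring modules
#'
#' @param hyperparams Optional named list of per-kind hyperparameter lists
#'   (names `donor`, `acceptor`, `exon`, `intron`).
#' @param seed Integer seed for weight initialization.
#' @return Named list of six untrained `ss_module`s, one per
#'   [module_kinds()] entry (exon/intron heads share initial convolution
#'   weights).
#' @export
build_module_set <- function(hyperparams = list(), seed = 1L) {
  exon <- split_heads(build_module("exon_pair", hyperparams$exon %||% list(),
                                   seed = derive_seed(seed, 3L)))
  intron <- split_heads(build_module("intron_pair", hyperparams$intron %||% list(),
                                     seed = derive_seed(seed, 4L)))
  mods <- c(list(donor = build_module("donor", hyperparams$donor %||% list(),
                                      seed = derive_seed(seed, 1L)),
                 acceptor = build_module("acceptor", hyperparams$acceptor %||% list(),
                                         seed = derive_seed(seed, 2L))),
            exon, intron)
  mods[module_kinds()]
}

#' Save / load a module set
#'
#' The archive is a single RDS file embedding both the architecture
#' specification and the weights of every module.
#'
#' @param modules Named list of `ss_module`s.
#' @param path File path.
#' @return `load_modules` returns the named module list.
#' @export
save_modules <- function(modules, path) {
  stopifnot(all(vapply(modules, inherits, logical(1), "ss_module")))
  saveRDS(modules, path)
  invisible(path)
}

#' @rdname save_modules
#' @export
load_modules <- function(path) {
  if (!file.exists(path)) stop("module archive not found: ", path)
  modules <- readRDS(path)
  stopifnot(all(vapply(modules, inherits, logical(1), "ss_module")))
  modules
}
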