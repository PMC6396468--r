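# Shared fixtures, built once per test run and memoized. Everything is
# generated in code under fixed seeds; nothing is read from disk outside
# tempdir().

.fix <- new.env(parent = emptyenv())

# small annotated genome: 10 genes x 3 exons, both strands
fixture_genome <- function() {
  if (is.null(.fix$genome)) {
    g <- generate_mini_genome(n_genes = 10L, exons_per_gene = 3L, seed = 101L)
    .fix$paths <- g
    .fix$genome <- load_genome(g$fasta)
    .fix$annotation <- load_annotation(g$gtf)
  }
  list(genome = .fix$genome, annotation = .fix$annotation, paths = .fix$paths)
}

# six lightly trained small modules: enough for finite, variable delta
# scores; quality is irrelevant for the plumbing tests that use them
tiny_modules <- function() {
  if (is.null(.fix$modules)) {
    fx <- fixture_genome()
    hp <- list(donor = list(hidden = c(8L, 4L)),
               acceptor = list(filters = 4L),
               exon = list(filters = 8L), intron = list(filters = 8L))
    mods <- build_module_set(hp, seed = 202L)
    dset <- make_splice_site_training_set(fx$annotation, fx$genome, "donor",
                                          seed = 203L)
    aset <- make_splice_site_training_set(fx$annotation, fx$genome, "acceptor",
                                          seed = 204L)
    mpra <- generate_mpra_like(300L, seed = 205L)
    mpra$label1 <- mpra$label
    mpra$label2 <- sigmoid(attr(mpra, "truth")$score * 0.5)
    mods$donor <- train_module(mods$donor, dset, epochs = 1L, seed = 1L)
    mods$acceptor <- train_module(mods$acceptor, aset, epochs = 1L, seed = 1L)
    ep <- train_module(build_module("exon_pair", hp$exon, seed = 206L),
                       mpra, epochs = 1L, seed = 1L)
    ip <- train_module(build_module("intron_pair", hp$intron, seed = 207L),
                       mpra, epochs = 1L, seed = 1L)
    mods[c("exon5p", "exon3p")] <- split_heads(ep)
    mods[c("intron5p", "intron3p")] <- split_heads(ip)
    .fix$modules <- mods
  }
  .fix$modules
}

# random feature rows of the composition design, plus a response generated
# from known coefficients
make_effect_rows <- function(n, beta = default_true_beta(), noise_sd = 0,
                             seed = 1L) {
  set.seed(seed)
  rows <- data.frame(
    dS_intron3p = stats::rnorm(n), dS_acceptor = stats::rnorm(n),
    dS_exon = stats::rnorm(n), dS_donor = stats::rnorm(n),
    dS_intron5p = stats::rnorm(n),
    ind_exon_ss = stats::rbinom(n, 1, 0.3),
    ind_intron5p_donor = stats::rbinom(n, 1, 0.2),
    ind_intron3p_acceptor = stats::rbinom(n, 1, 0.2)
  )
  X <- spliceshift:::effect_design_matrix(rows)
  rows$response <- as.vector(X %*% beta) +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  rows
}

# an SNV at 0-based genomic position pos0, alt chosen different from ref
make_snv <- function(genome, contig, pos0) {
  ref <- get_seq(genome, contig, pos0, pos0 + 1L)
  list(contig = contig, pos = pos0 + 1L, ref = ref,
       alt = setdiff(c("A", "C", "G", "T"), ref)[1])
}

# mirror an exon and a variant into the reverse-complemented genome
mirror_exon <- function(exon, contig_len) {
  list(contig = exon$contig, strand = if (exon$strand == "+") "-" else "+",
       start = contig_len - exon$end, end = contig_len - exon$start)
}

mirror_variant <- function(variant, contig_len) {
  v0 <- variant$pos - 1L
  v1 <- v0 + nchar(variant$ref)
  list(contig = variant$contig, pos = contig_len - v1 + 1L,
       ref = spliceshift:::revcomp(variant$ref),
       alt = spliceshift:::revcomp(variant$alt))
}
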