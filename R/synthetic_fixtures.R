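# Generators for fully synthetic inputs: a mini genome with annotated
# multi-exon genes, MPRA-like labelled 25-mers from a planted-motif ground
# truth, and variant sets whose true effects follow known composition-model
# coefficients. Every generator is a pure function of its arguments
# (including the seed) and writes standard formats that round-trip through
# the package's own readers.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a mini genome with annotated multi-exon genes
#'
#' Builds one random contig carrying `n_genes` non-overlapping genes,
#' alternating between the two strands. Each gene has `exons_per_gene` exons
#' of length `exon_len` separated by introns of length `intron_len`. Exon
#' boundaries carry the canonical splice dinucleotides (GT at intron starts,
#' AG at intron ends, in transcript orientation) independently with
#' probability `canonical_rate`. Writes a FASTA and a GTF that parse back
#' losslessly through [load_genome()] and [load_annotation()].
#'
#' @param dir Output directory (created if needed).
#' @param n_genes,exons_per_gene,intron_len,exon_len Geometry of the genome.
#' @param canonical_rate Probability that a splice dinucleotide is canonical.
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @return List with `fasta`, `gtf` (paths), `contig`, and `truth` (gene
#'   table and per-boundary canonical flags).
#' @export
generate_mini_genome <- function(dir = tempfile("minigenome"), n_genes = 10L,
                                 exons_per_gene = 3L, intron_len = 200L,
                                 exon_len = 60L, canonical_rate = 0.9,
                                 seed = 1L) {
  stopifnot(n_genes >= 1L, exons_per_gene >= 1L, exon_len >= 10L,
            intron_len >= 30L, canonical_rate >= 0, canonical_rate <= 1)
  set.seed(seed)
  margin <- 200L                       # room for flanks at gene/contig edges
  gene_len <- exons_per_gene * exon_len + (exons_per_gene - 1L) * intron_len
  contig <- "chrS"
  total <- n_genes * (gene_len + margin) + margin
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)

  genes <- vector("list", n_genes)
  exon_rows <- list()
  canonical_flags <- list()
  for (g in seq_len(n_genes)) {
    gstart <- margin + (g - 1L) * (gene_len + margin)
    strand <- if (g %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("gene%02d", g)
    starts <- gstart + (seq_len(exons_per_gene) - 1L) * (exon_len + intron_len)
    ends <- starts + exon_len
    # plant splice dinucleotides at internal boundaries, transcript sense
    for (k in seq_len(exons_per_gene)) {
      if (k < exons_per_gene) {        # intron following exon k (genomic)
        don_can <- stats::runif(1) < canonical_rate
        acc_can <- stats::runif(1) < canonical_rate
        i0 <- ends[k]                  # first intronic base (0-based)
        i1 <- starts[k + 1L]           # first base of next exon
        if (strand == "+") {
          if (don_can) bases[(i0 + 1L):(i0 + 2L)] <- c("G", "T")
          if (acc_can) bases[(i1 - 1L):i1] <- c("A", "G")
        } else {
          # transcript direction is genomic-reverse: the donor of the
          # downstream-transcript exon sits at the intron's genomic end
          if (don_can) bases[(i1 - 1L):i1] <- c("A", "C")   # revcomp(GT)
          if (acc_can) bases[(i0 + 1L):(i0 + 2L)] <- c("C", "T")  # revcomp(AG)
        }
        canonical_flags[[length(canonical_flags) + 1L]] <-
          data.frame(gene_id = gene_id, intron = k, donor_canonical = don_can,
                     acceptor_canonical = acc_can, stringsAsFactors = FALSE)
      }
    }
    genes[[g]] <- data.frame(gene_id = gene_id, contig = contig,
                             strand = strand, start = gstart,
                             end = gstart + gene_len, stringsAsFactors = FALSE)
    exon_rows[[g]] <- data.frame(gene_id = gene_id, contig = contig,
                                 strand = strand, start = starts, end = ends,
                                 stringsAsFactors = FALSE)
  }
  seqstr <- paste(bases, collapse = "")

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  writeLines(c(paste0(">", contig),
               substring(seqstr, seq(1, total, 70), pmin(seq(70, total + 69, 70), total))),
             fasta)
  ex <- do.call(rbind, exon_rows)
  gtf_lines <- sprintf(
    '%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
    ex$contig, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$gene_id
  )
  writeLines(gtf_lines, gtf)
  list(fasta = fasta, gtf = gtf, contig = contig,
       truth = list(genes = do.call(rbind, genes), exons = ex,
                    canonical = do.call(rbind, canonical_flags),
                    canonical_rate = canonical_rate, seed = seed))
}

# Centered log-odds PWM from a consensus string: consensus base probability
# `conf`, remainder spread evenly; columns centered so a uniform background
# sequence has expected sliding-sum score 0.
motif_pwm <- function(consensus = "CATCGT", conf = 0.85) {
  k <- nchar(consensus)
  idx <- match(strsplit(toupper(consensus), "")[[1]], c("A", "C", "G", "T"))
  stopifnot(!anyNA(idx))
  pwm <- matrix(log((1 - conf) / 3 / 0.25), nrow = 4L, ncol = k,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(idx, seq_len(k))] <- log(conf / 0.25)
  sweep(pwm, 2L, colMeans(pwm))
}

# Position-wise additive coefficients of the sliding-sum PWM score for a
# fixed sequence length: A[p, b] = sum of pwm entries covering position p.
sliding_coefficients <- function(pwm, seq_len) {
  k <- ncol(pwm)
  stopifnot(seq_len >= k)
  A <- matrix(0, nrow = seq_len, ncol = 4L)
  for (w in seq_len(seq_len - k + 1L)) {
    A[w:(w + k - 1L), ] <- A[w:(w + k - 1L), ] + t(pwm)
  }
  A
}

# ground-truth sequence score: sliding-window sum of PWM log-odds, linear in
# the one-hot encoding
mpra_truth_score <- function(sequences, pwm, scale) {
  L <- nchar(sequences[1])
  A <- sliding_coefficients(pwm, L)
  vapply(sequences, function(s) {
    scale * sum(A[cbind(seq_len(L), match(strsplit(s, "")[[1]],
                                          c("A", "C", "G", "T")))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate an MPRA-like labelled sequence library
#'
#' Emulates a massively parallel splicing reporter library of short random
#' sequences with measured PSI. The ground truth is a planted-motif model:
#' with probability `plant_frac` a motif instance sampled from the PWM is
#' written into the random sequence, and the latent splicing strength of any
#' sequence is the sliding-window sum of centered PWM log-odds (zero in
#' expectation under the uniform background), scaled by `scale`. Labels are
#' `psi = sigmoid(score + noise)` with Gaussian noise on the logit scale, so
#' the fitted model family matches the generative one and recovery tests
#' have a well-specified optimum.
#'
#' @param n Number of sequences.
#' @param seq_len Sequence length (default 25).
#' @param motif Named list: `consensus` (default "CATCGT"), `conf`
#'   (consensus base probability, default 0.85), `scale` (default 0.35,
#'   giving a latent-score spread of roughly one logit unit over background
#'   sequences), `plant_frac` (default 0.5).
#' @param noise_sd Logit-scale label noise (default 0.3).
#' @param seed Integer seed.
#' @return Data frame with `sequence`, `label` (PSI in (0, 1)), `split`
#'   (80/20), `planted`; ground truth (pwm, scale, scores) in
#'   `attr(, "truth")`.
#' @export
generate_mpra_like <- function(n, seq_len = 25L, motif = list(),
                               noise_sd = 0.3, seed = 1L) {
  stopifnot(n >= 1L, seq_len >= 8L, noise_sd >= 0)
  m <- utils::modifyList(list(consensus = "CATCGT", conf = 0.85,
                              scale = 0.35, plant_frac = 0.5), motif)
  set.seed(seed)
  k <- nchar(m$consensus)
  pwm <- motif_pwm(m$consensus, m$conf)
  probs <- exp(pwm + log(0.25))        # de-center columns to probabilities
  probs <- sweep(probs, 2L, colSums(probs), "/")
  base_mat <- matrix(sample(c("A", "C", "G", "T"), n * seq_len, replace = TRUE),
                     nrow = n)
  planted <- stats::runif(n) < m$plant_frac
  for (i in which(planted)) {
    at <- sample.int(seq_len - k + 1L, 1L)
    inst <- vapply(seq_len(k), function(j) {
      sample(c("A", "C", "G", "T"), 1L, prob = probs[, j])
    }, character(1))
    base_mat[i, at:(at + k - 1L)] <- inst
  }
  sequences <- apply(base_mat, 1L, paste, collapse = "")
  score <- mpra_truth_score(sequences, pwm, m$scale)
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  psi <- sigmoid(score + noise)
  d <- data.frame(sequence = sequences, label = psi,
                  split = ifelse(stats::runif(n) < 0.8, "train", "val"),
                  planted = planted, stringsAsFactors = FALSE)
  attr(d, "truth") <- list(pwm = pwm, scale = m$scale, plant_frac = m$plant_frac,
                           noise_sd = noise_sd, score = score, seed = seed)
  d
}

#' Generate a variant truth set with known composition coefficients
#'
#' Places SNVs and short indels (at most 10 nt) across the exons and
#' intronic flanks of an annotated genome, writes them as a VCF, and
#' simulates each variant's true delta-logit(PSI) from `true_beta` applied
#' to the actual module delta scores of its target exon (plus optional
#' Gaussian noise). Deletions spanning a splice site are included at a fixed
#' 5% rate to exercise the boundary-relocation rule.
#'
#' @param genome An `ss_genome`.
#' @param annotation An `ss_annotation`.
#' @param modules Named list of trained `ss_module`s used to compute the
#'   delta scores entering the simulated response.
#' @param n_variants Number of variants.
#' @param indel_frac Fraction of indels among the variants (default 0.2).
#' @param true_beta Numeric vector of 9 composition coefficients (intercept,
#'   five deltas, three interactions).
#' @param psi_ref_fn Function `n -> n` reference PSI draws (default
#'   `rbeta(n, 2, 2)`).
#' @param noise_sd Gaussian noise added to the simulated response (default 0).
#' @param la,ld Flank lengths (default 100).
#' @param seed Integer seed.
#' @param dir Output directory for the VCF.
#' @return List with `vcf` (path), `variants`, and `effects` — one row per
#'   variant: feature columns, `psi_ref`, `true_delta_logit`, `response`.
#' @export
generate_variant_truth_set <- function(genome, annotation, modules,
                                       n_variants = 300L, indel_frac = 0.2,
                                       true_beta = default_true_beta(),
                                       psi_ref_fn = function(n) stats::rbeta(n, 2, 2),
                                       noise_sd = 0, la = 100L, ld = 100L,
                                       seed = 1L,
                                       dir = tempfile("truthset")) {
  stopifnot(indel_frac >= 0, indel_frac <= 1, length(true_beta) == 9L,
            n_variants >= 1L)
  ex <- annotation$exons
  if (nrow(ex) == 0L) stop("annotation has no exons")
  set.seed(seed)
  span_frac <- if (indel_frac > 0) 0.05 else 0   # splice-site-spanning deletions
  vars <- list(); rows <- list(); kept <- 0L; attempts <- 0L
  while (kept < n_variants) {
    attempts <- attempts + 1L
    if (attempts > 50L * n_variants) stop("could not place the requested variants")
    e <- ex[sample.int(nrow(ex)), ][1, ]
    w <- exon_window(e, la, ld)
    kind <- if (stats::runif(1) < span_frac) "span_del"
            else if (stats::runif(1) < indel_frac) sample(c("ins", "del"), 1L)
            else "snv"
    res <- tryCatch({
      if (kind == "snv") {
        p0 <- sample(seq.int(w[1], w[2] - 1L), 1L)
        ref <- get_seq(genome, e$contig, p0, p0 + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      } else if (kind == "ins") {
        p0 <- sample(seq.int(w[1], w[2] - 1L), 1L)
        ref <- get_seq(genome, e$contig, p0, p0 + 1L)
        alt <- paste0(ref, random_dna(sample.int(10L, 1L)))
      } else if (kind == "del") {
        len <- sample.int(10L, 1L)
        # keep the deletion on one side of each splice site
        p0 <- sample(seq.int(w[1], w[2] - 1L - len), 1L)
        d0 <- p0 + 1L
        if ((d0 < e$start & d0 + len > e$start) ||
            (d0 < e$end & d0 + len > e$end)) stop("spans site")
        ref <- get_seq(genome, e$contig, p0, p0 + 1L + len)
        alt <- substr(ref, 1L, 1L)
      } else {                          # deletion spanning a splice site
        site <- if (stats::runif(1) < 0.5) e$start else e$end
        len <- sample(4:8, 1L)
        off <- sample.int(len - 2L, 1L)  # deleted span straddles the site
        d0 <- site - off
        p0 <- d0 - 1L
        ref <- get_seq(genome, e$contig, p0, d0 + len)
        alt <- substr(ref, 1L, 1L)
      }
      v <- data.frame(variant_id = sprintf("v%04d", kept + 1L),
                      contig = e$contig, pos = p0 + 1L, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
      pair <- apply_variant(genome, e, v, la, ld)
      sc <- module_delta_scores(pair, modules)
      list(v = v, sc = cbind(sc, exon_id = e$exon_id, kind = kind,
                             stringsAsFactors = FALSE))
    }, error = function(err) NULL)
    if (is.null(res)) next
    kept <- kept + 1L
    vars[[kept]] <- res$v
    rows[[kept]] <- res$sc
  }
  variants <- do.call(rbind, vars)
  effects <- cbind(variants["variant_id"], do.call(rbind, rows))
  X <- effect_design_matrix(effects)
  effects$true_delta_logit <- as.vector(X %*% true_beta)
  effects$psi_ref <- psi_ref_fn(n_variants)
  effects$response <- effects$true_delta_logit +
    if (noise_sd > 0) stats::rnorm(n_variants, 0, noise_sd) else 0

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "variants.vcf")
  ord <- order(variants$contig, variants$pos)
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$seqs),
            Biostrings::width(genome$seqs)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", variants$contig[ord],
            variants$pos[ord], variants$variant_id[ord], variants$ref[ord],
            variants$alt[ord])
  ), vcf)
  list(vcf = vcf, variants = variants, effects = effects,
       truth = list(true_beta = true_beta, noise_sd = noise_sd, seed = seed))
}

#' Default ground-truth composition coefficients for simulations
#'
#' Intercept near zero and positive weights on the five module deltas, with
#' negative interaction corrections for doubly-scored regions — the
#' qualitative pattern expected when overlapping modules must not be double
#' counted.
#'
#' @return Named numeric vector of 9 coefficients.
#' @export
default_true_beta <- function() {
  c(intercept = 0.05, dS_intron3p = 0.6, dS_acceptor = 1.0, dS_exon = 1.2,
    dS_donor = 1.1, dS_intron5p = 0.7, ind_exon_ss.dS_exon = -0.5,
    ind_intron5p_donor.dS_intron5p = -0.4,
    ind_intron3p_acceptor.dS_intron3p = -0.3)
}
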