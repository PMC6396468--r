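#' Read variants from a VCF file
#'
#' Parses a VCF 4.x file and returns one row per (record, ALT allele):
#' multi-allelic records are decomposed so that every variant carries exactly
#' one alternative allele. Symbolic and breakend alleles are rejected.
#'
#' @param vcf_path Path to an (uncompressed or gzipped) VCF.
#' @return Data frame with columns `variant_id`, `contig`, `pos` (1-based),
#'   `ref`, `alt`.
#' @export
read_vcf <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(variant_id = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               id = if (is.na(fix$ID[i])) "." else fix$ID[i],
               ref = toupper(fix$REF[i]), alt = toupper(alts),
               stringsAsFactors = FALSE)
  }))
  if (any(!grepl("^[ACGTN]+$", out$ref)) || any(!grepl("^[ACGTN]+$", out$alt))) {
    stop("only sequence-resolved SNV/indel alleles are supported")
  }
  data.frame(
    variant_id = ifelse(out$id != "." & !duplicated(out$id), out$id,
                        sprintf("%s:%d:%s>%s", out$contig, out$pos, out$ref, out$alt)),
    contig = out$contig, pos = out$pos, ref = out$ref, alt = out$alt,
    stringsAsFactors = FALSE
  )
}

# 0-based half-open REF interval of a variant. By convention an insertion
# occupies its single anchor base, which makes window intersection
# unambiguous for indels.
variant_interval <- function(variant) {
  v0 <- as.integer(variant$pos) - 1L
  c(v0, v0 + nchar(variant$ref))
}

# Genomic scoring window of an exon in 0-based half-open coordinates:
# la nt beyond the acceptor and ld nt beyond the donor, strand-aware.
exon_window <- function(exon, la, ld) {
  if (exon$strand == "+") c(exon$start - la, exon$end + ld)
  else c(exon$start - ld, exon$end + la)
}

#' Pair variants with the exons they may affect
#'
#' A variant is paired with an exon when its REF interval intersects the
#' exon extended by `la` intronic nt on the acceptor side and `ld` on the
#' donor side. One variant may pair with zero, one, or several exons; each
#' pair carries exactly one variant.
#'
#' @param variants Data frame as returned by [read_vcf()].
#' @param annotation An `ss_annotation`.
#' @param la,ld Intronic flank lengths (nt), default 100.
#' @return Data frame with one row per (variant, exon) pair: all variant
#'   columns plus `exon_id`, `gene_id`, `exon_strand`, `exon_start`,
#'   `exon_end`.
#' @export
map_variants_to_exons <- function(variants, annotation, la = 100L, ld = 100L) {
  stopifnot(inherits(annotation, "ss_annotation"), la >= 0L, ld >= 0L)
  ex <- annotation$exons
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    vi <- variant_interval(v)
    cand <- ex[ex$contig == v$contig, , drop = FALSE]
    if (nrow(cand) == 0L) next
    w0 <- ifelse(cand$strand == "+", cand$start - la, cand$start - ld)
    w1 <- ifelse(cand$strand == "+", cand$end + ld, cand$end + la)
    hit <- cand[vi[1] < w1 & vi[2] > w0, , drop = FALSE]
    if (nrow(hit) == 0L) next
    rows[[i]] <- data.frame(
      v[, c("variant_id", "contig", "pos", "ref", "alt")],
      exon_id = hit$exon_id, gene_id = hit$gene_id,
      exon_strand = hit$strand, exon_start = hit$start, exon_end = hit$end,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      exon_id = character(), gene_id = character(),
                      exon_strand = character(), exon_start = integer(),
                      exon_end = integer(), stringsAsFactors = FALSE)
  }
  out
}

# Trim the common prefix, then the common suffix, of REF/ALT to obtain the
# minimal edit: 0-based half-open ref interval [u0, u1) replaced by string b.
minimal_edit <- function(pos1, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  p <- 0L
  while (p < length(r) && p < length(a) && r[p + 1L] == a[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < length(r) - p && s < length(a) - p &&
         r[length(r) - s] == a[length(a) - s]) s <- s + 1L
  u0 <- pos1 - 1L + p
  u1 <- pos1 - 1L + length(r) - s
  list(u0 = u0, u1 = u1,
       b = if (length(a) - s >= p + 1L) paste(a[(p + 1L):(length(a) - s)], collapse = "") else "")
}

# Core alternative-sequence construction on a local plus-strand window.
# `seq` is a local sequence, exon at [es, ee), minimal edit [u0, u1) -> b,
# all 0-based within `seq`. Returns ref and alt ss_region objects.
apply_edit_local <- function(seq, es, ee, u0, u1, b, la, ld) {
  n <- nchar(seq)
  if (es - la < 0L || ee + ld > n) {
    stop("flanks exceed available sequence around the exon")
  }
  dl <- u1 - u0
  nb <- nchar(b)
  delta <- nb - dl
  if (dl == 0L) {                       # pure insertion at point u0
    # anchor-base rule: insertion point at or before the acceptor belongs to
    # the upstream intron; strictly inside (es, ee] it is exonic
    if (u0 <= es)      { es2 <- es + delta; ee2 <- ee + delta }
    else if (u0 <= ee) { es2 <- es;          ee2 <- ee + delta }
    else               { es2 <- es;          ee2 <- ee }
  } else {
    if (u1 <= es)      es2 <- es + delta
    else if (u0 >= es) es2 <- es
    else {                              # edit spans the acceptor site
      if (nb > 0L) stop("complex substitution spanning a splice site is not supported")
      es2 <- u0                         # new acceptor = deletion boundary
    }
    if (u1 <= ee)      ee2 <- ee + delta
    else if (u0 >= ee) ee2 <- ee
    else {                              # edit spans the donor site
      if (nb > 0L) stop("complex substitution spanning a splice site is not supported")
      ee2 <- u0                         # new donor = deletion 5' boundary
    }
  }
  if (ee2 - es2 < 1L) stop("deletion removes the entire exon; no exon left to score")
  alt <- paste0(substr(seq, 1L, u0), b, substring(seq, u1 + 1L))
  if (es2 - la < 0L || ee2 + ld > nchar(alt)) {
    stop("flanks exceed available sequence after applying the variant")
  }
  list(
    ref = new_region(substr(seq, es - la + 1L, ee + ld), la, la + (ee - es), la, ld),
    alt = new_region(substr(alt, es2 - la + 1L, ee2 + ld), la, la + (ee2 - es2), la, ld)
  )
}

#' Apply a variant to an exon region
#'
#' Builds the reference and alternative structured region sequences for one
#' (variant, exon) pair. SNVs substitute in place; insertions and deletions
#' not overlapping a splice site lengthen or shorten the corresponding
#' segment, after which flanks are re-extracted so the alternative region has
#' exactly `la` and `ld` intronic nucleotides. For deletions overlapping a
#' splice site the deleted span is removed and the new splice site is the
#' deletion boundary. Minus-strand exons are handled by reverse-complementing
#' into transcript orientation; the variant itself is given in plus-strand
#' VCF coordinates.
#'
#' @param genome An `ss_genome`.
#' @param exon One-row data frame/list with `contig`, `strand`, `start`, `end`.
#' @param variant One-row data frame/list with `contig`, `pos`, `ref`, `alt`.
#' @param la,ld Intronic flank lengths (nt), default 100.
#' @return List of class `ss_pair`: `variant`, `exon`, `ref_region`,
#'   `alt_region`.
#' @export
apply_variant <- function(genome, exon, variant, la = 100L, ld = 100L) {
  stopifnot(la >= 0L, ld >= 0L)
  if (variant$contig != exon$contig) stop("variant and exon on different contigs")
  v0 <- as.integer(variant$pos) - 1L
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  if (nchar(ref) < 1L || nchar(alt) < 1L) stop("REF and ALT must be non-empty")
  clen <- contig_length(genome, exon$contig)
  obs <- get_seq(genome, exon$contig, v0, min(v0 + nchar(ref), clen))
  if (obs != ref) {
    stop(sprintf("REF mismatch at %s:%d: VCF says %s, genome has %s",
                 exon$contig, variant$pos, ref, obs))
  }
  ed <- minimal_edit(as.integer(variant$pos), ref, alt)
  es <- as.integer(exon$start); ee <- as.integer(exon$end)
  margin <- la + ld + (ed$u1 - ed$u0) + nchar(alt) + 16L
  g0 <- max(0L, min(es, ed$u0) - margin)
  g1 <- min(clen, max(ee, ed$u1) + margin)
  local <- get_seq(genome, exon$contig, g0, g1)
  if (exon$strand == "+") {
    res <- apply_edit_local(local, es - g0, ee - g0, ed$u0 - g0, ed$u1 - g0,
                            ed$b, la, ld)
  } else if (exon$strand == "-") {
    L <- nchar(local)
    res <- apply_edit_local(revcomp(local),
                            L - (ee - g0), L - (es - g0),
                            L - (ed$u1 - g0), L - (ed$u0 - g0),
                            revcomp(ed$b), la, ld)
  } else stop("strand must be '+' or '-'")
  structure(list(variant = variant, exon = exon,
                 ref_region = res$ref, alt_region = res$alt),
            class = "ss_pair")
}

#' Default splice-site window sizes
#'
#' Donor windows take the last `donor_exonic` = 5 exonic and first
#' `donor_intronic` = 13 intronic nucleotides; acceptor windows span the last
#' `acceptor_intronic` = 50 intronic (covering most branch points) and first
#' `acceptor_exonic` = 3 exonic nucleotides.
#'
#' @param donor_exonic,donor_intronic,acceptor_intronic,acceptor_exonic
#'   Window sizes in nt.
#' @return Named list of window sizes.
#' @export
window_spec <- function(donor_exonic = 5L, donor_intronic = 13L,
                        acceptor_intronic = 50L, acceptor_exonic = 3L) {
  stopifnot(donor_exonic >= 1L, donor_intronic >= 1L,
            acceptor_intronic >= 1L, acceptor_exonic >= 1L)
  list(donor_exonic = as.integer(donor_exonic),
       donor_intronic = as.integer(donor_intronic),
       acceptor_intronic = as.integer(acceptor_intronic),
       acceptor_exonic = as.integer(acceptor_exonic))
}

#' Split a region into the five module sub-sequences
#'
#' Cuts a structured region into the sequences scored by the five modules:
#' donor and acceptor splice-site windows (fixed length, padded with `N`
#' where the exon or flank is shorter than the window), the full exon
#' segment, and the two intronic flanks (`intron3p` = acceptor-side flank,
#' named for the 3' end of the upstream intron; `intron5p` = donor-side
#' flank).
#'
#' @param region An `ss_region`.
#' @param windows A [window_spec()].
#' @return Named list of character strings: `donor`, `acceptor`, `exon`,
#'   `intron5p`, `intron3p`.
#' @export
split_region <- function(region, windows = window_spec()) {
  stopifnot(inherits(region, "ss_region"))
  s <- region$seq
  la <- region$la; ld <- region$ld
  ee <- region$exon_end
  exon <- substr(s, la + 1L, ee)
  elen <- nchar(exon)
  intron3p <- if (la > 0L) substr(s, 1L, la) else ""
  intron5p <- if (ld > 0L) substring(s, ee + 1L) else ""
  de <- windows$donor_exonic; di <- windows$donor_intronic
  ai <- windows$acceptor_intronic; ae <- windows$acceptor_exonic
  donor_ex <- pad_n(substr(exon, max(1L, elen - de + 1L), elen), de, "left")
  donor_in <- pad_n(substr(intron5p, 1L, min(di, ld)), di, "right")
  acc_in <- pad_n(substr(intron3p, max(1L, la - ai + 1L), la), ai, "left")
  acc_ex <- pad_n(substr(exon, 1L, min(ae, elen)), ae, "right")
  list(donor = paste0(donor_ex, donor_in),
       acceptor = paste0(acc_in, acc_ex),
       exon = exon,
       intron5p = intron5p,
       intron3p = intron3p)
}

# Genomic 0-based half-open intervals of the doubly-scored windows around an
# exon's splice sites, strand-aware. Used for the indicator features.
indicator_windows <- function(exon, windows = window_spec()) {
  de <- windows$donor_exonic; di <- windows$donor_intronic
  ai <- windows$acceptor_intronic; ae <- windows$acceptor_exonic
  es <- as.integer(exon$start); ee <- as.integer(exon$end)
  if (exon$strand == "+") {
    list(donor_exonic = c(max(es, ee - de), ee),
         donor_intronic = c(ee, ee + di),
         acceptor_exonic = c(es, min(ee, es + ae)),
         acceptor_intronic = c(es - ai, es))
  } else {
    list(donor_exonic = c(es, min(ee, es + de)),
         donor_intronic = c(es - di, es),
         acceptor_exonic = c(max(es, ee - ae), ee),
         acceptor_intronic = c(ee, ee + ai))
  }
}

intervals_intersect <- function(a, b) a[1] < b[2] && a[2] > b[1]
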