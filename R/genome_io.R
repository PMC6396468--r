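#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into an in-memory genome handle with random
#' access by contig and 0-based half-open interval. Sequence is uppercased.
#'
#' @param fasta_path Path to a FASTA file.
#' @return An object of class `ss_genome`.
#' @seealso [get_seq()], [load_annotation()]
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", fasta_path)
  # drop description after first whitespace, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(seqs = seqs), class = "ss_genome")
}

#' @export
print.ss_genome <- function(x, ...) {
  cat("<ss_genome> ", length(x$seqs), " contig(s): ",
      paste0(names(x$seqs), " (", Biostrings::width(x$seqs), " nt)",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract a genome slice
#'
#' @param genome An `ss_genome`.
#' @param contig Contig name.
#' @param start0,end0 0-based half-open interval.
#' @return Uppercase nucleotide string of length `end0 - start0`.
#' @export
get_seq <- function(genome, contig, start0, end0) {
  stopifnot(inherits(genome, "ss_genome"))
  if (!contig %in% names(genome$seqs)) {
    stop("contig not in genome: ", contig)
  }
  len <- length(genome$seqs[[contig]])
  if (start0 < 0 || end0 > len || start0 > end0) {
    stop(sprintf("interval [%d, %d) outside contig %s (length %d)",
                 start0, end0, contig, len))
  }
  if (end0 == start0) return("")
  toupper(as.character(Biostrings::subseq(genome$seqs[[contig]],
                                          start = start0 + 1L, end = end0)))
}

contig_length <- function(genome, contig) {
  stopifnot(inherits(genome, "ss_genome"))
  if (!contig %in% names(genome$seqs)) stop("contig not in genome: ", contig)
  length(genome$seqs[[contig]])
}

# Reverse-complement an entire genome handle (used by strand-symmetry tests).
revcomp_genome <- function(genome) {
  stopifnot(inherits(genome, "ss_genome"))
  structure(list(seqs = Biostrings::reverseComplement(genome$seqs)),
            class = "ss_genome")
}

#' Load exon annotation from GTF
#'
#' Reads a GTF (Ensembl dialect), keeps `exon` features, converts their
#' 1-based inclusive coordinates to the internal 0-based half-open
#' convention, and deduplicates exons shared by several transcripts on
#' (contig, strand, start, end).
#'
#' @param gtf_path Path to a GTF file with exon features carrying `gene_id`.
#' @return An `ss_annotation`: list with data frames `exons`
#'   (exon_id, gene_id, contig, strand, start, end) and `genes`
#'   (gene_id, contig, strand, start, end). Coordinates 0-based half-open.
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF: ", gtf_path)
  gene_id <- as.character(gr$gene_id)
  if (any(is.na(gene_id) | gene_id == "")) {
    stop("exon feature without gene_id in GTF: ", gtf_path)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("exon with undefined strand in GTF: ", gtf_path)
  }
  ex <- data.frame(
    gene_id = gene_id,
    contig  = as.character(GenomicRanges::seqnames(gr)),
    strand  = strand,
    start   = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end     = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(ex$start >= ex$end)) stop("exon with start >= end in GTF")
  key <- paste(ex$contig, ex$strand, ex$start, ex$end, sep = ":")
  ex <- ex[!duplicated(key), , drop = FALSE]
  ex <- ex[order(ex$contig, ex$start, ex$end), , drop = FALSE]
  ex$exon_id <- sprintf("exon_%s_%d_%d_%s", ex$contig, ex$start, ex$end,
                        ifelse(ex$strand == "+", "p", "m"))
  rownames(ex) <- NULL
  ex <- ex[, c("exon_id", "gene_id", "contig", "strand", "start", "end")]
  genes <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], contig = d$contig[1],
               strand = d$strand[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(exons = ex, genes = genes), class = "ss_annotation")
}

#' @export
print.ss_annotation <- function(x, ...) {
  cat("<ss_annotation> ", nrow(x$genes), " gene(s), ", nrow(x$exons),
      " unique exon(s)\n", sep = "")
  invisible(x)
}

#' Extract a structured exon region with intronic flanks
#'
#' Returns the sequence "acceptor-side flank | exon | donor-side flank" in
#' transcript 5'->3' orientation. For minus-strand exons the genomic slice is
#' reverse-complemented so that the acceptor flank always comes first;
#' downstream code never sees strand.
#'
#' @param genome An `ss_genome`.
#' @param exon One-row data frame (or list) with `contig`, `strand`, `start`,
#'   `end` (0-based half-open).
#' @param la,ld Intronic flank lengths (nt) on the acceptor and donor side.
#'   Default 100.
#' @return An `ss_region`: list with `seq`, `exon_start`, `exon_end`
#'   (offsets delimiting the exon within `seq`), `la`, `ld`.
#' @export
extract_region <- function(genome, exon, la = 100L, ld = 100L) {
  stopifnot(la >= 0L, ld >= 0L)
  es <- as.integer(exon$start); ee <- as.integer(exon$end)
  if (es >= ee) stop("exon start must be < end")
  strand <- as.character(exon$strand)
  clen <- contig_length(genome, exon$contig)
  if (strand == "+") {
    g0 <- es - la; g1 <- ee + ld
  } else if (strand == "-") {
    g0 <- es - ld; g1 <- ee + la
  } else stop("strand must be '+' or '-'")
  if (g0 < 0 || g1 > clen) {
    stop(sprintf("exon %s:%d-%d with flanks exceeds contig bounds",
                 exon$contig, es, ee))
  }
  s <- get_seq(genome, exon$contig, g0, g1)
  if (strand == "-") s <- revcomp(s)
  new_region(s, la, la + (ee - es), la, ld)
}

new_region <- function(seq, exon_start, exon_end, la, ld) {
  stopifnot(exon_start == la, nchar(seq) - exon_end == ld,
            exon_end - exon_start >= 1L)
  structure(list(seq = seq, exon_start = exon_start, exon_end = exon_end,
                 la = la, ld = ld), class = "ss_region")
}

#' @export
print.ss_region <- function(x, ...) {
  cat(sprintf("<ss_region> %d nt (la=%d | exon=%d | ld=%d)\n",
              nchar(x$seq), x$la, x$exon_end - x$exon_start, x$ld))
  invisible(x)
}

#' One-hot encode a nucleotide sequence
#'
#' Column order is fixed as A, C, G, T; `N` encodes as an all-zero row.
#' Case-insensitive; any other character is an error.
#'
#' @param sequence Nucleotide string over A/C/G/T/N.
#' @return Integer matrix with `nchar(sequence)` rows and 4 columns named
#'   A, C, G, T.
#' @export
one_hot <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  if (n == 0L) return(m)
  idx <- match(chars, c("A", "C", "G", "T"))
  bad <- is.na(idx) & chars != "N"
  if (any(bad)) {
    stop("invalid nucleotide character(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1L
  m
}
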