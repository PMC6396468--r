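test_that("VCF parsing decomposes multi-allelic records", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs1\tA\tC,G\t.\t.\t.",
    "chr1\t200\t.\tAT\tA\t.\t.\t."
  ), vcf)
  v <- read_vcf(vcf)
  expect_equal(nrow(v), 3L)
  expect_equal(v$alt[1:2], c("C", "G"))
  expect_equal(v$ref[3], "AT")
  expect_true(all(nchar(v$variant_id) > 0))
})

test_that("variant-exon pairing follows the flank-window rule", {
  # two-exon plus-strand gene with a 150-nt intron; windows la = ld = 100
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t201\t260\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tx\texon\t411\t470\t.\t+\t.\tgene_id "g"; transcript_id "t";'
  ), gtf)
  ann <- load_annotation(gtf)
  mkv <- function(pos) data.frame(variant_id = "v", contig = "chr1", pos = pos,
                                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  # intronic SNV 60 nt past the upstream donor, 90 nt before the downstream
  # acceptor: inside both windows -> 2 pairs
  expect_equal(nrow(map_variants_to_exons(mkv(320), ann, 100, 100)), 2L)
  # exonic SNV -> exactly one pair
  expect_equal(nrow(map_variants_to_exons(mkv(230), ann, 100, 100)), 1L)
  # 150 nt upstream of the acceptor with la = 100 -> no pairs
  expect_equal(nrow(map_variants_to_exons(mkv(51), ann, 100, 100)), 0L)
  # la = ld = 0 keeps only exonic variants
  expect_equal(nrow(map_variants_to_exons(mkv(320), ann, 0, 0)), 0L)
  expect_equal(nrow(map_variants_to_exons(mkv(230), ann, 0, 0)), 1L)
  # wrong contig
  v <- mkv(230); v$contig <- "chr2"
  expect_equal(nrow(map_variants_to_exons(v, ann, 100, 100)), 0L)
})

test_that("SNVs substitute exactly one base and preserve structure", {
  fx <- fixture_genome()
  ex <- fx$annotation$exons
  set.seed(42)
  for (i in sample(nrow(ex), 6)) {
    e <- ex[i, ]
    w <- spliceshift:::exon_window(e, 20L, 20L)
    v <- make_snv(fx$genome, e$contig, sample(seq(w[1], w[2] - 1L), 1))
    p <- apply_variant(fx$genome, e, v, 20, 20)
    expect_equal(p$ref_region$la, p$alt_region$la)
    expect_equal(p$ref_region$ld, p$alt_region$ld)
    expect_equal(nchar(p$ref_region$seq), nchar(p$alt_region$seq))
    d <- sum(strsplit(p$ref_region$seq, "")[[1]] != strsplit(p$alt_region$seq, "")[[1]])
    expect_equal(d, 1L)
  }
})

test_that("REF mismatches are rejected", {
  fx <- fixture_genome()
  e <- fx$annotation$exons[1, ]
  v <- make_snv(fx$genome, e$contig, e$start + 5L)
  v$ref <- setdiff(c("A", "C", "G", "T"), c(v$ref, v$alt))[1]
  expect_error(apply_variant(fx$genome, e, v), "REF mismatch")
})

test_that("insertions and plain deletions keep flanks byte-identical", {
  fx <- fixture_genome()
  e <- fx$annotation$exons[fx$annotation$exons$strand == "+", ][2, ]
  mid <- floor((e$start + e$end) / 2)
  anchor <- get_seq(fx$genome, e$contig, mid, mid + 1L)
  # 1-nt exonic insertion
  vi <- list(contig = e$contig, pos = mid + 1L, ref = anchor,
             alt = paste0(anchor, "A"))
  p <- apply_variant(fx$genome, e, vi, 15, 15)
  ref_len <- p$ref_region$exon_end - p$ref_region$exon_start
  alt_len <- p$alt_region$exon_end - p$alt_region$exon_start
  expect_equal(alt_len, ref_len + 1L)
  expect_identical(substr(p$alt_region$seq, 1, 15),
                   substr(p$ref_region$seq, 1, 15))
  expect_identical(substring(p$alt_region$seq, nchar(p$alt_region$seq) - 14),
                   substring(p$ref_region$seq, nchar(p$ref_region$seq) - 14))
  # 3-nt exonic deletion: flanks re-extracted, so donor-side flank shifts but
  # still has exactly ld intronic nt
  del_ref <- get_seq(fx$genome, e$contig, mid, mid + 4L)
  vd <- list(contig = e$contig, pos = mid + 1L, ref = del_ref, alt = anchor)
  pd <- apply_variant(fx$genome, e, vd, 15, 15)
  expect_equal(pd$alt_region$exon_end - pd$alt_region$exon_start, ref_len - 3L)
  expect_equal(pd$alt_region$la, 15L)
  expect_equal(nchar(pd$alt_region$seq) - pd$alt_region$exon_end, 15L)
})

test_that("a deletion over the donor relocates the splice site to its boundary", {
  fx <- fixture_genome()
  e <- fx$annotation$exons[fx$annotation$exons$strand == "+", ][1, ]
  # delete the last 2 exonic nt and the first 3 intronic nt
  d0 <- e$end - 2L
  v <- list(contig = e$contig, pos = d0,
            ref = get_seq(fx$genome, e$contig, d0 - 1L, d0 + 5L),
            alt = get_seq(fx$genome, e$contig, d0 - 1L, d0))
  p <- apply_variant(fx$genome, e, v, 10, 10)
  expect_equal(p$alt_region$exon_end - p$alt_region$exon_start,
               (e$end - e$start) - 2L)
  # donor-side flank = the ld nt following the deletion's 3' boundary
  expect_identical(substring(p$alt_region$seq, p$alt_region$exon_end + 1),
                   get_seq(fx$genome, e$contig, e$end + 3L, e$end + 13L))
  # exon now ends at the deletion's 5' boundary
  expect_identical(substr(p$alt_region$seq, p$alt_region$exon_start + 1,
                          p$alt_region$exon_end),
                   get_seq(fx$genome, e$contig, e$start, e$end - 2L))
})

test_that("deletions removing the whole exon are rejected", {
  fx <- fixture_genome()
  e <- fx$annotation$exons[fx$annotation$exons$strand == "+", ][1, ]
  d0 <- e$start - 3L
  v <- list(contig = e$contig, pos = d0,
            ref = get_seq(fx$genome, e$contig, d0 - 1L, e$end + 4L),
            alt = get_seq(fx$genome, e$contig, d0 - 1L, d0))
  expect_error(apply_variant(fx$genome, e, v, 10, 10), "entire exon")
})

test_that("minus-strand application equals the mirrored plus-strand application", {
  fx <- fixture_genome()
  rcg <- spliceshift:::revcomp_genome(fx$genome)
  L <- spliceshift:::contig_length(fx$genome, "chrS")
  ex <- fx$annotation$exons
  set.seed(7)
  for (i in sample(nrow(ex), 4)) {
    e <- ex[i, ]
    # one SNV and one 2-nt deletion inside the exon
    pos0 <- e$start + 4L
    snv <- make_snv(fx$genome, e$contig, pos0)
    del <- list(contig = e$contig, pos = pos0 + 1L,
                ref = get_seq(fx$genome, e$contig, pos0, pos0 + 3L),
                alt = get_seq(fx$genome, e$contig, pos0, pos0 + 1L))
    for (v in list(snv, del)) {
      p1 <- apply_variant(fx$genome, e, v, 12, 9)
      p2 <- apply_variant(rcg, mirror_exon(e, L), mirror_variant(v, L), 12, 9)
      expect_identical(p1$ref_region$seq, p2$ref_region$seq)
      expect_identical(p1$alt_region$seq, p2$alt_region$seq)
    }
  }
})

test_that("split_region cuts the documented windows and pads short inputs", {
  fx <- fixture_genome()
  e <- fx$annotation$exons[1, ]
  r <- extract_region(fx$genome, e, 100, 100)
  sp <- split_region(r)
  expect_equal(nchar(sp$donor), 18L)
  expect_equal(nchar(sp$acceptor), 53L)
  expect_equal(nchar(sp$exon), e$end - e$start)
  expect_equal(nchar(sp$intron3p), 100L)
  expect_equal(nchar(sp$intron5p), 100L)
  # window content: donor = last 5 exonic + first 13 intronic
  expect_identical(sp$donor, paste0(substring(sp$exon, nchar(sp$exon) - 4),
                                    substr(sp$intron5p, 1, 13)))
  expect_identical(sp$acceptor, paste0(substring(sp$intron3p, 51),
                                       substr(sp$exon, 1, 3)))
  # degenerate flanks: empty introns, N-padded splice-site windows
  r0 <- extract_region(fx$genome, e, 0, 0)
  sp0 <- split_region(r0)
  expect_equal(sp0$intron3p, "")
  expect_equal(sp0$intron5p, "")
  expect_equal(nchar(sp0$donor), 18L)
  expect_identical(substring(sp0$donor, 6), strrep("N", 13))
  expect_identical(substr(sp0$acceptor, 1, 50), strrep("N", 50))
  # exon shorter than the exonic windows: padded, not rejected
  short <- spliceshift:::new_region(paste0(strrep("A", 10), "CGT", strrep("G", 10)),
                                    10L, 13L, 10L, 10L)
  sps <- split_region(short)
  expect_equal(nchar(sps$donor), 18L)
  expect_identical(substr(sps$donor, 1, 2), "NN")   # 3-nt exon, 5-nt window
  expect_equal(nchar(sps$acceptor), 53L)
})
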