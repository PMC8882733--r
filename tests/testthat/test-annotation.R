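test_that("read_genome_fasta normalizes case, keeps order, rejects bad input", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">chr1", "acgt", ">chr2 description", "GGNNCC"), fa)
    g <- read_genome_fasta(fa)
    expect_s3_class(g, "genome_seq")
    expect_identical(names(g), c("chr1", "chr2"))
    expect_identical(unname(unclass(g)), c("ACGT", "GGNNCC"))

    writeLines(c(">chr1", "ACGT", ">chr1", "TTTT"), fa)
    expect_error(read_genome_fasta(fa), "duplicate chromosome")
    writeLines(c(">chr1", "ACXT"), fa)
    expect_error(read_genome_fasta(fa), "outside")
    writeLines(character(0), fa)
    expect_error(read_genome_fasta(fa))
})

test_that("read_gtf converts coordinates, sorts exons, handles edge cases", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    attr1 <- 'gene_id "G1"; transcript_id "T1";'
    writeLines(c(
        paste("chr1", "x", "exon", 501, 600, ".", "+", ".", attr1, sep = "\t"),
        paste("chr1", "x", "exon", 101, 200, ".", "+", ".", attr1, sep = "\t"),
        paste("chr1", "x", "exon", 301, 400, ".", "+", ".", attr1, sep = "\t"),
        paste("chr1", "x", "CDS", 101, 200, ".", "+", ".", attr1, sep = "\t")),
        gtf)
    ann <- read_gtf(gtf)
    expect_identical(ann$exons$start, c(100L, 300L, 500L))
    expect_identical(ann$exons$end, c(200L, 400L, 600L))
    expect_identical(ann$exons$exon_rank, 1:3)

    writeLines(paste("chr1", "x", "gene", 1, 500, ".", "+", ".",
                     'gene_id "G1";', sep = "\t"), gtf)
    expect_warning(ann0 <- read_gtf(gtf), "no exon")
    expect_identical(nrow(ann0$exons), 0L)

    writeLines(paste("chr1", "x", "exon", 1, 50, ".", "+", ".",
                     'gene_id "G1";', sep = "\t"), gtf)
    expect_error(read_gtf(gtf), "transcript_id")
})

test_that("GTF round-trip reproduces exon coordinates exactly", {
    fx <- std_fixture()
    gtf <- withr::local_tempfile(fileext = ".gtf")
    write_gtf(fx$ann, gtf)
    ann2 <- read_gtf(gtf)
    cols <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
    expect_identical(as.data.frame(fx$ann$exons[, cols, with = FALSE]),
                     as.data.frame(ann2$exons[, cols, with = FALSE]))
    # and re-writing gives byte-identical text
    gtf2 <- withr::local_tempfile(fileext = ".gtf")
    write_gtf(ann2, gtf2)
    expect_identical(readLines(gtf), readLines(gtf2))
})

test_that("exon_chain_between anchors boundaries exactly", {
    ann <- toy_annotation()
    ch <- exon_chain_between(ann, "chr1", 100, 600, "+")
    expect_length(ch, 1L)
    expect_identical(nrow(ch[[1]]), 3L)
    ch2 <- exon_chain_between(ann, "chr1", 100, 400, "+")
    expect_identical(nrow(ch2[[1]]), 2L)
    expect_identical(ch2[[1]]$end, c(200L, 400L))
    # start not on a boundary -> empty
    expect_length(exon_chain_between(ann, "chr1", 150, 600, "+"), 0L)
    # wrong strand / absent chromosome -> empty, not error
    expect_length(exon_chain_between(ann, "chr1", 100, 600, "-"), 0L)
    expect_length(exon_chain_between(ann, "chrX", 100, 600, "+"), 0L)
    # tolerance rescues near-boundary anchors
    expect_length(exon_chain_between(ann, "chr1", 98, 603, "+",
                                     tolerance_bp = 5L), 1L)
})

test_that("exon_chain_between agrees with brute-force enumeration", {
    fx <- std_fixture()
    ann <- fx$ann
    ex <- ann$exons
    # brute force: all consecutive-exon runs over all transcripts
    runs <- list()
    for (tid in ann$transcripts$transcript_id) {
        te <- ex[ex$transcript_id == tid][order(start)]
        n <- nrow(te)
        for (i in seq_len(n)) for (j in i:n)
            runs[[length(runs) + 1L]] <- list(
                tid = tid, chrom = te$chrom[1], strand = te$strand[1],
                start = te$start[i], end = te$end[j], n = j - i + 1L)
    }
    withr::with_seed(5L, probe <- sample(length(runs), 40L))
    for (rn in runs[probe]) {
        got <- exon_chain_between(ann, rn$chrom, rn$start, rn$end, rn$strand)
        expect_length(got, 1L)
        expect_identical(nrow(got[[1]]), rn$n)
        expect_identical(got[[1]]$transcript_id[1], rn$tid)
    }
    # off-boundary probes must return nothing at tolerance 0
    for (rn in runs[probe[1:10]]) {
        got <- exon_chain_between(ann, rn$chrom, rn$start + 1L, rn$end,
                                  rn$strand)
        expect_length(got, 0L)
    }
})

test_that("concat_exon_sequence concatenates and reverse-complements", {
    g <- structure(c(chr1 = "ACGTTTAA"), class = "genome_seq")
    ch1 <- data.table::data.table(chrom = "chr1", start = 0L, end = 4L)
    expect_identical(concat_exon_sequence(g, ch1, "+"), "ACGT")
    expect_identical(concat_exon_sequence(g, ch1, "-"), "ACGT")  # palindrome
    ch2 <- data.table::data.table(chrom = "chr1", start = c(0L, 4L),
                                  end = c(2L, 6L))
    expect_identical(concat_exon_sequence(g, ch2, "+"), "ACTT")
    expect_identical(concat_exon_sequence(g, ch2, "-"), revcomp("ACTT"))
    ch3 <- data.table::data.table(chrom = "chr1", start = 4L, end = 20L)
    expect_error(concat_exon_sequence(g, ch3, "+"), "out of bounds")
    # length conservation on a sampled real chain
    fx <- std_fixture()
    tr <- fx$truth[1]
    ch <- exon_chain_between(fx$ann, tr$chrom, tr$start, tr$end, tr$strand)[[1]]
    expect_identical(nchar(concat_exon_sequence(fx$genome, ch, tr$strand)),
                     sum(ch$end - ch$start))
})

test_that("classify_genomic_origin partitions candidates", {
    ann <- toy_annotation()
    expect_identical(classify_genomic_origin(ann, "chr1", 100, 600, "+"),
                     "exonic")
    expect_identical(classify_genomic_origin(ann, "chr1", 210, 290, "+"),
                     "intronic")
    expect_identical(classify_genomic_origin(ann, "chr2", 100, 600, "+"),
                     "intergenic")
    # every candidate gets exactly one label
    fx <- std_fixture()
    labs <- vapply(seq_len(nrow(fx$cands)), function(i) {
        ca <- fx$cands[i]
        classify_genomic_origin(fx$ann, ca$chrom, ca$start, ca$end, ca$strand)
    }, character(1))
    expect_true(all(labs %in% c("exonic", "intronic", "intergenic")))
    # truth BSJs are exonic by construction; shifted false BSJs are not
    expect_true(all(labs[fx$cands$label != "false_bsj"] == "exonic"))
    expect_true(all(labs[fx$cands$label == "false_bsj"] != "exonic"))
})
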