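test_that("sim_config validates its fields", {
    expect_s3_class(sim_config(), "sim_config")
    expect_error(sim_config(sub_rate = 1.2), "in \\[0, 1\\]")
    expect_error(sim_config(corruption = c(correct = 0.5, exon_skip = 0.4,
                                           truncation = 0, intron_retention = 0,
                                           false_bsj = 0)), "sum to 1")
    expect_error(sim_config(exon_len = c(250, 150)), "range")
    expect_error(sim_config(corruption = c(good = 1)), "must name")
})

test_that("generators are deterministic in the seed", {
    cfg <- sim_config(seed = 11L, n_genes = 4L, n_circ = 8L, n_reads = 30L)
    run <- function() {
        g <- simulate_genome(cfg)
        a <- simulate_annotation(g, cfg)
        tr <- simulate_circ_truth(a, g, cfg)
        rd <- simulate_long_reads(tr, a, g, cfg)
        ca <- corrupt_candidates(tr, a, g, cfg)
        list(g = unclass(g), a = a$exons, tr = tr, rd = rd, ca = ca)
    }
    expect_identical(run(), run())
    cfg2 <- sim_config(seed = 12L, n_genes = 4L, n_circ = 8L, n_reads = 30L)
    g2 <- simulate_genome(cfg2)
    expect_false(identical(unclass(simulate_genome(cfg)), unclass(g2)))
})

test_that("simulate_genome respects length and GC settings", {
    cfg <- sim_config(genome_len = 500L, gc = 1)
    g <- simulate_genome(cfg)
    expect_identical(nchar(g[[1]]), 500L)
    expect_false(grepl("[AT]", g[[1]]))
    expect_error(simulate_genome(sim_config(genome_len = 0L)), "positive")
})

test_that("simulate_annotation keeps genes in bounds and counts in range", {
    cfg <- sim_config(n_genes = 30L, exons_per_gene = c(2L, 8L))
    g <- simulate_genome(cfg)
    ann <- simulate_annotation(g, cfg)
    expect_identical(nrow(ann$genes), 30L)
    expect_true(all(ann$transcripts$n_exons >= 2L &
                        ann$transcripts$n_exons <= 8L))
    expect_true(all(ann$exons$end <= nchar(g[[1]])))
    # genes must not overlap
    gn <- ann$genes[order(start)]
    expect_true(all(gn$start[-1] >= gn$end[-nrow(gn)]))
    expect_error(simulate_annotation(g, sim_config(n_genes = 5000L,
                                                   genome_len = 1000L)),
                 "too short")
})

test_that("simulate_circ_truth anchors chains at exon boundaries", {
    fx <- std_fixture()
    expect_identical(nrow(fx$truth), 60L)
    expect_identical(anyDuplicated(fx$truth[, .(chrom, start, end, strand)]),
                     0L)
    # sequence equals the exon-chain concatenation, always
    for (i in seq_len(nrow(fx$truth))) {
        tr <- fx$truth[i]
        ch <- exon_chain_between(fx$ann, tr$chrom, tr$start, tr$end,
                                 tr$strand)
        expect_length(ch, 1L)
        expect_identical(concat_exon_sequence(fx$genome, ch[[1]], tr$strand),
                         tr$seq)
    }
    cfg_big <- sim_config(n_genes = 2L, n_circ = 500L)
    g <- simulate_genome(cfg_big)
    a <- simulate_annotation(g, cfg_big)
    expect_error(simulate_circ_truth(a, g, cfg_big), "available")
})

test_that("rolling-circle reads obey the circular substring property", {
    fx <- std_fixture()
    rd <- fx$reads
    seq_of <- stats::setNames(fx$truth$seq, fx$truth$circ_id)
    withr::with_seed(3L, idx <- sample(nrow(rd), 50L))
    for (i in idx) {
        r <- rd[i]
        s <- seq_of[[r$source_id]]
        expect_identical(nchar(r$seq), r$copies * nchar(s))
        expect_true(grepl(r$seq, strrep(s, r$copies + 1L), fixed = TRUE))
    }
})

test_that("read error rates match their binomial expectation", {
    cfg <- sim_config(seed = 9L, n_genes = 5L, n_circ = 10L, n_reads = 1000L,
                      sub_rate = 0.05, copy_range = c(1L, 1L))
    g <- simulate_genome(cfg)
    a <- simulate_annotation(g, cfg)
    tr <- simulate_circ_truth(a, g, cfg)
    rd <- simulate_long_reads(tr, a, g, cfg)
    seq_of <- stats::setNames(tr$seq, tr$circ_id)
    mism <- 0L; tot <- 0L
    for (i in seq_len(nrow(rd))) {
        r <- rd[i]
        tmpl <- rotate_sequence(seq_of[[r$source_id]], r$offset)
        a1 <- strsplit(r$seq, "")[[1]]
        a2 <- strsplit(tmpl, "")[[1]]
        mism <- mism + sum(a1 != a2)
        tot <- tot + length(a1)
    }
    se <- sqrt(0.05 * 0.95 / tot)
    expect_lt(abs(mism / tot - 0.05), 3 * se)
    # degenerate rate: nothing matches the template
    cfg1 <- sim_config(seed = 9L, n_genes = 2L, n_circ = 2L, n_reads = 2L,
                       sub_rate = 1, copy_range = c(1L, 1L))
    g1 <- simulate_genome(cfg1); a1_ <- simulate_annotation(g1, cfg1)
    t1 <- simulate_circ_truth(a1_, g1, cfg1)
    r1 <- simulate_long_reads(t1, a1_, g1, cfg1)
    tmpl <- rotate_sequence(stats::setNames(t1$seq, t1$circ_id)[[r1$source_id[1]]],
                            r1$offset[1])
    expect_identical(sum(strsplit(r1$seq[1], "")[[1]] ==
                             strsplit(tmpl, "")[[1]]), 0L)
})

test_that("corruption modes produce the advertised sequence arithmetic", {
    # all-correct profile: candidates byte-identical to truth
    cfg <- sim_config(seed = 4L, n_genes = 6L, n_circ = 12L,
                      corruption = c(correct = 1, exon_skip = 0,
                                     truncation = 0, intron_retention = 0,
                                     false_bsj = 0))
    g <- simulate_genome(cfg); a <- simulate_annotation(g, cfg)
    tr <- simulate_circ_truth(a, g, cfg)
    ca <- corrupt_candidates(tr, a, g, cfg)
    m <- merge(ca, tr[, .(circ_id, true_seq = seq)], by = "circ_id")
    expect_identical(nrow(ca), nrow(tr))
    expect_true(all(m$seq == m$true_seq))
    expect_true(all(m$label == "correct"))
    expect_true(all(ca$support >= 2L))

    # exon-skip-only profile on a 3-exon gene: every 3-exon chain loses its
    # middle exon; shorter chains fall back to correct (no feasible mode)
    cfg2 <- sim_config(seed = 4L, n_genes = 1L, exons_per_gene = c(3L, 3L),
                       n_circ = 6L,
                       corruption = c(correct = 0, exon_skip = 1,
                                      truncation = 0, intron_retention = 0,
                                      false_bsj = 0))
    g2 <- simulate_genome(cfg2); a2 <- simulate_annotation(g2, cfg2)
    t2 <- simulate_circ_truth(a2, g2, cfg2)
    suppressMessages(c2 <- corrupt_candidates(t2, a2, g2, cfg2))
    m2 <- merge(c2, t2[, .(circ_id, n_exons, true_seq = seq)], by = "circ_id")
    three <- m2[n_exons == 3L]
    expect_identical(nrow(three), 1L)
    ex2 <- a2$exons[order(start)]
    mid_len <- ex2$end[2] - ex2$start[2]
    expect_identical(three$label, "exon_skip")
    expect_identical(nchar(three$seq), nchar(three$true_seq) - mid_len)

    # conservation with pure-false extras
    cfg3 <- sim_config(seed = 4L, n_genes = 6L, n_circ = 12L, n_false = 5L)
    g3 <- simulate_genome(cfg3); a3 <- simulate_annotation(g3, cfg3)
    t3 <- simulate_circ_truth(a3, g3, cfg3)
    c3 <- corrupt_candidates(t3, a3, g3, cfg3)
    expect_identical(nrow(c3), nrow(t3) + 5L)
    expect_identical(sum(c3$label == "pure_false"), 5L)
})

test_that("planted correct fraction matches the profile in expectation", {
    cfg <- sim_config(seed = 31L, n_genes = 120L, n_circ = 500L)
    g <- simulate_genome(cfg)
    a <- simulate_annotation(g, cfg)
    tr <- simulate_circ_truth(a, g, cfg)
    ca <- corrupt_candidates(tr, a, g, cfg)
    p <- mean(ca$label == "correct")
    se <- sqrt(0.6 * 0.4 / nrow(ca))
    expect_lt(abs(p - 0.6), 3 * se)
})
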