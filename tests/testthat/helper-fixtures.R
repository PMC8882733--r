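# Shared fixtures, built in code. The standard benchmark world (default
# sim_config, seed 42) is expensive enough to be worth memoising across
# test files; everything else is constructed inline.

toy_genome <- function(len = 1200L, seed = 7L) {
    withr::with_seed(seed, structure(
        stats::setNames(paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = ""), "chr1"),
        class = "genome_seq"))
}

# canonical toy transcript: three exons [100,200), [300,400), [500,600)
toy_annotation <- function(strand = "+") {
    gene_annotation(data.table::data.table(
        chrom = "chr1", start = c(100L, 300L, 500L),
        end = c(200L, 400L, 600L), strand = strand,
        transcript_id = "T1", gene_id = "G1"))
}

.fixture_cache <- new.env(parent = emptyenv())

# standard benchmark fixture: genome, annotation, truth, reads, candidates
std_fixture <- function(seed = 42L) {
    key <- paste0("fx", seed)
    if (!exists(key, envir = .fixture_cache)) {
        cfg <- sim_config(seed = seed)
        g <- simulate_genome(cfg)
        a <- simulate_annotation(g, cfg)
        tr <- simulate_circ_truth(a, g, cfg)
        rd <- simulate_long_reads(tr, a, g, cfg)
        ca <- corrupt_candidates(tr, a, g, cfg)
        assign(key, list(cfg = cfg, genome = g, ann = a, truth = tr,
                         reads = rd, cands = ca), envir = .fixture_cache)
    }
    get(key, envir = .fixture_cache)
}

# rotation-strategy verdicts on the standard fixture (memoised: aligning
# all reads is the expensive step shared by several tests)
std_rotation_verdicts <- function(seed = 42L) {
    key <- paste0("rot", seed)
    if (!exists(key, envir = .fixture_cache)) {
        fx <- std_fixture(seed)
        assign(key, validate_by_reads(fx$cands, fx$reads),
               envir = .fixture_cache)
    }
    get(key, envir = .fixture_cache)
}
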