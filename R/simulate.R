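# Synthetic world: toy genome, compact gene models, true circRNA isoforms,
# rolling-circle long reads, and corrupted assembled-candidate sets with
# planted correctness. Every output is a pure function of the SimConfig
# (seed included); each stage draws from its own derived seed so stages can
# be re-run independently.

#' Simulation configuration
#'
#' Defaults describe the standard benchmark world used by the test suite:
#' a compact genome of `n_genes` non-overlapping single-isoform genes with
#' 3-5 exons of 150-250 bp separated by 200-400 bp introns; 60 true exonic
#' circRNAs built from runs of 1-3 consecutive exons; error-free
#' rolling-circle reads of 2-4 tandem copies; and a corruption profile
#' planting 60% correct candidates.
#'
#' @param seed integer master seed; every stage derives its own stream.
#' @param n_genes number of genes.
#' @param exons_per_gene inclusive integer range of exon counts per gene.
#' @param exon_len,intron_len,intergenic_len inclusive bp ranges.
#' @param genome_len chromosome length; `NULL` = generous upper bound.
#' @param gc GC content of the random genome.
#' @param n_circ number of true circRNA isoforms.
#' @param min_circ_exons,max_circ_exons exon-count range of circRNA chains.
#' @param n_reads total number of long reads.
#' @param copy_range inclusive range of tandem copies per rolling-circle read.
#' @param sub_rate,ins_rate,del_rate per-base error rates.
#' @param decoy_fraction fraction of reads drawn from linear transcripts.
#' @param decoy_len_range length range of linear decoy reads.
#' @param corruption named per-mode probabilities over
#'   `correct`, `exon_skip`, `truncation`, `intron_retention`, `false_bsj`;
#'   must sum to 1.
#' @param n_false number of additional pure-false candidates (BSJ absent
#'   from the truth set).
#' @param trunc_frac fraction of the targeted exon removed by the
#'   truncation mode (minimum removal 10 bp).
#' @param support_mean_correct,support_mean_false mean back-splice read
#'   support of correct / corrupted candidates; support is
#'   `2 + Geometric`, so every candidate passes the >= 2 read filter while
#'   correctness correlates with support.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exons_per_gene = c(3L, 5L),
                       exon_len = c(150L, 250L),
                       intron_len = c(200L, 400L),
                       intergenic_len = c(200L, 500L),
                       genome_len = NULL,
                       gc = 0.5,
                       n_circ = 60L,
                       min_circ_exons = 1L,
                       max_circ_exons = 3L,
                       n_reads = 600L,
                       copy_range = c(2L, 4L),
                       sub_rate = 0,
                       ins_rate = 0,
                       del_rate = 0,
                       decoy_fraction = 0,
                       decoy_len_range = c(300L, 1500L),
                       corruption = c(correct = 0.6, exon_skip = 0.15,
                                      truncation = 0.1,
                                      intron_retention = 0.1,
                                      false_bsj = 0.05),
                       n_false = 0L,
                       trunc_frac = 0.75,
                       support_mean_correct = 8,
                       support_mean_false = 3) {
    cfg <- as.list(environment())
    modes <- c("correct", "exon_skip", "truncation", "intron_retention",
               "false_bsj")
    if (!setequal(names(corruption), modes))
        stop("corruption profile must name exactly: ",
             paste(modes, collapse = ", "))
    cfg$corruption <- corruption[modes]
    rates <- c(cfg$sub_rate, cfg$ins_rate, cfg$del_rate, cfg$gc,
               cfg$decoy_fraction, unname(cfg$corruption))
    if (any(rates < 0 | rates > 1))
        stop("rates and probabilities must be in [0, 1]")
    if (abs(sum(cfg$corruption) - 1) > 1e-8)
        stop("corruption probabilities must sum to 1")
    for (f in c("exons_per_gene", "exon_len", "intron_len", "intergenic_len",
                "copy_range", "decoy_len_range")) {
        r <- cfg[[f]]
        if (length(r) != 2L || r[1] > r[2] || r[1] < 1)
            stop(f, " must be a nonempty positive range c(lo, hi)")
    }
    if (cfg$n_genes < 1 || cfg$n_circ < 1 || cfg$n_reads < 0)
        stop("n_genes and n_circ must be positive, n_reads nonnegative")
    if (cfg$support_mean_correct < 2 || cfg$support_mean_false < 2)
        stop("support means must be >= 2 (back-splice read filter)")
    cfg$seed <- as.integer(seed)
    structure(cfg, class = "sim_config")
}

with_stage_seed <- function(config, offset, code) {
    withr::with_seed(config$seed %% 2000000000L + offset, code)
}

#' Simulate a toy genome
#'
#' @param config a [sim_config()].
#' @return a `genome_seq` with a single chromosome `chrS`, long enough to
#'   hold the configured gene models (or `config$genome_len` if set).
#' @export
simulate_genome <- function(config) {
    stopifnot(inherits(config, "sim_config"))
    len <- config$genome_len
    if (is.null(len)) {
        per_gene <- config$exons_per_gene[2] * config$exon_len[2] +
            (config$exons_per_gene[2] - 1L) * config$intron_len[2] +
            config$intergenic_len[2]
        len <- config$n_genes * per_gene + config$intergenic_len[2]
    }
    if (len <= 0) stop("genome length must be positive")
    with_stage_seed(config, 0L, {
        structure(c(chrS = random_dna(len, config$gc)), class = "genome_seq")
    })
}

#' Simulate a gene annotation on a genome
#'
#' Lays non-overlapping single-transcript genes left to right with random
#' intergenic gaps, exon counts, exon and intron lengths within the
#' configured ranges; strands are random.
#'
#' @param genome a `genome_seq`.
#' @param config a [sim_config()].
#' @return a [gene_annotation()].
#' @export
simulate_annotation <- function(genome, config) {
    stopifnot(inherits(config, "sim_config"))
    chrom <- names(genome)[1]
    chrom_len <- nchar(genome[[1]])
    with_stage_seed(config, 1L, {
        rows <- vector("list", config$n_genes)
        pos <- 0L
        for (g in seq_len(config$n_genes)) {
            pos <- pos + runif_int(1L, config$intergenic_len)
            n_ex <- runif_int(1L, config$exons_per_gene)
            ex_len <- runif_int(n_ex, config$exon_len)
            in_len <- if (n_ex > 1L) runif_int(n_ex - 1L, config$intron_len)
                      else integer(0)
            starts <- pos + cumsum(c(0L, head(ex_len, -1L) + in_len))
            ends <- starts + ex_len
            strand <- sample(c("+", "-"), 1L)
            gid <- sprintf("G%03d", g)
            rows[[g]] <- data.table(
                chrom = chrom, start = starts, end = ends, strand = strand,
                transcript_id = paste0(gid, ".T1"), gene_id = gid)
            pos <- ends[n_ex]
        }
        if (pos > chrom_len)
            stop("genome too short (", chrom_len, " bp) for ", config$n_genes,
                 " genes (need ", pos, " bp)")
        gene_annotation(rbindlist(rows))
    })
}

# all candidate (transcript, first_exon, last_exon) runs usable as circRNAs
enumerate_chains <- function(annotation, max_exons, min_exons = 1L) {
    ex <- annotation$exons
    out <- list()
    for (tid in annotation$transcripts$transcript_id) {
        te <- ex[ex$transcript_id == tid]
        setorder(te, start)
        n <- nrow(te)
        for (i in seq_len(n)) for (j in i:min(n, i + max_exons - 1L)) {
            if (j - i + 1L < min_exons) next
            out[[length(out) + 1L]] <- data.table(
                transcript_id = tid, chrom = te$chrom[1],
                strand = te$strand[1], first_exon = i, last_exon = j,
                start = te$start[i], end = te$end[j])
        }
    }
    rbindlist(out)
}

#' Simulate true circRNA isoforms
#'
#' Samples `n_circ` distinct runs of consecutive exons; each circRNA is
#' anchored at exon boundaries of its source transcript and its full-length
#' sequence is the exon-chain concatenation (strand applied). Expression
#' weights are uniform on `[0.5, 1.5]`.
#'
#' @param annotation a [gene_annotation()].
#' @param genome a `genome_seq`.
#' @param config a [sim_config()].
#' @return `data.table` with columns `circ_id`, `chrom`, `start`, `end`,
#'   `strand`, `transcript_id`, `first_exon`, `last_exon`, `n_exons`,
#'   `block_starts`, `block_sizes` (comma strings, BED12 style), `seq`,
#'   `weight`.
#' @export
simulate_circ_truth <- function(annotation, genome, config) {
    stopifnot(inherits(config, "sim_config"))
    if (!any(annotation$transcripts$n_exons > 1L))
        stop("annotation has no multi-exon transcript")
    pool <- enumerate_chains(annotation, config$max_circ_exons,
                             config$min_circ_exons)
    if (nrow(pool) < config$n_circ)
        stop("requested ", config$n_circ, " circRNAs but only ", nrow(pool),
             " distinct exon-boundary chains are available")
    with_stage_seed(config, 2L, {
        pick <- pool[sample.int(nrow(pool), config$n_circ)]
        setorder(pick, chrom, start, end)
        ex <- annotation$exons
        res <- lapply(seq_len(nrow(pick)), function(r) {
            p <- pick[r]
            te <- ex[ex$transcript_id == p$transcript_id]
            setorder(te, start)
            chain <- te[p$first_exon:p$last_exon]
            data.table(
                circ_id = sprintf("circ%04d", r), chrom = p$chrom,
                start = p$start, end = p$end, strand = p$strand,
                transcript_id = p$transcript_id, first_exon = p$first_exon,
                last_exon = p$last_exon, n_exons = nrow(chain),
                block_starts = paste(chain$start - p$start, collapse = ","),
                block_sizes = paste(chain$end - chain$start, collapse = ","),
                seq = concat_exon_sequence(genome, chain, p$strand))
        })
        truth <- rbindlist(res)
        truth[, weight := runif(.N, 0.5, 1.5)]
        truth[]
    })
}

# apply per-base substitution / insertion / deletion errors
apply_seq_errors <- function(s, sub_rate, ins_rate, del_rate) {
    if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(s)
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    keep <- runif(n) >= del_rate
    subs <- runif(n) < sub_rate
    if (any(subs)) {
        alt <- vapply(b[subs], function(x)
            sample(setdiff(DNA_BASES, x), 1L), character(1))
        b[subs] <- alt
    }
    ins <- runif(n) < ins_rate
    pieces <- b
    if (any(ins))
        pieces[ins] <- paste0(b[ins],
                              sample(DNA_BASES, sum(ins), replace = TRUE))
    pieces[!keep] <- sub("^.", "", pieces[!keep])  # delete the original base
    paste(pieces, collapse = "")
}

# spliced (mature) sequence of a transcript, strand applied
linear_transcript_seq <- function(annotation, genome, transcript_id) {
    te <- annotation$exons[annotation$exons$transcript_id == transcript_id]
    if (nrow(te) == 0L) stop("unknown transcript: ", transcript_id)
    concat_exon_sequence(genome, te, te$strand[1])
}

#' Simulate rolling-circle long reads (plus linear decoys)
#'
#' A circRNA read is `k` tandem copies (`k` from `copy_range`) of the
#' circular full-length sequence starting at a uniform random rotation
#' offset, with per-base substitution/insertion/deletion errors applied.
#' A decoy read is an error-injected substring of a linear transcript of
#' the same gene set (the confounder the rotation strategy must resist).
#'
#' @param truth output of [simulate_circ_truth()].
#' @param annotation a [gene_annotation()].
#' @param genome a `genome_seq`.
#' @param config a [sim_config()].
#' @return `data.table` with columns `read_id`, `seq`, `source_id`,
#'   `source_type` (`"circ"` or `"linear"`), `copies`, `offset`.
#' @export
simulate_long_reads <- function(truth, annotation, genome, config) {
    stopifnot(inherits(config, "sim_config"))
    n_decoy <- round(config$n_reads * config$decoy_fraction)
    n_circ_reads <- config$n_reads - n_decoy
    if (nrow(truth) == 0L && n_circ_reads > 0L)
        stop("no true circRNAs to read from; set decoy_fraction = 1")
    with_stage_seed(config, 3L, {
        out <- vector("list", config$n_reads)
        if (n_circ_reads > 0L) {
            src <- sample.int(nrow(truth), n_circ_reads, replace = TRUE,
                              prob = truth$weight)
            for (i in seq_len(n_circ_reads)) {
                tr <- truth[src[i]]
                k <- runif_int(1L, config$copy_range)
                off <- sample.int(nchar(tr$seq), 1L) - 1L
                tmpl <- strrep(rotate_sequence(tr$seq, off), k)
                out[[i]] <- data.table(
                    read_id = sprintf("read%05d", i),
                    seq = apply_seq_errors(tmpl, config$sub_rate,
                                           config$ins_rate, config$del_rate),
                    source_id = tr$circ_id, source_type = "circ",
                    copies = k, offset = off)
            }
        }
        if (n_decoy > 0L) {
            txs <- annotation$transcripts$transcript_id
            for (i in seq_len(n_decoy)) {
                tid <- sample(txs, 1L)
                ms <- linear_transcript_seq(annotation, genome, tid)
                len <- min(nchar(ms), runif_int(1L, config$decoy_len_range))
                st <- sample.int(nchar(ms) - len + 1L, 1L)
                tmpl <- substr(ms, st, st + len - 1L)
                out[[n_circ_reads + i]] <- data.table(
                    read_id = sprintf("read%05d", n_circ_reads + i),
                    seq = apply_seq_errors(tmpl, config$sub_rate,
                                           config$ins_rate, config$del_rate),
                    source_id = tid, source_type = "linear",
                    copies = 1L, offset = st - 1L)
            }
        }
        rbindlist(out)
    })
}

# pick a corruption mode honoring feasibility (exon_skip needs an internal
# exon, intron_retention needs >= 2 exons). The probability of "correct" is
# preserved exactly (so the planted correct fraction is unbiased); infeasible
# corruption mass is redistributed among the feasible corruption modes, with
# "correct" as the last resort.
draw_mode <- function(profile, n_exons) {
    if (runif(1) < profile[["correct"]]) return("correct")
    p <- profile[setdiff(names(profile), "correct")]
    if (n_exons < 3L) p["exon_skip"] <- 0
    if (n_exons < 2L) p["intron_retention"] <- 0
    if (sum(p) <= 0) {
        message("no feasible corruption mode for ", n_exons,
                "-exon circRNA; emitting correct candidate")
        return("correct")
    }
    sample(names(p), 1L, prob = p)
}

support_draw <- function(n, mean_support) {
    # shifted geometric: 2 + Geom(p), mean = 2 + (1-p)/p
    extra <- mean_support - 2
    p <- 1 / (1 + extra)
    2L + rgeom(n, p)
}

#' Corrupt the truth set into an assembled-candidate set
#'
#' Emits exactly one candidate per true circRNA, with mode drawn from the
#' corruption profile, plus `config$n_false` pure-false candidates:
#' * `correct` - sequence preserved;
#' * `exon_skip` - one internal exon removed;
#' * `truncation` - `trunc_frac` of the largest (internal where possible)
#'   exon removed from one end of that exon (>= 10 bp);
#' * `intron_retention` - one genomic intron reinserted between two chain
#'   exons;
#' * `false_bsj` - BSJ endpoints shifted 35-80 bp off any exon boundary,
#'   sequence replaced by the genomic window at the shifted start.
#' Support counts are drawn from shifted geometric distributions whose mean
#' is higher for correct candidates, so precision rises with back-splice
#' read support by construction.
#'
#' @inheritParams simulate_long_reads
#' @return `data.table` with columns `candidate_id`, `chrom`, `start`,
#'   `end`, `strand`, `seq`, `support`, `id_tool`, `asm_tool`, `label`
#'   (the corruption mode; truth label), `circ_id` (source truth id or NA).
#' @export
corrupt_candidates <- function(truth, annotation, genome, config) {
    stopifnot(inherits(config, "sim_config"))
    ex <- annotation$exons
    bsj_key <- paste(truth$chrom, truth$start, truth$end, truth$strand)
    boundary_pts <- unique(c(ex$start, ex$end))
    with_stage_seed(config, 4L, {
        rows <- vector("list", nrow(truth) + config$n_false)
        for (r in seq_len(nrow(truth))) {
            tr <- truth[r]
            te <- ex[ex$transcript_id == tr$transcript_id]
            setorder(te, start)
            chain <- te[tr$first_exon:tr$last_exon]
            mode <- draw_mode(config$corruption, nrow(chain))
            blocks <- mapply(genome_subseq, chain$start, chain$end,
                             MoreArgs = list(genome = genome,
                                             chrom = tr$chrom))
            cand <- list(start = tr$start, end = tr$end, seq = NA_character_)
            if (mode == "correct") {
                gseq <- paste(blocks, collapse = "")
            } else if (mode == "exon_skip") {
                internal <- 2:(nrow(chain) - 1L)
                k <- internal[sample.int(length(internal), 1L)]
                gseq <- paste(blocks[-k], collapse = "")
            } else if (mode == "truncation") {
                n <- nrow(chain)
                cand_idx <- if (n >= 3L) 2:(n - 1L) else seq_len(n)
                lens <- nchar(blocks)[cand_idx]
                k <- cand_idx[which.max(lens)]
                g <- max(10L, as.integer(round(config$trunc_frac *
                                                   nchar(blocks[k]))))
                if (n == 2L) {
                    # keep both surviving flanks (incl. the 20 bp junction
                    # wrap and a 15 bp chance-extension budget under the
                    # <= 2-edit filter) below the 0.8 mapped_ratio bound:
                    # the remnant r of the truncated exon must exceed a
                    # quarter of the intact exon plus slack, so the intact
                    # exon cannot dominate the shortened candidate
                    other <- nchar(blocks[-k])
                    g <- min(g, nchar(blocks[k]) - (other %/% 4L + 45L))
                }
                g <- max(10L, min(g, nchar(blocks[k]) - 1L))
                from_5p <- if (n == 2L) k == 2L else sample(c(TRUE, FALSE), 1L)
                blk <- blocks[k]
                blocks[k] <- if (from_5p) substr(blk, g + 1L, nchar(blk))
                             else substr(blk, 1L, nchar(blk) - g)
                gseq <- paste(blocks, collapse = "")
            } else if (mode == "intron_retention") {
                j <- sample.int(nrow(chain) - 1L, 1L)
                intr <- genome_subseq(genome, tr$chrom,
                                      chain$end[j], chain$start[j + 1L])
                gseq <- paste(c(blocks[seq_len(j)], intr,
                                blocks[(j + 1L):nrow(chain)]), collapse = "")
            } else {  # false_bsj
                L <- nchar(tr$seq)
                # the shift must exceed 20% of the longest exon so the
                # exonic remainder of the shifted window cannot reach the
                # 0.8 mapped_ratio bound even when the rotation consumes
                # only intron (minus-strand windows)
                repeat {
                    ds <- sample(80:130, 1L)
                    de <- sample(80:130, 1L)
                    ns <- tr$start + ds
                    ne <- tr$end + de
                    key <- paste(tr$chrom, ns, ne, tr$strand)
                    if (!(key %in% bsj_key) && !(ns %in% boundary_pts) &&
                        !(ne %in% boundary_pts) &&
                        ns + L <= nchar(genome[[tr$chrom]])) break
                }
                cand$start <- ns
                cand$end <- ne
                gseq <- genome_subseq(genome, tr$chrom, ns, ns + L)
            }
            cand$seq <- if (tr$strand == "-") revcomp(gseq) else gseq
            rows[[r]] <- data.table(
                candidate_id = sprintf("cand%04d", r), chrom = tr$chrom,
                start = cand$start, end = cand$end, strand = tr$strand,
                seq = cand$seq,
                support = support_draw(1L, if (mode == "correct")
                    config$support_mean_correct else config$support_mean_false),
                id_tool = "sim_id", asm_tool = "sim_asm",
                label = mode, circ_id = tr$circ_id)
        }
        if (config$n_false > 0L) {
            chrom <- names(genome)[1]
            glen <- nchar(genome[[1]])
            for (i in seq_len(config$n_false)) {
                repeat {
                    L <- runif_int(1L, c(200L, 600L))
                    ns <- sample.int(glen - 2L * L, 1L)
                    ne <- ns + L
                    key <- paste(chrom, ns, ne, "+")
                    if (!(key %in% bsj_key) && !(ns %in% boundary_pts) &&
                        !(ne %in% boundary_pts)) break
                }
                rows[[nrow(truth) + i]] <- data.table(
                    candidate_id = sprintf("cand%04d", nrow(truth) + i),
                    chrom = chrom, start = ns, end = ne, strand = "+",
                    seq = genome_subseq(genome, chrom, ns, ne),
                    support = support_draw(1L, config$support_mean_false),
                    id_tool = "sim_id", asm_tool = "sim_asm",
                    label = "pure_false", circ_id = NA_character_)
            }
        }
        rbindlist(rows)
    })
}
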