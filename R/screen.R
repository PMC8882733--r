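# Structure classification and the exon-completeness screening protocol:
# an exonic candidate whose full-length sequence equals the complete
# annotated exon chain between its back-splice sites is considered reliable
# (Type 1 = one full exon, Type 2 = two complete adjacent exons, Type 3 =
# all exons between the back-splice sites); everything else is partial or
# uncertain and is screened out.

STRUCTURE_LABELS <- c("type1_single_exon_full", "type2_two_exons_full",
                      "type3_multi_exon_full", "partial_or_uncertain",
                      "non_exonic")

classify_structure_one <- function(candidate, annotation, genome,
                                   tolerance_bp = 0L, edit_tolerance = 0L) {
    origin <- classify_genomic_origin(annotation, candidate$chrom,
                                      candidate$start, candidate$end,
                                      candidate$strand, tolerance_bp)
    if (origin != "exonic")
        return(list(label = "non_exonic", transcript_id = NA_character_,
                    chain_exons = NA_integer_))
    chains <- exon_chain_between(annotation, candidate$chrom,
                                 candidate$start, candidate$end,
                                 candidate$strand, tolerance_bp)
    for (chain in chains) {
        cs <- concat_exon_sequence(genome, chain, candidate$strand)
        ok <- if (edit_tolerance == 0L) identical(cs, candidate$seq)
              else utils::adist(cs, candidate$seq) <= edit_tolerance
        if (ok) {
            n <- nrow(chain)
            label <- if (n == 1L) "type1_single_exon_full"
                     else if (n == 2L) "type2_two_exons_full"
                     else "type3_multi_exon_full"
            return(list(label = label,
                        transcript_id = chain$transcript_id[1],
                        chain_exons = n))
        }
    }
    list(label = "partial_or_uncertain", transcript_id = NA_character_,
         chain_exons = NA_integer_)
}

#' Classify candidate structure against the annotated exon chain
#'
#' Each candidate is `non_exonic` when its BSJ is not anchored at exon
#' boundaries ([classify_genomic_origin()]); otherwise its sequence is
#' compared against the exon-chain concatenation of every anchoring
#' transcript. An exact match (or within `edit_tolerance` edits) yields
#' `type1_single_exon_full` / `type2_two_exons_full` /
#' `type3_multi_exon_full` by chain length; anything else is
#' `partial_or_uncertain`. Exactly one label per candidate.
#'
#' @param candidates candidate `data.table` with `candidate_id`, `chrom`,
#'   `start`, `end`, `strand`, `seq`.
#' @param annotation a [gene_annotation()].
#' @param genome a `genome_seq`.
#' @param tolerance_bp BSJ-to-exon-boundary tolerance (default 0, exact).
#' @param edit_tolerance allowed edit distance between candidate sequence
#'   and chain concatenation (default 0, exact string equality).
#' @return `data.table`: `candidate_id`, `label`, `transcript_id`,
#'   `chain_exons`.
#' @export
classify_structure <- function(candidates, annotation, genome,
                               tolerance_bp = 0L, edit_tolerance = 0L) {
    cand <- as.data.table(candidates)
    out <- lapply(seq_len(nrow(cand)), function(i) {
        r <- classify_structure_one(cand[i], annotation, genome,
                                    tolerance_bp, edit_tolerance)
        data.table(candidate_id = cand$candidate_id[i], label = r$label,
                   transcript_id = r$transcript_id,
                   chain_exons = r$chain_exons)
    })
    rbindlist(out)
}

#' Screen candidates to full-exon-chain sequences
#'
#' Retains exactly the candidates classified type 1/2/3 by
#' [classify_structure()] and reports retained/discarded counts per source
#' assembly tool.
#'
#' @inheritParams classify_structure
#' @return list with `retained` (candidate subset), `classes`
#'   (classification table), `report` (per-tool retained/discarded counts).
#' @export
screen_full_exon <- function(candidates, annotation, genome,
                             tolerance_bp = 0L, edit_tolerance = 0L) {
    cand <- as.data.table(candidates)
    cls <- classify_structure(cand, annotation, genome, tolerance_bp,
                              edit_tolerance)
    keep_ids <- cls$candidate_id[cls$label %in% STRUCTURE_LABELS[1:3]]
    retained <- cand[cand$candidate_id %in% keep_ids]
    tool <- if ("asm_tool" %in% names(cand)) cand$asm_tool
            else rep("unknown", nrow(cand))
    report <- data.table(asm_tool = tool,
                         retained = cand$candidate_id %in% keep_ids)
    report <- report[, .(n_candidates = .N, n_retained = sum(retained),
                         n_discarded = sum(!retained)), by = asm_tool]
    list(retained = retained, classes = cls, report = report)
}
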