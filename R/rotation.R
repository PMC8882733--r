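# Read-alignment validation (evaluation strategy 3): rotate each assembled
# full-length sequence by 20 bp so the back-splice junction lies inside the
# reference, align long reads to the rotated references, keep alignments
# with 0.8 <= mapped_ratio <= 1 and at most 2 bp of mismatch + insertion +
# deletion, and call a candidate verified when enough alignments survive.

#' mapped_ratio of an alignment record
#'
#' `M / L`: aligned read bases over the candidate's full-length sequence
#' length. With read-side M, insertions can push the ratio above 1, which
#' is what the upper discard bound acts on.
#'
#' @param record one alignment record (list or single-row data.frame) with
#'   `query_aligned_bases` (and `ref_start`/`ref_end` for the
#'   reference-side variant).
#' @param L candidate full-length sequence length, `> 0`.
#' @param ref_side use reference bases spanned instead of read bases
#'   (sensitivity-analysis variant; default `FALSE`).
#' @return numeric ratio.
#' @export
mapped_ratio <- function(record, L, ref_side = FALSE) {
    if (!is.numeric(L) || any(L <= 0)) stop("L must be positive")
    m <- if (ref_side) record$ref_end - record$ref_start
         else record$query_aligned_bases
    m / L
}

#' Alignment filter of the read-validation strategy
#'
#' Keeps a record iff `min_ratio <= mapped_ratio <= max_ratio` and the
#' edited bases do not exceed `max_edit_bp`. Both ratio bounds and the edit
#' bound are inclusive: 0.8, 1.0 and 2 edits all pass; discarding applies
#' only strictly beyond the bounds. By default the edit bound applies to
#' the total of mismatched + inserted + deleted bases (the stricter reading
#' of the filter); `per_category = TRUE` applies it to each category
#' separately.
#'
#' @param record alignment record(s): list or data.frame with columns
#'   `query_aligned_bases`, `mismatches`, `inserted_bases`, `deleted_bases`.
#' @param L candidate full-length sequence length.
#' @param min_ratio,max_ratio inclusive mapped_ratio bounds (defaults 0.8, 1).
#' @param max_edit_bp inclusive edit bound in bp (default 2).
#' @param per_category apply `max_edit_bp` per edit category instead of to
#'   the total.
#' @param ref_side passed to [mapped_ratio()].
#' @return logical vector, one element per record.
#' @export
passes_filters <- function(record, L, min_ratio = 0.8, max_ratio = 1.0,
                           max_edit_bp = 2L, per_category = FALSE,
                           ref_side = FALSE) {
    r <- mapped_ratio(record, L, ref_side)
    edits_ok <- if (per_category)
        record$mismatches <= max_edit_bp &
            record$inserted_bases <= max_edit_bp &
            record$deleted_bases <= max_edit_bp
    else
        (record$mismatches + record$inserted_bases +
             record$deleted_bases) <= max_edit_bp
    r >= min_ratio & r <= max_ratio & edits_ok
}

#' Validate candidates by direct long-read alignment
#'
#' For each candidate: rotate its full-length sequence by `rotation_bp`,
#' align all reads against the rotated reference (built-in aligner, or
#' records from a SAM file aligned against the rotated references), apply
#' [passes_filters()], and call the candidate verified when at least
#' `min_support` alignments survive. Candidates shorter than the rotation
#' amount cannot form a rotated reference and are marked unverifiable
#' (`verified = NA`).
#'
#' @param candidates candidate `data.table` ([read_candidates()] /
#'   [corrupt_candidates()]): needs `candidate_id` and `seq`.
#' @param reads read `data.table` with `read_id`, `seq` (ignored when
#'   `sam_path` is given).
#' @param min_support minimum surviving alignments to verify (default 1).
#' @param rotation_bp upstream fragment length moved to the end (default 20).
#' @param min_ratio,max_ratio,max_edit_bp,per_category,ref_side filter
#'   settings, see [passes_filters()].
#' @param seed_k,max_edit_fraction built-in aligner settings
#'   ([align_reads()]).
#' @param sam_path optional SAM file of reads aligned to the rotated
#'   references (reference names = candidate ids); replaces the built-in
#'   aligner.
#' @return verdict `data.table`: `candidate_id`, `strategy` (`"rotation"`),
#'   `verified`, `support` (surviving alignment count), `score` (best
#'   mapped_ratio observed).
#' @export
validate_by_reads <- function(candidates, reads, min_support = 1L,
                              rotation_bp = 20L, min_ratio = 0.8,
                              max_ratio = 1.0, max_edit_bp = 2L,
                              per_category = FALSE, ref_side = FALSE,
                              seed_k = 11L, max_edit_fraction = 0.5,
                              sam_path = NULL) {
    stopifnot(min_support >= 1L)
    cand <- as.data.table(candidates)
    usable <- nchar(cand$seq) > rotation_bp
    if (any(!usable))
        message(sum(!usable), " candidate(s) shorter than the rotation ",
                "amount marked unverifiable")
    refs <- stats::setNames(
        vapply(cand$seq[usable], rotate_sequence, "", k = rotation_bp),
        cand$candidate_id[usable])
    recs <- if (is.null(sam_path))
        align_reads(reads, refs, max_edit_fraction, seed_k)
    else
        parse_alignment_file(sam_path, refs)
    L_of <- stats::setNames(nchar(cand$seq), cand$candidate_id)
    if (nrow(recs)) {
        recs$ratio <- mapped_ratio(recs, L_of[recs$ref_id], ref_side)
        recs$pass <- passes_filters(recs, L_of[recs$ref_id], min_ratio,
                                    max_ratio, max_edit_bp, per_category,
                                    ref_side)
        stat <- recs[, .(support = sum(pass), score = max(ratio)),
                     by = .(candidate_id = ref_id)]
    } else {
        stat <- data.table(candidate_id = character(0), support = integer(0),
                           score = numeric(0))
    }
    out <- merge(data.table(candidate_id = cand$candidate_id,
                            usable = usable),
                 stat, by = "candidate_id", all.x = TRUE, sort = FALSE)
    out[is.na(support), support := 0L]
    out[, `:=`(strategy = "rotation",
               verified = ifelse(usable, support >= min_support, NA))]
    setorder(out, candidate_id)
    out[, .(candidate_id, strategy, verified, support, score)]
}
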