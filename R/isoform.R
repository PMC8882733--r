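# Isoform-set validation (evaluation strategies 1 and 2): a candidate is
# verified when a reference full-length isoform (isoCirc- or CIRI-long-style
# set, or the synthetic truth set) shares its BSJ within a tolerance and its
# sequence is circularly similar above a threshold. Strategies 1 and 2 are
# the same engine with different reference-set slots.

#' Rotation-invariant sequence identity of two circular sequences
#'
#' Maximum over all rotations (of either sequence) of the number of matched
#' bases in a match-maximizing global alignment (the longest common
#' subsequence), divided by the longer length. Symmetric by construction;
#' equals 1 exactly when the two sequences are rotations of each other.
#'
#' @param seq_a,seq_b nonempty DNA strings.
#' @return identity in `[0, 1]`.
#' @examples
#' circular_identity("ACGTAC", "GTACAC")  # rotation -> 1
#' @export
circular_identity <- function(seq_a, seq_b) {
    stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
    na <- nchar(seq_a)
    nb <- nchar(seq_b)
    if (na == nb && grepl(seq_a, strrep(seq_b, 2L), fixed = TRUE))
        return(1)
    best <- max(cpp_rotation_lcs(seq_a, seq_b), cpp_rotation_lcs(seq_b, seq_a))
    best / max(na, nb)
}

#' Match one candidate against a reference isoform set
#'
#' The reference set is first restricted to isoforms on the candidate's
#' chromosome and strand whose BSJ endpoints both lie within
#' `bsj_tolerance_bp`; only those are compared by [circular_identity()]
#' (BSJ agreement gates the sequence comparison). Isoforms whose length
#' ratio already bounds identity below the threshold are skipped.
#'
#' @param candidate single candidate (list or one-row data.frame) with
#'   `candidate_id`, `chrom`, `start`, `end`, `strand`, `seq`.
#' @param reference_set `data.table` from [read_reference_isoforms()] (or a
#'   truth table with a `circ_id`/`isoform_id` column).
#' @param identity_threshold minimum circular identity (default 0.95).
#' @param bsj_tolerance_bp BSJ endpoint tolerance in bp (default 0).
#' @param strategy_label strategy name recorded in the verdict.
#' @return one-row verdict `data.table`: `candidate_id`, `strategy`,
#'   `verified`, `support` (number of matching isoforms), `score` (best
#'   identity computed, NA when no isoform shares the BSJ).
#' @export
match_candidate <- function(candidate, reference_set,
                            identity_threshold = 0.95,
                            bsj_tolerance_bp = 0L,
                            strategy_label = "isoform") {
    stopifnot(identity_threshold > 0, identity_threshold <= 1)
    ref <- as.data.table(reference_set)
    if (!"isoform_id" %in% names(ref) && "circ_id" %in% names(ref))
        setnames(ref, "circ_id", "isoform_id")
    hit <- ref[ref$chrom == candidate$chrom & ref$strand == candidate$strand &
                   abs(ref$start - candidate$start) <= bsj_tolerance_bp &
                   abs(ref$end - candidate$end) <= bsj_tolerance_bp]
    n_match <- 0L
    best <- NA_real_
    if (nrow(hit)) {
        for (i in seq_len(nrow(hit))) {
            bound <- min(nchar(candidate$seq), nchar(hit$seq[i])) /
                max(nchar(candidate$seq), nchar(hit$seq[i]))
            if (bound < identity_threshold) {
                # identity cannot reach the threshold; record the bound
                best <- max(best, bound, na.rm = TRUE)
                next
            }
            id <- circular_identity(candidate$seq, hit$seq[i])
            best <- max(best, id, na.rm = TRUE)
            if (id >= identity_threshold) n_match <- n_match + 1L
        }
    }
    data.table(candidate_id = candidate$candidate_id,
               strategy = strategy_label, verified = n_match > 0L,
               support = n_match, score = best)
}

#' Validate a candidate set against a reference isoform set
#'
#' Vectorized [match_candidate()] over a candidate table. An empty
#' reference set leaves every candidate unverified (with a message).
#'
#' @param candidates candidate `data.table`.
#' @inheritParams match_candidate
#' @return verdict `data.table`, one row per candidate.
#' @export
validate_by_isoforms <- function(candidates, reference_set,
                                 identity_threshold = 0.95,
                                 bsj_tolerance_bp = 0L,
                                 strategy_label = "isoform") {
    cand <- as.data.table(candidates)
    if (is.null(reference_set) || nrow(reference_set) == 0L) {
        message("empty reference isoform set: no candidate can be verified")
        return(data.table(candidate_id = cand$candidate_id,
                          strategy = strategy_label, verified = FALSE,
                          support = 0L, score = NA_real_))
    }
    out <- lapply(seq_len(nrow(cand)), function(i)
        match_candidate(cand[i], reference_set, identity_threshold,
                        bsj_tolerance_bp, strategy_label))
    res <- rbindlist(out)
    setorder(res, candidate_id)
    res[]
}
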