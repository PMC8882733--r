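# Ensemble verdicts and evaluation metrics: k-of-n strategy combination,
# cross-strategy TP/FP/FN confusion counts, precision/sensitivity/F1,
# assembly rate, and precision stratified by back-splice read support.

#' k-of-n ensemble verdict
#'
#' @param verdicts logical vector, one element per strategy (NA counts as
#'   not verified).
#' @param k minimum number of verifying strategies (default 2, the
#'   "at least two of the three" rule).
#' @return `TRUE` iff at least `k` strategies verified.
#' @export
ensemble_verdict <- function(verdicts, k = 2L) {
    if (length(verdicts) == 0L) stop("empty verdict list")
    if (k < 1L || k > length(verdicts))
        stop("k must be in [1, number of strategies]")
    sum(verdicts, na.rm = TRUE) >= k
}

#' Combine per-strategy verdict tables
#'
#' @param verdict_list list of verdict `data.table`s (one per strategy,
#'   each with `candidate_id`, `verified`).
#' @param k minimum number of verifying strategies.
#' @return `data.table` with `candidate_id`, `n_verified`, `verified`.
#' @export
combine_verdicts <- function(verdict_list, k = 2L) {
    if (length(verdict_list) == 0L) stop("empty verdict list")
    if (k < 1L || k > length(verdict_list))
        stop("k must be in [1, number of strategies]")
    ids <- sort(unique(unlist(lapply(verdict_list, `[[`, "candidate_id"))))
    n_ver <- rep(0L, length(ids))
    for (v in verdict_list) {
        ver <- ids %in% v$candidate_id[!is.na(v$verified) & v$verified]
        n_ver <- n_ver + as.integer(ver)
    }
    data.table(candidate_id = ids, n_verified = n_ver, verified = n_ver >= k)
}

#' Cross-strategy confusion counts
#'
#' For each assembly strategy S: TP = candidates of S verified by long
#' reads; FP = candidates of S not verified; FN = candidates verified in
#' any OTHER assembly strategy but not assembled by S. Candidates are
#' compared by an identity key (by convention `chrom:start-end:strand`,
#' since different assemblers report differing sequences for the same
#' circRNA).
#'
#' @param assembled_sets named list: strategy -> character vector of
#'   candidate keys assembled by that strategy.
#' @param verified_sets named list with the same names: the verified subset
#'   of each strategy's keys.
#' @return `data.table` with `strategy`, `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(assembled_sets, verified_sets) {
    stopifnot(is.list(assembled_sets), is.list(verified_sets),
              setequal(names(assembled_sets), names(verified_sets)))
    for (s in names(assembled_sets)) {
        if (!all(verified_sets[[s]] %in% assembled_sets[[s]]))
            stop("verified set of strategy '", s,
                 "' is not a subset of its assembled set")
    }
    rbindlist(lapply(names(assembled_sets), function(s) {
        asm <- unique(assembled_sets[[s]])
        ver <- unique(verified_sets[[s]])
        others <- unique(unlist(verified_sets[names(verified_sets) != s]))
        data.table(strategy = s, tp = length(ver),
                   fp = length(setdiff(asm, ver)),
                   fn = length(setdiff(others, asm)))
    }))
}

#' @rdname metrics
#' @export
precision <- function(counts) {
    d <- counts$tp + counts$fp
    ifelse(d == 0, 0, counts$tp / d)
}

#' @rdname metrics
#' @export
sensitivity <- function(counts) {
    d <- counts$tp + counts$fn
    ifelse(d == 0, 0, counts$tp / d)
}

#' Precision, sensitivity and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `sensitivity = TP/(TP+FN)`,
#' `F1 = 2*precision*sensitivity/(precision+sensitivity)`; any 0/0 is
#' defined as 0. All three accept a list/data.frame with `tp`, `fp`, `fn`
#' fields (vectorized over rows).
#'
#' @param counts confusion counts with fields `tp`, `fp`, `fn`.
#' @return numeric vector in `[0, 1]`.
#' @name metrics
#' @export
f1 <- function(counts) {
    p <- precision(counts)
    s <- sensitivity(counts)
    ifelse(p + s == 0, 0, 2 * p * s / (p + s))
}

#' Metrics table from confusion counts
#'
#' @param counts `data.table` from [confusion_counts()].
#' @return the table with `precision`, `sensitivity`, `f1` columns added.
#' @export
metrics_report <- function(counts) {
    out <- as.data.table(counts)
    out$precision <- precision(out)
    out$sensitivity <- sensitivity(out)
    out$f1 <- f1(out)
    out[]
}

#' Assembly rate
#'
#' `A / I`: number of assembled circRNAs over number of identified
#' circRNAs for a tool combination.
#'
#' @param n_assembled,n_identified nonnegative counts,
#'   `n_assembled <= n_identified`, `n_identified > 0`.
#' @return numeric rate in `[0, 1]`.
#' @export
assembly_rate <- function(n_assembled, n_identified) {
    if (any(n_identified <= 0)) stop("n_identified must be positive")
    if (any(n_assembled > n_identified))
        stop("n_assembled cannot exceed n_identified")
    n_assembled / n_identified
}

#' Precision stratified by back-splice read support
#'
#' For each threshold `t`, precision (fraction verified) over candidates
#' with `support >= t`; the stratum size `n` is reported so sparse strata
#' stay interpretable. Empty strata get `NA` precision, not 0.
#'
#' @param candidates candidate `data.table` with `candidate_id`, `support`.
#' @param verdicts verdict `data.table` with `candidate_id`, `verified`.
#' @param thresholds ascending integer support thresholds (default 1:10).
#' @return `data.table` with `threshold`, `precision`, `n`.
#' @export
stratified_precision <- function(candidates, verdicts, thresholds = 1:10) {
    if (is.unsorted(thresholds)) stop("thresholds must be ascending")
    m <- merge(as.data.table(candidates)[, .(candidate_id, support)],
               as.data.table(verdicts)[, .(candidate_id, verified)],
               by = "candidate_id")
    rbindlist(lapply(thresholds, function(t) {
        sel <- m$support >= t
        data.table(threshold = t,
                   precision = if (!any(sel)) NA_real_
                               else mean(m$verified[sel], na.rm = TRUE),
                   n = sum(sel))
    }))
}

#' Venn-style overlap of verified sets across strategies
#'
#' Counts candidates by the exact combination of strategies that verified
#' them (region sizes of the Venn diagram over verified sets); candidates
#' verified by no strategy are reported under `"none"`.
#'
#' @param verdict_list named list of verdict `data.table`s (one per
#'   strategy, each with `candidate_id`, `verified`).
#' @return `data.table` with `strategies` (`+`-joined combination) and `n`,
#'   sorted by decreasing `n`.
#' @export
strategy_overlap <- function(verdict_list) {
    if (length(verdict_list) == 0L) stop("empty verdict list")
    if (is.null(names(verdict_list)))
        names(verdict_list) <- paste0("S", seq_along(verdict_list))
    ids <- sort(unique(unlist(lapply(verdict_list, `[[`, "candidate_id"))))
    combo <- rep("", length(ids))
    for (nm in names(verdict_list)) {
        v <- verdict_list[[nm]]
        hit <- ids %in% v$candidate_id[!is.na(v$verified) & v$verified]
        combo[hit] <- paste(combo[hit], nm, sep = "+")
    }
    combo <- sub("^\\+", "", combo)
    combo[combo == ""] <- "none"
    out <- data.table(strategies = combo)[, .(n = .N), by = strategies]
    setorder(out, -n, strategies)
    out[]
}

#' Filter candidates by minimum back-splice read support
#'
#' The candidate-selection rule applied before evaluation: keep candidates
#' supported by at least `min_reads` back-splice reads (default 2).
#'
#' @param candidates candidate `data.table` with a `support` column.
#' @param min_reads minimum support (default 2).
#' @return the retained subset.
#' @export
min_support_filter <- function(candidates, min_reads = 2L) {
    stopifnot(min_reads >= 0L)
    cand <- as.data.table(candidates)
    cand[cand$support >= min_reads]
}
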