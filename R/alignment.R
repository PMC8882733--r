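# Alignment contract used by read validation. The built-in aligner is an
# exact unit-cost local aligner (match +1, mismatch/indel -1, Rcpp) gated by
# an exact k-mer seed-sharing prefilter; a SAM adapter ingests alignments
# produced by an external long-read aligner instead.
#
# "Mapped bases" (the M of mapped_ratio = M/L) counts READ bases consumed by
# match/mismatch/insertion columns, not reference span: insertions can then
# push M above the reference length L, which is the only way the discard
# rule for mapped_ratio > 1 can trigger. The reference-side alternative is
# available via `ref_side = TRUE` for sensitivity analysis.

empty_alignment_table <- function() {
    data.table(query_id = character(0), ref_id = character(0),
               score = integer(0), query_aligned_bases = integer(0),
               mismatches = integer(0), inserted_bases = integer(0),
               deleted_bases = integer(0), ref_start = integer(0),
               ref_end = integer(0))
}

#' Locally align one read against one reference
#'
#' Best-scoring local alignment under unit costs; among co-optimal
#' alignments the one with fewest edited bases is reported. Returns zero
#' rows when read and reference share no exact `seed_k`-mer, or when the
#' best alignment's edit fraction (edits / aligned read bases) exceeds
#' `max_edit_fraction`.
#'
#' @param read,reference DNA strings (nonempty).
#' @param max_edit_fraction maximum (mismatch+ins+del) / aligned-read-bases.
#' @param seed_k exact-match seed length gating the alignment (default 11).
#' @return `data.table` with 0 or 1 row: `query_id`, `ref_id`, `score`,
#'   `query_aligned_bases`, `mismatches`, `inserted_bases`, `deleted_bases`,
#'   `ref_start`, `ref_end` (reference interval, 0-based half-open).
#' @export
align_local <- function(read, reference, max_edit_fraction = 0.5,
                        seed_k = 11L) {
    stopifnot(nchar(read) > 0, nchar(reference) > 0)
    hits <- cpp_seed_hits(read, reference, as.integer(seed_k))[[1]]
    if (length(hits) == 0L) return(empty_alignment_table())
    a <- cpp_local_align(read, reference)
    alignment_record(a, "read", "ref", max_edit_fraction)
}

alignment_record <- function(a, query_id, ref_id, max_edit_fraction) {
    if (a$score <= 0L) return(empty_alignment_table())
    edits <- a$mismatches + a$inserted_bases + a$deleted_bases
    if (edits > max_edit_fraction * a$query_aligned_bases)
        return(empty_alignment_table())
    data.table(query_id = query_id, ref_id = ref_id, score = a$score,
               query_aligned_bases = a$query_aligned_bases,
               mismatches = a$mismatches, inserted_bases = a$inserted_bases,
               deleted_bases = a$deleted_bases,
               ref_start = a$r_start - 1L, ref_end = a$r_end)
}

#' Align many reads against many references (seed-gated)
#'
#' One shared k-mer index over all references; each read is aligned only
#' against references it shares a seed with.
#'
#' @param reads data.frame with `read_id`, `seq`.
#' @param refs named character vector of reference sequences.
#' @inheritParams align_local
#' @return alignment `data.table` (see [align_local()]), one row per
#'   surviving read/reference pair.
#' @export
align_reads <- function(reads, refs, max_edit_fraction = 0.5, seed_k = 11L) {
    if (nrow(reads) == 0L || length(refs) == 0L)
        return(empty_alignment_table())
    stopifnot(!is.null(names(refs)))
    hits <- cpp_seed_hits(reads$seq, unname(refs), as.integer(seed_k))
    out <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
        h <- hits[[i]]
        if (length(h) == 0L) next
        rec <- lapply(h, function(t) alignment_record(
            cpp_local_align(reads$seq[i], refs[[t]]),
            reads$read_id[i], names(refs)[t], max_edit_fraction))
        out[[i]] <- rbindlist(rec)
    }
    res <- rbindlist(out)
    if (nrow(res) == 0L) empty_alignment_table() else res
}

parse_cigar <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    if (length(ops) == 0L) return(NULL)
    data.table(len = as.integer(sub(".$", "", ops)),
               op = sub("^\\d+", "", ops))
}

md_mismatches <- function(md) {
    # mismatched reference bases appear as single letters outside ^-deletion
    # runs in the MD tag
    md <- gsub("\\^[A-Z]+", "", md)
    sum(gregexpr("[A-Z]", md)[[1]] > 0)
}

#' Parse a SAM file into alignment records
#'
#' Adapter for external long-read aligners (e.g. minimap2 -a). Aligned read
#' bases are the sum of M/=/X/I CIGAR lengths (clips excluded), deletions
#' the sum of D lengths; mismatches are `NM - I - D` when the NM tag is
#' present, otherwise counted from the MD tag. Unmapped records are
#' skipped; a mapped record with CIGAR `*` is skipped with a warning.
#'
#' @param path SAM file path.
#' @param references optional named character vector of reference sequences
#'   used to sanity-check reference ids.
#' @return alignment `data.table` (see [align_local()]).
#' @export
parse_alignment_file <- function(path, references = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ".circfleval"),
                            overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos", "cigar", "flag"),
        tag = c("NM", "MD"))
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    n <- length(x$qname)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        if (bitwAnd(x$flag[i], 4L) != 0L) next  # unmapped
        cig <- x$cigar[i]
        if (is.na(cig) || cig == "*") {
            warning("mapped record with CIGAR '*' skipped: ", x$qname[i])
            next
        }
        ct <- parse_cigar(cig)
        qa <- sum(ct$len[ct$op %in% c("M", "=", "X", "I")])
        ins <- sum(ct$len[ct$op == "I"])
        del <- sum(ct$len[ct$op == "D"])
        ref_consumed <- sum(ct$len[ct$op %in% c("M", "=", "X", "D", "N")])
        nm <- x$tag$NM[i]
        if (!is.null(nm) && !is.na(nm)) {
            mm <- nm - ins - del
        } else {
            md <- x$tag$MD[i]
            if (is.null(md) || is.na(md))
                stop("record ", x$qname[i], " has neither NM nor MD tag")
            mm <- md_mismatches(md)
        }
        if (mm < 0L) stop("inconsistent NM tag for record ", x$qname[i])
        rid <- as.character(x$rname[i])
        if (!is.null(references) && !(rid %in% names(references)))
            stop("alignment reference not in reference set: ", rid)
        out[[i]] <- data.table(
            query_id = x$qname[i], ref_id = rid, score = NA_integer_,
            query_aligned_bases = qa, mismatches = as.integer(mm),
            inserted_bases = ins, deleted_bases = del,
            ref_start = x$pos[i] - 1L,
            ref_end = x$pos[i] - 1L + ref_consumed)
    }
    res <- rbindlist(out)
    if (nrow(res) == 0L) empty_alignment_table() else res
}
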