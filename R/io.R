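# Plain-text readers/writers for the pipeline's exchange formats.
# Sequence IO goes through Biostrings; tables are TSV with a header line and
# stable column order so runs can be diffed byte for byte.

#' Write named sequences as FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                                width = 70L)
    invisible(path)
}

#' Write reads as FASTQ (constant quality)
#' @param reads data.frame with `read_id` and `seq` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
    ss <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
    Biostrings::writeXStringSet(
        ss, path, format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", nchar(reads$seq))))
    invisible(path)
}

#' Read a FASTQ file of long reads
#' @param path FASTQ path.
#' @return `data.table` with `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
    data.table(read_id = sub("\\s.*$", "", names(ss)),
               seq = toupper(as.character(ss)))
}

# BED6: chrom, start, end, name, score, strand (0-based half-open passthrough)
write_bed6 <- function(x, path, name_col = "candidate_id",
                       score_col = "support") {
    dt <- data.table(chrom = x$chrom, start = x$start, end = x$end,
                     name = x[[name_col]],
                     score = if (score_col %in% names(x)) x[[score_col]] else 0L,
                     strand = x$strand)
    fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

# BED12 for the truth set (block structure = exon chain)
write_bed12 <- function(truth, path) {
    dt <- data.table(truth$chrom, truth$start, truth$end, truth$circ_id,
                     0L, truth$strand, truth$start, truth$end, "0,0,0",
                     truth$n_exons, truth$block_sizes, truth$block_starts)
    fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read an assembled-candidate set
#'
#' Candidates are exchanged as a FASTA of full-length sequences plus a BED6
#' of BSJ intervals (name = candidate id, score = back-splice read support)
#' and an optional TSV of per-candidate metadata (`candidate_id`, `support`,
#' `id_tool`, `asm_tool`, and for synthetic data `label`, `circ_id`).
#'
#' @param fasta,bed,tsv input paths (`tsv` may be `NULL`).
#' @return `data.table` of candidates.
#' @export
read_candidates <- function(fasta, bed, tsv = NULL) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- data.table(candidate_id = sub("\\s.*$", "", names(ss)),
                       seq = toupper(as.character(ss)))
    bd <- fread(bed, header = FALSE,
                col.names = c("chrom", "start", "end", "candidate_id",
                              "support", "strand"))
    out <- merge(bd, seqs, by = "candidate_id", sort = FALSE)
    if (nrow(out) != nrow(bd))
        stop("candidate FASTA and BED do not agree on candidate ids")
    if (!is.null(tsv)) {
        meta <- fread(tsv)
        out[, support := NULL]
        out <- merge(out, meta, by = "candidate_id", sort = FALSE)
    } else {
        out[, `:=`(id_tool = "unknown", asm_tool = "unknown")]
    }
    setorder(out, candidate_id)
    out[]
}

write_candidates <- function(candidates, fasta, bed, tsv) {
    write_fasta(stats::setNames(candidates$seq, candidates$candidate_id),
                fasta)
    write_bed6(candidates, bed)
    meta_cols <- intersect(c("candidate_id", "support", "id_tool", "asm_tool",
                             "label", "circ_id"), names(candidates))
    fwrite(candidates[, meta_cols, with = FALSE], tsv, sep = "\t")
    invisible(NULL)
}

#' Read a reference full-length isoform set
#'
#' The FASTA+BED pair stands in for converted isoCirc or CIRI-long output
#' (or the synthetic truth set): full-length sequences keyed by isoform id,
#' with BSJ intervals and strands in the BED.
#'
#' @param fasta,bed input paths.
#' @return `data.table` with `isoform_id`, `chrom`, `start`, `end`,
#'   `strand`, `seq`.
#' @export
read_reference_isoforms <- function(fasta, bed) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- data.table(isoform_id = sub("\\s.*$", "", names(ss)),
                       seq = toupper(as.character(ss)))
    bd <- fread(bed, header = FALSE, fill = TRUE)
    bd <- bd[, c(1:4, 6), with = FALSE]
    setnames(bd, c("chrom", "start", "end", "isoform_id", "strand"))
    out <- merge(bd, seqs, by = "isoform_id", sort = FALSE)
    if (nrow(out) == 0L) warning("reference isoform set is empty")
    setorder(out, isoform_id)
    out[]
}

write_tsv <- function(x, path) {
    fwrite(x, path, sep = "\t")
    invisible(path)
}
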