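# Genome and gene-annotation model.
#
# Internal coordinates are 0-based half-open everywhere; GTF reading/writing
# converts the 1-based inclusive convention at the boundary, BED-style inputs
# pass through unchanged.

#' Read a genome FASTA
#'
#' @param path path to a FASTA file with at least one record.
#' @return a named character vector of uppercase chromosome sequences with
#'   class `genome_seq`; record order is preserved.
#' @export
read_genome_fasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) stop("FASTA file has no records: ", path)
    chroms <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(chroms))
        stop("duplicate chromosome name in FASTA: ",
             chroms[duplicated(chroms)][1])
    seqs <- toupper(as.character(ss))
    names(seqs) <- chroms
    check_dna_alphabet(seqs, "genome sequence")
    if (any(nchar(seqs) == 0L)) stop("empty sequence record in FASTA")
    structure(seqs, class = "genome_seq")
}

genome_subseq <- function(genome, chrom, start, end) {
    # 0-based half-open extraction
    s <- genome[[chrom]]
    if (is.null(s)) stop("chromosome not in genome: ", chrom)
    if (start < 0 || end > nchar(s) || start >= end)
        stop("interval [", start, ",", end, ") out of bounds for ", chrom,
             " (length ", nchar(s), ")")
    substr(s, start + 1L, end)
}

#' Construct a gene annotation from an exon table
#'
#' @param exons a data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `transcript_id`, `gene_id`.
#' @return a `gene_annotation` object: exon table sorted and ranked per
#'   transcript plus derived transcript and gene-span tables.
#' @export
gene_annotation <- function(exons) {
    ex <- as.data.table(exons)
    need <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
    if (!all(need %in% names(ex)))
        stop("exon table must have columns: ", paste(need, collapse = ", "))
    ex <- ex[, .(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end), strand = as.character(strand),
                 transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id))]
    if (nrow(ex)) {
        if (any(ex$start < 0L | ex$start >= ex$end))
            stop("invalid exon interval: need 0 <= start < end")
        if (!all(ex$strand %in% c("+", "-")))
            stop("strand must be '+' or '-'")
        bad <- ex[, .(n = length(unique(paste(chrom, strand)))),
                  by = transcript_id][n > 1L]
        if (nrow(bad))
            stop("transcript on multiple chromosomes/strands: ",
                 bad$transcript_id[1])
        setorder(ex, chrom, transcript_id, start)
        ovl <- ex[, any(start[-1] < end[-.N]), by = transcript_id][V1 == TRUE]
        if (nrow(ovl))
            stop("overlapping exons within transcript: ", ovl$transcript_id[1])
        ex[, exon_rank := seq_len(.N), by = transcript_id]
    } else {
        ex[, exon_rank := integer(0)]
    }
    if (nrow(ex)) {
        tx <- ex[, .(gene_id = gene_id[1], chrom = chrom[1],
                     strand = strand[1], n_exons = .N,
                     tx_start = min(start), tx_end = max(end)),
                 by = transcript_id]
        gn <- tx[, .(chrom = chrom[1], strand = strand[1],
                     start = min(tx_start), end = max(tx_end)),
                 by = gene_id]
    } else {
        tx <- data.table(transcript_id = character(0), gene_id = character(0),
                         chrom = character(0), strand = character(0),
                         n_exons = integer(0), tx_start = integer(0),
                         tx_end = integer(0))
        gn <- data.table(gene_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0))
    }
    structure(list(exons = ex, transcripts = tx, genes = gn),
              class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
    cat("gene_annotation:", nrow(x$genes), "genes,",
        nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons\n")
    invisible(x)
}

#' Read a GTF gene annotation
#'
#' Only `exon` features are used; they must carry `gene_id` and
#' `transcript_id` attributes. GTF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param path path to a GTF file.
#' @return a [gene_annotation()] object.
#' @export
read_gtf <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) {
        warning("GTF contains no exon features; annotation is empty")
        return(gene_annotation(data.table(
            chrom = character(0), start = integer(0), end = integer(0),
            strand = character(0), transcript_id = character(0),
            gene_id = character(0))))
    }
    tid <- gr$transcript_id
    gid <- gr$gene_id
    if (is.null(tid) || anyNA(tid))
        stop("exon feature missing transcript_id attribute")
    if (is.null(gid) || anyNA(gid))
        stop("exon feature missing gene_id attribute")
    gene_annotation(data.table(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        transcript_id = tid, gene_id = gid))
}

#' Write a gene annotation as GTF
#'
#' Emits one `exon` line per exon (coordinates converted back to 1-based
#' inclusive); `read_gtf(write_gtf(ann))` reproduces the exon table exactly.
#'
#' @param annotation a [gene_annotation()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
    stopifnot(inherits(annotation, "gene_annotation"))
    ex <- annotation$exons
    lines <- sprintf(
        "%s\tcircfleval\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id,
        ex$transcript_id)
    writeLines(lines, path)
    invisible(path)
}

#' Exon chains anchored at both back-splice sites
#'
#' For each transcript on `chrom`/`strand`, finds the run of consecutive
#' exons whose first exon start matches `bsj_start` and whose last exon end
#' matches `bsj_end`, each within `tolerance_bp`. A chain is the annotated
#' exon structure a full-length circRNA anchored at those back-splice sites
#' should contain.
#'
#' @param annotation a [gene_annotation()] object.
#' @param chrom chromosome name.
#' @param bsj_start,bsj_end BSJ interval, 0-based half-open,
#'   `bsj_start < bsj_end`.
#' @param strand `"+"` or `"-"`.
#' @param tolerance_bp maximum distance between a BSJ endpoint and an exon
#'   boundary for the endpoint to count as anchored (default 0: exact).
#' @return list of exon chains (one per anchoring transcript), each a
#'   `data.table` of exon rows; empty list when no transcript anchors both
#'   ends (including when the chromosome is absent).
#' @export
exon_chain_between <- function(annotation, chrom, bsj_start, bsj_end, strand,
                               tolerance_bp = 0L) {
    stopifnot(inherits(annotation, "gene_annotation"),
              bsj_start < bsj_end, tolerance_bp >= 0)
    sel <- annotation$exons$chrom == chrom & annotation$exons$strand == strand
    ex <- annotation$exons[sel]
    if (nrow(ex) == 0L) return(list())
    chains <- list()
    for (tid in unique(ex$transcript_id)) {
        te <- ex[ex$transcript_id == tid]
        setorder(te, start)
        ds <- abs(te$start - bsj_start)
        de <- abs(te$end - bsj_end)
        if (!any(ds <= tolerance_bp) || !any(de <= tolerance_bp)) next
        i <- which(ds == min(ds))[1]
        j <- which(de == min(de))[1]
        if (ds[i] > tolerance_bp || de[j] > tolerance_bp || j < i) next
        chains[[length(chains) + 1L]] <- te[i:j]
    }
    chains
}

#' Concatenate exon sequences of a chain
#'
#' Exon substrings are concatenated in genomic order; for minus-strand
#' chains the concatenation is reverse-complemented as a whole, matching the
#' convention of annotation-based circRNA assemblers.
#'
#' @param genome a `genome_seq` object ([read_genome_fasta()]).
#' @param chain a data.frame of exons (single chromosome), as returned by
#'   [exon_chain_between()].
#' @param strand `"+"` or `"-"`.
#' @return DNA string of the spliced sequence.
#' @export
concat_exon_sequence <- function(genome, chain, strand) {
    chain <- as.data.table(chain)
    if (nrow(chain) == 0L) stop("empty exon chain")
    if (length(unique(chain$chrom)) != 1L)
        stop("chain spans multiple chromosomes")
    setorder(chain, start)
    s <- paste(mapply(genome_subseq, chain$start, chain$end,
                      MoreArgs = list(genome = genome, chrom = chain$chrom[1])),
               collapse = "")
    if (strand == "-") revcomp(s) else s
}

#' Classify the genomic origin of a BSJ interval
#'
#' `exonic` when both BSJ endpoints coincide (within `tolerance_bp`) with
#' exon boundaries of a single transcript; `intronic` when the interval lies
#' inside a same-strand gene span but is not exonic; `intergenic` otherwise.
#'
#' @inheritParams exon_chain_between
#' @param start,end BSJ interval, 0-based half-open.
#' @return one of `"exonic"`, `"intronic"`, `"intergenic"`.
#' @export
classify_genomic_origin <- function(annotation, chrom, start, end, strand,
                                    tolerance_bp = 0L) {
    if (length(exon_chain_between(annotation, chrom, start, end, strand,
                                  tolerance_bp)) > 0L)
        return("exonic")
    gn <- annotation$genes
    inside <- gn$chrom == chrom & gn$strand == strand &
        gn$start <= start & end <= gn$end
    if (any(inside)) "intronic" else "intergenic"
}
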