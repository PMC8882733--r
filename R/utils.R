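# Small DNA string helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (alphabet ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
    stopifnot(is.character(x))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Rotate a sequence k positions to the left
#'
#' Moves the first `k` characters to the end, so the former position `k + 1`
#' becomes the new first base. Used to internalize a back-splice junction:
#' after rotation the junction lies `k` bases before the end of the sequence.
#'
#' @param sequence a single DNA string.
#' @param k integer, number of leading bases moved to the end;
#'   `0 <= k < nchar(sequence)`.
#' @return the rotated string, same length.
#' @examples
#' rotate_sequence("ACGTACGTAC", 3)
#' @export
rotate_sequence <- function(sequence, k) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    n <- nchar(sequence)
    if (!is.numeric(k) || length(k) != 1L || k < 0)
        stop("k must be a single nonnegative integer")
    k <- as.integer(k)
    if (n <= k)
        stop("sequence length (", n, ") must exceed rotation amount (", k, ")")
    if (k == 0L) return(sequence)
    paste0(substr(sequence, k + 1L, n), substr(sequence, 1L, k))
}

# random DNA string of length n; GC content gc in [0, 1]
random_dna <- function(n, gc = 0.5) {
    stopifnot(n >= 1, gc >= 0, gc <= 1)
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# uniform integer draw on an inclusive [lo, hi] range given as length-2
# vector; guards the sample() scalar expansion when lo == hi
runif_int <- function(n, range) {
    stopifnot(length(range) == 2L, range[1] <= range[2])
    if (range[1] == range[2]) return(rep(as.integer(range[1]), n))
    sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

check_dna_alphabet <- function(x, what = "sequence") {
    bad <- grepl("[^ACGTN]", x)
    if (any(bad))
        stop(what, " contains characters outside {A,C,G,T,N}: ",
             paste(head(names(x)[bad] %||% which(bad), 3), collapse = ", "))
    invisible(TRUE)
}
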