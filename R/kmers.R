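# Low-level k-mer string helpers shared by discovery, mapping and annotation.

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over plain character vectors. `N` maps to
#' `N`; input is uppercased first.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AANT"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", toupper(x)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement, collapsing the two sequencing strands
#' onto one representative.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmers("TTTT") # "AAAA"
#' @export
canonical_kmers <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# All k-mers of one sequence, in order of occurrence. Returns character(0)
# when the sequence is shorter than k.
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# k-mer table for many sequences at once: tibble(seq_idx, pos, kmer).
# Vectorised by grouping sequences of equal length so each offset is one
# substring() call over the whole group.
kmer_table <- function(seqs, k) {
  n <- nchar(seqs)
  keep <- which(n >= k)
  if (length(keep) == 0L) {
    return(tibble(seq_idx = integer(0), pos = integer(0), kmer = character(0)))
  }
  parts <- lapply(split(keep, n[keep]), function(idx) {
    len <- n[idx[1L]]
    s <- seqs[idx]
    npos <- len - k + 1L
    km <- character(length(idx) * npos)
    for (p in seq_len(npos)) {
      km[(p - 1L) * length(idx) + seq_along(idx)] <- substring(s, p, p + k - 1L)
    }
    tibble(
      seq_idx = rep(idx, times = npos),
      pos = rep(seq_len(npos), each = length(idx)),
      kmer = km
    )
  })
  bind_rows(parts)
}

# Canonical k-mer *set* of a set of sequences (k-mers containing N dropped).
canonical_kmer_set <- function(seqs, k) {
  tab <- kmer_table(toupper(seqs), k)
  km <- tab$kmer[!stringr::str_detect(tab$kmer, "N")]
  unique(canonical_kmers(km))
}
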