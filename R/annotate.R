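# k-mer containment classification of kChains against contaminant
# references (cpDNA, mtDNA, adapters, ...).

#' Build a contaminant k-mer index
#'
#' The index is the canonical k-mer set of one labelled reference
#' collection (e.g. chloroplast assemblies, mitochondrial genomes, adapter
#' lists).
#'
#' @param refs Reference sequences: a FASTA path, a tibble (`id`, `seq`),
#'   or a character vector.
#' @param label Class label assigned to matching kChains.
#' @param k k-mer length (>= 8).
#' @return A `contaminant_index` (list: `label`, `k`, `kmers` set).
#' @export
build_contaminant_index <- function(refs, label, k = 12L) {
  stopifnot(k >= 8)
  seqs <- if (is.character(refs) && length(refs) == 1L && file.exists(refs)) {
    read_sequences(refs, "fasta")$seq
  } else if (is.data.frame(refs)) {
    refs$seq
  } else {
    as.character(refs)
  }
  if (length(seqs) == 0L) abort("contaminant reference set is empty")
  kmers <- canonical_kmer_set(seqs, k)
  if (length(kmers) == 0L) {
    warn(paste0("k = ", k, " exceeds every reference length; index '", label, "' is empty"))
  }
  structure(list(label = label, k = as.integer(k), kmers = kmers),
    class = "contaminant_index"
  )
}

#' Classify kChains by k-mer containment
#'
#' For each sequence, containment against an index is the fraction of the
#' sequence's canonical k-mers present in the index's k-mer set. A sequence
#' is assigned the label of the highest-containment index whose containment
#' reaches `threshold`; otherwise it is `"nuclear"`. Ties are broken by
#' index order.
#'
#' @param kchains kChain tibble (`kchain_id`, `seq`) from
#'   [discover_kchains()], or a character vector of sequences.
#' @param indexes List of [build_contaminant_index()] objects.
#' @param threshold Containment threshold in `(0, 1]` (default 0.5).
#' @return A tibble `kchain_id`, `label`, `containment`.
#' @export
classify_kchains <- function(kchains, indexes, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  kc <- if (is.character(kchains)) {
    tibble(kchain_id = paste0("kchain_", seq_along(kchains)), seq = kchains)
  } else {
    tibble(kchain_id = kchains$kchain_id, seq = kchains$seq)
  }
  if (nrow(kc) == 0L) {
    return(tibble(kchain_id = character(0), label = character(0), containment = numeric(0)))
  }
  cont <- sapply(indexes, function(ix) {
    vapply(kc$seq, function(s) {
      km <- canonical_kmer_set(s, ix$k)
      if (length(km) == 0L) return(0)
      mean(km %in% ix$kmers)
    }, numeric(1), USE.NAMES = FALSE)
  })
  cont <- matrix(cont, nrow = nrow(kc))
  if (length(indexes) == 0L) {
    return(tibble(kchain_id = kc$kchain_id, label = "nuclear", containment = 0))
  }
  best <- apply(cont, 1L, which.max)
  best_c <- cont[cbind(seq_len(nrow(kc)), best)]
  tibble(
    kchain_id = kc$kchain_id,
    label = ifelse(best_c >= threshold,
      vapply(indexes, function(ix) ix$label, character(1))[best],
      "nuclear"
    ),
    containment = best_c
  )
}

#' Partition a kChain library into contamination bins
#'
#' Every kChain lands in exactly one bin; the `"nuclear"` bin is the
#' default downstream input, while e.g. a `"chloroplast"` bin can feed its
#' own quantification/ordination path.
#'
#' @inheritParams classify_kchains
#' @return Named list of kChain tibbles (one per label, plus `"nuclear"`),
#'   each with the `label` and `containment` columns appended.
#' @export
partition_library <- function(kchains, indexes, threshold = 0.5) {
  cls <- classify_kchains(kchains, indexes, threshold)
  kc <- left_join(kchains, cls, by = "kchain_id")
  labels <- unique(c("nuclear", vapply(indexes, function(ix) ix$label, character(1))))
  out <- lapply(labels, function(lb) filter(kc, .data$label == lb))
  names(out) <- labels
  out
}
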