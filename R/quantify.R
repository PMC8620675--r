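# Read-to-repeat mapping and abundance computation.

#' Map reads to repeat references with a gapless seed-and-extend mapper
#'
#' A lightweight local mapper for substitution-level divergence: exact
#' `seed_k`-mer seeds anchor each read to reference diagonals on both
#' strands, the seed is extended without gaps while the running identity of
#' the matched region stays at or above `min_identity`, and every read is
#' assigned to at most one reference -- the best-scoring match, ties broken
#' by reference order ("one alignment" per read). Covered reference
#' positions are incremented by one per mapped read.
#'
#' @param reads Read tibble (`id`, `seq`).
#' @param references Reference tibble (`id`/`kchain_id`, `seq`) or named
#'   character vector of sequences.
#' @param seed_k Exact seed length (default 12).
#' @param min_identity Minimum running identity in `(0.5, 1]` (default 0.9).
#' @param min_score Minimum matched bases for an alignment to count
#'   (default 25): the analogue of a local aligner's score floor, it keeps
#'   bare seed coincidences from depositing coverage.
#' @param chunk_size Reads per processing chunk (memory/speed knob).
#' @return Coverage tibble: `ref_id`, `length`, list-column `depth`.
#' @export
map_reads <- function(reads, references, seed_k = 12L, min_identity = 0.9,
                      min_score = 25L, chunk_size = 5000L) {
  stopifnot(min_identity > 0.5, min_identity <= 1)
  refs <- as_reference_tbl(references)
  if (nrow(refs) == 0L) abort("references must be non-empty")
  ref_seqs <- toupper(refs$seq)
  ref_len <- nchar(ref_seqs)
  # forward-strand seed index over all references
  idx <- kmer_table(ref_seqs, seed_k) |>
    rename(ref_idx = "seq_idx", ref_pos = "pos")
  hits_all <- vector("list", 0L)
  n <- nrow(reads)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  for (ch in chunks) {
    fwd <- toupper(reads$seq[ch])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      kt <- kmer_table(s, seed_k)
      if (nrow(kt) == 0L) next
      joined <- inner_join(kt, idx, by = "kmer", relationship = "many-to-many")
      if (nrow(joined) == 0L) next
      cand <- joined |>
        mutate(diag = .data$ref_pos - .data$pos) |>
        group_by(.data$seq_idx, .data$ref_idx, .data$diag) |>
        summarise(pos = min(.data$pos), .groups = "drop")
      ext <- .extend_candidates_cpp(
        s, ref_seqs, cand$seq_idx, cand$ref_idx, cand$diag, cand$pos,
        as.integer(seed_k), min_identity
      )
      res <- tibble(
        read_idx = ch[cand$seq_idx], ref_idx = cand$ref_idx,
        diag = cand$diag, strand = strand,
        score = ext$score, ref_start = ext$ref_start, ref_end = ext$ref_end
      )
      hits_all[[length(hits_all) + 1L]] <- res
    }
  }
  score_floor <- max(min_score, seed_k)
  cover <- if (length(hits_all)) {
    bind_rows(hits_all) |>
      filter(.data$score >= score_floor) |>
      # best alignment per read: highest score, then reference order, then
      # strand (+ first), then leftmost diagonal
      arrange(
        .data$read_idx, dplyr::desc(.data$score), .data$ref_idx,
        .data$strand, .data$diag
      ) |>
      distinct(.data$read_idx, .keep_all = TRUE)
  } else {
    tibble(ref_idx = integer(0), ref_start = integer(0), ref_end = integer(0))
  }
  depth <- lapply(seq_len(nrow(refs)), function(i) {
    rows <- cover[cover$ref_idx == i, , drop = FALSE]
    if (nrow(rows) == 0L) return(integer(ref_len[i]))
    cv <- IRanges::coverage(
      IRanges::IRanges(start = rows$ref_start, end = rows$ref_end),
      width = ref_len[i]
    )
    as.integer(cv)
  })
  tibble(ref_id = refs$id, length = ref_len, depth = depth)
}

as_reference_tbl <- function(references) {
  if (is.character(references)) {
    tibble(id = names(references), seq = unname(references))
  } else {
    ids <- if ("id" %in% names(references)) references$id else references$kchain_id
    tibble(id = ids, seq = references$seq)
  }
}

#' Abundance of a repeat from its coverage profile
#'
#' Abundance is the median (default) or mean of per-position coverage over
#' all positions of the repeat sequence, zeros included.
#'
#' @param profiles Coverage tibble from [map_reads()] or
#'   [coverage_from_sam()] (`ref_id`, `length`, `depth`).
#' @param statistic `"median"` or `"mean"`.
#' @return A tibble `ref_id`, `abundance`.
#' @export
abundance <- function(profiles, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  fn <- if (statistic == "median") {
    function(d) as.numeric(median(d))
  } else {
    function(d) mean(d)
  }
  tibble(
    ref_id = profiles$ref_id,
    abundance = purrr::map_dbl(profiles$depth, fn)
  )
}

#' Build the raw abundance matrix from per-sample coverage profiles
#'
#' @param profiles_by_sample Named list (sample id -> coverage tibble).
#'   A reference absent from a sample's profiles counts as all-zero.
#' @param manifest Sample manifest tibble (`sample_id`, `species`,
#'   `replicate`); column order of the matrix follows it.
#' @param statistic Passed to [abundance()].
#' @return An [abundance_matrix()] in state `"raw"`.
#' @export
build_abundance_matrix <- function(profiles_by_sample, manifest,
                                   statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  validate_manifest(manifest)
  if (!all(manifest$sample_id %in% names(profiles_by_sample))) {
    abort("profiles_by_sample must cover every manifest sample")
  }
  for (p in profiles_by_sample) {
    if (anyDuplicated(p$ref_id)) abort("duplicated reference ids in profiles")
  }
  ref_ids <- unique(unlist(lapply(profiles_by_sample, function(p) p$ref_id)))
  vals <- sapply(manifest$sample_id, function(sid) {
    ab <- abundance(profiles_by_sample[[sid]], statistic)
    out <- setNames(numeric(length(ref_ids)), ref_ids)
    out[ab$ref_id] <- ab$abundance
    out
  })
  vals <- matrix(vals,
    nrow = length(ref_ids),
    dimnames = list(ref_ids, manifest$sample_id)
  )
  abundance_matrix(vals, manifest, state = "raw")
}
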