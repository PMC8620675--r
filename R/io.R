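# Readers/writers for FASTA/FASTQ/SAM/TSV and read subsampling.

#' Read sequences from FASTA or FASTQ
#'
#' Parses a (possibly gzipped) FASTA or FASTQ file into a read tibble with
#' one row per record, in file order. Sequences are uppercased; `N` bases
#' are preserved.
#'
#' @param path Path to the sequence file (plain or `.gz`).
#' @param format `"fasta"` or `"fastq"`. Defaults to a guess from the file
#'   extension.
#' @return A tibble with columns `id`, `seq` and (for FASTQ) `qual`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_sequences(fq)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  res <- tryCatch(
    {
      if (format == "fastq") {
        ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
        qual <- as.character(S4Vectors::mcols(ss)$qualities)
        tibble(
          id = names(ss) %||% character(0),
          seq = unname(toupper(as.character(ss))),
          qual = if (length(ss)) unname(qual) else character(0)
        )
      } else {
        ss <- Biostrings::readBStringSet(path, format = "fasta")
        tibble(id = names(ss) %||% character(0), seq = unname(toupper(as.character(ss))))
      }
    },
    error = function(e) {
      abort(paste0("failed to parse ", path, " as ", format, ": ", conditionMessage(e)))
    }
  )
  res
}

#' Write sequences to FASTA
#'
#' @param x A tibble with an id column and a sequence column (`id`/`seq`, or
#'   `kchain_id`/`seq` as produced by [discover_kchains()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ids <- if ("id" %in% names(x)) x$id else x$kchain_id
  ss <- Biostrings::DNAStringSet(setNames(x$seq, ids))
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Reads without a `qual` column are written with constant quality `"I"`.
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  ss <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  qual <- if ("qual" %in% names(x) && !anyNA(x$qual)) {
    x$qual
  } else {
    strrep("I", nchar(x$seq))
  }
  Biostrings::writeXStringSet(
    ss, path,
    format = "fastq",
    qualities = Biostrings::BStringSet(qual)
  )
  invisible(path)
}

#' Subsample reads to a target number of bases
#'
#' Draws a uniformly random subset of whole reads (without replacement)
#' whose total base count does not exceed `target_bases`: reads are visited
#' in a random order and each is kept if it still fits, so no read is split
#' and the subset is maximal along the visiting order. With equal-length
#' reads this selects exactly `floor(target_bases / read_length)` reads.
#' The same seed always yields the same subset.
#'
#' @param reads Read tibble (`id`, `seq`, ...).
#' @param target_bases Non-negative total base budget.
#' @param seed Integer seed.
#' @return A tibble of the selected reads (original row order preserved).
#' @export
subsample_reads <- function(reads, target_bases, seed = 1L) {
  stopifnot(target_bases >= 0)
  len <- nchar(reads$seq)
  if (sum(len) <= target_bases) return(reads)
  ord <- withr::with_seed(seed, sample.int(nrow(reads)))
  fits <- cumsum(len[ord]) <= target_bases
  # skip-and-continue: after the first miss, re-admit later reads that fit
  if (!all(fits)) {
    budget <- target_bases
    keep <- logical(length(ord))
    l <- len[ord]
    for (i in seq_along(ord)) {
      if (l[i] <= budget) {
        keep[i] <- TRUE
        budget <- budget - l[i]
      }
    }
    fits <- keep
  }
  reads[sort(ord[fits]), , drop = FALSE]
}

#' Subsample a fraction of reads by count
#'
#' Convenience wrapper used by the discovery stage: keeps
#' `floor(fraction * n)` reads chosen uniformly at random.
#'
#' @param reads Read tibble.
#' @param fraction Fraction of reads to keep, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Subset of `reads` in original row order.
#' @export
subsample_fraction <- function(reads, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_keep <- floor(fraction * nrow(reads))
  idx <- withr::with_seed(seed, sample.int(nrow(reads), n_keep))
  reads[sort(idx), , drop = FALSE]
}

#' Per-position coverage from a SAM file
#'
#' Computes per-reference depth vectors from alignments. Only primary,
#' mapped alignments contribute ("one alignment" per read); depth is
#' incremented at reference positions consumed by CIGAR `M`/`=`/`X`
#' operations, so soft/hard clips, insertions and deletions never increment
#' depth. SAM positions are 1-based per the standard; the returned depth
#' vector is indexed 1..length.
#'
#' @param sam_path Path to a SAM (or BAM) file.
#' @param references Named integer vector of reference lengths
#'   (`ref_id` -> length). Must be consistent with the SAM header.
#' @return A tibble with one row per reference: `ref_id`, `length`, and a
#'   list-column `depth` of integer vectors.
#' @export
coverage_from_sam <- function(sam_path, references) {
  stopifnot(is.numeric(references), !is.null(names(references)))
  bam <- if (grepl("\\.bam$", sam_path)) {
    sam_path
  } else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(sam_path, dest, overwrite = TRUE, indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  for (rn in names(hdr)) {
    if (!rn %in% names(references)) {
      abort(paste0("reference in SAM header absent from `references`: ", rn))
    }
    if (hdr[[rn]] != references[[rn]]) {
      abort(paste0("reference length mismatch for ", rn))
    }
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  aln <- suppressWarnings(GenomicAlignments::readGAlignments(
    bam,
    use.names = TRUE,
    param = Rsamtools::ScanBamParam(flag = flags)
  )) # out-of-bound records are checked (and rejected) below
  if (length(aln)) {
    ends <- GenomicAlignments::end(aln)
    reflen <- references[as.character(GenomicAlignments::seqnames(aln))]
    bad <- which(ends > reflen)
    if (length(bad)) {
      abort(paste0(
        "alignment extends past reference end: ",
        paste(names(aln)[bad], collapse = ", ")
      ))
    }
  }
  cov <- suppressWarnings(GenomicAlignments::coverage(aln, drop.D.ranges = TRUE))
  tibble(
    ref_id = names(references),
    length = as.integer(unname(references)),
    depth = lapply(names(references), function(rn) {
      if (rn %in% names(cov)) {
        d <- as.integer(cov[[rn]])
        length(d) <- references[[rn]] # pad with NA then zero-fill
        d[is.na(d)] <- 0L
        d
      } else {
        integer(references[[rn]])
      }
    })
  )
}

#' Read / write a sample manifest
#'
#' A manifest is a TSV with columns `sample_id`, `species`, `replicate`,
#' `path`, `format`; sample ids must be unique.
#'
#' @param path Manifest TSV path.
#' @return A manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("sample_id", "species", "replicate")
  if (!all(need %in% names(m))) {
    abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(m$sample_id)) abort("duplicate sample_id in manifest")
  invisible(m)
}
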