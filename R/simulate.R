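# Synthetic multi-species studies with planted repeat families: the ground
# truth used to validate every downstream stage.

#' Specify a planted repeat family
#'
#' A repeat family is a random consensus sequence of `consensus_length`
#' inserted into each species' genome `copy_number` times; each copy is an
#' independently mutated version of the consensus (per-base substitution
#' probability `divergence`), emulating a taxon-specifically amplified
#' repeat.
#'
#' @param family_id Family name.
#' @param consensus_length Consensus length in bp (>= 30).
#' @param copy_number Named integer vector, species -> copies (>= 0).
#' @param divergence Per-copy per-base substitution rate in `[0, 1]`.
#' @param consensus Optional explicit consensus sequence (e.g. a slice of a
#'   contaminant genome); overrides `consensus_length`.
#' @return A `repeat_family` list.
#' @export
repeat_family <- function(family_id, consensus_length, copy_number,
                          divergence = 0.02, consensus = NULL) {
  if (!is.null(consensus)) consensus_length <- nchar(consensus)
  stopifnot(consensus_length >= 30, all(copy_number >= 0))
  structure(
    list(
      family_id = family_id, consensus_length = as.integer(consensus_length),
      copy_number = copy_number, divergence = divergence, consensus = consensus
    ),
    class = "repeat_family"
  )
}

#' Specify a synthetic multi-species study
#'
#' @param species Character vector of species names.
#' @param replicates Replicates per species (>= 1).
#' @param genome_length Background genome length per species, bp.
#' @param families List of [repeat_family()] specs.
#' @param read_length Read length, bp.
#' @param depth Sequencing depth (fold coverage, > 0).
#' @param error_rate Per-base substitution error rate in `[0, 0.2]`.
#' @param seed Master seed; all randomness in the study derives from it.
#' @return A `study_spec` list.
#' @export
study_spec <- function(species, replicates, genome_length, families,
                       read_length = 100L, depth = 20, error_rate = 0.005,
                       seed = 1L) {
  stopifnot(replicates >= 1, depth > 0, error_rate >= 0, error_rate <= 0.2)
  structure(
    list(
      species = species, replicates = as.integer(replicates),
      genome_length = as.integer(genome_length), families = families,
      read_length = as.integer(read_length), depth = depth,
      error_rate = error_rate, seed = as.integer(seed)
    ),
    class = "study_spec"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  nmut <- rbinom(1L, n, rate)
  if (nmut == 0L) return(seq)
  pos <- sample.int(n, nmut)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# Derive a bounded child seed from (master seed, label); keeps all derived
# seeds below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587) + 1L
}

#' Family consensus sequences of a study
#'
#' Each family's consensus is drawn once from the study seed (or taken
#' verbatim from the family spec), so every species plants mutated copies
#' of the same sequence -- shared families really are shared.
#'
#' @param spec A [study_spec()].
#' @return A tibble `family_id`, `seq`.
#' @export
family_consensus <- function(spec) {
  tibble(
    family_id = purrr::map_chr(spec$families, "family_id"),
    seq = purrr::map_chr(spec$families, function(f) {
      f$consensus %||% withr::with_seed(
        derive_seed(spec$seed, paste0("consensus:", f$family_id)),
        random_dna(f$consensus_length)
      )
    })
  )
}

#' Simulate one species genome with planted repeat copies
#'
#' Draws an i.i.d. uniform `{A,C,G,T}` background and inserts each family's
#' mutated copies at uniformly random, non-overlapping positions. Truth
#' intervals (1-based, inclusive) delimit every planted copy.
#'
#' @param spec A [study_spec()].
#' @param species Species name (must appear in `spec$species`).
#' @param seed Integer seed; defaults to a seed derived from the study seed
#'   and the species name.
#' @return A list with `genome` (single string), `truth`
#'   (tibble `family_id`, `start`, `end`) and `consensus`
#'   (tibble `family_id`, `seq` for every family in the spec).
#' @export
simulate_genome <- function(spec, species,
                            seed = derive_seed(spec$seed, paste0("genome:", species))) {
  stopifnot(species %in% spec$species)
  cons_tbl <- family_consensus(spec)
  withr::with_seed(seed, {
    consensus <- setNames(cons_tbl$seq, cons_tbl$family_id)
    copies <- purrr::map_int(spec$families, function(f) {
      as.integer(f$copy_number[[species]] %||% 0L)
    })
    total_insert <- sum(copies * nchar(consensus))
    if (total_insert > 0.5 * spec$genome_length) {
      abort("planted copies exceed half the background length; genome would be repeat-saturated")
    }
    background <- random_dna(spec$genome_length)
    # choose insertion slots between background positions; inserting at
    # distinct slots keeps copies non-overlapping
    n_copies <- sum(copies)
    pieces <- character(0)
    truth <- tibble(family_id = character(0), start = integer(0), end = integer(0))
    if (n_copies > 0L) {
      fam_of_copy <- rep(names(consensus), times = copies)
      slots <- sort(sample.int(spec$genome_length + 1L, n_copies)) - 1L
      fam_of_copy <- sample(fam_of_copy) # random interleaving of families
      inserts <- purrr::map2_chr(fam_of_copy, seq_len(n_copies), function(fam, i) {
        div <- spec$families[[match(fam, names(consensus))]]$divergence
        mutate_seq(consensus[[fam]], div)
      })
      # assemble genome: background split at slots with inserts in between
      bounds <- c(0L, slots, spec$genome_length)
      segs <- substring(background, head(bounds, -1L) + 1L, c(slots, spec$genome_length))
      pieces <- character(2L * n_copies + 1L)
      pieces[seq(1L, by = 2L, length.out = n_copies + 1L)] <- segs
      pieces[seq(2L, by = 2L, length.out = n_copies)] <- inserts
      widths <- nchar(pieces)
      starts <- cumsum(c(1L, head(widths, -1L)))
      ins_idx <- seq(2L, by = 2L, length.out = n_copies)
      truth <- tibble(
        family_id = fam_of_copy,
        start = starts[ins_idx],
        end = starts[ins_idx] + widths[ins_idx] - 1L
      )
      genome <- paste(pieces, collapse = "")
    } else {
      genome <- background
    }
    list(
      genome = genome,
      truth = arrange(truth, .data$start),
      consensus = tibble(family_id = names(consensus), seq = unname(consensus))
    )
  })
}

#' Simulate substitution-error reads from a genome
#'
#' Draws `round(depth * genome_length / read_length)` reads with uniform
#' start positions and uniform strand; each base is substituted
#' independently with probability `error_rate`. No indels are introduced.
#'
#' @param genome Genome string.
#' @param read_length Read length (<= genome length).
#' @param depth Fold coverage.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param id_prefix Prefix for read ids.
#' @return Read tibble (`id`, `seq`) with ground-truth `start` (1-based on
#'   the genome) and `strand` columns.
#' @export
simulate_reads <- function(genome, read_length, depth, error_rate, seed = 1L,
                           id_prefix = "r") {
  glen <- nchar(genome)
  stopifnot(read_length <= glen)
  n_reads <- round(depth * glen / read_length)
  withr::with_seed(seed, {
    starts <- sample.int(glen - read_length + 1L, n_reads, replace = TRUE)
    seqs <- substring(genome, starts, starts + read_length - 1L)
    minus <- runif(n_reads) < 0.5
    seqs[minus] <- revcomp(seqs[minus])
    if (error_rate > 0) {
      nerr <- rbinom(n_reads, read_length, error_rate)
      hit <- which(nerr > 0L)
      bases <- c("A", "C", "G", "T")
      for (i in hit) {
        pos <- sample.int(read_length, nerr[i])
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    tibble(
      id = sprintf("%s_%06d", id_prefix, seq_len(n_reads)),
      seq = seqs,
      start = starts,
      strand = ifelse(minus, "-", "+")
    )
  })
}

#' Simulate a complete multi-species study
#'
#' Simulates one genome per species (replicates of a species are
#' independent read draws from the same genome, as resequencing runs of one
#' taxon) and one read set per (species, replicate). Returns everything the
#' pipeline and its validation need: the manifest, in-memory reads, the
#' planted-copy truth table and the family consensus sequences. When `dir`
#' is given, FASTQ files plus manifest and truth TSVs are also written
#' there.
#'
#' @param spec A [study_spec()].
#' @param dir Optional output directory for FASTQ/TSV files.
#' @return A list with `manifest` (tibble `sample_id`, `species`,
#'   `replicate`, `path`, `format`), `reads` (named list of read tibbles),
#'   `truth` (tibble `family_id`, `sample_id`, `species`, `copy_number`),
#'   `consensus` (tibble `family_id`, `seq`) and `genomes` (named list).
#' @export
simulate_study <- function(spec, dir = NULL) {
  genomes <- purrr::map(setNames(spec$species, spec$species), function(sp) {
    simulate_genome(spec, sp)
  })
  consensus <- genomes[[1L]]$consensus
  manifest <- tidyr::expand_grid(species = spec$species, replicate = seq_len(spec$replicates)) |>
    mutate(
      sample_id = paste0(.data$species, "_rep", .data$replicate),
      path = NA_character_, format = "fastq"
    ) |>
    select("sample_id", "species", "replicate", "path", "format")
  reads <- purrr::map(seq_len(nrow(manifest)), function(i) {
    sp <- manifest$species[i]
    sid <- manifest$sample_id[i]
    simulate_reads(
      genomes[[sp]]$genome, spec$read_length, spec$depth, spec$error_rate,
      seed = derive_seed(spec$seed, paste0("reads:", sid)),
      id_prefix = sid
    )
  })
  names(reads) <- manifest$sample_id
  truth <- tidyr::expand_grid(
    family_id = purrr::map_chr(spec$families, "family_id"),
    sample_id = manifest$sample_id
  ) |>
    left_join(select(manifest, "sample_id", "species"), by = "sample_id") |>
    mutate(copy_number = purrr::map2_int(
      .data$family_id, .data$species,
      function(f, sp) {
        fam <- spec$families[[match(f, purrr::map_chr(spec$families, "family_id"))]]
        as.integer(fam$copy_number[[sp]] %||% 0L)
      }
    ))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(dir, paste0(manifest$sample_id, ".fastq"))
    purrr::walk2(reads, manifest$path, write_fastq)
    write_manifest(manifest, file.path(dir, "manifest.tsv"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
    write_fasta(
      tibble(id = consensus$family_id, seq = consensus$seq),
      file.path(dir, "consensus.fasta")
    )
  }
  list(
    manifest = manifest, reads = reads, truth = truth,
    consensus = consensus, genomes = genomes
  )
}

#' The package's default validation study
#'
#' Four species (A--D) with three replicates each over 100-kb backgrounds,
#' three 120-bp planted families with hierarchical sharing (one family
#' shared by A and B, one by A, B and C, one private to D; peak copy number
#' 300), and optionally a chloroplast-derived high-copy family present in
#' every species together with its source "chloroplast genome" reference.
#' Reads are 100 bp at 20x depth with 0.5% substitution error; copies
#' diverge from their consensus at 2%.
#'
#' @param seed Master seed.
#' @param with_chloroplast Also plant a cpDNA-derived family and return the
#'   chloroplast reference sequence.
#' @return A [study_spec()]; when `with_chloroplast` is TRUE the spec has an
#'   extra attribute `"cp_genome"` holding the contaminant reference.
#' @export
default_study <- function(seed = 1L, with_chloroplast = FALSE) {
  # taxon-specific amplification with rank crossover: A amplifies the
  # A/B-shared family far above the A/B/C-shared one, B the reverse, so
  # the two species stay distinguishable under rank-based normalization
  families <- list(
    repeat_family(
      "fam_shared_AB", 120,
      c(A = 300L, B = 100L, C = 0L, D = 0L)
    ),
    repeat_family(
      "fam_shared_ABC", 120,
      c(A = 60L, B = 260L, C = 300L, D = 0L)
    ),
    repeat_family(
      "fam_private_D", 120,
      c(A = 0L, B = 0L, C = 0L, D = 300L)
    )
  )
  cp_genome <- NULL
  if (with_chloroplast) {
    cp_genome <- withr::with_seed(derive_seed(seed, "cp_genome"), random_dna(3000L))
    # organellar DNA is effectively clonal: copies are exact cp segments
    families <- c(families, list(repeat_family(
      "fam_chloroplast", 120,
      c(A = 40L, B = 40L, C = 40L, D = 40L),
      divergence = 0,
      consensus = substring(cp_genome, 1001L, 1120L)
    )))
  }
  spec <- study_spec(
    species = c("A", "B", "C", "D"), replicates = 3L,
    genome_length = 100000L, families = families,
    read_length = 100L, depth = 20, error_rate = 0.005, seed = seed
  )
  attr(spec, "cp_genome") <- cp_genome
  spec
}
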