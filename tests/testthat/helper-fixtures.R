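# Shared fixtures. Expensive simulated studies are computed once per test
# session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy_meta <- function(sample_ids, species = NULL, replicate = NULL) {
  tibble::tibble(
    sample_id = sample_ids,
    species = species %||% sample_ids,
    replicate = replicate %||% rep(1L, length(sample_ids))
  )
}

toy_matrix <- function(values, sample_ids = colnames(values),
                       species = NULL, state = "raw") {
  kchainr::abundance_matrix(values, toy_meta(sample_ids, species), state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small three-species study with one planted family at graded copy
# numbers (60 / 20 / 0), used by quantify and pipeline tests.
small_study <- function() {
  memo("small_study", {
    fams <- list(kchainr::repeat_family(
      "famS", 120, c(X = 60L, Y = 20L, Z = 0L),
      divergence = 0.02
    ))
    spec <- kchainr::study_spec(c("X", "Y", "Z"), 2L, 20000L, fams,
      read_length = 100L, depth = 20, error_rate = 0.005, seed = 101L
    )
    kchainr::simulate_study(spec)
  })
}

# The package's default validation study (4 species x 3 replicates,
# 100-kb backgrounds, hierarchical family sharing, cpDNA family), with
# discovery, contamination partition and nuclear quantification run once.
acceptance_study <- function() {
  memo("acceptance_study", {
    spec <- kchainr::default_study(seed = 20260929L, with_chloroplast = TRUE)
    st <- kchainr::simulate_study(spec)
    pooled <- dplyr::bind_rows(st$reads)
    kchains <- kchainr::discover_kchains(pooled, seed = spec$seed)
    idx <- list(kchainr::build_contaminant_index(
      attr(spec, "cp_genome"), "chloroplast",
      k = 12L
    ))
    bins <- kchainr::partition_library(kchains, idx, 0.5)
    profiles <- lapply(
      stats::setNames(st$manifest$sample_id, st$manifest$sample_id),
      function(sid) kchainr::map_reads(st$reads[[sid]], bins$nuclear)
    )
    m_raw <- kchainr::build_abundance_matrix(profiles, st$manifest)
    m_norm <- kchainr::quantile_normalize(
      kchainr::log_transform(kchainr::filter_by_max(m_raw, 665))
    )
    list(
      spec = spec, study = st, kchains = kchains, bins = bins,
      m_raw = m_raw, m_norm = m_norm
    )
  })
}

# local-alignment identity of a chain against a consensus; 0 when the
# aligned stretch is shorter than min_len
chain_identity <- function(chain, consensus, min_len = 30L) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(chain), Biostrings::DNAString(consensus),
    type = "local"
  )
  if (Biostrings::nchar(pa) < min_len) return(0)
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# synthetic incidence graph from an explicit edge list
synthetic_graph <- function(n_kmers, n_reads, ek, er, k = 12L) {
  kchainr:::new_incidence_graph(
    k, TRUE,
    sprintf("kmer%03d", seq_len(n_kmers)),
    sprintf("read%03d", seq_len(n_reads)),
    ek = as.integer(ek), er = as.integer(er)
  )
}

# exhaustive best-bicluster score (edge count of the best qualifying
# subset pair) on small graphs, via subset-mask matrix products
brute_force_best <- function(A, min_density, min_kmers, min_reads) {
  nk <- nrow(A)
  nr <- ncol(A)
  masks <- function(n) {
    m <- matrix(0, 2^n - 1, n)
    for (i in seq_len(2^n - 1)) m[i, ] <- as.integer(intToBits(i)[1:n])
    m
  }
  ms <- masks(nk)
  mt <- masks(nr)
  sizes_s <- rowSums(ms)
  sizes_t <- rowSums(mt)
  E <- (ms %*% A) %*% t(mt)
  size_prod <- outer(sizes_s, sizes_t)
  dens <- E / size_prod
  valid <- outer(sizes_s >= min_kmers, sizes_t >= min_reads) & dens >= min_density
  if (!any(valid)) return(0)
  max(E[valid])
}
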