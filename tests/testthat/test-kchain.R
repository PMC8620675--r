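test_that("incidence graph links k-mers to the reads containing them", {
  reads <- tibble::tibble(id = "r1", seq = "ACGTAC")
  g <- extract_kmers(reads, 4L, canonical = FALSE, min_kmer_reads = 1L)
  expect_setequal(g$kmers, c("ACGT", "CGTA", "GTAC"))
  expect_equal(g$n_edges, 3L)

  # reverse-complement canonicalisation
  g2 <- extract_kmers(tibble::tibble(id = "r1", seq = "TTTT"), 4L,
    canonical = TRUE, min_kmer_reads = 1L
  )
  expect_equal(g2$kmers, "AAAA")

  # too-short reads contribute nothing
  expect_warning(
    g3 <- extract_kmers(tibble::tibble(id = "r", seq = "ACG"), 4L),
    "empty"
  )
  expect_equal(length(g3$kmers), 0L)

  # multiplicity within one read collapses to one edge
  g4 <- extract_kmers(tibble::tibble(id = "r", seq = "AAAAAAAA"), 4L,
    canonical = FALSE, min_kmer_reads = 1L
  )
  expect_equal(g4$n_edges, 1L)

  # min_kmer_reads filters singletons
  r5 <- tibble::tibble(id = c("a", "b"), seq = c("ACGTACGG", "ACGTTTAA"))
  g5 <- extract_kmers(r5, 4L, canonical = FALSE, min_kmer_reads = 2L)
  expect_true(all(vapply(g5$adj_k, length, integer(1)) >= 2L))
})

test_that("bipartite density is edges over possible edges", {
  # complete 4 k-mer x 5 read block: density exactly one (biclique)
  g <- synthetic_graph(6, 7,
    ek = c(rep(1:4, each = 5), 5, 6),
    er = c(rep(1:5, times = 4), 6, 7)
  )
  vs <- g$kmers[1:4]
  vt <- g$read_ids[1:5]
  expect_identical(graph_density(g, vs, vt), 1)
  # zero edges between disjoint corners
  expect_identical(graph_density(g, g$kmers[5:6], vt), 0)
  # 2x2 block with 2 edges
  expect_identical(graph_density(g, g$kmers[5:6], g$read_ids[6:7]), 0.5)
  # empty subsets refused
  expect_error(graph_density(g, character(0), vt), "empty")
  # density stays within [0, 1] on random subsets and matches a direct
  # edge count
  set.seed(4)
  for (i in 1:100) {
    vs_i <- sample(g$kmers, sample(1:6, 1))
    vt_i <- sample(g$read_ids, sample(1:7, 1))
    d <- graph_density(g, vs_i, vt_i)
    expect_gte(d, 0)
    expect_lte(d, 1)
    manual <- sum(vapply(match(vs_i, g$kmers), function(ki) {
      sum(g$read_ids[g$adj_k[[ki]]] %in% vt_i)
    }, numeric(1)))
    expect_equal(d, manual / (length(vs_i) * length(vt_i)))
  }
})

test_that("the greedy search recovers planted bicliques", {
  set.seed(99)
  nk <- 100L
  nr <- 200L
  # planted complete 10 x 20 block plus Bernoulli(0.01) noise
  ek <- rep(1:10, each = 20)
  er <- rep(1:20, times = 10)
  noise <- which(matrix(runif(nk * nr) < 0.01, nk, nr), arr.ind = TRUE)
  noise <- noise[noise[, 1] > 10 | noise[, 2] > 20, , drop = FALSE]
  g <- synthetic_graph(nk, nr, c(ek, noise[, 1]), c(er, noise[, 2]))
  bc <- find_biclusters(g, min_density = 0.5, min_kmers = 5L, min_reads = 10L)
  expect_gte(nrow(bc), 1L)
  top <- bc[1, ]
  planted_k <- g$kmers[1:10]
  planted_r <- g$read_ids[1:20]
  expect_gte(length(intersect(top$kmers[[1]], planted_k)) / 10, 0.9)
  expect_gte(length(intersect(top$read_ids[[1]], planted_r)) / 20, 0.9)
  expect_gte(top$density, 0.5)

  # two vertex-disjoint planted bicliques give two clusters with
  # disjoint k-mer sets
  ek2 <- c(rep(1:8, each = 15), rep(21:28, each = 15))
  er2 <- c(rep(1:15, times = 8), rep(31:45, times = 8))
  g2 <- synthetic_graph(40, 60, ek2, er2)
  bc2 <- find_biclusters(g2, min_kmers = 5L, min_reads = 10L)
  expect_equal(nrow(bc2), 2L)
  expect_length(intersect(bc2$kmers[[1]], bc2$kmers[[2]]), 0L)

  # graph smaller than the size minima yields nothing
  g3 <- synthetic_graph(3, 4, c(1, 2, 3), c(1, 2, 3))
  expect_equal(nrow(find_biclusters(g3, min_kmers = 5L, min_reads = 10L)), 0L)

  # monotonicity on planted structure: raising min_density never
  # increases the cluster count
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9, 1), function(d) {
    nrow(find_biclusters(g2, min_density = d, min_kmers = 5L, min_reads = 10L))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the greedy result matches exhaustive search on tiny graphs", {
  # clean planted 4x5 biclique in a 10+10 graph: greedy must find the
  # optimum exactly
  ek <- rep(1:4, each = 5)
  er <- rep(1:5, times = 4)
  A <- matrix(0, 10, 10)
  A[cbind(ek, er)] <- 1
  g <- synthetic_graph(10, 10, ek, er)
  bc <- find_biclusters(g, min_density = 0.5, min_kmers = 3L, min_reads = 3L)
  opt <- brute_force_best(A, 0.5, 3L, 3L)
  expect_equal(bc$n_edges[1], as.integer(opt))

  # noisy tiny graph: greedy never beats the optimum; its score is pinned
  set.seed(17)
  A2 <- matrix(as.numeric(runif(100) < 0.45), 10, 10)
  A2[1:4, 1:4] <- 1
  idx <- which(A2 == 1, arr.ind = TRUE)
  g2 <- synthetic_graph(10, 10, idx[, 1], idx[, 2])
  bc2 <- find_biclusters(g2, min_density = 0.6, min_kmers = 3L, min_reads = 3L)
  opt2 <- brute_force_best(A2, 0.6, 3L, 3L)
  expect_gte(nrow(bc2), 1L)
  expect_lte(bc2$n_edges[1], opt2)
  # the deterministic greedy result on this graph, pinned as a regression
  expect_identical(bc2$n_edges[1], 15L)
  expect_identical(bc2$density[1], 1)
})

test_that("chain assembly walks maximal non-branching overlap paths", {
  # unique path
  expect_equal(
    assemble_kchains(c("ACGT", "CGTA", "GTAC"), 4L,
      min_length = 4L, canonical = FALSE
    ),
    "ACGTAC"
  )
  # canonical mode reaches the same chain without crossing strands
  expect_equal(
    assemble_kchains(canonical_kmers(c("ACGT", "CGTA", "GTAC")), 4L,
      min_length = 4L, canonical = TRUE
    ),
    "ACGTAC"
  )
  # branch: shared prefix ends at the branch, each branch continues
  br <- assemble_kchains(c("ACGT", "CGTA", "CGTT"), 4L,
    min_length = 5L, canonical = FALSE
  )
  expect_setequal(br, c("ACGTA", "ACGTT"))
  # everything shorter than min_length is dropped
  expect_length(
    assemble_kchains(c("ACGT", "CGTA", "GTAC"), 4L, min_length = 30L),
    0L
  )
})

test_that("discovery is deterministic and silent on repeat-free genomes", {
  st <- small_study()
  pooled <- dplyr::bind_rows(st$reads)
  kc1 <- discover_kchains(pooled,
    k_values = 12L, fraction = 0.2,
    seed = 42L, max_clusters = 500L
  )
  kc2 <- discover_kchains(pooled,
    k_values = 12L, fraction = 0.2,
    seed = 42L, max_clusters = 500L
  )
  expect_identical(kc1, kc2)
  expect_gte(nrow(kc1), 1L)

  # every chain's k-mers are backed by the discovery reads: at least
  # min_density of its k-mers occur in the subsampled read set
  sub <- subsample_fraction(pooled, 0.2, seed = 42L)
  read_km <- kchainr:::canonical_kmer_set(sub$seq, 12L)
  for (s in kc1$seq[kc1$k == 12L]) {
    km <- kchainr:::canonical_kmer_set(s, 12L)
    expect_gte(mean(km %in% read_km), 0.5)
  }

  # Monte-Carlo: repeat-free random genomes yield no kChains in >= 95%
  # of seeds at the default thresholds
  n_hits <- 0L
  for (sd in 1:20) {
    spec0 <- study_spec("solo", 1L, 100000L, list(),
      depth = 4, error_rate = 0.005, seed = 1000L + sd
    )
    st0 <- simulate_study(spec0)
    kc0 <- discover_kchains(st0$reads[[1]],
      k_values = 12L, fraction = 0.25,
      seed = sd
    )
    if (nrow(kc0) > 0L) n_hits <- n_hits + 1L
  }
  expect_lte(n_hits, 1L) # >= 95% of 20 seeds clean
})

test_that("optional extension grows chains along unique supported paths", {
  set.seed(61)
  src <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  reads <- tibble::tibble(id = paste0("r", 1:5), seq = rep(src, 5))
  chain <- tibble::tibble(
    kchain_id = "kc1", seq = substring(src, 16, 45), length = 30L,
    k = 12L, bicluster_id = "bc_1"
  )
  ext <- extend_kchains(chain, reads, min_support = 2L)
  expect_equal(ext$seq, src) # recovers the full source sequence
  expect_equal(ext$length, 60L)
  # unsupported chains are left alone
  lone <- tibble::tibble(
    kchain_id = "kc2",
    seq = paste(rep("ACGTG", 8), collapse = ""), length = 40L,
    k = 12L, bicluster_id = "bc_2"
  )
  expect_equal(extend_kchains(lone, reads)$seq, lone$seq)
})
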