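# The discovery kernel: bipartite k-mer x read incidence graph, dense
# bicluster search, and consensus chain assembly.

#' Build the k-mer by read incidence graph
#'
#' Vertices are k-mers (V1) and read ids (V2); an edge links a k-mer and a
#' read iff the k-mer (or, in canonical mode, its reverse complement) is a
#' substring of the read. Multiple occurrences within one read collapse to
#' a single edge. k-mers containing `N` are skipped, and k-mers occurring
#' in fewer than `min_kmer_reads` reads are dropped from V1.
#'
#' @param reads Read tibble (`id`, `seq`).
#' @param k k-mer length (>= 4).
#' @param canonical Collapse strands onto canonical k-mers (default TRUE).
#' @param min_kmer_reads Minimum number of distinct reads a k-mer must occur
#'   in to enter the graph (default 2).
#' @return An `incidence_graph`: list with `k`, `canonical`, `kmers`
#'   (lexicographically sorted), `read_ids` (sorted), adjacency lists
#'   `adj_k` (k-mer index -> read indices) and `adj_r`, and `n_edges`.
#' @export
extract_kmers <- function(reads, k, canonical = TRUE, min_kmer_reads = 2L) {
  stopifnot(k >= 4, nrow(reads) > 0)
  read_ids <- sort(reads$id)
  seqs <- toupper(reads$seq[match(read_ids, reads$id)])
  if (k > max(nchar(seqs))) {
    warn("k exceeds the longest read; graph is empty")
    return(new_incidence_graph(k, canonical, character(0), read_ids,
      ek = integer(0), er = integer(0)
    ))
  }
  tab <- kmer_table(seqs, k)
  ok <- !stringr::str_detect(tab$kmer, "N")
  km <- tab$kmer[ok]
  rid <- tab$seq_idx[ok]
  if (canonical) {
    u <- unique(km)
    km <- canonical_kmers(u)[match(km, u)]
  }
  kmers <- sort(unique(km))
  kid <- match(km, kmers)
  # collapse multiplicity within a read to one edge
  key <- as.numeric(kid) * (length(read_ids) + 1) + rid
  first <- !duplicated(key)
  kid <- kid[first]
  rid <- rid[first]
  # degree filter on V1
  deg <- tabulate(kid, nbins = length(kmers))
  keep_k <- which(deg >= min_kmer_reads)
  sel <- kid %in% keep_k
  kid2 <- match(kid[sel], keep_k)
  new_incidence_graph(k, canonical, kmers[keep_k], read_ids,
    ek = kid2, er = rid[sel]
  )
}

new_incidence_graph <- function(k, canonical, kmers, read_ids, ek, er) {
  adj_k <- vector("list", length(kmers))
  ord <- order(ek, er)
  adj_k[] <- split(er[ord], factor(ek[ord], levels = seq_along(kmers)))
  adj_r <- vector("list", length(read_ids))
  ord2 <- order(er, ek)
  adj_r[] <- split(ek[ord2], factor(er[ord2], levels = seq_along(read_ids)))
  structure(
    list(
      k = as.integer(k), canonical = canonical,
      kmers = kmers, read_ids = read_ids,
      adj_k = adj_k, adj_r = adj_r,
      n_edges = length(ek)
    ),
    class = "incidence_graph"
  )
}

#' @export
print.incidence_graph <- function(x, ...) {
  cat("# incidence_graph: k=", x$k, if (x$canonical) " (canonical)", ", ",
    length(x$kmers), " k-mers x ", length(x$read_ids), " reads, ",
    x$n_edges, " edges\n",
    sep = ""
  )
  invisible(x)
}

#' Density of a bipartite subgraph
#'
#' The density of the subgraph spanned by k-mer subset `Vs` and read subset
#' `Vt` is `|Est| / (|Vs| * |Vt|)`, the fraction of possible k-mer/read
#' edges that are present. It lies in `[0, 1]` and equals 1 exactly when
#' the subgraph is a biclique.
#'
#' @param graph An `incidence_graph`.
#' @param kmers Character vector of k-mers (subset of `graph$kmers`).
#' @param reads Character vector of read ids (subset of `graph$read_ids`).
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(graph, kmers, reads) {
  if (length(kmers) == 0 || length(reads) == 0) {
    abort("density is undefined for empty vertex subsets")
  }
  ks <- match(kmers, graph$kmers)
  rs <- match(reads, graph$read_ids)
  if (anyNA(ks) || anyNA(rs)) abort("subset vertices must belong to the graph")
  in_vt <- logical(length(graph$read_ids))
  in_vt[rs] <- TRUE
  e <- sum(vapply(graph$adj_k[ks], function(a) sum(in_vt[a]), numeric(1)))
  e / (length(ks) * length(rs))
}

#' Find dense biclusters by deterministic seed-and-grow
#'
#' Greedy search for densely connected k-mer/read vertex subsets: seed at
#' the highest-degree unused k-mer with its full read neighbourhood, then
#' alternately add the k-mer and the read whose inclusion maximises the
#' resulting density, accepting additions while density stays at or above
#' `min_density`; finally prune vertices whose removal increases density.
#' A grown subgraph is accepted if it meets the size minima and the density
#' floor; its edges are then removed from the working graph and the search
#' continues from the next seed. Every k-mer absorbed into a grown
#' candidate (accepted or not) counts as used and is not seeded again, and
#' only k-mers whose remaining degree could support a qualifying cluster
#' (`degree >= ceiling(min_density * min_reads)`) are tried. Ties are
#' broken by lexicographic k-mer / read-id order (vertices are stored
#' sorted), so the search is fully deterministic.
#'
#' @param graph An `incidence_graph`.
#' @param min_density Minimum density in `(0, 1]` (default 0.5).
#' @param min_kmers Minimum `|Vs|` (default 5).
#' @param min_reads Minimum `|Vt|` (default 10).
#' @param max_clusters Cap on the number of returned clusters.
#' @param seed Accepted for interface stability; the search is
#'   deterministic and ignores it.
#' @return A tibble ordered by decreasing `n_kmers * n_reads * density`
#'   with columns `bicluster_id`, `kmers` (list), `read_ids` (list),
#'   `n_kmers`, `n_reads`, `n_edges`, `density`.
#' @export
find_biclusters <- function(graph, min_density = 0.5, min_kmers = 5L,
                            min_reads = 10L, max_clusters = 10000L,
                            seed = NULL) {
  stopifnot(min_density > 0, min_density <= 1)
  nk <- length(graph$kmers)
  nr <- length(graph$read_ids)
  empty <- tibble(
    bicluster_id = character(0), kmers = list(), read_ids = list(),
    n_kmers = integer(0), n_reads = integer(0), n_edges = integer(0),
    density = numeric(0)
  )
  if (nk == 0L || nr == 0L) return(empty)
  ek <- rep.int(seq_len(nk), lengths(graph$adj_k))
  er <- unlist(graph$adj_k, use.names = FALSE)
  out <- .bicluster_search_cpp(
    nk, nr, ek - 1L, er - 1L,
    min_density, as.integer(min_kmers), as.integer(min_reads),
    as.integer(max_clusters)
  )
  if (length(out) == 0L) return(empty)
  res <- tibble(
    kmers = purrr::map(out, function(b) graph$kmers[b$vs]),
    read_ids = purrr::map(out, function(b) graph$read_ids[b$vt]),
    n_kmers = purrr::map_int(out, function(b) length(b$vs)),
    n_reads = purrr::map_int(out, function(b) length(b$vt)),
    n_edges = purrr::map_int(out, function(b) as.integer(b$e)),
    density = purrr::map_dbl(out, "density")
  ) |>
    arrange(dplyr::desc(.data$n_kmers * .data$n_reads * .data$density))
  res$bicluster_id <- sprintf("bc_%d", seq_len(nrow(res)))
  select(
    res, "bicluster_id", "kmers", "read_ids",
    "n_kmers", "n_reads", "n_edges", "density"
  )
}

#' Assemble a bicluster's k-mers into consensus chains (kChains)
#'
#' Builds the `(k-1)`-overlap graph over the bicluster's k-mers (in
#' canonical mode each k-mer is considered in both orientations) and emits
#' every maximal non-branching path as a chain. A walk never reuses a
#' k-mer in either orientation, which both terminates cycles and prevents
#' a path from crossing onto its own reverse-complement strand at
#' palindromic k-mers. Chains shorter than `min_length` are discarded and
#' reverse-complement duplicates collapsed.
#'
#' @param kmers Character vector of k-mers (one bicluster's `Vs`).
#' @param k k-mer length.
#' @param min_length Minimum chain length in bp (default 30).
#' @param canonical Whether `kmers` are strand-collapsed canonical k-mers.
#' @return Character vector of chain sequences, longest first (ties
#'   lexicographic).
#' @export
assemble_kchains <- function(kmers, k, min_length = 30L, canonical = TRUE) {
  if (length(kmers) == 0L) return(character(0))
  canon <- sort(unique(if (canonical) canonical_kmers(kmers) else kmers))
  nodes <- if (canonical) sort(unique(c(canon, revcomp(canon)))) else canon
  canon_id <- if (canonical) match(canonical_kmers(nodes), canon) else seq_along(nodes)
  n <- length(nodes)
  suff <- substring(nodes, 2L, k)
  bases <- c("A", "C", "G", "T")
  succ <- matrix(NA_integer_, nrow = 4L, ncol = n)
  for (b in 1:4) succ[b, ] <- match(paste0(suff, bases[b]), nodes)
  out_deg <- colSums(!is.na(succ))
  in_deg <- tabulate(succ[!is.na(succ)], nbins = n)
  is_11 <- in_deg == 1L & out_deg == 1L
  only_succ <- integer(n)
  one_out <- which(out_deg == 1L)
  if (length(one_out)) {
    ss <- succ[, one_out, drop = FALSE]
    only_succ[one_out] <- ss[!is.na(ss)]
  }
  chains <- character(0)
  visited <- logical(n) # 1-in-1-out nodes consumed by some path
  walk <- function(u, v) {
    used <- logical(length(canon))
    used[canon_id[u]] <- TRUE
    path <- u
    nxt <- v
    repeat {
      if (used[canon_id[nxt]]) break
      path <- c(path, nxt)
      used[canon_id[nxt]] <- TRUE
      if (!is_11[nxt]) break
      nxt <- only_succ[nxt]
    }
    # consume every node sharing a used k-mer, in either orientation
    visited[canon_id %in% which(used)] <<- TRUE
    paste0(nodes[path[1L]], paste(substring(nodes[path[-1L]], k, k), collapse = ""))
  }
  starts <- which(out_deg > 0L & !is_11)
  for (u in starts) {
    for (v in succ[, u]) {
      if (!is.na(v)) chains <- c(chains, walk(u, v))
    }
  }
  for (u in which(is_11)) { # isolated cycles not reached from any start
    if (!visited[u]) chains <- c(chains, walk(u, only_succ[u]))
  }
  chains <- c(chains, nodes[out_deg == 0L & in_deg == 0L]) # isolated k-mers
  if (canonical) {
    chains <- ifelse(chains <= revcomp(chains), chains, revcomp(chains))
  }
  chains <- unique(chains)
  chains <- chains[nchar(chains) >= min_length]
  chains[order(-nchar(chains), chains)]
}

#' Discover kChains from pooled reads
#'
#' The end-to-end discovery operation: subsamples a fraction of the pooled
#' reads, and for each k in `k_values` builds the incidence graph, finds
#' dense biclusters, and assembles each bicluster's k-mers into chains.
#' Chains identical up to reverse complement are deduplicated across k
#' values and given stable ids `kchain_<k>_<serial>`.
#'
#' @param reads Read tibble pooled over all samples.
#' @param k_values Integer vector of k-mer lengths (default `c(12, 15)`).
#' @param fraction Fraction of reads used for discovery (default 0.10).
#' @param min_kmer_reads,min_density,min_kmers,min_reads,max_clusters
#'   Passed to [extract_kmers()] and [find_biclusters()].
#' @param min_length Minimum chain length in bp (default 30).
#' @param canonical Strand-collapsed k-mers (default TRUE).
#' @param seed Integer seed for the read subsample.
#' @return A tibble `kchain_id`, `seq`, `length`, `k`, `bicluster_id`.
#' @export
discover_kchains <- function(reads, k_values = c(12L, 15L), fraction = 0.10,
                             min_kmer_reads = 2L, min_density = 0.5,
                             min_kmers = 5L, min_reads = 10L,
                             min_length = 30L, max_clusters = 10000L,
                             canonical = TRUE, seed = 1L) {
  sub <- subsample_fraction(reads, fraction, seed = seed)
  res <- purrr::map(k_values, function(k) {
    g <- extract_kmers(sub, k, canonical = canonical, min_kmer_reads = min_kmer_reads)
    bc <- find_biclusters(g,
      min_density = min_density, min_kmers = min_kmers,
      min_reads = min_reads, max_clusters = max_clusters
    )
    if (nrow(bc) == 0L) {
      return(tibble(
        seq = character(0), k = integer(0), bicluster_id = character(0)
      ))
    }
    purrr::map2(bc$kmers, bc$bicluster_id, function(km, id) {
      ch <- assemble_kchains(km, k, min_length = min_length, canonical = canonical)
      if (length(ch) == 0L) {
        return(tibble(seq = character(0), k = integer(0), bicluster_id = character(0)))
      }
      tibble(seq = ch, k = as.integer(k), bicluster_id = id)
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(res) == 0L) {
    return(tibble(
      kchain_id = character(0), seq = character(0), length = integer(0),
      k = integer(0), bicluster_id = character(0)
    ))
  }
  canon <- ifelse(res$seq <= revcomp(res$seq), res$seq, revcomp(res$seq))
  res <- res[!duplicated(canon), , drop = FALSE]
  res |>
    group_by(.data$k) |>
    mutate(kchain_id = sprintf("kchain_%d_%04d", .data$k, dplyr::row_number())) |>
    ungroup() |>
    mutate(length = nchar(.data$seq)) |>
    select("kchain_id", "seq", "length", "k", "bicluster_id")
}

#' Greedily extend kChains against the full read set
#'
#' Optional post-processing: each chain end is extended one base at a time
#' while a unique best-supported successor k-mer exists among the reads'
#' k-mers (support = occurrence count, canonical). Extension stops at
#' ties, at support below `min_support`, or when the next k-mer is already
#' part of the chain. Off by default in [discover_kchains()]; useful when
#' the dense-core chains are shorter than the underlying repeat.
#'
#' @param kchains kChain tibble from [discover_kchains()] (`kchain_id`,
#'   `seq`, `k`).
#' @param reads Read tibble the chains were discovered from (typically the
#'   full pooled read set, not just the discovery subsample).
#' @param min_support Minimum k-mer occurrence count to extend through.
#' @return The kChain tibble with extended `seq` and updated `length`.
#' @export
extend_kchains <- function(kchains, reads, min_support = 2L) {
  if (nrow(kchains) == 0L) return(kchains)
  out <- kchains
  for (kv in unique(kchains$k)) {
    tab <- kmer_table(toupper(reads$seq), kv)
    km <- canonical_kmers(tab$kmer[!stringr::str_detect(tab$kmer, "N")])
    u <- unique(km)
    counts <- setNames(tabulate(match(km, u), nbins = length(u)), u)
    rows <- which(out$k == kv)
    bases <- c("A", "C", "G", "T")
    for (i in rows) {
      s <- out$seq[i]
      used <- new.env(parent = emptyenv())
      for (m in canonical_kmer_set(s, kv)) assign(m, TRUE, envir = used)
      step <- function(seq, right) {
        edge <- if (right) substring(seq, nchar(seq) - kv + 2L, nchar(seq)) else
          substring(seq, 1L, kv - 1L)
        cand <- if (right) paste0(edge, bases) else paste0(bases, edge)
        cc <- canonical_kmers(cand)
        sup <- counts[cc]
        sup[is.na(sup)] <- 0
        sup[vapply(cc, exists, logical(1), envir = used)] <- 0
        if (max(sup) < min_support || sum(sup == max(sup)) != 1L) return(NULL)
        b <- bases[which.max(sup)]
        assign(cc[which.max(sup)], TRUE, envir = used)
        if (right) paste0(seq, b) else paste0(b, seq)
      }
      repeat {
        s2 <- step(s, TRUE)
        if (is.null(s2)) break
        s <- s2
      }
      repeat {
        s2 <- step(s, FALSE)
        if (is.null(s2)) break
        s <- s2
      }
      out$seq[i] <- s
    }
  }
  out$length <- nchar(out$seq)
  out
}
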