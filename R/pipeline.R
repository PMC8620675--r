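# End-to-end workflow: subsample -> discover -> partition -> quantify ->
# normalize/filter -> ordinate -> tree, with seeded reproducibility.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. The resolved
#' configuration is written alongside the outputs of [run_pipeline()] so a
#' run is fully described by its manifest plus its config.
#'
#' @param k_values k-mer lengths for discovery.
#' @param discovery_fraction Fraction of pooled reads used for discovery.
#' @param min_kmer_reads,min_density,min_kmers,min_reads,max_clusters
#'   Incidence-graph and bicluster-search parameters.
#' @param min_length Minimum kChain length (bp).
#' @param seed_k,min_identity,min_score Mapper parameters.
#' @param statistic Abundance statistic, `"median"` or `"mean"`.
#' @param pseudo Pseudo-count for the log transform.
#' @param abundance_threshold Raw-scale max-abundance filter threshold.
#' @param filter_stage `"raw"` (default) or `"normalized"`: whether the
#'   abundance filter is applied before the log transform or after
#'   normalization.
#' @param containment_threshold Contamination containment threshold.
#' @param containment_k k for contaminant indexes.
#' @param metric Distance metric for the tree.
#' @param n_components PCA components.
#' @param seed Master seed for all randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k_values = c(12L, 15L), discovery_fraction = 0.10,
                            min_kmer_reads = 2L, min_density = 0.5,
                            min_kmers = 5L, min_reads = 10L,
                            max_clusters = 10000L, min_length = 30L,
                            seed_k = 12L, min_identity = 0.9,
                            min_score = 25L,
                            statistic = "median", pseudo = 1,
                            abundance_threshold = 665,
                            filter_stage = c("raw", "normalized"),
                            containment_threshold = 0.5, containment_k = 12L,
                            metric = "euclidean", n_components = 2L,
                            seed = 1L) {
  filter_stage <- match.arg(filter_stage)
  structure(
    list(
      k_values = k_values, discovery_fraction = discovery_fraction,
      min_kmer_reads = min_kmer_reads, min_density = min_density,
      min_kmers = min_kmers, min_reads = min_reads,
      max_clusters = max_clusters, min_length = min_length,
      seed_k = seed_k, min_identity = min_identity, min_score = min_score,
      statistic = statistic, pseudo = pseudo,
      abundance_threshold = abundance_threshold, filter_stage = filter_stage,
      containment_threshold = containment_threshold,
      containment_k = containment_k,
      metric = metric, n_components = n_components, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

load_sample_reads <- function(manifest, reads = NULL) {
  if (!is.null(reads)) return(reads)
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    read_sequences(manifest$path[i], manifest$format[i] %||% "auto")
  })
  names(out) <- manifest$sample_id
  out
}

#' Run the full repeat-profiling pipeline
#'
#' Pools the samples' reads, discovers kChains, partitions them against
#' any contaminant indexes, quantifies each bin (nuclear always; a
#' chloroplast bin additionally feeds its own matrix/ordination/tree
#' path), filters and normalizes the abundance matrices, ordinates them,
#' and infers neighbor-joining trees. All stage outputs are written to
#' `output_dir` together with the fully resolved configuration; identical
#' manifest + config + seed give identical outputs.
#'
#' @param manifest Sample manifest tibble (`sample_id`, `species`,
#'   `replicate`, and `path`/`format` unless `reads` is supplied).
#' @param output_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param reads Optional named list of in-memory read tibbles (overrides
#'   manifest paths).
#' @param contaminants Optional named list/character of contaminant
#'   references (label -> FASTA path, tibble or sequence vector).
#' @param references Optional known-repeat reference tibble/FASTA; when
#'   given, quantification runs against these references instead of
#'   discovered kChains (the "known repeat library" mode).
#' @return Invisibly, a list with the per-bin results (`kchains`,
#'   `annotation`, and per bin: `matrix_raw`, `matrix_norm`, `pca`,
#'   `assignment`, `tree`).
#' @export
run_pipeline <- function(manifest, output_dir, config = pipeline_config(),
                         reads = NULL, contaminants = NULL,
                         references = NULL) {
  validate_manifest(manifest)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  read_list <- load_sample_reads(manifest, reads)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    message(sprintf(
      "[%s] done in %.1fs", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ))
    res
  }

  if (is.null(references)) {
    pooled <- stage("pool", bind_rows(read_list))
    kchains <- stage("discover", discover_kchains(
      pooled,
      k_values = config$k_values, fraction = config$discovery_fraction,
      min_kmer_reads = config$min_kmer_reads, min_density = config$min_density,
      min_kmers = config$min_kmers, min_reads = config$min_reads,
      min_length = config$min_length, max_clusters = config$max_clusters,
      seed = config$seed
    ))
    write_fasta(kchains, file.path(output_dir, "kchains.fasta"))
  } else {
    kchains <- as_reference_tbl(references)
    kchains$kchain_id <- kchains$id
  }

  indexes <- lapply(names(contaminants %||% list()), function(lb) {
    build_contaminant_index(contaminants[[lb]], lb, k = config$containment_k)
  })
  bins <- stage("annotate", {
    p <- partition_library(kchains, indexes, config$containment_threshold)
    ann <- bind_rows(p)[, c("kchain_id", "label", "containment")]
    readr::write_tsv(ann, file.path(output_dir, "annotation.tsv"))
    p[vapply(p, nrow, integer(1)) > 0L]
  })

  results <- list(kchains = kchains, annotation = bind_rows(bins), bins = list())
  for (bin_name in names(bins)) {
    bin <- bins[[bin_name]]
    profiles <- stage(paste0("quantify:", bin_name), {
      lapply(setNames(manifest$sample_id, manifest$sample_id), function(sid) {
        map_reads(read_list[[sid]], bin,
          seed_k = config$seed_k, min_identity = config$min_identity,
          min_score = config$min_score
        )
      })
    })
    mat_raw <- build_abundance_matrix(profiles, manifest, statistic = config$statistic)
    norm <- stage(paste0("normalize:", bin_name), {
      m <- mat_raw
      if (config$filter_stage == "raw") {
        m <- filter_by_max(m, config$abundance_threshold)
      }
      m <- quantile_normalize(log_transform(m, pseudo = config$pseudo))
      if (config$filter_stage == "normalized") {
        m <- filter_by_max(m, config$abundance_threshold)
      }
      m
    })
    write_abundance_tsv(mat_raw, file.path(output_dir, paste0("matrix_raw_", bin_name, ".tsv")))
    write_abundance_tsv(norm, file.path(output_dir, paste0("matrix_normalized_", bin_name, ".tsv")))
    if (nrow(norm) < 2L) {
      warn(paste0("bin '", bin_name, "' has <2 repeats after filtering; skipping ordination"))
      results$bins[[bin_name]] <- list(matrix_raw = mat_raw, matrix_norm = norm)
      next
    }
    ord <- stage(paste0("ordinate:", bin_name), {
      pca <- pca_repeats(norm, n_components = config$n_components)
      asg <- assign_max_species(norm)
      readr::write_tsv(
        tidy.repeat_pca(pca, "samples"),
        file.path(output_dir, paste0("pca_samples_", bin_name, ".tsv"))
      )
      readr::write_tsv(
        tidy.repeat_pca(pca, "repeats"),
        file.path(output_dir, paste0("pca_repeats_", bin_name, ".tsv"))
      )
      readr::write_tsv(
        tidy.repeat_pca(pca, "variance"),
        file.path(output_dir, paste0("pca_variance_", bin_name, ".tsv"))
      )
      readr::write_tsv(asg, file.path(output_dir, paste0("assignment_", bin_name, ".tsv")))
      list(pca = pca, assignment = asg)
    })
    tree <- stage(paste0("tree:", bin_name), {
      d <- abundance_distance(norm, metric = config$metric)
      readr::write_tsv(
        as_tibble(as.data.frame(d), rownames = "sample_id"),
        file.path(output_dir, paste0("distances_", bin_name, ".tsv"))
      )
      tr <- neighbor_joining(d)
      write_newick(tr, file.path(output_dir, paste0("tree_", bin_name, ".nwk")))
      tr
    })
    results$bins[[bin_name]] <- list(
      matrix_raw = mat_raw, matrix_norm = norm,
      pca = ord$pca, assignment = ord$assignment, tree = tree
    )
  }
  jsonlite::write_json(
    unclass(config), file.path(output_dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(results)
}
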