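# PCA biplot of the abundance matrix: repeats as observations over
# sample-dimensions, samples placed by their (scaled) loadings, and the
# repeat--species association statistics.

#' PCA of the abundance matrix
#'
#' Repeats are the observations and samples the variables. Columns are
#' mean-centred and decomposed by exact SVD; components are ordered by
#' decreasing variance and sign-fixed so that each component's loading
#' vector has its largest-magnitude entry positive. Both clouds are placed
#' with a dual scaling carrying equal per-component energy: repeat
#' coordinates are `U %*% diag(d)` and sample coordinates `V %*% diag(d)`,
#' so repeats and the samples they are abundant in occupy the same region
#' of the PC plane and distances between the two clouds are comparable.
#'
#' @param x An `abundance_matrix` in state `"log"` or
#'   `"quantile_normalized"` (raw matrices are refused: run
#'   [log_transform()] first).
#' @param n_components Number of components to retain (default 2).
#' @return A `repeat_pca` object: `sample_scores` (samples x C),
#'   `repeat_coords` (repeats x C), `variance_fraction` (over all
#'   components), plus the full decomposition for reconstruction.
#' @export
pca_repeats <- function(x, n_components = 2L) {
  assert_state(x, c("log", "quantile_normalized"), "pca_repeats()")
  v <- am_values(x)
  stopifnot(n_components >= 1, n_components <= min(dim(v)))
  xc <- scale(v, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12)) abort("matrix is constant; PCA is undefined")
  sv <- svd(xc)
  # sign convention: largest-|loading| entry of each component positive
  for (c_i in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, c_i]))
    if (sv$v[j, c_i] < 0) {
      sv$v[, c_i] <- -sv$v[, c_i]
      sv$u[, c_i] <- -sv$u[, c_i]
    }
  }
  var_frac <- sv$d^2 / sum(sv$d^2)
  cidx <- seq_len(n_components)
  scores <- sv$v[, cidx, drop = FALSE] %*% diag(sv$d[cidx], n_components)
  coords <- sv$u[, cidx, drop = FALSE] %*% diag(sv$d[cidx], n_components)
  dimnames(scores) <- list(colnames(v), paste0("PC", cidx))
  dimnames(coords) <- list(rownames(v), paste0("PC", cidx))
  structure(
    list(
      sample_scores = scores, repeat_coords = coords,
      variance_fraction = var_frac, n_components = as.integer(n_components),
      svd = sv, center = attr(xc, "scaled:center"),
      sample_meta = sample_meta(x)
    ),
    class = "repeat_pca"
  )
}

#' @export
print.repeat_pca <- function(x, ...) {
  cat("# repeat_pca: ", nrow(x$repeat_coords), " repeats x ",
    nrow(x$sample_scores), " samples, ", x$n_components, " components\n",
    sep = ""
  )
  vf <- round(100 * x$variance_fraction[seq_len(x$n_components)], 1)
  cat("# variance explained: ", paste0("PC", seq_along(vf), " ", vf, "%", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.repeat_pca <- function(x, type = c("samples", "repeats", "variance"), ...) {
  type <- match.arg(type)
  if (type == "variance") {
    return(tibble(
      component = seq_along(x$variance_fraction),
      variance_fraction = x$variance_fraction
    ))
  }
  m <- if (type == "samples") x$sample_scores else x$repeat_coords
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(
    tibble(id = rownames(m)), out
  )
  if (type == "samples") {
    out <- left_join(out, x$sample_meta, by = c(id = "sample_id"))
  }
  out
}

#' @export
glance.repeat_pca <- function(x, ...) {
  tibble(
    n_repeats = nrow(x$repeat_coords),
    n_samples = nrow(x$sample_scores),
    var_pc1 = x$variance_fraction[1],
    var_pc2 = x$variance_fraction[2],
    cum_var_pc12 = sum(x$variance_fraction[1:2])
  )
}

#' Assign each repeat to the species it is most abundant in
#'
#' For every repeat the replicate-mean abundance is computed per species
#' and the repeat is assigned to the argmax species; exact ties go to the
#' lexicographically first species. All-zero repeats are assigned the same
#' way and flagged.
#'
#' @param x An `abundance_matrix` (any state).
#' @return A tibble `repeat_id`, `species`, `mean_abundance`,
#'   `zero_abundance`, plus one `mean_<species>` column per species.
#' @export
assign_max_species <- function(x) {
  v <- am_values(x)
  meta <- sample_meta(x)
  species <- sort(unique(meta$species))
  means <- sapply(species, function(sp) {
    cols <- meta$sample_id[meta$species == sp]
    rowMeans(v[, cols, drop = FALSE])
  })
  means <- matrix(means,
    nrow = nrow(v),
    dimnames = list(rownames(v), species)
  )
  best <- apply(means, 1L, which.max) # first max = lexicographically first
  out <- tibble(
    repeat_id = rownames(v),
    species = species[best],
    mean_abundance = unname(means[cbind(seq_len(nrow(v)), best)]),
    zero_abundance = unname(apply(v, 1L, function(r) all(r == 0)))
  )
  prof <- as_tibble(means, .name_repair = "minimal")
  names(prof) <- paste0("mean_", species)
  dplyr::bind_cols(out, prof)
}

#' Per-sample mean abundance of the repeats assigned to one species
#'
#' The abundance-profile summary behind "which other species also carry
#' this species' repeats": the mean abundance, per sample, of all repeats
#' whose maximum-abundance species is `focus_species`.
#'
#' @param x An `abundance_matrix`.
#' @param assignment Output of [assign_max_species()] on the same matrix.
#' @param focus_species Species whose assigned repeat set is summarised.
#' @return A tibble `sample_id`, `species`, `replicate`, `mean_abundance`
#'   (one row per sample, manifest order).
#' @export
profile_summary <- function(x, assignment, focus_species) {
  meta <- sample_meta(x)
  stopifnot(focus_species %in% meta$species)
  ids <- assignment$repeat_id[assignment$species == focus_species]
  if (length(ids) == 0L) {
    warn(paste0("no repeats assigned to species ", focus_species))
    return(mutate(meta, mean_abundance = NA_real_))
  }
  v <- am_values(x)
  mutate(meta, mean_abundance = unname(colMeans(v[ids, , drop = FALSE])))
}

#' Repeat-to-species-centroid distances on the PC1--PC2 plane
#'
#' For each repeat, the Euclidean distance on the PC1--PC2 plane between
#' the repeat's coordinates and the centroid of the sample scores of its
#' assigned species -- the geometric statement of repeat--species
#' association in the biplot. Also reports, per repeat, the minimum
#' distance to any other species' centroid.
#'
#' @param pca A `repeat_pca` with at least 2 components.
#' @param assignment Output of [assign_max_species()].
#' @return A tibble `repeat_id`, `species`, `dist_own`, `dist_other_min`,
#'   with a per-species summary in attribute `"by_species"`.
#' @export
biplot_association <- function(pca, assignment) {
  stopifnot(pca$n_components >= 2)
  sc <- pca$sample_scores[, 1:2, drop = FALSE]
  meta <- pca$sample_meta
  species <- sort(unique(meta$species))
  centroids <- t(sapply(species, function(sp) {
    colMeans(sc[meta$sample_id[meta$species == sp], , drop = FALSE])
  }))
  rc <- pca$repeat_coords[, 1:2, drop = FALSE]
  asg <- assignment[match(rownames(rc), assignment$repeat_id), , drop = FALSE]
  d_all <- sapply(seq_along(species), function(j) {
    sqrt((rc[, 1] - centroids[j, 1])^2 + (rc[, 2] - centroids[j, 2])^2)
  })
  d_all <- matrix(d_all, nrow = nrow(rc))
  own_j <- match(asg$species, species)
  d_own <- d_all[cbind(seq_len(nrow(rc)), own_j)]
  d_other <- vapply(seq_len(nrow(rc)), function(i) {
    min(d_all[i, -own_j[i]])
  }, numeric(1))
  out <- tibble(
    repeat_id = rownames(rc), species = asg$species,
    dist_own = d_own, dist_other_min = d_other
  )
  by_sp <- out |>
    group_by(.data$species) |>
    summarise(
      n = dplyr::n(),
      mean_dist_own = mean(.data$dist_own),
      mean_dist_other_min = mean(.data$dist_other_min),
      .groups = "drop"
    )
  attr(out, "by_species") <- by_sp
  out
}

#' Biplot of samples and repeats on the PC plane
#'
#' @param object A `repeat_pca`.
#' @param assignment Optional [assign_max_species()] output used to colour
#'   repeats by their associated species.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.repeat_pca <- function(object, assignment = NULL, ...) {
  samples <- tidy.repeat_pca(object, "samples")
  repeats <- tidy.repeat_pca(object, "repeats")
  if (!is.null(assignment)) {
    repeats <- left_join(repeats,
      select(assignment, "repeat_id", rep_species = "species"),
      by = c(id = "repeat_id")
    )
  } else {
    repeats$rep_species <- NA_character_
  }
  vf <- round(100 * object$variance_fraction[1:2], 1)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = repeats,
      ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$rep_species),
      shape = 16, alpha = 0.6, size = 1.5
    ) +
    ggplot2::geom_point(
      data = samples,
      ggplot2::aes(x = .data$PC1, y = .data$PC2, fill = .data$species),
      shape = 21, size = 3.2, colour = "black"
    ) +
    ggplot2::labs(
      x = paste0("PC1 (", vf[1], "%)"), y = paste0("PC2 (", vf[2], "%)"),
      colour = "repeat max-abundance species", fill = "sample species"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of one species' assigned-repeat abundance across samples
#'
#' @param x An `abundance_matrix`.
#' @param assignment Output of [assign_max_species()].
#' @param focus_species Species whose assigned repeats are profiled.
#' @return A ggplot object.
#' @export
plot_species_profile <- function(x, assignment, focus_species) {
  prof <- profile_summary(x, assignment, focus_species)
  ggplot2::ggplot(prof, ggplot2::aes(
    x = factor(.data$sample_id, levels = .data$sample_id),
    y = .data$mean_abundance, fill = .data$species
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "sample",
      y = paste0("mean abundance of ", focus_species, "-assigned repeats")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
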