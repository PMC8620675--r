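# structured toy matrix: 4 species x 2 replicates, species-private repeat
# blocks plus noise (log state)
structured_matrix <- function(seed = 21, noise = 0.1) {
  set.seed(seed)
  species <- rep(c("a", "b", "c", "d"), each = 2)
  ids <- paste0(species, "_rep", rep(1:2, 4))
  v <- matrix(rnorm(40 * 8, sd = noise), 40, 8, dimnames = list(paste0("rep", 1:40), ids))
  for (j in 1:4) {
    rows <- ((j - 1) * 10 + 1):(j * 10)
    v[rows, species == c("a", "b", "c", "d")[j]] <-
      v[rows, species == c("a", "b", "c", "d")[j]] + 5
  }
  abundance_matrix(pmax(v + 2, 0),
    toy_meta(ids, species, rep(1:2, 4)),
    state = "raw"
  ) |> log_transform()
}

test_that("PCA follows the SVD contract", {
  # rank-1 matrix: PC1 carries all variance
  sm <- toy_meta(c("s1", "s2", "s3"))
  X <- outer(c(1, 2, 3, 5), c(2, 1, 4))
  m <- abundance_matrix(
    matrix(X, 4, 3, dimnames = list(paste0("r", 1:4), sm$sample_id)),
    sm,
    state = "log"
  )
  p <- pca_repeats(m, 2)
  expect_lt(abs(p$variance_fraction[1] - 1), 1e-10)
  # variance fractions sum to one over all components
  expect_equal(sum(p$variance_fraction), 1)
  # reconstruction from the full decomposition
  sv <- p$svd
  xc <- scale(kchainr:::am_values(m), center = TRUE, scale = FALSE)
  expect_lt(max(abs(sv$u %*% diag(sv$d) %*% t(sv$v) - xc)), 1e-8)
  # sign convention: each loading vector's largest-|.| entry is positive
  for (c_i in 1:2) {
    expect_gt(sv$v[which.max(abs(sv$v[, c_i])), c_i], 0)
  }
  # deterministic
  p2 <- pca_repeats(m, 2)
  expect_identical(p$sample_scores, p2$sample_scores)
  # constant matrix refused
  cm <- abundance_matrix(
    matrix(3, 4, 3, dimnames = list(paste0("r", 1:4), sm$sample_id)),
    sm,
    state = "log"
  )
  expect_error(pca_repeats(cm), "constant")
  # raw state refused
  expect_error(pca_repeats(toy_matrix(matrix(1:4, 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))
  ))), "state")
})

test_that("repeats are assigned to their maximum-abundance species", {
  meta <- toy_meta(
    paste0(rep(c("A", "B"), each = 3), "_", 1:3),
    rep(c("A", "B"), each = 3), rep(1:3, 2)
  )
  v <- rbind(
    r1 = c(10, 12, 11, 1, 2, 1), # A
    r2 = c(1, 1, 1, 4, 4, 4), # B
    r3 = c(2, 2, 2, 2, 2, 2), # exact tie -> lexicographically first
    r4 = c(0, 0, 0, 0, 0, 0) # all-zero, flagged
  )
  colnames(v) <- meta$sample_id
  m <- abundance_matrix(v, meta, state = "raw")
  asg <- assign_max_species(m)
  expect_equal(asg$species, c("A", "B", "A", "A"))
  expect_equal(asg$zero_abundance, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(asg$mean_abundance[1], 11)

  # profile summary: a single assigned repeat equals its own row
  asg_b <- asg[asg$species == "B", ]
  prof <- profile_summary(m, asg, "B")
  expect_equal(nrow(prof), 6L)
  expect_equal(prof$mean_abundance, unname(v["r2", ]))
  # empty focus set warns
  expect_warning(profile_summary(m, asg[0, ], "B"), "no repeats")
})

test_that("biplot association puts repeats near their own species", {
  m <- structured_matrix()
  qn <- quantile_normalize(m)
  p <- pca_repeats(qn, 2)
  asg <- assign_max_species(qn)
  ba <- biplot_association(p, asg)
  expect_true(all(ba$dist_own >= 0))
  # private repeats sit closer to their own species' centroid on average
  expect_lt(mean(ba$dist_own), mean(ba$dist_other_min))
  # relabeling repeats leaves distances unchanged
  m2 <- qn
  m2$repeat_id <- paste0("x_", m2$repeat_id)
  m2 <- abundance_matrix(tibble::as_tibble(m2), sample_meta(qn), state = "quantile_normalized")
  ba2 <- biplot_association(pca_repeats(m2, 2), assign_max_species(m2))
  expect_equal(ba2$dist_own, ba$dist_own)
})

test_that("samples cluster with their replicates in PC space", {
  m <- structured_matrix()
  p <- pca_repeats(quantile_normalize(m), 2)
  sc <- p$sample_scores[, 1:2]
  meta <- sample_meta(m)
  for (i in seq_len(nrow(sc))) {
    d <- sqrt(rowSums((sc - matrix(sc[i, ], nrow(sc), 2, byrow = TRUE))^2))
    d[i] <- Inf
    expect_equal(meta$species[which.min(d)], meta$species[i])
  }
})

test_that("tidy, glance and autoplot surfaces work", {
  m <- structured_matrix()
  qn <- quantile_normalize(m)
  p <- pca_repeats(qn, 2)
  ts <- tidy(p, "samples")
  expect_equal(nrow(ts), 8L)
  expect_true(all(c("id", "PC1", "PC2", "species") %in% names(ts)))
  expect_equal(nrow(tidy(p, "repeats")), 40L)
  expect_equal(sum(tidy(p, "variance")$variance_fraction), 1)
  g <- glance(p)
  expect_equal(g$n_samples, 8L)
  expect_gte(g$cum_var_pc12, g$var_pc1)
  asg <- assign_max_species(qn)
  expect_s3_class(autoplot(p, asg), "ggplot")
  expect_s3_class(autoplot(qn), "ggplot")
  expect_s3_class(plot_species_profile(qn, asg, "a"), "ggplot")
  lt <- tidy(qn)
  expect_equal(nrow(lt), 40L * 8L)
})
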