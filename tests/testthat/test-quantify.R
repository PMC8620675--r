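ref2 <- function() {
  set.seed(31)
  tibble::tibble(
    id = c("repA", "repB"),
    seq = vapply(1:2, function(i) {
      paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    }, character(1))
  )
}

test_that("the mapper assigns reads to one reference and counts coverage", {
  refs <- ref2()
  # read equal to a 40-bp substring of repA
  rd <- tibble::tibble(id = "q1", seq = substring(refs$seq[1], 21, 60))
  prof <- map_reads(rd, refs, seed_k = 12L, min_identity = 0.9)
  expect_equal(prof$depth[[1]][21:60], rep(1L, 40))
  expect_equal(sum(prof$depth[[1]]), 40L)
  expect_equal(sum(prof$depth[[2]]), 0L)

  # 100-bp read with 5 scattered substitutions still maps (0.95 >= 0.9)
  rseq <- substring(refs$seq[1], 11, 110)
  ch <- strsplit(rseq, "")[[1]]
  for (p in c(20, 40, 60, 80, 95)) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  prof2 <- map_reads(tibble::tibble(id = "q2", seq = paste(ch, collapse = "")), refs)
  expect_gt(sum(prof2$depth[[1]]), 50L)

  # reverse-complement reads map to the same interval
  rd_rc <- tibble::tibble(id = "q3", seq = revcomp(substring(refs$seq[1], 21, 60)))
  prof3 <- map_reads(rd_rc, refs)
  expect_equal(prof3$depth[[1]][21:60], rep(1L, 40))

  # conservation: increments never exceed total read bases
  st <- small_study()
  cons <- tibble::tibble(id = "famS", seq = st$consensus$seq[1])
  pr <- map_reads(st$reads[[1]], cons)
  expect_lte(sum(pr$depth[[1]]), sum(nchar(st$reads[[1]]$seq)))
})

test_that("abundance is the order statistic over all positions", {
  prof <- tibble::tibble(
    ref_id = c("a", "b"),
    length = c(5L, 3L),
    depth = list(c(0L, 2L, 4L, 4L, 10L), c(0L, 0L, 0L))
  )
  expect_equal(abundance(prof, "median")$abundance, c(4, 0))
  expect_equal(abundance(prof, "mean")$abundance, c(4, 0))
})

test_that("the matrix builder follows the manifest and keeps zero rows", {
  manifest <- toy_meta(c("s1", "s2"))
  profs <- list(
    s1 = tibble::tibble(
      ref_id = c("a", "b"), length = c(3L, 3L),
      depth = list(c(1L, 2L, 3L), c(0L, 0L, 0L))
    ),
    s2 = tibble::tibble(
      ref_id = c("a", "b"), length = c(3L, 3L),
      depth = list(c(5L, 5L, 5L), c(0L, 0L, 0L))
    )
  )
  m <- build_abundance_matrix(profs, manifest)
  v <- kchainr:::am_values(m)
  expect_equal(v["a", ], c(s1 = 2, s2 = 5))
  expect_equal(v["b", ], c(s1 = 0, s2 = 0)) # all-zero row retained
  expect_equal(colnames(v), c("s1", "s2")) # manifest order
  # manifest order is respected even when reversed
  m2 <- build_abundance_matrix(profs, manifest[2:1, ])
  expect_equal(colnames(kchainr:::am_values(m2)), c("s2", "s1"))
  # duplicated reference ids are refused
  profs$s1 <- dplyr::bind_rows(profs$s1, profs$s1[1, ])
  expect_error(build_abundance_matrix(profs, manifest), "duplicated")
})

test_that("log transform and its state machine behave", {
  m <- toy_matrix(matrix(c(0, exp(1) - 1, 3, 7),
    2, 2,
    dimnames = list(c("r1", "r2"), c("s1", "s2"))
  ))
  lg <- log_transform(m, pseudo = 1)
  v <- kchainr:::am_values(lg)
  expect_equal(v["r1", "s1"], 0)
  expect_equal(v["r2", "s1"], 1)
  expect_equal(matrix_state(lg), "log")
  # monotonicity: order of entries preserved
  expect_equal(order(kchainr:::am_values(m)), order(v))
  # state transitions are enforced
  expect_error(log_transform(lg), "state")
  expect_error(quantile_normalize(m), "state")
})

test_that("quantile normalization equals the hand-derived fixture", {
  m <- toy_matrix(
    matrix(c(1, 3, 4, 2), 2, 2, dimnames = list(c("r1", "r2"), c("s1", "s2"))),
    state = "log"
  )
  qn <- quantile_normalize(m)
  expect_equal(
    unname(kchainr:::am_values(qn)),
    matrix(c(1.5, 3.5, 3.5, 1.5), 2, 2)
  )
  expect_equal(matrix_state(qn), "quantile_normalized")

  # idempotence: re-normalizing the normalized values changes nothing
  again <- quantile_normalize(
    toy_matrix(kchainr:::am_values(qn), state = "log")
  )
  expect_equal(kchainr:::am_values(again), kchainr:::am_values(qn))

  # every column's sorted vector is identical afterwards
  set.seed(8)
  big <- toy_matrix(
    matrix(rexp(60), 15, 4,
      dimnames = list(paste0("r", 1:15), paste0("s", 1:4))
    ),
    sample_ids = paste0("s", 1:4), state = "log"
  )
  vq <- kchainr:::am_values(quantile_normalize(big))
  sorted <- apply(vq, 2, sort)
  expect_equal(max(abs(sorted - sorted[, 1])), 0)
})

test_that("the max filter keeps exactly the rows above threshold", {
  m <- toy_matrix(matrix(
    c(
      149.9, 10, # max 149.9: dropped at 150
      150.1, 0, # max 150.1: kept at 150
      666, 1, # kept at 665
      665, 1 # dropped at 665 (strictly greater required)
    ),
    4, 2,
    byrow = TRUE,
    dimnames = list(c("low", "edge", "high", "at"), c("s1", "s2"))
  ))
  expect_equal(filter_by_max(m, 150)$repeat_id, c("edge", "high", "at"))
  expect_equal(filter_by_max(m, 665)$repeat_id, "high")
  expect_equal(nrow(filter_by_max(m, -1)), 4L)
})

test_that("raw abundance tracks planted copy number across samples", {
  st <- small_study()
  cons <- tibble::tibble(id = "famS", seq = st$consensus$seq[1])
  profs <- lapply(
    stats::setNames(st$manifest$sample_id, st$manifest$sample_id),
    function(sid) map_reads(st$reads[[sid]], cons)
  )
  m <- build_abundance_matrix(profs, st$manifest)
  v <- kchainr:::am_values(m)
  tr <- st$truth[st$truth$family_id == "famS", ]
  x <- tr$copy_number[match(colnames(v), tr$sample_id)]
  rho <- stats::cor(x, as.numeric(v["famS", ]), method = "spearman")
  expect_gte(rho, 0.95)
})
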