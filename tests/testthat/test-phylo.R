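test_that("abundance distances behave like metrics", {
  sm <- toy_meta(c("s1", "s2", "s3"))
  v <- matrix(c(0, 0, 3, 4, 0, 0), 2, 3,
    dimnames = list(c("r1", "r2"), sm$sample_id)
  )
  m <- abundance_matrix(v, sm, state = "log")
  d <- abundance_distance(m, "euclidean")
  expect_equal(d["s1", "s2"], 5) # 3-4-5 triangle
  expect_equal(d["s1", "s3"], 0) # identical columns
  # symmetry + triangle inequality on a random 5x6 matrix
  set.seed(12)
  sm6 <- toy_meta(paste0("t", 1:6))
  m6 <- abundance_matrix(
    matrix(runif(30), 5, 6, dimnames = list(paste0("r", 1:5), sm6$sample_id)),
    sm6,
    state = "log"
  )
  for (metric in c("euclidean", "manhattan")) {
    dd <- abundance_distance(m6, metric)
    expect_equal(dd, t(dd))
    expect_true(all(diag(dd) == 0))
    for (i in 1:6) {
      for (j in 1:6) {
        for (k in 1:6) expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
      }
    }
  }
  expect_error(abundance_distance(
    abundance_matrix(v[, 1, drop = FALSE], sm[1, ], state = "log")
  ), "2 samples")
})

test_that("neighbor joining is exact on additive distances", {
  # ((A:1,B:2):1,(C:3,D:4)) hand-derived distances
  D <- matrix(
    c(
      0, 3, 5, 6,
      3, 0, 6, 7,
      5, 6, 0, 7,
      6, 7, 7, 0
    ), 4, 4,
    dimnames = list(LETTERS[1:4], LETTERS[1:4])
  )
  tr <- neighbor_joining(D)
  # topology AB|CD by the four-point condition oracle: the sum paired with
  # the true split is the strict minimum
  sums <- c(
    AB_CD = D["A", "B"] + D["C", "D"],
    AC_BD = D["A", "C"] + D["B", "D"],
    AD_BC = D["A", "D"] + D["B", "C"]
  )
  expect_equal(names(which.min(sums)), "AB_CD")
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_true(ape::is.monophyletic(tr, c("C", "D")))
  expect_lt(max(abs(tree_path_lengths(tr) - D)), 1e-9)

  # random additive matrices, n = 4..10: topology and paths round trip
  set.seed(33)
  for (n in 4:10) {
    gen <- ape::rtree(n, rooted = FALSE)
    gen$edge.length <- runif(nrow(gen$edge), 0.1, 5)
    D_n <- ape::cophenetic.phylo(gen)
    mine <- neighbor_joining(D_n)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), ape::unroot(mine))), 0)
    ord <- order(rownames(D_n))
    expect_lt(max(abs(tree_path_lengths(mine) - D_n[ord, ord])), 1e-9)
    # agreement with the reference implementation
    ref <- ape::nj(stats::as.dist(D_n))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), ape::unroot(mine))), 0)
  }

  # n = 3: closed-form three-point branch lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$edge.length), c(0.5, 1.5, 2.5))
  expect_lt(max(abs(tree_path_lengths(t3) - D3)), 1e-12)

  # n = 2: the single edge splits the distance
  D2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- neighbor_joining(D2)
  expect_equal(tree_path_lengths(t2)["x", "y"], 5)

  # n = 1 refused
  expect_error(neighbor_joining(matrix(0, 1, 1, dimnames = list("a", "a"))), "2 taxa")

  # negative branch estimates are clamped with a warning
  Dneg <- matrix(
    c(
      0, 1, 10, 10,
      1, 0, 1, 9,
      10, 1, 0, 1,
      10, 9, 1, 0
    ), 4, 4,
    dimnames = list(letters[1:4], letters[1:4])
  )
  expect_warning(tneg <- neighbor_joining(Dneg), "clamped")
  expect_true(all(tneg$edge.length >= 0))
})

test_that("newick serialization quotes awkward labels and round trips", {
  D2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_match(write_newick(neighbor_joining(D2)), "^\\(A:1,B:1\\);$")

  # random 8-leaf round trip through the reference parser
  set.seed(14)
  gen <- ape::rtree(8, rooted = FALSE)
  gen$edge.length <- runif(nrow(gen$edge), 0.1, 5)
  tr <- neighbor_joining(ape::cophenetic.phylo(gen))
  back <- ape::read.tree(text = write_newick(tr))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
  ordm <- function(m) m[order(rownames(m)), order(colnames(m))]
  expect_lt(
    max(abs(ordm(ape::cophenetic.phylo(back)) - tree_path_lengths(tr))),
    1e-6
  )

  # labels containing spaces or metacharacters are quoted
  Dq <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
    dimnames = list(c("sp one", "sp,two", "ok"), c("sp one", "sp,two", "ok"))
  )
  txt <- write_newick(neighbor_joining(Dq))
  expect_match(txt, "'sp one'", fixed = TRUE)
  expect_match(txt, "'sp,two'", fixed = TRUE)
})
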