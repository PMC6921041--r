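test_that("web construction applies the co-occurrence threshold per sampling cell", {
  fx <- cached_fixture("tiny")
  md <- fx$metadata
  # hand-built incidence: 4 OTUs x the 15 samples of 3 MONO cells
  design <- build_design(md)
  combos <- enumerate_combinations(design)
  cells <- combination_cells(combos, 0, "MONO")
  ids <- unlist(lapply(seq_len(nrow(cells)), function(i) {
    md$sample_id[md$plot_id == cells$plot_id[i] &
                   md$tree_species == cells$species[i]]
  }))
  inc <- matrix(0L, 4, length(ids),
                dimnames = list(paste0("OTU", 1:4), ids))
  inc["OTU1", ids[1:3]] <- 1L   # 3 of 5 samples of tree 1
  inc["OTU2", ids[1:5]] <- 1L   # all 5 samples of tree 1
  inc["OTU3", ids[6]] <- 1L     # 1 of 5 samples of tree 2
  for (t in 1:5) {
    web <- build_web(inc, cells, md, threshold = t)
    expect_identical("OTU1" %in% colnames(web), t <= 3)
    expect_identical("OTU2" %in% colnames(web), TRUE)
    expect_identical("OTU3" %in% colnames(web), t == 1)
    expect_false("OTU4" %in% colnames(web))     # all-zero column dropped
  }
  web5 <- build_web(inc, cells, md, threshold = 5)
  expect_identical(colnames(web5), "OTU2")

  # a cell with missing samples is an error naming the cell
  expect_error(build_web(inc[, -1], cells, md, threshold = 1), "has 4 sample")
})

test_that("web OTU count is non-increasing in the link threshold", {
  fx <- cached_fixture("tiny")
  pp <- preprocess_counts(fx$counts, seed = 1)
  md <- fx$metadata[fx$metadata$sample_id %in% pp$samples, ]
  combos <- enumerate_combinations(build_design(md))
  for (id in c(0, 5)) {
    for (lv in c("MONO", "TWO", "HIGH")) {
      cells <- combination_cells(combos, id, lv)
      n <- vapply(1:5, function(t) {
        ncol(build_web(pp$incidence, cells, md, threshold = t))
      }, numeric(1))
      expect_true(all(diff(n) <= 0))
    }
  }
})

test_that("connectance, generality, C score, shared partners match hand examples", {
  full <- matrix(1L, 7, 10)
  expect_equal(connectance(full), 1)
  expect_equal(generality(full), 7)

  w <- matrix(0L, 7, 10)
  w[cbind(sample(1:7, 14, TRUE), rep(1:10, length.out = 14))] <- 1L
  w <- matrix(0L, 7, 10); w[1, 1:10] <- 1L; w[2, 1:4] <- 1L
  expect_equal(connectance(w), 14 / 70)

  # degrees {2,2,1}, L = 5 -> 1.8
  g <- matrix(c(1, 1, 0,
                1, 1, 1), 2, 3, byrow = TRUE)
  expect_equal(generality(g), 1.8)
  deg1 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(generality(deg1), 1)

  # C score: disjoint singletons 1, identical columns 0, {1,2} vs {2,3} 0.25
  expect_equal(c_score(matrix(c(1, 0, 0, 1), 2, 2)), 1)
  expect_equal(c_score(matrix(c(1, 1, 1, 1), 2, 2)), 0)
  w2 <- matrix(c(1, 0,
                 1, 1,
                 0, 1), 3, 2, byrow = TRUE)
  expect_equal(c_score(w2), 0.25)

  # shared partners: {f1,f2,f3}, {f2,f3}, {f3} -> (2+1+1)/3
  sp <- matrix(c(1, 1, 1,
                 0, 1, 1,
                 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(mean_shared_partners(sp), 4 / 3)
  expect_equal(mean_shared_partners(rbind(sp[1, ], sp[1, ])), 3)
  expect_equal(mean_shared_partners(matrix(c(1, 0, 0, 1), 2, 2)), 0)
})

test_that("NODF matches its defining examples and is permutation invariant", {
  tri <- matrix(c(1, 1, 1,
                  1, 1, 0,
                  1, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(nodf(tri), 100)
  expect_equal(nodf(matrix(c(1, 0, 0, 1), 2, 2)), 0)
  expect_equal(nodf(matrix(c(1, 1, 0,
                             0, 1, 1), 2, 3, byrow = TRUE)), 50)
  set.seed(21)
  for (i in 1:20) {
    w <- random_web(sample(3:8, 1), sample(3:20, 1))
    v <- nodf(w)
    expect_equal(nodf(w[sample(nrow(w)), sample(ncol(w))]), v)
    expect_gte(v, 0)
    expect_lte(v, 100)
  }
})

test_that("pairwise metrics agree with naive brute-force loops on random webs", {
  set.seed(31)
  for (i in 1:40) {
    w <- random_web(sample(3:10, 1), sample(3:30, 1))
    expect_equal(connectance(w), bf_connectance(w))
    expect_equal(generality(w), bf_generality(w))
    expect_equal(c_score(w), bf_cscore(w))
    expect_equal(mean_shared_partners(w), bf_shared_partners(w))
  }
})

test_that("NODF agrees with the vegan reference implementation on random webs", {
  skip_if_not_installed("vegan")
  set.seed(41)
  for (i in 1:30) {
    w <- random_web(sample(3:10, 1), sample(3:40, 1))
    v <- unname(vegan::nestednodf(w)$statistic["NODF"])
    expect_equal(nodf(w), v, tolerance = 1e-10)
  }
})

test_that("pooled alpha diversity matches direct entropy evaluation", {
  fx <- cached_fixture("tiny")
  pp <- preprocess_counts(fx$counts, seed = 1)
  md <- fx$metadata[fx$metadata$sample_id %in% pp$samples, ]
  combos <- enumerate_combinations(build_design(md))
  cells <- combination_cells(combos, 0, "MONO")
  ad <- alpha_diversity(pp$rarefied, cells, md)
  ids <- unlist(lapply(seq_len(nrow(cells)), function(i) {
    md$sample_id[md$plot_id == cells$plot_id[i] &
                   md$tree_species == cells$species[i]]
  }))
  pooled <- rowSums(pp$rarefied[, ids])
  pooled <- pooled[pooled > 0]
  expect_equal(ad$richness, length(pooled))
  p <- pooled / sum(pooled)
  expect_equal(ad$shannon, -sum(p * log(p)))

  # closed forms: equal abundances -> ln n; single OTU -> 0
  eq <- matrix(5L, 4, 5, dimnames = list(paste0("o", 1:4), ids[1:5]))
  one_cell <- cells[1, ]
  expect_equal(alpha_diversity(eq, one_cell, md)$shannon, log(4))
  single <- matrix(7L, 1, 5, dimnames = list("o1", ids[1:5]))
  a1 <- alpha_diversity(single, one_cell, md)
  expect_equal(a1$richness, 1)
  expect_equal(a1$shannon, 0)
  # pooled counts (700, 300)
  two <- matrix(c(350L, 150L), 2, 5, dimnames = list(c("o1", "o2"), ids[1:5]))
  two[] <- c(140L, 60L)
  expect_equal(alpha_diversity(two, one_cell, md)$shannon,
               -0.7 * log(0.7) - 0.3 * log(0.3))
})
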