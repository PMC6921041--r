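test_that("phi equals sign(ad-bc) * sqrt(X2/N) on all small tables with positive margins", {
  # exhaustive over all 2x2 tables with N <= 12
  for (a in 0:12) for (b in 0:(12 - a)) for (c in 0:(12 - a - b)) {
    for (d in 0:(12 - a - b - c)) {
      N <- a + b + c + d
      if (N == 0) next
      phi <- phi_coefficient(a, b, c, d)
      margins_pos <- all(c(a + b, c + d, a + c, b + d) > 0)
      if (!margins_pos) {
        expect_true(is.na(phi))
        next
      }
      tab <- matrix(c(a, c, b, d), 2, 2)
      x2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
      expect_equal(abs(phi), sqrt(unname(x2) / N), tolerance = 1e-10)
      expect_equal(sign(phi), sign(a * d - b * c))
      expect_gte(phi, -1)
      expect_lte(phi, 1)
    }
  }
})

test_that("phi attains the extrema exactly on perfect-association tables", {
  expect_equal(phi_coefficient(5, 0, 0, 5), 1)
  expect_equal(phi_coefficient(0, 5, 5, 0), -1)
  expect_equal(phi_coefficient(3, 1, 2, 4), 10 / sqrt(600))
})

test_that("phi tables encode plot occupancy in the expected 2x2 cells", {
  fx <- cached_fixture("tiny")
  md <- fx$metadata
  combos <- enumerate_combinations(build_design(md))
  cells <- combination_cells(combos, 0, "MONO")
  k <- nrow(cells)
  sample_of <- function(i, r) {
    md$sample_id[md$plot_id == cells$plot_id[i] &
                   md$tree_species == cells$species[i]][r]
  }
  all_ids <- unlist(lapply(seq_len(k), function(i) sample_of(i, 1:5)))
  inc <- matrix(0L, 3, length(all_ids),
                dimnames = list(paste0("OTU", 1:3), all_ids))
  inc["OTU1", sample_of(1, 1)] <- 1L                      # only plot 1
  inc["OTU2", vapply(seq_len(k), sample_of, character(1), r = 1)] <- 1L # everywhere
  inc["OTU3", c(sample_of(1, 2), sample_of(2, 1))] <- 1L  # plots 1 and 2
  ph <- phi_table(inc, cells, md)
  expect_equal(ph$phi[ph$otu_id == "OTU1" & ph$tree_species == cells$species[1]], 1)
  expect_true(all(is.na(ph$phi[ph$otu_id == "OTU2"])))    # zero absence margin
  phi12 <- ph$phi[ph$otu_id == "OTU3" & ph$tree_species == cells$species[1]]
  # a=1, b=1, c=0, d=k-2
  expect_equal(phi12, phi_coefficient(1, 1, 0, k - 2))
  phi_absent <- ph$phi[ph$otu_id == "OTU3" & ph$tree_species == cells$species[3]]
  expect_lt(phi_absent, 0)

  # a stricter presence rule drops single-sample presences
  ph5 <- phi_table(inc, cells, md, presence_min = 2L)
  expect_false("OTU1" %in% ph5$otu_id)
})

test_that("median positive phi filters undefined and non-positive values", {
  expect_equal(median_positive_phi(c(0.2, 0.6, 1.0)), 0.6)
  expect_equal(median_positive_phi(c(1, 1, 1)), 1)
  expect_true(is.na(median_positive_phi(c(-0.5, NA, 0))))
  set.seed(43)
  for (i in 1:10) {
    phi <- c(runif(20, -1, 1), rep(NA, 5))
    ref <- sort(phi[!is.na(phi) & phi > 0])
    expect_equal(median_positive_phi(phi),
                 if (length(ref)) median(ref) else NA_real_)
  }
})

test_that("guild contrasts report Kruskal-Wallis and post hoc on positive phi", {
  recs <- tibble::tibble(
    otu_id = rep(c("a1", "a2", "a3", "b1", "b2", "b3", "c1", "c2", "c3"),
                 each = 1),
    phi = c(1, 2, 3, 4, 5, 6, 7, 8, 9) / 10
  )
  guilds <- tibble::tibble(otu_id = recs$otu_id,
                           guild = rep(c("saprotroph", "ectomycorrhizal",
                                         "plant_pathogen"), each = 3))
  out <- group_phi_comparison(recs, guilds)
  expect_equal(out$kruskal$statistic, 7.2)
  expect_equal(nrow(out$posthoc), 3)
  expect_equal(sort(out$group_medians$median_phi), c(0.2, 0.5, 0.8))

  ident <- group_phi_comparison(
    tibble::tibble(otu_id = c("a1", "b1", "a2", "b2"), phi = c(.5, .5, .7, .7)),
    tibble::tibble(otu_id = c("a1", "a2", "b1", "b2"),
                   guild = rep(c("saprotroph", "unknown"), times = c(2, 2))))
  expect_equal(ident$kruskal$statistic, 0)

  expect_error(group_phi_comparison(recs[0, ], guilds), ">= 2 guilds")
})

test_that("planted high-phi guild is flagged as significantly higher", {
  set.seed(47)
  recs <- tibble::tibble(
    otu_id = sprintf("o%03d", 1:120),
    phi = c(runif(40, 0.6, 1), runif(80, 0.05, 0.4))
  )
  guilds <- tibble::tibble(
    otu_id = recs$otu_id,
    guild = c(rep("ectomycorrhizal", 40), rep("saprotroph", 80))
  )
  out <- group_phi_comparison(recs, guilds)
  expect_lt(out$kruskal$p.value, 1e-6)
  ecm <- out$group_medians$median_phi[out$group_medians$guild == "ectomycorrhizal"]
  sap <- out$group_medians$median_phi[out$group_medians$guild == "saprotroph"]
  expect_gt(ecm, sap)
  expect_true(all(out$posthoc$significant))
})

test_that("specialist ranking selects by maximum phi and clusters similar rows", {
  recs <- tibble::tibble(
    otu_id = rep(c("w", "x", "y", "z"), each = 2),
    tree_species = rep(c("spA", "spB"), times = 4),
    phi = c(0.9, -0.2, 0.9, -0.2, -0.5, 0.8, 0.1, 0.2)
  )
  out <- rank_specialists(recs, top_n = 3)
  expect_identical(sort(out$ranking$otu_id), c("w", "x", "y"))
  expect_equal(out$ranking$max_phi[out$ranking$otu_id == "y"], 0.8)
  # identical rows w and x merge first -> adjacent in the clustering order
  pos <- match(c("w", "x"), rownames(out$matrix))
  expect_equal(abs(diff(pos)), 1)

  all_back <- rank_specialists(recs, top_n = 100)
  expect_equal(nrow(all_back$ranking), 4)

  # clustering order matches the brute-force average-linkage merge heights
  set.seed(53)
  m <- rbind(matrix(rnorm(6, 0), 2), matrix(rnorm(6, 10), 2))
  recs2 <- tibble::tibble(
    otu_id = rep(sprintf("o%d", 1:4), times = 3),
    tree_species = rep(c("s1", "s2", "s3"), each = 4),
    phi = as.vector(m)
  )
  out2 <- rank_specialists(recs2, top_n = 4)
  ordered_groups <- match(rownames(out2$matrix), sprintf("o%d", 1:4)) <= 2
  expect_true(all(ordered_groups[1:2]) || all(!ordered_groups[1:2]))
})

test_that("frequent-OTU classification applies the strict all-plots rule", {
  fx <- cached_fixture("tiny")
  md <- fx$metadata
  combos <- enumerate_combinations(build_design(md))
  # keep 4 combos for speed
  sub <- combos[combos$combination_id %in% 0:3, ]
  inc <- matrix(0L, 2, nrow(md), dimnames = list(c("OTU1", "OTU2"), md$sample_id))
  inc["OTU1", ] <- 1L     # everywhere -> frequent at every level
  # OTU2: present in all plots except one monoculture used in every combination
  mono_plots <- unique(sub$plot_id[sub$level == "MONO"])
  always_used <- mono_plots[vapply(mono_plots, function(p) {
    all(vapply(0:3, function(id) p %in% sub$plot_id[sub$combination_id == id &
                                                      sub$level == "MONO"],
               logical(1)))
  }, logical(1))]
  expect_gt(length(always_used), 0)
  inc["OTU2", md$plot_id != always_used[1]] <- 1L
  out <- frequent_otus(inc, sub, md)
  expect_identical(out$frequent_all_levels, "OTU1")
  f2 <- out$flags[out$flags$otu_id == "OTU2", ]
  expect_false(f2$frequent[f2$level == "MONO"])
  expect_true(all(f2$frequent[f2$level != "MONO"]))
  expect_true(all(out$unique_frequent$otu_id != "OTU1"))
})
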