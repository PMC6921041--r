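test_that("build_design reconstructs the broken-stick plot set from metadata", {
  dsg <- generate_design(16, seed = 2)
  design <- build_design(dsg$metadata)
  expect_equal(nrow(design), 31)
  expect_equal(as.vector(table(design$richness)[c("1", "2", "4", "8", "16")]),
               c(16, 8, 4, 2, 1))
  expect_silent(validate_broken_stick(design))

  mono <- dsg$metadata[dsg$metadata$plot_richness == 1, ][1:5, ]
  one <- build_design(mono)
  expect_equal(nrow(one), 1)
  expect_equal(one$richness, 1L)
})

test_that("build_design rejects plots whose observed species disagree with richness", {
  dsg <- generate_design(16, seed = 2)
  md <- dsg$metadata
  two_plot <- md$plot_id[md$plot_richness == 2][1]
  extra <- md[md$plot_id == two_plot, ][1, ]
  extra$sample_id <- "extra_sample"
  extra$tree_species <- "intruder"
  expect_error(build_design(rbind(md, extra)), "declares richness 2 but 3")
})

test_that("combination enumeration reproduces the design's combinatorics", {
  dsg <- generate_design(16, seed = 3)
  co0 <- enumerate_combinations(dsg$design)
  expect_equal(length(unique(co0$combination_id)), 1024)  # 8 * 2^7
  co1 <- enumerate_combinations(dsg$design, excluded_species = dsg$pool[7])
  expect_equal(length(unique(co1$combination_id)), 576)
  # two excluded species sharing a TWO plot leave 1 plot-subset x 2^7 choices
  shared <- dsg$design$species[dsg$design$richness == 2][[3]]
  co2 <- enumerate_combinations(dsg$design, excluded_species = shared)
  expect_equal(length(unique(co2$combination_id)), 128)
  expect_error(enumerate_combinations(dsg$design, "not_a_species"),
               "not in the pool")
})

test_that("enumeration agrees with a brute-force oracle on an 8-species design", {
  dsg <- generate_design(8, seed = 4)
  design <- dsg$design
  two <- design[design$richness == 2, ]
  two <- two[order(two$plot_id), ]
  # oracle: all 3-subsets of the 4 TWO plots x one species per plot,
  # dropping choices with an excluded species
  oracle_count <- function(excluded) {
    n <- 0
    for (subset in utils::combn(seq_len(4), 3, simplify = FALSE)) {
      opts <- lapply(two$species[subset], identity)
      grid <- expand.grid(lapply(opts, seq_along))
      for (g in seq_len(nrow(grid))) {
        sp <- vapply(seq_len(3), function(i) opts[[i]][grid[g, i]], character(1))
        if (!any(sp %in% excluded)) n <- n + 1
      }
    }
    n
  }
  for (excl in list(character(0), dsg$pool[1], dsg$pool[c(1, 5)])) {
    co <- enumerate_combinations(design, excluded_species = excl)
    expect_equal(length(unique(co$combination_id)), oracle_count(excl))
  }
})

test_that("every emitted combination satisfies the structural invariants", {
  for (seed in 1:3) {
    dsg <- generate_design(8, seed = seed)
    co <- enumerate_combinations(dsg$design, excluded_species = dsg$pool[8])
    k <- 3
    plot_lookup <- setNames(dsg$design$species, dsg$design$plot_id)
    for (id in unique(co$combination_id)) {
      sp_ref <- NULL
      for (lv in c("MONO", "TWO", "HIGH")) {
        cells <- combination_cells(co, id, lv)
        expect_equal(nrow(cells), k)
        expect_false(anyDuplicated(cells$plot_id) > 0)
        if (is.null(sp_ref)) sp_ref <- sort(cells$species)
        expect_identical(sort(cells$species), sp_ref)      # same species per level
        for (i in seq_len(k)) {                            # planted pairs only
          expect_true(cells$species[i] %in% plot_lookup[[cells$plot_id[i]]])
        }
      }
      expect_false(dsg$pool[8] %in% sp_ref)
    }
  }
})

test_that("enumeration is deterministic across repeated runs", {
  dsg <- generate_design(16, seed = 6)
  a <- enumerate_combinations(dsg$design, excluded_species = dsg$pool[2])
  b <- enumerate_combinations(dsg$design, excluded_species = dsg$pool[2])
  expect_identical(a, b)
  expect_identical(unique(a$combination_id), 0:(576 - 1))
})

test_that("high-plot matching is lexicographically smallest and complete", {
  # 7 species, 7 plots all containing everything -> species i gets plot i
  pool <- sprintf("sp%02d", 1:16)
  plots <- tibble::tibble(
    plot_id = sprintf("H%02d", 1:7),
    richness = 16L,
    species = replicate(7, pool, simplify = FALSE)
  )
  m <- match_high_plots(pool[1:7], plots)
  expect_identical(m$plot_id, sprintf("H%02d", 1:7))

  # a species present in exactly one plot is forced there
  plots2 <- plots
  plots2$species[[3]] <- pool[1:7]
  plots2$species[1:2] <- list(pool[2:16], pool[2:16])
  plots2$species[4:7] <- replicate(4, pool[2:16], simplify = FALSE)
  m2 <- match_high_plots(pool[1:7], plots2)
  expect_identical(m2$plot_id[m2$species == pool[1]], "H03")

  # infeasible: two species both only available in the same single plot
  plots3 <- plots
  plots3$species <- replicate(7, pool[3:16], simplify = FALSE)
  plots3$species[[1]] <- pool
  expect_null(match_high_plots(pool[1:7], plots3))
})

test_that("matching size equals brute-force maximum over all assignments", {
  set.seed(10)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (trial in 1:15) {
    ns <- sample(3:5, 1)
    np <- ns + sample(0:1, 1)
    pool <- sprintf("s%d", seq_len(ns))
    plots <- tibble::tibble(
      plot_id = sprintf("H%d", seq_len(np)),
      richness = 4L,
      species = replicate(np, pool[runif(ns) < 0.6], simplify = FALSE)
    )
    got <- match_high_plots(pool, plots)
    # brute force: any injective assignment of species to plots
    feasible <- FALSE
    for (sel in utils::combn(np, ns, simplify = FALSE)) {
      for (p in perms(sel)) {
        ok <- all(vapply(seq_len(ns), function(i) {
          pool[i] %in% plots$species[[p[i]]]
        }, logical(1)))
        if (ok) feasible <- TRUE
      }
    }
    expect_identical(!is.null(got), feasible)
    if (!is.null(got)) {
      expect_false(anyDuplicated(got$plot_id) > 0)
      for (i in seq_len(ns)) {
        expect_true(got$species[i] %in%
                      plots$species[[match(got$plot_id[i], plots$plot_id)]])
      }
    }
  }
})
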