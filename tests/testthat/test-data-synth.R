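test_that("interaction count equals the deterministic density threshold", {
  ds <- generate_synthetic_dti(synth_spec(n_drugs = 50, n_targets = 20,
                                          density = 0.05, seed = 1))
  expect_identical(sum(ds$interactions), ceiling(0.05 * 1000)) # exactly 50
  expect_true(all(ds$interactions %in% c(0, 1)))
  expect_identical(dim(ds$interactions), c(20L, 50L))
})

test_that("generation is bit-for-bit reproducible by seed", {
  s <- synth_spec(n_drugs = 20, n_targets = 10, density = 0.1, seed = 42)
  d1 <- generate_synthetic_dti(s)
  d2 <- generate_synthetic_dti(s)
  expect_identical(d1$interactions, d2$interactions)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  d3 <- generate_synthetic_dti(synth_spec(n_drugs = 20, n_targets = 10,
                                          density = 0.1, seed = 43))
  expect_false(identical(d1$interactions, d3$interactions))
})

test_that("emitted pairs balance positives with sampled negatives", {
  ds <- generate_synthetic_dti(synth_spec(n_drugs = 30, n_targets = 20,
                                          density = 0.08, seed = 7))
  n_pos <- ceiling(0.08 * 600)
  expect_equal(nrow(ds$pairs), 2 * n_pos)
  expect_equal(sum(ds$pairs$label), n_pos)
  expect_equal(dim(ds$x), c(2 * n_pos, 4, 8))
  expect_identical(ds$y[, 1], ds$pairs$label)
  expect_equal(ds$y[, 2], 1 - ds$pairs$label)
})

test_that("pair_to_sequence tiles drug then target halves", {
  dv <- c(1, 2, 3); tv <- c(4, 5, 6)
  s <- pair_to_sequence(dv, tv, T = 2)
  expect_equal(s, rbind(dv, tv), ignore_attr = TRUE)
  s4 <- pair_to_sequence(dv, tv, T = 4)
  expect_identical(dim(s4), c(4L, 3L))
  expect_equal(s4[1, ], s4[2, ])
  expect_equal(s4[3, ], s4[4, ])
  # swapping drug and target reverses the halves
  expect_equal(pair_to_sequence(tv, dv, T = 2), rbind(tv, dv),
               ignore_attr = TRUE)
  expect_error(pair_to_sequence(dv, tv, T = 3), "even")
  expect_error(pair_to_sequence(dv, tv, T = 0), "even")
})

test_that("noiseless sequences are the exact feature tiling", {
  ds <- generate_synthetic_dti(synth_spec(n_drugs = 10, n_targets = 8,
                                          density = 0.1, noise_sd = 0,
                                          seed = 3))
  k <- 1L
  expected <- pair_to_sequence(ds$drug_features[ds$pairs$drug_col[k], ],
                               ds$target_features[ds$pairs$target_row[k], ],
                               ds$spec$T)
  expect_equal(matrix(ds$x[k, , ], ds$spec$T), expected, ignore_attr = TRUE)
})

test_that("adjacency files round-trip and reject malformed cells", {
  ds <- generate_synthetic_dti(synth_spec(n_drugs = 8, n_targets = 5,
                                          density = 0.2, seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_interaction_matrix(ds, path, "adjacency")
  back <- read_interaction_matrix(path, "adjacency")
  expect_identical(back$drugs, ds$drugs)
  expect_identical(back$targets, ds$targets)
  expect_equal(back$interactions, ds$interactions)
  # malformed cell
  lines <- readLines(path)
  lines[2] <- sub("\t0", "\t2", lines[2])
  writeLines(lines, path)
  expect_error(read_interaction_matrix(path, "adjacency"), "not 0/1")
  # ragged row
  writeLines(c("target\td1\td2", "t1\t0"), path)
  expect_error(read_interaction_matrix(path, "adjacency"), "expected 3 fields")
})

test_that("edge-list dialect is consistent with adjacency", {
  # every drug and target participates, ids already sorted, so the two
  # dialects describe identical datasets
  A <- rbind(c(1, 0, 1), c(0, 1, 1))
  ds <- dti_dataset(c("da", "db", "dc"), c("ta", "tb"), A)
  p_adj <- tempfile(); p_edge <- tempfile()
  write_interaction_matrix(ds, p_adj, "adjacency")
  write_interaction_matrix(ds, p_edge, "edge_list")
  from_adj <- read_interaction_matrix(p_adj, "adjacency")
  from_edge <- read_interaction_matrix(p_edge, "edge_list")
  expect_identical(from_adj$drugs, from_edge$drugs)
  expect_identical(from_adj$targets, from_edge$targets)
  expect_equal(from_adj$interactions, from_edge$interactions)
  # conversion preserves the interaction count
  expect_identical(sum(from_edge$interactions), sum(A))
  # edge-list round trip
  p2 <- tempfile()
  write_interaction_matrix(from_edge, p2, "edge_list")
  expect_identical(readLines(p2), readLines(p_edge))
})

test_that("an all-zero matrix still writes and reads as adjacency", {
  ds <- dti_dataset(c("d1", "d2"), c("t1"), matrix(0, 1, 2))
  path <- tempfile()
  write_interaction_matrix(ds, path, "adjacency")
  back <- read_interaction_matrix(path, "adjacency")
  expect_equal(sum(back$interactions), 0)
})

test_that("profile_features attaches SVD features usable for sequences", {
  ds <- generate_synthetic_dti(synth_spec(n_drugs = 12, n_targets = 9,
                                          density = 0.15, seed = 2))
  bare <- dti_dataset(ds$drugs, ds$targets, ds$interactions)
  feat <- profile_features(bare, d = 4, T = 2)
  expect_identical(dim(feat$drug_features), c(12L, 4L))
  expect_identical(dim(feat$target_features), c(9L, 4L))
  x <- ssoddi:::pair_sequences(feat, cbind(1L, 1L))
  expect_identical(dim(x), c(1L, 2L, 4L))
})
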