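test_that("collation unions ions across peptides sharing a key", {
  prot <- scenario_proteome()
  rows <- scenario_report()
  # two modified forms of the same site: add an M1 positional duplicate of
  # the A-site from a second precursor with different fragments
  extra <- data.table::copy(rows[rows$protein_group == "A"])
  extra[, `:=`(precursor_id = paste0(modified_sequence, ".3"),
               fragment_id = paste0(modified_sequence, "#3"),
               intensity = 500)]
  rows2 <- rbind(rows, extra)
  keymap <- quiet(phosphoreport:::build_keymap(rows2, "site", prot))
  mats <- quiet(collate_ions(rows2, keymap))
  a <- mats[["A_S3_M1"]]
  expect_identical(sort(a$ion_ids),
                   sort(unique(rows2$fragment_id[rows2$protein_group == "A"])))
})

test_that("a doubly phosphorylated peptide feeds both of its M2 matrices", {
  prot <- scenario_proteome()
  rows <- scenario_report()
  keymap <- quiet(phosphoreport:::build_keymap(rows, "site", prot))
  mats <- quiet(collate_ions(rows, keymap))
  frag <- rows$fragment_id[rows$protein_group == "D"][1]
  expect_true(frag %in% mats[["D_S4_M2"]]$ion_ids)
  expect_true(frag %in% mats[["D_T5_M2"]]$ion_ids)
})

test_that("duplicate (ion, sample) observations reduce to the maximum", {
  prot <- scenario_proteome()
  rows <- scenario_report(runs = "r1")
  dup <- data.table::copy(rows[1])
  rows$intensity[1] <- 90
  dup$intensity <- 110
  rows2 <- rbind(rows, dup)
  keymap <- quiet(phosphoreport:::build_keymap(rows2, "site", prot))
  mats <- quiet(collate_ions(rows2, keymap))
  expect_identical(attr(mats, "n_duplicates"), 1L)
  a <- mats[["A_S3_M1"]]
  expect_equal(a$values[rows$fragment_id[1], "r1"], 110)
})

test_that("sum and max quantification reduce columns as specified", {
  X <- matrix(c(2, NA, 4, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("i1", "i2"), c("s1", "s2")))
  m <- structure(list(key = "k", ion_ids = rownames(X),
                      sample_ids = colnames(X), values = X),
                 class = "ion_matrix")
  expect_equal(quantify_sum(m), c(s1 = log2(6), s2 = log2(6)))
  expect_equal(quantify_max(m), c(s1 = log2(4), s2 = log2(6)))
  # all-missing column stays missing
  X2 <- X; X2[, 2] <- NA
  m2 <- m; m2$values <- X2
  expect_true(is.na(quantify_sum(m2)["s2"]))
  expect_true(is.na(quantify_max(m2)["s2"]))
})

test_that("a single-ion matrix is returned unchanged by all three methods", {
  X <- matrix(2^c(3, 5, 6), 1, 3,
              dimnames = list("i1", c("a", "b", "c")))
  m <- structure(list(key = "k", ion_ids = "i1", sample_ids = colnames(X),
                      values = X), class = "ion_matrix")
  want <- c(a = 3, b = 5, c = 6)
  expect_equal(quantify_maxlfq(m), want)
  expect_equal(quantify_sum(m), want)
  expect_equal(quantify_max(m), want)
})

test_that("MaxLFQ recovers additive structure exactly on complete data", {
  set.seed(1)
  a <- rnorm(6); b <- rnorm(5)
  X <- outer(a, b, "+") + 20
  dimnames(X) <- list(paste0("i", 1:6), paste0("s", 1:5))
  w <- maxlfq_solve(X)
  expect_equal(unname(diff(w)), diff(b + 20), tolerance = 1e-10)
  expect_equal(unname(w), mean(a) + b + 20, tolerance = 1e-10)
})

test_that("MaxLFQ matches the pseudoinverse oracle on random matrices", {
  set.seed(2024)
  for (rep in 1:60) {
    X <- random_log2_matrix(sample(1:8, 1), sample(2:6, 1),
                            runif(1, 0, 0.5))
    got <- maxlfq_solve(X)
    want <- maxlfq_oracle(X)
    expect_identical(is.na(got), is.na(want))
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-8)
  }
})

test_that("scaling one sample shifts only that sample by log2(c)", {
  set.seed(7)
  X <- random_log2_matrix(5, 4, 0)  # complete
  w0 <- maxlfq_solve(X)
  c_fold <- 3.7
  X2 <- X
  X2[, 2] <- X2[, 2] + log2(c_fold)
  w1 <- maxlfq_solve(X2)
  expect_equal(w1[2] - w0[2], c(s2 = log2(c_fold)), tolerance = 1e-10)
  expect_equal(w1[-2], w0[-2], tolerance = 1e-10)
})

test_that("disconnected sample groups are quantified per component", {
  # ions 1-2 observed only in samples 1-2; ion 3 only in samples 3-4
  X <- matrix(c(10, 11, NA, NA,
                12, 13, NA, NA,
                NA, NA, 20, 21), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("i", 1:3), paste0("s", 1:4)))
  w <- maxlfq_solve(X)
  expect_equal(unname(w[2] - w[1]), 1)
  expect_equal(unname(w[4] - w[3]), 1)
  expect_equal(sum(w[1:2]), sum(colMeans(X[, 1:2], na.rm = TRUE)))
  expect_equal(sum(w[3:4]), sum(colMeans(X[, 3:4], na.rm = TRUE)))
  # a sample with no observations is missing
  X[, 4] <- NA
  expect_true(is.na(maxlfq_solve(X)[4]))
})

test_that("quantified cells are missing iff no ion was observed", {
  exp <- small_synth(seed = 5L, missing_rate = 0.4)
  rows <- quiet(filter_confident(exp$rows))
  keymap <- quiet(phosphoreport:::build_keymap(rows, "site", exp$proteome))
  mats <- quiet(collate_ions(rows, keymap))
  res <- quantify_keys(mats, "maxlfq")
  for (k in sample(res$keys, 20)) {
    observed <- colSums(!is.na(mats[[k]]$values)) > 0
    expect_identical(unname(is.na(res$log2_abundance[k, ])),
                     unname(!observed))
  }
  expect_identical(res$method, "maxlfq")
})

test_that("sum/max equal naive per-column reductions on random matrices", {
  set.seed(99)
  for (rep in 1:20) {
    X <- random_log2_matrix(sample(1:6, 1), sample(2:5, 1), runif(1, 0, 0.5))
    m <- as_ion_matrix(X)
    raw <- 2^X
    naive_sum <- log2(apply(raw, 2, function(v)
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)))
    naive_max <- log2(apply(raw, 2, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)))
    expect_equal(quantify_sum(m), naive_sum, tolerance = 1e-12)
    expect_equal(quantify_max(m), naive_max, tolerance = 1e-12)
  }
})
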