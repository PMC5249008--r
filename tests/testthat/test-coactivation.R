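test_that("binarize applies the 2->1, {0,1}->0 rule with NA policies", {
  tern <- matrix(c(0L, 1L, 2L, NA), 1, 4,
                 dimnames = list("g", paste0("c", 1:4)))
  expect_equal(unname(binarize(tern)["g", ]), c(0L, 0L, 1L, 0L))
  expect_equal(unname(binarize(tern, "drop")["g", ]), c(0L, 0L, 1L, NA))
  all2 <- matrix(2L, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_true(all(binarize(all2) == 1L))
})

test_that("binary active fractions track the planted mixture truth", {
  sim <- generate(synthetic_spec(n_genes = 60, n_cells = 2000, seed = 8))
  # truth-level check: active fraction ~ rho * (1 - zero fraction)
  frac <- rowMeans(sim$truth$active)
  expected <- sim$truth$gene_params$rho * (1 - sim$truth$gene_params$zero_prob)
  expect_lt(max(abs(frac - expected)), 0.05)
})

test_that("maturity groups partition cells by the anchor rule", {
  b <- toy_binary()
  b["GAP43", "c1"] <- 1L  # both anchors active
  b["OMP", "c8"] <- 0L; b["GAP43", "c8"] <- 0L  # neither
  g <- define_maturity_groups(b)
  expect_setequal(g$mature_cells, c("c2", "c3", "c4"))
  expect_setequal(g$immature_cells, c("c5", "c6", "c7"))
  expect_setequal(g$excluded_cells, c("c1", "c8"))
  expect_length(intersect(g$mature_cells, g$immature_cells), 0)
  expect_setequal(c(g$mature_cells, g$immature_cells, g$excluded_cells),
                  colnames(b))
  expect_error(define_maturity_groups(b, mature_marker = "NOPE"), "NOPE")
  # an all-inactive anchor empties a group without error
  b2 <- toy_binary(); b2["OMP", ] <- 0L
  expect_length(define_maturity_groups(b2)$mature_cells, 0)
})

test_that("Fisher two-sided p matches enumeration for all margins <= 12", {
  # every cell in 0:6 keeps all four margins at or below 12
  worst <- 0
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    got <- fisher_exact_2x2(tab)
    if (got$degenerate) {
      worst <- max(worst, abs(got$p_value - 1))
    } else {
      worst <- max(worst, abs(got$p_value - fisher_enum_oracle(tab)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Fisher p agrees with the standard R implementation", {
  withr::with_seed(23, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 6), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact_2x2(tab)$p_value,
                   stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("Fisher handles the printed closed-form and symmetry cases", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  # invariant under swapping both rows and both columns
  tab <- matrix(c(7, 2, 3, 9), 2)
  swapped <- tab[2:1, 2:1]
  expect_equal(fisher_exact_2x2(tab)$p_value, fisher_exact_2x2(swapped)$p_value,
               tolerance = 1e-14)
  # zero margin -> no information
  res <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("marker scan flags perfectly separated genes and skips flat ones", {
  cells <- paste0("c", 1:12)
  b <- rbind(
    OMP    = rep(c(1L, 0L), each = 6),
    GAP43  = rep(c(0L, 1L), each = 6),
    matgen = rep(c(1L, 0L), each = 6),
    immgen = rep(c(0L, 1L), each = 6),
    flat   = rep(c(1L, 0L), 6)
  )
  colnames(b) <- cells
  g <- define_maturity_groups(b)
  scan <- marker_coactivation_scan(b, g, alpha = 0.05)
  expect_setequal(scan$gene, c("matgen", "immgen", "flat"))
  expect_true(scan$significant[scan$gene == "matgen"])
  expect_equal(scan$direction[scan$gene == "matgen"], "mature-associated")
  expect_equal(scan$direction[scan$gene == "immgen"], "immature-associated")
  expect_equal(scan$p_value[scan$gene == "flat"], 1)
  expect_false(scan$significant[scan$gene == "flat"])
})

test_that("marker scan significance is monotone in alpha and Bonferroni factor", {
  sim <- generate(synthetic_spec(n_genes = 200, n_cells = 100,
                                 marker_plan = marker_plan(), seed = 12))
  b <- sim$truth$active
  g <- define_maturity_groups(b)
  s1 <- marker_coactivation_scan(b, g, alpha = 0.01)
  s2 <- marker_coactivation_scan(b, g, alpha = 0.05)
  expect_lte(sum(s1$significant), sum(s2$significant))
  s3 <- marker_coactivation_scan(b, g, alpha = 0.01, bonferroni_n = 38806)
  expect_lte(sum(s3$significant), sum(s1$significant))
  expect_equal(s1$p_bonferroni, pmin(1, s1$p_value * nrow(s1)))
})

test_that("permuted group labels on null data keep family-wise error controlled", {
  sim <- generate_null(synthetic_spec(n_genes = 150, n_cells = 100, seed = 3))
  b <- sim$truth$active
  cells <- colnames(b)
  n_sig <- sapply(1:50, function(s) {
    perm <- withr::with_seed(s, sample(cells))
    g <- structure(list(mature_cells = perm[1:40],
                        immature_cells = perm[41:80],
                        excluded_cells = perm[81:100],
                        mature_marker = "OMP", immature_marker = "GAP43"),
                   class = "maturity_groups")
    sum(marker_coactivation_scan(b, g, alpha = 0.01)$significant)
  })
  expect_gte(sum(n_sig == 0), 48)
})

test_that("kNN LOOCV accuracy is 1 for separated clusters, near chance for noise", {
  withr::with_seed(33, {
    f <- cbind(matrix(rnorm(10 * 50, 0), 10), matrix(rnorm(10 * 50, 20), 10))
  })
  colnames(f) <- paste0("c", 1:100)
  rownames(f) <- paste0("g", 1:10)
  labels <- rep(c("A", "B"), each = 50)
  expect_equal(knn_loocv_dataset_accuracy(f, labels, k = 5), 1)
  # permuted labels: chance-level
  withr::with_seed(34, {
    f2 <- matrix(rnorm(10 * 200), 10, dimnames = list(paste0("g", 1:10), paste0("c", 1:200)))
    perm_labels <- sample(rep(c("A", "B"), each = 100))
  })
  acc <- knn_loocv_dataset_accuracy(f2, perm_labels, k = 5)
  expect_lt(abs(acc - 0.5), 0.12)
})

test_that("kNN LOOCV matches class::knn.cv on tie-free data", {
  skip_if_not_installed("class")
  withr::with_seed(35, {
    f <- matrix(rnorm(8 * 60), 8, dimnames = list(paste0("g", 1:8), paste0("c", 1:60)))
  })
  # two classes with odd k: no vote ties, so the deterministic rule and the
  # randomized-tie reference must coincide
  labels <- rep(c("A", "B"), each = 30)
  acc_pkg <- knn_loocv_dataset_accuracy(f, labels, k = 3)
  acc_ref <- mean(as.character(class::knn.cv(t(f), labels, k = 3)) == labels)
  expect_equal(acc_pkg, acc_ref)
})

test_that("kNN LOOCV degenerate inputs follow the documented rules", {
  f <- matrix(1, 4, 6, dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  labels <- rep(c("A", "B"), 3)
  # identical rows: deterministic, never a crash
  expect_no_error(knn_loocv_dataset_accuracy(f, labels, k = 1))
  expect_error(knn_loocv_dataset_accuracy(f, labels, k = 6), "smaller")
  expect_error(knn_loocv_dataset_accuracy(f, rep("A", 6), k = 1), "classes")
})
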