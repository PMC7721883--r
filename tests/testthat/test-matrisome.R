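test_that("protein lists normalize case, whitespace and duplicates", {
  pl <- protein_list(c("Fn1", "FN1", " mmp9 ", "", "Col1a1"))
  expect_setequal(pl$symbols, c("FN1", "MMP9", "COL1A1"))
  expect_equal(pl$n_duplicates_dropped, 1L)

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(gene = c("Fn1", "FN1", "mmp9")), path,
                   row.names = FALSE)
  expect_message(pl2 <- load_protein_list(path, "gene"), "duplicate")
  expect_setequal(pl2$symbols, c("FN1", "MMP9"))
  expect_error(load_protein_list(path, "nope"), "not found")
  utils::write.csv(data.frame(gene = character(0)), path, row.names = FALSE)
  expect_error(load_protein_list(path, "gene"), "no usable symbols")

  # round trip: write the normalized list, re-load, identical set
  utils::write.csv(data.frame(symbol = pl2$symbols), path, row.names = FALSE)
  expect_setequal(load_protein_list(path)$symbols, pl2$symbols)
})

test_that("overlap counts obey the partition identities", {
  ov <- intersect_counts(protein_list(c("A", "B", "C"), "x"),
                         protein_list(c("B", "C", "D"), "y"))
  expect_equal(ov$n_intersect, 2L)
  expect_equal(ov$n_only_a, 1L)
  expect_equal(ov$n_only_b, 1L)

  dis <- intersect_counts(c("A", "B"), c("C", "D"))
  expect_equal(dis$n_intersect, 0L)
  same <- intersect_counts(c("A", "B"), c("a", "b"))
  expect_equal(same$n_intersect, 2L)
  expect_equal(same$n_only_a + same$n_only_b, 0L)

  withr::with_seed(81, {
    for (case in 1:10) {
      a <- sample(LETTERS, sample(3:20, 1))
      b <- sample(LETTERS, sample(3:20, 1))
      ov <- intersect_counts(a, b)
      expect_equal(ov$n_intersect + ov$n_only_a, ov$n_a)
      expect_equal(ov$n_intersect + ov$n_only_b, ov$n_b)
    }
  })
})

test_that("the DE filter applies FC > 1.5 (either direction) and FDR <= 0.1", {
  tab <- data.frame(symbol = c("UP", "WEAK", "NOISY", "DOWN", "EDGE"),
                    fold_change = c(2.0, 1.4, 2.0, 0.5, 1.5),
                    fdr = c(0.05, 0.05, 0.2, 0.1, 0.05))
  kept <- de_filter(tab)
  expect_setequal(kept$symbols, c("UP", "DOWN"))  # 0.5 < 1/1.5; FDR 0.1 kept
  expect_false("EDGE" %in% kept$symbols)          # FC exactly 1.5 is not > 1.5

  # monotone: relaxing either cutoff never loses a protein
  loose_fc <- de_filter(tab, fc_cutoff = 1.2)
  loose_fdr <- de_filter(tab, fdr_cutoff = 0.3)
  expect_true(all(kept$symbols %in% loose_fc$symbols))
  expect_true(all(kept$symbols %in% loose_fdr$symbols))

  expect_error(de_filter(tab[, 1:2]), "missing columns")
  bad <- tab
  bad$fold_change[1] <- -2
  expect_error(de_filter(bad), "positive ratios")
})

test_that("step-up adjustment reproduces the hand-computed example", {
  expect_equal(stepup_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(stepup_adjust(0.07), 0.07)  # single test: adjusted = raw
  withr::with_seed(82, {
    p <- stats::runif(50)
    adj <- stepup_adjust(p)
    expect_true(all(adj >= p))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
  })
})

test_that("two-way ANOVA p-values match a direct aov fit and route to t", {
  withr::with_seed(83, {
    geno <- factor(rep(c("WT", "KO"), each = 4))
    day <- factor(rep(rep(c("d0", "d20"), each = 2), 2))
    vals <- matrix(stats::rnorm(5 * 8, mean = 10), 5, 8,
                   dimnames = list(paste0("P", 1:5), NULL))
    res <- two_way_anova_stepup(vals, geno, day)
    for (i in 1:5) {
      a <- stats::anova(stats::lm(vals[i, ] ~ geno * day))
      expect_equal(res$p_a[i], a[["Pr(>F)"]][1])
      expect_equal(res$p_b[i], a[["Pr(>F)"]][2])
      expect_equal(res$p_ab[i], a[["Pr(>F)"]][3])
    }
    expect_equal(res$fdr_a, stepup_adjust(res$p_a))

    # single-level factor B routes to the unpaired two-sided Student t
    res_t <- two_way_anova_stepup(vals, geno, factor(rep("d52", 8)))
    expect_equal(res_t$test[1], "student_t")
    for (i in 1:5) {
      expect_equal(res_t$p_a[i],
                   stats::t.test(vals[i, ] ~ geno,
                                 var.equal = TRUE)$p.value)
    }
    expect_error(two_way_anova_stepup(vals, factor(rep("WT", 8)), day),
                 "two levels")

    # zero variance everywhere is flagged, p undefined
    flat <- matrix(5, 2, 8, dimnames = list(c("F1", "F2"), NULL))
    res_f <- two_way_anova_stepup(flat, geno, day)
    expect_true(all(res_f$degenerate))
    expect_true(all(is.na(res_f$p_a)))
  })
})

test_that("a complete-null screen stays near the nominal FDR", {
  withr::with_seed(84, {
    geno <- factor(rep(c("WT", "KO"), each = 4))
    day <- factor(rep(rep(c("d0", "d20"), each = 2), 2))
    hits <- vapply(1:40, function(rep) {
      vals <- matrix(stats::rnorm(100 * 8), 100, 8)
      sum(two_way_anova_stepup(vals, geno, day)$fdr_a <= 0.1, na.rm = TRUE)
    }, numeric(1))
    # under the complete null BH discoveries are rare: far below the
    # 10-per-screen worst case, and most screens find none
    expect_lt(mean(hits), 10)
    expect_gt(mean(hits == 0), 0.5)
  })
})

test_that("paired abundance test matches the closed form and edge rules", {
  same <- paired_abundance_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  const <- paired_abundance_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(const$degenerate)
  expect_equal(const$mean_diff, 1)
  expect_true(is.infinite(const$t))

  expect_error(paired_abundance_test(1, 2), "two complete pairs")

  withr::with_seed(85, {
    x <- stats::rnorm(12, 10, 2)
    y <- x + stats::rnorm(12, 0.5, 1)
    got <- paired_abundance_test(x, y)
    d <- x - y
    t_manual <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    p_manual <- 2 * stats::pt(-abs(t_manual), df = length(d) - 1)
    expect_equal(got$t, t_manual, tolerance = 1e-12)
    expect_equal(got$p, p_manual, tolerance = 1e-12)
  })
})
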