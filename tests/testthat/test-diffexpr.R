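make_log2_table <- function(n_probes = 100, noise_sd = 0.05,
                            planted = numeric(0), seed = 5,
                            array_sd = 0.1) {
  spec <- simulation_spec(n_probes = n_probes, probe_sd = 0.3,
                          animal_sd = 0, array_sd = array_sd,
                          noise_sd = noise_sd, planted_effects = planted,
                          seed = seed)
  tab <- generate_intensities(spec, make_annotation(n_probes,
                                                    names(planted)))
  tab$values <- log2(tab$values)
  tab$log2 <- TRUE
  tab
}

test_that("balanced-design lsmean difference equals the group-mean difference", {
  tab <- make_log2_table(20, noise_sd = 0.2, seed = 8)
  d <- tab$design
  isN <- d$condition == "non_inseminated"
  for (i in c(1, 7, 20)) {
    y <- tab$values[i, ]
    fit <- fit_probe_set(y, d, method = "array_means")
    oracle <- mean(y[isN]) - mean(y[!isN])
    expect_equal(fit$lsmean_diff, oracle, tolerance = 1e-8)
  }
  # multi-probe set: probe effect eliminated by array averaging
  y2 <- tab$values[1:3, ]
  fit2 <- fit_probe_set(y2, d)
  oracle2 <- mean(colMeans(y2)[isN]) - mean(colMeans(y2)[!isN])
  expect_equal(fit2$lsmean_diff, oracle2, tolerance = 1e-8)
})

test_that("closed-form and REML routes agree on balanced data", {
  tab <- make_log2_table(12, noise_sd = 0.15, seed = 21, array_sd = 0.3)
  d <- tab$design
  for (rows in list(1:2, 3:5)) {
    a <- fit_probe_set(tab$values[rows, ], d, method = "array_means")
    b <- fit_probe_set(tab$values[rows, ], d, method = "reml")
    expect_equal(a$lsmean_diff, b$lsmean_diff, tolerance = 1e-6)
    # Satterthwaite df in the balanced whole-plot stratum equal the
    # array-mean t-test df, so p-values agree too
    expect_equal(a$p_raw, b$p_raw, tolerance = 1e-4)
  }
})

test_that("a planted treatment shift is recovered", {
  # planted log2FC of -1 in the inseminated horn gives lsmean N - Y = +1
  tab <- make_log2_table(50, noise_sd = 0.05, planted = c(GENE1 = -1),
                         seed = 9, array_sd = 0)
  fit <- fit_probe_set(tab$values[1:2, ], tab$design)
  expect_gt(fit$lsmean_diff, 0.9)
  expect_lt(fit$lsmean_diff, 1.1)
})

test_that("orientation: higher expression with the embryo means up_in_embryo", {
  tab <- make_log2_table(10, noise_sd = 0.02, planted = c(GENE1 = 1.5),
                         seed = 10, array_sd = 0)
  fit <- fit_probe_set(tab$values[1:2, ], tab$design)
  expect_lt(fit$lsmean_diff, 0)
  expect_identical(fit$direction, "up_in_embryo")
  res <- fit_all_probe_sets(tab)
  expect_identical(res$direction[1], "up_in_embryo")
  expect_identical(res$direction[res$lsmean_diff > 0][1], "down_in_embryo")
})

test_that("degenerate and invalid inputs are flagged", {
  d <- array_design(3)
  flat <- matrix(5, 2, 6, dimnames = list(NULL, d$array_id))
  expect_warning(fit <- fit_probe_set(flat, d), "degenerate")
  expect_equal(fit$lsmean_diff, 0)
  expect_true(fit$degenerate)
  expect_error(fit_probe_set(flat[, 1:2, drop = FALSE], d[1:2, ]),
               "animals|condition")
  one_cond <- d[d$condition == "inseminated", ]
  expect_error(
    fit_probe_set(matrix(1:3, 1, dimnames = list(NULL, one_cond$array_id)),
                  one_cond),
    "condition")
})

test_that("vectorized fits match the single-probe-set route", {
  tab <- make_log2_table(30, noise_sd = 0.1, seed = 13)
  sets <- rep(sprintf("ps%02d", 1:15), each = 2)
  res <- fit_all_probe_sets(tab, sets)
  expect_equal(nrow(res), 15)
  for (i in c(1, 8, 15)) {
    rows <- which(sets == res$probe_set_id[i])
    single <- fit_probe_set(tab$values[rows, ], tab$design)
    expect_equal(res$lsmean_diff[i], single$lsmean_diff, tolerance = 1e-10)
    expect_equal(res$p_raw[i], single$p_raw, tolerance = 1e-10)
  }
})

test_that("bonferroni adjustment is correct, monotone and bounded", {
  # chip-scale threshold: alpha/m with m = 24123 is ~2.073e-6
  m <- 24123
  p <- c(2.0e-6, 2.1e-6, rep(0.5, m - 2))
  adj <- bonferroni(p, alpha = 0.05)
  expect_true(adj$significant[1])
  expect_false(adj$significant[2])
  expect_true(all(adj$p_adj <= 1))
  expect_equal(bonferroni(1, 0.05)$p_adj, 1)
  expect_equal(bonferroni(0.03, 0.05)$p_adj, 0.03)  # m = 1 is the identity
  set.seed(4)
  pr <- sort(runif(50))
  pa <- bonferroni(pr)$p_adj
  expect_true(all(diff(pa) >= 0))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("volcano table flags exactly the Bonferroni-significant sets", {
  res <- data.frame(probe_set_id = sprintf("p%d", 1:4),
                    lsmean_diff = c(-2, 1, 0.5, -0.2),
                    p_raw = c(0.049 / 4, 0.2, 0.9, 0.06 / 4))
  v <- volcano_table(res, alpha = 0.05)
  expect_identical(v$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(v$neg_log10_p_adj[1], -log10(0.049))
  null_res <- data.frame(probe_set_id = "p", lsmean_diff = 0, p_raw = 0.9)
  expect_false(any(volcano_table(null_res)$significant))
  expect_error(volcano_table(res[0, ]), "no results")
})

test_that("planted effects are detected with few false positives", {
  genes <- sprintf("G%02d", 1:10)
  planted <- stats::setNames(rep(-2, 10), genes)
  spec <- simulation_spec(n_probes = 2000, probe_sd = 0.3, animal_sd = 0,
                          array_sd = 0, noise_sd = 0.1,
                          planted_effects = planted, seed = 2024)
  ann <- make_annotation(2000, genes, probes_per_gene = 2)
  tab <- generate_intensities(spec, ann)
  tab$values <- log2(tab$values)
  tab$log2 <- TRUE
  sets <- ifelse(is.na(ann$gene_symbol), ann$probe_id, ann$gene_symbol)
  res <- fit_all_probe_sets(tab, sets)
  adj <- bonferroni(res$p_raw, alpha = 0.05)
  planted_idx <- which(res$probe_set_id %in% genes)
  expect_gte(sum(adj$significant[planted_idx]), 8)
  expect_lte(sum(adj$significant[-planted_idx]), 1)
})

test_that("family-wise error under the null stays near nominal", {
  n_rep <- 200
  hits <- 0L
  d <- array_design(3)
  set.seed(99)
  for (r in seq_len(n_rep)) {
    m <- matrix(stats::rnorm(1000 * 6, 0, 0.2), 1000, 6,
                dimnames = list(NULL, d$array_id))
    tabm <- structure(list(probe_ids = sprintf("p%04d", 1:1000),
                           array_ids = d$array_id, values = m,
                           design = d, log2 = TRUE),
                      class = "probe_table")
    res <- fit_all_probe_sets(tabm)
    if (any(bonferroni(res$p_raw, 0.05)$significant)) hits <- hits + 1L
  }
  rate <- hits / n_rep
  tol <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rate, 0.05 + tol)
})

test_that("comparative CT quantification follows its definition", {
  same <- ddct(list(a = c(20, 20), b = c(20, 20)),
               list(a = c(15, 15), b = c(15, 15)))
  expect_equal(same$delta_delta_ct, 0)
  expect_equal(same$fold_change, 1)
  one <- ddct(list(a = 21, b = 20), list(a = 15, b = 15))
  expect_equal(one$delta_delta_ct, 1)
  expect_equal(one$fold_change, 0.5)
  ex <- ddct(list(g1 = 25, g2 = 23), list(g1 = 20, g2 = 20))
  expect_equal(ex$delta_ct, c(g1 = 5, g2 = 3))
  expect_equal(ex$delta_delta_ct, 2)
  expect_equal(ex$fold_change, 0.25)
  expect_error(ddct(list(a = 1), list(a = 1)), "two groups")
  expect_error(ddct(list(a = 1, b = NA), list(a = 1, b = 1)), "finite")
})
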