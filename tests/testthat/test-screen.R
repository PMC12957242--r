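two_group_table <- function(x1, x2) {
  n <- length(x1)
  feature_table(matrix(2^c(x1, x2), ncol = 1,
                       dimnames = list(NULL, "M1")),
                group = rep(c("CP", "CT"), each = n),
                batch = paste0("b", seq_len(2 * n)))
}

test_that("no signal means p = 1, fold change 1, not passed", {
  tab <- two_group_table(rep(3, 4), rep(3, 4))
  res <- anova_screen(tab)
  expect_equal(res$p_value, 1)
  expect_equal(res$max_abs_fc, 1)
  expect_false(res$passed)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(8)
  x1 <- rnorm(6, 5, 0.3); x2 <- rnorm(6, 6, 0.3)
  tt <- t.test(x1, x2, var.equal = TRUE)
  ow <- oneway.test(c(x1, x2) ~ rep(c("a", "b"), each = 6),
                    var.equal = TRUE)
  expect_equal(unname(ow$statistic), unname(tt$statistic)^2,
               tolerance = 1e-9)
  # and the screen reports that same p-value on the 2^x areas
  res <- anova_screen(two_group_table(x1, x2))
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("ANOVA p-values agree with a permutation test", {
  cfg <- default_config()
  tab <- drop_qc(default_cohort())
  norm <- percentile_normalize(tab)
  res <- anova_screen(norm)
  la <- log_areas(norm)
  grp <- norm$group
  f_stat <- function(x, g) oneway.test(x ~ g, var.equal = TRUE)$statistic
  set.seed(9)
  # permutation check on null metabolites (planted metabolites have p ~ 0,
  # where a permutation test has no resolution)
  nulls <- setdiff(seq_len(ncol(la)),
                   c(cfg$differential_ids, cfg$reference_id))
  for (j in sample(nulls, 3)) {
    obs <- f_stat(la[, j], grp)
    perm <- replicate(400, f_stat(la[, j], sample(grp)))
    p_perm <- (1 + sum(perm >= obs)) / 401
    se <- sqrt(p_perm * (1 - p_perm) / 400)
    expect_lt(abs(res$p_value[j] - p_perm), 4 * se + 0.02)
  }
})

test_that("screening recovers exactly the planted differential set", {
  rep <- default_study_report()
  expect_setequal(rep$screened, planted_names())
  expect_equal(length(rep$screened), 29L)
})

test_that("the passed set is monotone in both thresholds", {
  tab <- percentile_normalize(drop_qc(default_cohort()))
  base <- anova_screen(tab, screen_config(p_threshold = 0.01,
                                          fc_threshold = 3))
  looser_fc <- anova_screen(tab, screen_config(p_threshold = 0.01,
                                               fc_threshold = 1.5))
  looser_p <- anova_screen(tab, screen_config(p_threshold = 0.2,
                                              fc_threshold = 3))
  expect_true(all(base$metabolite[base$passed] %in%
                  looser_fc$metabolite[looser_fc$passed]))
  expect_true(all(base$metabolite[base$passed] %in%
                  looser_p$metabolite[looser_p$passed]))
})

test_that("group statistics match hand computation and ignore sample order", {
  areas <- matrix(2^c(3, 3.3219281, 3.5849625, 3, 3, 3), ncol = 1,
                  dimnames = list(NULL, "M1"))  # 8,10,12 then 8,8,8
  areas[, 1] <- c(8, 10, 12, 8, 8, 8)
  tab <- feature_table(areas, group = rep(c("CP", "CT"), each = 3),
                       batch = paste0("b", 1:6))
  gs <- group_stats(tab)
  cp <- gs[gs$group == "CP", ]
  expect_equal(cp$mean, 10)
  expect_equal(cp$sd, 2)
  expect_equal(gs[gs$group == "CT", ]$sd, 0)

  perm <- subset_samples(tab, c(3, 1, 2, 6, 5, 4))
  expect_equal(group_stats(perm)$mean, gs$mean)
})

test_that("select_reference takes the smallest overall SD, ties to the left", {
  areas <- cbind(A = c(1, 2, 3, 4), B = c(2, 2, 2, 2.1),
                 C = c(2, 2, 2, 2.1))
  tab <- feature_table(areas, group = rep("CP", 4),
                       batch = paste0("b", 1:4))
  expect_equal(select_reference(tab), "B")
  expect_equal(select_reference(tab, candidates = c("C", "A")), "C")
  expect_equal(select_reference(tab, candidates = "A"), "A")
  expect_error(select_reference(tab, candidates = character(0)), "empty")
  expect_error(select_reference(tab, candidates = "Z"), "absent")
})

test_that("the generator plants the minimum-SD reference", {
  rep <- default_study_report()
  expect_equal(rep$reference, reference_name)
  # also the smallest SD within the screened candidates plus itself
  expect_equal(select_reference(rep$table,
                                candidates = c(rep$screened, reference_name)),
               reference_name)
})

test_that("HCA merges identical samples first and is permutation invariant", {
  set.seed(10)
  base <- matrix(rnorm(5 * 4, 10, 1), 5, 4)
  base[2, ] <- base[1, ]  # identical pair
  tab <- feature_table(2^base, group = rep("CP", 5),
                       batch = paste0("b", 1:5))
  cl <- hca(tab, k = 2, scale = FALSE)
  expect_equal(min(cl$sample_tree$height), 0, tolerance = 1e-9)
  first_merge <- cl$sample_tree$merge[1, ]
  expect_setequal(-first_merge, c(1, 2))

  perm <- sample(5)
  cl2 <- hca(subset_samples(tab, perm), k = 2, scale = FALSE)
  relabeled <- cl2$sample_cluster[match(tab$sample_id,
                                        rownames(cl2$scaled))]
  expect_equal(cluster_purity(cl$sample_cluster, relabeled), 1)
})

test_that("HCA on the screened cohort is pure by origin at k = 3", {
  rep <- default_study_report()
  expect_equal(rep$hca_purity, 1)
  expect_equal(length(unique(rep$hca$sample_cluster)), 3L)
})

test_that("constant matrices are rejected with advice to skip z-scoring", {
  tab <- feature_table(matrix(4, 4, 3), group = rep("CP", 4),
                       batch = paste0("b", 1:4))
  expect_error(hca(tab), "scale = FALSE")
})
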