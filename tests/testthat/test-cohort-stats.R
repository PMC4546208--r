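test_that("bootstrap clustering separates planted groups and is label-stable", {
  set.seed(30)
  x <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(NULL, paste0("S", 1:10)))
  x[, 6:10] <- x[, 6:10] + 3        # two groups offset in every feature
  # a uniform offset is invisible to the correlation distance, so the
  # offset design is clustered on Euclidean distance
  tr <- cluster_samples(x, distance = "euclidean", n_boot = 200, seed = 1)
  expect_gte(clade_support(tr, paste0("S", 6:10)), 0.95)
  expect_true(all(tr$bp >= 0 & tr$bp <= 1))

  # permuting the sample order preserves the set of bipartitions
  perm <- sample(10)
  tr2 <- cluster_samples(x[, perm], distance = "euclidean", n_boot = 200,
                         seed = 1)
  pp1 <- ape::prop.part(tr$phylo); pp2 <- ape::prop.part(tr2$phylo)
  sets1 <- lapply(pp1, function(i) sort(attr(pp1, "labels")[i]))
  sets2 <- lapply(pp2, function(i) sort(attr(pp2, "labels")[i]))
  expect_setequal(sapply(sets1, paste, collapse = ","),
                  sapply(sets2, paste, collapse = ","))

  # duplicate columns merge at zero height
  xd <- cbind(x[, 1:4], A = x[, 5], B = x[, 5])
  trd <- cluster_samples(xd, n_boot = 100, seed = 2)   # correlation distance
  h <- trd$hclust
  pairidx <- which(apply(h$merge, 1, function(r) all(r < 0)))
  labs <- lapply(pairidx, function(i) h$labels[-h$merge[i, ]])
  dup <- vapply(labs, function(l) setequal(l, c("A", "B")), TRUE)
  expect_true(any(dup))
  expect_equal(h$height[pairidx[dup][1]], 0, tolerance = 1e-12)

  expect_error(cluster_samples(cbind(x[, 1:2], NA)), "missing")
  # a Newick file with BP labels is written
  f <- withr::local_tempfile()
  write_cluster_newick(tr, f)
  expect_true(grepl("S1", readLines(f)[1]))
})

test_that("BP support grows with planted separation", {
  set.seed(31)
  bp <- vapply(c(0.3, 1, 4), function(eff) {
    res <- vapply(1:10, function(i) {
      x <- matrix(rnorm(100 * 8), 100, 8,
                  dimnames = list(NULL, paste0("S", 1:8)))
      x[1:30, 5:8] <- x[1:30, 5:8] + eff   # group-specific feature pattern
      clade_support(cluster_samples(x, n_boot = 100, seed = i),
                    paste0("S", 5:8))
    }, 0)
    res[is.na(res)] <- 0    # clade absent from the reference tree
    mean(res)
  }, 0)
  expect_true(all(diff(bp) >= 0) || bp[3] > bp[1])
  expect_gt(bp[3], 0.9)
})

test_that("variable-region ranking follows the chi-square homogeneity form", {
  m <- rbind(const = c(10, 10, 10, 10),
             strong = c(45, 45, 5, 5),
             weak = c(15, 12, 8, 10))
  tot <- matrix(50, 3, 4, dimnames = list(rownames(m), NULL))
  top <- top_variable_regions(m, tot, k = 3)
  expect_equal(top$region, c("strong", "weak", "const"))
  expect_equal(top$statistic[3], 0)
  # 2x2 collapsed table matches the hand formula sum (O-E)^2/E
  m2 <- matrix(c(30, 10), 1, 2); t2 <- matrix(c(50, 50), 1, 2)
  got <- top_variable_regions(m2, t2, k = 1)$statistic
  e <- 0.4 * 50                       # pooled phat = 40/100
  hand <- sum((c(30, 10) - e)^2 / e) + sum((c(20, 40) - 30)^2 / 30)
  expect_equal(got, hand)
  expect_warning(top_variable_regions(m, tot, k = 10), "returning all")
  # ranking invariant to sample order
  perm <- c(3, 1, 4, 2)
  expect_equal(top_variable_regions(m[, perm], tot[, perm], k = 3)$region,
               top$region)
})

test_that("PCA satisfies the SVD identities and separates planted groups", {
  x <- matrix(0, 5, 6, dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  x[1, ] <- c(1, 2, 3, 4, 5, 6)
  p1 <- pca_samples(x, 1)
  expect_equal(p1$explained_variance, 1)
  expect_error(pca_samples(x, 3), "rank")

  set.seed(33)
  y <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(NULL, paste0("s", 1:8)))
  y[1:10, 5:8] <- y[1:10, 5:8] + 3
  py <- pca_samples(y, 7)
  # full reconstruction of the centered matrix
  rec <- py$loadings %*% t(py$scores)
  expect_equal(unname(rec), unname(y - rowMeans(y)), tolerance = 1e-8)
  expect_gte(rank_auc(py$scores[, 1], grepl("[5-8]$", colnames(y))), 0.95)
  # sign convention: the largest-magnitude loading is positive
  expect_gt(py$loadings[which.max(abs(py$loadings[, 1])), 1], 0)
})

test_that("group variance comparison behaves under null and inflation", {
  set.seed(34)
  nullfrac <- replicate(10, {
    b <- matrix(runif(60 * 8, 0.2, 0.8), 60, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
    gv <- group_variance_test(b, paste0("s", 1:4), paste0("s", 5:8))
    gv$fraction_tumor_greater
  })
  expect_lt(abs(mean(nullfrac) - 0.5), 0.1)

  sig <- replicate(10, {
    base <- matrix(runif(200 * 8, 0.3, 0.5), 200, 8,
                   dimnames = list(NULL, paste0("s", 1:8)))
    base[, 1:4] <- base[, 1:4] + rnorm(800, 0, 0.1)   # doubled tumor noise
    base[, 5:8] <- base[, 5:8] + rnorm(800, 0, 0.05)
    gv <- group_variance_test(base, paste0("s", 1:4), paste0("s", 5:8))
    c(gv$fraction_tumor_greater, gv$sign_test_p)
  })
  expect_true(mean(sig[1, ]) > 0.5)
  expect_gte(mean(sig[2, ] < 0.01), 0.9)

  # constant features are excluded from the comparison
  b <- matrix(0.5, 5, 6, dimnames = list(NULL, paste0("s", 1:6)))
  gv <- group_variance_test(b, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(gv$n_compared, 0L)
  expect_error(group_variance_test(b, "s1", paste0("s", 4:6)), "2 samples")
})

test_that("the paired t-test matches its closed form and t.test", {
  r <- paired_t_test(c(0.2, 0.4, 0.5), c(0.1, 0.2, 0.3))
  expect_equal(r$t_statistic, 5, tolerance = 1e-6)
  expect_equal(r$df, 2)
  # closed-form df=2 CDF: P(T <= t) = 1/2 + t / (2 sqrt(2 + t^2))
  p_closed <- 2 * (1 - (0.5 + 5 / (2 * sqrt(2 + 25))))
  expect_equal(r$p_value, p_closed, tolerance = 1e-6)
  expect_equal(r$p_value, 0.0377, tolerance = 5e-3)

  same <- paired_t_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_true(same$undefined)
  expect_true(is.na(same$p_value))

  set.seed(35)
  x <- runif(20); y <- runif(20)
  r2 <- paired_t_test(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(r2$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(paired_t_test(1:2 / 10, 1:3 / 10), "equal length")
})

test_that("difference categories use right-open bins with a closed top", {
  expect_equal(unname(categorize_differences(0.25)), c(0, 0, 0, 1))
  expect_equal(unname(categorize_differences(0.05)), c(0, 1, 0, 0))
  expect_equal(names(categorize_differences(0)),
               c("[0,0.05)", "[0.05,0.1)", "[0.1,0.2)", "[0.2,1]"))
  expect_error(categorize_differences(1.2), "0, 1")
  set.seed(36)
  v <- runif(100)
  got <- categorize_differences(v)
  want <- c(sum(v < 0.05), sum(v >= 0.05 & v < 0.1),
            sum(v >= 0.1 & v < 0.2), sum(v >= 0.2))
  expect_equal(unname(got), want)
  expect_equal(sum(got), 100L)
})

test_that("delta-delta-Ct gives the 2^-ddCt ratio", {
  r <- delta_delta_ct(25, 20, 24, 20)
  expect_equal(r$delta_delta_ct, 1)
  expect_equal(r$ratio, 0.5)
  expect_equal(delta_delta_ct(20, 18, 20, 18)$ratio, 1)
  # triplicates are averaged per condition
  r3 <- delta_delta_ct(c(25.1, 24.9, 25), c(20, 20, 20),
                       c(24, 24, 24), c(20.1, 19.9, 20))
  expect_equal(r3$delta_delta_ct, (25 - 20) - (24 - 20))
  expect_error(delta_delta_ct(-1, 20, 20, 20), "positive")
})

test_that("per-gene validation statistics assemble correctly", {
  cfg <- sim_config(seed = 40, val_n_pairs = 30L, n_genes = 60L)
  g <- simulate_genome(cfg)
  tr <- simulate_truth(cfg, g)
  val <- simulate_validation_cohort(cfg, tr)
  res <- validate_cohort(val$beta, val$manifest)
  expect_equal(nrow(res), nrow(val$beta))
  cats <- as.matrix(res[, 6:9])
  expect_true(all(rowSums(cats) == 30))
  planted <- val$genes$gene_id[val$genes$planted]
  expect_true(all(res$p_value[match(planted, res$gene_id)] < 1e-3))
})
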