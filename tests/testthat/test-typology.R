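make_pred_table <- function(n_farms = 6, n_years = 2, seed = 31) {
  d <- generate_dataset(n_farms, n_years, seed = seed)
  d$probability <- plogis(6 * (d$latent_g - 0.4))
  d
}

test_that("profiles average per cell and exclude incomplete farm-years", {
  d <- make_pred_table(6, 2)
  # duplicate every record of one farm-year: means of pairs must be equal
  dup <- d[d$farm_id == "farm_0001" & d$year == 2011, ]
  prof_dup <- suppressMessages(build_profiles(rbind(d, dup), "probability"))
  prof <- suppressMessages(build_profiles(d, "probability"))
  expect_equal(prof_dup[prof_dup$farm_id == "farm_0001" &
                          prof_dup$year == 2011, ],
               prof[prof$farm_id == "farm_0001" & prof$year == 2011, ])
  expect_equal(nrow(prof), 12L)  # 6 farms x 2 years, all complete
  # drop one month of one farm-year: that profile disappears
  drop1 <- d[!(d$farm_id == "farm_0002" & d$year == 2012 & d$month == 5), ]
  expect_message(prof2 <- build_profiles(drop1, "probability"), "excluded")
  expect_equal(nrow(prof2), 11L)
  expect_equal(attr(prof2, "n_excluded"), 1L)
  expect_false(any(prof2$farm_id == "farm_0002" & prof2$year == 2012))
})

test_that("identical profiles merge first at height zero", {
  prof <- suppressMessages(build_profiles(make_pred_table(3, 1), "probability"))
  prof2 <- rbind(prof, prof[1, ])
  prof2$farm_id[4] <- "farm_copy"
  tree <- ward_d2_cluster(prof2)
  expect_equal(min(tree$hclust$height), 0)
  expect_error(ward_d2_cluster(prof[1, ]), "at least 2")
})

test_that("tree matches brute-force Ward.D2 agglomeration", {
  set.seed(32)
  for (rep_i in 1:5) {
    n <- sample(4:8, 1)
    prof <- data.frame(farm_id = sprintf("f%02d", 1:n), year = 2020)
    prof[paste0("m", 1:12)] <- matrix(runif(n * 12), n, 12)
    tree <- ward_d2_cluster(prof)
    oracle <- bf_ward_d2(as.matrix(prof[paste0("m", 1:12)]))
    expect_equal(sort(tree$hclust$height), sort(oracle$heights),
                 tolerance = 1e-8)
    for (step in seq_len(n - 1)) {
      got <- canonical_assignment(stats::cutree(tree$hclust, k = n - step))
      expect_equal(got, oracle$partitions[[step]],
                   info = sprintf("n=%d step=%d", n, step))
    }
  }
})

test_that("merge heights are monotone and clustering ignores input order", {
  prof <- suppressMessages(build_profiles(make_pred_table(8, 2), "probability"))
  tree <- ward_d2_cluster(prof)
  expect_true(all(diff(tree$hclust$height) >= -1e-12))
  perm <- sample(nrow(prof))
  tree_p <- ward_d2_cluster(prof[perm, ])
  for (K in 2:4) {
    a <- cut_and_summarize(tree, K)$assignments
    b <- cut_and_summarize(tree_p, K)$assignments
    b <- b[match(paste(a$farm_id, a$year), paste(b$farm_id, b$year)), ]
    expect_equal(canonical_assignment(a$cluster),
                 canonical_assignment(b$cluster))
  }
})

test_that("cluster cuts respect boundaries and sizes sum to profiles", {
  d <- make_pred_table(5, 2)
  prof <- suppressMessages(build_profiles(d, "probability"))
  tree <- ward_d2_cluster(prof)
  n <- nrow(prof)
  sol1 <- cut_and_summarize(tree, 1, d)
  expect_equal(unname(sol1$monthly_curves[1, ]),
               unname(colMeans(as.matrix(prof[paste0("m", 1:12)]))))
  soln <- cut_and_summarize(tree, n, d)
  expect_true(all(soln$cluster_sizes == 1))
  for (K in c(1, 3, n)) {
    expect_equal(sum(cut_and_summarize(tree, K)$cluster_sizes), n)
  }
  expect_error(cut_and_summarize(tree, n + 1), "exceeds")
  expect_error(cut_and_summarize(tree, 0), "K")
})

test_that("skimmed clusters are flagged by their fat summary", {
  d <- generate_dataset(12, 1, seed = 33,
                        archetype_mix = c(intensive = 0.4,
                                          extensive = 0.4, skimmed = 0.2))
  d$probability <- plogis(6 * (d$latent_g - 0.4))
  arch <- attr(d, "archetypes")
  skim <- d$farm_id %in% arch$farm_id[arch$archetype == "skimmed"]
  d$probability[skim] <- 0.95  # mimic saturated predictions
  prof <- suppressMessages(build_profiles(d, "probability"))
  sol <- cut_and_summarize(ward_d2_cluster(prof), 3, d)
  flagged <- flag_skimmed(sol, fat_threshold = 1)
  skim_fat <- sol$trait_summary$fat[sol$trait_summary$cluster %in% flagged]
  expect_true(all(skim_fat < 1))
  other_fat <- sol$trait_summary$fat[!sol$trait_summary$cluster %in% flagged]
  expect_true(all(other_fat > 3.5))
  expect_length(flag_skimmed(sol, fat_threshold = 0), 0L)
  expect_error(flag_skimmed(cut_and_summarize(ward_d2_cluster(prof), 3)),
               "trait summaries")
})

test_that("intensity index matches hand-computed sums on a small fixture", {
  # 5 farms x 3 years; clusters 1 = intensive, 2 = intermediate,
  # 3 = extensive; hand-computed sums and categories
  assignments <- data.frame(
    farm_id = rep(sprintf("f%d", 1:5), each = 3),
    year = rep(2019:2021, 5),
    cluster = c(1, 1, 1,   # f1: always intensive      -> -3
                3, 3, 3,   # f2: always extensive      -> +3
                1, 3, 1,   # f3: mixed                 -> -1
                2, 2, 2,   # f4: always intermediate   -> +3, intermediate
                1, 2, 3))  # f5: one of each           -> +1
  gm <- c(`1` = "intensive", `2` = "intermediate", `3` = "extensive")
  idx <- intensity_index(assignments, gm)
  expect_equal(idx$score_sum, c(-3, 3, -1, 3, 1))
  expect_equal(idx$category,
               c("always-intensive", "always-extensive", "intermediate",
                 "intermediate", "intermediate"))
  expect_true(all(abs(idx$score_sum) <= idx$n_years))
  expect_error(intensity_index(assignments, gm[1:2]), "unmapped")
  expect_error(intensity_index(assignments, c(`1` = "a", `2` = "b", `3` = "c")),
               "unknown group")
})

test_that("constant cluster membership accumulates over years", {
  a <- data.frame(farm_id = "f1", year = 2011:2021, cluster = 1)
  idx <- intensity_index(a, c(`1` = "intensive"))
  expect_equal(idx$score_sum, -11)
  expect_equal(idx$category, "always-intensive")
  alt <- data.frame(farm_id = "f2", year = 2012:2021,
                    cluster = rep(c(1, 3), 5))
  idx2 <- intensity_index(alt, c(`1` = "intensive", `3` = "extensive"))
  expect_equal(idx2$score_sum, 0)
  expect_equal(idx2$category, "intermediate")
})

test_that("cluster groups are assigned by probability level", {
  prof <- data.frame(farm_id = sprintf("f%d", 1:6), year = 2020)
  level <- c(0.1, 0.12, 0.5, 0.52, 0.9, 0.92)
  prof[paste0("m", 1:12)] <- matrix(rep(level, 12), 6, 12)
  sol <- cut_and_summarize(ward_d2_cluster(prof), 3)
  gm <- assign_cluster_groups(sol)
  curves <- rowMeans(sol$monthly_curves)
  expect_equal(unname(gm[which.min(curves)]), "intensive")
  expect_equal(unname(gm[which.max(curves)]), "extensive")
  expect_setequal(gm, c("intensive", "intermediate", "extensive"))
})
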