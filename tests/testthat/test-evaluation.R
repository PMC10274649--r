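test_that("train/test splits cover the corpus reproducibly", {
  corpus <- glycan_corpus(rep(fixture_structures(), 2)[1:10])
  sp <- split_train_test(corpus, 0.8, seed = 3)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_setequal(c(sp$train, sp$test), corpus$glycan_id)
  expect_length(intersect(sp$train, sp$test), 0L)
  sp2 <- split_train_test(corpus, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_test(corpus, 0.8, seed = 4)))
})

test_that("rank groups follow the published boundaries", {
  g <- assign_rank_groups(c(1, 2, 3, 4, 5, 6, 7))
  expect_equal(as.character(g),
               c("high", "unassigned", "medium", "medium", "unassigned",
                 "unassigned", "low"))
  expect_equal(as.character(assign_rank_groups(NA_integer_)), "low")  # miss
  all1 <- assign_rank_groups(rep(1, 5))
  expect_equal(sum(all1 == "medium"), 0L)
  expect_equal(sum(all1 == "low"), 0L)
})

test_that("binomial enrichment matches closed forms", {
  # 10 glycans, group q = 0.2; motif in 5 glycans, all in the group
  groups <- factor(rep(c("high", "low"), c(2, 8)),
                   levels = c("high", "medium", "low", "unassigned"))
  motifs <- cbind(m1 = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                  m2 = rep(0, 10))
  # construct: n = 5 occurrences with k = 5 in a q = 0.2 group needs a
  # 25-glycan layout; do it directly
  groups25 <- factor(rep(c("high", "low"), c(5, 20)),
                     levels = c("high", "medium", "low", "unassigned"))
  motifs25 <- cbind(m = rep(c(1, 0), c(5, 20)))
  enr <- motif_enrichment(groups25, motifs25)
  expect_equal(enr$p_value[enr$group == "high" & enr$motif_id == "m"],
               0.2^5, tolerance = 1e-12)           # 3.2e-4
  # k = 0 -> P(X >= 0) = 1
  enr0 <- motif_enrichment(groups25, cbind(m = rep(c(0, 1), c(5, 20))))
  expect_equal(enr0$p_value[enr0$group == "high"], 1)
  # q = 1 (group is everything) -> p = 1 even when k = n
  enr1 <- motif_enrichment(factor(rep("high", 10),
                                  levels = c("high", "medium", "low")),
                           cbind(m = rep(1, 10)))
  expect_equal(enr1$p_value[enr1$group == "high"], 1)
  expect_true(all(enr$p_bonferroni >= enr$p_value))
})

test_that("holdout evaluation validates its inputs", {
  corpus <- fixture_corpus()
  binding <- tibble::tibble(glycan_id = corpus$glycan_id, spacer_id = "Sp0",
                            `L@c1` = 5000)
  expect_error(holdout_evaluate(corpus, binding, character(0)), "nonempty")
  expect_error(holdout_evaluate(corpus, binding, "nope"), "unknown")
})

test_that("replicated evaluation reports monotone accuracy and exact ranks
           on a noiseless covered benchmark", {
  set.seed(1)
  cfg <- simulation_config(n_glycans = 80, seed = 3, sensitivity = 1,
                           fpr = 0, sdlog = 0, n_lectins = 12)
  corpus <- generate_corpus(cfg)
  catalog <- build_catalog(corpus)
  lectins <- tibble::tibble(lectin = sprintf("LEC%03d", seq_len(nrow(catalog))),
                            primary_motif = catalog$motif_id,
                            secondary_motif = NA_character_,
                            sensitivity = 1, fpr = 0, secondary_strength = 0.5)
  binding <- simulate_binding(corpus, lectins, catalog, cfg)
  config <- experiment_config(n_partitions = 2, seed = 5, pool_n = 150,
                              n_thresholds = 3)
  rep_out <- run_replicates(corpus, binding, config)
  acc <- rep_out$accuracy
  top1 <- acc$accuracy[acc$top_n == 1]
  top3 <- acc$accuracy[acc$top_n == 3]
  expect_true(all(top3 >= top1))
  expect_gte(top3, 0.8)
  # rank histogram accounts for every tested profile
  expect_equal(nrow(rep_out$ranks),
               sum(table(rep_out$ranks$partition)))
  # standard error is sd/sqrt(partitions)
  hit <- tapply(!is.na(rep_out$ranks$rank) & rep_out$ranks$rank <= 1,
                rep_out$ranks$partition, mean)
  expect_equal(acc$se[acc$top_n == 1], stats::sd(hit) / sqrt(length(hit)),
               tolerance = 1e-12)
})

test_that("holdout keeps the named glycans out of training and ranks them", {
  set.seed(2)
  cfg <- simulation_config(n_glycans = 70, seed = 11, sensitivity = 1,
                           fpr = 0, sdlog = 0)
  corpus <- generate_corpus(cfg)
  catalog <- build_catalog(corpus)
  lectins <- tibble::tibble(lectin = sprintf("LEC%03d", seq_len(nrow(catalog))),
                            primary_motif = catalog$motif_id,
                            secondary_motif = NA_character_,
                            sensitivity = 1, fpr = 0, secondary_strength = 0.5)
  binding <- simulate_binding(corpus, lectins, catalog, cfg)
  test_ids <- corpus$glycan_id[c(3, 10, 22)]
  config <- experiment_config(seed = 7, pool_n = 100, n_thresholds = 3)
  out <- holdout_evaluate(corpus, binding, test_ids, config)
  expect_equal(nrow(out$ranks), length(test_ids))
  expect_setequal(out$ranks$glycan_id, test_ids)
  expect_true(all(out$accuracy$accuracy >= 0 & out$accuracy$accuracy <= 1))
})

test_that("a profile whose glycan is missing from the pool is a miss", {
  ranks <- tibble::tibble(glycan_id = c("a", "b"), class = NA_character_,
                          rank = c(1L, NA_integer_), partition = 1L)
  acc <- lectinseq:::.accuracy_summary(ranks, c(1L, 3L))
  expect_equal(acc$accuracy[acc$top_n == 1], 0.5)
  expect_equal(acc$accuracy[acc$top_n == 3], 0.5)
})
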