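# Train/test evaluation of de novo sequencing accuracy: random 80/20
# partitions with replicates, named holdouts, rank groups and binomial
# motif enrichment.

#' Experiment configuration
#'
#' @param split Training fraction (default 0.8).
#' @param n_partitions Number of random train/test partitions (default 64).
#' @param seed Base RNG seed; partition `p` uses `seed + 7919 * p`.
#' @param top_n Ranks at which to report accuracy (default 1 and 3).
#' @param spacer_exclude Spacer ids removed before evaluation (e.g.
#'   `"Sp14"` for O-glycan runs).
#' @param pool_n Markov samples added to the candidate pool (default 20000).
#' @param max_nodes Size cap for Markov sampling.
#' @param catalog_max_size,catalog_min_count Motif catalog parameters.
#' @param t_min,t_max,n_thresholds Binarization parameters.
#' @param train_method,train_max_iter,train_gtol Boltzmann training
#'   parameters (see [boltzmann_train()]).
#' @return A named list of class `experiment_config`.
#' @export
experiment_config <- function(split = 0.8, n_partitions = 64L, seed = 1L,
                              top_n = c(1L, 3L), spacer_exclude = character(0),
                              pool_n = 20000L, max_nodes = 30L,
                              catalog_max_size = 5L, catalog_min_count = 6L,
                              t_min = 1000, t_max = 20000, n_thresholds = 8L,
                              train_method = "newton", train_max_iter = 100L,
                              train_gtol = 1e-6) {
  stopifnot(split > 0, split < 1, n_partitions >= 1)
  structure(list(split = split, n_partitions = n_partitions, seed = seed,
                 top_n = sort(top_n), spacer_exclude = spacer_exclude,
                 pool_n = pool_n, max_nodes = max_nodes,
                 catalog_max_size = catalog_max_size,
                 catalog_min_count = catalog_min_count,
                 t_min = t_min, t_max = t_max, n_thresholds = n_thresholds,
                 train_method = train_method,
                 train_max_iter = train_max_iter, train_gtol = train_gtol),
            class = "experiment_config")
}

#' Random train/test split of a corpus
#'
#' @param corpus Corpus tibble.
#' @param fraction Training fraction.
#' @param seed RNG seed; the same seed reproduces the same split.
#' @return List with `train` and `test` glycan-id vectors (disjoint cover
#'   of the corpus; `|train| = round(fraction * n)`).
#' @export
split_train_test <- function(corpus, fraction = 0.8, seed = 1L) {
  stopifnot(nrow(corpus) >= 2L, fraction > 0, fraction < 1)
  set.seed(seed)
  n_train <- round(fraction * nrow(corpus))
  n_train <- min(max(n_train, 1L), nrow(corpus) - 1L)
  train <- sample(corpus$glycan_id, n_train)
  list(train = sort(train), test = sort(setdiff(corpus$glycan_id, train)))
}

# evaluate one partition: returns per-test-glycan best rank over its
# binding rows, ranking the candidate pool by Boltzmann log-likelihood
.evaluate_partition <- function(corpus, feats, train_ids, test_ids, config,
                                seed_p) {
  stopifnot(!any(test_ids %in% train_ids))
  train_corpus <- corpus[corpus$glycan_id %in% train_ids, , drop = FALSE]
  catalog <- withCallingHandlers(
    build_catalog(train_corpus, config$catalog_max_size, config$catalog_min_count),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!nrow(catalog)) return(NULL)
  markov <- fit_markov(train_corpus)
  pool <- build_candidate_pool(markov, corpus, n = config$pool_n,
                               seed = seed_p, max_nodes = config$max_nodes)
  Mpool <- motif_matrix(pool, catalog)
  obs_train <- which(feats$glycan_id %in% train_ids)
  if (!length(obs_train)) return(NULL)
  # training rows never contain test glycans (leakage contract)
  stopifnot(!any(feats$glycan_id[obs_train] %in% test_ids))
  row_of <- match(corpus$structure[match(feats$glycan_id, corpus$glycan_id)],
                  pool$structure)
  params <- boltzmann_train(Mpool[row_of[obs_train], , drop = FALSE],
                            feats$bits[obs_train, , drop = FALSE],
                            method = config$train_method,
                            max_iter = config$train_max_iter,
                            gtol = config$train_gtol)
  out <- lapply(test_ids, function(gid) {
    rows <- which(feats$glycan_id == gid)
    if (!length(rows)) return(NULL)
    true_structure <- corpus$structure[match(gid, corpus$glycan_id)]
    best <- NA_integer_
    for (r in rows) {
      theta <- params$A + as.numeric(params$C %*% feats$bits[r, ])
      ll <- as.numeric(Mpool %*% theta)  # -F(l) is constant across the pool
      rk <- .rank_of(ll, pool$structure, true_structure)
      if (!is.na(rk) && (is.na(best) || rk < best)) best <- rk
    }
    tibble::tibble(glycan_id = gid,
                   class = corpus$class[match(gid, corpus$glycan_id)],
                   rank = best)
  })
  do.call(rbind, out)
}

.suppress_training_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("stopped at max_iter", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

.accuracy_summary <- function(ranks, top_n, by_partition = TRUE) {
  ranks$class[is.na(ranks$class)] <- "all"
  out <- list()
  for (cl in unique(ranks$class)) {
    sub <- ranks[ranks$class == cl, , drop = FALSE]
    for (n in top_n) {
      hit <- !is.na(sub$rank) & sub$rank <= n
      if (by_partition) {
        per <- tapply(hit, sub$partition, mean)
        m <- mean(per)
        se <- if (length(per) > 1) stats::sd(per) / sqrt(length(per)) else NA_real_
      } else {
        m <- mean(hit)
        se <- sqrt(m * (1 - m) / length(hit))  # Bernoulli sigma
      }
      out[[length(out) + 1L]] <- tibble::tibble(class = cl, top_n = n,
                                                accuracy = m, se = se)
    }
  }
  do.call(rbind, out)
}

#' Replicated random-partition evaluation
#'
#' For each partition the motif catalog and Markov model are rebuilt from
#' the training glycans only, the Boltzmann model is trained on the
#' training binding rows, and each test profile is ranked against the
#' candidate pool (Markov samples plus the full reference corpus). A test
#' glycan absent from the pool is an unranked miss and counts as a failure
#' at every `n`. Accuracy is averaged over partitions with standard error
#' `sd / sqrt(n_partitions)`.
#'
#' @param corpus Corpus tibble.
#' @param binding Binding table tibble.
#' @param config An [experiment_config()].
#' @return An `accuracy_report`: list with `accuracy` (tibble: class,
#'   top_n, accuracy, se), `ranks` (per partition and glycan) and `config`.
#' @export
run_replicates <- function(corpus, binding, config = experiment_config()) {
  feats <- binarize(filter_spacers(binding, config$spacer_exclude),
                    config$t_min, config$t_max, config$n_thresholds)
  all_ranks <- list()
  for (p in seq_len(config$n_partitions)) {
    seed_p <- config$seed + 7919L * p
    sp <- split_train_test(corpus, config$split, seed_p)
    ranks <- .suppress_training_warnings(
      .evaluate_partition(corpus, feats, sp$train, sp$test, config, seed_p))
    if (is.null(ranks)) {
      warning("partition ", p, " skipped (empty catalog or no training rows)")
      next
    }
    ranks$partition <- p
    all_ranks[[length(all_ranks) + 1L]] <- ranks
  }
  if (!length(all_ranks)) stop("no partition produced results")
  ranks <- do.call(rbind, all_ranks)
  structure(list(accuracy = .accuracy_summary(ranks, config$top_n),
                 ranks = ranks, config = config),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> ", length(unique(x$ranks$partition)), " partition(s), ",
      nrow(x$ranks), " tested profiles\n", sep = "")
  print(x$accuracy)
  invisible(x)
}

#' Named-holdout evaluation
#'
#' Evaluates a single partition whose test set is a named list of glycans
#' (e.g. the corpus glycans also reported in a target cell type); the
#' training set is the complement, so none of the held-out glycans are
#' seen in training. Accuracy uses the Bernoulli standard error.
#'
#' @param corpus Corpus tibble.
#' @param binding Binding table tibble.
#' @param test_ids Character vector of held-out glycan ids (must be in the
#'   corpus; nonempty).
#' @param config An [experiment_config()].
#' @return An `accuracy_report` with per-glycan ranks.
#' @export
holdout_evaluate <- function(corpus, binding, test_ids,
                             config = experiment_config()) {
  test_ids <- as.character(test_ids)
  if (!length(test_ids)) stop("test_ids must be nonempty")
  unknown <- setdiff(test_ids, corpus$glycan_id)
  if (length(unknown)) {
    stop("unknown glycan ids in test_ids: ", paste(unknown, collapse = ", "))
  }
  feats <- binarize(filter_spacers(binding, config$spacer_exclude),
                    config$t_min, config$t_max, config$n_thresholds)
  train_ids <- setdiff(corpus$glycan_id, test_ids)
  ranks <- .suppress_training_warnings(
    .evaluate_partition(corpus, feats, train_ids, test_ids, config,
                        config$seed))
  if (is.null(ranks)) stop("holdout evaluation failed (empty catalog or no training rows)")
  ranks$partition <- 1L
  structure(list(accuracy = .accuracy_summary(ranks, config$top_n,
                                              by_partition = FALSE),
                 ranks = ranks, config = config),
            class = "accuracy_report")
}

#' Assign prediction ranks to accuracy groups
#'
#' High accuracy contains only exactly predicted glycans (rank 1); medium
#' contains ranks 3 and 4; low contains ranks above 6, including unranked
#' misses. Ranks 2, 5 and 6 are left unassigned.
#'
#' @param ranks Integer vector of ranks (`NA` = miss).
#' @return Factor with levels `high`, `medium`, `low`, `unassigned`.
#' @export
assign_rank_groups <- function(ranks) {
  out <- rep("unassigned", length(ranks))
  out[!is.na(ranks) & ranks == 1] <- "high"
  out[!is.na(ranks) & ranks %in% c(3, 4)] <- "medium"
  out[is.na(ranks) | ranks > 6] <- "low"
  factor(out, levels = c("high", "medium", "low", "unassigned"))
}

#' Binomial motif enrichment of rank groups
#'
#' For a motif with `n` occurrences among tested glycans, of which `k` fall
#' in a group containing fraction `q` of the tested glycans, the one-sided
#' upper-tail p-value is `P(X >= k)` for `X ~ Binomial(n, q)`.
#'
#' @param groups Group assignment per tested glycan (from
#'   [assign_rank_groups()]).
#' @param motifs Binary motif matrix for the tested glycans, rows aligned
#'   with `groups`.
#' @return Tibble `group`, `motif_id`, `n_total`, `k_group`, `p_value`,
#'   `p_bonferroni`, sorted by p-value ascending within group.
#' @export
motif_enrichment <- function(groups, motifs) {
  stopifnot(length(groups) == nrow(motifs))
  groups <- as.character(groups)
  out <- list()
  for (g in c("high", "medium", "low")) {
    q <- mean(groups == g)
    n <- colSums(motifs)
    k <- if (any(groups == g)) {
      colSums(motifs[groups == g, , drop = FALSE])
    } else rep(0L, ncol(motifs))
    p <- ifelse(n > 0,
                stats::pbinom(k - 1, n, q, lower.tail = FALSE),
                1)
    out[[g]] <- tibble::tibble(group = g, motif_id = colnames(motifs),
                               n_total = as.integer(n), k_group = as.integer(k),
                               p_value = unname(pmin(p, 1)))
  }
  out <- do.call(rbind, out)
  out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
  out[order(match(out$group, c("high", "medium", "low")), out$p_value,
            method = "radix"), , drop = FALSE]
}

#' Run the standard synthetic sequencing benchmark
#'
#' End-to-end pipeline on simulated ground truth: generate a corpus, build
#' the full-corpus catalog, plant single-motif lectins, simulate binding,
#' then (i) check that each lectin's maximum-MI motif is its planted
#' primary, (ii) measure held-out top-n sequencing accuracy with
#' [run_replicates()], and (iii) compute the mean primary-motif
#' information fraction across lectins.
#'
#' @param seed Benchmark seed.
#' @param noiseless If `TRUE`, use sensitivity 1, false-positive rate 0 and
#'   zero RFU dispersion (binding exactly encodes motif presence).
#' @param n_partitions Number of evaluation partitions (default 4); 0
#'   skips the sequencing evaluation and reports only the specificity
#'   measures.
#' @param pool_n Markov samples in the candidate pool (default 1000).
#' @param sim_overrides Named list of [simulation_config()] overrides.
#' @param skip_info_fraction If `TRUE`, skip the greedy information
#'   fraction (the slowest step) when only accuracy is needed.
#' @return List with `mi_recovery` (fraction of lectins whose planted
#'   primary attains the maximal MI), `accuracy` (tibble), `report` (the
#'   full `accuracy_report`), `info_fraction_mean`, `info_fractions`,
#'   `catalog_size` and the inputs (`corpus`, `catalog`, `lectins`).
#' @export
run_synthetic_benchmark <- function(seed = 1L, noiseless = FALSE,
                                    n_partitions = 4L, pool_n = 1000L,
                                    sim_overrides = list(),
                                    skip_info_fraction = FALSE) {
  args <- c(list(seed = seed), sim_overrides)
  if (noiseless) {
    # deterministic binding; every motif is read out, so the catalog keeps
    # all motifs (the >5 count filter is a statistical-reliability device
    # with no role in the noiseless limit), and one lectin is planted per
    # distinguishable presence pattern (duplicate-pattern motifs carry no
    # extra information)
    args$sensitivity <- 1; args$fpr <- 0; args$sdlog <- 0
    args$n_concentrations <- 1L; args$n_replicates <- 1L
    if (is.null(sim_overrides$n_glycans)) args$n_glycans <- 300L
  }
  config <- do.call(simulation_config, args)
  corpus <- generate_corpus(config)
  catalog <- if (noiseless) {
    suppressWarnings(build_catalog(corpus, min_count = 1L))
  } else {
    build_catalog(corpus)
  }
  lectins <- if (noiseless) {
    M_all <- motif_matrix(corpus, catalog)
    rep_motifs <- catalog$motif_id[!duplicated(apply(M_all, 2, paste,
                                                     collapse = ""))]
    tibble::tibble(lectin = sprintf("LEC%04d", seq_along(rep_motifs)),
                   primary_motif = rep_motifs,
                   secondary_motif = NA_character_,
                   sensitivity = 1, fpr = 0, secondary_strength = 0.5)
  } else {
    plant_lectins(catalog, config, corpus)
  }
  binding <- simulate_binding(corpus, lectins, catalog, config)
  feats <- binarize(binding, n_thresholds = if (noiseless) 2L else 8L)
  M <- motif_matrix(corpus, catalog)
  Mobs <- M[match(feats$glycan_id, rownames(M)), , drop = FALSE]
  mi <- .mi_pairwise(feats$bits, Mobs)
  # per condition, the max-MI motif; recovery = planted primary attains it
  recovered <- vapply(seq_len(nrow(lectins)), function(i) {
    jj <- which(feats$schema$reagent == lectins$lectin[i])
    mi_cond <- apply(mi[jj, , drop = FALSE], 2, max)
    planted <- lectins$primary_motif[i]
    mi_cond[planted] >= max(mi_cond) - 1e-9
  }, logical(1))
  info_fractions <- NULL
  if (!skip_info_fraction) {
    info_fractions <- vapply(seq_len(nrow(lectins)), function(i) {
      jj <- which(feats$schema$reagent == lectins$lectin[i])
      best_j <- jj[which.max(apply(mi[jj, , drop = FALSE], 1, max))]
      primary_information_fraction(feats$bits[, best_j], Mobs)$fraction
    }, numeric(1))
  }
  if (n_partitions == 0L) {
    return(list(mi_recovery = mean(recovered), recovered = recovered,
                accuracy = NULL, report = NULL,
                info_fraction_mean = if (is.null(info_fractions)) NA_real_ else
                  mean(info_fractions, na.rm = TRUE),
                info_fractions = info_fractions,
                catalog_size = nrow(catalog),
                corpus = corpus, catalog = catalog, lectins = lectins,
                binding = binding))
  }
  if (noiseless) {
    # resequencing identifiability: with every catalog motif read out by a
    # perfect lectin, the true glycan's motif vector is the unique
    # likelihood maximizer, so each profile must rank its glycan first.
    # Separable data make weights diverge; Newton is capped (ordering is
    # invariant to the cap).
    feats1 <- binarize(binding, n_thresholds = 1L)
    markov <- fit_markov(corpus)
    pool <- build_candidate_pool(markov, corpus, n = pool_n, seed = seed)
    Mpool <- motif_matrix(pool, catalog)
    row_of <- match(corpus$structure[match(feats1$glycan_id, corpus$glycan_id)],
                    pool$structure)
    params <- .suppress_training_warnings(
      boltzmann_train(Mpool[row_of, , drop = FALSE], feats1$bits,
                      method = "newton", max_iter = 12L))
    ranks <- vapply(seq_len(nrow(feats1$bits)), function(r) {
      theta <- params$A + as.numeric(params$C %*% feats1$bits[r, ])
      .rank_of(as.numeric(Mpool %*% theta), pool$structure,
               pool$structure[row_of[r]])
    }, integer(1))
    rank_tab <- tibble::tibble(glycan_id = feats1$glycan_id,
                               class = NA_character_, rank = ranks,
                               partition = 1L)
    accuracy <- .accuracy_summary(rank_tab, c(1L, 3L), by_partition = FALSE)
    report <- structure(list(accuracy = accuracy, ranks = rank_tab,
                             config = NULL), class = "accuracy_report")
  } else {
    eval_config <- experiment_config(n_partitions = n_partitions, seed = seed,
                                     pool_n = pool_n)
    report <- run_replicates(corpus, binding, eval_config)
  }
  list(mi_recovery = mean(recovered), recovered = recovered,
       accuracy = report$accuracy, report = report,
       info_fraction_mean = if (is.null(info_fractions)) NA_real_ else
         mean(info_fractions, na.rm = TRUE),
       info_fractions = info_fractions,
       catalog_size = nrow(catalog),
       corpus = corpus, catalog = catalog, lectins = lectins,
       binding = binding)
}
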