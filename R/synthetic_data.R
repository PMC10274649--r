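# Ground-truth synthetic benchmarks: glycan corpora grown from a fixed
# vocabulary of common linkages, lectins planted on catalog motifs, and
# simulated RFU tables with a two-state log-normal noise model.

#' Table of common glycan linkages used by the corpus generator
#'
#' Each row is an allowed (child residue, anomer, anomeric position,
#' attachment position, parent residue) edge, drawn from linkage patterns
#' common in mammalian glycans (type-2 LacNAc, sialylation, fucosylation,
#' the mannose core, O-glycan cores). Restricting growth to a reusable
#' linkage vocabulary gives corpora in which motifs recur often enough for
#' presence statistics to be meaningful, as in real glycomes.
#'
#' @return Data frame with columns `child`, `anomer`, `cpos`, `ppos`,
#'   `parent`.
#' @export
linkage_vocabulary <- function() {
  edges <- rbind(
    c("Gal",    "b", "1", "4", "GlcNAc"),
    c("Gal",    "b", "1", "3", "GlcNAc"),
    c("Gal",    "b", "1", "3", "GalNAc"),
    c("Neu",    "a", "2", "3", "Gal"),
    c("Neu",    "a", "2", "6", "Gal"),
    c("Neu",    "a", "2", "6", "GalNAc"),
    c("Fuc",    "a", "1", "2", "Gal"),
    c("Fuc",    "a", "1", "3", "GlcNAc"),
    c("Fuc",    "a", "1", "6", "GlcNAc"),
    c("GlcNAc", "b", "1", "2", "Man"),
    c("GlcNAc", "b", "1", "4", "Man"),
    c("GlcNAc", "b", "1", "6", "Man"),
    c("GlcNAc", "b", "1", "3", "Gal"),
    c("GlcNAc", "b", "1", "6", "GalNAc"),
    c("GlcNAc", "b", "1", "3", "GalNAc"),
    c("GlcNAc", "b", "1", "4", "GlcNAc"),
    c("Man",    "a", "1", "3", "Man"),
    c("Man",    "a", "1", "6", "Man"),
    c("Man",    "b", "1", "4", "GlcNAc"),
    c("GalNAc", "b", "1", "4", "GlcNAc"),
    c("GalNAc", "a", "1", "3", "Gal"),
    c("Gal",    "b", "1", "4", "Glc"))
  stats::setNames(as.data.frame(edges, stringsAsFactors = FALSE),
                  c("child", "anomer", "cpos", "ppos", "parent"))
}

#' Simulation configuration
#'
#' Defaults are the package's standard benchmark conditions: 1000 glycans
#' of 2-15 residues over the seven-residue alphabet, 30 single-motif
#' lectins with sensitivity 0.95 and false-positive rate 0.02, and a
#' two-state log-normal RFU model with bound median 10000 and unbound
#' median 200 spanning the 1000-20000 RFU binarization window.
#'
#' @param n_glycans Corpus size.
#' @param size_range Residue-count range of generated glycans.
#' @param branching_prob Probability that a growth step extends an internal
#'   node rather than the most recent tip.
#' @param n_lectins Number of planted lectins.
#' @param sensitivity P(binding event | target motif present).
#' @param fpr P(binding event | no target motif).
#' @param secondary_prob Probability that a lectin carries a secondary
#'   motif.
#' @param secondary_strength Sensitivity multiplier for secondary motifs.
#' @param bound_median,unbound_median Median RFU of the bound and unbound
#'   states.
#' @param sdlog Log-normal dispersion of both states.
#' @param n_concentrations Concentrations measured per lectin; each is an
#'   independent draw of the firing process, as on real arrays where every
#'   reagent is assayed at several concentrations.
#' @param n_replicates Spacer presentations per glycan (replicate rows).
#' @param seed RNG seed recorded with the outputs.
#' @return A named list of class `simulation_config`.
#' @export
simulation_config <- function(n_glycans = 1000L, size_range = c(2L, 15L),
                              branching_prob = 0.25, n_lectins = 30L,
                              sensitivity = 0.95, fpr = 0.02,
                              secondary_prob = 0, secondary_strength = 0.5,
                              bound_median = 10000, unbound_median = 200,
                              sdlog = 0.5, n_concentrations = 2L,
                              n_replicates = 2L, seed = 1L) {
  stopifnot(n_glycans > 0, n_lectins > 0, size_range[1] >= 2,
            sensitivity >= 0, sensitivity <= 1, fpr >= 0, fpr <= 1,
            bound_median > unbound_median)
  structure(list(n_glycans = n_glycans, size_range = size_range,
                 branching_prob = branching_prob, n_lectins = n_lectins,
                 sensitivity = sensitivity, fpr = fpr,
                 secondary_prob = secondary_prob,
                 secondary_strength = secondary_strength,
                 bound_median = bound_median, unbound_median = unbound_median,
                 sdlog = sdlog, n_concentrations = n_concentrations,
                 n_replicates = n_replicates, seed = seed),
            class = "simulation_config")
}

#' Generate a random glycan corpus
#'
#' Grows random rooted trees over the seven-residue alphabet using the
#' fixed linkage vocabulary: each glycan starts from a reducing-end residue
#' and is extended one residue at a time, attaching to the most recent tip
#' (chain extension) or, with probability `branching_prob`, to a random
#' earlier residue with a free allowed position. Reproducible per seed.
#'
#' @param config A [simulation_config()].
#' @param vocabulary Linkage table (default [linkage_vocabulary()]).
#' @return A corpus tibble (see [glycan_corpus()]); duplicated structures
#'   are retained, as on real arrays, but ids are unique.
#' @export
generate_corpus <- function(config = simulation_config(),
                            vocabulary = linkage_vocabulary()) {
  set.seed(config$seed)
  roots <- c(GlcNAc = 0.45, GalNAc = 0.25, Man = 0.1, Gal = 0.1, Glc = 0.1)
  # array glycans are mostly small; sizes decay geometrically over the range
  size_vals <- seq(config$size_range[1], config$size_range[2])
  sizes <- sample(size_vals, config$n_glycans, replace = TRUE,
                  prob = 0.75^(size_vals - size_vals[1]))
  structures <- character(config$n_glycans)
  for (i in seq_len(config$n_glycans)) {
    repeat {
      s <- .grow_random_tree(sizes[i], roots, config$branching_prob, vocabulary)
      if (!is.null(s)) break
    }
    structures[i] <- s
  }
  glycan_corpus(structures, source = "synthetic")
}

.grow_random_tree <- function(target_size, roots, branching_prob, vocab) {
  name <- sample(names(roots), 1, prob = roots)
  nodes <- list(list(name = name, anomer = "?", cpos = "?", ppos = NA,
                     used_pos = character(0)))
  parent_of <- NA_integer_
  tip <- 1L
  while (length(nodes) < target_size) {
    # candidate attachment points: the current tip, or any node when branching
    v <- if (stats::runif(1) < branching_prob) {
      sample.int(length(nodes), 1)
    } else tip
    opts <- vocab[vocab$parent == nodes[[v]]$name &
                    !(vocab$ppos %in% nodes[[v]]$used_pos), , drop = FALSE]
    if (!nrow(opts) && branching_prob == 0) break  # chains never branch
    if (!nrow(opts)) {
      # fall back to any extensible node
      ok <- which(vapply(seq_along(nodes), function(u) {
        nrow(vocab[vocab$parent == nodes[[u]]$name &
                     !(vocab$ppos %in% nodes[[u]]$used_pos), ]) > 0
      }, logical(1)))
      if (!length(ok)) break
      v <- ok[sample.int(length(ok), 1)]
      opts <- vocab[vocab$parent == nodes[[v]]$name &
                      !(vocab$ppos %in% nodes[[v]]$used_pos), , drop = FALSE]
    }
    e <- opts[sample.int(nrow(opts), 1), ]
    nodes[[length(nodes) + 1L]] <- list(name = e$child, anomer = e$anomer,
                                        cpos = e$cpos, ppos = e$ppos,
                                        used_pos = character(0))
    nodes[[v]]$used_pos <- c(nodes[[v]]$used_pos, e$ppos)
    parent_of <- c(parent_of, v)
    tip <- length(nodes)
  }
  if (length(nodes) < 2L) return(NULL)
  kids <- split(seq_along(nodes)[-1], parent_of[-1])
  build <- function(i) {
    ks <- kids[[as.character(i)]]
    .new_node(nodes[[i]]$name, nodes[[i]]$anomer, nodes[[i]]$cpos,
              as.character(nodes[[i]]$ppos),
              children = if (is.null(ks)) list() else lapply(ks, build))
  }
  glycan_string(canonicalize(.as_glycan(build(1L))))
}

#' Plant lectin specificities on catalog motifs
#'
#' Assigns each simulated lectin a primary motif (sampled without
#' replacement while possible) and, with probability `secondary_prob`, an
#' independent secondary motif. When `corpus` is supplied, the panel is
#' designed the way real lectin panels are: primaries are restricted to
#' motifs with non-degenerate, mutually distinct presence patterns
#' (identical-presence motifs are indistinguishable from binding data),
#' and are then chosen greedily so that each added lectin maximally
#' refines the joint presence code over the corpus - a panel of
#' complementary, individually informative specificities. The greedy
#' refinement naturally favors motifs of balanced prevalence.
#'
#' @param catalog Motif catalog tibble.
#' @param config A [simulation_config()].
#' @param corpus Optional corpus tibble used to screen candidate motifs.
#' @return Tibble with columns `lectin`, `primary_motif`, `secondary_motif`
#'   (`NA` if none), `sensitivity`, `fpr`, `secondary_strength`.
#' @export
plant_lectins <- function(catalog, config = simulation_config(), corpus = NULL) {
  stopifnot(nrow(catalog) > 0)
  set.seed(config$seed + 1L)
  n <- config$n_lectins
  cand <- catalog$motif_id
  primary <- NULL
  if (!is.null(corpus)) {
    M <- motif_matrix(corpus, catalog)
    prev <- colMeans(M)
    pattern <- apply(M, 2, paste, collapse = "")
    ok <- prev > 0 & prev < 1 & !duplicated(pattern)
    if (sum(ok) >= 2L) {
      cand <- catalog$motif_id[ok]
      if (n <= length(cand)) {
        # greedy panel design: each lectin maximally refines the joint
        # presence code; ties broken by per-motif entropy then id
        Mc <- M[, cand, drop = FALSE]
        ent <- apply(Mc, 2, shannon_entropy)
        code <- rep("", nrow(Mc))
        chosen <- character(0)
        for (step in seq_len(n)) {
          left <- setdiff(cand, chosen)
          score <- vapply(left, function(id) {
            length(unique(paste(code, Mc[, id])))
          }, numeric(1))
          best <- left[order(-score, -ent[left], left)][1]
          chosen <- c(chosen, best)
          code <- paste(code, Mc[, best])
        }
        primary <- chosen
      }
    }
  }
  if (is.null(primary)) {
    if (n > length(cand)) {
      warning("more lectins than eligible motifs; sampling with replacement")
      primary <- sample(cand, n, replace = TRUE)
    } else {
      primary <- sample(cand, n)
    }
  }
  secondary <- rep(NA_character_, n)
  has2 <- stats::runif(n) < config$secondary_prob
  for (i in which(has2)) {
    pool <- setdiff(cand, primary[i])
    if (length(pool)) secondary[i] <- sample(pool, 1)
  }
  tibble::tibble(lectin = sprintf("LEC%02d", seq_len(n)),
                 primary_motif = primary, secondary_motif = secondary,
                 sensitivity = config$sensitivity, fpr = config$fpr,
                 secondary_strength = config$secondary_strength)
}

#' Simulate a lectin binding table
#'
#' For each (observation, lectin, concentration) a binding event fires
#' independently with probability `sensitivity` if the primary motif is
#' present, `sensitivity * secondary_strength` if only the secondary motif
#' is present, and `fpr` otherwise; RFU is then drawn log-normal around the
#' bound or unbound median. Each glycan is presented on `n_replicates`
#' spacers and each lectin measured at `n_concentrations` concentrations,
#' mirroring real array layouts. With `sdlog = 0`, `sensitivity = 1` and
#' `fpr = 0` the RFU exactly separates motif presence at any threshold
#' between the medians.
#'
#' @param corpus Corpus tibble.
#' @param lectins Planted lectin tibble from [plant_lectins()].
#' @param catalog Motif catalog the planted motif ids refer to.
#' @param config A [simulation_config()].
#' @param spacers Spacer labels used for replicate rows (recycled to
#'   `n_replicates`).
#' @return A binding table tibble with one condition column per lectin and
#'   concentration, named `"<lectin>@c<k>"`.
#' @export
simulate_binding <- function(corpus, lectins, catalog,
                             config = simulation_config(),
                             spacers = c("Sp0", "Sp8", "Sp13", "Sp21")) {
  set.seed(config$seed + 2L)
  M <- motif_matrix(corpus, catalog)
  nrep <- config$n_replicates
  spacers <- rep_len(spacers, nrep)
  n <- nrow(corpus) * nrep
  rows <- rep(seq_len(nrow(corpus)), each = nrep)
  out <- tibble::tibble(glycan_id = corpus$glycan_id[rows],
                        spacer_id = rep(spacers, nrow(corpus)))
  for (i in seq_len(nrow(lectins))) {
    p <- rep(lectins$fpr[i], n)
    if (!is.na(lectins$secondary_motif[i])) {
      sec <- M[rows, lectins$secondary_motif[i]] == 1
      p[sec] <- lectins$sensitivity[i] * lectins$secondary_strength[i]
    }
    prim <- M[rows, lectins$primary_motif[i]] == 1
    p[prim] <- lectins$sensitivity[i]
    for (k in seq_len(config$n_concentrations)) {
      fired <- stats::runif(n) < p
      rfu <- numeric(n)
      if (config$sdlog == 0) {  # exact two-state limit
        rfu[fired] <- config$bound_median
        rfu[!fired] <- config$unbound_median
      } else {
        rfu[fired] <- stats::rlnorm(sum(fired), log(config$bound_median),
                                    config$sdlog)
        rfu[!fired] <- stats::rlnorm(sum(!fired), log(config$unbound_median),
                                     config$sdlog)
      }
      out[[sprintf("%s@c%d", lectins$lectin[i], k)]] <- rfu
    }
  }
  out
}

#' Write planted lectin ground truth to JSON
#'
#' @param lectins Planted lectin tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lectins_json <- function(lectins, path) {
  jsonlite::write_json(lectins, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read planted lectin ground truth from JSON
#'
#' @param path File path.
#' @return Planted lectin tibble.
#' @export
read_lectins_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  df$secondary_motif <- as.character(df$secondary_motif)
  tibble::as_tibble(df)
}
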