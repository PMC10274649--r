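# Order-2 Markov model of glycan growth.
#
# The model grows a tree from the reducing end outward.  A growth token is
# either a residue token "name/anomer/child_pos/parent_pos" or the STOP
# symbol "$" ending a node's child list.  Each node's children are drawn
# sequentially (in canonical slot order): each draw is conditioned on the
# node's own residue token, its parent's token (the two residues below the
# growing position), and the previously drawn sibling token; BEGIN ("^")
# stands in for missing history.  On unbranched chains this reduces to
# predicting the next residue from the previous two, with a terminal STOP;
# the sibling component makes point-mass corpora fit point-mass models.

.TOK_STOP <- "$"
.TOK_BEGIN <- "^"

.res_token <- function(name, anomer, cpos, ppos, is_root) {
  if (is_root) name else paste(name, anomer, cpos, ppos, sep = "/")
}

.split_token <- function(tok) strsplit(tok, "/", fixed = TRUE)[[1]]

.hist_key <- function(parent_tok, grand_tok, sib_tok = .TOK_BEGIN) {
  paste(parent_tok, grand_tok, sib_tok, sep = " | ")
}

#' Construct a Markov glycome model
#'
#' Mostly used internally by [fit_markov()]; exposed so that models with
#' known closed-form entropy can be built directly in analyses and tests.
#'
#' @param root_dist Named numeric vector: distribution over root residue
#'   tokens (plain residue names).
#' @param transitions Named list; each element is a named numeric
#'   distribution over growth tokens (`"name/anomer/child_pos/parent_pos"`
#'   or `"$"` for STOP), keyed by `"parent | grandparent | previous-sibling"`
#'   histories (see [fit_markov()]). Histories absent from the list stop
#'   deterministically.
#' @return A `markov_glycome` model object.
#' @export
markov_model <- function(root_dist, transitions) {
  stopifnot(is.numeric(root_dist), !is.null(names(root_dist)))
  if (abs(sum(root_dist) - 1) > 1e-9 || any(root_dist < 0)) {
    stop("root_dist must be a probability distribution")
  }
  for (k in names(transitions)) {
    p <- transitions[[k]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("transition distribution for history \"", k, "\" does not sum to 1")
    }
  }
  structure(list(root_dist = root_dist, transitions = transitions),
            class = "markov_glycome")
}

#' @export
print.markov_glycome <- function(x, ...) {
  cat("<markov_glycome> ", length(x$root_dist), " root tokens, ",
      length(x$transitions), " histories\n", sep = "")
  invisible(x)
}

#' Fit an order-2 Markov growth model to a corpus
#'
#' Maximum-likelihood transition frequencies over all growth events
#' observed when traversing each corpus tree from the root outward; each
#' event is keyed by (parent residue, grandparent residue, previous sibling
#' drawn at this node) and includes the STOP event that terminates each
#' node's canonically ordered child list. No smoothing is applied: sampling
#' only visits histories reachable from fitted transitions.
#'
#' @param corpus A corpus tibble.
#' @return A `markov_glycome` model.
#' @export
fit_markov <- function(corpus) {
  stopifnot(nrow(corpus) >= 1L)
  root_counts <- new.env(parent = emptyenv())
  trans_counts <- new.env(parent = emptyenv())
  bump <- function(env, key, tok) {
    cur <- if (is.null(env[[key]])) numeric(0) else env[[key]]
    cur[tok] <- if (is.na(cur[tok])) 1 else cur[tok] + 1
    env[[key]] <- cur
  }
  for (g in corpus$tree) {
    g <- canonicalize(g)
    walk <- function(node, parent_tok, grand_tok, is_root) {
      tok <- .res_token(node$name, node$anomer, node$child_pos,
                        node$parent_pos, is_root)
      if (is_root) bump(root_counts, "root", tok)
      sib <- .TOK_BEGIN
      for (ch in node$children) {
        ctok <- .res_token(ch$name, ch$anomer, ch$child_pos, ch$parent_pos, FALSE)
        bump(trans_counts, .hist_key(tok, parent_tok, sib), ctok)
        sib <- ctok
        walk(ch, tok, parent_tok, FALSE)
      }
      bump(trans_counts, .hist_key(tok, parent_tok, sib), .TOK_STOP)
    }
    walk(g, .TOK_BEGIN, .TOK_BEGIN, TRUE)
  }
  rd <- root_counts[["root"]]
  rd <- rd / sum(rd)
  trans <- lapply(as.list(trans_counts), function(v) v / sum(v))
  markov_model(rd, trans)
}

# draw index from a cached cumulative distribution
.make_sampler <- function(model) {
  cache <- new.env(parent = emptyenv())
  list(
    draw_root = function() {
      u <- stats::runif(1)
      i <- findInterval(u, cumsum(model$root_dist)) + 1L
      names(model$root_dist)[min(i, length(model$root_dist))]
    },
    draw = function(key) {
      cd <- cache[[key]]
      if (is.null(cd)) {
        p <- model$transitions[[key]]
        if (is.null(p)) p <- c(1)
        if (is.null(names(p))) names(p) <- .TOK_STOP
        cd <- list(toks = names(p), cum = cumsum(p), p = p)
        cache[[key]] <- cd
      }
      u <- stats::runif(1)
      i <- min(findInterval(u, cd$cum) + 1L, length(cd$toks))
      list(tok = cd$toks[i], logp = log2(cd$p[[i]]))
    },
    root_logp = function(tok) log2(model$root_dist[[tok]])
  )
}

# grow one tree; returns NULL on rejection (size > max_nodes)
.grow_one <- function(sampler, max_nodes, want_tree = TRUE) {
  rt <- sampler$draw_root()
  logp <- sampler$root_logp(rt)
  name <- rt; anomer <- "?"; cpos <- "?"; ppos <- NA_character_
  nodes <- list(list(name = name, anomer = anomer, child_pos = cpos,
                     parent_pos = ppos))
  toks <- rt
  parent_of <- NA_integer_
  queue <- 1L  # indices whose child lists are still to be generated
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ptok <- if (is.na(parent_of[v])) .TOK_BEGIN else toks[parent_of[v]]
    sib <- .TOK_BEGIN
    repeat {
      d <- sampler$draw(.hist_key(toks[v], ptok, sib))
      logp <- logp + d$logp
      if (d$tok == .TOK_STOP) break
      sib <- d$tok
      if (length(nodes) + 1L > max_nodes) return(NULL)
      f <- .split_token(d$tok)
      nodes[[length(nodes) + 1L]] <- list(name = f[1], anomer = f[2],
                                          child_pos = f[3], parent_pos = f[4])
      toks <- c(toks, d$tok)
      parent_of <- c(parent_of, v)
      queue <- c(queue, length(nodes))
    }
  }
  tree <- NULL
  if (want_tree) {
    kids <- split(seq_along(nodes)[-1], parent_of[-1])
    build <- function(i) {
      ks <- kids[[as.character(i)]]
      ch <- if (is.null(ks)) list() else lapply(ks, build)
      .new_node(nodes[[i]]$name, nodes[[i]]$anomer, nodes[[i]]$child_pos,
                nodes[[i]]$parent_pos, children = ch)
    }
    tree <- canonicalize(.as_glycan(build(1L)))
  }
  list(tree = tree, logp2 = logp, n_nodes = length(nodes))
}

#' Sample glycans from a Markov glycome model
#'
#' Trees are grown root-outward, each decision conditioned on the previous
#' two residues; trees exceeding `max_nodes` residues are rejected and
#' redrawn. Reproducible given `seed`.
#'
#' @param model A `markov_glycome` model.
#' @param n Number of samples (default 20000, covering the plausible glycan
#'   space of a CFG-scale corpus whose model entropy is around 12 bits).
#' @param seed Optional RNG seed.
#' @param max_nodes Rejection cap on tree size (default 30).
#' @return List of `glycan_tree` objects of length `n`; warns if the
#'   rejection rate exceeds 50%.
#' @export
sample_glycans <- function(model, n = 20000L, seed = NULL, max_nodes = 30L) {
  if (!is.null(seed)) set.seed(seed)
  sampler <- .make_sampler(model)
  out <- vector("list", n)
  rejected <- 0L
  i <- 1L
  while (i <= n) {
    s <- .grow_one(sampler, max_nodes, want_tree = TRUE)
    if (is.null(s)) { rejected <- rejected + 1L; next }
    out[[i]] <- s$tree
    i <- i + 1L
  }
  if (rejected > 0.5 * (n + rejected)) {
    warning(sprintf("high rejection rate in sampling: %d of %d draws exceeded max_nodes = %d",
                    rejected, n + rejected, max_nodes))
  }
  attr(out, "rejected") <- rejected
  out
}

#' Log2-probability of a glycan under a Markov glycome model
#'
#' The probability of the product of all growth decisions along the
#' glycan's canonical generation order; `-Inf` if any decision is
#' unreachable under the model.
#'
#' @param model A `markov_glycome` model.
#' @param g A `glycan_tree`.
#' @return Log2 probability (scalar).
#' @export
glycan_logprob <- function(model, g) {
  g <- canonicalize(g)
  lp <- 0
  get_p <- function(key, tok) {
    p <- model$transitions[[key]]
    if (is.null(p)) p <- stats::setNames(1, .TOK_STOP)
    if (is.na(p[tok])) return(0)
    p[[tok]]
  }
  walk <- function(node, parent_tok, is_root) {
    tok <- .res_token(node$name, node$anomer, node$child_pos,
                      node$parent_pos, is_root)
    if (is_root) {
      pr <- model$root_dist[tok]
      lp <<- lp + if (is.na(pr)) -Inf else log2(pr)
    }
    sib <- .TOK_BEGIN
    for (ch in node$children) {
      ctok <- .res_token(ch$name, ch$anomer, ch$child_pos, ch$parent_pos, FALSE)
      p <- get_p(.hist_key(tok, parent_tok, sib), ctok)
      lp <<- lp + if (p > 0) log2(p) else -Inf
      sib <- ctok
      walk(ch, tok, FALSE)
    }
    p <- get_p(.hist_key(tok, parent_tok, sib), .TOK_STOP)
    lp <<- lp + if (p > 0) log2(p) else -Inf
  }
  walk(g, .TOK_BEGIN, TRUE)
  lp
}

#' Monte-Carlo entropy of a Markov glycome model
#'
#' Estimates `E[-log2 P(glycan)]` in bits by sampling, with a standard
#' error. A deterministic model has exactly zero entropy.
#'
#' @param model A `markov_glycome` model.
#' @param n_samples Number of Monte-Carlo samples (default 10000).
#' @param seed Optional RNG seed.
#' @param max_nodes Rejection cap on tree size.
#' @return List with `bits` (point estimate), `se` (standard error) and
#'   `n_samples`.
#' @export
model_entropy <- function(model, n_samples = 10000L, seed = NULL,
                          max_nodes = 30L) {
  if (!is.null(seed)) set.seed(seed)
  sampler <- .make_sampler(model)
  lp <- numeric(n_samples)
  i <- 1L
  while (i <= n_samples) {
    s <- .grow_one(sampler, max_nodes, want_tree = FALSE)
    if (is.null(s)) next
    lp[i] <- -s$logp2
    i <- i + 1L
  }
  list(bits = mean(lp), se = stats::sd(lp) / sqrt(n_samples),
       n_samples = n_samples)
}

#' Build the candidate glycan pool
#'
#' The deduplicated union of Markov-sampled glycans and the reference
#' corpus, with a provenance flag per glycan (`reference`, `generated` or
#' `both`). Likelihood ranking is carried out over this pool.
#'
#' @param model A `markov_glycome` model.
#' @param corpus Reference corpus tibble.
#' @param n Number of glycans to sample (default 20000).
#' @param seed Optional RNG seed.
#' @param max_nodes Rejection cap on tree size.
#' @return A pool tibble with columns `glycan_id`, `structure`, `class`,
#'   `source`, `tree`, `provenance`; reference rows keep their corpus ids.
#' @export
build_candidate_pool <- function(model, corpus, n = 20000L, seed = NULL,
                                 max_nodes = 30L) {
  ref <- corpus[!duplicated(corpus$structure), , drop = FALSE]
  pool <- tibble::tibble(glycan_id = ref$glycan_id,
                         structure = ref$structure,
                         class = ref$class, source = ref$source,
                         tree = ref$tree,
                         provenance = rep("reference", nrow(ref)))
  if (n > 0L) {
    samp <- sample_glycans(model, n = n, seed = seed, max_nodes = max_nodes)
    strs <- vapply(samp, glycan_string, character(1))
    dup <- duplicated(strs)
    samp <- samp[!dup]; strs <- strs[!dup]
    in_ref <- strs %in% pool$structure
    pool$provenance[pool$structure %in% strs] <- "both"
    if (any(!in_ref)) {
      new <- tibble::tibble(glycan_id = sprintf("S%05d", seq_len(sum(!in_ref))),
                            structure = strs[!in_ref],
                            class = NA_character_, source = "markov",
                            tree = samp[!in_ref],
                            provenance = "generated")
      pool <- rbind(pool, new)
    }
  }
  pool
}

#' Write a Markov glycome model to JSON
#'
#' @param model A `markov_glycome` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markov_json <- function(model, path) {
  jsonlite::write_json(list(root_dist = as.list(model$root_dist),
                            transitions = lapply(model$transitions, as.list)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Markov glycome model from JSON
#'
#' @param path File path.
#' @return A `markov_glycome` model.
#' @export
read_markov_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  markov_model(unlist(x$root_dist), lapply(x$transitions, unlist))
}
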