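# Information-theoretic measures of lectin-motif specificity.
#
# All entropies, mutual informations and cross-entropy losses are in bits
# (base 2).  Plug-in estimators throughout, with 0 * log 0 = 0.

.plogp <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

#' Shannon entropy of a discrete sample
#'
#' Plug-in entropy of the empirical distribution, base 2.
#'
#' @param x Vector (binary or any discrete labels).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x) {
  stopifnot(length(x) >= 1L)
  p <- tabulate(factor(x)) / length(x)
  -sum(.plogp(p))
}

#' Mutual information between two discrete samples
#'
#' `I(A:B) = H(A) + H(B) - H(AB)`, plug-in, base 2. `y` may be a matrix,
#' in which case its rows are treated as a joint variable (e.g. a motif
#' set). Satisfies `0 <= I <= min(H(A), H(B))`.
#'
#' @param x Vector of discrete labels.
#' @param y Vector, or matrix with `length(x)` rows.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (is.matrix(y)) y <- do.call(paste, c(as.data.frame(y), sep = "\r"))
  if (length(x) != length(y)) stop("length mismatch between x and y")
  joint <- paste(x, y, sep = "\r")
  max(shannon_entropy(x) + shannon_entropy(y) - shannon_entropy(joint), 0)
}

# pairwise MI (bits) between all columns of two binary matrices
.mi_pairwise <- function(X, Y) {
  n <- nrow(X)
  n11 <- crossprod(X, Y)
  cx <- colSums(X); cy <- colSums(Y)
  n10 <- outer(cx, rep(1, ncol(Y))) - n11
  n01 <- outer(rep(1, ncol(X)), cy) - n11
  n00 <- n - n11 - n10 - n01
  Hab <- -(.plogp(n11 / n) + .plogp(n10 / n) + .plogp(n01 / n) + .plogp(n00 / n))
  Hab <- matrix(Hab, ncol(X), ncol(Y))
  Ha <- -(.plogp(cx / n) + .plogp(1 - cx / n))
  Hb <- -(.plogp(cy / n) + .plogp(1 - cy / n))
  mi <- outer(Ha, Hb, "+") - Hab
  mi <- pmax(mi, 0)
  dimnames(mi) <- list(colnames(X), colnames(Y))
  mi
}

#' Lectin-motif mutual information table
#'
#' Computes MI between every lectin condition and every catalog motif.
#' Each threshold feature of a condition is one binarization of the same
#' measurement, so the per-condition MI for a motif is the maximum over
#' that condition's threshold features. Records under `min_bits` are
#' filtered from the report but retained in the raw output.
#'
#' @param features A `feature_matrix` from [binarize()].
#' @param motifs Binary motif matrix with `glycan_id` rownames (from
#'   [motif_matrix()]); rows are matched to observations via the feature
#'   matrix's `glycan_id`.
#' @param min_bits Display threshold in bits (default 0.3).
#' @return List with `report` (tibble sorted by MI descending, all records
#'   at least `min_bits`) and `raw` (all condition-motif records, including
#'   the best threshold per pair).
#' @export
mi_table <- function(features, motifs, min_bits = 0.3) {
  stopifnot(inherits(features, "feature_matrix"))
  idx <- match(features$glycan_id, rownames(motifs))
  if (anyNA(idx)) stop("feature rows with glycan ids missing from motif matrix")
  M <- motifs[idx, , drop = FALSE]
  mi <- .mi_pairwise(features$bits, M)
  conds <- unique(features$schema$condition)
  rows <- vector("list", length(conds) * ncol(M))
  r <- 0L
  Hmot <- apply(M, 2, shannon_entropy)
  for (cond in conds) {
    jj <- which(features$schema$condition == cond)
    sub <- mi[jj, , drop = FALSE]
    best <- apply(sub, 2, which.max)
    for (k in seq_len(ncol(M))) {
      r <- r + 1L
      j <- jj[best[k]]
      rows[[r]] <- tibble::tibble(
        condition = cond,
        reagent = features$schema$reagent[j],
        concentration = features$schema$concentration[j],
        threshold = features$schema$threshold[j],
        motif_id = colnames(M)[k],
        mi_bits = sub[best[k], k],
        h_lectin = shannon_entropy(features$bits[, j]),
        h_motif = Hmot[k])
    }
  }
  raw <- do.call(rbind, rows)
  raw <- raw[order(-raw$mi_bits, raw$condition, raw$motif_id, method = "radix"), ]
  list(report = raw[raw$mi_bits >= min_bits, , drop = FALSE], raw = raw)
}

#' Primary-motif information fraction for a lectin
#'
#' Greedily selects motifs maximizing the joint mutual information with the
#' lectin signal, stopping when the gain drops below `eps` bits or the set
#' reaches `max_motifs`. The primary motif is the first selected; the
#' fraction is `I(lectin : primary) / I(lectin : selected set)`.
#'
#' @param lectin Binary vector of the lectin's binding events.
#' @param motifs Binary motif matrix, rows aligned with `lectin`.
#' @param eps Minimum MI gain in bits to continue (default 0.01).
#' @param max_motifs Size cap on the greedy set (default 4).
#' @return List with `fraction` (`NA` if the lectin carries no motif
#'   information), `primary` (motif column name), `selected`, `mi_primary`
#'   and `mi_total` (bits).
#' @export
primary_information_fraction <- function(lectin, motifs, eps = 0.01,
                                         max_motifs = 4L) {
  stopifnot(length(lectin) == nrow(motifs))
  cols <- colnames(motifs)
  selected <- integer(0)
  joint <- rep("", length(lectin))
  mi_total <- 0
  mi_primary <- NA_real_
  repeat {
    remaining <- setdiff(seq_len(ncol(motifs)), selected)
    if (!length(remaining) || length(selected) >= max_motifs) break
    gains <- vapply(remaining, function(k) {
      mutual_information(lectin, paste(joint, motifs[, k], sep = "\r"))
    }, numeric(1))
    best <- remaining[which.max(gains)]
    gain <- max(gains) - mi_total
    if (length(selected) == 0L) {
      if (max(gains) <= 0) break
      mi_primary <- max(gains)
    } else if (gain < eps) {
      break
    }
    selected <- c(selected, best)
    joint <- paste(joint, motifs[, best], sep = "\r")
    mi_total <- max(gains)
  }
  if (!length(selected)) {
    return(list(fraction = NA_real_, primary = NA_character_,
                selected = character(0), mi_primary = NA_real_, mi_total = 0))
  }
  list(fraction = mi_primary / mi_total,
       primary = cols[selected[1]],
       selected = cols[selected],
       mi_primary = mi_primary, mi_total = mi_total)
}

# logistic cross-entropy in bits for predicted probabilities p
.xent_bits <- function(m, p) {
  p <- pmin(pmax(p, 1e-300), 1 - 1e-15)
  val <- -(sum(log2(p[m == 1])) + sum(log2(1 - p[m == 0]))) / length(m)
  # exact 0 * log 0 handling: cells where p was exactly 0/1 and correct
  val
}

#' First- versus second-order cross-entropy comparison for one motif
#'
#' Fits nested predictors of motif presence from two lectin binding
#' binaries: a zeroth-order constant, a first-order additive logistic model
#' in `l1` and `l2`, and a second-order model with the `l1*l2` interaction.
#' With two binary inputs the second-order model is saturated, so its
#' optimum is the per-cell empirical motif frequency (closed form); the
#' first-order model is fit by logistic regression. Losses are logistic
#' cross-entropies in bits; `dH1 = H - J(p1)` and `dH2 = H - J(p2)` measure
#' the information each model extracts about the motif.
#'
#' @param motif Binary vector of motif presence.
#' @param l1,l2 Binary lectin vectors. If `NULL`, chosen as the two most
#'   predictive single features from `features` (ties by feature name).
#' @param features Optional binary feature matrix used to pick `l1`, `l2`.
#' @return List with `H` (motif entropy, bits), losses `J0`, `J1`, `J2`,
#'   information gains `dH1`, `dH2`, the fitted cell probabilities `p2_cells`
#'   and the first-order coefficients (logit scale).
#' @export
order_comparison <- function(motif, l1 = NULL, l2 = NULL, features = NULL) {
  motif <- as.integer(motif)
  if (is.null(l1) || is.null(l2)) {
    stopifnot(!is.null(features))
    mi <- .mi_pairwise(as.matrix(features), matrix(motif, ncol = 1))[, 1]
    nm <- colnames(features)
    ord <- order(-mi, nm, method = "radix")
    l1 <- features[, ord[1]]; l2 <- features[, ord[2]]
  }
  stopifnot(length(l1) == length(motif), length(l2) == length(motif))
  H <- shannon_entropy(motif)
  if (H == 0 || length(unique(l1)) + length(unique(l2)) == 2L) {
    return(list(H = H, J0 = H, J1 = H, J2 = H, dH1 = 0, dH2 = 0,
                p2_cells = NULL, coef1 = NULL))
  }
  # zeroth order: optimal constant is the motif frequency; J0 = H exactly
  J0 <- H
  # first order: additive logistic fit
  fit1 <- suppressWarnings(stats::glm(motif ~ l1 + l2,
                                      family = stats::binomial()))
  J1 <- .xent_bits(motif, stats::fitted(fit1))
  # second order: saturated in (l1, l2); MLE is the empirical frequency of
  # the motif within each of the four cells
  cell <- factor(paste0(l1, l2), levels = c("00", "01", "10", "11"))
  freq <- tapply(motif, cell, mean)
  p2 <- freq[as.character(paste0(l1, l2))]
  m1 <- motif == 1
  J2 <- -(sum(.safe_log2(p2[m1])) + sum(.safe_log2(1 - p2[!m1]))) / length(motif)
  list(H = H, J0 = J0, J1 = min(J1, J0), J2 = min(J2, J1, J0),
       dH1 = max(H - J1, 0), dH2 = max(H - min(J2, J1), 0),
       p2_cells = freq, coef1 = stats::coef(fit1))
}

# log2 with the convention that contributions from p = 1 are 0 and
# observed outcomes never have fitted p = 0 in the saturated model
.safe_log2 <- function(p) {
  p <- pmax(p, 1e-300)
  log2(p)
}
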