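# Lectin binding tables and their binarization into threshold features.
#
# A binding table is a tibble with columns `glycan_id`, `spacer_id` and one
# numeric RFU column per condition, conditions named "reagent@concentration".
# Binarization turns each condition into a ladder of binary features, one
# per log-spaced RFU threshold; the bit is 1 iff the signal strictly
# exceeds the threshold.

#' Read and validate a lectin binding table
#'
#' CSV/TSV with a header row; first columns `glycan_id` and `spacer_id`,
#' remaining columns are RFU measurements per condition. RFU must be
#' non-negative finite numbers; missing cells are treated as 0 RFU with a
#' warning. Duplicated (glycan, spacer) rows are an error.
#'
#' @param path File path (or a data frame, validated in place).
#' @param corpus Optional corpus tibble; unknown glycan ids are reported as
#'   a warning.
#' @param sep Field separator; default `","` (use `"\t"` for TSV).
#' @return A validated binding table tibble.
#' @export
read_binding_table <- function(path, corpus = NULL, sep = ",") {
  df <- if (is.data.frame(path)) {
    as.data.frame(path)
  } else {
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  if (!all(c("glycan_id", "spacer_id") %in% names(df))) {
    stop("binding table must have glycan_id and spacer_id columns")
  }
  cond <- setdiff(names(df), c("glycan_id", "spacer_id"))
  if (!length(cond)) stop("binding table has no condition columns")
  key <- paste(df$glycan_id, df$spacer_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (glycan_id, spacer_id) rows: ",
         paste(unique(df$glycan_id[duplicated(key)]), collapse = ", "))
  }
  for (cn in cond) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric RFU in column \"%s\", row %d", cn, bad[1]))
      }
      v <- suppressWarnings(as.numeric(v))
    }
    if (anyNA(v)) {
      warning(sprintf("missing RFU in column \"%s\" treated as 0", cn))
      v[is.na(v)] <- 0
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      bad <- which(!is.finite(v) | v < 0)[1]
      stop(sprintf("negative or non-finite RFU in column \"%s\", row %d (value %s)",
                   cn, bad, format(v[bad])))
    }
    df[[cn]] <- v
  }
  if (!is.null(corpus)) {
    unknown <- setdiff(unique(df$glycan_id), corpus$glycan_id)
    if (length(unknown)) {
      warning("binding table glycan ids not in corpus: ",
              paste(utils::head(unknown, 5), collapse = ", "),
              if (length(unknown) > 5) ", ..." else "")
    }
  }
  tibble::as_tibble(df)
}

#' Remove rows presented on excluded spacers
#'
#' Spacer 14 is known to collapse O-glycans on the array and is excluded in
#' O-glycan evaluations.
#'
#' @param table A binding table tibble.
#' @param excluded Character vector of spacer ids to drop (e.g. `"Sp14"`).
#' @return The filtered table; warns if it becomes empty.
#' @export
filter_spacers <- function(table, excluded = character(0)) {
  out <- table[!(table$spacer_id %in% excluded), , drop = FALSE]
  if (!nrow(out) && nrow(table)) warning("all rows removed by spacer filter")
  out
}

#' Log-spaced RFU binarization thresholds
#'
#' @param t_min,t_max Threshold range in RFU (defaults 1000 and 20000).
#' @param n_thresholds Number of thresholds (default 8).
#' @return Numeric vector of thresholds `t_min * (t_max/t_min)^(k/(n-1))`.
#' @export
binding_thresholds <- function(t_min = 1000, t_max = 20000, n_thresholds = 8L) {
  if (!(t_min > 0 && t_max > t_min && n_thresholds >= 1L)) {
    stop("invalid threshold parameters: need t_min > 0, t_max > t_min, n >= 1")
  }
  if (n_thresholds == 1L) return(t_min)
  t_min * (t_max / t_min)^((seq_len(n_thresholds) - 1) / (n_thresholds - 1))
}

#' Binarize a binding table into threshold features
#'
#' Each condition column becomes `n_thresholds` binary features; feature
#' `(condition, t)` is 1 iff the RFU strictly exceeds `t`. Thresholds are
#' logarithmically spaced between `t_min` and `t_max`.
#'
#' @param table A binding table tibble.
#' @param t_min,t_max,n_thresholds See [binding_thresholds()].
#' @return A `feature_matrix` object: list with `bits` (observations x
#'   features 0/1 matrix), `schema` (tibble: `column`, `condition`,
#'   `reagent`, `concentration`, `threshold`), and the row identifiers
#'   `glycan_id`, `spacer_id`.
#' @export
binarize <- function(table, t_min = 1000, t_max = 20000, n_thresholds = 8L) {
  thr <- binding_thresholds(t_min, t_max, n_thresholds)
  cond <- setdiff(names(table), c("glycan_id", "spacer_id"))
  n <- nrow(table)
  bits <- matrix(0L, n, length(cond) * length(thr))
  cols <- character(ncol(bits))
  schema_cond <- character(ncol(bits)); schema_thr <- numeric(ncol(bits))
  j <- 0L
  for (cn in cond) {
    v <- table[[cn]]
    for (t in thr) {
      j <- j + 1L
      bits[, j] <- as.integer(v > t)
      cols[j] <- sprintf("%s>%.6g", cn, t)
      schema_cond[j] <- cn; schema_thr[j] <- t
    }
  }
  colnames(bits) <- cols
  reag <- sub("@.*$", "", schema_cond)
  conc <- ifelse(grepl("@", schema_cond), sub("^.*@", "", schema_cond), "")
  structure(list(bits = bits,
                 schema = tibble::tibble(column = cols, condition = schema_cond,
                                         reagent = reag, concentration = conc,
                                         threshold = schema_thr),
                 glycan_id = table$glycan_id,
                 spacer_id = table$spacer_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$bits), " observations x ", ncol(x$bits),
      " features (", length(unique(x$schema$condition)), " conditions x ",
      length(unique(x$schema$threshold)), " thresholds)\n", sep = "")
  invisible(x)
}

#' Write a feature matrix as CSV
#'
#' @param features A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  df <- data.frame(glycan_id = features$glycan_id,
                   spacer_id = features$spacer_id,
                   features$bits, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
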