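# Glycan trees in CFG-style IUPAC-condensed notation.
#
# A glycan is a rooted ordered labeled tree: the root is the reducing-end
# residue (rightmost in the condensed string), edges point toward the
# nonreducing end.  Internally a tree is a nested list of nodes with fields
# name / anomer / child_pos (anomeric carbon) / parent_pos (attachment
# position on the parent) / mods (e.g. "6S") / children.

#' Default residue alphabet
#'
#' The seven monosaccharide symbols used throughout: fucose, galactose,
#' N-acetylgalactosamine, glucose, N-acetylglucosamine, mannose and sialic
#' acid (collapsed to `Neu`).
#'
#' @return Character vector of residue names.
#' @export
residue_alphabet <- function() {
  c("Fuc", "Gal", "GalNAc", "Glc", "GlcNAc", "Man", "Neu")
}

#' Default residue name normalization map
#'
#' Sialic acid variants are collapsed to a single `Neu` symbol.
#'
#' @return Named character vector mapping raw names to normalized names.
#' @export
residue_name_map <- function() {
  c(Neu5Ac = "Neu", NeuAc = "Neu", Neu5Gc = "Neu", NeuGc = "Neu",
    NeuNAc = "Neu", Neu5ac = "Neu")
}

.new_node <- function(name, anomer = "?", child_pos = "?",
                      parent_pos = NA_character_, mods = "",
                      children = list()) {
  list(name = name, anomer = anomer, child_pos = child_pos,
       parent_pos = parent_pos, mods = mods, children = children)
}

# sort rank of a parent-attachment position: 1..9 numeric, "?" after, open
# slots ("X") last
.pos_rank <- function(pos) {
  ifelse(pos %in% as.character(1:9), as.integer(pos),
         ifelse(pos == "?", 10L, 11L))
}

.parse_error <- function(msg, span) {
  stop(sprintf("glycan parse error: %s (at \"%s\")", msg, span), call. = FALSE)
}

# strip trailing "(6S)"-style decoration; returns list(rest, mods)
.take_deco <- function(s) {
  m <- regexpr("\\(([0-9](,[0-9])?[SP])\\)$", s)
  if (m[1] > 0) {
    mods <- sub("^\\(|\\)$", "", regmatches(s, m))
    mods <- gsub("[()]", "", mods)
    list(rest = substr(s, 1, m[1] - 1L), mods = mods)
  } else {
    list(rest = s, mods = "")
  }
}

# trailing residue name, e.g. "Neu5Ac", "GlcNAc"
.take_name <- function(s) {
  m <- regexpr("[A-Za-z][A-Za-z0-9,]*$", s)
  if (m[1] < 0) .parse_error("expected residue name", s)
  nm <- regmatches(s, m)
  if (!grepl("^[A-Z]", nm)) .parse_error("residue name must be capitalized", s)
  list(rest = substr(s, 1, m[1] - 1L), name = nm)
}

.normalize_name <- function(name, name_map, strict, alphabet) {
  if (name %in% names(name_map)) name <- unname(name_map[[name]])
  if (strict && !(name %in% alphabet)) {
    .parse_error(sprintf("unknown residue \"%s\" (strict mode)", name), name)
  }
  name
}

# split trailing branch groups "(...)" off `s`, innermost-right first
.take_branches <- function(s) {
  branches <- character(0)
  while (endsWith(s, ")")) {
    depth <- 0L
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    open <- NA_integer_
    for (i in rev(seq_along(chars))) {
      if (chars[i] == ")") depth <- depth + 1L
      if (chars[i] == "(") {
        depth <- depth - 1L
        if (depth == 0L) { open <- i; break }
      }
    }
    if (is.na(open)) .parse_error("unbalanced parentheses", s)
    branches <- c(branches, substr(s, open + 1L, nchar(s) - 1L))
    s <- substr(s, 1, open - 1L)
  }
  list(rest = s, branches = branches)
}

# parse a child segment: chain ending in "<name><anomer><cpos>-<ppos>"
.parse_child <- function(s, ctx) {
  lm <- regexpr("([ab?])([0-9?]?)-([0-9?])$", s)
  if (lm[1] < 0) .parse_error("expected anomer/linkage", s)
  link <- regmatches(s, lm)
  anomer <- substr(link, 1, 1)
  body <- substr(link, 2, nchar(link))
  parts <- strsplit(body, "-", fixed = TRUE)[[1]]
  child_pos <- if (parts[1] == "") "?" else parts[1]
  parent_pos <- parts[2]
  s <- substr(s, 1, lm[1] - 1L)
  d <- .take_deco(s)
  n <- .take_name(d$rest)
  node <- .new_node(.normalize_name(n$name, ctx$name_map, ctx$strict, ctx$alphabet),
                    anomer = anomer, child_pos = child_pos,
                    parent_pos = parent_pos, mods = d$mods)
  .attach_children(n$rest, node, ctx)
}

# parse what is left of a residue token: branch groups then an inline chain
.attach_children <- function(rest, node, ctx) {
  b <- .take_branches(rest)
  kids <- list()
  if (nzchar(b$rest)) kids <- list(.parse_child(b$rest, ctx))
  for (br in b$branches) {
    if (!nzchar(br)) .parse_error("empty branch", rest)
    kids <- c(kids, list(.parse_child(br, ctx)))
  }
  node$children <- kids
  node
}

#' Parse an IUPAC-condensed glycan string
#'
#' Reducing end rightmost; branches parenthesized immediately left of their
#' attachment residue; `?` allowed for unknown anomers/positions; sulfation
#' and phosphorylation decorations such as `(6S)` are retained on the node
#' and can be removed with [strip_modifications()].
#'
#' @param text Glycan string, e.g. `"Neua2-6Galb1-4GlcNAc"`.
#' @param strict If `TRUE`, residues outside `alphabet` (after name
#'   normalization) raise an error; the default lenient mode passes them
#'   through so [filter_corpus()] can drop them.
#' @param alphabet Active residue alphabet (used only in strict mode).
#' @param name_map Named character vector of residue-name synonyms.
#' @return A canonical `glycan_tree` object.
#' @examples
#' g <- parse_iupac("Mana1-6(Mana1-3)Manb1-4GlcNAc")
#' glycan_string(g)
#' @export
parse_iupac <- function(text, strict = FALSE, alphabet = residue_alphabet(),
                        name_map = residue_name_map()) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s+", "", text)
  s <- gsub("–|—", "-", s)
  s <- gsub("α", "a", s)
  s <- gsub("β", "b", s)
  if (!nzchar(s)) .parse_error("empty glycan string", text)
  ctx <- list(strict = strict, alphabet = alphabet, name_map = name_map)
  d <- .take_deco(s)
  n <- .take_name(d$rest)
  root <- .new_node(.normalize_name(n$name, ctx$name_map, ctx$strict, ctx$alphabet),
                    mods = d$mods)
  root <- .attach_children(n$rest, root, ctx)
  canonicalize(.as_glycan(root))
}

.as_glycan <- function(node) {
  structure(node, class = "glycan_tree")
}

# residue token as written in condensed notation
.node_token <- function(node, as_root) {
  deco <- if (nzchar(node$mods)) paste0("(", node$mods, ")") else ""
  if (as_root) {
    paste0(node$name, deco)
  } else {
    paste0(node$name, deco, node$anomer, node$child_pos, "-", node$parent_pos)
  }
}

# canonical string of a subtree, `as_root` controlling the final token
.write_node <- function(node, as_root) {
  segs <- vapply(node$children, .write_node, character(1), as_root = FALSE)
  ranks <- vapply(node$children, function(ch) .pos_rank(ch$parent_pos), numeric(1))
  if (length(segs)) {
    ord <- order(ranks, segs, method = "radix")
    segs <- segs[ord]
    prefix <- paste0(segs[1],
                     paste0(vapply(segs[-1], function(s) paste0("(", s, ")"),
                                   character(1)), collapse = ""))
  } else {
    prefix <- ""
  }
  paste0(prefix, .node_token(node, as_root))
}

.sort_children <- function(node) {
  node$children <- lapply(node$children, .sort_children)
  if (length(node$children) > 1L) {
    segs <- vapply(node$children, .write_node, character(1), as_root = FALSE)
    ranks <- vapply(node$children, function(ch) .pos_rank(ch$parent_pos), numeric(1))
    node$children <- node$children[order(ranks, segs, method = "radix")]
  }
  node
}

#' Canonicalize a glycan tree
#'
#' Sorts sibling subtrees by (attachment position ascending, then canonical
#' substring), yielding one canonical string per isomorphism class.
#' Idempotent.
#'
#' @param g A `glycan_tree`.
#' @return The canonical `glycan_tree`, with its canonical string cached.
#' @export
canonicalize <- function(g) {
  stopifnot(inherits(g, "glycan_tree"))
  g2 <- .as_glycan(.sort_children(g))
  attr(g2, "string") <- .write_node(g2, as_root = TRUE)
  g2
}

#' Canonical string of a glycan tree
#'
#' @param g A `glycan_tree`.
#' @return IUPAC-condensed canonical string.
#' @export
glycan_string <- function(g) {
  s <- attr(g, "string")
  if (is.null(s)) s <- attr(canonicalize(g), "string")
  s
}

#' Number of residues in a glycan tree
#'
#' @param g A `glycan_tree`.
#' @return Integer node count.
#' @export
n_residues <- function(g) {
  count <- function(node) 1L + sum(vapply(node$children, count, integer(1)))
  count(g)
}

#' Residue names present in a glycan tree
#'
#' @param g A `glycan_tree`.
#' @return Character vector of node names in preorder.
#' @export
residue_names <- function(g) {
  walk <- function(node) c(node$name, unlist(lapply(node$children, walk)))
  walk(g)
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat("<glycan_tree> ", glycan_string(x), "  [", n_residues(x), " residues]\n",
      sep = "")
  invisible(x)
}

#' @export
format.glycan_tree <- function(x, ...) glycan_string(x)

#' Remove sulfation/phosphorylation decorations
#'
#' Drops per-residue modification annotations such as `(6S)`; the underlying
#' tree is unchanged.
#'
#' @param g A `glycan_tree`.
#' @return The undecorated canonical `glycan_tree`.
#' @export
strip_modifications <- function(g) {
  stopifnot(inherits(g, "glycan_tree"))
  strip <- function(node) {
    node$mods <- ""
    node$children <- lapply(node$children, strip)
    node
  }
  canonicalize(.as_glycan(strip(g)))
}

#' Build a glycan corpus from structure strings
#'
#' @param structures Character vector of IUPAC-condensed strings.
#' @param glycan_id Optional ids (default `G0001`, ...). Must be unique.
#' @param class Optional glycan class labels (e.g. `"N"`/`"O"`).
#' @param source Optional source tags.
#' @param ... Passed to [parse_iupac()].
#' @return Tibble with columns `glycan_id`, `structure` (canonical string),
#'   `class`, `source` and a list-column `tree` of parsed `glycan_tree`s.
#' @export
glycan_corpus <- function(structures, glycan_id = NULL, class = NA_character_,
                          source = NA_character_, ...) {
  n <- length(structures)
  if (is.null(glycan_id)) glycan_id <- sprintf("G%04d", seq_len(n))
  if (anyDuplicated(glycan_id)) stop("glycan_id values must be unique")
  trees <- lapply(structures, parse_iupac, ...)
  tibble::tibble(glycan_id = as.character(glycan_id),
                 structure = vapply(trees, glycan_string, character(1)),
                 class = rep_len(as.character(class), n),
                 source = rep_len(as.character(source), n),
                 tree = trees)
}

#' Filter a glycan corpus by alphabet and minimum size
#'
#' Retains only glycans whose residues all lie in `alphabet` and whose node
#' count is at least `min_size` (default 2). Order is preserved; idempotent.
#'
#' @param corpus A corpus tibble from [glycan_corpus()].
#' @param alphabet Allowed residue names.
#' @param min_size Minimum residue count.
#' @return The filtered corpus.
#' @export
filter_corpus <- function(corpus, alphabet = residue_alphabet(), min_size = 2L) {
  keep <- vapply(corpus$tree, function(g) {
    all(residue_names(g) %in% alphabet) && n_residues(g) >= min_size
  }, logical(1))
  corpus[keep, , drop = FALSE]
}

#' Read a glycan list file
#'
#' Plain text, one IUPAC-condensed string per line, optional tab-separated
#' `glycan_id` first column; `#` comments and blank lines ignored.
#'
#' @param path File path.
#' @param ... Passed to [glycan_corpus()].
#' @return A corpus tibble.
#' @export
read_glycan_list <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  two <- all(lengths(parts) >= 2L)
  if (two) {
    glycan_corpus(vapply(parts, `[[`, character(1), 2L),
                  glycan_id = vapply(parts, `[[`, character(1), 1L), ...)
  } else {
    glycan_corpus(vapply(parts, `[[`, character(1), 1L), ...)
  }
}

#' Read a corpus CSV
#'
#' Expects columns `glycan_id`, `structure`, and optionally `class`, `source`.
#'
#' @param path File path.
#' @param ... Passed to [glycan_corpus()].
#' @return A corpus tibble.
#' @export
read_corpus_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("glycan_id", "structure") %in% names(df)))
  glycan_corpus(df$structure, glycan_id = df$glycan_id,
                class = if ("class" %in% names(df)) df$class else NA_character_,
                source = if ("source" %in% names(df)) df$source else NA_character_,
                ...)
}

#' Write a corpus CSV
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_csv <- function(corpus, path) {
  utils::write.csv(corpus[, c("glycan_id", "structure", "class", "source")],
                   path, row.names = FALSE)
  invisible(path)
}
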