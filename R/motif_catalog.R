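# Motif enumeration, matching and the binary motif matrix.
#
# A motif is a connected fragment of a glycan tree that also records, per
# node, the exact number of unspecified nonreducing substituents ("open
# child slots", written as "X-" tokens) and whether the fragment root
# continues toward the reducing end (written "-X").  Terminal motifs like
# "Galb1-4GlcNAcb1-X" and internal motifs like "X-Galb1-4GlcNAcb1-X" are
# therefore distinct identities.

# flatten a glycan tree into parallel vectors for fast traversal
.flatten <- function(g) {
  name <- character(0); anomer <- character(0); cpos <- character(0)
  ppos <- character(0); mods <- character(0); parent <- integer(0)
  children <- list()
  rec <- function(node, par) {
    i <- length(name) + 1L
    name[i] <<- node$name; anomer[i] <<- node$anomer
    cpos[i] <<- node$child_pos; ppos[i] <<- node$parent_pos
    mods[i] <<- node$mods; parent[i] <<- par
    children[[i]] <<- integer(0)
    if (!is.na(par)) children[[par]] <<- c(children[[par]], i)
    for (ch in node$children) rec(ch, i)
  }
  rec(g, NA_integer_)
  list(name = name, anomer = anomer, cpos = cpos, ppos = ppos, mods = mods,
       parent = parent, children = children, n = length(name))
}

.flat_child_tok <- function(flat, v) {
  deco <- if (nzchar(flat$mods[v])) paste0("(", flat$mods[v], ")") else ""
  paste0(flat$name[v], deco, flat$anomer[v], flat$cpos[v], "-", flat$ppos[v])
}

.flat_top_tok <- function(flat, v) {
  deco <- if (nzchar(flat$mods[v])) paste0("(", flat$mods[v], ")") else ""
  if (is.na(flat$parent[v])) {
    paste0(flat$name[v], deco)
  } else {
    # fragment root that continues toward the reducing end
    paste0(flat$name[v], deco, flat$anomer[v], flat$cpos[v], "-X")
  }
}

.join_segs <- function(segs, ranks) {
  if (!length(segs)) return("")
  ord <- order(ranks, segs, method = "radix")
  segs <- segs[ord]
  paste0(segs[1],
         paste0(vapply(segs[-1], function(s) paste0("(", s, ")"), character(1)),
                collapse = ""))
}

# all connected fragments rooted at each node, memoized; each fragment is
# list(size, child_str, top_str)
.fragments <- function(flat, max_size) {
  memo <- vector("list", flat$n)
  rec <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    kids <- flat$children[[v]]
    combos <- list(list(size = 1L, segs = character(0), ranks = numeric(0)))
    for (k in kids) {
      kf <- rec(k)
      rk <- .pos_rank(flat$ppos[k])
      extra <- list()
      for (cmb in combos) {
        for (f in kf) {
          if (cmb$size + f$size <= max_size) {
            extra[[length(extra) + 1L]] <-
              list(size = cmb$size + f$size,
                   segs = c(cmb$segs, f$child_str),
                   ranks = c(cmb$ranks, rk))
          }
        }
      }
      combos <- c(combos, extra)
    }
    n_kids <- length(kids)
    frags <- lapply(combos, function(cmb) {
      n_open <- n_kids - length(cmb$segs)
      segs <- c(cmb$segs, rep("X-", n_open))
      ranks <- c(cmb$ranks, rep(11, n_open))
      prefix <- .join_segs(segs, ranks)
      list(size = cmb$size,
           child_str = paste0(prefix, .flat_child_tok(flat, v)),
           top_str = paste0(prefix, .flat_top_tok(flat, v)))
    })
    memo[[v]] <<- frags
    frags
  }
  for (v in seq_len(flat$n)) rec(v)
  memo
}

#' Enumerate connected subtree motifs of a glycan
#'
#' Every connected node subset of size at most `max_size` yields one motif
#' occurrence, annotated with the exact open-slot counts inherited from the
#' host glycan and with whether the fragment root continues toward the
#' reducing end. Occurrences of the same motif are collapsed and counted.
#'
#' @param g A `glycan_tree`.
#' @param max_size Maximum motif size in residues (default 5).
#' @return Tibble with columns `motif` (canonical motif string), `size` and
#'   `count` (number of occurrences within `g`).
#' @export
enumerate_motifs <- function(g, max_size = 5L) {
  stopifnot(inherits(g, "glycan_tree"), max_size >= 1L)
  flat <- .flatten(canonicalize(g))
  memo <- .fragments(flat, max_size)
  strs <- unlist(lapply(memo, function(fr) vapply(fr, `[[`, character(1), "top_str")))
  sizes <- unlist(lapply(memo, function(fr) vapply(fr, `[[`, integer(1), "size")))
  agg <- tapply(rep(1L, length(strs)), strs, sum)
  sz <- sizes[match(names(agg), strs)]
  out <- tibble::tibble(motif = names(agg), size = as.integer(sz),
                        count = as.integer(agg))
  out[order(out$size, out$motif, method = "radix"), , drop = FALSE]
}

#' Parse a motif string
#'
#' Motif strings use the glycan condensed dialect extended with `X-` tokens
#' for open child slots and a `-X` suffix on the root for motifs that
#' continue toward the reducing end.
#'
#' @param text Motif string, e.g. `"X-Galb1-4GlcNAcb1-X"`.
#' @param ... Passed to the residue token parser (see [parse_iupac()]).
#' @return A `glycan_motif` object.
#' @export
parse_motif <- function(text, ...) {
  s <- gsub("\\s+", "", text)
  ctx <- list(strict = FALSE, alphabet = residue_alphabet(),
              name_map = residue_name_map())
  dots <- list(...)
  for (nm in intersect(names(dots), names(ctx))) ctx[[nm]] <- dots[[nm]]
  lm <- regexpr("([ab?])([0-9?]?)-X$", s)
  root_open <- lm[1] > 0
  parse_seg <- function(seg) {
    if (seg == "X") return("OPEN")
    .motif_parse_child(seg, ctx)
  }
  if (root_open) {
    anomer <- substr(regmatches(s, lm), 1, 1)
    cpos <- sub("^.", "", sub("-X$", "", regmatches(s, lm)))
    if (!nzchar(cpos)) cpos <- "?"
    s2 <- substr(s, 1, lm[1] - 1L)
    d <- .take_deco(s2)
    n <- .take_name(d$rest)
    root <- .new_node(.normalize_name(n$name, ctx$name_map, ctx$strict, ctx$alphabet),
                      anomer = anomer, child_pos = cpos, mods = d$mods)
    rest <- n$rest
  } else {
    d <- .take_deco(s)
    n <- .take_name(d$rest)
    root <- .new_node(.normalize_name(n$name, ctx$name_map, ctx$strict, ctx$alphabet),
                      mods = d$mods)
    rest <- n$rest
  }
  root <- .motif_attach_children(rest, root, ctx)
  .as_motif(root, root_open)
}

.motif_parse_child <- function(s, ctx) {
  if (s == "X-" || s == "X") return("OPEN")
  lm <- regexpr("([ab?])([0-9?]?)-([0-9?])$", s)
  if (lm[1] < 0) .parse_error("expected anomer/linkage in motif", s)
  link <- regmatches(s, lm)
  anomer <- substr(link, 1, 1)
  parts <- strsplit(substr(link, 2, nchar(link)), "-", fixed = TRUE)[[1]]
  child_pos <- if (parts[1] == "") "?" else parts[1]
  parent_pos <- parts[2]
  s <- substr(s, 1, lm[1] - 1L)
  d <- .take_deco(s)
  n <- .take_name(d$rest)
  node <- .new_node(.normalize_name(n$name, ctx$name_map, ctx$strict, ctx$alphabet),
                    anomer = anomer, child_pos = child_pos,
                    parent_pos = parent_pos, mods = d$mods)
  .motif_attach_children(n$rest, node, ctx)
}

.motif_attach_children <- function(rest, node, ctx) {
  b <- .take_branches(rest)
  segs <- character(0)
  if (nzchar(b$rest)) segs <- b$rest
  segs <- c(segs, b$branches)
  open <- 0L
  kids <- list()
  for (seg in segs) {
    # a bare "X-" segment is one open slot on this node; "X-" prefixes glued
    # to deeper content are consumed by the recursive right-to-left parse
    if (seg == "X-" || seg == "X") { open <- open + 1L; next }
    kids <- c(kids, list(.motif_parse_child(seg, ctx)))
  }
  node$children <- kids
  node$open <- open
  node
}

.as_motif <- function(node, root_open) {
  m <- structure(node, class = "glycan_motif")
  attr(m, "root_open") <- root_open
  attr(m, "string") <- .write_motif_node(m, root_open = root_open)
  attr(m, "size") <- {
    count <- function(nd) 1L + sum(vapply(nd$children, count, integer(1)))
    count(m)
  }
  m
}

.motif_child_str <- function(node) {
  segs <- vapply(node$children, .motif_child_str, character(1))
  ranks <- vapply(node$children, function(ch) .pos_rank(ch$parent_pos), numeric(1))
  open <- if (is.null(node$open)) 0L else node$open
  segs <- c(segs, rep("X-", open))
  ranks <- c(ranks, rep(11, open))
  prefix <- .join_segs(segs, ranks)
  deco <- if (nzchar(node$mods)) paste0("(", node$mods, ")") else ""
  paste0(prefix, node$name, deco, node$anomer, node$child_pos, "-", node$parent_pos)
}

.write_motif_node <- function(node, root_open) {
  segs <- vapply(node$children, .motif_child_str, character(1))
  ranks <- vapply(node$children, function(ch) .pos_rank(ch$parent_pos), numeric(1))
  open <- if (is.null(node$open)) 0L else node$open
  segs <- c(segs, rep("X-", open))
  ranks <- c(ranks, rep(11, open))
  prefix <- .join_segs(segs, ranks)
  deco <- if (nzchar(node$mods)) paste0("(", node$mods, ")") else ""
  tok <- if (root_open) {
    paste0(node$name, deco, node$anomer, node$child_pos, "-X")
  } else {
    paste0(node$name, deco)
  }
  paste0(prefix, tok)
}

#' Canonical string of a motif
#'
#' @param m A `glycan_motif`.
#' @return Motif string with `X-` open-slot markers.
#' @export
motif_string <- function(m) attr(m, "string")

#' Motif size in residues
#'
#' @param m A `glycan_motif`.
#' @return Integer residue count.
#' @export
motif_size <- function(m) attr(m, "size")

#' @export
print.glycan_motif <- function(x, ...) {
  cat("<glycan_motif> ", motif_string(x), "  [", motif_size(x), " residues]\n",
      sep = "")
  invisible(x)
}

#' Exact context-aware motif matching
#'
#' Tests whether `motif` occurs in `g`: an injection of motif nodes into
#' glycan nodes preserving labels, anomers and linkage positions, with each
#' matched glycan node's count of unmatched nonreducing substituents equal
#' to the motif node's open-slot count, and with the motif root's
#' reducing-side continuation present iff the motif is marked internal
#' (`-X`). Unknown symbols (`?`) match only `?`.
#'
#' @param g A `glycan_tree`.
#' @param motif A `glycan_motif` (or motif string, parsed on the fly).
#' @return Logical scalar.
#' @export
match_motif <- function(g, motif) {
  if (is.character(motif)) motif <- parse_motif(motif)
  stopifnot(inherits(g, "glycan_tree"), inherits(motif, "glycan_motif"))
  root_open <- attr(motif, "root_open")
  match_at <- function(gn, mn, g_is_root) {
    if (gn$name != mn$name || gn$mods != mn$mods) return(FALSE)
    open <- if (is.null(mn$open)) 0L else mn$open
    gk <- gn$children; mk <- mn$children
    if (length(gk) != length(mk) + open) return(FALSE)
    assign_kids(mk, gk)
  }
  kid_compatible <- function(gn, mn) {
    gn$name == mn$name && gn$mods == mn$mods && gn$anomer == mn$anomer &&
      gn$child_pos == mn$child_pos && gn$parent_pos == mn$parent_pos
  }
  assign_kids <- function(mk, gk) {
    if (!length(mk)) return(TRUE)
    m1 <- mk[[1]]
    for (i in seq_along(gk)) {
      if (kid_compatible(gk[[i]], m1) && match_at(gk[[i]], m1, FALSE) &&
          assign_kids(mk[-1], gk[-i])) return(TRUE)
    }
    FALSE
  }
  root_compatible <- function(gn, is_root) {
    if (root_open) {
      !is_root && gn$anomer == motif$anomer && gn$child_pos == motif$child_pos
    } else {
      is_root
    }
  }
  found <- FALSE
  visit <- function(gn, is_root) {
    if (found) return(invisible(NULL))
    if (root_compatible(gn, is_root) && match_at(gn, motif, is_root)) {
      found <<- TRUE
      return(invisible(NULL))
    }
    for (ch in gn$children) visit(ch, FALSE)
  }
  visit(canonicalize(g), TRUE)
  found
}

#' Build a motif catalog from a corpus
#'
#' Enumerates all connected subtree motifs of size at most `max_size` across
#' the corpus and keeps those present in at least `min_count` glycans
#' (default 6, i.e. occurring in more than 5 glycans). Counting is at the
#' glycan level (presence), matching the binary motif variables used
#' downstream.
#'
#' @param corpus A corpus tibble.
#' @param max_size Maximum motif size (default 5).
#' @param min_count Minimum number of glycans containing the motif.
#' @return Tibble with columns `motif_id`, `motif` (string), `size`,
#'   `count`, ordered by (size, string). Empty catalogs are allowed (with a
#'   warning).
#' @export
build_catalog <- function(corpus, max_size = 5L, min_count = 6L) {
  stopifnot(nrow(corpus) >= 1L)
  per <- lapply(corpus$tree, .motif_strings_cached, max_size = max_size)
  all_strs <- unlist(per)
  agg <- table(all_strs)
  keep <- names(agg)[agg >= min_count]
  if (!length(keep)) {
    warning("empty motif catalog: no motif present in >= ", min_count, " glycans")
    return(tibble::tibble(motif_id = character(0), motif = character(0),
                          size = integer(0), count = integer(0)))
  }
  sizes <- vapply(keep, function(s) motif_size(parse_motif(s)), integer(1))
  ord <- order(sizes, keep, method = "radix")
  keep <- keep[ord]; sizes <- sizes[ord]
  tibble::tibble(motif_id = sprintf("M%05d", seq_along(keep)),
                 motif = keep, size = as.integer(sizes),
                 count = as.integer(agg[keep]))
}

# memoised per-structure motif-string sets: enumeration depends only on
# the canonical structure and the size cap
.enum_cache <- new.env(parent = emptyenv())

.motif_strings_cached <- function(g, max_size) {
  key <- paste0(max_size, "|", glycan_string(g))
  hit <- .enum_cache[[key]]
  if (!is.null(hit)) return(hit)
  strs <- enumerate_motifs(g, max_size)$motif
  if (length(.enum_cache) > 50000L) rm(list = ls(.enum_cache), envir = .enum_cache)
  .enum_cache[[key]] <- strs
  strs
}

#' Binary motif matrix for a corpus
#'
#' Row `g`, column `i` is 1 iff catalog motif `i` occurs in glycan `g`.
#' Computed via exhaustive fragment enumeration per glycan, which is
#' equivalent to [match_motif()] for motifs within the enumeration size.
#'
#' @param corpus A corpus tibble.
#' @param catalog A catalog tibble from [build_catalog()].
#' @return Integer matrix (glycans x motifs) with `glycan_id` rownames and
#'   `motif_id` colnames.
#' @export
motif_matrix <- function(corpus, catalog) {
  max_size <- if (nrow(catalog)) max(catalog$size) else 1L
  M <- matrix(0L, nrow(corpus), nrow(catalog),
              dimnames = list(corpus$glycan_id, catalog$motif_id))
  if (!nrow(catalog)) return(M)
  for (i in seq_len(nrow(corpus))) {
    strs <- .motif_strings_cached(corpus$tree[[i]], max_size)
    M[i, ] <- as.integer(catalog$motif %in% strs)
  }
  M
}

#' Write a motif catalog CSV
#'
#' @param catalog Catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_csv <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' Read a motif catalog CSV
#'
#' @param path File path.
#' @return Catalog tibble.
#' @export
read_catalog_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df[, c("motif_id", "motif", "size", "count")])
}
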