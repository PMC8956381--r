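#' Load a haplogroup tree from a TSV export
#'
#' Reads the canonical 3-column tab-separated interchange format for a
#' Phylotree-style haplogroup tree: columns \code{haplogroup}, \code{parent}
#' and \code{variants} (space-separated Phylotree tokens defining the branch
#' relative to its parent), one row per node, header row required. The root
#' row has an empty \code{parent} field.
#'
#' @param path path to the tree TSV file.
#' @return An object of class \code{haplogroup_tree}: a list with
#'   \code{nodes} (character vector of names), \code{parent} (named character
#'   vector; \code{NA} for the root), \code{branch} (named list of branch
#'   variant token vectors), \code{root}, \code{children} (named list) and
#'   \code{depth} (named integer vector, root = 0).
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          na.strings = NULL)
  need <- c("haplogroup", "parent", "variants")
  if (!all(need %in% names(df)))
    stop("tree TSV must have columns: ", paste(need, collapse = ", "))
  build_tree(df$haplogroup, df$parent, df$variants)
}

build_tree <- function(name, parent, variants) {
  name <- trimws(name); parent <- trimws(parent)
  if (anyDuplicated(name))
    stop("duplicate haplogroup name: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  is_root <- !nzchar(parent) | is.na(parent)
  if (sum(is_root) != 1L)
    stop("tree must have exactly one root (found ", sum(is_root), ")")
  bad <- !is_root & !(parent %in% name)
  if (any(bad))
    stop("unknown parent '", parent[bad][1L], "' for haplogroup '",
         name[bad][1L], "'")
  branch <- lapply(seq_along(name), function(i) {
    toks <- strsplit(trimws(variants[i]), "[[:space:]]+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) return(character())
    tryCatch(canonical_tokens(toks),
             error = function(e) stop("row ", i, " (", name[i], "): ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(branch) <- name
  par <- ifelse(is_root, NA_character_, parent)
  names(par) <- name
  root <- name[is_root]
  ## depth by iterative resolution; failure to resolve a node => cycle
  depth <- stats::setNames(rep(NA_integer_, length(name)), name)
  depth[root] <- 0L
  repeat {
    todo <- is.na(depth) & !is.na(depth[par[names(depth)]])
    if (!any(todo)) break
    depth[todo] <- depth[par[names(depth)[todo]]] + 1L
  }
  if (anyNA(depth))
    stop("cycle detected involving: ",
         paste(utils::head(names(depth)[is.na(depth)], 5L), collapse = ", "))
  children <- split(name[!is_root], parent[!is_root])
  children <- children[order(names(children))]
  tree <- structure(list(nodes = name, parent = par, branch = branch,
                         root = root, children = children, depth = depth),
                    class = "haplogroup_tree")
  tree$profiles <- compute_profiles(tree)
  tree
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("Haplogroup tree: ", length(x$nodes), " nodes, root '", x$root,
      "', max depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Serialize a haplogroup tree to the interchange TSV
#'
#' Inverse of [load_tree()]; loading the written file yields an identical
#' tree.
#'
#' @param tree a \code{haplogroup_tree}.
#' @param path output path.
#' @export
save_tree <- function(tree, path) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  df <- data.frame(
    haplogroup = tree$nodes,
    parent = ifelse(is.na(tree$parent[tree$nodes]), "", tree$parent[tree$nodes]),
    variants = vapply(tree$branch[tree$nodes], paste, "", collapse = " "),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Root-to-node cumulative profiles for every node, with back-mutation
## cancellation and same-position overwrite, computed in one pass down the
## tree. Returns a named list of canonical token vectors.
compute_profiles <- function(tree) {
  profiles <- vector("list", length(tree$nodes))
  names(profiles) <- tree$nodes
  apply_branch <- function(state, tokens) {
    # state: named character (key -> token)
    if (length(tokens)) {
      v <- parse_variant(tokens)
      keys <- variant_keys(tokens)
      for (i in seq_along(tokens)) {
        if (v$back[i]) {
          state <- state[names(state) != keys[i]]
        } else {
          state[keys[i]] <- v$token[i]
        }
      }
    }
    state
  }
  walk <- function(node, state) {
    state <- apply_branch(state, tree$branch[[node]])
    profiles[[node]] <<- unname(state)
    for (ch in tree$children[[node]]) walk(ch, state)
  }
  walk(tree$root, stats::setNames(character(), character()))
  profiles
}

#' Cumulative variant profile of a haplogroup
#'
#' Accumulates branch-defining variants along the root-to-node path. A
#' back-mutation token (trailing \code{"!"}) removes the ancestral variant at
#' its position and is itself excluded; a later substitution at an
#' already-mutated position replaces the recorded derived state.
#'
#' @param tree a \code{haplogroup_tree}.
#' @param hg haplogroup name.
#' @return character vector of canonical variant tokens (unordered set).
#' @export
cumulative_profile <- function(tree, hg) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  if (!hg %in% tree$nodes) stop("unknown haplogroup: ", hg)
  tree$profiles[[hg]]
}

ancestors_of <- function(tree, hg) {
  # hg first, root last (inclusive)
  out <- character(tree$depth[hg] + 1L)
  i <- 1L
  while (!is.na(hg)) {
    out[i] <- hg
    hg <- tree$parent[[hg]]
    i <- i + 1L
  }
  out
}

#' Most recent common ancestor of a set of haplogroups
#'
#' @param tree a \code{haplogroup_tree}.
#' @param hgs non-empty character vector of haplogroup names.
#' @return the name of the deepest node ancestral to (or equal to) every
#'   input.
#' @export
mrca <- function(tree, hgs) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  hgs <- unique(hgs)
  if (length(hgs) == 0L) stop("mrca of an empty set is undefined")
  unknown <- setdiff(hgs, tree$nodes)
  if (length(unknown)) stop("unknown haplogroup: ", paste(unknown, collapse = ", "))
  common <- ancestors_of(tree, hgs[1L])
  for (h in hgs[-1L]) common <- intersect(common, ancestors_of(tree, h))
  common[which.max(tree$depth[common])]
}

## Numeric-aware ordering of haplogroup names: split into alternating
## alpha/numeric segments, compare numeric segments numerically (H2 < H10).
hg_order <- function(names) {
  if (length(names) == 0L) return(integer())
  parts <- lapply(names, function(n)
    regmatches(n, gregexpr("[0-9]+|[^0-9]+", n))[[1L]])
  width <- max(vapply(parts, length, 0L))
  keys <- vapply(parts, function(p) {
    p <- c(p, rep("", width - length(p)))
    paste(vapply(p, function(seg) {
      if (grepl("^[0-9]+$", seg)) sprintf("1%020d", as.integer(seg))
      else sprintf("0%-20s", seg)
    }, ""), collapse = "\x01")
  }, "")
  order(keys, names)
}

sort_hg <- function(names) names[hg_order(names)]

#' Descendants of a haplogroup at a fixed level
#'
#' Returns the descendants exactly \code{level} tree edges below \code{hg},
#' in natural haplogroup order (numeric segments compared numerically, so
#' \code{"H2"} sorts before \code{"H10"}). With \code{collapse_empty = TRUE},
#' structural pass-through nodes that define no variants are skipped when
#' counting levels, so their children surface at the same level — both
#' countings of "sub-haplogroup level" are exposed because curated trees
#' differ in whether such nodes are named ranks.
#'
#' @param tree a \code{haplogroup_tree}.
#' @param hg haplogroup name.
#' @param level positive integer depth below \code{hg}.
#' @param collapse_empty logical; skip variant-less nodes when levelling.
#' @return character vector of haplogroup names (possibly empty).
#' @export
sub_haplogroups <- function(tree, hg, level = 1L, collapse_empty = FALSE) {
  stopifnot(inherits(tree, "haplogroup_tree"), level >= 1L)
  if (!hg %in% tree$nodes) stop("unknown haplogroup: ", hg)
  frontier <- list(list(node = hg, lev = 0L))
  hits <- character()
  while (length(frontier)) {
    cur <- frontier[[1L]]; frontier <- frontier[-1L]
    for (ch in tree$children[[cur$node]]) {
      pass <- collapse_empty && length(tree$branch[[ch]]) == 0L
      lev <- if (pass) cur$lev else cur$lev + 1L
      if (!pass && lev == level) hits <- c(hits, ch)
      else if (lev < level) frontier <- c(frontier, list(list(node = ch, lev = lev)))
    }
  }
  sort_hg(hits)
}

#' Variants that discriminate between candidate haplogroups
#'
#' A variant discriminates a candidate set when it is present in at least one
#' but not all of the candidates' cumulative profiles; targeting such
#' positions with new amplicons splits the set.
#'
#' @param tree a \code{haplogroup_tree}.
#' @param candidates character vector of >= 2 haplogroup names.
#' @return named list mapping each discriminating variant token to the
#'   character vector of candidates whose profile carries it.
#' @export
discriminating_variants <- function(tree, candidates) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  candidates <- unique(candidates)
  if (length(candidates) < 2L) stop("need >= 2 candidate haplogroups")
  profs <- lapply(candidates, function(h) cumulative_profile(tree, h))
  names(profs) <- candidates
  all_tok <- unique(unlist(profs, use.names = FALSE))
  out <- list()
  for (tok in all_tok) {
    carriers <- candidates[vapply(profs, function(p) tok %in% p, TRUE)]
    if (length(carriers) > 0L && length(carriers) < length(candidates))
      out[[tok]] <- carriers
  }
  out
}

#' Reconstruct a haplogroup's reference sequence
#'
#' Applies the cumulative profile of \code{hg} to the reference:
#' substitutions replace the base (bare transition tokens use the
#' transition partner of the reference base), deletions remove bases, and
#' insertions are added after their anchor position in ordinal order. The
#' result carries a \code{coord_map} attribute mapping each 1-based reference
#' position to its 1-based position in the returned sequence (deleted
#' positions map to the preceding surviving base).
#'
#' @param tree a \code{haplogroup_tree}.
#' @param hg haplogroup name.
#' @param reference reference sequence as a single character string.
#' @return character string; attributes \code{coord_map} (integer vector) and
#'   \code{warnings} (character vector of skipped/odd applications).
#' @export
reference_sequence <- function(tree, hg, reference) {
  prof <- cumulative_profile(tree, hg)
  apply_profile(prof, reference)
}

apply_profile <- function(tokens, reference) {
  ref <- strsplit(toupper(reference), "")[[1L]]
  n <- length(ref)
  warns <- character()
  keep <- rep(TRUE, n)      # FALSE = deleted
  base <- ref               # substituted state
  ins <- vector("list", n)  # ins[[p]] = bases inserted after position p
  if (length(tokens)) {
    v <- parse_variant(tokens)
    if (any(v$position > n | v$position < 1L))
      stop("variant position out of range: ",
           paste(v$token[v$position > n | v$position < 1L], collapse = ", "))
    for (i in seq_len(nrow(v))) {
      p <- v$position[i]
      switch(v$kind[i],
        transition = {
          partner <- .TRANSITION_PARTNER[base[p]]
          if (is.na(partner)) {
            warns <- c(warns, paste0("no transition partner for '", base[p],
                                     "' at ", p, "; token ", v$token[i], " skipped"))
          } else base[p] <- partner
        },
        transversion = base[p] <- v$derived[i],
        deletion = {
          if (!keep[p])
            warns <- c(warns, paste0("position ", p, " already deleted (", v$token[i], ")"))
          keep[p] <- FALSE
        },
        insertion = {
          cur <- ins[[p]]
          idx <- v$ins_index[i]
          bs <- strsplit(v$derived[i], "")[[1L]]
          need <- idx + length(bs) - 1L
          if (is.null(cur)) cur <- character()
          if (need > length(cur)) cur <- c(cur, rep("", need - length(cur)))
          cur[idx:(idx + length(bs) - 1L)] <- bs
          ins[[p]] <- cur
        })
    }
  }
  pieces <- character(n)
  coord <- integer(n)
  at <- 0L
  for (p in seq_len(n)) {
    if (keep[p]) { at <- at + 1L; pieces[p] <- base[p] } else pieces[p] <- ""
    coord[p] <- max(at, 1L)
    if (!is.null(ins[[p]])) {
      add <- ins[[p]][nzchar(ins[[p]])]
      pieces[p] <- paste0(pieces[p], paste(add, collapse = ""))
      at <- at + length(add)
    }
  }
  structure(paste(pieces, collapse = ""), coord_map = coord, warnings = warns)
}
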