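#' Amplicon panel helpers
#'
#' An amplicon panel is a data.frame with columns \code{name},
#' \code{start}, \code{end} (1-based inclusive rCRS-frame coordinates) and
#' \code{class} (\code{"CR"} or \code{"coding"}). \code{default_cr_amplicons}
#' returns the four tiled control-region amplicons used for the first
#' tracking cycle; \code{tiling_panel} builds a coding-region panel of fixed
#' size amplicons tiling an interval.
#'
#' @return amplicon data.frame.
#' @export
default_cr_amplicons <- function() {
  data.frame(name = c("CR1", "CR2", "CR3", "CR4"),
             start = c(16024L, 16268L, 1L, 220L),
             end = c(16365L, 16569L, 285L, 576L),
             class = "CR", stringsAsFactors = FALSE)
}

#' @rdname default_cr_amplicons
#' @param from,to interval to tile.
#' @param size amplicon length.
#' @param step tiling step (default \code{size}, i.e. non-overlapping).
#' @param class region class label.
#' @export
tiling_panel <- function(from = 600L, to = 16000L, size = 400L, step = size,
                         class = "coding") {
  starts <- seq(from, to, by = step)
  ends <- pmin(starts + size - 1L, to)
  keep <- ends >= starts
  data.frame(name = sprintf("%s_%05d", class, starts[keep]),
             start = starts[keep], end = ends[keep], class = class,
             stringsAsFactors = FALSE)
}

#' Read / write an amplicon panel TSV
#'
#' @param path TSV with header columns name, start, end, class.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "integer",
                                               "integer", "character"))
  stopifnot(all(c("name", "start", "end", "class") %in% names(df)))
  df
}

#' @rdname read_panel
#' @param panel amplicon data.frame.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Narrow a classification to the haplogroups worth tracking
#'
#' Takes Rank Group 1 and, when some of its members are scored (score > 0),
#' prefers the scored subset — scored haplogroups have database support for
#' the sample's private variants. At most the top five scored haplogroups
#' are kept for differentiation. Returns the narrowed set together with its
#' most recent common ancestor.
#'
#' @param result an \code{hg_classification}.
#' @param tree a \code{haplogroup_tree}.
#' @param max_scored cap on scored candidates kept (default 5).
#' @return list with \code{candidates} (character vector, score-ordered) and
#'   \code{mrca}.
#' @export
narrow_candidates <- function(result, tree, max_scored = 5L) {
  stopifnot(inherits(result, "hg_classification"))
  rg1 <- result$rank_groups[[1L]]
  if (length(rg1) == 0L) stop("empty Rank Group 1")
  cand <- result$candidates
  rows <- cand[cand$rank_group == 1L, ]
  scored <- rows$haplogroup[rows$score > 0]
  picked <- if (length(scored)) utils::head(scored, max_scored) else rg1
  list(candidates = picked, mrca = mrca(tree, picked))
}

#' Propose amplicons that discriminate between candidate haplogroups
#'
#' Greedy minimum-amplicon cover: among panel amplicons overlapping
#' uncovered territory, repeatedly pick the one whose contained
#' discriminating variants split the candidate set into the most classes
#' (ties broken by panel order), until the candidates are fully separated or
#' no amplicon refines the partition further.
#'
#' @param candidates character vector of >= 2 haplogroup names.
#' @param tree a \code{haplogroup_tree}.
#' @param covered matrix of ranges already covered by the sample (variants
#'   at covered positions are already observed and excluded).
#' @param panel amplicon data.frame.
#' @return data.frame of proposed amplicons with a \code{variants} column
#'   (space-separated resolved tokens); attribute \code{"non_discriminable"}
#'   is \code{TRUE} when no panel amplicon separates the candidates at all.
#' @export
propose_targets <- function(candidates, tree, covered, panel) {
  stopifnot(length(candidates) >= 2L, nrow(panel) >= 1L)
  disc <- discriminating_variants(tree, candidates)
  if (length(disc)) {
    pos <- variant_positions(names(disc))
    uncovered <- !pos_in_ranges(pos, covered)
    disc <- disc[uncovered]; pos <- pos[uncovered]
  }
  empty <- panel[0L, ]; empty$variants <- character()
  if (length(disc) == 0L) {
    # nothing new to resolve: either already separable from covered data or
    # profiles identical over reachable positions
    sep_now <- length(unique(vapply(candidates, function(g)
      paste(sort(cumulative_profile(tree, g)), collapse = "|"), ""))) == length(candidates)
    attr(empty, "non_discriminable") <- !sep_now
    return(empty)
  }
  amp_vars <- lapply(seq_len(nrow(panel)), function(i)
    names(disc)[pos >= panel$start[i] & pos <= panel$end[i]])
  signature <- rep("", length(candidates)); names(signature) <- candidates
  n_classes <- function(sig) length(unique(sig))
  chosen <- integer()
  repeat {
    if (n_classes(signature) == length(candidates)) break
    best <- 0L; best_gain <- 0L
    for (i in seq_len(nrow(panel))) {
      if (i %in% chosen || length(amp_vars[[i]]) == 0L) next
      sig2 <- signature
      for (v in amp_vars[[i]])
        sig2 <- paste(sig2, ifelse(candidates %in% disc[[v]], v, "."), sep = ";")
      gain <- n_classes(sig2) - n_classes(signature)
      if (gain > best_gain) { best_gain <- gain; best <- i }
    }
    if (best == 0L) break
    for (v in amp_vars[[best]])
      signature <- paste(signature, ifelse(candidates %in% disc[[v]], v, "."), sep = ";")
    chosen <- c(chosen, best)
  }
  if (length(chosen) == 0L) {
    attr(empty, "non_discriminable") <- TRUE
    return(empty)
  }
  out <- panel[chosen, , drop = FALSE]
  out$variants <- vapply(chosen, function(i) paste(amp_vars[[i]], collapse = " "), "")
  rownames(out) <- NULL
  attr(out, "non_discriminable") <- FALSE
  out
}

#' Start a haplogroup tracking run
#'
#' @param sample a \code{sample_profile} (typically from the first,
#'   control-region, amplicon set).
#' @param tree a \code{haplogroup_tree}.
#' @param db a \code{haplotype_db} or \code{NULL}.
#' @param n_amplicons number of amplicons the initial profile came from
#'   (counted into the amplicon total).
#' @return object of class \code{tracking_state}: \code{profile},
#'   \code{track_index}, \code{candidates}, \code{mrca}, \code{history},
#'   \code{finished}, \code{stalled}, \code{final_hg},
#'   \code{amplicons_used}.
#' @export
start_tracking <- function(sample, tree, db = NULL, n_amplicons = 0L) {
  res <- classify(sample, tree, db)
  nar <- narrow_candidates(res, tree)
  state <- structure(list(profile = sample, tree_root = tree$root,
                          track_index = 1L, candidates = nar$candidates,
                          mrca = nar$mrca, history = list(), finished = FALSE,
                          stalled = FALSE, final_hg = NA_character_,
                          amplicons_used = n_amplicons),
                     class = "tracking_state")
  state$history[[1L]] <- list(track = 1L, candidates = nar$candidates,
                              amplicons = n_amplicons)
  finish_check(state, tree)
}

finish_check <- function(state, tree) {
  cands <- state$candidates
  profs <- vapply(cands, function(g)
    paste(sort(cumulative_profile(tree, g)), collapse = "|"), "")
  if (length(cands) == 1L || length(unique(profs)) == 1L) {
    state$finished <- TRUE
    state$final_hg <- cands[which.max(tree$depth[cands])]
  }
  state
}

#' @export
print.tracking_state <- function(x, ...) {
  status <- if (x$finished) paste0("finished -> ", x$final_hg)
            else if (x$stalled) "stalled" else "in progress"
  cat("Tracking '", x$profile$sample_id, "': track ", x$track_index, ", ",
      length(x$candidates), " candidate(s) {",
      paste(utils::head(x$candidates, 6L), collapse = ", "), "}, ",
      x$amplicons_used, " amplicon(s) used, ", status, "\n", sep = "")
  invisible(x)
}

#' One tracking cycle: fold new fragment evidence in and re-classify
#'
#' New fragments are variant-called, merged into the sample profile
#' (conflicting overlapping calls are an error), the merged profile is
#' re-classified and the candidate set re-narrowed. Tracking finishes when a
#' single haplogroup remains, or when the remaining candidates carry
#' identical cumulative profiles (the deepest is reported — the
#' MRCA-verification endpoint).
#'
#' @param state a \code{tracking_state} (not finished).
#' @param new_fragments named character vector of fragment sequences.
#' @param tree,db,reference as elsewhere.
#' @param n_amplicons how many amplicons the new fragments came from
#'   (defaults to the number of fragments).
#' @param params,mask,circular passed to [build_sample_profile()].
#' @return updated \code{tracking_state}.
#' @export
track_update <- function(state, new_fragments, tree, db, reference,
                         n_amplicons = length(new_fragments),
                         params = alignment_params(),
                         mask = default_hotspot_mask(), circular = TRUE) {
  stopifnot(inherits(state, "tracking_state"))
  if (state$finished) stop("tracking already finished (final: ", state$final_hg, ")")
  old <- state$profile
  if (length(new_fragments)) {
    add <- build_sample_profile(new_fragments, reference, params = params,
                                mask = mask, sample_id = old$sample_id,
                                circular = circular)
    calls <- c(old$fragment_calls, add$fragment_calls)
    if (length(old$fragment_calls) == 0L)
      calls <- c(list(list(id = "initial", variants = old$variants,
                           ranges = old$ranges)), add$fragment_calls)
    check_fragment_conflicts(calls)
    merged <- sample_profile(old$sample_id,
                             c(old$variants, add$variants),
                             rbind(old$ranges, add$ranges),
                             fragment_calls = calls)
  } else merged <- old
  res <- classify(merged, tree, db)
  nar <- narrow_candidates(res, tree)
  prev <- state$candidates
  state$profile <- merged
  state$track_index <- state$track_index + 1L
  state$candidates <- nar$candidates
  state$mrca <- nar$mrca
  state$amplicons_used <- state$amplicons_used + n_amplicons
  state$history[[length(state$history) + 1L]] <-
    list(track = state$track_index, candidates = nar$candidates,
         amplicons = n_amplicons)
  state <- finish_check(state, tree)
  if (!state$finished && setequal(prev, state$candidates) &&
      length(new_fragments) == 0L)
    state$stalled <- TRUE
  state
}

#' Simulate tracking a haplogroup with noise-free amplicons
#'
#' The in-silico minimum-amplicon experiment: fragments are cut from the
#' haplogroup's reconstructed reference sequence for the control-region
#' amplicons, classification and narrowing run as in the live loop, and
#' further coding amplicons are drawn via [propose_targets()] until tracking
#' finishes or stalls. Deterministic.
#'
#' @param true_hg the haplogroup whose reference sequence is typed.
#' @param tree,db,reference as elsewhere.
#' @param cr_amplicons first-track amplicon set (default
#'   [default_cr_amplicons()]).
#' @param coding_panel panel for subsequent tracks (default a 400 bp tiling
#'   of the coding region).
#' @param max_tracks safety cap on track cycles.
#' @param params,mask passed through.
#' @return list of class \code{tracking_outcome}: \code{true_hg},
#'   \code{final_hg}, \code{tracks_used}, \code{amplicons_used},
#'   \code{agreed} (final equals truth, or carries an identical cumulative
#'   profile), \code{stalled}.
#' @export
simulate_tracking <- function(true_hg, tree, db = NULL,
                              reference = load_reference(),
                              cr_amplicons = default_cr_amplicons(),
                              coding_panel = tiling_panel(),
                              max_tracks = 30L,
                              params = alignment_params(),
                              mask = default_hotspot_mask()) {
  if (!true_hg %in% tree$nodes) stop("unknown haplogroup: ", true_hg)
  mut <- reference_sequence(tree, true_hg, reference)
  frs <- cut_amplicons(mut, cr_amplicons)
  prof <- build_sample_profile(frs, reference, params = params, mask = mask,
                               sample_id = true_hg, circular = TRUE)
  state <- start_tracking(prof, tree, db, n_amplicons = nrow(cr_amplicons))
  while (!state$finished && !state$stalled && state$track_index < max_tracks) {
    prop <- propose_targets(state$candidates, tree, state$profile$ranges,
                            coding_panel)
    if (nrow(prop) == 0L) {
      state$stalled <- isTRUE(attr(prop, "non_discriminable"))
      if (!state$stalled) {
        # separable in principle but not by new amplicons; verify at MRCA
        state$finished <- TRUE
        state$final_hg <- state$mrca
      }
      break
    }
    frs <- cut_amplicons(mut, prop)
    state <- track_update(state, frs, tree, db, reference,
                          n_amplicons = nrow(prop), params = params,
                          mask = mask)
  }
  final <- if (!is.na(state$final_hg)) state$final_hg else state$mrca
  agreed <- identical(final, true_hg) ||
    setequal(cumulative_profile(tree, final), cumulative_profile(tree, true_hg))
  structure(list(true_hg = true_hg, final_hg = final,
                 tracks_used = state$track_index,
                 amplicons_used = state$amplicons_used,
                 agreed = agreed, stalled = state$stalled),
            class = "tracking_outcome")
}

#' @export
print.tracking_outcome <- function(x, ...) {
  cat("Tracking outcome: true ", x$true_hg, " -> final ", x$final_hg,
      " (", ifelse(x$agreed, "agreed", "disagreed"),
      if (x$stalled) ", stalled" else "", "); ",
      x$tracks_used, " track(s), ", x$amplicons_used, " amplicon(s)\n",
      sep = "")
  invisible(x)
}

## Cut amplicon subsequences out of a (possibly indel-shifted) mutated
## genome using its coord_map back to reference coordinates. Amplicons
## within the rCRS frame only; the CR wrap is handled by the circular
## aligner downstream.
cut_amplicons <- function(mutated, amplicons) {
  map <- attr(mutated, "coord_map")
  n <- nchar(mutated)
  out <- character(nrow(amplicons))
  for (i in seq_len(nrow(amplicons))) {
    a <- amplicons$start[i]; b <- amplicons$end[i]
    ai <- if (is.null(map)) a else map[a]
    bi <- if (is.null(map)) b else map[b]
    out[i] <- substr(mutated, max(1L, ai), min(n, bi))
  }
  stats::setNames(out, amplicons$name)
}

#' Run the in-silico simulation over many haplogroups
#'
#' @param tree a \code{haplogroup_tree}.
#' @param hgs haplogroups to simulate (default: all nodes except the root).
#' @param ... passed to [simulate_tracking()].
#' @return data.frame with one row per haplogroup: true_hg, final_hg,
#'   tracks_used, amplicons_used, agreed, stalled.
#' @export
simulate_all <- function(tree, hgs = setdiff(tree$nodes, tree$root), ...) {
  rows <- lapply(hgs, function(h) {
    o <- simulate_tracking(h, tree, ...)
    data.frame(true_hg = o$true_hg, final_hg = o$final_hg,
               tracks_used = o$tracks_used, amplicons_used = o$amplicons_used,
               agreed = o$agreed, stalled = o$stalled,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
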