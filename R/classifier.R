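#' Fragment-range-aware variant identity
#'
#' The ranking statistic for candidate haplogroups:
#' \deqn{identity = (Vp - Vm) / Vs}
#' where \eqn{Vp} is the number of the haplogroup's profile variants present
#' among the sample variants, \eqn{Vm} the number of its profile variants
#' that fall inside the sample's covered ranges but are absent from the
#' sample, and \eqn{Vs} the number of sample variants. Profile variants
#' outside every covered range are not penalised — the sample never had a
#' chance to observe them.
#'
#' @param sample a \code{sample_profile}.
#' @param profile character vector of the haplogroup's cumulative profile
#'   tokens.
#' @return list with \code{Vp}, \code{Vm}, \code{Vs}, \code{identity}
#'   (\code{NaN} when \code{Vs == 0}), \code{extras} and \code{missing}
#'   token vectors.
#' @export
variant_identity <- function(sample, profile) {
  stopifnot(inherits(sample, "sample_profile"))
  Vs <- sample$Vs
  present <- profile %in% sample$variants
  in_range <- if (length(profile))
    pos_in_ranges(variant_positions(profile), sample$ranges) else logical()
  Vp <- sum(present)
  Vm <- sum(in_range & !present)
  list(Vp = Vp, Vm = Vm, Vs = Vs,
       identity = if (Vs > 0L) (Vp - Vm) / Vs else NaN,
       extras = setdiff(sample$variants, profile),
       missing = profile[in_range & !present])
}

#' Private-variant frequency score
#'
#' Scores a candidate haplogroup by how often its private variants — the
#' sample's extra variants beyond the haplogroup profile, and the profile
#' variants the sample is missing — have been observed in haplotypes of that
#' haplogroup in the haplotype database:
#' \deqn{score = \sum_{v \in extras} He(g, v)/H(g) +
#'              \sum_{v \in missing} Hm(g, v)/H(g)}
#' Unseen (haplogroup, variant) pairs and haplogroups absent from the
#' database contribute 0. Higher scores mean the sample's private variants
#' are familiar for that haplogroup, i.e. more support.
#'
#' @param hg haplogroup name.
#' @param extras,missing character vectors of variant tokens.
#' @param db a \code{haplotype_db} (or \code{NULL} for the empty database).
#' @return numeric score (0 with an empty database).
#' @export
eq2_score <- function(hg, extras, missing, db = NULL) {
  if (is.null(db)) return(0)
  H <- db_lookup(db, hg, channel = "H")
  if (H == 0) return(0)
  he <- sum(vapply(extras, function(v) db_lookup(db, hg, v, "He"), 0))
  hm <- sum(vapply(missing, function(v) db_lookup(db, hg, v, "Hm"), 0))
  (he + hm) / H
}

#' Classify a sample into ranked haplogroup candidates
#'
#' Computes the variant identity of the sample against every haplogroup in
#' the tree, keeps the haplogroups attaining the top \code{max_groups}
#' distinct identity values as Rank Groups 1..\code{max_groups}, and orders
#' each group by the private-variant frequency score (descending), breaking
#' ties by database frequency \eqn{H(g)} (descending) and then natural
#' haplogroup order. Identity grouping is exact: with a fixed sample,
#' identities share the denominator \eqn{Vs}, so groups are formed on the
#' integer numerator \eqn{Vp - Vm}. Samples with no variants (\eqn{Vs = 0})
#' are ranked by ascending \eqn{Vm} with identity reported as \code{NaN}.
#'
#' @param sample a \code{sample_profile}.
#' @param tree a \code{haplogroup_tree}.
#' @param db a \code{haplotype_db} or \code{NULL}.
#' @param max_groups number of rank groups to retain (default 4).
#' @param qc run the artificial-recombination QC check (needs per-fragment
#'   calls in the profile).
#' @return object of class \code{hg_classification}: \code{sample_id},
#'   \code{candidates} (data.frame: haplogroup, rank_group, Vp, Vm, Vs,
#'   identity, score, H, extras, missing), \code{rank_groups} (list of
#'   character vectors), \code{n_dropped_groups} (identity values beyond
#'   \code{max_groups}), \code{qc_flags}.
#' @export
classify <- function(sample, tree, db = NULL, max_groups = 4L, qc = FALSE) {
  stopifnot(inherits(sample, "sample_profile"),
            inherits(tree, "haplogroup_tree"))
  if (NROW(sample$ranges) == 0L) stop("sample has empty covered ranges")
  nodes <- tree$nodes
  stats <- lapply(nodes, function(g)
    variant_identity(sample, tree$profiles[[g]]))
  names(stats) <- nodes
  if (sample$Vs > 0L) {
    key <- vapply(stats, function(s) s$Vp - s$Vm, 0L)      # identity numerator
    vals <- sort(unique(key), decreasing = TRUE)
  } else {
    key <- -vapply(stats, `[[`, 0L, "Vm")                  # rank by fewest Vm
    vals <- sort(unique(key), decreasing = TRUE)
  }
  n_groups <- min(max_groups, length(vals))
  rows <- list(); rank_groups <- vector("list", n_groups)
  for (gi in seq_len(n_groups)) {
    members <- nodes[key == vals[gi]]
    sc <- vapply(members, function(g)
      eq2_score(g, stats[[g]]$extras, stats[[g]]$missing, db), 0)
    Hg <- vapply(members, function(g)
      if (is.null(db)) 0 else db_lookup(db, g, channel = "H"), 0)
    ord <- order(-sc, -Hg, hg_order(members))
    members <- members[ord]; sc <- sc[ord]; Hg <- Hg[ord]
    rank_groups[[gi]] <- members
    for (k in seq_along(members)) {
      g <- members[k]; s <- stats[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        haplogroup = g, rank_group = gi, Vp = s$Vp, Vm = s$Vm, Vs = s$Vs,
        identity = s$identity, score = sc[k], H = Hg[k],
        extras = paste(s$extras, collapse = " "),
        missing = paste(s$missing, collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  res <- structure(list(sample_id = sample$sample_id,
                        candidates = do.call(rbind, rows),
                        rank_groups = rank_groups,
                        n_dropped_groups = length(vals) - n_groups,
                        qc_flags = list()),
                   class = "hg_classification")
  if (qc) res$qc_flags <- qc_recombination(sample, tree, res)
  res
}

#' @export
print.hg_classification <- function(x, n = 10L, ...) {
  cat("Haplogroup classification for '", x$sample_id, "'\n", sep = "")
  top <- x$candidates[seq_len(min(n, nrow(x$candidates))),
                      c("haplogroup", "rank_group", "Vp", "Vm", "Vs",
                        "identity", "score")]
  print(top, row.names = FALSE)
  if (x$n_dropped_groups > 0L)
    cat("(", x$n_dropped_groups, " lower identity value(s) not shown)\n", sep = "")
  if (length(x$qc_flags))
    cat("QC flags:", vapply(x$qc_flags, `[[`, "", "message"), sep = "\n  ")
  invisible(x)
}

#' @export
summary.hg_classification <- function(object, ...) {
  rg1 <- object$rank_groups[[1L]]
  cat("Sample '", object$sample_id, "': Rank Group 1 = {",
      paste(rg1, collapse = ", "), "}\n", sep = "")
  cat("Groups retained: ", length(object$rank_groups),
      "; candidates listed: ", nrow(object$candidates), "\n", sep = "")
  invisible(object)
}

#' @export
as.data.frame.hg_classification <- function(x, ...) x$candidates

#' Flag possible artificial recombination between fragments
#'
#' Classifies each fragment's variants independently and compares the clades
#' they support. The sample is flagged when the per-fragment best haplogroups
#' have a most recent common ancestor close to the root (depth below
#' \code{depth_threshold}) while the joint classification is deeper —
#' fragments pulling toward distant clades suggest a chimeric assembly.
#' Inapplicable (empty result) for samples with fewer than two fragments.
#'
#' @param sample a \code{sample_profile} with per-fragment calls.
#' @param tree a \code{haplogroup_tree}.
#' @param result the sample's \code{hg_classification}.
#' @param depth_threshold tree depth below which an MRCA counts as "near
#'   root" (default 2).
#' @return list of flag records (possibly empty), each with \code{message},
#'   \code{fragments}, \code{fragment_hgs}, \code{mrca}.
#' @export
qc_recombination <- function(sample, tree, result, depth_threshold = 2L) {
  calls <- sample$fragment_calls
  if (length(calls) < 2L) return(list())
  per_frag <- character()
  for (cl in calls) {
    if (length(cl$variants) == 0L) next
    prof <- sample_profile(cl$id, cl$variants, cl$ranges)
    r <- classify(prof, tree, db = NULL, max_groups = 1L)
    per_frag[cl$id] <- r$rank_groups[[1L]][1L]
  }
  if (length(per_frag) < 2L) return(list())
  m <- mrca(tree, unname(per_frag))
  joint <- result$rank_groups[[1L]][1L]
  if (tree$depth[m] < depth_threshold && tree$depth[joint] >= depth_threshold) {
    list(list(
      message = paste0("fragments support distant clades (MRCA '", m,
                       "' at depth ", tree$depth[m], "; joint call '", joint,
                       "' at depth ", tree$depth[joint], "): ",
                       paste(names(per_frag), per_frag, sep = "->",
                             collapse = ", ")),
      fragments = names(per_frag), fragment_hgs = unname(per_frag), mrca = m))
  } else list()
}
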