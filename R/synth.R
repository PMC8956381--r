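#' Generate a random toy haplogroup tree
#'
#' Builds a small haplogroup tree for testing and simulation. Every branch
#' carries substitution variants at positions unique across the whole tree,
#' so cumulative profiles are unique by construction — except for optional
#' control-region-ambiguous sibling pairs, whose two siblings differ only at
#' coding positions and therefore collide when typed from control-region
#' data alone (the multi-candidate scenario fragmented samples hit in
#' practice). The root is named \code{"mt-MRCA"} and carries an empty
#' profile. All randomness flows from \code{seed}.
#'
#' @param n_hg total number of nodes including the root (>= 2).
#' @param seed integer seed fixing the tree.
#' @param reference reference string (for picking valid transversion bases).
#' @param branch_variants integer vector to sample each branch's variant
#'   count from.
#' @param cr_frac probability a variant position is drawn from the control
#'   region rather than the coding region.
#' @param transversion_frac probability a variant is a transversion.
#' @param cr_ambiguous_pairs number of sibling pairs sharing their CR
#'   profile.
#' @return a \code{haplogroup_tree}; attribute \code{"truth"} holds a
#'   data.frame (haplogroup, parent, n_branch_variants, cr_ambiguous).
#' @export
generate_toy_tree <- function(n_hg = 20L, seed = 1L,
                              reference = load_reference(),
                              branch_variants = 1:3,
                              cr_frac = 0.6,
                              transversion_frac = 0.15,
                              cr_ambiguous_pairs = 0L) {
  stopifnot(n_hg >= 2L, cr_frac >= 0, cr_frac <= 1)
  with_seed(seed, {
    cr_pool <- setdiff(c(16050:16350, 30:290), c(263L))  # keep 263 free for doc examples
    coding_pool <- setdiff(600:15900, 3107L)
    used <- integer()
    ref_base <- function(p) substr(reference, p, p)
    draw_variant <- function(region) {
      pool <- if (region == "CR") cr_pool else coding_pool
      pool <- setdiff(pool, used)
      if (length(pool) == 0L) stop("variant position pool exhausted")
      p <- pool[sample.int(length(pool), 1L)]
      used <<- c(used, p)
      rb <- ref_base(p)
      if (stats::runif(1) < transversion_frac && rb %in% c("A", "C", "G", "T")) {
        other_class <- if (is_purine(rb)) c("C", "T") else c("A", "G")
        paste0(p, sample(other_class, 1L))
      } else as.character(p)
    }
    draw_branch <- function(n = NULL) {
      n <- n %||% sample(branch_variants, 1L)
      vapply(seq_len(n), function(i)
        draw_variant(if (stats::runif(1) < cr_frac) "CR" else "coding"), "")
    }
    name <- "mt-MRCA"; parent <- NA_character_; branch <- list(character())
    child_counter <- stats::setNames(0L, "mt-MRCA")
    next_name <- function(par) {
      child_counter[par] <<- (if (is.na(child_counter[par])) 0L else child_counter[par]) + 1L
      k <- child_counter[[par]]
      if (par == "mt-MRCA") LETTERS[k]
      else if (grepl("[0-9]$", par)) paste0(par, letters[k])
      else paste0(par, k)
    }
    n_ambig_nodes <- 2L * cr_ambiguous_pairs
    n_regular <- n_hg - 1L - n_ambig_nodes
    if (n_regular < 0L) stop("n_hg too small for requested ambiguous pairs")
    for (i in seq_len(n_regular)) {
      par <- name[sample.int(length(name), 1L)]
      nm <- next_name(par)
      name <- c(name, nm); parent <- c(parent, par)
      branch <- c(branch, list(draw_branch()))
    }
    ambig <- character()
    for (k in seq_len(cr_ambiguous_pairs)) {
      par <- name[sample.int(length(name), 1L)]
      shared_cr <- draw_variant("CR")   # same CR token on both branches:
      for (s in 1:2) {                  # identical CR profiles, distinct from parent
        nm <- next_name(par)
        name <- c(name, nm); parent <- c(parent, par)
        branch <- c(branch, list(c(shared_cr, draw_variant("coding"))))
        ambig <- c(ambig, nm)
      }
    }
    tree <- build_tree(name, ifelse(is.na(parent), "", parent),
                       vapply(branch, paste, "", collapse = " "))
    truth <- data.frame(haplogroup = name,
                        parent = ifelse(is.na(parent), "", parent),
                        n_branch_variants = vapply(branch, length, 0L),
                        cr_ambiguous = name %in% ambig,
                        stringsAsFactors = FALSE)
    attr(tree, "truth") <- truth
    tree
  })
}

#' Generate aDNA-style sequence fragments for a haplogroup
#'
#' Cuts fragments from the haplogroup's reconstructed genome, optionally
#' applying a synthetic terminal-deamination damage model: C->T near the 5'
#' end and G->A near the 3' end, with probability
#' \code{damage * exp(-(offset)/damage_scale)} at each terminal offset. This
#' emulates the length profile and end-damage signature of ancient DNA
#' amplicon data; it is a labelled synthetic stand-in, not a calibrated
#' damage model.
#'
#' @param tree a \code{haplogroup_tree}.
#' @param hg haplogroup to sample from.
#' @param reference reference string.
#' @param region \code{"CR"} (fragments drawn within the control region),
#'   \code{"genome"} (uniform over the genome) or \code{"tiling"}
#'   (deterministic full-genome tiling).
#' @param n_fragments number of fragments (ignored for tiling).
#' @param frag_len mean fragment length; \code{frag_sd} its spread.
#' @param damage terminal damage probability in [0, 1].
#' @param damage_scale exponential decay scale (bases) of the damage.
#' @param seed integer seed.
#' @return named character vector of fragment sequences; attribute
#'   \code{"truth"} records the source haplogroup and settings.
#' @export
generate_sample <- function(tree, hg, reference = load_reference(),
                            region = c("CR", "genome", "tiling"),
                            n_fragments = 4L, frag_len = 320L, frag_sd = 40L,
                            damage = 0, damage_scale = 3, seed = 1L) {
  region <- match.arg(region)
  if (!hg %in% tree$nodes) stop("unknown haplogroup: ", hg)
  mut <- reference_sequence(tree, hg, reference)
  map <- attr(mut, "coord_map")
  L <- nchar(reference)
  with_seed(seed, {
    windows <- if (region == "tiling") {
      step <- max(50L, frag_len - 50L)
      starts <- seq(1L, L, by = step)
      cbind(starts, pmin(starts + frag_len - 1L, L))
    } else {
      lens <- pmax(60L, round(stats::rnorm(n_fragments, frag_len, frag_sd)))
      starts <- integer(n_fragments)
      for (i in seq_len(n_fragments)) {
        if (region == "CR") {
          # circular CR treated as offsets into 16024..16569+1..576
          cr_len <- (16569L - 16024L + 1L) + 576L
          off <- sample.int(max(1L, cr_len - lens[i]), 1L)
          starts[i] <- 16024L + off - 1L
        } else {
          starts[i] <- sample.int(max(1L, L - lens[i]), 1L)
        }
      }
      cbind(starts, starts + lens - 1L)
    }
    frs <- character(nrow(windows))
    for (i in seq_len(nrow(windows))) {
      a <- windows[i, 1L]; b <- windows[i, 2L]
      if (a > L) { a <- a - L; b <- b - L }
      if (b <= L) {
        frs[i] <- substr(mut, map[a], map[b])
      } else {                                   # wraps the origin
        b2 <- b - L
        frs[i] <- paste0(substr(mut, map[a], nchar(mut)),
                         substr(mut, 1L, map[b2]))
      }
    }
    if (damage > 0) frs <- vapply(frs, damage_ends, "",
                                  rate = damage, scale = damage_scale)
    names(frs) <- sprintf("%s_frag%02d", hg, seq_along(frs))
    attr(frs, "truth") <- list(haplogroup = hg, region = region,
                               damage = damage, seed = seed)
    frs
  })
}

damage_ends <- function(seq, rate, scale) {
  b <- strsplit(seq, "")[[1L]]
  n <- length(b)
  k <- min(n, 15L)
  p5 <- rate * exp(-(seq_len(k) - 1L) / scale)
  hit5 <- stats::runif(k) < p5 & b[seq_len(k)] == "C"
  b[seq_len(k)][hit5] <- "T"
  tail_idx <- n - seq_len(k) + 1L
  hit3 <- stats::runif(k) < p5 & b[tail_idx] == "G"
  b[tail_idx][hit3] <- "A"
  paste(b, collapse = "")
}

#' Evaluate classification agreement against known truth
#'
#' Classifies each truth-labelled sample and reports where the true
#' haplogroup lands in the ranked candidate list: per-rank cumulative
#' agreement counts (the rank-agreement curve) and the top-1 agreement rate.
#' A candidate's rank is its row in the deterministic ranked candidate
#' table.
#'
#' @param profiles list of \code{sample_profile} objects.
#' @param truth character vector of true haplogroup names (recycled names of
#'   \code{profiles} if missing and stored in attributes).
#' @param tree a \code{haplogroup_tree}.
#' @param db a \code{haplotype_db} or \code{NULL}.
#' @param max_rank deepest rank reported in the curve.
#' @return list with \code{table} (data.frame rank, n_agree, cum_agree,
#'   cum_rate), \code{top1_rate}, \code{n}.
#' @export
evaluate_agreement <- function(profiles, truth, tree, db = NULL,
                               max_rank = 10L) {
  stopifnot(length(profiles) >= 1L, length(truth) == length(profiles))
  ranks <- integer(length(profiles))
  for (i in seq_along(profiles)) {
    res <- classify(profiles[[i]], tree, db)
    hit <- match(truth[i], res$candidates$haplogroup)
    ranks[i] <- if (is.na(hit)) NA_integer_ else hit
  }
  n_agree <- vapply(seq_len(max_rank), function(r)
    sum(!is.na(ranks) & ranks == r), 0L)
  cum <- cumsum(n_agree)
  list(table = data.frame(rank = seq_len(max_rank), n_agree = n_agree,
                          cum_agree = cum, cum_rate = cum / length(profiles)),
       top1_rate = mean(!is.na(ranks) & ranks == 1L),
       n = length(profiles))
}

#' Generate a synthetic sequence corpus for database construction
#'
#' Draws \code{per_hg} samples per haplogroup; each sample is one fragment
#' covering either the control region or the whole genome. With probability
#' \code{extra_rate} a sample carries one private extra variant (a
#' transition at a position untouched by the tree), so the haplotype
#' database records non-trivial He counts.
#'
#' @param tree a \code{haplogroup_tree}.
#' @param reference reference string.
#' @param per_hg samples per haplogroup.
#' @param full_frac fraction of samples that are full-genome.
#' @param extra_rate probability of one private extra variant per sample.
#' @param seed integer seed.
#' @return data.frame (\code{id}, \code{sequence}, \code{haplogroup}) with
#'   attribute \code{"extras"} recording injected private variants.
#' @export
generate_corpus <- function(tree, reference = load_reference(), per_hg = 2L,
                            full_frac = 0.5, extra_rate = 0.3, seed = 1L) {
  with_seed(seed, {
    tree_pos <- unique(variant_positions(unlist(tree$profiles, use.names = FALSE)))
    free_pool <- setdiff(c(16060:16340, 40:280, 700:15800),
                         c(tree_pos, 3107L, 16519L, 523L, 524L))
    rows <- list(); extras <- list()
    for (hg in setdiff(tree$nodes, tree$root)) {
      mut <- reference_sequence(tree, hg, reference)
      map <- attr(mut, "coord_map")
      for (k in seq_len(per_hg)) {
        id <- sprintf("%s_s%02d", hg, k)
        full <- stats::runif(1) < full_frac
        seq <- if (full) as.character(mut) else
          paste0(substr(mut, map[16024L], nchar(mut)), substr(mut, 1L, map[576L]))
        extra <- NA_character_
        if (stats::runif(1) < extra_rate) {
          # inject a private transition at a tree-free position inside the span
          pool <- if (full) free_pool else
            free_pool[in_control_region(free_pool)]
          p <- pool[sample.int(length(pool), 1L)]
          at <- if (full) map[p] else {
            if (p >= 16024L) map[p] - map[16024L] + 1L
            else (nchar(mut) - map[16024L] + 1L) + map[p]
          }
          rb <- substr(seq, at, at)
          partner <- .TRANSITION_PARTNER[rb]
          if (!is.na(partner)) {
            substr(seq, at, at) <- unname(partner)
            extra <- as.character(p)
          }
        }
        rows[[id]] <- data.frame(id = id, sequence = seq, haplogroup = hg,
                                 stringsAsFactors = FALSE)
        extras[[id]] <- extra
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "extras") <- extras
    out
  })
}
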