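#' An empty haplotype database
#'
#' @return object of class \code{haplotype_db} with zero counts. Fields:
#'   \code{H} (named count vector per haplogroup), \code{He} / \code{Hm}
#'   (named count vectors keyed \code{"<haplogroup>\t<variant>"}: samples of
#'   that haplogroup carrying the extra variant / lacking the profile
#'   variant), \code{meta}.
#' @export
empty_haplotype_db <- function() {
  structure(list(H = stats::setNames(numeric(), character()),
                 He = stats::setNames(numeric(), character()),
                 Hm = stats::setNames(numeric(), character()),
                 meta = list(version = 1L, corpus_size = 0L,
                             iterations = 0L, min_len = NA_integer_)),
            class = "haplotype_db")
}

#' @export
print.haplotype_db <- function(x, ...) {
  cat("Haplotype DB: ", sum(x$H), " classifications over ", length(x$H),
      " haplogroup(s); ", length(x$He), " extra-variant and ", length(x$Hm),
      " missing-variant entries (corpus n = ", x$meta$corpus_size,
      ", ", x$meta$iterations, " iteration(s))\n", sep = "")
  invisible(x)
}

db_key <- function(hg, variant) paste0(hg, "\t", variant)

#' Look up a haplotype-database count
#'
#' @param db a \code{haplotype_db}.
#' @param hg haplogroup name.
#' @param variant variant token (ignored for channel \code{"H"}).
#' @param channel one of \code{"H"}, \code{"He"}, \code{"Hm"}.
#' @return the stored count, or 0 for absent keys.
#' @export
db_lookup <- function(db, hg, variant = NULL, channel = c("H", "He", "Hm")) {
  channel <- match.arg(channel)
  tab <- db[[channel]]
  key <- if (channel == "H") hg else db_key(hg, variant)
  out <- tab[key]
  if (is.na(out)) 0 else unname(out)
}

#' Filter a sequence corpus before database construction
#'
#' Drops records shorter than \code{min_len} bases (too little information;
#' they attract too many haplogroup predictions). Identical sequences under
#' different ids are all retained as distinct samples.
#'
#' @param records data.frame with columns \code{id}, \code{sequence}.
#' @param min_len minimum retained length in bases (default 400, boundary
#'   inclusive).
#' @return the filtered data.frame.
#' @export
filter_corpus <- function(records, min_len = 400L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  records[nchar(records$sequence) >= min_len, , drop = FALSE]
}

#' Build the haplotype frequency database by iterative self-classification
#'
#' Each record of the corpus is aligned, variant-called and classified
#' against the tree. Iteration 1 classifies with an empty database (variant
#' identity only); each later iteration re-classifies with the database of
#' the previous pass, so the frequency scores it produces can re-order rank
#' groups and shift credit. After every pass, each sample credits every
#' haplogroup in its Rank Group 1 (all tied top-identity haplogroups count,
#' each with weight 1): \eqn{H(g)} += 1, \eqn{He(g,v)} += 1 per extra
#' variant, \eqn{Hm(g,v)} += 1 per missing variant. On a corpus whose
#' classifications are stable this reaches a fixed point after the second
#' pass.
#'
#' @param records corpus data.frame (\code{id}, \code{sequence}).
#' @param tree a \code{haplogroup_tree}.
#' @param reference reference sequence string.
#' @param iterations number of classification passes (default 3).
#' @param min_len corpus length filter (default 400).
#' @param params,mask,circular passed to [build_sample_profile()].
#' @param credit_groups how many rank groups to credit (default 1: the
#'   top-identity tie set).
#' @return a \code{haplotype_db}.
#' @export
build_db <- function(records, tree, reference, iterations = 3L,
                     min_len = 400L, params = alignment_params(),
                     mask = default_hotspot_mask(), circular = TRUE,
                     credit_groups = 1L) {
  stopifnot(iterations >= 1L, inherits(tree, "haplogroup_tree"))
  records <- filter_corpus(records, min_len)
  if (nrow(records) == 0L) stop("corpus empty after length filtering")
  profiles <- lapply(seq_len(nrow(records)), function(i)
    build_sample_profile(
      stats::setNames(records$sequence[i], records$id[i]),
      reference, params = params, mask = mask,
      sample_id = records$id[i], circular = circular))
  db <- empty_haplotype_db()
  for (it in seq_len(iterations)) {
    H <- new.env(parent = emptyenv())
    He <- new.env(parent = emptyenv())
    Hm <- new.env(parent = emptyenv())
    bump <- function(env, key) assign(key, (if (exists(key, env)) get(key, env) else 0) + 1, env)
    for (prof in profiles) {
      res <- classify(prof, tree, db = db, max_groups = max(1L, credit_groups))
      groups <- seq_len(min(credit_groups, length(res$rank_groups)))
      cand <- res$candidates
      for (gi in groups) for (g in res$rank_groups[[gi]]) {
        row <- cand[cand$haplogroup == g & cand$rank_group == gi, ]
        bump(H, g)
        for (v in strsplit(row$extras, " ", fixed = TRUE)[[1L]])
          if (nzchar(v)) bump(He, db_key(g, v))
        for (v in strsplit(row$missing, " ", fixed = TRUE)[[1L]])
          if (nzchar(v)) bump(Hm, db_key(g, v))
      }
    }
    db <- empty_haplotype_db()
    db$H <- unlist(as.list(H)); if (is.null(db$H)) db$H <- stats::setNames(numeric(), character())
    db$He <- unlist(as.list(He)); if (is.null(db$He)) db$He <- stats::setNames(numeric(), character())
    db$Hm <- unlist(as.list(Hm)); if (is.null(db$Hm)) db$Hm <- stats::setNames(numeric(), character())
    db$meta <- list(version = 1L, corpus_size = nrow(records),
                    iterations = it, min_len = min_len)
  }
  db
}

#' Save / load a haplotype database
#'
#' Serialized as a diff-able, language-neutral trio under one path stem:
#' \code{<stem>.h.tsv} (haplogroup, H), \code{<stem>.hem.tsv} (haplogroup,
#' variant, channel, count) and \code{<stem>.meta.json}.
#'
#' @param db a \code{haplotype_db}.
#' @param stem path stem (no extension).
#' @return \code{load_db} returns the \code{haplotype_db}; \code{save_db}
#'   returns \code{stem} invisibly.
#' @export
save_db <- function(db, stem) {
  stopifnot(inherits(db, "haplotype_db"))
  h <- data.frame(haplogroup = names(db$H), H = unname(db$H))
  h <- h[order(h$haplogroup), , drop = FALSE]
  utils::write.table(h, paste0(stem, ".h.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  split_keys <- function(tab, channel) {
    if (length(tab) == 0L)
      return(data.frame(haplogroup = character(), variant = character(),
                        channel = character(), count = numeric()))
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    data.frame(haplogroup = vapply(parts, `[`, "", 1L),
               variant = vapply(parts, `[`, "", 2L),
               channel = channel, count = unname(tab))
  }
  hem <- rbind(split_keys(db$He, "He"), split_keys(db$Hm, "Hm"))
  hem <- hem[order(hem$channel, hem$haplogroup, hem$variant), , drop = FALSE]
  utils::write.table(hem, paste0(stem, ".hem.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(db$meta, paste0(stem, ".meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname save_db
#' @export
load_db <- function(stem) {
  meta_path <- paste0(stem, ".meta.json")
  if (!file.exists(meta_path)) stop("no database at stem: ", stem)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$version) || meta$version != 1L)
    stop("unsupported haplotype DB schema version: ", meta$version)
  db <- empty_haplotype_db()
  h <- utils::read.delim(paste0(stem, ".h.tsv"), colClasses = c("character", "numeric"))
  if (nrow(h)) db$H <- stats::setNames(h$H, h$haplogroup)
  hem <- utils::read.delim(paste0(stem, ".hem.tsv"),
                           colClasses = c("character", "character", "character", "numeric"))
  if (nrow(hem)) {
    he <- hem[hem$channel == "He", ]
    hm <- hem[hem$channel == "Hm", ]
    if (nrow(he)) db$He <- stats::setNames(he$count, db_key(he$haplogroup, he$variant))
    if (nrow(hm)) db$Hm <- stats::setNames(hm$count, db_key(hm$haplogroup, hm$variant))
  }
  to_int <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NA_integer_)
    suppressWarnings(as.integer(x))
  }
  meta$corpus_size <- to_int(meta$corpus_size)
  meta$iterations <- to_int(meta$iterations)
  meta$min_len <- to_int(meta$min_len)
  meta$version <- to_int(meta$version)
  db$meta <- meta
  db
}
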