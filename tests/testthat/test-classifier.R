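test_that("variant identity reproduces the worked ratio cases", {
  # Vs = 4, Vp = 3, Vm = 1 -> (3 - 1)/4 = 0.5
  prof <- sample_profile("s", c("73", "152", "263", "750"), c(1L, 1000L))
  hgprof <- c("73", "152", "263", "489")          # 489 in range, missing
  vi <- variant_identity(prof, hgprof)
  expect_equal(vi$Vp, 3L); expect_equal(vi$Vm, 1L); expect_equal(vi$Vs, 4L)
  expect_equal(vi$identity, 0.5)
  expect_setequal(vi$extras, "750")
  expect_setequal(vi$missing, "489")

  # perfect match: Vp = Vs, Vm = 0 -> 1.0
  vi2 <- variant_identity(prof, c("73", "152", "263", "750"))
  expect_equal(vi2$identity, 1.0)

  # profile variant outside every covered range is not penalised
  hg3 <- c("73", "152", "263", "16290")           # 16290 outside [1,1000]
  vi3 <- variant_identity(prof, hg3)
  expect_equal(vi3$Vm, 0L)
  expect_equal(vi3$identity, 0.75)
  expect_length(vi3$missing, 0L)
})

test_that("frequency score reproduces the worked toy-database case", {
  db <- empty_haplotype_db()
  db$H <- c(g = 10)
  db$He <- stats::setNames(4, haplogrouper:::db_key("g", "16311"))
  expect_equal(eq2_score("g", extras = "16311", missing = character(), db), 0.4)
  expect_equal(eq2_score("g", character(), character(), db), 0)
  expect_equal(eq2_score("g", extras = "9999", missing = character(), db), 0)
  expect_equal(eq2_score("unseen", extras = "16311", missing = character(), db), 0)
  expect_equal(eq2_score("g", "16311", "73", NULL), 0)
  db$Hm <- stats::setNames(2, haplogrouper:::db_key("g", "73"))
  expect_equal(eq2_score("g", "16311", "73", db), 0.4 + 0.2)
})

test_that("self-recovery: every unique-profile haplogroup tops its own classification", {
  tree <- generate_toy_tree(n_hg = 20L, seed = 17L, reference = REF)
  for (hg in setdiff(tree$nodes, tree$root)) {
    prof <- sample_profile(hg, cumulative_profile(tree, hg), c(1L, 16569L))
    res <- classify(prof, tree)
    expect_equal(res$rank_groups[[1L]], hg)
    expect_equal(res$candidates$identity[1L], 1.0)
  }
})

test_that("rank groups hold tied identities, capped at four, deterministically ordered", {
  tree <- generate_toy_tree(n_hg = 14L, seed = 21L, reference = REF,
                            cr_ambiguous_pairs = 1L)
  truth <- attr(tree, "truth")
  pair <- truth$haplogroup[truth$cr_ambiguous]
  # CR-only observation of a pair member: both siblings tie in Rank Group 1
  cr_prof <- cumulative_profile(tree, pair[1L])
  cr_prof <- cr_prof[haplogrouper:::in_control_region(variant_positions(cr_prof))]
  prof <- sample_profile("cr", cr_prof,
                         rbind(c(16024L, 16569L), c(1L, 576L)))
  res <- classify(prof, tree)
  expect_true(all(pair %in% res$rank_groups[[1L]]))
  expect_lte(length(res$rank_groups), 4L)
  ids <- vapply(res$rank_groups, function(g)
    res$candidates$identity[match(g[1L], res$candidates$haplogroup)], 0)
  expect_true(all(diff(ids) < 0))                # strictly decreasing groups
  within <- res$candidates[res$candidates$rank_group == 1L, ]
  expect_true(all(diff(within$score) <= 0))      # score-ordered inside
  # determinism
  res2 <- classify(prof, tree)
  expect_identical(res$candidates, res2$candidates)
})

test_that("database scores break ties within a rank group", {
  tree <- make_tree(c("r", "p", "g1", "g2"),
                    c("", "r", "p", "p"),
                    c("", "73", "8701", "9540"))
  # sample looks like p plus a private extra at 16126; only g1 has DB support
  prof <- sample_profile("s", c("73", "16126"),
                         rbind(c(1L, 600L), c(16000L, 16569L)))
  db <- empty_haplotype_db()
  db$H <- c(g1 = 10, g2 = 10, p = 10)
  db$He <- stats::setNames(6, haplogrouper:::db_key("g1", "16126"))
  res <- classify(prof, tree, db)
  rg1 <- res$candidates[res$candidates$rank_group == 1L, ]
  # p, g1, g2 all tie on identity (coding splitters are out of range)
  expect_setequal(rg1$haplogroup, c("p", "g1", "g2"))
  expect_equal(rg1$haplogroup[1L], "g1")          # scored first
  expect_gt(rg1$score[1L], rg1$score[2L])
})

test_that("with an empty database ordering degenerates to name order within groups", {
  tree <- make_tree(c("r", "b", "a"), c("", "r", "r"), c("", "73", "73"))
  prof <- sample_profile("s", "73", c(1L, 1000L))
  res <- classify(prof, tree)
  expect_equal(res$rank_groups[[1L]], c("a", "b"))
  expect_true(all(res$candidates$score[res$candidates$rank_group == 1L] == 0))
})

test_that("adding an empty covered range can only keep or lower identity", {
  tree <- generate_toy_tree(n_hg = 15L, seed = 29L, reference = REF)
  prof_narrow <- sample_profile("s", character(0), c(16024L, 16365L))
  hgs <- setdiff(tree$nodes, tree$root)
  for (hg in hgs[1:8]) {
    p <- cumulative_profile(tree, hg)
    vi_narrow <- variant_identity(
      sample_profile("s", intersect(p, character(0)), c(16024L, 16365L)), p)
    vi_wide <- variant_identity(
      sample_profile("s", character(0), rbind(c(16024L, 16365L), c(600L, 16000L))), p)
    expect_gte(vi_wide$Vm, vi_narrow$Vm)
  }
})

test_that("variant-free samples rank by fewest in-range profile variants", {
  tree <- make_tree(c("r", "a", "b"), c("", "r", "r"), c("", "73", "73 152"))
  prof <- sample_profile("empty", character(0), c(1L, 1000L))
  res <- classify(prof, tree)
  expect_equal(res$rank_groups[[1L]], "r")        # zero in-range variants
  expect_equal(res$rank_groups[[2L]], "a")
  expect_true(is.nan(res$candidates$identity[1L]))
})

test_that("recombination QC flags fragments supporting distant clades", {
  tree <- generate_toy_tree(n_hg = 20L, seed = 31L, reference = REF)
  deep <- tree$nodes[tree$depth >= 2L]
  # two deep haplogroups in different root clades
  clade_of <- function(h) haplogrouper:::ancestors_of(tree, h)[tree$depth[haplogrouper:::ancestors_of(tree, h)] == 1L]
  picks <- c()
  for (h in deep) {
    if (length(picks) == 0L) picks <- h
    else if (clade_of(h) != clade_of(picks[1L])) { picks <- c(picks, h); break }
  }
  expect_length(picks, 2L)
  mk_frag_call <- function(hg, id) {
    p <- cumulative_profile(tree, hg)
    list(id = id, variants = p,
         ranges = haplogrouper:::merge_ranges(
           cbind(variant_positions(p) - 50L, variant_positions(p) + 50L)))
  }
  calls <- list(mk_frag_call(picks[1L], "f1"), mk_frag_call(picks[2L], "f2"))
  chimera <- sample_profile("chimera",
                            unlist(lapply(calls, `[[`, "variants")),
                            do.call(rbind, lapply(calls, `[[`, "ranges")),
                            fragment_calls = calls)
  res <- classify(chimera, tree)
  flags <- qc_recombination(chimera, tree, res)
  expect_gte(length(flags), 1L)
  expect_true(all(c("f1", "f2") %in% flags[[1L]]$fragments))

  # all fragments from one haplogroup: no flag
  same <- list(mk_frag_call(picks[1L], "f1"), mk_frag_call(picks[1L], "f2"))
  clean <- sample_profile("clean", same[[1L]]$variants, same[[1L]]$ranges,
                          fragment_calls = same)
  expect_length(qc_recombination(clean, tree, classify(clean, tree)), 0L)

  # single fragment: check inapplicable
  single <- sample_profile("one", same[[1L]]$variants, same[[1L]]$ranges,
                           fragment_calls = same[1L])
  expect_length(qc_recombination(single, tree, classify(single, tree)), 0L)
})
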