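## tree with a CR-ambiguous sibling pair: d1/d2 share CR variant 16120 and
## differ only at one coding position each (8000 / 9000)
pair_tree <- function() {
  make_tree(c("r", "m", "d1", "d2", "e"),
            c("", "r", "m", "m", "r"),
            c("", "16080 150", "16120 8000", "16120 9000", "16300"))
}

cr_profile_of <- function(tree, hg, id = hg) {
  p <- cumulative_profile(tree, hg)
  p <- p[haplogrouper:::in_control_region(variant_positions(p))]
  sample_profile(id, p, rbind(c(16024L, 16569L), c(1L, 576L)))
}

test_that("narrowing prefers scored candidates and caps at the top five", {
  tree <- generate_toy_tree(n_hg = 12L, seed = 2L, reference = REF)
  prof <- sample_profile("s", cumulative_profile(tree, tree$nodes[3L]),
                         c(1L, 16569L))
  res <- classify(prof, tree)
  nar <- narrow_candidates(res, tree)
  expect_equal(nar$candidates, res$rank_groups[[1L]])  # no scores: keep all
  expect_equal(nar$mrca, mrca(tree, nar$candidates))

  # fake a 9-way tie with 3 scored members -> the 3 scored survive
  fake <- res
  fake$rank_groups[[1L]] <- paste0("g", 1:9)
  fake$candidates <- data.frame(
    haplogroup = paste0("g", 1:9), rank_group = 1L, Vp = 1L, Vm = 0L, Vs = 1L,
    identity = 1, score = c(0.9, 0.5, 0.1, rep(0, 6L)), H = 0,
    extras = "", missing = "", stringsAsFactors = FALSE)
  tr9 <- make_tree(c("r", paste0("g", 1:9)), c("", rep("r", 9L)),
                   c("", as.character(16101:16109)))
  expect_equal(narrow_candidates(fake, tr9)$candidates, c("g1", "g2", "g3"))

  # 9 scored candidates -> top five by score
  fake$candidates$score <- seq(0.9, 0.1, by = -0.1)
  expect_equal(narrow_candidates(fake, tr9)$candidates, paste0("g", 1:5))
})

test_that("amplicon proposal makes the forced choice and flags dead ends", {
  tree <- pair_tree()
  covered <- rbind(c(16024L, 16569L), c(1L, 576L))
  panel <- data.frame(name = c("off", "hit"),
                      start = c(3000L, 7900L), end = c(3400L, 8300L),
                      class = "coding", stringsAsFactors = FALSE)
  prop <- propose_targets(c("d1", "d2"), tree, covered, panel)
  expect_equal(prop$name, "hit")                      # contains 8000
  expect_match(prop$variants, "8000")
  expect_false(attr(prop, "non_discriminable"))

  # candidates separable only at positions no amplicon covers
  panel_off <- panel[1L, , drop = FALSE]
  prop2 <- propose_targets(c("d1", "d2"), tree, covered, panel_off)
  expect_equal(nrow(prop2), 0L)
  expect_true(attr(prop2, "non_discriminable"))

  # already separable from covered data: nothing new needed
  tree2 <- make_tree(c("r", "x", "y"), c("", "r", "r"),
                     c("", "16100", "16200"))
  prop3 <- propose_targets(c("x", "y"), tree2, covered, panel)
  expect_equal(nrow(prop3), 0L)
  expect_false(attr(prop3, "non_discriminable"))
})

test_that("a greedy pick can split three candidates with one spanning amplicon", {
  tree <- make_tree(c("r", "p", "q1", "q2"),
                    c("", "r", "p", "p"),
                    c("", "16150", "7100", "7300"))
  panel <- rbind(
    data.frame(name = "narrow", start = 7000L, end = 7150L, class = "coding"),
    data.frame(name = "wide", start = 7050L, end = 7350L, class = "coding"))
  prop <- propose_targets(c("p", "q1", "q2"), tree,
                          rbind(c(16024L, 16569L)), panel)
  expect_equal(prop$name, "wide")                     # splits into 3 classes
})

test_that("tracking resolves a CR-ambiguous pair in two tracks with one amplicon", {
  tree <- pair_tree()
  mut <- reference_sequence(tree, "d1", REF)
  frs <- haplogrouper:::cut_amplicons(mut, default_cr_amplicons())
  prof <- build_sample_profile(frs, REF, sample_id = "d1")
  state <- start_tracking(prof, tree, n_amplicons = 4L)
  expect_false(state$finished)
  expect_setequal(state$candidates, c("d1", "d2"))

  prop <- propose_targets(state$candidates, tree, state$profile$ranges,
                          tiling_panel())
  expect_equal(nrow(prop), 1L)
  new_frs <- haplogrouper:::cut_amplicons(mut, prop)
  state <- track_update(state, new_frs, tree, NULL, REF, n_amplicons = nrow(prop))
  expect_true(state$finished)
  expect_equal(state$final_hg, "d1")
  expect_equal(state$track_index, 2L)
  expect_equal(state$amplicons_used, 5L)
  expect_error(track_update(state, new_frs, tree, NULL, REF), "finished")
})

test_that("fragments with no discriminating content leave candidates unchanged", {
  tree <- pair_tree()
  prof <- cr_profile_of(tree, "d1")
  state <- start_tracking(prof, tree, n_amplicons = 4L)
  before <- state$candidates
  dull <- stats::setNames(substr(REF, 3000L, 3400L), "dull")
  state2 <- track_update(state, dull, tree, NULL, REF)
  expect_setequal(state2$candidates, before)
  expect_equal(state2$track_index, state$track_index + 1L)
  expect_false(state2$finished)
})

test_that("simulation outcomes match the constructed scenarios", {
  tree <- pair_tree()
  # unique CR signature: one track, only the CR amplicons
  out_e <- simulate_tracking("e", tree, reference = REF)
  expect_true(out_e$agreed)
  expect_equal(out_e$tracks_used, 1L)
  expect_equal(out_e$amplicons_used, 4L)
  # CR-ambiguous sibling: two tracks, one extra coding amplicon
  out_d <- simulate_tracking("d1", tree, reference = REF)
  expect_true(out_d$agreed)
  expect_equal(out_d$tracks_used, 2L)
  expect_equal(out_d$amplicons_used, 5L)
  expect_false(out_d$stalled)
})

test_that("profile-identical candidates finish at the deepest candidate", {
  tree <- make_tree(c("r", "x", "y"), c("", "r", "x"),
                    c("", "16150 400", ""))          # y adds nothing
  out <- simulate_tracking("x", tree, reference = REF)
  expect_true(out$agreed)                            # profile-identical
  expect_equal(out$final_hg, "y")                    # deepest of the tie
})

test_that("an undiscriminable sibling stalls and is judged at the MRCA", {
  tree <- pair_tree()
  panel_off <- data.frame(name = "off", start = 3000L, end = 3400L,
                          class = "coding", stringsAsFactors = FALSE)
  out <- simulate_tracking("d1", tree, reference = REF, coding_panel = panel_off)
  expect_true(out$stalled)
  expect_false(out$agreed)                           # MRCA profile differs
  expect_equal(out$final_hg, "m")
})

test_that("amplicons used never increase when the panel gets denser", {
  tree <- generate_toy_tree(n_hg = 14L, seed = 37L, reference = REF,
                            cr_ambiguous_pairs = 2L)
  coarse <- tiling_panel(size = 800L)
  dense <- rbind(coarse, tiling_panel(size = 400L))
  for (hg in attr(tree, "truth")$haplogroup[attr(tree, "truth")$cr_ambiguous]) {
    a_coarse <- simulate_tracking(hg, tree, reference = REF,
                                  coding_panel = coarse)$amplicons_used
    a_dense <- simulate_tracking(hg, tree, reference = REF,
                                 coding_panel = dense)$amplicons_used
    expect_lte(a_dense, a_coarse)
  }
})

test_that("the per-haplogroup simulation table is deterministic", {
  tree <- pair_tree()
  t1 <- simulate_all(tree, reference = REF)
  t2 <- simulate_all(tree, reference = REF)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 4L)
  expect_true(all(t1$agreed))
})

test_that("panel TSV round trips", {
  panel <- default_cr_amplicons()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  expect_identical(read_panel(path), panel)
})
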