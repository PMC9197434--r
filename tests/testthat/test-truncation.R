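# deep fixture: root -> (A, B); A -> (a1, a2); B -> (b1, b2); with junction
# levels 1 (root end) and 2, so a protected_levels = 0/1 config is used to
# allow cutting in these small trees
shallow_cfg <- function(...) truncation_config(protected_levels = 0L, ...)

test_that("low-TPP pruning merges groups and labels them by group TPP", {
  # group TPP 0.5% <= 1% -> healthy
  tree <- four_outlet_tree()
  r <- prune_low_tpp(tree, tpp_map(c(0, 0.5, 50, 49.5)),
                     truncation_config(protected_levels = 1L))
  expect_equal(r$report$outlets_after, 3L)
  expect_equal(r$report$merged_groups[["1"]], c(1L, 2L))
  merged <- r$tree$branches[[as.character(outlet_branch_ids(r$tree)[["1"]])]]
  expect_equal(merged$tissue, "healthy")
  expect_equal(merged$tpp, 0.5)

  # group TPP 3.8% > 1% -> tumor
  r2 <- prune_low_tpp(tree, tpp_map(c(0.8, 3, 48, 48.2)),
                      truncation_config(protected_levels = 1L))
  merged2 <- r2$tree$branches[[as.character(outlet_branch_ids(r2$tree)[["1"]])]]
  expect_equal(merged2$tissue, "tumor")
  expect_equal(merged2$tpp, 3.8)

  # all outlets above threshold: tree unchanged
  r3 <- prune_low_tpp(tree, tpp_map(c(10, 20, 30, 40)), shallow_cfg())
  expect_equal(r3$report$outlets_after, 4L)
  expect_length(r3$report$merged_groups, 0L)

  # missing TPP errors
  expect_error(prune_low_tpp(tree, tpp_map(c(50, 50))), "missing TPP")
})

test_that("protected proximal levels and short cut space block pruning", {
  tree <- four_outlet_tree()
  # terminal junctions sit at level 2; protecting 2 levels blocks everything
  r <- prune_low_tpp(tree, tpp_map(c(0, 0.5, 0.2, 99.3)),
                     truncation_config(protected_levels = 2L))
  expect_equal(r$report$outlets_after, 4L)
  # junction branches shorter than the cut space are preserved
  tree_short <- four_outlet_tree(lens = c(20e-3, 1e-3, 8e-3))
  r2 <- prune_low_tpp(tree_short, tpp_map(c(0, 0.5, 50, 49.5)),
                      shallow_cfg(min_cut_space = 2e-3))
  expect_equal(r2$report$outlets_after, 4L)
  # same tree with enough cut space prunes
  r3 <- prune_low_tpp(tree_short, tpp_map(c(0, 0.5, 50, 49.5)),
                      shallow_cfg(min_cut_space = 0.5e-3))
  expect_equal(r3$report$outlets_after, 3L)
})

test_that("pruned short outlets are extruded to the extension target", {
  tree <- four_outlet_tree(lens = c(20e-3, 3e-3, 8e-3))
  r <- prune_low_tpp(tree, tpp_map(c(0, 0.5, 50, 49.5)),
                     shallow_cfg(min_cut_space = 2.5e-3))
  expect_equal(r$report$outlets_after, 3L)
  expect_equal(r$report$extended_outlets, 1L)
  b <- r$tree$branches[[as.character(outlet_branch_ids(r$tree)[["1"]])]]
  expect_equal(centerline_length(b), 20e-3, tolerance = 1e-9)
  expect_true(b$was_extended)
})

test_that("same-tissue junctions merge, mixed junctions are preserved", {
  tree <- four_outlet_tree()
  # a1, a2 healthy (0%); b1 tumor, b2 healthy -> only (a1, a2) merges
  tpp <- tpp_map(c(0, 0, 99, 1))
  s1 <- prune_low_tpp(tree, tpp, shallow_cfg())
  # step 1 merged (1, 2) as healthy and (3, 4) as tumor (4 is a trigger);
  # rerun with TPPs that leave step 1 idle on the mixed junction
  tpp2 <- tpp_map(c(0, 0, 90, 10))
  s1b <- prune_low_tpp(tree, tpp2, shallow_cfg())
  expect_equal(s1b$report$merged_groups, list(`1` = c(1L, 2L)))
  s2 <- merge_same_tissue(s1b$tree, tpp2, simple_bc(1:4, tpp = c(0, 0, 90, 10)),
                          shallow_cfg(), prior_report = s1b$report)
  # the tumor-tumor pair (3, 4) merges; merged (1) stays; mixed root junction
  # of a healthy leaf and a tumor leaf is never a same-tissue group
  expect_equal(s2$report$members[["3"]], c(3L, 4L))
  expect_equal(s2$report$outlets_after, 2L)
  lab <- s2$report$labels_assigned
  expect_equal(unname(lab[c("1", "3")]), c("healthy", "tumor"))
})

test_that("cascading merges collapse a uniform subtree over fixpoint passes", {
  # ((h,h),(h,h)) with a tumor branch elsewhere to keep TPP at 100%
  p1 <- c(20e-3, 0, 0)
  p2 <- p1 + 12e-3 * c(1, 1, 0) / sqrt(2)
  p3a <- p2 + 8e-3 * c(1, 2, 0) / sqrt(5)
  p3b <- p2 + 8e-3 * c(2, 1, 0) / sqrt(5)
  tree <- vessel_tree(list(
    straight_branch(1, NA, c(0, 0, 0), c(1, 0, 0), 20e-3, 5e-3),
    straight_branch(2, 1, p1, c(1, 1, 0), 12e-3, 4e-3),
    straight_branch(3, 1, p1, c(1, -1, 0), 12e-3, 4e-3, outlet_id = 5),
    straight_branch(4, 2, p2, c(1, 2, 0), 8e-3, 3e-3),
    straight_branch(5, 2, p2, c(2, 1, 0), 8e-3, 3e-3),
    straight_branch(6, 4, p3a, c(1, 3, 0), 6e-3, 2.5e-3, outlet_id = 1),
    straight_branch(7, 4, p3a, c(3, 1, 0), 6e-3, 2.5e-3, outlet_id = 2),
    straight_branch(8, 5, p3b, c(1, 0.5, 0), 6e-3, 2.5e-3, outlet_id = 3),
    straight_branch(9, 5, p3b, c(0.5, 1, 0), 6e-3, 2.5e-3, outlet_id = 4)),
    root = 1)
  tpp <- perfusion_map_from_tpp(
    setNames(c(0, 0, 0, 0, 100), 1:5), 310)
  cfg <- truncation_config(protected_levels = 1L)
  s1 <- prune_low_tpp(tree, tpp, cfg)
  s2 <- merge_same_tissue(s1$tree, tpp, NULL, cfg, prior_report = s1$report)
  # the healthy 4-leaf subtree collapses to a single healthy leaf
  expect_equal(s2$report$outlets_after, 2L)
  expect_equal(sort(s2$report$members[["1"]]), 1:4)
  expect_equal(unname(s2$report$labels_assigned[["1"]]), "healthy")
})

test_that("residual low-TPP outlets follow the tumor-flow majority rule", {
  # leaf 1 has TPP 0.9% and cannot be pruned: its sibling junction is mixed
  tree <- four_outlet_tree()
  tpp <- tpp_map(c(0.9, 59.1, 40, 0))
  s1 <- prune_low_tpp(tree, tpp, truncation_config(protected_levels = 2L))
  expect_equal(s1$report$outlets_after, 4L)  # everything protected
  # tumor flow share of outlet 1: qt / (qt + qh)
  bc_major <- simple_bc(1:4, qh = 0.5, tpp = c(0.9, 59.1, 40, 0))
  s2 <- merge_same_tissue(s1$tree, tpp, bc_major,
                          truncation_config(protected_levels = 2L),
                          prior_report = s1$report)
  qt1 <- 310 * 0.415 * 0.9 / 100
  expect_true(qt1 / (qt1 + 0.5) > 0.5)
  expect_equal(unname(s2$report$labels_assigned[["1"]]), "tumor")
  # with dominant healthy flow the same outlet is labeled healthy
  bc_minor <- simple_bc(1:4, qh = 30, tpp = c(0.9, 59.1, 40, 0))
  s3 <- merge_same_tissue(s1$tree, tpp, bc_minor,
                          truncation_config(protected_levels = 2L),
                          prior_report = s1$report)
  expect_equal(unname(s3$report$labels_assigned[["1"]]), "healthy")
  # without flow BCs the residual outlet cannot be labeled
  expect_error(merge_same_tissue(s1$tree, tpp, NULL,
                                 truncation_config(protected_levels = 2L),
                                 prior_report = s1$report),
               "boundary conditions required")
})

test_that("truncation conserves TPP, flow, and renumbers by lowest member", {
  set.seed(5)
  for (seed in c(2, 9)) {
    tree <- generate_synthetic_tree(synthetic_tree_spec(12, rng_seed = seed))
    raw <- runif(12)^3
    tppv <- 100 * raw / sum(raw)
    tpp <- perfusion_map_from_tpp(setNames(tppv, 1:12), 310)
    bc <- simple_bc(1:12, qh = 8, tpp = tppv)
    res <- truncate_tree(tree, tpp, bc, truncation_config(), level = 2L)
    leaves <- res$tree$branches[as.character(tree_leaves(res$tree))]
    # TPP conservation across all leaves
    expect_equal(sum(vapply(leaves, function(b) b$tpp, numeric(1))), 100,
                 tolerance = 1e-9)
    # flow conservation: merged-leaf flow equals the sum of member flows
    bc_tr <- truncated_bc(bc, res$report)
    expect_equal(bc_tr$total_inflow, bc$total_inflow, tolerance = 1e-9)
    for (o in names(res$report$members))
      expect_equal(bc_tr$Q_b[[o]],
                   sum(bc$Q_b[as.character(res$report$members[[o]])]),
                   tolerance = 1e-12)
    # renumbering: merged id is the lowest member id
    for (o in names(res$report$merged_groups))
      expect_equal(as.integer(o), min(res$report$merged_groups[[o]]))
    # outlet count is non-increasing and protected levels survive
    expect_lte(res$report$outlets_after, res$report$outlets_before)
    lev <- junction_levels(res$tree)
    expect_true(all(c(0L, 1L) %in% lev))
  }
})

test_that("both truncation steps are idempotent on their own output", {
  tree <- generate_synthetic_tree(synthetic_tree_spec(10, rng_seed = 4))
  set.seed(7)
  raw <- runif(10)^3
  tpp <- perfusion_map_from_tpp(setNames(100 * raw / sum(raw), 1:10), 310)
  bc <- simple_bc(1:10, qh = 8, tpp = 100 * raw / sum(raw))
  s1 <- prune_low_tpp(tree, tpp, truncation_config())
  lv <- s1$tree$branches[as.character(tree_leaves(s1$tree))]
  tpp_after <- perfusion_map_from_tpp(
    setNames(vapply(lv, function(b) b$tpp, numeric(1)),
             vapply(lv, function(b) b$outlet_id, integer(1))), 310)
  s1b <- prune_low_tpp(s1$tree, tpp_after, truncation_config())
  expect_equal(s1b$report$outlets_after, s1$report$outlets_after)
  s2 <- merge_same_tissue(s1$tree, tpp, bc, truncation_config(),
                          prior_report = s1$report)
  s2b <- merge_same_tissue(s2$tree, tpp, bc, truncation_config(),
                           prior_report = s2$report)
  expect_equal(s2b$report$outlets_after, s2$report$outlets_after)
  expect_length(s2b$report$merged_groups[
    lengths(s2b$report$merged_groups) > lengths(s2$report$merged_groups)], 0L)
})
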