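mk_act <- function(reg, tgt, r, type = NULL, active = NULL) {
  n <- length(reg)
  data.frame(regulator = reg, target = tgt,
             edge_type = type %||% rep("tf_gene", n),
             cell_type = "NPC", condition = "normal",
             r = r, active = active %||% (abs(r) > 0.8),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("growth respects the strict gate, depth cap and duplicates", {
  act <- mk_act(c("R", "R", "a", "b", "c", "d"),
                c("a", "b", "c", "d", "e", "e"),
                c(0.9, 0.85, -0.95, 0.80, 0.99, 0.97))
  cs <- grow_cascade("R", act, cascade_corr_cutoff = 0.8, max_layers = 3)
  # r = 0.80 fails the strict "higher than 0.8" gate: b joins, d does not
  expect_setequal(cs$nodes$id, c("R", "a", "b", "c", "e"))
  expect_equal(cs$nodes$layer[cs$nodes$id == "e"], 3)
  # negative correlations count through the absolute value
  expect_true("c" %in% cs$nodes$id)
  # depth cap: a 4th layer never appears
  act2 <- rbind(act, mk_act("e", "f", 0.99))
  cs2 <- grow_cascade("R", act2, max_layers = 3)
  expect_false("f" %in% cs2$nodes$id)
  expect_true("f" %in% grow_cascade("R", act2, max_layers = 4)$nodes$id)
  # no passing layer-1 edges: root-only cascade
  lone <- grow_cascade("R", mk_act("R", "a", 0.5))
  expect_equal(cascade_size(lone), 1)
  expect_equal(nrow(lone$edges), 0)
})

test_that("lncrna_gene edges are exempt from the correlation gate", {
  act <- mk_act(c("R", "L"), c("L", "g"), c(0.9, 0.1),
                type = c("tf_lncrna", "lncrna_gene"),
                active = c(TRUE, TRUE))
  cs <- grow_cascade("R", act)
  expect_setequal(cs$nodes$id, c("R", "L", "g"))
  # but an inactive (unexpressed) enhancer edge does not attach
  act$active[2] <- FALSE
  expect_setequal(grow_cascade("R", act)$nodes$id, c("R", "L"))
})

test_that("growth equals brute-force layered reachability on random nets", {
  set.seed(71)
  for (i in 1:50) {
    act <- random_activation_table(sample(5:30, 1), sample(5:60, 1))
    if (nrow(act) == 0) next
    root <- sample(unique(act$regulator), 1)
    got <- grow_cascade(root, act)
    want <- oracle_cascade(root, act, 0.8, 3)
    expect_identical(sort(got$nodes$id), want$nodes)
    expect_identical(sort(paste(got$edges$parent, got$edges$child,
                                sep = "->")), want$edges)
    validate_cascade(got, max_layers = 3, cascade_corr_cutoff = 0.8)
  }
})

test_that("deleting edges or raising the cutoff never grows a cascade", {
  set.seed(72)
  for (i in 1:20) {
    act <- random_activation_table(12, 40)
    if (nrow(act) < 2) next
    root <- sample(unique(act$regulator), 1)
    full <- cascade_size(grow_cascade(root, act))
    drop <- cascade_size(grow_cascade(root, act[-sample(nrow(act), 1), ]))
    expect_lte(drop, full)
    expect_lte(cascade_size(grow_cascade(root, act,
                                         cascade_corr_cutoff = 0.9)), full)
  }
})

test_that("only roots with at least one regulation count as cascades", {
  act <- mk_act(c("T1", "T2"), c("a", "b"), c(0.95, 0.1))
  res <- build_all_cascades(c("T1", "T2"), act)
  grp <- res$NPC$normal
  expect_length(grp$cascades, 2)
  expect_identical(grp$counted, "T1")
})

test_that("comparison classifies lost, shrunk and stable cascades", {
  act_n <- mk_act(c("T1", "T1", "T2", "T3"), c("a", "b", "c", "d"),
                  c(0.9, 0.9, 0.9, 0.9))
  act_a <- act_n
  act_a$condition <- "ASD"
  act_a$r <- c(0.9, 0.1, 0.1, 0.9)       # T1 shrinks, T2 is lost, T3 stable
  act_a$active <- abs(act_a$r) > 0.8
  both <- rbind(act_n, act_a)
  res <- build_all_cascades(c("T1", "T2", "T3"), both)
  cmp <- compare_cascades(res$NPC$normal, res$NPC$ASD, size_threshold = 1)
  st <- setNames(cmp$report$status, cmp$report$root)
  expect_equal(unname(st[c("T1", "T2", "T3")]),
               c("shrunk", "lost", "stable"))
  expect_identical(cmp$lost_over_threshold, "T2")
  expect_identical(names(cmp$lost_edges), c("T1", "T2"))
  expect_equal(cmp$lost_edges$T1$child, "b")
  # identical groups: everything stable, nothing lost
  same <- compare_cascades(res$NPC$normal, res$NPC$normal)
  expect_true(all(same$report$status == "stable"))
  expect_length(same$lost_edges, 0)
})

test_that("every emitted cascade satisfies its invariants on synthetic data", {
  run <- default_run()
  expect_gt(length(run$cascades), 0)
  for (cs in run$cascades) {
    expect_no_error(validate_cascade(cs, max_layers = 3,
                                     cascade_corr_cutoff = 0.8))
  }
})
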