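test_that("consistent subsets are the order-free contiguous blocks shared by all sequences", {
  tr <- trial_of(c("A", "B", "C", "D", "E"),
                 c("C", "A", "B", "E", "D"),
                 c("B", "A", "C", "D", "E"))
  expect_equal(subset_keys(find_consistent_subsets(tr)),
               c("AB", "ABC", "DE"))

  single <- trial_of(c("A", "B", "C"))
  expect_equal(subset_keys(find_consistent_subsets(single)),
               c("AB", "BC"))

  reversed <- trial_of(c("A", "B", "C"), c("C", "B", "A"))
  expect_equal(subset_keys(find_consistent_subsets(reversed)),
               c("AB", "BC"))
})

test_that("every reported subset is verifiably contiguous in every sequence", {
  for (seed in 1:20) {
    set.seed(seed)
    ids <- LETTERS[1:6]
    seqs <- lapply(1:4, function(i) sample(ids))
    tr <- recall_trial(lapply(seqs, recall_sequence))
    for (s in find_consistent_subsets(tr)) {
      for (o in seqs) {
        p <- match(s, o)
        expect_equal(max(p) - min(p) + 1L, length(s))
      }
    }
  }
})

test_that("adding a sequence can only shrink the consistent-subset family", {
  for (seed in 1:15) {
    set.seed(seed)
    ids <- LETTERS[1:6]
    seqs <- lapply(1:4, function(i) sample(ids))
    small <- find_consistent_subsets(
      recall_trial(lapply(seqs[1:3], recall_sequence)))
    large <- find_consistent_subsets(
      recall_trial(lapply(seqs, recall_sequence)))
    expect_true(all(subset_keys(large) %in% subset_keys(small)))
  }
})

test_that("the cued first element is dropped from analysis when cue exclusion is on", {
  ## {A,C} is separated only in the cued sequence, and only by the cue
  ## itself; dropping the cue position rescues it
  s1 <- recall_sequence(c("C", "B", "A"), cued = TRUE, cue_id = "C")
  s2 <- recall_sequence(c("A", "C", "B"))
  tr <- recall_trial(list(s1, s2))
  with_cue <- subset_keys(find_consistent_subsets(tr))
  without <- subset_keys(find_consistent_subsets(tr,
                                                 exclude_cue_position = FALSE))
  expect_true("AC" %in% with_cue)
  expect_false("AC" %in% without)
  expect_true("BC" %in% without)
})

test_that("ordered trees nest subsets by containment with singleton leaves", {
  tree <- build_ordered_tree(list(c("A", "B"), c("A", "B", "C"),
                                  c("D", "E")), LETTERS[1:5])
  expect_equal(tree$members, LETTERS[1:5])
  kids <- vapply(tree$children, function(ch)
    paste(ch$members, collapse = ""), "")
  expect_setequal(kids, c("ABC", "DE"))
  abc <- tree$children[[which(kids == "ABC")]]
  expect_setequal(vapply(abc$children, function(ch)
    paste(ch$members, collapse = ""), ""), c("AB", "C"))

  flat <- build_ordered_tree(list(), c("A", "B", "C"))
  expect_length(flat$children, 3L)
  expect_true(all(vapply(flat$children, function(ch)
    length(ch$children) == 0L, TRUE)))

  ## subset equal to the root merges with the root
  deg <- build_ordered_tree(list(c("A", "B")), c("A", "B"))
  expect_length(deg$children, 2L)
})

test_that("partially overlapping subsets are rejected as corrupted input", {
  expect_error(build_ordered_tree(list(c("A", "B"), c("B", "C")),
                                  LETTERS[1:4]),
               "laminar")
})

test_that("tree height counts edges from root to deepest leaf", {
  expect_equal(tree_height(build_ordered_tree(list(), c("A", "B", "C"))), 1L)
  deep <- build_ordered_tree(list(c("A", "B"), c("A", "B", "C"),
                                  c("D", "E")), LETTERS[1:5])
  expect_equal(tree_height(deep), 3L)
  expect_equal(tree_height(build_ordered_tree(list(), "A")), 0L)
})

test_that("log-cardinality is log2 of the product of branch-count factorials", {
  expect_equal(log_cardinality(build_ordered_tree(list(), c("A", "B", "C"))),
               log2(factorial(3)), tolerance = 1e-12)
  two <- build_ordered_tree(list(c("A", "B"), c("C", "D", "E")),
                            LETTERS[1:5])
  expect_equal(log_cardinality(two), log2(2 * 2 * 6), tolerance = 1e-12)
  ## single node with one child contributes log2(1!) = 0
  one <- build_ordered_tree(list(), c("A"))
  expect_equal(log_cardinality(one), 0)
})

test_that("tree statistics are invariant to sequence order and relabeling", {
  set.seed(4)
  st <- map_structure(list(c("A", "B"), c("C", "D", "E")))
  tr <- generate_recall_sequences(st, seed = 9)
  tree1 <- build_ordered_tree(find_consistent_subsets(tr), tr$buildings)
  perm <- recall_trial(rev(tr$sequences))
  tree2 <- build_ordered_tree(find_consistent_subsets(perm), perm$buildings)
  expect_equal(tree_height(tree1), tree_height(tree2))
  expect_equal(log_cardinality(tree1), log_cardinality(tree2))

  relabel <- stats::setNames(letters[1:5], LETTERS[1:5])
  tr3 <- recall_trial(lapply(tr$sequences, function(s)
    recall_sequence(unname(relabel[s$ordering]), s$cued,
                    if (s$cued) unname(relabel[s$cue_id]))))
  tree3 <- build_ordered_tree(find_consistent_subsets(tr3), tr3$buildings)
  expect_equal(tree_height(tree1), tree_height(tree3))
  expect_equal(log_cardinality(tree1), log_cardinality(tree3))
})

test_that("jackknifing removes a cross-sub-map swap and keeps clean trials intact", {
  st <- map_structure(list(c("A", "B"), c("C", "D", "E")))
  clean <- generate_recall_sequences(st, seed = 21)
  jk <- jackknife_outliers(clean)
  expect_length(jk$removed, 0L)

  corrupted <- generate_recall_sequences(st, swap_prob = 1, seed = 7)
  idx <- attr(corrupted, "corrupted")
  expect_gt(idx, 0L)
  jk2 <- jackknife_outliers(corrupted)
  expect_true(idx %in% jk2$removed)
  expect_true(structures_equal(extract_submaps(jk2$tree), st))
})

test_that("fully random trials yield flat trees with no removals", {
  set.seed(5)
  seqs <- lapply(1:6, function(i) sample(LETTERS[1:6]))
  tr <- recall_trial(lapply(seqs, recall_sequence))
  jk <- jackknife_outliers(tr)
  expect_length(jk$removed, 0L)
  st <- extract_submaps(jk$tree)
  expect_length(st$submaps, 0L)
  expect_setequal(st$excluded, LETTERS[1:6])
})

test_that("jackknifing removes at most one sequence in most single-swap trials", {
  removed <- integer()
  for (seed in 1:40) {
    st <- random_structure(5, seed * 11)
    tr <- generate_recall_sequences(st, swap_prob = 1, seed = seed)
    removed <- c(removed, length(jackknife_outliers(tr)$removed))
  }
  expect_gte(mean(removed <= 1L), 0.9)
})

test_that("elementary sub-maps sit just above the leaves, singletons excluded", {
  tree <- build_ordered_tree(list(c("A", "B"), c("A", "B", "C"),
                                  c("D", "E")), LETTERS[1:5])
  st <- extract_submaps(tree)
  expect_equal(subset_keys(st$submaps), c("AB", "DE"))
  expect_equal(st$excluded, "C")

  flat <- extract_submaps(build_ordered_tree(list(), LETTERS[1:4]))
  expect_length(flat$submaps, 0L)
  expect_setequal(flat$excluded, LETTERS[1:4])

  full <- extract_submaps(build_ordered_tree(list(c("A", "B"), c("C", "D")),
                                             LETTERS[1:4]))
  expect_equal(subset_keys(full$submaps), c("AB", "CD"))
  expect_length(full$excluded, 0L)
})

test_that("circular recall protocols are detected, rotations only", {
  rot <- trial_of(c("A", "B", "C", "D", "E"), c("C", "D", "E", "A", "B"),
                  c("E", "A", "B", "C", "D"))
  expect_true(detect_circular(rot))
  not <- trial_of(c("A", "B", "C", "D", "E"), c("A", "C", "B", "D", "E"))
  expect_false(detect_circular(not))
  same <- trial_of(c("A", "B", "C"), c("A", "B", "C"))
  expect_true(detect_circular(same))
  rev_tr <- trial_of(c("A", "B", "C"), c("C", "B", "A"))
  expect_false(detect_circular(rev_tr))
})

test_that("degenerate and invalid trials raise errors", {
  expect_error(recall_trial(list()), "no recall")
  expect_error(recall_trial(list(recall_sequence(c("A", "B")),
                                 recall_sequence(c("A", "C")))),
               "permutations")
  expect_error(recall_sequence(c("A", "A", "B")), "exactly once")
  expect_error(jackknife_outliers(trial_of(c("A", "B"), c("B", "A"))),
               "at least 3")
})
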