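test_that("branch orders increment at branching nodes only", {
  # unbranched dendrite: one order-1 segment
  un <- read_swc(write_swc_lines(c("1 1 0 0 0 5 -1", "2 3 30 0 0 1 1",
                                   "3 3 60 0 0 1 2")))
  segs <- assign_branch_orders(un)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$order, 1L)
  expect_true(segs$is_tip)

  # one bifurcation: one order-1 and two order-2 segments
  bif <- read_swc(write_swc_lines(c("1 1 0 0 0 5 -1", "2 3 100 0 0 1 1",
                                    "3 3 100 100 0 1 2",
                                    "4 3 200 0 0 1 2")))
  sb <- assign_branch_orders(bif)
  expect_equal(sort(sb$order), c(1L, 2L, 2L))
  expect_equal(sum(sb$is_tip), 2)

  # full binary tree of depth 4: 2^(k-1) segments at order k
  tree <- read_swc(binary_tree_swc(4))
  st <- assign_branch_orders(tree)
  expect_equal(max(st$order), 4L)
  for (k in 1:4) {
    expect_equal(sum(st$order == k), 2^(k - 1), info = paste("order", k))
  }

  # a trifurcation increments the order once for all three children
  tri <- read_swc(write_swc_lines(c(
    "1 1 0 0 0 5 -1", "2 3 50 0 0 1 1", "3 3 100 0 0 1 2",
    "4 3 50 50 0 1 2", "5 3 50 -50 0 1 2")))
  strife <- assign_branch_orders(tri)
  expect_equal(sort(strife$order), c(1L, 2L, 2L, 2L))
})

test_that("morphometric features match hand computations", {
  # single unbranched dendrite of length L: complexity (1+1)*(L/1) = 2L
  un <- read_swc(write_swc_lines(c("1 1 0 0 0 5 -1", "2 3 0 40 0 1 1")))
  f <- morph_features(un)
  expect_equal(f$total_length, 40)
  expect_equal(f$complexity_index, 80)
  expect_equal(f$branching_index, 1)
  expect_equal(f$n_primary, 1)
  expect_equal(f$n_endings, 1)

  # symmetric bifurcation with segments 100/100/100 um
  bif <- read_swc(write_swc_lines(c("1 1 0 0 0 5 -1", "2 3 100 0 0 1 1",
                                    "3 3 100 100 0 1 2",
                                    "4 3 100 -100 0 1 2")))
  f2 <- morph_features(bif)
  expect_equal(f2$total_length, 300)
  expect_equal(f2$order1, 100)
  expect_equal(f2$order2, 200)
  expect_equal(f2$n_endings, 2)
  expect_equal(f2$branching_index, 2)
  expect_equal(f2$complexity_index, (2 + 2 + 2) * 300)   # tips at order 2+2
  # spine estimate: densities 1.0 and 2.0 per um on orders 1 and 2
  f3 <- morph_features(bif, spine_densities = c("1" = 1.0, "2" = 2.0))
  expect_equal(f3$est_total_spines, 1.0 * 100 + 2.0 * 200)
})

test_that("the soma-edge convention drops the soma-center link", {
  # soma at origin, first dendrite node at (10,0), branch node at (60,0)
  sw <- write_swc_lines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 1",
                          "3 3 60 0 0 1 2", "4 3 80 20 0 1 3",
                          "5 3 80 -20 0 1 3"))
  f_center <- morph_features(read_swc(sw), primary_from = "soma_center")
  f_edge <- morph_features(read_swc(sw), primary_from = "soma_edge")
  expect_equal(f_center$order1, 60)
  expect_equal(f_edge$order1, 50)
})

test_that("order lengths always sum to the total and endings equal leaves", {
  for (seed in 1:5) {
    coh <- gen_morph_cohort(morph_gen_params("active"),
                            morph_gen_params("silent"), 2, seed = seed)
    for (tree in coh$trees) {
      segs <- assign_branch_orders(tree)
      expect_equal(sum(segs$length_um),
                   morph_features(tree)$total_length, tolerance = 1e-9)
      leaves <- sum(!(tree$nodes$id %in% tree$nodes$parent) &
                      tree$nodes$type != 1)
      expect_equal(morph_features(tree)$n_endings, leaves)
    }
  }
})

test_that("features are invariant to rigid motion of the reconstruction", {
  coh <- gen_morph_cohort(morph_gen_params("active"),
                          morph_gen_params("silent"), 2, seed = 77)
  tree <- coh$trees[[3]]
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")]) %*% t(R)
  moved <- tree
  moved$nodes$x <- xyz[, 1] + 100
  moved$nodes$y <- xyz[, 2] - 42
  moved$nodes$z <- xyz[, 3] + 7
  f0 <- unlist(morph_features(tree))
  f1 <- unlist(morph_features(moved))
  expect_equal(f1, f0, tolerance = 1e-9)
})

test_that("detached dendrites are reported as not rooted at the soma", {
  nodes <- data.frame(id = 1:3, type = c(1L, 3L, 3L),
                      x = c(0, 1, 9), y = 0, z = 0, radius = 1,
                      parent = c(NA, 1L, NA))
  # morph_tree itself flags the multiple roots
  expect_error(morph_tree(nodes), "roots")
  # no soma at all
  no_soma <- morph_tree(data.frame(id = 1:2, type = 3L, x = c(0, 1), y = 0,
                                   z = 0, radius = 1, parent = c(NA, 1L)))
  expect_error(assign_branch_orders(no_soma), "soma")
})

test_that("soma position within the layer is a border-distance ratio", {
  borders <- list(deep = rbind(c(-100, 0), c(100, 0)),
                  superficial = rbind(c(-100, 8), c(100, 8)))
  tree_at <- function(yy) {
    read_swc(write_swc_lines(c(sprintf("1 1 0 %g 0 5 -1", yy),
                               sprintf("2 3 5 %g 0 1 1", yy))))
  }
  expect_equal(soma_layer_position(tree_at(0), borders), 0)
  expect_equal(soma_layer_position(tree_at(4), borders), 0.5)
  expect_equal(soma_layer_position(tree_at(6), borders), 0.75)
  expect_warning(pos <- soma_layer_position(tree_at(12), borders), "clamp")
  expect_equal(pos, 1)
})

test_that("group comparisons report Mann-Whitney and box statistics", {
  A <- cbind(len = c(10, 11, 12, 13, 14, 15), n = c(1, 2, 1, 2, 1, 2))
  S <- cbind(len = c(1, 2, 3, 4, 5, 6, 7), n = c(1, 2, 1, 2, 1, 2, 1))
  out <- compare_groups(A, S)
  expect_equal(nrow(out), 2)
  # fully separated feature: exact minimal two-sided p = 2 / C(13,6)
  expect_equal(out$p[out$feature == "len"], 2 / choose(13, 6),
               tolerance = 1e-12)
  expect_equal(out$active_median[out$feature == "len"], 12.5)
  # identical-ish feature: large p
  expect_gt(out$p[out$feature == "n"], 0.5)
})
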