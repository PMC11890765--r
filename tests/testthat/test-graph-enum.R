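# Graph enumeration against independent igraph-based oracles.

# oracle: count isomorphism classes of connected simple graphs on n
# vertices by brute force over adjacency masks, igraph does the
# isomorphism tests
oracle_simple_counts <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  reps <- list()
  for (mask in 0:(2^m - 1L)) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (any(sel))
      g <- igraph::add_edges(g, as.vector(t(pairs[sel, , drop = FALSE])))
    if (!igraph::is_connected(g)) next
    if (!any(vapply(reps, function(r) igraph::isomorphic(r, g),
                    logical(1))))
      reps[[length(reps) + 1L]] <- g
  }
  length(reps)
}

test_that("connected simple graph counts match the brute-force oracle", {
  gs <- enumerate_connected_simple_graphs(5L)
  counts <- table(vapply(gs, function(g) g$n, integer(1)))
  expect_identical(as.integer(counts), c(1L, 1L, 2L, 6L, 21L))
  for (n in 1:4) expect_identical(oracle_simple_counts(n),
                                  sum(vapply(gs, function(g) g$n,
                                             integer(1)) == n))
  expect_error(enumerate_connected_simple_graphs(0L), "between")
  expect_error(enumerate_connected_simple_graphs(7L), "between")
})

test_that("bond-order expansion honours the degree cap and dedups", {
  gs <- enumerate_connected_simple_graphs(4L)
  edge1 <- gs[[2L]]                       # the single edge on 2 vertices
  expect_length(expand_bond_orders(edge1), 3L)

  # triangle with all multiplicities 3 survives (every degree exactly 6)
  tri <- Filter(function(g) g$n == 3L && nrow(g$edges) == 3L, gs)[[1L]]
  mgs <- expand_bond_orders(tri)
  all3 <- Filter(function(mg) all(mg$mult == 3L), mgs)
  expect_length(all3, 1L)

  # 4-star: centre degree must stay within 6; count equals direct
  # enumeration with isomorphism dedup by canonical key
  star <- Filter(function(g) g$n == 4L && nrow(g$edges) == 3L &&
                   max(table(c(g$edges$i, g$edges$j))) == 3L, gs)[[1L]]
  mgs <- expand_bond_orders(star)
  grid <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  ok <- grid[rowSums(grid) <= 6L, , drop = FALSE]   # centre degree cap
  keys <- apply(ok, 1L, function(w) paste(sort(w), collapse = ","))
  expect_length(mgs, length(unique(keys)))
})

test_that("element labelling respects valency", {
  gs <- enumerate_connected_simple_graphs(2L)
  one <- gs[[1L]]
  expect_setequal(label_elements(one),
                  sort(vapply(organic_subset(), canonicalize, character(1))))
  # two-vertex triple bond: only valency >= 3 elements may sit on the ends
  mg3 <- list(n = 2L, edges = data.frame(i = 1L, j = 2L), mult = 3L)
  labs <- label_elements(mg3)
  expect_setequal(labs, c("B#B", "B#C", "B#N", "B#P", "C#C", "C#N",
                          "C#P", "N#N", "N#P", "P#P"))
  # halogen on a degree-2 vertex is excluded
  path3 <- Filter(function(g) g$n == 3L && nrow(g$edges) == 2L,
                  enumerate_connected_simple_graphs(3L))[[1L]]
  labs <- label_elements(list(n = 3L, edges = path3$edges,
                              mult = c(1L, 1L)), elements = c("C", "F"))
  for (s in labs) {
    g <- parse_smiles(s)
    nb <- lengths(molforge:::neighbour_list(g))
    expect_true(all(nb[g$atoms$element == "F"] <= 1L))
  }
})

test_that("cascade output is duplicate-free and valency-clean", {
  out <- fixture("enum3", function() enumerate_chemical_space(3L))
  expect_identical(anyDuplicated(out), 0L)
  for (s in sample(out, 30L)) {
    expect_identical(canonicalize(s), s)   # stored canonical form
  }
})
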