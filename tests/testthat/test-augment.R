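ten_node_graph <- function(seed = 1) {
  # connected random molecule-sized graph
  withr::with_seed(seed, {
    edges <- cbind(1:9, 2:10)                       # spanning path
    extra <- cbind(sample.int(10, 3), sample.int(10, 3))
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    make_graph(matrix(rnorm(10 * 4), 10, 4), rbind(edges, extra))
  })
}

test_that("substructure sampling keeps exactly ceiling(ratio * N) nodes", {
  g <- ten_node_graph()
  withr::with_seed(2, {
    for (trial in 1:50) {
      sub <- sample_substructure(g, 0.4)
      expect_equal(sub$n_nodes, 4L)
    }
  })
  single <- fixture_graphs()$singleton
  expect_identical(sample_substructure(single, 0.4), single)
})

test_that("sampled subgraphs are node-induced with copied features", {
  g <- ten_node_graph(3)
  key <- function(e) paste(e[, 1], e[, 2])
  withr::with_seed(4, {
    for (trial in 1:200) {
      sub <- sample_substructure(g, 0.5)
      # features are rows of the original feature matrix
      match_rows <- match(data.frame(t(sub$features)),
                          data.frame(t(g$features)))
      expect_false(any(is.na(match_rows)))
      kept <- sort(match_rows)
      allowed <- g$edges[g$edges[, 1] %in% kept & g$edges[, 2] %in% kept, ,
                         drop = FALSE]
      allowed_remap <- cbind(match(allowed[, 1], kept),
                             match(allowed[, 2], kept))
      expect_true(all(key(sub$edges) %in% key(allowed_remap)),
                  info = paste("trial", trial))
    }
  })
})

test_that("substructure sampling stays within one component", {
  g <- fixture_graphs()$two_component
  withr::with_seed(5, {
    for (trial in 1:20) {
      sub <- sample_substructure(g, 1)
      expect_lte(sub$n_nodes, 2L)   # component size, not ceiling(1 * 4)
    }
  })
})

test_that("node dropping removes ceiling(ratio * N) nodes, keeping >= 1", {
  g <- ten_node_graph()
  withr::with_seed(6, {
    sub <- augment_graph(g, "node_dropping", 0.2)
    expect_equal(sub$n_nodes, 8L)
    tiny <- augment_graph(fixture_graphs()$path3, "node_dropping", 0.99)
    expect_gte(tiny$n_nodes, 1L)
  })
})

test_that("edge perturbation rewires without touching nodes", {
  g <- ten_node_graph(7)
  withr::with_seed(8, {
    for (trial in 1:50) {
      sub <- augment_graph(g, "edge_perturbation", 0.4)
      expect_equal(sub$n_nodes, g$n_nodes)
      expect_identical(sub$features, g$features)
      expect_true(all(sub$edges[, 1] < sub$edges[, 2]))
      expect_equal(anyDuplicated(sub$edges), 0L)
    }
  })
})

test_that("attribute masking replaces the right number of rows in place", {
  g <- ten_node_graph(9)
  mv <- colMeans(g$features)
  withr::with_seed(10, {
    sub <- augment_graph(g, "attribute_masking", 0.4, mask_vector = mv)
    expect_equal(sub$n_nodes, 10L)
    expect_identical(sub$edges, g$edges)
    masked <- vapply(seq_len(10), function(i) {
      isTRUE(all.equal(sub$features[i, ], mv, check.attributes = FALSE))
    }, logical(1))
    changed <- rowSums(sub$features != g$features) > 0
    expect_equal(sum(masked), 4L)
    expect_true(all(changed[!masked] == FALSE))
  })
})

test_that("augmented graphs always satisfy the graph invariants", {
  d <- synth_molecules(40, seed = 15)
  methods <- c("substructure", "node_dropping", "edge_perturbation",
               "attribute_masking")
  withr::with_seed(16, {
    for (s in d$smiles[1:20]) {
      g <- smiles_to_graph(s)
      for (m in methods) {
        a <- augment_graph(g, m, 0.4)
        expect_gte(a$n_nodes, 1L)
        expect_equal(ncol(a$features), ncol(g$features))
        if (nrow(a$edges) > 0) {
          expect_true(all(a$edges >= 1 & a$edges <= a$n_nodes))
          expect_true(all(a$edges[, 1] != a$edges[, 2]))
        }
      }
    }
  })
  expect_error(augment_graph(ten_node_graph(), "something_else"),
               "arg")
})
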