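test_that("model validation finds cycles and malformed edges", {
  chain <- causal_model("chain", c("A", "B", "C"),
                        list(c("A", "B"), c("B", "C")))
  expect_identical(topological_order(chain), c("A", "B", "C"))
  expect_error(causal_model("cyc", c("A", "B"),
                            list(c("A", "B"), c("B", "A"))),
               "cycle")
  expect_error(causal_model("dup", c("A", "B"),
                            list(c("A", "B"), c("A", "B"))),
               "duplicate edge")
  expect_error(causal_model("self", c("A", "B"), list(c("A", "A"))),
               "self-loop")
  expect_error(causal_model("ghost", c("A", "B"), list(c("A", "C"))),
               "not among the vertices")
  for (m in truffle_models()) expect_silent(validate_model(m))
})

test_that("d-separation matches textbook cases", {
  chain <- causal_model("chain", c("X", "Y", "Z"),
                        list(c("X", "Y"), c("Y", "Z")))
  expect_true(d_separated(chain, "X", "Z", "Y"))
  expect_false(d_separated(chain, "X", "Z"))
  collider <- causal_model("collider", c("X", "Y", "Z"),
                           list(c("X", "Z"), c("Y", "Z")))
  expect_true(d_separated(collider, "X", "Y"))
  expect_false(d_separated(collider, "X", "Y", "Z"))
  # conditioning on a descendant of a collider also opens it
  wide <- causal_model("desc", c("X", "Y", "Z", "W"),
                       list(c("X", "Z"), c("Y", "Z"), c("Z", "W")))
  expect_false(d_separated(wide, "X", "Y", "W"))
  expect_error(d_separated(chain, "X", "Q"), "unknown vertex")
})

test_that("moral-graph d-separation agrees with exhaustive path blocking", {
  set.seed(42)
  for (i in 1:60) {
    nv <- sample(3:6, 1)
    m <- random_dag(nv, p = runif(1, 0.2, 0.6))
    pick <- sample(m$vertices, 2)
    others <- setdiff(m$vertices, pick)
    for (zsize in 0:min(2, length(others))) {
      z <- if (zsize) sample(others, zsize) else character(0)
      expect_identical(d_separated(m, pick[1], pick[2], z),
                       dsep_bruteforce(m, pick[1], pick[2], z),
                       info = paste(pick[1], pick[2], paste(z, collapse = ",")))
    }
  }
})

test_that("basis set has one claim per non-adjacent pair, all d-separated", {
  complete4 <- causal_model("full", c("A", "B", "C", "D"),
                            list(c("A", "B"), c("A", "C"), c("A", "D"),
                                 c("B", "C"), c("B", "D"), c("C", "D")))
  expect_length(basis_set(complete4), 0)

  edgeless <- causal_model("none", c("A", "B", "C"))
  bs <- basis_set(edgeless)
  expect_length(bs, 3)
  expect_true(all(vapply(bs, function(cl) length(cl$given) == 0, logical(1))))

  set.seed(7)
  for (i in 1:25) {
    m <- random_dag(sample(4:7, 1), p = runif(1, 0.2, 0.7))
    bs <- basis_set(m)
    expect_length(bs, choose(length(m$vertices), 2) - nrow(m$edges))
    ord <- topological_order(m)
    for (cl in bs) {
      expect_true(d_separated(m, cl$x, cl$y, cl$given))
      expect_identical(cl$response,
                       cl[c("x", "y")][[which.max(match(c(cl$x, cl$y), ord))]])
      expect_setequal(cl$given,
                      setdiff(union(parents(m, cl$x), parents(m, cl$y)),
                              c(cl$x, cl$y)))
    }
  }
})

test_that("the candidate models yield the published test degrees of freedom", {
  dfs <- vapply(truffle_models(), function(m) 2L * length(basis_set(m)),
                integer(1))
  expect_identical(dfs[c("single_A", "single_B", "single_C")],
                   c(single_A = 14L, single_B = 8L, single_C = 6L))
  expect_identical(dfs[paste0("cluster_", LETTERS[1:5])],
                   c(cluster_A = 14L, cluster_B = 10L, cluster_C = 8L,
                     cluster_D = 10L, cluster_E = 6L))
})

test_that("models survive a JSON round-trip and export to DOT", {
  m <- truffle_models()$cluster_D
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$vertices, m$vertices)
  expect_identical(m2$edges, m$edges)
  expect_identical(m2$family, m$family)
  expect_identical(m2$transform, m$transform)
  dot <- model_to_dot(m)
  expect_match(dot, "\"we_rest\" -> \"we_largest\"")
})
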