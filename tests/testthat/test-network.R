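test_that("rule documents parse to validated networks", {
  net <- parse_network("targets, factors\nA, B\nB, A & C\nC, !A")
  expect_s3_class(net, "BooleanNetwork")
  expect_equal(net$nodes, c("A", "B", "C"))
  expect_length(net$rules, 3)

  # comments, blank lines and word operators are accepted
  doc <- c("# a comment", "targets, factors", "", "A, B OR NOT C",
           "B, A", "C, 1")
  net2 <- parse_network(doc)
  expect_equal(net2$nodes, c("A", "B", "C"))
  expect_true(eval_expr(net2$rules$A, c(B = FALSE, C = FALSE)))
})

test_that("parsing rejects malformed documents with informative errors", {
  expect_error(parse_network("targets, factors\nA, B & D\nB, A"), "D")
  expect_error(parse_network("targets, factors\nA, B\nA, !B\nB, A"),
               "duplicate")
  expect_error(parse_network(""), "empty")
  expect_error(parse_network("targets, factors"), "no rules")
  expect_error(parse_network("targets, factors\nA, B &\nB, A"))
})

test_that("link counting uses distinct regulator-target pairs", {
  expect_equal(count_links(parse_network("targets, factors\nA, !B\nB, A")), 2)
  # B referenced twice in one rule counts once
  net <- parse_network("targets, factors\nA, B | (B & C)\nB, A\nC, A")
  expect_equal(length(expr_vars(net$rules$A)), 2)
  expect_equal(count_links(net), 4)
  # constants contribute no links
  expect_equal(count_links(parse_network("targets, factors\nA, 1\nB, A")), 1)
})

test_that("synchronous step evaluates rules on the input state and honors pins", {
  net <- parse_network("targets, factors\nA, !B\nB, A")
  expect_equal(step_state(net, c(A = 1, B = 1)), c(A = 0, B = 1))
  # pinned node takes its pinned value whatever the rules say
  for (s in list(c(A = 0, B = 0), c(A = 1, B = 0), c(A = 1, B = 1))) {
    nx <- step_state(net, s, perturbation(c(A = 0)))
    expect_equal(unname(nx["A"]), 0)
  }
  # identity rule fixed point
  idn <- parse_network("targets, factors\nA, A")
  expect_equal(step_state(idn, c(A = 1)), c(A = 1))
  # purity: repeated calls identical
  expect_identical(step_state(net, c(A = 1, B = 0)),
                   step_state(net, c(A = 1, B = 0)))
  expect_error(step_state(net, c(1, 0, 1)), "length")
})

test_that("evolution finds canonical attractors with transient lengths", {
  net <- toggle_net()
  r <- evolve_to_attractor(net, c(A = 0, B = 1))
  expect_equal(nrow(r$cycle), 2)
  expect_equal(r$cycle[1, ], c(A = 0, B = 1))  # lexicographically smallest first
  expect_equal(r$cycle[2, ], c(A = 1, B = 0))
  expect_equal(r$transient, 0)

  r2 <- evolve_to_attractor(net, c(A = 1, B = 1))
  expect_equal(nrow(r2$cycle), 1)
  expect_equal(r2$cycle[1, ], c(A = 1, B = 1))
  expect_equal(r2$transient, 0)

  # applying step L times to a cycle state returns that state
  net3 <- parse_network("targets, factors\nA, B\nB, C\nC, !A")
  r3 <- evolve_to_attractor(net3, c(A = 0, B = 0, C = 0))
  L <- nrow(r3$cycle)
  s <- r3$cycle[1, ]
  for (i in seq_len(L)) s <- step_state(net3, s)
  expect_equal(s, r3$cycle[1, ])

  # fully pinned network: fixed point equal to the pinned vector
  rp <- evolve_to_attractor(net, c(A = 1, B = 1),
                            perturbation(c(A = 1, B = 0)))
  expect_equal(nrow(rp$cycle), 1)
  expect_equal(rp$cycle[1, ], c(A = 1, B = 0))
})

test_that("pinned nodes hold their value across every attractor state", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      net <- generate_random_network(7, k = 2, seed = sample.int(1e6, 1))
      pin <- perturbation(stats::setNames(sample(0:1, 2), sample(net$nodes, 2)))
      ls <- enumerate_landscape(net, pin)
      for (a in ls$attractors)
        for (nm in names(pin))
          expect_true(all(a$cycle[, nm] == pin[[nm]]))
    }
  })
})

test_that("serialize/parse round-trip preserves rule semantics and annotations", {
  withr::with_seed(5, {
    for (rep in 1:8) {
      net <- generate_random_network(6, k = 2, n_outputs = 2,
                                     seed = sample.int(1e6, 1))
      rt <- parse_network(serialize_network(net))
      expect_equal(rt$nodes, net$nodes)
      for (nm in net$nodes) {
        vars <- sort(expr_vars(net$rules[[nm]]))
        expect_equal(sort(expr_vars(rt$rules[[nm]])), vars)
        if (length(vars))
          expect_equal(expr_truth_table(rt$rules[[nm]], vars),
                       expr_truth_table(net$rules[[nm]], vars))
      }
    }
  })
  # file + annotation sidecar round-trip
  net <- build_mini_ad_network()
  rules_f <- withr::local_tempfile(fileext = ".bnet")
  ann_f <- withr::local_tempfile(fileext = ".yaml")
  serialize_network(net, rules_f)
  write_annotations(net, ann_f)
  rt <- parse_network(rules_f, annotations = ann_f)
  expect_equal(rt$roles, net$roles)
  expect_equal(rt$phenotypes, net$phenotypes)
})

test_that("network construction enforces the role/phenotype contract", {
  expect_error(boolean_network(list(A = "B", B = "A"),
                               roles = c(A = "output")),
               "phenotype")
  expect_error(boolean_network(list(A = "B", B = "A"),
                               phenotypes = c(A = "Abeta")),
               "output")
  expect_error(boolean_network(stats::setNames(list("A", "A"), c("A A", "B"))),
               "whitespace")
})
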