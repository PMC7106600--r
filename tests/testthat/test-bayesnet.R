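test_that("acyclicity test agrees with a DFS back-edge oracle", {
  st2 <- list(a = c("1", "2"), b = c("1", "2"), c = c("1", "2"))
  expect_true(check_acyclic(new_dag(st2, rbind(c("a", "b"), c("b", "c")))))
  # a cycle cannot be constructed through new_dag, so probe the predicate
  # on a manipulated object
  dag <- new_dag(st2)
  dag$arcs <- rbind(c("a", "b"), c("b", "a"))
  expect_false(check_acyclic(dag))
  set.seed(51)
  nodes <- paste0("n", 1:50)
  for (rep in 1:300) {
    m <- sample(20:80, 1)
    arcs <- unique(cbind(sample(nodes, m, TRUE), sample(nodes, m, TRUE)))
    arcs <- arcs[arcs[, 1] != arcs[, 2], , drop = FALSE]
    dag <- structure(list(nodes = nodes,
                          states = stats::setNames(rep(list(c("1", "2")), 50), nodes),
                          arcs = arcs),
                     class = "pvq_dag")
    expect_equal(check_acyclic(dag), !dfs_has_cycle(nodes, arcs))
  }
})

test_that("DAG constructor rejects self-arcs, duplicates and cycles", {
  st <- list(a = c("1", "2"), b = c("1", "2"))
  expect_error(new_dag(st, rbind(c("a", "a"))), class = "pvq_dag_error")
  expect_error(new_dag(st, rbind(c("a", "b"), c("a", "b"))),
               class = "pvq_dag_error")
  expect_error(new_dag(st, rbind(c("a", "b"), c("b", "a"))),
               class = "pvq_dag_error")
  expect_error(new_dag(st, rbind(c("a", "z"))), class = "pvq_dag_error")
})

test_that("BIC local score matches its closed form and penalizes null parents", {
  # single binary node, all 8 observations in one state: ll = 0,
  # penalty = log(8)/2
  st <- list(x = c("yes", "no"))
  enc <- encode_discrete(data.frame(x = rep("yes", 8)), st)
  expect_equal(local_score("x", character(0), enc), -0.5 * log(8),
               tolerance = 1e-10)
  expect_equal(-0.5 * log(8), -1.0397, tolerance = 1e-4)
  # an independent parent never helps BIC at large n
  set.seed(52)
  st2 <- list(x = c("1", "2"), z = c("1", "2", "3"))
  worse <- 0
  for (rep in 1:50) {
    d <- data.frame(x = as.character(sample(1:2, 5000, TRUE)),
                    z = as.character(sample(1:3, 5000, TRUE)))
    enc2 <- encode_discrete(d, st2)
    if (local_score("x", "z", enc2) > local_score("x", character(0), enc2)) {
      worse <- worse + 1
    }
  }
  expect_equal(worse, 0)
})

test_that("network scores decompose and are invariant to node relabeling", {
  set.seed(53)
  d <- data.frame(a = as.character(sample(1:2, 300, TRUE)),
                  b = as.character(sample(1:3, 300, TRUE)),
                  c = as.character(sample(1:2, 300, TRUE)))
  st <- list(a = c("1", "2"), b = c("1", "2", "3"), c = c("1", "2"))
  dag <- new_dag(st, rbind(c("a", "b"), c("c", "b")))
  enc <- encode_discrete(d, st)
  for (spec in list(score_spec("bic"), score_spec("bdeu", ess = 2))) {
    total <- score_network(dag, enc, spec)
    parts <- local_score("a", character(0), enc, spec) +
      local_score("b", c("a", "c"), enc, spec) +
      local_score("c", character(0), enc, spec)
    expect_equal(total, parts, tolerance = 1e-9)
  }
  # relabel: swap names a <-> c everywhere
  d2 <- d; names(d2) <- c("c", "b", "a")
  st2 <- list(a = c("1", "2"), b = c("1", "2", "3"), c = c("1", "2"))
  dag2 <- new_dag(st2, rbind(c("c", "b"), c("a", "b")))
  expect_equal(score_network(dag2, encode_discrete(d2, st2)),
               score_network(dag, enc), tolerance = 1e-9)
})

test_that("hill-climbing recovers simple structures and honors constraints", {
  set.seed(54)
  n <- 5000
  a <- sample(1:2, n, TRUE)
  b <- ifelse(stats::runif(n) < 0.9, a, 3 - a)
  d <- data.frame(a = as.character(a), b = as.character(b))
  st <- list(a = c("1", "2"), b = c("1", "2"))
  got <- hill_climb(d, st)
  truth <- new_dag(st, rbind(c("a", "b")))
  expect_equal(shd(cpdag(got), cpdag(truth)), 0)

  d0 <- data.frame(a = as.character(sample(1:2, n, TRUE)),
                   b = as.character(sample(1:2, n, TRUE)))
  expect_equal(nrow(hill_climb(d0, st)$arcs), 0L)

  cons <- arc_constraints(whitelist = rbind(c("a", "b")))
  kept <- hill_climb(d0, st, constraints = cons)
  expect_true(any(kept$arcs[, 1] == "a" & kept$arcs[, 2] == "b"))

  blk <- arc_constraints(blacklist = rbind(c("a", "b"), c("b", "a")))
  none <- hill_climb(d, st, constraints = blk)
  expect_equal(nrow(none$arcs), 0L)
})

test_that("tabu search dominates hill-climbing and respects its contracts", {
  set.seed(55)
  st4 <- stats::setNames(rep(list(c("1", "2")), 4), c("a", "b", "c", "d"))
  n_worse <- 0
  for (rep in 1:150) {
    p <- matrix(stats::runif(16, -1.2, 1.2), 4)
    x <- matrix(0L, 250, 4)
    x[, 1] <- stats::rbinom(250, 1, 0.5)
    for (j in 2:4) {
      lp <- x[, seq_len(j - 1), drop = FALSE] %*% p[seq_len(j - 1), j]
      x[, j] <- stats::rbinom(250, 1, stats::plogis(lp))
    }
    d <- as.data.frame(apply(x + 1L, 2, as.character))
    names(d) <- names(st4)
    enc <- encode_discrete(d, st4)
    s_tb <- attr(tabu_search(enc, st4), "score")
    s_hc <- attr(hill_climb(enc, st4), "score")
    if (s_tb < s_hc - 1e-9) n_worse <- n_worse + 1
  }
  expect_equal(n_worse, 0)

  # no iterations: the whitelist graph comes back unchanged
  cons <- arc_constraints(whitelist = rbind(c("a", "b")))
  d0 <- data.frame(a = c("1", "2"), b = c("1", "2"), c = c("1", "2"),
                   d = c("1", "2"))
  frozen <- tabu_search(d0, st4, constraints = cons, tabu_length = 1,
                        max_iter = 0)
  expect_equal(unname(frozen$arcs), unname(rbind(c("a", "b"))))
  expect_error(tabu_search(d0, st4, tabu_length = 0), class = "pvq_search_error")
})

test_that("tabu reaches the exhaustive-enumeration optimum on 3-node colliders", {
  set.seed(56)
  arcsets <- all_3node_arcsets()
  expect_equal(length(arcsets), 25L)
  hits <- 0
  for (rep in 1:40) {
    d <- collider_data(2000)
    enc <- encode_discrete(d, binary3_states)
    scores <- vapply(arcsets, function(arcs) {
      score_network(new_dag(binary3_states, arcs), enc)
    }, numeric(1))
    best_cp <- cpdag(new_dag(binary3_states, arcsets[[which.max(scores)]]))
    got <- tabu_search(enc, binary3_states)
    hits <- hits + (shd(cpdag(got), best_cp) == 0)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("CPT estimation gives Dirichlet posterior means with an ML limit", {
  st <- list(x = c("1", "2"))
  dag <- new_dag(st)
  d <- data.frame(x = c("1", "1", "1", "2"))
  # Dirichlet posterior mean with ess = 1 spread over the r*q = 2 cells:
  # (3 + 1/2) / (4 + 1) and (1 + 1/2) / (4 + 1)
  bn <- fit_cpts(dag, d, ess = 1)
  expect_equal(unname(bn$cpts$x$prob[1, ]), c(3.5 / 5, 1.5 / 5),
               tolerance = 1e-12)
  # unseen parent configuration -> uniform prior mean
  st2 <- list(p = c("1", "2", "3"), x = c("1", "2"))
  dag2 <- new_dag(st2, rbind(c("p", "x")))
  d2 <- data.frame(p = c("1", "1", "2"), x = c("1", "2", "1"))
  bn2 <- fit_cpts(dag2, d2, ess = 1)
  expect_equal(unname(bn2$cpts$x$prob[3, ]), c(0.5, 0.5))
  # ess -> 0 approaches maximum likelihood on observed rows
  set.seed(57)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    dd <- data.frame(p = as.character(sample(1:3, n, TRUE)),
                     x = as.character(sample(1:2, n, TRUE)))
    bn_eps <- fit_cpts(dag2, dd, ess = 1e-9)
    tab <- table(factor(dd$p, levels = c("1", "2", "3")),
                 factor(dd$x, levels = c("1", "2")))
    for (j in 1:3) {
      if (sum(tab[j, ]) == 0) next
      expect_true(all(abs(bn_eps$cpts$x$prob[j, ] - tab[j, ] / sum(tab[j, ]))
                      < 1e-6))
    }
  }
  # invariants on a fitted network
  rows <- bn2$cpts$x$prob
  expect_true(all(rows >= 0))
  expect_true(all(abs(rowSums(rows) - 1) < 1e-9))
})

test_that("joint probabilities factorize and normalize", {
  bn <- bayes_net(list(x = c("1", "2")), NULL, list(x = matrix(c(0.7, 0.3), 1)))
  expect_equal(joint_probability(bn, c(x = "1")), 0.7)
  chain <- bayes_net(
    list(a = c("1", "2"), b = c("1", "2")),
    rbind(c("a", "b")),
    list(a = matrix(c(0.6, 0.4), 1), b = rbind(c(0.9, 0.1), c(0.2, 0.8)))
  )
  expect_equal(joint_probability(chain, c(a = "1", b = "1")), 0.54)
  expect_equal(joint_probability(chain, c(a = "2", b = "1")), 0.08)
  tot <- sum(vapply(expand.grid(a = c("1", "2"), b = c("1", "2"),
                                stringsAsFactors = FALSE) |>
                      asplit(1),
                    function(r) joint_probability(chain, unlist(r)), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
  set.seed(58)
  bn5 <- random_bn(5)
  grid <- expand.grid(bn5$states, stringsAsFactors = FALSE)
  tot5 <- sum(vapply(seq_len(nrow(grid)), function(i) {
    joint_probability(bn5, unlist(grid[i, ]))
  }, numeric(1)))
  expect_equal(tot5, 1, tolerance = 1e-9)
  expect_error(joint_probability(bn5, c(v1 = "1")), class = "pvq_inference_error")
})

test_that("variable elimination matches brute-force enumeration", {
  set.seed(59)
  for (rep in 1:30) {
    bn <- random_bn(sample(3:8, 1))
    nodes <- bn$dag$nodes
    tgt <- sample(nodes, 1)
    n_ev <- sample(0:(length(nodes) - 1), 1)
    evn <- setdiff(sample(nodes, n_ev), tgt)
    ev <- vapply(evn, function(v) sample(bn$states[[v]], 1), character(1))
    got <- posterior(bn, tgt, if (length(ev)) ev else NULL)
    want <- enum_posterior(bn, tgt, as.list(ev))
    expect_lt(max(abs(got - want)), 1e-9)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("posterior handles full evidence and inconsistent evidence", {
  chain <- bayes_net(
    list(a = c("1", "2"), b = c("1", "2")),
    rbind(c("a", "b")),
    list(a = matrix(c(0.6, 0.4), 1), b = rbind(c(1, 0), c(0.2, 0.8)))
  )
  # evidence on all nodes but the target = ratio of joint probabilities
  post <- posterior(chain, "a", c(b = "2"))
  expect_equal(unname(post["2"]), 0.4 * 0.8 / (0.6 * 0 + 0.4 * 0.8),
               tolerance = 1e-12)
  expect_equal(unname(post["1"]), 0, tolerance = 1e-12)
  expect_error(posterior(chain, "b", c(b = "1")), class = "pvq_inference_error")
  expect_error(posterior(chain, "a", c(b = "x")), class = "pvq_state_error")
  # impossible evidence: b = "2" given a = "1" has probability 0
  det <- bayes_net(
    list(a = c("1", "2"), b = c("1", "2")),
    rbind(c("a", "b")),
    list(a = matrix(c(1, 0), 1), b = rbind(c(1, 0), c(0.5, 0.5)))
  )
  expect_error(posterior(det, "a", c(b = "2")),
               class = "pvq_inconsistent_evidence")
})

test_that("risk prediction reduces to the marginal when SB is disconnected", {
  bn <- bayes_net(
    list(sb_group = c("with_sb", "without_sb"), x = c("1", "2")),
    NULL,
    list(sb_group = matrix(c(0.42, 0.58), 1), x = matrix(c(0.5, 0.5), 1))
  )
  for (xv in c("1", "2")) {
    pr <- predict_risk(bn, c(x = xv))
    expect_equal(pr$probability, 0.42, tolerance = 1e-12)
    expect_equal(pr$predicted, "without_sb")
  }
  # boundary convention: probability exactly at threshold -> with_sb
  bn2 <- bayes_net(
    list(sb_group = c("with_sb", "without_sb")), NULL,
    list(sb_group = matrix(c(0.5, 0.5), 1))
  )
  expect_equal(predict_risk(bn2, NULL)$predicted, "with_sb")
})

test_that("search output always satisfies acyclicity and its constraints", {
  set.seed(60)
  st4 <- stats::setNames(rep(list(c("1", "2")), 4), c("a", "b", "c", "d"))
  cons <- arc_constraints(whitelist = rbind(c("a", "b")),
                          blacklist = rbind(c("d", "a")))
  for (rep in 1:20) {
    d <- as.data.frame(matrix(as.character(sample(1:2, 4 * 150, TRUE)), 150))
    names(d) <- names(st4)
    got <- tabu_search(d, st4, constraints = cons)
    expect_true(check_acyclic(got))
    expect_true(any(got$arcs[, 1] == "a" & got$arcs[, 2] == "b"))
    expect_false(any(got$arcs[, 1] == "d" & got$arcs[, 2] == "a"))
    expect_gte(attr(got, "score"),
               score_network(new_dag(st4, rbind(c("a", "b"))),
                             encode_discrete(d, st4)) - 1e-9)
  }
})

test_that("unsupported constraint-based algorithms raise, supported resolve", {
  expect_identical(search_algorithm("tabu"), tabu_search)
  expect_identical(search_algorithm("hill_climbing"), hill_climb)
  for (nm in c("grow_shrink", "iamb", "fast_iamb", "inter_iamb", "mmpc")) {
    expect_error(search_algorithm(nm), class = "pvq_unsupported_algorithm")
  }
  expect_error(search_algorithm("simulated_annealing"),
               class = "pvq_unsupported_algorithm")
})

test_that("network JSON serialization preserves inference results", {
  set.seed(61)
  bn <- random_bn(5)
  f <- withr::local_tempfile(fileext = ".json")
  bn_to_json(bn, f)
  bn2 <- bn_from_json(f)
  tgt <- bn$dag$nodes[2]
  ev <- c(stats::setNames(bn$states[[bn$dag$nodes[4]]][1], bn$dag$nodes[4]))
  expect_equal(posterior(bn2, tgt, ev), posterior(bn, tgt, ev),
               tolerance = 1e-12)
  cons <- arc_constraints(whitelist = rbind(c("v1", "v2")),
                          blacklist = rbind(c("v3", "v1")))
  f2 <- withr::local_tempfile(fileext = ".json")
  constraints_to_json(cons, f2)
  cons2 <- constraints_from_json(f2)
  expect_equal(unname(cons2$whitelist), unname(cons$whitelist))
  expect_equal(unname(cons2$blacklist), unname(cons$blacklist))
})
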