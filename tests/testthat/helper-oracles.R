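# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written from first principles (enumeration, direct formulas)
# and never reuse the code paths they check.

# A random valid cohort tibble built directly from the schema.
random_cohort <- function(n, seed = NULL, schema = pvq_schema()) {
  if (!is.null(seed)) set.seed(seed)
  items <- schema$items
  cols <- list(patient_id = sprintf("R%04d", seq_len(n)))
  for (i in seq_len(nrow(items))) {
    cols[[items$column[i]]] <- sample(items$min[i]:items$max[i], n, TRUE)
  }
  for (v in names(schema$demographics)) {
    cols[[v]] <- sample(schema$demographics[[v]], n, TRUE)
  }
  cols$sb_status <- sample(schema$sb_levels, n, TRUE)
  tibble::as_tibble(cols)[, schema$columns]
}

# A random discrete Bayesian network over p nodes (cardinalities 2..3).
random_bn <- function(p, arc_prob = 0.4) {
  states <- stats::setNames(
    lapply(seq_len(p), function(i) as.character(seq_len(sample(2:3, 1)))),
    paste0("v", seq_len(p))
  )
  arcs <- NULL
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      if (stats::runif(1) < arc_prob) {
        arcs <- rbind(arcs, c(paste0("v", i), paste0("v", j)))
      }
    }
  }
  dag <- new_dag(states, arcs)
  cpts <- lapply(dag$nodes, function(v) {
    pa <- dag_parents(dag, v)
    r <- length(states[[v]])
    q <- if (length(pa) == 0) 1 else prod(vapply(states[pa], length, integer(1)))
    m <- matrix(stats::rgamma(q * r, 1) + 0.05, q)
    m / rowSums(m)
  })
  names(cpts) <- dag$nodes
  bayes_net(states, arcs, cpts)
}

# Brute-force posterior by full-joint enumeration.
enum_posterior <- function(bn, target, evidence = NULL) {
  grid <- expand.grid(bn$states, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  g <- grid[keep, , drop = FALSE]
  pj <- vapply(seq_len(nrow(g)), function(i) {
    joint_probability(bn, unlist(g[i, ]))
  }, numeric(1))
  out <- tapply(pj, factor(g[[target]], levels = bn$states[[target]]), sum)
  as.numeric(out / sum(pj))
}

# Recursive DFS back-edge cycle detector over an arc matrix.
dfs_has_cycle <- function(nodes, arcs) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    arcs[arcs[, 1] == v, 2]
  })
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 white 1 grey 2 black
  visit <- function(v) {
    color[v] <<- 1L
    for (w in adj[[v]]) {
      if (color[w] == 1L) return(TRUE)
      if (color[w] == 0L && visit(w)) return(TRUE)
    }
    color[v] <<- 2L
    FALSE
  }
  for (v in nodes) if (color[v] == 0L && visit(v)) return(TRUE)
  FALSE
}

# All 25 DAGs on three nodes, as arc matrices (NULL = empty graph).
all_3node_arcsets <- function(nodes = c("a", "b", "c")) {
  pairs <- t(utils::combn(nodes, 2))
  choices <- expand.grid(rep(list(0:2), nrow(pairs)))
  out <- list()
  for (k in seq_len(nrow(choices))) {
    arcs <- NULL
    for (e in seq_len(nrow(pairs))) {
      s <- choices[k, e]
      if (s == 1) arcs <- rbind(arcs, pairs[e, ])
      if (s == 2) arcs <- rbind(arcs, rev(pairs[e, ]))
    }
    if (!is.null(arcs) && dfs_has_cycle(nodes, arcs)) next
    out <- c(out, list(arcs))
  }
  out
}

# Direct-formula Pearson chi-squared (optionally Yates-corrected).
chisq_oracle <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (yates) sum((abs(tab - E) - 0.5)^2 / E) else sum((tab - E)^2 / E)
}

# Strong-signal three-node collider dataset (a -> c <- b).
collider_data <- function(n = 2000) {
  a <- sample(1:2, n, TRUE)
  b <- sample(1:2, n, TRUE)
  pc <- stats::plogis(3.6 * (a - 1.5) + 3.2 * (b - 1.5))
  cc <- 1 + stats::rbinom(n, 1, pc)
  data.frame(a = as.character(a), b = as.character(b), c = as.character(cc))
}

binary3_states <- list(a = c("1", "2"), b = c("1", "2"), c = c("1", "2"))

# The Table-like printed contingency tables used by the descriptive tests
# (rows = category, cols = without/with group).
printed_tables <- function() {
  list(
    gender = rbind(c(257, 260), c(67, 66)),
    education = rbind(c(178, 158), c(146, 168)),
    living_with = rbind(c(31, 36), c(49, 35), c(244, 255)),
    marital = rbind(c(115, 156), c(135, 103), c(18, 13), c(56, 54)),
    occupation = rbind(c(187, 142), c(52, 90), c(18, 21), c(60, 67), c(7, 6)),
    age_band = rbind(c(24, 52), c(54, 65), c(57, 66), c(72, 53), c(75, 71),
                     c(42, 19)),
    diagnosis = rbind(c(91, 191), c(59, 46), c(32, 22), c(11, 1), c(45, 25),
                      c(53, 22), c(13, 2), c(16, 14), c(4, 3))
  )
}
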