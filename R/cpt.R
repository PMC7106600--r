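# Conditional probability tables and the fitted network object.

#' Fit CPTs by Bayesian (Dirichlet posterior-mean) estimation
#'
#' For each node with child cardinality r and q parent configurations, the
#' estimated row j is the posterior mean under a Dirichlet prior with total
#' equivalent sample size `ess` spread uniformly over the child x parent
#' table:
#' p(child = k | parents = j) = (n_jk + ess/(r q)) / (n_j + ess/q).
#' A parent configuration never observed therefore gets the uniform prior
#' mean, and as ess -> 0 the estimate approaches the maximum-likelihood
#' frequencies wherever data exist.
#'
#' @param dag A `pvq_dag`.
#' @param data Data frame of discrete observations (or `pvq_encoded`).
#' @param ess Equivalent sample size (default 1).
#' @return An object of class `pvq_bn`: the DAG plus one CPT per node. Each
#'   CPT is a list with `node`, `parents`, `prob` (q x r matrix, rows
#'   summing to 1; rows ordered column-major over the parent states in
#'   parent order).
#' @export
fit_cpts <- function(dag, data, ess = 1) {
  stopifnot(inherits(dag, "pvq_dag"))
  if (ess <= 0) rlang::abort("ess must be positive", class = "pvq_cpt_error")
  enc <- if (inherits(data, "pvq_encoded")) data else
    encode_discrete(data, dag$states)
  cpts <- lapply(dag$nodes, function(v) {
    parents <- dag_parents(dag, v)
    counts <- t(family_counts(enc, v, parents))  # q x r
    r <- ncol(counts); q <- nrow(counts)
    prob <- (counts + ess / (r * q)) / (rowSums(counts) + ess / q)
    colnames(prob) <- dag$states[[v]]
    list(node = v, parents = parents, prob = prob)
  })
  names(cpts) <- dag$nodes
  structure(list(dag = dag, states = dag$states, cpts = cpts),
            class = "pvq_bn")
}

#' Construct a network directly from known CPTs
#'
#' Used for ground-truth generator networks and hand-built examples.
#'
#' @param states Named list of state vectors.
#' @param arcs Arc matrix / data frame (from, to).
#' @param cpts Named list: for each node, a q x r probability matrix (rows
#'   = parent configurations column-major in sorted-parent order, columns =
#'   child states; a root node has a single row).
#' @return A `pvq_bn`.
#' @export
bayes_net <- function(states, arcs, cpts) {
  dag <- new_dag(states, arcs)
  out <- lapply(dag$nodes, function(v) {
    parents <- dag_parents(dag, v)
    prob <- as.matrix(cpts[[v]])
    r <- length(states[[v]])
    q <- if (length(parents) == 0) 1L else prod(vapply(states[parents], length, integer(1)))
    if (nrow(prob) != q || ncol(prob) != r) {
      rlang::abort(sprintf("CPT for %s must be %d x %d (rows = parent configs, cols = states)",
                           v, q, r), class = "pvq_cpt_error")
    }
    if (any(prob < 0) || any(abs(rowSums(prob) - 1) > 1e-9)) {
      rlang::abort(sprintf("CPT rows for %s must be distributions", v),
                   class = "pvq_cpt_error")
    }
    colnames(prob) <- states[[v]]
    list(node = v, parents = parents, prob = prob)
  })
  names(out) <- dag$nodes
  structure(list(dag = dag, states = states, cpts = out), class = "pvq_bn")
}

#' @export
print.pvq_bn <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d nodes, %d arcs\n",
              length(x$dag$nodes), nrow(x$dag$arcs)))
  invisible(x)
}

#' Joint probability of a full assignment
#'
#' The joint factorizes as the product over nodes of the probability of the
#' node's state given its parents' states.
#'
#' @param bn A `pvq_bn`.
#' @param assignment Named character vector or one-row data frame giving a
#'   state for every node.
#' @return A probability.
#' @export
joint_probability <- function(bn, assignment) {
  stopifnot(inherits(bn, "pvq_bn"))
  if (is.data.frame(assignment)) {
    stopifnot(nrow(assignment) == 1)
    assignment <- unlist(lapply(assignment, as.character))
  }
  assignment <- stats::setNames(as.character(assignment), names(assignment))
  missing <- setdiff(bn$dag$nodes, names(assignment))
  if (length(missing) > 0) {
    rlang::abort(paste0("assignment must cover every node; missing: ",
                        paste(missing, collapse = ", ")),
                 class = "pvq_inference_error")
  }
  prod(vapply(bn$dag$nodes, function(v) {
    cpt <- bn$cpts[[v]]
    k <- match(assignment[[v]], bn$states[[v]])
    if (is.na(k)) rlang::abort(sprintf("invalid state for %s: %s", v, assignment[[v]]),
                               class = "pvq_state_error")
    j <- 1L; mult <- 1L
    for (p in cpt$parents) {
      s <- match(assignment[[p]], bn$states[[p]])
      if (is.na(s)) rlang::abort(sprintf("invalid state for %s: %s", p, assignment[[p]]),
                                 class = "pvq_state_error")
      j <- j + (s - 1L) * mult
      mult <- mult * length(bn$states[[p]])
    }
    cpt$prob[j, k]
  }, numeric(1)))
}

#' Ancestral sampling from a network
#'
#' Samples nodes in topological order, each from its CPT row given the
#' already-sampled parent states. Reproducible given the seed.
#'
#' @param bn A `pvq_bn`.
#' @param n Number of samples.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble with one character column per node.
#' @export
sample_network <- function(bn, n, seed = NULL) {
  stopifnot(inherits(bn, "pvq_bn"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ord <- topological_order(bn$dag)
  out <- matrix(0L, n, length(ord), dimnames = list(NULL, ord))
  for (v in ord) {
    cpt <- bn$cpts[[v]]
    if (length(cpt$parents) == 0) {
      j <- rep(1L, n)
    } else {
      j <- rep(1L, n); mult <- 1L
      for (p in cpt$parents) {
        j <- j + (out[, p] - 1L) * mult
        mult <- mult * length(bn$states[[p]])
      }
    }
    u <- stats::runif(n)
    cum <- matrix(t(apply(cpt$prob, 1, cumsum)), nrow = nrow(cpt$prob))  # q x r
    # state = 1 + number of cumulative cells strictly below u, clamped
    out[, v] <- pmin(1L + rowSums(cum[j, , drop = FALSE] < u),
                     length(bn$states[[v]]))
  }
  tibble::as_tibble(as.data.frame(
    lapply(stats::setNames(ord, ord), function(v) bn$states[[v]][out[, v]])
  ))[, bn$dag$nodes]
}
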