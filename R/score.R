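# Decomposable network scores for discrete data.
#
# Both scores factorize over families (node, parents), so search moves are
# evaluated from local differences only. Data is pre-encoded once into an
# integer matrix to make the count tabulations cheap.

#' Score specification
#'
#' @param family `"bic"` (penalized maximized multinomial log-likelihood)
#'   or `"bdeu"` (Bayesian Dirichlet-equivalent marginal likelihood with a
#'   uniform structural prior).
#' @param ess Equivalent sample size of the BDeu prior (ignored for BIC).
#' @return An object of class `pvq_score_spec`.
#' @export
score_spec <- function(family = c("bic", "bdeu"), ess = 1) {
  family <- match.arg(family)
  if (ess <= 0) rlang::abort("ess must be positive", class = "pvq_score_error")
  structure(list(family = family, ess = ess), class = "pvq_score_spec")
}

#' Encode a discrete data table against declared state sets
#'
#' @param data Data frame whose columns are discrete variables.
#' @param states Named list of state vectors; must cover every column used.
#' @return An object of class `pvq_encoded`: integer matrix (1-based state
#'   indices), cardinalities, and n.
#' @export
encode_discrete <- function(data, states) {
  data <- as.data.frame(data)
  nodes <- names(states)
  missing <- setdiff(nodes, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("data lacks column(s): ", paste(missing, collapse = ", ")),
                 class = "pvq_state_error")
  }
  if (nrow(data) == 0) rlang::abort("empty data", class = "pvq_state_error")
  mat <- matrix(0L, nrow(data), length(nodes), dimnames = list(NULL, nodes))
  for (v in nodes) {
    idx <- match(as.character(data[[v]]), states[[v]])
    if (anyNA(idx)) {
      bad <- unique(as.character(data[[v]])[is.na(idx)])
      rlang::abort(sprintf("variable %s has value(s) outside its state set: %s",
                           v, paste(bad, collapse = ", ")),
                   class = "pvq_state_error")
    }
    mat[, v] <- idx
  }
  structure(list(mat = mat,
                 card = vapply(states, length, integer(1)),
                 states = states,
                 n = nrow(data)),
            class = "pvq_encoded")
}

# Parent-configuration index (1-based, column-major in parent order).
config_index <- function(mat, parents, card) {
  if (length(parents) == 0) return(rep(1L, nrow(mat)))
  idx <- rep(1L, nrow(mat))
  mult <- 1L
  for (p in parents) {
    idx <- idx + (mat[, p] - 1L) * mult
    mult <- mult * card[[p]]
  }
  idx
}

# Family counts: r x q matrix of n_jk.
family_counts <- function(enc, node, parents) {
  r <- enc$card[[node]]
  q <- if (length(parents) == 0) 1L else prod(enc$card[parents])
  j <- config_index(enc$mat, parents, enc$card)
  cell <- enc$mat[, node] + r * (j - 1L)
  matrix(tabulate(cell, nbins = r * q), nrow = r)
}

#' Local (per-family) network score
#'
#' BIC: maximized multinomial log-likelihood of the child given its parents
#' minus (log N / 2) times the number of free parameters (r-1)q. BDeu: the
#' log marginal likelihood of the family under a Dirichlet prior with total
#' equivalent sample size `ess` spread uniformly over the child x parent
#' table.
#'
#' @param node Child node name.
#' @param parents Character vector of parent names (possibly empty).
#' @param enc Encoded data from [encode_discrete()].
#' @param spec A `pvq_score_spec`.
#' @return The local score (a real number).
#' @export
local_score <- function(node, parents, enc, spec = score_spec()) {
  stopifnot(inherits(enc, "pvq_encoded"))
  counts <- family_counts(enc, node, parents)
  r <- nrow(counts); q <- ncol(counts)
  if (spec$family == "bic") {
    nj <- colSums(counts)
    nz <- counts > 0
    ll <- sum(counts[nz] * log(counts[nz] / rep(nj, each = r)[nz]))
    ll - 0.5 * log(enc$n) * (r - 1) * q
  } else {
    ajk <- spec$ess / (r * q)
    aj <- spec$ess / q
    nj <- colSums(counts)
    sum(lgamma(aj) - lgamma(aj + nj)) +
      sum(lgamma(ajk + counts) - lgamma(ajk))
  }
}

#' Score a whole network structure
#'
#' By decomposability this is the sum of [local_score()] over all families.
#'
#' @param dag A `pvq_dag`.
#' @param data Data frame, or pre-encoded `pvq_encoded`.
#' @param spec A `pvq_score_spec`.
#' @return The network score.
#' @export
score_network <- function(dag, data, spec = score_spec()) {
  enc <- if (inherits(data, "pvq_encoded")) data else
    encode_discrete(data, dag$states)
  sum(vapply(dag$nodes,
             function(v) local_score(v, dag_parents(dag, v), enc, spec),
             numeric(1)))
}
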