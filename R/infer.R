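# Exact inference by variable elimination.
#
# Factors are dense numeric arrays stored column-major over their variable
# list. Networks in this problem are small (a dozen nodes, cardinalities
# 2..9), so exact elimination with a min-degree order is fast and there is
# no need for approximate schemes.

new_factor <- function(vars, card, val) {
  list(vars = vars, card = card, val = val)
}

cpt_factor <- function(bn, node) {
  cpt <- bn$cpts[[node]]
  vars <- c(node, cpt$parents)
  card <- vapply(bn$states[vars], length, integer(1))
  # prob is q x r (parent configs column-major x child states); factor wants
  # value indexed column-major over (child, parents...) = t(prob) flattened
  new_factor(vars, card, as.numeric(t(cpt$prob)))
}

factor_reduce <- function(f, evidence) {
  keep <- !(f$vars %in% names(evidence))
  if (all(keep)) return(f)
  idx_grid <- lapply(seq_along(f$vars), function(i) {
    if (keep[i]) seq_len(f$card[i]) else evidence[[f$vars[i]]]
  })
  grid <- as.matrix(expand.grid(idx_grid))
  lin <- as.vector((grid - 1) %*% cumprod(c(1, f$card[-length(f$card)]))) + 1
  new_factor(f$vars[keep], f$card[keep], f$val[lin])
}

factor_product <- function(f, g) {
  if (length(f$vars) == 0) return(new_factor(g$vars, g$card, g$val * f$val))
  if (length(g$vars) == 0) return(new_factor(f$vars, f$card, f$val * g$val))
  vars <- union(f$vars, g$vars)
  card <- integer(length(vars))
  card[match(f$vars, vars)] <- f$card
  card[match(g$vars, vars)] <- g$card
  # strides of each input factor inside the joint index space
  stride_in <- function(h) {
    s <- numeric(length(vars))
    s[match(h$vars, vars)] <- cumprod(c(1, h$card[-length(h$card)]))
    s
  }
  grid <- as.matrix(expand.grid(lapply(card, seq_len))) - 1
  fi <- as.vector(grid %*% stride_in(f)) + 1
  gi <- as.vector(grid %*% stride_in(g)) + 1
  new_factor(vars, card, f$val[fi] * g$val[gi])
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  if (length(f$vars) == 1) {
    return(new_factor(character(0), integer(0), sum(f$val)))
  }
  arr <- array(f$val, dim = f$card)
  val <- apply(arr, seq_along(f$card)[-i], sum)
  new_factor(f$vars[-i], f$card[-i], as.numeric(val))
}

#' Exact posterior distribution of one node
#'
#' Computes P(target | evidence) by variable elimination with a min-degree
#' elimination order over the factor-interaction graph. Evidence with zero
#' probability under the network raises an inconsistent-evidence error.
#'
#' @param bn A `pvq_bn`.
#' @param target Node name (must not be in the evidence).
#' @param evidence Named character vector (or one-row data frame) of
#'   observed states; may be empty for the marginal.
#' @return Named numeric vector over the target's states, summing to 1.
#' @export
#' @examples
#' bn <- bayes_net(
#'   list(a = c("y", "n"), b = c("y", "n")),
#'   data.frame(from = "a", to = "b"),
#'   list(a = matrix(c(0.3, 0.7), 1), b = rbind(c(0.9, 0.1), c(0.2, 0.8)))
#' )
#' posterior(bn, "b", c(a = "y"))
posterior <- function(bn, target, evidence = NULL) {
  stopifnot(inherits(bn, "pvq_bn"))
  if (!target %in% bn$dag$nodes) {
    rlang::abort(sprintf("unknown target node: %s", target),
                 class = "pvq_inference_error")
  }
  ev <- .as_evidence(bn, evidence)
  if (target %in% names(ev)) {
    rlang::abort("target must not appear in the evidence",
                 class = "pvq_inference_error")
  }
  factors <- lapply(bn$dag$nodes, function(v) factor_reduce(cpt_factor(bn, v), ev))
  elim <- setdiff(bn$dag$nodes, c(target, names(ev)))
  while (length(elim) > 0) {
    # min-degree: eliminate the variable appearing with fewest distinct
    # neighbors across current factors (ties: alphabetical)
    neigh <- lapply(elim, function(v) {
      unique(unlist(lapply(factors, function(f) if (v %in% f$vars) f$vars)))
    })
    deg <- vapply(neigh, length, integer(1))
    ord <- order(deg, elim)
    v <- elim[ord[1]]
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(prod_f, v)))
    elim <- setdiff(elim, v)
  }
  res <- Reduce(factor_product, factors)
  for (v in setdiff(res$vars, target)) res <- factor_marginalize(res, v)
  z <- sum(res$val)
  if (!is.finite(z) || z <= 0) {
    rlang::abort("evidence has zero probability under the network",
                 class = "pvq_inconsistent_evidence")
  }
  stats::setNames(res$val / z, bn$states[[target]])
}

.as_evidence <- function(bn, evidence) {
  if (is.null(evidence) || length(evidence) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (is.data.frame(evidence)) {
    stopifnot(nrow(evidence) == 1)
    evidence <- unlist(lapply(evidence, as.character))
  }
  vals <- as.character(evidence)
  vars <- names(evidence)
  bad <- setdiff(vars, bn$dag$nodes)
  if (length(bad) > 0) {
    rlang::abort(paste0("evidence names unknown node(s): ",
                        paste(bad, collapse = ", ")),
                 class = "pvq_inference_error")
  }
  idx <- mapply(function(v, s) match(s, bn$states[[v]]), vars, vals)
  if (anyNA(idx)) {
    bad <- vars[is.na(idx)]
    rlang::abort(paste0("evidence state invalid for node(s): ",
                        paste(bad, collapse = ", ")),
                 class = "pvq_state_error")
  }
  stats::setNames(as.integer(idx), vars)
}

#' Predict suicidal-behavior risk from feature evidence
#'
#' Computes the exact posterior probability of the `with_sb` state of the
#' network's group node given the supplied feature evidence, and thresholds
#' it into a predicted group. The boundary probability is classified as
#' `with_sb`.
#'
#' @param bn A fitted `pvq_bn` containing an `sb_group` node (name
#'   configurable via `sb_node`).
#' @param evidence Named character vector or one-row data frame of feature
#'   states.
#' @param threshold Classification threshold (default 0.5).
#' @param sb_node Name of the group node (default `"sb_group"`).
#' @return A list with `probability` (posterior of `with_sb`) and
#'   `predicted` (`"with_sb"` / `"without_sb"`).
#' @export
predict_risk <- function(bn, evidence, threshold = 0.5, sb_node = "sb_group") {
  if (!sb_node %in% bn$dag$nodes) {
    rlang::abort(sprintf("network has no %s node", sb_node),
                 class = "pvq_inference_error")
  }
  post <- posterior(bn, sb_node, evidence)
  p <- unname(post[["with_sb"]])
  list(probability = p,
       predicted = if (p >= threshold) "with_sb" else "without_sb")
}
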