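# Principal-component summary of the six DEQ items.
#
# The six depressive-experiences items are only weakly inter-correlated, so
# instead of a mean composite they are summarized by the first two principal
# components of their correlation matrix ("low self-esteem" and
# "interpersonal sensitivity") and the sign pattern of a patient's two
# scores is coded as a quadrant 00/01/10/11.

DEQ_ITEMS <- paste0("deq_", c(3, 16, 19, 48, 56, 62))

#' Fit the two-component PCA model for the DEQ block
#'
#' Standardizes the six items by their training mean and standard deviation
#' and eigendecomposes the 6x6 correlation matrix. The first two components
#' are retained (a fixed choice, not a variance cutoff). Sign indeterminacy
#' is resolved by orienting each component so the loading of DEQ item 19
#' ("I become terrified when I feel alone") is non-negative, which matches
#' the instrument's published orientation where item 19 loads positively on
#' both components.
#'
#' @param deq A data frame or matrix with columns `deq_3`, `deq_16`,
#'   `deq_19`, `deq_48`, `deq_56`, `deq_62` (n rows, responses 1..7).
#' @return An object of class `pvq_pca`: list with `item_order`, `means`,
#'   `sds`, `loadings` (6 x 2, unit columns), `variance_proportions`
#'   (length 6, eigenvalues / 6).
#' @export
fit_deq_pca <- function(deq) {
  X <- as.matrix(as.data.frame(deq)[, DEQ_ITEMS, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) rlang::abort("DEQ matrix contains NA", class = "pvq_scoring_error")
  if (nrow(X) < 7) {
    rlang::abort("need at least 7 rows to fit the DEQ PCA",
                 class = "pvq_sample_size_error")
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(paste0("constant DEQ column(s): ",
                        paste(DEQ_ITEMS[sds == 0], collapse = ", ")),
                 class = "pvq_degenerate_error")
  }
  means <- colMeans(X)
  R <- stats::cor(X)
  ed <- eigen(R, symmetric = TRUE)
  L <- ed$vectors[, 1:2, drop = FALSE]
  i19 <- match("deq_19", DEQ_ITEMS)
  for (c in 1:2) if (L[i19, c] < 0) L[, c] <- -L[, c]
  dimnames(L) <- list(DEQ_ITEMS, c("PC1", "PC2"))
  structure(
    list(item_order = DEQ_ITEMS,
         means = stats::setNames(means, DEQ_ITEMS),
         sds = stats::setNames(sds, DEQ_ITEMS),
         loadings = L,
         variance_proportions = ed$values / ncol(X)),
    class = "pvq_pca"
  )
}

#' Project DEQ responses onto the fitted components
#'
#' @param model A `pvq_pca` from [fit_deq_pca()].
#' @param deq Named vector, one-row data frame, or n-row data frame/matrix
#'   of DEQ responses.
#' @return A tibble with columns `pc1_score`, `pc2_score` (one row per
#'   input row). Scores are centered: projecting the training means gives
#'   (0, 0).
#' @export
project_deq <- function(model, deq) {
  stopifnot(inherits(model, "pvq_pca"))
  if (!is.data.frame(deq) && is.null(dim(deq))) {
    deq <- as.data.frame(as.list(deq))
  }
  X <- as.matrix(as.data.frame(deq)[, model$item_order, drop = FALSE])
  storage.mode(X) <- "double"
  Z <- sweep(sweep(X, 2, model$means), 2, model$sds, "/")
  S <- Z %*% model$loadings
  tibble::tibble(pc1_score = unname(S[, 1]), pc2_score = unname(S[, 2]))
}

#' Assign the DEQ quadrant code
#'
#' Codes the sign pattern of the two component scores: first digit 1 iff
#' `pc1_score >= threshold` (low self-esteem side), second digit 1 iff
#' `pc2_score >= threshold` (high interpersonal sensitivity side). The
#' boundary is assigned to the "high" side. With threshold 0 (the training
#' mean of centered scores) the four quadrants are: 00 high self-esteem /
#' low interpersonal sensitivity, 01 high self-esteem / high sensitivity,
#' 10 low self-esteem / low sensitivity, 11 low self-esteem / high
#' sensitivity.
#'
#' @param pc1_score,pc2_score Numeric vectors of component scores.
#' @param threshold Cut separating "low" from "high"; default 0.
#' @return Character vector with values in `c("00", "01", "10", "11")`.
#' @export
#' @examples
#' assign_quadrant(-0.5, 1.2)  # "01"
assign_quadrant <- function(pc1_score, pc2_score, threshold = 0) {
  if (any(!is.finite(pc1_score)) || any(!is.finite(pc2_score))) {
    rlang::abort("component scores must be finite", class = "pvq_scoring_error")
  }
  paste0(as.integer(pc1_score >= threshold), as.integer(pc2_score >= threshold))
}

#' @export
print.pvq_pca <- function(x, ...) {
  cat("DEQ principal-component model (2 components retained)\n")
  cat(sprintf("variance explained: PC1 %.1f%%, PC2 %.1f%% (cumulative %.1f%%)\n",
              100 * x$variance_proportions[1], 100 * x$variance_proportions[2],
              100 * sum(x$variance_proportions[1:2])))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Tidy a fitted DEQ PCA model
#'
#' @param x A `pvq_pca`.
#' @param ... Unused.
#' @return A tibble with one row per item x component: `item`, `component`,
#'   `loading`.
#' @export
tidy.pvq_pca <- function(x, ...) {
  tibble::tibble(
    item = rep(x$item_order, 2),
    component = rep(c("PC1", "PC2"), each = length(x$item_order)),
    loading = c(x$loadings[, 1], x$loadings[, 2])
  )
}

#' One-row summary of a fitted DEQ PCA model
#'
#' @param x A `pvq_pca`.
#' @param ... Unused.
#' @return A tibble with the variance proportions of the retained
#'   components and their cumulative share.
#' @export
glance.pvq_pca <- function(x, ...) {
  tibble::tibble(
    prop_var_pc1 = x$variance_proportions[1],
    prop_var_pc2 = x$variance_proportions[2],
    cum_var_2 = sum(x$variance_proportions[1:2])
  )
}
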