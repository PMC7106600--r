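# Fitting and applying the full item -> feature transform set.

#' Fit all feature transforms on a training cohort
#'
#' Fits, on the training records only: the DEQ two-component PCA, and
#' k-level quantile discretizers for the OQ and RFL mean composites. The
#' result is everything needed to map raw item responses to the discrete
#' feature set deterministically, so held-out cases can be scored without
#' touching their data during fitting.
#'
#' @param cohort Validated cohort tibble (training records only).
#' @param k Number of discretization levels for each composite (default 3).
#' @param quadrant_threshold Cut separating low/high component scores
#'   (default 0, the training mean of centered scores).
#' @param reversed OQ items to reverse-key (default 13, 24, 31).
#' @return An object of class `pvq_transforms`.
#' @export
fit_feature_transforms <- function(cohort, k = 3, quadrant_threshold = 0,
                                   reversed = OQ_REVERSED) {
  cohort <- tibble::as_tibble(cohort)
  pca <- fit_deq_pca(cohort)
  sc <- score_cohort_items(cohort, reversed)
  structure(
    list(
      pca = pca,
      oq_disc = fit_discretizer(sc$oq_mean, k),
      rfl_disc = fit_discretizer(sc$rfl_mean, k),
      k = as.integer(k),
      quadrant_threshold = quadrant_threshold,
      reversed = as.integer(reversed)
    ),
    class = "pvq_transforms"
  )
}

# Vectorized composite scoring of a whole cohort (internal).
score_cohort_items <- function(cohort, reversed = OQ_REVERSED) {
  oq_ids <- c(3L, 8L, 13L, 24L, 31L)
  oq <- as.matrix(cohort[, paste0("oq_", oq_ids)])
  rev_cols <- paste0("oq_", intersect(oq_ids, reversed))
  oq_scored <- oq
  oq_scored[, rev_cols] <- 4 - oq_scored[, rev_cols]
  rfl_ids <- c(2L, 5L, 10L, 12L, 14L, 17L, 19L, 20L, 22L, 24L, 40L, 45L, 50L)
  rfl <- as.matrix(cohort[, paste0("rfl_", rfl_ids)])
  tibble::tibble(
    oq_mean = rowMeans(oq_scored[, paste0("oq_", setdiff(oq_ids, 8L)), drop = FALSE]),
    oq8 = as.integer(oq[, "oq_8"]),
    rfl_mean = rowMeans(rfl),
    rfl25 = as.integer(as.matrix(cohort[, "rfl_25"])[, 1])
  )
}

#' Build the discrete feature table for a cohort
#'
#' Applies fitted transforms to every record: composite scoring with
#' reverse keying, PCA projection and quadrant assignment, quantile
#' discretization of the composites, demographic pass-through, and the
#' binary suicidal-behavior group label. Deterministic given the transforms;
#' the transforms must never have been fitted on held-out records that
#' appear here (pipeline hygiene is the caller's contract, enforced by
#' [loocv()] and [repeated_kfold()]).
#'
#' @param cohort Validated cohort tibble.
#' @param transforms A `pvq_transforms` from [fit_feature_transforms()].
#' @return A tibble with one row per record: `patient_id`, `oq_mean`, `oq8`,
#'   `rfl_mean`, `rfl25`, `pc1_score`, `pc2_score`, `deq_quadrant`,
#'   `oq_level`, `rfl_level`, the eight demographic columns, and `sb_group`.
#' @export
build_feature_table <- function(cohort, transforms) {
  stopifnot(inherits(transforms, "pvq_transforms"))
  cohort <- tibble::as_tibble(cohort)
  sc <- score_cohort_items(cohort, transforms$reversed)
  pj <- project_deq(transforms$pca, cohort)
  demo <- cohort[, names(pvq_schema()$demographics)]
  tibble::tibble(
    patient_id = as.character(cohort$patient_id),
    oq_mean = sc$oq_mean,
    oq8 = sc$oq8,
    rfl_mean = sc$rfl_mean,
    rfl25 = sc$rfl25,
    pc1_score = pj$pc1_score,
    pc2_score = pj$pc2_score,
    deq_quadrant = assign_quadrant(pj$pc1_score, pj$pc2_score,
                                   transforms$quadrant_threshold),
    oq_level = apply_discretizer(transforms$oq_disc, sc$oq_mean),
    rfl_level = apply_discretizer(transforms$rfl_disc, sc$rfl_mean)
  ) |>
    dplyr::bind_cols(demo) |>
    dplyr::mutate(sb_group = derive_sb_group(cohort$sb_status))
}

#' Serialize fitted transforms to JSON
#'
#' Writes means, standard deviations, loadings, bin edges, the quadrant
#' threshold and the reversal map so that scoring is reproducible across
#' processes.
#'
#' @param transforms A `pvq_transforms`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
transforms_to_json <- function(transforms, path = NULL) {
  stopifnot(inherits(transforms, "pvq_transforms"))
  x <- list(
    pca = list(
      item_order = transforms$pca$item_order,
      means = as.list(transforms$pca$means),
      sds = as.list(transforms$pca$sds),
      loadings = list(pc1 = unname(transforms$pca$loadings[, 1]),
                      pc2 = unname(transforms$pca$loadings[, 2])),
      variance_proportions = transforms$pca$variance_proportions
    ),
    oq_edges = transforms$oq_disc$edges,
    rfl_edges = transforms$rfl_disc$edges,
    k = transforms$k,
    quadrant_threshold = transforms$quadrant_threshold,
    reversed = transforms$reversed
  )
  js <- jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Restore fitted transforms from JSON
#'
#' @param path Path to a file written by [transforms_to_json()], or a JSON
#'   string.
#' @return A `pvq_transforms`.
#' @export
transforms_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  L <- cbind(x$pca$loadings$pc1, x$pca$loadings$pc2)
  dimnames(L) <- list(x$pca$item_order, c("PC1", "PC2"))
  pca <- structure(
    list(item_order = x$pca$item_order,
         means = unlist(x$pca$means)[x$pca$item_order],
         sds = unlist(x$pca$sds)[x$pca$item_order],
         loadings = L,
         variance_proportions = x$pca$variance_proportions),
    class = "pvq_pca"
  )
  structure(
    list(pca = pca,
         oq_disc = structure(list(edges = x$oq_edges, k = as.integer(x$k)),
                             class = "pvq_discretizer"),
         rfl_disc = structure(list(edges = x$rfl_edges, k = as.integer(x$k)),
                              class = "pvq_discretizer"),
         k = as.integer(x$k),
         quadrant_threshold = x$quadrant_threshold,
         reversed = as.integer(x$reversed)),
    class = "pvq_transforms"
  )
}
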