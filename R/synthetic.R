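# Synthetic cohort generator with a known ground truth.
#
# The generator samples feature-level truth first (from a known discrete
# network over quadrant, composite levels, demographics and the SB label)
# and then renders item-level Likert answers consistent with those
# features, so the preprocessing stage provably inverts the rendering in
# expectation and every recovery property (PCA loadings, composite levels,
# structure, CPTs, Bayes rate) is testable without any real data.

#' Default ground-truth network for cohort generation
#'
#' Topology (illustrative, shipped as data not dogma): gender ->
#' deq_quadrant, age_band -> rfl_level, and sb_group with parents
#' {deq_quadrant, rfl_level, oq_level, oq8}. The SB conditional table is a
#' logistic risk score: distress (high OQ composite, frequent ideation
#' item, low self-esteem quadrants) raises risk; reasons-for-living
#' protect. The intercept is set so the marginal SB rate is close to 1/2,
#' matching a balanced two-group cohort.
#'
#' @param schema Schema (default the enrollment-style `"table3"` age bands,
#'   whose marginals the generator uses).
#' @return A `pvq_bn` over the feature-level variables.
#' @export
default_truth_network <- function(schema = pvq_schema("table3")) {
  st <- feature_states(schema, k = 3)
  nodes <- c("gender", "age_band", "oq_level", "oq8", "deq_quadrant",
             "rfl_level", "sb_group")
  states <- st[nodes]
  arcs <- rbind(
    c("gender", "deq_quadrant"),
    c("age_band", "rfl_level"),
    c("deq_quadrant", "sb_group"),
    c("rfl_level", "sb_group"),
    c("oq_level", "sb_group"),
    c("oq8", "sb_group")
  )
  colnames(arcs) <- c("from", "to")

  # quadrant | gender: modest dependence (women lean toward the
  # high-sensitivity quadrants), shares near 1/4 overall
  q_w <- c(0.22, 0.26, 0.26, 0.26)
  q_m <- c(0.34, 0.21, 0.24, 0.21)
  q_o <- rep(0.25, 4)
  quadrant_cpt <- rbind(q_w, q_m, q_o)

  # rfl_level | age_band: protection increases with age
  rfl_cpt <- t(vapply(seq_len(6), function(i) {
    w <- (i - 1) / 5
    p <- (1 - w) * c(0.42, 0.34, 0.24) + w * c(0.24, 0.34, 0.42)
    p / sum(p)
  }, numeric(3)))

  # sb_group | (quadrant, rfl, oq, oq8) via a logistic risk score. Effect
  # sizes are chosen so every arc into the group node is strong enough for
  # penalized-likelihood recovery at large n; the intercept is solved so
  # the marginal group rate matches a balanced cohort (0.5015).
  # parents in sorted order: deq_quadrant, oq8, oq_level, rfl_level
  q_eff <- c("00" = -1.0, "01" = -0.35, "10" = 0.75, "11" = 1.1)
  grid <- expand.grid(deq_quadrant = seq_len(4), oq8 = seq_len(5),
                      oq_level = seq_len(3), rfl_level = seq_len(3))
  # main effects plus interactions: ideation amplifies distress, reasons
  # for living buffer the low-self-esteem quadrants. The interactions make
  # the conditional genuinely table-valued (not additive), so the full
  # parent set is identifiable from data.
  q_hi <- as.integer(grid$deq_quadrant >= 3)   # quadrants 10 and 11
  lp0 <- q_eff[grid$deq_quadrant] +
    0.75 * (grid$oq8 - 3) +          # oq8 state j = answer position j-1
    1.5 * (grid$oq_level - 2) -
    1.15 * (grid$rfl_level - 2) +
    0.5 * (grid$oq_level - 2) * (grid$oq8 - 3) -
    0.45 * q_hi * (grid$rfl_level - 2) -
    0.35 * (grid$oq8 - 3) * (grid$rfl_level - 2)
  # joint weight of each parent configuration (parents have no common
  # ancestors, so their joint is the product of their marginals)
  q_marg <- as.numeric(0.7954 * q_w + 0.2046 * q_m)
  age_marg <- c(0.1169, 0.1831, 0.1892, 0.1923, 0.2246, 0.0938) / 0.9999
  rfl_marg <- as.numeric(age_marg %*% rfl_cpt)
  oq8_marg <- c(0.35, 0.25, 0.20, 0.12, 0.08)
  w <- q_marg[grid$deq_quadrant] * oq8_marg[grid$oq8] *
    (1 / 3) * rfl_marg[grid$rfl_level]
  b0 <- stats::uniroot(function(b) sum(w / (1 + exp(-(b + lp0)))) - 0.5015,
                       c(-4, 4))$root
  p_sb <- 1 / (1 + exp(-(b0 + lp0)))
  sb_cpt <- cbind(with_sb = p_sb, without_sb = 1 - p_sb)

  bayes_net(states, arcs, list(
    gender = matrix(c(0.7954, 0.2046, 0), 1),
    age_band = matrix(c(0.1169, 0.1831, 0.1892, 0.1923, 0.2246, 0.0938) / 0.9999, 1),
    oq_level = matrix(c(1, 1, 1) / 3, 1),
    oq8 = matrix(c(0.35, 0.25, 0.20, 0.12, 0.08), 1),
    deq_quadrant = quadrant_cpt,
    rfl_level = rfl_cpt,
    sb_group = sb_cpt
  ))
}

#' Strong-signal ground-truth network
#'
#' A deliberately simple, strongly dependent variant used to test how
#' closely the end-to-end pipeline approaches a known classification
#' ceiling: the group node depends only on the OQ and RFL composite levels,
#' with large effects, so its conditional table is small enough to be
#' estimated and its structure recovered even at modest cohort sizes. The
#' remaining feature variables keep their marginals and backbone arcs but
#' carry no group signal.
#'
#' @param schema Schema (default `"table3"` age bands).
#' @return A `pvq_bn`.
#' @export
strong_truth_network <- function(schema = pvq_schema("table3")) {
  base <- default_truth_network(schema)
  states <- base$states
  arcs <- rbind(
    c("gender", "deq_quadrant"),
    c("age_band", "rfl_level"),
    c("oq_level", "sb_group"),
    c("rfl_level", "sb_group")
  )
  colnames(arcs) <- c("from", "to")
  # parents in sorted order: oq_level, rfl_level
  grid <- expand.grid(oq_level = seq_len(3), rfl_level = seq_len(3))
  lp0 <- 2.6 * (grid$oq_level - 2) - 2.0 * (grid$rfl_level - 2) +
    0.5 * (grid$oq_level - 2) * (grid$rfl_level - 2)
  age_marg <- c(0.1169, 0.1831, 0.1892, 0.1923, 0.2246, 0.0938) / 0.9999
  rfl_marg <- as.numeric(age_marg %*% base$cpts$rfl_level$prob)
  w <- (1 / 3) * rfl_marg[grid$rfl_level]
  # every conditional row is kept away from the 0.5 decision boundary
  # (logit margin 0.45), so the classification ceiling is stable under
  # resampling; the intercept targets a balanced marginal group rate
  push <- function(x) x + 0.45 * sign(x)
  b0 <- stats::optimize(function(b) {
    abs(sum(w / (1 + exp(-push(b + lp0)))) - 0.5015)
  }, c(-4, 4))$minimum
  p_sb <- 1 / (1 + exp(-push(b0 + lp0)))
  bayes_net(states, arcs, list(
    gender = base$cpts$gender$prob,
    age_band = base$cpts$age_band$prob,
    oq_level = base$cpts$oq_level$prob,
    oq8 = base$cpts$oq8$prob,
    deq_quadrant = base$cpts$deq_quadrant$prob,
    rfl_level = base$cpts$rfl_level$prob,
    sb_group = cbind(with_sb = p_sb, without_sb = 1 - p_sb)
  ))
}

#' Chance-level ground-truth network
#'
#' The group node is independent of every feature (a balanced coin), so
#' any cross-validated pipeline with correct hygiene must score at chance;
#' a score materially above 0.5 balanced accuracy on cohorts from this
#' network indicates information leaking from held-out cases into fitting.
#'
#' @param schema Schema (default `"table3"` age bands).
#' @return A `pvq_bn`.
#' @export
null_truth_network <- function(schema = pvq_schema("table3")) {
  base <- default_truth_network(schema)
  arcs <- rbind(
    c("gender", "deq_quadrant"),
    c("age_band", "rfl_level")
  )
  colnames(arcs) <- c("from", "to")
  bayes_net(base$states, arcs, list(
    gender = base$cpts$gender$prob,
    age_band = base$cpts$age_band$prob,
    oq_level = base$cpts$oq_level$prob,
    oq8 = base$cpts$oq8$prob,
    deq_quadrant = base$cpts$deq_quadrant$prob,
    rfl_level = base$cpts$rfl_level$prob,
    sb_group = matrix(c(0.5015, 0.4985), 1,
                      dimnames = list(NULL, c("with_sb", "without_sb")))
  ))
}

#' Generator configuration
#'
#' Defaults emulate the study cohort: n = 650, two near-balanced label
#' groups, highly inter-correlated RFL and OQ item blocks rendered from a
#' shared factor per block, DEQ items rendered from two orthogonal
#' components with the published loading pattern (variances scaled so
#' inter-item correlations stay weak), demographic marginals from the
#' published sample description, and a known feature-level truth network.
#'
#' @param n Cohort size (default 650).
#' @param oq_factor_loading,rfl_factor_loading Standardized loading of each
#'   item on its block factor; within-block latent correlation is its
#'   square (default 0.93, i.e. ~0.86 latent correlation, a "highly
#'   inter-correlated" block).
#' @param band_margin Fraction of each composite-level band left empty at
#'   both edges when drawing the block latent (default 0.22). The gap keeps
#'   latents away from the quantile bin boundaries so the discretized
#'   composites recover the true level faithfully — the generator's design
#'   goal is that preprocessing provably inverts the rendering.
#' @param quadrant_margin Minimum magnitude of each DEQ component score, as
#'   a fraction of the component standard deviation (default 0.6); the
#'   residual magnitude is rescaled so component variances still equal
#'   `deq_component_vars`. Keeps scores away from the quadrant boundary for
#'   the same reason.
#' @param deq_loadings 6 x 2 matrix of component loadings (default: the
#'   published pattern, columns normalized to unit length).
#' @param deq_component_vars Variances of the two component scores.
#' @param deq_noise_sd Per-item residual standard deviation.
#' @param truth_network A `pvq_bn` over feature-level variables including
#'   `sb_group` (default [default_truth_network()]).
#' @param demographic_marginals Named list of probability vectors for the
#'   demographics not generated by the truth network.
#' @param severity_split Probabilities of (ideation, low-severity attempt,
#'   high-severity attempt) within the with-SB group.
#' @param schema Questionnaire schema matching the truth network's age
#'   bands.
#' @return An object of class `pvq_generator_config`.
#' @export
generator_config <- function(n = 650,
                             oq_factor_loading = 0.93,
                             rfl_factor_loading = 0.93,
                             band_margin = 0.22,
                             quadrant_margin = 0.6,
                             deq_loadings = NULL,
                             deq_component_vars = 0.65 * c(1.452, 1.131)^2,
                             deq_noise_sd = NULL,
                             truth_network = NULL,
                             demographic_marginals = NULL,
                             severity_split = c(ideation = 170, low = 77, high = 79) / 326,
                             schema = pvq_schema("table3")) {
  if (is.null(deq_loadings)) {
    L <- cbind(c(-0.277, 0.464, 0.357, -0.509, 0.184, -0.537),
               c(0.515, 0.286, 0.471, 0.234, 0.555, 0.262))
    deq_loadings <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  }
  dimnames(deq_loadings) <- list(DEQ_ITEMS, c("PC1", "PC2"))
  if (is.null(deq_noise_sd)) {
    # residual noise fills item variance up to ~1 per standardized item
    deq_noise_sd <- sqrt(max(1e-6, (6 - sum(deq_component_vars)) / 6))
  }
  if (is.null(truth_network)) truth_network <- default_truth_network(schema)
  defaults <- list(
    diagnosis = c(mild_depressive = 0.0185, moderate_depressive = 0.0831,
                  major_depressive = 0.4338, bipolar = 0.1615,
                  adjustment = 0.1077, anxiety = 0.1154,
                  mixed_episode = 0.0231, dysthymia = 0.0108, other = 0.0461),
    children = c("0" = 0.2374, "1" = 0.3414, "2" = 0.2455, "3" = 0.1177,
                 "4" = 0.0423, "5+" = 0.0157),
    schooling = c(basic = 0.20, secondary = 0.3169, technical = 0.1831,
                  university = 0.30),
    cohabitation = c(alone = 0.1031, friends = 0, couple = 0.1292,
                     family = 0.7677),
    marital_status = c(single = 0.4169, married = 0.3662, separated = 0.12,
                       widow = 0.0492, free_union = 0.0477),
    occupation = c(employed = 0.5062, student = 0.2185, unemployed = 0.06,
                   housewife = 0.1954, `retired/not_working` = 0.02)
  )
  if (!is.null(demographic_marginals)) {
    defaults[names(demographic_marginals)] <- demographic_marginals
  }
  for (v in names(defaults)) {
    p <- defaults[[v]]
    if (abs(sum(p) - 1) > 1e-3 || any(p < 0)) {  # printed %s carry rounding
      rlang::abort(sprintf("marginal for %s must be a probability vector", v),
                   class = "pvq_generator_error")
    }
    defaults[[v]] <- p / sum(p)
  }
  if (abs(sum(severity_split) - 1) > 1e-6) {
    rlang::abort("severity_split must sum to 1", class = "pvq_generator_error")
  }
  if (oq_factor_loading <= 0 || oq_factor_loading >= 1 ||
      rfl_factor_loading <= 0 || rfl_factor_loading >= 1) {
    rlang::abort("factor loadings must lie in (0, 1)",
                 class = "pvq_generator_error")
  }
  if (band_margin < 0 || band_margin >= 0.5) {
    rlang::abort("band_margin must lie in [0, 0.5)", class = "pvq_generator_error")
  }
  structure(list(n = as.integer(n),
                 oq_factor_loading = oq_factor_loading,
                 rfl_factor_loading = rfl_factor_loading,
                 band_margin = band_margin,
                 quadrant_margin = quadrant_margin,
                 deq_loadings = deq_loadings,
                 deq_component_vars = deq_component_vars,
                 deq_noise_sd = deq_noise_sd,
                 truth_network = truth_network,
                 demographic_marginals = defaults,
                 severity_split = severity_split,
                 schema = schema),
            class = "pvq_generator_config")
}

#' Map latent values to ordinal Likert answers
#'
#' The answer is `offset` plus the number of thresholds at or below the
#' latent value, so larger latents never map to smaller answers and values
#' below every threshold give the scale minimum.
#'
#' @param latent Numeric vector.
#' @param thresholds Strictly increasing cut points.
#' @param offset Scale minimum (default 1).
#' @return Integer answers in `offset .. offset + length(thresholds)`.
#' @export
likertize <- function(latent, thresholds, offset = 1L) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    rlang::abort("thresholds must be strictly increasing",
                 class = "pvq_generator_error")
  }
  as.integer(offset) + as.integer(findInterval(latent, thresholds))
}

# Level -> latent band sampler: given ordinal level l of k on [lo, hi],
# draw uniformly inside that level's sub-interval, leaving a margin gap at
# both edges so discretization boundaries fall in low-density regions.
.band_latent <- function(level, k, lo, hi, margin = 0) {
  w <- (hi - lo) / k
  lo + (level - 1) * w + margin * w +
    stats::runif(length(level)) * w * (1 - 2 * margin)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per record: (1) feature-level states (including the SB label) are
#' sampled from the truth network by ancestral sampling; (2) block latents
#' are drawn inside the band implied by each composite level, and the DEQ
#' component scores take the half-normal magnitude with the sign pattern
#' of the sampled quadrant; (3) items are rendered from the latents through
#' the block-factor model and discretized onto their Likert scales;
#' (4) remaining demographics are sampled from their marginals and the SB
#' severity from its split. Reproducible given the seed.
#'
#' @param config A `pvq_generator_config`.
#' @param seed Integer seed.
#' @return An object of class `pvq_cohort`: `records` (a validated cohort
#'   tibble), `truth` (per-record latent scores, true feature states and
#'   true conditional SB probability), plus the config.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "pvq_generator_config"))
  set.seed(as.integer(seed))
  n <- config$n
  bn <- config$truth_network
  feat <- sample_network(bn, n, seed = NULL)

  # --- OQ block: latent f on [0,4] inside the sampled level band ----------
  oq_level <- as.integer(feat$oq_level)
  f_oq <- .band_latent(oq_level, 3, 0, 4, config$band_margin)
  lam <- config$oq_factor_loading
  sd_scale_oq <- 4 / sqrt(12)
  z_f <- (f_oq - 2) / sd_scale_oq
  oq_scored <- vapply(1:4, function(j) {
    x <- lam * z_f + sqrt(1 - lam^2) * stats::rnorm(n)
    pmin(pmax(as.integer(round(2 + sd_scale_oq * x)), 0L), 4L)
  }, integer(n))
  # scored value -> answer position (items 13/24/31 are reverse-keyed)
  oq_items <- tibble::tibble(
    oq_3 = oq_scored[, 1],
    oq_8 = as.integer(feat$oq8),
    oq_13 = 4L - oq_scored[, 2],
    oq_24 = 4L - oq_scored[, 3],
    oq_31 = 4L - oq_scored[, 4]
  )

  # --- RFL block: latent g on [1,6] inside the sampled level band ---------
  rfl_level <- as.integer(feat$rfl_level)
  g_rfl <- .band_latent(rfl_level, 3, 1, 6, config$band_margin)
  lam_r <- config$rfl_factor_loading
  sd_scale_rfl <- 5 / sqrt(12)
  z_g <- (g_rfl - 3.5) / sd_scale_rfl
  rfl_ids <- c(2, 5, 10, 12, 14, 17, 19, 20, 22, 24, 25, 40, 45, 50)
  rfl_items <- vapply(seq_along(rfl_ids), function(j) {
    x <- lam_r * z_g + sqrt(1 - lam_r^2) * stats::rnorm(n)
    pmin(pmax(as.integer(round(3.5 + sd_scale_rfl * x)), 1L), 6L)
  }, integer(n))
  colnames(rfl_items) <- paste0("rfl_", rfl_ids)

  # --- DEQ block: component scores with the quadrant's sign pattern -------
  quad <- as.character(feat$deq_quadrant)
  s1 <- ifelse(substr(quad, 1, 1) == "1", 1, -1)
  s2 <- ifelse(substr(quad, 2, 2) == "1", 1, -1)
  v <- config$deq_component_vars
  # |score| = margin + half-normal, with the half-normal scale solved so
  # E[score^2] equals the configured component variance
  pc_mag <- function(v_c) {
    m <- config$quadrant_margin * sqrt(v_c)
    k2 <- 2 * sqrt(2 / pi)
    s <- (-m * k2 / 2) + sqrt((m * k2 / 2)^2 - (m^2 - v_c))
    m + abs(stats::rnorm(n, sd = s))
  }
  pc1 <- s1 * pc_mag(v[1])
  pc2 <- s2 * pc_mag(v[2])
  Z <- cbind(pc1, pc2) %*% t(config$deq_loadings) +
    matrix(stats::rnorm(n * 6, sd = config$deq_noise_sd), n, 6)
  deq_thresholds <- stats::qnorm(seq_len(6) / 7)
  deq_items <- apply(Z, 2, likertize, thresholds = deq_thresholds,
                     offset = 1L)
  colnames(deq_items) <- DEQ_ITEMS

  # --- demographics and SB severity ---------------------------------------
  demo_marg <- config$demographic_marginals
  demo <- lapply(names(demo_marg), function(v) {
    p <- demo_marg[[v]]
    sample(names(p), n, replace = TRUE, prob = p)
  })
  names(demo) <- names(demo_marg)
  sb_group <- as.character(feat$sb_group)
  sev <- sample(c("ideation", "attempt_low_severity", "attempt_high_severity"),
                n, replace = TRUE, prob = config$severity_split)
  sb_status <- ifelse(sb_group == "with_sb", sev, "none")

  records <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n))
  ) |>
    dplyr::bind_cols(oq_items, tibble::as_tibble(deq_items),
                     tibble::as_tibble(rfl_items)) |>
    dplyr::mutate(
      diagnosis = demo$diagnosis,
      children = demo$children,
      gender = as.character(feat$gender),
      age_band = as.character(feat$age_band),
      schooling = demo$schooling,
      cohabitation = demo$cohabitation,
      marital_status = demo$marital_status,
      occupation = demo$occupation,
      sb_status = sb_status
    )
  records <- records[, pvq_schema(config$schema$age_bands)$columns]

  # true conditional SB probability given the sampled parents
  sb_parents <- dag_parents(bn$dag, "sb_group")
  p_sb <- vapply(seq_len(n), function(i) {
    ev <- vapply(sb_parents, function(p) as.character(feat[[p]][i]), character(1))
    j <- 1L; mult <- 1L
    for (p in sb_parents) {
      s <- match(ev[[p]], bn$states[[p]])
      j <- j + (s - 1L) * mult
      mult <- mult * length(bn$states[[p]])
    }
    bn$cpts$sb_group$prob[j, "with_sb"]
  }, numeric(1))

  truth <- tibble::tibble(
    patient_id = records$patient_id,
    f_oq = f_oq, g_rfl = g_rfl, pc1 = pc1, pc2 = pc2,
    true_oq_level = oq_level, true_rfl_level = rfl_level,
    true_quadrant = quad, true_sb = sb_group, p_sb = p_sb
  )

  probs <- validate_cohort(records, config$schema)
  if (nrow(probs) > 0) {
    rlang::abort("internal error: generated cohort failed validation",
                 class = "pvq_generator_error")
  }
  structure(list(records = records, truth = truth, config = config,
                 seed = seed),
            class = "pvq_cohort")
}

#' @export
print.pvq_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PVQ cohort: %d records (%d with SB), seed %d\n",
              nrow(x$records), sum(x$truth$true_sb == "with_sb"), x$seed))
  invisible(x)
}

#' Bayes-optimal classification rates of a truth network
#'
#' Enumerates the full joint distribution of the network and computes the
#' error rates of the optimal classifier that thresholds the exact
#' posterior P(with_sb | all other variables). This is the ceiling any
#' pipeline trained on data from this network can approach.
#'
#' @param bn A `pvq_bn` containing the group node.
#' @param sb_node Name of the group node.
#' @param threshold Decision threshold (default 0.5, boundary to
#'   `with_sb`).
#' @return A one-row tibble: `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `accuracy`.
#' @export
bayes_optimal_rate <- function(bn, sb_node = "sb_group", threshold = 0.5) {
  stopifnot(inherits(bn, "pvq_bn"))
  others <- setdiff(bn$dag$nodes, sb_node)
  grid <- expand.grid(lapply(bn$states[others], seq_along))
  p_joint <- function(cfg, sb_state) {
    asg <- vapply(others, function(v) bn$states[[v]][cfg[[v]]], character(1))
    joint_probability(bn, c(stats::setNames(asg, others),
                            stats::setNames(sb_state, sb_node)))
  }
  pw <- numeric(nrow(grid)); po <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pw[i] <- p_joint(grid[i, , drop = FALSE], "with_sb")
    po[i] <- p_joint(grid[i, , drop = FALSE], "without_sb")
  }
  tot <- pw + po
  pred_w <- ifelse(tot > 0, pw / tot >= threshold, FALSE)
  sens <- sum(pw[pred_w]) / sum(pw)
  spec <- sum(po[!pred_w]) / sum(po)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2,
                 accuracy = sum(pw[pred_w]) + sum(po[!pred_w]))
}
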