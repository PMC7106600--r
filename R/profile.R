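# Per-patient risk profiling: protective/risk factor attribution and the
# clinician-facing report.

#' Markov blanket of a node
#'
#' Parents, children and children's other parents; conditioning on the
#' blanket renders the node independent of every other variable.
#'
#' @param dag A `pvq_dag`.
#' @param node Node name.
#' @return Character vector of node names (sorted).
#' @export
markov_blanket <- function(dag, node) {
  pa <- dag$arcs[dag$arcs[, 2] == node, 1]
  ch <- dag$arcs[dag$arcs[, 1] == node, 2]
  spouses <- dag$arcs[dag$arcs[, 2] %in% ch, 1]
  sort(setdiff(unique(c(pa, ch, spouses)), node), method = "radix")
}

#' Attribute risk to individual evidence variables
#'
#' For each evidence variable inside the Markov blanket of the group node,
#' the strength is the log-ratio of the posterior risk with the full
#' evidence to the posterior risk with that one variable's state removed:
#' strength = log P(with_sb | e) - log P(with_sb | e minus v).
#' Positive strengths mark states currently pushing the patient toward the
#' risk group; negative strengths mark protective states. Variables outside
#' the blanket have strength 0 by conditional independence when the blanket
#' is fully observed. Results are sorted by decreasing |strength|.
#'
#' @param bn A fitted `pvq_bn`.
#' @param evidence Named character vector of observed feature states.
#' @param sb_node Group node name.
#' @return A tibble: `variable`, `state`, `strength`, `direction`
#'   (`risk` / `protective` / `neutral`).
#' @export
identify_factors <- function(bn, evidence, sb_node = "sb_group") {
  if (is.data.frame(evidence)) {
    stopifnot(nrow(evidence) == 1)
    evidence <- unlist(lapply(evidence, as.character))
  }
  full <- posterior(bn, sb_node, evidence)[["with_sb"]]
  blanket <- markov_blanket(bn$dag, sb_node)
  vars <- intersect(names(evidence), blanket)
  rows <- lapply(vars, function(v) {
    reduced <- posterior(bn, sb_node, evidence[setdiff(names(evidence), v)])
    strength <- log(full) - log(reduced[["with_sb"]])
    tibble::tibble(variable = v, state = unname(evidence[[v]]),
                   strength = strength)
  })
  out <- if (length(rows) == 0) {
    tibble::tibble(variable = character(), state = character(),
                   strength = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  out |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$strength > 1e-12 ~ "risk",
      .data$strength < -1e-12 ~ "protective",
      TRUE ~ "neutral"
    )) |>
    dplyr::arrange(dplyr::desc(abs(.data$strength)))
}

#' Default mapping of network variables to intervention focus areas
#'
#' The three areas a clinician can work on: satisfaction with life (the
#' OQ well-being items), satisfaction with oneself and achievements (the
#' OQ self items and the depressive-experience quadrant), and reasons to
#' live (the RFL variables). Shipped as an editable named list.
#'
#' @return Named list: variable -> subset of the three focus-area labels.
#' @export
default_focus_map <- function() {
  list(
    oq_level = c("satisfaction_with_life", "satisfaction_with_self_achievements"),
    oq8 = "satisfaction_with_life",
    deq_quadrant = "satisfaction_with_self_achievements",
    rfl_level = "reasons_to_live",
    rfl25 = "reasons_to_live"
  )
}

#' Render a per-patient risk profile
#'
#' Scores one raw questionnaire record through the fitted transforms,
#' computes the exact posterior risk and the factor attribution, maps the
#' risk-direction variables onto intervention focus areas, and renders a
#' plain-text report. Deterministic; never mutates the fitted artifacts.
#' The report carries a fixed disclaimer: outputs are research artifacts,
#' not diagnostic instruments.
#'
#' @param bn A fitted `pvq_bn`.
#' @param transforms A `pvq_transforms`.
#' @param record One-row cohort tibble (raw item responses).
#' @param config A `pvq_config` (defines which features are evidence).
#' @param focus_map Variable -> focus-area mapping (default
#'   [default_focus_map()]).
#' @param threshold Classification threshold.
#' @return An object of class `pvq_profile`: `patient_id`,
#'   `risk_probability`, `predicted_group`, `factor_findings` (tibble),
#'   `focus_areas` (tibble variable/area), `report` (character lines).
#' @export
render_profile <- function(bn, transforms, record, config = pipeline_config(),
                           focus_map = default_focus_map(),
                           threshold = config$threshold) {
  record <- tibble::as_tibble(record)
  stopifnot(nrow(record) == 1)
  ft <- build_feature_table(record, transforms)
  ev_nodes <- intersect(setdiff(config$nodes, "sb_group"), bn$dag$nodes)
  evidence <- vapply(ev_nodes, function(v) as.character(ft[[v]][1]), character(1))
  pr <- predict_risk(bn, evidence, threshold = threshold)
  findings <- identify_factors(bn, evidence)
  risk_vars <- findings$variable[findings$direction == "risk"]
  fa <- purrr::imap(focus_map, function(areas, v) {
    if (v %in% risk_vars) tibble::tibble(variable = v, area = areas) else NULL
  })
  focus_areas <- dplyr::bind_rows(
    c(list(tibble::tibble(variable = character(), area = character())),
      purrr::compact(fa))
  )
  report <- c(
    sprintf("Patient %s", ft$patient_id[1]),
    sprintf("Estimated probability of the suicidal-behavior group: %.1f%%",
            100 * pr$probability),
    sprintf("Predicted group: %s", pr$predicted),
    "",
    if (nrow(findings) == 0 || all(findings$direction == "neutral")) {
      "No informative factors: the model's risk estimate does not depend on this patient's answers."
    } else {
      c("Factor attribution (leave-one-variable-out log risk ratio):",
        sprintf("  %-14s state=%-4s %-10s strength=%+.3f",
                findings$variable, findings$state, findings$direction,
                findings$strength))
    },
    "",
    if (nrow(focus_areas) > 0) {
      c("Suggested focus areas:",
        sprintf("  - %s (triggered by %s)", focus_areas$area,
                focus_areas$variable))
    } else {
      "Suggested focus areas: none triggered."
    },
    "",
    "This output is a research artifact, not a diagnostic instrument."
  )
  structure(list(patient_id = ft$patient_id[1],
                 risk_probability = pr$probability,
                 predicted_group = pr$predicted,
                 factor_findings = findings,
                 focus_areas = focus_areas,
                 report = report),
            class = "pvq_profile")
}

#' @export
print.pvq_profile <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}

#' Assign taxonomy roles to network variables
#'
#' Classifies each variable of a fitted network into the three-way
#' attribute taxonomy: sociodemographic attributes impact vulnerability,
#' trait-like attributes (depressive-experience quadrant, reasons for
#' living) coexist and are relatively stable, and the state variables (OQ
#' composite and ideation item, the group node) are part of the state of
#' psychological vulnerability. The mapping is configuration, not
#' inference.
#'
#' @param nodes Character vector of network variable names.
#' @param overrides Named character vector variable -> role to override
#'   defaults.
#' @return A tibble `variable`, `role` with roles in
#'   `impacts_vulnerability`, `coexists_stable`, `part_of_state`.
#' @export
attribute_roles <- function(nodes, overrides = NULL) {
  demo <- names(pvq_schema()$demographics)
  role <- vapply(nodes, function(v) {
    if (!is.null(overrides) && v %in% names(overrides)) return(overrides[[v]])
    if (v %in% demo) "impacts_vulnerability"
    else if (v %in% c("deq_quadrant", "rfl_level", "rfl25")) "coexists_stable"
    else "part_of_state"
  }, character(1))
  tibble::tibble(variable = nodes, role = unname(role))
}
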