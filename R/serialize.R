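# JSON serialization of networks and arc constraints.

#' Serialize a fitted network to JSON
#'
#' Writes nodes, state sets, arcs and CPT rows so the network can be
#' reloaded for scoring in another process.
#'
#' @param bn A `pvq_bn`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string.
#' @export
bn_to_json <- function(bn, path = NULL) {
  stopifnot(inherits(bn, "pvq_bn"))
  x <- list(
    nodes = bn$dag$nodes,
    states = bn$states,
    arcs = if (nrow(bn$dag$arcs) == 0) list() else
      lapply(seq_len(nrow(bn$dag$arcs)), function(i)
        list(from = bn$dag$arcs[i, 1], to = bn$dag$arcs[i, 2])),
    cpts = lapply(bn$cpts, function(cpt) list(
      node = cpt$node,
      parents = cpt$parents,
      prob = lapply(seq_len(nrow(cpt$prob)), function(j) unname(cpt$prob[j, ]))
    ))
  )
  js <- jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Restore a network from JSON
#'
#' @param path Path to a file written by [bn_to_json()], or a JSON string.
#' @return A `pvq_bn`.
#' @export
bn_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  states <- lapply(x$states, function(s) unlist(s))
  arcs <- if (length(x$arcs) == 0) NULL else
    do.call(rbind, lapply(x$arcs, function(a) c(a$from, a$to)))
  cpts <- lapply(x$cpts, function(cpt)
    do.call(rbind, lapply(cpt$prob, unlist)))
  names(cpts) <- vapply(x$cpts, `[[`, character(1), "node")
  bayes_net(states, arcs, cpts)
}

#' Read arc constraints from JSON
#'
#' The file format is `{"whitelist": [{"from": ..., "to": ...}, ...],
#' "blacklist": [...]}`.
#'
#' @param path File path or JSON string.
#' @return A `pvq_constraints`.
#' @export
constraints_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  to_mat <- function(df) {
    if (is.null(df) || NROW(df) == 0) NULL else as.matrix(df[, c("from", "to")])
  }
  arc_constraints(whitelist = to_mat(x$whitelist), blacklist = to_mat(x$blacklist))
}

#' Write arc constraints to JSON
#'
#' @param constraints A `pvq_constraints`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string.
#' @export
constraints_to_json <- function(constraints, path = NULL) {
  stopifnot(inherits(constraints, "pvq_constraints"))
  as_list <- function(m) {
    if (nrow(m) == 0) return(list())
    lapply(seq_len(nrow(m)), function(i) list(from = m[i, 1], to = m[i, 2]))
  }
  js <- jsonlite::toJSON(list(whitelist = as_list(constraints$whitelist),
                              blacklist = as_list(constraints$blacklist)),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Illustrative default constraints for the feature-level network
#'
#' A plausible expert prior for this domain, shipped as editable data and
#' clearly labeled illustrative: sociodemographic variables are exogenous
#' (no arc may point into them, and the group node may not point anywhere),
#' and the trait-to-state ordering keeps the group node downstream of the
#' questionnaire-derived features via a whitelisted backbone.
#'
#' @param nodes Feature variables in the network (default: the pipeline
#'   default node set).
#' @param schema Questionnaire schema.
#' @return A `pvq_constraints`.
#' @export
default_constraints <- function(nodes = pipeline_config()$nodes,
                                schema = pvq_schema()) {
  demo <- intersect(names(schema$demographics), nodes)
  others <- setdiff(nodes, demo)
  bl <- rbind(
    # nothing points into a demographic
    if (length(demo) > 0)
      cbind(from = rep(setdiff(nodes, ""), each = length(demo)),
            to = rep(demo, times = length(nodes))),
    # the response variable is a sink
    cbind(from = "sb_group", to = setdiff(nodes, "sb_group"))
  )
  bl <- bl[bl[, 1] != bl[, 2], , drop = FALSE]
  arc_constraints(blacklist = bl)
}
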