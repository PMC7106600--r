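# Constrained score-based structure search: greedy hill-climbing and tabu
# search. Both start from the whitelist (expert) graph, move through single
# arc additions, deletions and reversals that respect the constraints and
# acyclicity, and are fully deterministic: equal-scoring moves are broken
# lexicographically by (child, parent, add < delete < reverse).

# Shared search engine. tabu_length = 0 turns tabu escapes off (plain
# hill-climbing).
.structure_search <- function(data, states, constraints, spec, max_iter,
                              tabu_length = 0L, max_tabu_escapes = 0L) {
  if (is.null(constraints)) constraints <- arc_constraints()
  stopifnot(inherits(constraints, "pvq_constraints"))
  enc <- if (inherits(data, "pvq_encoded")) data else
    encode_discrete(data, states)
  nodes <- names(states)
  p <- length(nodes)
  ni <- stats::setNames(seq_len(p), nodes)

  wl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  bl <- wl
  if (nrow(constraints$whitelist) > 0) {
    bad <- setdiff(c(constraints$whitelist), nodes)
    if (length(bad) > 0) {
      rlang::abort(paste0("whitelist names unknown node(s): ",
                          paste(unique(bad), collapse = ", ")),
                   class = "pvq_constraint_error")
    }
    wl[constraints$whitelist] <- TRUE
  }
  if (nrow(constraints$blacklist) > 0) {
    keep <- constraints$blacklist[, 1] %in% nodes &
      constraints$blacklist[, 2] %in% nodes
    bl[constraints$blacklist[keep, , drop = FALSE]] <- TRUE
  }

  A <- wl
  start_dag <- adj_to_dag(A, states)
  if (!check_acyclic(start_dag)) {
    rlang::abort("whitelist graph is cyclic", class = "pvq_constraint_error")
  }

  # family-score cache
  cache <- new.env(parent = emptyenv())
  fam_score <- function(child, parent_set) {
    key <- paste(child, paste(sort(parent_set, method = "radix"), collapse = ","), sep = "|")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- local_score(child, parent_set, enc, spec)
      cache[[key]] <- v
    }
    v
  }
  cur_fam <- vapply(nodes, function(v) fam_score(v, nodes[A[, ni[v]]]),
                    numeric(1))
  cur_score <- sum(cur_fam)
  best_A <- A
  best_score <- cur_score

  tabu <- character(0)  # FIFO of forbidden move keys
  move_key <- function(type, from, to) paste(type, from, to, sep = "|")
  inverse_key <- function(type, from, to) {
    switch(type,
           add = move_key("delete", from, to),
           delete = move_key("add", from, to),
           reverse = move_key("reverse", to, from))
  }

  legal_moves <- function(A) {
    # returns list of moves: type, from, to, delta
    moves <- list()
    for (j in seq_len(p)) for (i in seq_len(p)) {
      if (i == j) next
      from <- nodes[i]; to <- nodes[j]
      if (!A[i, j] && !A[j, i] && !bl[i, j]) {
        if (!adj_has_path(A, j, i)) {            # add keeps acyclicity
          d <- fam_score(to, c(nodes[A[, j]], from)) - cur_fam[[to]]
          moves[[length(moves) + 1L]] <- list(type = "add", from = from,
                                              to = to, delta = d)
        }
      } else if (A[i, j] && !wl[i, j]) {
        d_del <- fam_score(to, setdiff(nodes[A[, j]], from)) - cur_fam[[to]]
        moves[[length(moves) + 1L]] <- list(type = "delete", from = from,
                                            to = to, delta = d_del)
        if (!bl[j, i]) {
          A2 <- A; A2[i, j] <- FALSE
          if (!adj_has_path(A2, i, j)) {         # reversal keeps acyclicity
            d <- d_del +
              fam_score(from, c(nodes[A[, i]], to)) - cur_fam[[from]]
            moves[[length(moves) + 1L]] <- list(type = "reverse", from = from,
                                                to = to, delta = d)
          }
        }
      }
    }
    moves
  }

  pick_best <- function(moves, allowed) {
    # deterministic: among allowed moves with maximal delta, first in
    # lexicographic (child, parent, add < delete < reverse) order
    moves <- moves[allowed]
    if (length(moves) == 0) return(NULL)
    type_rank <- c(add = 1L, delete = 2L, reverse = 3L)
    child <- vapply(moves, function(m)
      if (m$type == "reverse") m$from else m$to, character(1))
    parent <- vapply(moves, function(m)
      if (m$type == "reverse") m$to else m$from, character(1))
    tr <- type_rank[vapply(moves, `[[`, character(1), "type")]
    delta <- vapply(moves, `[[`, numeric(1), "delta")
    ord <- order(child, parent, tr)
    moves <- moves[ord]; delta <- delta[ord]
    moves[[which.max(delta)]]
  }

  apply_move <- function(m) {
    i <- ni[[m$from]]; j <- ni[[m$to]]
    if (m$type == "add") {
      A[i, j] <<- TRUE
      cur_fam[[m$to]] <<- fam_score(m$to, nodes[A[, j]])
    } else if (m$type == "delete") {
      A[i, j] <<- FALSE
      cur_fam[[m$to]] <<- fam_score(m$to, nodes[A[, j]])
    } else {
      A[i, j] <<- FALSE
      A[j, i] <<- TRUE
      cur_fam[[m$to]] <<- fam_score(m$to, nodes[A[, j]])
      cur_fam[[m$from]] <<- fam_score(m$from, nodes[A[, i]])
    }
    cur_score <<- sum(cur_fam)
    if (tabu_length > 0) {
      tabu <<- c(tabu, inverse_key(m$type, m$from, m$to))
      if (length(tabu) > tabu_length) tabu <<- utils::tail(tabu, tabu_length)
    }
  }

  iter <- 0L
  escapes <- 0L
  while (iter < max_iter) {
    moves <- legal_moves(A)
    if (length(moves) == 0) break
    keys <- vapply(moves, function(m) move_key(m$type, m$from, m$to),
                   character(1))
    deltas <- vapply(moves, `[[`, numeric(1), "delta")
    # aspiration: a tabu move is allowed if it beats the best score seen
    allowed <- !(keys %in% tabu) | (cur_score + deltas > best_score + 1e-9)
    improving <- allowed & (deltas > 1e-9)
    if (any(improving)) {
      m <- pick_best(moves, improving)
      apply_move(m)
      iter <- iter + 1L
      if (cur_score > best_score + 1e-9) {
        best_score <- cur_score
        best_A <- A
        escapes <- 0L
      }
    } else if (tabu_length > 0 && escapes < max_tabu_escapes) {
      m <- pick_best(moves, allowed)
      if (is.null(m)) break
      apply_move(m)
      iter <- iter + 1L
      escapes <- escapes + 1L
      if (cur_score > best_score + 1e-9) {
        best_score <- cur_score
        best_A <- A
        escapes <- 0L
      }
    } else break
  }
  out <- adj_to_dag(best_A, states)
  attr(out, "score") <- best_score
  out
}

#' Greedy hill-climbing structure search
#'
#' Starts from the whitelist graph and repeatedly applies the single best
#' arc addition, deletion or reversal that keeps the graph acyclic,
#' respects the constraints and strictly increases the score, stopping at a
#' local optimum (or after `max_iter` moves). Whitelist arcs are never
#' deleted; blacklist arcs never added.
#'
#' @param data Data frame of discrete observations (or `pvq_encoded`).
#' @param states Named list of state vectors for every node.
#' @param constraints A `pvq_constraints` (default: none).
#' @param spec A `pvq_score_spec` (default BIC).
#' @param max_iter Maximum number of accepted moves.
#' @return The locally optimal `pvq_dag`; its score is in attribute
#'   `"score"`.
#' @export
hill_climb <- function(data, states, constraints = NULL, spec = score_spec(),
                       max_iter = 200L) {
  .structure_search(data, states, constraints, spec, max_iter,
                    tabu_length = 0L, max_tabu_escapes = 0L)
}

#' Tabu structure search
#'
#' Hill-climbing that, at a local optimum, accepts the best non-improving
#' constrained move whose inverse is not on the tabu list (a FIFO of the
#' inverses of recently applied moves), then keeps climbing; the
#' best-scoring DAG visited is returned. An aspiration rule admits a tabu
#' move when it beats the best score seen. Deterministic given data,
#' constraints, score and the lexicographic tie-break.
#'
#' @inheritParams hill_climb
#' @param tabu_length Length of the FIFO tabu list (default 10).
#' @param max_tabu_escapes Budget of consecutive non-improving moves before
#'   termination (default 10).
#' @return The best `pvq_dag` visited; its score is in attribute `"score"`.
#' @export
tabu_search <- function(data, states, constraints = NULL, spec = score_spec(),
                        tabu_length = 10L, max_iter = 200L,
                        max_tabu_escapes = 10L) {
  if (tabu_length < 1) rlang::abort("tabu_length must be >= 1",
                                    class = "pvq_search_error")
  .structure_search(data, states, constraints, spec, max_iter,
                    tabu_length = as.integer(tabu_length),
                    max_tabu_escapes = as.integer(max_tabu_escapes))
}

#' Registered structure-search algorithms
#'
#' The calibration harness recognizes the full family of named algorithms;
#' only the score-based pair is implemented. Requesting a constraint-based
#' name raises an "unsupported algorithm" error so a configured name is
#' never silently substituted.
#'
#' @param name Algorithm name.
#' @return The search function for supported names.
#' @export
search_algorithm <- function(name) {
  supported <- list(hill_climbing = hill_climb, tabu = tabu_search)
  known_unsupported <- c("grow_shrink", "iamb", "fast_iamb", "inter_iamb",
                         "mmpc")
  if (name %in% names(supported)) return(supported[[name]])
  if (name %in% known_unsupported) {
    rlang::abort(sprintf("unsupported algorithm: %s (constraint-based search is not implemented)", name),
                 class = "pvq_unsupported_algorithm")
  }
  rlang::abort(sprintf("unknown algorithm: %s", name),
               class = "pvq_unsupported_algorithm")
}
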