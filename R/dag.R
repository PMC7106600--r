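# Directed acyclic graphs over named discrete variables.
#
# A pvq_dag stores the node names, their declared state sets, and the arc
# set as a two-column character matrix. Internally the searches work on a
# logical adjacency matrix; this object is the user-facing form.

#' Create a DAG over discrete variables
#'
#' @param states Named list: one character vector of states per node.
#' @param arcs Two-column matrix or data frame of arcs (from, to); may have
#'   zero rows.
#' @return An object of class `pvq_dag`.
#' @export
#' @examples
#' new_dag(list(a = c("y", "n"), b = c("y", "n")), data.frame(from = "a", to = "b"))
new_dag <- function(states, arcs = NULL) {
  stopifnot(is.list(states), length(names(states)) == length(states))
  nodes <- names(states)
  if (is.null(arcs) || NROW(arcs) == 0) {
    arcs <- matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to")))
  } else {
    arcs <- as.matrix(as.data.frame(arcs)[, 1:2])
    colnames(arcs) <- c("from", "to")
  }
  bad <- setdiff(c(arcs), nodes)
  if (length(bad) > 0) {
    rlang::abort(paste0("arc endpoint(s) not in node set: ",
                        paste(unique(bad), collapse = ", ")),
                 class = "pvq_dag_error")
  }
  if (any(arcs[, 1] == arcs[, 2])) {
    rlang::abort("self-arcs are not allowed", class = "pvq_dag_error")
  }
  key <- paste(arcs[, 1], arcs[, 2], sep = "\r")
  if (anyDuplicated(key)) {
    rlang::abort("duplicate arcs are not allowed", class = "pvq_dag_error")
  }
  dag <- structure(list(nodes = nodes, states = states, arcs = arcs),
                   class = "pvq_dag")
  if (!check_acyclic(dag)) {
    rlang::abort("arc set contains a directed cycle", class = "pvq_dag_error")
  }
  dag
}

# Logical adjacency matrix (rows = from, cols = to).
dag_adj <- function(dag) {
  p <- length(dag$nodes)
  A <- matrix(FALSE, p, p, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$arcs) > 0) A[dag$arcs] <- TRUE
  A
}

adj_to_dag <- function(A, states) {
  idx <- which(A, arr.ind = TRUE)
  arcs <- cbind(from = rownames(A)[idx[, 1]], to = colnames(A)[idx[, 2]])
  arcs <- arcs[order(arcs[, 1], arcs[, 2]), , drop = FALSE]
  new_dag(states, arcs)
}

# TRUE iff a directed path from -> ... -> to exists in adjacency A.
adj_has_path <- function(A, from, to) {
  frontier <- from
  seen <- rep(FALSE, nrow(A))
  seen[from] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Test whether a graph is acyclic
#'
#' A directed graph is acyclic iff a topological ordering exists, i.e. no
#' route leaves a node and returns to it. Implemented by repeated removal
#' of in-degree-zero nodes (Kahn's algorithm).
#'
#' @param dag A `pvq_dag` (its arc set may have been manipulated).
#' @return `TRUE` or `FALSE`.
#' @export
check_acyclic <- function(dag) {
  A <- matrix(FALSE, length(dag$nodes), length(dag$nodes),
              dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$arcs) > 0) A[dag$arcs] <- TRUE
  remaining <- rep(TRUE, nrow(A))
  repeat {
    indeg <- colSums(A[remaining, remaining, drop = FALSE])
    zero <- which(indeg == 0)
    if (length(zero) == 0) break
    remaining[which(remaining)[zero]] <- FALSE
    if (!any(remaining)) return(TRUE)
  }
  !any(remaining)
}

#' Parents of a node
#'
#' @param dag A `pvq_dag`.
#' @param node Node name.
#' @return Character vector of parent names (sorted).
#' @export
dag_parents <- function(dag, node) {
  sort(dag$arcs[dag$arcs[, 2] == node, 1], method = "radix")
}

#' Topological ordering of a DAG
#'
#' @param dag A `pvq_dag`.
#' @return Character vector of node names, parents before children.
#' @export
topological_order <- function(dag) {
  A <- dag_adj(dag)
  ord <- character(0)
  remaining <- stats::setNames(rep(TRUE, length(dag$nodes)), dag$nodes)
  while (any(remaining)) {
    sub <- A[remaining, remaining, drop = FALSE]
    zero <- names(which(colSums(sub) == 0))
    if (length(zero) == 0) rlang::abort("graph is cyclic", class = "pvq_dag_error")
    ord <- c(ord, zero)
    remaining[zero] <- FALSE
  }
  ord
}

#' @export
print.pvq_dag <- function(x, ...) {
  cat(sprintf("DAG: %d nodes, %d arcs\n", length(x$nodes), nrow(x$arcs)))
  if (nrow(x$arcs) > 0) {
    cat(paste0("  ", x$arcs[, 1], " -> ", x$arcs[, 2], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Arc constraints for structure search
#'
#' The whitelist is the expert initial graph: arcs that must be present in
#' every candidate structure and are never deleted. The blacklist names
#' arcs that must never appear.
#'
#' @param whitelist,blacklist Two-column matrices / data frames of arcs
#'   (from, to); `NULL` for none.
#' @return An object of class `pvq_constraints`.
#' @export
arc_constraints <- function(whitelist = NULL, blacklist = NULL) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0) {
      return(matrix(character(), ncol = 2,
                    dimnames = list(NULL, c("from", "to"))))
    }
    x <- as.matrix(as.data.frame(x)[, 1:2])
    colnames(x) <- c("from", "to")
    x
  }
  wl <- norm(whitelist); bl <- norm(blacklist)
  wk <- paste(wl[, 1], wl[, 2], sep = "\r")
  bk <- paste(bl[, 1], bl[, 2], sep = "\r")
  if (length(intersect(wk, bk)) > 0) {
    rlang::abort("whitelist and blacklist overlap", class = "pvq_constraint_error")
  }
  structure(list(whitelist = wl, blacklist = bl), class = "pvq_constraints")
}

#' Completed partially directed graph (CPDAG) of a DAG
#'
#' Two DAGs encode the same conditional-independence model iff they share a
#' skeleton and v-structures; the CPDAG represents that equivalence class,
#' with compelled arcs directed and reversible arcs undirected. Computed by
#' orienting v-structures on the skeleton and closing under the Meek rules.
#'
#' @param dag A `pvq_dag`.
#' @return A list with `nodes`, `directed` (two-column matrix) and
#'   `undirected` (two-column matrix, each edge once with from < to).
#' @export
cpdag <- function(dag) {
  nodes <- dag$nodes
  p <- length(nodes)
  A <- dag_adj(dag)                      # original orientation
  skel <- A | t(A)
  D <- matrix(FALSE, p, p, dimnames = dimnames(A))  # compelled i -> j
  # v-structures: a -> c <- b with a, b non-adjacent
  for (ci in seq_len(p)) {
    pa <- which(A[, ci])
    if (length(pa) >= 2) {
      for (u in seq_along(pa)) for (v in seq_len(u - 1L)) {
        a <- pa[u]; b <- pa[v]
        if (!skel[a, b]) { D[a, ci] <- TRUE; D[b, ci] <- TRUE }
      }
    }
  }
  U <- skel & !(D | t(D))
  repeat {
    changed <- FALSE
    und <- which(U & upper.tri(U) | U & lower.tri(U), arr.ind = TRUE)
    for (k in seq_len(nrow(und))) {
      i <- und[k, 1]; j <- und[k, 2]
      if (!U[i, j]) next
      orient <- FALSE
      # Meek rule 1: exists x -> i with x, j non-adjacent  => i -> j
      xs <- which(D[, i])
      if (any(!skel[xs, j])) orient <- TRUE
      # Meek rule 2: directed path i -> x -> j  => i -> j
      if (!orient && any(D[i, ] & D[, j])) orient <- TRUE
      # Meek rule 3: x - i, y - i undirected; x -> j, y -> j; x, y non-adj
      if (!orient) {
        xs <- which(U[i, ] & D[, j])
        if (length(xs) >= 2) {
          for (u in seq_along(xs)) for (v in seq_len(u - 1L)) {
            if (!skel[xs[u], xs[v]]) { orient <- TRUE; break }
          }
        }
      }
      if (orient) {
        D[i, j] <- TRUE
        U[i, j] <- FALSE; U[j, i] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  di <- which(D, arr.ind = TRUE)
  directed <- cbind(from = nodes[di[, 1]], to = nodes[di[, 2]])
  ui <- which(U & upper.tri(U), arr.ind = TRUE)
  undirected <- cbind(from = nodes[pmin(ui[, 1], ui[, 2])],
                      to = nodes[pmax(ui[, 1], ui[, 2])])
  list(nodes = nodes,
       directed = directed[order(directed[, 1], directed[, 2]), , drop = FALSE],
       undirected = undirected[order(undirected[, 1], undirected[, 2]), , drop = FALSE])
}

#' Structural Hamming distance between two CPDAGs
#'
#' Counts node pairs whose edge status differs between the two equivalence
#' classes: present vs absent, undirected vs directed, or directed with
#' opposite orientation each contribute 1.
#'
#' @param cp1,cp2 CPDAGs from [cpdag()] over the same node set.
#' @return Non-negative integer.
#' @export
shd <- function(cp1, cp2) {
  stopifnot(setequal(cp1$nodes, cp2$nodes))
  status <- function(cp) {
    s <- list()
    if (NROW(cp$directed) > 0) {
      for (k in seq_len(nrow(cp$directed))) {
        a <- cp$directed[k, 1]; b <- cp$directed[k, 2]
        key <- paste(sort(c(a, b)), collapse = "\r")
        s[[key]] <- paste0("dir:", a, ">", b)
      }
    }
    if (NROW(cp$undirected) > 0) {
      for (k in seq_len(nrow(cp$undirected))) {
        key <- paste(sort(cp$undirected[k, ]), collapse = "\r")
        s[[key]] <- "und"
      }
    }
    s
  }
  s1 <- status(cp1); s2 <- status(cp2)
  keys <- union(names(s1), names(s2))
  sum(vapply(keys, function(k) {
    !identical(s1[[k]] %||% "none", s2[[k]] %||% "none")
  }, logical(1)))
}
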