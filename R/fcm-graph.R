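#' Construct a fuzzy cognitive map
#'
#' An FCM is a signed, weighted directed graph: concepts (nodes) linked by
#' causal influences with weights in \eqn{[-1, 1]}. The class stores concepts
#' in a stable declaration order, which fixes row/column order of the
#' adjacency matrix and makes all downstream computations reproducible.
#'
#' @param concepts a character vector of concept ids (used as labels too), or
#'   a data.frame with columns \code{id} and \code{label}. Ids are short
#'   whitespace-free tokens, unique within the graph.
#' @param links a data.frame with columns \code{source}, \code{target},
#'   \code{weight}. Weights are nonzero reals in \eqn{[-1, 1]}; self-loops
#'   and duplicate ordered dyads are rejected.
#' @param metadata named list of free-form provenance annotations.
#'
#' @return an object of class \code{fcm_graph} with elements \code{concepts}
#'   (data.frame \code{id}, \code{label}), \code{links} (data.frame
#'   \code{source}, \code{target}, \code{weight}) and \code{metadata}.
#'
#' @examples
#' g <- fcm_graph(c("A", "B", "C"),
#'                data.frame(source = "A", target = "B", weight = 0.5))
#' n_links(g)
#' @export
fcm_graph <- function(concepts, links = NULL, metadata = list()) {
  concepts <- as_concept_frame(concepts)
  links <- as_link_frame(links)
  g <- new_fcm_graph(concepts, links, metadata)
  errs <- fcm_structural_errors(g)
  if (nrow(errs) > 0L) {
    abort("invalid fcm_graph:\n%s", paste("-", errs$message, collapse = "\n"))
  }
  g
}

# unchecked constructor; validate_fcm() can inspect objects built this way
new_fcm_graph <- function(concepts, links, metadata = list()) {
  structure(list(concepts = concepts, links = links, metadata = metadata),
            class = "fcm_graph")
}

as_concept_frame <- function(concepts) {
  if (is.character(concepts)) {
    concepts <- data.frame(id = concepts, label = concepts,
                           stringsAsFactors = FALSE)
  }
  if (!is.data.frame(concepts) || !all(c("id", "label") %in% names(concepts))) {
    abort("concepts must be a character vector or a data.frame with columns 'id' and 'label'")
  }
  data.frame(id = as.character(concepts$id), label = as.character(concepts$label),
             stringsAsFactors = FALSE)
}

as_link_frame <- function(links) {
  if (is.null(links) || (is.data.frame(links) && nrow(links) == 0L)) {
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  if (!is.data.frame(links) || !all(c("source", "target", "weight") %in% names(links))) {
    abort("links must be a data.frame with columns 'source', 'target', 'weight'")
  }
  data.frame(source = as.character(links$source),
             target = as.character(links$target),
             weight = as.numeric(links$weight),
             stringsAsFactors = FALSE)
}

# hard structural violations, as a findings data.frame (see validate_fcm)
fcm_structural_errors <- function(g) {
  f <- empty_findings()
  ids <- g$concepts$id
  if (length(ids) < 1L) f <- add_finding(f, "error", "empty", "graph declares no concepts")
  if (anyDuplicated(ids)) {
    f <- add_finding(f, "error", "dup_concept",
                     sprintf("duplicate concept ids: %s",
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(grepl("[[:space:]]", ids))) {
    f <- add_finding(f, "error", "id_whitespace", "concept ids must not contain whitespace")
  }
  if (any(!nzchar(g$concepts$label))) {
    f <- add_finding(f, "error", "empty_label", "concept labels must be non-empty")
  }
  l <- g$links
  if (nrow(l) > 0L) {
    undecl <- setdiff(unique(c(l$source, l$target)), ids)
    if (length(undecl) > 0L) {
      f <- add_finding(f, "error", "undeclared",
                       sprintf("link endpoints not declared as concepts: %s",
                               paste(undecl, collapse = ", ")))
    }
    self <- l$source == l$target
    if (any(self)) {
      f <- add_finding(f, "error", "self_loop",
                       sprintf("self-loops are not allowed: %s",
                               paste(unique(l$source[self]), collapse = ", ")))
    }
    dyad <- paste(l$source, l$target, sep = "\r")
    if (anyDuplicated(dyad)) {
      d <- l[duplicated(dyad), , drop = FALSE]
      f <- add_finding(f, "error", "dup_dyad",
                       sprintf("duplicate ordered dyads: %s",
                               paste(unique(paste0(d$source, "->", d$target)), collapse = ", ")))
    }
    bad <- !is.finite(l$weight) | abs(l$weight) > 1 | l$weight == 0
    if (any(bad)) {
      b <- l[bad, , drop = FALSE]
      f <- add_finding(f, "error", "weight_range",
                       sprintf("weights must be nonzero reals in [-1, 1]; offending: %s",
                               paste(sprintf("%s->%s (%g)", b$source, b$target, b$weight),
                                     collapse = ", ")))
    }
  }
  f
}

#' @export
print.fcm_graph <- function(x, ...) {
  cat(sprintf("<fcm_graph> %d concepts, %d links\n",
              nrow(x$concepts), nrow(x$links)))
  if (nrow(x$links) > 0L) {
    w <- x$links$weight
    cat(sprintf("  weights: %d positive, %d negative, |w| in [%.2f, %.2f]\n",
                sum(w > 0), sum(w < 0), min(abs(w)), max(abs(w))))
  }
  if (length(x$metadata) > 0L) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of concepts / links in a graph
#' @param g an \code{fcm_graph}.
#' @return integer count.
#' @export
n_concepts <- function(g) nrow(g$concepts)

#' @rdname n_concepts
#' @export
n_links <- function(g) nrow(g$links)

#' Convert a graph to its adjacency matrix
#'
#' Entry \eqn{(i, j)} is the weight of the link from concept \eqn{i} to
#' concept \eqn{j}, 0 where no link exists. Row/column order is the concept
#' declaration order, and the diagonal is identically zero (self-loops are
#' forbidden).
#'
#' @param g an \code{fcm_graph}.
#' @return a numeric \eqn{N \times N} matrix with concept ids as dimnames.
#' @export
as_adjacency <- function(g) {
  ids <- g$concepts$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(g$links) > 0L) {
    A[cbind(match(g$links$source, ids), match(g$links$target, ids))] <- g$links$weight
  }
  A
}

#' Rebuild a graph from an adjacency matrix
#'
#' Inverse of \code{\link{as_adjacency}}: every nonzero entry becomes a link.
#' Links are emitted in row-major order (by source, then target), so
#' \code{fcm_from_adjacency(as_adjacency(g))} reproduces \code{g}'s link set.
#'
#' @param A square numeric matrix with concept ids as dimnames (or ids given
#'   separately via \code{ids}).
#' @param ids optional character vector of concept ids overriding dimnames.
#' @param labels optional labels (defaults to ids).
#' @param metadata provenance list.
#' @return an \code{fcm_graph}.
#' @export
fcm_from_adjacency <- function(A, ids = NULL, labels = NULL, metadata = list()) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) abort("A must be a square matrix")
  if (is.null(ids)) ids <- rownames(A)
  if (is.null(ids)) abort("A needs dimnames or an explicit 'ids' vector")
  if (is.null(labels)) labels <- ids
  nz <- which(t(A) != 0)  # transpose => row-major traversal of A
  j <- (nz - 1L) %/% nrow(A) + 1L  # source index in A
  i <- (nz - 1L) %% nrow(A) + 1L   # target index in A
  links <- data.frame(source = ids[j], target = ids[i],
                      weight = A[cbind(j, i)], stringsAsFactors = FALSE)
  fcm_graph(data.frame(id = ids, label = labels, stringsAsFactors = FALSE),
            links, metadata)
}
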