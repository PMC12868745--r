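#' Per-concept degree scores and structural typology
#'
#' FCM degree measures use absolute weights: a strong inhibiting influence
#' contributes as much structure as a strong promoting one.
#' \itemize{
#'   \item indegree(v) = sum of |w(u -> v)| over incoming links;
#'   \item outdegree(v) = sum of |w(v -> u)| over outgoing links;
#'   \item centrality = indegree + outdegree (degree centrality, the measure
#'     of a concept's significance in the map).
#' }
#' Types: \emph{driver} (transmitter) has outgoing influence only
#' (indegree 0, outdegree > 0); \emph{receiver} incoming only; \emph{ordinary}
#' both; \emph{isolated} neither. Every concept gets exactly one type.
#'
#' @param g an \code{fcm_graph}.
#' @return data.frame with columns \code{id}, \code{label}, \code{indegree},
#'   \code{outdegree}, \code{centrality}, \code{ctype}, one row per concept in
#'   declaration order.
#' @export
component_scores <- function(g) {
  ids <- g$concepts$id
  aw <- abs(g$links$weight)
  indeg <- vapply(split(aw, factor(g$links$target, levels = ids)), sum, numeric(1))
  outdeg <- vapply(split(aw, factor(g$links$source, levels = ids)), sum, numeric(1))
  ctype <- ifelse(indeg > 0 & outdeg > 0, "ordinary",
           ifelse(outdeg > 0, "driver",
           ifelse(indeg > 0, "receiver", "isolated")))
  data.frame(id = ids, label = g$concepts$label,
             indegree = unname(indeg), outdegree = unname(outdeg),
             centrality = unname(indeg + outdeg), ctype = ctype,
             stringsAsFactors = FALSE)
}

#' Whole-network structural measures
#'
#' Computes the standard FCM validation metrics:
#' \itemize{
#'   \item density = C / (N (N - 1)): realised fraction of possible ordered
#'     links (self-loops excluded, hence the N(N-1) denominator);
#'   \item connections per component = C / N;
#'   \item counts of drivers, receivers, ordinaries and isolated concepts;
#'   \item complexity = receivers / drivers (the R/T ratio): high values mean
#'     many outcomes per forcing variable — a map dominated by consequences
#'     rather than controls. Undefined (NA) when the map has no driver.
#' }
#'
#' @param g an \code{fcm_graph} with at least two concepts.
#' @return a list of class \code{network_metrics} with fields
#'   \code{n_components}, \code{n_connections}, \code{density},
#'   \code{connections_per_component}, \code{n_drivers}, \code{n_receivers},
#'   \code{n_ordinaries}, \code{n_isolated}, \code{complexity}.
#' @export
network_metrics <- function(g) {
  N <- n_concepts(g)
  if (N < 2L) abort("network metrics need at least 2 concepts (density undefined)")
  sc <- component_scores(g)
  tab <- table(factor(sc$ctype, levels = c("driver", "receiver", "ordinary", "isolated")))
  C <- n_links(g)
  structure(list(
    n_components = N,
    n_connections = C,
    density = C / (N * (N - 1)),
    connections_per_component = C / N,
    n_drivers = unname(tab[["driver"]]),
    n_receivers = unname(tab[["receiver"]]),
    n_ordinaries = unname(tab[["ordinary"]]),
    n_isolated = unname(tab[["isolated"]]),
    complexity = if (tab[["driver"]] > 0) unname(tab[["receiver"]] / tab[["driver"]]) else NA_real_
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("<network_metrics>\n")
  cat(sprintf("  components              %d\n", x$n_components))
  cat(sprintf("  connections             %d\n", x$n_connections))
  cat(sprintf("  density                 %.3f\n", x$density))
  cat(sprintf("  connections/component   %.3f\n", x$connections_per_component))
  cat(sprintf("  drivers                 %d\n", x$n_drivers))
  cat(sprintf("  receivers               %d\n", x$n_receivers))
  cat(sprintf("  ordinaries              %d\n", x$n_ordinaries))
  if (x$n_isolated > 0) cat(sprintf("  isolated                %d\n", x$n_isolated))
  cat(sprintf("  complexity (R/T)        %s\n",
              if (is.na(x$complexity)) "undefined (no drivers)" else format(x$complexity)))
  invisible(x)
}

#' Component score table sorted by centrality
#'
#' The reporting layout for per-concept scores: rows ordered by descending
#' centrality (ties broken by label, ascending), display columns rounded
#' half-up to 2 decimals while the unrounded values are kept alongside.
#'
#' @param g an \code{fcm_graph}.
#' @return data.frame with columns \code{label}, \code{indegree},
#'   \code{outdegree}, \code{centrality} (2-dp display values), \code{ctype},
#'   plus unrounded \code{indegree_raw}, \code{outdegree_raw},
#'   \code{centrality_raw} and the concept \code{id}.
#' @export
metrics_table <- function(g) {
  sc <- component_scores(g)
  ord <- order(-sc$centrality, sc$label)
  sc <- sc[ord, , drop = FALSE]
  out <- data.frame(label = sc$label,
                    indegree = round_half_up(sc$indegree, 2),
                    outdegree = round_half_up(sc$outdegree, 2),
                    centrality = round_half_up(sc$centrality, 2),
                    ctype = sc$ctype,
                    indegree_raw = sc$indegree,
                    outdegree_raw = sc$outdegree,
                    centrality_raw = sc$centrality,
                    id = sc$id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write network-level and per-concept metric reports
#'
#' Emits a JSON document mirroring the two reporting tables (whole-network
#' measures and the per-concept centrality table).
#'
#' @param g an \code{fcm_graph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_report <- function(g, path) {
  jsonlite::write_json(list(network = unclass(network_metrics(g)),
                            components = metrics_table(g)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
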