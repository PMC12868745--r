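#' The AMD case-study marginal profile
#'
#' Per-concept absolute indegree/outdegree totals and structural types for
#' the 36-concept acid-mine-drainage consensus map, as published for the
#' Mwambashi/Kafue riparian case study. Total absolute indegree and outdegree
#' both sum to 33.50.
#'
#' @return a \code{\link{marginal_profile}} with 36 rows.
#' @export
amd_marginal_profile <- function() {
  path <- system.file("extdata", "amd_marginals.csv", package = "fcmtools",
                      mustWork = TRUE)
  marginal_profile(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The AMD case-study consensus network
#'
#' The shipped 36-concept, 40-link fuzzy cognitive map of acid-mine-drainage
#' impacts on riparian communities. The study released only the per-concept
#' degree marginals, not the edge list, so this network is a \emph{synthetic
#' marginal-consistent reconstruction}: it reproduces every published
#' indegree/outdegree total (and therefore all degree-based network measures)
#' exactly, but its individual links are an artefact of the deterministic
#' allocator in \code{\link{reconstruct_from_marginals}}, not elicited data.
#' Link signs follow the map's causal semantics — mitigating links from the
#' two drivers (public awareness, lime expenditure) are negative, impact
#' cascades positive — and are interpretive.
#'
#' The edge list is frozen in the package (\code{extdata/amd_consensus_edges.csv});
#' a regression test guards it against allocator drift.
#'
#' @return an \code{fcm_graph} with 36 concepts and 40 links.
#' @examples
#' g <- amd_fixture()
#' network_metrics(g)
#' @export
amd_fixture <- function() {
  path <- system.file("extdata", "amd_consensus_edges.csv", package = "fcmtools",
                      mustWork = TRUE)
  profile <- amd_marginal_profile()
  g <- read_fcm_edgelist(path, concepts = profile[, c("id", "label")])
  g$metadata$description <- "synthetic marginal-consistent AMD consensus reconstruction"
  g
}

# regenerate the shipped edge list from the shipped marginals; used by the
# freeze test and by analysis/01_build_fixture.R
build_amd_fixture <- function() {
  reconstruct_from_marginals(amd_marginal_profile(), n_edges = 40L)
}
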