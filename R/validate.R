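empty_findings <- function() {
  data.frame(severity = character(), code = character(), message = character(),
             stringsAsFactors = FALSE)
}

add_finding <- function(f, severity, code, message) {
  rbind(f, data.frame(severity = severity, code = code, message = message,
                      stringsAsFactors = FALSE))
}

#' Validate the structural coherence of a fuzzy cognitive map
#'
#' Returns findings instead of throwing, so it is usable as a diagnostic on
#' graphs of any provenance (including aggregation output). Hard violations
#' (out-of-range weights, self-loops, duplicate dyads, undeclared endpoints)
#' are reported with severity \code{"error"}; structural oddities that a
#' coherent consensus map should not show are warnings:
#' \itemize{
#'   \item reciprocal dyads with opposite signs (A influences B positively
#'     while B influences A negatively) — contradictory causal claims;
#'   \item isolated concepts (no incoming or outgoing link).
#' }
#'
#' @param g an \code{fcm_graph} (or an unchecked structure of the same shape).
#' @return a data.frame of findings with columns \code{severity}, \code{code},
#'   \code{message}; zero rows when the graph is clean.
#' @export
validate_fcm <- function(g) {
  f <- fcm_structural_errors(g)
  l <- g$links
  if (nrow(l) > 0L) {
    key <- paste(l$source, l$target, sep = "\r")
    rev_key <- paste(l$target, l$source, sep = "\r")
    j <- match(rev_key, key)
    has_rev <- !is.na(j)
    contra <- has_rev & sign(l$weight) != sign(l$weight[j]) & l$source < l$target
    for (i in which(contra)) {
      f <- add_finding(f, "warning", "reciprocal_contradiction",
                       sprintf("reciprocal links with opposite signs: %s->%s (%+.2f) vs %s->%s (%+.2f)",
                               l$source[i], l$target[i], l$weight[i],
                               l$target[i], l$source[i], l$weight[j[i]]))
    }
  }
  linked <- unique(c(l$source, l$target))
  isolated <- setdiff(g$concepts$id, linked)
  for (id in isolated) {
    f <- add_finding(f, "warning", "isolated_concept",
                     sprintf("concept '%s' has no incoming or outgoing links", id))
  }
  f
}
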