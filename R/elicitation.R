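#' A single respondent's causal map
#'
#' One participant's raw causal claims: ordered concept dyads with a Likert
#' magnitude (1 = weakest influence, 5 = strongest) and a direction (+1
#' promoting, -1 inhibiting).
#'
#' @param respondent_id string identifying the participant.
#' @param claims data.frame with columns \code{source}, \code{target},
#'   \code{magnitude} (integer 1-5), \code{direction} (+1 or -1). Self-loops
#'   and duplicate dyads are rejected.
#' @return an object of class \code{respondent_map}.
#' @export
respondent_map <- function(respondent_id, claims) {
  if (!is_string(respondent_id) || !nzchar(respondent_id)) {
    abort("respondent_id must be a non-empty string")
  }
  need <- c("source", "target", "magnitude", "direction")
  if (!is.data.frame(claims) || !all(need %in% names(claims))) {
    abort("claims must be a data.frame with columns %s", paste(need, collapse = ", "))
  }
  claims <- data.frame(source = as.character(claims$source),
                       target = as.character(claims$target),
                       magnitude = as.integer(claims$magnitude),
                       direction = as.integer(claims$direction),
                       stringsAsFactors = FALSE)
  if (nrow(claims) > 0L) {
    if (any(is.na(claims$magnitude)) || any(!claims$magnitude %in% 1:5)) {
      abort("respondent %s: magnitudes must be integers in 1..5", respondent_id)
    }
    if (any(!claims$direction %in% c(-1L, 1L))) {
      abort("respondent %s: directions must be +1 or -1", respondent_id)
    }
    if (any(claims$source == claims$target)) {
      abort("respondent %s: self-loop claims are not allowed", respondent_id)
    }
    if (anyDuplicated(paste(claims$source, claims$target, sep = "\r"))) {
      abort("respondent %s: duplicate dyad claims", respondent_id)
    }
  }
  structure(list(respondent_id = respondent_id, claims = claims),
            class = "respondent_map")
}

#' @export
print.respondent_map <- function(x, ...) {
  cat(sprintf("<respondent_map> %s: %d claims\n", x$respondent_id, nrow(x$claims)))
  invisible(x)
}

#' Map a Likert rating to a fuzzy causal weight
#'
#' The default mapping sends magnitude \eqn{m \in \{1..5\}} to \eqn{m/5}, so
#' signed weights land on \eqn{\{\pm 0.2, \pm 0.4, \pm 0.6, \pm 0.8, \pm 1\}}
#' — the endpoints of the elicitation scale hit the endpoints of the fuzzy
#' scale. The mapping table is overridable for instruments with different
#' anchoring.
#'
#' @param magnitude integer vector of Likert ratings in 1..5.
#' @param direction vector of +1 / -1 signs.
#' @param mapping numeric vector of length 5: the unsigned weight assigned to
#'   each magnitude.
#' @return numeric vector of signed weights in \eqn{[-1, 1]}.
#' @examples
#' likert_to_fuzzy(c(5, 3), c(1, -1))  # +1.0, -0.6
#' @export
likert_to_fuzzy <- function(magnitude, direction, mapping = (1:5) / 5) {
  if (length(mapping) != 5L || any(mapping < 0) || any(mapping > 1)) {
    abort("mapping must be 5 unsigned weights in [0, 1]")
  }
  magnitude <- as.integer(magnitude)
  if (any(is.na(magnitude)) || any(!magnitude %in% 1:5)) {
    abort("magnitudes must be integers in 1..5")
  }
  if (any(!direction %in% c(-1, 1))) abort("directions must be +1 or -1")
  direction * mapping[magnitude]
}

# respondent_map -> data.frame(source, target, weight)
fuzzify_map <- function(map, mapping = (1:5) / 5) {
  cl <- map$claims
  data.frame(source = cl$source, target = cl$target,
             weight = likert_to_fuzzy(cl$magnitude, cl$direction, mapping),
             stringsAsFactors = FALSE)
}

#' Min-max rescale one respondent's weight magnitudes
#'
#' Rescales \eqn{|w|} to \eqn{(|w| - \min)/(\max - \min)} within a single
#' respondent's map, preserving signs, to damp inter-individual differences
#' in scale use (one respondent's "3" may be another's "5"). A constant map
#' (\eqn{\max = \min}) rescales to magnitude 1 everywhere: a respondent who
#' used one rating throughout expressed no internal contrast, so every claim
#' is taken at full strength.
#'
#' @param weights data.frame with columns \code{source}, \code{target},
#'   \code{weight} (one respondent's fuzzified map).
#' @return the same data.frame with rescaled \code{weight}.
#' @export
rescale_map <- function(weights) {
  if (!is.data.frame(weights) || nrow(weights) == 0L) {
    abort("rescale_map needs at least one claim")
  }
  m <- abs(weights$weight)
  rng <- range(m)
  m2 <- if (rng[1] == rng[2]) rep(1, length(m)) else (m - rng[1]) / (rng[2] - rng[1])
  weights$weight <- sign(weights$weight) * m2
  weights
}

#' Aggregation settings for consensus map building
#'
#' @param presence_fraction minimum fraction of respondents that must claim a
#'   dyad for it to be retained; the count threshold is
#'   \code{ceiling(presence_fraction * R)} ("at least" semantics). Default 0.30.
#' @param weight_floor minimum absolute consensus weight; dyads whose mean
#'   weight falls below it are dropped. Default 0.10.
#' @param rescale apply per-respondent min-max rescaling before averaging.
#'   Default \code{TRUE}.
#' @param outlier_iqr_mult claims outside median +/- this multiple of the IQR
#'   of their dyad's claimed weights are flagged (never dropped). Default 1.5.
#' @param likert_mapping magnitude-to-weight table passed to
#'   \code{\link{likert_to_fuzzy}}.
#' @return a list of class \code{aggregation_config}.
#' @export
aggregation_config <- function(presence_fraction = 0.30, weight_floor = 0.10,
                               rescale = TRUE, outlier_iqr_mult = 1.5,
                               likert_mapping = (1:5) / 5) {
  if (!(presence_fraction > 0 && presence_fraction <= 1)) {
    abort("presence_fraction must be in (0, 1]")
  }
  if (!(weight_floor >= 0 && weight_floor < 1)) abort("weight_floor must be in [0, 1)")
  structure(list(presence_fraction = presence_fraction,
                 weight_floor = weight_floor,
                 rescale = isTRUE(rescale),
                 outlier_iqr_mult = outlier_iqr_mult,
                 likert_mapping = likert_mapping),
            class = "aggregation_config")
}

#' Aggregate respondent maps into a consensus fuzzy cognitive map
#'
#' Implements the consensus protocol: each respondent's claims are fuzzified
#' (\code{\link{likert_to_fuzzy}}), optionally min-max rescaled within
#' respondent, then averaged per ordered dyad over the respondents who
#' claimed it (absence is non-response, not a zero). A dyad is retained iff
#' at least \code{ceiling(presence_fraction * R)} respondents claimed it and
#' the absolute mean weight reaches \code{weight_floor}. Outlying claims
#' (outside median +/- \code{outlier_iqr_mult} * IQR within their dyad) are
#' flagged in the report but never dropped; the consensus graph is passed
#' through \code{\link{validate_fcm}} and its findings attached.
#'
#' @param maps list of \code{respondent_map} objects sharing a concept
#'   vocabulary.
#' @param config an \code{\link{aggregation_config}}.
#' @param concepts optional explicit concept vocabulary (character vector or
#'   id/label data.frame); defaults to the union of claimed endpoints in
#'   first-appearance order.
#' @return a list with elements \code{graph} (the consensus
#'   \code{fcm_graph}) and \code{report} (an \code{aggregation_report}).
#' @export
aggregate_maps <- function(maps, config = aggregation_config(), concepts = NULL) {
  if (!is.list(maps) || length(maps) == 0L ||
      !all(vapply(maps, inherits, logical(1), "respondent_map"))) {
    abort("maps must be a non-empty list of respondent_map objects")
  }
  R <- length(maps)
  k_min <- ceiling(config$presence_fraction * R)

  fuzz <- lapply(maps, function(m) {
    w <- fuzzify_map(m, config$likert_mapping)
    if (config$rescale && nrow(w) > 0L) w <- rescale_map(w)
    if (nrow(w) > 0L) w$respondent <- m$respondent_id
    w
  })
  claims <- do.call(rbind, fuzz[vapply(fuzz, nrow, integer(1)) > 0L])
  if (is.null(concepts)) {
    if (is.null(claims)) abort("no claims supplied and no explicit concept vocabulary")
    concepts <- unique(as.vector(rbind(claims$source, claims$target)))
  }
  if (is.null(claims)) {
    claims <- data.frame(source = character(), target = character(),
                         weight = numeric(), respondent = character())
  }

  dyad <- factor(paste(claims$source, claims$target, sep = "\r"),
                 levels = unique(paste(claims$source, claims$target, sep = "\r")))
  by_dyad <- split(claims, dyad)
  summ <- do.call(rbind, lapply(by_dyad, function(d) {
    data.frame(source = d$source[1], target = d$target[1],
               n_claims = nrow(d), mean_weight = mean(d$weight),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summ)) {
    summ <- data.frame(source = character(), target = character(),
                       n_claims = integer(), mean_weight = numeric())
  }
  rownames(summ) <- NULL

  reason <- rep(NA_character_, nrow(summ))
  reason[summ$n_claims < k_min] <- "presence"
  below <- is.na(reason) & (abs(summ$mean_weight) < config$weight_floor |
                              summ$mean_weight == 0)
  reason[below] <- "weight_floor"
  keep <- is.na(reason)

  links <- summ[keep, c("source", "target", "mean_weight")]
  names(links)[3] <- "weight"
  graph <- fcm_graph(concepts, links,
                     metadata = list(aggregation = list(
                       n_respondents = R,
                       presence_fraction = config$presence_fraction,
                       presence_count_min = k_min,
                       weight_floor = config$weight_floor,
                       rescale = config$rescale)))

  outliers <- do.call(rbind, lapply(by_dyad, function(d) {
    if (nrow(d) < 4L) return(NULL)   # IQR is meaningless on tiny dyads
    med <- stats::median(d$weight)
    iqr <- stats::IQR(d$weight)
    out <- abs(d$weight - med) > config$outlier_iqr_mult * iqr & iqr > 0
    d[out, c("respondent", "source", "target", "weight")]
  }))
  if (is.null(outliers)) {
    outliers <- data.frame(respondent = character(), source = character(),
                           target = character(), weight = numeric())
  }
  rownames(outliers) <- NULL

  dropped <- summ[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  rownames(dropped) <- NULL

  report <- structure(list(
    n_respondents = R,
    presence_count_min = k_min,
    config = unclass(config),
    retained = cbind(summ[keep, , drop = FALSE], row.names = NULL),
    dropped = dropped,
    outliers = outliers,
    findings = validate_fcm(graph)
  ), class = "aggregation_report")

  list(graph = graph, report = report)
}

#' @export
print.aggregation_report <- function(x, ...) {
  cat(sprintf("<aggregation_report> R = %d respondents, presence threshold k >= %d\n",
              x$n_respondents, x$presence_count_min))
  cat(sprintf("  retained %d dyads; dropped %d (%s); %d outlying claims flagged\n",
              nrow(x$retained), nrow(x$dropped),
              if (nrow(x$dropped) > 0) paste(names(table(x$dropped$reason)),
                                             table(x$dropped$reason),
                                             sep = ": ", collapse = ", ") else "none",
              nrow(x$outliers)))
  nw <- sum(x$findings$severity == "warning")
  ne <- sum(x$findings$severity == "error")
  cat(sprintf("  consensus validation: %d errors, %d warnings\n", ne, nw))
  invisible(x)
}

#' Serialise an aggregation report to JSON
#'
#' @param report an \code{aggregation_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_aggregation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full elicitation-to-consensus pipeline
#'
#' Reads a respondent claims file and applies fuzzification, optional
#' rescaling and consensus aggregation. Deterministic for fixed input and
#' configuration.
#'
#' @param claims a path to a claims file (see \code{\link{read_claims}}) or a
#'   list of \code{respondent_map} objects.
#' @param config an \code{\link{aggregation_config}}.
#' @param concepts optional explicit concept vocabulary.
#' @return as \code{\link{aggregate_maps}}: list with \code{graph} and
#'   \code{report}.
#' @export
consensus_pipeline <- function(claims, config = aggregation_config(),
                               concepts = NULL) {
  maps <- if (is.character(claims)) read_claims(claims) else claims
  aggregate_maps(maps, config, concepts)
}
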