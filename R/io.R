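#' Read a fuzzy cognitive map from a delimited edge list
#'
#' The file must have a header \code{source,target,weight}. Concept order in
#' the resulting graph is declaration order: first appearance in the file,
#' scanning each row source-before-target. Malformed rows fail with the
#' offending line number; self-loops, duplicate ordered dyads and
#' out-of-range weights are validation errors.
#'
#' @param path path to the edge-list file.
#' @param delim field delimiter, comma by default.
#' @param concepts optional character vector (or id/label data.frame) fixing
#'   the concept set and order; required when the file alone cannot declare
#'   every concept (header-only files, graphs with isolated concepts).
#' @param metadata extra provenance entries merged into the graph metadata.
#' @return an \code{fcm_graph}.
#' @export
read_fcm_edgelist <- function(path, delim = ",", concepts = NULL,
                              metadata = list()) {
  if (!file.exists(path)) abort("no such file: %s", path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", quote = "\"",
                           strip.white = TRUE, check.names = FALSE,
                           blank.lines.skip = FALSE)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(raw))) {
    abort("edge list %s must have header columns %s (found: %s)",
          path, paste(need, collapse = ","), paste(names(raw), collapse = ","))
  }
  w <- suppressWarnings(as.numeric(raw$weight))
  bad <- which(is.na(w) | !nzchar(raw$source) | !nzchar(raw$target))
  if (length(bad) > 0L) {
    abort("malformed row at line %d of %s (source=%s target=%s weight=%s)",
          bad[1] + 1L, path, raw$source[bad[1]], raw$target[bad[1]], raw$weight[bad[1]])
  }
  links <- data.frame(source = raw$source, target = raw$target, weight = w,
                      stringsAsFactors = FALSE)
  md <- c(list(source_file = path), metadata)
  if (is.null(concepts)) {
    ids <- unique(as.vector(rbind(links$source, links$target)))
    if (length(ids) == 0L) {
      abort("edge list %s has no data rows; pass 'concepts' to build an empty graph", path)
    }
    return(fcm_graph(ids, links, md))
  }
  fcm_graph(concepts, links, md)
}

#' Write a graph as a delimited edge list
#'
#' Weights are serialised at 6 decimal places, so
#' \code{read_fcm_edgelist(write_fcm_edgelist(g, p))} round-trips exactly for
#' weights representable at that precision. Concepts without links are not
#' representable in this format; use \code{\link{write_fcm_json}} to preserve
#' them.
#'
#' @param g an \code{fcm_graph}.
#' @param path output path.
#' @param delim field delimiter.
#' @return \code{path}, invisibly.
#' @export
write_fcm_edgelist <- function(g, path, delim = ",") {
  lines <- c(paste(c("source", "target", "weight"), collapse = delim))
  if (nrow(g$links) > 0L) {
    lines <- c(lines, paste(g$links$source, g$links$target,
                            sprintf("%.6f", g$links$weight), sep = delim))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a graph as a delimited adjacency matrix
#'
#' Square matrix with concept ids as the first row and first column; zero
#' entries mean no link.
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return \code{read_fcm_adjacency}: an \code{fcm_graph};
#'   \code{write_fcm_adjacency}: \code{path}, invisibly.
#' @export
read_fcm_adjacency <- function(path, delim = ",") {
  if (!file.exists(path)) abort("no such file: %s", path)
  tab <- utils::read.table(path, sep = delim, header = TRUE, row.names = 1,
                           check.names = FALSE)
  A <- as.matrix(tab)
  if (nrow(A) != ncol(A) || !identical(rownames(A), colnames(A))) {
    abort("adjacency file %s is not a square id-labelled matrix", path)
  }
  storage.mode(A) <- "double"
  fcm_from_adjacency(A, metadata = list(source_file = path))
}

#' @rdname read_fcm_adjacency
#' @param g an \code{fcm_graph}.
#' @export
write_fcm_adjacency <- function(g, path, delim = ",") {
  A <- as_adjacency(g)
  header <- paste(c("", colnames(A)), collapse = delim)
  rows <- vapply(seq_len(nrow(A)), function(i) {
    paste(c(rownames(A)[i], sprintf("%.6f", A[i, ])), collapse = delim)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read / write a whole model as JSON
#'
#' JSON carries concepts (with labels), links and metadata, so it preserves
#' isolated concepts and provenance that the edge-list format cannot.
#'
#' @param path file path.
#' @return \code{read_fcm_json}: an \code{fcm_graph};
#'   \code{write_fcm_json}: \code{path}, invisibly.
#' @export
read_fcm_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("concepts", "links") %in% names(doc))) {
    abort("model file %s must carry 'concepts' and 'links'", path)
  }
  links <- doc$links
  if (length(links) == 0L) links <- NULL
  md <- doc$metadata
  if (is.null(md)) md <- list()
  fcm_graph(as_concept_frame(doc$concepts), links, as.list(md))
}

#' @rdname read_fcm_json
#' @param g an \code{fcm_graph}.
#' @export
write_fcm_json <- function(g, path) {
  jsonlite::write_json(list(concepts = g$concepts, links = g$links,
                            metadata = g$metadata),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write respondent causal claims
#'
#' Claims files are delimited text with header
#' \code{respondent,source,target,magnitude,direction}: one row per causal
#' claim, magnitude an integer Likert rating 1-5, direction +1 or -1.
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return \code{read_claims}: a list of \code{respondent_map} objects (see
#'   \code{\link{respondent_map}}), in order of first appearance;
#'   \code{write_claims}: \code{path}, invisibly.
#' @export
read_claims <- function(path, delim = ",") {
  if (!file.exists(path)) abort("no such file: %s", path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", strip.white = TRUE)
  need <- c("respondent", "source", "target", "magnitude", "direction")
  if (!all(need %in% names(raw))) {
    abort("claims file %s must have header columns %s", path,
          paste(need, collapse = ","))
  }
  mag <- suppressWarnings(as.integer(raw$magnitude))
  dir <- suppressWarnings(as.integer(raw$direction))
  bad <- which(is.na(mag) | is.na(dir) | !nzchar(raw$source) | !nzchar(raw$target))
  if (length(bad) > 0L) {
    abort("malformed claim at line %d of %s", bad[1] + 1L, path)
  }
  split_idx <- split(seq_len(nrow(raw)), factor(raw$respondent, levels = unique(raw$respondent)))
  lapply(names(split_idx), function(r) {
    i <- split_idx[[r]]
    respondent_map(r, data.frame(source = raw$source[i], target = raw$target[i],
                                 magnitude = mag[i], direction = dir[i],
                                 stringsAsFactors = FALSE))
  })
}

#' @rdname read_claims
#' @param maps list of \code{respondent_map} objects.
#' @export
write_claims <- function(maps, path, delim = ",") {
  header <- paste(c("respondent", "source", "target", "magnitude", "direction"),
                  collapse = delim)
  rows <- unlist(lapply(maps, function(m) {
    if (nrow(m$claims) == 0L) return(character())
    paste(m$respondent_id, m$claims$source, m$claims$target,
          m$claims$magnitude, m$claims$direction, sep = delim)
  }))
  writeLines(c(header, rows), path)
  invisible(path)
}
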