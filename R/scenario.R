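squashing_fn <- function(tag) {
  switch(tag,
         tanh = tanh,
         # logistic rescaled to (-1, 1) so the origin is a fixed point
         logistic = function(x) 2 / (1 + exp(-x)) - 1,
         linear = function(x) pmin(pmax(x, -1), 1),
         abort("unknown squashing '%s' (use tanh, logistic or linear)", tag))
}

#' Clamped steady-state activation of a fuzzy cognitive map
#'
#' Iterates the propagation rule
#' \deqn{x_i(t+1) = f\big(\sum_j w_{ji}\, x_j(t)\big)}
#' for unclamped concepts, holding clamped concepts at their clamp values,
#' starting from the zero vector extended by the clamps. \eqn{f} is a bounded
#' squashing function with \eqn{f(0) = 0}, so activation can only appear where
#' influence arrives: concepts unreachable from any clamped concept stay at
#' exactly zero. With \code{self_memory = TRUE} the rule becomes
#' \eqn{x_i(t+1) = f(x_i(t) + \sum_j w_{ji} x_j(t))} (Kosko-style state
#' persistence); the default has no memory term.
#'
#' Iteration stops when the max absolute change falls below \code{tolerance}.
#' Non-convergence is reported, never thrown; a period-2 oscillation (state
#' returning to the one before last) is detected and flagged.
#'
#' @param g an \code{fcm_graph}.
#' @param clamps named numeric vector: concept id -> activation in [-1, 1].
#'   May be empty (baseline run).
#' @param squashing one of \code{"tanh"} (default), \code{"logistic"}
#'   (rescaled to (-1,1)), \code{"linear"} (clip to [-1,1]).
#' @param tolerance convergence threshold on the max absolute update.
#' @param max_iterations iteration cap.
#' @param self_memory include the concept's own previous activation in the
#'   update argument.
#' @return list with \code{activation} (named vector over all concepts),
#'   \code{converged}, \code{oscillating}, \code{iterations}.
#' @examples
#' g <- fcm_graph(c("A", "B"), data.frame(source = "A", target = "B", weight = 0.8))
#' steady_state(g, c(A = 1))$activation[["B"]]  # tanh(0.8)
#' @export
steady_state <- function(g, clamps = numeric(), squashing = "tanh",
                         tolerance = 1e-6, max_iterations = 1000L,
                         self_memory = FALSE) {
  f <- squashing_fn(squashing)
  ids <- g$concepts$id
  clamps <- unlist(clamps)
  if (length(clamps) > 0L) {
    unknown <- setdiff(names(clamps), ids)
    if (length(unknown) > 0L) {
      abort("clamped concepts not in graph: %s", paste(unknown, collapse = ", "))
    }
    if (any(abs(clamps) > 1)) abort("clamp values must lie in [-1, 1]")
  }
  Wt <- t(as_adjacency(g))        # Wt %*% x = incoming influence per concept
  x <- stats::setNames(numeric(length(ids)), ids)
  x[names(clamps)] <- clamps
  free <- setdiff(ids, names(clamps))

  converged <- FALSE
  oscillating <- FALSE
  iter <- 0L
  x_prev2 <- NULL
  while (iter < max_iterations) {
    iter <- iter + 1L
    arg <- drop(Wt %*% x)
    if (self_memory) arg <- arg + x
    x_new <- x
    x_new[free] <- f(arg[free])
    if (max(abs(x_new - x)) < tolerance) {
      x <- x_new
      converged <- TRUE
      break
    }
    if (!is.null(x_prev2) && max(abs(x_new - x_prev2)) < tolerance) {
      x <- x_new
      oscillating <- TRUE
      break
    }
    x_prev2 <- x
    x <- x_new
  }
  list(activation = x, converged = converged, oscillating = oscillating,
       iterations = iter)
}

#' Define a scenario: clamped concepts plus engine options
#'
#' A scenario is an intervention expressed as activations held fixed during
#' simulation: clamping a concept at -1 represents fully suppressing it, +1
#' fully promoting it.
#'
#' @param name scenario label.
#' @param clamps named numeric vector of clamp activations in [-1, 1].
#' @param squashing,tolerance,max_iterations engine options, see
#'   \code{\link{steady_state}}.
#' @param prune_epsilon concepts whose absolute steady-state change stays
#'   below this (and that are not clamped) are reported as pruned — the
#'   "unaffected, removed from the model" set.
#' @param self_memory see \code{\link{steady_state}}.
#' @return a list of class \code{scenario_spec}.
#' @export
scenario_spec <- function(name, clamps, squashing = "tanh", tolerance = 1e-6,
                          max_iterations = 1000L, prune_epsilon = 1e-4,
                          self_memory = FALSE) {
  clamps <- unlist(clamps)
  if (length(clamps) == 0L || is.null(names(clamps)) || any(!nzchar(names(clamps)))) {
    abort("a scenario needs at least one named clamp")
  }
  if (any(abs(clamps) > 1)) abort("clamp values must lie in [-1, 1]")
  if (prune_epsilon < 0) abort("prune_epsilon must be non-negative")
  structure(list(name = name, clamps = clamps, squashing = squashing,
                 tolerance = tolerance, max_iterations = max_iterations,
                 prune_epsilon = prune_epsilon, self_memory = self_memory),
            class = "scenario_spec")
}

#' Read a scenario specification from JSON
#'
#' Expected fields: \code{name}, \code{clamps} (object: concept id ->
#' activation), optional \code{squashing}, \code{tolerance},
#' \code{max_iterations}, \code{prune_epsilon}, \code{self_memory}.
#'
#' @param path JSON file path.
#' @return a \code{scenario_spec}.
#' @export
read_scenario_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$name) || is.null(doc$clamps)) {
    abort("scenario file %s must carry 'name' and 'clamps'", path)
  }
  args <- list(name = doc$name, clamps = unlist(doc$clamps))
  for (opt in c("squashing", "tolerance", "max_iterations", "prune_epsilon",
                "self_memory")) {
    if (!is.null(doc[[opt]])) args[[opt]] <- doc[[opt]]
  }
  do.call(scenario_spec, args)
}

#' Run a clamped scenario against a baseline
#'
#' Computes the unclamped baseline steady state and the clamped scenario
#' steady state, and reports the per-concept change (delta). Under the
#' default origin-preserving squashing the baseline is identically zero, so
#' deltas equal the scenario activations. Unclamped concepts whose |delta|
#' stays below \code{prune_epsilon} are listed as pruned: the intervention
#' cannot reach them.
#'
#' @param g an \code{fcm_graph}.
#' @param spec a \code{\link{scenario_spec}}.
#' @return a list of class \code{scenario_result}: \code{name},
#'   \code{table} (data.frame: id, label, baseline, activation, delta,
#'   clamped, pruned), \code{pruned} (ids), \code{converged},
#'   \code{oscillating}, \code{iterations}.
#' @export
run_scenario <- function(g, spec) {
  if (!inherits(spec, "scenario_spec")) abort("spec must be a scenario_spec")
  base <- steady_state(g, numeric(), spec$squashing, spec$tolerance,
                       spec$max_iterations, spec$self_memory)
  scen <- steady_state(g, spec$clamps, spec$squashing, spec$tolerance,
                       spec$max_iterations, spec$self_memory)
  delta <- scen$activation - base$activation
  clamped <- g$concepts$id %in% names(spec$clamps)
  pruned <- abs(delta) < spec$prune_epsilon & !clamped
  tab <- data.frame(id = g$concepts$id, label = g$concepts$label,
                    baseline = unname(base$activation),
                    activation = unname(scen$activation),
                    delta = unname(delta),
                    clamped = clamped, pruned = pruned,
                    stringsAsFactors = FALSE)
  structure(list(name = spec$name, table = tab,
                 pruned = tab$id[tab$pruned],
                 converged = base$converged && scen$converged,
                 oscillating = base$oscillating || scen$oscillating,
                 iterations = max(base$iterations, scen$iterations)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s': %s after %d iterations\n", x$name,
              if (x$converged) "converged" else if (x$oscillating)
                "oscillating (period 2)" else "did not converge",
              x$iterations))
  cat(sprintf("  %d concepts pruned (unreached); largest |delta|:\n",
              length(x$pruned)))
  tab <- x$table[order(-abs(x$table$delta)), ]
  top <- utils::head(tab[!tab$pruned, c("label", "delta", "clamped")], 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-35s %+0.4f%s\n", top$label[i], top$delta[i],
                if (top$clamped[i]) " (clamped)" else ""))
  }
  invisible(x)
}

#' Write a scenario result as a delimited table
#'
#' One row per concept: id, label, delta, clamped and pruned flags — a
#' long-format table ready for bar-chart plotting of per-concept change.
#'
#' @param result a \code{scenario_result}.
#' @param path output path.
#' @param delim field delimiter.
#' @return \code{path}, invisibly.
#' @export
write_scenario_result <- function(result, path, delim = ",") {
  tab <- result$table
  tab$scenario <- result$name
  utils::write.table(tab[, c("scenario", "id", "label", "delta", "clamped", "pruned")],
                     path, sep = delim, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The three AMD mitigation scenarios
#'
#' Builds and runs the cumulative intervention set studied for the AMD
#' system:
#' \enumerate{
#'   \item \strong{Pollution control}: suppress acid pollution at the source
#'     (clamp \code{acid_pollution} negative).
#'   \item \strong{Driver mitigation}: additionally raise public awareness and
#'     reduce lime expenditure (the two drivers).
#'   \item \strong{Ordinary mitigation}: additionally suppress the seven
#'     intermediate (ordinary) impact concepts — poor water quality,
#'     contaminated fish, abandoned fishing, abandoned farming, fish catch
#'     reduction, crop yield reduction, seeking medical care.
#' }
#' "Additively" means each scenario keeps the previous scenario's clamps.
#' Clamp magnitude defaults to full activation (1): the study states
#' intervention directions, not strengths.
#'
#' @param g an \code{fcm_graph} containing the AMD concept ids (see
#'   \code{\link{amd_fixture}}).
#' @param clamp_magnitude absolute clamp value in (0, 1].
#' @param ... further options passed to \code{\link{scenario_spec}}.
#' @return named list of three \code{scenario_result} objects
#'   (\code{s1}, \code{s2}, \code{s3}).
#' @export
amd_scenarios <- function(g, clamp_magnitude = 1, ...) {
  m <- clamp_magnitude
  if (!(m > 0 && m <= 1)) abort("clamp_magnitude must be in (0, 1]")
  s1 <- c(acid_pollution = -m)
  s2 <- c(s1, peoples_awareness = +m, lime_expenditure = -m)
  s3 <- c(s2, poor_water_quality = -m, contaminated_fish = -m,
          abandoned_fishing = -m, abandoned_farming = -m,
          fish_catch_reduction = -m, crop_yield_reduction = -m,
          seeking_medical_care = -m)
  missing <- setdiff(names(s3), g$concepts$id)
  if (length(missing) > 0L) {
    abort("graph lacks concepts required by the AMD scenarios: %s",
          paste(missing, collapse = ", "))
  }
  specs <- list(s1 = scenario_spec("pollution_control", s1, ...),
                s2 = scenario_spec("driver_mitigation", s2, ...),
                s3 = scenario_spec("ordinary_mitigation", s3, ...))
  lapply(specs, function(sp) run_scenario(g, sp))
}
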