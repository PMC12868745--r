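# Fixtures built in code: random valid FCMs and small canonical graphs.

# sparse random FCM with 2-dp weights (the serialisation/reconstruction grid)
random_fcm <- function(n_concepts = 6, density = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("c%02d", seq_len(n_concepts))
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  m <- max(1L, round(density * nrow(pairs)))
  links <- pairs[sample(nrow(pairs), m), ]
  links$weight <- sample(c(-1, 1), m, replace = TRUE) * sample(1:100, m, replace = TRUE) / 100
  fcm_graph(ids, links)
}

chain_graph <- function(weights) {
  ids <- LETTERS[seq_len(length(weights) + 1)]
  fcm_graph(ids, data.frame(source = ids[-length(ids)], target = ids[-1],
                            weight = weights))
}

# truth graph on the Likert grid (|w| multiples of 0.2), for noiseless
# elicitation round-trips
grid_truth <- function() {
  fcm_graph(c("amd", "water", "fish", "income", "health"),
            data.frame(
              source = c("amd", "amd", "water", "water", "fish", "amd"),
              target = c("water", "health", "fish", "income", "income", "income"),
              weight = c(1.0, 0.8, 0.6, -0.4, 0.8, 0.2)))
}

# identical respondent maps: every respondent claims the truth graph verbatim
verbatim_maps <- function(truth, n) {
  claims <- data.frame(source = truth$links$source,
                       target = truth$links$target,
                       magnitude = as.integer(round(5 * abs(truth$links$weight))),
                       direction = as.integer(sign(truth$links$weight)))
  lapply(seq_len(n), function(i) respondent_map(sprintf("r%02d", i), claims))
}

# naive double-loop reference for degree scores, independent of the package's
# vectorised implementation
naive_scores <- function(g) {
  ids <- g$concepts$id
  out <- data.frame(id = ids, indegree = 0, outdegree = 0)
  for (i in seq_along(ids)) {
    for (j in seq_len(nrow(g$links))) {
      if (g$links$target[j] == ids[i]) out$indegree[i] <- out$indegree[i] + abs(g$links$weight[j])
      if (g$links$source[j] == ids[i]) out$outdegree[i] <- out$outdegree[i] + abs(g$links$weight[j])
    }
  }
  out$centrality <- out$indegree + out$outdegree
  out
}
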