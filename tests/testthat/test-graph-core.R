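test_that("constructor enforces structural invariants", {
  expect_error(fcm_graph(c("A", "B"),
                         data.frame(source = "A", target = "A", weight = 0.3)),
               "self-loop")
  expect_error(fcm_graph(c("A", "B"),
                         data.frame(source = c("A", "A"), target = c("B", "B"),
                                    weight = c(0.5, 0.7))),
               "duplicate ordered dyads")
  expect_error(fcm_graph(c("A", "B"),
                         data.frame(source = "A", target = "B", weight = 1.2)),
               "weights")
  expect_error(fcm_graph(c("A", "B"),
                         data.frame(source = "A", target = "B", weight = 0)),
               "weights")
  expect_error(fcm_graph(c("A", "B"),
                         data.frame(source = "A", target = "Z", weight = 0.5)),
               "not declared")
  expect_error(fcm_graph(character(0)), "no concepts")
  expect_error(fcm_graph(c("A", "A")), "duplicate concept ids")
})

test_that("edge-list files parse, reject malformed input, and name bad lines", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,weight", "A,B,0.5", "B,C,-0.5", "A,C,1.0"), p)
  g <- read_fcm_edgelist(p)
  expect_equal(n_concepts(g), 3)
  expect_equal(n_links(g), 3)
  expect_equal(g$concepts$id, c("A", "B", "C"))  # declaration order

  writeLines(c("source,target,weight", "A,B,0.5", "A,A,0.3"), p)
  expect_error(read_fcm_edgelist(p), "self-loop")

  writeLines(c("source,target,weight", "A,B,0.5", "B,C,oops"), p)
  expect_error(read_fcm_edgelist(p), "line 3")

  expect_error(read_fcm_edgelist(file.path(tempdir(), "absent.csv")), "no such file")
})

test_that("write/read edge list round-trips random graphs exactly", {
  p <- withr::local_tempfile(fileext = ".csv")
  for (seed in 1:8) {
    g <- random_fcm(n_concepts = sample(3:9, 1), density = 0.3, seed = seed)
    write_fcm_edgelist(g, p)
    g2 <- read_fcm_edgelist(p, concepts = g$concepts)
    expect_equal(g2$concepts, g$concepts)
    expect_equal(g2$links, g$links, ignore_attr = TRUE)
  }
})

test_that("empty-links graph writes a header-only file", {
  g <- fcm_graph(c("A", "B"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_fcm_edgelist(g, p)
  expect_length(readLines(p), 1L)
  g2 <- read_fcm_edgelist(p, concepts = c("A", "B"))
  expect_equal(n_links(g2), 0L)
})

test_that("adjacency matrix matches links and inverts", {
  g <- fcm_graph(c("A", "B"), data.frame(source = "A", target = "B", weight = 0.7))
  expect_equal(unname(as_adjacency(g)), matrix(c(0, 0, 0.7, 0), 2, 2))

  for (seed in 1:6) {
    g <- random_fcm(n_concepts = 7, density = 0.25, seed = seed)
    A <- as_adjacency(g)
    expect_equal(sum(A != 0), n_links(g))   # nonzero count == link count
    expect_true(all(diag(A) == 0))
    g2 <- fcm_from_adjacency(A)
    ord <- order(g$links$source, g$links$target)
    expect_equal(g2$links, g$links[ord, ], ignore_attr = TRUE)
  }
})

test_that("adjacency and JSON files round-trip, JSON keeps isolated concepts", {
  g <- fcm_graph(c("A", "B", "C", "Z"),
                 data.frame(source = c("A", "B"), target = c("B", "C"),
                            weight = c(0.25, -0.75)),
                 metadata = list(note = "round-trip"))
  pa <- withr::local_tempfile(fileext = ".csv")
  write_fcm_adjacency(g, pa)
  ga <- read_fcm_adjacency(pa)
  expect_equal(ga$concepts$id, g$concepts$id)
  ord <- order(g$links$source, g$links$target)
  expect_equal(ga$links, g$links[ord, ], ignore_attr = TRUE)

  pj <- withr::local_tempfile(fileext = ".json")
  write_fcm_json(g, pj)
  gj <- read_fcm_json(pj)
  expect_equal(gj$concepts, g$concepts)
  expect_equal(gj$links, g$links, ignore_attr = TRUE)
  expect_equal(gj$metadata$note, "round-trip")
})

test_that("validator reports contradictions and isolation without throwing", {
  g <- fcm_graph(c("A", "B", "Z"),
                 data.frame(source = c("A", "B"), target = c("B", "A"),
                            weight = c(0.8, -0.6)))
  f <- validate_fcm(g)
  expect_equal(sum(f$code == "reciprocal_contradiction"), 1L)
  expect_equal(sum(f$code == "isolated_concept"), 1L)
  expect_true(all(f$severity == "warning"))

  # same-sign reciprocity is not contradictory
  g2 <- fcm_graph(c("A", "B"),
                  data.frame(source = c("A", "B"), target = c("B", "A"),
                             weight = c(0.8, 0.6)))
  expect_equal(nrow(validate_fcm(g2)), 0L)

  # hard violations come back as error findings, not conditions
  raw <- fcmtools:::new_fcm_graph(
    data.frame(id = c("A", "B"), label = c("A", "B")),
    data.frame(source = "A", target = "B", weight = 1.7))
  f3 <- validate_fcm(raw)
  expect_true(any(f3$severity == "error" & f3$code == "weight_range"))
})
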