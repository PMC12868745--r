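test_that("single-edge steady state matches the closed-form fixed point", {
  g <- chain_graph(0.8)
  for (sq in c("tanh", "logistic", "linear")) {
    f <- switch(sq, tanh = tanh,
                logistic = function(x) 2 / (1 + exp(-x)) - 1,
                linear = function(x) pmin(pmax(x, -1), 1))
    ss <- steady_state(g, c(A = 1), squashing = sq)
    expect_true(ss$converged)
    expect_equal(ss$activation[["B"]], f(0.8), tolerance = 1e-6)
  }
  expect_equal(steady_state(g, c(A = 1))$activation[["B"]], tanh(0.8),
               tolerance = 1e-6)
})

test_that("origin is a fixed point: no clamps or zero clamps give zeros", {
  g <- random_fcm(7, 0.3, seed = 5)
  expect_true(all(steady_state(g)$activation == 0))
  expect_true(all(steady_state(g, stats::setNames(0, g$concepts$id[1]))$activation == 0))
})

test_that("three-node chain composes squashings with the right sign", {
  g <- fcm_graph(c("A", "B", "C"),
                 data.frame(source = c("A", "B"), target = c("B", "C"),
                            weight = c(0.5, -0.5)))
  r <- run_scenario(g, scenario_spec("chain", c(A = 1)))
  dC <- r$table$delta[r$table$id == "C"]
  expect_equal(dC, tanh(-0.5 * tanh(0.5)), tolerance = 1e-6)
  expect_lt(dC, 0)
})

test_that("negating all clamps negates every delta (odd squashing)", {
  for (seed in 1:5) {
    g <- random_fcm(8, 0.25, seed = 300 + seed)
    ids <- g$concepts$id
    clamps <- stats::setNames(c(1, -0.5), ids[1:2])
    r1 <- run_scenario(g, scenario_spec("fwd", clamps))
    r2 <- run_scenario(g, scenario_spec("rev", -clamps))
    expect_equal(r2$table$delta, -r1$table$delta, tolerance = 1e-9)
  }
})

test_that("concepts unreachable from clamps have delta exactly zero", {
  # two disconnected chains; clamp the head of the first
  g <- fcm_graph(c("A", "B", "C", "X", "Y"),
                 data.frame(source = c("A", "B", "X"),
                            target = c("B", "C", "Y"),
                            weight = c(0.9, 0.8, 0.7)))
  r <- run_scenario(g, scenario_spec("local", c(A = 1)))
  tab <- r$table
  expect_identical(tab$delta[tab$id %in% c("X", "Y")], c(0, 0))
  expect_true(all(c("X", "Y") %in% r$pruned))
  expect_true(all(abs(tab$delta[tab$id %in% c("B", "C")]) > 0))
})

test_that("clamping a pure receiver propagates nothing", {
  g <- fcm_graph(c("A", "B", "C"),
                 data.frame(source = c("A", "B"), target = c("C", "C"),
                            weight = c(0.5, 0.5)))
  r <- run_scenario(g, scenario_spec("receiver", c(C = -1)))
  expect_setequal(r$pruned, c("A", "B"))
})

test_that("non-convergence is reported as a flag, not an error", {
  g <- chain_graph(c(0.8, 0.8, 0.8))
  r <- run_scenario(g, scenario_spec("tight", c(A = 1), max_iterations = 1L))
  expect_false(r$converged)
  expect_true(is.finite(max(abs(r$table$delta))))
})

test_that("scenario engine is deterministic and validates clamps", {
  g <- random_fcm(8, 0.3, seed = 17)
  sp <- scenario_spec("rep", stats::setNames(0.8, g$concepts$id[2]))
  r1 <- run_scenario(g, sp)
  r2 <- run_scenario(g, sp)
  expect_identical(r1$table, r2$table)

  expect_error(run_scenario(g, scenario_spec("bad", c(nope = 1))), "nope")
  expect_error(scenario_spec("bad", c(A = 2)), "\\[-1, 1\\]")
})

test_that("scenario specs load from JSON and results export as tables", {
  g <- chain_graph(c(0.5, 0.5))
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "from_file", clamps = list(A = -1),
                            squashing = "tanh", prune_epsilon = 1e-4),
                       p, auto_unbox = TRUE)
  sp <- read_scenario_spec(p)
  r <- run_scenario(g, sp)
  expect_equal(r$name, "from_file")
  expect_equal(r$table$delta[r$table$id == "B"], tanh(-0.5), tolerance = 1e-6)

  out <- withr::local_tempfile(fileext = ".csv")
  write_scenario_result(r, out)
  tab <- utils::read.csv(out)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$scenario[1], "from_file")
})

test_that("the three AMD mitigation scenarios behave as reported", {
  g <- amd_fixture()
  res <- amd_scenarios(g)
  expect_named(res, c("s1", "s2", "s3"))
  expect_true(all(vapply(res, function(r) r$converged, logical(1))))

  # suppressing acid pollution cannot reach the two drivers (indegree 0)
  expect_setequal(res$s1$pruned, c("peoples_awareness", "lime_expenditure"))

  # cumulative clamps: scenario 2 prunes no more than scenario 1
  expect_lte(length(res$s2$pruned), length(res$s1$pruned))
  expect_true(all(res$s2$table$clamped[res$s2$table$id %in%
                                         c("peoples_awareness", "lime_expenditure")]))

  # all seven clamped ordinaries carry their clamp in scenario 3
  ords <- c("poor_water_quality", "contaminated_fish", "abandoned_fishing",
            "abandoned_farming", "fish_catch_reduction", "crop_yield_reduction",
            "seeking_medical_care")
  t3 <- res$s3$table
  expect_true(all(abs(t3$delta[t3$id %in% ords]) > 0))
  expect_equal(nrow(t3), 36L)

  expect_error(amd_scenarios(chain_graph(0.5)), "lacks concepts")
})
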