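test_that("Likert ratings map onto the signed fuzzy scale", {
  expect_equal(likert_to_fuzzy(5, 1), 1.0)
  expect_equal(likert_to_fuzzy(5, -1), -1.0)
  expect_equal(likert_to_fuzzy(3, 1), 0.6)
  expect_equal(likert_to_fuzzy(c(1, 2, 4), c(-1, 1, -1)), c(-0.2, 0.4, -0.8))
  expect_error(likert_to_fuzzy(6, 1), "1..5")
  expect_error(likert_to_fuzzy(3, 0), "directions")
  # overridable mapping table
  expect_equal(likert_to_fuzzy(3, 1, mapping = c(0.1, 0.3, 0.5, 0.7, 0.9)), 0.5)
})

test_that("min-max rescaling normalises magnitudes and keeps signs", {
  w <- data.frame(source = c("a", "b", "c"), target = c("x", "y", "z"),
                  weight = c(0.2, 0.6, 1.0))
  expect_equal(rescale_map(w)$weight, c(0, 0.5, 1))

  w$weight <- c(0.8, 0.8, 0.8)   # degenerate constant map
  expect_equal(rescale_map(w)$weight, c(1, 1, 1))

  w2 <- data.frame(source = c("a", "b"), target = c("x", "y"),
                   weight = c(0.4, -0.8))
  expect_equal(rescale_map(w2)$weight, c(0, -1))

  # scale invariance: a positive rescaling of magnitudes changes nothing
  w3 <- data.frame(source = letters[1:4], target = LETTERS[1:4],
                   weight = c(0.2, -0.5, 0.9, 0.4))
  w3b <- w3; w3b$weight <- w3b$weight * 0.5
  expect_equal(rescale_map(w3)$weight, rescale_map(w3b)$weight)

  expect_error(rescale_map(w3[0, ]), "at least one claim")
})

test_that("presence retention uses the at-least-30%% ceiling rule", {
  # 18 respondents at 0.30 => k >= 6: a dyad claimed 5 times drops, 6 keeps
  truth <- grid_truth()
  maps <- verbatim_maps(truth, 18)
  extra <- data.frame(source = "health", target = "income",
                      magnitude = 5L, direction = 1L)
  for (i in 1:5) {
    m <- maps[[i]]
    maps[[i]] <- respondent_map(m$respondent_id, rbind(m$claims, extra))
  }
  cfg <- aggregation_config(rescale = FALSE)
  res <- aggregate_maps(maps, cfg)
  expect_equal(res$report$presence_count_min, 6L)
  d <- res$report$dropped
  expect_equal(d$reason[d$source == "health" & d$target == "income"], "presence")

  maps[[6]] <- respondent_map(maps[[6]]$respondent_id,
                              rbind(maps[[6]]$claims, extra))
  res6 <- aggregate_maps(maps, cfg)
  expect_true(any(res6$graph$links$source == "health" &
                    res6$graph$links$target == "income"))
})

test_that("aggregation is idempotent, order-invariant and range-safe", {
  truth <- grid_truth()
  cfg <- aggregation_config(rescale = FALSE)
  maps <- verbatim_maps(truth, 12)

  res <- aggregate_maps(maps, cfg)
  ord <- order(res$graph$links$source, res$graph$links$target)
  tord <- order(truth$links$source, truth$links$target)
  expect_equal(res$graph$links[ord, ], truth$links[tord, ], ignore_attr = TRUE)

  res_shuffled <- aggregate_maps(maps[sample(length(maps))], cfg)
  sord <- order(res_shuffled$graph$links$source, res_shuffled$graph$links$target)
  expect_equal(res_shuffled$graph$links[sord, ], res$graph$links[ord, ],
               ignore_attr = TRUE)

  # noisy bundle: consensus weights always inside [-1, 1]
  noisy <- simulate_respondents(truth, 18, seed = 7)
  resn <- aggregate_maps(noisy, aggregation_config())
  expect_true(all(abs(resn$graph$links$weight) <= 1))
  expect_true(all(abs(resn$graph$links$weight) >= 0.10))  # weight floor
})

test_that("raising retention thresholds never adds links", {
  truth <- grid_truth()
  maps <- simulate_respondents(truth, 18, presence_prob = 0.6, seed = 11)
  key <- function(g) paste(g$links$source, g$links$target)
  base <- key(aggregate_maps(maps, aggregation_config(0.30, 0.10, rescale = FALSE))$graph)
  for (pf in c(0.4, 0.6, 0.8)) {
    k <- key(aggregate_maps(maps, aggregation_config(pf, 0.10, rescale = FALSE))$graph)
    expect_true(all(k %in% base))
  }
  for (fl in c(0.3, 0.5, 0.7)) {
    k <- key(aggregate_maps(maps, aggregation_config(0.30, fl, rescale = FALSE))$graph)
    expect_true(all(k %in% base))
  }
})

test_that("single respondent with rescaling off aggregates to their own map", {
  truth <- grid_truth()
  one <- verbatim_maps(truth, 1)
  res <- aggregate_maps(one, aggregation_config(weight_floor = 0, rescale = FALSE))
  ord <- order(res$graph$links$source, res$graph$links$target)
  tord <- order(truth$links$source, truth$links$target)
  expect_equal(res$graph$links[ord, ], truth$links[tord, ], ignore_attr = TRUE)
})

test_that("outlying claims are flagged in the report but never dropped", {
  mk <- function(r, mag) respondent_map(r, data.frame(
    source = "a", target = "b", magnitude = mag, direction = 1L))
  maps <- list(mk("r1", 1L), mk("r2", 1L), mk("r3", 2L), mk("r4", 2L), mk("r5", 5L))
  res <- aggregate_maps(maps, aggregation_config(rescale = FALSE, weight_floor = 0))
  expect_equal(res$report$outliers$respondent, "r5")
  expect_equal(n_links(res$graph), 1L)  # flagged, not removed
  expect_equal(res$graph$links$weight, mean(c(0.2, 0.2, 0.4, 0.4, 1.0)))
})

test_that("claims files round-trip and drive the pipeline deterministically", {
  truth <- grid_truth()
  maps <- simulate_respondents(truth, 18, seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_claims(maps, p)
  maps2 <- read_claims(p)
  expect_equal(length(maps2), length(maps))
  expect_equal(maps2[[4]]$claims, maps[[4]]$claims, ignore_attr = TRUE)

  cfg <- aggregation_config(rescale = FALSE)
  g1 <- consensus_pipeline(p, cfg)$graph
  g2 <- consensus_pipeline(maps, cfg)$graph
  expect_equal(g1$links, g2$links, ignore_attr = TRUE)

  writeLines(c("respondent,source,target,magnitude,direction",
               "r1,a,b,5,1", "r1,b,c,,1"), p)
  expect_error(read_claims(p), "line 3")
})

test_that("aggregation report serialises to JSON with provenance", {
  truth <- grid_truth()
  res <- aggregate_maps(simulate_respondents(truth, 18, seed = 5),
                        aggregation_config())
  p <- withr::local_tempfile(fileext = ".json")
  write_aggregation_report(res$report, p)
  doc <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(doc$n_respondents, 18L)
  expect_equal(doc$config$presence_fraction, 0.30)
  expect_equal(res$graph$metadata$aggregation$presence_count_min, 6L)
})
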