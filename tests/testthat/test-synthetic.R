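test_that("the default circadian design yields 480 points at 3-minute spacing", {
  des <- sampling_design(3, 24)
  expect_identical(des$n_timepoints, 480L)
  expect_equal(des$time_hours[2] - des$time_hours[1], 0.05)
  expect_identical(sampling_design(30, 5)$n_timepoints, 10L)
  expect_error(sampling_design(7, 24), "divide")
  expect_error(sampling_design(-3, 24), "positive")
})

test_that("planted networks validate their edges", {
  expect_error(planted_network("A", tibble::tibble(regulator = "A",
                                                   target = "A",
                                                   coupling = 1)),
               "self-loops")
  expect_error(planted_network(c("A", "B"),
                               tibble::tibble(regulator = "A", target = "B",
                                              coupling = 2)),
               "0, 1")
  expect_error(planted_network(c("A", "B"),
                               tibble::tibble(regulator = "A", target = "C",
                                              coupling = 0.5)),
               "listed")
})

test_that("random planted cascades are acyclic and reproducible", {
  net <- random_planted_network(8, 10, seed = 4)
  net2 <- random_planted_network(8, 10, seed = 4)
  expect_identical(net$edges, net2$edges)
  g <- igraph::graph_from_data_frame(net$edges[1:2])
  expect_true(igraph::is_dag(g))
  cyc <- random_planted_network(5, 18, seed = 1, acyclic = FALSE)
  expect_identical(nrow(cyc$edges), 18L)
})

test_that("simulation is deterministic and emits a matching gold standard", {
  des <- sampling_design(3, 6)
  net <- random_planted_network(5, 4, seed = 3, mode = "circadian")
  a <- simulate_expression(net, des, seed = 11)
  b <- simulate_expression(net, des, seed = 11)
  expect_identical(a$expression, b$expression)
  expect_identical(ncol(a$expression) - 1L, des$n_timepoints)
  expect_true(all(as.matrix(a$expression[-1]) >= 0))

  gold_pos <- a$gold[a$gold$label == 1L, c("regulator", "target")]
  expect_setequal(paste(gold_pos$regulator, gold_pos$target),
                  paste(net$edges$regulator, net$edges$target))
  expect_identical(nrow(a$gold), pair_count(5))
})

test_that("uncoupled genes are pairwise independent at lag 1", {
  des <- sampling_design(3, 24)
  net <- planted_network(c("A", "B", "C"),
                         tibble::tibble(regulator = character(),
                                        target = character(),
                                        coupling = numeric()),
                         mode = "linear-lag")
  cors <- vapply(1:20, function(s) {
    sim <- simulate_expression(net, des, seed = s)
    m <- as.matrix(sim$expression[-1])
    nt <- ncol(m)
    max(abs(cor(m[1, -nt], m[2, -1])), abs(cor(m[2, -nt], m[3, -1])),
        abs(cor(m[1, -nt], m[3, -1])))
  }, numeric(1))
  # lag-1 cross-correlation stays at the sampling-noise floor ~ 1/sqrt(n)
  expect_lt(median(cors), 3 / sqrt(des$n_timepoints))
})

test_that("median TE increases with planted coupling strength", {
  des <- sampling_design(3, 24)
  med_te <- vapply(c(0.1, 0.4, 0.8), function(cp) {
    net <- planted_network(c("drv", "rsp"),
                           tibble::tibble(regulator = "drv", target = "rsp",
                                          coupling = cp),
                           mode = "linear-lag")
    median(vapply(1:15, function(s) {
      sim <- simulate_expression(net, des, seed = s)
      m <- as.matrix(sim$expression[-1])
      transfer_entropy(m[1, ], m[2, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_te) > 0))
})

test_that("strongly coupled edges out-rank non-edges in TE", {
  des <- sampling_design(3, 24)
  ratio_ok <- vapply(1:20, function(s) {
    net <- random_planted_network(6, 5, c(0.7, 1), seed = s,
                                  mode = "linear-lag")
    sim <- simulate_expression(net, des, seed = s + 500)
    te <- all_pairs_te(sim$expression, n_permutations = 0)
    scored <- dplyr::left_join(
      te,
      dplyr::rename(sim$gold, source = "regulator"),
      by = c("source", "target")
    )
    w <- stats::wilcox.test(scored$te[scored$label == 1],
                            scored$te[scored$label == 0],
                            alternative = "greater", exact = FALSE)
    median(scored$te[scored$label == 1]) >
      median(scored$te[scored$label == 0]) & w$p.value < 0.05
  }, logical(1))
  expect_gte(mean(ratio_ok), 0.8)
})

test_that("the rhythm reference is periodic, phase-correct, and seeded", {
  des <- sampling_design(3, 24)
  clean <- make_rhythm_reference(des, peak_phase_hours = 17, noise_sd = 0)
  expect_true(all(clean >= 0))
  expect_equal(des$time_hours[which.max(clean)], 17, tolerance = 0.05)
  a <- make_rhythm_reference(des, seed = 2)
  b <- make_rhythm_reference(des, seed = 2)
  expect_identical(a, b)

  # profiles 12 h apart are antiphase: negative cosine similarity of
  # the centered waveforms
  w1 <- make_rhythm_reference(des, peak_phase_hours = 5, noise_sd = 0)
  w2 <- make_rhythm_reference(des, peak_phase_hours = 17, noise_sd = 0)
  c1 <- w1 - mean(w1)
  c2 <- w2 - mean(w2)
  expect_lt(sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2)), 0)
})

test_that("delayed coupling weakens lag-1 estimation as a model mismatch", {
  des <- sampling_design(3, 24)
  edge <- tibble::tibble(regulator = "drv", target = "rsp", coupling = 0.9)
  te_at_lag <- function(lag) {
    net <- planted_network(c("drv", "rsp"), edge, mode = "linear-lag",
                           lag = lag)
    median(vapply(1:10, function(s) {
      sim <- simulate_expression(net, des, seed = s + 300)
      m <- as.matrix(sim$expression[-1])
      transfer_entropy(m[1, ], m[2, ])
    }, numeric(1)))
  }
  expect_gt(te_at_lag(1), te_at_lag(2))
  expect_error(planted_network(c("a", "b"),
                               tibble::tibble(regulator = "a", target = "b",
                                              coupling = 0.5), lag = 0),
               "lag")
})
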