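triangle_graph <- function(d_ac = 2.2) {
  measurement_graph(
    data.frame(id = c("A", "B", "C"),
               tier = c("anchor", "backbone", "backbone"),
               fixed_pka = c(0, NA, NA)),
    data.frame(acid_1 = c("A", "B", "A"), acid_2 = c("B", "C", "C"),
               delta_pka = c(1, 1, d_ac)))
}

test_that("a single anchored edge is reproduced exactly", {
  g <- measurement_graph(
    data.frame(id = c("A", "B"), tier = c("anchor", "backbone"),
               fixed_pka = c(10, NA)),
    data.frame(acid_1 = "A", acid_2 = "B", delta_pka = 1.5))
  sol <- solve_ladder(g)
  expect_equal(unname(sol$assigned["B"]), 11.5)
  expect_equal(sol$ssd, 0)
})

test_that("the inconsistent triangle matches the brute-force minimizer", {
  sol <- solve_ladder(triangle_graph())
  # frozen values computed independently by numeric minimization of the
  # SSD objective (closed form: B = 16/15, C = 32/15, SSD = 0.04/3)
  expect_equal(unname(sol$assigned["B"]), 16 / 15, tolerance = 1e-9)
  expect_equal(unname(sol$assigned["C"]), 32 / 15, tolerance = 1e-9)
  expect_equal(sol$ssd, 0.0133333333, tolerance = 1e-7)
  expect_equal(consistency_sd(sol), 0.115470054, tolerance = 1e-7)
  nm <- nm_solve_ladder(triangle_graph(), c(A = 0))
  expect_equal(unname(nm[c("B", "C")]), unname(sol$assigned[c("B", "C")]),
               tolerance = 1e-7)
})

test_that("consistent edges are recovered exactly with zero SSD", {
  sol <- solve_ladder(triangle_graph(d_ac = 2))
  expect_equal(unname(sol$assigned[c("B", "C")]), c(1, 2), tolerance = 1e-12)
  expect_equal(sol$ssd, 0, tolerance = 1e-20)
  expect_equal(consistency_sd(sol), 0)
})

test_that("consistency sd is undefined when n_m <= n_c", {
  g <- measurement_graph(
    data.frame(id = c("A", "B", "C"), tier = c("anchor", "backbone",
                                               "backbone"),
               fixed_pka = c(0, NA, NA)),
    data.frame(acid_1 = c("A", "B"), acid_2 = c("B", "C"),
               delta_pka = c(1, 1)))
  sol <- solve_ladder(g)
  expect_true(is.na(sol$s))
  expect_error(consistency_sd(sol), "n_m <= n_c")
})

test_that("edge reversal leaves the solution unchanged", {
  g1 <- triangle_graph()
  g2 <- measurement_graph(
    g1$nodes,
    data.frame(acid_1 = c("B", "C", "A"), acid_2 = c("A", "B", "C"),
               delta_pka = c(-1, -1, 2.2)))
  expect_equal(solve_ladder(g1)$assigned, solve_ladder(g2)$assigned,
               tolerance = 1e-12)
  expect_equal(solve_ladder(g1)$ssd, solve_ladder(g2)$ssd,
               tolerance = 1e-12)
})

test_that("shifting anchors shifts every pKa by the same constant (gauge)", {
  for (seed in c(4, 9, 23)) {
    rg <- random_anchored_graph(seed)
    s0 <- solve_ladder(rg$graph)
    shift <- 3.7
    g2 <- rg$graph
    g2$nodes$fixed_pka <- g2$nodes$fixed_pka + shift
    s1 <- solve_ladder(g2)
    expect_equal(s1$assigned, s0$assigned + shift, tolerance = 1e-9)
    expect_equal(s1$ssd, s0$ssd, tolerance = 1e-9)
  }
})

test_that("edge exclusion removes measurements but keeps their record", {
  g <- triangle_graph()
  g2 <- exclude_edges(g, data.frame(acid_1 = "A", acid_2 = "C",
                                    reason = "delta too large"))
  expect_false(g2$edges$included[3])
  expect_equal(g2$edges$reason[3], "delta too large")
  sol <- solve_ladder(g2)
  expect_equal(unname(sol$assigned[c("B", "C")]), c(1, 2), tolerance = 1e-12)
  # identity on an empty exclusion list; error on unknown edges
  expect_equal(exclude_edges(g, data.frame()), g)
  expect_error(exclude_edges(g, data.frame(acid_1 = "A", acid_2 = "Z")),
               "no measurement")
})

test_that("graph validation reports partners, big deltas and anchor gaps", {
  g <- measurement_graph(
    data.frame(id = c("A", "B", "C", "D", "E"),
               tier = c("anchor", "backbone", "backbone", "backbone",
                        "backbone"),
               fixed_pka = c(0, NA, NA, NA, NA)),
    data.frame(acid_1 = c("A", "B", "D"), acid_2 = c("B", "C", "E"),
               delta_pka = c(1, 1.8, 0.3)))
  d <- validate_graph(g)
  expect_true(any(d$level == "warning" & grepl("only", d$message)))
  expect_true(any(d$level == "flag" & grepl("1.80", d$message)))
  # D-E component has no anchor
  expect_true(any(d$level == "error" & grepl("D, E", d$subject)))
  expect_error(solve_ladder(g), "unsolvable component.*D, E")
})

test_that("tiered solving reduces to plain solving for one tier", {
  rg <- random_anchored_graph(31)
  expect_equal(tiered_solve(rg$graph)$assigned,
               solve_ladder(rg$graph)$assigned, tolerance = 1e-12)
})

test_that("tiered solving recovers a consistent 3-tier network exactly", {
  net <- gen_network(network_plan(n_acids = 15, noise_sd = 0, seed = 5))
  expect_setequal(unique(net$graph$nodes$tier),
                  c("anchor", "backbone", "secondary", "tertiary"))
  sol <- tiered_solve(net$graph)
  expect_lt(max(abs(sol$assigned[names(net$true_pka)] - net$true_pka)),
            1e-10)
  expect_equal(sol$ssd, 0, tolerance = 1e-18)
  expect_equal(length(sol$steps), 3L)
})

test_that("per-step consistency tracks the injected noise level", {
  svals <- matrix(NA_real_, 30, 3)
  for (i in 1:30) {
    net <- gen_network(network_plan(n_acids = 30, n_edges = 120,
                                    noise_sd = 0.03, seed = 400 + i))
    sol <- tiered_solve(net$graph)
    svals[i, ] <- vapply(sol$steps, `[[`, numeric(1), "s")
  }
  means <- colMeans(svals)
  expect_true(all(means > 0.02 & means < 0.04))
})

test_that("duplicate measurements between one pair each count toward n_m", {
  g <- measurement_graph(
    data.frame(id = c("A", "B"), tier = c("anchor", "backbone"),
               fixed_pka = c(0, NA)),
    data.frame(acid_1 = c("A", "A"), acid_2 = c("B", "B"),
               delta_pka = c(1.0, 1.2)))
  sol <- solve_ladder(g)
  expect_equal(sol$n_m, 2L)
  expect_equal(unname(sol$assigned["B"]), 1.1)
  expect_equal(sol$ssd, 2 * 0.1^2, tolerance = 1e-12)
})
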