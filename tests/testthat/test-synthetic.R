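test_that("generated spectra are sums of Gaussian bands scaled by concentration", {
  sp <- acid_spec("x", 30,
                  neutral_bands = data.frame(center = 350, width = 20,
                                             height = 100),
                  anion_bands = data.frame(center = c(320, 380),
                                           width = c(10, 15),
                                           height = c(50, 70)),
                  concentration = 2)
  grid <- 300:400
  s0 <- gen_spectrum(acid_spec("z", 30, data.frame(center = numeric(),
                                                   width = numeric(),
                                                   height = numeric()),
                               data.frame(center = 1, width = 1,
                                          height = 1), 1),
                     "neutral", grid)
  expect_true(all(s0$absorbance == 0))
  sn <- gen_spectrum(sp, "neutral", grid)
  expect_equal(sn$absorbance[grid == 350], 100 * 2)
  # two overlapping bands add pointwise
  sa <- gen_spectrum(sp, "anion", grid, concentration = 1)
  b1 <- 50 * exp(-0.5 * ((grid - 320) / 10)^2)
  b2 <- 70 * exp(-0.5 * ((grid - 380) / 15)^2)
  expect_equal(sa$absorbance, b1 + b2, tolerance = 1e-12)
})

test_that("simulated speciation conserves base and satisfies mass action", {
  ac <- demo_acids()
  plan <- titration_plan(ac$a, ac$b,
                         base_additions = seq(0, 1, 0.05) * 1.8e-4,
                         noise_sd = 0, seed = 4)
  sim <- gen_titration(plan)
  sp <- sim$speciation
  cons <- 1e-4 * sp$alpha_ha + 8e-5 * sp$alpha_hb - sp$D
  expect_lt(max(abs(cons)), 1e-10)
  K <- 10^0.75
  inner <- sp$alpha_ha > 0 & sp$alpha_ha < 1
  resid <- sp$alpha_ha[inner] * (1 - sp$alpha_hb[inner]) -
    K * (1 - sp$alpha_ha[inner]) * sp$alpha_hb[inner]
  expect_lt(max(abs(resid)), 1e-10)
  # no base, no dissociation
  expect_equal(unname(unlist(sp[sp$D == 0, c("alpha_ha", "alpha_hb")])),
               c(0, 0))
})

test_that("equal acids dissociate identically (symmetric titration)", {
  a <- acid_spec("p", 30, data.frame(center = 320, width = 20, height = 10),
                 data.frame(center = 380, width = 20, height = 12), 1e-4)
  b <- acid_spec("q", 30, data.frame(center = 340, width = 15, height = 9),
                 data.frame(center = 420, width = 25, height = 11), 1e-4)
  plan <- titration_plan(a, b, base_additions = c(0.5, 1, 1.5) * 1e-4,
                         noise_sd = 0, seed = 1)
  sp <- gen_titration(plan)$speciation
  expect_equal(sp$alpha_ha, sp$alpha_hb, tolerance = 1e-12)
  expect_equal(sp$alpha_ha, sp$D / 2e-4, tolerance = 1e-10)
})

test_that("over-titration beyond the total acid is refused", {
  ac <- demo_acids()
  expect_error(titration_plan(ac$a, ac$b, base_additions = 2e-4),
               "total acid")
})

test_that("a fixed seed reproduces simulations bit for bit", {
  ac <- demo_acids()
  plan <- titration_plan(ac$a, ac$b, seq(0.1, 0.9, 0.2) * 1.8e-4,
                         noise_sd = 0.01, seed = 99)
  s1 <- gen_titration(plan)
  s2 <- gen_titration(plan)
  expect_identical(s1$mixtures, s2$mixtures)
  n1 <- gen_network(network_plan(n_acids = 12, seed = 7))
  n2 <- gen_network(network_plan(n_acids = 12, seed = 7))
  expect_identical(n1, n2)
  n3 <- gen_network(network_plan(n_acids = 12, seed = 8))
  expect_false(identical(n1$graph$edges, n3$graph$edges))
})

test_that("generated networks are solvable and truthful at zero noise", {
  for (seed in c(2, 17)) {
    net <- gen_network(network_plan(n_acids = 18, noise_sd = 0,
                                    seed = seed))
    diag <- validate_graph(net$graph)
    expect_false(any(diag$level == "error"))
    sol <- tiered_solve(net$graph)
    expect_lt(max(abs(sol$assigned[names(net$true_pka)] - net$true_pka)),
              1e-9)
  }
  # single anchored acid is trivially solved
  net1 <- gen_network(network_plan(n_acids = 1, noise_sd = 0, seed = 1,
                                   tiers = c(anchor = 1, backbone = 0,
                                             secondary = 0, tertiary = 0)))
  expect_equal(nrow(net1$graph$nodes), 1L)
  expect_equal(net1$graph$nodes$fixed_pka, unname(net1$true_pka))
})

test_that("packaged fixtures have the expected shape and content", {
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  t4 <- load_fixture("table4")
  expect_equal(nrow(t2), 40L)
  expect_equal(nrow(t3), 15L)
  expect_equal(nrow(t4), 5L)
  expect_equal(t2$pka_mecn[t2$name == "Indole"], 32.78)
  expect_equal(t4$name[1], "Pyrrole")
  expect_equal(t4$name[5], "1H-1,2,3-Triazole")
  # every benchmark compound resolves in the main table
  expect_true(all(t3$name %in% t2$name))
  expect_error(load_fixture("table9"))
})

test_that("fixture files match their locked checksums", {
  sums <- tools::md5sum(vapply(
    c("table2_acidities.csv", "table3_conversion_benchmark.csv",
      "table4_recommended.csv"),
    function(f) system.file("extdata", f, package = "acidladder",
                            mustWork = TRUE), character(1)))
  expect_equal(unname(sums),
               c("566ac4e17a6d7083dbb7b87318cf67ef",
                 "88dbc62b7ecbc5fd588c5a73a5d88d99",
                 "e3c06ec595007c5c96786e57ef9f8374"))
})
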