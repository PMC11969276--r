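# shared fixtures built in code

# two spectrally well-separated synthetic acids, pKa difference 0.75
demo_acids <- function(pka_a = 30, pka_b = 30.75) {
  list(
    a = acid_spec("HA", pka_a,
                  neutral_bands = data.frame(center = 320, width = 22,
                                             height = 9000),
                  anion_bands = data.frame(center = 370, width = 26,
                                           height = 12000),
                  concentration = 1e-4),
    b = acid_spec("HB", pka_b,
                  neutral_bands = data.frame(center = 300, width = 18,
                                             height = 8000),
                  anion_bands = data.frame(center = 420, width = 30,
                                           height = 11000),
                  concentration = 8e-5))
}

demo_basis <- function(grid = seq(220, 500, by = 1)) {
  ac <- demo_acids()
  species_basis(gen_spectrum(ac$a, "neutral", grid, concentration = 1),
                gen_spectrum(ac$a, "anion", grid, concentration = 1),
                gen_spectrum(ac$b, "neutral", grid, concentration = 1),
                gen_spectrum(ac$b, "anion", grid, concentration = 1))
}

# SSD objective of a measurement graph, written directly from the edge
# list -- independent of solve_ladder's linear algebra
ladder_ssd <- function(graph, values) {
  ed <- graph$edges[graph$edges$included, , drop = FALSE]
  sum((ed$delta_pka - (values[ed$acid_2] - values[ed$acid_1]))^2)
}

# derivative-free oracle: Nelder-Mead with restarts on the raw SSD
nm_solve_ladder <- function(graph, frozen) {
  free <- sort(setdiff(graph$nodes$id, names(frozen)))
  obj <- function(p) {
    names(p) <- free
    ladder_ssd(graph, c(frozen, p))
  }
  p <- rep(mean(frozen), length(free))
  if (length(free) == 1L) {
    opt <- stats::optimize(function(v) obj(v), mean(frozen) + c(-30, 30),
                           tol = 1e-12)
    p <- opt$minimum
  } else {
    for (k in 1:60) {
      o <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15))
      if (max(abs(o$par - p)) < 1e-10) { p <- o$par; break }
      p <- o$par
    }
  }
  names(p) <- free
  c(frozen, p)[sort(c(names(frozen), free))]
}

# random connected anchored single-tier graph with <= n_max nodes
random_anchored_graph <- function(seed, n_max = 8, n_edges_max = 16,
                                  noise_sd = 0.05) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  ids <- sprintf("n%02d", seq_len(n))
  true <- stats::runif(n, 10, 14)
  names(true) <- ids
  # spanning chain plus random extras
  e1 <- ids[seq_len(n - 1)]
  e2 <- ids[seq_len(n - 1) + 1]
  extra <- max(0, sample(0:n_edges_max, 1) - (n - 1))
  for (k in seq_len(extra)) {
    i <- sample.int(n, 1)
    rest <- setdiff(seq_len(n), i)
    j <- rest[sample.int(length(rest), 1)]
    e1 <- c(e1, ids[i]); e2 <- c(e2, ids[j])
  }
  delta <- true[e2] - true[e1] + stats::rnorm(length(e1), 0, noise_sd)
  g <- measurement_graph(
    data.frame(id = ids, tier = c("anchor", rep("backbone", n - 1)),
               fixed_pka = c(true[1], rep(NA_real_, n - 1))),
    data.frame(acid_1 = e1, acid_2 = e2, delta_pka = as.numeric(delta)))
  list(graph = g, true_pka = true)
}
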